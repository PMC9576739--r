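# Internal polygon helpers shared by the segmentation and colocalization
# stages. Polygons follow the polyclip convention: a "poly" is a list of
# contours, each a list(x =, y =) of vertices; holes carry opposite
# orientation under the nonzero fill rule. All coordinates are nm.

#' @importFrom sp point.in.polygon
NULL

# Signed area of one contour (shoelace); positive = counter-clockwise.
contour_signed_area <- function(cc) {
  n <- length(cc$x)
  if (n < 3) return(0)
  j <- c(2:n, 1L)
  0.5 * sum(cc$x * cc$y[j] - cc$x[j] * cc$y)
}

# Net area of a multipolygon with holes. Contours are assumed consistently
# oriented (outers CCW, holes CW), as polyclip returns them; the signed sum
# then subtracts holes. abs() guards a globally reversed input.
poly_area <- function(poly) {
  if (length(poly) == 0) return(0)
  abs(sum(vapply(poly, contour_signed_area, numeric(1))))
}

# Force every contour counter-clockwise. Required before feeding hand-built
# contour collections to polyclip under the nonzero fill rule.
poly_ccw <- function(poly) {
  lapply(poly, function(cc) {
    if (contour_signed_area(cc) < 0) list(x = rev(cc$x), y = rev(cc$y)) else cc
  })
}

poly_bbox <- function(poly) {
  xs <- unlist(lapply(poly, `[[`, "x"), use.names = FALSE)
  ys <- unlist(lapply(poly, `[[`, "y"), use.names = FALSE)
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

bbox_overlaps <- function(a, b) {
  a["xmin"] <= b["xmax"] && b["xmin"] <= a["xmax"] &&
    a["ymin"] <= b["ymax"] && b["ymin"] <= a["ymax"]
}

# Union of a collection of contours (nonzero fill). polyclip returns an
# empty result when one operand is empty, so self-union uses A as both
# operands.
poly_union <- function(a, b = NULL) {
  if (is.null(b) || length(b) == 0) {
    if (length(a) == 0) return(list())
    if (length(a) == 1) return(poly_ccw(a))
    a <- poly_ccw(a)
    return(polyclip::polyclip(a, a, op = "union",
                              fillA = "nonzero", fillB = "nonzero"))
  }
  if (length(a) == 0) return(poly_union(b))
  polyclip::polyclip(poly_ccw(a), poly_ccw(b), op = "union",
                     fillA = "nonzero", fillB = "nonzero")
}

poly_intersect <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(list())
  polyclip::polyclip(poly_ccw(a), poly_ccw(b), op = "intersection",
                     fillA = "nonzero", fillB = "nonzero")
}

poly_minus <- function(a, b) {
  if (length(a) == 0) return(list())
  if (length(b) == 0) return(poly_ccw(a))
  polyclip::polyclip(poly_ccw(a), poly_ccw(b), op = "minus",
                     fillA = "nonzero", fillB = "nonzero")
}

# Even-odd point-in-multipolygon membership. Points on any contour boundary
# count as inside. Orientation-agnostic, so holes are handled correctly for
# polyclip output (a point in a hole lies inside two contours -> even ->
# outside).
points_in_poly <- function(x, y, poly) {
  if (length(poly) == 0 || length(x) == 0) return(logical(length(x)))
  crossings <- integer(length(x))
  boundary <- logical(length(x))
  for (cc in poly) {
    r <- sp::point.in.polygon(x, y, cc$x, cc$y)
    crossings <- crossings + (r == 1L)
    boundary <- boundary | (r >= 2L)
  }
  (crossings %% 2L == 1L) | boundary
}

# Regular-polygon approximation of a disk, for tests and synthetic truth.
disk_poly <- function(cx, cy, r, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(list(x = cx + r * cos(th), y = cy + r * sin(th)))
}
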