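# Vector-geometry primitives underlying both the 2D and 3D counterpart
# analyses: oriented lines and planes, the three plane-construction rules
# used on CBCT landmarks, and point-to-plane / point-to-line measurement.
# All coordinates are millimetres.

.geom <- new.env(parent = emptyenv())
.geom$point_tol <- 1e-9  # mm: below this, points/offsets count as coincident
.geom$angle_tol <- 1e-6  # rad: below this, directions count as parallel

#' Get or set the global geometry tolerances
#'
#' All degeneracy checks in the package (coincident points, parallel lines,
#' collinear plane-defining triplets, underdetermined plane constructions)
#' share two tolerances: a point tolerance in millimetres and an angle
#' tolerance in radians.
#'
#' @param point New point tolerance in mm, or `NULL` to leave unchanged.
#' @param angle New angle tolerance in radians, or `NULL` to leave unchanged.
#' @return Invisibly (when setting) or visibly (when called with no
#'   arguments), a list with elements `point` and `angle`.
#' @examples
#' geometry_tolerance()
#' old <- geometry_tolerance(point = 1e-8)
#' geometry_tolerance(point = old$point)
#' @export
geometry_tolerance <- function(point = NULL, angle = NULL) {
  old <- list(point = .geom$point_tol, angle = .geom$angle_tol)
  if (is.null(point) && is.null(angle)) return(old)
  if (!is.null(point)) {
    stopifnot(is.numeric(point), length(point) == 1L, is.finite(point), point > 0)
    .geom$point_tol <- point
  }
  if (!is.null(angle)) {
    stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle), angle > 0)
    .geom$angle_tol <- angle
  }
  invisible(old)
}

stop_degenerate <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("counterpart3d_degenerate_geometry", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_validation <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("counterpart3d_validation_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

.check_point <- function(p, d, what = "point") {
  if (!is.numeric(p) || length(p) != d || !all(is.finite(p)))
    stop_validation(sprintf("%s must be a finite numeric vector of length %d", what, d))
  unname(p)
}

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v, what = "direction") {
  n <- .vnorm(v)
  if (n <= .geom$point_tol)
    stop_degenerate(sprintf("%s has (near-)zero length", what))
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Construct a 2D line through two points
#'
#' The line is stored in anchor + unit-direction form (oriented from `p`
#' to `q`), so vertical lines need no special casing.
#'
#' @param p,q Numeric length-2 points (mm); must be distinct.
#' @param what Optional character vector of two landmark names, used in the
#'   error message when the points coincide.
#' @return An object of class `"line2"` with fields `anchor` and `direction`.
#' @examples
#' line_through(c(0, 0), c(3, 4))$direction  # (0.6, 0.8)
#' @export
line_through <- function(p, q, what = c("p", "q")) {
  p <- .check_point(p, 2L, what[1L]); q <- .check_point(q, 2L, what[2L])
  d <- q - p
  if (.vnorm(d) <= .geom$point_tol)
    stop_degenerate(sprintf("cannot construct a line: points '%s' and '%s' coincide",
                            what[1L], what[2L]))
  structure(list(anchor = p, direction = d / .vnorm(d)), class = "line2")
}

#' Construct the line through a point parallel to a reference line
#'
#' @param p Numeric length-2 point (mm).
#' @param ref A `"line2"` object giving the direction.
#' @return A `"line2"` anchored at `p` with `ref`'s direction.
#' @export
line_parallel_through <- function(p, ref) {
  p <- .check_point(p, 2L)
  stopifnot(inherits(ref, "line2"))
  structure(list(anchor = p, direction = ref$direction), class = "line2")
}

#' Intersect two 2D lines
#'
#' @param a,b `"line2"` objects; must not be parallel.
#' @param what Optional character vector of two construction names for error
#'   reporting.
#' @return The numeric length-2 intersection point.
#' @export
intersect_lines <- function(a, b, what = c("a", "b")) {
  stopifnot(inherits(a, "line2"), inherits(b, "line2"))
  da <- a$direction; db <- b$direction
  crs <- da[1L] * db[2L] - da[2L] * db[1L]
  if (abs(crs) <= .geom$angle_tol)
    stop_degenerate(sprintf("lines '%s' and '%s' are parallel or coincident",
                            what[1L], what[2L]))
  # solve a$anchor + t*da = b$anchor + s*db for t
  rhs <- b$anchor - a$anchor
  t <- (rhs[1L] * db[2L] - rhs[2L] * db[1L]) / crs
  unname(a$anchor + t * da)
}

#' Orthogonally project a 2D point onto a line
#'
#' @param p Numeric length-2 point (mm).
#' @param l A `"line2"` object.
#' @return The foot of the perpendicular from `p` to `l`.
#' @export
project_point_onto_line <- function(p, l) {
  p <- .check_point(p, 2L)
  stopifnot(inherits(l, "line2"))
  t <- sum((p - l$anchor) * l$direction)
  unname(l$anchor + t * l$direction)
}

.new_plane3 <- function(anchor, normal, provenance) {
  structure(list(anchor = unname(anchor), normal = unname(normal),
                 provenance = provenance),
            class = "plane3")
}

#' Plane through three points
#'
#' The normal follows the right-hand rule over `(p2 - p1) x (p3 - p1)`, so
#' signed distances against three-point planes are reproducible.
#'
#' @param p1,p2,p3 Numeric length-3 points (mm); must not be collinear.
#' @param what Optional character vector of three landmark names for error
#'   reporting.
#' @return An object of class `"plane3"` with fields `anchor` (= `p1`),
#'   unit `normal`, and `provenance = "three_points"`.
#' @export
plane_from_three_points <- function(p1, p2, p3, what = c("p1", "p2", "p3")) {
  p1 <- .check_point(p1, 3L, what[1L])
  p2 <- .check_point(p2, 3L, what[2L])
  p3 <- .check_point(p3, 3L, what[3L])
  n <- .cross3(p2 - p1, p3 - p1)
  if (.vnorm(n) <= 2 * .geom$point_tol)  # |n| = 2 * triangle area
    stop_degenerate(sprintf(
      "points '%s', '%s', '%s' are collinear or coincident; no unique plane",
      what[1L], what[2L], what[3L]))
  .new_plane3(p1, n / .vnorm(n), "three_points")
}

#' Plane through two points, normal (perpendicular) to a reference plane
#'
#' Used for the lingual-tuberosity and anterior-clinoid planes of the 3D
#' analysis: the plane contains both points and is perpendicular to the
#' reference (axial) plane. The construction is underdetermined when the
#' segment between the points is parallel to the reference normal.
#'
#' @param p1,p2 Numeric length-3 points (mm); must be distinct.
#' @param ref A `"plane3"` the result must be perpendicular to.
#' @param what Optional character vector of two landmark names for error
#'   reporting.
#' @return A `"plane3"` containing `p1` and `p2`, with
#'   `normal %.% ref$normal == 0` and `provenance = "two_points_normal"`.
#' @export
plane_from_two_points_normal <- function(p1, p2, ref, what = c("p1", "p2")) {
  p1 <- .check_point(p1, 3L, what[1L])
  p2 <- .check_point(p2, 3L, what[2L])
  stopifnot(inherits(ref, "plane3"))
  d <- p2 - p1
  if (.vnorm(d) <= .geom$point_tol)
    stop_degenerate(sprintf("points '%s' and '%s' coincide; plane underdetermined",
                            what[1L], what[2L]))
  d <- d / .vnorm(d)
  n <- .cross3(ref$normal, d)
  # |cross| = sin(angle between segment and ref normal)
  if (.vnorm(n) <= .geom$angle_tol)
    stop_degenerate(sprintf(
      "segment '%s'-'%s' is parallel to the reference-plane normal; plane underdetermined",
      what[1L], what[2L]))
  .new_plane3(p1, n / .vnorm(n), "two_points_normal")
}

#' Plane through one point, parallel to a reference plane
#'
#' Used for the PNS plane of the 3D analysis (through the posterior nasal
#' spine, parallel to the coronal plane).
#'
#' @param p Numeric length-3 point (mm).
#' @param ref A `"plane3"` giving the orientation.
#' @return A `"plane3"` anchored at `p` with `ref`'s normal and
#'   `provenance = "point_parallel"`.
#' @export
plane_parallel_through_point <- function(p, ref) {
  p <- .check_point(p, 3L)
  stopifnot(inherits(ref, "plane3"))
  .new_plane3(p, ref$normal, "point_parallel")
}

#' Distance from a point to a plane
#'
#' The workhorse of the 3D analysis: every 3D part length is a
#' point-to-plane distance. Unsigned by default; the signed variant uses
#' the plane's stored normal orientation and is useful for diagnosing
#' anterior/posterior placement errors.
#'
#' @param p Numeric length-3 point (mm).
#' @param plane A `"plane3"` object.
#' @param signed If `TRUE`, return the signed distance `n . (p - anchor)`.
#' @return Distance in mm (non-negative unless `signed = TRUE`).
#' @export
point_plane_distance <- function(p, plane, signed = FALSE) {
  p <- .check_point(p, 3L)
  stopifnot(inherits(plane, "plane3"))
  d <- sum(plane$normal * (p - plane$anchor))
  if (signed) d else abs(d)
}

#' @export
print.line2 <- function(x, ...) {
  cat(sprintf("<line2> anchor (%.6g, %.6g), direction (%.6g, %.6g)\n",
              x$anchor[1L], x$anchor[2L], x$direction[1L], x$direction[2L]))
  invisible(x)
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3 %s> anchor (%.6g, %.6g, %.6g), normal (%.6g, %.6g, %.6g)\n",
              x$provenance, x$anchor[1L], x$anchor[2L], x$anchor[3L],
              x$normal[1L], x$normal[2L], x$normal[3L]))
  invisible(x)
}
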