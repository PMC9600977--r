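# 3D horizontal counterpart analysis on CBCT landmarks.
#
# The scan is first oriented into a canonical anatomical frame (x left ->
# right, y posterior -> anterior, z inferior -> superior) from three
# user-picked point triplets, one per view, on the most external slice of
# the volume. Three measurement planes are then constructed:
#   PNS plane      through the posterior nasal spine, parallel to the
#                  coronal plane
#   LT plane       through the two lingual tuberosities, normal to the
#                  axial plane (separates mandibular corpus from ramus)
#   clinoid plane  through the two anterior clinoid processes, normal to
#                  the axial plane (separates anterior from middle cranial
#                  floor)
# Every part length is an (unsigned) point-to-plane distance.

#' Build an orientation frame from three picked point triplets
#'
#' Each triplet defines one of the axial, coronal and sagittal reference
#' planes. The returned rigid transform maps scanner coordinates into the
#' canonical frame (x left to right, y posterior to anterior, z inferior to
#' superior) in which the axial plane is z-constant, the coronal plane
#' y-constant and the sagittal plane x-constant.
#'
#' When the picked planes are not exactly mutually orthogonal, the axial
#' normal is honoured exactly (it anchors both "normal to the axial plane"
#' constructions), the coronal normal is orthogonalized against it, and the
#' third axis completes a right-handed basis. Triplet point order fixes the
#' normal sign by the right-hand rule, so supply each triplet so that its
#' normal points along the positive canonical axis (axial: superior;
#' coronal: anterior; sagittal: patient-left to patient-right).
#'
#' @param axial_pts,coronal_pts,sagittal_pts 3 x 3 numeric matrices, one
#'   picked point per row; each triplet must be non-collinear.
#' @return An object of class `"orientation_frame"`: fields `rotation`
#'   (3 x 3, determinant +1), `translation` (length 3, mm), and the three
#'   canonical planes `axial`, `coronal`, `sagittal` expressed in target
#'   coordinates. A point `p` maps to `rotation %*% p + translation`.
#' @export
build_orientation_frame <- function(axial_pts, coronal_pts, sagittal_pts) {
  as_triplet <- function(m, what) {
    m <- as.matrix(m)
    if (!is.numeric(m) || !all(dim(m) == c(3L, 3L)) || !all(is.finite(m)))
      stop_validation(paste0(what, " triplet must be a finite 3 x 3 matrix (one point per row)"))
    m
  }
  ax <- as_triplet(axial_pts, "axial")
  co <- as_triplet(coronal_pts, "coronal")
  sg <- as_triplet(sagittal_pts, "sagittal")

  p_ax <- plane_from_three_points(ax[1L, ], ax[2L, ], ax[3L, ],
                                  what = paste0("axial point ", 1:3))
  p_co <- plane_from_three_points(co[1L, ], co[2L, ], co[3L, ],
                                  what = paste0("coronal point ", 1:3))
  p_sg <- plane_from_three_points(sg[1L, ], sg[2L, ], sg[3L, ],
                                  what = paste0("sagittal point ", 1:3))

  ez <- p_ax$normal
  cosang <- abs(sum(ez * p_co$normal))
  if (cosang > cos(10 * pi / 180))
    stop_degenerate(sprintf(
      "axial and coronal plane normals are within 10 degrees of parallel (angle %.2f deg); orientation setup is not orthogonal",
      acos(pmin(1, cosang)) * 180 / pi))
  ey <- p_co$normal - sum(p_co$normal * ez) * ez
  ey <- ey / .vnorm(ey)
  ex <- .cross3(ey, ez)  # right-handed: ex = ey x ez

  R <- rbind(ex, ey, ez)
  dimnames(R) <- NULL
  # origin of the target frame: common point of the three (orthogonalized)
  # planes, each pinned at its own picked anchor
  origin <- solve(R, c(sum(ex * p_sg$anchor),
                       sum(ey * p_co$anchor),
                       sum(ez * p_ax$anchor)))
  tr <- as.numeric(-R %*% origin)

  canon <- function(anchor, normal, prov)
    .new_plane3(as.numeric(R %*% anchor + tr), normal, prov)
  structure(list(rotation = R, translation = tr,
                 axial = canon(p_ax$anchor, c(0, 0, 1), "three_points"),
                 coronal = canon(p_co$anchor, c(0, 1, 0), "three_points"),
                 sagittal = canon(p_sg$anchor, c(1, 0, 0), "three_points")),
            class = "orientation_frame")
}

#' The identity orientation frame
#'
#' For landmark sets already expressed in the canonical anatomical frame
#' (e.g. synthetic skulls, or scans oriented upstream).
#'
#' @return An `"orientation_frame"` with identity rotation, zero
#'   translation, and the canonical planes z = 0 (axial), y = 0 (coronal),
#'   x = 0 (sagittal).
#' @export
canonical_frame <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0),
                 axial = .new_plane3(c(0, 0, 0), c(0, 0, 1), "three_points"),
                 coronal = .new_plane3(c(0, 0, 0), c(0, 1, 0), "three_points"),
                 sagittal = .new_plane3(c(0, 0, 0), c(1, 0, 0), "three_points")),
            class = "orientation_frame")
}

#' Apply an orientation frame to a 3D landmark set
#'
#' Rigidly transforms every landmark into the canonical frame; all pairwise
#' distances are preserved.
#'
#' @param lm A `"landmarks3d"` set in scanner coordinates.
#' @param frame An `"orientation_frame"`.
#' @return The transformed `"landmarks3d"` set.
#' @export
apply_frame <- function(lm, frame) {
  stopifnot(inherits(lm, "landmarks3d"), inherits(frame, "orientation_frame"))
  out <- lm
  out$coords <- t(frame$rotation %*% t(lm$coords) + frame$translation)
  colnames(out$coords) <- c("x", "y", "z")
  out
}

#' Construct the three 3D measurement planes
#'
#' @param lm An oriented (canonical-frame) `"landmarks3d"` set.
#' @param frame The `"orientation_frame"` the landmarks are expressed in;
#'   its axial and coronal planes anchor the constructions. Defaults to the
#'   canonical frame.
#' @return A list of class `"ceph3d_planes"` with `"plane3"` fields
#'   `pns_plane` (through PNS, parallel to coronal), `lt_plane` (through
#'   rLT and lLT, normal to axial) and `clinoid_plane` (through the two
#'   anterior clinoid processes, normal to axial).
#' @export
construct_measurement_planes <- function(lm, frame = canonical_frame()) {
  stopifnot(inherits(lm, "landmarks3d"), inherits(frame, "orientation_frame"))
  validate_landmarks(lm)
  P <- function(name) .lmk(lm, name)
  structure(list(
    pns_plane = plane_parallel_through_point(P("PNS"), frame$coronal),
    lt_plane = plane_from_two_points_normal(P("rLT"), P("lLT"), frame$axial,
                                            what = c("rLT", "lLT")),
    clinoid_plane = plane_from_two_points_normal(P("r_clinoid"), P("l_clinoid"),
                                                 frame$axial,
                                                 what = c("r_clinoid", "l_clinoid"))),
    class = "ceph3d_planes")
}

#' Measure the seven 3D part lengths
#'
#' Point-to-plane distances, unsigned by default:
#' \describe{
#'   \item{maxillary_skeletal}{A to the PNS plane.}
#'   \item{mandibular_skeletal}{B to the lingual-tuberosity plane.}
#'   \item{maxillary_dental}{SPr to the PNS plane.}
#'   \item{mandibular_dental}{IPr to the lingual-tuberosity plane.}
#'   \item{mcf}{basion to the anterior-clinoid plane.}
#'   \item{ramus_right, ramus_left}{each condylion to the
#'     lingual-tuberosity plane; both sides are always computed.}
#' }
#'
#' @param lm The oriented `"landmarks3d"` set the planes were built from.
#' @param planes A `"ceph3d_planes"` list.
#' @param signed If `TRUE`, report signed distances (debugging aid for
#'   anterior/posterior placement errors).
#' @return An object of class `"measurements3d"`: a named numeric vector of
#'   the seven lengths in mm, with the subject id as attribute.
#' @export
measure_3d <- function(lm, planes, signed = FALSE) {
  stopifnot(inherits(lm, "landmarks3d"), inherits(planes, "ceph3d_planes"))
  P <- function(name) .lmk(lm, name)
  d <- function(p, plane) point_plane_distance(p, plane, signed = signed)
  m <- c(maxillary_skeletal  = d(P("A"),   planes$pns_plane),
         mandibular_skeletal = d(P("B"),   planes$lt_plane),
         maxillary_dental    = d(P("SPr"), planes$pns_plane),
         mandibular_dental   = d(P("IPr"), planes$lt_plane),
         mcf                 = d(P("Ba"),  planes$clinoid_plane),
         ramus_right         = d(P("rCo"), planes$lt_plane),
         ramus_left          = d(P("lCo"), planes$lt_plane))
  structure(m, class = "measurements3d", subject = lm$subject, unit = "mm")
}

#' Run the full 3D horizontal counterpart analysis
#'
#' Orients the landmark set (when a frame built from picked triplets is
#' supplied), constructs the PNS, lingual-tuberosity and clinoid planes,
#' and measures the seven part lengths.
#'
#' @param lm A complete `"landmarks3d"` set.
#' @param frame An `"orientation_frame"`; the default assumes `lm` is
#'   already in the canonical anatomical frame.
#' @return A list of class `"ceph3d_analysis"` with fields `landmarks`
#'   (oriented), `frame`, `planes` and `measurements`.
#' @export
analyze3d <- function(lm, frame = canonical_frame()) {
  stopifnot(inherits(lm, "landmarks3d"))
  oriented <- apply_frame(lm, frame)
  planes <- construct_measurement_planes(oriented, frame = canonical_frame())
  structure(list(landmarks = oriented, frame = frame, planes = planes,
                 measurements = measure_3d(oriented, planes)),
            class = "ceph3d_analysis")
}

#' @export
print.measurements3d <- function(x, ...) {
  cat(sprintf("<measurements3d> subject '%s' (mm)\n", attr(x, "subject")))
  print(round(stats::setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' @export
print.ceph3d_analysis <- function(x, ...) {
  print(x$measurements)
  invisible(x)
}

#' @export
print.orientation_frame <- function(x, ...) {
  cat("<orientation_frame>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", round(x$translation, 6), "\n")
  invisible(x)
}
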