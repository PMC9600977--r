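# 2D horizontal counterpart analysis on lateral-cephalogram landmarks.
#
# The constructed frame follows the classical simplified tracing:
#   FOP  functional occlusal plane, through Poc and Aoc
#   Ref  reference line, parallel to the FOP through articulare (Ar)
#   PM   pterygomandibular line, SE to PTM
#   PRa  posterior ramus alignment, Ar through the FOP/posterior-ramus point
#   ARa  anterior ramus alignment, parallel to PRa through LT
#   Go   gonion, constructed from two tangent lines (diagnostic only; it
#        takes part in no horizontal measurement)
# All six horizontal lengths are separations measured along Ref, i.e.
# absolute differences of scalar projections onto Ref's direction.

#' Construct the 2D analysis frame (lines and derived points)
#'
#' Builds the functional occlusal plane, the reference line through Ar, the
#' pterygomandibular line, the posterior and anterior ramus alignments, the
#' constructed gonion, and the two on-Ref anchor points `pm_ref`
#' (PM line intersected with Ref) and `ara_ref` (ARa intersected with Ref).
#'
#' @param lm A complete `"landmarks2d"` set (see [required_landmarks_2d]).
#' @return An object of class `"ceph2d_frame"`: a list with `"line2"` fields
#'   `fop`, `ref`, `pm_line`, `pra`, `ara` and point fields `go`, `pm_ref`,
#'   `ara_ref`.
#' @examples
#' lm <- landmarks2d(rbind(
#'   Poc = c(10, 0), Aoc = c(30, 0), Ar = c(-25, 40), SE = c(0, 50),
#'   PTM = c(5, 10), LT = c(0, 0), pra_fop_point = c(-15, 0), A = c(45, 25),
#'   B = c(42, -15), SPr = c(48, 15), IPr = c(46, -5), Me = c(40, -20),
#'   corpus_lowest = c(20, -22), ramus_posterior_most = c(-22, 20)))
#' fr <- construct_frame(lm)
#' fr$pm_ref   # (1.25, 40)
#' @export
construct_frame <- function(lm) {
  stopifnot(inherits(lm, "landmarks2d"))
  validate_landmarks(lm)
  P <- function(name) .lmk(lm, name)

  fop <- line_through(P("Poc"), P("Aoc"), what = c("Poc", "Aoc"))
  ref <- line_parallel_through(P("Ar"), fop)
  pm_line <- line_through(P("SE"), P("PTM"), what = c("SE", "PTM"))
  pra <- line_through(P("Ar"), P("pra_fop_point"), what = c("Ar", "pra_fop_point"))
  ara <- line_parallel_through(P("LT"), pra)

  go <- intersect_lines(
    line_through(P("Me"), P("corpus_lowest"), what = c("Me", "corpus_lowest")),
    line_through(P("Ar"), P("ramus_posterior_most"), what = c("Ar", "ramus_posterior_most")),
    what = c("Me-corpus_lowest tangent", "Ar-ramus_posterior_most tangent"))

  pm_ref <- intersect_lines(pm_line, ref, what = c("PM (SE-PTM)", "Ref"))
  ara_ref <- intersect_lines(ara, ref, what = c("ARa", "Ref"))

  structure(list(fop = fop, ref = ref, pm_line = pm_line, pra = pra, ara = ara,
                 go = go, pm_ref = pm_ref, ara_ref = ara_ref,
                 subject = lm$subject),
            class = "ceph2d_frame")
}

# scalar coordinate along Ref: projection onto the Ref direction
.along_ref <- function(frame, p) sum((p - frame$ref$anchor) * frame$ref$direction)

#' Measure the six 2D horizontal part lengths
#'
#' All lengths are along-Ref separations (absolute differences of scalar
#' projections onto the Ref direction):
#' \describe{
#'   \item{maxillary_skeletal}{A point to `pm_ref`, in parallel with Ref.}
#'   \item{mandibular_skeletal}{orthogonal projection of B on Ref to
#'     `ara_ref`.}
#'   \item{maxillary_dental}{SPr to `pm_ref`, in parallel with Ref.}
#'   \item{mandibular_dental}{orthogonal projection of IPr on Ref to
#'     `ara_ref`.}
#'   \item{mcf}{middle cranial floor: Ar to the neutral PM point `pm_ref`,
#'     along Ref.}
#'   \item{ramus}{ramus width: Ar to `ara_ref`, along Ref.}
#' }
#'
#' @param lm The `"landmarks2d"` set the frame was constructed from.
#' @param frame The matching `"ceph2d_frame"`.
#' @return An object of class `"measurements2d"`: a named numeric vector of
#'   the six lengths in mm, with the subject id as attribute.
#' @export
measure_2d <- function(lm, frame) {
  stopifnot(inherits(lm, "landmarks2d"), inherits(frame, "ceph2d_frame"))
  P <- function(name) .lmk(lm, name)
  s <- function(p) .along_ref(frame, p)

  b_on_ref <- project_point_onto_line(P("B"), frame$ref)
  ipr_on_ref <- project_point_onto_line(P("IPr"), frame$ref)
  s_pm <- s(frame$pm_ref)
  s_ara <- s(frame$ara_ref)
  s_ar <- s(P("Ar"))

  m <- c(maxillary_skeletal  = abs(s(P("A")) - s_pm),
         mandibular_skeletal = abs(s(b_on_ref) - s_ara),
         maxillary_dental    = abs(s(P("SPr")) - s_pm),
         mandibular_dental   = abs(s(ipr_on_ref) - s_ara),
         mcf                 = abs(s_ar - s_pm),
         ramus               = abs(s_ar - s_ara))
  structure(m, class = "measurements2d", subject = lm$subject, unit = "mm")
}

#' Run the full 2D horizontal counterpart analysis
#'
#' Convenience wrapper: validates the landmark set, constructs the frame and
#' measures the six lengths.
#'
#' @param lm A complete `"landmarks2d"` set.
#' @return A list of class `"ceph2d_analysis"` with fields `landmarks`,
#'   `frame` and `measurements`.
#' @export
analyze2d <- function(lm) {
  frame <- construct_frame(lm)
  structure(list(landmarks = lm, frame = frame,
                 measurements = measure_2d(lm, frame)),
            class = "ceph2d_analysis")
}

#' @export
print.measurements2d <- function(x, ...) {
  cat(sprintf("<measurements2d> subject '%s' (mm)\n", attr(x, "subject")))
  print(round(stats::setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' @export
print.ceph2d_analysis <- function(x, ...) {
  print(x$measurements)
  invisible(x)
}
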