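# Part-minus-counterpart discrepancies, the millimetre-difference harmony
# classification, and the cohort statistics used to compare 2D and 3D
# discrepancies (Kolmogorov-Smirnov normality, paired Student's t).

.index_names <- c("mcf_ramus", "skeletal_arches", "dental_arches")

#' Classify a part-counterpart discrepancy as harmonic or not
#'
#' The millimetre-difference method: a part whose length differs from its
#' counterpart by 0 to 2.5 mm (boundary inclusive) is in harmonic, ideal
#' balance; anything larger is non-harmonic. Classification is symmetric in
#' sign and monotone in `|d|`.
#'
#' @param d Numeric vector of discrepancies in mm (signed or not).
#' @param threshold Harmony threshold in mm (default 2.5).
#' @return Character vector, `"harmonic"` or `"non_harmonic"`.
#' @examples
#' classify_harmony(c(0, 2.5, -3))  # harmonic, harmonic, non_harmonic
#' @export
classify_harmony <- function(d, threshold = 2.5) {
  if (!is.numeric(d) || !all(is.finite(d)))
    stop_validation("discrepancies must be finite numbers")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0)
    stop_validation("threshold must be a single positive number (mm)")
  ifelse(abs(d) <= threshold, "harmonic", "non_harmonic")
}

#' Compute the three part-minus-counterpart discrepancies
#'
#' Subtracts each counterpart from its part, in the conventional listing
#' order: middle cranial floor minus ramus, maxillary minus mandibular
#' skeletal arch, maxillary minus mandibular dento-alveolar arch. For 3D
#' measurements the ramus side entering the first index is the right one by
#' convention; `ramus = "left"` or `"mean"` select alternatives.
#'
#' @param m A `"measurements2d"` or `"measurements3d"` vector.
#' @param threshold Harmony threshold in mm passed to [classify_harmony()].
#' @param ramus For 3D input, which ramus feeds the MCF-ramus index:
#'   `"right"` (default), `"left"` or `"mean"`.
#' @return An object of class `"discrepancy_report"`: a list with fields
#'   `values` (named numeric, mm), `harmony` (named character),
#'   `dimension` (`"2D"` or `"3D"`), `subject`, `threshold` and `ramus`.
#' @examples
#' m <- structure(c(maxillary_skeletal = 45, mandibular_skeletal = 48,
#'                  maxillary_dental = 48, mandibular_dental = 51,
#'                  mcf = 27, ramus_right = 25, ramus_left = 25),
#'                class = "measurements3d", subject = "demo", unit = "mm")
#' discrepancies(m)$values  # mcf_ramus 2, skeletal -3, dental -3
#' @export
discrepancies <- function(m, threshold = 2.5, ramus = c("right", "left", "mean")) {
  ramus <- match.arg(ramus)
  if (inherits(m, "measurements2d")) {
    dim_tag <- "2D"
    need <- c("maxillary_skeletal", "mandibular_skeletal", "maxillary_dental",
              "mandibular_dental", "mcf", "ramus")
  } else if (inherits(m, "measurements3d")) {
    dim_tag <- "3D"
    need <- c("maxillary_skeletal", "mandibular_skeletal", "maxillary_dental",
              "mandibular_dental", "mcf", "ramus_right", "ramus_left")
  } else {
    stop_validation("m must be a measurements2d or measurements3d object")
  }
  miss <- setdiff(need, names(m))
  if (length(miss) || !all(is.finite(m[need])))
    stop_validation(paste0("incomplete measurement set; missing or non-finite: ",
                           paste(union(miss, need[!is.finite(m[need])]), collapse = ", ")))
  ram <- if (dim_tag == "2D") m[["ramus"]] else switch(ramus,
    right = m[["ramus_right"]],
    left = m[["ramus_left"]],
    mean = (m[["ramus_right"]] + m[["ramus_left"]]) / 2)
  v <- c(mcf_ramus = m[["mcf"]] - ram,
         skeletal_arches = m[["maxillary_skeletal"]] - m[["mandibular_skeletal"]],
         dental_arches = m[["maxillary_dental"]] - m[["mandibular_dental"]])
  structure(list(values = v,
                 harmony = stats::setNames(classify_harmony(v, threshold), names(v)),
                 dimension = dim_tag,
                 subject = attr(m, "subject"),
                 threshold = threshold,
                 ramus = if (dim_tag == "3D") ramus else "lateral"),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat(sprintf("<discrepancy_report %s> subject '%s' (mm, harmony threshold %g mm)\n",
              x$dimension, x$subject, x$threshold))
  df <- data.frame(index = names(x$values),
                   part_minus_counterpart = round(unname(x$values), 4),
                   harmony = unname(x$harmony))
  print(df, row.names = FALSE)
  invisible(x)
}

.new_test_result <- function(statistic, df, p, alpha, method) {
  structure(list(statistic = statistic, degrees_of_freedom = df,
                 p_value = p, alpha = alpha, reject = p < alpha,
                 method = method),
            class = "counterpart_test")
}

#' Paired (or unpaired) Student's t-test
#'
#' Paired by default, matching a within-subject 2D-vs-3D comparison; the
#' unpaired (Welch) variant is available for sensitivity analysis. Wraps
#' [stats::t.test()] and reports a degenerate-test error, rather than a
#' spurious statistic, when the paired differences have zero variance.
#'
#' @param x,y Numeric vectors; equal length (and n >= 2) when paired.
#' @param alpha Significance level (default 0.05).
#' @param paired Paired test (default `TRUE`).
#' @return An object of class `"counterpart_test"` with fields `statistic`,
#'   `degrees_of_freedom`, `p_value`, `alpha`, `reject`.
#' @examples
#' r <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
#' round(c(r$statistic, r$p_value), 4)  # 3.4641 0.0742
#' @export
paired_t_test <- function(x, y, alpha = 0.05, paired = TRUE) {
  if (!is.numeric(x) || !is.numeric(y) || !all(is.finite(c(x, y))))
    stop_validation("x and y must be finite numeric vectors")
  if (paired && length(x) != length(y))
    stop_validation(sprintf("paired test requires equal lengths (got %d and %d)",
                            length(x), length(y)))
  if (length(x) < 2L || length(y) < 2L)
    stop_validation("need at least two observations per group")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_validation("alpha must be in (0, 1)")
  if (paired && stats::sd(x - y) <= 0)
    stop(structure(class = c("counterpart3d_degenerate_test", "error", "condition"),
                   list(message = "paired differences have zero variance; t-test undefined",
                        call = sys.call())))
  tt <- stats::t.test(x, y, paired = paired)
  .new_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                   alpha, if (paired) "paired Student's t" else "Welch two-sample t")
}

#' Kolmogorov-Smirnov normality test
#'
#' The classical KS statistic against a normal distribution with the
#' sample's own mean and standard deviation:
#' `D = sup |ECDF(x) - Phi((x - mean) / sd)|`, with an asymptotic p-value.
#' Because the null parameters are estimated from the same sample, this
#' classical variant is anti-conservative; set `lilliefors = TRUE` for the
#' corrected null distribution (requires the \pkg{nortest} package). The
#' uncorrected variant is the default, as commonly reported by clinical
#' statistics software.
#'
#' @param x Numeric vector, n >= 4.
#' @param alpha Significance level (default 0.05).
#' @param lilliefors Use the Lilliefors correction (default `FALSE`).
#' @return An object of class `"counterpart_test"`; `reject = TRUE` means
#'   normality is rejected.
#' @export
ks_normality <- function(x, alpha = 0.05, lilliefors = FALSE) {
  if (!is.numeric(x) || !all(is.finite(x)))
    stop_validation("x must be a finite numeric vector")
  if (length(x) < 4L)
    stop_validation("Kolmogorov-Smirnov normality test needs n >= 4")
  if (stats::sd(x) <= 0)
    stop_validation("sample has zero variance; normality test undefined")
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop_validation("the 'nortest' package is required for the Lilliefors correction")
    kt <- nortest::lillie.test(x)
    return(.new_test_result(unname(kt$statistic), NA_real_, kt$p.value, alpha,
                            "Lilliefors-corrected KS normality"))
  }
  kt <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x), exact = FALSE))
  .new_test_result(unname(kt$statistic), NA_real_, kt$p.value, alpha,
                   "Kolmogorov-Smirnov normality (fitted normal, asymptotic)")
}

#' @export
print.counterpart_test <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4f%s, p = %.4g (alpha %g): %s\n",
              x$method, x$statistic,
              if (is.finite(x$degrees_of_freedom))
                sprintf(", df %g", x$degrees_of_freedom) else "",
              x$p_value, x$alpha,
              if (x$reject) "reject" else "do not reject"))
  invisible(x)
}

#' Summarize a paired 2D/3D discrepancy cohort
#'
#' Pairs 2D and 3D discrepancy reports by subject identifier and, per index,
#' reports mean and SD (n - 1 denominator) of the 2D and 3D discrepancies,
#' KS normality p-values for each series, and the paired Student's t p-value
#' for the 2D-vs-3D comparison. An index whose paired differences are
#' degenerate (zero variance) is reported with `NA` statistics and a note
#' rather than aborting the whole table.
#'
#' @param reports_2d,reports_3d Lists of `"discrepancy_report"` objects
#'   (dimension 2D and 3D respectively), paired by subject id.
#' @param units `"mm"` (default) or `"cm"` for the reported means and SDs.
#' @param alpha Significance level for both tests.
#' @return An object of class `"cohort_table"`: a data frame with one row
#'   per index and columns `index`, `n`, `mean_2d`, `sd_2d`, `mean_3d`,
#'   `sd_3d`, `ks_p_2d`, `ks_p_3d`, `t`, `df`, `p_value`, `note`; attribute
#'   `units` records the length unit.
#' @export
cohort_summary <- function(reports_2d, reports_3d, units = c("mm", "cm"),
                           alpha = 0.05) {
  units <- match.arg(units)
  check_side <- function(reports, dim_tag) {
    stopifnot(is.list(reports), length(reports) >= 2L)
    ok <- vapply(reports, function(r)
      inherits(r, "discrepancy_report") && r$dimension == dim_tag, logical(1L))
    if (!all(ok))
      stop_validation(paste0("all ", dim_tag, " entries must be ", dim_tag,
                             " discrepancy reports"))
    reports
  }
  reports_2d <- check_side(reports_2d, "2D")
  reports_3d <- check_side(reports_3d, "3D")
  ids2 <- vapply(reports_2d, function(r) as.character(r$subject), character(1L))
  ids3 <- vapply(reports_3d, function(r) as.character(r$subject), character(1L))
  if (anyDuplicated(ids2) || anyDuplicated(ids3))
    stop_validation("duplicate subject identifiers within a cohort")
  unpaired <- c(setdiff(ids2, ids3), setdiff(ids3, ids2))
  if (length(unpaired))
    stop_validation(paste0("unpaired subject(s): ", paste(unpaired, collapse = ", ")))
  ord <- match(ids2, ids3)
  n <- length(ids2)
  scale <- if (units == "cm") 0.1 else 1

  rows <- lapply(.index_names, function(idx) {
    v2 <- vapply(reports_2d, function(r) r$values[[idx]], numeric(1L))
    v3 <- vapply(reports_3d[ord], function(r) r$values[[idx]], numeric(1L))
    ks2 <- tryCatch(ks_normality(v2, alpha)$p_value, error = function(e) NA_real_)
    ks3 <- tryCatch(ks_normality(v3, alpha)$p_value, error = function(e) NA_real_)
    tt <- tryCatch(paired_t_test(v2, v3, alpha), error = function(e) e)
    if (inherits(tt, "error")) {
      t_stat <- NA_real_; t_df <- NA_real_; p <- NA_real_
      note <- conditionMessage(tt)
    } else {
      t_stat <- tt$statistic; t_df <- tt$degrees_of_freedom; p <- tt$p_value
      note <- ""
    }
    data.frame(index = idx, n = n,
               mean_2d = mean(v2) * scale, sd_2d = stats::sd(v2) * scale,
               mean_3d = mean(v3) * scale, sd_3d = stats::sd(v3) * scale,
               ks_p_2d = ks2, ks_p_3d = ks3,
               t = t_stat, df = t_df, p_value = p, note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, units = units, alpha = alpha,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> n = %d subjects, units %s\n",
              x$n[1L], attr(x, "units")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}
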