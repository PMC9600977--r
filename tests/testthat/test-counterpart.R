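test_that("discrepancies follow the part-minus-counterpart convention", {
  lm3 <- f3d_landmarks()
  d3 <- discrepancies(analyze3d(lm3)$measurements)
  expect_equal(unname(d3$values),
               c(27 - 25, 45 - 48, 48 - 51), tolerance = 1e-12)
  expect_identical(names(d3$values),
                   c("mcf_ramus", "skeletal_arches", "dental_arches"))
  expect_identical(d3$dimension, "3D")

  lm2 <- f2d_landmarks()
  d2 <- discrepancies(analyze2d(lm2)$measurements)
  expect_equal(unname(d2$values),
               c(26.25 - 15, 43.75 - 52, 46.75 - 56), tolerance = 1e-12)
  expect_identical(d2$dimension, "2D")

  # ramus side convention (right by default)
  m <- structure(c(maxillary_skeletal = 45, mandibular_skeletal = 45,
                   maxillary_dental = 48, mandibular_dental = 48,
                   mcf = 30, ramus_right = 28, ramus_left = 24),
                 class = "measurements3d", subject = "s", unit = "mm")
  expect_equal(discrepancies(m)$values[["mcf_ramus"]], 2)
  expect_equal(discrepancies(m, ramus = "left")$values[["mcf_ramus"]], 6)
  expect_equal(discrepancies(m, ramus = "mean")$values[["mcf_ramus"]], 4)
  # identical part and counterpart gives zero
  expect_equal(discrepancies(m)$values[["skeletal_arches"]], 0)

  m_bad <- m[-1]
  class(m_bad) <- "measurements3d"
  expect_error(discrepancies(m_bad), class = "counterpart3d_validation_error")
})

test_that("harmony classification has an inclusive 2.5 mm boundary, symmetric in sign", {
  expect_identical(classify_harmony(0), "harmonic")
  expect_identical(classify_harmony(2.5), "harmonic")
  expect_identical(classify_harmony(-2.5), "harmonic")
  expect_identical(classify_harmony(-3), "non_harmonic")
  expect_identical(classify_harmony(2.5 + 1e-9), "non_harmonic")
  # monotone in |d|, symmetric in sign
  d <- seq(0, 6, by = 0.25)
  lab <- classify_harmony(d)
  expect_identical(lab, classify_harmony(-d))
  expect_true(all(diff(lab == "harmonic") <= 0))
  # configurable threshold
  expect_identical(classify_harmony(3, threshold = 4), "harmonic")
  expect_error(classify_harmony(NaN), class = "counterpart3d_validation_error")
  expect_error(classify_harmony(1, threshold = 0), class = "counterpart3d_validation_error")
})

test_that("paired t-test matches the closed form and its symmetries", {
  r <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)  # 3.4641
  expect_equal(r$degrees_of_freedom, 2)
  expect_equal(r$p_value, 2 * stats::pt(-sqrt(12), df = 2), tolerance = 1e-9)
  expect_equal(round(r$p_value, 4), 0.0742)
  expect_false(r$reject)

  # antisymmetry: swapping the groups negates t, p unchanged
  set.seed(9)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  a <- paired_t_test(x, y); b <- paired_t_test(y, x)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  expect_error(paired_t_test(x, x), class = "counterpart3d_degenerate_test")
  expect_error(paired_t_test(x, x + 5), class = "counterpart3d_degenerate_test")
  expect_error(paired_t_test(1:3, 1:4), class = "counterpart3d_validation_error")
  expect_error(paired_t_test(1, 2), class = "counterpart3d_validation_error")

  # unpaired variant tolerates unequal lengths
  w <- paired_t_test(x, c(y, 0.3), paired = FALSE)
  expect_true(is.finite(w$statistic) && w$p_value >= 0 && w$p_value <= 1)
})

test_that("the implemented t distribution reproduces the df=2 critical value", {
  crit <- stats::uniroot(function(t) 2 * stats::pt(-t, df = 2) - 0.05,
                         c(1, 50), tol = 1e-10)$root
  expect_equal(crit, 4.3027, tolerance = 1e-3)
  # and paired_t_test flips its decision exactly there
  d <- c(1, 2, 3)
  mk <- function(scale) {
    v <- d - mean(d) + scale * stats::sd(d) / sqrt(3)
    paired_t_test(v, rep(0, 3))$reject
  }
  expect_false(mk(crit * 0.999))
  expect_true(mk(crit * 1.001))
})

test_that("KS normality statistic equals the brute-force ECDF-gap oracle", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- switch(1 + i %% 3,
                stats::rnorm(n, 2, 3),
                stats::rexp(n),
                stats::runif(n, -1, 1))
    r <- ks_normality(x)
    expect_equal(r$statistic, ks_stat_oracle(x), tolerance = 1e-12)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
  # affine invariance: standardization is built in
  x <- stats::rnorm(40)
  expect_equal(ks_normality(3 + 5 * x)$statistic, ks_normality(x)$statistic,
               tolerance = 1e-12)
  # a heavy-tailed sample at n=500 is firmly rejected
  set.seed(123)
  heavy <- stats::rt(500, df = 1)
  expect_true(ks_normality(heavy)$reject)
  expect_error(ks_normality(c(1, 2, 3)), class = "counterpart3d_validation_error")
})

test_that("cohort summary equals brute-force recomputation and converts units exactly", {
  set.seed(55)
  cohort <- generate_cohort(10, skull_config(), seed = 42)
  rep <- cohort_reports(cohort)
  tab <- cohort_summary(rep$reports_2d, rep$reports_3d)
  expect_identical(nrow(tab), 3L)
  for (i in 1:3) {
    idx <- tab$index[i]
    v2 <- sapply(rep$reports_2d, function(r) r$values[[idx]])
    v3 <- sapply(rep$reports_3d, function(r) r$values[[idx]])
    expect_equal(tab$mean_2d[i], mean(v2), tolerance = 1e-12)
    expect_equal(tab$sd_2d[i], stats::sd(v2), tolerance = 1e-12)  # n-1 denominator
    expect_equal(tab$mean_3d[i], mean(v3), tolerance = 1e-12)
    expect_equal(tab$sd_3d[i], stats::sd(v3), tolerance = 1e-12)
    expect_equal(tab$p_value[i], stats::t.test(v2, v3, paired = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  tab_cm <- cohort_summary(rep$reports_2d, rep$reports_3d, units = "cm")
  expect_equal(tab_cm$mean_2d, tab$mean_2d / 10, tolerance = 1e-12)
  expect_equal(tab_cm$sd_3d, tab$sd_3d / 10, tolerance = 1e-12)
  expect_equal(tab_cm$p_value, tab$p_value)  # tests are unit-free
})

test_that("cohort summary validates pairing and surfaces degenerate indices", {
  cohort <- generate_cohort(4, skull_config(), seed = 3)
  rep <- cohort_reports(cohort)
  broken <- rep$reports_3d
  broken[[2]]$subject <- "someone_else"
  expect_error(cohort_summary(rep$reports_2d, broken),
               class = "counterpart3d_validation_error")
  expect_error(cohort_summary(rep$reports_2d, broken), regexp = "someone_else")

  # identical 2D and 3D reports: per-index degenerate t surfaced as a note
  ident_3d <- lapply(rep$reports_2d, function(r) { r$dimension <- "3D"; r })
  tab <- cohort_summary(rep$reports_2d, ident_3d)
  expect_true(all(is.na(tab$p_value)))
  expect_true(all(nzchar(tab$note)))
  expect_equal(tab$mean_2d, tab$mean_3d)
})

test_that("a cohort with no planted 2D/3D shift stays within sampling noise of zero", {
  cohort <- generate_cohort(18, skull_config(), seed = 2024)
  rep <- cohort_reports(cohort)
  tab <- cohort_summary(rep$reports_2d, rep$reports_3d)
  for (i in 1:3) {
    v2 <- sapply(rep$reports_2d, function(r) r$values[[tab$index[i]]])
    v3 <- sapply(rep$reports_3d, function(r) r$values[[tab$index[i]]])
    se <- stats::sd(v2 - v3) / sqrt(length(v2))
    expect_lt(abs(tab$mean_2d[i] - tab$mean_3d[i]), 3 * se)
  }
})
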