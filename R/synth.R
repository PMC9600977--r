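# Seeded synthetic skull-landmark generator.
#
# Landmarks are laid out directly in the canonical anatomical frame so that
# every planted part length is realized *exactly* by the 3D plane
# constructions (PNS plane at y = 0, lingual-tuberosity and clinoid planes
# vertical), and the auxiliary lateral-cephalogram landmarks are placed so
# that the 2D constructions reproduce the same planted lengths: the
# pterygomandibular line projects vertically through the PNS plane and the
# ramus alignments vertically through the lingual tuberosity, which pins
# the lingual tuberosity's anteroposterior position at
# y_LT = ramus_right - mcf. For a bilaterally symmetric, noise-free skull
# the three 2D discrepancies therefore equal the 3D ones exactly.
# Asymmetry offsets act on the x and z coordinates of the bilateral pairs
# (the anteroposterior position is what the planted lengths are defined
# against), so planted lengths stay exact under asymmetry too.

.default_lengths <- c(maxillary_skeletal = 52, mandibular_skeletal = 57,
                      maxillary_dental = 49, mandibular_dental = 52,
                      mcf = 34.5, ramus_right = 33, ramus_left = 33)

.default_halfwidths <- c(lt = 30, clinoid = 12, condyle = 50)

.default_asymmetry <- c(lt_x = 0, lt_z = 0, clinoid_x = 0, clinoid_z = 0,
                        condyle_x = 0, condyle_z = 0)

# vertical (z) template offsets, mm, relative to the palatal plane (z = 0),
# following typical Class I craniofacial vertical proportions: cranial-base
# landmarks 2-4 cm above the palate, occlusal plane just below it, lingual
# tuberosity at corpus level, symphysis lowest
.default_vertical <- c(PNS = 0, A = -4, SPr = -14, occ = -17, LT = -24,
                       IPr = -20, B = -45, Me = -55, corpus_lowest = -57,
                       clinoid = 26, Ba = 8, Co = 24, Ar = 22, SE = 35,
                       PTM = -3, ramus_posterior_most = -35)

.merge_named <- function(defaults, user, what) {
  if (is.null(user)) return(defaults)
  if (!is.numeric(user) || is.null(names(user)))
    stop_validation(paste0(what, " must be a named numeric vector"))
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop_validation(paste0("unknown ", what, " name(s): ", paste(bad, collapse = ", ")))
  defaults[names(user)] <- user
  defaults
}

#' Configuration for the synthetic skull generator
#'
#' @param lengths Named numeric vector of planted part lengths in mm
#'   (`maxillary_skeletal`, `mandibular_skeletal`, `maxillary_dental`,
#'   `mandibular_dental`, `mcf`, `ramus_right`, `ramus_left`); partial
#'   overrides of the defaults are allowed. The defaults describe a
#'   skeletal Class I configuration whose part-counterpart discrepancies
#'   (+1.5, -5, -3 mm) sit in the clinically reported range.
#' @param halfwidths Named bilateral half-widths in mm (`lt`, `clinoid`,
#'   `condyle`): distance of each paired landmark from the midsagittal
#'   plane.
#' @param asymmetry Named offsets in mm applied to the *left* member of each
#'   bilateral pair, in x (`lt_x`, `clinoid_x`, `condyle_x`) and z
#'   (`lt_z`, `clinoid_z`, `condyle_z`).
#' @param vertical_offsets Named overrides of the template's vertical (z)
#'   landmark offsets in mm (see `counterpart3d:::.default_vertical`).
#' @param noise_sd Landmark-placement noise SD in mm (isotropic Gaussian,
#'   applied independently to the 3D landmarks and to the projected 2D
#'   landmarks, emulating two independent tracings). Default 0.5 mm.
#' @param length_sd Between-subject SD in mm applied to every planted
#'   length by [generate_cohort()] (default 2 mm); scalar or named like
#'   `lengths`.
#' @param magnification Uniform lateral-projection magnification factor
#'   (default 1, i.e. orthographic without enlargement).
#' @param seed Optional integer seed making [generate_skull()]
#'   deterministic.
#' @return A list of class `"skull_config"`.
#' @export
skull_config <- function(lengths = NULL, halfwidths = NULL, asymmetry = NULL,
                         vertical_offsets = NULL, noise_sd = 0.5,
                         length_sd = 2, magnification = 1, seed = NULL) {
  lengths <- .merge_named(.default_lengths, lengths, "length")
  halfwidths <- .merge_named(.default_halfwidths, halfwidths, "halfwidth")
  asymmetry <- .merge_named(.default_asymmetry, asymmetry, "asymmetry offset")
  vertical <- .merge_named(.default_vertical, vertical_offsets, "vertical offset")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop_validation("all planted lengths must be positive and finite")
  if (any(!is.finite(halfwidths)) || any(halfwidths <= 0))
    stop_validation("all halfwidths must be positive and finite")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || !is.finite(noise_sd) ||
      noise_sd < 0)
    stop_validation("noise_sd must be a single non-negative number (mm)")
  if (any(!is.finite(length_sd)) || any(length_sd < 0))
    stop_validation("length_sd must be non-negative")
  if (!is.numeric(magnification) || length(magnification) != 1L ||
      !is.finite(magnification) || magnification <= 0)
    stop_validation("magnification must be a single positive number")
  structure(list(lengths = lengths, halfwidths = halfwidths,
                 asymmetry = asymmetry, vertical_offsets = vertical,
                 noise_sd = noise_sd, length_sd = length_sd,
                 magnification = magnification, seed = seed),
            class = "skull_config")
}

# run expr under a temporary RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# noiseless landmark layout realizing the planted lengths
.skull_layout <- function(cfg) {
  L <- cfg$lengths; hw <- cfg$halfwidths; asy <- cfg$asymmetry
  vz <- cfg$vertical_offsets
  y_lt <- unname(L["ramus_right"] - L["mcf"])  # 2D/3D template coupling
  y_cl <- 8                                    # clinoid plane, anterior of PNS
  main <- rbind(
    Ba        = c(0, y_cl - L[["mcf"]], vz[["Ba"]]),
    rCo       = c(hw[["condyle"]], y_lt - L[["ramus_right"]], vz[["Co"]]),
    lCo       = c(-hw[["condyle"]] + asy[["condyle_x"]],
                  y_lt - L[["ramus_left"]], vz[["Co"]] + asy[["condyle_z"]]),
    rLT       = c(hw[["lt"]], y_lt, vz[["LT"]]),
    lLT       = c(-hw[["lt"]] + asy[["lt_x"]], y_lt, vz[["LT"]] + asy[["lt_z"]]),
    A         = c(0, L[["maxillary_skeletal"]], vz[["A"]]),
    B         = c(0, y_lt + L[["mandibular_skeletal"]], vz[["B"]]),
    SPr       = c(0, L[["maxillary_dental"]], vz[["SPr"]]),
    IPr       = c(0, y_lt + L[["mandibular_dental"]], vz[["IPr"]]),
    PNS       = c(0, 0, vz[["PNS"]]),
    r_clinoid = c(hw[["clinoid"]], y_cl, vz[["clinoid"]]),
    l_clinoid = c(-hw[["clinoid"]] + asy[["clinoid_x"]], y_cl,
                  vz[["clinoid"]] + asy[["clinoid_z"]]))
  y_b <- y_lt + L[["mandibular_skeletal"]]
  aux <- rbind(
    Ar                   = c(0, -L[["mcf"]], vz[["Ar"]]),
    SE                   = c(0, 0, vz[["SE"]]),
    PTM                  = c(0, 0, vz[["PTM"]]),
    Poc                  = c(0, y_lt + 18, vz[["occ"]]),
    Aoc                  = c(0, y_lt + 38, vz[["occ"]]),
    pra_fop_point        = c(0, -L[["mcf"]], vz[["occ"]]),
    Me                   = c(0, y_b - 3, vz[["Me"]]),
    corpus_lowest        = c(0, (y_b + y_lt) / 2, vz[["corpus_lowest"]]),
    ramus_posterior_most = c(0, -L[["mcf"]] - 1.5, vz[["ramus_posterior_most"]]))
  list(main = main, aux = aux)
}

#' Project a synthetic skull to lateral-cephalogram landmarks
#'
#' Orthographic lateral projection: the mediolateral (x) axis is dropped,
#' mapping canonical (x, y, z) to 2D (x, y) = (y, z). Bilateral pairs
#' collapse to the projection of their midpoint (the "averaged shadow"
#' convention of lateral radiography); the auxiliary midsagittal template
#' points (Ar, SE, PTM, occlusal contacts, tangent points) project
#' directly. A uniform magnification factor emulates cephalostat
#' enlargement.
#'
#' @param skull A `"synthetic_skull"` object.
#' @param magnification Uniform scale factor applied to the projected
#'   coordinates (defaults to the skull's configured value).
#' @return A noise-free `"landmarks2d"` set.
#' @export
project_lateral <- function(skull, magnification = skull$config$magnification) {
  stopifnot(inherits(skull, "synthetic_skull"))
  m3 <- skull$lm3d_true$coords
  aux <- skull$aux3d
  pair_mid <- function(r, l) (m3[r, ] + m3[l, ]) / 2
  pts3 <- rbind(
    A = m3["A", ], B = m3["B", ], SPr = m3["SPr", ], IPr = m3["IPr", ],
    LT = pair_mid("rLT", "lLT"),
    aux)
  coords2 <- pts3[, c("y", "z"), drop = FALSE] * magnification
  colnames(coords2) <- c("x", "y")
  landmarks2d(coords2, subject = skull$lm3d_true$subject)
}

#' Add landmark-placement noise
#'
#' Independent isotropic Gaussian perturbation of every coordinate,
#' modelling operator landmark-identification error.
#'
#' @param lm A `"landmarks2d"` or `"landmarks3d"` set.
#' @param sigma Noise SD in mm (>= 0; 0 returns the set unchanged).
#' @param seed Optional integer seed; when given, the caller's RNG stream is
#'   left untouched.
#' @return The perturbed landmark set.
#' @export
add_landmark_noise <- function(lm, sigma, seed = NULL) {
  stopifnot(inherits(lm, "landmark_set"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop_validation("sigma must be a single non-negative number (mm)")
  if (sigma == 0) return(lm)
  out <- lm
  out$coords <- .with_seed(seed, {
    lm$coords + stats::rnorm(length(lm$coords), mean = 0, sd = sigma)
  })
  out
}

#' Generate one synthetic skull
#'
#' Places the 12 anatomical 3D landmarks in the canonical frame so that the
#' seven planted part lengths are realized exactly by the 3D plane
#' constructions, places the auxiliary lateral-cephalogram landmarks
#' consistently (see the package vignette for the template geometry),
#' projects the matched 2D landmark set, and optionally perturbs both sets
#' with independent placement noise. The generator verifies its own output:
#' a configuration whose noise-free landmarks fail to reproduce the planted
#' lengths (e.g. after degenerate user overrides) raises a generation error
#' with the offending construction named.
#'
#' @param config A `"skull_config"` object.
#' @param subject Subject identifier.
#' @return An object of class `"synthetic_skull"`: fields `lm3d`/`lm2d`
#'   (observed, noise applied), `lm3d_true`/`lm2d_true` (noise-free),
#'   `aux3d` (auxiliary midsagittal template points), `truth3d`/`truth2d`
#'   (planted measurement sets), `config` and `seed`.
#' @examples
#' sk <- generate_skull(skull_config(noise_sd = 0, seed = 1))
#' all.equal(unclass(analyze3d(sk$lm3d)$measurements), unclass(sk$truth3d))
#' @export
generate_skull <- function(config = skull_config(), subject = "synthetic") {
  stopifnot(inherits(config, "skull_config"))
  layout <- .skull_layout(config)
  lm3d_true <- landmarks3d(layout$main, subject = subject)

  truth3d <- structure(
    config$lengths[c("maxillary_skeletal", "mandibular_skeletal",
                     "maxillary_dental", "mandibular_dental", "mcf",
                     "ramus_right", "ramus_left")],
    class = "measurements3d", subject = subject, unit = "mm")
  t2 <- config$lengths[c("maxillary_skeletal", "mandibular_skeletal",
                         "maxillary_dental", "mandibular_dental", "mcf",
                         "ramus_right")]
  names(t2)[6L] <- "ramus"  # the lateral view sees the conventional (right) ramus
  truth2d <- structure(t2, class = "measurements2d", subject = subject, unit = "mm")

  skull <- structure(list(lm3d_true = lm3d_true, aux3d = layout$aux,
                          truth3d = truth3d, truth2d = truth2d,
                          config = config, seed = config$seed),
                     class = "synthetic_skull")
  lm2d_true <- tryCatch(project_lateral(skull, magnification = 1),
                        error = function(e) stop_validation(
                          paste0("synthetic template projection failed: ",
                                 conditionMessage(e))))
  skull$lm2d_true <- lm2d_true

  # self-check: the noise-free layout must reproduce the planted lengths
  chk <- tryCatch({
    m3 <- analyze3d(lm3d_true)$measurements
    m2 <- analyze2d(lm2d_true)$measurements
    max(abs(unclass(m3) - unclass(truth3d)),
        abs(unclass(m2) - unclass(truth2d)))
  }, error = function(e) e)
  if (inherits(chk, "error"))
    stop_validation(paste0("configuration yields a degenerate construction: ",
                           conditionMessage(chk)))
  if (chk > 1e-6)
    stop_validation(sprintf(
      "configuration breaks the template geometry: planted lengths missed by %.3g mm",
      chk))

  .with_seed(config$seed, {
    skull$lm3d <- add_landmark_noise(lm3d_true, config$noise_sd)
    skull$lm2d <- add_landmark_noise(
      if (config$magnification == 1) lm2d_true
      else project_lateral(skull), config$noise_sd)
    skull
  })
}

#' Generate a cohort of synthetic skulls
#'
#' Draws `n` skulls with independent placement-noise realizations and
#' (optionally) between-subject variation of the planted part lengths
#' (`config$length_sd`, Gaussian, truncated to stay positive).
#'
#' @param n Number of subjects (>= 1).
#' @param config Base `"skull_config"`; its `seed` field is ignored in
#'   favour of per-subject seeds derived from `seed`.
#' @param seed Integer seed for the whole cohort; identical `(config,
#'   seed)` pairs give identical cohorts.
#' @return A list of `"synthetic_skull"` objects, class `"skull_cohort"`,
#'   with subjects `"S01"`, `"S02"`, ...
#' @export
generate_cohort <- function(n, config = skull_config(), seed = NULL) {
  stopifnot(inherits(config, "skull_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_validation("n must be a positive integer")
  n <- as.integer(n)
  .with_seed(seed, {
    subject_seeds <- sample.int(.Machine$integer.max, n)
    sdv <- .merge_named(stats::setNames(rep(if (length(config$length_sd) == 1L)
      config$length_sd else 0, length(.default_lengths)),
      names(.default_lengths)),
      if (length(config$length_sd) > 1L) config$length_sd else NULL,
      "length")
    skulls <- vector("list", n)
    for (i in seq_len(n)) {
      cfg_i <- config
      repeat {
        lens <- config$lengths + stats::rnorm(length(config$lengths), 0,
                                              sdv[names(config$lengths)])
        if (all(lens > 1)) break
      }
      cfg_i$lengths <- lens
      cfg_i$seed <- subject_seeds[i]
      skulls[[i]] <- generate_skull(cfg_i, subject = sprintf("S%02d", i))
    }
    structure(skulls, class = "skull_cohort")
  })
}

#' Analyze a synthetic cohort in 2D and 3D
#'
#' Runs the full 2D and 3D horizontal counterpart analyses on every skull's
#' observed (noisy) landmark sets and returns the paired discrepancy
#' reports, ready for [cohort_summary()].
#'
#' @param cohort A `"skull_cohort"` (or plain list of `"synthetic_skull"`).
#' @param threshold Harmony threshold in mm.
#' @param ramus Ramus side convention for the 3D MCF-ramus index.
#' @return A list with fields `reports_2d` and `reports_3d`.
#' @export
cohort_reports <- function(cohort, threshold = 2.5,
                           ramus = c("right", "left", "mean")) {
  ramus <- match.arg(ramus)
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  r2 <- lapply(cohort, function(sk)
    discrepancies(analyze2d(sk$lm2d)$measurements, threshold = threshold))
  r3 <- lapply(cohort, function(sk)
    discrepancies(analyze3d(sk$lm3d)$measurements, threshold = threshold,
                  ramus = ramus))
  list(reports_2d = r2, reports_3d = r3)
}

#' @export
print.synthetic_skull <- function(x, ...) {
  cat(sprintf("<synthetic_skull> subject '%s', noise SD %g mm, seed %s\n",
              x$lm3d_true$subject, x$config$noise_sd,
              if (is.null(x$seed)) "none" else x$seed))
  cat("planted 3D lengths (mm):\n")
  print(round(unclass(x$truth3d), 3))
  invisible(x)
}

#' @export
print.skull_cohort <- function(x, ...) {
  cat(sprintf("<skull_cohort> %d synthetic subjects\n", length(x)))
  invisible(x)
}
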