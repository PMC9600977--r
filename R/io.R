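# Landmark file readers/writers (CSV, JSON, 3D Slicer FCSV), report export
# and run configuration.
#
# CSV landmark dialect: header `name,laterality,x,y[,z]`, mm, UTF-8,
# '.' decimal; chosen for hand-editability.
# FCSV: the 3D Slicer markups-fiducial dialect (comma-separated, with a
# `# Markups fiducial file` header); landmark names are taken from the
# `label` column, and the `# CoordinateSystem` header (RAS or LPS) is
# honoured. The canonical anatomical frame of this package coincides with
# RAS, so LPS coordinates have their x and y signs flipped on input.

#' Read a landmark file
#'
#' @param path Path to a CSV, JSON or FCSV landmark file.
#' @param format File format; `"auto"` (default) infers it from the file
#'   extension and header.
#' @param scale Optional scale factor (mm per stored unit) applied to 2D
#'   sets at load time.
#' @return A `"landmarks2d"` or `"landmarks3d"` object, depending on the
#'   file's dimensionality (FCSV is always 3D).
#' @examples
#' lm2 <- read_landmarks(system.file("extdata", "example_2d.csv",
#'                                   package = "counterpart3d"))
#' analyze2d(lm2)$measurements
#' lm3 <- read_landmarks(system.file("extdata", "example_3d.fcsv",
#'                                   package = "counterpart3d"))
#' analyze3d(lm3)$measurements
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json", "fcsv"),
                           scale = 1) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_validation(paste0("landmark file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (ext == "fcsv" || grepl("^# Markups fiducial file", first)) "fcsv"
      else if (ext == "json") "json"
      else "csv"
  }
  switch(format,
         csv = .read_landmarks_csv(path, scale),
         json = .read_landmarks_json(path, scale),
         fcsv = .read_landmarks_fcsv(path))
}

.finish_set <- function(df, d, subject, unit, scale, path) {
  dup <- unique(df$name[duplicated(df$name)])
  if (length(dup))
    stop_validation(paste0("duplicate landmark label(s) in ", path, ": ",
                           paste(dup, collapse = ", ")))
  m <- as.matrix(df[, c("x", "y", "z")[seq_len(d)], drop = FALSE])
  rownames(m) <- df$name
  if (d == 2L) landmarks2d(m, subject = subject, scale = scale, unit = unit)
  else landmarks3d(m, subject = subject, unit = unit)
}

.read_landmarks_csv <- function(path, scale) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_validation(
                   paste0("cannot parse CSV landmark file ", path, ": ",
                          conditionMessage(e))))
  if (!all(c("name", "x", "y") %in% names(df)))
    stop_validation(paste0(path, ": CSV landmark files need columns name,x,y[,z] ",
                           "(line 1 is the header)"))
  d <- if ("z" %in% names(df)) 3L else 2L
  axes <- c("x", "y", "z")[seq_len(d)]
  df[axes] <- lapply(df[axes], function(col) suppressWarnings(as.numeric(col)))
  bad <- which(!stats::complete.cases(df[, axes]))
  if (length(bad))
    stop_validation(paste0(path, ": non-numeric or missing coordinates on line(s) ",
                           paste(bad + 1L, collapse = ", ")))
  subject <- if ("subject" %in% names(df)) as.character(df$subject[1L]) else
    tools::file_path_sans_ext(basename(path))
  .finish_set(df, d, subject, "mm", scale, path)
}

.read_landmarks_json <- function(path, scale) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_validation(
                    paste0("cannot parse JSON landmark file ", path, ": ",
                           conditionMessage(e))))
  if (is.null(obj$landmarks))
    stop_validation(paste0(path, ": JSON landmark files need a 'landmarks' array"))
  df <- as.data.frame(obj$landmarks, stringsAsFactors = FALSE)
  d <- if (!is.null(df$z)) 3L else 2L
  unit <- if (!is.null(obj$unit)) obj$unit else "mm"
  if (!identical(unit, "mm") && !identical(unit, "cm"))
    stop_validation(paste0(path, ": ambiguous unit '", unit,
                           "'; landmark files must declare mm or cm"))
  f <- if (identical(unit, "cm")) 10 else 1
  df$x <- df$x * f; df$y <- df$y * f
  if (d == 3L) df$z <- df$z * f
  subject <- if (!is.null(obj$subject)) obj$subject else
    tools::file_path_sans_ext(basename(path))
  .finish_set(df, d, subject, "mm", scale, path)
}

.read_landmarks_fcsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  if (!length(header) || !grepl("Markups fiducial file", header[1L]))
    stop_validation(paste0(path, ": not a Markups fiducial (FCSV) file ",
                           "(missing '# Markups fiducial file' header on line 1)"))
  cs <- "RAS"
  cs_line <- grep("CoordinateSystem", header, value = TRUE)
  if (length(cs_line)) {
    val <- trimws(sub(".*=", "", cs_line[1L]))
    cs <- switch(val, "0" = "RAS", "1" = "LPS", RAS = "RAS", LPS = "LPS",
                 stop_validation(paste0(path, ": unsupported CoordinateSystem '",
                                        val, "' (expected RAS or LPS)")))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body))
    stop_validation(paste0(path, ": no fiducial records"))
  df <- utils::read.csv(text = body, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L)
    stop_validation(paste0(path, ": FCSV records need at least 12 columns ",
                           "(id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,...)"))
  out <- data.frame(name = as.character(df[[12L]]),
                    x = as.numeric(df[[2L]]), y = as.numeric(df[[3L]]),
                    z = as.numeric(df[[4L]]), stringsAsFactors = FALSE)
  bad <- which(!stats::complete.cases(out))
  if (length(bad))
    stop_validation(paste0(path, ": non-numeric coordinates in record(s) ",
                           paste(bad, collapse = ", ")))
  if (cs == "LPS") {  # LPS -> RAS: flip x (L->R) and y (P->A)
    out$x <- -out$x
    out$y <- -out$y
  }
  .finish_set(out, 3L, tools::file_path_sans_ext(basename(path)), "mm", 1, path)
}

#' Write a landmark set to file
#'
#' @param lm A `"landmarks2d"` or `"landmarks3d"` set.
#' @param path Output path.
#' @param format `"csv"` (default), `"json"`, or `"fcsv"` (3D sets only;
#'   written with an RAS `CoordinateSystem` header).
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(lm, path, format = c("csv", "json", "fcsv")) {
  stopifnot(inherits(lm, "landmark_set"))
  format <- match.arg(format)
  df <- as.data.frame(lm)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(list(subject = lm$subject, unit = lm$unit,
                              landmarks = df),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (!inherits(lm, "landmarks3d"))
      stop_validation("FCSV output is defined for 3D landmark sets only")
    recs <- sprintf("vtkMRMLMarkupsFiducialNode_%d,%.10g,%.10g,%.10g,0,0,0,1,1,1,0,%s,,",
                    seq_len(nrow(df)) - 1L, df$x, df$y, df$z, df$name)
    writeLines(c("# Markups fiducial file version = 4.11",
                 "# CoordinateSystem = RAS",
                 "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
                 recs), path)
  }
  invisible(path)
}

.plane_to_list <- function(pl)
  list(anchor = pl$anchor, normal = pl$normal, provenance = pl$provenance)

.report_to_list <- function(report) {
  if (inherits(report, "ceph2d_analysis")) {
    fr <- report$frame
    line_to_list <- function(l) list(anchor = l$anchor, direction = l$direction)
    list(type = "ceph2d_analysis",
         subject = report$landmarks$subject,
         landmarks = as.data.frame(report$landmarks),
         frame = list(fop = line_to_list(fr$fop), ref = line_to_list(fr$ref),
                      pm_line = line_to_list(fr$pm_line),
                      pra = line_to_list(fr$pra), ara = line_to_list(fr$ara),
                      go = fr$go, pm_ref = fr$pm_ref, ara_ref = fr$ara_ref),
         measurements_mm = as.list(unclass(report$measurements)))
  } else if (inherits(report, "ceph3d_analysis")) {
    list(type = "ceph3d_analysis",
         subject = report$landmarks$subject,
         landmarks = as.data.frame(report$landmarks),
         orientation = list(rotation = report$frame$rotation,
                            translation = report$frame$translation),
         planes = lapply(report$planes, .plane_to_list),
         measurements_mm = as.list(unclass(report$measurements)))
  } else if (inherits(report, "discrepancy_report")) {
    list(type = "discrepancy_report", subject = report$subject,
         dimension = report$dimension, threshold_mm = report$threshold,
         ramus = report$ramus, values_mm = as.list(report$values),
         harmony = as.list(report$harmony))
  } else if (inherits(report, "cohort_table")) {
    list(type = "cohort_table", units = attr(report, "units"),
         alpha = attr(report, "alpha"), table = as.data.frame(report))
  } else {
    stop_validation("unsupported report object")
  }
}

#' Write an analysis report
#'
#' JSON output carries full provenance (landmarks, constructed lines or
#' planes as anchor + normal, orientation, configuration); CSV is the flat
#' cohort-table layout (one row per index: 2D mean and SD, 3D mean and SD,
#' paired-t p-value), available for `"cohort_table"` objects.
#'
#' @param report A `"ceph2d_analysis"`, `"ceph3d_analysis"`,
#'   `"discrepancy_report"` or `"cohort_table"` object.
#' @param path Output path.
#' @param format `"json"` (default) or `"csv"` (cohort tables only).
#' @param config Optional run configuration ([run_config()]) echoed into the
#'   JSON report for provenance.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("json", "csv"),
                         config = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!inherits(report, "cohort_table"))
      stop_validation("CSV report output is defined for cohort tables only")
    df <- as.data.frame(report)
    unit <- attr(report, "units")
    names(df) <- sub("^(mean|sd)_(2d|3d)$", paste0("\\1_\\2_", unit), names(df))
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  obj <- .report_to_list(report)
  if (!is.null(config)) {
    obj$config <- unclass(config)
    obj$config_hash <- .config_hash(config)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a JSON discrepancy report
#'
#' Reconstructs a `"discrepancy_report"` written by [write_report()], e.g.
#' to assemble a cohort comparison from per-subject report files.
#'
#' @param path Path to a JSON report of type `discrepancy_report`.
#' @return A `"discrepancy_report"` object.
#' @export
read_discrepancy_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "discrepancy_report"))
    stop_validation(paste0(path, ": not a discrepancy_report JSON file"))
  structure(list(values = unlist(obj$values_mm),
                 harmony = unlist(obj$harmony),
                 dimension = obj$dimension, subject = obj$subject,
                 threshold = obj$threshold_mm, ramus = obj$ramus),
            class = "discrepancy_report")
}

.config_hash <- function(config) {
  # small order-stable fingerprint; no external digest dependency
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 997 + 1)) %% 2^31
}

#' Run configuration
#'
#' Bundles the knobs shared by the pipeline: harmony threshold,
#' significance level, ramus side convention, report units, geometry
#' tolerance and seed. Serialized into every JSON report for provenance;
#' can be read from a YAML file with [read_run_config()], with individual
#' fields overridable.
#'
#' @param threshold Harmony threshold in mm (default 2.5).
#' @param alpha Significance level (default 0.05).
#' @param ramus Ramus side convention for the 3D MCF-ramus index.
#' @param units Report units, `"mm"` or `"cm"`.
#' @param geometry_tol Point tolerance in mm for degeneracy checks.
#' @param seed Optional integer seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(threshold = 2.5, alpha = 0.05,
                       ramus = c("right", "left", "mean"),
                       units = c("mm", "cm"), geometry_tol = 1e-9,
                       seed = NULL) {
  structure(list(threshold = threshold, alpha = alpha,
                 ramus = match.arg(ramus), units = match.arg(units),
                 geometry_tol = geometry_tol, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file whose keys mirror the [run_config()]
#'   arguments.
#' @param ... Overrides applied on top of the file's values.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_validation(paste0(path, ": unknown configuration key(s): ",
                           paste(bad, collapse = ", ")))
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}
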