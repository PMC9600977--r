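# Named landmark sets. Coordinates are stored as an n x 2 or n x 3 matrix
# with landmark names as rownames; everything downstream addresses points
# by name. Axis conventions:
#   2D: x posterior -> anterior (+), y inferior -> superior (+)
#   3D: x left -> right (+), y posterior -> anterior (+), z inferior -> superior (+)
# The 3D convention coincides with the RAS convention of 3D Slicer.

#' Landmark dictionaries
#'
#' Required landmark names for a full 2D or 3D horizontal counterpart
#' analysis, and the laterality of the bilateral 3D landmarks.
#'
#' The 2D set contains the classical lateral-cephalogram points (Ar, Me, SE,
#' PTM, Poc, Aoc, A, SPr, IPr, B, LT) plus three auxiliary tangent landmarks
#' that stand in for outline information a tracing provides but a coordinate
#' file cannot: `corpus_lowest` (lower-most point of the mandibular corpus)
#' and `ramus_posterior_most` (posterior-most point of the ramus), which feed
#' the gonion construction, and `pra_fop_point` (the point where the
#' functional occlusal plane meets the posterior ramus margin), which anchors
#' the posterior ramus alignment. Gonion itself is constructed, never input.
#'
#' The 3D set is purely anatomical: basion, both condylia, both lingual
#' tuberosities (apex of the retromolar triangle), A, B, superior and
#' inferior prosthion, the posterior nasal spine and both anterior clinoid
#' processes.
#'
#' @format Character vectors of landmark names; `laterality_3d` is a named
#'   character vector mapping bilateral 3D landmark names to
#'   `"right"`/`"left"`.
#' @name landmark_dictionary
NULL

#' @rdname landmark_dictionary
#' @export
required_landmarks_2d <- c("Ar", "Me", "SE", "PTM", "Poc", "Aoc", "A", "SPr",
                           "IPr", "B", "LT",
                           "corpus_lowest", "ramus_posterior_most", "pra_fop_point")

#' @rdname landmark_dictionary
#' @export
required_landmarks_3d <- c("Ba", "rCo", "lCo", "rLT", "lLT", "A", "B",
                           "SPr", "IPr", "PNS", "r_clinoid", "l_clinoid")

#' @rdname landmark_dictionary
#' @export
laterality_3d <- c(rCo = "right", lCo = "left",
                   rLT = "right", lLT = "left",
                   r_clinoid = "right", l_clinoid = "left")

.coerce_coords <- function(coords, d) {
  if (is.data.frame(coords)) {
    nm <- if (!is.null(coords$name)) as.character(coords$name) else rownames(coords)
    cols <- intersect(c("x", "y", "z")[seq_len(d)], names(coords))
    if (length(cols) == d) {
      m <- as.matrix(coords[, cols, drop = FALSE])
    } else {
      m <- as.matrix(coords[, vapply(coords, is.numeric, logical(1L)), drop = FALSE])
    }
    rownames(m) <- nm
    coords <- m
  } else if (is.list(coords)) {
    coords <- do.call(rbind, coords)
  }
  if (!is.matrix(coords) || !is.numeric(coords) || ncol(coords) != d)
    stop_validation(sprintf("landmark coordinates must form an n x %d numeric matrix", d))
  if (is.null(rownames(coords)) || anyNA(rownames(coords)) || any(rownames(coords) == ""))
    stop_validation("every landmark must be named (matrix rownames or a 'name' column)")
  dup <- unique(rownames(coords)[duplicated(rownames(coords))])
  if (length(dup))
    stop_validation(paste0("duplicate landmark name(s): ", paste(dup, collapse = ", ")))
  colnames(coords) <- c("x", "y", "z")[seq_len(d)]
  coords
}

.new_landmarks <- function(coords, d, subject, unit, cls, scale = 1) {
  coords <- .coerce_coords(coords, d) * scale
  if (!all(is.finite(coords)))
    stop_validation(paste0("non-finite coordinates for landmark(s): ",
                           paste(rownames(coords)[!apply(is.finite(coords), 1L, all)],
                                 collapse = ", ")))
  structure(list(coords = coords, subject = subject, unit = unit),
            class = c(cls, "landmark_set"))
}

#' Create a 2D lateral-cephalogram landmark set
#'
#' @param coords An n x 2 numeric matrix with landmark names as rownames, a
#'   data frame with columns `name`, `x`, `y`, or a named list of length-2
#'   points. Axis convention: x posterior to anterior, y inferior to superior.
#' @param subject Subject identifier.
#' @param scale Optional source-image scale factor (mm per stored unit),
#'   applied at construction; use e.g. `1/1.1` to undo a 10 % cephalostat
#'   magnification.
#' @param unit Unit label after scaling (always millimetres for analysis).
#' @return An object of class `"landmarks2d"`.
#' @seealso [required_landmarks_2d], [validate_landmarks()]
#' @export
landmarks2d <- function(coords, subject = "", scale = 1, unit = "mm") {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale), scale > 0)
  .new_landmarks(coords, 2L, subject, unit, "landmarks2d", scale)
}

#' Create a 3D CBCT landmark set
#'
#' @param coords An n x 3 numeric matrix with landmark names as rownames, a
#'   data frame with columns `name`, `x`, `y`, `z`, or a named list of
#'   length-3 points. Axis convention (RAS): x left to right, y posterior to
#'   anterior, z inferior to superior. Coordinates must already be in mm
#'   (voxel indices are converted upstream).
#' @param subject Subject identifier.
#' @param unit Unit label.
#' @return An object of class `"landmarks3d"`.
#' @seealso [required_landmarks_3d], [validate_landmarks()]
#' @export
landmarks3d <- function(coords, subject = "", unit = "mm") {
  .new_landmarks(coords, 3L, subject, unit, "landmarks3d")
}

#' Validate a landmark set against its dictionary
#'
#' Checks that every landmark required for a full analysis is present and
#' finite; unknown names produce a warning (they are carried along but take
#' no part in any construction).
#'
#' @param lm A `"landmarks2d"` or `"landmarks3d"` object.
#' @param complete If `TRUE` (default) missing required landmarks are an
#'   error; if `FALSE` they are returned.
#' @return Invisibly, a list with character vectors `missing` and `unknown`.
#' @export
validate_landmarks <- function(lm, complete = TRUE) {
  stopifnot(inherits(lm, "landmark_set"))
  dict <- if (inherits(lm, "landmarks2d")) required_landmarks_2d else required_landmarks_3d
  have <- rownames(lm$coords)
  missing <- setdiff(dict, have)
  unknown <- setdiff(have, dict)
  if (length(unknown))
    warning(paste0("unknown landmark name(s), ignored by the analysis: ",
                   paste(unknown, collapse = ", ")), call. = FALSE)
  if (complete && length(missing))
    stop_validation(paste0("missing required landmark(s): ",
                           paste(missing, collapse = ", ")))
  invisible(list(missing = missing, unknown = unknown))
}

# internal point accessor: errors with the landmark's name
.lmk <- function(lm, name) {
  i <- match(name, rownames(lm$coords))
  if (is.na(i))
    stop_validation(paste0("landmark '", name, "' is missing from the set"))
  unname(lm$coords[i, ])
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- ncol(x$coords)
  cat(sprintf("<%s> %d landmarks, subject '%s', unit %s\n",
              class(x)[1L], nrow(x$coords), x$subject, x$unit))
  print(round(x$coords, 4))
  invisible(x)
}

#' @export
as.data.frame.landmark_set <- function(x, ...) {
  df <- data.frame(name = rownames(x$coords), x$coords, row.names = NULL,
                   stringsAsFactors = FALSE)
  if (inherits(x, "landmarks3d")) {
    df$laterality <- unname(laterality_3d[df$name])
    df$laterality[is.na(df$laterality)] <- "midline"
  }
  df
}
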