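#' Read a parcellated BOLD time series
#'
#' One row per frame, one column per ROI, tab-delimited. An optional
#' header row of ROI ids is accepted and checked against the
#' parcellation; without a header, column order is taken to be ROI
#' order `1..n_rois`.
#'
#' @param path Path to the TSV file.
#' @param parcellation A [parcellation()] the columns must match.
#' @param tr_seconds Repetition time in seconds. The acquisition TR is
#'   not recoverable from a text matrix and there is no safe default,
#'   so it is a required argument.
#' @param scan_id,subject_id Identifiers stored on the object.
#' @return A `scan_timeseries`: list with `data` (frames x ROIs
#'   matrix), `tr_seconds`, `scan_id`, `subject_id`.
#' @export
read_timeseries <- function(path, parcellation, tr_seconds,
                            scan_id = basename(path), subject_id = NA_character_) {
  stopifnot(inherits(parcellation, "parcellation"))
  first <- readLines(path, n = 1L)
  tokens <- strsplit(trimws(first), "[\t ]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(tokens)))) ||
    identical(tokens, as.character(seq_along(tokens)))
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           colClasses = "numeric",
                           check.names = FALSE)
  mat <- as.matrix(tab)
  if (has_header) {
    ids <- suppressWarnings(as.integer(colnames(mat)))
    if (anyNA(ids) || !identical(ids, seq_len(n_rois(parcellation)))) {
      stop("time-series header does not list roi ids 1..",
           n_rois(parcellation), ": ", path)
    }
  }
  if (ncol(mat) != n_rois(parcellation)) {
    stop(sprintf("time series has %d columns but parcellation has %d ROIs: %s",
                 ncol(mat), n_rois(parcellation), path))
  }
  if (anyNA(mat) || any(!is.finite(mat))) {
    stop("non-numeric or non-finite cell in time series: ", path)
  }
  scan_timeseries(mat, tr_seconds, scan_id = scan_id, subject_id = subject_id)
}

#' @rdname read_timeseries
#' @param data Frames x ROIs numeric matrix.
#' @export
scan_timeseries <- function(data, tr_seconds, scan_id = NA_character_,
                            subject_id = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) stop("a scan needs at least 2 frames")
  if (any(!is.finite(data))) stop("time series contains non-finite values")
  if (length(tr_seconds) != 1L || !is.finite(tr_seconds) || tr_seconds <= 0) {
    stop("tr_seconds must be a single positive number")
  }
  structure(
    list(data = data, tr_seconds = as.numeric(tr_seconds),
         scan_id = scan_id, subject_id = subject_id),
    class = "scan_timeseries"
  )
}

#' Write a time series as TSV with an roi-id header
#'
#' @param ts A `scan_timeseries`.
#' @param path Output path.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "scan_timeseries"))
  mat <- ts$data
  colnames(mat) <- seq_len(ncol(mat))
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read realignment parameters
#'
#' Whitespace-delimited text, exactly 6 numeric columns per frame:
#' translations x, y, z in mm, then three rotations. Rotations are
#' radians by default; pass `rotation_units = "degrees"` for the other
#' common dialect (converted to radians on read).
#'
#' @param path Path to the motion file.
#' @param rotation_units `"radians"` (default) or `"degrees"`.
#' @return A `motion_trace`: frames x 6 numeric matrix with columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z` (mm / radians).
#' @export
read_motion <- function(path, rotation_units = c("radians", "degrees")) {
  rotation_units <- match.arg(rotation_units)
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) != 6L) {
    stop(sprintf("motion file must have exactly 6 columns, found %d: %s",
                 ncol(tab), path))
  }
  mat <- as.matrix(tab)
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat))) stop("non-finite realignment parameter: ", path)
  if (rotation_units == "degrees") {
    mat[, 4:6] <- mat[, 4:6] * pi / 180
  }
  motion_trace(mat)
}

#' @rdname read_motion
#' @param params Frames x 6 numeric matrix (mm, radians).
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  storage.mode(params) <- "double"
  if (ncol(params) != 6L) stop("motion trace must have 6 columns")
  if (nrow(params) < 1L) stop("motion trace must have at least 1 frame")
  if (any(!is.finite(params))) stop("motion trace contains non-finite values")
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(params, class = c("motion_trace", "matrix", "array"))
}

#' Check that a scan's time series and motion trace agree
#'
#' @param ts A `scan_timeseries`.
#' @param motion A `motion_trace`.
#' @return Invisibly `TRUE`; errors on frame-count mismatch.
#' @export
check_frames_match <- function(ts, motion) {
  stopifnot(inherits(ts, "scan_timeseries"), inherits(motion, "motion_trace"))
  if (nrow(ts$data) != nrow(motion)) {
    stop(sprintf(
      "frame-count mismatch for scan %s: %d time-series frames vs %d motion frames",
      ts$scan_id, nrow(ts$data), nrow(motion)))
  }
  invisible(TRUE)
}

# canonical labels used throughout the analysis tables
.group_levels <- c("control", "ADHD")
.sex_levels <- c("M", "F")

normalize_group <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("control", "td", "typical", "con")] <- "control"
  out[key == "adhd"] <- "ADHD"
  if (anyNA(out)) {
    stop("unrecognized group label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  factor(out, levels = .group_levels)
}

normalize_sex <- function(x) {
  key <- toupper(substr(trimws(as.character(x)), 1L, 1L))
  if (any(!key %in% .sex_levels)) {
    stop("unrecognized sex label(s): ",
         paste(unique(x[!key %in% .sex_levels]), collapse = ", "))
  }
  factor(key, levels = .sex_levels)
}

#' Read a phenotype table
#'
#' CSV with at least `subject_id`, `wave`, `group`, `sex`, `age`.
#' Group and sex labels are normalized to the canonical
#' `control`/`ADHD` and `M`/`F` factors regardless of case. One row
#' per scan; a duplicated (subject_id, wave) key is an integrity
#' error.
#'
#' @param path CSV path.
#' @return A data frame of scan-record stubs, one row per scan.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "wave", "group", "sex", "age")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(tab$subject_id, tab$wave, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), c("subject_id", "wave"), drop = FALSE]
    stop("duplicate (subject_id, wave) scan key: ",
         paste(paste(dup$subject_id, dup$wave, sep = "/"), collapse = ", "))
  }
  tab$group <- normalize_group(tab$group)
  tab$sex <- normalize_sex(tab$sex)
  tab$age <- as.numeric(tab$age)
  if (anyNA(tab$age)) stop("non-numeric age in phenotype table")
  tab
}

#' Write an analysis record table as CSV
#'
#' @param records Data frame of per-scan analysis rows.
#' @param path Output CSV path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read/write a connectivity matrix as TSV
#'
#' Matrices are written with an roi-id header; the undefined diagonal
#' is stored as `NA`.
#'
#' @param mat Square numeric matrix (Fisher-z values).
#' @param path File path.
#' @return `read_matrix` returns the matrix with `NA` diagonal.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  out <- mat
  colnames(out) <- seq_len(ncol(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(tab)
  storage.mode(mat) <- "double"
  dimnames(mat) <- NULL
  if (nrow(mat) != ncol(mat)) stop("matrix file is not square: ", path)
  mat
}
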