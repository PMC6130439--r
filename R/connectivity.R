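#' Per-scan Fisher-z connectivity matrix
#'
#' Pearson-correlates every ROI pair over the retained frames and
#' applies the Fisher variance-stabilizing transform `z = atanh(r)`.
#' One frame set is used for all pairs (frame selection is scan-level,
#' never pair-level). The diagonal is undefined after the transform
#' and is stored as `NA`.
#'
#' Perfect correlations (`|r| = 1`, which essentially never arise on
#' real-valued BOLD data) would map to infinite z; they are capped at
#' `atanh(1 - 1e-7)` with a warning. A constant ROI has no defined
#' correlation: its row/column is `NA` and a warning names the scan.
#'
#' @param ts A `scan_timeseries`.
#' @param mask Logical frame mask of retained frames (default: all).
#' @return `n_rois` x `n_rois` symmetric matrix of Fisher-z values
#'   with `NA` diagonal.
#' @examples
#' ts <- scan_timeseries(matrix(rnorm(40), 10, 4), tr_seconds = 2)
#' z <- correlation_matrix(ts)
#' @export
correlation_matrix <- function(ts, mask = rep(TRUE, nrow(ts$data))) {
  stopifnot(inherits(ts, "scan_timeseries"), is.logical(mask),
            length(mask) == nrow(ts$data))
  x <- ts$data[mask, , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 retained frames, got ", nrow(x))
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning(sprintf("scan %s: %d constant ROI(s) have undefined correlations",
                    ts$scan_id, sum(constant)))
  }
  r <- suppressWarnings(stats::cor(x))
  cap <- 1 - 1e-7
  over <- is.finite(r) & abs(r) >= 1
  over[row(r) == col(r)] <- FALSE
  if (any(over)) {
    warning(sprintf("scan %s: %d perfect correlation(s) capped at |r| = 1 - 1e-7",
                    ts$scan_id, sum(over) / 2))
    r[over] <- sign(r[over]) * cap
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  z
}
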