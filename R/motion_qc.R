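# Seed hygiene: functions that consume randomness take an explicit
# seed and restore the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Framewise displacement
#'
#' FD at frame *t* is the sum of absolute backward differences of the
#' six realignment parameters, with rotations converted to arc length
#' on a sphere of radius `head_radius_mm` (the conventional 50 mm head
#' model): `FD_t = sum(|d trans|) + head_radius_mm * sum(|d rot|)`.
#' The first frame has no predecessor and is assigned FD = 0.
#'
#' @param trace A `motion_trace` (see [read_motion()]).
#' @param head_radius_mm Sphere radius used for the rotation-to-mm
#'   conversion; default 50.
#' @return An `fd_series`: numeric vector of per-frame FD in mm, with
#'   attribute `head_radius_mm`.
#' @examples
#' m <- motion_trace(rbind(rep(0, 6), c(0.1, 0.1, 0.1, 0, 0, 0)))
#' compute_fd(m)  # 0, 0.3
#' @export
compute_fd <- function(trace, head_radius_mm = 50) {
  stopifnot(inherits(trace, "motion_trace"))
  if (any(!is.finite(trace))) stop("non-finite realignment parameters")
  d <- abs(diff(trace))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  structure(fd, head_radius_mm = head_radius_mm, class = "fd_series")
}

#' Censor frames by FD threshold
#'
#' Frames whose FD *exceeds* the threshold are dropped: the comparison
#' is strict, so a frame exactly at the threshold is kept.
#'
#' @param fd An `fd_series` (or numeric FD vector).
#' @param threshold_mm Censoring threshold in mm; default 0.2.
#' @return Logical keep-flag per frame (a frame mask).
#' @export
censor_frames <- function(fd, threshold_mm = 0.2) {
  as.vector(fd <= threshold_mm)
}

#' Minutes of data retained by a frame mask
#'
#' @param mask Logical frame mask.
#' @param tr_seconds Repetition time in seconds.
#' @return Minutes of retained data.
#' @export
minutes_kept <- function(mask, tr_seconds) {
  sum(mask) * tr_seconds / 60
}

#' Select a fixed duration of clean frames at random
#'
#' To equate the amount of data entering every connectivity matrix,
#' exactly `ceiling(target_minutes * 60 / tr_seconds)` frames are
#' sampled uniformly without replacement from the frames the censoring
#' mask kept. Eligibility is strict: a scan must retain *more than*
#' `target_minutes` of clean data, otherwise it is excluded (returned
#' as `NULL`, with the shortfall in the `"reason"` attribute carried
#' by a zero-length result -- see Value).
#'
#' @param mask Logical frame mask after censoring.
#' @param tr_seconds Repetition time in seconds.
#' @param target_minutes Minutes of data to select; default 4.
#' @param seed Integer seed making the selection reproducible.
#' @return A logical frame mask with exactly the target number of
#'   `TRUE` entries, or `NULL` when the scan is ineligible
#'   (insufficient clean data). Ineligibility is a recorded signal,
#'   not an error, so batch processing can continue.
#' @export
select_clean_frames <- function(mask, tr_seconds, target_minutes = 4, seed) {
  stopifnot(is.logical(mask))
  if (minutes_kept(mask, tr_seconds) <= target_minutes) {
    return(NULL)
  }
  n_target <- as.integer(ceiling(target_minutes * 60 / tr_seconds))
  kept <- which(mask)
  pick <- with_seed(seed, sort(sample(kept, n_target)))
  out <- rep(FALSE, length(mask))
  out[pick] <- TRUE
  out
}

#' Mean FD over retained frames
#'
#' @param fd Numeric FD vector.
#' @param mask Logical frame mask (default: all frames).
#' @return Mean FD in mm.
#' @export
mean_fd <- function(fd, mask = rep(TRUE, length(fd))) {
  mean(as.vector(fd)[mask])
}

#' Secondary scan-level FD-connectivity quality control
#'
#' After frame-level censoring, a residual across-scan association
#' between mean FD and the averaged negative-connectivity metric
#' indicates motion leakage. This step iteratively removes the scan
#' whose deletion most reduces the absolute Pearson correlation
#' between `mean_fd` and `avg_neg_conn` (leave-one-out influence),
#' until the association is non-significant at `alpha` or
#' `max_removed` scans have been dropped. The removal criterion is a
#' documented, configurable package choice.
#'
#' @param records Data frame with numeric `mean_fd` and `avg_neg_conn`
#'   columns and a `scan_id` column.
#' @param alpha Significance level for the stopping rule; default 0.05.
#' @param max_removed Maximum number of scans to remove.
#' @return List with `removed` (scan ids in removal order), `p_value`
#'   and `r` of the final FD-connectivity correlation, and `n_final`.
#' @export
secondary_fd_qc <- function(records, alpha = 0.05, max_removed = 30L) {
  stopifnot(all(c("scan_id", "mean_fd", "avg_neg_conn") %in% names(records)))
  if (nrow(records) < 10L) {
    stop("secondary FD QC needs at least 10 scans, got ", nrow(records))
  }
  if (max_removed <= 0L) {
    warning("max_removed is 0; secondary FD QC removed nothing")
  }
  keep <- records
  removed <- character(0)
  ct <- stats::cor.test(keep$mean_fd, keep$avg_neg_conn)
  while (ct$p.value < alpha && length(removed) < max_removed &&
         nrow(keep) > 10L) {
    loo <- vapply(seq_len(nrow(keep)), function(i) {
      abs(stats::cor(keep$mean_fd[-i], keep$avg_neg_conn[-i]))
    }, numeric(1))
    drop_i <- which.min(loo)
    removed <- c(removed, keep$scan_id[drop_i])
    keep <- keep[-drop_i, , drop = FALSE]
    ct <- stats::cor.test(keep$mean_fd, keep$avg_neg_conn)
  }
  list(removed = removed,
       r = unname(ct$estimate),
       p_value = ct$p.value,
       n_final = nrow(keep))
}
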