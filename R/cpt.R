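#' Count responses in an identical-pairs CPT trial log
#'
#' The task presents `target` trials (identical back-to-back stimuli,
#' respond), `stim` trials (clearly different, easy rejection) and
#' `catch` trials (off by one digit, difficult rejection). The default
#' design is 300 trials at 20% targets, 20% catch, 60% stim.
#'
#' @param trials Data frame with columns `type` (one of `target`,
#'   `stim`, `catch`) and `responded` (0/1). A `trial_index` column is
#'   accepted and ignored: scoring depends on counts only.
#' @return A `cpt_counts` list: `n_target`, `n_hit`, `n_stim`,
#'   `n_fa_easy`, `n_catch`, `n_fa_difficult`.
#' @export
count_cpt_trials <- function(trials) {
  stopifnot(all(c("type", "responded") %in% names(trials)))
  type <- as.character(trials$type)
  if (!all(type %in% c("target", "stim", "catch"))) {
    stop("trial type must be one of target/stim/catch")
  }
  resp <- as.integer(trials$responded)
  stopifnot(all(resp %in% c(0L, 1L)))
  cpt_counts(
    n_target = sum(type == "target"),
    n_hit = sum(resp[type == "target"]),
    n_stim = sum(type == "stim"),
    n_fa_easy = sum(resp[type == "stim"]),
    n_catch = sum(type == "catch"),
    n_fa_difficult = sum(resp[type == "catch"])
  )
}

#' @rdname count_cpt_trials
#' @param n_target,n_hit,n_stim,n_fa_easy,n_catch,n_fa_difficult
#'   Trial and response counts per trial type.
#' @export
cpt_counts <- function(n_target, n_hit, n_stim, n_fa_easy,
                       n_catch, n_fa_difficult) {
  out <- list(n_target = n_target, n_hit = n_hit,
              n_stim = n_stim, n_fa_easy = n_fa_easy,
              n_catch = n_catch, n_fa_difficult = n_fa_difficult)
  if (any(unlist(out) < 0)) stop("counts must be non-negative")
  if (n_hit > n_target || n_fa_easy > n_stim || n_fa_difficult > n_catch) {
    stop("response count exceeds its trial count")
  }
  class(out) <- "cpt_counts"
  out
}

# A raw rate of 0 or 1 has an infinite normal quantile; the half-count
# rule conditionally adds 0.5 to the count and 1 to the denominator,
# only for degenerate rates. "clamp" replaces 0/1 by 1/(2n) and
# 1 - 1/(2n); "loglinear" adds 0.5/1 unconditionally.
corrected_rate <- function(x, n, method) {
  if (n <= 0) stop("zero trial denominator")
  p <- x / n
  switch(method,
    half_count = if (p == 0 || p == 1) (x + 0.5) / (n + 1) else p,
    loglinear = (x + 0.5) / (n + 1),
    clamp = min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n)),
    stop("unknown correction method: ", method)
  )
}

#' Score a CPT count table into d-prime per difficulty
#'
#' Perceptual sensitivity is `d' = qnorm(H) - qnorm(F)`, computed
#' separately for the easy discrimination (targets vs `stim`
#' nontargets) and the difficult discrimination (targets vs `catch`
#' nontargets). Higher d' means better target/noise discrimination.
#' Degenerate hit or false-alarm rates (0 or 1) are corrected so d'
#' stays finite; the default `"half_count"` correction touches only
#' degenerate rates.
#'
#' @param counts A `cpt_counts` object.
#' @param correction `"half_count"` (default), `"loglinear"`, or
#'   `"clamp"`.
#' @return A `dprime_result` list: `dprime_easy`, `dprime_difficult`,
#'   `hit_rate`, `fa_rate_easy`, `fa_rate_difficult` (after
#'   correction), and the `correction` tag.
#' @examples
#' score_cpt(cpt_counts(60, 48, 180, 36, 60, 18))
#' @export
score_cpt <- function(counts,
                      correction = c("half_count", "loglinear", "clamp")) {
  stopifnot(inherits(counts, "cpt_counts"))
  correction <- match.arg(correction)
  H <- corrected_rate(counts$n_hit, counts$n_target, correction)
  Fe <- corrected_rate(counts$n_fa_easy, counts$n_stim, correction)
  Fd <- corrected_rate(counts$n_fa_difficult, counts$n_catch, correction)
  structure(
    list(
      dprime_easy = stats::qnorm(H) - stats::qnorm(Fe),
      dprime_difficult = stats::qnorm(H) - stats::qnorm(Fd),
      hit_rate = H, fa_rate_easy = Fe, fa_rate_difficult = Fd,
      correction = correction
    ),
    class = "dprime_result"
  )
}

#' Equal-variance SDT response probabilities
#'
#' The simulator's counterpart of the d' definition: with sensitivity
#' `dprime` and symmetric criterion `c`, the hit probability is
#' `pnorm(dprime/2 - c)` and the false-alarm probability
#' `pnorm(-dprime/2 - c)`. Scoring expected counts recovers `dprime`
#' exactly as the number of trials grows.
#'
#' @param dprime Sensitivity.
#' @param criterion Criterion `c`; 0 is unbiased.
#' @return Named vector `c(hit = , fa = )`.
#' @examples
#' sdt_response_probs(2, 0)  # ~ (0.841, 0.159)
#' @export
sdt_response_probs <- function(dprime, criterion = 0) {
  stopifnot(is.finite(dprime), is.finite(criterion))
  c(hit = stats::pnorm(dprime / 2 - criterion),
    fa = stats::pnorm(-dprime / 2 - criterion))
}
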