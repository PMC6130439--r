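#' Longitudinal model specifications
#'
#' Three nested fixed-effect structures, each with a subject-level
#' random intercept capturing repeated scans and mean FD always
#' included as a motion covariate:
#' * **Model 1** -- main effects only: `group + age + sex + mean_fd`
#'   (7 parameters counting the two variance components);
#' * **Model 2** -- Model 1 plus the group-by-age interaction (8);
#' * **Model 3** -- full omnibus: all two-way interactions of group,
#'   age and sex plus their three-way interaction (11).
#'
#' @param model Model number 1, 2 or 3, or one of `"Model1"`,
#'   `"Model2"`, `"Model3"`.
#' @return A `model_spec` list with `name` and fixed-effect `terms`.
#' @export
model_spec <- function(model = 1) {
  name <- if (is.numeric(model)) paste0("Model", model) else model
  terms <- switch(name,
    Model1 = c("group", "age_c", "sex", "mean_fd"),
    Model2 = c("group", "age_c", "sex", "mean_fd", "group:age_c"),
    Model3 = c("group", "age_c", "sex", "mean_fd",
               "group:age_c", "group:sex", "age_c:sex",
               "group:age_c:sex"),
    stop("unknown model spec: ", name)
  )
  structure(list(name = name, terms = terms), class = "model_spec")
}

# shared mixed-model engine: ML fit, Satterthwaite t tests, AIC.
# When no subject has a repeat scan the random-intercept variance is
# unidentifiable; the fit degenerates to ordinary least squares,
# returned flagged (this is also the exact estimator for that design).
.fit_mixed <- function(fixed_rhs, outcome, data, subject_col = "subject_id") {
  fixed_formula <- stats::as.formula(paste(outcome, "~", fixed_rhs))
  mm <- stats::model.matrix(fixed_formula, data = data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  has_repeats <- max(table(data[[subject_col]])) >= 2L
  if (has_repeats) {
    full <- stats::as.formula(
      paste(outcome, "~", fixed_rhs, "+ (1 |", subject_col, ")"))
    fit <- lmerTest::lmer(full, data = data, REML = FALSE)
    co <- stats::coef(summary(fit))
    coefficients <- data.frame(
      term = rownames(co),
      estimate = co[, "Estimate"],
      se = co[, "Std. Error"],
      df = co[, "df"],
      t = co[, "t value"],
      p = co[, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE
    )
    singular <- lme4::isSingular(fit)
    aic <- stats::AIC(fit)
    df_model <- ncol(mm) + 2L
    method <- "lmm"
  } else {
    fit <- stats::lm(fixed_formula, data = data)
    co <- stats::coef(summary(fit))
    coefficients <- data.frame(
      term = rownames(co),
      estimate = co[, "Estimate"],
      se = co[, "Std. Error"],
      df = fit$df.residual,
      t = co[, "t value"],
      p = co[, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE
    )
    singular <- TRUE
    aic <- stats::AIC(fit)
    df_model <- ncol(mm) + 1L
    method <- "ols"
  }
  structure(
    list(coefficients = coefficients, aic = aic,
         n_obs = nrow(data),
         n_subjects = length(unique(data[[subject_col]])),
         df_model = df_model, singular = singular,
         method = method, outcome = outcome, fit = fit),
    class = "lmm_result"
  )
}

#' Fit a longitudinal mixed-effects model to scan records
#'
#' Maximum-likelihood fit (so AICs are comparable across fixed-effect
#' structures) with a subject random intercept; per-term t statistics
#' and p values use Satterthwaite denominator degrees of freedom. Age
#' is mean-centred before entering interactions by default.
#'
#' @param records Per-scan analysis table with `subject_id`, `group`,
#'   `sex`, `age`, `mean_fd` and the outcome column.
#' @param outcome Name of the outcome column (e.g. `"avg_neg_conn"`).
#' @param spec A [model_spec()].
#' @param center_age Mean-centre age before fitting (default `TRUE`).
#' @return An `lmm_result`: `coefficients` (term, estimate, se, df, t,
#'   p), `aic`, `n_obs`, `n_subjects`, `df_model` (fixed effects plus
#'   variance components), `singular` flag, `method`, and the
#'   underlying fit.
#' @export
fit_lmm <- function(records, outcome = "avg_neg_conn",
                    spec = model_spec(1), center_age = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("subject_id", "group", "sex", "age", "mean_fd", outcome)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(records[need])) stop("missing values in outcome or covariates")
  data <- records
  data$group <- normalize_group(data$group)
  data$sex <- normalize_sex(data$sex)
  data$age_c <- if (center_age) data$age - mean(data$age) else data$age
  out <- .fit_mixed(paste(spec$terms, collapse = " + "), outcome, data)
  out$spec <- spec
  out
}

#' Select the best model by AIC
#'
#' @param results Named or unnamed list of `lmm_result` fits of the
#'   same outcome on the same observations.
#' @return List with `best` (the winning `lmm_result`), `table`
#'   (name, df_model, aic, delta_aic), and `tie` flag. Ties go to the
#'   first of the tied minima.
#' @export
select_model <- function(results) {
  stopifnot(length(results) >= 1L)
  n_obs <- vapply(results, `[[`, numeric(1), "n_obs")
  outcomes <- vapply(results, `[[`, character(1), "outcome")
  if (length(unique(n_obs)) > 1L || length(unique(outcomes)) > 1L) {
    stop("AICs are not comparable: fits differ in observations or outcome")
  }
  aic <- vapply(results, `[[`, numeric(1), "aic")
  names_out <- vapply(seq_along(results), function(i) {
    sp <- results[[i]]$spec
    if (!is.null(sp)) sp$name else paste0("fit", i)
  }, character(1))
  best_i <- which.min(aic)
  tie <- sum(aic == aic[best_i]) > 1L
  list(
    best = results[[best_i]],
    table = data.frame(name = names_out, df_model =
                         vapply(results, `[[`, integer(1), "df_model"),
                       aic = aic, delta_aic = aic - aic[best_i],
                       row.names = NULL, stringsAsFactors = FALSE),
    tie = tie
  )
}

#' Edgewise mixed-model fits with BH-FDR correction
#'
#' Fits the model separately to every mask edge's Fisher-z values and
#' applies the Benjamini-Hochberg step-up correction per term across
#' edges. A failing single-edge fit is recorded as missing and the
#' remaining edges proceed.
#'
#' @param edge_vals Scans x edges matrix from [edge_values()]; row
#'   order must match `records`.
#' @param records Per-scan analysis table (see [fit_lmm()]).
#' @param spec A [model_spec()]; the connection-level analysis uses
#'   Model 1.
#' @param center_age Mean-centre age (default `TRUE`).
#' @return An `edge_stats` data frame: `edge`, `roi_i`, `roi_j`,
#'   `term`, `estimate`, `se`, `t`, `p`, `q`.
#' @export
edgewise_fit <- function(edge_vals, records, spec = model_spec(1),
                         center_age = TRUE) {
  stopifnot(is.matrix(edge_vals), nrow(edge_vals) == nrow(records))
  per_edge <- lapply(colnames(edge_vals), function(edge) {
    rec <- records
    rec$.edge_z <- edge_vals[, edge]
    res <- tryCatch(
      fit_lmm(rec, outcome = ".edge_z", spec = spec,
              center_age = center_age),
      error = function(e) NULL
    )
    ij <- as.integer(strsplit(edge, "-", fixed = TRUE)[[1]])
    if (is.null(res)) {
      return(data.frame(edge = edge, roi_i = ij[1], roi_j = ij[2],
                        term = NA_character_, estimate = NA_real_,
                        se = NA_real_, t = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    co <- res$coefficients
    data.frame(edge = edge, roi_i = ij[1], roi_j = ij[2],
               term = co$term, estimate = co$estimate, se = co$se,
               t = co$t, p = co$p, stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, per_edge)
  stats_df$q <- NA_real_
  for (term in unique(stats_df$term[!is.na(stats_df$term)])) {
    sel <- which(stats_df$term == term)
    stats_df$q[sel] <- stats::p.adjust(stats_df$p[sel], method = "BH")
  }
  class(stats_df) <- c("edge_stats", "data.frame")
  stats_df
}

#' Summed significant t scores per region
#'
#' For each ROI, sums the t statistics of its incident edges that are
#' significant uncorrected at `p_cut` and point in the requested
#' direction -- the tabular analogue of the cortical-surface effect
#' maps. ROIs with no qualifying incident edge score zero.
#'
#' @param stats An `edge_stats` table from [edgewise_fit()].
#' @param term Model term of interest (e.g. `"groupADHD"`).
#' @param direction `"positive"` or `"negative"` sign of t to sum.
#' @param p_cut Uncorrected significance cut; default 0.05.
#' @param n_rois Number of ROIs in the map.
#' @return Data frame `roi_id`, `summed_t`.
#' @export
summed_t_map <- function(stats, term,
                         direction = c("negative", "positive"),
                         p_cut = 0.05,
                         n_rois = max(stats$roi_i, stats$roi_j)) {
  direction <- match.arg(direction)
  if (!term %in% stats$term) stop("unknown term: ", term)
  rows <- stats[!is.na(stats$p) & stats$term == term &
                  stats$p < p_cut &
                  (if (direction == "negative") stats$t < 0
                   else stats$t > 0), , drop = FALSE]
  out <- numeric(n_rois)
  for (k in seq_len(nrow(rows))) {
    out[rows$roi_i[k]] <- out[rows$roi_i[k]] + rows$t[k]
    out[rows$roi_j[k]] <- out[rows$roi_j[k]] + rows$t[k]
  }
  data.frame(roi_id = seq_len(n_rois), summed_t = out)
}

#' Gender-balanced permutation inference
#'
#' Counters a group-wise sex imbalance by repeatedly refitting the
#' model on subsets in which the ADHD scans are randomly thinned to a
#' chosen male/female composition (all control scans always retained)
#' and averaging the per-term p values over iterations. The study
#' design this mirrors selects 123 ADHD male and 100 ADHD female
#' scans per iteration, 10,000 times.
#'
#' @param records Per-scan analysis table.
#' @param spec A [model_spec()].
#' @param outcome Outcome column name.
#' @param n_male,n_female Number of ADHD male / female scans to retain
#'   per iteration.
#' @param n_perm Number of iterations.
#' @param seed Integer seed.
#' @return List with `mean_p` (named per-term average), `p` (n_perm x
#'   terms matrix of per-iteration p values), `n_perm`.
#' @export
gender_balanced_permutation <- function(records, spec = model_spec(1),
                                        outcome = "avg_neg_conn",
                                        n_male, n_female,
                                        n_perm = 10000L, seed = 1L) {
  records$group <- normalize_group(records$group)
  records$sex <- normalize_sex(records$sex)
  # centre age once on the full sample so terms are identical across
  # iterations (and across the degenerate full-sample case)
  records$age <- records$age - mean(records$age)
  adhd_m <- which(records$group == "ADHD" & records$sex == "M")
  adhd_f <- which(records$group == "ADHD" & records$sex == "F")
  ctrl <- which(records$group == "control")
  if (n_male > length(adhd_m) || n_female > length(adhd_f)) {
    stop(sprintf(
      "infeasible selection: need %d male / %d female ADHD scans, have %d / %d",
      n_male, n_female, length(adhd_m), length(adhd_f)))
  }
  full_fit <- fit_lmm(records, outcome = outcome, spec = spec,
                      center_age = FALSE)
  term_names <- full_fit$coefficients$term
  p_mat <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      take <- sort(c(ctrl,
                     if (n_male == length(adhd_m)) adhd_m
                     else sample(adhd_m, n_male),
                     if (n_female == length(adhd_f)) adhd_f
                     else sample(adhd_f, n_female)))
      res <- fit_lmm(records[take, , drop = FALSE], outcome = outcome,
                     spec = spec, center_age = FALSE)
      stats::setNames(res$coefficients$p, res$coefficients$term)
    }, stats::setNames(numeric(length(term_names)), term_names)))
  })
  list(mean_p = colMeans(p_mat), p = p_mat, n_perm = n_perm)
}

#' Brain-behavior coupling models
#'
#' Models CPT sensitivity (d') as a function of the averaged
#' negative-connectivity metric, controlling for mean FD, age and sex,
#' with a subject random intercept. `which = "both"` stacks the easy
#' and difficult d' per scan into a repeated-measures form with a
#' difficulty factor and a connectivity-by-difficulty interaction;
#' `"easy"` / `"difficult"` fit one stratum. Group and its interaction
#' with connectivity are optional moderators.
#'
#' @param records Per-scan table with `dprime_easy`,
#'   `dprime_difficult`, `avg_neg_conn`, `mean_fd`, `age`, `sex`,
#'   `group`, `subject_id`.
#' @param which `"both"` (repeated measures), `"easy"`, or
#'   `"difficult"`.
#' @param include_group Add a group main effect.
#' @param group_interaction Add group x connectivity (implies the
#'   group main effect).
#' @param center_age Mean-centre age (default `TRUE`).
#' @return An `lmm_result`. A negative `avg_neg_conn` coefficient
#'   means more negative connectivity predicts higher d'.
#' @export
brain_behavior_fit <- function(records,
                               which = c("both", "easy", "difficult"),
                               include_group = FALSE,
                               group_interaction = FALSE,
                               center_age = TRUE) {
  which <- match.arg(which)
  need <- c("subject_id", "group", "sex", "age", "mean_fd",
            "avg_neg_conn", "dprime_easy", "dprime_difficult")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- records
  data$group <- normalize_group(data$group)
  data$sex <- normalize_sex(data$sex)
  data$age_c <- if (center_age) data$age - mean(data$age) else data$age

  terms <- c("avg_neg_conn", "mean_fd", "age_c", "sex")
  if (include_group || group_interaction) terms <- c(terms, "group")
  if (group_interaction) terms <- c(terms, "group:avg_neg_conn")

  if (which == "both") {
    long <- rbind(
      transform(data, dprime = data$dprime_easy, difficulty = "easy"),
      transform(data, dprime = data$dprime_difficult,
                difficulty = "difficult")
    )
    long$difficulty <- factor(long$difficulty,
                              levels = c("easy", "difficult"))
    terms <- c(terms, "difficulty", "avg_neg_conn:difficulty")
    out <- .fit_mixed(paste(terms, collapse = " + "), "dprime", long)
  } else {
    outcome <- paste0("dprime_", which)
    out <- .fit_mixed(paste(terms, collapse = " + "), outcome, data)
  }
  out$which <- which
  out
}
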