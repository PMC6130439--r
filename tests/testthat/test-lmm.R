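test_that("single-scan-per-subject designs reduce to OLS exactly", {
  rec <- make_records(n_per_group = 40L, seed = 21L, p_repeat = 0)
  fit <- fit_lmm(rec, "avg_neg_conn", model_spec(1))
  expect_equal(fit$method, "ols")
  expect_true(fit$singular)

  # closed-form normal-equations oracle
  X <- cbind(1, rec$group == "ADHD", rec$age - mean(rec$age),
             rec$sex == "F", rec$mean_fd)
  beta <- solve(t(X) %*% X, t(X) %*% rec$avg_neg_conn)[, 1]
  expect_equal(unname(fit$coefficients$estimate), unname(beta),
               tolerance = 1e-6)
})

test_that("an outcome copying a covariate is recovered identically", {
  rec <- make_records(n_per_group = 30L, seed = 22L, p_repeat = 0)
  rec$outcome <- rec$mean_fd
  # summary.lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_lmm(rec, "outcome", model_spec(1)))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "mean_fd"], 1, tolerance = 1e-8)
  expect_lt(max(abs(resid(fit$fit))), 1e-10)
})

test_that("mixed fits carry the documented parameter accounting", {
  rec <- make_records(n_per_group = 50L, seed = 23L)
  fits <- lapply(1:3, function(m) fit_lmm(rec, "avg_neg_conn",
                                          model_spec(m)))
  expect_equal(vapply(fits, `[[`, integer(1), "df_model"), c(7L, 8L, 11L))
  expect_equal(fits[[1]]$method, "lmm")
  expect_true(all(is.finite(vapply(fits, `[[`, numeric(1), "aic"))))
  # Satterthwaite df are fractional and within (0, n)
  df <- fits[[1]]$coefficients$df
  expect_true(all(df > 0 & df < fits[[1]]$n_obs))
})

test_that("rank-deficient designs name the aliased terms", {
  rec <- make_records(n_per_group = 20L, seed = 24L)
  rec$sex <- "M"   # sexF aliased with intercept
  expect_error(fit_lmm(rec, "avg_neg_conn", model_spec(1)),
               "aliased.*sexF")
})

test_that("planted group and sex effects are recovered with signs", {
  rec <- make_records(n_per_group = 120L, seed = 25L,
                      beta_group = 0.05, beta_sex = -0.04)
  co <- fit_lmm(rec, "avg_neg_conn", model_spec(1))$coefficients
  expect_gt(co$estimate[co$term == "groupADHD"], 0)
  expect_lt(co$p[co$term == "groupADHD"], 0.05)
  expect_lt(co$estimate[co$term == "sexF"], 0)
})

test_that("AIC selection prefers the generating main-effects model", {
  wins <- 0L
  for (s in 1:20) {
    rec <- make_records(n_per_group = 60L, seed = 300L + s)
    fits <- lapply(1:3, function(m) fit_lmm(rec, "avg_neg_conn",
                                            model_spec(m)))
    sel <- select_model(fits)
    wins <- wins + (sel$best$spec$name == "Model1")
  }
  expect_gt(wins, 10L)
})

test_that("model selection handles ties, singletons, and misuse", {
  rec <- make_records(n_per_group = 30L, seed = 26L)
  f1 <- fit_lmm(rec, "avg_neg_conn", model_spec(1))
  one <- select_model(list(f1))
  expect_equal(one$best$spec$name, "Model1")
  expect_false(one$tie)
  dup <- select_model(list(f1, f1))
  expect_true(dup$tie)
  expect_equal(dup$table$delta_aic, c(0, 0))

  rec2 <- make_records(n_per_group = 31L, seed = 27L)
  f2 <- fit_lmm(rec2, "avg_neg_conn", model_spec(1))
  expect_error(select_model(list(f1, f2)), "not comparable")
})

test_that("edgewise q-values follow BH and flow into summed-t maps", {
  set.seed(28)
  rec <- make_records(n_per_group = 25L, seed = 28L)
  n_edges <- 6L
  edge_vals <- vapply(seq_len(n_edges), function(e) {
    rec$avg_neg_conn + rnorm(nrow(rec), sd = 0.05)
  }, numeric(nrow(rec)))
  colnames(edge_vals) <- paste(1:6, 7:12, sep = "-")
  ew <- edgewise_fit(edge_vals, rec)
  expect_s3_class(ew, "edge_stats")
  expect_true(all(ew$q >= ew$p, na.rm = TRUE))
  for (term in unique(ew$term)) {
    sel <- ew$term == term
    expect_equal(ew$q[sel], bh_brute_force(ew$p[sel]), tolerance = 1e-12)
  }

  tm <- summed_t_map(ew, "groupADHD", "positive", p_cut = 0.5,
                     n_rois = 12)
  # brute-force per-ROI loop oracle
  brute <- numeric(12)
  rows <- ew[ew$term == "groupADHD" & ew$p < 0.5 & ew$t > 0, ]
  for (k in seq_len(nrow(rows))) {
    for (roi in c(rows$roi_i[k], rows$roi_j[k])) {
      brute[roi] <- brute[roi] + rows$t[k]
    }
  }
  expect_equal(tm$summed_t, brute)
  expect_error(summed_t_map(ew, "nonexistent"), "unknown term")
  # untouched ROIs score zero
  none <- summed_t_map(ew, "groupADHD", "positive", p_cut = 1e-12,
                       n_rois = 12)
  expect_true(all(none$summed_t[setdiff(1:12, c(ew$roi_i, ew$roi_j))] == 0))
})

test_that("degenerate full-sample permutation equals the single fit", {
  rec <- make_records(n_per_group = 40L, seed = 29L)
  n_m <- sum(rec$group == "ADHD" & rec$sex == "M")
  n_f <- sum(rec$group == "ADHD" & rec$sex == "F")
  perm <- gender_balanced_permutation(rec, model_spec(1), "avg_neg_conn",
                                      n_male = n_m, n_female = n_f,
                                      n_perm = 1L, seed = 8L)
  direct <- fit_lmm(rec, "avg_neg_conn", model_spec(1))
  expect_equal(unname(perm$mean_p),
               direct$coefficients$p, tolerance = 1e-12)
})

test_that("permutation is seed-deterministic and checks feasibility", {
  rec <- make_records(n_per_group = 40L, seed = 30L)
  n_m <- sum(rec$group == "ADHD" & rec$sex == "M")
  run <- function(seed) {
    gender_balanced_permutation(rec, model_spec(1), "avg_neg_conn",
                                n_male = n_m - 5L, n_female = 3L,
                                n_perm = 10L, seed = seed)
  }
  expect_equal(run(5)$mean_p, run(5)$mean_p)
  expect_false(isTRUE(all.equal(run(5)$mean_p, run(6)$mean_p)))
  expect_error(
    gender_balanced_permutation(rec, model_spec(1), "avg_neg_conn",
                                n_male = 10000L, n_female = 1L,
                                n_perm = 2L, seed = 1L),
    "infeasible")
})

test_that("balancing the sexes weakens a sex-confounded group effect", {
  # plant a sex effect and make ADHD overwhelmingly male, so the
  # naive group contrast borrows the sex difference
  set.seed(31)
  rec <- make_records(n_per_group = 80L, seed = 31L, beta_group = 0.01,
                      beta_sex = -0.06)
  rec$sex[rec$group == "ADHD"] <- ifelse(
    runif(sum(rec$group == "ADHD")) < 0.9, "M", "F")
  rec$sex[rec$group == "control"] <- ifelse(
    runif(sum(rec$group == "control")) < 0.5, "M", "F")
  rec$avg_neg_conn <- -0.28 + 0.01 * (rec$group == "ADHD") -
    0.06 * (rec$sex == "F") + rnorm(nrow(rec), sd = 0.04)
  # refit ignoring sex so the confound can act on the group term
  naive <- fit_lmm(rec, "avg_neg_conn", model_spec(1))
  n_f <- sum(rec$group == "ADHD" & rec$sex == "F")
  bal <- gender_balanced_permutation(
    rec, model_spec(1), "avg_neg_conn",
    n_male = min(sum(rec$group == "control" & rec$sex == "M"),
                 sum(rec$group == "ADHD" & rec$sex == "M")),
    n_female = n_f, n_perm = 50L, seed = 9L)
  p_naive <- naive$coefficients$p[naive$coefficients$term == "groupADHD"]
  expect_gte(bal$mean_p[["groupADHD"]], p_naive * 0.5)
})

test_that("brain-behavior fits expose difficulty and moderation terms", {
  rec <- make_records(n_per_group = 60L, seed = 32L)
  set.seed(32)
  rec$dprime_easy <- 2 - 2.8 * rec$avg_neg_conn + rnorm(nrow(rec), sd = 0.3)
  rec$dprime_difficult <- 0.6 - 2.8 * rec$avg_neg_conn +
    rnorm(nrow(rec), sd = 0.3)
  both <- brain_behavior_fit(rec, "both")
  terms <- both$coefficients$term
  expect_true("difficultydifficult" %in% terms)
  expect_true("avg_neg_conn:difficultydifficult" %in% terms)
  slope <- both$coefficients$estimate[terms == "avg_neg_conn"]
  expect_lt(slope, 0)

  easy <- brain_behavior_fit(rec, "easy")
  expect_lt(easy$coefficients$estimate[
    easy$coefficients$term == "avg_neg_conn"], 0)

  mod <- brain_behavior_fit(rec, "easy", group_interaction = TRUE)
  expect_true(any(grepl("avg_neg_conn:groupADHD|groupADHD:avg_neg_conn",
                        mod$coefficients$term)))
})
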