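test_that("the same seed reproduces the cohort bit for bit", {
  cfg <- quick_config(n_subjects_per_group = 6L, seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$timeseries[[1]]$data, b$timeseries[[1]]$data)
  expect_identical(a$trials[[3]], b$trials[[3]])
  c2 <- generate_cohort(quick_config(n_subjects_per_group = 6L, seed = 12L))
  expect_false(identical(a$truth$zeta, c2$truth$zeta))
})

test_that("degenerate noise collapses every scan to the same latent rho", {
  cfg <- quick_config(n_subjects_per_group = 8L, tau_subject = 0,
                      sigma_scan = 0, delta_group = 0, delta_sex = 0,
                      beta_age = 0, seed = 4L)
  ch <- generate_cohort(cfg)
  expect_equal(ch$truth$rho, rep(tanh(cfg$z0), nrow(ch$truth)))
})

test_that("expected_edge_r follows the factor-model closed form", {
  cfg <- quick_config()
  expect_equal(expected_edge_r(cfg, 0), 0)
  noiseless <- quick_config(sigma_roi = 0)
  expect_equal(expected_edge_r(noiseless, atanh(-0.35)), -0.35)
  # lambda = 1, sigma_roi = 1: attenuation is exactly 1/2
  expect_equal(expected_edge_r(cfg, atanh(-0.6)), -0.3)
  expect_equal(expected_avg_z(cfg, atanh(-0.6)), atanh(-0.3))
})

test_that("empirical edge correlations match the closed-form oracle", {
  # fixed latent rho; long scans so the Monte-Carlo error is small
  rho <- -0.5
  cfg <- synthetic_config(
    n_subjects_per_group = 13L, p_wave2 = 0, n_frames = 2000L,
    z0 = atanh(rho), delta_group = 0, delta_sex = 0, beta_age = 0,
    tau_subject = 0, sigma_scan = 0, spike_prob = 0, seed = 21L)
  ch <- generate_cohort(cfg)
  parc <- cfg$parcellation
  dmn <- default_rois(parc)
  tp <- taskpos_rois(parc)
  edge_r <- vapply(ch$timeseries, function(ts) {
    r <- cor(ts$data)
    mean(r[dmn, tp])
  }, numeric(1))
  expect_equal(mean(edge_r), rho / 2, tolerance = 0.02 / abs(rho / 2))
  # within-network pairs: expected r = lambda^2/(lambda^2+sigma^2) = 1/2
  within_r <- vapply(ch$timeseries, function(ts) {
    r <- cor(ts$data[, dmn])
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_equal(mean(within_r), 0.5, tolerance = 0.05)
})

test_that("ages respect the longitudinal design", {
  ch <- generate_cohort(synthetic_config(n_subjects_per_group = 60L,
                                         p_wave2 = 0.8, p_wave3 = 0.5,
                                         seed = 7L))
  ph <- ch$phenotypes
  expect_true(all(ph$age >= 7 & ph$age <= 15))
  for (sid in unique(ph$subject_id)) {
    ages <- ph$age[ph$subject_id == sid][order(ph$wave[ph$subject_id == sid])]
    if (length(ages) > 1) {
      lags <- diff(ages)
      expect_true(all(lags >= 0.5 & lags <= 2.5))
    }
  }
})

test_that("female scans shift the latent value by exactly delta_sex", {
  cfg <- quick_config(n_subjects_per_group = 30L, tau_subject = 0,
                      sigma_scan = 0, beta_age = 0, seed = 9L)
  tr <- generate_cohort(cfg)$truth
  for (g in c("control", "ADHD")) {
    sub <- tr[tr$group == g, ]
    if (any(sub$sex == "F") && any(sub$sex == "M")) {
      expect_equal(unique(sub$zeta[sub$sex == "F"]) -
                     unique(sub$zeta[sub$sex == "M"]),
                   cfg$delta_sex)
    }
  }
})

test_that("invalid configurations are rejected up front", {
  expect_error(quick_config(target_frac = 0.6, catch_frac = 0.5),
               "exceed 1")
  expect_error(quick_config(tau_subject = -1), "non-negative")
  expect_error(quick_config(z0 = -4, tau_subject = 0.5),
               "near-degenerate")
  expect_error(quick_config(p_wave2 = 1.2), "\\[0, 1\\]")
})

test_that("cohort writer emits the full study layout", {
  dir <- withr::local_tempdir()
  ch <- generate_cohort(quick_config(n_subjects_per_group = 3L, seed = 2L))
  write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "phenotypes.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  id <- ch$phenotypes$scan_id[1]
  expect_true(file.exists(file.path(dir, "timeseries", paste0(id, ".tsv"))))
  back <- read_cohort_dir(dir, tr_seconds = ch$config$tr_seconds)
  expect_equal(nrow(back$phenotypes), nrow(ch$phenotypes))
  expect_equal(back$timeseries[[id]]$data, ch$timeseries[[id]]$data,
               ignore_attr = TRUE)
})
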