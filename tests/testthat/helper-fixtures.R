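# shared fixtures, all generated in code at test time

# the spec toy: 2 default, 3 task-positive, 1 other region
tiny_parc <- function() {
  parcellation(c("Default", "Default", "DorsalAttn", "CinguloOperc",
                 "FrontoParietal", "Other"))
}

quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects_per_group = 12L, n_frames = 150L,
                   tr_seconds = 2.0, seed = 1L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# reference connectivity matrices from an independent synthetic sample
reference_mats <- function(parc = toy_parcellation(), n_scans = 10L,
                           seed = 424L, n_frames = 200L, z0 = -0.95) {
  cfg <- synthetic_config(
    n_subjects_per_group = as.integer(ceiling(n_scans / 2)),
    p_wave2 = 0, parcellation = parc, n_frames = n_frames,
    z0 = z0, seed = seed)
  ch <- generate_cohort(cfg)
  lapply(ch$timeseries, function(ts) {
    fd <- compute_fd(ch$motion[[ts$scan_id]])
    correlation_matrix(ts, censor_frames(fd))
  })
}

# analysis records simulated directly at the scan-record level (no
# imaging), for model-level unit tests
make_records <- function(n_per_group = 60L, seed = 1L,
                         beta_group = 0.025, beta_sex = -0.02,
                         beta_age = -0.004, tau = 0.03, sigma = 0.04,
                         p_repeat = 0.35) {
  set.seed(seed)
  n <- 2L * n_per_group
  group <- rep(c("control", "ADHD"), each = n_per_group)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  age0 <- runif(n, 7, 11)
  u <- rnorm(n, sd = tau)
  rows <- lapply(seq_len(n), function(i) {
    waves <- 1L + (runif(1) < p_repeat)
    age <- age0[i] + (seq_len(waves) - 1L) * 1.5
    data.frame(subject_id = sprintf("S%03d", i), wave = seq_len(waves),
               group = group[i], sex = sex[i], age = age,
               mean_fd = runif(waves, 0.05, 0.15), u = u[i],
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec$scan_id <- sprintf("%s_w%d", rec$subject_id, rec$wave)
  rec$avg_neg_conn <- -0.28 + beta_group * (rec$group == "ADHD") +
    beta_sex * (rec$sex == "F") + beta_age * (rec$age - 11) +
    rec$u + rnorm(nrow(rec), sd = sigma)
  rec$u <- NULL
  rec
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m >= 2) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}
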