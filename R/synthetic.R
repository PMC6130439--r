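#' Configuration for the synthetic longitudinal cohort
#'
#' Bundles every knob of the generator with defaults that emulate the
#' statistical structure of a longitudinal child ADHD resting-state
#' cohort: 1-3 scans per subject about 1.5 years apart, baseline ages
#' 7-11, a latent default-mode-to-task-positive anticorrelation
#' modulated by group, sex, age and subject random effects, spiky
#' FD-generating head motion with global signal artifacts, and
#' identical-pairs CPT responses whose sensitivity is coupled to the
#' connectivity level.
#'
#' The latent model operates on the Fisher-z scale. For scan *s* of
#' subject *i*:
#' `zeta_s = z0 + delta_group*[ADHD] + delta_sex*[F] +
#'  beta_age*(age - age_ref) + u_i + eps_s`,
#' with `u_i ~ N(0, tau_subject^2)`, `eps_s ~ N(0, sigma_scan^2)`, and
#' latent factor correlation `rho_s = tanh(zeta_s)`. Each frame draws
#' a default-mode factor and a task-positive factor as standard
#' bivariate normal with correlation `rho_s` (plus an independent
#' factor for unassigned ROIs); an ROI's signal is
#' `lambda_loading * own-network factor + N(0, sigma_roi^2)` noise, so
#' a default-to-task-positive ROI pair has expected Pearson
#' correlation `rho_s * lambda_loading^2 / (lambda_loading^2 +
#' sigma_roi^2)` (see [expected_edge_r()]).
#'
#' @param n_subjects_per_group Subjects per group (default 40, a demo
#'   size that runs in seconds; recovery studies use larger values).
#' @param p_wave2,p_wave3 Probability of a second scan, and of a third
#'   given a second.
#' @param baseline_age_range Baseline age range in years.
#' @param lag_mean_years,lag_sd_years Between-wave lag mean and jitter.
#' @param sex_ratio Named vector of male proportions per group.
#' @param parcellation A [parcellation()]; default [toy_parcellation()].
#' @param n_frames,tr_seconds Frames per scan and repetition time (s).
#' @param z0 Baseline latent Fisher-z (negative: anticorrelated).
#' @param delta_group ADHD shift (positive: toward zero, i.e. weaker
#'   anticorrelation).
#' @param delta_sex Female shift (negative: stronger anticorrelation).
#' @param beta_age Per-year shift; negative means anticorrelation
#'   strengthens with age.
#' @param age_ref Reference age (years) for centring the age effect.
#' @param tau_subject Subject random-intercept SD (z units).
#' @param sigma_scan Scan-level latent noise SD (z units).
#' @param lambda_loading ROI loading on its network factor.
#' @param sigma_roi ROI-specific noise SD.
#' @param fd_base_mean Mean baseline framewise displacement (mm).
#' @param spike_prob Per-frame probability of a motion spike.
#' @param spike_mag_mm Spike displacement magnitude (mm).
#' @param artifact_gain Global BOLD artifact per mm of spike.
#' @param a_easy,a_difficult d' intercepts for the easy/difficult
#'   discriminations.
#' @param b_conn Slope of true d' on minus the expected averaged
#'   connectivity (positive couples stronger anticorrelation to
#'   better vigilance).
#' @param sigma_dprime Between-scan SD of true d' around its mean.
#' @param criterion SDT response criterion c.
#' @param n_trials,target_frac,catch_frac CPT design: total trials and
#'   target/catch fractions (rest are easy "stim" nontargets).
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects_per_group = 40L,
                             p_wave2 = 0.35,
                             p_wave3 = 0.06,
                             baseline_age_range = c(7, 11),
                             lag_mean_years = 1.5,
                             lag_sd_years = 0.15,
                             sex_ratio = c(control = 0.51, ADHD = 0.71),
                             parcellation = toy_parcellation(),
                             n_frames = 200L,
                             tr_seconds = 2.0,
                             z0 = -0.60,
                             delta_group = 0.06,
                             delta_sex = -0.05,
                             beta_age = -0.010,
                             age_ref = 11,
                             tau_subject = 0.08,
                             sigma_scan = 0.05,
                             lambda_loading = 1,
                             sigma_roi = 1,
                             fd_base_mean = 0.10,
                             spike_prob = 0.05,
                             spike_mag_mm = 0.5,
                             artifact_gain = 1,
                             a_easy = 2.0,
                             a_difficult = 0.57,
                             b_conn = 2.8,
                             sigma_dprime = 0.5,
                             criterion = 0.5,
                             n_trials = 300L,
                             target_frac = 0.20,
                             catch_frac = 0.20,
                             seed = 1L) {
  config <- as.list(environment())
  stopifnot(inherits(parcellation, "parcellation"))
  fracs <- c(p_wave2, p_wave3, target_frac, catch_frac, spike_prob)
  if (any(fracs < 0 | fracs > 1)) stop("probabilities must lie in [0, 1]")
  if (target_frac + catch_frac > 1) {
    stop("target_frac + catch_frac must not exceed 1")
  }
  if (any(c(tau_subject, sigma_scan, sigma_roi, sigma_dprime,
            fd_base_mean, spike_mag_mm) < 0)) {
    stop("scale parameters must be non-negative")
  }
  if (n_subjects_per_group < 1L || n_frames < 10L || tr_seconds <= 0) {
    stop("invalid cohort dimensions")
  }
  age_span <- max(abs(baseline_age_range - age_ref)) + 4.5
  bound <- abs(z0) + abs(delta_group) + abs(delta_sex) +
    abs(beta_age) * age_span + 3 * (tau_subject + sigma_scan)
  if (bound >= 5) {
    stop(sprintf(
      "latent bound %.2f implies near-degenerate factor correlations (tanh ~ +/-1)",
      bound))
  }
  class(config) <- "synthetic_config"
  config
}

#' Expected edge correlation under the factor model
#'
#' Closed-form oracle: a default-to-task-positive ROI pair with latent
#' Fisher-z value `zeta` has expected Pearson correlation
#' `tanh(zeta) * lambda^2 / (lambda^2 + sigma_roi^2)`.
#'
#' @param config A [synthetic_config()].
#' @param zeta Latent Fisher-z value(s).
#' @return Expected Pearson correlation(s).
#' @export
expected_edge_r <- function(config, zeta) {
  stopifnot(inherits(config, "synthetic_config"))
  kappa <- config$lambda_loading^2 /
    (config$lambda_loading^2 + config$sigma_roi^2)
  tanh(zeta) * kappa
}

#' Expected averaged Fisher-z metric
#'
#' The expected value of the averaged negative-connectivity metric
#' for a scan with latent value `zeta`: the Fisher transform of the
#' attenuated edge correlation, `atanh(expected_edge_r)`.
#'
#' @inheritParams expected_edge_r
#' @export
expected_avg_z <- function(config, zeta) {
  atanh(expected_edge_r(config, zeta))
}

# factor index per ROI: 1 = default-mode, 2 = task-positive, 3 = other
.factor_index <- function(parcellation) {
  ifelse(parcellation$network == "Default", 1L,
         ifelse(parcellation$network %in% task_positive_networks(), 2L, 3L))
}

# one scan's BOLD matrix + motion trace; artifact ties motion spikes
# to a global signal offset so censoring measurably matters
.simulate_scan <- function(config, rho) {
  n <- config$n_frames
  fidx <- .factor_index(config$parcellation)
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  x3 <- stats::rnorm(n)
  factors <- cbind(x1, rho * x1 + sqrt(1 - rho^2) * x2, x3)
  noise <- matrix(stats::rnorm(n * length(fidx), sd = config$sigma_roi),
                  nrow = n)
  bold <- config$lambda_loading * factors[, fidx, drop = FALSE] + noise

  # random-walk realignment parameters; rotation increments scaled so
  # each of the 6 parameters contributes equally to expected FD
  s <- config$fd_base_mean / (6 * sqrt(2 / pi))
  inc <- matrix(stats::rnorm(n * 6, sd = s), nrow = n)
  inc[, 4:6] <- inc[, 4:6] / 50
  inc[1, ] <- 0
  params <- apply(inc, 2, cumsum)
  spikes <- stats::runif(n) < config$spike_prob
  spikes[1] <- FALSE
  if (any(spikes)) {
    # transient displacement: out at the spike frame, back the next
    offset <- rep(0, n)
    offset[spikes] <- config$spike_mag_mm
    params[, 1] <- params[, 1] + offset
    bold[spikes, ] <- bold[spikes, ] +
      config$artifact_gain * config$spike_mag_mm
  }
  list(bold = bold, params = params)
}

# fixed-design CPT trial log for one scan: hit rate set by the easy
# d', catch false alarms set so scoring recovers the difficult d'
.simulate_trials <- function(config, dprime_easy, dprime_difficult) {
  n <- config$n_trials
  n_target <- round(n * config$target_frac)
  n_catch <- round(n * config$catch_frac)
  n_stim <- n - n_target - n_catch
  type <- sample(rep(c("target", "catch", "stim"),
                     c(n_target, n_catch, n_stim)))
  zH <- dprime_easy / 2 - config$criterion
  p <- c(target = stats::pnorm(zH),
         stim = stats::pnorm(zH - dprime_easy),
         catch = stats::pnorm(zH - dprime_difficult))
  data.frame(
    trial_index = seq_len(n),
    type = type,
    responded = as.integer(stats::runif(n) < p[type]),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subjects, waves, ages, latent connectivity values, parcel
#' time series, motion traces and CPT trial logs under a single seed
#' (same config, bit-identical outputs). The latent truth behind each
#' scan is returned so recovery can be checked.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort` list:
#' \describe{
#'   \item{phenotypes}{one row per scan: `scan_id`, `subject_id`,
#'     `wave`, `group`, `sex`, `age`.}
#'   \item{timeseries, motion, trials}{named lists keyed by `scan_id`.}
#'   \item{truth}{per-scan latent truth: `zeta`, `rho`,
#'     `expected_avg_z`, `dprime_true_easy`, `dprime_true_difficult`.}
#'   \item{parcellation, config}{the inputs.}
#' }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(config) {
  n_per <- config$n_subjects_per_group
  groups <- rep(.group_levels, each = n_per)
  subject_id <- sprintf("S%04d", seq_along(groups))
  male_p <- config$sex_ratio[groups]
  sex <- ifelse(stats::runif(length(groups)) < male_p, "M", "F")
  age0 <- stats::runif(length(groups),
                       config$baseline_age_range[1],
                       config$baseline_age_range[2])
  n_waves <- as.integer(1L +
    (stats::runif(length(groups)) < config$p_wave2) *
      (1L + (stats::runif(length(groups)) < config$p_wave3)))
  u <- stats::rnorm(length(groups), sd = config$tau_subject)

  rows <- list()
  for (i in seq_along(groups)) {
    age <- age0[i]
    for (w in seq_len(n_waves[i])) {
      if (w > 1L) {
        age <- age + max(0.5, stats::rnorm(1, config$lag_mean_years,
                                           config$lag_sd_years))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id[i], wave = w,
        group = groups[i], sex = sex[i], age = age,
        u = u[i], stringsAsFactors = FALSE
      )
    }
  }
  ph <- do.call(rbind, rows)
  ph$scan_id <- sprintf("%s_w%d", ph$subject_id, ph$wave)
  eps <- stats::rnorm(nrow(ph), sd = config$sigma_scan)
  zeta <- config$z0 +
    config$delta_group * (ph$group == "ADHD") +
    config$delta_sex * (ph$sex == "F") +
    config$beta_age * (ph$age - config$age_ref) +
    ph$u + eps
  rho <- tanh(zeta)
  m <- expected_avg_z(config, zeta)
  d_easy <- config$a_easy + config$b_conn * (-m) +
    stats::rnorm(nrow(ph), sd = config$sigma_dprime)
  d_diff <- config$a_difficult + config$b_conn * (-m) +
    stats::rnorm(nrow(ph), sd = config$sigma_dprime)

  timeseries <- vector("list", nrow(ph))
  motion <- vector("list", nrow(ph))
  trials <- vector("list", nrow(ph))
  for (s in seq_len(nrow(ph))) {
    sim <- .simulate_scan(config, rho[s])
    timeseries[[s]] <- scan_timeseries(sim$bold, config$tr_seconds,
                                       scan_id = ph$scan_id[s],
                                       subject_id = ph$subject_id[s])
    motion[[s]] <- motion_trace(sim$params)
    trials[[s]] <- .simulate_trials(config, d_easy[s], d_diff[s])
  }
  names(timeseries) <- names(motion) <- names(trials) <- ph$scan_id

  truth <- data.frame(
    scan_id = ph$scan_id, subject_id = ph$subject_id, wave = ph$wave,
    group = ph$group, sex = ph$sex, age = ph$age,
    zeta = zeta, rho = rho, expected_avg_z = m,
    dprime_true_easy = d_easy, dprime_true_difficult = d_diff,
    stringsAsFactors = FALSE
  )
  phenotypes <- ph[, c("scan_id", "subject_id", "wave",
                       "group", "sex", "age")]
  rownames(phenotypes) <- NULL
  structure(
    list(phenotypes = phenotypes, timeseries = timeseries,
         motion = motion, trials = trials, truth = truth,
         parcellation = config$parcellation, config = config),
    class = "synthetic_cohort"
  )
}

#' Write a synthetic cohort to the on-disk study layout
#'
#' Produces the directory layout the pipeline stages consume:
#' `phenotypes.csv`, `parcellation.tsv`, `truth.csv`, and per-scan
#' files under `timeseries/`, `motion/` and `trials/`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  for (sub in c("", "timeseries", "motion", "trials")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.table(cohort$parcellation, file.path(dir, "parcellation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in cohort$phenotypes$scan_id) {
    write_timeseries(cohort$timeseries[[id]],
                     file.path(dir, "timeseries", paste0(id, ".tsv")))
    utils::write.table(cohort$motion[[id]],
                       file.path(dir, "motion", paste0(id, ".txt")),
                       sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.csv(cohort$trials[[id]],
                     file.path(dir, "trials", paste0(id, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
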