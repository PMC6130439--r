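# per-stage seed fan-out: stable substream per stage name so a stage
# rerun in isolation reproduces the full-pipeline behaviour
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + h) %% 2147483647L
}

#' Read a cohort study directory
#'
#' Reads the layout written by [write_cohort()] (or assembled by
#' hand): `phenotypes.csv`, `parcellation.tsv`, and per-scan files
#' under `timeseries/` and `motion/`, plus optional `trials/`.
#' A scan listed in the phenotype table with a missing time-series or
#' motion file is an error naming the scan.
#'
#' @param dir Study directory.
#' @param tr_seconds Repetition time in seconds (required; it is not
#'   recoverable from text matrices).
#' @param rotation_units Units of the motion files' rotation columns.
#' @return A list with `phenotypes`, `parcellation`, `timeseries`,
#'   `motion`, `trials` (possibly empty).
#' @export
read_cohort_dir <- function(dir, tr_seconds,
                            rotation_units = c("radians", "degrees")) {
  rotation_units <- match.arg(rotation_units)
  phenotypes <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  if (!"scan_id" %in% names(phenotypes)) {
    phenotypes$scan_id <- sprintf("%s_w%d", phenotypes$subject_id,
                                  phenotypes$wave)
  }
  parcellation <- read_parcellation(file.path(dir, "parcellation.tsv"))
  timeseries <- list()
  motion <- list()
  trials <- list()
  for (k in seq_len(nrow(phenotypes))) {
    id <- phenotypes$scan_id[k]
    ts_path <- file.path(dir, "timeseries", paste0(id, ".tsv"))
    mo_path <- file.path(dir, "motion", paste0(id, ".txt"))
    if (!file.exists(ts_path)) stop("missing time-series file for scan ", id)
    if (!file.exists(mo_path)) stop("missing motion file for scan ", id)
    timeseries[[id]] <- read_timeseries(
      ts_path, parcellation, tr_seconds,
      scan_id = id, subject_id = phenotypes$subject_id[k])
    motion[[id]] <- read_motion(mo_path, rotation_units)
    check_frames_match(timeseries[[id]], motion[[id]])
    tr_path <- file.path(dir, "trials", paste0(id, ".csv"))
    if (file.exists(tr_path)) {
      trials[[id]] <- utils::read.csv(tr_path, stringsAsFactors = FALSE)
    }
  }
  list(phenotypes = phenotypes, parcellation = parcellation,
       timeseries = timeseries, motion = motion, trials = trials)
}

#' Motion QC and connectivity for a set of scans
#'
#' Runs the per-scan chain -- framewise displacement, strict
#' 0.2 mm-style censoring, fixed-duration random clean-frame
#' selection, Fisher-z connectivity, averaged negative-connectivity
#' metric -- and assembles the per-scan analysis table. Ineligible
#' scans (not strictly more than `target_minutes` of clean data) are
#' excluded and accounted for, not fatal.
#'
#' @param timeseries,motion Named lists keyed by scan id.
#' @param phenotypes Data frame with `scan_id`, `subject_id`, `wave`,
#'   `group`, `sex`, `age`.
#' @param mask An `edge_mask` used for the averaged metric.
#' @param threshold_mm FD censoring threshold (default 0.2).
#' @param target_minutes Minutes of clean data per matrix (default 4).
#' @param head_radius_mm Rotation-to-mm radius (default 50).
#' @param seed Base seed; each scan's frame selection uses a derived
#'   per-scan seed.
#' @return List: `records` (per-scan rows with `mean_fd` over
#'   censoring-retained frames and `avg_neg_conn`), `qc` (per-scan
#'   accounting: frames, clean frames, minutes, eligibility, reason),
#'   `matrices` (named list for included scans).
#' @export
process_scans <- function(timeseries, motion, phenotypes, mask,
                          threshold_mm = 0.2, target_minutes = 4,
                          head_radius_mm = 50, seed = 1L) {
  stopifnot(setequal(names(timeseries), phenotypes$scan_id),
            setequal(names(motion), phenotypes$scan_id))
  qc <- list()
  recs <- list()
  mats <- list()
  for (k in seq_len(nrow(phenotypes))) {
    id <- phenotypes$scan_id[k]
    ts <- timeseries[[id]]
    check_frames_match(ts, motion[[id]])
    fd <- compute_fd(motion[[id]], head_radius_mm)
    keep <- censor_frames(fd, threshold_mm)
    mins <- minutes_kept(keep, ts$tr_seconds)
    sel <- select_clean_frames(keep, ts$tr_seconds, target_minutes,
                               seed = stage_seed(seed, id))
    eligible <- !is.null(sel)
    qc[[k]] <- data.frame(
      scan_id = id, n_frames = length(keep), n_clean = sum(keep),
      minutes_clean = mins, eligible = eligible,
      reason = if (eligible) "included" else
        sprintf("only %.2f min clean data (need > %g)", mins,
                target_minutes),
      stringsAsFactors = FALSE
    )
    if (!eligible) next
    z <- correlation_matrix(ts, sel)
    mats[[id]] <- z
    recs[[length(recs) + 1L]] <- data.frame(
      scan_id = id,
      mean_fd = mean_fd(fd, keep),
      avg_neg_conn = average_negative_connectivity(z, mask),
      stringsAsFactors = FALSE
    )
  }
  records <- merge(phenotypes, do.call(rbind, recs), by = "scan_id")
  records <- records[order(match(records$scan_id, phenotypes$scan_id)), ]
  rownames(records) <- NULL
  list(records = records, qc = do.call(rbind, qc), matrices = mats)
}

#' Score every scan's CPT trial log
#'
#' @param trials Named list of trial logs keyed by scan id.
#' @param correction Degenerate-rate correction, see [score_cpt()].
#' @return Data frame `scan_id`, `dprime_easy`, `dprime_difficult`.
#' @export
score_cohort_cpt <- function(trials, correction = "half_count") {
  out <- lapply(names(trials), function(id) {
    d <- score_cpt(count_cpt_trials(trials[[id]]), correction)
    data.frame(scan_id = id, dprime_easy = d$dprime_easy,
               dprime_difficult = d$dprime_difficult,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build the full analysis table for a synthetic cohort
#'
#' Convenience wrapper chaining [process_scans()] and
#' [score_cohort_cpt()] over an in-memory [generate_cohort()] result.
#'
#' @param cohort A `synthetic_cohort`.
#' @param mask An `edge_mask`.
#' @param ... Passed to [process_scans()].
#' @return As [process_scans()], with d' columns merged into
#'   `records`.
#' @export
process_cohort <- function(cohort, mask, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  out <- process_scans(cohort$timeseries, cohort$motion,
                       cohort$phenotypes, mask, ...)
  dp <- score_cohort_cpt(cohort$trials)
  out$records <- merge(out$records, dp, by = "scan_id", sort = FALSE)
  out
}

#' Sex-balancing selection counts
#'
#' Chooses how many ADHD male and female scans to retain per
#' permutation iteration so the ADHD male count matches the control
#' male count (the study's balancing rule), keeping as many ADHD
#' female scans as available up to the control female count scaled by
#' the same ratio.
#'
#' @param records Per-scan analysis table.
#' @return List `n_male`, `n_female`.
#' @export
balanced_selection_counts <- function(records) {
  g <- normalize_group(records$group)
  s <- normalize_sex(records$sex)
  ctrl_m <- sum(g == "control" & s == "M")
  adhd_m <- sum(g == "ADHD" & s == "M")
  adhd_f <- sum(g == "ADHD" & s == "F")
  ctrl_f <- sum(g == "control" & s == "F")
  n_male <- min(ctrl_m, adhd_m)
  n_female <- min(adhd_f, max(1L, round(n_male * ctrl_f / max(ctrl_m, 1L))))
  list(n_male = n_male, n_female = n_female)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on a synthetic study: simulate the cohort
#' and an independent reference sample, write the study layout,
#' censor and select frames, build connectivity matrices, define the
#' anticorrelated mask from the reference sample, average the metric,
#' score the CPT, run the secondary FD QC, fit Models 1-3 with AIC
#' selection, edgewise fits with BH-FDR and summed-t maps,
#' gender-balanced permutation, and brain-behavior models. Writes
#' `report.json` (machine readable, deterministic under the config
#' seed) and `summary.txt` to `out_dir`. Reruns with an unchanged
#' config reproduce the report byte for byte.
#'
#' @param config A YAML file path or a list. Recognized keys:
#'   `cohort` (arguments of [synthetic_config()]), `reference`
#'   (`n_subjects`), `qc` (`fd_threshold_mm`, `target_minutes`,
#'   `head_radius_mm`, `secondary_alpha`, `secondary_max_removed`),
#'   `mask` (`scope`, `rule`, `r_cut`, `fraction`, `average`),
#'   `permutation` (`n_perm`, optional `n_male`, `n_female`), `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- as.integer(cfg$seed %||% 1L)
  qc_cfg <- cfg$qc %||% list()
  mask_cfg <- cfg$mask %||% list()
  perm_cfg <- cfg$permutation %||% list()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------
  cohort_args <- cfg$cohort %||% list()
  cohort_args$seed <- stage_seed(seed, "simulate")
  sc <- do.call(synthetic_config, cohort_args)
  cohort <- run_stage("simulate", {
    ch <- generate_cohort(sc)
    write_cohort(ch, file.path(out_dir, "data"))
    ch
  })

  # -- reference mask ------------------------------------------------
  mask <- run_stage("mask", {
    ref_args <- cohort_args
    ref_args$n_subjects_per_group <- as.integer(
      ceiling((cfg$reference$n_subjects %||% 30L) / 2))
    ref_args$p_wave2 <- 0
    ref_args$seed <- stage_seed(seed, "reference")
    ref_cohort <- generate_cohort(do.call(synthetic_config, ref_args))
    ref_mats <- lapply(ref_cohort$timeseries, function(ts) {
      fd <- compute_fd(ref_cohort$motion[[ts$scan_id]],
                       qc_cfg$head_radius_mm %||% 50)
      correlation_matrix(ts, censor_frames(fd,
        qc_cfg$fd_threshold_mm %||% 0.2))
    })
    m <- build_mask(ref_mats, cohort$parcellation,
                    scope = mask_cfg$scope %||% "dmn_to_taskpos",
                    rule = mask_cfg$rule %||% "density",
                    r_cut = mask_cfg$r_cut %||% -0.35,
                    fraction = mask_cfg$fraction %||% 0.05,
                    average = mask_cfg$average %||% "z")
    write_mask(m, file.path(out_dir, "mask.tsv"))
    m
  })

  # -- fd / connectivity / metric / cpt ------------------------------
  proc <- run_stage("connectivity", {
    process_cohort(cohort, mask,
                   threshold_mm = qc_cfg$fd_threshold_mm %||% 0.2,
                   target_minutes = qc_cfg$target_minutes %||% 4,
                   head_radius_mm = qc_cfg$head_radius_mm %||% 50,
                   seed = stage_seed(seed, "frames"))
  })
  records <- proc$records

  # -- secondary FD QC ----------------------------------------------
  sqc <- run_stage("secondary_qc", {
    secondary_fd_qc(records,
                    alpha = qc_cfg$secondary_alpha %||% 0.05,
                    max_removed = qc_cfg$secondary_max_removed %||% 30L)
  })
  records <- records[!records$scan_id %in% sqc$removed, , drop = FALSE]
  run_stage("records", write_records(records,
                                     file.path(out_dir, "records.csv")))

  # -- models --------------------------------------------------------
  fits <- run_stage("fit", {
    out <- lapply(1:3, function(m) {
      # higher-order interaction cells can be empty in small cohorts;
      # an unfittable model is recorded, not fatal
      tryCatch(fit_lmm(records, "avg_neg_conn", model_spec(m)),
               error = function(e) list(failed = conditionMessage(e),
                                        spec = model_spec(m)))
    })
    if (is.null(out[[1]]$coefficients)) {
      stop("Model 1 could not be fitted: ", out[[1]]$failed)
    }
    out
  })
  fitted_ok <- vapply(fits, function(f) !is.null(f$coefficients),
                      logical(1))
  selection <- select_model(fits[fitted_ok])

  ew <- run_stage("edgewise", {
    ev <- edge_values(proc$matrices[records$scan_id], mask)
    edgewise_fit(ev, records)
  })
  tmap <- summed_t_map(ew, "groupADHD", "positive",
                       n_rois = n_rois(cohort$parcellation))

  perm <- run_stage("permute", {
    counts <- if (!is.null(perm_cfg$n_male)) {
      list(n_male = perm_cfg$n_male, n_female = perm_cfg$n_female)
    } else {
      balanced_selection_counts(records)
    }
    gender_balanced_permutation(
      records, model_spec(1), "avg_neg_conn",
      n_male = counts$n_male, n_female = counts$n_female,
      n_perm = perm_cfg$n_perm %||% 200L,
      seed = stage_seed(seed, "permute"))
  })

  behavior <- run_stage("behavior", {
    list(both = brain_behavior_fit(records, "both"),
         easy = brain_behavior_fit(records, "easy"),
         difficult = brain_behavior_fit(records, "difficult"))
  })

  # -- report --------------------------------------------------------
  coef_tab <- function(f) f$coefficients
  report <- list(
    seed = seed,
    config_hash = substr(digest_config(cfg), 1, 16),
    cohort = list(
      n_subjects = length(unique(cohort$phenotypes$subject_id)),
      n_scans = nrow(cohort$phenotypes),
      n_scans_included = nrow(records),
      n_removed_secondary_qc = length(sqc$removed)
    ),
    qc = list(per_scan = proc$qc,
              secondary = list(removed = sqc$removed,
                               final_r = sqc$r,
                               final_p = sqc$p_value)),
    mask = list(
      scope = attr(mask, "scope"), rule = attr(mask, "rule"),
      n_candidates = nrow(candidate_edges(
        cohort$parcellation, attr(mask, "scope"))),
      n_edges = nrow(mask),
      density_pct = mask_density_pct(
        nrow(mask),
        nrow(candidate_edges(cohort$parcellation, attr(mask, "scope"))))
    ),
    group_means = list(
      control = mean(records$avg_neg_conn[records$group == "control"]),
      adhd = mean(records$avg_neg_conn[records$group == "ADHD"])
    ),
    models = list(
      fits = lapply(fits, function(f) {
        if (is.null(f$coefficients)) {
          list(name = f$spec$name, failed = f$failed)
        } else {
          list(name = f$spec$name, df = f$df_model, aic = f$aic,
               coefficients = coef_tab(f))
        }
      }),
      best = selection$best$spec$name,
      aic_table = selection$table
    ),
    edgewise = list(
      n_edges = nrow(mask),
      n_discoveries = vapply(
        split(ew$q, ew$term),
        function(q) sum(q < 0.05, na.rm = TRUE), integer(1)),
      summed_t_group_top = utils::head(
        tmap[order(-abs(tmap$summed_t)), ], 10)
    ),
    permutation = list(n_perm = perm$n_perm,
                       mean_p = as.list(perm$mean_p)),
    behavior = lapply(behavior, coef_tab)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(.report_summary(report), file.path(out_dir, "summary.txt"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_config <- function(cfg) {
  # cheap order-stable structural checksum of the serialized config
  s <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  codes <- utf8ToInt(s)
  sprintf("%08x%08x",
          sum(codes * (seq_along(codes) %% 97L)) %% 2147483647L,
          sum(codes) %% 2147483647L)
}

.report_summary <- function(report) {
  m1 <- report$models$fits[[1]]$coefficients
  fmt_term <- function(term) {
    row <- m1[m1$term == term, ]
    sprintf("  %-14s B = %+.4f, t = %+.2f, p = %.4g",
            term, row$estimate, row$t, row$p)
  }
  c(
    sprintf("Scans: %d simulated, %d included (%d removed by secondary FD QC)",
            report$cohort$n_scans, report$cohort$n_scans_included,
            report$cohort$n_removed_secondary_qc),
    sprintf("Mask: %d of %d candidate edges (%d%% density)",
            report$mask$n_edges, report$mask$n_candidates,
            report$mask$density_pct),
    sprintf("Averaged negative connectivity: control %.3f, ADHD %.3f",
            report$group_means$control, report$group_means$adhd),
    sprintf("Best model by AIC: %s", report$models$best),
    "Model 1 effects:",
    vapply(c("groupADHD", "sexF", "age_c"), fmt_term, character(1)),
    sprintf("Gender-balanced permutation (%d iterations): mean p(group) = %.4g",
            report$permutation$n_perm, report$permutation$mean_p$groupADHD)
  )
}
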