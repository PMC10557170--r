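# File-based pipeline orchestration: YAML config -> EDF/CSV/TSV artifacts.

#' Default pipeline configuration
#'
#' Nested configuration mirroring the generator, detector, spectral and trial
#' parameter sets, plus a global seed. [read_config()] merges a user YAML
#' file over these defaults and rejects unknown keys, so configs are typo-safe
#' and every run can be reproduced from the resolved config written next to
#' its outputs.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    cohort = list(n_subjects = 4, recording_duration = 1800,
                  sampling_rate = 125, hypnogram_type = "cycling"),
    subject = list(age_baseline = 60, spindle_density = 2,
                   spindle_amplitude = 50, background_rms = 10,
                   spindle_coherence_baseline = 0.58,
                   coherence_decline_per_visit = 0.04,
                   background_coherence = 0.44),
    detector = list(fc = 13.5, cycles = 7, threshold_multiplier = 4.5,
                    boundary_multiplier = 2, min_duration = 0.5, max_duration = 3, merge_gap = 0.5,
                    q_min = 0, smoothing_window = 0.1),
    spectral = list(band_low = 10, band_high = 16, epoch_length = 10,
                    half_bandwidth = 1),
    trial = list(n_min = 10, n_max = 150, n_step = 5, reps = 10000,
                 alpha = 0.05, target_power = 0.95)
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]])) {
      if (!is.list(user[[key]])) stop("config key must be a section: ", full)
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Read and resolve a pipeline configuration
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides optional named list merged over the file (e.g. a
#'   command-line `--seed`).
#' @return Fully resolved configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

config_objects <- function(cfg) {
  list(
    cohort = cohort_spec(n_subjects = cfg$cohort$n_subjects, seed = cfg$seed,
                         recording_duration = cfg$cohort$recording_duration,
                         sampling_rate = cfg$cohort$sampling_rate,
                         hypnogram_type = cfg$cohort$hypnogram_type),
    template = do.call(subject_spec, cfg$subject),
    detector = do.call(detector_params, cfg$detector),
    spectral = do.call(spectral_params, cfg$spectral),
    design = trial_design(n_grid = seq(cfg$trial$n_min, cfg$trial$n_max,
                                       by = cfg$trial$n_step),
                          reps = cfg$trial$reps, alpha = cfg$trial$alpha,
                          target_power = cfg$trial$target_power,
                          seed = cfg$seed)
  )
}

write_resolved_config <- function(cfg, out_dir) {
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
}

pipeline_log <- function(...) message(sprintf(...))

#' Simulate a synthetic paired cohort to disk
#'
#' Writes, per subject and visit, an EDF recording and a hypnogram CSV, plus
#' a cohort-wide ground-truth TSV and a manifest CSV listing every file with
#' its seeds. Rerunning with the same config reproduces the text outputs
#' byte-identically.
#'
#' @param cfg configuration list from [read_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
run_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  obj <- config_objects(cfg)
  cohort <- generate_paired_cohort(obj$cohort, obj$template)
  gt_path <- file.path(out_dir, "ground_truth.tsv")
  manifest <- list()
  first <- TRUE
  for (subj in cohort) {
    for (visit in c("baseline", "followup")) {
      v <- subj[[visit]]
      base <- sprintf("%s_%s", subj$subject_id, visit)
      edf <- file.path(out_dir, paste0(base, ".edf"))
      hyp <- file.path(out_dir, paste0(base, "_hypnogram.csv"))
      write_edf(v$recording, edf, patient_id = subj$subject_id, recording_id = visit)
      write_hypnogram_csv(v$hypnogram, hyp)
      write_ground_truth_tsv(v$ground_truth, gt_path, subject_id = subj$subject_id,
                             visit = visit, append = !first)
      first <- FALSE
      age <- if (visit == "baseline") subj$age_baseline else subj$age_followup
      manifest[[length(manifest) + 1]] <- data.frame(
        subject_id = subj$subject_id, visit = visit, age_years = fmt_num(age),
        edf = basename(edf), hypnogram = basename(hyp),
        n_ground_truth_events = nrow(v$ground_truth), seed = cfg$seed,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_resolved_config(cfg, out_dir)
  pipeline_log("simulate: wrote %d recordings to %s", nrow(manifest), out_dir)
  invisible(manifest)
}

read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", dir)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Detect spindles for every recording in a simulated/ingested directory
#'
#' Reads each EDF + hypnogram pair listed in the manifest, band-pass filters
#' it, runs the wavelet detector and writes a combined events TSV. Failures
#' on individual recordings are reported and skipped; the run continues.
#'
#' @param cfg configuration list.
#' @param rec_dir directory holding manifest, EDFs and hypnograms.
#' @param out_dir output directory.
#' @return List with the events data frame and a character vector of failed
#'   recording ids, invisibly.
#' @export
run_detect <- function(cfg, rec_dir, out_dir = rec_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- config_objects(cfg)
  manifest <- read_manifest(rec_dir)
  all_events <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      rec <- bandpass(read_edf(file.path(rec_dir, row$edf)))
      hyp <- read_hypnogram_csv(file.path(rec_dir, row$hypnogram))
      ev <- detect_spindles(rec, hyp, obj$detector)
      n2_min <- sum(unclass(hyp) == "N2") * 30 / 60
      if (n2_min > 0) {
        dens <- spindle_density(ev, n2_min)
        pipeline_log("detect: %s %s: %d events, %.2f/min pooled",
                     row$subject_id, row$visit, nrow(ev),
                     dens$density[dens$channel == "all"])
      }
      ev
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s_%s", row$subject_id, row$visit))
      pipeline_log("detect: FAILED %s %s: %s", row$subject_id, row$visit,
                   conditionMessage(res))
      next
    }
    if (nrow(res)) {
      res <- cbind(subject_id = row$subject_id, visit = row$visit,
                   as.data.frame(res), stringsAsFactors = FALSE)
      all_events[[length(all_events) + 1]] <- res
    }
  }
  events <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame(subject_id = character(0), visit = character(0),
               channel = character(0), start = numeric(0), end = numeric(0),
               duration = numeric(0), mean_power = numeric(0),
               peak_frequency = numeric(0), quality_q = numeric(0))
  out <- events
  for (cn in c("start", "end", "duration", "mean_power", "peak_frequency", "quality_q")) {
    out[[cn]] <- fmt_num(out[[cn]])
  }
  names(out) <- c("subject_id", "visit", "channel", "start_s", "end_s",
                  "duration_s", "mean_power_uv2", "peak_freq_hz", "q")
  utils::write.table(out, file.path(out_dir, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (length(failures)) warning("detection failed for: ", paste(failures, collapse = ", "))
  invisible(list(events = events, failures = failures))
}

read_events_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(subject_id = df$subject_id, visit = df$visit, channel = df$channel,
             start = df$start_s, end = df$end_s, duration = df$duration_s,
             mean_power = df$mean_power_uv2, peak_frequency = df$peak_freq_hz,
             quality_q = df$q, stringsAsFactors = FALSE)
}

#' Compute per-recording sigma metrics from pipeline artifacts
#'
#' @param cfg configuration list.
#' @param rec_dir directory with manifest/EDF/hypnograms.
#' @param events_path events TSV from [run_detect()].
#' @param out_dir output directory for `metrics.csv`.
#' @return The metrics data frame, invisibly.
#' @export
run_metrics <- function(cfg, rec_dir, events_path = file.path(rec_dir, "events.tsv"),
                        out_dir = rec_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!file.exists(events_path)) stop("events file not found: ", events_path)
  obj <- config_objects(cfg)
  manifest <- read_manifest(rec_dir)
  events <- read_events_tsv(events_path)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- bandpass(read_edf(file.path(rec_dir, row$edf)))
    hyp <- read_hypnogram_csv(file.path(rec_dir, row$hypnogram))
    ev <- events[events$subject_id == row$subject_id & events$visit == row$visit, ,
                 drop = FALSE]
    rows[[length(rows) + 1]] <- compute_subject_metrics(
      rec, hyp, ev, obj$spectral, subject_id = row$subject_id,
      visit = row$visit, age = as.numeric(row$age_years))
  }
  metrics <- do.call(rbind, rows)
  ok <- is.finite(metrics$spindle_sigma_power)
  if (sum(ok) >= 2 && sum(is.finite(metrics$n2_sigma_power)) >= 2) {
    ksp <- ks_compare(metrics$n2_sigma_power, metrics$spindle_sigma_power[ok])
    ksc <- ks_compare(metrics$n2_sigma_coherence, metrics$spindle_sigma_coherence[ok])
    pipeline_log("metrics: NREM2 vs spindle sigma power KS D = %.3f (p = %.3g); coherence D = %.3f (p = %.3g)",
                 ksp$D, ksp$p_value, ksc$D, ksc$p_value)
  }
  out <- data.frame(subject_id = metrics$subject_id, visit = metrics$visit,
                    age_years = fmt_num(metrics$age),
                    n2_sigma_power_uv2 = fmt_num(metrics$n2_sigma_power),
                    n2_sigma_coh = fmt_num(metrics$n2_sigma_coherence),
                    spindle_sigma_power_uv2 = fmt_num(metrics$spindle_sigma_power),
                    spindle_sigma_coh = fmt_num(metrics$spindle_sigma_coherence),
                    spindle_density_per_min = fmt_num(metrics$spindle_density),
                    n_epochs_used = metrics$n_epochs_used,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(out_dir, "metrics.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(metrics)
}

read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(subject_id = df$subject_id, visit = df$visit, age = df$age_years,
             n2_sigma_power = df$n2_sigma_power_uv2,
             n2_sigma_coherence = df$n2_sigma_coh,
             spindle_sigma_power = df$spindle_sigma_power_uv2,
             spindle_sigma_coherence = df$spindle_sigma_coh,
             spindle_density = df$spindle_density_per_min,
             n_epochs_used = df$n_epochs_used, stringsAsFactors = FALSE)
}

#' Simulated-trial power analysis over a metrics table
#'
#' Builds power curves for the NREM2-sigma and spindle-sigma coherence
#' metrics (subsampled paired t-test trials) and writes a combined power-curve
#' CSV plus a JSON summary of the minimal sample size at the target power.
#'
#' @param cfg configuration list.
#' @param metrics_path metrics CSV from [run_metrics()], or a metrics data
#'   frame.
#' @param out_dir output directory.
#' @param metrics_cols metric columns to analyse.
#' @return Named list of `power_curve` objects, invisibly.
#' @export
run_trial_power <- function(cfg, metrics_path, out_dir,
                            metrics_cols = c("n2_sigma_coherence",
                                             "spindle_sigma_coherence")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- if (is.character(metrics_path)) read_metrics_csv(metrics_path) else metrics_path
  if (nrow(metrics) == 0) stop("empty metrics table")
  obj <- config_objects(cfg)
  curves <- list()
  summary <- list()
  rows <- list()
  for (mc in metrics_cols) {
    paired <- metrics_to_paired(metrics, mc)
    cv <- power_curve(paired, obj$design, metric_name = mc)
    curves[[mc]] <- cv
    minn <- tryCatch(min_sample_size(cv), error = function(e) NA_integer_)
    summary[[mc]] <- list(min_n = minn, target_power = obj$design$target_power,
                          n_subjects = nrow(paired))
    rows[[mc]] <- data.frame(n = cv$n, power = fmt_num(cv$power),
                             mc_se = fmt_num(cv$mc_se), reps = cv$reps,
                             metric_name = mc, stringsAsFactors = FALSE)
    pipeline_log("trial-power: %s min n at %.0f%% power: %s", mc,
                 100 * obj$design$target_power,
                 if (is.na(minn)) "not reached on grid" else minn)
  }
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "power_curves.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "power_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_resolved_config(cfg, out_dir)
  invisible(curves)
}

#' Run the full pipeline: simulate, detect, metrics, trial power
#'
#' @param cfg configuration list from [read_config()].
#' @param out_dir output directory for all artifacts.
#' @return Named list of `power_curve` objects, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  run_simulate(cfg, out_dir)
  run_detect(cfg, out_dir)
  run_metrics(cfg, out_dir)
  run_trial_power(cfg, file.path(out_dir, "metrics.csv"), out_dir)
}
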