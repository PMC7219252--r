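#' Specification of a synthetic before/after study
#'
#' Describes a multi-subject, multi-protocol, multi-session study of the kind
#' the pipeline analyzes: per session a pre-treatment EEG, a post-treatment
#' EEG and a clean calibration baseline, plus repeated MVC EMG trials before
#' and after. Per-protocol effect parameters plant ground-truth changes: the
#' post-EEG mu-band power is the pre power times `mu_factor`, and the after
#' EMG trials' spectral median and plateau RMS are the before values times
#' `mpf_factor` and `rms_factor`.
#'
#' @param subjects number of subjects (default 7).
#' @param protocols named list of protocol effect lists with elements
#'   `mu_factor`, `mpf_factor`, `rms_factor` (all default 1 = no effect).
#' @param sessions number of sessions per protocol, first..last (default 4).
#' @param eeg_duration pre/post EEG length in seconds (default 360, i.e. 6 min
#'   of rest, of which the edge-trimmed interior 4 min are analyzed).
#' @param baseline_duration calibration baseline length in seconds (default 60).
#' @param emg_trials MVC trials per measurement (default 5).
#' @param artifact_events_per_min rate of injected blink/muscle/movement
#'   artifacts in the pre/post EEG (default 2 per minute; the baseline stays
#'   clean).
#' @param eeg an [eeg_spec()]-like parameter list: `channels`,
#'   `band_amplitudes`, `background_exponent`, `background_scale`,
#'   `sampling_rate`.
#' @param emg an [emg_spec()]-like parameter list: `duration`, `sampling_rate`,
#'   `target_mpf`, `rms_scale`, `onset_time`, `peak_force`, `plateau_duration`.
#' @return an object of class `study_spec`.
#' @export
study_spec <- function(subjects = 7,
                       protocols = list(CMT = list(), ACMT = list(),
                                        SCMT = list(mu_factor = 0.78)),
                       sessions = 4,
                       eeg_duration = 360,
                       baseline_duration = 60,
                       emg_trials = 5,
                       artifact_events_per_min = 2,
                       eeg = list(),
                       emg = list()) {
  protocols <- lapply(protocols, function(p) {
    utils::modifyList(list(mu_factor = 1, mpf_factor = 1, rms_factor = 1), p)
  })
  if (is.null(names(protocols)) || any(names(protocols) == "")) {
    stop("protocols must be a named list", call. = FALSE)
  }
  structure(list(subjects = subjects, protocols = protocols,
                 sessions = sessions, eeg_duration = eeg_duration,
                 baseline_duration = baseline_duration,
                 emg_trials = emg_trials,
                 artifact_events_per_min = artifact_events_per_min,
                 eeg = eeg, emg = emg),
            class = "study_spec")
}

#' Simulate a complete synthetic study on disk
#'
#' Writes, for every subject x protocol x session, pre/post/baseline EEG as
#' EDF and before/after MVC EMG + force trials as two-column CSV, all readable
#' by the io layer, together with a ground-truth JSON sidecar recording every
#' planted parameter. Fully deterministic given `seed`; changing the seed
#' changes the data but not the layout.
#'
#' @param spec a [study_spec()].
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @return a `study_layout`: the nested list of file paths plus the ground
#'   truth, invisibly also written to `out_dir/ground_truth.json`.
#' @export
simulate_study <- function(spec, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory %s", out_dir), call. = FALSE)
  }
  seed_base <- as.integer(seed)
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    # double arithmetic: exact well past 2^31, avoids integer overflow
    as.integer((as.numeric(seed_base) * 48271 + counter * 10007) %% 2147483629)
  }
  eeg_args <- utils::modifyList(
    list(channels = c("Cz", "C3", "C4"),
         band_amplitudes = c(theta = 4, mu = 6, beta = 3, gamma = 1.5),
         background_exponent = 1, background_scale = 5, sampling_rate = 256),
    spec$eeg)
  emg_args <- utils::modifyList(
    list(duration = 8, sampling_rate = 2000, target_mpf = 120,
         rms_scale = 200, onset_time = 0.5, peak_force = 300,
         plateau_duration = 7),
    spec$emg)

  make_spec <- function(dur, mu_factor = 1, sd) {
    amps <- eeg_args$band_amplitudes
    if (is.list(amps)) {
      amps <- lapply(amps, function(a) { a[["mu"]] <- a[["mu"]] * sqrt(mu_factor); a })
    } else {
      amps[["mu"]] <- amps[["mu"]] * sqrt(mu_factor)
    }
    eeg_spec(duration = dur, sampling_rate = eeg_args$sampling_rate,
             channels = eeg_args$channels, band_amplitudes = amps,
             background_exponent = eeg_args$background_exponent,
             background_scale = eeg_args$background_scale, seed = sd)
  }
  random_schedule <- function(dur, sd) {
    n_ev <- round(spec$artifact_events_per_min * dur / 60)
    if (n_ev < 1L) return(artifact_schedule())
    kinds <- c("blink", "muscle_burst", "movement")
    with_seed(sd, {
      events <- lapply(seq_len(n_ev), function(i) {
        list(channels = sample(eeg_args$channels, 1L),
             start = stats::runif(1, 1, dur - 2),
             duration = stats::runif(1, 0.3, 0.8),
             kind = kinds[(i - 1L) %% 3L + 1L],
             amplitude = stats::runif(1, 300, 800))
      })
      artifact_schedule(events)
    })
  }
  write_eeg <- function(path, dur, mu_factor, artifacts) {
    rec <- make_eeg(make_spec(dur, mu_factor, next_seed()))
    if (artifacts) {
      rec <- inject_artifacts(rec, random_schedule(dur, next_seed()),
                              next_seed())$recording
    }
    write_edf(rec, path)
    path
  }
  write_trials <- function(dir_, tag, mpf, rms) {
    lapply(seq_len(spec$emg_trials), function(t) {
      es <- emg_spec(duration = emg_args$duration,
                     sampling_rate = emg_args$sampling_rate,
                     target_mpf = mpf, rms_scale = rms,
                     onset_time = emg_args$onset_time,
                     peak_force = emg_args$peak_force,
                     plateau_duration = emg_args$plateau_duration,
                     seed = next_seed())
      trial <- make_emg_trial(es, trial_id = sprintf("%s_%d", tag, t),
                              session_tag = tag)
      paths <- list(emg = file.path(dir_, sprintf("emg_%s_%d.csv", tag, t)),
                    force = file.path(dir_, sprintf("force_%s_%d.csv", tag, t)))
      write_emg_csv(trial, paths$emg, paths$force)
      paths
    })
  }

  subjects <- lapply(seq_len(spec$subjects), function(s) {
    prots <- lapply(names(spec$protocols), function(p) {
      eff <- spec$protocols[[p]]
      sess <- lapply(seq_len(spec$sessions), function(k) {
        d <- file.path(out_dir, sprintf("sub%02d", s), p, sprintf("sess%d", k))
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        list(
          pre = write_eeg(file.path(d, "pre.edf"), spec$eeg_duration, 1, TRUE),
          post = write_eeg(file.path(d, "post.edf"), spec$eeg_duration,
                           eff$mu_factor, TRUE),
          baseline = write_eeg(file.path(d, "baseline.edf"),
                               spec$baseline_duration, 1, FALSE),
          emg_before = write_trials(d, "before", emg_args$target_mpf,
                                    emg_args$rms_scale),
          emg_after = write_trials(d, "after",
                                   emg_args$target_mpf * eff$mpf_factor,
                                   emg_args$rms_scale * eff$rms_factor)
        )
      })
      names(sess) <- sprintf("sess%d", seq_len(spec$sessions))
      sess
    })
    names(prots) <- names(spec$protocols)
    prots
  })
  names(subjects) <- sprintf("sub%02d", seq_len(spec$subjects))

  layout <- structure(
    list(subjects = subjects,
         ground_truth = list(spec = unclass(spec), seed = seed_base),
         root = out_dir),
    class = "study_layout"
  )
  jsonlite::write_json(layout$ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  layout
}

#' Rebuild a study layout from a simulated study directory
#'
#' Reconstructs the `study_layout` of a directory written by
#' [simulate_study()] from its `ground_truth.json` sidecar, so a study can be
#' simulated and analyzed in separate processes.
#'
#' @param root the directory passed to [simulate_study()].
#' @return a `study_layout`.
#' @export
load_study_layout <- function(root) {
  gt_path <- file.path(root, "ground_truth.json")
  if (!file.exists(gt_path)) {
    stop(sprintf("%s has no ground_truth.json; not a simulated study?", root),
         call. = FALSE)
  }
  gt <- jsonlite::read_json(gt_path)
  spec <- gt$spec
  subjects <- lapply(seq_len(spec$subjects), function(s) {
    prots <- lapply(names(spec$protocols), function(p) {
      sess <- lapply(seq_len(spec$sessions), function(k) {
        d <- file.path(root, sprintf("sub%02d", s), p, sprintf("sess%d", k))
        trials <- function(tag) lapply(seq_len(spec$emg_trials), function(t)
          list(emg = file.path(d, sprintf("emg_%s_%d.csv", tag, t)),
               force = file.path(d, sprintf("force_%s_%d.csv", tag, t))))
        list(pre = file.path(d, "pre.edf"), post = file.path(d, "post.edf"),
             baseline = file.path(d, "baseline.edf"),
             emg_before = trials("before"), emg_after = trials("after"))
      })
      names(sess) <- sprintf("sess%d", seq_len(spec$sessions))
      sess
    })
    names(prots) <- names(spec$protocols)
    prots
  })
  names(subjects) <- sprintf("sub%02d", seq_len(spec$subjects))
  structure(list(subjects = subjects, ground_truth = gt, root = root),
            class = "study_layout")
}

# EEG chain for one recording: trim -> high-pass -> ASR -> epoch -> reject ->
# Welch -> band powers. Returns the table plus quality metrics.
process_eeg <- function(path, model, cfg, scheme) {
  rec <- read_edf(path)
  rec <- trim_edges(rec, cfg$eeg$trim_s)
  rec <- highpass_fir(rec, cfg$eeg$highpass_hz)
  ap <- asr_params(cfg$eeg$asr$window_s, cfg$eeg$asr$cutoff_sd,
                   cfg$eeg$asr$overlap)
  rec <- asr_clean(rec, model, ap)
  flagged <- attr(rec, "flagged_fraction")
  eset <- epoch_recording(rec, cfg$eeg$epoch_s)
  eset <- reject_epochs(eset, rejection_criteria(
    cfg$eeg$reject$p2p_min_uV, cfg$eeg$reject$p2p_max_uV,
    cfg$eeg$reject$kurtosis_z, cfg$eeg$epoch_s))
  psd <- welch_psd(eset)
  list(table = band_powers(psd, scheme),
       kept = sum(eset$keep_mask), total = length(eset$keep_mask),
       flagged_fraction = flagged)
}

#' Run the full study pipeline
#'
#' Executes trim, high-pass, ASR (calibrated on each session's baseline),
#' epoching, rejection, Welch PSD and band-power ratios for every EEG pair,
#' and filtering, onset detection, segment selection, MPF/RMS and fatigue
#' ratios for every EMG set; then the paired statistical layer across
#' subjects. Deterministic given the layout's files and the configuration.
#'
#' @param layout a `study_layout` from [simulate_study()] (or assembled by
#'   hand around real files with the same shape).
#' @param config a configuration list from [load_config()] /
#'   [default_config()].
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` plus per-table CSV files.
#' @return a `run_report`: data frames `sessions`, `treatment`, `group`,
#'   `stats` and `provenance`.
#' @export
run_study <- function(layout, config = default_config(), out_dir = NULL) {
  cfg <- validate_config(config)
  scheme <- band_scheme(cfg$bands)
  op <- onset_params(cfg$emg$onset_fraction, cfg$emg$segment_s)
  spectral_metrics <- c("relative_mu", "absolute_theta", "absolute_mu",
                        "absolute_beta", "absolute_gamma")
  ap <- asr_params(cfg$eeg$asr$window_s, cfg$eeg$asr$cutoff_sd,
                   cfg$eeg$asr$overlap)

  rows <- list()
  failures <- character()
  for (sub in names(layout$subjects)) {
    for (prot in names(layout$subjects[[sub]])) {
      sessions <- layout$subjects[[sub]][[prot]]
      for (k in seq_along(sessions)) {
        se <- sessions[[k]]
        res <- tryCatch({
          baseline <- highpass_fir(read_edf(se$baseline), cfg$eeg$highpass_hz)
          model <- asr_calibrate(baseline, ap)
          pre <- process_eeg(se$pre, model, cfg, scheme)
          post <- process_eeg(se$post, model, cfg, scheme)
          eeg_rows <- do.call(rbind, lapply(
            pre$table$channel_labels, function(ch) {
              do.call(rbind, lapply(spectral_metrics, function(m) {
                sr <- session_ratio(pre$table, post$table, m, ch)
                data.frame(subject = sub, protocol = prot, session = k,
                           channel = ch, metric = m, before = sr$before,
                           after = sr$after, ratio = sr$ratio,
                           percent_change = sr$percent_change)
              }))
            }))
          before_idx <- lapply(se$emg_before, function(p)
            fatigue_indices(read_emg_csv(p$emg, p$force), op))
          after_idx <- lapply(se$emg_after, function(p)
            fatigue_indices(read_emg_csv(p$emg, p$force), op))
          fr <- fatigue_ratio(before_idx, after_idx)
          emg_rows <- do.call(rbind, lapply(c("mpf", "rms"), function(m) {
            sr <- fr[[m]]
            data.frame(subject = sub, protocol = prot, session = k,
                       channel = "EMG", metric = m,
                       before = sr$before, after = sr$after, ratio = sr$ratio,
                       percent_change = sr$percent_change)
          }))
          rbind(eeg_rows, emg_rows)
        }, error = function(e) {
          failures <<- c(failures, sprintf("%s/%s/sess%d: %s", sub, prot, k,
                                           conditionMessage(e)))
          NULL
        })
        if (!is.null(res)) rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (!length(rows)) {
    stop(paste(c("no usable session in the study:", failures),
               collapse = "\n  "), call. = FALSE)
  }
  sessions_df <- do.call(rbind, rows)
  rownames(sessions_df) <- NULL

  # Treatment change: last-session ratio against first-session ratio.
  key <- c("subject", "protocol", "channel", "metric")
  split_on <- interaction(sessions_df$subject, sessions_df$protocol,
                          sessions_df$channel, sessions_df$metric,
                          drop = TRUE, lex.order = TRUE)
  treatment_df <- do.call(rbind, lapply(split(sessions_df, split_on), function(g) {
    g <- g[order(g$session), ]
    first <- make_session_ratio(g$metric[1], g$before[1], g$after[1])
    last <- make_session_ratio(g$metric[1], g$before[nrow(g)], g$after[nrow(g)])
    data.frame(subject = g$subject[1], protocol = g$protocol[1],
               channel = g$channel[1], metric = g$metric[1],
               first_ratio = first$ratio, last_ratio = last$ratio,
               treatment_change = treatment_change(first, last))
  }))
  rownames(treatment_df) <- NULL

  group_split <- interaction(treatment_df$protocol, treatment_df$channel,
                             treatment_df$metric, drop = TRUE, lex.order = TRUE)
  group_df <- do.call(rbind, lapply(split(treatment_df, group_split), function(g) {
    sess <- sessions_df[sessions_df$protocol == g$protocol[1] &
                          sessions_df$channel == g$channel[1] &
                          sessions_df$metric == g$metric[1], ]
    data.frame(protocol = g$protocol[1], channel = g$channel[1],
               metric = g$metric[1], n_subjects = nrow(g),
               mean_session_change = mean(sess$percent_change),
               mean_first_ratio = mean(g$first_ratio),
               mean_last_ratio = mean(g$last_ratio),
               mean_treatment_change = mean(g$treatment_change))
  }))
  rownames(group_df) <- NULL

  stats_df <- do.call(rbind, lapply(split(treatment_df, group_split), function(g) {
    if (nrow(g) < 3L) {
      return(data.frame(protocol = g$protocol[1], channel = g$channel[1],
                        metric = g$metric[1], test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        n = nrow(g), significant = NA))
    }
    res <- tryCatch(
      analyze_metric(paired_sample(g$first_ratio, g$last_ratio, g$metric[1]),
                     g$metric[1], cfg$stats$policy, cfg$stats$alpha),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(protocol = g$protocol[1], channel = g$channel[1],
                        metric = g$metric[1], test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        n = nrow(g), significant = NA))
    }
    data.frame(protocol = g$protocol[1], channel = g$channel[1],
               metric = g$metric[1], test = res$test_name,
               statistic = res$statistic, p_value = res$p_value,
               n = res$n_effective, significant = res$significant)
  }))
  rownames(stats_df) <- NULL

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  report <- structure(
    list(sessions = sessions_df, treatment = treatment_df, group = group_df,
         stats = stats_df, failures = failures,
         provenance = list(config = cfg,
                           config_md5 = unname(tools::md5sum(cfg_file)),
                           package_version = as.character(
                             utils::packageVersion("musupp")))),
    class = "run_report"
  )
  unlink(cfg_file)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(sessions = sessions_df, treatment = treatment_df, group = group_df,
           stats = stats_df, failures = failures,
           provenance = report$provenance),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    for (tb in c("sessions", "treatment", "group", "stats")) {
      utils::write.csv(report[[tb]], file.path(out_dir, paste0(tb, ".csv")),
                       row.names = FALSE)
    }
  }
  report
}
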