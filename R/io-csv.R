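#' Read a paired EMG + force trial from two-column CSV files
#'
#' Each file has a header `time_s,value`; the two files must have equal row
#' counts and a common uniform time step (tolerance 1 ppm), from which the
#' sampling rate is inferred. Values are taken as-is (EMG in uV, force in
#' load-cell units) -- readers never resample or rescale.
#'
#' @param emg_path,force_path CSV paths.
#' @param trial_id,session_tag metadata passed to [emg_trial()].
#' @return an [emg_trial()].
#' @export
read_emg_csv <- function(emg_path, force_path, trial_id = basename(emg_path),
                         session_tag = NA_character_) {
  emg <- read_timeseries_csv(emg_path)
  force <- read_timeseries_csv(force_path)
  if (nrow(emg) != nrow(force)) {
    stop(sprintf("length mismatch: %s has %d rows, %s has %d rows",
                 emg_path, nrow(emg), force_path, nrow(force)), call. = FALSE)
  }
  fs_e <- infer_rate(emg$time_s, emg_path)
  fs_f <- infer_rate(force$time_s, force_path)
  if (abs(fs_e - fs_f) > 1e-6 * fs_e) {
    stop("EMG and force files disagree on sampling rate", call. = FALSE)
  }
  emg_trial(emg$value, force$value, fs_e, trial_id = trial_id,
            session_tag = session_tag)
}

read_timeseries_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("CSV file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop(sprintf("%s must have columns time_s,value", path), call. = FALSE)
  }
  df
}

infer_rate <- function(time_s, path) {
  d <- diff(time_s)
  if (any(d <= 0)) {
    stop(sprintf("time column of %s is not strictly increasing", path),
         call. = FALSE)
  }
  step <- stats::median(d)
  if (any(abs(d - step) > 1e-6 * step)) {
    stop(sprintf("time column of %s is not uniform (beyond 1 ppm)", path),
         call. = FALSE)
  }
  1 / step
}

#' Write an EMG trial to two-column CSV files
#'
#' Emits the format read by [read_emg_csv()]: header `time_s,value`, time from
#' zero at the trial's sampling rate.
#'
#' @param trial an [emg_trial()].
#' @param emg_path,force_path output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_emg_csv <- function(trial, emg_path, force_path) {
  tt <- (seq_along(trial$emg) - 1) / trial$sampling_rate
  write_one <- function(v, path) {
    utils::write.csv(data.frame(time_s = tt, value = v), path,
                     row.names = FALSE, quote = FALSE)
  }
  write_one(trial$emg, emg_path)
  write_one(trial$force, force_path)
  invisible(c(emg_path, force_path))
}
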