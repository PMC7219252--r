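#' Write a recording to an EDF file
#'
#' Writes 16-bit European Data Format with one-second data records. Samples are
#' mapped to the digital range -32768..32767 over `physical_range`; values
#' outside the range raise an error rather than being clipped silently.
#'
#' @param rec a [recording()] whose length is a whole number of seconds and
#'   whose sampling rate is an integer (EDF stores fixed-size records).
#' @param path output file path.
#' @param physical_range length-2 numeric, the physical min/max in uV encoded
#'   in the header. Default +-3000 uV, the gross-artifact rejection ceiling, so
#'   nothing below the rejection rule can saturate.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_range = c(-3000, 3000)) {
  fs <- rec$sampling_rate
  if (fs != round(fs)) {
    stop("write_edf requires an integer sampling rate", call. = FALSE)
  }
  n <- n_samples(rec)
  if (n %% fs != 0) {
    stop("write_edf requires a whole number of 1-s records; trim or pad the recording",
         call. = FALSE)
  }
  pmin_ <- physical_range[1]; pmax_ <- physical_range[2]
  if (pmin_ >= pmax_) stop("physical_range must be increasing", call. = FALSE)
  if (any(rec$samples < pmin_ | rec$samples > pmax_)) {
    stop(sprintf("samples exceed the physical range [%g, %g] uV; refusing to clip",
                 pmin_, pmax_), call. = FALSE)
  }
  ns <- n_channels(rec)
  n_rec <- n %/% fs
  dmin <- -32767L; dmax <- 32767L   # symmetric so 0 uV is exactly representable

  pad <- function(x, w) {
    x <- as.character(x)
    if (nchar(x) > w) stop(sprintf("EDF header field '%s' exceeds %d chars", x, w),
                           call. = FALSE)
    formatC(x, width = -w)  # left-justified, space padded
  }
  num <- function(x, w) pad(formatC(x, format = "fg", width = 1, digits = 7), w)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8), pad("1", 8), pad(ns, 4),
    paste(vapply(rec$channel_labels, pad, "", w = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(rep(num(pmin_, 8), ns), collapse = ""),
    paste(rep(num(pmax_, 8), ns), collapse = ""),
    paste(rep(pad(dmin, 8), ns), collapse = ""),
    paste(rep(pad(dmax, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- matrix(as.integer(round((rec$samples - pmin_) * scale + dmin)),
                nrow = ns)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Converts digital samples to physical units (uV) using the header's
#' physical/digital scaling. Channels are returned in stored order unless a
#' subset is requested.
#'
#' @param path EDF file path.
#' @param channels optional character vector of channel labels to load (in the
#'   requested order); absent channels raise an error.
#' @return a [recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("EDF file not found: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") {
    stop(sprintf("malformed EDF header in %s: version field '%s'", path, version),
         call. = FALSE)
  }
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || n_rec < 1L ||
      is.na(hdr_bytes) || hdr_bytes != 256L * (ns + 1L)) {
    stop(sprintf("malformed EDF header in %s", path), call. = FALSE)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")   # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1L) {
    stop("EDF files with per-signal sampling rates are not supported",
         call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  total <- n_rec * spr[1]
  samples <- matrix(0, nrow = ns, ncol = total)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                     signed = TRUE, endian = "little")
    if (length(block) < ns * spr[1]) {
      stop(sprintf("truncated EDF data in %s (record %d)", path, r),
           call. = FALSE)
    }
    samples[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
      matrix(block, nrow = ns, byrow = TRUE)
  }
  for (i in seq_len(ns)) {
    samples[i, ] <- (samples[i, ] - dmin[i]) * (pmax_[i] - pmin_[i]) /
      (dmax[i] - dmin[i]) + pmin_[i]
  }
  rec <- recording(samples, fs, labels)
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing)) {
      stop(sprintf("channel(s) not found in %s: %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    rec <- recording(samples[match(channels, labels), , drop = FALSE], fs,
                     channels)
  }
  rec
}
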