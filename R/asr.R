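#' ASR parameters
#'
#' Tunables of artifact subspace reconstruction: the sliding-window length and
#' overlap, the component-threshold cutoff in standard deviations, and the
#' Weiszfeld (geometric-median) iteration controls.
#'
#' @param window_length sliding-window length in seconds (default 0.25).
#' @param cutoff threshold in standard deviations above the calibration mean
#'   component RMS (default 5).
#' @param window_overlap fractional overlap of consecutive windows in `[0, 1)`
#'   (default 0.5; cross-faded with a raised-cosine weight).
#' @param weiszfeld_tol relative convergence tolerance of the geometric-median
#'   iteration (default 1e-8).
#' @param weiszfeld_max_iter iteration cap (default 500).
#' @return an object of class `asr_params`.
#' @export
asr_params <- function(window_length = 0.25, cutoff = 5, window_overlap = 0.5,
                       weiszfeld_tol = 1e-8, weiszfeld_max_iter = 500L) {
  if (window_length <= 0) stop("window_length must be > 0", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (window_overlap < 0 || window_overlap >= 1) {
    stop("window_overlap must lie in [0, 1)", call. = FALSE)
  }
  structure(list(window_length = window_length, cutoff = cutoff,
                 window_overlap = window_overlap,
                 weiszfeld_tol = weiszfeld_tol,
                 weiszfeld_max_iter = as.integer(weiszfeld_max_iter)),
            class = "asr_params")
}

# Geometric median of the rows of X by Weiszfeld iteration.
geometric_median <- function(X, tol = 1e-8, max_iter = 500L) {
  y <- colMeans(X)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(X, 2, y)^2))
    d <- pmax(d, 1e-12 * max(d, 1e-300))
    w <- 1 / d
    y_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((y_new - y)^2)) <= tol * max(sqrt(sum(y^2)), 1e-300)) {
      return(y_new)
    }
    y <- y_new
  }
  stop(sprintf("Weiszfeld iteration did not converge in %d iterations", max_iter),
       call. = FALSE)
}

asr_window_starts <- function(n, win, hop) {
  starts <- seq(1L, n - win + 1L, by = hop)
  if (starts[length(starts)] != n - win + 1L) starts <- c(starts, n - win + 1L)
  starts
}

#' Calibrate an ASR model on clean baseline data
#'
#' The robust calibration covariance is the geometric median (Weiszfeld
#' iteration) of per-window sample covariances; the mixing matrix is its
#' principal square root. Baseline windows are projected onto the covariance
#' eigenbasis and per-component RMS amplitudes collected; the per-component
#' ceiling is `mean + cutoff * SD` of those RMS values.
#'
#' @param baseline a clean [recording()] at least 10 window lengths long, with
#'   the same channels as the data to be cleaned (conventionally ~1 min of
#'   quiet standing).
#' @param params an [asr_params()].
#' @return an object of class `asr_model`: mixing matrix, eigenbasis
#'   (eigenvalues ascending), per-component thresholds (uV RMS), calibration
#'   rate and channel labels.
#' @export
asr_calibrate <- function(baseline, params = asr_params()) {
  fs <- baseline$sampling_rate
  win <- round(params$window_length * fs)
  n <- n_samples(baseline)
  if (n < 10L * win) {
    stop("baseline too short: need at least 10 ASR window lengths", call. = FALSE)
  }
  hop <- max(1L, round(win * (1 - params$window_overlap)))
  starts <- asr_window_starts(n, win, hop)
  nch <- n_channels(baseline)

  covs <- matrix(0, nrow = length(starts), ncol = nch * nch)
  for (k in seq_along(starts)) {
    X <- baseline$samples[, starts[k]:(starts[k] + win - 1L), drop = FALSE]
    covs[k, ] <- as.vector(tcrossprod(X) / win)
  }
  C <- matrix(geometric_median(covs, params$weiszfeld_tol,
                               params$weiszfeld_max_iter), nch, nch)
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  ord <- order(eg$values)                       # ascending
  vals <- eg$values[ord]; vecs <- eg$vectors[, ord, drop = FALSE]
  if (vals[1] <= 1e-10 * vals[nch]) {
    stop("calibration covariance is rank-deficient; supply a longer or noisier baseline",
         call. = FALSE)
  }
  mixing <- vecs %*% (t(vecs) * sqrt(vals))

  rms <- matrix(0, nrow = length(starts), ncol = nch)
  for (k in seq_along(starts)) {
    X <- baseline$samples[, starts[k]:(starts[k] + win - 1L), drop = FALSE]
    Y <- crossprod(vecs, X)
    rms[k, ] <- sqrt(rowMeans(Y^2))
  }
  thr <- colMeans(rms) + params$cutoff * apply(rms, 2, stats::sd)
  structure(
    list(mixing = mixing, eigvec = vecs, eigval = vals,
         component_threshold = thr, calibration_rate = fs,
         channel_labels = baseline$channel_labels),
    class = "asr_model"
  )
}

# Moore-Penrose pseudoinverse via SVD.
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d, 0) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Clean a recording with a calibrated ASR model
#'
#' For each sliding window the window covariance is eigendecomposed and each
#' component's variance compared against the calibration ceiling mapped into
#' the window's basis (`tau_j^2 = sum_i t_i^2 (v_i . u_j)^2`). Components above
#' their ceiling are flagged and the window is reconstructed from the retained
#' subspace by least squares through the model mixing matrix; if every
#' component is flagged the window reconstructs to zero. Overlapping windows
#' are blended with a raised-cosine cross-fade. Channel count and length are
#' always preserved.
#'
#' @param rec the [recording()] to clean; channels and rate must match the
#'   model.
#' @param model an [asr_model()] from [asr_calibrate()].
#' @param params the [asr_params()] used for the sliding windows.
#' @return the cleaned [recording()], with attribute `flagged_fraction` (share
#'   of windows where any component was reconstructed) as a quality metric.
#' @export
asr_clean <- function(rec, model, params = asr_params()) {
  if (!identical(rec$channel_labels, model$channel_labels)) {
    stop("recording channels do not match the ASR model", call. = FALSE)
  }
  if (rec$sampling_rate != model$calibration_rate) {
    stop("recording rate does not match the ASR calibration rate", call. = FALSE)
  }
  fs <- rec$sampling_rate
  win <- round(params$window_length * fs)
  n <- n_samples(rec)
  if (win > n) stop("ASR window longer than the recording", call. = FALSE)
  hop <- max(1L, round(win * (1 - params$window_overlap)))
  starts <- asr_window_starts(n, win, hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 0.5) / win)  # strictly > 0
  nch <- n_channels(rec)
  t2 <- model$component_threshold^2
  M <- model$mixing
  Vc <- model$eigvec

  num <- matrix(0, nrow = nch, ncol = n)
  den <- numeric(n)
  n_flagged <- 0L
  for (s0 in starts) {
    idx <- s0:(s0 + win - 1L)
    X <- rec$samples[, idx, drop = FALSE]
    Cw <- tcrossprod(X) / win
    eg <- eigen((Cw + t(Cw)) / 2, symmetric = TRUE)
    U <- eg$vectors
    d <- eg$values
    P <- crossprod(Vc, U)               # (i, j) = v_i . u_j
    tau2 <- colSums(t2 * P^2)
    flag <- d > tau2
    if (any(flag)) {
      n_flagged <- n_flagged + 1L
      VM <- crossprod(U, M)             # rows follow components
      VM[flag, ] <- 0
      R <- M %*% pinv(VM) %*% t(U)
      X <- R %*% X
    }
    num[, idx] <- num[, idx] + sweep(X, 2, w, `*`)
    den[idx] <- den[idx] + w
  }
  out <- sweep(num, 2, den, `/`)
  res <- recording(out, fs, rec$channel_labels, rec$start_trim_applied)
  attr(res, "flagged_fraction") <- n_flagged / length(starts)
  res
}
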