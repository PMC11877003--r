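# Envelope preprocessing: band-pass filter -> amplitude envelope -> moving
# average -> per-session standardisation -> (optional) full-rank PCA.
# The stage order is fixed; every stage is individually switchable.

#' Preprocessing configuration
#'
#' @param low,high band edges in Hz (defaults 1 and 45).
#' @param envelope extract the amplitude envelope (analytic-signal modulus).
#' @param window moving-average window in samples (default 25); `step` is
#'   always 1.
#' @param standardise z-score each channel within each session.
#' @param pca orthogonalise with a group full-rank PCA.
#' @param sampling_rate sampling rate in Hz.
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(low = 1, high = 45, envelope = TRUE,
                              window = 25L, standardise = TRUE, pca = FALSE,
                              sampling_rate = 250) {
  stopifnot(low > 0, high > low, high < sampling_rate / 2, window >= 1L)
  structure(list(low = low, high = high, envelope = envelope,
                 window = as.integer(window), standardise = standardise,
                 pca = pca, sampling_rate = sampling_rate),
            class = "preprocess_config")
}

#' Zero-phase band-pass filter
#'
#' 5th-order Butterworth applied forward-backward (`signal::filtfilt`), so
#' the effective response is squared and the phase is zero.
#'
#' @param x `T x Nc` matrix (columns are channels) or a vector.
#' @param low,high band edges (Hz).
#' @param rate sampling rate (Hz).
#' @return Filtered data, same shape.
#' @export
bandpass <- function(x, low, high, rate) {
  if (low <= 0 || high <= low || high >= rate / 2)
    stop("band must satisfy 0 < low < high < Nyquist (", rate / 2, " Hz)")
  bf <- signal::butter(5, c(low, high) / (rate / 2), type = "pass")
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  out <- apply(x, 2L, function(ch) signal::filtfilt(bf, ch))
  if (vec) as.vector(out) else out
}

#' Amplitude envelope via the analytic signal
#'
#' Modulus of the analytic signal, computed per channel with the FFT
#' construction (negative frequencies zeroed, positive doubled).
#'
#' @param x `T x Nc` matrix or vector, finite.
#' @return Nonnegative envelope, same shape.
#' @export
amplitude_envelope <- function(x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("signal must be finite")
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  out <- apply(x, 2L, function(ch) Mod(stats::fft(stats::fft(ch) * h,
                                                  inverse = TRUE) / n))
  if (vec) as.vector(out) else out
}

#' Moving average (step 1, trimmed)
#'
#' Each output sample is the mean of a `window`-sample block; the output has
#' length `T - window + 1` (no padding).
#'
#' @param x `T x Nc` matrix or vector with `T >= window`.
#' @param window window length in samples.
#' @return Smoothed data of `T - window + 1` rows.
#' @export
moving_average <- function(x, window = 25L) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (nrow(x) < window) stop("signal shorter than the smoothing window")
  k <- rep(1 / window, window)
  out <- apply(x, 2L, function(ch) {
    f <- stats::filter(ch, k, sides = 1)
    as.vector(f[window:length(ch)])
  })
  out <- matrix(out, nrow = nrow(x) - window + 1L)
  if (vec) as.vector(out) else out
}

#' Per-channel z-scoring within a session
#'
#' @param x `T x Nc` matrix.
#' @return Matrix with each column mean 0 and unit variance.
#' @export
standardise <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2L, sd)
  zero <- which(sds < .Machine$double.eps^0.5)
  if (length(zero))
    stop("zero-variance channel(s): ", paste(zero, collapse = ", "))
  sweep(sweep(x, 2L, colMeans(x)), 2L, sds, "/")
}

#' Fit a group full-rank PCA and project sessions
#'
#' Eigendecomposition of the covariance of the session-concatenated data;
#' `W` has the eigenvectors on the rows (all components kept). Eigenvector
#' sign is fixed by making each row's largest-magnitude entry positive.
#'
#' @param sessions list of `T x Nc` matrices.
#' @return List with `projection` (a [pca_projection]) and `sessions`
#'   (projected matrices `x %*% t(W)`).
#' @export
fit_apply_pca <- function(sessions) {
  sessions <- lapply(sessions, as.matrix)
  X <- do.call(rbind, sessions)
  if (nrow(X) <= ncol(X)) stop("need more samples than channels for a full-rank PCA")
  eg <- eigen(cov(X), symmetric = TRUE)
  if (min(eg$values) < .Machine$double.eps * max(eg$values) * nrow(X))
    stop("data covariance is rank deficient; full-rank PCA impossible")
  W <- t(eg$vectors)
  for (r in seq_len(nrow(W)))
    if (W[r, which.max(abs(W[r, ]))] < 0) W[r, ] <- -W[r, ]
  list(projection = pca_projection(W),
       sessions = lapply(sessions, function(x) x %*% t(W)))
}

#' Run the full preprocessing pipeline on a list of sessions
#'
#' Stage order is fixed: band-pass, envelope, moving average, standardise,
#' PCA; each stage is applied only if enabled in the configuration. The
#' moving average shortens each session by `window - 1` samples.
#'
#' @param sessions list of [session_data] objects or `T x Nc` matrices.
#' @param config a [preprocess_config].
#' @return List with `sessions` (processed `T x Nc` matrices) and
#'   `projection` (a [pca_projection] or `NULL`).
#' @export
preprocess_sessions <- function(sessions, config = preprocess_config()) {
  xs <- lapply(sessions, session_matrix)
  if (!is.null(config$low))
    xs <- lapply(xs, bandpass, low = config$low, high = config$high,
                 rate = config$sampling_rate)
  if (isTRUE(config$envelope)) xs <- lapply(xs, amplitude_envelope)
  if (config$window > 1L) xs <- lapply(xs, moving_average, window = config$window)
  if (isTRUE(config$standardise)) xs <- lapply(xs, standardise)
  projection <- NULL
  if (isTRUE(config$pca)) {
    p <- fit_apply_pca(xs)
    xs <- p$sessions
    projection <- p$projection
  }
  list(sessions = xs, projection = projection)
}
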