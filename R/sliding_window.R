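# Sliding-window / K-means baseline: windowed standard deviations and
# correlations clustered separately into power states and FC states.

#' Sliding-window power and FC features
#'
#' For each window of `window` samples (advanced by `step`), the per-channel
#' standard deviation and the vectorised upper triangle of the channel
#' correlation matrix. Each window is indexed by its centre sample.
#'
#' @param x `T x Nc` matrix.
#' @param window window size in samples (default 500, i.e. 2 s at 250 Hz).
#' @param step step size in samples (default 10).
#' @return List of class `window_features` with `centres`, `sd` (`n_windows
#'   x Nc`), `corr` (`n_windows x Nc(Nc-1)/2`), `window`, `step`.
#' @export
window_features <- function(x, window = 500L, step = 10L) {
  x <- as.matrix(x)
  Tn <- nrow(x); Nc <- ncol(x)
  if (Tn < window) stop("data shorter than one window")
  starts <- seq(1L, Tn - window + 1L, by = step)
  ut <- upper.tri(matrix(0, Nc, Nc))
  sdm <- matrix(0, length(starts), Nc)
  crm <- matrix(0, length(starts), sum(ut))
  for (i in seq_along(starts)) {
    w <- x[starts[i]:(starts[i] + window - 1L), , drop = FALSE]
    sdm[i, ] <- apply(w, 2L, sd)
    crm[i, ] <- cor(w)[ut]
  }
  structure(list(centres = starts + (window - 1L) %/% 2L, sd = sdm,
                 corr = crm, window = window, step = step),
            class = "window_features")
}

#' K-means state sequences from window features
#'
#' Clusters the standard-deviation features and the correlation features
#' separately, yielding one power state sequence and one FC state sequence
#' over the window grid.
#'
#' @param features a [window_features].
#' @param K number of states per sequence.
#' @param seed seed for the k-means restarts.
#' @param n_restarts random restarts (`nstart`); the lowest-inertia solution
#'   is kept.
#' @return List with `power_states`, `fc_states` (integer vectors),
#'   `power_centroids`, `fc_centroids`, `centres`.
#' @export
kmeans_states <- function(features, K = 4L, seed = 1L, n_restarts = 10L) {
  if (nrow(features$sd) < K) stop("fewer windows than states")
  set.seed(seed)
  km1 <- kmeans(features$sd, centers = K, nstart = n_restarts, iter.max = 100L)
  km2 <- kmeans(features$corr, centers = K, nstart = n_restarts, iter.max = 100L)
  list(power_states = km1$cluster, fc_states = km2$cluster,
       power_centroids = km1$centers, fc_centroids = km2$centers,
       centres = features$centres)
}

#' Per-state power and FC maps relative to the across-state average
#'
#' For every state, the per-channel standard deviation and channel
#' correlation matrix of the samples assigned to it, minus the unweighted
#' mean across states.
#'
#' @param x `T x Nc` data matrix.
#' @param states integer state label per sample of `x`.
#' @return List with `sd` (`K x Nc` relative power maps), `corr`
#'   (`Nc x Nc x K` relative FC maps), and the uncentred `sd_abs`,
#'   `corr_abs`.
#' @export
state_maps <- function(x, states) {
  x <- as.matrix(x)
  K <- max(states)
  Nc <- ncol(x)
  sdm <- matrix(0, K, Nc)
  crm <- array(0, c(Nc, Nc, K))
  for (k in seq_len(K)) {
    idx <- which(states == k)
    if (length(idx) < 2L) stop("state ", k, " has fewer than 2 samples")
    sdm[k, ] <- apply(x[idx, , drop = FALSE], 2L, sd)
    crm[, , k] <- cor(x[idx, , drop = FALSE])
  }
  list(sd = sweep(sdm, 2L, colMeans(sdm)),
       corr = sweep(crm, c(1L, 2L), apply(crm, c(1L, 2L), mean)),
       sd_abs = sdm, corr_abs = crm)
}

#' Correlation between power and FC state time courses
#'
#' Pearson correlation between the one-hot indicator of every power state
#' and every FC state over the shared window grid.
#'
#' @param power_states,fc_states integer state sequences on the same grid.
#' @return `K1 x K2` correlation matrix.
#' @export
state_tc_correlation <- function(power_states, fc_states) {
  stopifnot(length(power_states) == length(fc_states))
  P <- one_hot(power_states)
  Q <- one_hot(fc_states)
  if (any(apply(P, 2L, sd) == 0) || any(apply(Q, 2L, sd) == 0))
    stop("constant state indicator (a state never or always occurs)")
  cor(P, Q)
}

#' Sliding-window state recovery accuracy against a known state sequence
#'
#' Convenience wrapper: computes window features, clusters them with K-means
#' and scores both state sequences against the ground truth at the window
#' centres after optimal label matching.
#'
#' @param x `T x Nc` data.
#' @param power_truth,fc_truth ground-truth state sequences (per sample).
#' @param window,step,K,seed passed through.
#' @return List with `power_accuracy`, `fc_accuracy`, `states`.
#' @export
sliding_window_recovery <- function(x, power_truth, fc_truth, window = 500L,
                                    step = 10L, K = NULL, seed = 1L) {
  wf <- window_features(x, window, step)
  Kp <- if (is.null(K)) max(power_truth) else K
  Kf <- if (is.null(K)) max(fc_truth) else K
  set.seed(seed)
  km1 <- kmeans(wf$sd, centers = Kp, nstart = 10L, iter.max = 100L)
  km2 <- kmeans(wf$corr, centers = Kf, nstart = 10L, iter.max = 100L)
  ref_p <- power_truth[wf$centres]
  ref_f <- fc_truth[wf$centres]
  mp <- match_labels(km1$cluster, ref_p, K = max(Kp, max(ref_p)))
  mf <- match_labels(km2$cluster, ref_f, K = max(Kf, max(ref_f)))
  list(power_accuracy = mp$accuracy, fc_accuracy = mf$accuracy,
       states = list(power = mp$pred, fc = mf$pred, centres = wf$centres))
}
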