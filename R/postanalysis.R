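# Post-fit statistics: renormalised mode time courses, mode matching,
# max-statistic permutation tests, network recalculation under a fixed
# dynamic, epoching and the two-level evoked-response GLM.

new_stat_result <- function(stat, null_max, n_perm, extra = list()) {
  p <- (1 + vapply(abs(stat), function(v) sum(null_max >= v), numeric(1))) /
    (1 + n_perm)
  p <- array(p, dim = dim(as.array(stat)))
  structure(c(list(stat = stat, null_max = null_max, p = p,
                   sig = p <= 0.05, n_perm = n_perm), extra),
            class = "stat_result")
}

#' Write a permutation-test result to disk
#'
#' JSON with the observed statistics, p-values, significance mask and a
#' summary of the null maxima, plus a flat CSV table (one row per tested
#' element).
#'
#' @param res a `stat_result`.
#' @param path output path without extension (writes `<path>.json` and
#'   `<path>.csv`).
#' @return `path`, invisibly.
#' @export
write_stat_result <- function(res, path) {
  stopifnot(inherits(res, "stat_result"))
  obj <- list(stat = res$stat, p = res$p, sig = res$sig,
              n_perm = res$n_perm,
              null_max_quantiles = as.list(quantile(res$null_max,
                                                    c(.5, .95, .99))))
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  st <- as.matrix(res$stat)
  idx <- which(!is.na(st), arr.ind = TRUE)
  utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2],
                              stat = st[idx],
                              p = as.matrix(res$p)[idx],
                              significant = as.matrix(res$sig)[idx]),
                   paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Renormalise mode time courses by overall mode magnitude
#'
#' Reweights the simplex mixing weights by each mode's overall magnitude so
#' they read as contributions to the total variance (power modes, weight =
#' mean `E_j` diagonal) or total correlation (FC modes, weight = mean
#' absolute off-diagonal of `R_j`):
#' `alpha~_jt = alpha_jt w_j / sum_k alpha_kt w_k`.
#'
#' @param weights `T x J` simplex matrix (`alpha` or `beta`).
#' @param modes the matching [power_mode_set] or [fc_mode_set].
#' @return `T x J` renormalised simplex matrix.
#' @export
renormalise <- function(weights, modes) {
  weights <- as.matrix(weights)
  if (inherits(modes, "power_mode_set")) {
    stopifnot(ncol(weights) == modes$J1)
    w <- rowMeans(modes$e)
  } else if (inherits(modes, "fc_mode_set")) {
    stopifnot(ncol(weights) == modes$J2)
    w <- apply(modes$R, 3L, function(R) mean(abs(R[upper.tri(R)])))
  } else stop("modes must be a power_mode_set or fc_mode_set")
  if (all(w == 0)) stop("degenerate all-zero mode weights")
  num <- sweep(weights, 2L, w, "*")
  num / rowSums(num)
}

#' Relative power map
#'
#' Per-mode `E_j` diagonal minus the across-mode mean diagonal.
#'
#' @param modes a [power_mode_set].
#' @return `J1 x Nc` matrix of relative power maps.
#' @export
relative_power_map <- function(modes) {
  sweep(modes$e, 2L, colMeans(modes$e))
}

#' FC degree map
#'
#' Per-mode node degree (row sums of `R_j` excluding the diagonal) minus the
#' across-mode mean degree.
#'
#' @param modes an [fc_mode_set].
#' @return `J2 x Nc` matrix of relative degree maps.
#' @export
fc_degree_map <- function(modes) {
  deg <- t(apply(modes$R, 3L, function(R) rowSums(R) - diag(R)))
  sweep(deg, 2L, colMeans(deg))
}

cosine_matrix <- function(A, B, centre = TRUE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (centre) {
    A <- A - rowMeans(A)
    B <- B - rowMeans(B)
  }
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) stop("zero-norm map")
  (A %*% t(B)) / outer(na, nb)
}

#' Match two sets of spatial maps by cosine similarity
#'
#' Cosine similarity on mean-centred maps; the assignment of B-modes to
#' A-modes maximises the total matched similarity (exact search). With
#' unequal counts the smaller set is matched into the larger.
#'
#' @param A,B `J x D` matrices of spatial maps (rows are modes).
#' @param centre mean-centre each map first.
#' @return List with `perm` (for each row of A, the matched row of B),
#'   `cosine` (full matrix), `matched` (cosines of the matched pairs).
#' @export
match_modes <- function(A, B, centre = TRUE) {
  cm <- cosine_matrix(A, B, centre)
  perm <- solve_assignment(cm)
  matched <- ifelse(is.na(perm), NA_real_, cm[cbind(seq_len(nrow(cm)), perm)])
  list(perm = perm, cosine = cm, matched = matched)
}

#' Max-statistic permutation test on a cosine-similarity matrix
#'
#' The null is built by independently permuting the spatial elements
#' (parcels) of each map in B — preserving each map's value distribution
#' while destroying spatial correspondence — recomputing the full cosine
#' matrix and recording its maximum. The resulting p-values are familywise
#' error controlled across all pairs.
#'
#' @param A,B `J x D` map matrices, `D >= 3`.
#' @param n_perm permutations (>= 1; a warning is given below 100).
#' @param seed RNG seed.
#' @param centre mean-centre maps.
#' @return A `stat_result` with the observed cosine matrix, null maxima,
#'   add-one p-values and the 5% significance mask.
#' @export
maxstat_cosine_test <- function(A, B, n_perm = 1000L, seed = 1L,
                                centre = TRUE) {
  A <- as.matrix(A); B <- as.matrix(B)
  D <- ncol(A)
  if (D < 3L) stop("need at least 3 spatial elements")
  if (n_perm < 1L) stop("n_perm must be positive")
  if (n_perm < 100L) warning("fewer than 100 permutations")
  obs <- cosine_matrix(A, B, centre)
  set.seed(seed)
  null_max <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    Bp <- t(apply(B, 1L, sample))
    null_max[r] <- max(cosine_matrix(A, Bp, centre))
  }
  new_stat_result(obs, null_max, n_perm)
}

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' Coupling between power and FC mode time courses across sessions
#'
#' Per session, the Pearson correlation between every alpha and every beta
#' time course, Fisher-z transformed. The group null randomly sign-flips
#' each session's z-matrix and takes the maximum absolute mean z over all
#' pairs (familywise control).
#'
#' @param alphas,betas lists (one element per session) of `T x J1` / `T x J2`
#'   time courses on aligned time axes.
#' @param n_perm sign-flip permutations.
#' @param seed RNG seed.
#' @return A `stat_result` whose `stat` is the mean Fisher z per pair, with
#'   `r` (back-transformed mean correlation) and `z_sessions`.
#' @export
coupling_matrix <- function(alphas, betas, n_perm = 1000L, seed = 1L) {
  S <- length(alphas)
  if (S < 2L) stop("group inference requires at least 2 sessions")
  stopifnot(length(betas) == S)
  zs <- lapply(seq_len(S), function(s) {
    a <- as.matrix(alphas[[s]]); b <- as.matrix(betas[[s]])
    stopifnot(nrow(a) == nrow(b))
    if (any(apply(a, 2L, sd) == 0) || any(apply(b, 2L, sd) == 0))
      stop("constant mode time course in session ", s)
    fisher_z(cor(a, b))
  })
  sign_flip_max_test(zs, n_perm, seed)
}

sign_flip_max_test <- function(zs, n_perm, seed) {
  S <- length(zs)
  Z <- vapply(zs, identity, zs[[1]])          # J1 x J2 x S
  obs <- apply(Z, c(1L, 2L), mean)
  set.seed(seed)
  null_max <- numeric(n_perm)
  Zf <- matrix(Z, ncol = S)                   # (J1*J2) x S
  for (r in seq_len(n_perm)) {
    f <- sample(c(-1, 1), S, replace = TRUE)
    null_max[r] <- max(abs(Zf %*% f) / S)
  }
  new_stat_result(obs, null_max, n_perm,
                  extra = list(r = tanh(obs), z_sessions = Z))
}

#' Change in power-FC coupling between two conditions
#'
#' Per session the difference of Fisher-z coupling matrices (condition 2
#' minus condition 1), tested with the group sign-flip maximum-statistic
#' test.
#'
#' @param rest,task lists with elements `alpha`, `beta` per session (same
#'   sessions, same order).
#' @param n_perm,seed permutation settings.
#' @return A `stat_result` on the per-pair mean z difference.
#' @export
coupling_change <- function(rest, task, n_perm = 1000L, seed = 1L) {
  S <- length(rest$alpha)
  if (length(task$alpha) != S) stop("session sets do not match")
  if (S < 2L) stop("group inference requires at least 2 sessions")
  zd <- lapply(seq_len(S), function(s)
    fisher_z(cor(as.matrix(task$alpha[[s]]), as.matrix(task$beta[[s]]))) -
      fisher_z(cor(as.matrix(rest$alpha[[s]]), as.matrix(rest$beta[[s]]))))
  sign_flip_max_test(zd, n_perm, seed)
}

#' Recalculate per-mode networks given a fixed mixing time course
#'
#' Solves the elementwise linear least-squares problem
#' `min_{C_j} sum_t || x_t x_t' - sum_j m_jt C_j ||_F^2`
#' over the whole recording, symmetrises each solution and splits it into a
#' power part (square root of the diagonal) and an implied correlation.
#'
#' @param sessions list of `T x Nc` matrices (or one matrix).
#' @param mixing list of `T x J` mixing matrices matching `sessions` (or one
#'   matrix); must have full column rank.
#' @return List with `cov` (`Nc x Nc x J`), `power` (`J x Nc` standard
#'   deviations), `fc` (`Nc x Nc x J` correlations).
#' @export
recalc_networks <- function(sessions, mixing) {
  if (is.matrix(sessions) || inherits(sessions, "session_data"))
    sessions <- list(sessions)
  if (is.matrix(mixing)) mixing <- list(mixing)
  X <- do.call(rbind, lapply(sessions, session_matrix))
  M <- do.call(rbind, lapply(mixing, as.matrix))
  stopifnot(nrow(X) == nrow(M))
  J <- ncol(M); Nc <- ncol(X)
  MtM <- crossprod(M)
  if (rcond(MtM) < 1e-12) stop("mixing design is rank deficient")
  # Y[t, ] = vec(x_t x_t'): crossprod of columnwise products
  Y <- matrix(0, nrow(X), Nc * Nc)
  for (a in seq_len(Nc)) Y[, ((a - 1) * Nc + 1):(a * Nc)] <- X * X[, a]
  Bhat <- solve(MtM, crossprod(M, Y))
  cov_j <- array(0, c(Nc, Nc, J))
  power <- matrix(0, J, Nc)
  fc <- array(0, c(Nc, Nc, J))
  for (j in seq_len(J)) {
    Cj <- matrix(Bhat[j, ], Nc, Nc)
    Cj <- (Cj + t(Cj)) / 2
    cov_j[, , j] <- Cj
    dj <- pmax(diag(Cj), .Machine$double.eps)
    power[j, ] <- sqrt(dj)
    fc[, , j] <- Cj / tcrossprod(sqrt(dj))
  }
  list(cov = cov_j, power = power, fc = fc)
}

#' Epoch a time course around event onsets
#'
#' Cuts trials on the sample grid from `round(window[1] * rate)` to
#' `round(window[2] * rate)` samples relative to each onset (inclusive).
#' Trials whose window leaves the recording are dropped (count reported).
#'
#' @param tc `T x J` time course (e.g. renormalised mixing coefficients).
#' @param events data frame with `onset_sample` (1-based) and `condition`.
#' @param rate sampling rate (Hz).
#' @param window epoch window in seconds, default `c(-0.5, 2)`.
#' @return Object of class `epoch_set`: `data` (trials x time x modes),
#'   `time` (seconds, strictly increasing), `condition`, `n_dropped`.
#' @export
epoch_timecourse <- function(tc, events, rate, window = c(-0.5, 2)) {
  tc <- as.matrix(tc)
  pre <- round(window[1] * rate); post <- round(window[2] * rate)
  stopifnot(pre < post)
  keep <- events$onset_sample + pre >= 1 &
    events$onset_sample + post <= nrow(tc)
  n_dropped <- sum(!keep)
  events <- events[keep, , drop = FALSE]
  if (!nrow(events)) stop("no valid trials after windowing")
  n_time <- post - pre + 1L
  out <- array(0, c(nrow(events), n_time, ncol(tc)))
  for (i in seq_len(nrow(events))) {
    idx <- (events$onset_sample[i] + pre):(events$onset_sample[i] + post)
    out[i, , ] <- tc[idx, , drop = FALSE]
  }
  structure(list(data = out, time = (pre:post) / rate,
                 condition = as.character(events$condition),
                 n_dropped = n_dropped),
            class = "epoch_set")
}

#' Two-level evoked-response GLM with max-statistic permutation inference
#'
#' First level (per session): each trial is baseline-corrected by its mean
#' over the pre-stimulus window, then ordinary least squares on separate
#' condition regressors gives per-condition mean responses; a contrast
#' vector over conditions yields one effect per (time, mode). Second level:
#' a one-sample t-statistic across sessions per cell; the null sign-flips
#' whole sessions and records the maximum |t| over all cells, controlling
#' the familywise error across time points and modes.
#'
#' @param epochs list of `epoch_set` objects, one per session (>= 2).
#' @param contrasts named list of numeric contrast vectors; each may be
#'   named by condition (e.g. `c(faces = 1, scrambled = -1)`) or given in
#'   `sort(unique(conditions))` order.
#' @param n_perm,seed permutation settings.
#' @param baseline portion of the window used for baseline correction,
#'   default all `time < 0`.
#' @return Named list (one `stat_result` per contrast) with `effect` (group
#'   mean, time x modes), `stat` (t), `p`, `sig`, `time`.
#' @export
evoked_glm <- function(epochs, contrasts, n_perm = 1000L, seed = 1L,
                       baseline = NULL) {
  S <- length(epochs)
  if (S < 2L) stop("group inference requires at least 2 sessions")
  time <- epochs[[1]]$time
  conds <- sort(unique(unlist(lapply(epochs, `[[`, "condition"))))
  if (is.null(baseline)) baseline <- which(time < 0)
  first_level <- function(ep, cvec) {
    d <- ep$data
    bl <- apply(d[, baseline, , drop = FALSE], c(1L, 3L), mean)
    d <- sweep(d, c(1L, 3L), bl)
    eff <- 0
    for (k in seq_along(conds)) {
      if (cvec[k] == 0) next
      idx <- which(ep$condition == conds[k])
      if (!length(idx)) stop("contrast references absent condition: ", conds[k])
      eff <- eff + cvec[k] * apply(d[idx, , , drop = FALSE], c(2L, 3L), mean)
    }
    eff                                            # time x modes
  }
  out <- list()
  for (cn in names(contrasts)) {
    cvec <- contrasts[[cn]]
    if (!is.null(names(cvec))) {
      if (!all(names(cvec) %in% conds))
        stop("contrast references absent condition: ",
             paste(setdiff(names(cvec), conds), collapse = ", "))
      full <- setNames(numeric(length(conds)), conds)
      full[names(cvec)] <- cvec
      cvec <- full
    }
    if (length(cvec) != length(conds)) stop("contrast length mismatch")
    E <- vapply(epochs, first_level, matrix(0, length(time),
                                            dim(epochs[[1]]$data)[3]),
                cvec = cvec)                       # time x modes x S
    Ef <- matrix(E, ncol = S)
    mu <- rowMeans(Ef)
    se <- sqrt(pmax(apply(Ef, 1L, var), .Machine$double.eps) / S)
    tt <- mu / se
    set.seed(seed)
    null_max <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      f <- sample(c(-1, 1), S, replace = TRUE)
      Ep <- sweep(Ef, 2L, f, "*")
      mup <- rowMeans(Ep)
      sep <- sqrt(pmax(apply(Ep, 1L, var), .Machine$double.eps) / S)
      null_max[r] <- max(abs(mup / sep))
    }
    stat <- matrix(tt, length(time))
    res <- new_stat_result(stat, null_max, n_perm,
                           extra = list(effect = matrix(mu, length(time)),
                                        time = time))
    out[[cn]] <- res
  }
  out
}
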