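# Variational training of the multi-dynamic network-modes model.
#
# The generative model has K latent logit sequences theta^k (K = 2: power and
# FC; K = 1 for the single-dynamic special case). Their joint prior is
# autoregressive: an LSTM consumes the concatenated logits up to t-1 and per
# dynamic emits a Gaussian mean (linear head) and an isotropic scale
# (softplus head). The amortized posterior is a bidirectional LSTM over the
# data sequence with analogous heads. Training minimises the per-sequence
# free energy
#   L = -E_q[log p(x_t | theta)] + sum_{t>=2} sum_k KL(q(theta_t^k) || p(theta_t^k | theta_{1:t-1}))
# with one reparameterised posterior sample for the likelihood term and the
# Gaussian-Gaussian KL in closed form. All gradients are analytic (see
# lstm.R and the compiled observation kernels) and are verified against
# finite differences in the test suite.

#' Training configuration
#'
#' @param sequence_length samples per training sequence (sessions are chunked
#'   into non-overlapping sequences of this length; remainders are dropped).
#' @param batch_size sequences per gradient step.
#' @param n_epochs training epochs.
#' @param learning_rate Adam step size.
#' @param kl_anneal_epochs epochs over which the KL weight ramps linearly
#'   from 0 to 1.
#' @param lr_decay factor by which the learning rate is reduced over the
#'   second half of training (halved smoothly; 1 = constant rate).
#' @param n_starts independent random restarts; the run with the lowest final
#'   training loss is kept.
#' @param hidden_dim recurrent width of the prior LSTM and of each direction
#'   of the posterior BiLSTM.
#' @param J1,J2 number of power and FC modes (ignored by the single-dynamic
#'   model, which uses `J1` full-covariance modes).
#' @param seed integer seed; each restart derives its own stream from it.
#' @param do_pca orthogonalise the data with a full-rank PCA before the
#'   encoder (the likelihood is still evaluated in the original space, which
#'   is algebraically identical for an orthonormal rotation).
#' @param jitter diagonal jitter in the correlation-factor parameterisation.
#' @return A list of class `training_config`.
#' @export
training_config <- function(sequence_length = 200L, batch_size = 32L,
                            n_epochs = 40L, learning_rate = 1e-3,
                            kl_anneal_epochs = 10L, n_starts = 10L,
                            hidden_dim = 64L, J1 = 4L, J2 = 4L, seed = 1L,
                            do_pca = FALSE, jitter = 1e-6, lr_decay = 0.5) {
  stopifnot(sequence_length >= 2L, batch_size >= 1L, n_epochs >= 1L,
            n_starts >= 1L, hidden_dim >= 1L, J1 >= 1L, J2 >= 1L)
  structure(list(sequence_length = as.integer(sequence_length),
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 learning_rate = learning_rate,
                 kl_anneal_epochs = as.integer(kl_anneal_epochs),
                 n_starts = as.integer(n_starts),
                 hidden_dim = as.integer(hidden_dim),
                 J1 = as.integer(J1), J2 = as.integer(J2),
                 seed = as.integer(seed), do_pca = isTRUE(do_pca),
                 jitter = jitter, lr_decay = lr_decay),
            class = "training_config")
}

#' Chunk sessions into fixed-length training sequences
#'
#' Sequences never span a session boundary; each session contributes
#' `floor(T / sequence_length)` sequences and the trailing remainder is
#' dropped. Sessions shorter than one sequence are excluded with a warning.
#'
#' @param sessions list of `T x Nc` matrices (or `session_data` objects).
#' @param sequence_length samples per sequence.
#' @return List of `sequence_length x Nc` matrices.
#' @export
chunk_sessions <- function(sessions, sequence_length) {
  out <- list()
  for (s in seq_along(sessions)) {
    x <- session_matrix(sessions[[s]])
    n <- floor(nrow(x) / sequence_length)
    if (n < 1L) {
      warning("session ", s, " is shorter than one sequence (",
              nrow(x), " < ", sequence_length, "); excluded")
      next
    }
    for (k in seq_len(n))
      out[[length(out) + 1L]] <-
        x[((k - 1L) * sequence_length + 1L):(k * sequence_length), , drop = FALSE]
  }
  out
}

# accept either a bare matrix or a session_data object
session_matrix <- function(x) {
  if (inherits(x, "session_data")) return(t(x$x))
  as.matrix(x)
}

#' Reparameterised Gaussian sample
#'
#' Returns `m + s * noise`, the reparameterisation-trick sample through which
#' gradients flow to the variational mean and scale.
#'
#' @param m,s,noise conformable numerics (`s > 0`).
#' @return `m + s * noise`.
#' @export
reparameterised_sample <- function(m, s, noise) {
  if (any(s <= 0)) stop("posterior scale must be strictly positive")
  m + s * noise
}

# ---------------------------------------------------------------------------
# Parameter initialisation
# ---------------------------------------------------------------------------

init_heads <- function(in_dim, Js, scale_init) {
  heads <- list()
  for (k in seq_along(Js)) {
    heads[[paste0("Wm", k)]] <- matrix(rnorm(in_dim * Js[k], sd = 0.05), in_dim, Js[k])
    heads[[paste0("bm", k)]] <- rep(0, Js[k])
    heads[[paste0("Ws", k)]] <- matrix(rnorm(in_dim, sd = 0.01), in_dim, 1L)
    heads[[paste0("bs", k)]] <- inv_softplus(scale_init)
  }
  heads
}

# Observation parameters start from the statistics of randomly chosen
# training sequences: a cheap, data-driven initialisation that places every
# mode in the right scale regime.
# Observation parameters are initialised from short-window K-means
# centroids: windowed standard deviations (for the power modes) and
# windowed correlations (for the FC modes) are clustered into J groups, so
# every mode starts distinct and aligned with structure actually present in
# the data. Cold random-sequence initialisation is prone to mode-merging
# local optima; centroid seeding plants one mode per empirical regime.
# Windows are short (50 samples) so that fast state switching still yields
# cluster-able features; the centroid averages out the per-window noise.
init_window_stats <- function(seqs, window = 50L, step = 25L,
                              max_windows = 4000L) {
  Nc <- ncol(seqs[[1]])
  ut <- upper.tri(diag(Nc))
  window <- max(2L, min(window, min(vapply(seqs, nrow, integer(1)))))
  step <- max(1L, min(step, window))
  sds <- list(); crs <- list()
  for (x in seqs) {
    starts <- seq(1L, nrow(x) - window + 1L, by = step)
    for (s0 in starts) {
      w <- x[s0:(s0 + window - 1L), , drop = FALSE]
      sds[[length(sds) + 1L]] <- apply(w, 2L, sd)
      cw <- suppressWarnings(cor(w))
      cw[!is.finite(cw)] <- 0
      crs[[length(crs) + 1L]] <- cw[ut]
    }
    if (length(sds) >= max_windows) break
  }
  list(sd = do.call(rbind, sds), corr = do.call(rbind, crs))
}

init_obs_multi <- function(seqs, J1, J2, jitter) {
  Nc <- ncol(seqs[[1]])
  ws <- init_window_stats(seqs)
  e_raw <- matrix(0, J1, Nc)
  km1 <- tryCatch(kmeans(ws$sd, centers = J1, nstart = 5L, iter.max = 50L),
                  error = function(e) NULL)
  for (j in seq_len(J1)) {
    base <- if (!is.null(km1)) pmax(km1$centers[j, ], 0.05)
            else pmax(apply(seqs[[sample.int(length(seqs), 1L)]], 2L, sd), 0.05)
    e_raw[j, ] <- inv_softplus(base * exp(rnorm(Nc, sd = 0.05)))
  }
  Lraw <- array(0, c(Nc, Nc, J2))
  km2 <- tryCatch(kmeans(ws$corr, centers = J2, nstart = 5L, iter.max = 50L),
                  error = function(e) NULL)
  ut <- upper.tri(diag(Nc))
  for (j in seq_len(J2)) {
    Rj <- diag(Nc)
    if (!is.null(km2)) {
      Rj[ut] <- km2$centers[j, ]
      Rj <- Rj + t(Rj) - diag(Nc)
    } else Rj <- suppressWarnings(cor(seqs[[sample.int(length(seqs), 1L)]]))
    Rj[!is.finite(Rj)] <- 0
    diag(Rj) <- 1
    # shrink toward the identity until the centroid is safely PD
    Lj <- diag(Nc)
    for (lam in c(0.9, 0.7, 0.5, 0.2)) {
      Rs <- lam * Rj + (1 - lam) * diag(Nc)
      Ltry <- tryCatch(t(chol(Rs)), error = function(e) NULL)
      if (!is.null(Ltry)) { Lj <- Ltry; break }
    }
    Lraw[, , j] <- Lj + matrix(rnorm(Nc * Nc, sd = 0.01), Nc, Nc)
  }
  list(e_raw = e_raw, Lraw = Lraw)
}

init_obs_single <- function(seqs, J, jitter) {
  Nc <- ncol(seqs[[1]])
  ws <- init_window_stats(seqs)
  feats <- cbind(ws$sd, ws$corr)
  km <- tryCatch(kmeans(feats, centers = J, nstart = 5L, iter.max = 50L),
                 error = function(e) NULL)
  ut <- upper.tri(diag(Nc))
  Lraw <- array(0, c(Nc, Nc, J))
  for (j in seq_len(J)) {
    if (!is.null(km)) {
      d <- pmax(km$centers[j, seq_len(Nc)], 0.05)
      Rj <- diag(Nc); Rj[ut] <- km$centers[j, -seq_len(Nc)]
      Rj <- Rj + t(Rj) - diag(Nc)
      Rj[!is.finite(Rj)] <- 0; diag(Rj) <- 1
      Cj <- diag(d)
      for (lam in c(0.9, 0.7, 0.5, 0.2)) {
        Cs <- (lam * Rj + (1 - lam) * diag(Nc)) * tcrossprod(d)
        Lj <- tryCatch(t(chol(Cs)), error = function(e) NULL)
        if (!is.null(Lj)) { Cj <- Lj; break }
      }
    } else {
      x <- seqs[[sample.int(length(seqs), 1L)]]
      Cv <- 0.9 * cov(x) + 0.1 * (mean(diag(cov(x))) + 0.01) * diag(Nc)
      Cj <- t(chol(Cv))
    }
    Lraw[, , j] <- Cj + matrix(rnorm(Nc * Nc, sd = 0.01), Nc, Nc)
  }
  list(Lraw = Lraw)
}

init_params <- function(type, seqs, cfg) {
  Nc <- ncol(seqs[[1]])
  Js <- if (type == "multi") c(cfg$J1, cfg$J2) else cfg$J1
  H <- cfg$hidden_dim
  enc <- c(list(rnn = bilstm_init(Nc, H)), init_heads(2L * H, Js, scale_init = 0.1))
  pri <- c(list(rnn = lstm_init(sum(Js), H)), init_heads(H, Js, scale_init = 1.0))
  obs <- if (type == "multi") init_obs_multi(seqs, cfg$J1, cfg$J2, cfg$jitter)
         else init_obs_single(seqs, cfg$J1, cfg$jitter)
  list(enc = enc, pri = pri, obs = obs)
}

# ---------------------------------------------------------------------------
# Free energy and its gradient for one batch
# ---------------------------------------------------------------------------

# Xenc: B x T x Nc array seen by the encoder; Xll: (B*T) x Nc matrix for the
# likelihood (identical unless PCA rotation is in use). noise: list of
# (B*T) x J_k standard-normal matrices. Returns mean per-sequence loss and,
# if grad, gradients in the same nested shape as params.
fe_grad <- function(params, Xenc, Xll, noise, klw, type, jitter, grad = TRUE) {
  B <- dim(Xenc)[1]; Tn <- dim(Xenc)[2]; Nc <- dim(Xenc)[3]
  K <- if (type == "multi") 2L else 1L
  Js <- vapply(seq_len(K), function(k) ncol(noise[[k]]), integer(1))
  H2 <- ncol(params$enc$rnn$fwd$U) / 4L * 2L

  enc <- bilstm_forward(params$enc$rnn, Xenc)
  Hf <- matrix(enc$H, B * Tn, H2)

  m <- list(); sraw <- list(); s <- list(); th <- list()
  for (k in seq_len(K)) {
    m[[k]] <- sweep(Hf %*% params$enc[[paste0("Wm", k)]], 2L,
                    params$enc[[paste0("bm", k)]], "+")
    sraw[[k]] <- Hf %*% params$enc[[paste0("Ws", k)]] + params$enc[[paste0("bs", k)]]
    s[[k]] <- softplus(sraw[[k]])
    th[[k]] <- m[[k]] + as.vector(s[[k]]) * noise[[k]]
  }
  mix <- lapply(th, softmax_mix)

  if (type == "multi") {
    e <- softplus(params$obs$e_raw)
    Rarr <- constrain_fc(params$obs$Lraw, jitter = jitter)$R
    obs <- .obs_gfg_cpp(Xll, mix[[1]], mix[[2]], e, Rarr, grad)
  } else {
    Cj <- cov_modes_from_raw(params$obs$Lraw, jitter)
    obs <- .obs_full_cpp(Xll, mix[[1]], Cj, grad)
  }
  ll_sum <- sum(obs$ll)

  # prior over t = 2..T: LSTM input at step t is theta_{t-1} (both dynamics)
  Uin <- array(0, c(B, Tn - 1L, sum(Js)))
  off <- 0L
  for (k in seq_len(K)) {
    tharr <- array(th[[k]], c(B, Tn, Js[k]))
    Uin[, , off + seq_len(Js[k])] <- tharr[, seq_len(Tn - 1L), , drop = FALSE]
    off <- off + Js[k]
  }
  pri <- lstm_forward(params$pri$rnn, Uin)
  Hp <- matrix(pri$H, B * (Tn - 1L), dim(pri$H)[3])

  # indices of flat (B*T) rows belonging to t = 2..T, in (b, t) flat order
  post_rows <- as.vector(outer(seq_len(B), seq(2L, Tn), function(b, t) (t - 1L) * B + b))

  mu <- list(); sgraw <- list(); sg <- list()
  kl_total <- 0
  for (k in seq_len(K)) {
    mu[[k]] <- sweep(Hp %*% params$pri[[paste0("Wm", k)]], 2L,
                     params$pri[[paste0("bm", k)]], "+")
    sgraw[[k]] <- Hp %*% params$pri[[paste0("Ws", k)]] + params$pri[[paste0("bs", k)]]
    sg[[k]] <- softplus(sgraw[[k]])
    mp <- m[[k]][post_rows, , drop = FALSE]
    sp <- s[[k]][post_rows]
    diffk <- mp - mu[[k]]
    kl_total <- kl_total + sum(Js[k] * log(sg[[k]] / sp) +
                                 (Js[k] * sp^2 + rowSums(diffk^2)) / (2 * sg[[k]]^2) -
                                 Js[k] / 2)
  }
  loss <- (-ll_sum + klw * kl_total) / B
  if (!grad) return(list(loss = loss, ll = ll_sum / B, kl = kl_total / B))

  cll <- -1 / B
  ckl <- klw / B

  # ----- likelihood path -----
  dth <- list()
  dmix <- if (type == "multi") list(obs$dA, obs$dB) else list(obs$dA)
  for (k in seq_len(K)) {
    dthk <- mix[[k]] * (dmix[[k]] - rowSums(dmix[[k]] * mix[[k]]))
    dth[[k]] <- cll * dthk
  }
  if (type == "multi") {
    de_raw <- cll * obs$de * sigmoid(params$obs$e_raw)
    dLraw <- array(0, dim(params$obs$Lraw))
    for (j in seq_len(dim(dLraw)[3]))
      dLraw[, , j] <- cll * constrain_fc_grad(params$obs$Lraw[, , j],
                                              obs$dR[, , j], jitter)
    dobs <- list(e_raw = de_raw, Lraw = dLraw)
  } else {
    dLraw <- array(0, dim(params$obs$Lraw))
    for (j in seq_len(dim(dLraw)[3])) {
      L <- params$obs$Lraw[, , j]; L[upper.tri(L)] <- 0
      dCj <- obs$dC[, , j]
      g <- cll * (dCj + t(dCj)) %*% L
      g[upper.tri(g)] <- 0
      dLraw[, , j] <- g
    }
    dobs <- list(Lraw = dLraw)
  }

  # ----- KL path -----
  dm_direct <- list(); ds_direct <- list()
  dHp <- matrix(0, nrow(Hp), ncol(Hp))
  gpri_heads <- list()
  for (k in seq_len(K)) {
    mp <- m[[k]][post_rows, , drop = FALSE]
    sp <- s[[k]][post_rows]
    diffk <- mp - mu[[k]]
    inv_sg2 <- as.vector(1 / sg[[k]]^2)
    dmp <- ckl * diffk * inv_sg2
    dmu <- -dmp
    dsp <- ckl * (-Js[k] / sp + Js[k] * sp * inv_sg2)
    dsg <- ckl * (Js[k] / as.vector(sg[[k]]) -
                    (Js[k] * sp^2 + rowSums(diffk^2)) / as.vector(sg[[k]])^3)
    dsgraw <- matrix(dsg * as.vector(sigmoid(sgraw[[k]])), ncol = 1L)
    gpri_heads[[paste0("Wm", k)]] <- crossprod(Hp, dmu)
    gpri_heads[[paste0("bm", k)]] <- colSums(dmu)
    gpri_heads[[paste0("Ws", k)]] <- crossprod(Hp, dsgraw)
    gpri_heads[[paste0("bs", k)]] <- sum(dsgraw)
    dHp <- dHp + dmu %*% t(params$pri[[paste0("Wm", k)]]) +
      dsgraw %*% t(params$pri[[paste0("Ws", k)]])
    dm_direct[[k]] <- dmp
    ds_direct[[k]] <- dsp
  }
  dHp3 <- array(dHp, c(B, Tn - 1L, ncol(Hp)))
  gpri_rnn <- lstm_backward(params$pri$rnn, pri, dHp3)

  # gradient into the prior inputs theta_{1..T-1}
  off <- 0L
  for (k in seq_len(K)) {
    dUk <- gpri_rnn$dX[, , off + seq_len(Js[k]), drop = FALSE]   # B x (T-1) x Jk
    dth_in <- matrix(0, B * Tn, Js[k])
    pre_rows <- as.vector(outer(seq_len(B), seq_len(Tn - 1L),
                                function(b, t) (t - 1L) * B + b))
    dth_in[pre_rows, ] <- matrix(dUk, B * (Tn - 1L), Js[k])
    dth[[k]] <- dth[[k]] + dth_in
    off <- off + Js[k]
  }

  # ----- posterior heads and encoder -----
  dHf <- matrix(0, nrow(Hf), ncol(Hf))
  genc_heads <- list()
  for (k in seq_len(K)) {
    dmk <- dth[[k]]
    dmk[post_rows, ] <- dmk[post_rows, , drop = FALSE] + dm_direct[[k]]
    dsk <- rowSums(dth[[k]] * noise[[k]])
    dsk[post_rows] <- dsk[post_rows] + ds_direct[[k]]
    dsraw <- matrix(dsk * as.vector(sigmoid(sraw[[k]])), ncol = 1L)
    genc_heads[[paste0("Wm", k)]] <- crossprod(Hf, dmk)
    genc_heads[[paste0("bm", k)]] <- colSums(dmk)
    genc_heads[[paste0("Ws", k)]] <- crossprod(Hf, dsraw)
    genc_heads[[paste0("bs", k)]] <- sum(dsraw)
    dHf <- dHf + dmk %*% t(params$enc[[paste0("Wm", k)]]) +
      dsraw %*% t(params$enc[[paste0("Ws", k)]])
  }
  dHf3 <- array(dHf, c(B, Tn, ncol(Hf)))
  genc_rnn <- bilstm_backward(params$enc$rnn, enc, dHf3)

  relabel <- function(g) setNames(g[c("dW", "dU", "db")], c("W", "U", "b"))
  grads <- list(enc = c(list(rnn = list(fwd = relabel(genc_rnn$fwd),
                                        bwd = relabel(genc_rnn$bwd))),
                        genc_heads),
                pri = c(list(rnn = relabel(gpri_rnn)), gpri_heads),
                obs = dobs)
  list(loss = loss, ll = ll_sum / B, kl = kl_total / B, grads = grads)
}

cov_modes_from_raw <- function(Lraw, jitter) {
  Nc <- dim(Lraw)[1]; J <- dim(Lraw)[3]
  Cj <- array(0, c(Nc, Nc, J))
  for (j in seq_len(J)) {
    L <- Lraw[, , j]; L[upper.tri(L)] <- 0
    Cj[, , j] <- tcrossprod(L) + jitter * diag(Nc)
  }
  Cj
}

#' Variational free energy of a batch of sequences
#'
#' Evaluates the per-sequence training loss (negative ELBO): one
#' reparameterised-sample likelihood term plus the closed-form
#' Gaussian-Gaussian KL between the amortized posterior and the recurrent
#' prior, summed from the second time step.
#'
#' @param model a trained model (from [train_mdynemo] or
#'   [train_single_dynamic]).
#' @param sequences list of `T_seq x Nc` matrices.
#' @param noise optional list of standard-normal matrices (one per dynamic,
#'   `(B*T_seq) x J_k`); drawn internally when `NULL`.
#' @param seed seed used when drawing `noise`.
#' @param kl_weight KL annealing weight (1 = full ELBO).
#' @return List with `loss` (mean per-sequence free energy), `ll`, `kl`.
#' @export
free_energy <- function(model, sequences, noise = NULL, seed = 1L,
                        kl_weight = 1) {
  X <- stack_sequences(sequences)
  Xenc <- encoder_view(model, X)
  B <- dim(X)[1]; Tn <- dim(X)[2]
  K <- if (model$type == "multi") 2L else 1L
  Js <- if (model$type == "multi") c(model$J1, model$J2) else model$J1
  if (is.null(noise)) {
    set.seed(seed)
    noise <- lapply(seq_len(K), function(k) matrix(rnorm(B * Tn * Js[k]), B * Tn, Js[k]))
  }
  Xll <- matrix(X, B * Tn, dim(X)[3])
  out <- fe_grad(model$params, Xenc, Xll, noise, klw = kl_weight,
                 type = model$type, jitter = model$config$jitter, grad = FALSE)
  if (!is.finite(out$loss)) stop("non-finite free energy")
  out
}

stack_sequences <- function(sequences) {
  B <- length(sequences)
  Tn <- nrow(sequences[[1]]); Nc <- ncol(sequences[[1]])
  X <- array(0, c(B, Tn, Nc))
  for (b in seq_len(B)) X[b, , ] <- sequences[[b]]
  X
}

encoder_view <- function(model, X) {
  if (is.null(model$pca)) return(X)
  W <- model$pca$W
  B <- dim(X)[1]; Tn <- dim(X)[2]
  Xf <- matrix(X, B * Tn, dim(X)[3]) %*% t(W)
  array(Xf, dim(X))
}

# ---------------------------------------------------------------------------
# Training loop
# ---------------------------------------------------------------------------

train_loop <- function(type, sessions, config, verbose) {
  seqs <- chunk_sessions(sessions, config$sequence_length)
  if (!length(seqs)) stop("no session yields a full training sequence")
  if (max(vapply(seqs, function(x) max(abs(x)), numeric(1))) < 1e-8)
    warning("degenerate (near-constant) data: the fit will be uninformative")
  pca <- NULL
  if (config$do_pca) {
    pca <- fit_apply_pca(lapply(sessions, session_matrix))$projection
    enc_seqs <- lapply(seqs, function(x) x %*% t(pca$W))
  } else enc_seqs <- seqs

  S <- length(seqs)
  Tn <- config$sequence_length
  Nc <- ncol(seqs[[1]])
  K <- if (type == "multi") 2L else 1L
  Js <- if (type == "multi") c(config$J1, config$J2) else config$J1
  bsz <- min(config$batch_size, S)

  best <- NULL
  all_final <- numeric(0)
  for (start in seq_len(config$n_starts)) {
    set.seed(config$seed + 7919L * start)
    params <- init_params(type, seqs, config)
    opt <- adam_init(params)
    history <- numeric(config$n_epochs)
    init_loss <- NA_real_
    diverged <- FALSE
    for (epoch in seq_len(config$n_epochs)) {
      klw <- min(1, epoch / max(1L, config$kl_anneal_epochs))
      frac <- epoch / config$n_epochs
      lr <- config$learning_rate *
        if (frac > 0.5) config$lr_decay ^ (2 * (frac - 0.5)) else 1
      ord <- sample.int(S)
      ep_losses <- numeric(0)
      for (bstart in seq(1L, S, by = bsz)) {
        idx <- ord[bstart:min(bstart + bsz - 1L, S)]
        B <- length(idx)
        X <- stack_sequences(seqs[idx])
        Xenc <- if (config$do_pca) stack_sequences(enc_seqs[idx]) else X
        Xll <- matrix(X, B * Tn, Nc)
        noise <- lapply(seq_len(K), function(k)
          matrix(rnorm(B * Tn * Js[k]), B * Tn, Js[k]))
        out <- tryCatch(
          fe_grad(params, Xenc, Xll, noise, klw, type, config$jitter, grad = TRUE),
          error = function(e) NULL)
        if (is.null(out) || !is.finite(out$loss)) { diverged <- TRUE; break }
        if (is.na(init_loss)) init_loss <- out$loss
        if (out$loss > abs(init_loss) * 10 + 10) { diverged <- TRUE; break }
        ep_losses <- c(ep_losses, out$loss)
        st <- adam_step(params, out$grads, opt, lr = lr)
        params <- st$params; opt <- st$state
      }
      if (diverged) break
      history[epoch] <- mean(ep_losses)
      if (verbose)
        message(sprintf("start %d epoch %d loss %.4f (kl weight %.2f)",
                        start, epoch, history[epoch], klw))
    }
    final <- if (diverged) Inf else history[config$n_epochs]
    all_final <- c(all_final, final)
    if (is.null(best) || final < best$final)
      best <- list(params = params, history = history, final = final,
                   start = start)
  }
  if (!is.finite(best$final)) stop("all training restarts diverged")
  model <- structure(list(type = type, params = best$params, config = config,
                          Nc = Nc, J1 = config$J1,
                          J2 = if (type == "multi") config$J2 else NA_integer_,
                          pca = pca, loss_history = best$history,
                          final_losses = all_final, best_start = best$start),
                     class = "mdynemo_model")
  model$modes <- model_modes(model)
  model
}

#' Train the multi-dynamic network-modes model
#'
#' Fits separate power and FC mode sets and their two latent mixing dynamics
#' by minimising the variational free energy with Adam, KL annealing and
#' best-of-`n_starts` restart selection.
#'
#' @param sessions list of `T x Nc` matrices (preprocessed amplitude
#'   envelopes) or `session_data` objects.
#' @param config a [training_config].
#' @param verbose print per-epoch loss.
#' @return An object of class `mdynemo_model` (`type = "multi"`) holding the
#'   network parameters, the constrained mode sets (`$modes$power`,
#'   `$modes$fc`), the per-epoch loss history of the selected restart and the
#'   final loss of every restart.
#' @export
train_mdynemo <- function(sessions, config = training_config(),
                          verbose = FALSE) {
  train_loop("multi", sessions, config, verbose)
}

#' Train the single-dynamic (shared dynamics) special case
#'
#' One latent logit sequence drives a mixture of full covariance modes
#' `C_j` (no power/correlation split): the standard shared-dynamics network
#' modes model used as a comparison baseline.
#'
#' @inheritParams train_mdynemo
#' @return An object of class `mdynemo_model` (`type = "single"`) whose
#'   `$modes$cov` is an `Nc x Nc x J1` array of covariance modes.
#' @export
train_single_dynamic <- function(sessions, config = training_config(),
                                 verbose = FALSE) {
  train_loop("single", sessions, config, verbose)
}

model_modes <- function(model) {
  if (model$type == "multi") {
    list(power = constrain_power(model$params$obs$e_raw),
         fc = constrain_fc(model$params$obs$Lraw, jitter = model$config$jitter))
  } else {
    list(cov = cov_modes_from_raw(model$params$obs$Lraw, model$config$jitter))
  }
}

#' Infer mixing coefficients for a session
#'
#' Runs the amortized posterior (BiLSTM encoder) over the full session and
#' returns the softmax of the posterior means: the mode time courses. Output
#' length equals input length.
#'
#' @param model a trained `mdynemo_model`.
#' @param x `T x Nc` matrix (or `session_data`).
#' @return For a multi-dynamic model, a [mixing_coefficients] object; for a
#'   single-dynamic model, a list with `alpha` and `theta`.
#' @export
infer_mixing <- function(model, x) {
  x <- session_matrix(x)
  if (ncol(x) != model$Nc)
    stop("session has ", ncol(x), " channels but the model was trained on ",
         model$Nc)
  X <- array(x, c(1L, nrow(x), ncol(x)))
  Xenc <- encoder_view(model, X)
  enc <- bilstm_forward(model$params$enc$rnn, Xenc)
  Hf <- matrix(enc$H, nrow(x), dim(enc$H)[3])
  post_mean <- function(k)
    sweep(Hf %*% model$params$enc[[paste0("Wm", k)]], 2L,
          model$params$enc[[paste0("bm", k)]], "+")
  if (model$type == "multi")
    return(mixing_coefficients(post_mean(1L), post_mean(2L)))
  th <- post_mean(1L)
  list(alpha = softmax_mix(th), theta = th)
}

#' Session-level observation parameters by dual estimation
#'
#' Freezes the group model's temporal posterior (the mixing-coefficient time
#' courses inferred for this session) and re-optimises only the observation
#' parameters on the session data.
#'
#' @param model a trained multi-dynamic `mdynemo_model`.
#' @param x `T x Nc` session matrix (or `session_data`).
#' @param n_iter Adam iterations.
#' @param learning_rate Adam step size.
#' @return List with the session-level `power` ([power_mode_set]) and `fc`
#'   ([fc_mode_set]) mode sets and the mixing coefficients used.
#' @export
dual_estimate <- function(model, x, n_iter = 300L, learning_rate = 0.02) {
  stopifnot(model$type == "multi")
  x <- session_matrix(x)
  if (nrow(x) < model$Nc * (model$Nc + 1) / 2)
    warning("session of length ", nrow(x), " is short for estimating ",
            model$Nc, "x", model$Nc, " mode structure")
  mix <- infer_mixing(model, x)
  obs_par <- model$params$obs
  opt <- adam_init(obs_par)
  jitter <- model$config$jitter
  for (it in seq_len(n_iter)) {
    e <- softplus(obs_par$e_raw)
    Rarr <- constrain_fc(obs_par$Lraw, jitter = jitter)$R
    res <- .obs_gfg_cpp(x, mix$alpha, mix$beta, e, Rarr, TRUE)
    de_raw <- -res$de * sigmoid(obs_par$e_raw) / nrow(x)
    dLraw <- array(0, dim(obs_par$Lraw))
    for (j in seq_len(dim(dLraw)[3]))
      dLraw[, , j] <- -constrain_fc_grad(obs_par$Lraw[, , j], res$dR[, , j],
                                         jitter) / nrow(x)
    st <- adam_step(obs_par, list(e_raw = de_raw, Lraw = dLraw), opt,
                    lr = learning_rate)
    obs_par <- st$params; opt <- st$state
  }
  list(power = constrain_power(obs_par$e_raw),
       fc = constrain_fc(obs_par$Lraw, jitter = jitter),
       mixing = mix)
}
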