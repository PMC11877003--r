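# Independent straight-line evaluation of the variational free energy for
# tiny instances: scalar loops, explicit matrix inverses and determinants,
# direct softmax and closed-form KL. Shares nothing with the package's
# batched implementation beyond the parameter values themselves.

oracle_free_energy <- function(params, X, noise, klw, type, jitter = 1e-6) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; Nc <- dim(X)[3]
  K <- length(noise)
  Js <- vapply(noise, ncol, integer(1))
  sp <- function(x) log1p(exp(x))          # softplus, small arguments only

  cell <- function(p, x, h, c) {
    H <- length(h)
    z <- as.vector(x %*% p$W) + as.vector(h %*% p$U) + p$b
    i <- 1 / (1 + exp(-z[seq_len(H)]))
    f <- 1 / (1 + exp(-z[H + seq_len(H)]))
    o <- 1 / (1 + exp(-z[2 * H + seq_len(H)]))
    g <- tanh(z[3 * H + seq_len(H)])
    c2 <- f * c + i * g
    list(h = o * tanh(c2), c = c2)
  }
  run_lstm <- function(p, xs) {             # xs: T x D -> T x H
    H <- nrow(p$U)
    h <- rep(0, H); c <- rep(0, H)
    out <- matrix(0, nrow(xs), H)
    for (t in seq_len(nrow(xs))) {
      st <- cell(p, xs[t, ], h, c)
      h <- st$h; c <- st$c
      out[t, ] <- h
    }
    out
  }

  total <- 0
  for (b in seq_len(B)) {
    xs <- matrix(X[b, , ], Tn, Nc)
    hf <- run_lstm(params$enc$rnn$fwd, xs)
    hb <- run_lstm(params$enc$rnn$bwd, xs[Tn:1, , drop = FALSE])[Tn:1, , drop = FALSE]
    henc <- cbind(hf, hb)
    m <- list(); s <- list(); th <- list()
    for (k in seq_len(K)) {
      m[[k]] <- matrix(0, Tn, Js[k]); s[[k]] <- numeric(Tn)
      th[[k]] <- matrix(0, Tn, Js[k])
      for (t in seq_len(Tn)) {
        m[[k]][t, ] <- as.vector(henc[t, ] %*% params$enc[[paste0("Wm", k)]]) +
          params$enc[[paste0("bm", k)]]
        s[[k]][t] <- sp(sum(henc[t, ] * params$enc[[paste0("Ws", k)]]) +
                          params$enc[[paste0("bs", k)]])
        eps <- noise[[k]][(t - 1) * B + b, ]
        th[[k]][t, ] <- m[[k]][t, ] + s[[k]][t] * eps
      }
    }
    # likelihood term, one sample
    ll <- 0
    for (t in seq_len(Tn)) {
      if (type == "multi") {
        a <- exp(th[[1]][t, ]); a <- a / sum(a)
        bb <- exp(th[[2]][t, ]); bb <- bb / sum(bb)
        e <- log1p(exp(params$obs$e_raw))
        g <- as.vector(a %*% e)
        Fm <- matrix(0, Nc, Nc)
        for (j in seq_along(bb)) {
          L <- params$obs$Lraw[, , j]; L[upper.tri(L)] <- 0
          M <- L %*% t(L) + jitter * diag(Nc)
          Rj <- diag(1 / sqrt(diag(M))) %*% M %*% diag(1 / sqrt(diag(M)))
          Fm <- Fm + bb[j] * Rj
        }
        C <- diag(g) %*% Fm %*% diag(g)
      } else {
        a <- exp(th[[1]][t, ]); a <- a / sum(a)
        C <- matrix(0, Nc, Nc)
        for (j in seq_along(a)) {
          L <- params$obs$Lraw[, , j]; L[upper.tri(L)] <- 0
          C <- C + a[j] * (L %*% t(L) + jitter * diag(Nc))
        }
      }
      ll <- ll - 0.5 * (Nc * log(2 * pi) + log(det(C)) +
                          drop(xs[t, ] %*% solve(C) %*% xs[t, ]))
    }
    # KL term, t = 2..T, prior conditioned on sampled history
    kl <- 0
    uin <- do.call(cbind, lapply(th, function(M) M))[seq_len(Tn - 1), , drop = FALSE]
    hpri <- run_lstm(params$pri$rnn, matrix(uin, Tn - 1, sum(Js)))
    for (t in 2:Tn) {
      for (k in seq_len(K)) {
        mu <- as.vector(hpri[t - 1, ] %*% params$pri[[paste0("Wm", k)]]) +
          params$pri[[paste0("bm", k)]]
        sg <- sp(sum(hpri[t - 1, ] * params$pri[[paste0("Ws", k)]]) +
                   params$pri[[paste0("bs", k)]])
        mq <- m[[k]][t, ]; sq <- s[[k]][t]
        kl <- kl + sum(log(sg / sq) + (sq^2 + (mq - mu)^2) / (2 * sg^2) - 0.5)
      }
    }
    total <- total + (-ll + klw * kl)
  }
  total / B
}
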