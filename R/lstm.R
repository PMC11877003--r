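# Batched LSTM machinery with analytic backpropagation.
#
# Arrays are B x T x D (batch, time, feature). A single LSTM layer carries
# parameters W (D x 4H), U (H x 4H), b (4H), gate order i, f, o, g. The
# recurrent state is reset at every sequence boundary (sequences are treated
# as independent), so no state is threaded between calls.
#
# Correctness of every backward pass is pinned by finite-difference tests.

lstm_init <- function(input_dim, hidden_dim, gain = 0.1) {
  H <- hidden_dim
  list(W = matrix(rnorm(input_dim * 4 * H, sd = gain), input_dim, 4 * H),
       U = matrix(rnorm(H * 4 * H, sd = gain), H, 4 * H),
       # forget-gate bias starts at 1 (standard recipe for gradient flow)
       b = c(rep(0, H), rep(1, H), rep(0, 2 * H)))
}

# layout shim: B x T x D array <-> cube with one B x D matrix per time slice
to_cube <- function(X) aperm(X, c(1L, 3L, 2L))
from_cube <- function(X) aperm(X, c(1L, 3L, 2L))

lstm_forward <- function(par, X) {
  out <- .lstm_fwd_cpp(par$W, par$U, par$b, to_cube(X))
  list(H = from_cube(out$H), cache = out, Xc = to_cube(X))
}

lstm_backward <- function(par, fwd, dH) {
  cc <- fwd$cache
  g <- .lstm_bwd_cpp(par$W, par$U, fwd$Xc, cc$H, cc$i, cc$f, cc$o, cc$g, cc$c,
                     to_cube(dH))
  list(dW = g$dW, dU = g$dU, db = as.vector(g$db), dX = from_cube(g$dX))
}

# Bidirectional LSTM: forward pass + time-reversed pass, outputs concatenated
# along the feature axis (B x T x 2H).
bilstm_init <- function(input_dim, hidden_dim, gain = 0.1) {
  list(fwd = lstm_init(input_dim, hidden_dim, gain),
       bwd = lstm_init(input_dim, hidden_dim, gain))
}

rev_time <- function(X) X[, rev(seq_len(dim(X)[2])), , drop = FALSE]

bilstm_forward <- function(par, X) {
  ff <- lstm_forward(par$fwd, X)
  bb <- lstm_forward(par$bwd, rev_time(X))
  H <- array(0, c(dim(X)[1], dim(X)[2], 2L * dim(ff$H)[3]))
  H[, , seq_len(dim(ff$H)[3])] <- ff$H
  H[, , dim(ff$H)[3] + seq_len(dim(ff$H)[3])] <- rev_time(bb$H)
  list(H = H, ff = ff, bb = bb)
}

bilstm_backward <- function(par, fwd, dH) {
  Hh <- dim(fwd$ff$H)[3]
  dHf <- dH[, , seq_len(Hh), drop = FALSE]
  dHb <- rev_time(dH[, , Hh + seq_len(Hh), drop = FALSE])
  gf <- lstm_backward(par$fwd, fwd$ff, dHf)
  gb <- lstm_backward(par$bwd, fwd$bb, dHb)
  list(fwd = gf[c("dW", "dU", "db")], bwd = gb[c("dW", "dU", "db")],
       dX = gf$dX + rev_time(gb$dX))
}

# ---------------------------------------------------------------------------
# Adam over an arbitrary nested list of numeric parameters.
# ---------------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) return(lapply(p, zero_like))
    p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
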