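# Variational trainer: sequence chunking, the free-energy objective and its
# gradients, sampling, amortized inference and dual estimation.

test_that("chunk_sessions counts and never spans session boundaries", {
  mk <- function(T_len) matrix(seq_len(T_len * 2), T_len, 2)
  expect_length(chunk_sessions(list(mk(400)), 200), 2)
  expect_length(chunk_sessions(list(mk(399)), 200), 1)
  chunks <- chunk_sessions(list(mk(500), mk(250)), 200)
  expect_length(chunks, 3)
  # enumeration oracle: every chunk is a contiguous slice of one session
  sess <- list(mk(500), mk(250))
  expected <- c(lapply(c(1, 201), function(s) sess[[1]][s:(s + 199), ]),
                list(sess[[2]][1:200, ]))
  expect_equal(chunks, expected)
  expect_warning(chunk_sessions(list(mk(100), mk(400)), 200), "excluded")
})

test_that("reparameterised_sample is the affine reparameterisation", {
  expect_equal(reparameterised_sample(3, 2, 0), 3)
  expect_equal(reparameterised_sample(3, 2, 1), 5)
  expect_error(reparameterised_sample(0, -1, 0), "positive")
  set.seed(1)
  draws <- reparameterised_sample(0.7, 1.3, rnorm(1e5))
  expect_lt(abs(mean(draws) - 0.7), 3 * 1.3 / sqrt(1e5))
})

test_that("free energy matches the independent term-by-term oracle", {
  set.seed(5)
  B <- 2L; Tn <- 4L; Nc <- 2L
  cfg <- training_config(sequence_length = Tn, hidden_dim = 3L, J1 = 2L,
                         J2 = 2L, n_starts = 1L)
  seqs <- lapply(1:3, function(i) matrix(rnorm(Tn * Nc), Tn, Nc))
  X <- mdynemo:::stack_sequences(seqs[1:B])
  Xll <- matrix(X, B * Tn, Nc)
  for (type in c("multi", "single")) {
    params <- mdynemo:::init_params(type, seqs, cfg)
    K <- if (type == "multi") 2L else 1L
    noise <- lapply(seq_len(K), function(k) matrix(rnorm(B * Tn * 2), B * Tn, 2))
    for (klw in c(0.3, 1)) {
      got <- mdynemo:::fe_grad(params, X, Xll, noise, klw, type,
                               jitter = 1e-6, grad = FALSE)$loss
      want <- oracle_free_energy(params, X, noise, klw, type)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("KL term vanishes when the posterior equals the prior", {
  set.seed(6)
  Tn <- 5L; Nc <- 2L; B <- 1L
  cfg <- training_config(sequence_length = Tn, hidden_dim = 3L, J1 = 2L,
                         J2 = 2L, n_starts = 1L)
  seqs <- list(matrix(rnorm(Tn * Nc), Tn, Nc))
  params <- mdynemo:::init_params("multi", seqs, cfg)
  # collapse both distributions to fixed N(c, softplus(b)^2): zero weights,
  # identical biases
  for (k in 1:2) {
    params$enc[[paste0("Wm", k)]][] <- 0
    params$pri[[paste0("Wm", k)]][] <- 0
    params$enc[[paste0("Ws", k)]][] <- 0
    params$pri[[paste0("Ws", k)]][] <- 0
    params$enc[[paste0("bm", k)]][] <- 0.3
    params$pri[[paste0("bm", k)]][] <- 0.3
    params$enc[[paste0("bs", k)]] <- 0.1
    params$pri[[paste0("bs", k)]] <- 0.1
  }
  X <- mdynemo:::stack_sequences(seqs)
  noise <- lapply(1:2, function(k) matrix(rnorm(Tn * 2), Tn, 2))
  out <- mdynemo:::fe_grad(params, X, matrix(X, Tn, Nc), noise, 1, "multi",
                           1e-6, grad = FALSE)
  expect_equal(out$kl, 0, tolerance = 1e-10)
  # shifting the posterior mean by d with unit-like scales gives the
  # closed-form KL d^2/(2 sigma^2) per dimension, summed over t = 2..T
  for (k in 1:2) params$enc[[paste0("bm", k)]][] <- 1.3
  sg <- log1p(exp(0.1))
  out2 <- mdynemo:::fe_grad(params, X, matrix(X, Tn, Nc), noise, 1, "multi",
                            1e-6, grad = FALSE)
  expect_equal(out2$kl, (Tn - 1) * 2 * 2 * 0.5 / sg^2, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences on a tiny instance", {
  set.seed(7)
  B <- 2L; Tn <- 4L; Nc <- 2L
  cfg <- training_config(sequence_length = Tn, hidden_dim = 3L, J1 = 2L,
                         J2 = 2L, n_starts = 1L)
  seqs <- lapply(1:3, function(i) matrix(rnorm(Tn * Nc), Tn, Nc))
  X <- mdynemo:::stack_sequences(seqs[1:B])
  Xll <- matrix(X, B * Tn, Nc)
  for (type in c("multi", "single")) {
    params <- mdynemo:::init_params(type, seqs, cfg)
    K <- if (type == "multi") 2L else 1L
    noise <- lapply(seq_len(K), function(k) matrix(rnorm(B * Tn * 2), B * Tn, 2))
    out <- mdynemo:::fe_grad(params, X, Xll, noise, 0.8, type, 1e-6, TRUE)
    lossf <- function(p) mdynemo:::fe_grad(p, X, Xll, noise, 0.8, type, 1e-6,
                                           grad = FALSE)$loss
    # probe a handful of coordinates in every parameter leaf
    paths <- list(c("enc", "rnn", "fwd", "W"), c("enc", "rnn", "bwd", "U"),
                  c("enc", "Wm1"), c("enc", "Ws1"), c("enc", "bs1"),
                  c("pri", "rnn", "W"), c("pri", "rnn", "b"),
                  c("pri", "Wm1"), c("pri", "bs1"),
                  if (type == "multi") c("obs", "e_raw"), c("obs", "Lraw"))
    paths <- Filter(Negate(is.null), paths)
    h <- 1e-5
    for (pth in paths) {
      leaf <- params[[pth]]
      gleaf <- out$grads[[pth]]
      for (i in sample(length(leaf), min(3, length(leaf)))) {
        p1 <- params; p1[[pth]][i] <- p1[[pth]][i] + h
        p2 <- params; p2[[pth]][i] <- p2[[pth]][i] - h
        num <- (lossf(p1) - lossf(p2)) / (2 * h)
        expect_equal(gleaf[i], num, tolerance = 5e-3,
                     label = paste(c(pth, i), collapse = "/"))
      }
    }
  }
})

test_that("training is deterministic under a fixed seed and returns valid modes", {
  set.seed(11)
  sim <- simulate_sessions(sim_config(Nc = 4L, n_states_power = 2L,
                                      n_states_fc = 2L, T_session = 400L,
                                      n_sessions = 1L, seed = 2L))
  xs <- lapply(sim$sessions, function(s) t(s$x))
  cfg <- training_config(sequence_length = 50L, batch_size = 4L,
                         n_epochs = 3L, n_starts = 1L, hidden_dim = 4L,
                         J1 = 2L, J2 = 2L, seed = 9L, learning_rate = 5e-3)
  m1 <- train_mdynemo(xs, cfg)
  m2 <- train_mdynemo(xs, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_true(all(is.finite(m1$loss_history)))
  # constraints hold at exit
  expect_true(all(m1$modes$power$e > 0))
  for (j in 1:2) {
    Rj <- m1$modes$fc$R[, , j]
    expect_equal(diag(Rj), rep(1, 4))
    expect_gt(min(eigen(Rj, symmetric = TRUE)$values), 0)
  }
})

test_that("near-constant data is flagged as degenerate but does not crash", {
  xs <- list(matrix(1e-14 * rnorm(400), 100, 4))
  cfg <- training_config(sequence_length = 25L, batch_size = 4L,
                         n_epochs = 2L, n_starts = 1L, hidden_dim = 3L,
                         J1 = 2L, J2 = 2L, seed = 1L)
  expect_warning(train_mdynemo(xs, cfg), "degenerate")
})

test_that("infer_mixing returns simplex rows of matching length", {
  model <- fresh_model(Nc = 3L, J1 = 2L, J2 = 2L)
  x <- matrix(rnorm(60 * 3), 60, 3)
  mix <- infer_mixing(model, x)
  expect_equal(nrow(mix$alpha), 60)
  expect_equal(rowSums(mix$alpha), rep(1, 60), tolerance = 1e-6)
  expect_equal(rowSums(mix$beta), rep(1, 60), tolerance = 1e-6)
  expect_true(all(mix$alpha >= 0))
  # deterministic (posterior mean, no sampling)
  expect_identical(mix$alpha, infer_mixing(model, x)$alpha)
  # shuffled time keeps the structural invariant
  mix2 <- infer_mixing(model, x[sample(60), ])
  expect_equal(rowSums(mix2$alpha), rep(1, 60), tolerance = 1e-6)
  expect_error(infer_mixing(model, matrix(0, 10, 5)), "channels")
})

test_that("dual estimation with one mode recovers the session moments", {
  set.seed(13)
  model <- fresh_model(Nc = 3L, J1 = 1L, J2 = 1L, seed = 13)
  Rtrue <- random_correlation(3, scale = 2)
  g <- c(1.5, 0.8, 1.2)
  C <- diag(g) %*% Rtrue %*% diag(g)
  x <- matrix(rnorm(4000 * 3), 4000, 3) %*% chol(C)
  est <- dual_estimate(model, x, n_iter = 400L, learning_rate = 0.05)
  # with J = 1 the mixture is constant: E^2 -> session variance, R -> session
  # correlation (up to optimisation tolerance)
  expect_equal(as.vector(est$power$e), apply(x, 2, sd), tolerance = 0.05)
  expect_equal(est$fc$R[, , 1], cor(x), tolerance = 0.05)
})

test_that("single-dynamic model with one mode reduces to a static covariance fit", {
  set.seed(17)
  x <- matrix(rnorm(2000 * 3), 2000, 3) %*% chol(random_correlation(3, scale = 2))
  cfg <- training_config(sequence_length = 100L, batch_size = 8L,
                         n_epochs = 25L, n_starts = 1L, hidden_dim = 3L,
                         J1 = 1L, seed = 3L, learning_rate = 2e-2,
                         kl_anneal_epochs = 5L)
  m <- train_single_dynamic(list(x), cfg)
  expect_equal(m$modes$cov[, , 1], cov(x), tolerance = 0.12)
  mix <- infer_mixing(m, x)
  expect_equal(as.vector(mix$alpha), rep(1, 2000))
})
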