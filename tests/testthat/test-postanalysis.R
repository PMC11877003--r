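# Post-fit statistics: renormalisation, mode matching, permutation tests,
# network recalculation, epoching and the evoked-response GLM.

test_that("renormalise reweights by mode magnitude and keeps the simplex", {
  pm <- power_mode_set(rbind(c(2, 2), c(2, 2)))       # equal weights
  a <- random_simplex(20, 2)
  expect_equal(renormalise(a, pm), a, tolerance = 1e-12)
  pm1 <- power_mode_set(matrix(c(3, 1), 1, 2))
  expect_equal(renormalise(matrix(1, 5, 1), pm1), matrix(1, 5, 1))
  # formula oracle
  set.seed(1)
  pm2 <- tiny_power_modes(3L, 4L)
  a3 <- random_simplex(10, 3)
  w <- rowMeans(pm2$e)
  want <- sweep(a3, 2, w, "*") / as.vector(sweep(a3, 2, w, "*") %*% rep(1, 3))
  got <- renormalise(a3, pm2)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(rowSums(got), rep(1, 10), tolerance = 1e-12)
  # FC weights use mean absolute off-diagonal
  fm <- tiny_fc_modes(2L, 4L)
  v <- apply(fm$R, 3, function(R) mean(abs(R[upper.tri(R)])))
  b <- random_simplex(10, 2)
  wantb <- sweep(b, 2, v, "*") / as.vector(sweep(b, 2, v, "*") %*% rep(1, 2))
  expect_equal(renormalise(b, fm), wantb, tolerance = 1e-12)
})

test_that("relative power and FC degree maps are centred across modes", {
  pm <- power_mode_set(matrix(c(1, 1, 1, 1), 2, 2))
  expect_equal(relative_power_map(pm), matrix(0, 2, 2))
  set.seed(2)
  pm2 <- tiny_power_modes(3L, 5L, seed = 2)
  rp <- relative_power_map(pm2)
  expect_equal(colSums(rp), rep(0, 5), tolerance = 1e-12)
  expect_equal(rp, sweep(pm2$e, 2, colMeans(pm2$e)), tolerance = 1e-12)
  # identity modes have zero degree before centering
  fmI <- fc_mode_set(array(diag(4), c(4, 4, 2)))
  expect_equal(fc_degree_map(fmI), matrix(0, 2, 4))
  # loop oracle on a random set
  fm <- tiny_fc_modes(3L, 5L, seed = 3)
  deg <- matrix(0, 3, 5)
  for (j in 1:3) for (a in 1:5)
    deg[j, a] <- sum(fm$R[a, -a, j])
  expect_equal(fc_degree_map(fm), sweep(deg, 2, colMeans(deg)),
               tolerance = 1e-12)
})

test_that("match_modes recovers shuffles and maximises total similarity", {
  set.seed(4)
  A <- matrix(rnorm(4 * 10), 4, 10)
  shuffle <- c(3L, 1L, 4L, 2L)
  B <- A[shuffle, ]
  m <- match_modes(A, B)
  expect_equal(m$perm[shuffle], 1:4)   # row j of B is row shuffle[j] of A
  expect_equal(unname(m$matched), rep(1, 4), tolerance = 1e-12)
  # orthogonal maps: matched cosines near zero
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))[, 1:4]
  m2 <- match_modes(t(Q[, 1:2]), t(Q[, 3:4]), centre = FALSE)
  expect_lt(max(abs(m2$matched)), 1e-10)
  expect_error(match_modes(matrix(0, 2, 5), matrix(rnorm(10), 2, 5)),
               "zero-norm")
})

test_that("maxstat cosine test flags self-matches and controls the null", {
  set.seed(5)
  A <- matrix(rnorm(4 * 38), 4, 38)
  res <- maxstat_cosine_test(A, A, n_perm = 1000L, seed = 6L)
  expect_true(all(diag(res$p) <= 0.01))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_identical(res$sig, res$p <= 0.05)
  # independent maps: typically nothing significant
  B <- matrix(rnorm(4 * 38), 4, 38)
  res2 <- maxstat_cosine_test(A, B, n_perm = 500L, seed = 7L)
  expect_lt(mean(res2$sig), 0.2)
  expect_error(maxstat_cosine_test(A[, 1:2], A[, 1:2]), "at least 3")
  expect_error(maxstat_cosine_test(A, A, n_perm = 0L), "positive")
  expect_warning(maxstat_cosine_test(A, A, n_perm = 50L, seed = 1L), "100")
})

test_that("coupling_matrix detects shared dynamics and requires groups", {
  set.seed(8)
  alphas <- lapply(1:8, function(s) random_simplex(500, 3))
  # shared dynamics: beta == alpha, diagonal strongly coupled
  res <- coupling_matrix(alphas, alphas, n_perm = 500L, seed = 9L)
  expect_true(all(diag(res$sig)))
  expect_equal(dim(res$stat), c(3L, 3L))
  expect_error(coupling_matrix(alphas[1], alphas[1]), "2 sessions")
  # independent dynamics: diagonal mostly quiet
  betas <- lapply(1:8, function(s) random_simplex(500, 3))
  res2 <- coupling_matrix(alphas, betas, n_perm = 500L, seed = 10L)
  expect_lt(mean(res2$sig), 0.25)
})

test_that("recalc_networks inverts the generative mixing", {
  set.seed(11)
  # one-hot mixing with long segments: per-mode covariance equals the
  # segment sample covariance
  C1 <- diag(c(1, 2, 0.5)) %*% random_correlation(3) %*% diag(c(1, 2, 0.5))
  C2 <- diag(3)
  x <- rbind(matrix(rnorm(3000 * 3), 3000, 3) %*% chol(C1),
             matrix(rnorm(3000 * 3), 3000, 3) %*% chol(C2))
  m <- cbind(rep(c(1, 0), each = 3000), rep(c(0, 1), each = 3000))
  rn <- recalc_networks(x, m)
  seg_cov <- crossprod(x[1:3000, ]) / 3000      # second moment, zero-mean model
  expect_equal(rn$cov[, , 1], seg_cov, tolerance = 1e-10)
  expect_equal(rn$power[1, ], sqrt(diag(seg_cov)), tolerance = 1e-10)
  expect_equal(rn$fc[, , 1], cov2cor(seg_cov), tolerance = 1e-10)
  # J = 1, constant mixing: the global second-moment matrix
  rn1 <- recalc_networks(x, matrix(1, 6000, 1))
  expect_equal(rn1$cov[, , 1], crossprod(x) / 6000, tolerance = 1e-10)
  expect_error(recalc_networks(x, cbind(m[, 1], m[, 1])), "rank")
})

test_that("epoching follows the sample-grid arithmetic and drops bad trials", {
  tc <- matrix(seq_len(1000 * 2), 1000, 2)
  ev <- data.frame(onset_sample = c(100, 500, 990),
                   condition = c("a", "a", "b"))
  ep <- epoch_timecourse(tc, ev, rate = 250, window = c(-0.5, 2))
  # only the onset at 500 fits (-125 ... +500 inclusive = 626 samples)
  expect_equal(dim(ep$data), c(1L, 626L, 2L))
  expect_equal(ep$n_dropped, 2L)
  expect_equal(ep$time[1], -0.5)
  expect_equal(ep$time[626], 2)
  expect_true(all(diff(ep$time) > 0))
  expect_equal(ep$data[1, , 1], tc[375:1000, 1])
  expect_error(epoch_timecourse(tc, data.frame(onset_sample = 1,
                                               condition = "a"), 250),
               "no valid trials")
})

test_that("evoked GLM finds forced responses and stays quiet on nulls", {
  set.seed(12)
  rate <- 100
  n_tr <- 30L
  mk_epochs <- function(effect) {
    # trials x time x modes around zero; "effect" adds a bump to mode 2
    # between 0.1 and 0.5 s
    tm <- seq(-0.5, 2, by = 1 / rate)
    d <- array(rnorm(n_tr * length(tm) * 3, sd = 0.3),
               c(n_tr, length(tm), 3))
    bump <- which(tm > 0.1 & tm < 0.5)
    d[, bump, 2] <- d[, bump, 2] + effect
    structure(list(data = d, time = tm,
                   condition = rep(c("stim", "ctl"), length.out = n_tr),
                   n_dropped = 0L), class = "epoch_set")
  }
  eps <- lapply(1:6, function(s) mk_epochs(effect = 1))
  res <- evoked_glm(eps, contrasts = list(mean = c(ctl = 0.5, stim = 0.5)),
                    n_perm = 300L, seed = 13L)$mean
  tm <- res$time
  bump <- which(tm > 0.15 & tm < 0.45)
  expect_true(all(res$sig[bump, 2]))
  expect_lt(mean(res$sig[, c(1, 3)]), 0.05)
  # all-zero epochs: no crash, nothing significant
  zeps <- lapply(1:4, function(s) {
    e <- mk_epochs(0); e$data[] <- 0; e
  })
  rz <- evoked_glm(zeps, contrasts = list(mean = c(ctl = .5, stim = .5)),
                   n_perm = 100L, seed = 14L)$mean
  expect_false(any(rz$sig))
  expect_error(evoked_glm(eps, contrasts = list(bad = c(nothere = 1)),
                          n_perm = 100L), "absent condition")
  expect_error(evoked_glm(eps[1], contrasts = list(mean = c(ctl = .5,
                                                            stim = .5))),
               "2 sessions")
})

test_that("coupling_change flags induced coupling and matches sessions", {
  set.seed(15)
  S <- 8L
  rest <- list(alpha = lapply(1:S, function(s) random_simplex(400, 2)),
               beta = lapply(1:S, function(s) random_simplex(400, 2)))
  # task: beta follows alpha -> coupling increases
  task <- list(alpha = lapply(1:S, function(s) random_simplex(400, 2)))
  task$beta <- lapply(task$alpha, function(a)
    softmax_mix(log(a + 1e-6) + matrix(rnorm(length(a), sd = 0.5),
                                       nrow(a), ncol(a))))
  res <- coupling_change(rest, task, n_perm = 500L, seed = 16L)
  expect_true(any(res$sig))
  expect_gt(res$stat[1, 1], 0)
  # identical conditions: nothing significant at this seed
  res0 <- coupling_change(rest, rest, n_perm = 500L, seed = 17L)
  expect_false(any(res0$sig))
  expect_error(coupling_change(rest,
                               list(alpha = task$alpha[1:3],
                                    beta = task$beta[1:3])),
               "do not match")
})

test_that("permutation p-values are calibrated under the null", {
  # repeated null coupling tests: the familywise false-positive rate stays
  # near the nominal 5%
  set.seed(18)
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    alphas <- lapply(1:6, function(s) random_simplex(150, 2))
    betas <- lapply(1:6, function(s) random_simplex(150, 2))
    res <- coupling_matrix(alphas, betas, n_perm = 200L, seed = 100L + r)
    hits <- hits + any(res$sig)
  }
  fpr <- hits / n_rep
  expect_gt(fpr, 0.005)
  expect_lt(fpr, 0.12)
})
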