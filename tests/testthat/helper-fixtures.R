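# Shared fixtures: small valid mode sets and random correlation matrices.

random_correlation <- function(Nc, rank = Nc, scale = 1) {
  A <- matrix(rnorm(Nc * rank), Nc, rank)
  M <- scale * tcrossprod(A) + diag(Nc)
  d <- 1 / sqrt(diag(M))
  M * tcrossprod(d)
}

tiny_power_modes <- function(J1 = 2L, Nc = 3L, seed = 1L) {
  set.seed(seed)
  power_mode_set(matrix(exp(rnorm(J1 * Nc, sd = 0.3)), J1, Nc))
}

tiny_fc_modes <- function(J2 = 2L, Nc = 3L, seed = 1L) {
  set.seed(seed)
  R <- array(0, c(Nc, Nc, J2))
  for (j in seq_len(J2)) R[, , j] <- random_correlation(Nc)
  fc_mode_set(R)
}

random_simplex <- function(Tn, J) {
  w <- matrix(rexp(Tn * J), Tn, J)
  w / rowSums(w)
}

# a minimal trained-model shell around freshly initialised parameters, for
# tests that exercise inference-side code without a full training run
fresh_model <- function(type = "multi", Nc = 3L, J1 = 2L, J2 = 2L,
                        hidden = 4L, seed = 1L, Tn = 50L) {
  set.seed(seed)
  cfg <- training_config(sequence_length = 10L, hidden_dim = hidden,
                         J1 = J1, J2 = J2, n_starts = 1L, seed = seed)
  seqs <- lapply(1:3, function(i) matrix(rnorm(Tn * Nc), Tn, Nc))
  params <- mdynemo:::init_params(type, seqs, cfg)
  m <- structure(list(type = type, params = params, config = cfg, Nc = Nc,
                      J1 = J1, J2 = if (type == "multi") J2 else NA_integer_,
                      pca = NULL),
                 class = "mdynemo_model")
  m$modes <- mdynemo:::model_modes(m)
  m
}
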