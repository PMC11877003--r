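# Ground-truth simulator: hidden-Markov state sequences driving the power
# and FC parts of the covariance, either independently (multi-dynamic) or
# jointly (shared dynamics). Mixing is hard one-hot (HMM-style), so the
# state sequences double as the ground-truth mode time courses.

#' Simulation configuration
#'
#' @param Nc channels.
#' @param n_states_power,n_states_fc number of hidden states per chain.
#' @param stay_prob diagonal of the transition matrix (remainder uniform over
#'   the other states); the implied mean state lifetime is
#'   `1 / (1 - stay_prob)` samples.
#' @param T_session samples per session.
#' @param n_sessions number of sessions.
#' @param shared_dynamics if `TRUE` one chain drives both power and FC.
#' @param sep_power,sep_fc mode-separation scales: 0 makes all modes of that
#'   part identical, larger values make them more distinct.
#' @param sampling_rate nominal sampling rate attached to the sessions (Hz).
#' @param seed integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(Nc = 20L, n_states_power = 3L, n_states_fc = 3L,
                       stay_prob = 0.98, T_session = 12800L, n_sessions = 4L,
                       shared_dynamics = FALSE, sep_power = 0.4,
                       sep_fc = 0.6, sampling_rate = 250, seed = 1L) {
  stopifnot(stay_prob > 0, stay_prob < 1, Nc >= 1L, n_states_power >= 1L,
            n_states_fc >= 1L, T_session >= 1L, n_sessions >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

#' Sample a hidden Markov state sequence
#'
#' Uniform initial state; transition matrix with `stay_prob` on the diagonal
#' and the remaining mass spread uniformly over the other states, so state
#' lifetimes are geometric with mean `1 / (1 - stay_prob)`.
#'
#' @param n_states number of states.
#' @param stay_prob self-transition probability.
#' @param T_len sequence length.
#' @param seed optional seed (left untouched when `NULL`).
#' @return Integer vector of states in `1..n_states`.
#' @export
sample_markov_chain <- function(n_states, stay_prob, T_len, seed = NULL) {
  stopifnot(n_states >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (n_states == 1L) return(rep(1L, T_len))
  s <- integer(T_len)
  s[1] <- sample.int(n_states, 1L)
  u <- runif(T_len)
  jump <- sample.int(n_states - 1L, T_len, replace = TRUE)
  for (t in 2:T_len) {
    if (u[t] < stay_prob) s[t] <- s[t - 1]
    else {
      k <- jump[t]
      s[t] <- if (k >= s[t - 1]) k + 1L else k
    }
  }
  s
}

#' Draw random generating mode sets
#'
#' Power mode diagonals are log-normal, `exp(sep_power * z)` with standard
#' normal `z` per channel, so `sep_power = 0` collapses all modes to ones.
#' FC modes are built from random low-rank factors,
#' `R_j = corr(sep_fc * A_j A_j' + I)`, so `sep_fc = 0` gives the identity.
#'
#' @param Nc channels.
#' @param n_power,n_fc mode counts.
#' @param sep_power,sep_fc separation scales (>= 0).
#' @param rank rank of the FC factors.
#' @param seed optional seed.
#' @return List with `power` ([power_mode_set]) and `fc` ([fc_mode_set]).
#' @export
make_random_modes <- function(Nc, n_power, n_fc, sep_power = 0.4,
                              sep_fc = 0.6, rank = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sep_power >= 0, sep_fc >= 0)
  e <- exp(sep_power * matrix(rnorm(n_power * Nc), n_power, Nc))
  R <- array(0, c(Nc, Nc, n_fc))
  for (j in seq_len(n_fc)) {
    A <- matrix(rnorm(Nc * rank), Nc, rank)
    M <- sep_fc * tcrossprod(A) + diag(Nc)
    d <- 1 / sqrt(diag(M))
    R[, , j] <- M * tcrossprod(d)
  }
  list(power = power_mode_set(e), fc = fc_mode_set(R))
}

#' Simulate sessions from the hidden-Markov ground truth
#'
#' Each sample is drawn as `x_t ~ N(0, G_t F_t G_t)` where `G_t` and `F_t`
#' are selected (one-hot) by the power and FC state sequences. With
#' `shared_dynamics = TRUE` a single chain drives both.
#'
#' @param config a [sim_config].
#' @param modes optional list with `power` and `fc` mode sets; drawn with
#'   [make_random_modes] when `NULL`.
#' @return List of class `ground_truth_sim` with `sessions` (list of
#'   [session_data]), `truth` (per-session integer state sequences
#'   `power_states`, `fc_states`), `modes`, and `state_covs` (the
#'   `Nc x Nc` generating covariance for every power x FC state pair,
#'   array `Nc x Nc x n_power x n_fc`).
#' @export
simulate_sessions <- function(config, modes = NULL) {
  set.seed(config$seed)
  if (is.null(modes))
    modes <- make_random_modes(config$Nc, config$n_states_power,
                               config$n_states_fc, config$sep_power,
                               config$sep_fc)
  J1 <- modes$power$J1; J2 <- modes$fc$J2; Nc <- config$Nc
  # Cholesky factor for every (power state, fc state) covariance
  chols <- vector("list", J1 * J2)
  state_covs <- array(0, c(Nc, Nc, J1, J2))
  for (a in seq_len(J1)) for (b in seq_len(J2)) {
    g <- modes$power$e[a, ]
    C <- modes$fc$R[, , b] * tcrossprod(g)
    state_covs[, , a, b] <- C
    chols[[(a - 1) * J2 + b]] <- t(chol(C))
  }
  sessions <- list(); power_states <- list(); fc_states <- list()
  for (s in seq_len(config$n_sessions)) {
    sp <- sample_markov_chain(config$n_states_power, config$stay_prob,
                              config$T_session)
    sf <- if (config$shared_dynamics) {
      if (config$n_states_fc != config$n_states_power)
        stop("shared dynamics requires equal state counts")
      sp
    } else sample_markov_chain(config$n_states_fc, config$stay_prob,
                               config$T_session)
    X <- matrix(0, config$T_session, Nc)
    key <- (sp - 1L) * J2 + sf
    for (k in unique(key)) {
      idx <- which(key == k)
      Z <- matrix(rnorm(length(idx) * Nc), length(idx), Nc)
      X[idx, ] <- Z %*% t(chols[[k]])
    }
    sessions[[s]] <- session_data(t(X), sampling_rate = config$sampling_rate,
                                  id = paste0("sim", s))
    power_states[[s]] <- sp
    fc_states[[s]] <- sf
  }
  structure(list(sessions = sessions,
                 truth = list(power_states = power_states,
                              fc_states = fc_states),
                 modes = modes, state_covs = state_covs, config = config),
            class = "ground_truth_sim")
}

#' One-hot indicator matrix of a state sequence
#'
#' @param states integer vector in `1..n_states`.
#' @param n_states number of states (defaults to `max(states)`).
#' @return `T x n_states` 0/1 matrix.
#' @export
one_hot <- function(states, n_states = max(states)) {
  M <- matrix(0, length(states), n_states)
  M[cbind(seq_along(states), states)] <- 1
  M
}

#' Ground-truth covariance path for one simulated session
#'
#' @param sim a `ground_truth_sim`.
#' @param session session index.
#' @param idx time indices (defaults to the full session).
#' @return `Nc x Nc x length(idx)` array.
#' @export
truth_covariance <- function(sim, session = 1L, idx = NULL) {
  sp <- sim$truth$power_states[[session]]
  sf <- sim$truth$fc_states[[session]]
  if (is.null(idx)) idx <- seq_along(sp)
  C <- array(0, c(dim(sim$state_covs)[1], dim(sim$state_covs)[2], length(idx)))
  for (i in seq_along(idx))
    C[, , i] <- sim$state_covs[, , sp[idx[i]], sf[idx[i]]]
  C
}

#' Simulate a task session with state forcing at event onsets
#'
#' Generates one resting session, then at each event onset forces the
#' designated chain into the designated state for `window` samples with the
#' given probability (per event). With `prob = 0` the output distribution is
#' identical to the resting simulation, giving a null condition for
#' type-I-error testing.
#'
#' @param config a [sim_config] (`n_sessions` is ignored; one session is
#'   produced).
#' @param onsets event onset samples (1-based); forced windows must not
#'   overlap.
#' @param window forced-window length in samples.
#' @param chain `"power"` or `"fc"`.
#' @param state state forced during the window; may be a named vector mapping
#'   condition label to state.
#' @param prob per-event forcing probability.
#' @param condition condition label(s), recycled over events.
#' @param modes optional generating mode sets.
#' @return List with `session` ([session_data]), `truth` (state sequences
#'   after forcing), `modes`, and `events` (data frame `onset_sample`,
#'   `condition`).
#' @export
simulate_task <- function(config, onsets, window, chain = c("power", "fc"),
                          state = 1L, prob = 1, condition = "stim",
                          modes = NULL) {
  chain <- match.arg(chain)
  stopifnot(window >= 1L, all(onsets >= 1L),
            all(onsets + window - 1L <= config$T_session))
  o <- sort(onsets)
  if (any(diff(o) < window)) stop("overlapping forced windows are not allowed")
  set.seed(config$seed)
  if (is.null(modes))
    modes <- make_random_modes(config$Nc, config$n_states_power,
                               config$n_states_fc, config$sep_power,
                               config$sep_fc)
  condition <- rep_len(condition, length(onsets))
  sp <- sample_markov_chain(config$n_states_power, config$stay_prob,
                            config$T_session)
  sf <- if (config$shared_dynamics) sp
        else sample_markov_chain(config$n_states_fc, config$stay_prob,
                                 config$T_session)
  forced <- runif(length(onsets)) < prob
  for (i in seq_along(onsets)) {
    if (!forced[i]) next
    st <- if (!is.null(names(state))) state[[condition[i]]] else state
    win <- onsets[i]:(onsets[i] + window - 1L)
    if (chain == "power") sp[win] <- st else sf[win] <- st
  }
  J2 <- modes$fc$J2; Nc <- config$Nc
  X <- matrix(0, config$T_session, Nc)
  key <- (sp - 1L) * J2 + sf
  for (k in unique(key)) {
    idx <- which(key == k)
    a <- (k - 1L) %/% J2 + 1L; b <- (k - 1L) %% J2 + 1L
    C <- modes$fc$R[, , b] * tcrossprod(modes$power$e[a, ])
    Z <- matrix(rnorm(length(idx) * Nc), length(idx), Nc)
    X[idx, ] <- Z %*% chol(C)
  }
  list(session = session_data(t(X), sampling_rate = config$sampling_rate,
                              id = "task"),
       truth = list(power_states = sp, fc_states = sf),
       modes = modes,
       events = data.frame(onset_sample = onsets, condition = condition,
                           stringsAsFactors = FALSE))
}
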