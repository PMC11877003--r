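# Umbrella pipeline: simulate -> preprocess -> train (+ single-dynamic
# baseline) -> infer -> sliding window -> post-analysis, with seeded,
# reproducible artefacts.

#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline]. Any element can be overridden by
#' supplying a partial list with the same structure (e.g. parsed from YAML).
#'
#' @param seed global seed; each stage derives its own seed from it.
#' @param out_dir artefact directory.
#' @return Nested configuration list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("mdynemo_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(Nc = 20L, n_states_power = 3L, n_states_fc = 3L,
                    stay_prob = 0.98, T_session = 12800L, n_sessions = 4L,
                    shared_dynamics = FALSE, sep_power = 0.4, sep_fc = 0.6),
    preprocess = list(enabled = FALSE),
    train = list(sequence_length = 200L, batch_size = 32L, n_epochs = 12L,
                 learning_rate = 5e-3, kl_anneal_epochs = 6L, n_starts = 1L,
                 hidden_dim = 32L, do_pca = FALSE),
    single_dynamic = list(enabled = FALSE),
    sliding_window = list(window = 500L, step = 10L)
  ), class = "run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", nm)
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

stage_seed <- function(seed, k) (seed * 97L + 1009L * k) %% 2147483647L

#' Run the end-to-end pipeline on simulated data
#'
#' Simulates multi-dynamic (or shared-dynamics) sessions, optionally
#' preprocesses them, trains the multi-dynamic model (and the single-dynamic
#' baseline if enabled), infers mixing coefficients, runs the
#' sliding-window baseline and scores everything against the ground truth.
#' All artefacts (config, seeds, state sequences, recovery summary) are
#' written to the output directory.
#'
#' @param config a [run_config] or a partial override list.
#' @param verbose print stage progress.
#' @return Invisible list with the trained model, the simulation, recovery
#'   scores and the artefact directory.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  if (!inherits(config, "run_config"))
    config <- merge_config(run_config(), config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[", ..., "]")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("simulate")
  sc <- do.call(sim_config, c(config$simulate,
                              list(seed = stage_seed(config$seed, 1L))))
  sim <- stage("simulate", simulate_sessions(sc))
  write_sessions(sim$sessions, file.path(config$out_dir, "sessions"))

  xs <- lapply(sim$sessions, session_matrix)
  if (isTRUE(config$preprocess$enabled)) {
    say("preprocess")
    pc <- do.call(preprocess_config,
                  config$preprocess[setdiff(names(config$preprocess), "enabled")])
    xs <- stage("preprocess", preprocess_sessions(xs, pc))$sessions
  }

  say("train")
  tc <- do.call(training_config,
                c(config$train[setdiff(names(config$train), "enabled")],
                  list(J1 = sc$n_states_power, J2 = sc$n_states_fc,
                       seed = stage_seed(config$seed, 2L))))
  model <- stage("train", train_mdynemo(xs, tc))
  saveRDS(model, file.path(config$out_dir, "model.rds"))

  say("infer")
  mixes <- stage("infer", lapply(xs, infer_mixing, model = model))
  rec <- stage("score", score_recovery(model, mixes, sim))

  say("sliding-window")
  sw <- stage("sliding-window", sliding_window_recovery(
    xs[[1]], sim$truth$power_states[[1]], sim$truth$fc_states[[1]],
    window = config$sliding_window$window, step = config$sliding_window$step,
    seed = stage_seed(config$seed, 3L)))

  single <- NULL
  if (isTRUE(config$single_dynamic$enabled)) {
    say("single-dynamic")
    tcs <- tc; tcs$J1 <- sc$n_states_power
    single <- stage("single-dynamic", train_single_dynamic(xs, tcs))
    saveRDS(single, file.path(config$out_dir, "model_single.rds"))
  }

  summary <- list(alpha_recovery_r = rec$alpha_r, beta_recovery_r = rec$beta_r,
                  power_cosine = rec$power_cosine, fc_cosine = rec$fc_cosine,
                  sliding_window_power_accuracy = sw$power_accuracy,
                  sliding_window_fc_accuracy = sw$fc_accuracy)
  meta <- list(config = unclass(config), seed = config$seed,
               config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("mdynemo")),
               summary = summary)
  jsonlite::write_json(meta, file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", config$out_dir)
  invisible(list(model = model, single = single, sim = sim,
                 recovery = rec, sliding_window = sw,
                 out_dir = config$out_dir))
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small rolling hash; enough to stamp artefacts with their configuration
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Score inferred mixing and modes against simulation ground truth
#'
#' Matches inferred modes to generating modes (cosine on mode maps), then
#' reports the mean Pearson correlation between each matched inferred time
#' course and the ground-truth one-hot state indicator, plus matched mode
#' cosines and the cross-dynamic coupling of matched pairs.
#'
#' @param model trained multi-dynamic model.
#' @param mixes list of [mixing_coefficients], one per session.
#' @param sim the `ground_truth_sim` the sessions came from.
#' @return List with `alpha_r`, `beta_r` (mean matched time-course
#'   correlations), `power_cosine`, `fc_cosine` (mean matched mode cosines),
#'   `cross_abs_r` (mean |corr(alpha_j, beta_j)| over matched pairs) and the
#'   per-mode details.
#' @export
score_recovery <- function(model, mixes, sim) {
  # match on time courses: average correlation between inferred and true
  # indicators across sessions decides the mode <-> state pairing
  S <- length(mixes)
  J1 <- model$J1; J2 <- model$J2
  K1 <- sim$config$n_states_power; K2 <- sim$config$n_states_fc
  ra <- matrix(0, J1, K1); rb <- matrix(0, J2, K2)
  for (s in seq_len(S)) {
    ra <- ra + cor(mixes[[s]]$alpha, one_hot(sim$truth$power_states[[s]], K1)) / S
    rb <- rb + cor(mixes[[s]]$beta, one_hot(sim$truth$fc_states[[s]], K2)) / S
  }
  pa <- solve_assignment(ra)
  pb <- solve_assignment(rb)
  alpha_r <- mean(ra[cbind(seq_len(J1), pa)], na.rm = TRUE)
  beta_r <- mean(rb[cbind(seq_len(J2), pb)], na.rm = TRUE)
  # matched mode cosines (uncentred: modes live on comparable positive scales)
  pw <- cosine_matrix(model$modes$power$e, sim$modes$power$e, centre = FALSE)
  power_cosine <- mean(pw[cbind(which(!is.na(pa)), pa[!is.na(pa)])])
  vecR <- function(R) t(apply(R, 3L, function(M) M[upper.tri(M)]))
  fcm <- cosine_matrix(vecR(model$modes$fc$R), vecR(sim$modes$fc$R),
                       centre = FALSE)
  fc_cosine <- mean(fcm[cbind(which(!is.na(pb)), pb[!is.na(pb)])])
  # cross-dynamic coupling of matched pairs (power mode j vs fc mode j in
  # ground-truth state order)
  cross <- c()
  npair <- min(K1, K2)
  for (s in seq_len(S)) {
    a <- mixes[[s]]$alpha[, order(pa)[seq_len(npair)], drop = FALSE]
    b <- mixes[[s]]$beta[, order(pb)[seq_len(npair)], drop = FALSE]
    cross <- c(cross, abs(diag(cor(a, b))))
  }
  list(alpha_r = alpha_r, beta_r = beta_r, power_cosine = power_cosine,
       fc_cosine = fc_cosine, cross_abs_r = mean(cross),
       alpha_r_matrix = ra, beta_r_matrix = rb, perm_power = pa,
       perm_fc = pb)
}
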