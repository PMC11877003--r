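#' @useDynLib mdynemo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor cov var quantile setNames kmeans cov2cor
#' @importFrom utils head tail read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Domain types.
#
# The observation model factorises the instantaneous data covariance as
#   C_t = G_t F_t G_t
# where G_t is diagonal with the per-channel standard deviations ("power")
# and F_t is a unit-diagonal positive-definite correlation matrix ("FC").
# Each part is a time-varying convex mixture of a small basis of modes:
#   G_t = sum_j alpha_jt E_j,   F_t = sum_j beta_jt R_j.
# ---------------------------------------------------------------------------

#' Construct a set of power modes
#'
#' A power mode is a diagonal matrix `E_j` of strictly positive per-channel
#' standard deviations. The set is stored compactly as a `J1 x Nc` matrix of
#' diagonals.
#'
#' @param e numeric `J1 x Nc` matrix of strictly positive mode diagonals
#'   (rows are modes).
#' @return An object of class `power_mode_set` with fields `e`, `J1`, `Nc`.
#' @export
power_mode_set <- function(e) {
  e <- as.matrix(e)
  if (!all(is.finite(e))) stop("power mode diagonals must be finite")
  if (any(e <= 0)) stop("power mode diagonals must be strictly positive")
  structure(list(e = e, J1 = nrow(e), Nc = ncol(e)), class = "power_mode_set")
}

#' Construct a set of FC (correlation) modes
#'
#' An FC mode is a symmetric positive-definite correlation matrix `R_j`
#' (unit diagonal).
#'
#' @param R array `Nc x Nc x J2` (or a list of matrices) of correlation modes.
#' @param tol positive-definiteness / symmetry tolerance.
#' @return An object of class `fc_mode_set` with fields `R` (array), `J2`, `Nc`.
#' @export
fc_mode_set <- function(R, tol = 1e-6) {
  if (is.list(R)) R <- array(unlist(R), dim = c(nrow(R[[1]]), ncol(R[[1]]), length(R)))
  if (is.matrix(R)) R <- array(R, dim = c(nrow(R), ncol(R), 1L))
  stopifnot(length(dim(R)) == 3L, dim(R)[1] == dim(R)[2])
  for (j in seq_len(dim(R)[3])) {
    Rj <- R[, , j]
    if (max(abs(Rj - t(Rj))) > tol) stop("FC mode ", j, " is not symmetric")
    if (max(abs(diag(Rj) - 1)) > tol) stop("FC mode ", j, " does not have unit diagonal")
    if (!is_pd(Rj, tol = tol)) stop("FC mode ", j, " is not positive definite")
  }
  structure(list(R = R, J2 = dim(R)[3], Nc = dim(R)[1]), class = "fc_mode_set")
}

#' Mixing coefficients for the two dynamics
#'
#' Holds the simplex weight time courses `alpha` (power) and `beta` (FC)
#' together with the latent logits they are the row-wise softmax of.
#'
#' @param theta1,theta2 `T x J1` / `T x J2` latent logit matrices.
#' @return Object of class `mixing_coefficients` with fields `alpha`, `beta`,
#'   `theta1`, `theta2`.
#' @export
mixing_coefficients <- function(theta1, theta2) {
  structure(list(alpha = softmax_mix(theta1), beta = softmax_mix(theta2),
                 theta1 = theta1, theta2 = theta2),
            class = "mixing_coefficients")
}

#' Orthonormal PCA projection
#'
#' @param W `Nc x Nc` matrix whose rows are eigenvectors of the data
#'   covariance (full rank).
#' @param tol orthonormality tolerance.
#' @return Object of class `pca_projection`.
#' @export
pca_projection <- function(W, tol = 1e-8) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("PCA projection must be square (full rank)")
  if (max(abs(crossprod(W) - diag(nrow(W)))) > tol)
    stop("PCA projection rows are not orthonormal within tolerance ", tol)
  structure(list(W = W, Nc = nrow(W)), class = "pca_projection")
}

# Cholesky is the canonical positive-definiteness test.
is_pd <- function(M, tol = 1e-6) {
  ok <- tryCatch({
    chol(M + diag(0, nrow(M)))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(FALSE)
  min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > -tol
}

# ---------------------------------------------------------------------------
# Operations
# ---------------------------------------------------------------------------

#' Row-wise softmax
#'
#' Maps a `T x J` matrix of logits to simplex weights row by row, with the
#' usual max-subtraction for numerical stability (the output is invariant
#' under adding a constant to a row).
#'
#' @param logits numeric matrix (rows are time points).
#' @return Matrix of the same shape with nonnegative rows summing to one.
#' @export
softmax_mix <- function(logits) {
  logits <- as.matrix(logits)
  bad <- which(!apply(logits, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite logits at row(s): ", paste(head(bad, 5L), collapse = ", "))
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Build the time-varying standard-deviation matrices G_t
#'
#' `G_t = sum_j alpha_jt E_j`: the diagonal of `G_t` is the alpha-weighted
#' average of the mode diagonals.
#'
#' @param alpha `T x J1` simplex weights.
#' @param modes a [power_mode_set].
#' @return `T x Nc` matrix of G_t diagonals.
#' @export
build_G <- function(alpha, modes) {
  alpha <- as.matrix(alpha)
  if (ncol(alpha) != modes$J1)
    stop("alpha has ", ncol(alpha), " columns but mode set has J1 = ", modes$J1)
  alpha %*% modes$e
}

#' Build the time-varying correlation matrices F_t
#'
#' `F_t = sum_j beta_jt R_j`. A convex combination of correlation matrices is
#' itself a correlation matrix (unit diagonal, positive definite).
#'
#' @param beta `T x J2` simplex weights.
#' @param modes an [fc_mode_set].
#' @return `Nc x Nc x T` array of correlation matrices.
#' @export
build_F <- function(beta, modes) {
  beta <- as.matrix(beta)
  if (ncol(beta) != modes$J2)
    stop("beta has ", ncol(beta), " columns but mode set has J2 = ", modes$J2)
  Nc <- modes$Nc
  Rflat <- matrix(modes$R, nrow = Nc * Nc)      # (Nc^2) x J2
  array(Rflat %*% t(beta), dim = c(Nc, Nc, nrow(beta)))
}

#' Assemble the time-varying covariance C_t = G_t F_t G_t
#'
#' @param G `T x Nc` matrix of G_t diagonals (strictly positive).
#' @param F `Nc x Nc x T` array of correlation matrices.
#' @return Object of class `tv_covariance` with fields `C` (array
#'   `Nc x Nc x T`), `G`, `F`.
#' @export
build_covariance <- function(G, F) {
  G <- as.matrix(G)
  if (any(G <= 0)) stop("G diagonals must be strictly positive")
  Tn <- nrow(G)
  stopifnot(dim(F)[3] == Tn, dim(F)[1] == ncol(G))
  C <- F
  for (t in seq_len(Tn)) C[, , t] <- C[, , t] * tcrossprod(G[t, ])
  structure(list(C = C, G = G, F = F), class = "tv_covariance")
}

#' Project mode matrices through an orthonormal PCA rotation
#'
#' Returns `W M W'` for each mode matrix `M` (a similarity transform, so
#' eigenvalues are preserved). The covariance built from projected modes
#' equals `W C_t W'`.
#'
#' @param W a [pca_projection].
#' @param modes a [power_mode_set], [fc_mode_set] or a single matrix.
#' @return List of projected matrices (or a single matrix).
#' @export
project_modes <- function(W, modes) {
  P <- W$W
  proj <- function(M) P %*% M %*% t(P)
  if (inherits(modes, "power_mode_set"))
    return(lapply(seq_len(modes$J1), function(j) proj(diag(modes$e[j, ], modes$Nc))))
  if (inherits(modes, "fc_mode_set"))
    return(lapply(seq_len(modes$J2), function(j) proj(modes$R[, , j])))
  proj(as.matrix(modes))
}

#' Zero-mean Gaussian log-likelihood under a time-varying covariance
#'
#' `sum_t log N(x_t | 0, C_t)`, evaluated by Cholesky factorisation of each
#' `C_t`.
#'
#' @param x `T x Nc` data matrix.
#' @param C a `tv_covariance` (from [build_covariance]) or an `Nc x Nc x T`
#'   array.
#' @param per_sample if `TRUE`, return the length-`T` vector of per-sample
#'   log densities instead of their sum.
#' @return Scalar log-likelihood (or vector if `per_sample`).
#' @export
log_likelihood <- function(x, C, per_sample = FALSE) {
  x <- as.matrix(x)
  Carr <- if (inherits(C, "tv_covariance")) C$C else C
  if (is.matrix(Carr)) Carr <- array(Carr, dim = c(nrow(Carr), ncol(Carr), 1L))
  if (dim(Carr)[3] == 1L && nrow(x) > 1L)
    Carr <- array(Carr, dim = c(dim(Carr)[1], dim(Carr)[2], nrow(x)))
  ll <- .loglik_tv_cpp(x, Carr)
  if (per_sample) return(ll)
  sum(ll)
}

#' Constrain raw parameters to a valid power mode set
#'
#' The diagonals are `softplus(raw)` entrywise: a smooth, total map from
#' unconstrained reals to strictly positive values.
#'
#' @param raw `J1 x Nc` matrix of unconstrained values.
#' @return A [power_mode_set] whose `raw_params` field stores `raw`.
#' @export
constrain_power <- function(raw) {
  raw <- as.matrix(raw)
  if (!all(is.finite(raw))) stop("raw power parameters must be finite")
  ms <- power_mode_set(softplus(raw))
  ms$raw_params <- raw
  ms
}

#' Constrain raw Cholesky-like factors to a valid FC mode set
#'
#' Each mode is parameterised by an unconstrained lower-triangular factor
#' `L_j`: with `M = L_j L_j' + jitter * I` and `D = diag(M)`,
#' `R_j = D^{-1/2} M D^{-1/2}` has unit diagonal and is positive definite for
#' any raw input.
#'
#' @param Lraw array `Nc x Nc x J2` of raw factors (upper triangle ignored).
#' @param jitter diagonal jitter added before normalisation.
#' @return An [fc_mode_set] with a `raw_params` field.
#' @export
constrain_fc <- function(Lraw, jitter = 1e-6) {
  if (is.matrix(Lraw)) Lraw <- array(Lraw, dim = c(nrow(Lraw), ncol(Lraw), 1L))
  Nc <- dim(Lraw)[1]; J2 <- dim(Lraw)[3]
  R <- array(0, dim = c(Nc, Nc, J2))
  for (j in seq_len(J2)) {
    L <- Lraw[, , j]
    L[upper.tri(L)] <- 0
    M <- tcrossprod(L) + jitter * diag(Nc)
    d <- 1 / sqrt(diag(M))
    R[, , j] <- M * tcrossprod(d)
  }
  ms <- fc_mode_set(R)
  ms$raw_params <- Lraw
  ms
}

# Backward pass of constrain_fc for one mode: given dR (gradient w.r.t. the
# correlation matrix, all entries treated independently), return dL.
constrain_fc_grad <- function(L, dR, jitter = 1e-6) {
  L[upper.tri(L)] <- 0
  M <- tcrossprod(L) + jitter * diag(nrow(L))
  d <- 1 / sqrt(diag(M))
  R <- M * tcrossprod(d)
  dRs <- (dR + t(dR)) / 2
  dM <- dRs * tcrossprod(d)
  diag(dM) <- -rowSums((dRs * R) * (1 - diag(nrow(L)))) / diag(M)
  dL <- 2 * dM %*% L
  dL[upper.tri(dL)] <- 0
  dL
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))
# inverse of softplus, for data-driven initialisation
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-10))))
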