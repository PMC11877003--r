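# Optimal assignment by exhaustive permutation search. Mode/state counts in
# this package are small (<= 8), where enumeration is exact and instant, and
# coincides with the Hungarian-algorithm optimum.

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Solve a (small) linear assignment problem
#'
#' Finds the permutation `p` maximising `sum_i score[i, p[i]]` by exhaustive
#' search. With unequal dimensions the smaller side is matched injectively
#' into the larger.
#'
#' @param score numeric score matrix (rows assigned to columns).
#' @return Integer vector `p` of length `nrow(score)` (`NA`-free when
#'   `nrow <= ncol`).
#' @export
solve_assignment <- function(score) {
  score <- as.matrix(score)
  n <- nrow(score); m <- ncol(score)
  if (max(n, m) > 8L) stop("assignment by enumeration supports at most 8 items")
  transposed <- FALSE
  if (n > m) { score <- t(score); transposed <- TRUE; tmp <- n; n <- m; m <- tmp }
  perms <- all_permutations(m)
  best <- -Inf; bestp <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, seq_len(n)]
    val <- sum(score[cbind(seq_len(n), p)])
    if (val > best) { best <- val; bestp <- p }
  }
  bestp <- unname(bestp)
  if (!transposed) return(bestp)
  # invert the injection: column c of the original got row bestp[c]
  out <- rep(NA_integer_, m)
  out[bestp] <- seq_len(n)
  out
}

#' Match predicted labels to reference labels
#'
#' Builds the confusion matrix and finds the label permutation maximising
#' agreement, returning the relabelled prediction and its accuracy.
#'
#' @param pred,ref integer label vectors of equal length.
#' @param K number of labels (defaults to the observed maximum).
#' @return List with `pred` (relabelled), `perm` (new label of each predicted
#'   label), `accuracy`.
#' @export
match_labels <- function(pred, ref, K = max(pred, ref)) {
  conf <- matrix(0, K, K)
  for (i in seq_along(pred)) conf[pred[i], ref[i]] <- conf[pred[i], ref[i]] + 1
  perm <- solve_assignment(conf)
  relab <- perm[pred]
  list(pred = relab, perm = perm, accuracy = mean(relab == ref))
}
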