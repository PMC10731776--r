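#' Full-kernel status normalization for network fusion
#'
#' Rescales a nonnegative similarity matrix into a row-stochastic status
#' matrix that reserves half of each row's mass for the node itself:
#' `P(i,j) = W(i,j) / (2 * sum_k!=i W(i,k))` off the diagonal and
#' `P(i,i) = 1/2`. This keeps the diffusion numerically stable regardless
#' of each node's total similarity mass.
#'
#' @param W Symmetric nonnegative labeled matrix.
#' @return Row-stochastic matrix of the same shape.
#' @export
snf_normalize <- function(W) {
  W <- as.matrix(W)
  n <- nrow(W)
  off <- W
  diag(off) <- 0
  rs <- rowSums(off)
  zero <- rs == 0
  if (any(zero)) {
    warn("rows with zero off-diagonal mass: using uniform fallback")
    off[zero, ] <- 1
    diag(off) <- 0
    rs[zero] <- n - 1
  }
  P <- off / (2 * rs)
  diag(P) <- 0.5
  dimnames(P) <- dimnames(W)
  P
}

#' K-nearest-neighbor local affinity kernel
#'
#' Keeps only each row's `K` largest off-diagonal similarities (ties at the
#' boundary broken by ascending label order for reproducibility) and
#' renormalizes them to sum to 1; all other entries, including the
#' diagonal, are 0. This sparse kernel carries only locally trustworthy
#' similarity during diffusion.
#'
#' @param W Symmetric nonnegative labeled matrix.
#' @param K Neighborhood size, `1 <= K < n`.
#' @return Row-stochastic sparse kernel matrix.
#' @export
snf_local_affinity <- function(W, K) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (K < 1 || K >= n) abort("K must satisfy 1 <= K < n")
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    # order by similarity desc, then label asc: deterministic under ties
    nb <- cand[order(-W[i, cand], rownames(W)[cand], method = "radix")][1:K]
    tot <- sum(W[i, nb])
    S[i, nb] <- if (tot > 0) W[i, nb] / tot else 1 / K
  }
  S
}

#' Fuse similarity networks by iterative cross-diffusion
#'
#' Implements similarity network fusion: each view is normalized into a
#' status matrix and a KNN local-affinity kernel; then, repeatedly, each
#' view's status matrix is replaced by its own local kernel applied to the
#' average status of the *other* views (`P_v <- S_v %*% mean(P_-v) %*% t(S_v)`,
#' re-symmetrized and renormalized into a status matrix, which keeps the
#' diffusion mass-conserving), so views exchange information through
#' locally reliable edges. The fused network is the average of the final
#' status matrices,
#' with unit diagonal and off-diagonal entries min-max rescaled to \[0, 1\].
#'
#' When all views are numerically identical (including the single-view
#' case) there is no cross-view information to exchange: consensus already
#' holds, and the fused output is the common input itself (diagonal set to
#' 1, off-diagonal rescaled), which preserves the ranking of its entries
#' exactly.
#'
#' @param views List of `similarity_matrix` objects with identical labels.
#' @param K Neighborhood size for the local kernels.
#' @param t Maximum diffusion iterations; iteration stops early when the
#'   largest status change falls below `tol`.
#' @param tol Early-stopping threshold on `max |P - P_prev|`.
#' @return A `similarity_matrix` of kind `"fused"`.
#' @export
snf_fuse <- function(views, K, t = 20, tol = 1e-8) {
  if (!length(views)) abort("need at least one view")
  views <- lapply(views, as.matrix)
  labs <- rownames(views[[1]])
  for (v in views) {
    if (!identical(rownames(v), labs)) abort("views have mismatched labels")
  }
  V <- length(views)
  identical_views <- all(vapply(
    views, function(v) max(abs(v - views[[1]])) < 1e-12, TRUE))
  if (identical_views) {
    return(finish_fused(views[[1]], labs))
  }
  P <- lapply(views, snf_normalize)
  S <- lapply(views, snf_local_affinity, K = K)
  for (it in seq_len(t)) {
    Pnew <- vector("list", V)
    for (v in seq_len(V)) {
      others <- Reduce(`+`, P[-v]) / (V - 1)
      Q <- S[[v]] %*% others %*% t(S[[v]])
      Pnew[[v]] <- suppressWarnings(snf_normalize((Q + t(Q)) / 2))
    }
    delta <- max(vapply(seq_len(V), function(v) max(abs(Pnew[[v]] - P[[v]])), 1.0))
    P <- Pnew
    if (delta < tol) break
  }
  finish_fused(Reduce(`+`, P) / V, labs)
}

# symmetrize, unit diagonal, min-max rescale of the off-diagonal
finish_fused <- function(M, labs) {
  M <- (M + t(M)) / 2
  off <- row(M) != col(M)
  rng <- range(M[off])
  M[off] <- if (rng[2] > rng[1]) (M[off] - rng[1]) / (rng[2] - rng[1]) else 0
  diag(M) <- 1
  dimnames(M) <- list(labs, labs)
  similarity_matrix(M, kind = "fused")
}
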