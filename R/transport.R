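#' Entropic 2-Wasserstein distance between two point clouds
#'
#' Treats `P` and `Q` as uniform empirical distributions over their rows and
#' solves the entropy-regularized optimal transport problem with squared
#' Euclidean ground cost by Sinkhorn iteration in the log domain (stable
#' for small `epsilon`). The returned value is the square root of the
#' transported cost `<Gamma, C>` under the converged plan, i.e. an entropic
#' approximation of the 2-Wasserstein distance.
#'
#' @param P,Q Numeric matrices with the same number of rows (points) and
#'   columns (dimensions); vectors are treated as single points.
#' @param epsilon Entropic regularization strength, in squared-distance
#'   units; smaller is closer to the exact distance but needs more
#'   iterations.
#' @param iters Maximum Sinkhorn iterations.
#' @param tol Convergence threshold on the marginal violation.
#' @param return_plan If `TRUE`, also return the transport plan (used by
#'   the autoencoder's gradient).
#' @param warn_nonconv Warn when the marginal constraint has not converged
#'   after `iters` iterations.
#' @return The distance (scalar), or a list `(distance, plan, converged)`
#'   when `return_plan = TRUE`. A warning is raised if the marginals have
#'   not converged after `iters` iterations.
#' @export
sinkhorn_w2 <- function(P, Q, epsilon = 0.01, iters = 500, tol = 1e-7,
                        return_plan = FALSE, warn_nonconv = TRUE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) abort("point clouds must have equal sizes")
  if (ncol(P) != ncol(Q)) abort("point clouds must have equal dimension")
  stopifnot(epsilon > 0, iters >= 1)
  n <- nrow(P)
  C <- outer(rowSums(P ^ 2), rowSums(Q ^ 2), "+") - 2 * tcrossprod(P, Q)
  C[C < 0] <- 0
  loga <- -log(n)
  f <- rep(0, n); g <- rep(0, n)
  converged <- FALSE
  # epsilon scaling: anneal the regularization from a coarse level down to
  # the target, warm-starting the potentials at each level; cuts the
  # iteration count dramatically for small epsilon
  eps0 <- max(mean(C), epsilon)
  levels <- unique(c(eps0 * 0.25 ^ (0:ceiling(log(eps0 / epsilon) / log(4))),
                     epsilon))
  levels <- pmax(levels, epsilon)
  # at least half the iteration budget is reserved for the target level
  warm <- if (length(levels) > 1) {
    max(1L, min(25L, floor(iters / (2L * (length(levels) - 1L)))))
  } else 0L
  used <- 0L
  for (ep in levels) {
    final <- ep <= epsilon * (1 + 1e-12)
    budget <- if (final) iters - used else min(warm, max(0L, iters - used))
    it <- 0L
    while (it < budget) {
      it <- it + 1L; used <- used + 1L
      M <- (-C + outer(f, g, "+")) / ep          # log kernel with potentials
      f <- f + ep * (loga - lse_rows(M))
      M <- (-C + outer(f, g, "+")) / ep
      g <- g + ep * (loga - lse_cols(M))
      if (it %% 5 == 0 || it == budget) {
        M <- (-C + outer(f, g, "+")) / ep
        err <- max(abs(exp(lse_rows(M)) - 1 / n))
        if (err < tol) { if (final) converged <- TRUE; break }
      }
    }
  }
  if (!converged && warn_nonconv) {
    warn("Sinkhorn did not reach marginal tolerance; result is approximate")
  }
  Gam <- exp((-C + outer(f, g, "+")) / epsilon)
  w2 <- sqrt(max(sum(Gam * C), 0))
  if (return_plan) list(distance = w2, plan = Gam, converged = converged) else w2
}

# row/column log-sum-exp with C-speed max extraction
lse_rows <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx + log(rowSums(exp(M - mx)))
}
lse_cols <- function(M) lse_rows(t(M))

#' Exact empirical 2-Wasserstein distance by optimal assignment
#'
#' For two equal-size uniform point clouds the optimal transport plan is a
#' permutation; the distance is the square root of the mean squared
#' Euclidean cost of the minimum-cost assignment (Hungarian algorithm).
#' Serves as the exact reference for [sinkhorn_w2()].
#'
#' @inheritParams sinkhorn_w2
#' @return Scalar distance.
#' @export
exact_w2 <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) abort("point clouds must have equal sizes")
  if (!requireNamespace("clue", quietly = TRUE)) {
    abort("exact_w2 requires the 'clue' package")
  }
  C <- outer(rowSums(P ^ 2), rowSums(Q ^ 2), "+") - 2 * tcrossprod(P, Q)
  C[C < 0] <- 0
  idx <- as.integer(clue::solve_LSAP(C))
  sqrt(mean(C[cbind(seq_len(nrow(C)), idx)]))
}

#' Closed-form 2-Wasserstein distance between diagonal Gaussians
#'
#' For `N(mu1, diag(sigma1^2))` and `N(mu2, diag(sigma2^2))` the squared
#' 2-Wasserstein distance is `||mu1 - mu2||^2 + ||sigma1 - sigma2||^2`.
#' Used as the per-node prior penalty when `wd_mode = "gaussian"` and as an
#' independent check of the sample-based estimate.
#'
#' @param mu1,mu2 Mean vectors.
#' @param sigma1,sigma2 Standard-deviation vectors (same length as means).
#' @return Scalar distance.
#' @export
gaussian_w2 <- function(mu1, sigma1, mu2, sigma2) {
  stopifnot(length(mu1) == length(mu2), length(sigma1) == length(sigma2))
  if (any(sigma1 < 0) || any(sigma2 < 0)) abort("standard deviations must be nonnegative")
  sqrt(sum((mu1 - mu2) ^ 2) + sum((sigma1 - sigma2) ^ 2))
}
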