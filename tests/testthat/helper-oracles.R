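# Independent reference implementations used to validate the package's
# vectorized code paths. Each oracle is written in the most literal style
# possible (explicit recursion / loops), deliberately sharing no code with
# the implementation it checks.

# semantic contribution by exhaustive enumeration of every upward path:
# contribution of a node is the max over all root-to-node paths of
# omega^length(path)
oracle_semantic_contribution <- function(dag, omega) {
  best <- setNames(rep(-Inf, length(dag$nodes)), dag$nodes)
  walk <- function(node, value) {
    if (value > best[[node]]) best[[node]] <<- value
    parents <- dag$edges$parent[dag$edges$child == node]
    for (p in parents) walk(p, value * omega)
  }
  walk(dag$root, 1)
  best[is.finite(best)]
}

oracle_dss1 <- function(dag1, dag2, omega) {
  c1 <- oracle_semantic_contribution(dag1, omega)
  c2 <- oracle_semantic_contribution(dag2, omega)
  shared <- intersect(names(c1), names(c2))
  if (!length(shared)) return(0)
  num <- 0
  for (d in shared) num <- num + c1[[d]] + c2[[d]]
  num / (sum(c1) + sum(c2))
}

# GIP kernel entry by entry, straight from the definition
oracle_gip <- function(P, eta_prime = 1) {
  n <- nrow(P)
  eta <- eta_prime / mean(apply(P, 1, function(r) sum(r^2)))
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    K[i, j] <- exp(-eta * sum((P[i, ] - P[j, ])^2))
  }
  K
}

# functional similarity entry by entry from the set definition
oracle_dfs <- function(sets, base) {
  n <- length(sets)
  S <- diag(1, n)
  ss <- function(d, ds) max(vapply(ds, function(e) base[d, e], 1.0))
  for (x in 1:n) for (y in 1:n) {
    if (x == y) next
    sx <- sets[[x]]; sy <- sets[[y]]
    if (!length(sx) || !length(sy)) { S[x, y] <- 0; next }
    S[x, y] <- (sum(vapply(sy, function(d) ss(d, sx), 1.0)) +
                sum(vapply(sx, function(d) ss(d, sy), 1.0))) /
               (length(sx) + length(sy))
  }
  S
}

# literal step-by-step network fusion recurrence, scalar loops throughout
oracle_snf <- function(views, K, t, tol = 1e-8) {
  n <- nrow(views[[1]])
  V <- length(views)
  normalize1 <- function(W) {
    P <- matrix(0, n, n)
    for (i in 1:n) {
      s <- 0
      for (k in 1:n) if (k != i) s <- s + W[i, k]
      for (j in 1:n) P[i, j] <- if (i == j) 0.5 else W[i, j] / (2 * s)
    }
    P
  }
  affinity1 <- function(W) {
    S <- matrix(0, n, n)
    labs <- rownames(W)
    for (i in 1:n) {
      cand <- setdiff(1:n, i)
      o <- cand[order(-W[i, cand], labs[cand], method = "radix")][1:K]
      tot <- sum(W[i, o])
      for (j in o) S[i, j] <- W[i, j] / tot
    }
    S
  }
  P <- lapply(views, normalize1)
  S <- lapply(views, affinity1)
  for (it in 1:t) {
    Pn <- vector("list", V)
    for (v in 1:V) {
      others <- matrix(0, n, n)
      for (w in setdiff(1:V, v)) others <- others + P[[w]]
      others <- others / (V - 1)
      Q <- S[[v]] %*% others %*% t(S[[v]])
      Pn[[v]] <- normalize1((Q + t(Q)) / 2)
    }
    delta <- 0
    for (v in 1:V) delta <- max(delta, max(abs(Pn[[v]] - P[[v]])))
    P <- Pn
    if (delta < tol) break
  }
  M <- matrix(0, n, n)
  for (v in 1:V) M <- M + P[[v]]
  M <- M / V
  M <- (M + t(M)) / 2
  off <- row(M) != col(M)
  rng <- range(M[off])
  M[off] <- (M[off] - rng[1]) / (rng[2] - rng[1])
  diag(M) <- 1
  dimnames(M) <- dimnames(views[[1]])
  M
}

# confusion-matrix metrics and curve areas by explicit counting over all
# distinct thresholds
oracle_metrics <- function(scores, labels, threshold) {
  pred <- ifelse(scores >= threshold, 1, 0)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  prec <- if (tp + fp) tp / (tp + fp) else 0
  rec <- if (tp + fn) tp / (tp + fn) else 0
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- t(vapply(thr, function(s) {
    p <- scores >= s
    c(fpr = sum(p & labels == 0) / sum(labels == 0),
      tpr = sum(p & labels == 1) / sum(labels == 1))
  }, c(fpr = 0, tpr = 0)))
  roc <- rbind(c(0, 0), roc)
  auroc <- sum(diff(roc[, "fpr"]) * (head(roc[, "tpr"], -1) + diff(roc[, "tpr"]) / 2))
  pr <- t(vapply(thr, function(s) {
    p <- scores >= s
    c(rec = sum(p & labels == 1) / sum(labels == 1),
      prec = sum(p & labels == 1) / sum(p))
  }, c(rec = 0, prec = 0)))
  aupr <- sum(diff(c(0, pr[, "rec"])) * pr[, "prec"])
  list(auroc = auroc, aupr = aupr, precision = prec, recall = rec,
       f1 = if (prec + rec) 2 * prec * rec / (prec + rec) else 0,
       accuracy = (tp + tn) / length(labels))
}

# random DAG with nodes on levels, edges only upward; always connected
random_dag <- function(n_nodes, seed) {
  set.seed(seed)
  stopifnot(n_nodes >= 1)
  nodes <- paste0("n", seq_len(n_nodes))
  edges <- data.frame(child = character(), parent = character())
  if (n_nodes > 1) {
    for (i in 2:n_nodes) {
      # attach node i under 1-2 earlier nodes (closer to the root)
      k <- sample(1:min(2, i - 1), 1)
      par <- nodes[i]
      kids <- sample(nodes[seq_len(i - 1)], k)
      edges <- rbind(edges, data.frame(child = kids, parent = par))
    }
  }
  disease_dag(root = nodes[1], edges = edges)
}

random_similarity <- function(n, seed, labels = sprintf("e%02d", 1:n)) {
  set.seed(seed)
  W <- matrix(runif(n * n), n)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- list(labels, labels)
  similarity_matrix(W)
}

# strip class/attributes, keep dim + dimnames (for expect_equal on matrices)
bare <- function(m) matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))

tiny_config <- function(..., epochs = 30L) {
  mdlink_config(scales = c(4L, 8L), base_hidden_dims = c(32L, 16L),
                epochs = epochs, knn_k_disease = 4L, knn_k_microbe = 8L,
                cv_folds = 3L, xgb_nrounds = 20L, sinkhorn_iters = 20L,
                ...)
}
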