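#' Labeled square similarity matrix
#'
#' Thin wrapper validating the contract every similarity family obeys:
#' square, symmetric (to 1e-12, then exactly symmetrized), entries in
#' \[0, 1\] (tiny numerical drift is clamped).
#'
#' @param values Square numeric matrix with identical row/column labels.
#' @param kind One of `"DSS1"`, `"DSS2"`, `"GIP"`, `"DFS"`, `"fused"`.
#' @return The matrix with class `similarity_matrix` and a `kind` attribute.
#' @export
similarity_matrix <- function(values, kind = "fused") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("similarity matrix must be square")
  if (is.null(rownames(values))) abort("similarity matrix must be labeled")
  if (!identical(rownames(values), colnames(values))) {
    abort("row and column labels must match")
  }
  if (max(abs(values - t(values))) > 1e-12) abort("similarity matrix not symmetric")
  values <- (values + t(values)) / 2
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9) {
    abort("similarity entries must lie in [0, 1]")
  }
  values[] <- pmin(pmax(values, 0), 1)
  structure(values, kind = kind,
            class = c("similarity_matrix", "matrix", "array"))
}

#' Semantic contribution of each ontology node to a disease
#'
#' In a rooted disease DAG the disease itself contributes 1, and every
#' ancestor contributes the maximum over its children's contributions
#' scaled by the decay factor `omega`; with `omega <= 1` this equals
#' `omega ^ depth` for the shortest child-to-parent path from the root.
#'
#' @param dag A [disease_dag()].
#' @param omega Decay factor in (0, 1].
#' @return Named numeric vector over `dag$nodes`, root mapped to 1.
#' @export
semantic_contribution <- function(dag, omega = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), omega > 0, omega <= 1)
  nodes <- dag$nodes
  depth <- setNames(rep(NA_real_, length(nodes)), nodes)
  depth[dag$root] <- 0
  frontier <- dag$root
  # BFS upward along child -> parent edges
  while (length(frontier)) {
    nxt <- unique(dag$edges$parent[dag$edges$child %in% frontier])
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- depth[frontier[1]] + 1
    frontier <- nxt
  }
  if (anyNA(depth)) {
    abort(paste0("nodes unreachable from root ", dag$root, ": ",
                 paste(names(depth)[is.na(depth)], collapse = ", ")))
  }
  omega ^ depth
}

#' Semantic value of a disease
#'
#' Sum of the semantic contributions of every node in the disease's DAG;
#' at least 1 since the root always contributes 1.
#'
#' @inheritParams semantic_contribution
#' @return A scalar `>= 1`.
#' @export
semantic_value <- function(dag, omega = 0.5) {
  sum(semantic_contribution(dag, omega))
}

#' Semantic similarity between two diseases (shared-ancestor score)
#'
#' Contributions of nodes present in both DAGs are summed from both sides
#' and normalized by the two semantic values, giving a symmetric score in
#' \[0, 1\]; disjoint ontologies score 0, identical ones score 1.
#'
#' @param dag1,dag2 [disease_dag()] objects.
#' @param omega Decay factor in (0, 1].
#' @return Scalar similarity.
#' @export
dss1 <- function(dag1, dag2, omega = 0.5) {
  c1 <- semantic_contribution(dag1, omega)
  c2 <- semantic_contribution(dag2, omega)
  shared <- intersect(names(c1), names(c2))
  if (!length(shared)) return(0)
  sum(c1[shared] + c2[shared]) / (sum(c1) + sum(c2))
}

#' Pairwise semantic similarity matrix over a DAG forest
#'
#' @param dags Named list of [disease_dag()] objects.
#' @inheritParams dss1
#' @return A `similarity_matrix` of kind `"DSS1"`.
#' @export
dss1_matrix <- function(dags, omega = 0.5) {
  ids <- names(dags)
  if (is.null(ids)) abort("dags must be a named list")
  contrib <- lapply(dags, semantic_contribution, omega = omega)
  vals <- vapply(contrib, sum, 1.0)
  n <- length(ids)
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
      if (length(shared)) {
        S[i, j] <- S[j, i] <-
          sum(contrib[[i]][shared] + contrib[[j]][shared]) / (vals[i] + vals[j])
      }
    }
  }
  similarity_matrix(S, kind = "DSS1")
}

#' Symptom-profile cosine similarity between diseases
#'
#' Each disease is a nonnegative vector of symptom weights (e.g. inverse
#' document frequencies from literature co-occurrence); similarity is the
#' cosine of the two vectors. A disease with an all-zero profile gets
#' similarity 0 to every other disease (diagonal kept at 1) with a warning,
#' rather than propagating NaN.
#'
#' @param profiles Nonnegative disease-by-symptom matrix with row labels.
#' @return A `similarity_matrix` of kind `"DSS2"`.
#' @export
dss2 <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) abort("symptom profiles must have row labels")
  if (min(profiles) < 0) abort("symptom weights must be nonnegative")
  nrm <- sqrt(rowSums(profiles ^ 2))
  zero <- nrm == 0
  if (any(zero)) {
    warn(paste0("all-zero symptom profile for: ",
                paste(rownames(profiles)[zero], collapse = ", ")))
    nrm[zero] <- 1
  }
  S <- tcrossprod(profiles / nrm)
  S[zero, ] <- 0
  S[, zero] <- 0
  diag(S) <- 1
  S[S > 1] <- 1
  similarity_matrix((S + t(S)) / 2, kind = "DSS2")
}

#' Gaussian interaction profile kernel similarity
#'
#' Treats each entity's row (microbe) or column (disease) of the binary
#' association matrix as its interaction profile and applies a Gaussian
#' kernel whose bandwidth is `eta_prime` divided by the mean squared
#' profile norm, so the kernel is scale-free in the number of associations.
#'
#' @param A An [association_matrix()].
#' @param axis `"disease"` (column profiles) or `"microbe"` (row profiles).
#' @param eta_prime Bandwidth numerator, conventionally 1.
#' @return A `similarity_matrix` of kind `"GIP"` with unit diagonal.
#' @export
gip_kernel <- function(A, axis = c("disease", "microbe"), eta_prime = 1) {
  axis <- match.arg(axis)
  P <- if (axis == "disease") t(unclass(A)) else unclass(A)
  if (nrow(P) < 2) abort("need at least 2 entities on the chosen axis")
  sq <- rowSums(P ^ 2)
  if (mean(sq) == 0) abort("association matrix is all zero: GIP bandwidth undefined")
  eta <- eta_prime / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0
  K <- exp(-eta * d2)
  diag(K) <- 1
  similarity_matrix((K + t(K)) / 2, kind = "GIP")
}

#' Best similarity between an entity and an entity set
#'
#' The maximum base similarity between `d` and any member of `ds`; the
#' building block of set-based functional similarity.
#'
#' @param d Entity id.
#' @param ds Character vector of entity ids (nonempty).
#' @param base A `similarity_matrix` indexing `d` and all of `ds`.
#' @return Scalar similarity.
#' @export
set_similarity <- function(d, ds, base) {
  if (!length(ds)) abort("entity set is empty")
  if (!d %in% rownames(base) || !all(ds %in% rownames(base))) {
    abort("entity not indexed in base similarity matrix")
  }
  max(base[d, ds])
}

#' Set-based functional similarity from a partner association matrix
#'
#' Two target entities (e.g. microbes) are similar when the partner sets
#' they associate with (e.g. their diseases) are similar under a base
#' similarity over the partner axis: each member of either set is matched
#' to its best counterpart in the other set, and the matched scores are
#' averaged over both directions.
#'
#' Entities with no partner associations get off-diagonal similarity 0
#' (diagonal 1) with a warning.
#'
#' @param A_partner Binary target-by-partner matrix (rows = target axis).
#' @param base `similarity_matrix` over the partner axis (columns of
#'   `A_partner`).
#' @return A `similarity_matrix` of kind `"DFS"` over the target axis.
#' @export
functional_similarity <- function(A_partner, base) {
  A_partner <- as.matrix(A_partner)
  if (!all(colnames(A_partner) %in% rownames(base))) {
    abort("base similarity does not cover the partner axis")
  }
  ids <- rownames(A_partner)
  sets <- apply(A_partner, 1, function(r) colnames(A_partner)[r != 0],
                simplify = FALSE)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warn(paste0("entities with no partner associations: ",
                paste(ids[empty], collapse = ", ")))
  }
  n <- length(ids)
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  B <- unclass(base)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sx <- sets[[i]]; sy <- sets[[j]]
      if (!length(sx) || !length(sy)) next
      Bxy <- B[sx, sy, drop = FALSE]
      S[i, j] <- S[j, i] <-
        (sum(apply(Bxy, 2, max)) + sum(apply(Bxy, 1, max))) /
        (length(sx) + length(sy))
    }
  }
  similarity_matrix(S, kind = "DFS")
}

#' Merge two same-axis similarity matrices from different sources
#'
#' Entrywise: the average where both sources report a nonzero value, the
#' nonzero value where only one does, and 0 where neither does. Used to
#' combine functional similarities derived from two partner databases.
#'
#' @param S_a,S_b `similarity_matrix` objects with identical labels.
#' @return A merged `similarity_matrix`.
#' @export
merge_similarities <- function(S_a, S_b) {
  if (!identical(rownames(S_a), rownames(S_b))) {
    abort("similarity matrices have different labels")
  }
  a <- unclass(S_a); b <- unclass(S_b)
  both <- a != 0 & b != 0
  out <- a + b          # covers the "exactly one nonzero" and "both zero" cases
  out[both] <- (a[both] + b[both]) / 2
  similarity_matrix(out, kind = attr(S_a, "kind"))
}
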