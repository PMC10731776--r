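# stage-keyed substream: every synthetic stage derives its own seed from
# the master seed so stages are independently reproducible
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% .Machine$integer.max
}

#' Generate a planted-block microbe-disease association matrix
#'
#' Microbes and diseases are assigned to clusters round-robin; a pair is
#' associated with probability `p_in` when its clusters are linked (by
#' default, when they are the same cluster) and `p_out` otherwise, after
#' which every cell is flipped independently with probability
#' `flip_noise`. This emulates the sparse block structure of curated
#' association databases while giving the pipeline a known ground truth.
#'
#' @param nm,nd Numbers of microbes and diseases (`>= n_clusters`).
#' @param n_clusters Number of planted clusters on each axis.
#' @param p_in,p_out Association probabilities for linked / unlinked
#'   cluster pairs, `0 <= p_out < p_in <= 1`.
#' @param flip_noise Independent flip probability per cell.
#' @param seed Integer seed; regeneration is bit-identical.
#' @param cluster_link Optional binary `n_clusters x n_clusters` matrix of
#'   cluster compatibility; defaults to the identity.
#' @return An object of class `planted_world`: the [association_matrix()]
#'   `A`, cluster labels, the link matrix and the generating parameters.
#' @export
make_planted_association <- function(nm = 150, nd = 30, n_clusters = 4,
                                     p_in = 0.3, p_out = 0.02,
                                     flip_noise = 0.01, seed = 1L,
                                     cluster_link = NULL) {
  # p_in == p_out is allowed: it gives a structureless null world
  stopifnot(nm >= n_clusters, nd >= n_clusters, n_clusters >= 1,
            p_out >= 0, p_out <= p_in, p_in <= 1, p_in > 0,
            flip_noise >= 0, flip_noise < 0.5)
  if (is.null(cluster_link)) cluster_link <- diag(1, n_clusters)
  set.seed(substream_seed(seed, "association"))
  mc <- rep_len(seq_len(n_clusters), nm)
  dc <- rep_len(seq_len(n_clusters), nd)
  p <- matrix(p_out, nm, nd)
  p[cluster_link[cbind(rep(mc, nd), rep(dc, each = nm))] == 1] <- p_in
  A <- matrix(rbinom(nm * nd, 1, p), nm, nd)
  flip <- matrix(rbinom(nm * nd, 1, flip_noise), nm, nd)
  A <- abs(A - flip)
  dimnames(A) <- list(sprintf("m%03d", seq_len(nm)), sprintf("d%03d", seq_len(nd)))
  structure(list(
    A = association_matrix(A),
    microbe_clusters = setNames(mc, rownames(A)),
    disease_clusters = setNames(dc, colnames(A)),
    cluster_link = cluster_link,
    p_in = p_in, p_out = p_out, flip_noise = flip_noise, seed = seed
  ), class = "planted_world")
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf("<planted_world> %d microbes x %d diseases, %d clusters, density %.3f\n",
              nrow(x$A), ncol(x$A), nrow(x$cluster_link), mean(x$A)))
  invisible(x)
}

#' Generate a toy ontology DAG forest for a set of diseases
#'
#' Each planted cluster owns a shared ancestor chain of length `depth`;
#' each disease attaches to its cluster's chain with probability
#' `share_prob` and otherwise to a private chain of the same length. Two
#' diseases on the same shared chain have many common ancestors (high
#' semantic similarity); diseases on private chains share none.
#'
#' @param world A `planted_world` (supplies disease ids and clusters), or
#'   `NULL` with `disease_clusters` given explicitly.
#' @param depth Ancestors per chain.
#' @param share_prob Probability of attaching to the cluster chain.
#' @param seed Integer seed.
#' @param disease_clusters Named integer vector (used when `world` is
#'   `NULL`).
#' @return Named list of [disease_dag()] objects.
#' @export
make_dag_forest <- function(world = NULL, depth = 4, share_prob = 0.8,
                            seed = 1L, disease_clusters = NULL) {
  if (!is.null(world)) disease_clusters <- world$disease_clusters
  if (is.null(disease_clusters)) abort("need a world or disease_clusters")
  set.seed(substream_seed(seed, "dagforest"))
  chain_edges <- function(tip, anc) {
    data.frame(child = c(tip, head(anc, -1)), parent = anc,
               stringsAsFactors = FALSE)
  }
  lapply(setNames(nm = names(disease_clusters)), function(d) {
    cl <- disease_clusters[[d]]
    anc <- if (runif(1) < share_prob) {
      sprintf("anc_c%d_%d", cl, seq_len(depth))
    } else {
      sprintf("anc_%s_%d", d, seq_len(depth))
    }
    disease_dag(root = d, edges = chain_edges(d, anc))
  })
}

#' Generate a disease-by-symptom weight matrix with cluster signal
#'
#' Each cluster loads on its own block of symptoms with weight `signal`;
#' uniform noise in \[0, 1\] is added everywhere. At `signal = 0` the
#' profiles carry no cluster information; increasing `signal` raises the
#' within-cluster cosine similarity above the between-cluster one.
#'
#' @param world A `planted_world`.
#' @param n_symptoms Total symptom count (`>= n_clusters`).
#' @param signal Cluster loading strength.
#' @param seed Integer seed.
#' @return Nonnegative disease-by-symptom matrix with dimnames.
#' @export
make_symptom_matrix <- function(world, n_symptoms = 40, signal = 2,
                                seed = 1L) {
  dc <- world$disease_clusters
  k <- nrow(world$cluster_link)
  stopifnot(n_symptoms >= k, signal >= 0)
  set.seed(substream_seed(seed, "symptoms"))
  block <- rep_len(seq_len(k), n_symptoms)
  S <- matrix(runif(length(dc) * n_symptoms), length(dc), n_symptoms)
  for (i in seq_along(dc)) {
    S[i, block == dc[i]] <- S[i, block == dc[i]] + signal
  }
  dimnames(S) <- list(names(dc), sprintf("s%03d", seq_len(n_symptoms)))
  S
}

#' Write a complete synthetic input set to disk
#'
#' Materializes the planted association matrix, ontology edge list and
#' symptom matrix in the TSV formats the readers accept, so the
#' command-line pipeline can be exercised without external databases.
#'
#' @param dir Output directory (created if needed).
#' @param world A `planted_world`; defaults to the standard planted
#'   setting.
#' @param seed Integer seed for the ontology and symptom stages.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_inputs <- function(dir, world = make_planted_association(),
                                   seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(assoc = file.path(dir, "associations.tsv"),
             dags = file.path(dir, "disease_dags.tsv"),
             symptoms = file.path(dir, "symptoms.tsv"))
  pos <- which(unclass(world$A) == 1, arr.ind = TRUE)
  writeLines(paste(rownames(world$A)[pos[, 1]], colnames(world$A)[pos[, 2]],
                   sep = "\t"), paths["assoc"])
  dags <- make_dag_forest(world, seed = seed)
  edges <- dplyr::bind_rows(lapply(dags, function(g) {
    dplyr::mutate(g$edges, disease = g$root, .before = 1)
  }))
  write.table(edges, paths["dags"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_matrix_tsv(make_symptom_matrix(world, seed = seed), paths["symptoms"])
  invisible(paths)
}
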