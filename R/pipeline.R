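#' Run the full association-prediction pipeline
#'
#' End-to-end path from a binary association matrix to cross-validated
#' predictions:
#'
#' 1. **Disease similarity views** — ontology semantic similarity (when
#'    DAGs are supplied), symptom-profile cosine similarity (when symptom
#'    weights are supplied), and the Gaussian interaction profile kernel
#'    over disease columns (always available).
#' 2. **Microbe similarity views** — set-based functional similarity of
#'    the microbes' disease sets (base: semantic similarity when
#'    available, else the disease GIP kernel), the microbe GIP kernel,
#'    and optionally a drug-based functional similarity when microbe-drug
#'    associations plus a drug similarity matrix are supplied.
#' 3. **Fusion** — similarity network fusion per axis.
#' 4. **Embedding** — one variational graph autoencoder per axis (disease
#'    features: columns of `A`; microbe features: rows of `A`), embeddings
#'    are the concatenated per-scale posterior means.
#' 5. **Classification** — concatenated pair embeddings, uniform negative
#'    sampling, stratified k-fold gradient-boosted-tree cross-validation.
#'
#' @param A An [association_matrix()].
#' @param disease_dags Optional named list of [disease_dag()] covering the
#'   diseases of `A`.
#' @param symptom_profiles Optional nonnegative disease-by-symptom matrix.
#' @param drug_assoc Optional binary microbe-by-drug matrix.
#' @param drug_sim Optional drug-by-drug `similarity_matrix` (required with
#'   `drug_assoc`).
#' @param cfg An [mdlink_config()].
#' @param verbose Log pipeline stages.
#' @return An object of class `mdlink_result`: fused networks, the two
#'   autoencoder fits, embeddings, the pair dataset and the `mdlink_cv`
#'   evaluation.
#' @examples
#' \donttest{
#' world <- make_planted_association(nm = 40, nd = 12, n_clusters = 3, seed = 2)
#' cfg <- mdlink_config(epochs = 30, scales = c(8, 16), knn_k_microbe = 10,
#'                      cv_folds = 5, xgb_nrounds = 30)
#' res <- mdlink_run(world$A, disease_dags = make_dag_forest(world),
#'                   symptom_profiles = make_symptom_matrix(world), cfg = cfg)
#' glance(res)
#' }
#' @export
mdlink_run <- function(A, disease_dags = NULL, symptom_profiles = NULL,
                       drug_assoc = NULL, drug_sim = NULL,
                       cfg = mdlink_config(), verbose = FALSE) {
  stopifnot(inherits(A, "association_matrix"))
  validate_config(cfg)
  t0 <- Sys.time()

  # --- disease views
  gip_d <- gip_kernel(A, "disease")
  d_views <- list(GIP = gip_d)
  dss1_m <- NULL
  if (!is.null(disease_dags)) {
    if (!all(colnames(A) %in% names(disease_dags))) {
      abort("disease_dags must cover every disease of A")
    }
    dss1_m <- dss1_matrix(disease_dags[colnames(A)], omega = cfg$omega)
    d_views <- c(list(DSS1 = dss1_m), d_views)
  }
  if (!is.null(symptom_profiles)) {
    if (!all(colnames(A) %in% rownames(symptom_profiles))) {
      abort("symptom_profiles must cover every disease of A")
    }
    d_views <- c(d_views, list(DSS2 = dss2(symptom_profiles[colnames(A), ])))
  }
  log_stage("similarity", axis = "disease", views = length(d_views),
            verbose = verbose)
  SM_d <- snf_fuse(d_views, K = min(cfg$knn_k_disease, ncol(A) - 1),
                   t = cfg$snf_iterations)

  # --- microbe views
  base_d <- if (!is.null(dss1_m)) dss1_m else gip_d
  dfs1 <- suppressWarnings(functional_similarity(unclass(A), base_d))
  m_views <- list(DFS1 = dfs1, GIP = gip_kernel(A, "microbe"))
  if (!is.null(drug_assoc)) {
    if (is.null(drug_sim)) abort("drug_assoc requires drug_sim")
    m_views <- c(m_views, list(
      DFS2 = suppressWarnings(functional_similarity(drug_assoc, drug_sim))))
  }
  log_stage("similarity", axis = "microbe", views = length(m_views),
            verbose = verbose)
  SM_m <- snf_fuse(m_views, K = min(cfg$knn_k_microbe, nrow(A) - 1),
                   t = cfg$snf_iterations)

  # --- embeddings (independent models per axis, shared hyperparameters)
  log_stage("embed", axis = "disease", nodes = ncol(A), verbose = verbose)
  fit_d <- vgae_train(SM_d, t(unclass(A)), cfg, verbose = verbose)
  log_stage("embed", axis = "microbe", nodes = nrow(A), verbose = verbose)
  fit_m <- vgae_train(SM_m, unclass(A), cfg, verbose = verbose)

  # --- pair classification
  ds <- build_pair_dataset(A, vgae_embed(fit_m), vgae_embed(fit_d),
                           negative_ratio = cfg$negative_ratio,
                           seed = cfg$seed)
  log_stage("evaluate", pairs = nrow(ds$pairs), folds = cfg$cv_folds,
            verbose = verbose)
  cv <- crossval(ds, folds = cfg$cv_folds, cfg = cfg)
  log_stage("done",
            elapsed_s = sprintf("%.1f", as.numeric(Sys.time() - t0, units = "secs")),
            seed = cfg$seed, verbose = verbose)

  structure(list(
    A = A, fused_disease = SM_d, fused_microbe = SM_m,
    vgae_disease = fit_d, vgae_microbe = fit_m,
    Zd = vgae_embed(fit_d), Zm = vgae_embed(fit_m),
    pairs = ds, cv = cv, cfg = cfg
  ), class = "mdlink_result")
}

#' @export
print.mdlink_result <- function(x, ...) {
  cat(sprintf("<mdlink_result> %d microbes x %d diseases\n",
              nrow(x$A), ncol(x$A)))
  print(x$cv)
  invisible(x)
}

#' @rdname glance.mdlink_cv
#' @method glance mdlink_result
#' @export
glance.mdlink_result <- function(x, ...) glance(x$cv)

#' @rdname tidy.mdlink_cv
#' @method tidy mdlink_result
#' @export
tidy.mdlink_result <- function(x, ...) tidy(x$cv)

#' Rank candidate microbes from a pipeline result
#'
#' @param result An `mdlink_result`.
#' @param disease_id Disease column label.
#' @param top_k Candidates to return.
#' @return See [rank_candidates()].
#' @export
predict_candidates <- function(result, disease_id, top_k = 20) {
  rank_candidates(result$A, result$Zm, result$Zd, result$cv$model,
                  disease_id, top_k)
}
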