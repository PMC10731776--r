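#' Run configuration for the association-prediction pipeline
#'
#' Collects every tunable hyperparameter of the pipeline in one validated
#' list: similarity-network fusion (KNN sizes, iteration count), the
#' multi-scale variational graph autoencoder (latent scales, base hidden
#' widths, optimizer schedule, prior penalty), and the downstream classifier
#' (negative sampling ratio, cross-validation folds, decision threshold).
#'
#' Defaults follow the reference setting for human microbe-disease data:
#' 5 fused-network neighbors on the disease axis, 30 on the microbe axis,
#' and latent scales of 16, 32 and 64 dimensions (a 112-dimensional
#' concatenated embedding per node).
#'
#' @param knn_k_disease Neighborhood size for disease-network fusion.
#' @param knn_k_microbe Neighborhood size for microbe-network fusion.
#' @param snf_iterations Maximum cross-diffusion iterations.
#' @param scales Integer vector of latent dimensionalities, one per
#'   variational head; samples are concatenated column-wise.
#' @param base_hidden_dims Widths of the two shared graph-convolution layers.
#' @param learning_rate,lr_step,lr_gamma Adam learning rate and its step
#'   decay: the rate is multiplied by `lr_gamma` every `lr_step` epochs.
#' @param epochs Full-graph gradient steps.
#' @param wd_mode How the latent-prior discrepancy is measured: `"sinkhorn"`
#'   matches each scale's embedding rows to an equal-size standard-normal
#'   sample cloud by entropic optimal transport; `"gaussian"` uses the
#'   closed-form 2-Wasserstein distance between diagonal Gaussians per node.
#' @param sinkhorn_epsilon Entropic regularization strength (squared-distance
#'   units) used when `wd_mode = "sinkhorn"`.
#' @param sinkhorn_iters Sinkhorn iterations.
#' @param negative_ratio Sampled negatives per known positive pair.
#' @param cv_folds Stratified cross-validation folds.
#' @param decision_threshold Score cut for F1/precision/recall/accuracy.
#' @param omega Semantic contribution decay factor for ontology similarity,
#'   in (0, 1].
#' @param xgb_nrounds Boosting rounds for the pair classifier.
#' @param seed Integer seed governing all randomness.
#'
#' @return A list of class `mdlink_config`.
#' @examples
#' cfg <- mdlink_config(epochs = 50, seed = 7)
#' cfg$scales
#' @export
mdlink_config <- function(knn_k_disease = 5L,
                          knn_k_microbe = 30L,
                          snf_iterations = 20L,
                          scales = c(16L, 32L, 64L),
                          base_hidden_dims = c(256L, 128L),
                          learning_rate = 0.01,
                          lr_step = 50L,
                          lr_gamma = 0.5,
                          epochs = 200L,
                          wd_mode = c("sinkhorn", "gaussian"),
                          sinkhorn_epsilon = 0.1,
                          sinkhorn_iters = 50L,
                          negative_ratio = 1,
                          cv_folds = 10L,
                          decision_threshold = 0.5,
                          omega = 0.5,
                          xgb_nrounds = 100L,
                          seed = 1L) {
  wd_mode <- match.arg(wd_mode)
  cfg <- list(
    knn_k_disease = as.integer(knn_k_disease),
    knn_k_microbe = as.integer(knn_k_microbe),
    snf_iterations = as.integer(snf_iterations),
    scales = as.integer(scales),
    base_hidden_dims = as.integer(base_hidden_dims),
    learning_rate = as.numeric(learning_rate),
    lr_step = as.integer(lr_step),
    lr_gamma = as.numeric(lr_gamma),
    epochs = as.integer(epochs),
    wd_mode = wd_mode,
    sinkhorn_epsilon = as.numeric(sinkhorn_epsilon),
    sinkhorn_iters = as.integer(sinkhorn_iters),
    negative_ratio = as.numeric(negative_ratio),
    cv_folds = as.integer(cv_folds),
    decision_threshold = as.numeric(decision_threshold),
    omega = as.numeric(omega),
    xgb_nrounds = as.integer(xgb_nrounds),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "mdlink_config")
}

validate_config <- function(cfg) {
  stopifnot(
    length(cfg$scales) >= 1, all(cfg$scales > 0),
    length(cfg$base_hidden_dims) == 2, all(cfg$base_hidden_dims > 0),
    cfg$omega > 0, cfg$omega <= 1,
    cfg$cv_folds >= 2,
    cfg$epochs >= 1,
    cfg$sinkhorn_epsilon > 0, cfg$sinkhorn_iters >= 1,
    cfg$knn_k_disease >= 1, cfg$knn_k_microbe >= 1,
    cfg$snf_iterations >= 1,
    cfg$negative_ratio >= 0,
    cfg$decision_threshold > 0, cfg$decision_threshold < 1,
    cfg$learning_rate > 0, cfg$lr_step >= 1,
    cfg$lr_gamma > 0, cfg$lr_gamma <= 1,
    cfg$xgb_nrounds >= 1
  )
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [mdlink_config()].
#'
#' @param path Path to a YAML file whose keys are `mdlink_config()` argument
#'   names.
#' @return A list of class `mdlink_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("read_config requires the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(mdlink_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  do.call(mdlink_config, vals)
}

#' @export
print.mdlink_config <- function(x, ...) {
  cat("<mdlink_config>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}
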