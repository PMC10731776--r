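#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with midrank handling of tied
#' scores; equivalent to trapezoidal integration of the ROC curve.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels 0/1 labels.
#' @return AUROC in \[0, 1\].
#' @export
metric_auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUROC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: scores are swept from high to low (tied
#' scores handled as one group) and precision is accumulated over recall
#' increments.
#'
#' @inheritParams metric_auroc
#' @return AUPR in \[0, 1\].
#' @export
metric_aupr <- function(scores, labels) {
  labels <- as.numeric(labels)
  npos <- sum(labels == 1)
  if (npos == 0) abort("AUPR needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1, length(y)), grp, sum)
  tp <- cumsum(tp_g); n_cum <- cumsum(n_g)
  prec <- tp / n_cum
  rec <- tp / npos
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Thresholded binary classification metrics
#'
#' @inheritParams metric_auroc
#' @param threshold Scores `>= threshold` are called positive.
#' @return Tibble with one row: f1, precision, recall, accuracy.
#' @export
metric_confusion <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(f1 = f1, precision = precision, recall = recall,
                 accuracy = (tp + tn) / length(labels))
}

#' Build the labeled pair dataset for classification
#'
#' Every known association becomes a positive pair; negatives are drawn
#' uniformly without replacement from the unknown (zero) cells of the
#' association matrix, `negative_ratio` per positive. Each pair's feature
#' vector is the concatenation of its microbe and disease embeddings.
#'
#' @param A An [association_matrix()].
#' @param Zm,Zd Embedding matrices whose row names cover the microbes and
#'   diseases of `A`.
#' @param negative_ratio Sampled negatives per positive.
#' @param seed Integer seed for the negative draw.
#' @return An object of class `mdlink_pairs`: a list with `pairs` (tibble:
#'   microbe, disease, label) and `features` (numeric matrix, one row per
#'   pair).
#' @export
build_pair_dataset <- function(A, Zm, Zd, negative_ratio = 1, seed = 1L) {
  if (!all(rownames(A) %in% rownames(Zm))) abort("Zm does not cover all microbes")
  if (!all(colnames(A) %in% rownames(Zd))) abort("Zd does not cover all diseases")
  pos <- which(unclass(A) == 1, arr.ind = TRUE)
  if (!nrow(pos)) abort("association matrix has no positives")
  n_neg <- round(negative_ratio * nrow(pos))
  zero <- which(unclass(A) == 0, arr.ind = TRUE)
  if (n_neg > nrow(zero)) {
    abort("negative_ratio too large: not enough unknown cells to sample")
  }
  neg <- if (n_neg > 0) {
    set.seed(seed)
    zero[sample.int(nrow(zero), n_neg), , drop = FALSE]
  } else zero[0, , drop = FALSE]
  idx <- rbind(pos, neg)
  pairs <- tibble::tibble(
    microbe = rownames(A)[idx[, 1]],
    disease = colnames(A)[idx[, 2]],
    label = rep(c(1L, 0L), c(nrow(pos), nrow(neg)))
  )
  features <- cbind(Zm[pairs$microbe, , drop = FALSE],
                    Zd[pairs$disease, , drop = FALSE])
  colnames(features) <- c(paste0("m", seq_len(ncol(Zm))),
                          paste0("d", seq_len(ncol(Zd))))
  rownames(features) <- NULL
  structure(list(pairs = pairs, features = features), class = "mdlink_pairs")
}

#' @export
print.mdlink_pairs <- function(x, ...) {
  cat(sprintf("<mdlink_pairs> %d pairs (%d positive), %d features\n",
              nrow(x$pairs), sum(x$pairs$label), ncol(x$features)))
  invisible(x)
}

#' @rdname tidy.mdlink_cv
#' @method tidy mdlink_pairs
#' @export
tidy.mdlink_pairs <- function(x, ...) x$pairs

# stratified fold assignment, deterministic given seed
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    fold[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  fold
}

# one gradient-boosted-tree fit with library-default booster parameters
fit_gbt <- function(features, labels, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

score_gbt <- function(model, features) {
  predict(model, xgboost::xgb.DMatrix(features, nthread = 1))
}

#' Cross-validated association prediction
#'
#' Stratified k-fold cross-validation over labeled pairs: per fold a
#' gradient-boosted-tree classifier (binary logistic objective, library
#' defaults otherwise) is fit on the training pairs and scores the held-out
#' pairs. Six metrics are reported per fold and averaged: threshold-free
#' AUROC and AUPR, plus F1, precision, recall and accuracy at the decision
#' threshold.
#'
#' @param ds An `mdlink_pairs` dataset from [build_pair_dataset()].
#' @param folds Number of folds (`>= 2`).
#' @param cfg An [mdlink_config()]; supplies the seed, boosting rounds and
#'   decision threshold.
#' @return An object of class `mdlink_cv` with elements `per_fold`
#'   (tibble), `summary` (one-row tibble of fold means), `predictions`
#'   (tibble with out-of-fold scores) and `model` (a final classifier fit
#'   on all pairs, for ranking).
#' @export
crossval <- function(ds, folds = 10, cfg = mdlink_config()) {
  stopifnot(inherits(ds, "mdlink_pairs"), folds >= 2)
  y <- ds$pairs$label
  fold <- stratified_folds(y, folds, cfg$seed)
  per_fold <- vector("list", folds)
  preds <- vector("list", folds)
  for (k in seq_len(folds)) {
    te <- fold == k
    if (length(unique(y[te])) < 2 || length(unique(y[!te])) < 2) {
      abort(sprintf("fold %d contains a single class; use fewer folds", k))
    }
    fit <- fit_gbt(ds$features[!te, , drop = FALSE], y[!te], cfg$xgb_nrounds)
    sc <- score_gbt(fit, ds$features[te, , drop = FALSE])
    per_fold[[k]] <- dplyr::bind_cols(
      tibble::tibble(fold = k,
                     auroc = metric_auroc(sc, y[te]),
                     aupr = metric_aupr(sc, y[te])),
      metric_confusion(sc, y[te], cfg$decision_threshold)
    )
    preds[[k]] <- dplyr::mutate(ds$pairs[te, ], fold = k, score = sc)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  summary <- dplyr::summarise(per_fold, dplyr::across(-"fold", mean))
  final <- fit_gbt(ds$features, y, cfg$xgb_nrounds)
  structure(list(per_fold = per_fold, summary = summary,
                 predictions = dplyr::bind_rows(preds),
                 threshold = cfg$decision_threshold,
                 model = final),
            class = "mdlink_cv")
}

#' @export
print.mdlink_cv <- function(x, ...) {
  cat(sprintf("<mdlink_cv> %d folds\n", nrow(x$per_fold)))
  s <- x$summary
  cat(sprintf("  mean AUROC %.4f  AUPR %.4f  F1 %.4f  acc %.4f\n",
              s$auroc, s$aupr, s$f1, s$accuracy))
  invisible(x)
}

#' Tidy per-fold results
#'
#' `tidy()` returns the per-fold metric table (or the pair table / loss
#' history for the other result types); `glance()` returns a one-row
#' summary.
#'
#' @param x An `mdlink_cv`, `mdlink_pairs` or `mdlink_vgae` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mdlink_cv <- function(x, ...) x$per_fold

#' One-row model summaries
#'
#' @inheritParams tidy.mdlink_cv
#' @return A one-row tibble.
#' @export
glance.mdlink_cv <- function(x, ...) {
  dplyr::mutate(x$summary, folds = nrow(x$per_fold), threshold = x$threshold)
}

#' Rank candidate microbes for a disease
#'
#' Scores every microbe *not* already associated with the disease by the
#' fitted classifier and returns the `top_k` highest-scoring candidates
#' (ties broken by microbe label for reproducibility). Scores are
#' interpreted as association probabilities.
#'
#' @param A An [association_matrix()].
#' @param Zm,Zd Embedding matrices (as in [build_pair_dataset()]).
#' @param model A fitted classifier (e.g. `fit$model` from [crossval()]).
#' @param disease_id Disease column label of `A`.
#' @param top_k Number of candidates to return.
#' @return Tibble with columns `rank`, `microbe`, `score`, sorted by
#'   nonincreasing score.
#' @export
rank_candidates <- function(A, Zm, Zd, model, disease_id, top_k = 20) {
  if (!disease_id %in% colnames(A)) abort(paste0("unknown disease: ", disease_id))
  cand <- rownames(A)[unclass(A)[, disease_id] == 0]
  if (!length(cand) || top_k == 0) {
    return(tibble::tibble(rank = integer(), microbe = character(),
                          score = numeric()))
  }
  feats <- cbind(Zm[cand, , drop = FALSE],
                 matrix(rep(Zd[disease_id, ], each = length(cand)),
                        nrow = length(cand)))
  colnames(feats) <- c(paste0("m", seq_len(ncol(Zm))),
                       paste0("d", seq_len(ncol(Zd))))
  sc <- score_gbt(model, feats)
  o <- order(-sc, cand, method = "radix")[seq_len(min(top_k, length(cand)))]
  tibble::tibble(rank = seq_along(o), microbe = cand[o], score = sc[o])
}
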