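#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_tile
#'   labs facet_wrap scale_fill_viridis_c theme_minimal coord_equal
NULL

#' @export
ggplot2::autoplot

roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  tibble::tibble(fpr = c(0, cumsum(1 - y) / sum(1 - y)),
                 tpr = c(0, cumsum(y) / sum(y)))
}

pr_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  tp <- cumsum(y)
  tibble::tibble(recall = tp / sum(y), precision = tp / seq_along(y))
}

#' ROC and precision-recall curves of a cross-validated fit
#'
#' Curves are computed from the pooled out-of-fold scores.
#'
#' @param object An `mdlink_cv`.
#' @param ... Unused.
#' @return A ggplot with one panel per curve type.
#' @export
autoplot.mdlink_cv <- function(object, ...) {
  p <- object$predictions
  df <- dplyr::bind_rows(
    dplyr::mutate(roc_points(p$score, p$label), panel = "ROC",
                  x = .data$fpr, y = .data$tpr),
    dplyr::mutate(pr_points(p$score, p$label), panel = "Precision-recall",
                  x = .data$recall, y = .data$precision)
  )
  ggplot(df, aes(.data$x, .data$y)) +
    geom_line(color = "#2166ac") +
    facet_wrap(~panel, scales = "free") +
    labs(x = NULL, y = NULL,
         title = sprintf("Out-of-fold performance (AUROC %.3f, AUPR %.3f)",
                         object$summary$auroc, object$summary$aupr)) +
    theme_minimal()
}

#' Loss history of an autoencoder fit
#'
#' @param object An `mdlink_vgae`.
#' @param ... Unused.
#' @return A ggplot of each loss component against the epoch.
#' @export
autoplot.mdlink_vgae <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("bce_adj", "wd_prior", "aux_1", "aux_2", "total"),
                            names_to = "component", values_to = "loss")
  ggplot(df, aes(.data$epoch, .data$loss, color = .data$component)) +
    geom_line() +
    labs(x = "epoch", y = "loss", color = NULL,
         title = "Autoencoder training loss") +
    theme_minimal()
}

#' Heatmap of a similarity matrix
#'
#' @param S A `similarity_matrix`.
#' @param title Plot title; defaults to the matrix kind.
#' @return A ggplot tile map.
#' @export
plot_similarity <- function(S, title = attr(S, "kind")) {
  df <- tibble::as_tibble(as.table(unclass(S)), .name_repair = "minimal")
  names(df) <- c("row", "col", "value")
  ggplot(df, aes(.data$col, .data$row, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "similarity", title = title) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
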