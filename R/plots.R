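# ggplot2 displays for the main result types.

#' @importFrom ggplot2 ggplot aes geom_boxplot geom_col geom_tile
#'   geom_point scale_fill_gradient2 labs theme_minimal stat_ecdf
#'   facet_wrap geom_text
NULL

#' Plot per-run cross-validation metrics
#'
#' Boxplot of the per-run F-measure, precision, recall and auROC of a
#' [repeated_cv()] result.
#'
#' @param object A `binding_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binding_eval
#' @export
autoplot.binding_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_run,
                              c("f_measure", "precision", "recall",
                                "auroc"),
                              names_to = "metric")
  ggplot(long, aes(x = .data$metric, y = .data$value)) +
    geom_boxplot() +
    labs(title = object$model_tag, x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot drop-column importances
#'
#' @param object An `importance_result` from
#'   [drop_column_importance()].
#' @param ... Unused.
#' @return A ggplot of normalized importance per feature.
#' @method autoplot importance_result
#' @export
autoplot.importance_result <- function(object, ...) {
  d <- dplyr::arrange(object, .data$normalized)
  d$feature <- factor(d$feature, levels = d$feature)
  ggplot(d, aes(x = .data$normalized, y = .data$feature)) +
    geom_col() +
    labs(x = "normalized accuracy drop", y = NULL) +
    theme_minimal()
}

#' Plot the cross-DBD transfer matrix
#'
#' Heat map of F-measures, training family on rows and test family on
#' columns, value printed in each cell.
#'
#' @param object A `cross_dbd` from [cross_dbd_eval()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cross_dbd
#' @export
autoplot.cross_dbd <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$test, y = .data$train,
                fill = .data$f_measure)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$f_measure))) +
    scale_fill_gradient2(midpoint = 0.5) +
    labs(x = "test family", y = "training family") +
    theme_minimal()
}

#' Plot coherence correlation distributions
#'
#' Empirical CDFs of the within-set pairwise lagged correlations of the
#' bound and unbound gene sets.
#'
#' @param object A `coherence_result` from [coherence_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coherence_result
#' @export
autoplot.coherence_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$correlation, colour = .data$set)) +
    stat_ecdf() +
    labs(x = "max single-lag |Spearman|", y = "ECDF") +
    theme_minimal()
}

#' Heat map of standardized per-TF model performance
#'
#' @param standardized Output of [standardize_performance()].
#' @return A ggplot, TFs on rows (ordered by group when present) and
#'   models on columns, fill = z-scored F-measure.
#' @export
plot_performance_heatmap <- function(standardized) {
  d <- standardized
  if ("group" %in% names(d)) {
    ord <- unique(d$tf[order(d$group)])
    d$tf <- factor(d$tf, levels = ord)
  }
  ggplot(d, aes(x = .data$model_tag, y = .data$tf, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2() +
    labs(x = NULL, y = NULL, fill = "z(F)") +
    theme_minimal()
}

#' Heat map of bound-versus-unbound feature comparisons
#'
#' Signed significance display of [compare_feature_distributions()]:
#' tiles colored by `direction * -log10(adjusted p)`.
#'
#' @param comparison Output of [compare_feature_distributions()].
#' @param cap Cap on `-log10(p)` for display, default 10.
#' @return A ggplot.
#' @export
plot_feature_comparison <- function(comparison, cap = 10) {
  d <- comparison
  d$signed <- d$direction * pmin(-log10(d$p_adjusted), cap)
  d$feature <- factor(d$feature, levels = feature_names())
  ggplot(d, aes(x = .data$feature, y = .data$tf, fill = .data$signed)) +
    geom_tile() +
    scale_fill_gradient2() +
    labs(x = NULL, y = NULL, fill = "sign x -log10(padj)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}
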