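roc_points <- function(truth, prob) {
  pos <- truth == "positive"
  ord <- order(prob, decreasing = TRUE)
  tibble::tibble(
    fpr = c(0, cumsum(!pos[ord]) / sum(!pos)),
    tpr = c(0, cumsum(pos[ord]) / sum(pos))
  )
}

#' ROC curves of pooled cross-validation predictions
#'
#' @param cv prediction tibble from [leave_one_patient_out_cv()] or the
#'   pooled `cv` element of [run_mil_pipeline()].
#' @return a ggplot.
#' @export
plot_cv_roc <- function(cv) {
  curves <- cv |>
    dplyr::group_by(.data$sv_type) |>
    dplyr::group_modify(~ roc_points(.x$truth, .x$prob)) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       colour = .data$sv_type)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "SV type",
                  title = "Leave-one-patient-out ROC") +
    ggplot2::theme_minimal()
}

#' @method autoplot tadmil_model
#' @export
autoplot.tadmil_model <- function(object, ...) {
  if (is.null(object$cv_predictions)) {
    stop("model carries no CV predictions to plot")
  }
  cv <- dplyr::mutate(object$cv_predictions,
                      sv_type = object$sv_type %||% "model")
  plot_cv_roc(cv)
}

#' Heatmap of instance-feature enrichment z-scores
#'
#' @param enrichment result of [instance_enrichment()], optionally with
#'   a `group` column (e.g. cancer type) for a multi-column heatmap.
#' @return a ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  if (is.null(enrichment$group)) enrichment$group <- "all"
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(.data$group,
                               factor(.data$feature,
                                      levels = rev(unique(.data$feature))),
                               fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z",
                  title = "Instance feature enrichment") +
    ggplot2::theme_minimal()
}

#' Heatmap of regulatory-swap z-scores
#'
#' @param swaps result of [regulatory_swap_analysis()], optionally with
#'   a `target` column when several target tissues are combined.
#' @return a ggplot.
#' @export
plot_swap <- function(swaps) {
  if (is.null(swaps[["target"]])) swaps$target <- "target"
  ggplot2::ggplot(swaps, ggplot2::aes(.data$source, .data$target,
                                      fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "Source tissue", y = "Target tissue", fill = "z",
                  title = "Regulatory-track swap effect") +
    ggplot2::theme_minimal()
}
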