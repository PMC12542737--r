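#' Plot methods for result types
#'
#' Each major result type has an `autoplot()` method (or `plot_*()`
#' helper) returning a ggplot.
#'
#' @name plots
NULL

#' Effect heatmap of drug-taxon associations
#'
#' Mirrors the per-drug association panels: taxa on the x axis, drugs on
#' the y axis, tiles colored by partial correlation (or log-odds), starred
#' at the chosen FDR cut.
#'
#' @param records Association records with `fdr_q`.
#' @param fdr_threshold Significance cut marked on the plot.
#' @return A ggplot.
#' @export
plot_associations <- function(records, fdr_threshold = 0.1) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$taxon_id, y = .data$drug_code,
                               fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      data = filter(records, .data$fdr_q <= fdr_threshold),
      label = "*", size = 3, na.rm = TRUE
    ) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @describeIn plot_associations Carryover hit counts per window.
#' @param object,x Result object.
#' @param ... Unused.
#' @method autoplot dm_carryover
#' @export
autoplot.dm_carryover <- function(object, fdr_threshold = 0.1, ...) {
  hits <- carryover_hits(object, fdr_threshold)
  ggplot2::ggplot(hits,
                  ggplot2::aes(x = factor(.data$window_years),
                               y = .data$n_hits, fill = .data$drug_code)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "last use more than (years) before sampling",
                  y = "significant associations", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_associations Per-drug proportions of winning additive
#'   models (M1/M2/M3).
#' @method autoplot dm_competing
#' @export
autoplot.dm_competing <- function(object, ...) {
  props <- summarize_best_models(object)
  ggplot2::ggplot(props,
                  ggplot2::aes(x = .data$drug_code, y = .data$proportion,
                               fill = .data$best_model)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "proportion of associations",
                  fill = "best model") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' @describeIn plot_associations Conditional explained variance per
#'   selected factor.
#' @method autoplot dm_partition
#' @export
autoplot.dm_partition <- function(object, ...) {
  d <- filter(as_tibble(object), .data$selected)
  ggplot2::ggplot(d,
                  ggplot2::aes(x = stats::reorder(.data$factor_id, .data$conditional_r2),
                               y = .data$conditional_r2,
                               fill = .data$factor_group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "conditional R²", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_associations Per-repeat transfer AUROC.
#' @method autoplot dm_transfer
#' @export
autoplot.dm_transfer <- function(object, ...) {
  d <- object$repeats
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$repeat_id), y = .data$auroc)) +
    ggplot2::geom_col(fill = "#4292C6") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "repeat", y = "transfer AUROC") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
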