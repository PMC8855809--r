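#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a burden test result
#'
#' Fold-enrichment bars with the observed/expected counts and p-value
#' annotated.
#'
#' @param object A `burden_result` tibble (rows may be several classes
#'   or sets bound together).
#' @param ... Unused.
#' @method autoplot burden_result
#' @export
autoplot.burden_result <- function(object, ...) {
  d <- as_tibble(unclass(object)) |>
    mutate(label = sprintf("O=%d E=%.2f p=%.2g", observed, expected, p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = interaction(variant_class, gene_set,
                                                  sep = " / "),
                                  y = fold)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = label), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "fold enrichment (O/E)",
                  title = "De novo mutation burden") +
    ggplot2::theme_minimal()
}

#' Plot module enrichment results
#'
#' -log10 p per module, faceted by target set, with the FDR < 0.10
#' threshold line when q-values are present.
#'
#' @param object An `enrichment_result` tibble.
#' @param ... Unused.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- as_tibble(unclass(object))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = module, y = -log10(p_value))) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::facet_wrap(~target_set) +
    ggplot2::labs(x = "module", y = "-log10 hypergeometric p") +
    ggplot2::theme_minimal()
  if ("q_value" %in% names(d) && any(d$q_value < 0.1)) {
    sig <- d |> filter(q_value < 0.1)
    p <- p + ggplot2::geom_point(data = sig, shape = 8,
                                 ggplot2::aes(y = -log10(p_value) + 0.15))
  }
  p
}

#' Heatmap of aggregate module scores across stages
#'
#' @param scores Tibble from [aggregate_module_scores()].
#' @return A ggplot object.
#' @export
plot_module_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = stage, y = module, fill = score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "differentiation stage", y = "coexpression module",
                  fill = "aggregate\nscore") +
    ggplot2::theme_minimal()
}
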