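# ggplot2 summaries of enrichment results and networks.

#' Plot enrichment results
#'
#' `"bubble"` shows the richness factor on the x-axis with bubble size the
#' overlap count and colour the p-value (the conventional pathway-enrichment
#' bubble chart); `"bar"` shows -LgP bars per set, filled by direction.
#'
#' @param results Enrichment tibble from [enrich()].
#' @param type `"bubble"` or `"bar"`.
#' @param top_n Sets shown per direction (by ascending p).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, type = c("bubble", "bar"), top_n = 10L) {
  type <- match.arg(type)
  assert_cols(results,
              c("set_id", "p_value", "richness_factor", "neg_log_p",
                "direction", "k"),
              "results")
  shown <- results |>
    group_by(.data$direction) |>
    dplyr::slice_min(.data$p_value, n = top_n, with_ties = FALSE) |>
    ungroup() |>
    mutate(set_id = stats::reorder(.data$set_id, .data$neg_log_p))
  if (type == "bubble") {
    ggplot2::ggplot(shown,
                    ggplot2::aes(x = .data$richness_factor, y = .data$set_id)) +
      ggplot2::geom_point(ggplot2::aes(size = .data$k,
                                       colour = .data$p_value)) +
      ggplot2::scale_colour_gradient(low = "#b2182b", high = "#2166ac") +
      ggplot2::facet_wrap(ggplot2::vars(.data$direction), scales = "free_y") +
      ggplot2::labs(x = "richness factor", y = NULL, size = "genes",
                    colour = "P value")
  } else {
    ggplot2::ggplot(shown,
                    ggplot2::aes(x = .data$neg_log_p, y = .data$set_id,
                                 fill = .data$direction)) +
      ggplot2::geom_col() +
      ggplot2::scale_fill_manual(values = c(up = "#b2182b",
                                            down = "#2166ac")) +
      ggplot2::labs(x = "-LgP", y = NULL, fill = NULL)
  }
}

#' Plot a CNC network
#'
#' Simple force-directed layout: squares for miRNAs, circled points for
#' lncRNAs, plain points for mRNAs; red up, blue down; dashed edges are
#' negative correlations.
#'
#' @param object A `cnc_network`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cnc_network <- function(object, ...) {
  if (nrow(object$nodes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  g <- as.igraph(object)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |> mutate(x = xy[, 1], y = xy[, 2])
  pos <- setNames(seq_len(nrow(nodes)), nodes$gene_id)
  edges <- object$edges |>
    mutate(
      x = nodes$x[pos[.data$gene_a]], y = nodes$y[pos[.data$gene_a]],
      xend = nodes$x[pos[.data$gene_b]], yend = nodes$y[pos[.data$gene_b]],
      sign = ifelse(is.na(.data$r) | .data$r < 0, "negative", "positive")
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$sign),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$direction,
                   shape = .data$gene_class, size = .data$degree)
    ) +
    ggplot2::scale_colour_manual(values = c(up = "#b2182b", down = "#2166ac")) +
    ggplot2::scale_shape_manual(values = c(miRNA = 15, lncRNA = 10,
                                           mRNA = 16)) +
    ggplot2::scale_linetype_manual(values = c(negative = "dashed",
                                              positive = "solid")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "direction", shape = "class", size = "degree")
}
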