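# broom-style tidiers for the pipeline's result objects.

#' Tidy a CNC network into its edge table
#'
#' @param x A `cnc_network`.
#' @param ... Ignored.
#' @return Tibble of edges with both node classes and directions attached.
#' @export
tidy.cnc_network <- function(x, ...) {
  node_info <- x$nodes |> select("gene_id", "gene_class", "direction")
  x$edges |>
    left_join(node_info |> rename(class_a = "gene_class",
                                  direction_a = "direction"),
              by = c(gene_a = "gene_id")) |>
    left_join(node_info |> rename(class_b = "gene_class",
                                  direction_b = "direction"),
              by = c(gene_b = "gene_id")) |>
    as_tibble()
}

#' One-row summary of a CNC network
#'
#' @param x A `cnc_network`.
#' @param ... Ignored.
#' @return Tibble with node/edge counts by class and type and the threshold.
#' @export
glance.cnc_network <- function(x, ...) {
  cls <- table(factor(x$nodes$gene_class, levels = GENE_CLASSES))
  typ <- table(factor(x$edges$edge_type,
                      levels = c("miRNA-mRNA", "miRNA-lncRNA", "lncRNA-mRNA")))
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_mirna = as.integer(cls[["miRNA"]]),
    n_lncrna = as.integer(cls[["lncRNA"]]),
    n_mrna = as.integer(cls[["mRNA"]]),
    n_mirna_mrna = as.integer(typ[["miRNA-mRNA"]]),
    n_mirna_lncrna = as.integer(typ[["miRNA-lncRNA"]]),
    n_lncrna_mrna = as.integer(typ[["lncRNA-mRNA"]]),
    threshold = x$threshold, mrna_mode = x$mrna_mode
  )
}

#' Tidy a core selection into a long component table
#'
#' @param x A `cnc_core`.
#' @param ... Ignored.
#' @return Tibble with `component` and `gene_id`.
#' @export
tidy.cnc_core <- function(x, ...) {
  bind_rows(
    if (!is.null(x$core_genes)) tibble(component = "core_gene",
                                       gene_id = x$core_genes),
    tibble(component = "sub_core_mrna", gene_id = x$sub_core_mrnas),
    tibble(component = "core_mirna", gene_id = x$core_mirnas),
    tibble(component = "core_lncrna", gene_id = x$core_lncrnas)
  )
}

#' One-row summary of a core selection
#'
#' @param x A `cnc_core`.
#' @param ... Ignored.
#' @return Tibble of component sizes and core-network counts.
#' @export
glance.cnc_core <- function(x, ...) {
  tibble(
    n_core_genes = length(x$core_genes %||% character(0)),
    n_sub_core_mrnas = length(x$sub_core_mrnas),
    n_core_mirnas = length(x$core_mirnas),
    n_core_lncrnas = length(x$core_lncrnas),
    n_core_total = length(x$sub_core_mrnas) + length(x$core_mirnas) +
      length(x$core_lncrnas),
    n_core_edges = nrow(x$network$edges)
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `cnc_run`.
#' @param ... Ignored.
#' @return Tibble of the headline counts of every stage.
#' @export
glance.cnc_run <- function(x, ...) {
  sig <- x$de |> filter(.data$significant)
  n_sig <- function(cls, dir = NULL) {
    rows <- sig$gene_class == cls
    if (!is.null(dir)) rows <- rows & sig$direction == dir
    sum(rows)
  }
  tibble(
    n_de_mirna = n_sig("miRNA"),
    n_de_mirna_up = n_sig("miRNA", "up"),
    n_de_mirna_down = n_sig("miRNA", "down"),
    n_de_lncrna = n_sig("lncRNA"),
    n_de_lncrna_up = n_sig("lncRNA", "up"),
    n_de_lncrna_down = n_sig("lncRNA", "down"),
    n_candidates = nrow(x$candidates),
    n_candidates_up = sum(x$candidates$direction == "up"),
    n_candidates_down = sum(x$candidates$direction == "down"),
    n_network_edges = nrow(x$network$edges),
    n_selected_mrnas = nrow(x$selected_mrnas),
    n_go_genes = length(x$go_genes),
    n_kegg_genes = length(x$kegg_genes)
  ) |>
    bind_cols(glance(x$core))
}
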