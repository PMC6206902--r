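# Core-gene funnel: GO/KEGG intersection -> reference filter -> core network.

#' Intersect GO-derived and KEGG-derived gene sets
#'
#' @param go_genes,kegg_genes Character vectors of gene ids from the two
#'   enrichment analyses (e.g. [genes_from_significant_sets()]).
#' @return Sorted character vector of genes present in both.
#' @export
intersect_core <- function(go_genes, kegg_genes) {
  sort(intersect(unique(as.character(go_genes)),
                 unique(as.character(kegg_genes))))
}

#' Filter core genes by a curated reference list
#'
#' Matching is case-insensitive after whitespace stripping (curated lists mix
#' symbol casings); the returned ids keep the casing used in `core`.
#'
#' @param core Character vector of core gene ids.
#' @param reference Nonempty character vector of reference gene ids (e.g. a
#'   curated osteogenesis gene list).
#' @return Sorted character vector of core genes present in the reference.
#' @export
filter_by_reference <- function(core, reference) {
  reference <- trimws(as.character(reference))
  reference <- reference[nzchar(reference)]
  if (length(reference) == 0L) {
    abort("`reference` is empty: supply a curated reference gene list.")
  }
  core <- unique(as.character(core))
  sort(core[tolower(trimws(core)) %in% tolower(reference)])
}

#' Extract the core CNC network around sub-core mRNAs
#'
#' Takes the induced subgraph on the sub-core mRNAs plus all their miRNA and
#' lncRNA network neighbours. With `lncrna_adjacency = "shared_mirna"`,
#' lncRNAs adjacent to the core miRNAs are also pulled in (for networks in
#' which lncRNAs attach to mRNAs only through shared miRNAs).
#'
#' @param net A `cnc_network`.
#' @param sub_core Character vector of sub-core mRNA ids.
#' @param lncrna_adjacency `"direct"` (default) or `"shared_mirna"`.
#' @return A `cnc_core` list: `sub_core_mrnas`, `core_mirnas`, `core_lncrnas`
#'   (sorted, deduplicated) and `network`, the induced `cnc_network`.
#' @export
extract_core_network <- function(net, sub_core,
                                 lncrna_adjacency = c("direct", "shared_mirna")) {
  stopifnot(inherits(net, "cnc_network"))
  lncrna_adjacency <- match.arg(lncrna_adjacency)
  sub_core <- sort(unique(as.character(sub_core)))
  present <- intersect(sub_core, net$nodes$gene_id[net$nodes$gene_class == "mRNA"])
  if (length(present) == 0L) {
    warn("No sub-core mRNA is present in the network; core network is empty.")
  }
  touches <- function(ids) {
    net$edges$gene_a %in% ids | net$edges$gene_b %in% ids
  }
  neighbours_of <- function(ids) {
    e <- net$edges[touches(ids), , drop = FALSE]
    setdiff(unique(c(e$gene_a, e$gene_b)), ids)
  }
  class_of <- setNames(net$nodes$gene_class, net$nodes$gene_id)
  nbr <- neighbours_of(present)
  core_mirnas <- sort(nbr[class_of[nbr] == "miRNA"])
  core_lncrnas <- sort(nbr[class_of[nbr] == "lncRNA"])
  if (lncrna_adjacency == "shared_mirna" && length(core_mirnas) > 0L) {
    nbr2 <- neighbours_of(core_mirnas)
    core_lncrnas <- sort(unique(c(core_lncrnas,
                                  nbr2[class_of[nbr2] == "lncRNA"])))
  }
  keep <- c(present, core_mirnas, core_lncrnas)
  edges <- net$edges |>
    filter(.data$gene_a %in% keep & .data$gene_b %in% keep)
  nodes <- net$nodes |> filter(.data$gene_id %in% keep)
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = nodes$gene_id))
  nodes$degree <- as.integer(deg[nodes$gene_id])
  sub_net <- structure(
    list(nodes = nodes, edges = edges, threshold = net$threshold,
         mrna_mode = net$mrna_mode),
    class = "cnc_network"
  )
  validate_cnc_network(sub_net)
  structure(
    list(sub_core_mrnas = present, core_mirnas = core_mirnas,
         core_lncrnas = core_lncrnas, network = sub_net,
         lncrna_adjacency = lncrna_adjacency),
    class = "cnc_core"
  )
}

#' Run the full core-gene funnel
#'
#' Chains [intersect_core()], [filter_by_reference()] and
#' [extract_core_network()]: genes supported by both enrichment analyses are
#' the core genes, those also present in the curated reference list are the
#' sub-core mRNAs, and the sub-core neighbourhood of the CNC network is the
#' core network.
#'
#' @inheritParams extract_core_network
#' @param go_genes,kegg_genes Gene sets from the two enrichment analyses.
#' @param reference Curated reference gene list.
#' @return A `cnc_core` with the additional element `core_genes`
#'   (the GO/KEGG intersection).
#' @export
core_selection <- function(go_genes, kegg_genes, reference, net,
                           lncrna_adjacency = c("direct", "shared_mirna")) {
  core_genes <- intersect_core(go_genes, kegg_genes)
  sub_core <- filter_by_reference(core_genes, reference)
  out <- extract_core_network(net, sub_core, lncrna_adjacency)
  out$core_genes <- core_genes
  out
}

#' @export
print.cnc_core <- function(x, ...) {
  cat("<cnc_core>\n")
  if (!is.null(x$core_genes)) {
    cat(sprintf("  core genes (GO ∩ KEGG): %d\n", length(x$core_genes)))
  }
  cat(sprintf("  sub-core mRNAs: %d | core miRNAs: %d | core lncRNAs: %d\n",
              length(x$sub_core_mrnas), length(x$core_mirnas),
              length(x$core_lncrnas)))
  cat(sprintf("  core network: %d nodes, %d edges\n",
              nrow(x$network$nodes), nrow(x$network$edges)))
  invisible(x)
}
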