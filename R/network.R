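# Coding-noncoding co-expression network construction.
#
# Edges join genes of different classes whose expression profiles correlate
# beyond a strict |r| cut, with a sign rule per edge type encoding negative
# regulation: miRNA edges must be negative (and miRNA-mRNA edges additionally
# need a predicted binding site), lncRNA-mRNA edges must be positive.

#' Pearson correlation between two expression profiles
#'
#' Thin checked wrapper around the product-moment correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3, both nonconstant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Need at least 3 paired samples.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined for a constant profile.")
  }
  cor(x, y, method = "pearson")
}

#' Cross-class correlations among genes of interest
#'
#' Computes Pearson r across all samples (both groups pooled) for every pair
#' of listed genes belonging to different classes; within-class pairs are
#' skipped. Genes with a constant profile are excluded with a warning.
#'
#' @param expr Log2-scale expression tibble.
#' @param genes Tibble with `gene_id` and `gene_class` naming the genes to
#'   correlate (e.g. DE miRNAs, DE lncRNAs and candidate mRNAs).
#' @return Tibble: `gene_a`, `gene_b`, `class_a`, `class_b`, `r`,
#'   `n_samples`, with `gene_a`/`gene_b` in canonical class order
#'   (miRNA < lncRNA < mRNA, then id).
#' @export
cross_class_correlations <- function(expr, genes) {
  validate_expression(expr)
  assert_cols(genes, c("gene_id", "gene_class"), "genes")
  genes <- genes |> distinct(.data$gene_id, .data$gene_class)
  missing <- setdiff(genes$gene_id, expr$gene_id)
  if (length(missing) > 0L) {
    abort(sprintf("Gene(s) not in the expression table: %s.",
                  paste(head(missing, 5), collapse = ", ")))
  }
  m <- expr_matrix(expr)[genes$gene_id, , drop = FALSE]
  constant <- apply(m, 1L, sd) == 0
  if (any(constant)) {
    warn(sprintf(
      "%d constant gene(s) excluded from correlations: %s.",
      sum(constant), paste(head(rownames(m)[constant], 5), collapse = ", ")
    ))
    genes <- genes[!constant, ]
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(genes) < 2L) {
    return(tibble(gene_a = character(0), gene_b = character(0),
                  class_a = character(0), class_b = character(0),
                  r = numeric(0), n_samples = integer(0)))
  }
  genes <- genes |>
    mutate(rank = match(.data$gene_class, GENE_CLASSES)) |>
    arrange(.data$rank, .data$gene_id)
  cmat <- cor(t(m[genes$gene_id, , drop = FALSE]))
  idx <- which(upper.tri(cmat), arr.ind = TRUE)
  out <- tibble(
    gene_a = genes$gene_id[idx[, 1L]],
    gene_b = genes$gene_id[idx[, 2L]],
    class_a = genes$gene_class[idx[, 1L]],
    class_b = genes$gene_class[idx[, 2L]],
    r = cmat[idx],
    n_samples = ncol(m)
  ) |>
    filter(.data$class_a != .data$class_b) |>
    arrange(match(.data$class_a, GENE_CLASSES), .data$gene_a,
            match(.data$class_b, GENE_CLASSES), .data$gene_b)
  out
}

edge_type_of <- function(class_a, class_b) {
  key <- paste(pmin(match(class_a, GENE_CLASSES), match(class_b, GENE_CLASSES)),
               pmax(match(class_a, GENE_CLASSES), match(class_b, GENE_CLASSES)))
  c("1 2" = "miRNA-lncRNA", "1 3" = "miRNA-mRNA", "2 3" = "lncRNA-mRNA")[key]
}

#' Build the coding-noncoding co-expression network
#'
#' An edge is kept iff `|r|` strictly exceeds `threshold` and the class-
#' specific sign rule holds: miRNA–mRNA and miRNA–lncRNA edges require
#' `r < 0` (negative regulation), miRNA–mRNA edges additionally require a
#' supporting predicted target site, and lncRNA–mRNA edges require `r > 0`.
#' With `mrna_mode = "predicted"` (for studies where mRNAs were predicted,
#' not measured) miRNA–mRNA edges come from the target table plus opposite
#' predicted directions, with `r` recorded as missing, and no lncRNA–mRNA
#' edges are formed.
#'
#' @param corrs Correlation table from [cross_class_correlations()].
#' @param targets Target table from [predict_targets()] (support for
#'   miRNA–mRNA edges).
#' @param directions Tibble `gene_id`, `gene_class`, `direction` covering all
#'   network genes (DE results for measured classes, inferred directions for
#'   predicted mRNAs).
#' @param threshold Correlation magnitude cut, strict, in `(0, 1]`.
#' @param mrna_mode `"measured"` or `"predicted"`.
#' @return A `cnc_network`: list with `nodes` (tibble `gene_id`, `gene_class`,
#'   `direction`, `degree`), `edges` (tibble `gene_a`, `gene_b`, `edge_type`,
#'   `r`, `support`), and `threshold`.
#' @export
build_cnc_network <- function(corrs, targets, directions, threshold = 0.9,
                              mrna_mode = c("measured", "predicted")) {
  mrna_mode <- match.arg(mrna_mode)
  assert_scalar_num(threshold, "threshold", lower = 0, upper = 1,
                    strict_lower = TRUE)
  assert_cols(directions, c("gene_id", "gene_class", "direction"), "directions")
  assert_cols(targets, c("mirna_id", "target_id"), "targets")
  support_key <- paste(targets$mirna_id, targets$target_id)
  dir_of <- setNames(directions$direction, directions$gene_id)

  if (mrna_mode == "measured") {
    assert_cols(corrs, c("gene_a", "gene_b", "class_a", "class_b", "r"),
                "corrs")
    edges <- corrs |>
      mutate(
        edge_type = edge_type_of(.data$class_a, .data$class_b),
        support = ifelse(
          .data$edge_type == "miRNA-mRNA",
          paste(.data$gene_a, .data$gene_b) %in% support_key |
            paste(.data$gene_b, .data$gene_a) %in% support_key,
          NA
        )
      ) |>
      filter(
        abs(.data$r) > threshold,
        dplyr::case_when(
          .data$edge_type == "miRNA-mRNA" ~ .data$r < 0 & .data$support,
          .data$edge_type == "miRNA-lncRNA" ~ .data$r < 0,
          .data$edge_type == "lncRNA-mRNA" ~ .data$r > 0
        )
      ) |>
      select("gene_a", "gene_b", "edge_type", "r", "support")
  } else {
    mirna_corrs <- corrs |>
      filter(.data$class_a != "mRNA", .data$class_b != "mRNA") |>
      mutate(edge_type = edge_type_of(.data$class_a, .data$class_b),
             support = NA) |>
      filter(abs(.data$r) > threshold, .data$r < 0) |>
      select("gene_a", "gene_b", "edge_type", "r", "support")
    pred_edges <- targets |>
      filter(.data$mirna_id %in% names(dir_of),
             .data$target_id %in% names(dir_of)) |>
      filter(dir_of[.data$mirna_id] != dir_of[.data$target_id]) |>
      mutate(edge_type = "miRNA-mRNA", r = NA_real_, support = TRUE) |>
      select(gene_a = "mirna_id", gene_b = "target_id", "edge_type", "r",
             "support")
    edges <- bind_rows(mirna_corrs, pred_edges)
  }

  node_ids <- unique(c(edges$gene_a, edges$gene_b))
  missing_dir <- setdiff(node_ids, directions$gene_id)
  if (length(missing_dir) > 0L) {
    abort(sprintf("Network gene(s) without a direction: %s.",
                  paste(head(missing_dir, 5), collapse = ", ")))
  }
  nodes <- directions |>
    filter(.data$gene_id %in% node_ids) |>
    distinct(.data$gene_id, .data$gene_class, .data$direction)
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = nodes$gene_id))
  nodes$degree <- as.integer(deg[nodes$gene_id])
  nodes <- nodes |>
    arrange(match(.data$gene_class, GENE_CLASSES), .data$gene_id)
  edges <- edges |> arrange(.data$edge_type, .data$gene_a, .data$gene_b)

  net <- structure(
    list(nodes = nodes, edges = edges, threshold = threshold,
         mrna_mode = mrna_mode),
    class = "cnc_network"
  )
  validate_cnc_network(net)
  net
}

# exhaustive post-construction check of the edge predicate and handshake law
validate_cnc_network <- function(net) {
  e <- net$edges
  if (nrow(e) > 0L) {
    measured <- !is.na(e$r)
    stopifnot(
      all(abs(e$r[measured]) > net$threshold),
      all(e$r[measured & e$edge_type != "lncRNA-mRNA"] < 0),
      all(e$r[measured & e$edge_type == "lncRNA-mRNA"] > 0),
      all(e$support[e$edge_type == "miRNA-mRNA"]),
      all(e$gene_a != e$gene_b)
    )
  }
  stopifnot(sum(net$nodes$degree) == 2L * nrow(e))
  invisible(net)
}

#' @export
print.cnc_network <- function(x, ...) {
  cat("<cnc_network>\n")
  cat(sprintf("  %d nodes (%s)\n", nrow(x$nodes),
              paste(sprintf("%d %s", table(factor(x$nodes$gene_class,
                                                  levels = GENE_CLASSES)),
                            GENE_CLASSES), collapse = ", ")))
  cat(sprintf("  %d edges, |r| > %g (%s mRNA mode)\n", nrow(x$edges),
              x$threshold, x$mrna_mode))
  invisible(x)
}

#' Convert a CNC network to an igraph graph
#'
#' Node attributes: `gene_class`, `direction`, `degree`; edge attributes:
#' `edge_type`, `r`, `support`.
#'
#' @param x A `cnc_network`.
#' @param ... Ignored.
#' @return An undirected [igraph::igraph] graph.
#' @export
as.igraph.cnc_network <- function(x, ...) {
  igraph::graph_from_data_frame(
    d = x$edges,
    directed = FALSE,
    vertices = x$nodes |> select("gene_id", "gene_class", "direction", "degree")
  )
}

#' Select mRNAs from the network by degree
#'
#' @param net A `cnc_network`.
#' @param min_degree Minimum number of incident edges.
#' @return Tibble of mRNA nodes (`gene_id`, `direction`, `degree`) with
#'   `degree >= min_degree`, sorted by descending degree then id.
#' @export
select_mrnas_by_degree <- function(net, min_degree = 1L) {
  stopifnot(inherits(net, "cnc_network"))
  min_degree <- assert_count(min_degree, "min_degree", 0L)
  net$nodes |>
    filter(.data$gene_class == "mRNA", .data$degree >= min_degree) |>
    arrange(desc(.data$degree), .data$gene_id) |>
    select("gene_id", "direction", "degree")
}
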