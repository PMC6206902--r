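# End-to-end pipeline: (simulate | load) -> differential expression ->
# target prediction -> CNC network -> enrichment -> core-gene funnel.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its documented default.
#' Unknown arguments are rejected. When `simulate = TRUE` the inputs come
#' from [simulate_study()] under `sim`; otherwise the `*_path` arguments name
#' the input files.
#'
#' @param simulate Generate inputs with the synthetic module (default) or
#'   read them from the `*_path` files.
#' @param sim A [sim_spec()] used when `simulate = TRUE`; its `rng_seed` is
#'   the run seed.
#' @param expression_path,groups_path,mirna_fasta,utr_fasta,go_gmt,kegg_gmt,reference_path
#'   Input files used when `simulate = FALSE`.
#' @param floor Intensity clamp before the log2 transform.
#' @param normalization `"log2"` or `"quantile"` (see [log2_normalize()]).
#' @param alpha Differential-expression significance threshold.
#' @param de_correction `"none"` or `"BH"`.
#' @param scheme Alignment [scoring_scheme()].
#' @param energy Duplex [energy_model()].
#' @param cor_threshold Correlation magnitude cut for network edges (strict).
#' @param min_degree Minimum degree for mRNA selection.
#' @param enrich_alpha Enrichment significance threshold.
#' @param enrich_correction `"none"` or `"BH"`.
#' @param mrna_mode `"measured"` or `"predicted"` (see [build_cnc_network()]).
#' @param lncrna_adjacency `"direct"` or `"shared_mirna"` (see
#'   [extract_core_network()]).
#' @return A `cnc_config` list.
#' @export
cnc_config <- function(simulate = TRUE, sim = sim_spec(),
                       expression_path = NULL, groups_path = NULL,
                       mirna_fasta = NULL, utr_fasta = NULL,
                       go_gmt = NULL, kegg_gmt = NULL, reference_path = NULL,
                       floor = 1, normalization = "log2",
                       alpha = 0.05, de_correction = "none",
                       scheme = scoring_scheme(), energy = energy_model(),
                       cor_threshold = 0.9, min_degree = 1L,
                       enrich_alpha = 0.05, enrich_correction = "none",
                       mrna_mode = "measured",
                       lncrna_adjacency = "direct") {
  stopifnot(inherits(sim, "cnc_sim_spec"), inherits(scheme, "cnc_scheme"))
  normalization <- match.arg(normalization, c("log2", "quantile"))
  de_correction <- match.arg(de_correction, c("none", "BH"))
  enrich_correction <- match.arg(enrich_correction, c("none", "BH"))
  mrna_mode <- match.arg(mrna_mode, c("measured", "predicted"))
  lncrna_adjacency <- match.arg(lncrna_adjacency, c("direct", "shared_mirna"))
  assert_scalar_num(cor_threshold, "cor_threshold", lower = 0, upper = 1,
                    strict_lower = TRUE)
  if (!simulate) {
    paths <- list(expression_path, groups_path, mirna_fasta, utr_fasta,
                  go_gmt, kegg_gmt, reference_path)
    if (any(vapply(paths, is.null, logical(1)))) {
      abort("With `simulate = FALSE` all input paths must be supplied.")
    }
  }
  structure(
    list(simulate = simulate, sim = sim,
         expression_path = expression_path, groups_path = groups_path,
         mirna_fasta = mirna_fasta, utr_fasta = utr_fasta,
         go_gmt = go_gmt, kegg_gmt = kegg_gmt,
         reference_path = reference_path,
         floor = floor, normalization = normalization,
         alpha = alpha, de_correction = de_correction,
         scheme = scheme, energy = energy,
         cor_threshold = cor_threshold,
         min_degree = assert_count(min_degree, "min_degree", 0L),
         enrich_alpha = enrich_alpha, enrich_correction = enrich_correction,
         mrna_mode = mrna_mode, lncrna_adjacency = lncrna_adjacency),
    class = "cnc_config"
  )
}

flatten_listcol <- function(df) {
  is_list <- vapply(df, is.list, logical(1))
  df[is_list] <- lapply(df[is_list], function(col) {
    vapply(col, paste, character(1), collapse = ";")
  })
  df
}

#' Run the full CNC analysis pipeline
#'
#' Executes simulate/load -> normalization -> two-group differential
#' expression (miRNA, lncRNA and, in measured mode, mRNA) -> seeded
#' Smith-Waterman target prediction for the significant miRNAs -> candidate
#' direction inference by negative regulation -> cross-class Pearson
#' correlations -> CNC network construction and degree-based mRNA selection
#' -> per-direction GO and KEGG over-representation -> core-gene funnel.
#' Every intermediate table is written under `out_dir` together with a
#' manifest sufficient to reproduce the run byte-for-byte.
#'
#' @param config A [cnc_config()].
#' @param out_dir Output directory (created if needed); `inputs/` holds the
#'   (simulated or copied) inputs, `results/` the result tables.
#' @return A `cnc_run` list with all intermediate objects and `out_dir`.
#' @export
run_pipeline <- function(config = cnc_config(), out_dir) {
  stopifnot(inherits(config, "cnc_config"))
  inputs_dir <- file.path(out_dir, "inputs")
  results_dir <- file.path(out_dir, "results")
  dir.create(inputs_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- inputs ----
  if (config$simulate) {
    study <- simulate_study(config$sim)
    expr <- study$expression
    groups <- study$groups
    mirnas <- study$mirnas
    utrs <- study$utrs
    go <- study$go
    kegg <- study$kegg
    reference <- study$reference
    write_expression(expr, file.path(inputs_dir, "expression.tsv"))
    write_groups(groups, file.path(inputs_dir, "groups.tsv"))
    write_fasta(mirnas, file.path(inputs_dir, "mirnas.fasta"))
    write_fasta(utrs, file.path(inputs_dir, "utrs.fasta"))
    write_gmt(go, file.path(inputs_dir, "go.gmt"))
    write_gmt(kegg, file.path(inputs_dir, "kegg.gmt"))
    write_gene_list(reference, file.path(inputs_dir, "reference.txt"))
    readr::write_tsv(study$truth$de_genes,
                     file.path(inputs_dir, "truth_de_genes.tsv"))
    readr::write_tsv(study$truth$target_pairs,
                     file.path(inputs_dir, "truth_target_pairs.tsv"))
    readr::write_tsv(study$truth$enriched_sets,
                     file.path(inputs_dir, "truth_enriched_sets.tsv"))
  } else {
    study <- NULL
    expr <- read_expression(config$expression_path)
    groups <- read_groups(config$groups_path)
    mirnas <- read_fasta(config$mirna_fasta)
    utrs <- read_fasta(config$utr_fasta)
    go <- read_gmt(config$go_gmt)
    kegg <- read_gmt(config$kegg_gmt)
    reference <- read_gene_list(config$reference_path)
  }

  # ---- differential expression ----
  norm <- log2_normalize(expr, floor = config$floor,
                         method = config$normalization)
  de_classes <- if (config$mrna_mode == "measured") GENE_CLASSES
  else c("miRNA", "lncRNA")
  de <- differential_expression(norm, groups, alpha = config$alpha,
                                correction = config$de_correction,
                                classes = de_classes)
  de_mirna <- de |> filter(.data$gene_class == "miRNA")
  de_lncrna <- de |> filter(.data$gene_class == "lncRNA")
  readr::write_tsv(de_mirna, file.path(results_dir, "de_mirna.tsv"))
  readr::write_tsv(de_lncrna, file.path(results_dir, "de_lncrna.tsv"))
  if (config$mrna_mode == "measured") {
    readr::write_tsv(de |> filter(.data$gene_class == "mRNA"),
                     file.path(results_dir, "de_mrna.tsv"))
  }

  # ---- target prediction for significant miRNAs ----
  sig_mirnas <- de_mirna$gene_id[de_mirna$significant]
  sig_mirnas <- intersect(sig_mirnas, names(mirnas))
  if (length(sig_mirnas) == 0L) {
    abort("No significant miRNA with a sequence; cannot predict targets.")
  }
  sites <- scan_sites(mirnas[sig_mirnas], utrs, config$scheme, config$energy)
  target_table <- predict_targets(mirnas[sig_mirnas], utrs, config$scheme,
                                  config$energy, sites = sites)
  candidates <- infer_candidate_directions(de_mirna, target_table)
  readr::write_tsv(sites, file.path(results_dir, "target_sites.tsv"))
  readr::write_tsv(target_table, file.path(results_dir, "target_table.tsv"))
  readr::write_tsv(candidates, file.path(results_dir, "candidates.tsv"))

  # ---- correlations and network ----
  sig_lncrnas <- de_lncrna$gene_id[de_lncrna$significant]
  cor_genes <- bind_rows(
    tibble(gene_id = sig_mirnas, gene_class = "miRNA"),
    tibble(gene_id = sig_lncrnas, gene_class = "lncRNA"),
    if (config$mrna_mode == "measured") {
      tibble(gene_id = candidates$gene_id, gene_class = "mRNA")
    }
  )
  corrs <- cross_class_correlations(norm, cor_genes)
  directions <- bind_rows(
    de |> filter(.data$significant, .data$gene_class != "mRNA") |>
      select("gene_id", "gene_class", "direction"),
    candidates |> select("gene_id", "gene_class", "direction")
  )
  net <- build_cnc_network(corrs, target_table, directions,
                           threshold = config$cor_threshold,
                           mrna_mode = config$mrna_mode)
  selected <- select_mrnas_by_degree(net, config$min_degree)
  readr::write_tsv(corrs, file.path(results_dir, "correlations.tsv"))
  write_network(net, file.path(results_dir, "network_edges.tsv"), "tsv")
  write_network(net, file.path(results_dir, "network.graphml"), "graphml")
  readr::write_tsv(selected, file.path(results_dir, "network_mrnas.tsv"))

  # ---- enrichment, per direction ----
  dir_of <- setNames(selected$direction, selected$gene_id)
  query_up <- selected$gene_id[selected$direction == "up"]
  query_down <- selected$gene_id[selected$direction == "down"]
  run_enrich <- function(collection) {
    bind_rows(
      enrich(query_up, collection, config$enrich_alpha, "up",
             config$enrich_correction),
      enrich(query_down, collection, config$enrich_alpha, "down",
             config$enrich_correction)
    )
  }
  enr_go <- run_enrich(go)
  enr_kegg <- run_enrich(kegg)
  readr::write_tsv(flatten_listcol(enr_go),
                   file.path(results_dir, "enrichment_go.tsv"))
  readr::write_tsv(flatten_listcol(enr_kegg),
                   file.path(results_dir, "enrichment_kegg.tsv"))
  genes_of <- function(enr) {
    sort(unique(c(
      genes_from_significant_sets(enr |> filter(.data$direction == "up"),
                                  query_up),
      genes_from_significant_sets(enr |> filter(.data$direction == "down"),
                                  query_down)
    )))
  }
  go_genes <- genes_of(enr_go)
  kegg_genes <- genes_of(enr_kegg)

  # ---- core funnel ----
  core <- core_selection(go_genes, kegg_genes, reference, net,
                         config$lncrna_adjacency)
  core_report <- bind_rows(
    tibble(component = "core_gene", gene_id = core$core_genes),
    tibble(component = "sub_core_mrna", gene_id = core$sub_core_mrnas),
    tibble(component = "core_mirna", gene_id = core$core_mirnas),
    tibble(component = "core_lncrna", gene_id = core$core_lncrnas)
  ) |>
    mutate(direction = dplyr::coalesce(
      dir_of[.data$gene_id],
      setNames(directions$direction, directions$gene_id)[.data$gene_id]
    ))
  readr::write_tsv(core_report, file.path(results_dir, "core_selection.tsv"))
  write_network(core$network,
                file.path(results_dir, "core_network_edges.tsv"), "tsv")
  write_network(core$network,
                file.path(results_dir, "core_network.graphml"), "graphml")

  # ---- manifest ----
  manifest <- list(
    tool = "cncnet", version = as.character(packageVersion("cncnet")),
    rng_seed = if (config$simulate) config$sim$rng_seed else NA,
    config = config_as_list(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(
    list(config = config, out_dir = out_dir, study = study,
         expression = norm, groups = groups, de = de,
         sites = sites, target_table = target_table, candidates = candidates,
         correlations = corrs, network = net, selected_mrnas = selected,
         enrichment_go = enr_go, enrichment_kegg = enr_kegg,
         go_genes = go_genes, kegg_genes = kegg_genes, core = core),
    class = "cnc_run"
  )
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$scheme <- unclass(out$scheme)
  out
}

#' @export
print.cnc_run <- function(x, ...) {
  cat("<cnc_run>", x$out_dir, "\n")
  sig <- x$de |> filter(.data$significant) |> count(.data$gene_class)
  cat("  significant DE:",
      paste(sprintf("%s %d", sig$gene_class, sig$n), collapse = ", "), "\n")
  cat(sprintf("  candidates: %d | network: %d nodes / %d edges\n",
              nrow(x$candidates), nrow(x$network$nodes),
              nrow(x$network$edges)))
  cat(sprintf("  core: %d GO∩KEGG genes -> %d sub-core mRNAs, %d miRNAs, %d lncRNAs\n",
              length(x$core$core_genes), length(x$core$sub_core_mrnas),
              length(x$core$core_mirnas), length(x$core$core_lncrnas)))
  invisible(x)
}
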