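# Synthetic two-group microarray study with planted ground truth.
#
# The generator emulates the study design the pipeline targets: a small
# two-group experiment (control vs induced, >= 3 replicates each) measuring
# miRNAs, lncRNAs and mRNAs, with planted differentially expressed genes,
# planted miRNA->mRNA regulations realised both as anticorrelated expression
# profiles and as exact-complement 3'UTR binding sites, gene-set collections
# enriched for the planted differential genes, and a curated-style reference
# gene list. Every planted feature is recorded in a truth table so downstream
# stages can be tested for recovery.

#' Specification of a synthetic study
#'
#' @param n_mirna,n_lncrna,n_mrna Number of genes per class.
#' @param n_ctrl,n_induced Replicates per group (>= 2).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-gene
#'   baseline intensities on the log2 scale.
#' @param de_fraction_per_class Fraction of genes per class planted as
#'   differentially expressed (directions alternate up/down).
#' @param planted_log2fc Magnitude of the planted effect, log2 units.
#' @param noise_sd Within-group residual standard deviation, log2 units.
#' @param n_target_pairs Number of planted miRNA->mRNA regulations. Each pair
#'   couples a DE miRNA to a DE mRNA of opposite direction: the target's log2
#'   profile is the mirror image of its regulator's plus a small independent
#'   perturbation (sd `0.2 * noise_sd`), and the target's UTR carries an
#'   exact-complement binding site.
#' @param mirna_length miRNA length in nucleotides.
#' @param utr_length 3'UTR length in nucleotides (>= `mirna_length`).
#' @param n_genesets Gene sets per collection.
#' @param geneset_size Members per gene set.
#' @param enriched_fraction Fraction of an enriched set's members drawn from
#'   planted DE mRNAs (planted targets first).
#' @param rng_seed Integer seed; stage-specific substreams are derived from it
#'   and it is echoed into all outputs.
#' @return A validated `cnc_sim_spec` list.
#' @export
sim_spec <- function(n_mirna = 60L, n_lncrna = 80L, n_mrna = 400L,
                     n_ctrl = 3L, n_induced = 3L,
                     baseline_log2_mean = 8, baseline_log2_sd = 1.2,
                     de_fraction_per_class = 0.25, planted_log2fc = 2,
                     noise_sd = 0.25, n_target_pairs = 12L,
                     mirna_length = 22L, utr_length = 200L,
                     n_genesets = 20L, geneset_size = 20L,
                     enriched_fraction = 0.5, rng_seed = 20260901L) {
  spec <- list(
    n_mirna = assert_count(n_mirna, "n_mirna", 1L),
    n_lncrna = assert_count(n_lncrna, "n_lncrna", 1L),
    n_mrna = assert_count(n_mrna, "n_mrna", 1L),
    n_ctrl = assert_count(n_ctrl, "n_ctrl", 2L),
    n_induced = assert_count(n_induced, "n_induced", 2L),
    baseline_log2_mean = assert_scalar_num(baseline_log2_mean, "baseline_log2_mean"),
    baseline_log2_sd = assert_scalar_num(baseline_log2_sd, "baseline_log2_sd", 0),
    de_fraction_per_class = assert_scalar_num(de_fraction_per_class,
                                              "de_fraction_per_class", 0, 1),
    planted_log2fc = assert_scalar_num(planted_log2fc, "planted_log2fc", 0),
    noise_sd = assert_scalar_num(noise_sd, "noise_sd", 0, strict_lower = TRUE),
    n_target_pairs = assert_count(n_target_pairs, "n_target_pairs", 0L),
    mirna_length = assert_count(mirna_length, "mirna_length", 1L),
    utr_length = assert_count(utr_length, "utr_length", 1L),
    n_genesets = assert_count(n_genesets, "n_genesets", 0L),
    geneset_size = assert_count(geneset_size, "geneset_size", 1L),
    enriched_fraction = assert_scalar_num(enriched_fraction,
                                          "enriched_fraction", 0, 1),
    rng_seed = assert_count(rng_seed, "rng_seed", 0L)
  )
  if (spec$rng_seed > 2^31 - 100) abort("`rng_seed` too large (32-bit limit).")
  structure(spec, class = "cnc_sim_spec")
}

sim_gene_ids <- function(spec) {
  list(
    miRNA = sprintf("miR-%03d", seq_len(spec$n_mirna)),
    lncRNA = sprintf("lnc-%03d", seq_len(spec$n_lncrna)),
    mRNA = sprintf("gene-%03d", seq_len(spec$n_mrna))
  )
}

sim_sample_ids <- function(spec) {
  tibble(
    sample_id = c(sprintf("ctrl_%d", seq_len(spec$n_ctrl)),
                  sprintf("ind_%d", seq_len(spec$n_induced))),
    group = rep(c("control", "induced"), c(spec$n_ctrl, spec$n_induced))
  )
}

#' Simulate an expression matrix with planted structure
#'
#' Intensities are generated on the log2 scale and exponentiated, so the
#' differential-expression module's log2 transform inverts the generator
#' exactly. Planted DE genes differ in group mean by `planted_log2fc` on the
#' log2 scale; planted target genes mirror their regulator's profile (see
#' [sim_spec()]).
#'
#' @param spec A [sim_spec()].
#' @return List with `expression` (tibble: `gene_id`, `gene_class`, sample
#'   columns of positive intensities), `groups` (tibble: `sample_id`,
#'   `group`), and `truth` (a `cnc_truth` list: `de_genes`, `target_pairs`,
#'   `enriched_sets`, `reference_genes`, `rng_seed`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "cnc_sim_spec"))
  ids <- sim_gene_ids(spec)
  groups <- sim_sample_ids(spec)
  n_samp <- nrow(groups)
  g_ind <- as.numeric(groups$group == "induced")

  withr::with_seed(spec$rng_seed, {
    de_genes <- purrr::map2(ids, names(ids), function(gid, cls) {
      n_de <- round(spec$de_fraction_per_class * length(gid))
      if (n_de == 0L || spec$planted_log2fc == 0) {
        return(NULL)
      }
      picked <- sort(sample(gid, n_de))
      tibble(gene_id = picked, gene_class = cls,
             direction = rep_len(c("up", "down"), n_de))
    }) |> bind_rows()
    if (nrow(de_genes) == 0L) {
      de_genes <- tibble(gene_id = character(0), gene_class = character(0),
                         direction = character(0))
    }

    target_pairs <- sim_pick_pairs(spec, de_genes)
    if (nrow(target_pairs) > 0L) {
      max_start <- spec$utr_length - spec$mirna_length + 1L
      if (max_start < 1L) {
        abort("`utr_length` is shorter than `mirna_length`.")
      }
      target_pairs$utr_start <- sample.int(max_start, nrow(target_pairs),
                                           replace = TRUE)
      target_pairs$utr_end <- target_pairs$utr_start + spec$mirna_length - 1L
    }

    all_ids <- unlist(ids, use.names = FALSE)
    all_class <- rep(names(ids), lengths(ids))
    mu <- rnorm(length(all_ids), spec$baseline_log2_mean, spec$baseline_log2_sd)
    names(mu) <- all_ids
    effect <- setNames(rep(0, length(all_ids)), all_ids)
    if (nrow(de_genes) > 0L) {
      effect[de_genes$gene_id] <-
        ifelse(de_genes$direction == "up", 1, -1) * spec$planted_log2fc
    }
    noise <- matrix(rnorm(length(all_ids) * n_samp, 0, spec$noise_sd),
                    nrow = length(all_ids))
    log2m <- mu + outer(effect, g_ind) + noise
    rownames(log2m) <- all_ids
    # planted targets: mirror the regulator's deviation from baseline, plus a
    # small independent perturbation, so anticorrelation is near-deterministic
    if (nrow(target_pairs) > 0L) {
      eps <- matrix(rnorm(nrow(target_pairs) * n_samp, 0, 0.2 * spec$noise_sd),
                    nrow = nrow(target_pairs))
      for (i in seq_len(nrow(target_pairs))) {
        m_id <- target_pairs$mirna_id[i]
        t_id <- target_pairs$gene_id[i]
        log2m[t_id, ] <- mu[t_id] - (log2m[m_id, ] - mu[m_id]) + eps[i, ]
      }
    }
  })

  expression <- tibble(gene_id = all_ids, gene_class = all_class) |>
    bind_cols(as_tibble(2^log2m, .name_repair = ~ groups$sample_id))
  attr(expression, "rng_seed") <- spec$rng_seed
  truth <- structure(
    list(
      de_genes = de_genes,
      target_pairs = target_pairs,
      enriched_sets = tibble(set_id = character(0), collection = character(0),
                             direction = character(0)),
      reference_genes = character(0),
      rng_seed = spec$rng_seed
    ),
    class = "cnc_truth"
  )
  list(expression = expression, groups = groups, truth = truth)
}

# pair DE miRNAs with DE mRNAs of the opposite direction, alternating
sim_pick_pairs <- function(spec, de_genes) {
  empty <- tibble(mirna_id = character(0), gene_id = character(0),
                  utr_start = integer(0), utr_end = integer(0))
  if (spec$n_target_pairs == 0L) return(empty)
  mir_up <- de_genes$gene_id[de_genes$gene_class == "miRNA" &
                               de_genes$direction == "up"]
  mir_dn <- de_genes$gene_id[de_genes$gene_class == "miRNA" &
                               de_genes$direction == "down"]
  mrna_up <- de_genes$gene_id[de_genes$gene_class == "mRNA" &
                                de_genes$direction == "up"]
  mrna_dn <- de_genes$gene_id[de_genes$gene_class == "mRNA" &
                                de_genes$direction == "down"]
  n_a <- ceiling(spec$n_target_pairs / 2) # up-miRNA -> down-mRNA
  n_b <- spec$n_target_pairs - n_a        # down-miRNA -> up-mRNA
  if (length(mir_up) < n_a || length(mrna_dn) < n_a ||
      length(mir_dn) < n_b || length(mrna_up) < n_b) {
    abort(paste(
      "`n_target_pairs` too large for the planted DE gene counts;",
      "increase `de_fraction_per_class` or gene numbers."
    ))
  }
  bind_rows(
    tibble(mirna_id = sample(mir_up, n_a), gene_id = sample(mrna_dn, n_a)),
    tibble(mirna_id = sample(mir_dn, n_b), gene_id = sample(mrna_up, n_b))
  ) |>
    mutate(utr_start = NA_integer_, utr_end = NA_integer_)
}

#' Simulate miRNA sequences
#'
#' Uniform random RNA sequences of length `mirna_length`, one per miRNA.
#'
#' @param spec A [sim_spec()].
#' @return Named character vector of miRNA sequences (5'->3').
#' @export
simulate_mirnas <- function(spec) {
  stopifnot(inherits(spec, "cnc_sim_spec"))
  ids <- sim_gene_ids(spec)$miRNA
  withr::with_seed(spec$rng_seed + 1L, {
    seqs <- vapply(ids, function(i) {
      paste(sample(c("A", "C", "G", "U"), spec$mirna_length, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  seqs
}

#' Simulate 3'UTR sequences with planted binding sites
#'
#' Background sequence is uniform over A/C/G/U; each planted (miRNA, gene)
#' pair's UTR carries the exact reverse complement of the full miRNA at the
#' coordinates recorded in the truth table.
#'
#' @param spec A [sim_spec()].
#' @param truth Truth table from [simulate_expression()].
#' @param mirna_seqs Named miRNA sequences covering every planted pair.
#' @return Named character vector of UTR sequences (5'->3'), one per mRNA.
#' @export
simulate_utrs <- function(spec, truth, mirna_seqs) {
  stopifnot(inherits(spec, "cnc_sim_spec"), inherits(truth, "cnc_truth"))
  if (spec$utr_length < spec$mirna_length) {
    abort("`utr_length` is shorter than `mirna_length`.")
  }
  pairs <- truth$target_pairs
  missing <- setdiff(pairs$mirna_id, names(mirna_seqs))
  if (length(missing) > 0L) {
    abort(sprintf("Planted miRNA(s) without a sequence: %s.",
                  paste(missing, collapse = ", ")))
  }
  ids <- sim_gene_ids(spec)$mRNA
  withr::with_seed(spec$rng_seed + 2L, {
    utrs <- vapply(ids, function(i) {
      paste(sample(c("A", "C", "G", "U"), spec$utr_length, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  for (i in seq_len(nrow(pairs))) {
    site <- reverse_complement(mirna_seqs[[pairs$mirna_id[i]]])
    target <- pairs$gene_id[i]
    utrs[[target]] <- paste0(
      substr(utrs[[target]], 1L, pairs$utr_start[i] - 1L),
      site,
      substr(utrs[[target]], pairs$utr_end[i] + 1L, spec$utr_length)
    )
  }
  utrs
}

#' Simulate a gene-set collection with planted enrichment
#'
#' A fifth of the sets (at least one) are planted as enriched: they draw
#' `enriched_fraction` of their members from planted DE mRNAs of a single
#' direction, planted target genes first, and alternate direction from set to
#' set. Remaining members, and all members of non-enriched sets, are drawn
#' uniformly from the mRNA universe. The background is the full mRNA universe.
#'
#' @param spec A [sim_spec()].
#' @param truth Truth table from [simulate_expression()].
#' @param prefix Set-id prefix, e.g. `"GO"` or `"KEGG"` (also selects a
#'   distinct random substream so the two collections differ).
#' @return A `cnc_genesets` collection (see [new_genesets()]); planted set ids
#'   and directions are in `attr(, "enriched_sets")`.
#' @export
simulate_genesets <- function(spec, truth, prefix = "GO") {
  stopifnot(inherits(spec, "cnc_sim_spec"), inherits(truth, "cnc_truth"))
  universe <- sim_gene_ids(spec)$mRNA
  if (spec$geneset_size > length(universe)) {
    abort("`geneset_size` exceeds the mRNA universe.")
  }
  offset <- 3L + (sum(utf8ToInt(prefix)) %% 100L)
  empty_attr <- tibble(set_id = character(0), direction = character(0))
  if (spec$n_genesets == 0L) {
    out <- new_genesets(list(), background = universe)
    attr(out, "enriched_sets") <- empty_attr
    return(out)
  }
  de_mrna <- truth$de_genes |> filter(.data$gene_class == "mRNA")
  targeted <- intersect(truth$target_pairs$gene_id, de_mrna$gene_id)
  n_enr <- if (nrow(de_mrna) > 0L && spec$enriched_fraction > 0) {
    max(1L, round(0.2 * spec$n_genesets))
  } else 0L
  set_ids <- sprintf("%s_S%03d", prefix, seq_len(spec$n_genesets))
  withr::with_seed(spec$rng_seed + offset, {
    sets <- vector("list", spec$n_genesets)
    enr_dir <- rep_len(c("up", "down"), n_enr)
    for (s in seq_len(spec$n_genesets)) {
      if (s <= n_enr) {
        dir <- enr_dir[s]
        pool_target <- targeted[de_mrna$direction[match(targeted, de_mrna$gene_id)] == dir]
        pool_other <- setdiff(de_mrna$gene_id[de_mrna$direction == dir], pool_target)
        k <- round(spec$enriched_fraction * spec$geneset_size)
        de_part <- head(c(pool_target, sample(pool_other)), k)
        rest <- sample(setdiff(universe, de_part),
                       spec$geneset_size - length(de_part))
        sets[[s]] <- sort(c(de_part, rest))
      } else {
        sets[[s]] <- sort(sample(universe, spec$geneset_size))
      }
    }
  })
  names(sets) <- set_ids
  out <- new_genesets(sets, background = universe,
                      set_names = sprintf("synthetic set %s", set_ids))
  attr(out, "enriched_sets") <- tibble(
    set_id = head(set_ids, n_enr),
    direction = rep_len(c("up", "down"), n_enr)
  )
  out
}

#' Simulate a curated-style reference gene list
#'
#' Mimics a curated disease/process gene database: roughly half of the planted
#' target mRNAs (the recoverable core), plus decoy DE mRNAs that are not
#' planted targets and decoy non-DE mRNAs, so that reference filtering is
#' exercised in both directions.
#'
#' @param spec A [sim_spec()].
#' @param truth Truth table from [simulate_expression()].
#' @return Sorted character vector of reference gene ids.
#' @export
simulate_reference <- function(spec, truth) {
  stopifnot(inherits(spec, "cnc_sim_spec"), inherits(truth, "cnc_truth"))
  targeted <- truth$target_pairs$gene_id
  de_mrna <- truth$de_genes$gene_id[truth$de_genes$gene_class == "mRNA"]
  universe <- sim_gene_ids(spec)$mRNA
  withr::with_seed(spec$rng_seed + 5L, {
    core <- if (length(targeted) > 0L) {
      sort(sample(targeted, ceiling(length(targeted) / 2)))
    } else character(0)
    decoy_de <- setdiff(de_mrna, targeted)
    decoy_de <- if (length(decoy_de) > 0L) {
      sample(decoy_de, min(4L, length(decoy_de)))
    } else character(0)
    decoy_null <- setdiff(universe, de_mrna)
    decoy_null <- if (length(decoy_null) > 0L) {
      sample(decoy_null, min(4L, length(decoy_null)))
    } else character(0)
  })
  sort(unique(c(core, decoy_de, decoy_null)))
}

#' Simulate a complete synthetic study
#'
#' Runs all generators under seed substreams derived from `spec$rng_seed` and
#' assembles the truth table: expression and groups, miRNA and UTR sequences,
#' one "GO" and one "KEGG" gene-set collection, and the reference gene list.
#'
#' @param spec A [sim_spec()].
#' @return A `cnc_study` list: `spec`, `expression`, `groups`, `truth`,
#'   `mirnas`, `utrs`, `go`, `kegg`, `reference`.
#' @export
simulate_study <- function(spec = sim_spec()) {
  sim <- simulate_expression(spec)
  mirnas <- simulate_mirnas(spec)
  utrs <- simulate_utrs(spec, sim$truth, mirnas)
  go <- simulate_genesets(spec, sim$truth, prefix = "GO")
  kegg <- simulate_genesets(spec, sim$truth, prefix = "KEGG")
  reference <- simulate_reference(spec, sim$truth)
  truth <- sim$truth
  truth$enriched_sets <- bind_rows(
    attr(go, "enriched_sets") |> mutate(collection = "GO"),
    attr(kegg, "enriched_sets") |> mutate(collection = "KEGG")
  ) |> select("set_id", "collection", "direction")
  truth$reference_genes <- reference
  structure(
    list(spec = spec, expression = sim$expression, groups = sim$groups,
         truth = truth, mirnas = mirnas, utrs = utrs, go = go, kegg = kegg,
         reference = reference),
    class = "cnc_study"
  )
}
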