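test_that("identical spec and seed give identical outputs", {
  s1 <- simulate_study(tiny_spec())
  s2 <- simulate_study(tiny_spec())
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$utrs, s2$utrs)
  expect_identical(s1$go$sets, s2$go$sets)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(tiny_spec(rng_seed = 43L))
  expect_false(identical(s1$expression, s3$expression))
})

test_that("a spec without planted structure yields an empty truth table", {
  spec <- tiny_spec(de_fraction_per_class = 0, n_target_pairs = 0L)
  sim <- simulate_expression(spec)
  expect_equal(nrow(sim$truth$de_genes), 0L)
  expect_equal(nrow(sim$truth$target_pairs), 0L)
  expect_equal(nrow(sim$expression),
               spec$n_mirna + spec$n_lncrna + spec$n_mrna)
  # UTRs are still produced, one per mRNA, all background
  utrs <- simulate_utrs(spec, sim$truth, simulate_mirnas(spec))
  expect_length(utrs, spec$n_mrna)
  expect_true(all(nchar(utrs) == spec$utr_length))
})

test_that("invalid specs are rejected", {
  expect_error(tiny_spec(n_ctrl = 1L), ">=")
  expect_error(tiny_spec(noise_sd = 0), ">")
  expect_error(
    simulate_utrs(tiny_spec(utr_length = 5L, n_target_pairs = 0L),
                  simulate_expression(tiny_spec(n_target_pairs = 0L))$truth,
                  simulate_mirnas(tiny_spec())),
    "shorter"
  )
})

test_that("planted group difference matches the generating model", {
  # Monte-Carlo over re-simulations: the mean log2 group difference of
  # planted genes equals the planted effect within 0.05 log2 units
  diffs <- vapply(1:200, function(s) {
    spec <- tiny_spec(rng_seed = 1000L + s, n_target_pairs = 0L)
    sim <- simulate_expression(spec)
    m <- log2(as.matrix(sim$expression[, sim$groups$sample_id]))
    rownames(m) <- sim$expression$gene_id
    de <- sim$truth$de_genes
    d <- rowMeans(m[de$gene_id, sim$groups$group == "induced", drop = FALSE]) -
      rowMeans(m[de$gene_id, sim$groups$group == "control", drop = FALSE])
    mean(d * ifelse(de$direction == "up", 1, -1))
  }, numeric(1))
  expect_equal(mean(diffs), 2.0, tolerance = 0.05 / 2.0)
})

test_that("planted pairs obey the direction law and carry exact sites", {
  study <- simulate_study(tiny_spec())
  truth <- study$truth
  dir_of <- setNames(truth$de_genes$direction, truth$de_genes$gene_id)
  expect_true(all(dir_of[truth$target_pairs$mirna_id] !=
                    dir_of[truth$target_pairs$gene_id]))
  for (i in seq_len(nrow(truth$target_pairs))) {
    p <- truth$target_pairs[i, ]
    expect_identical(
      substr(study$utrs[[p$gene_id]], p$utr_start, p$utr_end),
      reverse_complement(study$mirnas[[p$mirna_id]])
    )
  }
})

test_that("planted UTR sites are exact reverse complements at the coords", {
  # the documented identity: miR 5'-UGAGGUAG-3' plants CUACCUCA
  expect_identical(reverse_complement("UGAGGUAG"), "CUACCUCA")
})

test_that("gene sets respect the enrichment construction rules", {
  # enriched_fraction = 1 and small sets: enriched sets are subsets of DE genes
  spec <- tiny_spec(enriched_fraction = 1, geneset_size = 3L)
  sim <- simulate_expression(spec)
  gs <- simulate_genesets(spec, sim$truth, prefix = "GO")
  enr <- attr(gs, "enriched_sets")
  de_ids <- sim$truth$de_genes$gene_id
  expect_gt(nrow(enr), 0L)
  for (sid in enr$set_id) {
    expect_true(all(gs$sets[[sid]] %in% de_ids))
  }
  expect_false(anyDuplicated(names(gs$sets)) > 0)

  # no sets requested: empty but valid collection
  gs0 <- simulate_genesets(tiny_spec(n_genesets = 0L), sim$truth)
  expect_length(gs0$sets, 0L)
  expect_gt(length(gs0$background), 0L)
})

test_that("a planted enriched set is significant for the DE query", {
  # 100 DE genes in a 1000-gene background, set size 20, half from DE
  spec <- sim_spec(n_mirna = 4L, n_lncrna = 4L, n_mrna = 1000L,
                   de_fraction_per_class = 0.1, n_target_pairs = 0L,
                   n_genesets = 10L, geneset_size = 20L,
                   enriched_fraction = 0.5, rng_seed = 7L)
  sim <- simulate_expression(spec)
  gs <- simulate_genesets(spec, sim$truth, prefix = "GO")
  query <- sim$truth$de_genes$gene_id[sim$truth$de_genes$gene_class == "mRNA"]
  res <- enrich(query, gs)
  planted <- attr(gs, "enriched_sets")$set_id
  expect_lt(res$p_value[res$set_id == planted[1]], 0.05)
  expect_true(res$set_id[1] %in% planted)
})
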