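test_that("sequence normalization maps DNA to RNA and rejects junk", {
  expect_identical(normalize_sequence("acgt"), "ACGU")
  expect_identical(normalize_sequence("UGAGGUAG"), "UGAGGUAG")
  expect_error(normalize_sequence("ACGN"), "Invalid")
})

test_that("a full complement scores per the seeded scoring definition", {
  # 8 matches at +5: gapless site, score 40, UTR coords 3-10
  plain <- scoring_scheme(match = 5, seed_scale = 1, score_threshold = 0)
  s1 <- sw_align_seeded("UGAGGUAG", "AACUACCUCAAA", plain)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$score, 40)
  expect_equal(s1$utr_start, 3L)
  expect_equal(s1$utr_end, 10L)
  expect_identical(s1$mirna_aln, "GAUGGAGU")
  expect_identical(s1$utr_aln, "CUACCUCA")
  expect_false(grepl("-", s1$mirna_aln, fixed = TRUE))
  # seed 2-8 scaled 4x: positions 2-8 score 7 x 20, position 1 scores 5
  scaled <- scoring_scheme(match = 5, seed_scale = 4, score_threshold = 0)
  s2 <- sw_align_seeded("UGAGGUAG", "AACUACCUCAAA", scaled)
  expect_equal(s2$score[1], 145)
})

test_that("a miRNA longer than the UTR yields no sites", {
  out <- sw_align_seeded("UGAGGUAGUA", "ACGU",
                         scoring_scheme(score_threshold = 0))
  expect_equal(nrow(out), 0L)
})

test_that("the seeded aligner equals exhaustive alignment enumeration", {
  set.seed(101)
  for (i in 1:200) {
    mir_len <- sample(4:7, 1)
    utr_len <- sample(mir_len:12, 1)
    mirna <- rand_rna(mir_len)
    utr <- rand_rna(utr_len)
    scheme <- rand_scheme(mir_len, gappy = i %% 2 == 0, threshold = 1)
    oracle <- oracle_best_score(mirna, utr, scheme)
    got <- sw_align_seeded(mirna, utr, scheme)
    if (oracle >= scheme$score_threshold) {
      expect_equal(got$score[1], oracle,
                   info = sprintf("case %d: %s vs %s", i, mirna, utr))
    } else {
      expect_equal(nrow(got), 0L,
                   info = sprintf("case %d: %s vs %s", i, mirna, utr))
    }
  }
})

test_that("no reported alignment has a gap at seed positions", {
  set.seed(202)
  n_gapped <- 0L
  for (i in 1:150) {
    mir_len <- sample(6:10, 1)
    mirna <- rand_rna(mir_len)
    utr <- rand_rna(sample(20:30, 1))
    scheme <- rand_scheme(mir_len, gappy = TRUE, threshold = 4)
    sites <- sw_align_seeded(mirna, utr, scheme)
    for (r in seq_len(nrow(sites))) {
      site <- sites[r, ]
      if (grepl("-", paste0(site$mirna_aln, site$utr_aln))) {
        n_gapped <- n_gapped + 1L
      }
      expect_false(gap_in_seed(site, mir_len, scheme))
    }
  }
  expect_gt(n_gapped, 0L) # the property was exercised on gapped alignments
})

test_that("complementary flanks never lower the best score", {
  set.seed(303)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (i in 1:50) {
    mir_len <- sample(5:8, 1)
    mirna <- rand_rna(mir_len)
    utr <- rand_rna(sample(mir_len:15, 1))
    scheme <- rand_scheme(mir_len, gappy = i %% 2 == 0, threshold = 1)
    base <- sw_align_seeded(mirna, utr, scheme)
    base_best <- if (nrow(base) > 0) base$score[1] else -Inf
    flank <- sample(c("A", "C", "G", "U"), 1)
    # extend the miRNA 3' end and the UTR 5' end with a complementary pair
    ext <- sw_align_seeded(paste0(mirna, flank),
                           paste0(comp[[flank]], utr), scheme)
    ext_best <- if (nrow(ext) > 0) ext$score[1] else -Inf
    expect_gte(ext_best, base_best)
  }
})

test_that("duplex energies follow the reduced nearest-neighbour model", {
  # single paired column: initiation term only, no stacks
  one <- duplex_free_energy(tibble::tibble(mirna_aln = "U", utr_aln = "A"))
  expect_equal(one$energy, energy_model()$initiation)
  # zero paired columns: initiation only, flagged
  expect_warning(
    none <- duplex_free_energy(tibble::tibble(mirna_aln = "A", utr_aln = "A")),
    "no paired column"
  )
  expect_equal(none$energy,
               energy_model()$initiation + energy_model()$mismatch_penalty)
  # three consecutive G:C pairs: initiation + 2 GG/CC stacks
  tab <- rna_stack_energies()
  gg <- tab$dg[tab$stack == "GG/CC"]
  three <- duplex_free_energy(tibble::tibble(mirna_aln = "CCC",
                                             utr_aln = "GGG"))
  expect_equal(three$energy, energy_model()$initiation + 2 * gg)
  # mismatches and gaps destabilize additively (no consecutive paired
  # columns here, so no stack terms)
  mixed <- duplex_free_energy(tibble::tibble(mirna_aln = "C-CAC",
                                             utr_aln = "GAGGG"))
  em <- energy_model()
  expect_equal(mixed$energy,
               em$initiation + em$gap_penalty + em$mismatch_penalty)
})

test_that("appending a Watson-Crick pair never increases the energy", {
  set.seed(404)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  bases <- c("A", "C", "G", "U")
  for (i in 1:1000) {
    n <- sample(1:8, 1)
    mir <- character(n); utr <- character(n)
    for (k in seq_len(n)) {
      kind <- sample(c("pair", "mismatch", "gap_m", "gap_u"), 1,
                     prob = c(0.6, 0.2, 0.1, 0.1))
      if (kind == "pair") {
        b <- sample(bases, 1); utr[k] <- b; mir[k] <- comp[[b]]
      } else if (kind == "mismatch") {
        b <- sample(bases, 1); utr[k] <- b; mir[k] <- b
      } else if (kind == "gap_m") {
        mir[k] <- "-"; utr[k] <- sample(bases, 1)
      } else {
        mir[k] <- sample(bases, 1); utr[k] <- "-"
      }
    }
    aln <- tibble::tibble(mirna_aln = paste(mir, collapse = ""),
                          utr_aln = paste(utr, collapse = ""))
    e0 <- suppressWarnings(duplex_free_energy(aln))$energy
    b <- sample(bases, 1)
    aln2 <- tibble::tibble(mirna_aln = paste0(aln$mirna_aln, comp[[b]]),
                           utr_aln = paste0(aln$utr_aln, b))
    e1 <- suppressWarnings(duplex_free_energy(aln2))$energy
    expect_lte(e1, e0)
  }
})

test_that("predicted targets pass both thresholds and recover planted sites", {
  study <- simulate_study(tiny_spec(mirna_length = 22L, utr_length = 60L))
  truth <- study$truth
  scheme <- scoring_scheme()
  tt <- predict_targets(study$mirnas, study$utrs, scheme)
  expect_true(all(tt$best_score >= scheme$score_threshold))
  expect_true(all(tt$best_energy <= scheme$energy_threshold))
  planted <- paste(truth$target_pairs$mirna_id, truth$target_pairs$gene_id)
  expect_true(all(planted %in% paste(tt$mirna_id, tt$target_id)))
  # empty UTR set: empty table, not an error
  empty <- predict_targets(study$mirnas, character(0), scheme)
  expect_equal(nrow(empty), 0L)
})

test_that("background scans almost never produce a predicted target", {
  # small unplanted fixture scanned across 100 seeded simulations
  hits <- vapply(1:100, function(s) {
    spec <- sim_spec(n_mirna = 3L, n_lncrna = 1L, n_mrna = 3L,
                     de_fraction_per_class = 0, n_target_pairs = 0L,
                     mirna_length = 22L, utr_length = 60L,
                     n_genesets = 0L, rng_seed = 5000L + s)
    truth <- simulate_expression(spec)$truth
    mirnas <- simulate_mirnas(spec)
    utrs <- simulate_utrs(spec, truth, mirnas)
    nrow(predict_targets(mirnas, utrs))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.99)
})

test_that("candidate directions follow the negative-regulation majority rule", {
  de <- tibble::tibble(
    gene_id = c("m1", "m2", "m3"),
    direction = c("down", "down", "up"),
    significant = TRUE
  )
  tt <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m3", "m3"),
    target_id = c("gA", "gB", "gB", "gB", "gC"),
    target_class = "mRNA"
  )
  # gA: one down regulator -> up; gB: 2 down + 1 up -> up; gC: one up -> down
  out <- infer_candidate_directions(de, tt)
  expect_identical(out$direction[out$gene_id == "gA"], "up")
  expect_identical(out$direction[out$gene_id == "gB"], "up")
  expect_identical(out$direction[out$gene_id == "gC"], "down")
  # exact tie: dropped with a warning
  tie <- tibble::tibble(mirna_id = c("m1", "m3"), target_id = "gT",
                        target_class = "mRNA")
  expect_warning(out2 <- infer_candidate_directions(de, tie), "tied")
  expect_equal(nrow(out2), 0L)
  # missing DE direction is an error
  expect_error(
    infer_candidate_directions(de, tibble::tibble(
      mirna_id = "mX", target_id = "gA", target_class = "mRNA"
    )),
    "without a DE direction"
  )
})
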