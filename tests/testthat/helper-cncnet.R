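# Shared fixtures and independent oracles.

# small study spec for fast tests
tiny_spec <- function(...) {
  args <- modifyList(
    list(n_mirna = 8L, n_lncrna = 8L, n_mrna = 30L,
         de_fraction_per_class = 0.5, planted_log2fc = 2, noise_sd = 0.25,
         n_target_pairs = 2L, mirna_length = 12L, utr_length = 40L,
         n_genesets = 6L, geneset_size = 5L, enriched_fraction = 0.6,
         rng_seed = 42L),
    list(...)
  )
  do.call(sim_spec, args)
}

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# --- alignment oracle: exhaustive max over all gapped local alignments ------
#
# Top-down recursion over (row of the reversed miRNA, UTR position, previous
# column type), enumerating pair / gap-in-UTR / gap-in-miRNA columns with
# affine gap costs, no adjacent opposite-strand gaps, and the no-gap-in-seed
# rule. Memoized; structurally independent of the package's row-vectorized
# dynamic program.
oracle_best_score <- function(mirna, utr, scheme) {
  rev_mir <- rev(strsplit(mirna, "")[[1]])
  utr_c <- strsplit(utr, "")[[1]]
  L <- length(rev_mir)
  n <- length(utr_c)
  if (L > n) return(NA_real_)
  orig <- function(a) L - a + 1L
  in_seed <- function(p) p >= scheme$seed_start & p <= scheme$seed_end
  base <- c(scheme$mismatch, scheme$match, scheme$wobble)
  pair_score <- function(a, j) {
    s <- base[cncnet:::pair_type(rev_mir[a], utr_c[j]) + 1L]
    if (in_seed(orig(a))) s * scheme$seed_scale else s
  }
  memo <- new.env(parent = emptyenv())
  suffix <- function(a, j, prev) {
    key <- paste(a, j, prev)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- 0 # stop here
    if (a <= L && j <= n) {
      best <- max(best, pair_score(a, j) + suffix(a + 1L, j + 1L, "M"))
    }
    if (a <= L && prev != "Y" && !in_seed(orig(a))) {
      cost <- if (prev == "M") scheme$gap_open else scheme$gap_extend
      best <- max(best, cost + suffix(a + 1L, j, "X"))
    }
    utr_gap_ok <- !(a > 1L && a <= L && in_seed(orig(a - 1L)) &&
                      in_seed(orig(a)))
    if (j <= n && prev != "X" && utr_gap_ok) {
      cost <- if (prev == "M") scheme$gap_open else scheme$gap_extend
      best <- max(best, cost + suffix(a, j + 1L, "Y"))
    }
    memo[[key]] <- best
    best
  }
  best <- -Inf
  for (a0 in seq_len(L)) {
    for (j0 in seq_len(n)) {
      best <- max(best, pair_score(a0, j0) + suffix(a0 + 1L, j0 + 1L, "M"))
    }
  }
  best
}

# random valid scoring scheme for property tests
rand_scheme <- function(mir_len, gappy = FALSE, threshold = 1) {
  mism <- -sample(2:5, 1)
  scoring_scheme(
    match = sample(3:6, 1),
    mismatch = mism,
    wobble = sample(seq(mism + 1L, 2L), 1),
    gap_open = if (gappy) -sample(1:3, 1) else -sample(6:10, 1),
    gap_extend = if (gappy) -1 else -sample(3:5, 1),
    seed_start = 2L,
    seed_end = min(4L, mir_len - 1L),
    seed_scale = sample(1:4, 1),
    score_threshold = threshold,
    energy_threshold = 0
  )
}

# --- hypergeometric oracles -------------------------------------------------

# closed-form tail by direct combinatorial summation
oracle_hyper_choose <- function(k, m, n, N) {
  js <- k:min(m, n)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# brute force: enumerate every possible query subset of the background
oracle_hyper_enum <- function(k, m, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= m) >= k) # the first m background elements are the set
}

# seed-law checker: walk alignment columns and flag gaps at seed positions
gap_in_seed <- function(site, mirna_len, scheme) {
  mc <- strsplit(site$mirna_aln, "")[[1]]
  uc <- strsplit(site$utr_aln, "")[[1]]
  pos <- site$mirna_end # leftmost column uses the 3'-most covered position
  for (i in seq_along(mc)) {
    if (uc[i] == "-") { # gap in UTR: consumes miRNA position pos
      if (pos >= scheme$seed_start && pos <= scheme$seed_end) return(TRUE)
      pos <- pos - 1L
    } else if (mc[i] == "-") { # gap in miRNA: straddles pos+1 and pos
      if (pos + 1L <= scheme$seed_end && pos >= scheme$seed_start) return(TRUE)
    } else {
      pos <- pos - 1L
    }
  }
  FALSE
}
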