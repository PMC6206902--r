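# Seeded Smith-Waterman scan of miRNAs against 3'UTRs.
#
# The miRNA is aligned antiparallel to the UTR: the aligned miRNA string runs
# 3'->5' left-to-right over the UTR written 5'->3'. Columns are scored by
# complementarity (A:U and G:C match, G:U wobble, otherwise mismatch) under an
# affine gap model. Pair scores inside the seed window (positions counted from
# the miRNA 5' end) are scaled up and gaps are disallowed there. Internally
# the DP runs over the reversed miRNA so both strings advance left-to-right.

sw_dp <- function(rev_mir, utr, scheme) {
  L <- length(rev_mir)
  n <- length(utr)
  orig_pos <- L - seq_len(L) + 1L # miRNA position from the 5' end, per row
  in_seed <- orig_pos >= scheme$seed_start & orig_pos <= scheme$seed_end
  # gap in the miRNA string between rows a and a+1 sits between miRNA
  # positions orig_pos[a] and orig_pos[a]-1; forbidden when both are in seed
  utr_gap_forbidden <- orig_pos <= scheme$seed_end &
    (orig_pos - 1L) >= scheme$seed_start

  base <- c(scheme$mismatch, scheme$match, scheme$wobble)
  M <- matrix(-Inf, L, n)
  X <- matrix(-Inf, L, n) # gap in UTR string: consumes miRNA only
  Y <- matrix(-Inf, L, n) # gap in miRNA string: consumes UTR only
  open <- scheme$gap_open
  ext <- scheme$gap_extend
  j_idx <- seq_len(n)

  for (a in seq_len(L)) {
    sa <- base[pair_type(rev_mir[a], utr) + 1L]
    if (in_seed[a]) sa <- sa * scheme$seed_scale
    if (a == 1L) {
      M[a, ] <- sa
    } else {
      prev_best <- pmax(0, M[a - 1L, ], X[a - 1L, ], Y[a - 1L, ])
      M[a, ] <- sa + c(0, prev_best[-n])
      if (!in_seed[a]) {
        X[a, ] <- pmax(M[a - 1L, ] + open, X[a - 1L, ] + ext)
      }
    }
    if (!utr_gap_forbidden[a] && n > 1L) {
      t_vec <- M[a, ] + open - ext * (j_idx + 1)
      Y[a, -1L] <- ext * j_idx[-1L] + cummax(t_vec)[-n]
    }
  }
  list(M = M, X = X, Y = Y, in_seed = in_seed)
}

sw_traceback <- function(dp, rev_mir, utr, scheme, a, j) {
  M <- dp$M; X <- dp$X; Y <- dp$Y
  open <- scheme$gap_open
  ext <- scheme$gap_extend
  base <- c(scheme$mismatch, scheme$match, scheme$wobble)
  eps <- 1e-9
  L <- length(rev_mir)
  mir_chars <- character(0)
  utr_chars <- character(0)
  state <- "M"
  end_j <- j
  end_a <- a
  repeat {
    if (state == "M") {
      mir_chars <- c(rev_mir[a], mir_chars)
      utr_chars <- c(utr[j], utr_chars)
      s <- base[pair_type(rev_mir[a], utr[j]) + 1L]
      if (dp$in_seed[a]) s <- s * scheme$seed_scale
      prev <- M[a, j] - s
      if (a == 1L || j == 1L || prev <= eps) break
      a <- a - 1L; j <- j - 1L
      # tie preference: pairing, then gap-in-UTR, then gap-in-miRNA
      state <- if (abs(M[a, j] - prev) < eps) "M"
      else if (abs(X[a, j] - prev) < eps) "X"
      else "Y"
    } else if (state == "X") {
      mir_chars <- c(rev_mir[a], mir_chars)
      utr_chars <- c("-", utr_chars)
      val <- X[a, j]
      a <- a - 1L
      state <- if (abs(M[a, j] + open - val) < eps) "M" else "X"
    } else {
      mir_chars <- c("-", mir_chars)
      utr_chars <- c(utr[j], utr_chars)
      val <- Y[a, j]
      j <- j - 1L
      state <- if (abs(M[a, j] + open - val) < eps) "M" else "Y"
    }
  }
  tibble(
    utr_start = j, utr_end = end_j,
    # rows run over the reversed miRNA, so the last row is the 5'-most base
    mirna_start = L - end_a + 1L, mirna_end = L - a + 1L,
    mirna_aln = paste(mir_chars, collapse = ""),
    utr_aln = paste(utr_chars, collapse = "")
  )
}

sw_scan_region <- function(rev_mir, utr, scheme, offset) {
  n <- length(utr)
  if (n < 1L || length(rev_mir) > n) return(NULL)
  dp <- sw_dp(rev_mir, utr, scheme)
  best <- max(dp$M)
  if (!is.finite(best) || best < scheme$score_threshold) return(NULL)
  # deterministic tie-break: smallest UTR end, then shortest miRNA stretch
  hits <- which(abs(dp$M - best) < 1e-9, arr.ind = TRUE)
  pick <- hits[order(hits[, "col"], hits[, "row"])[1L], ]
  site <- sw_traceback(dp, rev_mir, utr, scheme, pick[["row"]], pick[["col"]])
  site$score <- best
  left <- if (site$utr_start > 1L) {
    sw_scan_region(rev_mir, utr[seq_len(site$utr_start - 1L)], scheme, offset)
  }
  right <- if (site$utr_end < n) {
    sw_scan_region(rev_mir, utr[(site$utr_end + 1L):n], scheme,
                   offset + site$utr_end)
  }
  site$utr_start <- site$utr_start + offset
  site$utr_end <- site$utr_end + offset
  bind_rows(site, left, right)
}

#' Seeded Smith-Waterman alignment of one miRNA against one UTR
#'
#' Finds all non-overlapping local alignments (candidate binding sites) of a
#' miRNA against a 3'UTR scoring at or above the scheme's score threshold.
#' The miRNA is aligned antiparallel: the reported `mirna_aln` string runs
#' 3'->5' left-to-right under `utr_aln` written 5'->3'. Pair scores inside the
#' seed window are multiplied by `seed_scale`, and no gap may involve a seed
#' position. Sites are reported best-first; equal-scoring alternatives are
#' resolved deterministically towards the leftmost UTR coordinates.
#'
#' @param mirna miRNA sequence, 5'->3' (DNA or RNA alphabet).
#' @param utr Target UTR sequence, 5'->3'.
#' @param scheme A [scoring_scheme()].
#' @return Tibble with one row per site: `utr_start`, `utr_end` (1-based
#'   inclusive), `score`, `mirna_aln`, `utr_aln`. A miRNA longer than the UTR
#'   yields zero rows.
#' @examples
#' sw_align_seeded("UGAGGUAG", "AACUACCUCAAA",
#'                 scoring_scheme(seed_scale = 1, score_threshold = 0))
#' @export
sw_align_seeded <- function(mirna, utr, scheme = scoring_scheme()) {
  mirna <- normalize_sequence(mirna)
  utr <- normalize_sequence(utr)
  if (nchar(mirna) < 1L || nchar(utr) < 1L) {
    abort("Sequences must be nonempty.")
  }
  if (scheme$seed_end > nchar(mirna)) {
    abort("`seed_end` exceeds the miRNA length.")
  }
  empty <- tibble(
    utr_start = integer(0), utr_end = integer(0), score = numeric(0),
    mirna_start = integer(0), mirna_end = integer(0),
    mirna_aln = character(0), utr_aln = character(0)
  )
  if (nchar(mirna) > nchar(utr)) return(empty)
  rev_mir <- rev(strsplit(mirna, "")[[1]])
  utr_chars <- strsplit(utr, "")[[1]]
  sites <- sw_scan_region(rev_mir, utr_chars, scheme, 0L)
  if (is.null(sites)) return(empty)
  sites |>
    arrange(desc(.data$score), .data$utr_start) |>
    select("utr_start", "utr_end", "score", "mirna_start", "mirna_end",
           "mirna_aln", "utr_aln")
}

#' Scan all miRNA/UTR pairs for candidate binding sites
#'
#' Runs [sw_align_seeded()] for every combination of miRNA and UTR and
#' evaluates the duplex free energy of each reported site. No energy filter is
#' applied here; [predict_targets()] enforces the dual thresholds.
#'
#' @param mirnas Named character vector of miRNA sequences (5'->3').
#' @param utrs Named character vector of UTR sequences (5'->3').
#' @param scheme A [scoring_scheme()].
#' @param model Energy-model parameters from [energy_model()].
#' @return Tibble: `mirna_id`, `utr_id`, `utr_start`, `utr_end`, `score`,
#'   `energy`, `mirna_aln`, `utr_aln`, sorted by miRNA then descending score.
#' @export
scan_sites <- function(mirnas, utrs, scheme = scoring_scheme(),
                       model = energy_model()) {
  empty <- tibble(
    mirna_id = character(0), utr_id = character(0),
    utr_start = integer(0), utr_end = integer(0), score = numeric(0),
    energy = numeric(0), mirna_start = integer(0), mirna_end = integer(0),
    mirna_aln = character(0), utr_aln = character(0)
  )
  if (length(mirnas) == 0L || length(utrs) == 0L) return(empty)
  if (is.null(names(mirnas)) || is.null(names(utrs))) {
    abort("`mirnas` and `utrs` must be named.")
  }
  combos <- tidyr::expand_grid(mirna_id = names(mirnas), utr_id = names(utrs))
  sites <- purrr::pmap(combos, function(mirna_id, utr_id) {
    hits <- sw_align_seeded(mirnas[[mirna_id]], utrs[[utr_id]], scheme)
    if (nrow(hits) == 0L) return(NULL)
    tibble(mirna_id = mirna_id, utr_id = utr_id, hits)
  })
  sites <- bind_rows(sites)
  if (nrow(sites) == 0L) return(empty)
  sites |>
    duplex_free_energy(model) |>
    arrange(.data$mirna_id, desc(.data$score), .data$utr_id, .data$utr_start) |>
    select("mirna_id", "utr_id", "utr_start", "utr_end", "score", "energy",
           "mirna_start", "mirna_end", "mirna_aln", "utr_aln")
}

#' Predict miRNA targets under dual score and energy thresholds
#'
#' A (miRNA, target) pair enters the table when at least one site passes both
#' the alignment-score threshold and the free-energy threshold of the scheme.
#'
#' @inheritParams scan_sites
#' @param target_class Class label recorded for the targets
#'   (`"mRNA"` or `"lncRNA"`).
#' @param sites Optional precomputed site table from [scan_sites()]; when
#'   supplied the scan is skipped.
#' @return Tibble: `mirna_id`, `target_id`, `target_class`, `best_score`,
#'   `best_energy`, `n_sites`, sorted by miRNA then descending best score.
#' @export
predict_targets <- function(mirnas, utrs, scheme = scoring_scheme(),
                            model = energy_model(), target_class = "mRNA",
                            sites = NULL) {
  target_class <- match.arg(target_class, c("mRNA", "lncRNA"))
  if (is.null(sites)) sites <- scan_sites(mirnas, utrs, scheme, model)
  sites <- sites |> filter(.data$energy <= scheme$energy_threshold)
  if (nrow(sites) == 0L) {
    return(tibble(
      mirna_id = character(0), target_id = character(0),
      target_class = character(0), best_score = numeric(0),
      best_energy = numeric(0), n_sites = integer(0)
    ))
  }
  sites |>
    group_by(.data$mirna_id, .data$utr_id) |>
    summarise(
      best_score = max(.data$score),
      best_energy = min(.data$energy),
      n_sites = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(target_class = target_class) |>
    arrange(.data$mirna_id, desc(.data$best_score), .data$utr_id) |>
    select(mirna_id = "mirna_id", target_id = "utr_id", "target_class",
           "best_score", "best_energy", "n_sites")
}

#' Infer candidate mRNA directions by negative regulation
#'
#' Each candidate target's predicted direction is the opposite of the majority
#' direction of its significant regulating miRNAs; exact ties are dropped with
#' a warning.
#'
#' @param de_mirnas Differential-expression tibble for miRNAs (needs
#'   `gene_id`, `direction`, `significant`), e.g. from
#'   [differential_expression()].
#' @param target_table Output of [predict_targets()].
#' @return Tibble: `gene_id`, `gene_class`, `direction`, `n_up_regulators`,
#'   `n_down_regulators`.
#' @export
infer_candidate_directions <- function(de_mirnas, target_table) {
  assert_cols(de_mirnas, c("gene_id", "direction", "significant"), "de_mirnas")
  assert_cols(target_table, c("mirna_id", "target_id", "target_class"),
              "target_table")
  missing <- setdiff(target_table$mirna_id, de_mirnas$gene_id)
  if (length(missing) > 0L) {
    abort(sprintf(
      "miRNA(s) in `target_table` without a DE direction: %s.",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  sig <- de_mirnas |> filter(.data$significant)
  out <- target_table |>
    dplyr::inner_join(
      sig |> select("gene_id", mirna_direction = "direction"),
      by = c(mirna_id = "gene_id")
    ) |>
    group_by(.data$target_id, .data$target_class) |>
    summarise(
      n_up_regulators = sum(.data$mirna_direction == "up"),
      n_down_regulators = sum(.data$mirna_direction == "down"),
      .groups = "drop"
    ) |>
    mutate(direction = dplyr::case_when(
      .data$n_up_regulators > .data$n_down_regulators ~ "down",
      .data$n_down_regulators > .data$n_up_regulators ~ "up",
      TRUE ~ NA_character_
    ))
  tied <- is.na(out$direction)
  if (any(tied)) {
    warn(sprintf(
      "%d candidate(s) dropped: tied up/down regulator counts (%s).",
      sum(tied), paste(head(out$target_id[tied], 5), collapse = ", ")
    ))
    out <- out[!tied, ]
  }
  out |>
    arrange(.data$target_id) |>
    select(gene_id = "target_id", gene_class = "target_class", "direction",
           "n_up_regulators", "n_down_regulators")
}
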