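# Alignment scoring scheme and RNA duplex free-energy model.

#' miRanda-style alignment scoring scheme
#'
#' Bundles the parameters of the seeded Smith–Waterman scan: base-pair scores
#' (Watson–Crick match, G:U wobble, mismatch), affine gap penalties, the seed
#' window (positions counted from the miRNA 5' end) in which pair scores are
#' scaled up and gaps are disallowed, and the dual reporting thresholds on
#' alignment score and duplex free energy.
#'
#' Defaults follow the canonical parameterisation of the published algorithm
#' family: match +5, mismatch -3, wobble +2, gap open -9, gap extend -4,
#' seed at positions 2–8 scaled 4x, score threshold 140 and energy threshold
#' -20 kcal/mol. All are overridable.
#'
#' @param match Score for an A:U or G:C pair (must exceed `mismatch`).
#' @param mismatch Score for a non-pairing column.
#' @param wobble Score for a G:U pair (must exceed `mismatch`).
#' @param gap_open Penalty for opening a gap (<= 0).
#' @param gap_extend Penalty for extending a gap (<= 0).
#' @param seed_start,seed_end 1-based seed window from the miRNA 5' end.
#' @param seed_scale Multiplier (>= 1) applied to pair scores inside the seed.
#' @param score_threshold Minimum alignment score for a reported site.
#' @param energy_threshold Maximum (i.e. most positive) duplex free energy in
#'   kcal/mol for a reported site; hits must be at least this stable.
#' @return A `cnc_scheme` list.
#' @examples
#' scoring_scheme(score_threshold = 120)
#' @export
scoring_scheme <- function(match = 5, mismatch = -3, wobble = 2,
                           gap_open = -9, gap_extend = -4,
                           seed_start = 2L, seed_end = 8L, seed_scale = 4,
                           score_threshold = 140, energy_threshold = -20) {
  assert_scalar_num(match, "match")
  assert_scalar_num(mismatch, "mismatch")
  assert_scalar_num(wobble, "wobble")
  assert_scalar_num(gap_open, "gap_open", upper = 0)
  assert_scalar_num(gap_extend, "gap_extend", upper = 0)
  seed_start <- assert_count(seed_start, "seed_start", lower = 1L)
  seed_end <- assert_count(seed_end, "seed_end", lower = 1L)
  assert_scalar_num(seed_scale, "seed_scale", lower = 1)
  assert_scalar_num(score_threshold, "score_threshold")
  assert_scalar_num(energy_threshold, "energy_threshold")
  if (match <= mismatch) abort("`match` must be greater than `mismatch`.")
  if (wobble <= mismatch) abort("`wobble` must be greater than `mismatch`.")
  if (seed_start >= seed_end) abort("`seed_start` must be < `seed_end`.")
  structure(
    list(
      match = match, mismatch = mismatch, wobble = wobble,
      gap_open = gap_open, gap_extend = gap_extend,
      seed_start = seed_start, seed_end = seed_end, seed_scale = seed_scale,
      score_threshold = score_threshold, energy_threshold = energy_threshold
    ),
    class = "cnc_scheme"
  )
}

#' @export
print.cnc_scheme <- function(x, ...) {
  cat("<cnc_scheme>\n")
  cat(sprintf("  pair scores: match %+g, wobble %+g, mismatch %+g\n",
              x$match, x$wobble, x$mismatch))
  cat(sprintf("  gaps: open %g, extend %g (none inside seed)\n",
              x$gap_open, x$gap_extend))
  cat(sprintf("  seed: positions %d-%d from miRNA 5' end, scale %gx\n",
              x$seed_start, x$seed_end, x$seed_scale))
  cat(sprintf("  thresholds: score >= %g, energy <= %g kcal/mol\n",
              x$score_threshold, x$energy_threshold))
  invisible(x)
}

#' Normalize a nucleotide sequence to RNA
#'
#' Uppercases and converts T to U; any character outside A/C/G/T/U is an error.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of uppercase RNA sequences.
#' @examples
#' normalize_sequence("acgt")
#' @export
normalize_sequence <- function(seq) {
  if (!is.character(seq)) abort("`seq` must be character.")
  out <- chartr("T", "U", toupper(seq))
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    abort(sprintf(
      "Invalid nucleotide character(s) in sequence(s): %s.",
      paste(head(which(bad), 5), collapse = ", ")
    ))
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' @param seq Character vector of RNA sequences (A/C/G/U).
#' @return Reverse complements as RNA.
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_sequence(seq)
  vapply(seq, function(s) {
    chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# pair classification: 1 = Watson-Crick, 2 = wobble, 0 = mismatch
pair_type <- function(a, b) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  wb <- (a == "G" & b == "U") | (a == "U" & b == "G")
  ifelse(wc, 1L, ifelse(wb, 2L, 0L))
}

# duplex free energy -----------------------------------------------------------

energy_env <- new.env(parent = emptyenv())

#' Nearest-neighbour RNA stack free energies
#'
#' Reads the stacking free-energy table shipped with the package
#' (`inst/extdata/stack_energies.tsv`): Watson–Crick nearest-neighbour
#' parameters at 37 degrees C plus representative G:U wobble stacks, in
#' kcal/mol. Keys are written `XY/WZ` with the target strand 5'->3' on top and
#' the miRNA strand 3'->5' below, so X pairs W and Y pairs Z.
#'
#' @return Tibble with columns `stack` and `dg`.
#' @export
rna_stack_energies <- function() {
  if (is.null(energy_env$table)) {
    path <- system.file("extdata", "stack_energies.tsv", package = "cncnet")
    tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    energy_env$table <- tab
    energy_env$lookup <- setNames(tab$dg, tab$stack)
  }
  energy_env$table
}

#' Duplex free-energy model parameters
#'
#' The reduced model used throughout: a constant duplex-initiation term, a sum
#' of nearest-neighbour stack terms over consecutive paired columns, and fixed
#' destabilisation penalties per mismatched and per gapped column. Stacks not
#' listed in the shipped table (some wobble contexts) fall back to a mild
#' default so that every stacking contribution is stabilising.
#'
#' @param initiation Duplex initiation free energy (kcal/mol).
#' @param mismatch_penalty Destabilisation per mismatched column (kcal/mol).
#' @param gap_penalty Destabilisation per gap column (kcal/mol).
#' @param default_stack Fallback stack term for unlisted paired stacks.
#' @return List of energy-model parameters.
#' @export
energy_model <- function(initiation = 4.09, mismatch_penalty = 1.0,
                         gap_penalty = 2.0, default_stack = -0.5) {
  assert_scalar_num(initiation, "initiation")
  assert_scalar_num(mismatch_penalty, "mismatch_penalty", lower = 0)
  assert_scalar_num(gap_penalty, "gap_penalty", lower = 0)
  assert_scalar_num(default_stack, "default_stack", upper = 0)
  list(
    initiation = initiation, mismatch_penalty = mismatch_penalty,
    gap_penalty = gap_penalty, default_stack = default_stack
  )
}

duplex_energy_one <- function(mirna_aln, utr_aln, model) {
  rna_stack_energies() # ensure lookup is loaded
  lookup <- energy_env$lookup
  mc <- strsplit(mirna_aln, "")[[1]]
  uc <- strsplit(utr_aln, "")[[1]]
  if (length(mc) != length(uc)) {
    abort("Aligned strings must have equal length.")
  }
  gap <- mc == "-" | uc == "-"
  ptype <- integer(length(mc))
  ptype[!gap] <- pair_type(mc[!gap], uc[!gap])
  paired <- !gap & ptype > 0L
  dg <- model$initiation
  dg <- dg + sum(!gap & ptype == 0L) * model$mismatch_penalty
  dg <- dg + sum(gap) * model$gap_penalty
  runs <- which(paired[-length(paired)] & paired[-1])
  if (length(runs) > 0L) {
    keys <- paste0(uc[runs], uc[runs + 1L], "/", mc[runs], mc[runs + 1L])
    vals <- lookup[keys]
    vals[is.na(vals)] <- model$default_stack
    dg <- dg + sum(vals)
  }
  if (!any(paired)) {
    attr(dg, "degenerate") <- TRUE
  }
  dg
}

#' Duplex free energy of miRNA:target alignments
#'
#' Computes the free energy (kcal/mol; lower is more stable) of each aligned
#' duplex as initiation + nearest-neighbour stack terms over consecutive
#' paired columns + per-mismatch and per-gap destabilisation penalties.
#' The aligned miRNA string runs 3'->5' under the target strand 5'->3', as
#' produced by [sw_align_seeded()].
#'
#' @param alignments Tibble with columns `mirna_aln` and `utr_aln`
#'   (gaps as `-`), e.g. the output of [sw_align_seeded()] or [scan_sites()].
#' @param model Energy-model parameters from [energy_model()].
#' @return `alignments` with an `energy` column appended (replaced if present).
#'   Alignments with no paired column get initiation energy only, with a
#'   warning.
#' @export
duplex_free_energy <- function(alignments, model = energy_model()) {
  assert_cols(alignments, c("mirna_aln", "utr_aln"), "alignments")
  n_degenerate <- 0L
  energy <- vapply(seq_len(nrow(alignments)), function(i) {
    dg <- duplex_energy_one(alignments$mirna_aln[i], alignments$utr_aln[i], model)
    if (isTRUE(attr(dg, "degenerate"))) n_degenerate <<- n_degenerate + 1L
    as.numeric(dg)
  }, numeric(1))
  if (n_degenerate > 0L) {
    warn(sprintf(
      "%d alignment(s) have no paired column; energy is the initiation term only.",
      n_degenerate
    ))
  }
  alignments$energy <- energy
  alignments
}
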