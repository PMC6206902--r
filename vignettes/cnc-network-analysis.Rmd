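---
title: "Methods: coding–noncoding network analysis with cncnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coding–noncoding network analysis with cncnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cncnet` implements the coding–noncoding co-expression (CNC) workflow used
to dissect miRNA–mRNA–lncRNA regulation in small two-group expression
studies, such as induced osteoblast differentiation of mesenchymal stem
cells profiled on miRNA/lncRNA microarrays. This vignette is the package's
account of the underlying models, the tunable parameters, the synthetic
study the test suite runs against, and the design decisions taken where the
workflow is conventionally underspecified.

## The statistical model, stage by stage

**Differential expression.** Intensities are clamped at a floor (default 1)
and log2-transformed; an optional quantile mode (via limma) equalises
per-sample distributions. Each gene is tested with a two-sample t-test of
induced vs control and the log2 fold change is the difference of group
means on the log2 scale. The default test is the pooled-variance Student t
rather than Welch: at microarray-scale replication (n = 3 per group) the
Welch–Satterthwaite approximation is noticeably conservative — on a fully
null 10,000-gene matrix it rejects ~3% at a nominal 5% — while the pooled
test holds its level exactly under the homoscedastic noise model the
generator (and most single-batch microarray data) follows.
`method = "welch"` restores the unequal-variance test, and `welch_t()` is
exposed directly. Significance uses the raw *P* < α filter (α = 0.05)
conventional for this workflow; Benjamini–Hochberg adjustment is a flag,
not the default, because the funnel's semantics are defined on the raw
filter. Degenerate genes (constant in both groups) get *p* = 1 when the
groups agree and a flagged *p* = 0 when two constants differ.

**Target prediction.** The scan is a seeded local alignment in the style of
the classical miRNA target predictors: the miRNA (reported 3'→5') is aligned
antiparallel to the UTR (5'→3'); A:U and G:C pair at `match`, the G:U wobble
at `wobble` (between match and mismatch, reflecting its intermediate
thermodynamic stability), anything else at `mismatch`; gaps are affine
(`gap_open` ≤ `gap_extend` ≤ 0, the standard convention that opening costs
more than extending). The seed — positions `seed_start`–`seed_end` from the
miRNA 5' end, default 2–8 — is where pairing determines targeting, so pair
scores there are multiplied by `seed_scale` and no gap may consume or
straddle a seed position. Defaults (match +5, mismatch −3, wobble +2, open
−9, extend −4, seed 2–8 ×4, score ≥ 140, ΔG ≤ −20 kcal/mol) are the
canonical parameterisation of that algorithm family; every one is a
`scoring_scheme()` field. Reported sites are maximal non-overlapping local
alignments found best-first; remaining UTR segments are re-scanned, so a
strong site never shadows a weaker non-overlapping one.

Free energy uses a deliberately reduced nearest-neighbour model:
ΔG = initiation (+4.09) + Σ stack terms over consecutive paired columns +
1.0 per mismatch + 2.0 per gap column, with the Watson–Crick stack table at
37 °C plus a representative wobble subset shipped as
`inst/extdata/stack_energies.tsv` (unlisted wobble stacks fall back to a
mild −0.5). There is no loop-entropy or ensemble folding term: the model is
monotone (appending a Watson–Crick pair never raises ΔG, a property the
tests check over random alignments), cheap, and exactly auditable by manual
table lookup — the right trade-off for a dual-threshold filter, not a
folding engine.

**Negative regulation.** Candidate mRNAs take the direction opposite to the
majority of their significant regulating miRNAs; exact ties are dropped
with a warning rather than guessed.

**Network.** Pearson r is computed over all samples of both groups pooled —
at n = 3 + 3 restricting to one group would leave r essentially
meaningless, and condition-driven co-variation is precisely what a CNC
network displays. An edge requires |r| strictly > `cor_threshold` (0.9)
*and* the class sign rule: miRNA–mRNA and miRNA–lncRNA edges negative
(repression), with miRNA–mRNA edges additionally needing a predicted site;
lncRNA–mRNA edges positive (co-expression/ceRNA-style coupling). The
threshold is interpreted as strict on |r| with the sign layered on top —
the only reading under which miRNA edges are negative yet the stated 0.9
magnitude applies to all edge types. mRNAs are then ranked by degree;
`min_degree` defaults to 1 (any supported, correlated mRNA stays), since
the workflow's degree rule is conventionally left unstated and 1 is the
weakest defensible cut — it is a flag for stricter funnels. For studies
where mRNAs were never measured, `mrna_mode = "predicted"` builds
miRNA–mRNA edges from target support plus opposite directions with r
recorded as missing.

**Enrichment.** One-sided hypergeometric over-representation
(equivalently Fisher's exact test), run separately per direction, reporting
the richness factor k/m (query hits over set size — the bubble-chart
x-axis) and −LgP = −log10 *p*. The background is the full annotation
universe of the collection; query genes outside it are dropped with a
warning. No correction by default, BH by flag, matching the raw-*P*
convention above.

**Core funnel.** Core genes are the exact intersection of the genes found
in significant sets of the two collections; sub-core mRNAs are the core
genes present in a curated reference list (matching is case-insensitive
after whitespace stripping, because curated symbol lists mix casings; no
ortholog mapping is attempted). The core network is the induced subgraph on
the sub-core mRNAs and their miRNA/lncRNA neighbours. Because in
predicted-mRNA networks lncRNAs may attach to mRNAs only through shared
miRNAs, `lncrna_adjacency = "shared_mirna"` optionally pulls in lncRNAs
adjacent to the core miRNAs; the default is direct adjacency.

## The synthetic study

`sim_spec()` defines the generating model; its defaults are the package's
standing study conditions: 60 miRNAs, 80 lncRNAs and 400 mRNAs over 3 + 3
samples; per-gene baselines N(8, 1.2²) on the log2 scale; 25% of each class
planted as DE with alternating directions at log2FC = 2; within-group noise
sd 0.25 (log2 units); 12 planted miRNA→mRNA regulations; 22-nt miRNAs and
200-nt UTRs; two collections of 20 size-20 gene sets with half of an
enriched set's members drawn from planted DE mRNAs. These magnitudes are
free choices — the workflow's source data ship only as supplementary
spreadsheets with no distributional description — picked to look like a
small single-batch microarray: log-normal intensities spanning a few
orders of magnitude, effects clearly above noise, replication at the
typical minimum.

Three design points deserve explanation.

* **Closed-loop scales.** Intensities are generated on log2 scale and
  exponentiated, so the DE module's transform inverts the generator
  exactly and planted log2FCs are recovered without bias.
* **Provable recovery.** Planted structure is exact rather than
  probabilistic wherever a downstream threshold must provably fire: UTR
  sites are full-length exact complements of the miRNA, and a planted
  target's log2 profile is the mirror image of its regulator's (group
  effect and residual negated) plus a small independent perturbation of sd
  0.2 × `noise_sd`. A softer alternative — mirrored latent offsets of sd
  2 × `noise_sd` on top of independent noise — leaves the planted
  correlation near −0.95, which at n = 6 samples fails |r| > 0.9 in a
  non-negligible fraction of draws and inflates within-group variance
  enough to cost DE power; the mirror construction pins the planted r
  beyond the cut essentially surely while leaving marginal means and DE
  behaviour untouched. Enriched sets draw their DE members planted-targets
  first, direction-pure and alternating, so each collection contains sets
  that must rank first for the candidate queries.
* **Determinism.** Every generator op seeds a substream derived from
  `rng_seed` (expression +0, miRNAs +1, UTRs +2, gene sets +offset by
  collection prefix, reference +5), the seed is echoed into output headers,
  and equal spec + seed reproduces every file byte-for-byte.

What the generator does **not** emulate: probe-level artifacts (spatial
effects, background correction, dye bias), batch structure, heavy-tailed
or intensity-dependent noise, correlated null genes, paralogous UTR
families, or annotation noise in gene sets. Passing recovery tests
therefore certify the pipeline's logic — thresholds, sign rules, funnel
algebra — not robustness to real microarray pathology; on real data the
false-positive structure will be worse than the planted one.

Background scans do produce occasional wobble-rich spurious sites that pass
both default thresholds once thousands of miRNA×UTR combinations are
scanned — as in real target prediction, where candidate lists are
chance-inflated. The funnel tolerates them: spurious candidates lack
reference-list support and enriched-set membership, so exact core recovery
holds anyway (and the tests assert exactly that).

## Numerical choices

* Strict inequalities at both the correlation cut (|r| > 0.9) and the
  score/energy thresholds read "greater than threshold" literally; the
  energy threshold is "at most" (−20 kcal/mol), i.e. more stable, since ΔG
  is negative — the only physically sensible reading.
* Alignment tie-breaking is fully deterministic: traceback prefers pairing,
  then gap-in-UTR, then gap-in-miRNA; among equal-scoring cells the
  smallest UTR end (hence leftmost site) wins. Coordinates are 0-based
  half-open internally and 1-based inclusive in all reports.
* Float comparisons in traceback use an absolute 1e-9 tolerance against
  integer-valued score arithmetic.
* A miRNA longer than its UTR yields an empty result, not an error; empty
  sequence sets yield empty tables; an empty correlation table yields a
  valid empty network.
* Test problem sizes are the package's chosen desk scale: oracle
  equivalence on 200 random pairs with |miRNA| ≤ 7 and |UTR| ≤ 12 against
  an exhaustive enumeration oracle; hypergeometric agreement with
  combinatorial summation for N ≤ 30 and true subset enumeration for
  N ≤ 12; DE calibration on a 10,000-gene null matrix; end-to-end recovery
  and byte-level determinism at the default study conditions above.

## Limitations

* Only 3'UTRs are scanned in the pipeline; the prediction module accepts
  any sequence set (lncRNAs as targets included) but CDS/5'UTR scanning,
  conservation filtering and ensemble thermodynamics are out of scope.
* The hypergeometric test ignores gene-set topology (no GO-DAG
  propagation) and annotation bias.
* Pearson r at n = 6 is a noisy estimator; the 0.9 cut controls the null
  rate (~1.5% of independent pairs) but guarantees nothing about effect
  sizes. Partial correlations and soft-threshold (WGCNA-style) networks
  are deliberately not provided.
* The reference-list filter is only as good as the curated list; the
  shipped `osteogenesis_genes.txt` is a small convenience fixture, not a
  database snapshot.
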