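# Hypergeometric gene-set over-representation analysis.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set id -> member gene ids).
#' @param background Gene universe; defaults to the union of all members.
#'   Members must be contained in it.
#' @param set_names Optional human-readable set descriptions (recycled name
#'   attribute; defaults to the set ids).
#' @return A `cnc_genesets` object.
#' @export
new_genesets <- function(sets, background = NULL, set_names = NULL) {
  if (!is.list(sets)) abort("`sets` must be a list of character vectors.")
  if (length(sets) > 0L) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      abort("Set ids must be unique and non-missing.")
    }
    if (any(lengths(sets) == 0L)) abort("Empty gene sets are not allowed.")
    sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  }
  members <- unique(unlist(sets, use.names = FALSE)) %||% character(0)
  background <- sort(unique(as.character(background %||% members)))
  stray <- setdiff(members, background)
  if (length(stray) > 0L) {
    abort(sprintf("Set member(s) outside the background: %s.",
                  paste(head(stray, 5), collapse = ", ")))
  }
  set_names <- set_names %||% names(sets)
  if (length(sets) > 0L) names(set_names) <- names(sets)
  structure(
    list(sets = sets, set_names = set_names, background = background),
    class = "cnc_genesets"
  )
}

#' @export
print.cnc_genesets <- function(x, ...) {
  cat(sprintf("<cnc_genesets> %d sets over %d background genes\n",
              length(x$sets), length(x$background)))
  invisible(x)
}

#' Hypergeometric over-representation p-value
#'
#' One-sided upper tail P(X >= k) for drawing `k` annotated genes in a query
#' of size `n` from a background of `N` genes of which `m` are annotated
#' (equivalently a one-sided Fisher exact test).
#'
#' @param k Query genes in the set.
#' @param m Set size within the background.
#' @param n Query size.
#' @param N Background size.
#' @return p-value; vectorized over its arguments.
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10) # 1 / choose(10, 5)
#' @export
hypergeom_pvalue <- function(k, m, n, N) {
  if (any(k < 0 | m < 0 | n < 0 | N < 1 | k > pmin(m, n) | m > N | n > N)) {
    abort("Inconsistent counts: need 0 <= k <= min(m, n) and m, n <= N.")
  }
  phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Tests every set of a collection for over-representation of a query gene
#' list under the hypergeometric law, reporting the richness factor (k/m, the
#' fraction of the set hit by the query) and -LgP (-log10 p). Query genes
#' outside the background are dropped with a warning. Sets are reported in
#' ascending p order.
#'
#' @param query Character vector of gene ids (e.g. one direction's candidate
#'   or DE genes).
#' @param collection A `cnc_genesets` collection.
#' @param alpha Significance threshold.
#' @param direction Optional direction label (`"up"`/`"down"`) echoed into
#'   the result, for per-direction runs.
#' @param correction `"none"` (raw p, default) or `"BH"`.
#' @return Tibble: `set_id`, `name`, `k`, `m`, `n`, `N`, `p_value`, `p_adj`,
#'   `richness_factor`, `neg_log_p`, `direction`, `significant`, and a
#'   list-column `genes` of the query genes hitting each set.
#' @export
enrich <- function(query, collection, alpha = 0.05, direction = NA_character_,
                   correction = c("none", "BH")) {
  correction <- match.arg(correction)
  stopifnot(inherits(collection, "cnc_genesets"))
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1)
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$background)
  if (length(outside) > 0L) {
    warn(sprintf("%d query gene(s) outside the background were dropped: %s.",
                 length(outside), paste(head(outside, 5), collapse = ", ")))
    query <- setdiff(query, outside)
  }
  if (length(collection$sets) == 0L) {
    return(tibble(
      set_id = character(0), name = character(0), k = integer(0),
      m = integer(0), n = integer(0), N = integer(0), p_value = numeric(0),
      p_adj = numeric(0), richness_factor = numeric(0), neg_log_p = numeric(0),
      direction = character(0), significant = logical(0), genes = list()
    ))
  }
  N <- length(collection$background)
  n <- length(query)
  hits <- lapply(collection$sets, intersect, x = query)
  out <- tibble(
    set_id = names(collection$sets),
    name = unname(collection$set_names[names(collection$sets)]),
    k = unname(lengths(hits)),
    m = unname(lengths(collection$sets)),
    n = n,
    N = N,
    genes = unname(hits)
  ) |>
    mutate(
      p_value = hypergeom_pvalue(.data$k, .data$m, .data$n, .data$N),
      p_adj = p.adjust(.data$p_value, method = "BH"),
      richness_factor = .data$k / .data$m,
      neg_log_p = -log10(.data$p_value),
      direction = direction,
      significant = if (correction == "BH") .data$p_adj < alpha
      else .data$p_value < alpha
    ) |>
    arrange(.data$p_value, .data$set_id) |>
    select("set_id", "name", "k", "m", "n", "N", "p_value", "p_adj",
           "richness_factor", "neg_log_p", "direction", "significant", "genes")
  out
}

#' Union of query genes in significant sets
#'
#' @param results Enrichment tibble from [enrich()] (one direction).
#' @param query The query gene list the results were computed from.
#' @return Sorted character vector: union over significant sets of the set
#'   members intersected with the query.
#' @export
genes_from_significant_sets <- function(results, query) {
  assert_cols(results, c("significant", "genes"), "results")
  sig <- results |> filter(.data$significant)
  sort(intersect(unique(unlist(sig$genes, use.names = FALSE)),
                 as.character(query)))
}
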