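# Readers and writers for the pipeline's plain-text dialects.
#
# Expression tables are TSV with gene_id, gene_class, then sample columns and
# a sample->group sidecar TSV; sequences are FASTA; gene sets are GMT; gene
# lists are one id per line. Writers and readers round-trip on canonical
# form, and generator outputs carry the seed in a comment header.

seed_header <- function(x) {
  seed <- attr(x, "rng_seed")
  if (is.null(seed)) character(0) else sprintf("# rng_seed=%d", seed)
}

write_tsv_with_header <- function(df, path, header = character(0)) {
  if (length(header) > 0L) {
    readr::write_lines(header, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Write / read an expression table
#'
#' @param expr Expression tibble (`gene_id`, `gene_class`, sample columns).
#' @param path TSV path. Comment lines starting `#` are permitted and carry
#'   the generator seed for simulated data.
#' @return `read_expression()` returns the expression tibble;
#'   `write_expression()` returns `path` invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  write_tsv_with_header(expr, path, seed_header(expr))
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  probs <- readr::problems(expr)
  if (nrow(probs) > 0L) {
    abort(sprintf("Malformed expression table %s at line(s): %s.",
                  path, paste(head(unique(probs$row), 5), collapse = ", ")))
  }
  validate_expression(expr)
  expr
}

#' Write / read a sample-to-group table
#'
#' @param groups Tibble with `sample_id` and `group`.
#' @param path TSV path.
#' @return `read_groups()` returns the tibble; the writer returns `path`
#'   invisibly.
#' @export
write_groups <- function(groups, path) {
  assert_cols(groups, c("sample_id", "group"), "groups")
  write_tsv_with_header(groups, path, seed_header(groups))
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  groups <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            progress = FALSE)
  assert_cols(groups, c("sample_id", "group"), "groups")
  if (anyDuplicated(groups$sample_id)) {
    abort(sprintf("Duplicate sample_id(s) in %s.", path))
  }
  groups
}

#' Write / read sequences as FASTA
#'
#' Sequences are normalized to the RNA alphabet on read (T -> U).
#'
#' @param seqs Named character vector of sequences.
#' @param path FASTA path.
#' @return `read_fasta()` returns a named character vector; the writer
#'   returns `path` invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("Sequences must have unique names.")
  }
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(normalize_sequence(seqs)),
                              path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate sequence id(s) in %s.", path))
  }
  setNames(normalize_sequence(as.character(set)), ids)
}

#' Write / read a gene-set collection as GMT
#'
#' GMT lines are `set_id<TAB>description<TAB>member...`. On read the
#' background defaults to the union of all members unless supplied.
#'
#' @param collection A `cnc_genesets`.
#' @param path GMT path.
#' @param background Optional gene universe for the read collection.
#' @return `read_gmt()` returns a `cnc_genesets`; the writer returns `path`
#'   invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "cnc_genesets"))
  lines <- purrr::imap_chr(collection$sets, function(members, id) {
    paste(c(id, unname(collection$set_names[id]), members), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, background = NULL) {
  raw <- readr::read_lines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) {
    return(new_genesets(list(), background = background))
  }
  sets <- fgsea::gmtPathways(path)
  fields <- strsplit(raw, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    abort(sprintf("Malformed GMT line(s) in %s: %s.",
                  path, paste(head(which(short), 5), collapse = ", ")))
  }
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  names(descriptions) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(descriptions))) {
    abort(sprintf("Duplicate set id(s) in %s.", path))
  }
  new_genesets(sets, background = background,
               set_names = descriptions[names(sets)])
}

#' Write / read a plain-text gene list
#'
#' One gene id per line; blanks and `#` comments are ignored on read.
#'
#' @param genes Character vector of gene ids.
#' @param path File path.
#' @return `read_gene_list()` returns a character vector; the writer returns
#'   `path` invisibly.
#' @export
write_gene_list <- function(genes, path) {
  readr::write_lines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readr::read_lines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a CNC network to disk
#'
#' `"tsv"` writes the edge list (`source`, `target`, `edge_type`, `r`,
#' `support`); `"graphml"` writes the full graph with node attributes
#' (`gene_class`, `direction`, `degree`) via igraph.
#'
#' @param net A `cnc_network`.
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(net, "cnc_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- net$edges |>
      select(source = "gene_a", target = "gene_b", "edge_type", "r", "support")
    readr::write_tsv(edges, path)
  } else {
    igraph::write_graph(as.igraph(net), path, format = "graphml")
  }
  invisible(path)
}
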