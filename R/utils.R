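# internal assertions ---------------------------------------------------------

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s (got %s).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, lower, x))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s (got %s).", name, upper, x))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_scalar_num(x, name, lower = lower)
  if (x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number (got %s).", name, x))
  }
  invisible(as.integer(x))
}

assert_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# expression-table helpers -----------------------------------------------------

GENE_CLASSES <- c("miRNA", "lncRNA", "mRNA")

#' Sample columns of an expression table
#'
#' An expression table stores one row per gene with `gene_id` and `gene_class`
#' metadata columns followed by one numeric column per sample. This helper
#' returns the sample column names.
#'
#' @param expr Expression tibble (`gene_id`, `gene_class`, sample columns).
#' @return Character vector of sample column names.
#' @export
sample_cols <- function(expr) {
  assert_cols(expr, c("gene_id", "gene_class"), "expr")
  setdiff(names(expr), c("gene_id", "gene_class"))
}

validate_expression <- function(expr, groups = NULL) {
  assert_cols(expr, c("gene_id", "gene_class"), "expr")
  samples <- sample_cols(expr)
  if (length(samples) < 4L) {
    abort("Expression table needs at least 4 sample columns (2 per group).")
  }
  if (anyDuplicated(expr$gene_id)) {
    dup <- unique(expr$gene_id[duplicated(expr$gene_id)])
    abort(sprintf("Duplicate gene_id(s): %s.", paste(head(dup, 5), collapse = ", ")))
  }
  bad_class <- setdiff(unique(expr$gene_class), GENE_CLASSES)
  if (length(bad_class) > 0L) {
    abort(sprintf(
      "Unknown gene_class value(s): %s (expected miRNA, lncRNA, mRNA).",
      paste(bad_class, collapse = ", ")
    ))
  }
  m <- as.matrix(expr[samples])
  if (!is.numeric(m) || anyNA(m)) {
    abort("Sample columns must be numeric with no missing values.")
  }
  if (!is.null(groups)) {
    assert_cols(groups, c("sample_id", "group"), "groups")
    if (!setequal(groups$sample_id, samples)) {
      abort("`groups$sample_id` must match the expression sample columns exactly.")
    }
    tab <- table(groups$group)
    if (!setequal(names(tab), c("control", "induced"))) {
      abort("`groups$group` must use the labels 'control' and 'induced'.")
    }
    if (any(tab < 2L)) {
      abort("Each group needs at least 2 replicates (t-test undefined otherwise).")
    }
  }
  invisible(expr)
}

expr_matrix <- function(expr) {
  samples <- sample_cols(expr)
  m <- as.matrix(expr[samples])
  rownames(m) <- expr$gene_id
  m
}
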