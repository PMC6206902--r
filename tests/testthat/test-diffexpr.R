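make_expr <- function(m, classes = "mRNA") {
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(nrow(m))),
    gene_class = rep_len(classes, nrow(m))
  ) |>
    dplyr::bind_cols(tibble::as_tibble(m, .name_repair = ~ colnames(m)))
}

groups6 <- tibble::tibble(
  sample_id = c("c1", "c2", "c3", "i1", "i2", "i3"),
  group = rep(c("control", "induced"), each = 3)
)

test_that("log2 transform clamps at the floor and inverts powers of two", {
  m <- matrix(c(1024, 0, 2, 8, 1, 0.5), nrow = 1,
              dimnames = list(NULL, groups6$sample_id))
  out <- log2_normalize(make_expr(m), floor = 1)
  expect_equal(unlist(out[1, groups6$sample_id], use.names = FALSE),
               c(10, 0, 1, 3, 0, 0))
  expect_error(log2_normalize(make_expr(m), floor = 0), ">")
  expect_error(log2_normalize(make_expr(-m)), "nonnegative")
})

test_that("quantile mode equalizes the per-sample distributions", {
  set.seed(9)
  m <- matrix(rlnorm(50 * 6, 6, 1), nrow = 50,
              dimnames = list(NULL, groups6$sample_id))
  out <- log2_normalize(make_expr(m), method = "quantile")
  vals <- as.matrix(out[groups6$sample_id])
  sorted <- apply(vals, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
})

test_that("welch_t matches hand-derived and textbook-formula values", {
  # identical groups
  r0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$p_value, 1)
  # shifted groups: mean diff -3, se = sqrt(2/3), df = 4
  r1 <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r1$df, 4)
  expect_equal(r1$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  # unequal sizes and variances vs the Welch-Satterthwaite formulas
  x <- c(1, 2, 3, 4); y <- c(10, 20, 30)
  se2x <- var(x) / 4; se2y <- var(y) / 3
  t_ref <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df_ref <- (se2x + se2y)^2 / (se2x^2 / 3 + se2y^2 / 2)
  r2 <- welch_t(x, y)
  expect_equal(r2$t_stat, t_ref, tolerance = 1e-12)
  expect_equal(r2$df, df_ref, tolerance = 1e-12)
  expect_equal(r2$p_value, 2 * pt(-abs(t_ref), df_ref), tolerance = 1e-12)
})

test_that("degenerate constant groups are resolved explicitly", {
  eq <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p_value, 1)
  expect_true(eq$degenerate)
  ne <- welch_t(c(2, 2, 2), c(5, 5, 5))
  expect_equal(ne$p_value, 0)
  expect_true(ne$degenerate)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("planted DE genes are recovered with correct directions", {
  spec <- tiny_spec(planted_log2fc = 3, noise_sd = 0.1, n_target_pairs = 0L)
  sim <- simulate_expression(spec)
  de <- differential_expression(log2_normalize(sim$expression), sim$groups)
  truth <- sim$truth$de_genes
  hit <- de[match(truth$gene_id, de$gene_id), ]
  expect_true(all(hit$significant))
  expect_identical(hit$direction, truth$direction)
  # empty rejection region
  de0 <- differential_expression(log2_normalize(sim$expression), sim$groups,
                                 alpha = 0)
  expect_equal(sum(de0$significant), 0L)
})

test_that("swapping group labels negates effects and keeps p-values", {
  spec <- tiny_spec(n_target_pairs = 0L)
  sim <- simulate_expression(spec)
  norm <- log2_normalize(sim$expression)
  swapped <- sim$groups |>
    dplyr::mutate(group = ifelse(group == "control", "induced", "control"))
  a <- differential_expression(norm, sim$groups)
  b <- differential_expression(norm, swapped)
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$t_stat, -a$t_stat)
  expect_equal(b$p_value, a$p_value)
})

test_that("BH correction never rejects more than the raw filter", {
  spec <- tiny_spec(n_target_pairs = 0L)
  sim <- simulate_expression(spec)
  norm <- log2_normalize(sim$expression)
  raw <- differential_expression(norm, sim$groups, correction = "none")
  bh <- differential_expression(norm, sim$groups, correction = "BH")
  expect_lte(sum(bh$significant), sum(raw$significant))
})

test_that("zero-variance genes get p = 1 with a warning", {
  m <- matrix(c(rep(5, 6), rnorm(6, 8)), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, groups6$sample_id))
  expr <- make_expr(m)
  expect_warning(
    de <- differential_expression(expr, groups6),
    "constant"
  )
  expect_equal(de$p_value[1], 1)
  expect_false(de$significant[1])
})
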