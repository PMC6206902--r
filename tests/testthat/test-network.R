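test_that("pearson_r reproduces closed-form values", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(x, rep(1, 4)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("cross-class correlations enumerate exactly the cross-class pairs", {
  m <- matrix(rnorm(18), nrow = 3,
              dimnames = list(NULL, sprintf("s%d", 1:6)))
  expr <- tibble::tibble(
    gene_id = c("miR-1", "lnc-1", "gene-1"),
    gene_class = c("miRNA", "lncRNA", "mRNA")
  ) |>
    dplyr::bind_cols(tibble::as_tibble(m, .name_repair = ~ colnames(m)))
  genes <- expr[, c("gene_id", "gene_class")]
  out <- cross_class_correlations(expr, genes)
  expect_equal(nrow(out), 3L)
  expect_setequal(paste(out$class_a, out$class_b),
                  c("miRNA lncRNA", "miRNA mRNA", "lncRNA mRNA"))
  # invariant under permuting the input gene order
  out2 <- cross_class_correlations(expr, genes[c(3, 1, 2), ])
  expect_identical(out, out2)
  # a constant gene is dropped with a warning; other records intact
  expr2 <- expr
  expr2[2, sprintf("s%d", 1:6)] <- as.list(rep(1, 6))
  expect_warning(out3 <- cross_class_correlations(expr2, genes), "constant")
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$r, out$r[out$class_a == "miRNA" & out$class_b == "mRNA"])
})

test_that("planted pairs anticorrelate below -0.9 in nearly all simulations", {
  rs <- vapply(1:200, function(s) {
    spec <- sim_spec(n_mirna = 4L, n_lncrna = 4L, n_mrna = 12L,
                     de_fraction_per_class = 0.5, n_target_pairs = 2L,
                     n_genesets = 0L, rng_seed = 9000L + s)
    sim <- simulate_expression(spec)
    m <- log2(as.matrix(sim$expression[, sim$groups$sample_id]))
    rownames(m) <- sim$expression$gene_id
    p <- sim$truth$target_pairs[1, ]
    cor(m[p$mirna_id, ], m[p$gene_id, ])
  }, numeric(1))
  expect_gte(mean(rs <= -0.9), 0.95)
})

test_that("the null rate of |r| > 0.9 matches the Pearson null at n = 6", {
  set.seed(77)
  n_pairs <- 10000L
  x <- matrix(rnorm(n_pairs * 6), n_pairs)
  y <- matrix(rnorm(n_pairs * 6), n_pairs)
  xc <- x - rowMeans(x); yc <- y - rowMeans(y)
  r <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
  # analytic null via the t transform: |r| > r0 <=> |t| > r0*sqrt(4)/sqrt(1-r0^2)
  p_true <- 2 * pt(0.9 * 2 / sqrt(1 - 0.81), df = 4, lower.tail = FALSE)
  mc_sd <- sqrt(p_true * (1 - p_true) / n_pairs)
  expect_lt(abs(mean(abs(r) > 0.9) - p_true), 4 * mc_sd)
})

toy_network_inputs <- function() {
  corrs <- tibble::tibble(
    gene_a = c("miR-1", "miR-1", "miR-2", "lnc-1", "lnc-1", "miR-2"),
    gene_b = c("gene-1", "lnc-1", "gene-2", "gene-1", "gene-2", "gene-1"),
    class_a = c("miRNA", "miRNA", "miRNA", "lncRNA", "lncRNA", "miRNA"),
    class_b = c("mRNA", "lncRNA", "mRNA", "mRNA", "mRNA", "mRNA"),
    r = c(-0.95, -0.95, -0.91, 0.95, 0.5, -0.99),
    n_samples = 6L
  )
  targets <- tibble::tibble(mirna_id = "miR-1", target_id = "gene-1",
                            target_class = "mRNA")
  directions <- tibble::tibble(
    gene_id = c("miR-1", "miR-2", "lnc-1", "gene-1", "gene-2"),
    gene_class = c("miRNA", "miRNA", "lncRNA", "mRNA", "mRNA"),
    direction = c("down", "down", "up", "up", "up")
  )
  list(corrs = corrs, targets = targets, directions = directions)
}

test_that("edges obey the threshold, sign and target-support rules", {
  inp <- toy_network_inputs()
  net <- build_cnc_network(inp$corrs, inp$targets, inp$directions,
                           threshold = 0.9)
  # kept: miR-1/gene-1 (supported, negative), miR-1/lnc-1 (negative),
  #       lnc-1/gene-1 (positive)
  # dropped: miR-2/gene-2 and miR-2/gene-1 (no site support),
  #          lnc-1/gene-2 (|r| below cut)
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(paste(net$edges$gene_a, net$edges$gene_b),
                  c("miR-1 gene-1", "miR-1 lnc-1", "lnc-1 gene-1"))
  expect_equal(sum(net$nodes$degree), 2L * nrow(net$edges))
  # strict cut at 1.0 removes everything
  net1 <- build_cnc_network(inp$corrs, inp$targets, inp$directions,
                            threshold = 1.0)
  expect_equal(nrow(net1$edges), 0L)
  # empty correlation table is a valid empty network
  net0 <- build_cnc_network(inp$corrs[0, ], inp$targets, inp$directions)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(nrow(net0$nodes), 0L)
})

test_that("predicted-mRNA mode builds miRNA-mRNA edges from target support", {
  inp <- toy_network_inputs()
  net <- build_cnc_network(inp$corrs, inp$targets, inp$directions,
                           threshold = 0.9, mrna_mode = "predicted")
  mm <- net$edges[net$edges$edge_type == "miRNA-mRNA", ]
  expect_equal(nrow(mm), 1L)
  expect_true(is.na(mm$r))
  expect_identical(c(mm$gene_a, mm$gene_b), c("miR-1", "gene-1"))
  expect_false("lncRNA-mRNA" %in% net$edges$edge_type)
})

test_that("degree selection sorts and filters mRNA nodes", {
  # star around gene-1 (degree 3), gene-2/gene-3 degree 2, gene-4 degree 1,
  # gene-5 isolated
  corrs <- tibble::tibble(
    gene_a = c("miR-1", "lnc-1", "lnc-2", "lnc-1", "lnc-2", "lnc-1", "lnc-2",
               "lnc-3"),
    gene_b = c("gene-1", "gene-1", "gene-1", "gene-2", "gene-2", "gene-3",
               "gene-3", "gene-4"),
    class_a = c("miRNA", rep("lncRNA", 7)),
    class_b = "mRNA",
    r = c(-0.95, rep(0.95, 7)),
    n_samples = 6L
  )
  targets <- tibble::tibble(mirna_id = "miR-1", target_id = "gene-1",
                            target_class = "mRNA")
  directions <- tibble::tibble(
    gene_id = c("miR-1", "lnc-1", "lnc-2", "lnc-3", sprintf("gene-%d", 1:5)),
    gene_class = c("miRNA", rep("lncRNA", 3), rep("mRNA", 5)),
    direction = c("down", rep("up", 8))
  )
  net <- build_cnc_network(corrs, targets, directions)
  sel <- select_mrnas_by_degree(net, min_degree = 2L)
  expect_identical(sel$gene_id, c("gene-1", "gene-2", "gene-3"))
  expect_identical(sel$degree, c(3L, 2L, 2L))
  sel1 <- select_mrnas_by_degree(net, min_degree = 1L)
  expect_false("gene-5" %in% sel1$gene_id) # isolated mRNA never enters
})

test_that("tidiers summarise networks consistently", {
  inp <- toy_network_inputs()
  net <- build_cnc_network(inp$corrs, inp$targets, inp$directions)
  td <- tidy(net)
  expect_equal(nrow(td), nrow(net$edges))
  expect_true(all(c("class_a", "class_b", "direction_a") %in% names(td)))
  gl <- glance(net)
  expect_equal(gl$n_edges, 3L)
  expect_equal(gl$n_mirna + gl$n_lncrna + gl$n_mrna, gl$n_nodes)
  g <- as.igraph(net)
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(unname(igraph::degree(g)[net$nodes$gene_id]),
               net$nodes$degree)
})
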