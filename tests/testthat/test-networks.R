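# coexpr_networks: PCC, edge p-values, network construction, Diff1/Diff2

test_that("pcc matches hand values and the stats::cor oracle", {
  set.seed(1)
  x <- stats::rnorm(10)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x + 5), -1)
  # hand evaluation: cov = 1.5, sd_a = 1, sd_b = sqrt(7/3)
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 4)), 1.5 / sqrt(7 / 3),
               tolerance = 1e-12)
  for (i in 1:50) {
    a <- stats::rnorm(7); b <- stats::rnorm(7)
    expect_equal(pcc(a, b), stats::cor(a, b), tolerance = 1e-10)
  }
  expect_error(pcc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pcc(1:2, 1:2), "length >= 3")
})

test_that("pcc_pvalue matches the cor.test oracle and its critical point", {
  expect_equal(pcc_pvalue(0, 10), 1)
  expect_equal(pcc_pvalue(1, 10), 0)
  expect_equal(pcc_pvalue(-1, 10), 0)
  # critical |r| at len = 7, alpha = 0.05: invert the t quantile (oracle)
  tcrit <- stats::qt(0.975, df = 5)
  rcrit <- tcrit / sqrt(5 + tcrit^2)
  expect_equal(rcrit, 0.754, tolerance = 1e-3)
  expect_lt(pcc_pvalue(rcrit + 1e-6, 7), 0.05)
  expect_gt(pcc_pvalue(rcrit - 1e-6, 7), 0.05)
  # oracle agreement on random instances
  set.seed(2)
  for (i in 1:50) {
    a <- stats::rnorm(9); b <- stats::rnorm(9)
    expect_equal(pcc_pvalue(stats::cor(a, b), 9),
                 stats::cor.test(a, b)$p.value, tolerance = 1e-10)
  }
  expect_error(pcc_pvalue(0.5, 2), "parameter error")
})

test_that("build_network equals the brute-force exhaustive-pairs oracle", {
  set.seed(3)
  H <- matrix(stats::rnorm(7 * 10), 7, 10,
              dimnames = list(NULL, sprintf("g%02d", 1:10)))
  net <- build_network(H, colnames(H), 0.05, "t1", "case")
  expect_identical(network_keys(net),
                   oracle_network_edges(H, colnames(H), 0.05))
  expect_true(all(net$edges$pvalue < 0.05))
  expect_true(all(abs(net$edges$pcc) <= 1))
  expect_false(any(net$edges$u == net$edges$v))

  # identical columns give one certain edge
  H2 <- cbind(a = c(1, 3, 2, 5, 4), b = c(1, 3, 2, 5, 4))
  net2 <- build_network(H2, c("a", "b"), 0.05)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$pcc, 1)

  # constant column excluded with a warning; tiny sets warn and are empty
  H3 <- cbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(3, 1, 2))
  expect_warning(net3 <- build_network(H3, c("a", "b", "c"), 0.5), "constant")
  expect_false("b" %in% net3$nodes)
  expect_warning(net4 <- build_network(H3, "a", 0.05), "fewer than two")
  expect_equal(nrow(net4$edges), 0L)
})

test_that("edges are invariant to gene order and monotone in alpha", {
  set.seed(4)
  H <- matrix(stats::rnorm(7 * 15), 7, 15,
              dimnames = list(NULL, sprintf("g%02d", 1:15)))
  g <- colnames(H)
  n1 <- build_network(H, g, 0.2)
  n2 <- build_network(H[, rev(g)], rev(g), 0.2)
  expect_identical(network_keys(n1), network_keys(n2))
  # lowering alpha only removes edges
  for (a in c(0.1, 0.05, 0.01)) {
    sub <- build_network(H, g, a)
    expect_true(all(network_keys(sub) %in% network_keys(n1)))
  }
})

test_that("differential networks satisfy the set-algebra identities", {
  # hand example
  mk <- function(edges, cond) {
    structure(list(condition_label = cond, tissue_id = "t",
                   nodes = c("a", "b", "c", "d"),
                   edges = data.frame(u = edges[, 1], v = edges[, 2],
                                      pcc = 1, pvalue = 0.01,
                                      stringsAsFactors = FALSE)),
              class = "CoexpressionNetwork")
  }
  c1 <- mk(rbind(c("a", "b"), c("b", "c")), "case")
  c2 <- mk(rbind(c("b", "c"), c("c", "d")), "control")
  den <- differential_network(c1, c2)
  expect_identical(paste(den$diff1$u, den$diff1$v), "a b")
  expect_identical(paste(den$diff2$u, den$diff2$v), "c d")
  expect_identical(differential_network(c1, c1)$diff1,
                   den$diff1[0, ])

  # identities on 100 random network pairs, plus igraph degree oracle
  has_igraph <- requireNamespace("igraph", quietly = TRUE)
  for (seed in 1:100) {
    nets <- random_network_pair(20, seed)
    dd <- differential_network(nets$c1, nets$c2)
    k1 <- network_keys(nets$c1); k2 <- network_keys(nets$c2)
    d1 <- paste(dd$diff1$u, dd$diff1$v, sep = "|")
    d2 <- paste(dd$diff2$u, dd$diff2$v, sep = "|")
    expect_length(intersect(d1, k2), 0)
    expect_length(intersect(d2, k1), 0)
    expect_setequal(c(d1, intersect(k1, k2)), k1)
    expect_setequal(c(d2, intersect(k1, k2)), k2)
    if (has_igraph && seed <= 10) {
      g <- igraph::graph_from_data_frame(dd$diff1[, c("u", "v")],
                                         directed = FALSE,
                                         vertices = dd$nodes)
      expect_equal(dd$degree1[dd$nodes],
                   igraph::degree(g)[dd$nodes])
    }
  }

  # tissue mismatch
  c3 <- mk(rbind(c("a", "b")), "case"); c3$tissue_id <- "other"
  expect_error(differential_network(c3, c2), "mismatch")
})

test_that("edge lists are written as TSV with the documented columns", {
  nets <- random_network_pair(10, 1)
  den <- differential_network(nets$c1, nets$c2)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(nets$c1, f1)
  write_edge_list(den, f2)
  t1 <- utils::read.delim(f1)
  expect_true(all(c("gene_u", "gene_v", "pcc", "pvalue", "condition",
                    "tissue") %in% names(t1)))
  t2 <- utils::read.delim(f2)
  expect_true(all(t2$diff_side %in% c("case_specific", "control_specific")))
})
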