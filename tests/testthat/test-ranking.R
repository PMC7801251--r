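# candidate_ranking: R(u), per-tissue top lists, consensus, product rank

test_that("relatedness_score is the mean anchor correlation", {
  # two anchors with known correlations to u
  k <- 7
  set.seed(7)
  base <- stats::rnorm(k)
  H <- cbind(u = base,
             v1 = base + stats::rnorm(k, sd = 0.3),
             v2 = -base + stats::rnorm(k, sd = 0.3))
  r <- relatedness_score("u", c("v1", "v2"), H)
  expect_equal(r, mean(c(stats::cor(H[, "u"], H[, "v1"]),
                         stats::cor(H[, "u"], H[, "v2"]))), tolerance = 1e-12)
  expect_lte(abs(r), 1)

  # perfect correlation with every anchor -> exactly 1
  H2 <- cbind(u = base, a1 = 2 * base, a2 = base + 3)
  expect_equal(relatedness_score("u", c("a1", "a2"), H2), 1)

  # brute-force loop oracle on 30 genes x 5 anchors
  set.seed(8)
  H3 <- matrix(stats::rnorm(7 * 35), 7, 35,
               dimnames = list(NULL, sprintf("g%02d", 1:35)))
  anchors <- sprintf("g%02d", 31:35)
  for (u in sprintf("g%02d", 1:30)) {
    oracle <- mean(vapply(anchors,
                          function(v) stats::cor(H3[, u], H3[, v]),
                          numeric(1)))
    expect_equal(relatedness_score(u, anchors, H3), oracle,
                 tolerance = 1e-12)
  }

  # duplicated anchors are deduplicated (score unchanged)
  expect_equal(relatedness_score("g01", c(anchors, anchors[1]), H3),
               relatedness_score("g01", anchors, H3))

  # constant anchor skipped with warning, |S| reduced
  H4 <- cbind(H3, flat = rep(1, 7))
  expect_warning(r4 <- relatedness_score("g01", c(anchors, "flat"), H4),
                 "constant")
  expect_equal(r4, relatedness_score("g01", anchors, H3))
})

test_that("rank_tissue sorts by score with lexicographic ties", {
  k <- 7
  set.seed(9)
  anchor <- stats::rnorm(k)
  mkcol <- function(w) w * anchor + (1 - abs(w)) * stats::rnorm(k)
  H <- cbind(a = anchor, g1 = mkcol(0.95), g2 = mkcol(0.05), g3 = mkcol(0.6))
  rk <- rank_tissue(H, c("g1", "g2", "g3"), "a", top_n = 2, tissue_id = "t")
  expect_identical(rk$top_list, names(sort(-rk$scores))[1:2])
  expect_length(rk$top_list, 2)

  # equal scores -> lexicographic gene order; small pool warns
  H5 <- cbind(a = anchor, zz = anchor + 1, aa = anchor + 1)
  expect_warning(rk2 <- rank_tissue(H5, c("zz", "aa"), "a", top_n = 30),
                 "smaller than top_n")
  expect_identical(rk2$top_list, c("aa", "zz"))

  # anchors are excluded from the candidate pool
  rk3 <- suppressWarnings(rank_tissue(H, c("a", "g1", "g2"), "a", 10))
  expect_false("a" %in% rk3$top_list)
})

test_that("consensus candidates respect the min_tissues rule monotonically", {
  mk <- function(tissue, genes, scores = seq_along(genes)) {
    structure(list(tissue_id = tissue,
                   scores = stats::setNames(scores, genes),
                   top_list = genes, top_n = 30L), class = "GeneRanking")
  }
  rks <- list(mk("t1", c("a", "b")), mk("t2", c("a", "c")),
              mk("t3", c("a", "b")), mk("t4", c("a", "d")),
              mk("t5", c("b", "c")))
  cc <- consensus_candidates(rks, min_tissues = 4)
  expect_identical(cc$candidates$gene_id, "a")  # a: 5 tissues, b: 3
  # degenerate min_tissues = 1 -> union of all top lists
  cc1 <- consensus_candidates(rks, 1)
  expect_setequal(cc1$candidates$gene_id, c("a", "b", "c", "d"))
  # monotone: raising min_tissues never adds candidates
  prev <- cc1$candidates$gene_id
  for (mt in 2:5) {
    cur <- consensus_candidates(rks, mt)$candidates$gene_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(consensus_candidates(list(), 1), "empty")
})

test_that("composite_rank multiplies per-criterion competition ranks", {
  scores <- c(g1 = 0.9, g2 = 0.5, g3 = 0.7, g4 = 0.5, g5 = 0.1)
  fc     <- c(g1 = 3,   g2 = 2,   g3 = 1,   g4 = 5,   g5 = 4)
  deg    <- c(g1 = 10,  g2 = 2,   g3 = 8,   g4 = 2,   g5 = 1)
  cr <- composite_rank(scores, fc, deg)
  # hand oracle: ranks descending with ties.method = "min"
  hand <- rank(-scores, ties.method = "min") *
    rank(-fc, ties.method = "min") * rank(-deg, ties.method = "min")
  expect_equal(cr[names(hand)], hand)
  # best-in-all gene has product 1 and top priority
  cr2 <- composite_rank(c(g1 = 1, g2 = 0), c(g1 = 2, g2 = 1),
                        c(g1 = 5, g2 = 0))
  expect_identical(names(cr2)[1], "g1")
  expect_equal(unname(cr2["g1"]), 1)
  # identical products ordered lexicographically
  cr3 <- composite_rank(c(b = 1, a = 1), c(b = 1, a = 1), c(b = 1, a = 1))
  expect_identical(names(cr3), c("a", "b"))
  # missing gene names the gene and the map
  expect_error(composite_rank(scores, fc[-1], deg), "g1.*fc|fc.*g1")
})

test_that("planted anchor-correlated genes reach the consensus list", {
  ds <- generate_paired_dataset(synthetic_spec(seed = 11))
  fit <- jcnmf(ds$case, ds$control, mode = "soft", seed = 11, restarts = 2)
  cm <- assign_clusters(fit$W1)
  rks <- lapply(seq_len(nrow(cm)), function(i) {
    gs <- select_tissue_gene_set(fit$H1, cm$cluster_index[i], 1,
                                 cm$tissue_id[i])
    rank_tissue(fit$H1, gs$gene_ids, ds$truth$anchor_ids, 30,
                cm$tissue_id[i])
  })
  cc <- consensus_candidates(rks, 4)
  hit <- mean(ds$truth$planted_candidates %in% cc$candidates$gene_id)
  expect_gte(hit, 0.8)
})
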