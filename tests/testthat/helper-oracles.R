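# Independent oracles and small fixtures built in code.
# Oracles deliberately use different routes than the implementation:
# stats::cor / cor.test / t.test / igraph instead of the package's own
# formulas, or brute-force double loops instead of vectorized paths.

make_expression <- function(m = 3, n = 20, seed = 1, label = "case",
                            tissues = sprintf("t%d", seq_len(m)),
                            genes = sprintf("g%02d", seq_len(n))) {
  set.seed(seed)
  vals <- matrix(stats::rgamma(m * n, shape = 2, scale = 3), m, n,
                 dimnames = list(tissues, genes))
  expression_matrix(vals, label)
}

# brute-force co-expression network: double loop, cor.test as the
# independent significance oracle
oracle_network_edges <- function(H, genes, alpha) {
  out <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i >= j) next
      ct <- stats::cor.test(H[, genes[i]], H[, genes[j]])
      if (ct$p.value < alpha) {
        out[[length(out) + 1L]] <- sort(c(genes[i], genes[j]))
      }
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, character(1), collapse = "|"))
}

network_keys <- function(net) {
  if (!nrow(net$edges)) return(character(0))
  sort(paste(net$edges$u, net$edges$v, sep = "|"))
}

# random co-expression networks for set-algebra properties
random_network_pair <- function(n_nodes = 20, seed = 1, tissue = "tX") {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  rand_edges <- function(p) {
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < p
    data.frame(u = pairs[keep, 1], v = pairs[keep, 2],
               pcc = stats::runif(sum(keep), -1, 1),
               pvalue = stats::runif(sum(keep), 0, 0.05),
               stringsAsFactors = FALSE)
  }
  mknet <- function(cond, p) {
    structure(list(condition_label = cond, tissue_id = tissue,
                   nodes = nodes, edges = rand_edges(p)),
              class = "CoexpressionNetwork")
  }
  list(c1 = mknet("case", 0.2), c2 = mknet("control", 0.2))
}

expect_tsv_file <- function(path) {
  expect_true(file.exists(path))
  expect_gt(file.size(path), 0)
}
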