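# Co-expression networks on columns of H and their differential networks.
#
# Correlations are computed between gene columns of the module x gene matrix
# H (vectors of length k, the module count), not on raw expression.  An edge
# is placed when the two-sided correlation test clears the alpha threshold
# (default P < 0.05, no multiple-testing correction).  The differential
# networks Diff1/Diff2 are the condition-specific edge set differences.

#' Sample Pearson correlation coefficient
#'
#' Direct evaluation of the sample PCC with `n - 1` denominators:
#' `sum((a - mean(a)) (b - mean(b))) / ((n - 1) sd(a) sd(b))`.
#'
#' @param a,b Numeric vectors of equal length `>= 3`, neither constant.
#' @return The correlation in `[-1, 1]`.
#' @export
pcc <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 3L) stop("parameter error: vectors must have length >= 3")
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (sa == 0 || sb == 0) {
    stop("undefined correlation: constant input vector")
  }
  sum((a - mean(a)) * (b - mean(b))) / ((length(a) - 1) * sa * sb)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t transform `t = r sqrt((len - 2) / (1 - r^2))` on `len - 2`
#' degrees of freedom; `r = +/-1` returns `p = 0`.
#'
#' @param r Correlation value, `|r| <= 1`.
#' @param len Number of paired observations, `>= 3`.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
pcc_pvalue <- function(r, len) {
  if (len < 3) stop("parameter error: len must be >= 3")
  if (any(abs(r) > 1 + 1e-12)) stop("parameter error: |r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  t <- r[!exact] * sqrt((len - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(-abs(t), df = len - 2)
  p
}

#' Build a PCC co-expression network over a gene set
#'
#' Tests every unordered pair of genes in `gene_set` using the columns of
#' `H`; the pair becomes an edge iff its two-sided correlation p-value is
#' strictly below `alpha`. Constant columns are excluded with a warning.
#'
#' @param H Modules x genes matrix with gene column names.
#' @param gene_set Character vector of gene IDs, a subset of `colnames(H)`.
#' @param alpha Edge significance threshold in `(0, 1)` (default 0.05).
#' @param tissue_id,condition_label Labels carried into the result.
#' @return An object of class `"CoexpressionNetwork"`: list with
#'   `condition_label`, `tissue_id`, `nodes` and an `edges` data frame with
#'   columns `u`, `v` (u < v lexicographically), `pcc`, `pvalue`.
#' @export
build_network <- function(H, gene_set, alpha = 0.05,
                          tissue_id = NA_character_,
                          condition_label = NA_character_) {
  if (alpha <= 0 || alpha >= 1) stop("parameter error: alpha must be in (0, 1)")
  missing <- setdiff(gene_set, colnames(H))
  if (length(missing)) {
    stop("gene(s) absent from H: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  gene_set <- unique(gene_set)
  sub <- H[, gene_set, drop = FALSE]
  const <- apply(sub, 2L, stats::sd) == 0
  if (any(const)) {
    warning("excluding constant column(s): ",
            paste(gene_set[const], collapse = ", "))
    gene_set <- gene_set[!const]
    sub <- sub[, gene_set, drop = FALSE]
  }
  empty <- data.frame(u = character(), v = character(),
                      pcc = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  if (length(gene_set) < 2L) {
    warning("fewer than two usable genes: returning an empty network")
    return(structure(list(condition_label = condition_label,
                          tissue_id = tissue_id,
                          nodes = gene_set, edges = empty),
                     class = "CoexpressionNetwork"))
  }
  C <- stats::cor(sub)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  pv <- pcc_pvalue(C[ut], nrow(sub))
  keep <- pv < alpha
  edges <- if (any(keep)) {
    u0 <- gene_set[ut[keep, 1L]]
    v0 <- gene_set[ut[keep, 2L]]
    data.frame(u = pmin(u0, v0), v = pmax(u0, v0),
               pcc = C[ut][keep], pvalue = pv[keep],
               stringsAsFactors = FALSE)
  } else empty
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(condition_label = condition_label, tissue_id = tissue_id,
                 nodes = gene_set, edges = edges),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf("CoexpressionNetwork '%s'/'%s': %d nodes, %d edges\n",
              x$condition_label, x$tissue_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Degree of every node over an edge data frame; zero for isolated nodes.
edge_degrees <- function(edges, nodes) {
  deg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(factor(c(edges$u, edges$v), levels = nodes))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Differential co-expression network (Diff1/Diff2)
#'
#' `diff1` holds the edges present only in the case network `c1`, `diff2`
#' the edges present only in the control network `c2`; node degrees are
#' computed on each difference set over the union of the node sets, with
#' isolated nodes at degree zero.
#'
#' @param c1,c2 `CoexpressionNetwork` objects for the same tissue
#'   (case and control).
#' @return An object of class `"DifferentialNetwork"`: list with
#'   `tissue_id`, `nodes`, edge data frames `diff1`, `diff2`, and named
#'   integer degree maps `degree1`, `degree2`.
#' @export
differential_network <- function(c1, c2) {
  if (!identical(c1$tissue_id, c2$tissue_id)) {
    stop("tissue mismatch: '", c1$tissue_id, "' vs '", c2$tissue_id, "'")
  }
  k1 <- edge_key(c1$edges$u, c1$edges$v)
  k2 <- edge_key(c2$edges$u, c2$edges$v)
  nodes <- union(c1$nodes, c2$nodes)
  diff1 <- c1$edges[!(k1 %in% k2), , drop = FALSE]
  diff2 <- c2$edges[!(k2 %in% k1), , drop = FALSE]
  rownames(diff1) <- rownames(diff2) <- NULL
  structure(list(tissue_id = c1$tissue_id, nodes = nodes,
                 diff1 = diff1, diff2 = diff2,
                 degree1 = edge_degrees(diff1, nodes),
                 degree2 = edge_degrees(diff2, nodes)),
            class = "DifferentialNetwork")
}

#' @export
print.DifferentialNetwork <- function(x, ...) {
  cat(sprintf("DifferentialNetwork '%s': %d case-specific, %d control-specific edges over %d nodes\n",
              x$tissue_id, nrow(x$diff1), nrow(x$diff2), length(x$nodes)))
  invisible(x)
}

#' Write network edge lists as TSV
#'
#' Co-expression networks get columns `gene_u`, `gene_v`, `pcc`, `pvalue`,
#' `condition`, `tissue`; differential networks add
#' `diff_side` in `{case_specific, control_specific}`.
#'
#' @param x A `CoexpressionNetwork` or `DifferentialNetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "CoexpressionNetwork")) {
    tab <- data.frame(gene_u = x$edges$u, gene_v = x$edges$v,
                      pcc = x$edges$pcc, pvalue = x$edges$pvalue,
                      condition = x$condition_label, tissue = x$tissue_id,
                      stringsAsFactors = FALSE)
  } else if (inherits(x, "DifferentialNetwork")) {
    side <- function(e, lab) if (nrow(e)) cbind(e, diff_side = lab) else NULL
    tab <- rbind(side(x$diff1, "case_specific"), side(x$diff2, "control_specific"))
    if (is.null(tab)) {
      tab <- data.frame(u = character(), v = character(), pcc = numeric(),
                        pvalue = numeric(), diff_side = character())
    }
    names(tab)[names(tab) == "u"] <- "gene_u"
    names(tab)[names(tab) == "v"] <- "gene_v"
    tab$tissue <- x$tissue_id
  } else {
    stop("unsupported network object")
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
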