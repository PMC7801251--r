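# Guilt-by-association candidate ranking.
#
# A gene u is scored by its mean Pearson correlation R(u) with a set S of
# known phenotype-anchor genes, computed on the gene columns of H.  Per
# tissue the top-N non-anchor genes are kept; genes recurring in at least
# `min_tissues` per-tissue top lists become consensus candidates, orderable
# further by the product rank of R(u), fold change and network degree.

#' Anchor-relatedness score R(u)
#'
#' `R(u) = sum(PCC(H[, u], H[, v]) for v in S) / |S|` over the deduplicated
#' anchor set S. Constant anchor columns are skipped with a warning and `|S|`
#' reduced accordingly.
#'
#' @param u Gene ID, a column of `H`.
#' @param anchors Character vector of anchor gene IDs (columns of `H`).
#' @param H Modules x genes matrix with gene column names.
#' @return The mean correlation, in `[-1, 1]`.
#' @export
relatedness_score <- function(u, anchors, H) {
  anchors <- unique(anchors)
  missing <- setdiff(c(u, anchors), colnames(H))
  if (length(missing)) {
    stop("gene(s) absent from H: ", paste(missing, collapse = ", "))
  }
  if (length(anchors) == 0L) stop("anchor set must be non-empty")
  usable <- anchors[apply(H[, anchors, drop = FALSE], 2L, stats::sd) > 0]
  if (length(usable) < length(anchors)) {
    warning("skipping constant anchor column(s): ",
            paste(setdiff(anchors, usable), collapse = ", "))
  }
  if (length(usable) == 0L) stop("no usable (non-constant) anchors")
  mean(vapply(usable, function(v) pcc(H[, u], H[, v]), numeric(1)))
}

#' Rank a tissue's genes by anchor relatedness
#'
#' Scores every non-anchor gene of `gene_set` by [relatedness_score()]
#' (vectorized) and keeps the `top_n` highest, ties broken by lexicographic
#' gene ID.
#'
#' @param H Modules x genes matrix (the condition used for scoring; the case
#'   condition's `H1` by default in the pipeline).
#' @param gene_set Character vector of gene IDs to score (anchors are
#'   removed from the candidate pool).
#' @param anchors Character vector of anchor gene IDs.
#' @param top_n Size of the kept list (default 30); if fewer genes are
#'   available, all are returned with a warning.
#' @param tissue_id Optional label carried into the result.
#' @return An object of class `"GeneRanking"`: list with `tissue_id`,
#'   `scores` (named, all scored genes), `top_list` (ordered gene IDs) and
#'   `top_n`.
#' @export
rank_tissue <- function(H, gene_set, anchors, top_n = 30,
                        tissue_id = NA_character_) {
  if (top_n < 1) stop("parameter error: top_n must be >= 1")
  anchors <- unique(anchors)
  pool <- setdiff(unique(gene_set), anchors)
  missing <- setdiff(c(pool, anchors), colnames(H))
  if (length(missing)) {
    stop("gene(s) absent from H: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  const <- pool[apply(H[, pool, drop = FALSE], 2L, stats::sd) == 0]
  if (length(const)) {
    warning("excluding constant candidate column(s): ",
            paste(const, collapse = ", "))
    pool <- setdiff(pool, const)
  }
  usable <- anchors[apply(H[, anchors, drop = FALSE], 2L, stats::sd) > 0]
  if (length(usable) < length(anchors)) {
    warning("skipping constant anchor column(s): ",
            paste(setdiff(anchors, usable), collapse = ", "))
  }
  if (length(usable) == 0L) stop("no usable (non-constant) anchors")
  if (length(pool) == 0L) stop("no scorable genes in gene_set")
  scores <- rowMeans(stats::cor(H[, pool, drop = FALSE],
                                H[, usable, drop = FALSE]))
  names(scores) <- pool
  if (length(pool) < top_n) {
    warning("gene set smaller than top_n: returning all ", length(pool), " genes")
  }
  ord <- order(-scores, names(scores))
  top <- names(scores)[ord][seq_len(min(top_n, length(scores)))]
  structure(list(tissue_id = tissue_id, scores = scores,
                 top_list = top, top_n = as.integer(top_n)),
            class = "GeneRanking")
}

#' @export
print.GeneRanking <- function(x, ...) {
  cat(sprintf("GeneRanking '%s': %d genes scored, top %d kept (best R(u) = %.3f)\n",
              x$tissue_id, length(x$scores), length(x$top_list),
              if (length(x$top_list)) x$scores[x$top_list[1]] else NA_real_))
  invisible(x)
}

#' Cross-tissue consensus candidates
#'
#' A gene is a consensus candidate when it appears in the top lists of at
#' least `min_tissues` tissues. Candidates are ordered by tissue count
#' (descending), then mean R(u) over the tissues where the gene was scored
#' (descending), then gene ID.
#'
#' @param rankings List of per-tissue `GeneRanking` objects.
#' @param min_tissues Minimum number of tissues (default 4).
#' @return An object of class `"ConsensusCandidates"`: list with
#'   `per_tissue_top` (named list of top lists), a `candidates` data frame
#'   (`gene_id`, `tissue_count`, `mean_R`), `top_n`, `min_tissues`.
#' @export
consensus_candidates <- function(rankings, min_tissues = 4) {
  if (length(rankings) == 0L) stop("empty rankings")
  if (min_tissues < 1) stop("parameter error: min_tissues must be >= 1")
  tops <- lapply(rankings, `[[`, "top_list")
  names(tops) <- vapply(rankings, `[[`, character(1), "tissue_id")
  counts <- table(unlist(tops, use.names = FALSE))
  cand <- names(counts)[counts >= min_tissues]
  mean_r <- vapply(cand, function(g) {
    vals <- unlist(lapply(rankings, function(rk) rk$scores[g]))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  tab <- data.frame(gene_id = cand,
                    tissue_count = as.integer(counts[cand]),
                    mean_R = unname(mean_r),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$tissue_count, -tab$mean_R, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(per_tissue_top = tops, candidates = tab,
                 top_n = rankings[[1]]$top_n,
                 min_tissues = as.integer(min_tissues)),
            class = "ConsensusCandidates")
}

#' @export
print.ConsensusCandidates <- function(x, ...) {
  cat(sprintf("ConsensusCandidates: %d genes in >= %d of %d tissues (top_n = %d)\n",
              nrow(x$candidates), x$min_tissues, length(x$per_tissue_top),
              x$top_n))
  invisible(x)
}

#' Composite product rank
#'
#' Ranks genes independently by anchor relatedness, fold change and network
#' degree (descending: larger is better, competition ranks, rank 1 = best)
#' and multiplies the three rank positions; a smaller product means higher
#' priority. Output is sorted by product, ties by gene ID.
#'
#' @param scores Named R(u) map covering the candidate genes.
#' @param fc Named fold-change map covering the candidate genes.
#' @param degree Named network-degree map covering the candidate genes.
#' @return Named numeric vector of rank products, sorted by priority.
#' @export
composite_rank <- function(scores, fc, degree) {
  genes <- names(scores)
  if (is.null(genes)) stop("`scores` must be a named map")
  for (nm in c("fc", "degree")) {
    map <- get(nm)
    absent <- setdiff(genes, names(map))
    if (length(absent)) {
      stop("gene '", absent[1], "' missing from map '", nm, "'")
    }
  }
  r1 <- rank(-scores, ties.method = "min")
  r2 <- rank(-fc[genes], ties.method = "min")
  r3 <- rank(-degree[genes], ties.method = "min")
  prod <- stats::setNames(as.numeric(r1 * r2 * r3), genes)
  prod[order(prod, genes)]
}

#' Write per-tissue and consensus rankings as TSV
#'
#' @param rankings List of `GeneRanking` objects.
#' @param consensus A `ConsensusCandidates`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_rankings <- function(rankings, consensus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- do.call(rbind, lapply(rankings, function(rk) {
    data.frame(tissue_id = rk$tissue_id,
               gene_id = rk$top_list,
               R_score = unname(rk$scores[rk$top_list]),
               rank = seq_along(rk$top_list),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(per, file.path(dir, "per_tissue_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(consensus$candidates, file.path(dir, "consensus_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
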