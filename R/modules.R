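# Tissue -> module assignment and tissue gene-set extraction.
#
# Each tissue is "best characterized" by the module (column of W) on which it
# has its largest loading; the tissue's gene set is read off the matching row
# of H as the genes with weights clearly above the row mean.

#' Assign each tissue to its best-characterizing module
#'
#' For each tissue (row of `W`), the assigned cluster is the argmax of the
#' row; ties are broken by the lowest module index.
#'
#' @param W Nonnegative tissues x modules loading matrix with tissue row
#'   names (e.g. `fit$W1`).
#' @return A data frame of class `"TissueClusterMap"` with columns
#'   `tissue_id`, `cluster_index`, `loading_weight`.
#' @export
assign_clusters <- function(W) {
  if (!is.matrix(W) || !is.numeric(W)) stop("`W` must be a numeric matrix")
  if (any(W < 0)) stop("`W` must be nonnegative")
  zero <- rowSums(W) == 0
  if (any(zero)) {
    ids <- if (is.null(rownames(W))) which(zero) else rownames(W)[zero]
    stop("all-zero loading row for tissue(s): ", paste(ids, collapse = ", "))
  }
  idx <- max.col(W, ties.method = "first")
  out <- data.frame(
    tissue_id = if (is.null(rownames(W))) paste0("T", seq_len(nrow(W))) else rownames(W),
    cluster_index = idx,
    loading_weight = W[cbind(seq_len(nrow(W)), idx)],
    stringsAsFactors = FALSE)
  class(out) <- c("TissueClusterMap", "data.frame")
  out
}

#' Extract a tissue's gene set from a row of H
#'
#' Selects the genes whose weight in row `cluster_index` of `H` exceeds
#' `mean(row) + z_cutoff * sd(row)` (sample standard deviation, strict
#' inequality). With `z_cutoff = 0` this is "strictly above the row mean".
#'
#' @param H Modules x genes matrix with gene column names (e.g. `fit$H1`).
#' @param cluster_index Row of `H` to threshold, in `1..k`.
#' @param z_cutoff Nonnegative multiplier on the row standard deviation
#'   (default 1).
#' @param tissue_id Optional tissue label carried into the result.
#' @return An object of class `"TissueGeneSet"`: list with `tissue_id`,
#'   `cluster_index`, `gene_ids`, `weights` (named, selected genes only) and
#'   `threshold_rule` (`z_cutoff`, `row_mean`, `row_sd`).
#' @export
select_tissue_gene_set <- function(H, cluster_index, z_cutoff = 1,
                                   tissue_id = NA_character_) {
  if (!is.matrix(H) || !is.numeric(H)) stop("`H` must be a numeric matrix")
  if (cluster_index < 1 || cluster_index > nrow(H)) {
    stop("parameter error: cluster_index must be in 1..", nrow(H))
  }
  if (z_cutoff < 0) stop("parameter error: z_cutoff must be >= 0")
  row <- H[cluster_index, ]
  if (is.null(names(row))) names(row) <- paste0("g", seq_along(row))
  mu <- mean(row)
  sdev <- stats::sd(row)
  if (sdev == 0) {
    warning("constant H row ", cluster_index, ": no gene exceeds the threshold")
  }
  sel <- row > mu + z_cutoff * sdev
  structure(list(tissue_id = tissue_id,
                 cluster_index = as.integer(cluster_index),
                 gene_ids = names(row)[sel],
                 weights = row[sel],
                 threshold_rule = list(z_cutoff = z_cutoff,
                                       row_mean = mu, row_sd = sdev)),
            class = "TissueGeneSet")
}

#' @export
print.TissueGeneSet <- function(x, ...) {
  cat(sprintf("TissueGeneSet '%s' (cluster %d): %d genes above mean + %g sd\n",
              x$tissue_id, x$cluster_index, length(x$gene_ids),
              x$threshold_rule$z_cutoff))
  invisible(x)
}
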