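# Per-tissue rewiring significance: matched-pair t-test on degree vectors.
#
# For each tissue the degrees of a shared gene list in the case-specific and
# control-specific differential edge sets form two paired vectors; the tissue
# whose paired t-test gives the smallest p-value is the key tissue.

#' Paired degree vectors from a differential network
#'
#' @param den A `DifferentialNetwork`.
#' @param gene_list Non-empty ordered character vector; genes absent from a
#'   network get degree 0.
#' @return List with integer vectors `d1` (case-specific degrees) and `d2`
#'   (control-specific degrees), both named by `gene_list`.
#' @export
degree_vectors <- function(den, gene_list) {
  if (length(gene_list) == 0L) stop("empty gene_list")
  pick <- function(deg) {
    out <- stats::setNames(integer(length(gene_list)), gene_list)
    hit <- intersect(gene_list, names(deg))
    out[hit] <- deg[hit]
    out
  }
  list(d1 = pick(den$degree1), d2 = pick(den$degree2))
}

#' Matched-pair t-test on two paired vectors
#'
#' Computes `d = d1 - d2` elementwise and
#' `t = sum(d) / sqrt((n sum(d^2) - sum(d)^2) / (n - 1))`, algebraically
#' identical to the textbook paired form `t = mean(d) sqrt(n) / sd(d)`, with
#' a two-sided p-value on `n - 1` degrees of freedom. All-zero differences
#' return `t = 0, p = 1` flagged as degenerate; constant non-zero
#' differences return an infinite `t` with `p = 0`, also flagged.
#'
#' @param d1,d2 Numeric vectors of equal length `n >= 2`.
#' @return List with `t`, `p`, `n` and logical `degenerate`.
#' @export
matched_pair_ttest <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("`d1` and `d2` must have equal length")
  n <- length(d1)
  if (n < 2L) stop("parameter error: need n >= 2 pairs")
  d <- d1 - d2
  sd_ <- sum(d)
  sd2 <- sum(d^2)
  denom2 <- (n * sd2 - sd_^2) / (n - 1)
  if (all(d == 0)) {
    return(list(t = 0, p = 1, n = n, degenerate = TRUE))
  }
  if (denom2 <= 0) {
    # constant non-zero differences: zero variance, infinitely significant
    return(list(t = sign(sd_) * Inf, p = 0, n = n, degenerate = TRUE))
  }
  t <- sd_ / sqrt(denom2)
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), n = n,
       degenerate = FALSE)
}

#' Per-tissue rewiring significance table
#'
#' Applies [degree_vectors()] and [matched_pair_ttest()] to each tissue's
#' differential network over a shared gene list.
#'
#' @param dens Named list of `DifferentialNetwork` objects (one per tissue).
#' @param gene_lists Either a single character vector used for every tissue,
#'   or a named list of per-tissue gene vectors.
#' @return A data frame of class `"TissueSignificance"` with columns
#'   `tissue_id`, `n_genes`, `t`, `p`.
#' @export
tissue_significance <- function(dens, gene_lists) {
  if (length(dens) == 0L) stop("empty differential-network list")
  rows <- lapply(seq_along(dens), function(i) {
    den <- dens[[i]]
    gl <- if (!is.list(gene_lists)) gene_lists
          else if (is.null(names(gene_lists))) gene_lists[[i]]
          else gene_lists[[den$tissue_id]]
    dv <- degree_vectors(den, gl)
    tt <- matched_pair_ttest(dv$d1, dv$d2)
    data.frame(tissue_id = den$tissue_id, n_genes = tt$n,
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("TissueSignificance", "data.frame")
  out
}

#' Identify the key tissue
#'
#' The tissue with the minimum rewiring p-value; ties broken by larger
#' `|t|`, then lexicographic tissue ID.
#'
#' @param results A `TissueSignificance` data frame (or any data frame with
#'   columns `tissue_id`, `t`, `p`).
#' @return The key tissue ID (character scalar).
#' @export
key_tissue <- function(results) {
  if (nrow(results) == 0L) stop("empty significance table")
  ord <- order(results$p, -abs(results$t), results$tissue_id)
  results$tissue_id[ord][1]
}
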