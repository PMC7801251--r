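# Joint-correlation NMF.
#
# Two paired nonnegative matrices X1, X2 (tissues x genes, same shape) are
# factorized as Xi ~ Wi Hi.  In the soft mode the tissue Gram matrices of the
# loadings are pulled toward a conserved tissue-correlation matrix R:
#
#   min  ||X1 - W1 H1||F^2 + ||X2 - W2 H2||F^2
#        + lambda ( ||W1 W1' - R||F^2 + ||W2 W2' - R||F^2 ),  W, H >= 0
#
# solved by KKT multiplicative updates.  Because R is nonnegative (negative
# tissue correlations are clipped to zero) the penalty gradient splits into
# nonnegative numerator/denominator parts and the updates stay nonnegative:
#
#   Hi <- Hi * (Wi' Xi)            / (Wi' Wi Hi + eps)
#   Wi <- Wi * (Xi Hi' + 2 l R Wi) / (Wi Hi Hi' + 2 l Wi Wi' Wi + eps)
#
# lambda = 0 reduces exactly to the classical Lee--Seung updates (mode
# "none"); mode "hard" shares a single W across both conditions.

#' Estimate the conserved tissue-correlation matrix R
#'
#' Computes the tissue-by-tissue Pearson correlation of the gene-expression
#' rows in each condition, averages the two matrices, clips negative entries
#' to zero (the multiplicative solver requires a nonnegative target) and
#' forces a unit diagonal.
#'
#' @param X1,X2 `ExpressionMatrix` objects over identical tissues and genes.
#' @return An object of class `"ConservedCorrelation"`: list with
#'   `tissue_ids` and the m x m matrix `R` (symmetric, entries in `[0, 1]`,
#'   unit diagonal).
#' @export
estimate_conserved_correlation <- function(X1, X2) {
  if (!identical(tissue_ids(X1), tissue_ids(X2)) ||
      !identical(gene_ids(X1), gene_ids(X2))) {
    stop("alignment error: X1 and X2 must share identical tissue and gene identifiers")
  }
  for (X in list(X1, X2)) {
    sds <- apply(X$values, 1L, stats::sd)
    bad <- sds == 0 | !is.finite(sds)
    if (any(bad)) {
      stop("undefined tissue correlation: zero variance across genes in tissue(s) ",
           paste(tissue_ids(X)[bad], collapse = ", "),
           " (condition '", X$condition_label, "')")
    }
  }
  C1 <- stats::cor(t(X1$values))
  C2 <- stats::cor(t(X2$values))
  R <- (C1 + C2) / 2
  R[R < 0] <- 0
  R <- (R + t(R)) / 2
  diag(R) <- 1
  structure(list(tissue_ids = tissue_ids(X1), R = R),
            class = "ConservedCorrelation")
}

#' @export
print.ConservedCorrelation <- function(x, ...) {
  cat(sprintf("ConservedCorrelation over %d tissues (off-diagonal range %.3f..%.3f)\n",
              nrow(x$R), min(x$R[upper.tri(x$R)]), max(x$R[upper.tri(x$R)])))
  invisible(x)
}

# One multiplicative-update solve from a seeded random initialization.
# The factor entries start uniform, scaled by sqrt(mean(X) / k) so the
# update trajectory is exactly scale-covariant (X -> cX maps the whole
# trajectory W, H -> sqrt(c) W, sqrt(c) H); the iteration itself runs in
# compiled code (src/jcnmf_mu.cpp).
jcnmf_single <- function(X1, X2, k, lambda, mode, max_iter, tol, seed, eps) {
  m <- nrow(X1); n <- ncol(X1)
  scale <- sqrt(mean(c(X1, X2)) / k)
  init <- with_seed(seed, list(
    W1 = matrix(stats::runif(m * k), m, k) * scale,
    H1 = matrix(stats::runif(k * n), k, n) * scale,
    W2 = matrix(stats::runif(m * k), m, k) * scale,
    H2 = matrix(stats::runif(k * n), k, n) * scale))
  W2 <- if (mode == "hard") init$W1 else init$W2
  lam <- if (mode == "soft") lambda else 0
  R <- attr(mode, "R")
  if (is.null(R)) R <- matrix(0, m, m)
  fit <- jcnmf_mu(X1, X2, init$W1, init$H1, W2, init$H2, R,
                  lam, as.integer(mode == "hard"),
                  as.integer(max_iter), tol, eps)
  fit$objective_trace <- as.numeric(fit$objective_trace)
  fit$seed <- seed
  fit
}

#' Fit the joint-correlation NMF
#'
#' Factorizes two paired tissues x genes matrices. Modes:
#' \describe{
#'   \item{`"soft"`}{jcNMF: penalizes deviations of each `Wi Wi'` from the
#'     conserved tissue-correlation matrix `R` with weight `lambda`.}
#'   \item{`"hard"`}{joint NMF with a single shared loading matrix
#'     (`W1 = W2`), solved on the concatenated data.}
#'   \item{`"none"`}{two independent classical NMFs.}
#' }
#' Multiple random restarts are run and the fit with the lowest final
#' objective is returned; results are deterministic given `seed`.
#'
#' @param X1,X2 `ExpressionMatrix` objects over identical tissues and genes
#'   (`X1` = case, `X2` = control).
#' @param k Number of modules (default: the number of tissues).
#' @param lambda Penalty weight `>= 0`; ignored for modes `"hard"`/`"none"`.
#' @param mode `"soft"`, `"hard"` or `"none"`.
#' @param max_iter Maximum multiplicative-update iterations (default 5000).
#' @param tol Relative objective-change convergence tolerance (default 1e-6).
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @param restarts Number of random restarts (default 5).
#' @param R Optional precomputed [estimate_conserved_correlation()] result;
#'   estimated from the data when `NULL` and `mode = "soft"`.
#' @param eps Multiplicative-update guard (default 1e-12).
#' @return An object of class `"jcnmf_fit"`: list with nonnegative factors
#'   `W1`, `H1`, `W2`, `H2`, plus `k`, `lambda`, `mode`, `R`,
#'   `objective_trace`, `objective`, `constraint_residual`
#'   (`||W1 W1' - W2 W2'||F`), `n_iter`, `converged`, `seed`, `restart_seed`.
#' @export
jcnmf <- function(X1, X2, k = NULL, lambda = 1,
                  mode = c("soft", "hard", "none"),
                  max_iter = 5000, tol = 1e-6, seed = 1, restarts = 5,
                  R = NULL, eps = 1e-12) {
  mode <- match.arg(mode)
  if (!identical(tissue_ids(X1), tissue_ids(X2)) ||
      !identical(gene_ids(X1), gene_ids(X2))) {
    stop("alignment error: X1 and X2 must share identical tissue and gene identifiers")
  }
  m <- nrow(X1$values); n <- ncol(X1$values)
  if (is.null(k)) k <- m
  if (k < 1 || k > min(m, n)) {
    stop("parameter error: k must satisfy 1 <= k <= min(tissues, genes)")
  }
  if (all(X1$values == 0) || all(X2$values == 0)) {
    stop("degenerate input: an all-zero expression matrix cannot be factorized")
  }
  if (lambda < 0) stop("parameter error: lambda must be >= 0")
  if (restarts < 1) stop("parameter error: restarts must be >= 1")

  Rmat <- NULL
  if (mode == "soft" && lambda > 0) {
    if (is.null(R)) R <- estimate_conserved_correlation(X1, X2)
    Rmat <- R$R
  }
  mode_tag <- mode
  attr(mode_tag, "R") <- Rmat

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- jcnmf_single(X1$values, X2$values, k,
                        lambda, mode_tag, max_iter, tol,
                        seed = seed + r - 1L, eps = eps)
    if (is.null(best) ||
        fit$objective_trace[fit$n_iter] < best$objective_trace[best$n_iter]) {
      best <- fit
    }
  }

  modules <- paste0("M", seq_len(k))
  dimnames(best$W1) <- dimnames(best$W2) <- list(tissue_ids(X1), modules)
  dimnames(best$H1) <- dimnames(best$H2) <- list(modules, gene_ids(X1))
  structure(list(W1 = best$W1, H1 = best$H1, W2 = best$W2, H2 = best$H2,
                 k = k,
                 lambda = if (mode == "soft") lambda else 0,
                 mode = mode,
                 R = Rmat,
                 objective_trace = best$objective_trace,
                 objective = best$objective_trace[best$n_iter],
                 constraint_residual = frobenius(tcrossprod(best$W1) -
                                                 tcrossprod(best$W2)),
                 n_iter = best$n_iter,
                 converged = best$converged,
                 seed = seed,
                 restart_seed = best$seed),
            class = "jcnmf_fit")
}

#' @export
print.jcnmf_fit <- function(x, ...) {
  cat(sprintf(paste0("jcnmf_fit (mode %s, k = %d, lambda = %g): objective %.6g",
                     " after %d iterations%s; constraint residual %.4g\n"),
              x$mode, x$k, x$lambda, x$objective, x$n_iter,
              if (x$converged) " (converged)" else "", x$constraint_residual))
  invisible(x)
}

#' Write factor matrices and run metadata
#'
#' `W` matrices are written as tissues x modules TSVs with tissue-name row
#' labels, `H` matrices as modules x genes TSVs with gene-ID column labels,
#' and the run metadata (k, lambda, mode, seed, iterations, final objective,
#' constraint residual) as a JSON report.
#'
#' @param fit A `jcnmf_fit`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_factorization <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("W1", "W2", "H1", "H2")) {
    utils::write.table(fit[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  meta <- list(k = fit$k, lambda = fit$lambda, mode = fit$mode,
               seed = fit$seed, restart_seed = fit$restart_seed,
               n_iter = fit$n_iter, converged = fit$converged,
               objective = fit$objective,
               constraint_residual = fit$constraint_residual)
  jsonlite::write_json(meta, file.path(dir, "factorization.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
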