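# Paired synthetic data with planted ground truth.
#
# The generator states a small world matching the method's assumptions:
#   * a block-dominant tissue loading matrix W (tissue i loads on module
#     ((i - 1) mod k) + 1), shared by both conditions so the tissue Gram
#     matrices agree exactly;
#   * a module x gene matrix H whose gene columns carry the co-expression
#     structure: module genes have a high weight in their own module row
#     plus a small gene-specific direction shared across conditions (so
#     their pairwise correlations are high and stable in BOTH conditions);
#   * "ubiquitous" anchor and candidate genes with a high weight in every
#     row plus a low-rank direction: anchors follow a fixed cross-module
#     profile f in both conditions, candidate genes follow f only in the
#     case condition (target pairwise correlation `edge_effect`), making
#     every candidate--candidate and candidate--anchor pair a planted
#     case-specific edge in every tissue gene set;
#   * optionally a block of "rewired" genes inside one tissue's module
#     that keep their module column in the case but are silenced (low,
#     flat) in the control, planting case-specific edges between each
#     rewired gene and its module in that tissue only;
#   * X = W H + truncated Gaussian noise (sd = noise_sd * mean signal),
#     clipped at zero.

#' Parameters of the planted-structure paired-data generator
#'
#' @param m Number of tissues (default 7).
#' @param n Number of genes (default 500); must satisfy `n >= 10 k`.
#' @param k Number of modules (default 7).
#' @param noise_sd Noise level as a fraction of the mean signal (default 0.1).
#' @param n_anchors Number of planted anchor genes (default 6).
#' @param n_planted_candidates Number of planted candidate genes (default 10).
#' @param rewired_tissue Tissue index receiving extra planted case-specific
#'   edges, or `NULL` for none (default 3).
#' @param edge_effect Target pairwise correlation of planted edges, in
#'   `(0, 1]` (default 0.9).
#' @param seed Integer seed; the whole construction is deterministic in it.
#' @return A validated list of class `"SyntheticSpec"`.
#' @export
synthetic_spec <- function(m = 7, n = 500, k = 7, noise_sd = 0.1,
                           n_anchors = 6, n_planted_candidates = 10,
                           rewired_tissue = 3, edge_effect = 0.9, seed = 1) {
  if (n < 10 * k) stop("infeasible spec: need n >= 10 * k")
  if (noise_sd < 0) stop("infeasible spec: noise_sd must be >= 0")
  if (edge_effect <= 0 || edge_effect > 1) {
    stop("infeasible spec: edge_effect must be in (0, 1]")
  }
  if (n_anchors + n_planted_candidates > n) {
    stop("infeasible spec: n_anchors + n_planted_candidates exceeds n")
  }
  if (n_anchors < 1) stop("infeasible spec: need at least one anchor")
  if (!is.null(rewired_tissue) &&
      (rewired_tissue < 1 || rewired_tissue > m)) {
    stop("infeasible spec: rewired_tissue out of range")
  }
  structure(list(m = m, n = n, k = k, noise_sd = noise_sd,
                 n_anchors = n_anchors,
                 n_planted_candidates = n_planted_candidates,
                 rewired_tissue = if (!is.null(rewired_tissue)) as.integer(rewired_tissue),
                 edge_effect = edge_effect, seed = seed),
            class = "SyntheticSpec")
}

# Direction vectors live in the centered unit sphere of R^k so that the
# sample PCC between two planted columns is an EXACT inner-product identity:
# for d_u = sqrt(rho) fhat + sqrt(1-rho) zhat_u with zhat_u a centered unit
# vector orthogonal to fhat, PCC(d_u, d_v) = rho + (1-rho) (zhat_u . zhat_v).
# A per-vector constant shift (-min) makes entries nonnegative without
# touching any correlation.
center_unit <- function(v) {
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

# project v onto the orthogonal complement of the (unit) vectors in basis
proj_out <- function(v, basis) {
  for (b in basis) v <- v - sum(v * b) * b
  v
}

# random centered unit vector orthogonal to the (centered unit) refs
rand_orth_cu <- function(k, refs = list()) {
  z <- stats::rnorm(k)
  z <- proj_out(z - mean(z), refs)
  z / sqrt(sum(z^2))
}

# rho-mixture with a shared profile, shifted entrywise nonnegative
mix_dir <- function(shared, rho, k, refs = list()) {
  d <- sqrt(rho) * shared + sqrt(1 - rho) * rand_orth_cu(k, c(list(shared), refs))
  d - min(d)
}

# Fixed cross-module profiles: centered, unit norm, mutually orthogonal,
# with bounded coordinates so their correlation with any single-module
# contrast stays clearly below the k = 7 edge-significance threshold.
synthetic_profiles <- function(k) {
  j <- seq_len(k) - 1
  list(f = center_unit(cos(2 * pi * j / k)))
}

#' Generate a paired case/control dataset with known ground truth
#'
#' See the package's methods vignette for the construction and the rationale
#' behind the fixed internal signal levels.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `case` and `control` (`ExpressionMatrix` objects) and
#'   `truth`, a list of class `"GroundTruth"` with `module_membership`
#'   (named integer, `NA` for ubiquitous genes), `tissue_gene_sets` (planted
#'   per-tissue gene sets), `planted_case_edges` (per-tissue data frames
#'   `u`,`v`), `planted_candidates`, `anchor_ids`, `tf_ids`, `true_R`,
#'   `rewired_tissue`.
#' @export
generate_paired_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  m <- spec$m; n <- spec$n; k <- spec$k
  rho <- spec$edge_effect

  # fixed signal levels (see methods vignette)
  h_hi <- 8; h_lo <- 1.5          # module-row weights: own module vs others
  ubiq_base <- 6                  # ubiquitous genes: weight in every row
  ubiq_amp <- 6                   # amplitude of their cross-module profile
  module_jitter <- 0.6            # per-gene direction of module genes
  n_clique <- 24L                 # rewired genes (silenced in the control)
  w_off <- 0.08                   # off-module tissue loading

  gene <- sprintf("g%04d", seq_len(n))
  tissue <- sprintf("T%d", seq_len(m))
  n_ubiq <- spec$n_anchors + spec$n_planted_candidates
  ubiq_idx <- seq(n - n_ubiq + 1L, n)
  anchor_ids <- gene[ubiq_idx[seq_len(spec$n_anchors)]]
  candidate_ids <- gene[ubiq_idx[spec$n_anchors + seq_len(spec$n_planted_candidates)]]
  module_idx <- setdiff(seq_len(n), ubiq_idx)
  membership <- stats::setNames(rep(NA_integer_, n), gene)
  membership[module_idx] <- sort(rep_len(seq_len(k), length(module_idx)))

  tissue_module <- ((seq_len(m) - 1L) %% k) + 1L
  W <- matrix(w_off, m, k, dimnames = list(tissue, paste0("M", seq_len(k))))
  W[cbind(seq_len(m), tissue_module)] <- 1

  prof <- synthetic_profiles(k)

  out <- with_seed(spec$seed, {
    H1 <- matrix(h_lo, k, n, dimnames = list(paste0("M", seq_len(k)), gene))
    H2 <- H1

    # module genes: identical columns in both conditions
    for (i in module_idx) {
      mod <- membership[i]
      col <- rep(h_lo, k)
      col[mod] <- h_hi
      col <- col + module_jitter * stats::rnorm(k)
      H1[, i] <- H2[, i] <- pmax(col, 0)
    }

    # anchors: base + rho-mixed fixed profile, identical in both conditions
    for (id in anchor_ids) {
      d <- mix_dir(prof$f, rho, k)
      H1[, id] <- H2[, id] <- ubiq_base + ubiq_amp * d
    }

    # candidates: follow the anchors' profile only in the case condition
    for (id in candidate_ids) {
      d_case <- mix_dir(prof$f, rho, k)
      d_ctrl <- center_unit(stats::rnorm(k))
      H1[, id] <- ubiq_base + ubiq_amp * d_case
      H2[, id] <- ubiq_base + ubiq_amp * (d_ctrl - min(d_ctrl))
    }

    # rewiring: a block of the rewired tissue's module genes keeps its
    # normal module column in the case but is silenced (low, flat,
    # decohered) in the control, so every correlation between a rewired
    # gene and its module becomes case-specific in that tissue only
    clique_ids <- character(0)
    if (!is.null(spec$rewired_tissue)) {
      mod_r <- tissue_module[spec$rewired_tissue]
      pool <- gene[which(membership == mod_r)]
      clique_ids <- pool[seq_len(min(n_clique, length(pool)))]
      for (id in clique_ids) {
        H2[, id] <- pmax(h_lo + module_jitter * stats::rnorm(k), 0)
      }
    }

    S1 <- W %*% H1
    S2 <- W %*% H2
    sd_noise <- spec$noise_sd * mean(c(S1, S2))
    X1 <- pmax(S1 + matrix(stats::rnorm(m * n, sd = sd_noise), m, n), 0)
    X2 <- pmax(S2 + matrix(stats::rnorm(m * n, sd = sd_noise), m, n), 0)
    list(X1 = X1, X2 = X2, S1 = S1, S2 = S2,
         H1 = H1, H2 = H2, clique_ids = clique_ids)
  })

  true_R <- {
    C1 <- stats::cor(t(out$S1)); C2 <- stats::cor(t(out$S2))
    R <- (C1 + C2) / 2; R[R < 0] <- 0; diag(R) <- 1
    R
  }

  ubiq_ids <- c(anchor_ids, candidate_ids)
  gene_sets <- lapply(seq_len(m), function(t) {
    c(gene[which(membership == tissue_module[t])], ubiq_ids)
  })
  names(gene_sets) <- tissue

  # planted case-specific edges: all pairs touching a candidate within the
  # ubiquitous block (every tissue) + every rewired-gene -- own-module pair
  # (rewired tissue only)
  ubiq_pairs <- do.call(rbind, lapply(seq_along(candidate_ids), function(i) {
    u <- candidate_ids[i]
    partners <- c(anchor_ids, candidate_ids[seq_len(i - 1L)])
    data.frame(u = pmin(u, partners), v = pmax(u, partners),
               stringsAsFactors = FALSE)
  }))
  planted <- lapply(seq_len(m), function(t) {
    e <- ubiq_pairs
    if (!is.null(spec$rewired_tissue) && t == spec$rewired_tissue &&
        length(out$clique_ids) >= 1L) {
      mod_genes <- gene[which(membership == tissue_module[t])]
      rew <- do.call(rbind, lapply(out$clique_ids, function(q) {
        partners <- setdiff(mod_genes, q)
        data.frame(u = pmin(q, partners), v = pmax(q, partners),
                   stringsAsFactors = FALSE)
      }))
      rew <- rew[!duplicated(edge_key(rew$u, rew$v)), , drop = FALSE]
      e <- rbind(e, rew)
    }
    rownames(e) <- NULL
    e
  })
  names(planted) <- tissue

  truth <- structure(list(module_membership = membership,
                          tissue_gene_sets = gene_sets,
                          planted_case_edges = planted,
                          planted_candidates = candidate_ids,
                          anchor_ids = anchor_ids,
                          tf_ids = character(0),
                          rewired_genes = out$clique_ids,
                          rewired_tissue = spec$rewired_tissue,
                          true_R = true_R,
                          true_W = W, true_H1 = out$H1, true_H2 = out$H2),
                     class = "GroundTruth")

  list(case = expression_matrix(out$X1, "case"),
       control = expression_matrix(out$X2, "control"),
       truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes the case and control matrices in the same genes x tissues TSV
#' format that [load_expression_table()] reads, plus `anchors.txt` and a
#' `ground_truth.json`.
#'
#' @param dataset Output of [generate_paired_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(dataset$case, file.path(dir, "case.tsv"))
  write_expression_table(dataset$control, file.path(dir, "control.tsv"))
  writeLines(c("# planted anchor genes", dataset$truth$anchor_ids),
             file.path(dir, "anchors.txt"))
  truth <- dataset$truth
  truth$module_membership <- as.list(truth$module_membership)
  jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
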