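# End-to-end pipeline: data_io -> jcNMF -> tissue modules -> networks ->
# candidate ranking -> tissue significance, with TSV/JSON outputs.

#' Pipeline configuration
#'
#' Collects all inputs and tunable parameters of a run. Defaults follow the
#' published analysis where it states them (fold-change cutoff 1.2, edge
#' threshold P < 0.05, top 30 genes per tissue, consensus over at least 4
#' tissues).
#'
#' @param case,control `ExpressionMatrix` objects (or paths to expression
#'   tables) for the two conditions.
#' @param anchor_ids Character vector (or path to a gene-list file) of known
#'   phenotype-anchor genes; mandatory.
#' @param tf_ids Character vector (or path) of transcription-factor genes.
#' @param fc_cutoff Inclusive DEG fold-change cutoff (default 1.2).
#' @param pseudocount Fold-change pseudocount (default 0.1).
#' @param k Module count; `NULL` means the number of tissues.
#' @param lambda Soft-constraint weight (default 1).
#' @param mode Factorization mode: `"soft"`, `"hard"` or `"none"`.
#' @param alpha Edge significance threshold (default 0.05).
#' @param z_cutoff Tissue gene-set threshold in row-sd units (default 1).
#' @param top_n Per-tissue candidate list size (default 30).
#' @param min_tissues Consensus support threshold (default 4).
#' @param seed Integer seed for the factorization.
#' @param restarts,max_iter,tol Solver controls (defaults 5, 5000, 1e-6).
#' @param score_side Condition whose `H` is used for anchor-relatedness
#'   scoring: `"case"` (default) or `"control"`.
#' @param degree_genes Gene class paired in the degree test: `"all"`
#'   (default), `"tf"`, `"anchors"` or `"deg"`.
#' @param outdir Output directory for TSV/JSON artifacts, or `NULL` to skip
#'   writing.
#' @return A list of class `"RunConfig"`.
#' @export
dct_config <- function(case, control, anchor_ids, tf_ids = character(),
                       fc_cutoff = 1.2, pseudocount = 0.1, k = NULL,
                       lambda = 1, mode = "soft", alpha = 0.05, z_cutoff = 1,
                       top_n = 30, min_tissues = 4, seed = 1, restarts = 5,
                       max_iter = 5000, tol = 1e-6,
                       score_side = c("case", "control"),
                       degree_genes = c("all", "tf", "anchors", "deg"),
                       outdir = NULL) {
  if (is.character(case)) case <- load_expression_table(case, "case")
  if (is.character(control)) control <- load_expression_table(control, "control")
  if (is.character(anchor_ids) && length(anchor_ids) == 1L && file.exists(anchor_ids)) {
    anchor_ids <- read_gene_list(anchor_ids)
  }
  if (is.character(tf_ids) && length(tf_ids) == 1L && file.exists(tf_ids)) {
    tf_ids <- read_gene_list(tf_ids)
  }
  structure(list(case = case, control = control,
                 anchor_ids = anchor_ids, tf_ids = tf_ids,
                 fc_cutoff = fc_cutoff, pseudocount = pseudocount, k = k,
                 lambda = lambda, mode = mode, alpha = alpha,
                 z_cutoff = z_cutoff, top_n = top_n,
                 min_tissues = min_tissues, seed = seed, restarts = restarts,
                 max_iter = max_iter, tol = tol,
                 score_side = match.arg(score_side),
                 degree_genes = match.arg(degree_genes),
                 outdir = outdir),
            class = "RunConfig")
}

validate_config <- function(config) {
  m <- nrow(config$case$values)
  if (!identical(tissue_ids(config$case), tissue_ids(config$control)) ||
      !identical(gene_ids(config$case), gene_ids(config$control))) {
    stop("validation error: case and control must share identical tissue and gene identifiers")
  }
  if (config$min_tissues > m) {
    stop("validation error: min_tissues (", config$min_tissues,
         ") exceeds the number of tissues (", m, ")")
  }
  if (length(config$anchor_ids) == 0L) {
    stop("validation error: anchor gene list must be non-empty")
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    stop("validation error: alpha must be in (0, 1)")
  }
  invisible(config)
}

#' Run the full dynamic cross-tissue analysis
#'
#' Executes the whole pipeline on a [dct_config()] and (optionally) writes
#' all module outputs plus a JSON run report. The report carries no
#' timestamps, so identical configurations and seeds produce byte-identical
#' report bodies.
#'
#' @param config A `RunConfig` from [dct_config()].
#' @return Invisibly, a list of class `"dct_run"` with elements `report`
#'   (the JSON-serializable run summary), `catalog`, `fit`, `clusters`,
#'   `gene_sets`, `networks`, `dens`, `rankings`, `consensus`,
#'   `significance`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)

  # data_io ----
  fc <- max_fold_change(config$case, config$control, config$pseudocount)
  catalog <- assemble_feature_genes(fc, config$fc_cutoff,
                                    config$tf_ids, config$anchor_ids)
  X1 <- subset_genes(config$case, catalog$feature_ids)
  X2 <- subset_genes(config$control, catalog$feature_ids)

  # jcnmf_core ----
  fit <- jcnmf(X1, X2, k = config$k, lambda = config$lambda,
               mode = config$mode, max_iter = config$max_iter,
               tol = config$tol, seed = config$seed,
               restarts = config$restarts)

  # tissue_modules ---- (per condition; networks use the union per tissue)
  clusters1 <- assign_clusters(fit$W1)
  clusters2 <- assign_clusters(fit$W2)
  tissues <- clusters1$tissue_id
  gene_sets <- lapply(seq_along(tissues), function(i) {
    gs1 <- select_tissue_gene_set(fit$H1, clusters1$cluster_index[i],
                                  config$z_cutoff, tissues[i])
    gs2 <- select_tissue_gene_set(fit$H2, clusters2$cluster_index[i],
                                  config$z_cutoff, tissues[i])
    list(case = gs1, control = gs2,
         union = union(gs1$gene_ids, gs2$gene_ids))
  })
  names(gene_sets) <- tissues

  # coexpr_networks ----
  networks <- lapply(tissues, function(t) {
    gs <- gene_sets[[t]]$union
    list(case = build_network(fit$H1, gs, config$alpha, t, "case"),
         control = build_network(fit$H2, gs, config$alpha, t, "control"))
  })
  names(networks) <- tissues
  dens <- lapply(networks, function(nw) differential_network(nw$case, nw$control))

  # candidate_ranking ----
  Hscore <- if (config$score_side == "case") fit$H1 else fit$H2
  rankings <- lapply(tissues, function(t) {
    rank_tissue(Hscore, gene_sets[[t]]$union, catalog$anchor_ids,
                config$top_n, t)
  })
  consensus <- consensus_candidates(rankings, config$min_tissues)
  composite <- if (nrow(consensus$candidates)) {
    cand <- consensus$candidates$gene_id
    total_deg <- Reduce(`+`, lapply(dens, function(den) {
      stats::setNames(vapply(cand, function(g) {
        if (g %in% names(den$degree1)) den$degree1[[g]] else 0L
      }, integer(1)), cand)
    }))
    composite_rank(stats::setNames(consensus$candidates$mean_R, cand),
                   fc, total_deg)
  } else numeric(0)

  # tissue_significance ----
  deg_universe <- switch(config$degree_genes,
                         all = catalog$feature_ids,
                         tf = catalog$tf_ids,
                         anchors = catalog$anchor_ids,
                         deg = catalog$deg_ids)
  gene_lists <- lapply(dens, function(den) {
    gl <- intersect(den$nodes, deg_universe)
    if (length(gl) == 0L) den$nodes else gl
  })
  sig <- tissue_significance(dens, gene_lists)
  key <- key_tissue(sig)

  report <- list(
    package = "dctnet",
    version = as.character(utils::packageVersion("dctnet")),
    config = list(fc_cutoff = config$fc_cutoff,
                  pseudocount = config$pseudocount,
                  k = fit$k, lambda = config$lambda, mode = config$mode,
                  alpha = config$alpha, z_cutoff = config$z_cutoff,
                  top_n = config$top_n, min_tissues = config$min_tissues,
                  seed = config$seed, restarts = config$restarts,
                  max_iter = config$max_iter, tol = config$tol,
                  score_side = config$score_side,
                  degree_genes = config$degree_genes),
    inputs = list(n_tissues = length(tissues),
                  n_genes = length(gene_ids(config$case)),
                  n_feature_genes = length(catalog$feature_ids),
                  n_degs = length(catalog$deg_ids),
                  n_tfs = length(catalog$tf_ids),
                  n_anchors = length(catalog$anchor_ids)),
    factorization = list(objective = fit$objective,
                         constraint_residual = fit$constraint_residual,
                         n_iter = fit$n_iter, converged = fit$converged,
                         restart_seed = fit$restart_seed),
    tissue_clusters = list(case = clusters1$cluster_index,
                           control = clusters2$cluster_index),
    tissue_significance = sig,
    key_tissue = key,
    candidates = consensus$candidates,
    composite_rank = as.list(composite))

  run <- structure(list(report = report, catalog = catalog, fit = fit,
                        clusters = list(case = clusters1, control = clusters2),
                        gene_sets = gene_sets, networks = networks,
                        dens = dens, rankings = rankings,
                        consensus = consensus, significance = sig),
                   class = "dct_run")

  if (!is.null(config$outdir)) write_run_outputs(run, config$outdir)
  invisible(run)
}

#' @export
print.dct_run <- function(x, ...) {
  cat(sprintf(paste0("dct_run: %d feature genes, key tissue '%s', ",
                     "%d consensus candidates\n"),
              x$report$inputs$n_feature_genes, x$report$key_tissue,
              nrow(x$consensus$candidates)))
  invisible(x)
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_feature_catalog(run$catalog, file.path(outdir, "feature_genes.tsv"))
  write_factorization(run$fit, file.path(outdir, "factorization"))
  utils::write.table(rbind(cbind(run$clusters$case, condition = "case"),
                           cbind(run$clusters$control, condition = "control")),
                     file.path(outdir, "tissue_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gs_tab <- do.call(rbind, lapply(names(run$gene_sets), function(t) {
    do.call(rbind, lapply(c("case", "control"), function(cond) {
      gs <- run$gene_sets[[t]][[cond]]
      if (length(gs$gene_ids) == 0L) return(NULL)
      data.frame(tissue_id = t, condition = cond,
                 cluster_index = gs$cluster_index, gene_id = gs$gene_ids,
                 weight = unname(gs$weights), stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(gs_tab, file.path(outdir, "tissue_gene_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (t in names(run$dens)) {
    write_edge_list(run$networks[[t]]$case,
                    file.path(outdir, paste0("network_", t, "_case.tsv")))
    write_edge_list(run$networks[[t]]$control,
                    file.path(outdir, paste0("network_", t, "_control.tsv")))
    write_edge_list(run$dens[[t]],
                    file.path(outdir, paste0("den_", t, ".tsv")))
  }
  write_rankings(run$rankings, run$consensus, outdir)
  utils::write.table(run$significance,
                     file.path(outdir, "tissue_significance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(outdir)
}
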