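# Expression containers and table IO.
#
# The working unit is a tissues x genes matrix of nonnegative FPKM-like
# values for ONE condition.  On disk the conventional orientation is
# genes x tissues (genes as rows, first column = gene ID, header = tissue
# names); the constructor stores the transpose.

#' Construct an expression matrix for one condition
#'
#' Wraps a numeric tissues x genes matrix of nonnegative expression values
#' (FPKM-like units) together with a condition label. Row names are tissue
#' identifiers in developmental order; column names are gene identifiers.
#'
#' @param values Numeric matrix, tissues in rows and genes in columns, with
#'   unique row and column names. All entries must be finite and `>= 0`.
#' @param condition_label Free-text label for the condition (e.g. `"case"`).
#' @return An object of class `"ExpressionMatrix"`: a list with elements
#'   `condition_label` and `values`.
#' @examples
#' m <- matrix(c(1, 2, 0, 0, 5, 1), nrow = 2,
#'             dimnames = list(c("t1", "t2"), c("g1", "g2", "g3")))
#' expression_matrix(m, "case")
#' @export
expression_matrix <- function(values, condition_label = "") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (tissues x genes)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have tissue row names and gene column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("format error: duplicate tissue identifiers")
  }
  if (anyDuplicated(colnames(values))) {
    stop("format error: duplicate gene identifiers")
  }
  if (any(!is.finite(values))) {
    stop("domain error: expression values must be finite and numeric")
  }
  if (any(values < 0)) {
    stop("domain error: negative expression values are not allowed")
  }
  structure(list(condition_label = as.character(condition_label)[1],
                 values = values),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s': %d tissues x %d genes\n",
              x$condition_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Tissue and gene identifiers of an expression matrix
#'
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers in stored order.
#' @export
tissue_ids <- function(x) rownames(x$values)

#' @rdname tissue_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' Read an expression table from a delimited text file
#'
#' Expects genes as rows: the first column holds gene identifiers, the header
#' row holds tissue names, and the body is numeric. The matrix is transposed
#' internally to tissues x genes. Tab- and comma-separated files are
#' supported (chosen from the file extension, `.csv` meaning comma).
#'
#' @param path Path to the table.
#' @param condition_label Condition label to attach.
#' @return An [expression_matrix()].
#' @export
load_expression_table <- function(path, condition_label = "") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("format error: empty expression table")
  hdr <- strsplit(first, sep, fixed = TRUE)[[1]]
  if (length(hdr) < 2L) stop("format error: expression table needs a gene-ID column and at least one tissue column")
  # A header of tissue names must not be numeric: a numeric-looking first row
  # means the header is missing.
  if (all(!is.na(suppressWarnings(as.numeric(hdr[-1]))))) {
    stop("format error: missing header row of tissue names")
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  gene <- as.character(tab[[1]])
  if (anyDuplicated(gene)) {
    stop("format error: duplicate gene identifiers in expression table")
  }
  body <- tab[, -1, drop = FALSE]
  num <- vapply(body, is.numeric, logical(1))
  if (!all(num)) {
    stop("domain error: non-numeric expression values in column(s) ",
         paste(names(body)[!num], collapse = ", "))
  }
  values <- t(as.matrix(body))
  colnames(values) <- gene
  expression_matrix(values, condition_label)
}

#' Write an expression table
#'
#' Writes in the same genes x tissues orientation that
#' [load_expression_table()] reads, so a write/read round trip reproduces the
#' numeric content (up to the decimal precision of the text representation).
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path (`.csv` switches to comma separation).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- data.frame(gene_id = gene_ids(x), t(x$values),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene-ID list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored; surrounding whitespace is trimmed.
#'
#' @param path Path to the list.
#' @return Character vector of unique identifiers in first-seen order.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Maximum fold change per gene across tissues
#'
#' For each gene the fold change in a tissue is `max(r, 1/r)` with
#' `r = (case + pseudocount) / (control + pseudocount)`, and the reported
#' value is the maximum over tissues, so it is always `>= 1` and symmetric
#' under swapping case and control.
#'
#' @param case,control `ExpressionMatrix` objects with identical tissue and
#'   gene identifiers.
#' @param pseudocount Nonnegative value added to both conditions to guard
#'   zero FPKM entries (default 0.1).
#' @return Named numeric vector, one maximum fold change per gene.
#' @export
max_fold_change <- function(case, control, pseudocount = 0.1) {
  if (!identical(gene_ids(case), gene_ids(control)) ||
      !identical(tissue_ids(case), tissue_ids(control))) {
    stop("alignment error: case and control must share identical tissue and gene identifiers")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop("`pseudocount` must be a single nonnegative number")
  }
  if (pseudocount == 0 && any(case$values == 0 | control$values == 0)) {
    stop("domain error: zero expression with pseudocount 0 gives undefined fold change")
  }
  r <- (case$values + pseudocount) / (control$values + pseudocount)
  fc <- pmax(r, 1 / r)
  apply(fc, 2L, max)
}

#' Assemble the feature-gene catalog
#'
#' Feature genes are the deduplicated union of fold-change-filtered DEGs,
#' transcription factors and anchor genes, in first-seen order (DEGs, then
#' TFs, then anchors). TFs and anchors enter regardless of their expression
#' change; anchors absent from the expression data are a hard error because
#' downstream ranking requires them.
#'
#' @param fc Named fold-change map from [max_fold_change()]; its names define
#'   the measured gene universe.
#' @param fc_cutoff Inclusive DEG cutoff, `>= 1` (default 1.2).
#' @param tf_ids Character vector of transcription-factor gene IDs.
#' @param anchor_ids Character vector of known phenotype-anchor gene IDs.
#' @return An object of class `"FeatureGeneCatalog"`: list with `deg_ids`,
#'   `tf_ids`, `anchor_ids`, `feature_ids` and `per_gene_max_fc`.
#' @export
assemble_feature_genes <- function(fc, fc_cutoff = 1.2,
                                   tf_ids = character(),
                                   anchor_ids = character()) {
  if (!is.numeric(fc) || is.null(names(fc))) {
    stop("`fc` must be a named numeric fold-change map")
  }
  if (fc_cutoff < 1) stop("`fc_cutoff` must be >= 1")
  anchor_ids <- unique(as.character(anchor_ids))
  tf_ids <- unique(as.character(tf_ids))
  missing_anchor <- setdiff(anchor_ids, names(fc))
  if (length(missing_anchor)) {
    stop("anchor gene(s) absent from the expression matrices: ",
         paste(missing_anchor, collapse = ", "))
  }
  tf_absent <- setdiff(tf_ids, names(fc))
  if (length(tf_absent)) {
    warning(length(tf_absent), " TF id(s) absent from the expression matrices were dropped")
    tf_ids <- setdiff(tf_ids, tf_absent)
  }
  deg_ids <- names(fc)[fc >= fc_cutoff]
  feature_ids <- unique(c(deg_ids, tf_ids, anchor_ids))
  structure(list(deg_ids = deg_ids,
                 tf_ids = tf_ids,
                 anchor_ids = anchor_ids,
                 feature_ids = feature_ids,
                 per_gene_max_fc = fc[feature_ids]),
            class = "FeatureGeneCatalog")
}

#' @export
print.FeatureGeneCatalog <- function(x, ...) {
  cat(sprintf("FeatureGeneCatalog: %d feature genes (%d DEGs, %d TFs, %d anchors)\n",
              length(x$feature_ids), length(x$deg_ids), length(x$tf_ids),
              length(x$anchor_ids)))
  invisible(x)
}

#' Write the feature-gene catalog as TSV
#'
#' Columns: `gene_id`, `source_flags` (comma-joined subset of deg/tf/anchor)
#' and `max_fold_change`.
#'
#' @param catalog A `FeatureGeneCatalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_catalog <- function(catalog, path) {
  flags <- vapply(catalog$feature_ids, function(g) {
    paste(c("deg", "tf", "anchor")[c(g %in% catalog$deg_ids,
                                     g %in% catalog$tf_ids,
                                     g %in% catalog$anchor_ids)],
          collapse = ",")
  }, character(1))
  tab <- data.frame(gene_id = catalog$feature_ids,
                    source_flags = flags,
                    max_fold_change = unname(catalog$per_gene_max_fc),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix to a gene set
#'
#' @param x An `ExpressionMatrix`.
#' @param genes Character vector of gene IDs (must all be present).
#' @return An `ExpressionMatrix` with columns reordered/subset to `genes`.
#' @export
subset_genes <- function(x, genes) {
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing)) {
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  expression_matrix(x$values[, genes, drop = FALSE], x$condition_label)
}
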