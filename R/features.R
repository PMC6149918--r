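# Expression-derived module features: per-gene z-score normalization across
# samples, per-sample module activity scores (the mean z-scored expression of
# the module's genes), and a plain absolute-Pearson co-expression layer
# builder.

#' Construct an expression matrix
#'
#' @param values gene x sample numeric matrix, no missing values.
#' @param gene_ids,sample_ids row/column identifiers; taken from dimnames
#'   when omitted.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample ids are required")
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids),
                 values = values),
            class = "expression_matrix")
}

#' Read a gene x sample expression TSV
#'
#' Genes as rows; first column gene ids; header row of sample ids.
#'
#' @param path TSV file path.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  expression_matrix(vals, gene_ids = df[[1]], sample_ids = colnames(df)[-1])
}

#' Per-gene z-score transformation
#'
#' Each gene's expression is centered and scaled across samples (sample
#' standard deviation, n - 1 denominator), so every row has mean 0 and sd 1.
#'
#' @param expr an [expression_matrix()] where every gene has nonzero
#'   variance over >= 2 samples.
#' @return the standardized [expression_matrix()].
#' @export
zscore <- function(expr) {
  v <- expr$values
  if (ncol(v) < 2L) stop("z-score needs >= 2 samples")
  sds <- apply(v, 1, sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero))
    stop("zero-variance gene(s): ",
         paste(expr$gene_ids[zero], collapse = ", "))
  z <- (v - rowMeans(v)) / sds
  expression_matrix(z, expr$gene_ids, expr$sample_ids)
}

#' Module activity score per sample
#'
#' e_C(j) = mean over the module's genes of the z-scored expression in sample
#' j. Standardization is applied internally, so raw expression can be passed
#' directly.
#'
#' @param module character vector of gene ids (or integer row indices).
#' @param expr an [expression_matrix()].
#' @param standardized set TRUE if `expr` is already z-scored.
#' @return named numeric vector, one activity score per sample.
#' @export
activity_score <- function(module, expr, standardized = FALSE) {
  z <- if (standardized) expr else zscore(expr)
  idx <- if (is.character(module)) match(module, z$gene_ids)
         else as.integer(module)
  if (anyNA(idx) || any(idx < 1L | idx > length(z$gene_ids)))
    stop("module gene(s) missing from the expression matrix")
  colMeans(z$values[idx, , drop = FALSE])
}

#' Stack module activity scores into a feature matrix
#'
#' One column per module, one row per sample; column k is
#' [activity_score()] of the k-th module. Ready to be written as TSV for any
#' downstream classifier.
#'
#' @param modules nonempty list of gene sets.
#' @param expr an [expression_matrix()].
#' @return sample x module numeric matrix with class `activity_features`.
#' @export
feature_matrix <- function(modules, expr) {
  if (length(modules) == 0L) stop("empty module list")
  z <- zscore(expr)
  cols <- lapply(modules, activity_score, expr = z, standardized = TRUE)
  out <- do.call(cbind, cols)
  colnames(out) <- if (!is.null(names(modules))) names(modules)
                   else paste0("module", seq_along(modules))
  rownames(out) <- z$sample_ids
  class(out) <- c("activity_features", class(out))
  out
}

#' Absolute-Pearson co-expression layer
#'
#' Edge weight w_ij = |pearson(expr_i, expr_j)| with zero diagonal. The
#' optional hard `threshold` zeroes weights below the cutoff; this is a plain
#' thresholded correlation network, not a partial-correlation (PCIT-style)
#' filter.
#'
#' @param expr an [expression_matrix()] with >= 3 samples and no
#'   zero-variance gene.
#' @param threshold weights strictly below this are set to 0 (default 0).
#' @return symmetric gene x gene weight matrix usable as a multiplex layer.
#' @export
coexpression_layer <- function(expr, threshold = 0) {
  v <- expr$values
  if (ncol(v) < 3L) stop("co-expression needs >= 3 samples")
  sds <- apply(v, 1, sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(expr$gene_ids[sds == 0], collapse = ", "))
  W <- abs(cor(t(v)))
  diag(W) <- 0
  if (threshold > 0) W[W < threshold] <- 0
  dimnames(W) <- list(expr$gene_ids, expr$gene_ids)
  W
}
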