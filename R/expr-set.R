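#' Two-group expression set
#'
#' Container for a genes-by-samples expression matrix with a binary group
#' label per sample (0 = normal, 1 = disease).  This is the universal input
#' of the package: every scoring, simulation and evaluation function takes
#' one.  The genes-by-samples orientation follows the microarray convention.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.  A data
#'   frame whose first column holds gene identifiers (remaining columns
#'   numeric) is also accepted.
#' @param group Binary labels (0/1), one per sample, in column order; or a
#'   two-column data frame `(sample_id, label)` matched to `colnames(values)`
#'   by name, order-independent.
#' @param gene_ids Character vector of unique gene identifiers.  Defaults to
#'   `rownames(values)` (or the data frame's first column), falling back to
#'   `gene1..geneP`.
#'
#' @return An object of class `expr_set`: a list with elements `values`
#'   (numeric matrix with `gene_ids` as rownames), `group` (integer 0/1
#'   vector), and `gene_ids`.
#' @examples
#' x <- matrix(rnorm(40), nrow = 4)
#' es <- expr_set(x, group = rep(c(0, 1), each = 5))
#' es
#' @export
expr_set <- function(values, group, gene_ids = NULL) {
  if (is.data.frame(values)) {
    if (is.null(gene_ids)) gene_ids <- as.character(values[[1]])
    values <- as.matrix(values[, -1, drop = FALSE])
    storage.mode(values) <- "double"
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  p <- nrow(values)
  n <- ncol(values)
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(p))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != p) {
    abort("`gene_ids` must have one entry per row of `values`.")
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    abort(paste0("Duplicate gene ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(sprintf("Missing expression value at gene '%s', sample column %d.",
                  gene_ids[bad[1]], bad[2]))
  }
  if (is.data.frame(group)) {
    if (ncol(group) < 2) abort("Label table must have columns (sample_id, label).")
    if (is.null(colnames(values))) {
      abort("Matching labels by sample name requires column names on `values`.")
    }
    idx <- match(colnames(values), as.character(group[[1]]))
    if (anyNA(idx)) {
      missing <- colnames(values)[is.na(idx)]
      abort(paste0("No label for sample(s): ", paste(head(missing, 5), collapse = ", ")))
    }
    group <- group[[2]][idx]
  }
  group <- as.integer(group)
  if (length(group) != n) abort("`group` must have one label per sample.")
  if (!all(group %in% c(0L, 1L))) abort("Group labels must be 0 (normal) or 1 (disease).")
  n1 <- sum(group == 1L)
  n0 <- sum(group == 0L)
  if (n0 < 1L || n1 < 1L) abort("Each group must contain at least one sample.")
  rownames(values) <- gene_ids
  structure(
    list(values = values, group = group, gene_ids = gene_ids),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d genes x %d samples (%d normal, %d disease)\n",
              nrow(x$values), ncol(x$values), n_normal(x), n_disease(x)))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

n_disease <- function(es) sum(es$group == 1L)
n_normal <- function(es) sum(es$group == 0L)

disease_values <- function(es) es$values[, es$group == 1L, drop = FALSE]
normal_values <- function(es) es$values[, es$group == 0L, drop = FALSE]

#' Keep a subset of samples
#'
#' @param es An [expr_set()].
#' @param samples Integer or logical index into the sample columns.
#' @return An `expr_set` with the selected samples.
#' @export
subset_samples <- function(es, samples) {
  expr_set(es$values[, samples, drop = FALSE], es$group[samples], es$gene_ids)
}

#' Orient genes by the sign of the full-data Welch t
#'
#' Negates every gene row whose full-data Welch t-statistic is negative, so
#' that each gene's mean difference (disease minus normal) is nonnegative.
#' This is the standard transform applied before scoring real data, where
#' effect directions are unknown.
#'
#' @param es An [expr_set()].
#' @return An `expr_set` with flipped rows, carrying a logical attribute
#'   `flipped` (one entry per gene).
#' @seealso [rank_genes()] for orientation applied at the score level.
#' @export
orient_by_full_t <- function(es) {
  tt <- welch_t(es)
  flip <- !is.na(tt$score) & tt$score < 0
  v <- es$values
  v[flip, ] <- -v[flip, ]
  out <- expr_set(v, es$group, es$gene_ids)
  attr(out, "flipped") <- flip
  out
}
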