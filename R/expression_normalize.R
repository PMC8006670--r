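# Expression compendium container and the two in-scope normalization
# stages: per-dataset quantile normalization and per-dataset z-scoring.

#' Construct an expression compendium
#'
#' A gene x sample matrix of expression values together with per-sample
#' metadata assigning each sample to a dataset and a platform. All
#' normalization, contrast and correlation operations consume this container.
#'
#' @param values numeric matrix, rows = genes (rownames required),
#'   columns = samples (colnames required).
#' @param sample_meta data.frame with columns `sample`, `dataset`,
#'   `platform`; one row per column of `values`, in any order.
#' @return An object of class `expression_compendium`: list with `values`
#'   (matrix, columns reordered to match `sample_meta`) and `sample_meta`.
#' @export
expression_compendium <- function(values, sample_meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  stopifnot(is.data.frame(sample_meta),
            all(c("sample", "dataset", "platform") %in% names(sample_meta)))
  sample_meta$sample <- as.character(sample_meta$sample)
  sample_meta$dataset <- as.character(sample_meta$dataset)
  sample_meta$platform <- as.character(sample_meta$platform)
  if (anyDuplicated(sample_meta$sample)) {
    stop("a sample may belong to only one dataset (duplicate sample rows)")
  }
  if (!setequal(sample_meta$sample, colnames(values))) {
    stop("sample metadata does not match the columns of the expression matrix")
  }
  values <- values[, sample_meta$sample, drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_compendium")
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("expression_compendium: %d genes x %d samples, %d dataset(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_meta$dataset))))
  invisible(x)
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The expression file has a header whose first column is `gene` followed by
#' sample ids; the metadata file has columns `sample`, `dataset`, `platform`.
#'
#' @param expr_path path to the expression TSV.
#' @param meta_path path to the sample-metadata TSV.
#' @return An [expression_compendium()].
#' @export
read_compendium <- function(expr_path, meta_path) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  genes <- as.character(expr[[1L]])
  values <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(values) <- genes
  expression_compendium(values, meta)
}

#' Write a compendium to expression + sample-metadata TSV files
#'
#' @param comp an [expression_compendium()].
#' @param expr_path,meta_path output paths.
#' @return `expr_path`, invisibly.
#' @export
write_compendium <- function(comp, expr_path, meta_path) {
  stopifnot(inherits(comp, "expression_compendium"))
  df <- data.frame(gene = rownames(comp$values), comp$values,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(comp$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr_path)
}

#' Impute missing values by the per-gene, per-dataset mean
#'
#' @param comp an [expression_compendium()].
#' @return The compendium with every NA replaced by the mean of the same
#'   gene's non-missing values within the same dataset. A (gene, dataset)
#'   segment that is entirely missing is an error.
#' @export
impute_missing <- function(comp) {
  stopifnot(inherits(comp, "expression_compendium"))
  v <- comp$values
  if (!anyNA(v)) return(comp)
  for (ds in unique(comp$sample_meta$dataset)) {
    cols <- comp$sample_meta$sample[comp$sample_meta$dataset == ds]
    block <- v[, cols, drop = FALSE]
    if (anyNA(block)) {
      mu <- rowMeans(block, na.rm = TRUE)
      if (anyNA(mu) || any(!is.finite(mu))) {
        stop("gene with no observed value in dataset ", ds)
      }
      idx <- which(is.na(block), arr.ind = TRUE)
      block[idx] <- mu[idx[, 1L]]
      v[, cols] <- block
    }
  }
  comp$values <- v
  comp
}

#' Quantile-normalize expression values within each dataset
#'
#' Forces every sample of a dataset onto a common empirical distribution:
#' after normalization each column's sorted values equal the vector of
#' row-wise means of the column-sorted matrix, and ties within a column
#' receive the mean of the reference values at their rank positions.
#' Normalization is applied per dataset (samples of different datasets never
#' share a reference distribution); cross-dataset scale is handled afterwards
#' by [zscore_by_dataset()].
#'
#' @param comp an [expression_compendium()] without missing values (see
#'   [impute_missing()]); every dataset needs >= 2 samples.
#' @param impute logical; impute missing values first instead of failing.
#' @return The quantile-normalized compendium.
#' @export
quantile_normalize <- function(comp, impute = FALSE) {
  stopifnot(inherits(comp, "expression_compendium"))
  if (impute) comp <- impute_missing(comp)
  if (anyNA(comp$values)) {
    stop("missing values present; impute first (impute = TRUE)")
  }
  v <- comp$values
  for (ds in unique(comp$sample_meta$dataset)) {
    cols <- comp$sample_meta$sample[comp$sample_meta$dataset == ds]
    if (length(cols) < 2L) {
      stop("quantile normalization undefined for single-sample dataset ", ds)
    }
    v[, cols] <- limma::normalizeQuantiles(v[, cols, drop = FALSE],
                                           ties = TRUE)
  }
  comp$values <- v
  comp
}

#' z-score each gene within each dataset
#'
#' Cross-study standardization: for every gene, within every dataset, values
#' are replaced by (x - mean) / sd with the sample standard deviation (n - 1
#' denominator), putting all datasets on the same per-gene scale so they can
#' be pooled. Constant (gene, dataset) segments map to 0, which keeps
#' degenerate rows labelled "unchanged" downstream.
#'
#' @param comp an [expression_compendium()]; every dataset needs >= 2
#'   samples.
#' @return The z-scored compendium. Idempotent up to floating-point noise.
#' @export
zscore_by_dataset <- function(comp) {
  stopifnot(inherits(comp, "expression_compendium"))
  if (anyNA(comp$values)) stop("missing values present; impute first")
  v <- comp$values
  for (ds in unique(comp$sample_meta$dataset)) {
    cols <- comp$sample_meta$sample[comp$sample_meta$dataset == ds]
    if (length(cols) < 2L) {
      stop("z-scoring undefined for single-sample dataset ", ds)
    }
    block <- v[, cols, drop = FALSE]
    mu <- rowMeans(block)
    sd_ <- apply(block, 1L, stats::sd)
    z <- (block - mu) / ifelse(sd_ > 0, sd_, 1)
    z[sd_ == 0, ] <- 0
    v[, cols] <- z
  }
  comp$values <- v
  comp
}
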