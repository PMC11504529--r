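#' Construct an expression matrix container
#'
#' A light container for gene-by-sample (or gene-by-cell) expression data.
#' Rows are genes, columns are samples, matching the convention of the bulk
#' RNA-seq portals this pipeline consumes.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   rownames of `values`).
#' @param sample_ids Character vector of unique sample/cell identifiers
#'   (defaults to colnames of `values`).
#' @param unit One of `"counts"`, `"normalized"`, `"lognorm"`. Under
#'   `"counts"` all values must be nonnegative and integral (tolerance 1e-9).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `unit`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              unit = c("counts", "normalized", "lognorm")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required (or set dimnames on `values`)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids)) {
    stop("row count (", nrow(values), ") != number of gene_ids (",
         length(gene_ids), ")")
  }
  if (ncol(values) != length(sample_ids)) {
    stop("column count (", ncol(values), ") != number of sample_ids (",
         length(sample_ids), ")")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene_ids: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5),
               collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample_ids: ",
         paste(utils::head(unique(sample_ids[duplicated(sample_ids)]), 5),
               collapse = ", "))
  }
  if (anyNA(values)) stop("expression values contain NA")
  if (unit == "counts") {
    if (any(values < 0)) stop("negative values not allowed under unit=counts")
    if (max(abs(values - round(values))) > 1e-9) {
      stop("non-integral values under unit=counts")
    }
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         unit = unit),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", length(x$gene_ids), " genes x ",
      length(x$sample_ids), " samples [unit=", x$unit, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by gene and/or sample identifiers
#'
#' @param x An `ExpressionMatrix`.
#' @param genes,samples Character vectors of identifiers to keep (NULL = all).
#' @return An `ExpressionMatrix` restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  g <- if (is.null(genes)) x$gene_ids else genes
  s <- if (is.null(samples)) x$sample_ids else samples
  missing_g <- setdiff(g, x$gene_ids)
  missing_s <- setdiff(s, x$sample_ids)
  if (length(missing_g)) stop("unknown genes: ",
                              paste(utils::head(missing_g, 5), collapse = ", "))
  if (length(missing_s)) stop("unknown samples: ",
                              paste(utils::head(missing_s, 5), collapse = ", "))
  expression_matrix(x$values[g, s, drop = FALSE], g, s, unit = x$unit)
}
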