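#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression (largest expression gets
#' the largest rank; midranks for ties). Walking down the list from the most
#' to the least expressed gene, two empirical distributions are accumulated:
#' the in-set distribution weighted by `rank^alpha` (weights normalized to
#' sum to one over the set) and the uniform distribution over out-of-set
#' genes. The sample's score for the set is the sum over all list positions
#' of the difference between the two cumulative distributions. Scores depend
#' on expression only through within-sample ranks.
#'
#' @param expr `ExpressionMatrix`.
#' @param sets `GeneSetCollection` (or named list of gene vectors).
#' @param alpha Rank-weighting exponent; 0.25 is the canonical ssGSEA
#'   choice, 0 reduces in-set weights to uniform.
#' @param normalize If TRUE, divide the whole score matrix by its range so
#'   all scores lie in an interval of width 1.
#' @param min_genes Sets with fewer matched genes are skipped with a
#'   warning (default 2).
#' @return An `ActivityScore` object: list with `scores` (sample-by-set
#'   matrix), `alpha`, `normalized`, `sample_ids`, `set_names`.
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25, normalize = FALSE,
                         min_genes = 2) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  matched <- lapply(sets, function(s) intersect(s, expr$gene_ids))
  keep <- lengths(matched) >= min_genes
  if (!any(lengths(matched) > 0)) stop("no gene set overlaps the expression matrix")
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " set(s) with < ", min_genes,
            " matched genes: ",
            paste(utils::head(names(sets)[!keep], 5), collapse = ", "))
  }
  matched <- matched[keep]
  n_genes <- length(expr$gene_ids)
  scores <- matrix(NA_real_, length(expr$sample_ids), length(matched),
                   dimnames = list(expr$sample_ids, names(matched)))
  in_set_idx <- lapply(matched, function(s) match(s, expr$gene_ids))
  for (j in seq_along(expr$sample_ids)) {
    v <- expr$values[, j]
    r <- rank(v)                      # midranks; largest expression = n
    ord <- order(-v, expr$gene_ids)   # descending, ties by gene id
    w <- r^alpha
    for (k in seq_along(matched)) {
      inset <- logical(n_genes)
      inset[in_set_idx[[k]]] <- TRUE
      inset_ord <- inset[ord]
      w_ord <- w[ord]
      m <- sum(inset_ord)
      p_in <- cumsum(ifelse(inset_ord, w_ord, 0)) /
        sum(w_ord[inset_ord])
      p_out <- cumsum(!inset_ord) / max(n_genes - m, 1)
      scores[j, k] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rg <- range(scores)
    if (diff(rg) > 0) scores <- scores / diff(rg)
  }
  structure(list(scores = scores, alpha = alpha, normalized = normalize,
                 sample_ids = expr$sample_ids, set_names = colnames(scores)),
            class = "ActivityScore")
}

#' @export
print.ActivityScore <- function(x, ...) {
  cat("ActivityScore:", length(x$sample_ids), "samples x",
      length(x$set_names), "sets (alpha=", x$alpha, ")\n")
  invisible(x)
}

#' Stromal, immune and combined microenvironment scores
#'
#' StromalScore and ImmuneScore are unnormalized ssGSEA scores for the two
#' supplied sets; ESTIMATEScore is their sum. (The tumor-purity polynomial
#' of the original ESTIMATE tool is platform-calibrated and out of scope.)
#'
#' @param expr `ExpressionMatrix`.
#' @param stromal_set,immune_set Character vectors of gene symbols.
#' @param alpha ssGSEA exponent.
#' @return Data frame: sample_id, StromalScore, ImmuneScore, ESTIMATEScore.
#' @export
estimate_scores <- function(expr, stromal_set, immune_set, alpha = 0.25) {
  act <- ssgsea_score(expr,
                      gene_set_collection(list(stromal = stromal_set,
                                               immune = immune_set)),
                      alpha = alpha, normalize = FALSE)
  if (!all(c("stromal", "immune") %in% act$set_names)) {
    stop("stromal or immune set has insufficient overlap with expression")
  }
  data.frame(sample_id = act$sample_ids,
             StromalScore = act$scores[, "stromal"],
             ImmuneScore = act$scores[, "immune"],
             ESTIMATEScore = act$scores[, "stromal"] + act$scores[, "immune"],
             stringsAsFactors = FALSE)
}

#' Composite per-sample immunoactivity
#'
#' The mean of z-scored set scores over a chosen subset of gene sets; higher
#' values indicate a more immunocompetent sample. Zero-variance set columns
#' are dropped with a warning.
#'
#' @param act `ActivityScore`.
#' @param set_subset Sets to aggregate (default: all).
#' @return Named numeric vector, one value per sample.
#' @export
composite_immunoactivity <- function(act, set_subset = NULL) {
  stopifnot(inherits(act, "ActivityScore"))
  if (is.null(set_subset)) set_subset <- act$set_names
  if (!length(set_subset)) stop("set_subset is empty")
  bad <- setdiff(set_subset, act$set_names)
  if (length(bad)) stop("unknown sets: ", paste(bad, collapse = ", "))
  s <- act$scores[, set_subset, drop = FALSE]
  sds <- apply(s, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance set(s): ",
            paste(colnames(s)[sds == 0], collapse = ", "))
    s <- s[, sds > 0, drop = FALSE]
    if (!ncol(s)) stop("all selected sets have zero variance")
  }
  z <- scale(s)
  stats::setNames(rowMeans(z), act$sample_ids)
}
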