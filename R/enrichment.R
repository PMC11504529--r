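#' Hypergeometric over-representation of a gene list
#'
#' Upper-tail hypergeometric test of each gene set's overlap with the
#' query list against the stated universe, with Benjamini-Hochberg
#' adjustment across the tested sets. A set passes when both `p < 0.05`
#' and `q < 0.05`.
#'
#' @param gene_list Query genes (must be a subset of `universe`).
#' @param universe Background genes.
#' @param collection `GeneSetCollection` (sets are intersected with the
#'   universe before testing).
#' @param p_thresh,q_thresh Screening thresholds (both default 0.05).
#' @return Data frame: set, overlap, set_size, list_size, universe_size,
#'   p, q, passes.
#' @export
hypergeometric_enrichment <- function(gene_list, universe, collection,
                                      p_thresh = 0.05, q_thresh = 0.05) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!length(universe)) stop("empty universe")
  if (!length(gene_list)) stop("empty gene list")
  out_of_universe <- setdiff(gene_list, universe)
  if (length(out_of_universe)) {
    stop("gene_list not contained in universe: ",
         paste(utils::head(out_of_universe, 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, gene_list))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, list_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$passes <- out$p < p_thresh & out$q < q_thresh
  out[order(out$p), ]
}
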