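#' Sequential single-cell quality-control filter
#'
#' Applies, in a fixed order, the four QC rules: (1) drop genes detected
#' (count > 0) in fewer than `min_cells_per_gene` cells; (2) drop cells
#' with fewer than `min_features_create` detected features; (3) drop cells
#' with fewer than `min_features_filter` detected features; (4) drop cells
#' whose mitochondrial read fraction (genes named with `mito_prefix`)
#' exceeds `max_mito_frac`. Every removal count is reported. The order is
#' pinned because the counts depend on it: the gene filter and the
#' 300-feature rule mirror object creation, the 500-feature and
#' mitochondrial rules mirror downstream processing.
#'
#' @param counts `ExpressionMatrix` with unit counts.
#' @param min_cells_per_gene Default 100.
#' @param min_features_create Default 300.
#' @param min_features_filter Default 500.
#' @param max_mito_frac Default 0.05.
#' @param mito_prefix Default `"MT-"`.
#' @return List with `counts` (filtered `ExpressionMatrix`) and `report`
#'   (`QCReport`: named integer vector of in/removed/out counts).
#' @export
qc_filter <- function(counts, min_cells_per_gene = 100,
                      min_features_create = 300,
                      min_features_filter = 500,
                      max_mito_frac = 0.05, mito_prefix = "MT-") {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$unit != "counts") stop("qc_filter requires unit=counts")
  m <- counts$values
  n_cells_in <- ncol(m)
  n_genes_in <- nrow(m)

  det_cells <- rowSums(m > 0)
  keep_g <- det_cells >= min_cells_per_gene
  n_rm_gene <- sum(!keep_g)
  m <- m[keep_g, , drop = FALSE]
  if (!nrow(m)) stop("no genes left after the gene-detection filter")

  feats <- colSums(m > 0)
  keep1 <- feats >= min_features_create
  n_rm_300 <- sum(!keep1)
  m <- m[, keep1, drop = FALSE]
  if (!ncol(m)) stop("no cells left after the ", min_features_create,
                     "-feature filter")

  feats <- colSums(m > 0)
  keep2 <- feats >= min_features_filter
  n_rm_500 <- sum(!keep2)
  m <- m[, keep2, drop = FALSE]
  if (!ncol(m)) stop("no cells left after the ", min_features_filter,
                     "-feature filter")

  mito <- startsWith(rownames(m), mito_prefix)
  mito_frac <- if (any(mito)) {
    colSums(m[mito, , drop = FALSE]) / pmax(colSums(m), 1)
  } else rep(0, ncol(m))
  keep3 <- mito_frac <= max_mito_frac
  n_rm_mito <- sum(!keep3)
  m <- m[, keep3, drop = FALSE]
  if (!ncol(m)) stop("no cells left after the mitochondrial filter")

  report <- c(n_cells_in = n_cells_in, n_genes_in = n_genes_in,
              n_removed_gene_filter = n_rm_gene,
              n_removed_feature_300 = n_rm_300,
              n_removed_feature_500 = n_rm_500,
              n_removed_mito = n_rm_mito,
              n_cells_out = ncol(m), n_genes_out = nrow(m))
  list(counts = expression_matrix(m, unit = "counts"), report = report)
}

#' Log-normalize single-cell counts
#'
#' Per cell: `value -> ln(1 + value * scale_factor / cell_total)`. Applying
#' it to already log-normalized input is an error, never a silent double
#' normalization.
#'
#' @param counts `ExpressionMatrix` with unit counts.
#' @param scale_factor Default 10000.
#' @return `ExpressionMatrix` with unit lognorm.
#' @export
log_normalize <- function(counts, scale_factor = 10000) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$unit != "counts") {
    stop("log_normalize requires unit=counts (got '", counts$unit, "')")
  }
  totals <- colSums(counts$values)
  if (any(totals == 0)) stop("zero-total cell(s): ",
                             paste(utils::head(
                               counts$sample_ids[totals == 0], 5),
                               collapse = ", "))
  v <- log1p(sweep(counts$values, 2, totals, "/") * scale_factor)
  expression_matrix(v, counts$gene_ids, counts$sample_ids, unit = "lognorm")
}

#' Select highly variable genes
#'
#' Genes are ranked by standardized dispersion: the ratio of each gene's
#' variance to the value predicted by a local-regression (loess) fit of
#' log-variance on log-mean across genes. The top `n` are returned; ties
#' broken by gene id.
#'
#' @param lognorm `ExpressionMatrix` with unit lognorm.
#' @param n Number of genes (default 2000, capped at the gene count).
#' @return Character vector of gene ids.
#' @export
select_hvg <- function(lognorm, n = 2000) {
  stopifnot(inherits(lognorm, "ExpressionMatrix"))
  n <- min(n, length(lognorm$gene_ids))
  mu <- rowMeans(lognorm$values)
  v <- apply(lognorm$values, 1, stats::var)
  disp <- rep(0, length(v))
  ok <- v > 0 & mu > 0
  if (sum(ok) >= 10) {
    lf <- tryCatch(
      stats::loess(log(v[ok]) ~ log(mu[ok]), span = 0.5, degree = 2),
      error = function(e) NULL)
    trend <- if (is.null(lf)) {
      stats::fitted(stats::lm(log(v[ok]) ~ log(mu[ok])))
    } else stats::fitted(lf)
    disp[ok] <- log(v[ok]) - trend
  } else {
    disp[ok] <- v[ok]
  }
  ord <- order(-disp, lognorm$gene_ids)
  lognorm$gene_ids[ord][seq_len(n)]
}

#' Embed cells by PCA over highly variable genes
#'
#' Per-gene z-scoring across cells with values clipped at `+/- clip`, then
#' PCA. When `n_pcs` is NULL a permutation check selects the retained PCs:
#' a stated fraction of genes has its cell labels permuted, the leading
#' variance of the permuted data is recorded over `n_perm` rounds, and PCs
#' whose variance exceeds the permutation maximum are kept (at least 2).
#'
#' @param lognorm `ExpressionMatrix` unit lognorm.
#' @param hvg Genes to use (default: all).
#' @param n_pcs Number of PCs, or NULL for the permutation choice.
#' @param clip Z-score clip bound (default 10).
#' @param perm_frac Fraction of genes permuted per round (default 0.1).
#' @param n_perm Permutation rounds (default 5).
#' @param seed Seed for the permutation check.
#' @return List with `coords` (cell-by-PC), `var_frac`, `n_pcs`.
#' @export
embed_cells <- function(lognorm, hvg = NULL, n_pcs = 10, clip = 10,
                        perm_frac = 0.1, n_perm = 5, seed = 1) {
  stopifnot(inherits(lognorm, "ExpressionMatrix"))
  if (is.null(hvg)) hvg <- lognorm$gene_ids
  m <- lognorm$values[hvg, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  m <- m[sds > 0, , drop = FALSE]
  z <- t(scale(t(m)))
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  max_pc <- min(dim(z)) - 1
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  var_frac <- var_all / sum(var_all)
  if (is.null(n_pcs)) {
    rng <- local_rng(seed)
    n_gperm <- max(1, round(perm_frac * nrow(z)))
    null_max <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      zp <- z
      gi <- sample.int(nrow(z), n_gperm)
      for (g in gi) zp[g, ] <- zp[g, sample.int(ncol(z))]
      null_max[b] <- stats::prcomp(t(zp), center = TRUE)$sdev[1]^2
    }
    rng$restore()
    n_pcs <- max(2, sum(var_all > max(null_max)))
  }
  n_pcs <- min(n_pcs, max_pc)
  list(coords = pc$x[, seq_len(n_pcs), drop = FALSE],
       var_frac = var_frac[seq_len(n_pcs)], n_pcs = n_pcs)
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Builds the k-nearest-neighbor graph on the embedding (Euclidean),
#' weights edges by the Jaccard similarity of the two cells' neighbor sets
#' (shared nearest neighbors), and partitions the graph by modularity
#' optimization (Louvain) at the given resolution. Deterministic for a
#' fixed input.
#'
#' @param embedding Cell-by-PC coordinate matrix (rownames = cell ids).
#' @param k_neighbors Neighborhood size (default 20).
#' @param resolution Modularity resolution; smaller values merge clusters,
#'   approaching one cluster as it goes to 0 (default 1).
#' @param prune Jaccard pruning threshold below which SNN edges are
#'   dropped (default 1/15).
#' @param seed Seed for the modularity optimization (its vertex sweep uses
#'   the session RNG); fixed by default so the partition is reproducible.
#' @return Named integer vector cell -> cluster id (1-based, by size).
#' @export
cluster_cells <- function(embedding, k_neighbors = 20, resolution = 1,
                          prune = 1 / 15, seed = 1) {
  n <- nrow(embedding)
  if (n < 3) stop("need >= 3 cells")
  if (k_neighbors >= n) stop("k_neighbors must be < n_cells")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  # neighbor sets include the cell itself, matching the usual SNN recipe
  nb <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  # candidate edges: i-j whenever either is in the other's kNN list
  cand <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nn)))
  cand <- unique(t(apply(cand, 1, sort)))
  jac <- vapply(seq_len(nrow(cand)), function(r) {
    i <- cand[r, 1]; j <- cand[r, 2]
    length(intersect(nb[[i]], nb[[j]])) / length(union(nb[[i]], nb[[j]]))
  }, numeric(1))
  keep <- jac >= prune
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(keep)) {
    g <- igraph::add_edges(g, t(cand[keep, , drop = FALSE]))
    igraph::E(g)$weight <- jac[keep]
  }
  rng <- local_rng(seed)
  cm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                resolution = resolution)
  rng$restore()
  memb <- igraph::membership(cm)
  # relabel by decreasing size for stable ids
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relabel[as.character(memb)])
  names(out) <- rownames(embedding)
  out
}

#' Annotate clusters by marker-set scores
#'
#' Each cluster is labelled with the cell type whose marker set has the
#' highest mean z-scored expression (z per gene across cells, averaged over
#' marker genes and cluster cells). The margin between the top two scores
#' is reported; clusters with margin below `uncertain_margin` are flagged
#' uncertain. Ties break lexicographically and are flagged.
#'
#' @param lognorm `ExpressionMatrix` unit lognorm.
#' @param clusters Named cluster id per cell.
#' @param marker_sets `GeneSetCollection`: cell type -> marker genes.
#' @param uncertain_margin Flagging threshold (default 0.1).
#' @return A `CellAnnotation`: list with `cluster_label` (data frame:
#'   cluster, label, margin, uncertain) and `cell_cluster` (named vector).
#' @export
annotate_clusters <- function(lognorm, clusters, marker_sets,
                              uncertain_margin = 0.1) {
  stopifnot(inherits(lognorm, "ExpressionMatrix"))
  if (!length(marker_sets)) stop("marker_sets is empty")
  z <- t(scale(t(lognorm$values)))
  z[is.na(z)] <- 0
  set_scores <- vapply(names(marker_sets), function(tp) {
    genes <- intersect(marker_sets[[tp]], lognorm$gene_ids)
    if (!length(genes)) stop("marker set '", tp,
                             "' has no genes in the matrix")
    colMeans(z[genes, , drop = FALSE])
  }, numeric(ncol(z)))
  rows <- lapply(sort(unique(clusters)), function(cl) {
    cells <- names(clusters)[clusters == cl]
    sc <- colMeans(set_scores[cells, , drop = FALSE])
    ord <- order(-sc, names(sc))
    margin <- if (length(sc) > 1) sc[ord[1]] - sc[ord[2]] else Inf
    data.frame(cluster = cl, label = names(sc)[ord[1]],
               margin = margin,
               uncertain = margin < uncertain_margin,
               stringsAsFactors = FALSE)
  })
  structure(list(cluster_label = do.call(rbind, rows),
                 cell_cluster = clusters),
            class = "CellAnnotation")
}

#' @export
print.CellAnnotation <- function(x, ...) {
  cat("CellAnnotation:", nrow(x$cluster_label), "clusters over",
      length(x$cell_cluster), "cells\n")
  print(x$cluster_label, row.names = FALSE)
  invisible(x)
}

#' One-vs-rest cluster marker genes
#'
#' Per cluster, a Wilcoxon rank-sum test of each gene in the cluster's
#' cells against all other cells, BH adjustment within the cluster, and the
#' log2 fold change of mean log-normalized expression (pseudocount 1).
#'
#' @param lognorm `ExpressionMatrix` unit lognorm.
#' @param clusters Named cluster id per cell (each cluster >= 3 cells).
#' @param genes Genes to test (default all).
#' @return Data frame: cluster, gene, log2fc, p, p_adj, sorted within
#'   cluster by p then -log2fc.
#' @export
cluster_markers <- function(lognorm, clusters, genes = NULL) {
  stopifnot(inherits(lognorm, "ExpressionMatrix"))
  if (is.null(genes)) genes <- lognorm$gene_ids
  tab <- table(clusters)
  if (any(tab < 3)) stop("cluster(s) with < 3 cells: ",
                         paste(names(tab)[tab < 3], collapse = ", "))
  out <- list()
  for (cl in sort(unique(clusters))) {
    inc <- names(clusters)[clusters == cl]
    outc <- setdiff(names(clusters), inc)
    p <- numeric(length(genes))
    l2 <- numeric(length(genes))
    for (gi in seq_along(genes)) {
      a <- lognorm$values[genes[gi], inc]
      b <- lognorm$values[genes[gi], outc]
      p[gi] <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      l2[gi] <- log2((mean(a) + 1) / (mean(b) + 1))
    }
    p[is.na(p)] <- 1
    df <- data.frame(cluster = cl, gene = genes, log2fc = l2, p = p,
                     p_adj = stats::p.adjust(p, method = "BH"),
                     stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- df[order(df$p, -df$log2fc), ]
  }
  do.call(rbind, out)
}
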