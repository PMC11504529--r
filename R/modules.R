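#' Differential expression between low and high immunoactivity groups
#'
#' Count-scale normalization by median-of-ratios size factors (per-sample
#' median, over genes with positive geometric mean, of the ratio of the
#' sample's count to the gene's geometric mean), followed by a per-gene
#' Welch t-test on `log2(normalized + 1)` and Benjamini-Hochberg
#' adjustment. Intended to produce a ranked DE gene list for module
#' discovery, not to reproduce any particular negative-binomial test.
#'
#' @param expr `ExpressionMatrix` with unit counts (normalized input is
#'   accepted and used as-is with size factors 1).
#' @param groups Named character vector (`low`/`high`) per sample, or a
#'   clinical data frame with `sample_id` and `group`.
#' @param lfc_thresh Absolute log2-fold-change threshold for calling
#'   direction (default 1).
#' @param padj_thresh BH-adjusted p threshold (default 0.05).
#' @return Data frame: gene, log2fc (high vs low), stat, p, p_adj,
#'   direction (`up`/`down`/`ns`). All-zero genes are dropped with a
#'   message. Size factors are attached as attribute `size_factors`.
#' @export
differential_expression <- function(expr, groups, lfc_thresh = 1,
                                    padj_thresh = 0.05) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$sample_id)
  }
  groups <- groups[expr$sample_ids]
  use <- !is.na(groups) & groups %in% c("low", "high")
  if (sum(groups[use] == "low") < 3 || sum(groups[use] == "high") < 3) {
    stop("need >= 3 samples per group")
  }
  vals <- expr$values[, use, drop = FALSE]
  grp <- groups[use]
  nz <- rowSums(vals) > 0
  if (any(!nz)) {
    message("dropping ", sum(!nz), " all-zero gene(s)")
    vals <- vals[nz, , drop = FALSE]
  }
  sf <- if (expr$unit == "counts") size_factors(vals) else
    stats::setNames(rep(1, ncol(vals)), colnames(vals))
  norm <- sweep(vals, 2, sf, "/")
  lx <- log2(norm + 1)
  hi <- lx[, grp == "high", drop = FALSE]
  lo <- lx[, grp == "low", drop = FALSE]
  n1 <- ncol(hi); n2 <- ncol(lo)
  m1 <- rowMeans(hi); m2 <- rowMeans(lo)
  v1 <- apply(hi, 1, stats::var); v2 <- apply(lo, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df = df)
  p[!is.finite(stat)] <- 1         # zero-variance, zero-difference genes
  stat[!is.finite(stat)] <- 0
  p_adj <- stats::p.adjust(p, method = "BH")
  l2fc <- m1 - m2
  direction <- ifelse(p_adj < padj_thresh & l2fc >= lfc_thresh, "up",
                      ifelse(p_adj < padj_thresh & l2fc <= -lfc_thresh,
                             "down", "ns"))
  out <- data.frame(gene = rownames(vals), log2fc = l2fc, stat = stat,
                    p = p, p_adj = p_adj, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "size_factors") <- sf
  out
}

#' Median-of-ratios size factors
#' @param counts Gene-by-sample count matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  geo <- exp(rowMeans(lg))
  ok <- is.finite(geo) & geo > 0 & rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) stop("no gene expressed in all samples; cannot size-normalize")
  sf <- apply(counts[ok, , drop = FALSE], 2, function(col)
    stats::median(col / geo[ok]))
  sf
}

#' PCA check of sample clustering on a gene subset
#'
#' Principal components of samples over the standardized gene subset, the
#' per-PC variance fractions, and a pass flag testing whether PC1-PC3
#' jointly explain at least `threshold` of the variance. Running it on all
#' genes and again on a filtered subset reproduces the before/after
#' contrast used to show that removing non-differential genes sharpens the
#' grouping.
#'
#' @param expr `ExpressionMatrix`.
#' @param gene_subset Genes to use (>= 3); default all.
#' @param threshold Cumulative-variance pass threshold (default 0.75).
#' @return List with `coords` (sample-by-PC), `var_frac`, `cum3`, `pass`.
#' @export
pca_cluster_check <- function(expr, gene_subset = NULL, threshold = 0.75) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (is.null(gene_subset)) gene_subset <- expr$gene_ids
  if (length(gene_subset) < 3) stop("need >= 3 genes")
  if (length(expr$sample_ids) < 3) stop("need >= 3 samples")
  m <- t(expr$values[gene_subset, , drop = FALSE])
  sds <- apply(m, 2, stats::sd)
  m <- m[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  cum3 <- sum(var_frac[seq_len(min(3, length(var_frac)))])
  list(coords = pc$x, var_frac = var_frac, cum3 = cum3,
       pass = cum3 >= threshold)
}

#' Choose the soft-thresholding power for a signed network
#'
#' For each candidate power, builds the signed adjacency, computes the
#' connectivity distribution, and measures the scale-free fit as the signed
#' R-squared of the log-log regression of binned degree frequency on
#' degree (positive only when the slope is negative). Returns the smallest
#' candidate whose fit reaches `r2_target`, falling back with a warning to
#' `default_power` if none qualifies.
#'
#' @param expr `ExpressionMatrix` (genes in rows).
#' @param candidate_powers Integer candidates (default 1:10, 12, 14, 16).
#' @param r2_target Scale-free fit target (default 0.8).
#' @param default_power Fallback (default 6).
#' @param n_bins Degree histogram bins (default 10).
#' @return List with `power`, `fit_table` (power, r2, mean_adj), `selected`
#'   (logical: a candidate met the target).
#' @export
pick_soft_power <- function(expr, candidate_powers = c(1:10, 12, 14, 16),
                            r2_target = 0.8, default_power = 6,
                            n_bins = 10) {
  if (!length(candidate_powers)) stop("no candidate powers")
  cm <- stats::cor(t(expr$values))
  fit <- lapply(candidate_powers, function(beta) {
    a <- ((1 + cm) / 2)^beta
    k <- rowSums(a) - 1
    r2 <- scale_free_fit(k, n_bins)
    data.frame(power = beta, r2 = r2, mean_adj = mean(a[upper.tri(a)]))
  })
  ft <- do.call(rbind, fit)
  ok <- which(ft$r2 >= r2_target)
  if (length(ok)) {
    list(power = ft$power[ok[1]], fit_table = ft, selected = TRUE)
  } else {
    warning("no candidate power reached scale-free R2 >= ", r2_target,
            "; falling back to ", default_power)
    list(power = default_power, fit_table = ft, selected = FALSE)
  }
}

# signed scale-free fit index: R2 of log10 p(k) ~ log10 k, negated if the
# slope is positive (a rising degree distribution is not scale-free)
scale_free_fit <- function(k, n_bins = 10) {
  if (stats::sd(k) == 0) return(0)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tabulate(cuts, nbins = n_bins) / length(k)
  keep <- !is.na(dk) & pk > 0 & dk > 0
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Signed co-expression adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta` on the Pearson correlations of gene
#' expression profiles; anticorrelated genes get adjacency near 0 rather
#' than being folded onto positive correlations. Diagonal set to 1.
#'
#' @param expr `ExpressionMatrix` (genes in rows) or a gene-by-sample
#'   matrix.
#' @param beta Soft-thresholding power (>= 1).
#' @return Symmetric gene-by-gene adjacency in `[0, 1]`.
#' @export
signed_adjacency <- function(expr, beta) {
  if (beta < 1) stop("beta must be >= 1")
  m <- if (inherits(expr, "ExpressionMatrix")) expr$values else as.matrix(expr)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) stop("constant gene(s): ",
                          paste(utils::head(rownames(m)[sds == 0], 5),
                                collapse = ", "))
  a <- ((1 + stats::cor(t(m))) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j` and connectivity `k_i = sum_{u != i} a_iu`: the
#' fraction of shared network neighborhood between genes i and j. Entries
#' lie in `[0, 1]`; diagonal 1.
#'
#' @param a Symmetric adjacency with entries in `[0, 1]`.
#' @return The TOM, same dimnames as `a`.
#' @export
topological_overlap <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (min(a) < -1e-12 || max(a) > 1 + 1e-12) stop("adjacency outside [0,1]")
  diag(a) <- 1
  n <- nrow(a)
  num_shared <- a %*% a - 2 * a   # removes u = i and u = j terms (diag = 1)
  k <- rowSums(a) - 1
  kmin <- outer(k, k, pmin)
  tom <- (num_shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a static
#' height; clusters below `min_size` are then reassigned as a unit to the
#' retained module with the highest mean inter-cluster TOM when that
#' attachment exceeds `attach_tom`, otherwise labelled `"grey"`
#' (unassigned). Deterministic.
#'
#' @param tom Topological overlap matrix.
#' @param min_size Minimum module size (>= 3; default 30).
#' @param cut_height Static tree-cut height on the 1-TOM scale
#'   (default 0.8).
#' @param attach_tom Minimum mean TOM for attaching a small cluster to a
#'   module (default 0.2).
#' @return Named character vector gene -> module label (`"M1"`, `"M2"`, ...
#'   by decreasing size, or `"grey"`).
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.8,
                           attach_tom = 0.2) {
  if (min_size < 3) stop("min_size must be >= 3")
  d <- 1 - tom
  if (max(d) - min(d) < 1e-12) stop("degenerate dissimilarity (all equal)")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= min_size])
  labels <- rep("grey", nrow(tom))
  names(labels) <- rownames(tom)
  if (length(big)) {
    # name modules by decreasing size for stable, order-free labels
    big <- big[order(-sizes[as.character(big)],
                     as.integer(names(sizes[as.character(big)])))]
    for (i in seq_along(big)) labels[cl == big[i]] <- paste0("M", i)
    small <- setdiff(as.integer(names(sizes)), big)
    for (s in small) {
      members <- which(cl == s)
      mean_tom <- vapply(seq_along(big), function(i) {
        mean(tom[members, which(cl == big[i]), drop = FALSE])
      }, numeric(1))
      if (max(mean_tom) >= attach_tom) {
        labels[members] <- paste0("M", which.max(mean_tom))
      }
    }
  }
  labels
}

#' Module eigengenes, module membership (kME) and final assignment
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression, scaled to unit variance and sign-oriented to
#' correlate positively with the module's mean standardized expression.
#' kME is the Pearson correlation of every gene with every eigengene; the
#' final assignment sends each gene to its maximum-kME module when that
#' kME reaches `kme_thresh`, and to `"grey"` otherwise.
#'
#' @param expr `ExpressionMatrix`.
#' @param labels Named character vector gene -> module (from
#'   [detect_modules()]); `"grey"` genes contribute no eigengene.
#' @param kme_thresh Minimum own-module kME for assignment (default 0.75).
#' @return List with `eigengenes` (sample-by-module, unit variance), `kme`
#'   (gene-by-module), `assignment` (named character per gene after the
#'   kME rule).
#' @export
module_eigengenes <- function(expr, labels, kme_thresh = 0.75) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  labels <- labels[expr$gene_ids]
  mods <- setdiff(sort(unique(labels)), "grey")
  if (!length(mods)) stop("no non-grey module in labels")
  eg <- matrix(NA_real_, length(expr$sample_ids), length(mods),
               dimnames = list(expr$sample_ids, mods))
  for (m in mods) {
    genes <- names(labels)[labels == m]
    if (length(genes) < 3) stop("module ", m, " has < 3 genes")
    z <- t(scale(t(expr$values[genes, , drop = FALSE])))
    pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
    e <- pc$x[, 1]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    eg[, m] <- e / stats::sd(e)
  }
  kme <- stats::cor(t(expr$values), eg)
  rownames(kme) <- expr$gene_ids
  best <- mods[max.col(kme, ties.method = "first")]
  best_kme <- kme[cbind(seq_len(nrow(kme)), max.col(kme, ties.method = "first"))]
  assignment <- ifelse(best_kme >= kme_thresh, best, "grey")
  names(assignment) <- expr$gene_ids
  list(eigengenes = eg, kme = kme, assignment = assignment)
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation and two-sided p-value of each eigengene against each
#' numeric (or binary-coded) trait; pairs with `|r| >= flag_thresh` are
#' flagged as strongly associated.
#'
#' @param eigengenes Sample-by-module matrix.
#' @param traits Sample-by-trait data frame or matrix (numeric; code binary
#'   traits as 0/1).
#' @param flag_thresh Flagging threshold on `|r|` (default 0.85).
#' @return Data frame: module, trait, r, p, flagged.
#' @export
module_trait_correlation <- function(eigengenes, traits,
                                     flag_thresh = 0.85) {
  traits <- as.matrix(traits)
  if (!is.numeric(traits)) stop("traits must be numeric (code binaries 0/1)")
  const <- apply(traits, 2, function(v) stats::sd(v) == 0)
  if (any(const)) stop("constant trait(s): ",
                       paste(colnames(traits)[const], collapse = ", "))
  out <- list()
  for (m in colnames(eigengenes)) {
    for (tr in colnames(traits)) {
      ct <- stats::cor.test(eigengenes[, m], traits[, tr])
      out[[length(out) + 1]] <- data.frame(
        module = m, trait = tr, r = unname(ct$estimate), p = ct$p.value,
        flagged = abs(ct$estimate) >= flag_thresh,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
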