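#' Estimate immune cell-type fractions by nonnegative least squares
#'
#' For each bulk sample, the vector of signature-gene expression is
#' regressed on the columns of the signature matrix under a nonnegativity
#' constraint, and the coefficients are renormalized to sum to one — the
#' relative-proportion reading of signature deconvolution. A per-sample
#' permutation p-value measures whether the signature fits the sample
#' better than the same values with gene labels shuffled (statistic:
#' relative residual-norm improvement); samples with `p >= 0.05` are flagged
#' as unreliable fits.
#'
#' @param expr `ExpressionMatrix` (unit counts or normalized; counts are
#'   converted to counts-per-million internally).
#' @param sig Signature matrix: numeric gene-by-cell-type matrix with
#'   rownames (genes) and colnames (cell types), all values >= 0.
#' @param n_perm Permutations for the per-sample p-value (default 100).
#' @param seed Integer seed for the permutations.
#' @return A `CellFractions` object: list with `fractions`
#'   (sample-by-cell-type matrix, rows sum to 1), `fit_stats` (data frame:
#'   sample_id, residual_norm, p_value, reliable), `celltype_ids`,
#'   `sample_ids`.
#' @export
estimate_fractions <- function(expr, sig, n_perm = 100, seed = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  sig <- as.matrix(sig)
  if (any(sig < 0)) stop("signature matrix must be nonnegative")
  if (any(colSums(sig) == 0)) stop("signature has an all-zero column")
  if (anyDuplicated(rownames(sig))) stop("duplicate signature genes")
  shared <- intersect(rownames(sig), expr$gene_ids)
  if (length(shared) < 0.5 * nrow(sig)) {
    stop("only ", length(shared), "/", nrow(sig),
         " signature genes present in expression (need >= 50%)")
  }
  if (qr(sig[shared, , drop = FALSE])$rank < ncol(sig)) {
    stop("signature matrix is rank-deficient on the shared genes")
  }
  vals <- expr$values
  if (expr$unit == "counts") {
    vals <- sweep(vals, 2, colSums(vals), "/") * 1e6
  }
  A <- sig[shared, , drop = FALSE]
  n_s <- length(expr$sample_ids)
  k <- ncol(A)
  fr <- matrix(0, n_s, k, dimnames = list(expr$sample_ids, colnames(A)))
  resid_norm <- numeric(n_s)
  p_val <- numeric(n_s)
  rng <- local_rng(seed)
  for (j in seq_len(n_s)) {
    y <- vals[shared, j]
    fit <- pracma::lsqnonneg(A, y)
    co <- fit$x
    if (sum(co) == 0) {
      fr[j, ] <- rep(1 / k, k)
    } else {
      fr[j, ] <- co / sum(co)
    }
    resid_norm[j] <- sqrt(sum((y - A %*% co)^2))
    # improvement statistic: 1 - residual/||y||; permuted gene labels as null
    obs_stat <- 1 - resid_norm[j] / sqrt(sum(y^2))
    better <- 0L
    for (b in seq_len(n_perm)) {
      yp <- y[sample.int(length(y))]
      fp <- pracma::lsqnonneg(A, yp)
      stat_p <- 1 - sqrt(sum((yp - A %*% fp$x)^2)) / sqrt(sum(yp^2))
      if (stat_p >= obs_stat) better <- better + 1L
    }
    p_val[j] <- (1 + better) / (1 + n_perm)
  }
  rng$restore()
  structure(
    list(fractions = fr,
         fit_stats = data.frame(sample_id = expr$sample_ids,
                                residual_norm = resid_norm, p_value = p_val,
                                reliable = p_val < 0.05,
                                stringsAsFactors = FALSE),
         celltype_ids = colnames(A), sample_ids = expr$sample_ids),
    class = "CellFractions")
}

#' @export
print.CellFractions <- function(x, ...) {
  cat("CellFractions:", length(x$sample_ids), "samples x",
      length(x$celltype_ids), "cell types;",
      sum(x$fit_stats$reliable), "reliable fits (p < 0.05)\n")
  invisible(x)
}

#' Compare cell-type fractions between tumor and control groups
#'
#' Two-sided Wilcoxon rank-sum test per cell type with Benjamini-Hochberg
#' adjustment across cell types.
#'
#' @param fr `CellFractions`.
#' @param labels Named character vector (`tumor`/`control`) per sample, or a
#'   clinical data frame with `sample_id` and `state`.
#' @return Data frame: celltype, p_wilcoxon, p_adj_BH, direction (sign of
#'   tumor median minus control median: `"up"`, `"down"`, `"equal"`).
#' @export
compare_fraction_groups <- function(fr, labels) {
  stopifnot(inherits(fr, "CellFractions"))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$state, labels$sample_id)
  }
  labels <- labels[fr$sample_ids]
  for (g in c("tumor", "control")) {
    if (sum(labels == g, na.rm = TRUE) < 3) stop("group '", g,
                                                 "' has < 3 samples")
  }
  tum <- fr$fractions[which(labels == "tumor"), , drop = FALSE]
  ctl <- fr$fractions[which(labels == "control"), , drop = FALSE]
  res <- lapply(fr$celltype_ids, function(ct) {
    p <- suppressWarnings(
      stats::wilcox.test(tum[, ct], ctl[, ct], exact = NULL)$p.value)
    d_med <- stats::median(tum[, ct]) - stats::median(ctl[, ct])
    data.frame(celltype = ct, p_wilcoxon = p,
               direction = if (d_med > 0) "up" else if (d_med < 0) "down"
               else "equal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj_BH <- stats::p.adjust(out$p_wilcoxon, method = "BH")
  out[, c("celltype", "p_wilcoxon", "p_adj_BH", "direction")]
}

#' Rank cell types by median fraction
#'
#' @param fr `CellFractions`.
#' @param subset Optional character vector of sample ids (default all).
#' @return Data frame sorted by descending median fraction; ties broken
#'   lexicographically by cell-type id.
#' @export
rank_abundance <- function(fr, subset = NULL) {
  stopifnot(inherits(fr, "CellFractions"))
  if (is.null(subset)) subset <- fr$sample_ids
  if (!length(subset)) stop("empty sample subset")
  bad <- setdiff(subset, fr$sample_ids)
  if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
  med <- apply(fr$fractions[subset, , drop = FALSE], 2, stats::median)
  ord <- order(-med, names(med))
  data.frame(celltype = names(med)[ord], median_fraction = unname(med[ord]),
             stringsAsFactors = FALSE)
}

#' Correlate gene expression with estimated infiltration levels
#'
#' Spearman correlation (midranks for ties) between each requested gene's
#' expression and each cell type's estimated fraction across the shared
#' samples. The p-value uses the t approximation, switching to exact
#' enumeration over all rank permutations when `n <= exact_n`.
#'
#' @param expr `ExpressionMatrix`.
#' @param fr `CellFractions`.
#' @param genes Genes to test (default: all in `expr`).
#' @param exact_n Sample-size cutoff for exact enumeration (default 9).
#' @return Data frame: gene, celltype, spearman_rho, p. Undefined
#'   correlations (constant vector) are reported as NA, never coerced to 0.
#' @export
gene_infiltration_correlation <- function(expr, fr, genes = NULL,
                                          exact_n = 9) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(fr, "CellFractions"))
  shared <- intersect(expr$sample_ids, fr$sample_ids)
  if (length(shared) < 3) stop("need >= 3 shared samples")
  if (is.null(genes)) genes <- expr$gene_ids
  out <- vector("list", length(genes) * length(fr$celltype_ids))
  i <- 0
  for (g in genes) {
    x <- expr$values[g, shared]
    for (ct in fr$celltype_ids) {
      y <- fr$fractions[shared, ct]
      i <- i + 1
      st <- spearman_test(x, y, exact_n = exact_n)
      out[[i]] <- data.frame(gene = g, celltype = ct,
                             spearman_rho = st$rho, p = st$p,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Spearman rho with midranks; exact permutation p for small n, else the
# t approximation on n-2 df.
spearman_test <- function(x, y, exact_n = 9) {
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    perms <- all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    rho_null <- as.vector(
      stats::cor(rx, t(ry_perm)))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  list(rho = rho, p = p)
}

# all n! permutations of 1..n as a matrix (rows = permutations)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1, length.out = n - pos),
                       drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(block)
    r <- r + nrow(sub)
  }
  out
}
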