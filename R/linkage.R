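#' Correlate single cells with bulk samples
#'
#' Pearson correlation between every cell's log-normalized profile and
#' every bulk sample's profile over their shared genes. Linear-scale bulk
#' (counts or normalized) is log-transformed (`log2(x + 1)`) first so that
#' the correlation weighs genes evenly instead of being dominated by
#' high-abundance genes; log-normalized bulk is used as-is.
#'
#' @param sc_lognorm `ExpressionMatrix` unit lognorm (cells).
#' @param bulk_expr `ExpressionMatrix` (bulk samples).
#' @param min_shared Minimum shared genes (default 100).
#' @return A `CellBulkCorrelation`: list with `S` (cell-by-sample
#'   correlation matrix), `n_shared_genes`, `cell_ids`, `sample_ids`.
#' @export
cell_bulk_correlation <- function(sc_lognorm, bulk_expr, min_shared = 100) {
  stopifnot(inherits(sc_lognorm, "ExpressionMatrix"),
            inherits(bulk_expr, "ExpressionMatrix"))
  shared <- intersect(sc_lognorm$gene_ids, bulk_expr$gene_ids)
  if (length(shared) < min_shared) {
    stop("only ", length(shared), " shared genes (need >= ", min_shared, ")")
  }
  sc <- sc_lognorm$values[shared, , drop = FALSE]
  bk <- bulk_expr$values[shared, , drop = FALSE]
  if (bulk_expr$unit %in% c("counts", "normalized")) bk <- log2(bk + 1)
  sd_c <- apply(sc, 2, stats::sd)
  sd_s <- apply(bk, 2, stats::sd)
  if (any(sd_c == 0)) stop("zero-variance cell(s) on shared genes")
  if (any(sd_s == 0)) stop("zero-variance bulk sample(s) on shared genes")
  S <- stats::cor(sc, bk)
  structure(list(S = S, n_shared_genes = length(shared),
                 cell_ids = colnames(sc), sample_ids = colnames(bk)),
            class = "CellBulkCorrelation")
}

#' Symmetrized KNN graph Laplacian over cells
#'
#' K-nearest-neighbor graph on the cell embedding (Euclidean), symmetrized
#' by the union rule, unweighted; returns the combinatorial Laplacian
#' `L = D - A` (positive semidefinite).
#'
#' @param embedding Cell-by-PC matrix (rownames = cell ids).
#' @param k_neighbors Neighborhood size (>= 2).
#' @return List with `L` (Laplacian), `A` (adjacency), `n_components`
#'   (connected components; disconnection is legal and reported).
#' @export
build_cell_graph <- function(embedding, k_neighbors = 10) {
  if (k_neighbors < 2) stop("k_neighbors must be >= 2")
  n <- nrow(embedding)
  if (k_neighbors >= n) stop("k_neighbors must be < n_cells")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, order(d[i, ])[seq_len(k_neighbors)]] <- 1
  }
  A <- pmax(A, t(A))        # union symmetrization
  L <- diag(rowSums(A)) - A
  dimnames(L) <- dimnames(A) <- list(rownames(embedding), rownames(embedding))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  list(L = L, A = A, n_components = igraph::count_components(g))
}

#' Phenotype-guided cell selection by graph-regularized sparse Cox
#'
#' Treats each single cell's correlation with the bulk samples as one
#' covariate column of a Cox model for bulk survival and minimizes
#'
#' `-logPL(beta) / n_samples + lambda * (alpha_mix * ||beta||_1 +
#'  (1 - alpha_mix) * beta' L beta)`
#'
#' where `logPL` is the Breslow partial log-likelihood with per-sample
#' linear predictor `sum_c beta_c S[c, sample]` and `L` is the cell-graph
#' Laplacian. Solved by proximal gradient descent with backtracking line
#' search; the soft-threshold step produces exact zeros, so a cell is
#' `background` iff its coefficient is shrunk to zero, `plus`
#' (poor-survival-associated) iff positive, `minus` iff negative. When
#' `lambda` is NULL, a geometric 10-point path from the smallest
#' all-zero lambda downward is searched and the value maximizing the
#' cross-validated partial likelihood, subject to a cap on the selected
#' cell fraction, is used.
#'
#' @param corr `CellBulkCorrelation` (or a cell-by-sample matrix).
#' @param clinical Clinical data frame with `sample_id`, `time`, `event`
#'   covering the bulk samples.
#' @param L Cell-graph Laplacian from [build_cell_graph()] (or its list).
#' @param lambda Penalty weight, or NULL for the path search.
#' @param alpha_mix L1-vs-Laplacian mixing in `[0, 1]` (default 0.5).
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum proximal-gradient iterations.
#' @param n_folds Cross-validation folds for the path search (default 5).
#' @param max_selected_frac Cap on the fraction of nonzero cells accepted
#'   during the path search (default 0.3).
#' @param n_lambda Path length (default 10).
#' @param seed Seed for the CV fold assignment.
#' @return A `CellPhenotypeScores`: list with `beta` (named per cell),
#'   `class` (plus/minus/background), `lambda`, `alpha_mix`, `converged`,
#'   `n_iter`, `objective_trace`, `selected_frac`, and (path mode)
#'   `path` (data frame: lambda, n_nonzero, cv_loglik).
#' @export
penalized_cox_select <- function(corr, clinical, L, lambda = NULL,
                                 alpha_mix = 0.5, tol = 1e-6,
                                 max_iter = 2000, n_folds = 5,
                                 max_selected_frac = 0.3, n_lambda = 10,
                                 seed = 1) {
  S <- if (inherits(corr, "CellBulkCorrelation")) corr$S else as.matrix(corr)
  if (is.list(L) && !is.matrix(L)) L <- L$L
  if (!is.null(lambda) && lambda < 0) stop("lambda must be >= 0")
  if (alpha_mix < 0 || alpha_mix > 1) stop("alpha_mix must be in [0, 1]")
  ids <- intersect(colnames(S), clinical$sample_id)
  if (length(ids) < 3) stop("too few bulk samples shared with clinical")
  cl <- clinical[match(ids, clinical$sample_id), ]
  if (sum(cl$event) < 1) stop("no events in clinical data")
  X <- t(S[, ids, drop = FALSE])        # samples x cells
  X <- scale(X)                          # standardize cell columns
  n <- nrow(X)
  p <- ncol(X)
  time <- cl$time
  event <- cl$event

  # Breslow negative log partial likelihood (scaled by 1/n) and gradient
  ord <- order(time)
  negpl <- function(beta, Xm, tv, ev) {
    eta <- drop(Xm %*% beta)
    -breslow_loglik(beta, Xm, tv, ev) / nrow(Xm)
  }
  negpl_grad <- function(beta, Xm, tv, ev) {
    eta <- drop(Xm %*% beta)
    w <- exp(eta)
    g <- numeric(length(beta))
    for (i in which(ev == 1)) {
      at_risk <- tv >= tv[i]
      wr <- w[at_risk]
      g <- g - (Xm[i, ] - colSums(Xm[at_risk, , drop = FALSE] * wr) / sum(wr))
    }
    g / nrow(Xm)
  }

  fit_one <- function(lam, Xm, tv, ev, beta0 = NULL) {
    pen_smooth <- function(b) lam * (1 - alpha_mix) * drop(t(b) %*% L %*% b)
    grad_smooth <- function(b) negpl_grad(b, Xm, tv, ev) +
      2 * lam * (1 - alpha_mix) * drop(L %*% b)
    obj <- function(b) negpl(b, Xm, tv, ev) + pen_smooth(b) +
      lam * alpha_mix * sum(abs(b))
    beta <- if (is.null(beta0)) numeric(ncol(Xm)) else beta0
    step <- 1
    f_cur <- obj(beta)
    trace <- f_cur
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      g <- grad_smooth(beta)
      repeat {
        prop <- soft_threshold(beta - step * g, step * lam * alpha_mix)
        f_prop <- obj(prop)
        # backtrack until the proximal step decreases the objective
        if (is.finite(f_prop) && f_prop <= f_cur + 1e-12) break
        step <- step / 2
        if (step < 1e-12) { prop <- beta; f_prop <- f_cur; break }
      }
      rel <- abs(f_cur - f_prop) / max(abs(f_cur), 1e-10)
      beta <- prop
      f_cur <- f_prop
      trace <- c(trace, f_cur)
      step <- min(step * 2, 1)
      if (rel < tol) { converged <- TRUE; break }
    }
    list(beta = beta, converged = converged, n_iter = it, trace = trace,
         objective = f_cur)
  }

  path_df <- NULL
  if (is.null(lambda)) {
    g0 <- negpl_grad(numeric(p), X, time, event)
    lam_max <- max(abs(g0)) / max(alpha_mix, 0.01)
    lams <- lam_max * 0.75^(seq_len(n_lambda) - 1)
    rng <- local_rng(seed)
    folds <- sample(rep(seq_len(n_folds), length.out = n))
    rng$restore()
    cv_ll <- numeric(length(lams))
    nnz <- integer(length(lams))
    warm <- NULL
    for (li in seq_along(lams)) {
      full <- fit_one(lams[li], X, time, event, beta0 = warm)
      warm <- full$beta
      nnz[li] <- sum(full$beta != 0)
      ll <- 0
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        if (sum(event[tr]) < 1 || sum(event[!tr]) < 1) next
        ft <- fit_one(lams[li], X[tr, , drop = FALSE], time[tr], event[tr])
        # CV partial likelihood by the difference method (full minus train)
        ll <- ll + (breslow_loglik(ft$beta, X, time, event) -
                      breslow_loglik(ft$beta, X[tr, , drop = FALSE],
                                     time[tr], event[tr]))
      }
      cv_ll[li] <- ll
    }
    path_df <- data.frame(lambda = lams, n_nonzero = nnz, cv_loglik = cv_ll)
    ok <- nnz > 0 & nnz <= max_selected_frac * p
    if (any(ok)) {
      # among lambdas whose CV likelihood is within cv_slack of the best
      # admissible one, take the smallest (densest) — recall-friendly
      best <- max(cv_ll[ok])
      near <- ok & cv_ll >= best - 2
      lambda <- min(lams[near])
    } else {
      lambda <- lams[which.max(cv_ll)]
    }
  }

  res <- fit_one(lambda, X, time, event)
  beta <- stats::setNames(res$beta, colnames(X))
  cls <- ifelse(beta > 0, "plus", ifelse(beta < 0, "minus", "background"))
  structure(list(beta = beta, class = cls, lambda = lambda,
                 alpha_mix = alpha_mix, laplacian = L,
                 converged = res$converged, n_iter = res$n_iter,
                 objective_trace = res$trace,
                 selected_frac = mean(beta != 0), path = path_df),
            class = "CellPhenotypeScores")
}

#' @export
print.CellPhenotypeScores <- function(x, ...) {
  cat(sprintf(
    "CellPhenotypeScores: %d cells; %d plus, %d minus, %d background (lambda=%.4g)\n",
    length(x$beta), sum(x$class == "plus"), sum(x$class == "minus"),
    sum(x$class == "background"), x$lambda))
  invisible(x)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Call phenotype-linked subpopulations
#'
#' Groups nonzero-coefficient cells by (annotated parent type, coefficient
#' sign) and names each call by the composition rule: cell-type initial +
#' immunoactivity-group letter (L/H) + sign letter (p for plus =
#' poor-survival-associated, n for minus). Calls smaller than `min_cells`
#' are reported but flagged.
#'
#' @param scores `CellPhenotypeScores`.
#' @param annotation `CellAnnotation` covering all scored cells.
#' @param group_context `"low"` or `"high"` immunoactivity context.
#' @param min_cells Flagging threshold (default 10).
#' @return List of `SubpopulationCall`s: each a list with `name`,
#'   `members`, `parent_type`, `sign`, `group_context`, `flagged`.
#' @export
classify_and_call <- function(scores, annotation, group_context = "low",
                              min_cells = 10) {
  stopifnot(inherits(scores, "CellPhenotypeScores"),
            inherits(annotation, "CellAnnotation"))
  group_context <- match.arg(group_context, c("low", "high"))
  cells <- names(scores$beta)
  missing <- setdiff(cells, names(annotation$cell_cluster))
  if (length(missing)) stop("annotation missing for ",
                            length(missing), " cell(s)")
  lab <- annotation$cluster_label
  type_of <- stats::setNames(
    lab$label[match(annotation$cell_cluster, lab$cluster)],
    names(annotation$cell_cluster))
  calls <- list()
  for (tp in unique(type_of[cells])) {
    for (sgn in c("plus", "minus")) {
      members <- cells[scores$class[cells] == sgn & type_of[cells] == tp]
      if (!length(members)) next
      nm <- paste0(substr(tp, 1, 1),
                   toupper(substr(group_context, 1, 1)),
                   if (sgn == "plus") "p" else "n")
      calls[[length(calls) + 1]] <- structure(
        list(name = nm, members = members, parent_type = tp, sign = sgn,
             group_context = group_context,
             flagged = length(members) < min_cells),
        class = "SubpopulationCall")
    }
  }
  calls
}

#' @export
print.SubpopulationCall <- function(x, ...) {
  cat(sprintf("SubpopulationCall %s: %d %s cells of type %s (%s group)%s\n",
              x$name, length(x$members), x$sign, x$parent_type,
              x$group_context, if (x$flagged) " [flagged: small]" else ""))
  invisible(x)
}

#' Subpopulation signature genes and module intersection
#'
#' Markers of the call's member cells against the other cells of the same
#' parent type (one-vs-rest within type), thresholded, then intersected
#' with the co-expression module gene list.
#'
#' @param call A `SubpopulationCall`.
#' @param lognorm `ExpressionMatrix` unit lognorm.
#' @param annotation `CellAnnotation` (to find the parent type's cells).
#' @param module_genes Character vector of module genes.
#' @param padj_thresh,lfc_thresh Marker thresholds (defaults 0.05, 0.25).
#' @return List with `signature_genes`, `module_intersection`, `markers`
#'   (full marker table), `skipped` (TRUE when the call has < 3 members).
#' @export
subpopulation_signature <- function(call, lognorm, annotation, module_genes,
                                    padj_thresh = 0.05, lfc_thresh = 0.25) {
  stopifnot(inherits(call, "SubpopulationCall"))
  if (length(call$members) < 3) {
    return(list(signature_genes = character(0),
                module_intersection = character(0),
                markers = NULL, skipped = TRUE))
  }
  lab <- annotation$cluster_label
  type_of <- stats::setNames(
    lab$label[match(annotation$cell_cluster, lab$cluster)],
    names(annotation$cell_cluster))
  parent_cells <- names(type_of)[type_of == call$parent_type]
  parent_cells <- intersect(parent_cells, lognorm$sample_ids)
  grp <- stats::setNames(
    ifelse(parent_cells %in% call$members, 1L, 2L), parent_cells)
  sub <- subset_expression(lognorm, samples = parent_cells)
  mk <- cluster_markers(sub, grp)
  mk <- mk[mk$cluster == 1, ]
  sig <- mk$gene[mk$p_adj < padj_thresh & abs(mk$log2fc) >= lfc_thresh]
  list(signature_genes = sig,
       module_intersection = intersect(sig, module_genes),
       markers = mk, skipped = FALSE)
}

#' Trend of bulk immune score against subpopulation expression
#'
#' For each member cell, takes its mean signature-gene expression and the
#' immune score of its best-correlated bulk sample, and reports the
#' Spearman correlation between the two across cells: a negative trend
#' reproduces the poor-survival pattern of low-immune-score linkage.
#'
#' @param call A `SubpopulationCall`.
#' @param signature_genes Signature genes for the call.
#' @param sc_lognorm `ExpressionMatrix` unit lognorm.
#' @param corr `CellBulkCorrelation`.
#' @param bulk_immune_scores Named numeric vector per bulk sample.
#' @return List with `rho`, `n`, `per_cell` (data frame).
#' @export
score_trend <- function(call, signature_genes, sc_lognorm, corr,
                        bulk_immune_scores) {
  stopifnot(inherits(call, "SubpopulationCall"),
            inherits(corr, "CellBulkCorrelation"))
  if (!length(call$members)) stop("empty call")
  if (!length(signature_genes)) stop("empty signature")
  cells <- intersect(call$members, sc_lognorm$sample_ids)
  genes <- intersect(signature_genes, sc_lognorm$gene_ids)
  expr_mean <- colMeans(sc_lognorm$values[genes, cells, drop = FALSE])
  best_sample <- corr$sample_ids[max.col(corr$S[cells, , drop = FALSE],
                                         ties.method = "first")]
  sc_of_best <- bulk_immune_scores[best_sample]
  if (stats::sd(sc_of_best) == 0 || stats::sd(expr_mean) == 0) {
    stop("constant scores; trend undefined")
  }
  rho <- stats::cor(expr_mean, sc_of_best, method = "spearman")
  list(rho = rho, n = length(cells),
       per_cell = data.frame(cell = cells, mean_signature_expr = expr_mean,
                             best_bulk = best_sample,
                             bulk_immune_score = unname(sc_of_best),
                             stringsAsFactors = FALSE))
}
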