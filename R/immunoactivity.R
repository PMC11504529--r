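#' Partition samples into low/moderate/high activity groups
#'
#' Exact optimal one-dimensional k-means: dynamic programming over the
#' sorted scores minimizes the total within-group sum of squared deviations
#' from group means, which guarantees groups are contiguous in score order
#' and makes the partition deterministic. With the default `k_groups = 3`
#' the groups are labelled low / moderate / high in score order.
#'
#' @param scores Named numeric vector of per-sample scalars (e.g. composite
#'   immunoactivity).
#' @param k_groups Number of groups (default 3).
#' @return An `ImmunoGroups` object: list with `label` (named character per
#'   sample), `boundaries` (k-1 cut values: midpoints between adjacent
#'   groups on the score scale), `wss` (minimal total within-group sum of
#'   squares), `sizes`.
#' @export
partition_by_activity <- function(scores, k_groups = 3) {
  if (length(unique(scores)) < k_groups) {
    stop("need >= ", k_groups, " distinct scores")
  }
  ord <- order(scores)
  x <- scores[ord]
  n <- length(x)
  k <- k_groups
  # prefix sums for O(1) interval cost: cost(i..j) = sum (x - mean)^2
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  cost <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    q <- cs2[j + 1] - cs2[i]
    q - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)       # D[m, j] = best cost of first j points in m groups
  B <- matrix(0L, k, n)        # argmin start of last group
  for (j in 1:n) {
    D[1, j] <- cost(1, j)
    B[1, j] <- 1L
  }
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        for (i in m:j) {
          v <- D[m - 1, i - 1] + cost(i, j)
          if (v < D[m, j]) {
            D[m, j] <- v
            B[m, j] <- i
          }
        }
      }
    }
  }
  # backtrack
  grp_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- B[m, j]
    grp_sorted[i:j] <- m
    j <- i - 1
  }
  label_names <- if (k == 3) c("low", "moderate", "high") else
    paste0("g", seq_len(k))
  lab <- character(length(scores))
  lab[ord] <- label_names[grp_sorted]
  names(lab) <- names(scores)
  boundaries <- vapply(seq_len(k - 1), function(m) {
    hi_lo <- max(x[grp_sorted == m])
    lo_hi <- min(x[grp_sorted == m + 1])
    (hi_lo + lo_hi) / 2
  }, numeric(1))
  structure(list(label = lab, boundaries = boundaries, wss = D[k, n],
                 sizes = table(factor(lab, levels = label_names))),
            class = "ImmunoGroups")
}

#' @export
print.ImmunoGroups <- function(x, ...) {
  cat("ImmunoGroups:", paste(names(x$sizes), as.integer(x$sizes),
                             sep = "=", collapse = " "),
      sprintf("(wss=%.4g)\n", x$wss))
  invisible(x)
}

#' Fit the within-state regression of activity on abundance
#'
#' Ordinary least squares `y = k x + b` for one state's
#' (abundance, activity) points, with the coefficient of determination and
#' the two-sided t-test p-value for the slope.
#'
#' @param x Abundance values (cell-type proportions).
#' @param y Activity values (pathway/ssGSEA scores).
#' @param state State label to attach (`"tumor"` or `"control"`).
#' @return A `StateRegression` object: list with `state`, `k` (slope), `b`
#'   (intercept), `r2`, `p`, `n`, and the `x`, `y` used (kept for
#'   bootstrapping).
#' @export
fit_state_regression <- function(x, y, state = "tumor") {
  if (length(x) < 3) stop("need >= 3 points")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  k <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  p <- if (ss_tot == 0 || ss_res < .Machine$double.eps * ss_tot) {
    if (abs(k) > 0) 0 else 1
  } else {
    summary(fit)$coefficients[2, 4]
  }
  structure(list(state = state, k = k, b = b, r2 = max(0, min(1, r2)),
                 p = p, n = length(x), x = x, y = y),
            class = "StateRegression")
}

#' @export
print.StateRegression <- function(x, ...) {
  cat(sprintf("StateRegression [%s]: k=%.4g b=%.4g R2=%.3f p=%.3g n=%d\n",
              x$state, x$k, x$b, x$r2, x$p, x$n))
  invisible(x)
}

#' Slope change between tumor and control states
#'
#' `delta_k = k_tumor - k_control`, with a percentile bootstrap confidence
#' interval obtained by resampling points within each state and refitting
#' both regressions. The qualitative call reads the interval: `enhanced`
#' when it lies entirely above zero (activity per unit abundance increased
#' in tumor), `weakened` when entirely below, `unchanged` otherwise.
#'
#' @param tumor,control `StateRegression` objects carrying their points.
#' @param boot_reps Bootstrap replicates (>= 100).
#' @param conf Interval level (default 0.95).
#' @param seed Integer seed.
#' @param celltype Optional cell-type tag carried through to the result.
#' @return A `DeltaK` object: list with `delta_k`, `ci`, `call`, `celltype`,
#'   `k_tumor`, `k_control`, `boot_reps`.
#' @export
delta_k <- function(tumor, control, boot_reps = 1000, conf = 0.95,
                    seed = 1, celltype = NA_character_) {
  stopifnot(inherits(tumor, "StateRegression"),
            inherits(control, "StateRegression"))
  if (boot_reps < 100) stop("boot_reps must be >= 100")
  dk <- tumor$k - control$k
  rng <- local_rng(seed)
  boot_slope <- function(x, y, n_rep) {
    n <- length(x)
    idx <- matrix(sample.int(n, n * n_rep, replace = TRUE), n, n_rep)
    xb <- matrix(x[idx], n, n_rep)
    yb <- matrix(y[idx], n, n_rep)
    xm <- colMeans(xb)
    ym <- colMeans(yb)
    num <- colSums(xb * yb) - n * xm * ym
    den <- colSums(xb^2) - n * xm^2
    num / den
  }
  kt <- boot_slope(tumor$x, tumor$y, boot_reps)
  kc <- boot_slope(control$x, control$y, boot_reps)
  rng$restore()
  dks <- kt - kc
  dks <- dks[is.finite(dks)]
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(dks, c(a, 1 - a), type = 7))
  call <- if (ci[1] > 0) "enhanced" else if (ci[2] < 0) "weakened" else
    "unchanged"
  structure(list(delta_k = dk, ci = ci, call = call, celltype = celltype,
                 k_tumor = tumor$k, k_control = control$k,
                 boot_reps = boot_reps, conf = conf),
            class = "DeltaK")
}

#' @export
print.DeltaK <- function(x, ...) {
  cat(sprintf("DeltaK%s: %.4g [%.4g, %.4g] -> %s\n",
              if (is.na(x$celltype)) "" else paste0(" (", x$celltype, ")"),
              x$delta_k, x$ci[1], x$ci[2], x$call))
  invisible(x)
}

#' Per-stage abundance and pathway-score trajectories
#'
#' For an ordered set of sample stages, computes per-stage medians of each
#' cell type's fraction and pathway/activity score, and the Spearman
#' correlation between the two stage-ordered trajectories per cell type
#' (how abundance changes track pathway-strength changes across stages).
#'
#' @param fr `CellFractions`.
#' @param act `ActivityScore` whose set names correspond to cell types
#'   (one activity score per cell type).
#' @param stages Named list of sample-id vectors, in stage order.
#' @return List with `medians` (data frame: stage, celltype,
#'   median_fraction, median_score) and `trend` (data frame: celltype, rho;
#'   rho is NA when a trajectory is flat).
#' @export
stagewise_abundance_pathway <- function(fr, act, stages) {
  stopifnot(inherits(fr, "CellFractions"), inherits(act, "ActivityScore"))
  if (length(stages) < 2) stop("need >= 2 stages")
  if (any(!lengths(stages))) stop("stage with no samples: ",
                                  names(stages)[!lengths(stages)][1])
  cts <- intersect(fr$celltype_ids, act$set_names)
  if (!length(cts)) stop("no cell type shared between fractions and scores")
  rows <- list()
  for (s in names(stages)) {
    ids <- stages[[s]]
    for (ct in cts) {
      rows[[length(rows) + 1]] <- data.frame(
        stage = s, celltype = ct,
        median_fraction = stats::median(fr$fractions[ids, ct]),
        median_score = stats::median(act$scores[ids, ct]),
        stringsAsFactors = FALSE)
    }
  }
  med <- do.call(rbind, rows)
  trend <- do.call(rbind, lapply(cts, function(ct) {
    d <- med[med$celltype == ct, ]
    d <- d[match(names(stages), d$stage), ]
    rho <- if (length(unique(d$median_fraction)) < 2 ||
               length(unique(d$median_score)) < 2) NA_real_ else
      stats::cor(d$median_fraction, d$median_score, method = "spearman")
    data.frame(celltype = ct, rho = rho, stringsAsFactors = FALSE)
  }))
  list(medians = med, trend = trend)
}
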