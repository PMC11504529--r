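#' Fit a Cox proportional-hazards model
#'
#' Multivariate Cox regression maximizing the Breslow-ties partial
#' likelihood (Newton-type optimization), with per-covariate Wald tests.
#' Covariates are standardized internally for numerical stability and the
#' coefficients reported back on the original scale.
#'
#' @param clinical Clinical data frame with `sample_id`, `time`, `event`.
#' @param covariates Sample-by-covariate numeric matrix (rownames =
#'   sample ids) or data frame.
#' @return A `CoxFit` object: list with `coef`, `se`, `z`, `p` (named per
#'   covariate), `log_partial_likelihood`, `n`, `n_events`, `converged`,
#'   and the underlying `survival::coxph` fit in `$fit`.
#' @export
fit_cox <- function(clinical, covariates) {
  covariates <- as.matrix(covariates)
  if (is.null(rownames(covariates))) {
    if (nrow(covariates) != nrow(clinical)) stop("covariate rows unmatched")
    rownames(covariates) <- clinical$sample_id
  }
  ids <- intersect(clinical$sample_id, rownames(covariates))
  cl <- clinical[match(ids, clinical$sample_id), ]
  X <- covariates[ids, , drop = FALSE]
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(cl$event) < 1) stop("no events in clinical data")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("constant covariate(s): ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  Xs <- scale(X, center = ctr, scale = scl)
  df <- data.frame(time = cl$time, event = cl$event, Xs)
  fm <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                paste(colnames(X), collapse = " + ")))
  fit <- survival::coxph(fm, data = df, ties = "breslow")
  sm <- summary(fit)
  conv <- is.null(fit$info) && all(is.finite(stats::coef(fit)))
  nm <- colnames(X)
  coef_orig <- stats::setNames(stats::coef(fit) / scl, nm)
  se_orig <- stats::setNames(sm$coefficients[, "se(coef)"] / scl, nm)
  structure(list(coef = coef_orig, se = se_orig,
                 z = stats::setNames(sm$coefficients[, "z"], nm),
                 p = stats::setNames(sm$coefficients[, "Pr(>|z|)"], nm),
                 log_partial_likelihood = fit$loglik[2],
                 n = nrow(df), n_events = sum(cl$event),
                 converged = conv, fit = fit,
                 center = ctr, scale = scl),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat("CoxFit:", x$n, "subjects,", x$n_events, "events; logPL =",
      sprintf("%.4f", x$log_partial_likelihood), "\n")
  print(data.frame(coef = x$coef, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' Breslow partial log-likelihood (direct evaluation)
#'
#' Evaluates the Breslow-ties Cox partial log-likelihood at a coefficient
#' vector by direct summation over risk sets. Used for auditing fits and by
#' the phenotype-linkage selector.
#'
#' @param beta Coefficient vector.
#' @param X Subject-by-covariate matrix.
#' @param time,event Survival times and 0/1 event flags.
#' @return Scalar log partial likelihood.
#' @export
breslow_loglik <- function(beta, X, time, event) {
  eta <- unname(drop(X %*% beta))
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[at_risk])))
  }
  ll
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' @param clinical Clinical data frame with `time` and `event`.
#' @param groups Named group label per sample (2 groups), or column name in
#'   `clinical`.
#' @return A `SurvivalCurvePair`: list with `curves` (data frame: group,
#'   time, n_risk, n_event, surv), `logrank_chi2`, `logrank_p` (NA when no
#'   events occur), and the `survival::survfit` object in `$fit`.
#' @export
km_logrank <- function(clinical, groups) {
  if (is.character(groups) && length(groups) == 1) {
    grp <- clinical[[groups]]
  } else {
    grp <- groups[clinical$sample_id]
  }
  if (length(unique(grp)) != 2) stop("need exactly 2 groups")
  if (any(table(grp) < 1)) stop("empty group")
  df <- data.frame(time = clinical$time, event = clinical$event, grp = grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ grp, data = df)
  strata_names <- sub("^grp=", "", rep(names(sf$strata), sf$strata))
  curves <- data.frame(group = strata_names, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv, stringsAsFactors = FALSE)
  if (sum(df$event) == 0) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
    chi2 <- sd_$chisq
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(curves = curves, logrank_chi2 = chi2, logrank_p = p,
                 fit = sf), class = "SurvivalCurvePair")
}

#' Time-dependent ROC at a fixed horizon
#'
#' Cumulative-case / dynamic-control ROC for a risk score at the given
#' horizon, with censoring handled through Kaplan-Meier estimates: for each
#' cutpoint c, sensitivity is `P(score > c | event by t)` and 1-specificity
#' is `P(score > c | survival past t)`, each estimated from the KM survival
#' of the score-defined subgroup weighted by its size. With no censoring
#' this reduces exactly to the empirical ROC of the binary
#' event-by-horizon outcome. AUC by trapezoid.
#'
#' @param risk_scores Named numeric vector (higher = higher risk).
#' @param clinical Clinical data frame with `sample_id`, `time`, `event`.
#' @param horizon Evaluation time, in the clinical table's time unit.
#' @return List with `curve` (data frame: cutoff, tpr, fpr) and `auc`.
#' @export
time_dependent_roc <- function(risk_scores, clinical, horizon) {
  ids <- intersect(names(risk_scores), clinical$sample_id)
  if (!length(ids)) {
    ids <- clinical$sample_id
    if (length(risk_scores) != length(ids)) stop("risk scores unmatched")
    names(risk_scores) <- ids
  }
  cl <- clinical[match(ids, clinical$sample_id), ]
  x <- risk_scores[ids]
  if (horizon <= 0 || horizon > max(cl$time)) {
    stop("horizon outside the observed time range")
  }
  km_at <- function(sel) {
    # KM survival at `horizon` within subgroup sel
    if (!any(sel)) return(NA_real_)
    sf <- survival::survfit(survival::Surv(cl$time[sel], cl$event[sel]) ~ 1)
    s <- summary(sf, times = horizon, extend = TRUE)$surv
    if (!length(s)) 1 else s
  }
  S_all <- km_at(rep(TRUE, length(x)))
  if (!is.finite(S_all) || S_all >= 1 || S_all <= 0) {
    stop("degenerate horizon: estimated event probability is 0 or 1 ",
         "(all censored before the horizon, or no survivors)")
  }
  cuts <- sort(unique(x))
  cutoffs <- c(-Inf, cuts)
  tpr <- fpr <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    c_ <- cutoffs[i]
    sel <- x > c_
    p_sel <- mean(sel)
    S_sel <- if (any(sel)) km_at(sel) else 1
    tpr[i] <- (1 - S_sel) * p_sel / (1 - S_all)
    fpr[i] <- S_sel * p_sel / S_all
  }
  # numerical guards: probabilities clipped to [0,1] and snapped to 12
  # digits so equal staircase levels sort together despite fp noise
  tpr <- round(pmin(pmax(tpr, 0), 1), 12)
  fpr <- round(pmin(pmax(fpr, 0), 1), 12)
  ord <- order(fpr, tpr)
  fs <- c(0, fpr[ord], 1)
  ts <- c(0, tpr[ord], 1)
  auc <- sum(diff(fs) * (utils::head(ts, -1) + utils::tail(ts, -1)) / 2)
  list(curve = data.frame(cutoff = cutoffs, tpr = tpr, fpr = fpr),
       auc = auc)
}
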