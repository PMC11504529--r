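#' Simulate a bulk cohort as mixtures of cell-type signatures
#'
#' Generates a gene-by-sample bulk expression matrix as `signature %*%
#' t(fractions)` perturbed by multiplicative log-normal noise, together with
#' the planted truth and a clinical table with exponential
#' proportional-hazards survival. Each cell type owns a block of 20 marker
#' genes with elevated mean expression, so the signature columns are well
#' separated; remaining genes share a common baseline. The per-sample
#' log-hazard is `risk_slope` per standard deviation of the first cell
#' type's (centred) fraction: samples rich in the first cell type are the
#' high-risk samples, and the planted effect size is stated in log-hazard
#' units per fraction SD regardless of the Dirichlet spread. Censoring
#' times are drawn from an independent exponential calibrated so that a
#' fraction `censor_frac` of baseline-risk subjects is censored.
#'
#' @param n_samples Number of bulk samples (>= 8).
#' @param n_genes Number of genes (>= 20 * n_celltypes).
#' @param n_celltypes Number of cell types (>= 3).
#' @param dirichlet_conc Dirichlet concentration: scalar or vector of length
#'   `n_celltypes`.
#' @param noise_sd SD of the log-normal multiplicative noise (0 = exact
#'   mixtures).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param risk_slope Log-hazard gained per SD of cell type 1's fraction;
#'   default `1`.
#' @param base_rate Baseline exponential event rate per month; default 0.02.
#' @param censor_frac Target censoring fraction at baseline risk; default 0.2.
#' @param tumor_frac Fraction of samples labelled tumor (rest control).
#' @return List with `expr` (ExpressionMatrix, unit=normalized), `truth`
#'   (list: `signature`, `fractions`, `noise_sd`, `risk_coef`), and
#'   `clinical` (data frame with state, time in months, event).
#' @export
generate_bulk_cohort <- function(n_samples, n_genes, n_celltypes,
                                 dirichlet_conc = 1, noise_sd = 0.1,
                                 seed = 1, risk_slope = 1, base_rate = 0.02,
                                 censor_frac = 0.2, tumor_frac = 0.5) {
  if (n_samples < 8) stop("n_samples must be >= 8")
  if (n_celltypes < 3) stop("n_celltypes must be >= 3")
  if (n_genes < 20 * n_celltypes) stop("n_genes must be >= 20 * n_celltypes")
  rng <- local_rng(seed)

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  type_ids <- sprintf("CT%02d", seq_len(n_celltypes))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  # signature: shared baseline + 20 elevated markers per type
  base <- exp(stats::rnorm(n_genes, mean = 2, sd = 0.5))
  sig <- matrix(rep(base, n_celltypes), n_genes, n_celltypes,
                dimnames = list(gene_ids, type_ids))
  marker_idx <- vector("list", n_celltypes)
  for (t in seq_len(n_celltypes)) {
    idx <- ((t - 1) * 20 + 1):(t * 20)
    marker_idx[[t]] <- gene_ids[idx]
    sig[idx, t] <- sig[idx, t] * stats::runif(20, 6, 10)
  }

  fractions <- rdirichlet(n_samples, rep_len(dirichlet_conc, n_celltypes))
  dimnames(fractions) <- list(sample_ids, type_ids)

  mean_expr <- sig %*% t(fractions)
  noise <- if (noise_sd > 0) {
    matrix(exp(stats::rnorm(n_genes * n_samples, 0, noise_sd)),
           n_genes, n_samples)
  } else 1
  expr <- expression_matrix(mean_expr * noise, gene_ids, sample_ids,
                            unit = "normalized")

  f1 <- fractions[, 1]
  risk_coef <- risk_slope * (f1 - mean(f1)) / stats::sd(f1)
  ev_time <- stats::rexp(n_samples, rate = base_rate * exp(risk_coef))
  cens_rate <- base_rate * censor_frac / (1 - censor_frac)
  cens_time <- stats::rexp(n_samples, rate = cens_rate)
  time <- pmin(ev_time, cens_time)
  event <- as.integer(ev_time <= cens_time)

  n_tumor <- round(tumor_frac * n_samples)
  state <- c(rep("tumor", n_tumor), rep("control", n_samples - n_tumor))
  clinical <- data.frame(sample_id = sample_ids, state = state,
                         time = time, event = event,
                         stringsAsFactors = FALSE)
  rng$restore()
  list(expr = expr,
       truth = list(signature = sig, fractions = fractions,
                    noise_sd = noise_sd, risk_coef = risk_coef,
                    marker_genes = marker_idx, risk_celltype = type_ids[1]),
       clinical = clinical)
}

#' Simulate two-state abundance/activity pairs with planted slopes
#'
#' Per state, abundance `x` is uniform on `x_range` and activity
#' `y = k x + b + Normal(0, sigma)`. This is the planted analogue of
#' comparing how per-cell-type activity responds to abundance in tumor
#' versus control tissue.
#'
#' @param k_control,k_tumor Planted slopes.
#' @param b_control,b_tumor Intercepts.
#' @param sigma Noise SD (>= 0).
#' @param n_control,n_tumor Points per state (>= 3).
#' @param x_range Abundance interval, default `c(0, 1)`.
#' @param seed Integer seed.
#' @return Data frame with columns `state`, `x`, `y`.
#' @export
generate_two_state <- function(k_control, k_tumor, b_control = 0,
                               b_tumor = 0, sigma = 0.05,
                               n_control = 30, n_tumor = 30,
                               x_range = c(0, 1), seed = 1) {
  if (n_control < 3 || n_tumor < 3) stop("need >= 3 points per state")
  if (sigma < 0) stop("sigma must be >= 0")
  rng <- local_rng(seed)
  sim1 <- function(n, k, b, state) {
    x <- stats::runif(n, x_range[1], x_range[2])
    y <- k * x + b + stats::rnorm(n, 0, sigma)
    data.frame(state = state, x = x, y = y, stringsAsFactors = FALSE)
  }
  out <- rbind(sim1(n_control, k_control, b_control, "control"),
               sim1(n_tumor, k_tumor, b_tumor, "tumor"))
  rng$restore()
  out
}

#' Simulate single cells with a planted phenotype-linked subpopulation
#'
#' Counts are negative-binomial around type-specific means; each type's
#' marker genes are elevated. A planted subpopulation inside one type has
#' its `shift_genes` means multiplied by `2^shift_size`; when `shift_genes`
#' are the markers of the bulk cohort's risk-linked cell type, the shifted
#' cells correlate preferentially with high-risk bulk samples — the mixing
#' rule through which planted cells become phenotype-linked. Optional
#' engineered QC failures (cells under the feature thresholds, high-mito
#' cells, and mitochondrial genes named with `mito_prefix`) make filter
#' counts predictable.
#'
#' @param n_cells_per_type Named integer vector: cells per cell type.
#' @param marker_sets `GeneSetCollection` (or named list) of per-type marker
#'   genes; names must match `names(n_cells_per_type)`; genes must be in
#'   `gene_ids`.
#' @param gene_ids Genes to simulate (use the bulk cohort's genes to share
#'   identifiers with bulk).
#' @param planted List with `parent_type`, `n_cells`, `shift_genes`,
#'   `shift_size` (log2 fold shift); or NULL for no subpopulation.
#' @param base_mean Mean count of a background gene; default 0.5.
#' @param marker_fold Fold elevation of a type's markers; default 8.
#' @param dispersion NB size parameter (smaller = noisier); default 2.
#' @param n_fail_low,n_fail_mid,n_fail_mito Engineered QC-failing cells:
#'   below the object-creation feature rule, between the two feature
#'   thresholds, above 5% mitochondrial fraction.
#' @param fail_features Detected-feature counts given to the two kinds of
#'   engineered low-feature cells; defaults `c(low = 100, mid = 400)`
#'   match the standard 300/500 rules.
#' @param n_mito_genes Number of `mito_prefix`-named genes appended.
#' @param mito_prefix Prefix for mitochondrial gene names.
#' @param seed Integer seed.
#' @return List with `counts` (ExpressionMatrix unit=counts) and `truth`
#'   (list: `type_of_cell`, `planted_subpop`, `shift_genes`, `shift_size`,
#'   `qc_fail` counts).
#' @export
generate_single_cells <- function(n_cells_per_type, marker_sets, gene_ids,
                                  planted = NULL,
                                  base_mean = 0.5, marker_fold = 8,
                                  dispersion = 2,
                                  n_fail_low = 0, n_fail_mid = 0,
                                  n_fail_mito = 0,
                                  fail_features = c(low = 100, mid = 400),
                                  n_mito_genes = 10,
                                  mito_prefix = "MT-", seed = 1) {
  types <- names(n_cells_per_type)
  if (is.null(types)) stop("n_cells_per_type must be named by cell type")
  unknown <- setdiff(unlist(marker_sets), gene_ids)
  if (length(unknown)) stop("marker sets reference unknown genes: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  if (!is.null(planted)) {
    if (!planted$parent_type %in% types) stop("planted parent_type unknown")
    if (length(setdiff(planted$shift_genes, gene_ids))) {
      stop("planted shift_genes not all in gene_ids")
    }
  }
  rng <- local_rng(seed)

  mito_genes <- paste0(mito_prefix, seq_len(n_mito_genes))
  all_genes <- c(gene_ids, mito_genes)
  n_genes <- length(all_genes)

  cell_ids <- character(0)
  type_of_cell <- character(0)
  mu_cols <- list()
  planted_cells <- character(0)

  for (tp in types) {
    n_c <- n_cells_per_type[[tp]]
    ids <- sprintf("%s_c%04d", tp, seq_len(n_c))
    mu <- rep(base_mean, n_genes)
    names(mu) <- all_genes
    mk <- intersect(marker_sets[[tp]], gene_ids)
    mu[mk] <- mu[mk] * marker_fold
    mu[mito_genes] <- base_mean * 0.3   # low normal mito background
    mu_t <- matrix(mu, n_genes, n_c)
    if (!is.null(planted) && planted$parent_type == tp) {
      sub <- seq_len(min(planted$n_cells, n_c))
      mu_t[match(planted$shift_genes, all_genes), sub] <-
        mu_t[match(planted$shift_genes, all_genes), sub] * 2^planted$shift_size
      planted_cells <- c(planted_cells, ids[sub])
    }
    mu_cols[[tp]] <- mu_t
    cell_ids <- c(cell_ids, ids)
    type_of_cell <- c(type_of_cell, rep(tp, n_c))
  }
  mu_all <- do.call(cbind, mu_cols)
  counts <- matrix(stats::rnbinom(length(mu_all), mu = as.vector(mu_all),
                                  size = dispersion),
                   n_genes, length(cell_ids))
  dimnames(counts) <- list(all_genes, cell_ids)

  # engineered QC failures appended as extra cells
  qc_ids <- character(0)
  add_cells <- function(n, maker, tag) {
    if (n == 0) return(NULL)
    ids <- sprintf("QC%s_c%03d", tag, seq_len(n))
    m <- vapply(seq_len(n), function(i) maker(), numeric(n_genes))
    qc_ids <<- c(qc_ids, ids)
    colnames(m) <- ids
    m
  }
  nf_low <- fail_features[["low"]]
  nf_mid <- fail_features[["mid"]]
  if ((n_fail_low > 0 && nf_low > length(gene_ids)) ||
      (n_fail_mid > 0 && nf_mid > length(gene_ids))) {
    stop("fail_features exceed the number of non-mitochondrial genes")
  }
  lowf <- add_cells(n_fail_low, function() {
    v <- numeric(n_genes)
    idx <- sample.int(length(gene_ids), nf_low)
    v[idx] <- 1 + stats::rpois(nf_low, 1)
    v
  }, "low")
  midf <- add_cells(n_fail_mid, function() {
    v <- numeric(n_genes)
    idx <- sample.int(length(gene_ids), nf_mid)
    v[idx] <- 1 + stats::rpois(nf_mid, 1)
    v
  }, "mid")
  mitof <- add_cells(n_fail_mito, function() {
    # plenty of features but >5% of reads mitochondrial
    v <- stats::rpois(n_genes, 2) + 1
    v[match(mito_genes, all_genes)] <- round(sum(v) * 0.15 / n_mito_genes)
    v
  }, "mito")
  counts <- cbind(counts, lowf, midf, mitof)
  type_of_cell <- c(type_of_cell, rep(NA_character_, length(qc_ids)))
  names(type_of_cell) <- colnames(counts)

  rng$restore()
  list(counts = expression_matrix(counts, unit = "counts"),
       truth = list(type_of_cell = type_of_cell,
                    planted_subpop = planted_cells,
                    shift_genes = if (is.null(planted)) character(0) else
                      planted$shift_genes,
                    shift_size = if (is.null(planted)) 0 else
                      planted$shift_size,
                    dispersion = dispersion,
                    qc_fail = c(low = n_fail_low, mid = n_fail_mid,
                                mito = n_fail_mito)))
}

#' Simulate expression with planted co-expression blocks
#'
#' Genes in a block share a latent standard-normal factor so that every
#' within-block pair has Pearson correlation approximately `within_cor`;
#' background genes are independent noise.
#'
#' @param n_genes Total genes.
#' @param block_sizes Integer vector of block sizes (sum <= n_genes).
#' @param within_cor Target within-block correlation in `[0, 1)`.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return List with `expr` (ExpressionMatrix, unit=normalized) and `labels`
#'   (integer vector per gene: block index, 0 = background).
#' @export
generate_module_blocks <- function(n_genes, block_sizes, within_cor,
                                   n_samples, seed = 1) {
  if (sum(block_sizes) > n_genes) stop("sum(block_sizes) > n_genes")
  if (within_cor < 0 || within_cor >= 1) stop("within_cor must be in [0, 1)")
  rng <- local_rng(seed)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  labels <- integer(n_genes)
  vals <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  pos <- 1
  for (b in seq_along(block_sizes)) {
    idx <- pos:(pos + block_sizes[b] - 1)
    z <- stats::rnorm(n_samples)
    vals[idx, ] <- sqrt(within_cor) * matrix(z, length(idx), n_samples,
                                             byrow = TRUE) +
      sqrt(1 - within_cor) * vals[idx, ]
    labels[idx] <- b
    pos <- pos + block_sizes[b]
  }
  names(labels) <- gene_ids
  rng$restore()
  list(expr = expression_matrix(vals, gene_ids, sample_ids,
                                unit = "normalized"),
       labels = labels)
}

# Dirichlet draws via gamma normalization
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

# Run a block under a private RNG stream; callers get reproducibility from
# the seed without clobbering the session RNG.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}
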