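make_sig <- function(n_genes = 60, k = 4, seed = 1) {
  set.seed(seed)
  sig <- matrix(rlnorm(n_genes * k, 1, 0.5), n_genes, k,
                dimnames = list(sprintf("g%03d", 1:n_genes),
                                paste0("ct", 1:k)))
  for (j in 1:k) sig[((j - 1) * 10 + 1):(j * 10), j] <-
      sig[((j - 1) * 10 + 1):(j * 10), j] * 8
  sig
}

test_that("exact mixtures and pure columns are recovered to 1e-6", {
  sig <- make_sig()
  mix <- cbind(0.3 * sig[, 1] + 0.7 * sig[, 2], sig[, 3])
  expr <- expression_matrix(mix, rownames(sig), c("m1", "pure"),
                            unit = "normalized")
  fr <- estimate_fractions(expr, sig, n_perm = 10, seed = 1)
  expect_equal(unname(fr$fractions["m1", ]), c(0.3, 0.7, 0, 0),
               tolerance = 1e-6)
  expect_equal(unname(fr$fractions["pure", ]), c(0, 0, 1, 0),
               tolerance = 1e-6)
  expect_equal(rowSums(fr$fractions), c(m1 = 1, pure = 1), tolerance = 1e-9)
})

test_that("fractions are invariant to positive scaling of a sample", {
  sig <- make_sig()
  set.seed(2)
  w <- c(0.2, 0.1, 0.4, 0.3)
  y <- as.vector(sig %*% w) * rlnorm(60, 0, 0.05)
  expr <- expression_matrix(cbind(a = y, b = 13.7 * y), rownames(sig),
                            c("a", "b"), unit = "normalized")
  fr <- estimate_fractions(expr, sig, n_perm = 10, seed = 3)
  expect_equal(fr$fractions["a", ], fr$fractions["b", ], tolerance = 1e-8)
})

test_that("nnls residual never increases when the signature grows", {
  sig <- make_sig(60, 4)
  set.seed(4)
  for (r in 1:5) {
    y <- as.vector(sig %*% runif(4)) * rlnorm(60, 0, 0.2)
    r_small <- pracma::lsqnonneg(sig[, 1:3], y)
    r_full <- pracma::lsqnonneg(sig, y)
    expect_lte(sqrt(sum(r_full$resid.norm)),
               sqrt(sum(r_small$resid.norm)) + 1e-8)
  }
})

test_that("recovery improves monotonically as noise shrinks", {
  mean_r <- vapply(c(0.4, 0.2, 0.05), function(ns) {
    b <- generate_bulk_cohort(20, 120, 6, noise_sd = ns, seed = 77)
    fr <- estimate_fractions(b$expr, b$truth$signature, n_perm = 5,
                             seed = 1)
    mean(vapply(seq_len(20), function(i)
      cor(fr$fractions[i, ], b$truth$fractions[i, ]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("group comparison matches exact rank-sum enumeration at small n", {
  sig <- make_sig()
  set.seed(11)
  k <- 4
  fr_mat <- matrix(rexp(10 * k), 10, k)
  fr_mat <- fr_mat / rowSums(fr_mat)
  dimnames(fr_mat) <- list(paste0("s", 1:10), colnames(sig))
  fr <- structure(list(fractions = fr_mat,
                       fit_stats = data.frame(sample_id = rownames(fr_mat)),
                       celltype_ids = colnames(fr_mat),
                       sample_ids = rownames(fr_mat)),
                  class = "CellFractions")
  labels <- setNames(rep(c("tumor", "control"), each = 5), rownames(fr_mat))
  res <- compare_fraction_groups(fr, labels)
  for (ct in colnames(fr_mat)) {
    p_oracle <- oracle_ranksum_p(fr_mat[1:5, ct], fr_mat[6:10, ct])
    expect_equal(res$p_wilcoxon[res$celltype == ct], p_oracle,
                 tolerance = 1e-10)
  }
  expect_true(all(res$p_adj_BH >= res$p_wilcoxon - 1e-12))
})

test_that("a planted fraction shift is detected with the smallest p", {
  hits <- 0
  for (s in 1:8) {
    b <- generate_bulk_cohort(24, 120, 6, dirichlet_conc = 2,
                              noise_sd = 0.05, seed = 100 + s)
    fr_true <- b$truth$fractions
    # plant: tumor samples get cell type 2 doubled then renormalized
    tum <- b$clinical$sample_id[b$clinical$state == "tumor"]
    fr_true[tum, 2] <- fr_true[tum, 2] * 3
    fr_true <- fr_true / rowSums(fr_true)
    fr <- structure(list(fractions = fr_true,
                         fit_stats = data.frame(sample_id = rownames(fr_true)),
                         celltype_ids = colnames(fr_true),
                         sample_ids = rownames(fr_true)),
                    class = "CellFractions")
    res <- compare_fraction_groups(fr, setNames(b$clinical$state,
                                                b$clinical$sample_id))
    if (res$celltype[which.min(res$p_wilcoxon)] == colnames(fr_true)[2]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 7)
})

test_that("abundance ranking orders by median with lexicographic ties", {
  fr_mat <- rbind(c(0.4, 0.1, 0.25, 0.25), c(0.4, 0.1, 0.25, 0.25))
  dimnames(fr_mat) <- list(c("s1", "s2"), c("ctB", "ctA", "ctD", "ctC"))
  fr <- structure(list(fractions = fr_mat, celltype_ids = colnames(fr_mat),
                       sample_ids = rownames(fr_mat)),
                  class = "CellFractions")
  rk <- rank_abundance(fr)
  expect_identical(rk$celltype, c("ctB", "ctC", "ctD", "ctA"))
  expect_error(rank_abundance(fr, character(0)), "empty")
})

test_that("spearman correlation matches exact enumeration at n = 6", {
  set.seed(21)
  x <- rnorm(6)
  y <- rnorm(6)
  st <- tmeprofiler:::spearman_test(x, y, exact_n = 9)
  # brute force over all 720 permutations of y's ranks
  perms <- tmeprofiler:::all_permutations(6)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  rho_null <- apply(perms, 1, function(p) cor(rx, ry[p]))
  expect_equal(st$rho, rho_obs)
  expect_equal(st$p, mean(abs(rho_null) >= abs(rho_obs) - 1e-12))

  # perfect and reversed ranks
  expect_equal(tmeprofiler:::spearman_test(1:6, 2 * (1:6))$rho, 1)
  expect_equal(tmeprofiler:::spearman_test(1:6, 6:1)$rho, -1)
  # constant vector -> NA, not zero
  expect_true(is.na(tmeprofiler:::spearman_test(rep(1, 6), rnorm(6))$rho))
})

test_that("gene-infiltration correlation reports rho, exact p and missing", {
  set.seed(31)
  fr_mat <- matrix(rexp(6 * 2), 6, 2)
  fr_mat <- fr_mat / rowSums(fr_mat)
  dimnames(fr_mat) <- list(paste0("s", 1:6), c("A", "B"))
  fr <- structure(list(fractions = fr_mat, celltype_ids = c("A", "B"),
                       sample_ids = rownames(fr_mat)),
                  class = "CellFractions")
  ev <- rbind(g1 = fr_mat[, "A"],            # identical to a fraction
              g2 = max(fr_mat[, "A"]) - fr_mat[, "A"],  # reversed
              g3 = rep(2, 6))                # constant -> missing
  expr <- expression_matrix(ev, rownames(ev), rownames(fr_mat),
                            unit = "normalized")
  res <- gene_infiltration_correlation(expr, fr)
  expect_equal(res$spearman_rho[res$gene == "g1" & res$celltype == "A"], 1)
  expect_equal(res$spearman_rho[res$gene == "g2" & res$celltype == "A"], -1)
  expect_true(is.na(res$spearman_rho[res$gene == "g3" &
                                       res$celltype == "A"]))
  # p at n = 6 equals the permutation enumeration done independently
  perms <- tmeprofiler:::all_permutations(6)
  rx <- rank(ev["g1", ]); ry <- rank(fr_mat[, "B"])
  rho_obs <- cor(rx, ry)
  p_exact <- mean(apply(perms, 1, function(p) abs(cor(rx, ry[p]))) >=
                    abs(rho_obs) - 1e-12)
  expect_equal(res$p[res$gene == "g1" & res$celltype == "B"], p_exact,
               tolerance = 1e-10)
})
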