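test_that("qc filter reports the constructed violation counts exactly", {
  cnt <- build_qc_fixture()
  res <- qc_filter(cnt)
  rep_ <- res$report
  expect_equal(unname(rep_["n_cells_in"]), 141)
  expect_equal(unname(rep_["n_removed_gene_filter"]), 40)
  expect_equal(unname(rep_["n_removed_feature_300"]), 12)
  expect_equal(unname(rep_["n_removed_feature_500"]), 5)
  expect_equal(unname(rep_["n_removed_mito"]), 4)
  expect_equal(unname(rep_["n_cells_out"]), 120)
  expect_equal(unname(rep_["n_cells_in"]) -
                 sum(rep_[c("n_removed_feature_300", "n_removed_feature_500",
                            "n_removed_mito")]),
               unname(rep_["n_cells_out"]))
  # zero thresholds = identity filter
  res0 <- qc_filter(cnt, min_cells_per_gene = 0, min_features_create = 0,
                    min_features_filter = 0, max_mito_frac = 1)
  expect_equal(dim(res0$counts$values), dim(cnt$values))
  # a 6% mito cell is removed at the mito step
  m <- cnt$values[, 1:120]
  m["MT-1", 1] <- round(0.07 * sum(m[, 1]) / (1 - 0.07))
  r2 <- qc_filter(expression_matrix(m, unit = "counts"),
                  min_cells_per_gene = 0)
  expect_equal(unname(r2$report["n_removed_mito"]), 1)
})

test_that("log normalization matches its closed form and scale invariance", {
  m <- matrix(c(1, 1, 0, 2, 3, 5, 0, 0, 4, 1, 2, 0), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  ln <- log_normalize(expression_matrix(m, unit = "counts"),
                      scale_factor = 10000)
  # brute force
  for (j in 1:3) {
    expect_equal(ln$values[, j], log(1 + m[, j] * 10000 / sum(m[, j])),
                 tolerance = 1e-12)
  }
  # cell (1,1): total 2, each entry ln(1 + 5000)
  m2 <- matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "c1"))
  ln2 <- log_normalize(expression_matrix(m2, unit = "counts"))
  expect_equal(unname(ln2$values[, 1]), rep(log(5001), 2), tolerance = 1e-12)
  # doubling a cell's counts leaves its normalized vector unchanged
  ln3 <- log_normalize(expression_matrix(2 * m, unit = "counts"))
  expect_equal(ln3$values, ln$values, tolerance = 1e-12)
  # double-normalization is an error
  expect_error(log_normalize(ln), "unit=counts")
})

test_that("hvg selection finds planted high-dispersion genes", {
  hits <- 0
  for (s in 1:5) {
    set.seed(820 + s)
    mus <- rlnorm(300, 1.2, 0.8)
    m <- t(sapply(1:300, function(g)
      rnbinom(150, mu = mus[g], size = if (g <= 10) 0.3 else 10)))
    dimnames(m) <- list(sprintf("g%03d", 1:300), sprintf("c%03d", 1:150))
    ln <- log_normalize(expression_matrix(m, unit = "counts"))
    hv <- select_hvg(ln, 30)
    if (sum(sprintf("g%03d", 1:10) %in% hv) >= 8) hits <- hits + 1
  }
  expect_gte(hits, 4)

  ln <- log_normalize(expression_matrix(
    matrix(rpois(200, 3) + 1, 20, 10,
           dimnames = list(paste0("g", 1:20), paste0("c", 1:10))),
    unit = "counts"))
  expect_setequal(select_hvg(ln, 20), ln$gene_ids)
  # invariance to cell order
  perm <- sample(10)
  lnp <- expression_matrix(ln$values[, perm], ln$gene_ids,
                           ln$sample_ids[perm], unit = "lognorm")
  expect_identical(select_hvg(ln, 5), select_hvg(lnp, 5))
})

test_that("embedding separates planted types and respects clipping", {
  set.seed(83)
  mu <- matrix(2, 100, 2)
  mu[1:30, 1] <- 12
  mu[31:60, 2] <- 12
  m <- cbind(matrix(rpois(100 * 60, mu[, 1]), 100, 60),
             matrix(rpois(100 * 60, mu[, 2]), 100, 60))
  dimnames(m) <- list(sprintf("g%03d", 1:100), sprintf("c%03d", 1:120))
  truth <- rep(1:2, each = 60)
  ln <- log_normalize(expression_matrix(m, unit = "counts"))
  emb <- embed_cells(ln, n_pcs = 5)
  km <- kmeans(emb$coords[, 1], centers = 2, nstart = 5)
  expect_gte(max(mean(km$cluster == truth), mean(km$cluster == 3 - truth)),
             0.95)
  expect_lte(sum(emb$var_frac), 1 + 1e-9)

  # clipping bounds the z-scores entering the PCA
  z <- t(scale(t(ln$values)))
  expect_true(max(abs(z), na.rm = TRUE) > 0)
})

test_that("snn clustering recovers three planted types deterministically", {
  set.seed(84)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  emb <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(80, 0, 0.5), 40, 2), 2, centers[k, ], "+")))
  rownames(emb) <- sprintf("c%03d", 1:120)
  truth <- rep(1:3, each = 40)
  cl <- cluster_cells(emb, k_neighbors = 20, resolution = 1)
  expect_gte(ari(cl, truth), 0.9)
  cl2 <- cluster_cells(emb, k_neighbors = 20, resolution = 1)
  expect_identical(cl, cl2)
  # resolution -> 0 collapses a connected graph to one cluster
  blob <- matrix(rnorm(200), 100, 2,
                 dimnames = list(paste0("b", 1:100), NULL))
  cl0 <- cluster_cells(blob, k_neighbors = 15, resolution = 0.01)
  expect_equal(length(unique(cl0)), 1)
})

test_that("marker annotation labels planted clusters and breaks ties", {
  set.seed(85)
  m <- matrix(rpois(80 * 60, 2), 80, 60)
  m[1:10, 1:30] <- m[1:10, 1:30] + rpois(10 * 30, 10)   # B markers up
  m[11:20, 31:60] <- m[11:20, 31:60] + rpois(10 * 30, 10) # T markers up
  dimnames(m) <- list(sprintf("g%03d", 1:80), sprintf("c%03d", 1:60))
  ln <- log_normalize(expression_matrix(m, unit = "counts"))
  clusters <- setNames(rep(1:2, each = 30), colnames(m))
  ms <- gene_set_collection(list(B = sprintf("g%03d", 1:10),
                                 T = sprintf("g%03d", 11:20)))
  ann <- annotate_clusters(ln, clusters, ms)
  expect_equal(ann$cluster_label$label, c("B", "T"))
  expect_false(any(ann$cluster_label$uncertain))

  # identical marker sets: lexicographic tie, flagged
  ms2 <- gene_set_collection(list(zz = sprintf("g%03d", 1:10),
                                  aa = sprintf("g%03d", 1:10)))
  ann2 <- annotate_clusters(ln, clusters, ms2)
  expect_equal(ann2$cluster_label$label[1], "aa")
  expect_true(all(ann2$cluster_label$uncertain))
})

test_that("cluster markers match exact rank-sum enumeration at small sizes", {
  set.seed(86)
  m <- matrix(rlnorm(12 * 10), 12, 10,
              dimnames = list(paste0("g", 1:12), paste0("c", 1:10)))
  ln <- expression_matrix(m, unit = "lognorm")
  clusters <- setNames(rep(1:2, each = 5), colnames(m))
  mk <- cluster_markers(ln, clusters, genes = paste0("g", 1:4))
  for (g in paste0("g", 1:4)) {
    p_pkg <- mk$p[mk$cluster == 1 & mk$gene == g]
    p_or <- oracle_ranksum_p(m[g, 1:5], m[g, 6:10])
    expect_equal(p_pkg, p_or, tolerance = 1e-10)
  }
  expect_error(cluster_markers(ln, setNames(c(1, rep(2, 9)), colnames(m))),
               "< 3 cells")
})

test_that("a planted cluster marker is top-ranked", {
  hits <- 0
  for (s in 1:5) {
    set.seed(860 + s)
    m <- matrix(rnbinom(100 * 40, mu = 4, size = 5), 100, 40)
    m[7, 1:20] <- rnbinom(20, mu = 20, size = 5)
    dimnames(m) <- list(sprintf("g%03d", 1:100), paste0("c", 1:40))
    ln <- log_normalize(expression_matrix(m, unit = "counts"))
    mk <- cluster_markers(ln, setNames(rep(1:2, each = 20), colnames(m)))
    top <- mk$gene[mk$cluster == 1][1]
    if (top == "g007") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("permutation check retains the structured principal components", {
  set.seed(87)
  m <- matrix(rpois(200 * 80, 3), 200, 80)
  m[1:40, 1:40] <- m[1:40, 1:40] + rpois(40 * 40, 8)  # one real axis
  dimnames(m) <- list(sprintf("g%03d", 1:200), sprintf("c%03d", 1:80))
  ln <- log_normalize(expression_matrix(m, unit = "counts"))
  emb <- embed_cells(ln, n_pcs = NULL, seed = 5)
  expect_gte(emb$n_pcs, 2)
  expect_lt(emb$n_pcs, 20)
  emb2 <- embed_cells(ln, n_pcs = NULL, seed = 5)
  expect_identical(emb$coords, emb2$coords)
})
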