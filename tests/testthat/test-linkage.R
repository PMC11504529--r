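# small linked scenario shared across linkage tests (cheap version of the
# pipeline's study conditions)
linked_fixture <- function(seed, n_bulk = 40, cells_per_type = 60,
                           n_planted = 25) {
  b <- generate_bulk_cohort(n_bulk, 200, 6, dirichlet_conc = 2,
                            noise_sd = 0.1, risk_slope = 2, seed = seed)
  ms <- gene_set_collection(setNames(b$truth$marker_genes,
                                     colnames(b$truth$signature)))
  sc_ms <- gene_set_collection(list(Macrophage = ms$CT04, Bcell = ms$CT02,
                                    Tcell = ms$CT03))
  planted <- list(parent_type = "Bcell", n_cells = n_planted,
                  shift_genes = ms$CT01, shift_size = 3)
  scg <- generate_single_cells(
    setNames(rep(cells_per_type, 3), c("Macrophage", "Bcell", "Tcell")),
    sc_ms, gene_ids = b$expr$gene_ids, planted = planted, seed = seed + 1)
  ln <- log_normalize(scg$counts)
  emb <- embed_cells(ln, select_hvg(ln, 150), n_pcs = 10)
  list(bulk = b, sc = scg, ln = ln, emb = emb, marker_sets = sc_ms)
}

test_that("cell-bulk correlation matches brute-force pairwise correlation", {
  set.seed(91)
  genes <- sprintf("g%03d", 1:120)
  sc <- expression_matrix(matrix(rlnorm(120 * 5), 120, 5,
                                 dimnames = list(genes, paste0("c", 1:5))),
                          unit = "lognorm")
  bk <- expression_matrix(matrix(rlnorm(120 * 4), 120, 4,
                                 dimnames = list(genes, paste0("s", 1:4))),
                          unit = "lognorm")
  co <- cell_bulk_correlation(sc, bk)
  for (i in 1:5) for (j in 1:4) {
    expect_equal(co$S[i, j], cor(sc$values[, i], bk$values[, j]),
                 tolerance = 1e-12)
  }
  # proportional and antiproportional profiles
  bk2 <- bk
  bk2$values[, 1] <- 3 * sc$values[, 2]
  bk2$values[, 2] <- -2 * sc$values[, 2] + 10
  co2 <- cell_bulk_correlation(sc, bk2)
  expect_equal(co2$S[2, 1], 1, tolerance = 1e-12)
  expect_equal(co2$S[2, 2], -1, tolerance = 1e-12)

  short <- expression_matrix(matrix(1:20 + 0, 10, 2,
                                    dimnames = list(genes[1:10],
                                                    c("a", "b"))),
                             unit = "lognorm")
  expect_error(cell_bulk_correlation(short, bk), "shared genes")
})

test_that("cell graph laplacian has the expected spectrum and row sums", {
  emb3 <- matrix(c(0, 0, 1, 0, 0.5, 1), 3, 2, byrow = TRUE,
                 dimnames = list(paste0("c", 1:3), NULL))
  g <- build_cell_graph(emb3, k_neighbors = 2)
  expect_equal(sort(eigen(g$L)$values), c(0, 3, 3), tolerance = 1e-9)
  expect_equal(rowSums(g$L), rep(0, 3), ignore_attr = TRUE,
               tolerance = 1e-12)

  set.seed(92)
  emb10 <- matrix(rnorm(20), 10, 2,
                  dimnames = list(paste0("c", 1:10), NULL))
  g10 <- build_cell_graph(emb10, 3)
  x <- rnorm(10)
  quad <- drop(t(x) %*% g10$L %*% x)
  direct <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    if (g10$A[i, j] == 1) direct <- direct + (x[i] - x[j])^2
  }
  expect_equal(quad, direct, tolerance = 1e-10)
  expect_gte(min(eigen(g10$L)$values), -1e-8)
})

test_that("full shrinkage and the unpenalized limit behave as Cox theory says", {
  fx <- linked_fixture(seed = 93, n_bulk = 30, cells_per_type = 20,
                       n_planted = 8)
  corr <- cell_bulk_correlation(fx$ln, fx$bulk$expr)
  g <- build_cell_graph(fx$emb$coords, 5)
  # large lambda: everything shrunk to background
  sel_inf <- penalized_cox_select(corr, fx$bulk$clinical, g$L, lambda = 50,
                                  alpha_mix = 1)
  expect_true(all(sel_inf$beta == 0))
  expect_true(all(sel_inf$class == "background"))

  # lambda = 0 with a single cell column reduces to unpenalized Cox
  one <- corr$S[1, , drop = FALSE]
  sel0 <- penalized_cox_select(one, fx$bulk$clinical,
                               matrix(0, 1, 1), lambda = 0, max_iter = 5000,
                               tol = 1e-10)
  cf <- fit_cox(fx$bulk$clinical,
                matrix(scale(corr$S[1, ]), ncol = 1,
                       dimnames = list(corr$sample_ids, "c1")))
  # fit_cox reports the original-scale coefficient; the selector works on
  # the standardized column, so compare on the standardized scale
  expect_equal(unname(sel0$beta[1]), unname(cf$coef * cf$scale),
               tolerance = 1e-3)
})

test_that("objective decreases monotonically and the path is sparsifying", {
  fx <- linked_fixture(seed = 94, n_bulk = 30, cells_per_type = 25,
                       n_planted = 10)
  corr <- cell_bulk_correlation(fx$ln, fx$bulk$expr)
  g <- build_cell_graph(fx$emb$coords, 5)
  lam_path <- 0.8 * 0.7^(0:9)
  nnz <- integer(10)
  for (i in seq_along(lam_path)) {
    sel <- penalized_cox_select(corr, fx$bulk$clinical, g$L,
                                lambda = lam_path[i])
    expect_true(all(diff(sel$objective_trace) <= 1e-10),
                label = paste("monotone at lambda", lam_path[i]))
    nnz[i] <- sum(sel$beta != 0)
  }
  expect_true(all(diff(nnz) >= 0))  # lambda decreasing -> nonzeros grow
})

test_that("with no graph penalty the selector matches an L1 coordinate-descent oracle", {
  # tiny instance: 10 cells, known survival; oracle = cyclic coordinate
  # descent on the same objective
  set.seed(95)
  n <- 20; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  tm <- rexp(n, 0.1 * exp(0.8 * X[, 1]))
  cl <- data.frame(sample_id = paste0("s", 1:n), state = "tumor",
                   time = tm, event = 1)
  S <- t(X)
  dimnames(S) <- list(paste0("c", 1:p), cl$sample_id)
  lam <- 0.05
  sel <- penalized_cox_select(S, cl, matrix(0, p, p), lambda = lam,
                              alpha_mix = 1, tol = 1e-12, max_iter = 20000)
  # coordinate-descent oracle on the standardized design
  Xs <- scale(t(S))
  negpl <- function(b) -breslow_loglik(b, Xs, cl$time, cl$event) / n
  obj <- function(b) negpl(b) + lam * sum(abs(b))
  b <- numeric(p)
  for (sweep_i in 1:400) {
    for (j in 1:p) {
      f <- function(v) { bb <- b; bb[j] <- v; obj(bb) }
      b[j] <- optimize(f, c(-3, 3), tol = 1e-10)$minimum
      if (abs(b[j]) < 1e-6) b[j] <- 0
    }
  }
  expect_equal(unname(sel$beta), b, tolerance = 0.02)
  expect_equal(obj(unname(sel$beta)), obj(b), tolerance = 1e-5)
})

test_that("subpopulation calls compose names and recover planted cells", {
  fx <- linked_fixture(seed = 96, n_bulk = 40, cells_per_type = 60,
                       n_planted = 25)
  corr <- cell_bulk_correlation(fx$ln, fx$bulk$expr)
  g <- build_cell_graph(fx$emb$coords, 8)
  sel <- penalized_cox_select(corr, fx$bulk$clinical, g$L, seed = 97)
  clu <- cluster_cells(fx$emb$coords, k_neighbors = 15)
  ann <- annotate_clusters(fx$ln, clu, fx$marker_sets)
  calls <- classify_and_call(sel, ann, group_context = "low")
  expect_true(all(vapply(calls, function(x)
    grepl("^[A-Z]L[pn]$", x$name), logical(1))))
  bl_plus <- Filter(function(x) x$sign == "plus" &&
                      x$parent_type == "Bcell", calls)
  expect_length(bl_plus, 1)
  expect_equal(bl_plus[[1]]$name, "BLp")
  pl <- fx$sc$truth$planted_subpop
  expect_gte(length(intersect(bl_plus[[1]]$members, pl)) / length(pl), 0.6)

  # all-zero scores give an empty call list
  sel0 <- sel
  sel0$beta[] <- 0
  sel0$class[] <- "background"
  expect_length(classify_and_call(sel0, ann), 0)
})

test_that("signature intersection obeys set algebra and recovers shift genes", {
  fx <- linked_fixture(seed = 98, n_bulk = 40, cells_per_type = 60,
                       n_planted = 30)
  clu <- cluster_cells(fx$emb$coords, k_neighbors = 15)
  ann <- annotate_clusters(fx$ln, clu, fx$marker_sets)
  pl <- fx$sc$truth$planted_subpop
  call <- structure(list(name = "BLp", members = pl, parent_type = "Bcell",
                         sign = "plus", group_context = "low",
                         flagged = FALSE), class = "SubpopulationCall")
  shift <- fx$sc$truth$shift_genes
  module_genes <- c(shift, sprintf("G%04d", 200:210))
  sg <- subpopulation_signature(call, fx$ln, ann, module_genes)
  expect_true(all(sg$module_intersection %in% sg$signature_genes))
  expect_true(all(sg$module_intersection %in% module_genes))
  expect_gte(length(intersect(sg$module_intersection, shift)) /
               length(shift), 0.8)
  # disjoint module list gives an empty intersection
  sg2 <- subpopulation_signature(call, fx$ln, ann, c("nope1", "nope2"))
  expect_length(sg2$module_intersection, 0)
  # tiny call is skipped
  small <- call
  small$members <- pl[1:2]
  expect_true(subpopulation_signature(small, fx$ln, ann,
                                      module_genes)$skipped)
})

test_that("score trend is negative for cells linked to low-immune bulk", {
  # constructed monotone case: cells whose expression increases while the
  # immune score of their best-matched bulk decreases
  set.seed(99)
  genes <- sprintf("g%03d", 1:150)
  n_cells <- 12
  base <- rlnorm(150)
  # each cell shares a private perturbation direction with one bulk
  # sample, so its best-correlated bulk is its partner; the cell's
  # signature expression rises with its index
  dirs <- matrix(rnorm(150 * n_cells, 0, 2), 150, n_cells)
  sc_m <- sapply(1:n_cells, function(i) {
    v <- base + dirs[, i] + rnorm(150, 0, 0.01)
    v[1:50] <- v[1:50] + 0.3 * i
    v
  })
  dimnames(sc_m) <- list(genes, paste0("c", 1:n_cells))
  bulk_m <- sapply(1:n_cells, function(i) base + dirs[, i] +
                     rnorm(150, 0, 0.01))
  dimnames(bulk_m) <- list(genes, paste0("s", 1:n_cells))
  sc_x <- expression_matrix(sc_m, unit = "lognorm")
  bk_x <- expression_matrix(bulk_m, unit = "lognorm")
  co <- cell_bulk_correlation(sc_x, bk_x)
  imm <- setNames(seq(1, 0, length.out = n_cells), paste0("s", 1:n_cells))
  call <- structure(list(name = "BLp", members = paste0("c", 1:n_cells),
                         parent_type = "Bcell", sign = "plus",
                         group_context = "low", flagged = FALSE),
                    class = "SubpopulationCall")
  tr <- score_trend(call, genes[1:50], sc_x, co, imm)
  expect_lt(tr$rho, -0.9)
})
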