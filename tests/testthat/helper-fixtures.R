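# A fixture with exactly known QC violations: 120 good cells, 12 cells
# under 300 features, 5 cells between 300 and 499 features, 4 high-mito
# cells. 600 regular genes + 10 mito genes; regular genes are expressed
# everywhere so the gene filter removes only the 40 genes planted to be
# rare.
build_qc_fixture <- function(seed = 81) {
  set.seed(seed)
  n_genes <- 600
  genes <- c(sprintf("G%03d", 1:n_genes), paste0("MT-", 1:10))
  good <- sapply(1:120, function(i) {
    v <- rpois(n_genes + 10, 3) + 1   # all features detected
    v
  })
  low <- sapply(1:12, function(i) {
    v <- numeric(n_genes + 10)
    v[sample(n_genes, 100)] <- 1
    v
  })
  mid <- sapply(1:5, function(i) {
    v <- numeric(n_genes + 10)
    v[sample(n_genes, 400)] <- 1
    v
  })
  mito <- sapply(1:4, function(i) {
    v <- rpois(n_genes + 10, 3) + 1
    v[n_genes + (1:10)] <- round(sum(v) * 0.02)  # ~17% mito
    v
  })
  m <- cbind(good, low, mid, mito)
  # plant 40 rare genes detected in < 100 cells: zero them except 5 cells
  rare <- 1:40
  m[rare, ] <- 0
  m[rare, 1:5] <- 1
  dimnames(m) <- list(genes, sprintf("c%03d", seq_len(ncol(m))))
  expression_matrix(m, unit = "counts")
}
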