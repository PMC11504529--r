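# Independent brute-force oracles, coded from the definitions, against
# which the package implementations are checked. They deliberately share
# no code with R/.

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  idx <- comb2(c(tab))
  ra <- comb2(rowSums(tab))
  cb <- comb2(colSums(tab))
  expected <- ra * cb / choose(sum(tab), 2)
  maxidx <- (ra + cb) / 2
  if (maxidx == expected) return(1)
  (idx - expected) / (maxidx - expected)
}

# literal running-sum ssGSEA for one sample and one set
oracle_ssgsea_one <- function(values, gene_ids, set, alpha) {
  n <- length(values)
  r <- rank(values)                       # midranks, largest value -> n
  ord <- order(-values, gene_ids)         # walk from most expressed down
  in_set <- gene_ids %in% set
  num <- 0
  p_in <- 0
  p_out <- 0
  w_total <- sum(r[in_set]^alpha)
  m <- sum(in_set)
  score <- 0
  for (pos in seq_len(n)) {
    g <- ord[pos]
    if (in_set[g]) {
      p_in <- p_in + r[g]^alpha / w_total
    } else {
      p_out <- p_out + 1 / (n - m)
    }
    score <- score + (p_in - p_out)
  }
  unname(score)
}

# exhaustive best contiguous k-partition of sorted scores
oracle_partition3 <- function(scores) {
  x <- sort(scores)
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  best <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      w <- ss(x[1:i]) + ss(x[(i + 1):j]) + ss(x[(j + 1):n])
      if (w < best) best <- w
    }
  }
  best
}

# element-wise signed adjacency and triple-loop TOM
oracle_adjacency <- function(m, beta) {
  n <- nrow(m)
  a <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a[i, j] <- ((1 + cor(m[i, ], m[j, ])) / 2)^beta
  }
  diag(a) <- 1
  a
}

oracle_tom <- function(a) {
  n <- nrow(a)
  k <- sapply(1:n, function(i) sum(a[i, -i]))
  tom <- matrix(1, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# OLS slope/intercept/R2/p from the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  k <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b <- mean(y) - k * mean(x)
  res <- y - (k * x + b)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  tval <- k / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  list(k = k, b = b, r2 = r2, p = p)
}

# Breslow partial likelihood by direct risk-set enumeration
oracle_breslow <- function(beta, X, time, event) {
  eta <- as.vector(X %*% beta)
  total <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      rs <- which(time >= time[i])
      total <- total + eta[i] - log(sum(exp(eta[rs])))
    }
  }
  total
}

# hypergeometric upper-tail p by summing the pmf
oracle_hyper_p <- function(k, K, N, n) {
  kmax <- min(K, n)
  sum(sapply(k:kmax, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n)))
}

# exact two-sided rank-sum p by enumerating group assignments
oracle_ranksum_p <- function(a, b) {
  ab <- c(a, b)
  n <- length(ab)
  na <- length(a)
  r <- rank(ab)
  obs <- sum(r[1:na])
  combs <- utils::combn(n, na)
  stats_null <- apply(combs, 2, function(idx) sum(rank(ab)[idx]))
  mu <- na * (n + 1) / 2
  mean(abs(stats_null - mu) >= abs(obs - mu) - 1e-9)
}

# empirical AUC of a binary outcome with midrank tie handling
oracle_binary_auc <- function(score, outcome) {
  pos <- score[outcome == 1]
  neg <- score[outcome == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

random_expression <- function(n_genes, n_samples, seed,
                              unit = "normalized") {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * n_samples), n_genes, n_samples)
  expression_matrix(m, sprintf("g%02d", 1:n_genes),
                    sprintf("s%02d", 1:n_samples), unit = unit)
}
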