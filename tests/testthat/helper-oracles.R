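# Independent brute-force oracles used across the test files. Each one is a
# deliberately naive re-derivation of the quantity it checks, sharing no code
# with the package internals.

# Named matrix with probe/sample dimnames from a plain numeric matrix.
named_matrix <- function(vals, nr, nc) {
  matrix(vals, nr, nc,
         dimnames = list(sprintf("P%03d", seq_len(nr)),
                         sprintf("S%03d", seq_len(nc))))
}

# One-way ANOVA F by explicit sum-of-squares decomposition for one probe.
oracle_f_oneway <- function(y, cls) {
  cls <- as.factor(cls)
  grand <- mean(y)
  ssb <- 0; ssw <- 0
  for (l in levels(cls)) {
    yl <- y[cls == l]
    ssb <- ssb + length(yl) * (mean(yl) - grand)^2
    ssw <- ssw + sum((yl - mean(yl))^2)
  }
  K <- nlevels(cls); n <- length(y)
  f <- (ssb / (K - 1)) / (ssw / (n - K))
  list(f = f, p = pf(f, K - 1, n - K, lower.tail = FALSE))
}

# Bayes posterior by direct Gaussian density arithmetic (diagonal model).
# means: p x K; vars: p-vector (shared) or p x K; priors: K-vector.
oracle_posterior <- function(x, means, vars, priors) {
  K <- ncol(means)
  dens <- vapply(seq_len(K), function(k) {
    v <- if (is.matrix(vars)) vars[, k] else vars
    prod(dnorm(x, means[, k], sqrt(v)))
  }, numeric(1))
  joint <- dens * priors
  list(posterior = joint / sum(joint), px = sum(joint))
}

# Benjamini-Hochberg step-up, literal definition: q_i = min over j with
# p_(j) >= p_(i) of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- p[ord] * m / seq_len(m)
  # running minimum from the largest rank down
  for (i in m:1) adj[i] <- min(adj[i:m], 1)
  q[ord] <- adj
  q
}

# Hypergeometric upper tail P(overlap >= k) by exhaustive enumeration of all
# possible query draws from the universe.
oracle_hyper_enum <- function(universe_size, set_size, query_size, k) {
  draws <- combn(universe_size, query_size)
  # treat elements 1..set_size as the set members
  hits <- colSums(draws <= set_size)
  mean(hits >= k)
}

# Weighted KS running-sum enrichment score, naive element-by-element walk.
oracle_es <- function(stat, hit_names, weight = 1) {
  ord <- names(sort(stat, decreasing = TRUE))
  nh <- sum(ord %in% hit_names)
  n <- length(ord)
  wsum <- sum(abs(stat[ord[ord %in% hit_names]])^weight)
  run <- 0; best <- 0
  for (g in ord) {
    if (g %in% hit_names) run <- run + abs(stat[[g]])^weight / wsum
    else run <- run - 1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# UPGMA by brute force on a distance matrix: repeatedly merge the closest
# pair of clusters, recomputing average-linkage distances from the original
# pairwise matrix. Returns the sorted merge heights.
oracle_upgma_heights <- function(d) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(dm[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Two-factor fixed-effects fit by explicit normal equations for one probe.
oracle_paired_t <- function(y, cls, grp) {
  X <- model.matrix(~ factor(cls) + factor(grp, levels = c("MOKO", "CUP")))
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  g <- ncol(X)
  se <- sqrt(s2 * XtXi[g, g])
  t_stat <- beta[g] / se
  list(effect = beta[g], t = t_stat, p = 2 * pt(-abs(t_stat), df))
}

# Default-style small cohort used by several files (kept small for speed).
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_config(
    n_classes = 3, n_probes = 150, probes_per_class_signature = 10,
    n_primary_per_class = 6, n_metastasis_per_class = 6, n_cup = 6,
    n_normal = 4, instability_signature_size = 10, seed = seed, ...))
}
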