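# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / direct formula and never call the package code
# paths they are checking.

# Benjamini-Hochberg by exhaustive scan over all candidate cutoffs.
bh_brute <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  selected_k <- 0
  for (k in seq_len(m)) if (p[o][k] <= k / m * alpha) selected_k <- k
  if (selected_k == 0) integer() else sort(o[seq_len(selected_k)])
}

# Exhaustive agglomeration under average linkage (UPGMA): at every step
# evaluate the mean original-space distance between every cluster pair.
average_brute <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list()
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    merges <- c(merges, list(lapply(clusters, sort)))
    heights <- c(heights, best_h)
  }
  list(partitions = merges, heights = heights)
}

# Exhaustive agglomeration under Ward's criterion: merge the pair whose union
# minimally increases total within-cluster SSE; report hclust ward.D2-scale
# heights sqrt(2 * delta SSE).
ward_brute <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  sse <- function(idx) {
    if (length(idx) == 1) return(0)
    sub <- X[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- as.list(seq_len(n))
  merges <- list(); heights <- numeric()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      dd <- sse(c(clusters[[i]], clusters[[j]])) -
        sse(clusters[[i]]) - sse(clusters[[j]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    merges <- c(merges, list(lapply(clusters, sort)))
    heights <- c(heights, sqrt(2 * best_d))
  }
  list(partitions = merges, heights = heights)
}

# Canonical string form of a partition (list of index vectors) for comparison.
partition_key <- function(parts) {
  paste(sort(vapply(parts, function(x) paste(sort(x), collapse = ","), "")),
        collapse = "|")
}

# Partition induced by cutting an hclust tree at k clusters, as a key.
hclust_partition_key <- function(tree, k) {
  labs <- stats::cutree(tree, k = k)
  partition_key(split(seq_along(labs), labs))
}

# Studentized-range upper tail P(Q > q) for k means and df error degrees of
# freedom, by direct numerical integration (independent of stats::ptukey).
sr_tail <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z)
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    k * stats::integrate(f, -8, 8, rel.tol = 1e-9)$value
  }
  # s = sqrt(chi2_df / df)
  dens <- function(s)
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) * exp(-df * s^2 / 2)
  g <- function(s) vapply(s, function(si) dens(si) * inner(si), numeric(1))
  cdf <- stats::integrate(g, 1e-6, 10, rel.tol = 1e-8)$value
  1 - cdf
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
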