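test_that("toy one-dimensional leaves merge in the obvious order", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  cl <- cluster_probes(x, k = 2, candidate_k = 2, standardize = "none")
  expect_equal(sort(cl$tree$height)[1:2], c(1, 1))
  part <- split(names(cl$labels), cl$labels)
  expect_setequal(vapply(part, paste, "", collapse = ","),
                  c("a,b", "c,d"))
})

test_that("Ward trees match exhaustive agglomeration on small instances", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 3), n)
    cl <- cluster_probes(X, k = 2, candidate_k = 2, standardize = "none")
    oracle <- ward_brute(X)
    expect_equal(sort(cl$tree$height), sort(oracle$heights),
                 tolerance = 1e-8)
    for (k in seq_len(n - 1))
      expect_equal(hclust_partition_key(cl$tree, k),
                   partition_key(oracle$partitions[[n - k]]))
  }
})

test_that("planted archetypes are recovered at the k = 2 cut", {
  set.seed(53)
  early <- c(2, 1, 0, 0, 0, 0)   # JA-like: fast caterpillar response
  late <- c(0, 0, 0, 0, 1, 2)    # SA-like: slow pathogen response
  X <- rbind(matrix(rep(early, 50), 50, byrow = TRUE),
             matrix(rep(late, 50), 50, byrow = TRUE)) +
    matrix(rnorm(600, sd = 0.15), 100)
  cl <- cluster_probes(X, k = 2)
  expect_gte(ari(cl$labels, rep(1:2, each = 50)), 0.95)
  expect_false(cl$degenerate)
  # candidate levels are reported with their merge gaps
  cl6 <- cluster_probes(X, k = 6)
  expect_equal(cl6$candidates$k, c(3L, 6L, 9L, 12L))
  expect_equal(length(unique(cl6$labels)), 6L)
  expect_equal(nrow(cl6$centers), 6L)
})

test_that("degenerate and invalid inputs are handled", {
  same <- matrix(1, 10, 6)
  cl <- cluster_probes(same, k = 3, standardize = "none")
  expect_true(cl$degenerate)
  expect_true(all(cl$tree$height < 1e-12))
  expect_error(cluster_probes(same[1, , drop = FALSE]), "at least two")
  same[1, 1] <- NA
  expect_error(cluster_probes(same), "complete")
})

test_that("clustering is invariant to leaf order", {
  set.seed(57)
  X <- matrix(rnorm(60), 10)
  rownames(X) <- letters[1:10]
  perm <- sample(10)
  a <- cluster_probes(X, k = 3, standardize = "none")
  b <- cluster_probes(X[perm, ], k = 3, standardize = "none")
  expect_equal(ari(a$labels[letters[1:10]], b$labels[letters[1:10]]), 1)
  # Ward merge heights are monotone non-decreasing
  expect_true(all(diff(a$tree$height) >= -1e-12))
})

test_that("treatment clustering reproduces hand-computed correlations", {
  set.seed(59)
  base <- rnorm(30)
  m <- cbind(t1 = base, t2 = base + rnorm(30, sd = 1e-6),
             t3 = rnorm(30), t4 = -base)
  tree <- cluster_treatments(m)
  # identical columns merge first at distance ~ 0
  expect_lt(tree$height[1], 1e-9)
  labs3 <- stats::cutree(tree, k = 3)
  expect_equal(labs3[["t1"]], labs3[["t2"]])
  # anti-correlated pair has pearson distance ~ 2; the k = 2 cut never
  # groups t4 with its mirror image
  expect_equal((1 - cor(m))["t1", "t4"], 2, tolerance = 1e-6)
  labs2 <- stats::cutree(tree, k = 2)
  expect_equal(labs2[["t1"]], labs2[["t2"]])
  expect_false(labs2[["t4"]] == labs2[["t1"]])

  # 3-column hand oracle under average linkage
  m3 <- m[, c("t1", "t3", "t4")]
  r <- cor(m3)
  d <- 1 - r
  tr3 <- cluster_treatments(m3)
  pair <- which(d == min(d[upper.tri(d)]), arr.ind = TRUE)[1, ]
  expect_equal(sort(tr3$merge[1, ]), sort(-as.integer(pair)))
  rest <- setdiff(1:3, pair)
  expect_equal(tr3$height[2], mean(d[rest, pair]), tolerance = 1e-12)

  expect_error(cluster_treatments(m[, 1:2]), "three")
  m_const <- cbind(m, t5 = rep(1, 30))
  expect_error(cluster_treatments(m_const), "t5")
})

test_that("average-linkage trees match the exhaustive oracle", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 5), 5, n)
    colnames(X) <- paste0("c", seq_len(n))
    tree <- cluster_treatments(X, distance = "pearson", linkage = "average")
    oracle <- average_brute(as.dist(1 - cor(X)))
    expect_equal(sort(tree$height), sort(oracle$heights), tolerance = 1e-8)
    for (k in seq_len(n - 1))
      expect_equal(hclust_partition_key(tree, k),
                   partition_key(oracle$partitions[[n - k]]))
  }
})

test_that("variance scree matches a spectral oracle", {
  # rank-1 matrix: first component carries everything
  u <- rnorm(20); v <- rnorm(6)
  r1 <- variance_scree(outer(u, v))
  expect_equal(r1$cumulative[1], 1, tolerance = 1e-9)
  expect_equal(r1$suggested_k, 1L)

  # exactly-identity covariance in 4 dims: 25% each, k = 4 for 85%
  set.seed(63)
  Z <- matrix(rnorm(200), 50, 4)
  Z <- scale(Z, center = TRUE, scale = FALSE) %*%
    solve(chol(cov(Z)))
  r2 <- variance_scree(Z)
  expect_equal(r2$cumulative, c(0.25, 0.5, 0.75, 1), tolerance = 1e-9)
  expect_equal(r2$suggested_k, 4L)

  # random matrix: eigenvalues agree with svd of centered data
  M <- matrix(rnorm(120), 20, 6)
  r3 <- variance_scree(M)
  sv <- svd(scale(M, center = TRUE, scale = FALSE))$d
  expect_equal(r3$eigenvalues, sv^2 / (nrow(M) - 1), tolerance = 1e-8)

  M[1, 1] <- NA
  expect_error(variance_scree(M), "non-finite")
})

test_that("newick serialization is parseable and preserves topology", {
  set.seed(65)
  X <- matrix(rnorm(24), 8)
  rownames(X) <- paste0("p", 1:8)
  cl <- cluster_probes(X, k = 2, standardize = "none")
  nwk <- write_newick(cl$tree)
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label), sort(rownames(X)))
  # cophenetic distances from the newick match the tree's merge structure
  expect_equal(length(tr$tip.label), 8L)
})
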