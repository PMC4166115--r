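#' Ward clustering of per-probe expression vectors
#'
#' Clusters the 6-value expected differential-expression vectors
#' Y(probe, Trt x Time) with an agglomerative hierarchical algorithm under
#' Ward's criterion (each merge minimizes the increase in total within-cluster
#' variance; `stats::hclust` method `"ward.D2"` on Euclidean distances, whose
#' merge heights are `sqrt(2 * delta SSE)`).
#'
#' The vectors can be standardized first. `"zscore"` (default) centers and
#' scales each design-cell column against its pooled mean and SD across
#' probes; `"pca"` replaces the vectors by their principal-component scores
#' (covariance-based), an alternative reading of covariance-standardized
#' coefficients; `"none"` clusters raw vectors.
#'
#' Assignments are produced at the candidate levels (default 3, 6, 9 and 12
#' clusters, with k = 6 the default cut) and each candidate level is annotated
#' with its relative merge-height gap, a stability measure: large gaps mark
#' cuts that are well separated in merge height.
#'
#' @param vectors numeric matrix, one row per probe (complete rows only).
#' @param k default cut level.
#' @param candidate_k levels reported in the stability table.
#' @param standardize `"zscore"`, `"pca"` or `"none"`.
#' @return list of class `probe_clustering`: `tree` (hclust), `k`, `labels`
#'   (cut at `k`), `centers` (per-cluster mean profile on the original
#'   scale), `candidates` (k, merge gap), `n`, `standardize`, `degenerate`
#'   (`TRUE` when all merge heights are 0).
#' @export
cluster_probes <- function(vectors, k = 6L, candidate_k = c(3L, 6L, 9L, 12L),
                           standardize = c("zscore", "pca", "none")) {
  standardize <- match.arg(standardize)
  vectors <- as.matrix(vectors)
  if (anyNA(vectors))
    stop("cluster_probes: vectors must be complete (no missing cells)",
         call. = FALSE)
  n <- nrow(vectors)
  if (n < 2)
    stop("cluster_probes: need at least two complete vectors", call. = FALSE)
  x <- switch(standardize,
              zscore = {
                mu <- colMeans(vectors)
                sdv <- apply(vectors, 2, stats::sd)
                sdv[sdv == 0] <- 1
                scale(vectors, center = mu, scale = sdv)
              },
              pca = stats::prcomp(vectors, center = TRUE, scale. = FALSE)$x,
              none = vectors)
  tree <- stats::hclust(stats::dist(x, method = "euclidean"),
                        method = "ward.D2")
  k <- min(k, n)
  labels <- stats::cutree(tree, k = k)
  centers <- do.call(rbind, lapply(sort(unique(labels)), function(cl)
    colMeans(vectors[labels == cl, , drop = FALSE])))
  rownames(centers) <- sort(unique(labels))
  heights <- tree$height
  gap_at <- function(kk) {
    # cutting at kk clusters sits between merge n-kk and n-kk+1
    if (kk >= n || kk < 1) return(NA_real_)
    lo <- heights[n - kk]
    hi <- if (kk == 1) NA_real_ else heights[n - kk + 1]
    if (is.na(hi) || lo == 0) return(NA_real_)
    (hi - lo) / lo
  }
  candidates <- data.frame(k = candidate_k,
                           height_gap = vapply(candidate_k, gap_at,
                                               numeric(1)))
  structure(list(tree = tree, k = k, labels = labels, centers = centers,
                 candidates = candidates, n = n, standardize = standardize,
                 degenerate = all(heights < 1e-12)),
            class = "probe_clustering")
}

#' Hierarchical clustering of treatments across expression profiles
#'
#' Eisen-style clustering of treatment columns of a gene x treatment
#' expression matrix. Distances: `"pearson"` (default) uses `1 - r` computed
#' on pairwise-complete observations (range 0 for identical to 2 for
#' anti-correlated profiles); `"covariance"` embeds the centered columns and
#' uses their Euclidean distance, `sqrt(c_ii + c_jj - 2 c_ij)`. Linkages:
#' single, complete, average (default, the best-performing combination for
#' this design) and Ward.
#'
#' @param mat numeric matrix, genes in rows, treatments in columns.
#' @param distance `"pearson"` or `"covariance"`.
#' @param linkage `"average"`, `"single"`, `"complete"` or `"ward"`.
#' @return `hclust` tree over the treatment columns.
#' @export
cluster_treatments <- function(mat, distance = c("pearson", "covariance"),
                               linkage = c("average", "single", "complete",
                                           "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  mat <- as.matrix(mat)
  if (ncol(mat) < 3)
    stop("cluster_treatments: need at least three treatments", call. = FALSE)
  if (distance == "pearson") {
    sds <- apply(mat, 2, stats::sd, na.rm = TRUE)
    if (any(!is.na(sds) & sds == 0))
      stop("cluster_treatments: zero-variance column(s): ",
           paste(colnames(mat)[!is.na(sds) & sds == 0], collapse = ", "),
           call. = FALSE)
    r <- stats::cor(mat, use = "pairwise.complete.obs")
    d <- stats::as.dist(1 - r)
  } else {
    cc <- stats::cov(mat, use = "pairwise.complete.obs")
    dd <- outer(diag(cc), diag(cc), `+`) - 2 * cc
    d <- stats::as.dist(sqrt(pmax(dd, 0)))
  }
  if (anyNA(d))
    stop("cluster_treatments: undefined distances (all-missing overlap)",
         call. = FALSE)
  stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
}

#' Eigenvalue scree of the expression covariance matrix
#'
#' Computes the eigenvalues of the covariance matrix of the expression data,
#' their cumulative variance fractions, and the smallest number of components
#' reaching a target fraction (default 85%, the criterion used to gauge how
#' many clusters the data supports).
#'
#' @param mat numeric matrix (observations x variables).
#' @param target cumulative variance fraction to reach.
#' @return list: `eigenvalues` (decreasing), `cumulative` (fractions),
#'   `suggested_k`.
#' @export
variance_scree <- function(mat, target = 0.85) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat)))
    stop("variance_scree: non-finite entries", call. = FALSE)
  if (ncol(mat) < 2)
    stop("variance_scree: need at least two columns", call. = FALSE)
  ev <- eigen(stats::cov(mat), symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  cum <- cumsum(ev) / sum(ev)
  list(eigenvalues = ev, cumulative = cum,
       suggested_k = which(cum >= target)[1])
}

#' Write an hclust tree as Newick text
#'
#' Serializes a linkage tree with branch lengths derived from merge heights
#' (leaf branch length = height of its first merge; internal branch length =
#' parent height minus own height).
#'
#' @param tree an `hclust` object.
#' @param path output file; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  lab <- if (is.null(tree$labels)) as.character(seq_along(tree$order))
  else tree$labels
  node_str <- function(i, parent_h) {
    if (i < 0) {  # leaf
      sprintf("%s:%g", lab[-i], parent_h)
    } else {
      h <- tree$height[i]
      sprintf("(%s,%s):%g",
              node_str(tree$merge[i, 1], h), node_str(tree$merge[i, 2], h),
              parent_h - h)
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  nwk <- sprintf("(%s,%s);",
                 node_str(tree$merge[root, 1], h),
                 node_str(tree$merge[root, 2], h))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
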