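# K-means partitioning of anchored occupancy patterns.
#
# Lloyd's algorithm with k-means++ seeding and best-of-restarts selection is
# implemented here directly so that seeding, restart tie-breaking and
# empty-cluster handling are fully specified and reproducible under a fixed
# seed; distances are Euclidean on the (rpm) densities with no row scaling by
# default, since pause classes separate partly by absolute occupancy.

.kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(0, k, ncol(m))
  first <- sample.int(n, 1L)
  centers[1L, ] <- m[first, ]
  d2 <- rowSums((m - matrix(centers[1L, ], n, ncol(m), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    tot <- sum(d2)
    pick <- if (tot <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / tot)
    centers[j, ] <- m[pick, ]
    d2 <- pmin(d2, rowSums((m - matrix(centers[j, ], n, ncol(m),
                                       byrow = TRUE))^2))
  }
  centers
}

.dist2_to_centers <- function(m, centers) {
  # n x k matrix of squared Euclidean distances
  cross <- m %*% t(centers)
  sweep(sweep(-2 * cross, 2, rowSums(centers^2), "+"), 1, rowSums(m^2), "+")
}

.lloyd <- function(m, k, max_iter = 100L) {
  centers <- .kmeanspp_init(m, k)
  assign <- rep(0L, nrow(m))
  prev_inertia <- Inf
  for (iter in seq_len(max_iter)) {
    d2 <- .dist2_to_centers(m, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(m)), new_assign)])
    # within numerical noise, Lloyd iterations never increase inertia
    .assert(inertia <= prev_inertia + 1e-6 * (1 + abs(prev_inertia)),
            "internal error: inertia increased during Lloyd iteration")
    prev_inertia <- inertia
    for (j in which(tabulate(new_assign, k) == 0L)) {
      # re-seed an empty cluster from the point farthest from its center
      far <- which.max(d2[cbind(seq_len(nrow(m)), new_assign)])
      centers[j, ] <- m[far, ]
      new_assign[far] <- j
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      rows <- which(assign == j)
      if (length(rows)) centers[j, ] <- colMeans(m[rows, , drop = FALSE])
    }
  }
  d2 <- .dist2_to_centers(m, centers)
  inertia <- sum(pmax(d2[cbind(seq_len(nrow(m)), assign)], 0))
  list(assignments = assign, centers = centers, inertia = inertia)
}

#' K-means clustering of an anchored occupancy matrix
#'
#' Best-of-`restarts` Lloyd's solution with k-means++ seeding; empty clusters
#' are re-seeded from the farthest point. Deterministic for a fixed seed;
#' ties between restarts are broken by the earlier restart.
#'
#' @param m An `AnchorMatrix` (or plain numeric matrix with row names).
#' @param k Number of clusters (fixed a priori).
#' @param seed Integer RNG seed.
#' @param restarts Number of independent initialisations (default 50).
#' @param row_scaling `"none"` (default), `"unit_max"` (rows divided by their
#'   maximum) or `"zscore"` (rows standardised).
#' @return A `ClusterResult`: list with `k`, `assignments` (named integer
#'   vector), `centroids` (k x bins), `seed`, `restarts`, `inertia`.
#' @export
kmeans_cluster <- function(m, k, seed = 1L, restarts = 50L,
                           row_scaling = c("none", "unit_max", "zscore")) {
  row_scaling <- match.arg(row_scaling)
  x <- unclass(m)
  .assert(is.matrix(x) && all(is.finite(x)),
          "matrix must be finite and numeric")
  .assert(k >= 1 && k <= nrow(x), "k must be in [1, number of rows]")
  x <- switch(row_scaling,
    none = x,
    unit_max = x / pmax(apply(x, 1, max), .Machine$double.eps),
    zscore = t(scale(t(x)))
  )
  x[!is.finite(x)] <- 0  # constant rows under zscore
  best <- NULL
  .with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- .lloyd(x, k)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  assignments <- setNames(best$assignments, rownames(m))
  structure(
    list(k = as.integer(k), assignments = assignments,
         centroids = best$centers, seed = as.integer(seed),
         restarts = as.integer(restarts), inertia = best$inertia,
         row_scaling = row_scaling),
    class = "ClusterResult"
  )
}

#' Per-cluster mean profiles and sizes
#'
#' @param m The `AnchorMatrix` the clustering was computed from.
#' @param cr A `ClusterResult` produced from `m`.
#' @return List with `profiles` (k x bins matrix of per-cluster column means
#'   of `m`) and `sizes` (integer vector summing to `nrow(m)`).
#' @export
cluster_profiles <- function(m, cr) {
  .assert(length(cr$assignments) == nrow(m) &&
            all(names(cr$assignments) == rownames(m)),
          "ClusterResult does not match the matrix")
  profiles <- matrix(NA_real_, cr$k, ncol(m))
  sizes <- integer(cr$k)
  for (j in seq_len(cr$k)) {
    rows <- which(cr$assignments == j)
    sizes[j] <- length(rows)
    if (length(rows))
      profiles[j, ] <- colMeans(m[rows, , drop = FALSE])
  }
  list(profiles = profiles, sizes = sizes)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions up to relabeling, expectation 0 under random
#' labeling.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return The ARI, a number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  .assert(length(a) == length(b), "labelings must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Heatmap row order for a clustered matrix
#'
#' Cluster-major order (clusters sorted by descending mean centroid signal),
#' rows within a cluster by descending row sum. The result is a permutation
#' of the row indices.
#'
#' @param m The clustered `AnchorMatrix`.
#' @param cr The matching `ClusterResult`.
#' @return Integer permutation of `seq_len(nrow(m))`.
#' @export
heatmap_order <- function(m, cr) {
  cluster_rank <- order(-rowMeans(cr$centroids))
  rank_of <- match(seq_len(cr$k), cluster_rank)
  ord <- order(rank_of[cr$assignments], -rowSums(m), rownames(m))
  ord
}

#' Write cluster assignments, centroids and sizes as TSV
#'
#' @param cr A `ClusterResult`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the directory.
#' @export
write_cluster_result <- function(cr, dir, prefix = "clusters") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(data.frame(gene = names(cr$assignments),
                        cluster = unname(cr$assignments)),
             file.path(dir, paste0(prefix, "_assignments.tsv")))
  cent <- data.frame(cluster = seq_len(cr$k), cr$centroids)
  names(cent) <- c("cluster", paste0("bin", seq_len(ncol(cr$centroids))))
  .write_tsv(cent, file.path(dir, paste0(prefix, "_centroids.tsv")))
  sizes <- as.data.frame(table(factor(cr$assignments, levels = seq_len(cr$k))))
  names(sizes) <- c("cluster", "n_genes")
  .write_tsv(sizes, file.path(dir, paste0(prefix, "_sizes.tsv")))
  invisible(dir)
}

#' @export
print.ClusterResult <- function(x, ...) {
  sizes <- tabulate(x$assignments, x$k)
  cat(sprintf("ClusterResult: k=%d, n=%d, inertia=%.4g, seed=%d\n",
              x$k, length(x$assignments), x$inertia, x$seed))
  cat("  sizes:", paste(sizes, collapse = "/"), "\n")
  invisible(x)
}
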