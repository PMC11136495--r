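#' Sort neurons by principal-component loading
#'
#' Each neuron's dF/F trace is z-scored over time (constant neurons
#' become zero vectors), the z-scored matrix is decomposed by SVD, and
#' every neuron receives the loading of its trace on the requested
#' temporal component. The permutation orders neurons by descending
#' loading, ties broken by original index. The sign of each component is
#' fixed so that the summed loading is nonnegative (SVD leaves it
#' arbitrary).
#'
#' @param dff neurons x time matrix (>= 2 neurons, >= 2 timepoints).
#' @param component which principal component, 1 or 2.
#' @return an object of class `sort_result` with elements
#'   `permutation` (row order for display), `loadings` and `method`.
#' @export
pc_sort <- function(dff, component = 1L) {
  dff <- as.matrix(dff)
  if (nrow(dff) < 2L || ncol(dff) < 2L)
    stop("need >= 2 neurons and >= 2 timepoints")
  component <- as.integer(component)
  if (!component %in% c(1L, 2L)) stop("component must be 1 or 2")
  z <- .zscore_rows(dff)
  if (all(z == 0)) stop("all neurons are constant; PCA is degenerate")
  sv <- svd(z, nu = 0L, nv = component)
  v <- sv$v[, component]
  loadings <- as.numeric(z %*% v)
  if (sum(loadings) < 0) loadings <- -loadings
  perm <- order(-loadings, seq_along(loadings))
  structure(list(permutation = perm, loadings = loadings,
                 method = list(name = "pc_sort", component = component)),
            class = "sort_result")
}

#' Peak cross-correlation at nonnegative lags
#'
#' The asymmetric similarity used for cluster ordering: the maximum over
#' lags `0..max_lag` of the Pearson correlation between `x[1:(n-l)]` and
#' `y[(1+l):n]` (i.e. `y` delayed by `l` samples relative to `x`). A
#' zero-variance overlapping segment contributes correlation 0 at that
#' lag. On ties the smallest lag is reported.
#'
#' @param x,y numeric vectors of equal length `n >= max_lag + 2`.
#' @param max_lag maximum lag in samples (>= 0).
#' @return list with `value` (peak correlation) and `lag` (its lag).
#' @export
peak_xcorr_nonneg <- function(x, y, max_lag) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < max_lag + 2L) stop("series too short for max_lag")
  vals <- vapply(0:max_lag, function(l) {
    a <- x[seq_len(n - l)]
    b <- y[seq.int(1L + l, n)]
    if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  }, numeric(1L))
  best <- which.max(vals)
  list(value = vals[best], lag = best - 1L)
}

#' Cluster-based raster sort (simplified similarity sort)
#'
#' A simplified version of the published Rastermap ordering: k-means on
#' the per-neuron z-scored activity (seeded, 10 random restarts, best
#' inertia kept), clusters chained greedily by asymmetric similarity --
#' starting from the cluster with the greatest summed
#' [peak_xcorr_nonneg()] similarity to all others and repeatedly
#' appending the unvisited cluster most similar to the last appended
#' one -- and neurons ranked within each cluster by correlation to their
#' cluster mean. The published algorithm's within-cluster upsampling in
#' principal-component space is deliberately not reproduced.
#'
#' @param dff neurons x time matrix.
#' @param n_clusters number of clusters (1..neurons).
#' @param seed RNG seed (recorded in the result).
#' @param max_lag maximum nonnegative lag for the similarity.
#' @return `sort_result` with `permutation`, `cluster` (per-neuron
#'   label), `rank` (within-cluster position) and `method`.
#' @export
cluster_sort <- function(dff, n_clusters, seed = 1L, max_lag = 10L) {
  dff <- as.matrix(dff)
  n <- nrow(dff)
  if (n_clusters < 1L || n_clusters > n)
    stop("n_clusters must lie in 1..neurons")
  z <- .zscore_rows(dff)
  if (n_clusters == 1L) {
    cl <- rep(1L, n)
  } else {
    set.seed(seed)
    cl <- kmeans(z, centers = n_clusters, nstart = 10L,
                 iter.max = 100L)$cluster
  }
  means <- do.call(rbind, lapply(seq_len(n_clusters), function(k)
    colMeans(z[cl == k, , drop = FALSE])))
  order_k <- if (n_clusters == 1L) 1L else {
    sim <- matrix(0, n_clusters, n_clusters)
    for (i in seq_len(n_clusters)) for (j in seq_len(n_clusters))
      if (i != j)
        sim[i, j] <- peak_xcorr_nonneg(means[i, ], means[j, ], max_lag)$value
    chain <- which.max(rowSums(sim))
    while (length(chain) < n_clusters) {
      cand <- setdiff(seq_len(n_clusters), chain)
      s <- vapply(cand, function(j)
        peak_xcorr_nonneg(means[chain[length(chain)], ], means[j, ],
                          max_lag)$value, numeric(1L))
      chain <- c(chain, cand[which.max(s)])
    }
    chain
  }
  perm <- integer(0)
  rank_within <- integer(n)
  for (k in order_k) {
    members <- which(cl == k)
    rs <- vapply(members, function(i) {
      if (sd(z[i, ]) == 0 || sd(means[k, ]) == 0) 0 else
        cor(z[i, ], means[k, ])
    }, numeric(1L))
    o <- members[order(-rs, members)]
    rank_within[o] <- seq_along(o)
    perm <- c(perm, o)
  }
  structure(list(permutation = perm, cluster = cl, rank = rank_within,
                 method = list(name = "cluster_sort", seed = seed,
                               n_clusters = n_clusters, max_lag = max_lag)),
            class = "sort_result")
}

#' Superneuron averaging of a sorted raster
#'
#' Averages consecutive blocks of `bin` adjacent neurons in the sorted
#' raster into single display rows ("superneurons"; the last block may
#' be smaller), optionally z-scoring each row separately for display
#' (constant rows become zero).
#'
#' @param dff_sorted neurons x time matrix, already in display order.
#' @param bin neurons per display row (default 50).
#' @param zscore z-score each superneuron row over time?
#' @return matrix of class `superneuron_matrix` with
#'   `ceiling(neurons / bin)` rows; `bin` and `zscored` kept as
#'   attributes.
#' @export
superneurons <- function(dff_sorted, bin = 50L, zscore = TRUE) {
  dff_sorted <- as.matrix(dff_sorted)
  n <- nrow(dff_sorted)
  if (n < 1L) stop("need at least one neuron")
  groups <- (seq_len(n) - 1L) %/% bin
  rows <- do.call(rbind, lapply(unique(groups), function(g)
    colMeans(dff_sorted[groups == g, , drop = FALSE])))
  if (zscore) rows <- .zscore_rows(rows)
  structure(rows, bin = as.integer(bin), zscored = zscore,
            class = c("superneuron_matrix", class(rows)))
}

#' Render a superneuron raster
#'
#' Displays a [superneurons()] matrix with a viridis lookup table (low
#' activity dark blue, intermediate green, maximum yellow), rows top to
#' bottom in sort order.
#'
#' @param x a `superneuron_matrix`.
#' @param ... passed to [graphics::image()].
#' @importFrom graphics image
#' @importFrom grDevices hcl.colors
#' @export
plot.superneuron_matrix <- function(x, ...) {
  m <- t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE]
  image(m, col = hcl.colors(64L, "viridis"), axes = FALSE,
        xlab = "time", ylab = "superneuron", ...)
  invisible(x)
}
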