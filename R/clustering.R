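#' 2-D log-log histogram of IMF frequency-energy features
#'
#' Bins an IMF feature population on a fixed log10-frequency by log10-energy
#' grid. A shared default grid (60 x 60 cells over 1 Hz - 5 kHz and
#' 1e-8 - 1) keeps histograms from different conditions directly
#' comparable. Features at or below zero, or outside the grid, are clamped
#' to the nearest edge cell and counted in `n_clamped`, so the cell counts
#' always sum to the feature count.
#'
#' @param features an [decompose_trace_windows()] result (or any data frame
#'   with `frequency_hz` and `energy` columns); rows from several traces
#'   can be pooled with `rbind` first.
#' @param freq_range,energy_range grid limits (linear units).
#' @param freq_bins,energy_bins number of cells per axis.
#' @return a `feature_histogram_2d`: list with `freq_edges`, `energy_edges`
#'   (log10 units), `counts` (freq x energy matrix), `total`, `n_clamped`.
#' @export
feature_histogram_2d <- function(features,
                                 freq_range = c(1, 5000),
                                 energy_range = c(1e-8, 1),
                                 freq_bins = 60L, energy_bins = 60L) {
  stopifnot(is.data.frame(features),
            all(c("frequency_hz", "energy") %in% names(features)))
  if (nrow(features) == 0L) stop("empty feature list", call. = FALSE)
  stopifnot(freq_range[1] > 0, energy_range[1] > 0,
            freq_range[2] > freq_range[1], energy_range[2] > energy_range[1])
  fe <- seq(log10(freq_range[1]), log10(freq_range[2]),
            length.out = freq_bins + 1L)
  ee <- seq(log10(energy_range[1]), log10(energy_range[2]),
            length.out = energy_bins + 1L)
  bin_of <- function(v, edges) {
    lx <- suppressWarnings(log10(v))
    lx[!is.finite(lx)] <- edges[1]          # zeros -> lowest bin
    i <- findInterval(lx, edges, rightmost.closed = TRUE)
    pmin(pmax(i, 1L), length(edges) - 1L)
  }
  lf <- suppressWarnings(log10(features$frequency_hz))
  le <- suppressWarnings(log10(features$energy))
  out_of_range <- !is.finite(lf) | !is.finite(le) |
    lf < fe[1] | lf > fe[length(fe)] | le < ee[1] | le > ee[length(ee)]
  fi <- bin_of(features$frequency_hz, fe)
  eji <- bin_of(features$energy, ee)
  counts <- matrix(0L, nrow = freq_bins, ncol = energy_bins)
  for (k in seq_len(nrow(features)))
    counts[fi[k], eji[k]] <- counts[fi[k], eji[k]] + 1L
  structure(
    list(freq_edges = fe, energy_edges = ee, counts = counts,
         total = nrow(features), n_clamped = sum(out_of_range)),
    class = "feature_histogram_2d")
}

#' @export
print.feature_histogram_2d <- function(x, ...) {
  cat(sprintf("<feature_histogram_2d> %d x %d cells, %d features (%d clamped)\n",
              nrow(x$counts), ncol(x$counts), x$total, x$n_clamped))
  invisible(x)
}

# Cell-center coordinates (log10 units) and counts of non-empty cells.
hist_cells <- function(hist) {
  fc <- (hist$freq_edges[-1] + hist$freq_edges[-length(hist$freq_edges)]) / 2
  ec <- (hist$energy_edges[-1] + hist$energy_edges[-length(hist$energy_edges)]) / 2
  nz <- which(hist$counts > 0, arr.ind = TRUE)
  data.frame(row = nz[, 1], col = nz[, 2],
             logf = fc[nz[, 1]], loge = ec[nz[, 2]],
             count = hist$counts[nz])
}

# Weighted Lloyd k-means with k-means++ initialization (stats::kmeans has no
# observation weights). X: n x 2 matrix, w: weights. Returns assignment and
# weighted inertia.
weighted_kmeans_once <- function(X, w, k, max_iter = 100L) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  # k-means++: first center by weight, then by weight * squared distance
  i0 <- sample.int(n, 1L, prob = w)
  centers[1L, ] <- X[i0, ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  if (k > 1L) for (j in 2:k) {
    p <- w * d2
    if (sum(p) == 0) p <- w
    ij <- sample.int(n, 1L, prob = p)
    centers[j, ] <- X[ij, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  assign_prev <- integer(n)
  for (it in seq_len(max_iter)) {
    dists <- vapply(seq_len(k), function(j)
      rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2),
      numeric(n))
    assign <- max.col(-dists, ties.method = "first")
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    for (j in seq_len(k)) {
      mem <- assign == j
      if (any(mem)) {
        centers[j, ] <- colSums(X[mem, , drop = FALSE] * w[mem]) / sum(w[mem])
      } else {
        # re-seed an empty cluster at the worst-fit point
        centers[j, ] <- X[which.max(apply(dists, 1L, min) * w), ]
      }
    }
  }
  dists <- vapply(seq_len(k), function(j)
    rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2),
    numeric(n))
  assign <- max.col(-dists, ties.method = "first")
  inertia <- sum(w * dists[cbind(seq_len(n), assign)])
  list(assignment = assign, centers = centers, inertia = inertia)
}

#' Cluster histogram cells by frequency and energy
#'
#' Weighted k-means (weights = cell counts) on the non-empty cell centers
#' in (log10 frequency, log10 energy) space — Euclidean distance in linear
#' units would be meaningless across several decades. Uses k-means++
#' initialization with `restarts` restarts, keeping the solution with the
#' lowest weighted inertia; deterministic for a fixed seed. Cluster labels
#' are canonicalized 0..k-1 by ascending centroid frequency, then energy,
#' so cluster 0/1 are the low-frequency low/high-energy pair.
#'
#' @param hist a [feature_histogram_2d()].
#' @param k number of clusters (default 6).
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts (default 20).
#' @return a `feature_clustering`: list with `cells` (data frame of
#'   non-empty cells with a `cluster` column), `centers` (log10 units),
#'   `inertia`, `k`, `seed`.
#' @export
cluster_features <- function(hist, k = 6L, seed = 1L, restarts = 20L) {
  stopifnot(inherits(hist, "feature_histogram_2d"))
  cells <- hist_cells(hist)
  k <- as.integer(k)
  if (nrow(cells) < k)
    stop(sprintf("only %d non-empty cells for k = %d clusters",
                 nrow(cells), k), call. = FALSE)
  X <- as.matrix(cells[, c("logf", "loge")])
  w <- as.numeric(cells$count)
  best <- with_seed(stream_seed(seed, "kmeans"), {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- weighted_kmeans_once(X, w, k)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    best
  })
  # canonical order: centroid frequency, then energy
  ord <- order(best$centers[, 1], best$centers[, 2])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k) - 1L
  cells$cluster <- relabel[best$assignment]
  centers <- best$centers[ord, , drop = FALSE]
  rownames(centers) <- as.character(seq_len(k) - 1L)
  colnames(centers) <- c("logf", "loge")
  structure(
    list(cells = cells, centers = centers, inertia = best$inertia,
         k = k, seed = seed),
    class = "feature_clustering")
}

#' Per-cluster summaries: centroid, occupancy, entropy
#'
#' For every cluster: the count-weighted mean of its member cell centers
#' in log10 space, reported back in linear units (Hz, energy); the
#' occupancy (fraction of all IMFs in the cluster); and the Shannon
#' entropy (bits) of the within-cluster normalized count distribution over
#' member cells, measuring how dispersed the cluster is. Empty clusters
#' get occupancy 0 and `NA` centroids.
#'
#' @param clustering a [cluster_features()] result.
#' @return a data frame: `cluster`, `centroid_freq_hz`, `centroid_energy`,
#'   `occupancy`, `entropy_bits`, `n_cells`.
#' @export
cluster_summaries <- function(clustering) {
  stopifnot(inherits(clustering, "feature_clustering"))
  cells <- clustering$cells
  total <- sum(cells$count)
  out <- lapply(seq_len(clustering$k) - 1L, function(cl) {
    mem <- cells[cells$cluster == cl, , drop = FALSE]
    if (nrow(mem) == 0L)
      return(data.frame(cluster = cl, centroid_freq_hz = NA_real_,
                        centroid_energy = NA_real_, occupancy = 0,
                        entropy_bits = NA_real_, n_cells = 0L))
    wsum <- sum(mem$count)
    data.frame(
      cluster = cl,
      centroid_freq_hz = 10^(sum(mem$logf * mem$count) / wsum),
      centroid_energy = 10^(sum(mem$loge * mem$count) / wsum),
      occupancy = wsum / total,
      entropy_bits = shannon_entropy(mem$count / wsum),
      n_cells = nrow(mem))
  })
  do.call(rbind, out)
}
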