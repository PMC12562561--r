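test_that("2-D feature histograms count every feature on a shared grid", {
  one <- data.frame(frequency_hz = 100, energy = 0.01)
  h1 <- feature_histogram_2d(one)
  expect_equal(sum(h1$counts), 1)
  expect_equal(h1$total, 1)

  f <- make_blobs(3, 50)
  h <- feature_histogram_2d(f)
  expect_equal(sum(h$counts), nrow(f))

  # identical grids across conditions by construction
  h2 <- feature_histogram_2d(f[1:30, ])
  expect_identical(h$freq_edges, h2$freq_edges)
  expect_identical(h$energy_edges, h2$energy_edges)

  # zero / out-of-range values clamp to edge cells but are still counted
  odd <- data.frame(frequency_hz = c(0, 1e9), energy = c(1e-20, 5))
  ho <- feature_histogram_2d(odd)
  expect_equal(sum(ho$counts), 2)
  expect_equal(ho$n_clamped, 2)

  expect_error(feature_histogram_2d(one[0, ]), "empty")
})

test_that("weighted k-means recovers planted blobs exactly and deterministically", {
  f <- make_blobs(6, 200)
  h <- feature_histogram_2d(f)
  cl <- cluster_features(h, k = 6, seed = 4)

  # map every feature to its cell's cluster; each blob must map to exactly
  # one cluster and no cluster to two blobs (perfect partition agreement)
  cell_key <- function(cells) paste(cells$row, cells$col)
  fe <- f
  fi <- findInterval(log10(fe$frequency_hz), h$freq_edges,
                     rightmost.closed = TRUE)
  ei <- findInterval(log10(fe$energy), h$energy_edges, rightmost.closed = TRUE)
  lab <- cl$cells$cluster[match(paste(fi, ei), cell_key(cl$cells))]
  tab <- table(fe$blob, lab)
  expect_equal(sum(tab > 0), 6)               # one nonzero cell per row
  expect_true(all(rowSums(tab > 0) == 1))

  expect_identical(cluster_features(h, k = 6, seed = 4)$cells$cluster,
                   cl$cells$cluster)
  cl2 <- cluster_features(h, k = 6, seed = 99)
  expect_identical(cl2$cells$cluster, cl$cells$cluster)  # easy geometry

  expect_error(cluster_features(feature_histogram_2d(
    data.frame(frequency_hz = 100, energy = 0.01)), k = 6), "non-empty")
})

test_that("weighted k-means agrees with stats::kmeans on count-expanded points", {
  f <- make_blobs(3, 80, seed = 31)
  h <- feature_histogram_2d(f)
  cl <- cluster_features(h, k = 3, seed = 1)
  cells <- cl$cells
  X <- as.matrix(cells[, c("logf", "loge")])
  expanded <- X[rep(seq_len(nrow(X)), cells$count), ]
  set.seed(1)
  km <- stats::kmeans(expanded, centers = 3, nstart = 10)
  # same partition of cells (up to label permutation) and same inertia
  ex_lab <- km$cluster[cumsum(cells$count)]
  expect_equal(length(unique(paste(cells$cluster, ex_lab))), 3)
  expect_equal(cl$inertia, km$tot.withinss, tolerance = 1e-8)
})

test_that("k equal to the number of occupied cells gives zero inertia", {
  f <- data.frame(frequency_hz = c(10, 100, 1000), energy = c(1e-2, 1e-4, 1e-6))
  h <- feature_histogram_2d(f)
  cl <- cluster_features(h, k = 3, seed = 2)
  expect_equal(cl$inertia, 0)
  expect_equal(sort(unique(cl$cells$cluster)), 0:2)
})

test_that("cluster summaries report centroids, occupancy, and entropy", {
  f <- make_blobs(6, 150, seed = 32)
  h <- feature_histogram_2d(f)
  cl <- cluster_features(h, k = 6, seed = 3)
  s <- cluster_summaries(cl)
  expect_equal(sum(s$occupancy), 1, tolerance = 1e-9)
  expect_true(all(s$entropy_bits >= 0))
  expect_equal(s$cluster, 0:5)
  # canonical ordering by centroid frequency
  expect_true(all(diff(s$centroid_freq_hz) > 0))
  # centroids near the planted means (within one within-blob SD in log space)
  planted_f <- 10^seq(0.5, 3.3, length.out = 6)
  expect_true(all(abs(log10(s$centroid_freq_hz) - log10(planted_f)) < 0.06 + 0.02))

  # analytic two-cell case: equal counts, one cluster
  two <- data.frame(frequency_hz = c(10, 12), energy = c(0.01, 0.01))
  h2 <- feature_histogram_2d(two)
  cl2 <- cluster_features(h2, k = 1, seed = 1)
  s2 <- cluster_summaries(cl2)
  expect_equal(s2$entropy_bits, 1)
  expect_equal(log10(s2$centroid_freq_hz),
               mean(cl2$cells$logf), tolerance = 1e-12)
})

test_that("summaries are invariant to label permutation and empty grid bands", {
  f <- make_blobs(4, 100, seed = 33)
  h <- feature_histogram_2d(f)
  s <- cluster_summaries(cluster_features(h, k = 4, seed = 5))
  s_reseeded <- cluster_summaries(cluster_features(h, k = 4, seed = 123))
  expect_equal(s, s_reseeded, tolerance = 1e-9)   # canonical labels

  # widening the energy grid with empty bands of identical width changes nothing
  h_wide <- feature_histogram_2d(f, energy_range = c(10^-9.2, 1),
                                 energy_bins = 69L)
  expect_equal(diff(h$energy_edges)[1], diff(h_wide$energy_edges)[1],
               tolerance = 1e-12)
  s_wide <- cluster_summaries(cluster_features(h_wide, k = 4, seed = 5))
  expect_equal(s_wide, s, tolerance = 1e-9)
})
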