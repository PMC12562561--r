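test_that("periodogram concentrates sinusoid power and keeps DC", {
  fs <- 1000
  t <- seq_len(4096) / fs
  x <- sin(2 * pi * 125 * t)           # exact bin frequency at L = 4096
  ps <- periodogram_psd(x, 4096, sampling_rate = fs)
  expect_gte(ps$power[which.min(abs(ps$frequency - 125))] / sum(ps$power), 0.99)

  const <- periodogram_psd(rep(3, 2048), 1024, sampling_rate = fs)
  expect_equal(const$frequency[which.max(const$power)], 0)
  expect_lt(sum(const$power[-1]) / const$power[1], 1e-20)

  expect_error(periodogram_psd(rnorm(100), 1024, sampling_rate = fs),
               "shorter")
})

test_that("periodogram density scaling is Parseval-consistent", {
  set.seed(11)
  x <- rnorm(2^17)
  ps <- periodogram_psd(x, 2^13, sampling_rate = 1e4)
  df <- ps$frequency[2] - ps$frequency[1]
  # exact identity against the mean square of the analyzed samples
  expect_equal(sum(ps$power) * df, mean(x^2), tolerance = 1e-10)
  # and the white-noise variance it estimates
  expect_lt(abs(sum(ps$power) * df - 1), 0.02)
})

test_that("median spectrum is the per-frequency median", {
  mk <- function(p) structure(list(frequency = c(0, 1, 2), power = p,
                                   segment_length = 4L, n_segments = 1L,
                                   sampling_rate = 4, estimator = "x"),
                              class = "power_spectrum")
  med <- median_psd(list(mk(c(1, 1, 1)), mk(c(2, 2, 2)), mk(c(9, 9, 9))))
  expect_equal(med$power, c(2, 2, 2))
  one <- median_psd(list(mk(c(5, 6, 7))))
  expect_equal(one$power, c(5, 6, 7))
  bad <- structure(list(frequency = c(0, 1, 3), power = 1:3,
                        segment_length = 4L, n_segments = 1L,
                        sampling_rate = 4, estimator = "x"),
                   class = "power_spectrum")
  expect_error(median_psd(list(mk(1:3), bad)), "grid")
})

test_that("relative spectra are ratios with masked zero-control bins", {
  mk <- function(p) structure(list(frequency = 0:3, power = p,
                                   segment_length = 8L, n_segments = 1L,
                                   sampling_rate = 8, estimator = "x"),
                              class = "power_spectrum")
  ctrl <- mk(c(2, 2, 0, 2))
  self <- relative_psd(ctrl, ctrl)
  expect_equal(self$ratio[c(1, 2, 4)], rep(1, 3))
  expect_true(is.na(self$ratio[3]))

  dbl <- relative_psd(mk(c(4, 4, 4, 4)), mk(c(2, 2, 2, 2)))
  expect_equal(dbl$ratio, rep(2, 4))
})

test_that("windowed spectra follow the Hamming-taper contract", {
  fs <- 10000
  tr <- current_trace(rnorm(3000), fs)
  ws <- windowed_spectra(tr)
  expect_equal(ws$W, 128L)                       # 12.8 ms at 10 kHz

  taper <- scgating:::hamming_taper(128)
  expect_equal(taper[1], 2 * (25 / 46) - 1)      # i = 0 weight = 4/46
  expect_true(all(abs(taper) <= 1))

  ws1 <- windowed_spectra(current_trace(rnorm(300), fs), W = 64, stride = 1)
  expect_equal(ws1$n_windows, 300 - 64 + 1)

  # tapering never increases the power of a window
  set.seed(12)
  x <- rnorm(128)
  expect_lte(sum((x * taper)^2), sum(x^2))

  expect_error(windowed_spectra(current_trace(rnorm(50), fs), W = 128),
               "shortest")
})

test_that("peak entropy matches an independent histogram recount", {
  set.seed(13)
  mkws <- function(pw) structure(
    list(power = pw, frequency = seq_len(nrow(pw)) - 1, W = 8L, stride = 1L,
         a0 = 25 / 46, n_windows = ncol(pw), sampling_rate = 100),
    class = "windowed_spectra")
  a <- mkws(matrix(rexp(5 * 40), 5, 40))
  b <- mkws(matrix(rexp(5 * 40, 0.5), 5, 40))
  got <- peak_entropy(list(a = a, b = b), K = 1000)

  pooled <- c(a$power, b$power)
  sg <- sd(pooled)
  for (cond in list(a, b)) {
    key <- if (identical(cond, a)) "a" else "b"
    for (i in 1:5) {
      v <- cond$power[i, ]
      v <- v[v > 0 & v <= 10 * sg]
      cnt <- table(cut(v, breaks = seq(0, 10 * sg, length.out = 1001),
                       include.lowest = FALSE))
      p <- as.numeric(cnt) / sum(cnt)
      p <- p[p > 0]
      expect_equal(got[[key]]$entropy_bits[i], -sum(p * log2(p)),
                   tolerance = 1e-12)
    }
    expect_true(all(got[[key]]$entropy_bits >= 0))
    expect_true(all(got[[key]]$entropy_bits <= log2(1000)))
  }
})

test_that("constant spectra give zero peak entropy; degenerate input errors", {
  mkws <- function(pw) structure(
    list(power = pw, frequency = seq_len(nrow(pw)) - 1, W = 8L, stride = 1L,
         a0 = 25 / 46, n_windows = ncol(pw), sampling_rate = 100),
    class = "windowed_spectra")
  const <- mkws(matrix(2, 4, 30))
  set.seed(14)
  varying <- mkws(matrix(rexp(4 * 30), 4, 30))
  got <- peak_entropy(list(c0 = const, v = varying))
  expect_equal(got$c0$entropy_bits, rep(0, 4))

  expect_error(peak_entropy(list(a = const, b = const)), "degenerate|zero")
  expect_error(peak_entropy(list(a = mkws(matrix(1, 3, 1)))), "2 windows")
})
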