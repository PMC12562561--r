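test_that("Shannon entropy satisfies the textbook identities", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum")
  expect_error(shannon_entropy(c(1.2, -0.2)), "nonnegative")
  # maximal iff uniform, zero iff degenerate
  set.seed(1)
  for (k in c(3, 8, 16)) {
    p <- runif(k); p <- p / sum(p)
    expect_lte(shannon_entropy(p), log2(k) + 1e-12)
  }
})

test_that("dwell histograms normalize, pool states, and clamp outliers", {
  dw <- data.frame(state = c("O", "C", "O", "C"),
                   duration = c(0.01, 0.01, 0.5, 0.5))
  edges <- c(0.001, 0.1, 1)
  h <- dwell_histogram(dw, edges)
  expect_equal(h$probabilities, c(0.5, 0.5))
  expect_equal(sum(h$probabilities), 1)

  h1 <- dwell_histogram(data.frame(state = "O", duration = 0.01), edges)
  expect_equal(h1$probabilities, c(1, 0))

  # durations outside the edges go to the nearest end bin
  out <- dwell_histogram(data.frame(state = c("O", "C"),
                                    duration = c(1e-6, 50)), edges)
  expect_equal(out$counts, c(1, 1))
  expect_equal(out$n_clamped, 2)

  set.seed(2)
  for (i in 1:5) {
    d <- data.frame(state = sample(c("O", "C"), 50, TRUE),
                    duration = rexp(50, 100))
    expect_equal(sum(dwell_histogram(d)$probabilities), 1, tolerance = 1e-12)
  }
})

test_that("sample entropy equals the brute-force oracle on random series", {
  set.seed(3)
  for (i in 1:8) {
    x <- runif(200 + 50 * i)
    for (m in c(1L, 2L, 3L)) {
      r <- 0.2 * sd(x)
      for (v in c("default", "richman")) {
        got <- sample_entropy(x, m = m, r = r, variant = v)
        expect_false(got$undefined)
        expect_equal(got$value, sampen_oracle(x, m, r, v), tolerance = 1e-12)
      }
    }
  }
})

test_that("periodic series yield zero sample entropy (oracle-confirmed)", {
  x <- rep(c(1, 2), 25)
  # every m-match extends to m+1; the Richman-Moorman count is exactly zero,
  # the all-template normalization differs only by boundary templates
  rm_ <- sample_entropy(x, m = 2, r = 0.3, variant = "richman")
  expect_equal(rm_$value, 0)
  expect_equal(sampen_oracle(x, 2, 0.3, "richman"), 0)
  def <- sample_entropy(x, m = 2, r = 0.3)
  expect_equal(def$value, sampen_oracle(x, 2, 0.3), tolerance = 1e-12)
  expect_lt(abs(def$value), 1e-3)
})

test_that("degenerate cases are flagged undefined, never numeric", {
  # strictly increasing, steps larger than r: no m-template matches
  no_match <- sample_entropy(seq(0, 10, by = 1), m = 2, r = 0.3)
  expect_true(no_match$undefined)
  expect_true(is.na(no_match$value))
  expect_match(no_match$reason, "C\\^m")

  # m-matches that never extend to m+1
  x <- c(0, 0, 5, 0, 0, 9)
  never <- sample_entropy(x, m = 2, r = 0.1)
  expect_true(never$undefined)
  expect_true(is.na(never$value))

  expect_error(sample_entropy(c(1, 2, 3), m = 2, r = 0.1), "short")
  expect_error(sample_entropy(runif(50), m = 2, r = -1), "r")
})

test_that("sample entropy is scale invariant", {
  set.seed(5)
  x <- runif(400)
  base <- sample_entropy(x, m = 2, r = 0.2 * sd(x))$value
  for (c_ in c(0.01, 7, 1e4)) {
    expect_equal(sample_entropy(c_ * x, m = 2, r = 0.2 * sd(c_ * x))$value,
                 base, tolerance = 1e-12)
  }
})

test_that("regular gating is less entropic than its shuffle", {
  set.seed(6)
  periodic <- rep(c(1, 2), 2000) + rnorm(4000, sd = 0.01)
  shuffled <- sample(periodic)
  sp <- sample_entropy(periodic, m = 2, r = 0.2 * sd(periodic))$value
  ss <- sample_entropy(shuffled, m = 2, r = 0.2 * sd(shuffled))$value
  expect_lt(sp, ss)
})

test_that("windowed sample entropy splits, summarizes, and falls back", {
  set.seed(7)
  d <- rexp(8000, 100)
  w <- windowed_sample_entropy(d, window = 4000)
  expect_equal(w$n_windows, 2L)
  expect_equal(w$mean, mean(w$values))
  expect_equal(w$se, sd(w$values) / sqrt(2))

  dup <- windowed_sample_entropy(c(d[1:4000], d[1:4000]), window = 4000)
  expect_equal(dup$se, 0)

  expect_warning(w1 <- windowed_sample_entropy(d[1:100], window = 4000),
                 "single window")
  expect_equal(w1$n_windows, 1L)

  # stationary series: windowed mean agrees with the whole-series value
  whole <- sample_entropy(d, m = 2, r = 0.2 * sd(d))$value
  expect_lt(abs(w$mean - whole), 3 * max(w$se, 0.02))
})
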