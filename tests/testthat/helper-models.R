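# Shared builders for small test models and an independent SampEn oracle.

two_state_model <- function(tau_open = 0.004, tau_closed = 0.001,
                            closed_dist = "exponential",
                            alpha = 1.5, t_min = 1e-4, t_max = Inf, ...) {
  open <- gating_state("O", TRUE, "exponential", tau = tau_open)
  closed <- if (closed_dist == "exponential")
    gating_state("C", FALSE, "exponential", tau = tau_closed)
  else
    gating_state("C", FALSE, "pareto", alpha = alpha, t_min = t_min,
                 t_max = t_max)
  gating_model(list(open, closed), rbind(c(0, 1), c(1, 0)), ...)
}

# Brute-force SampEn oracle: full pairwise Chebyshev distance matrices built
# with outer(), no shared code with the package's compiled counting loop.
sampen_oracle <- function(x, m, r, variant = c("default", "richman")) {
  variant <- match.arg(variant)
  n <- length(x)
  cheb <- function(mm) {
    n_tpl <- n - mm + 1L
    D <- matrix(0, n_tpl, n_tpl)
    for (k in 0:(mm - 1L)) {
      v <- x[(1L + k):(n_tpl + k)]
      D <- pmax(D, abs(outer(v, v, `-`)))
    }
    D
  }
  Dm <- cheb(m)
  Dm1 <- cheb(m + 1L)
  count_pairs <- function(D) (sum(D <= r) - nrow(D)) # ordered pairs, j != i
  if (variant == "default") {
    b <- count_pairs(Dm) / ((n - m + 1) * (n - m))
    a <- count_pairs(Dm1) / ((n - m) * (n - m - 1))
  } else {
    idx <- seq_len(n - m)
    b <- count_pairs(Dm[idx, idx, drop = FALSE]) / ((n - m) * (n - m - 1))
    a <- count_pairs(Dm1) / ((n - m) * (n - m - 1))
  }
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

# Empirical log-log survival slope of dwell samples over a fit range.
survival_slope <- function(d, t_lo, t_hi, n_grid = 30) {
  tg <- 10^seq(log10(t_lo), log10(t_hi), length.out = n_grid)
  S <- vapply(tg, function(t) mean(d > t), 0)
  keep <- S > 0
  unname(coef(stats::lm(log10(S[keep]) ~ log10(tg[keep])))[2])
}

# Sample-grid quantization of an event sequence by midpoint occupancy, the
# same contract render_current_trace() documents (but recomputed here).
quantize_events <- function(events, fs) {
  n <- round(attr(events, "total_duration") * fs)
  ends <- cumsum(events$duration)
  mid <- (seq_len(n) - 0.5) / fs
  i <- findInterval(mid, ends, left.open = TRUE) + 1L
  i[i > nrow(events)] <- nrow(events)
  events$conducting[i]
}

se_mean_test <- function(x) stats::sd(x) / sqrt(length(x))

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# Planted feature populations: k log-space Gaussian blobs, well separated.
make_blobs <- function(k = 6, n_per = 200, seed = 30) {
  set.seed(seed)
  centers_f <- 10^seq(0.5, 3.3, length.out = k)
  centers_e <- 10^seq(-7, -1, length.out = k)
  do.call(rbind, lapply(seq_len(k), function(j) {
    data.frame(
      frequency_hz = 10^(log10(centers_f[j]) + rnorm(n_per, sd = 0.06)),
      energy = 10^(log10(centers_e[j]) + rnorm(n_per, sd = 0.06)),
      blob = j)
  }))
}

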