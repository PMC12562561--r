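test_that("event sequences are reproducible, alternating, and conserve duration", {
  m <- gating_regime("control")
  ev1 <- simulate_event_sequence(m, 2, seed = 7)
  ev2 <- simulate_event_sequence(m, 2, seed = 7)
  expect_identical(ev1, ev2)
  ev3 <- simulate_event_sequence(m, 2, seed = 8)
  expect_false(identical(ev1$duration, ev3$duration))

  expect_true(all(ev1$duration > 0))
  expect_true(all(diff(as.integer(ev1$conducting)) != 0))  # strict alternation
  expect_equal(sum(ev1$duration), 2, tolerance = 1e-12)

  expect_error(simulate_event_sequence(m, -1), "duration")
})

test_that("model validation rejects malformed schemes", {
  o <- gating_state("O", TRUE, "exponential", tau = 0.004)
  c_ <- gating_state("C", FALSE, "exponential", tau = 0.001)
  expect_error(gating_model(list(o, c_), rbind(c(0.5, 0.5), c(1, 0))),
               "opposite|alternation|class")
  expect_error(gating_model(list(o, c_), rbind(c(0, 0.7), c(1, 0))),
               "sum to 1")
  expect_error(gating_model(list(o, o), rbind(c(0, 1), c(1, 0))),
               "unique|open and one closed")
  expect_error(gating_model(list(o, c_), rbind(c(0, 1), c(1, 0)),
                            open_level = 0, closed_level = 0), "differ")
  expect_error(gating_model(list(o, c_), rbind(c(0, 1), c(1, 0)),
                            sampling_rate = 1500, filter_cutoff = 1000),
               "twice")
  expect_error(gating_state("C", FALSE, "pareto", alpha = 0.9, t_min = 1e-4),
               "alpha")
})

test_that("empirical dwell means recover the configured exponential taus", {
  m <- two_state_model(tau_open = 0.004, tau_closed = 0.001)
  ev <- simulate_event_sequence(m, 200, seed = 3)
  ev <- ev[-nrow(ev), ]          # last event is truncated by design
  open_d <- ev$duration[ev$conducting]
  n <- length(open_d)
  se <- 0.004 / sqrt(n)   # exponential-mean standard error tau/sqrt(n)
  expect_lt(abs(mean(open_d) - 0.004), 3 * se)
  closed_d <- ev$duration[!ev$conducting]
  expect_lt(abs(mean(closed_d) - 0.001), 3 * 0.001 / sqrt(length(closed_d)))
})

test_that("power-law closed dwells show the expected log-log survival slope", {
  m <- two_state_model(tau_open = 0.001, closed_dist = "pareto",
                       alpha = 1.5, t_min = 1e-4, t_max = 10)
  ev <- simulate_event_sequence(m, 300, seed = 5)
  d <- ev$duration[!ev$conducting]
  expect_gt(length(d), 5000)
  slope <- survival_slope(d, 1e-4, 0.01)   # fit well below the cap
  expect_lt(abs(slope - (-0.5)), 0.05)
})

test_that("stationary open probability matches analytic and simulated values", {
  expect_equal(stationary_open_probability(two_state_model(0.004, 0.001)), 0.8)
  expect_equal(stationary_open_probability(two_state_model(0.002, 0.002)), 0.5)

  m <- gating_regime("control")
  pop <- stationary_open_probability(m)
  fr <- vapply(1:8, function(s) {
    ev <- simulate_event_sequence(m, 25, seed = s)
    sum(ev$duration[ev$conducting]) / sum(ev$duration)
  }, 0)
  expect_lt(abs(mean(fr) - pop), 3 * se_mean_test(fr))
})

test_that("truncated power-law mean dwell matches a direct numeric integral", {
  s <- gating_state("C", FALSE, "pareto", alpha = 1.5, t_min = 1e-4,
                    t_max = 0.02)
  nrm <- stats::integrate(function(t) t^-1.5, 1e-4, 0.02)$value
  mu <- stats::integrate(function(t) t * t^-1.5 / nrm, 1e-4, 0.02)$value
  expect_equal(state_mean_dwell(s), mu, tolerance = 1e-6)
  expect_identical(
    state_mean_dwell(gating_state("C", FALSE, "pareto", alpha = 1.5,
                                  t_min = 1e-4)), Inf)
})

test_that("rendering quantizes events to the sample grid by midpoint", {
  m <- two_state_model(tau_open = 0.004, tau_closed = 0.001)
  ev <- simulate_event_sequence(m, 0.0005, seed = 1)
  # overwrite with the worked square wave: O 0.3 ms then C 0.2 ms at 10 kHz
  ev <- ev[0, ]
  ev[1, ] <- list("O", TRUE, 3e-4)
  ev[2, ] <- list("C", FALSE, 2e-4)
  attr(ev, "total_duration") <- 5e-4
  class(ev) <- c("event_sequence", "data.frame")
  tr <- render_current_trace(ev, m, noise_sigma = 0, filter = FALSE)
  expect_equal(tr$samples, c(10, 10, 10, 0, 0))
})

test_that("rendered noise level and filter attenuation are as configured", {
  m <- two_state_model(tau_open = 0.05, tau_closed = 0.05)
  ev <- simulate_event_sequence(m, 10, seed = 2)
  clean <- render_current_trace(ev, m, seed = 2, noise_sigma = 0, filter = FALSE)
  noisy <- render_current_trace(ev, m, seed = 2, noise_sigma = 1, filter = FALSE)
  resid <- noisy$samples - clean$samples
  expect_lt(abs(sd(resid) - 1), 0.05)        # Gaussian sample-SD oracle

  filt <- render_current_trace(ev, m, seed = 2, noise_sigma = 1, filter = TRUE)
  p_raw <- periodogram_psd(noisy, 8192)
  p_flt <- periodogram_psd(filt, 8192)
  hi <- p_raw$frequency > 2000
  atten <- sum(p_raw$power[hi]) / sum(p_flt$power[hi])
  expect_gte(atten, 10)

  # noise stream is independent of the event stream
  noisy_b <- render_current_trace(ev, m, seed = 99, noise_sigma = 1,
                                  filter = FALSE)
  expect_false(identical(noisy$samples, noisy_b$samples))
  expect_identical(clean$samples,
                   render_current_trace(ev, m, seed = 99, noise_sigma = 0,
                                        filter = FALSE)$samples)
})
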