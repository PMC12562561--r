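#' Simulate a semi-Markov gating event sequence
#'
#' Draws an alternating open/closed state path from the embedded jump chain
#' of a gating model, with each dwell drawn from that state's dwell-time
#' distribution. The path starts from the stationary distribution of the
#' embedded chain and is truncated (last event shortened, not dropped) so
#' the dwell durations sum exactly to `duration`.
#'
#' @param model a [gating_model()].
#' @param duration total simulated time in seconds.
#' @param seed integer seed; identical inputs give identical sequences.
#' @return an `event_sequence`: data frame columns `state` (label),
#'   `conducting` (logical) and `duration` (s), with attributes
#'   `total_duration` and `seed`.
#' @export
#' @examples
#' m <- gating_regime("control")
#' ev <- simulate_event_sequence(m, duration = 1, seed = 1)
#' head(ev)
simulate_event_sequence <- function(model, duration, seed = 1L) {
  stopifnot(inherits(model, "gating_model"))
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(seed, "seed")

  with_seed(stream_seed(seed, "events"), {
    n_states <- length(model$states)
    cum_rows <- t(apply(model$transition_probs, 1L, cumsum))
    mu <- vapply(model$states, state_mean_dwell, 0)
    # stationary start so long traces are stationary from sample one
    e <- eigen(t(model$transition_probs))
    pi_ <- Re(e$vectors[, which.min(abs(e$values - 1))])
    pi_ <- pmax(pi_ / sum(pi_), 0); pi_ <- pi_ / sum(pi_)
    mean_event <- sum(pi_ * mu)

    path <- integer(0)
    total <- 0
    state <- findInterval(stats::runif(1), cumsum(pi_)) + 1L
    while (TRUE) {
      # generate the state path in blocks sized from the expected event rate
      n_blk <- max(1024L, ceiling(1.2 * (duration - total) / mean_event))
      blk <- integer(n_blk)
      u <- stats::runif(n_blk)
      for (i in seq_len(n_blk)) {
        blk[i] <- state
        state <- findInterval(u[i], cum_rows[state, ]) + 1L
      }
      # dwells drawn state-by-state so each state's draws are one stream
      d_blk <- numeric(n_blk)
      for (s in seq_len(n_states)) {
        idx <- which(blk == s)
        if (length(idx)) d_blk[idx] <- draw_dwells(model$states[[s]], length(idx))
      }
      path <- c(path, blk)
      if (length(path) == n_blk) dwells <- d_blk else dwells <- c(dwells, d_blk)
      total <- total + sum(d_blk)
      if (total >= duration) break
    }
    cut <- which(cumsum(dwells) >= duration)[1L]
    path <- path[seq_len(cut)]
    dwells <- dwells[seq_len(cut)]
    dwells[cut] <- duration - sum(dwells[-cut])

    out <- data.frame(state = model$labels[path],
                      conducting = model$conducting[path],
                      duration = dwells,
                      stringsAsFactors = FALSE)
    attr(out, "total_duration") <- duration
    attr(out, "seed") <- seed
    class(out) <- c("event_sequence", "data.frame")
    out
  })
}

# Digital 4-pole Bessel-type low pass (bilinear transform of the analog
# prototype built from the reverse Bessel polynomial), applied forward only.
bessel_lowpass <- function(x, sampling_rate, cutoff) {
  # poles of s^4 + 10 s^3 + 45 s^2 + 105 s + 105, -3 dB at 2.113918 rad/s
  p <- polyroot(c(105, 105, 45, 10, 1))
  w3db <- 2.113917674904215
  warped <- 2 * sampling_rate * tan(pi * cutoff / sampling_rate)
  p <- p / w3db * warped
  g <- Re(prod(-p))                       # unit DC gain
  zp <- signal::bilinear(Sz = numeric(0), Sp = p, Sg = g, T = 1 / sampling_rate)
  flt <- signal::as.Arma(signal::Zpg(zero = zp$zero, pole = zp$pole, gain = zp$gain))
  as.numeric(signal::filter(flt, x))
}

#' Render an event sequence as a sampled current trace
#'
#' Produces the piecewise-constant current (closed/open conductance levels)
#' sampled at the model's rate, adds i.i.d. Gaussian noise, and optionally
#' applies the model's analogue-style low-pass filter. Event boundaries are
#' quantized to the sample grid by sample-midpoint occupancy: sample `i`
#' covers `[i*dt, (i+1)*dt)` and takes the state active at its midpoint.
#'
#' @param events an [simulate_event_sequence()] result.
#' @param model the [gating_model()] that produced it.
#' @param seed integer seed for the noise stream (independent of the event
#'   stream, so noise can be varied with gating fixed).
#' @param noise_sigma noise SD in pA; defaults to the model's.
#' @param filter apply the low-pass filter at `model$filter_cutoff`?
#' @param trace_id identifier for the trace.
#' @return a [current_trace()].
#' @export
render_current_trace <- function(events, model, seed = 1L,
                                 noise_sigma = model$noise_sigma,
                                 filter = TRUE, trace_id = "sim") {
  stopifnot(inherits(events, "event_sequence"), inherits(model, "gating_model"))
  if (nrow(events) == 0L) stop("empty event sequence", call. = FALSE)
  fs <- model$sampling_rate
  total <- attr(events, "total_duration")
  n <- round(total * fs)
  if (n < 2L)
    stop("sequence shorter than 2 samples at the model sampling rate",
         call. = FALSE)
  ends <- cumsum(events$duration)
  mid <- (seq_len(n) - 0.5) / fs
  ev <- findInterval(mid, ends, left.open = TRUE) + 1L
  ev[ev > nrow(events)] <- nrow(events)      # guard the last midpoint
  cur <- ifelse(events$conducting[ev], model$open_level, model$closed_level)
  if (noise_sigma > 0)
    cur <- cur + with_seed(stream_seed(seed, "noise"),
                           stats::rnorm(n, sd = noise_sigma))
  if (filter) cur <- bessel_lowpass(cur, fs, model$filter_cutoff)
  current_trace(cur, fs,
                que_um = attr(model, "que_um") %||% NA_real_,
                ca_um = attr(model, "ca_um") %||% NA_real_,
                trace_id = trace_id, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete synthetic recording in one call
#'
#' Convenience wrapper: [simulate_event_sequence()] followed by
#' [render_current_trace()], returning both the trace and the exact event
#' ground truth.
#'
#' @inheritParams simulate_event_sequence
#' @inheritParams render_current_trace
#' @param duration trace duration in seconds.
#' @return list with elements `trace` ([current_trace()]) and `events`.
#' @export
#' @examples
#' rec <- simulate_recording(gating_regime("control"), duration = 0.5, seed = 7)
#' rec$trace
simulate_recording <- function(model, duration, seed = 1L,
                               noise_sigma = model$noise_sigma,
                               filter = TRUE, trace_id = "sim") {
  events <- simulate_event_sequence(model, duration, seed = seed)
  trace <- render_current_trace(events, model, seed = seed,
                                noise_sigma = noise_sigma, filter = filter,
                                trace_id = trace_id)
  list(trace = trace, events = events)
}
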