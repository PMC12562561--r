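#' Define one conformational state of a gating scheme
#'
#' A state is either conducting (open) or non-conducting (closed) and carries
#' its dwell-time distribution: exponential with mean `tau`, or a power law
#' with density `f(t) ~ t^(-alpha)` on `[t_min, t_max]` (so the log-log
#' survival curve has slope `-(alpha - 1)`), with an optional upper cap
#' `t_max` that keeps simulated dwells and the mean bounded.
#'
#' @param label short state name, e.g. `"O1"`.
#' @param conducting logical; `TRUE` for open states.
#' @param dist `"exponential"` or `"pareto"`.
#' @param tau mean dwell time in seconds (exponential states).
#' @param alpha power-law density exponent; must exceed 1 so the
#'   distribution is normalizable (an uncapped mean additionally needs
#'   `alpha > 2`).
#' @param t_min minimum dwell in seconds (Pareto states).
#' @param t_max optional upper dwell cap in seconds; `Inf` disables it.
#' @return a `gating_state` object.
#' @export
#' @examples
#' gating_state("O1", TRUE, "exponential", tau = 0.004)
#' gating_state("C1", FALSE, "pareto", alpha = 1.5, t_min = 1e-4, t_max = 0.1)
gating_state <- function(label, conducting,
                         dist = c("exponential", "pareto"),
                         tau = NULL, alpha = NULL, t_min = NULL, t_max = Inf) {
  dist <- match.arg(dist)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.logical(conducting), length(conducting) == 1L)
  if (dist == "exponential") {
    check_scalar(tau, "tau", positive = TRUE)
  } else {
    check_scalar(alpha, "alpha")
    if (alpha <= 1)
      stop("`alpha` must be > 1 for a normalizable dwell distribution",
           call. = FALSE)
    check_scalar(t_min, "t_min", positive = TRUE)
    check_scalar(t_max, "t_max", finite = FALSE)
    if (t_max <= t_min) stop("`t_max` must exceed `t_min`", call. = FALSE)
  }
  structure(
    list(label = label, conducting = conducting, dist = dist,
         tau = tau, alpha = alpha, t_min = t_min, t_max = t_max),
    class = "gating_state")
}

#' Mean dwell time of a gating state
#'
#' Exponential states have mean `tau`. Power-law states have density
#' `f(t) = t^(-alpha) / N` on `[t_min, t_max]` with
#' `N = (t_max^(1-alpha) - t_min^(1-alpha)) / (1 - alpha)`; the mean is
#' `(t_max^(2-alpha) - t_min^(2-alpha)) / ((2 - alpha) N)` (log-limit
#' formulas at `alpha = 2`). Without a cap the mean is finite only for
#' `alpha > 2` and `Inf` otherwise.
#'
#' @param state a [gating_state()].
#' @return mean dwell in seconds.
#' @export
state_mean_dwell <- function(state) {
  stopifnot(inherits(state, "gating_state"))
  if (state$dist == "exponential") return(state$tau)
  a <- state$alpha; lo <- state$t_min; hi <- state$t_max
  if (is.infinite(hi)) {
    if (a <= 2) return(Inf)
    return((a - 1) / (a - 2) * lo)
  }
  nrm <- (hi^(1 - a) - lo^(1 - a)) / (1 - a)
  num <- if (a == 2) log(hi / lo) else (hi^(2 - a) - lo^(2 - a)) / (2 - a)
  num / nrm
}

# Draw n dwell times from a state's distribution (uses the current RNG).
draw_dwells <- function(state, n) {
  if (state$dist == "exponential") return(stats::rexp(n, rate = 1 / state$tau))
  a <- state$alpha; lo <- state$t_min; hi <- state$t_max
  u <- stats::runif(n)
  if (is.infinite(hi)) return(lo * (1 - u)^(-1 / (a - 1)))
  # inverse CDF of the truncated power law f(t) ~ t^(-alpha)
  (lo^(1 - a) + u * (hi^(1 - a) - lo^(1 - a)))^(1 / (1 - a))
}

#' Assemble a semi-Markov gating model
#'
#' The model combines a list of states, a transition matrix of the embedded
#' jump chain, the two conductance levels, the baseline noise level, and the
#' acquisition constants (sampling rate and analogue low-pass cutoff).
#' Openings and closings strictly alternate: each transition row must place
#' all its probability on states of the opposite conducting class.
#'
#' @param states list of [gating_state()] objects (at least one per class).
#' @param transition_probs square matrix, rows/cols ordered as `states`;
#'   row `i` gives the probability of jumping to each state when leaving
#'   state `i`. Entries within the same conducting class must be zero and
#'   each row must sum to 1.
#' @param open_level,closed_level conductance levels in pA; must differ.
#' @param noise_sigma Gaussian noise SD in pA added when rendering.
#' @param sampling_rate digitization rate in Hz (default 10 kHz).
#' @param filter_cutoff low-pass cutoff in Hz (default 1 kHz); must be below
#'   the Nyquist frequency.
#' @return a `gating_model` object.
#' @export
gating_model <- function(states, transition_probs,
                         open_level = 10, closed_level = 0,
                         noise_sigma = 1,
                         sampling_rate = 10000, filter_cutoff = 1000) {
  if (!is.list(states) || !all(vapply(states, inherits, TRUE, "gating_state")))
    stop("`states` must be a list of gating_state objects", call. = FALSE)
  labels <- vapply(states, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("state labels must be unique", call. = FALSE)
  cond <- vapply(states, `[[`, TRUE, "conducting")
  if (!any(cond) || all(cond))
    stop("model needs at least one open and one closed state", call. = FALSE)
  n <- length(states)
  transition_probs <- as.matrix(transition_probs)
  if (!all(dim(transition_probs) == c(n, n)))
    stop("`transition_probs` must be ", n, "x", n, call. = FALSE)
  if (any(transition_probs < 0))
    stop("transition probabilities must be nonnegative", call. = FALSE)
  same_class <- outer(cond, cond, `==`)
  if (any(transition_probs[same_class] != 0))
    stop("transitions within one conducting class must have probability 0 ",
         "(open/closed alternation)", call. = FALSE)
  if (any(abs(rowSums(transition_probs) - 1) > 1e-9))
    stop("every row of `transition_probs` must sum to 1", call. = FALSE)
  if (open_level == closed_level)
    stop("`open_level` and `closed_level` must differ", call. = FALSE)
  check_scalar(noise_sigma, "noise_sigma")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar(filter_cutoff, "filter_cutoff", positive = TRUE)
  if (sampling_rate <= 2 * filter_cutoff)
    stop("`sampling_rate` must exceed twice `filter_cutoff`", call. = FALSE)
  dimnames(transition_probs) <- list(labels, labels)
  structure(
    list(states = states, labels = labels, conducting = cond,
         transition_probs = transition_probs,
         open_level = open_level, closed_level = closed_level,
         noise_sigma = noise_sigma,
         sampling_rate = sampling_rate, filter_cutoff = filter_cutoff),
    class = "gating_model")
}

#' @export
print.gating_model <- function(x, ...) {
  cat(sprintf("<gating_model> %d states (%d open, %d closed)\n",
              length(x$states), sum(x$conducting), sum(!x$conducting)))
  for (s in x$states) {
    dd <- if (s$dist == "exponential")
      sprintf("exp(tau = %.4g s)", s$tau)
    else
      sprintf("pareto(alpha = %.3g, t_min = %.4g s, t_max = %.4g s)",
              s$alpha, s$t_min, s$t_max)
    cat(sprintf("  %-4s %-6s %s\n", s$label,
                if (s$conducting) "open" else "closed", dd))
  }
  cat(sprintf("  levels %g/%g pA, noise %g pA, fs %g Hz, cutoff %g Hz\n",
              x$closed_level, x$open_level, x$noise_sigma,
              x$sampling_rate, x$filter_cutoff))
  invisible(x)
}

#' Named gating regimes shipped with the package
#'
#' Three synthetic study conditions emulating the statistical signatures of
#' BK-channel activity under different stimulation:
#' \describe{
#'   \item{`control`}{unstimulated channel: 2 open + 3 closed exponential
#'     states spanning sub-millisecond to tens-of-milliseconds scales; low
#'     open probability (about 0.2).}
#'   \item{`ca_high`}{strong calcium activation: long openings are
#'     stabilized and the closed dwell-time distribution follows a truncated
#'     power law (no characteristic closed timescale); open probability
#'     above 0.9.}
#'   \item{`que_low`}{weak flavonoid activation: open probability close to
#'     control but with broadened, more evenly mixed intermediate dwell
#'     scales.}
#' }
#' All rate values are package choices: they reproduce distribution shapes
#' and orderings, not fitted rate constants.
#'
#' @param name regime name.
#' @return a [gating_model()] with attributes `que_um` and `ca_um` giving the
#'   nominal condition labels.
#' @export
#' @examples
#' m <- gating_regime("control")
#' stationary_open_probability(m)
gating_regime <- function(name = c("control", "ca_high", "que_low")) {
  name <- match.arg(name)
  ex <- function(lab, open, tau) gating_state(lab, open, "exponential", tau = tau)
  pa <- function(lab, alpha, t_min, t_max)
    gating_state(lab, FALSE, "pareto", alpha = alpha, t_min = t_min, t_max = t_max)
  if (name == "control") {
    states <- list(ex("O1", TRUE, 0.0010), ex("O2", TRUE, 0.009),
                   ex("C1", FALSE, 5e-4), ex("C2", FALSE, 0.006),
                   ex("C3", FALSE, 0.080))
    P <- rbind(O1 = c(0, 0, 0.5, 0.3, 0.2),
               O2 = c(0, 0, 0.4, 0.4, 0.2),
               C1 = c(0.7, 0.3, 0, 0, 0),
               C2 = c(0.6, 0.4, 0, 0, 0),
               C3 = c(0.5, 0.5, 0, 0, 0))
    cond <- c(que_um = 0, ca_um = 0)
  } else if (name == "ca_high") {
    states <- list(ex("O1", TRUE, 0.003), ex("O2", TRUE, 0.012),
                   pa("C1", 1.5, 1e-4, 0.001),
                   pa("C2", 1.5, 1e-4, 0.002),
                   pa("C3", 1.5, 1e-4, 0.005))
    P <- rbind(O1 = c(0, 0, 0.5, 0.3, 0.2),
               O2 = c(0, 0, 0.5, 0.3, 0.2),
               C1 = c(0.3, 0.7, 0, 0, 0),
               C2 = c(0.3, 0.7, 0, 0, 0),
               C3 = c(0.3, 0.7, 0, 0, 0))
    cond <- c(que_um = 0, ca_um = 100)
  } else {
    states <- list(ex("O1", TRUE, 0.0010), ex("O2", TRUE, 0.007),
                   ex("C1", FALSE, 0.0012), ex("C2", FALSE, 0.012),
                   ex("C3", FALSE, 0.050))
    P <- rbind(O1 = c(0, 0, 1/3, 1/3, 1/3),
               O2 = c(0, 0, 1/3, 1/3, 1/3),
               C1 = c(0.5, 0.5, 0, 0, 0),
               C2 = c(0.5, 0.5, 0, 0, 0),
               C3 = c(0.5, 0.5, 0, 0, 0))
    cond <- c(que_um = 10, ca_um = 0)
  }
  m <- gating_model(states, P, open_level = 10, closed_level = 0,
                    noise_sigma = 1, sampling_rate = 10000,
                    filter_cutoff = 1000)
  attr(m, "que_um") <- unname(cond["que_um"])
  attr(m, "ca_um") <- unname(cond["ca_um"])
  attr(m, "regime") <- name
  m
}

#' Analytic stationary open-state probability of a gating model
#'
#' Computes `sum_open pi_i E[dwell_i] / sum_all pi_j E[dwell_j]` where `pi`
#' is the stationary distribution of the embedded jump chain — the exact
#' long-run fraction of time the channel spends conducting, used as ground
#' truth for the half-amplitude estimator.
#'
#' @param model a [gating_model()].
#' @return probability in `[0, 1]`.
#' @export
#' @examples
#' m <- gating_regime("ca_high")
#' stationary_open_probability(m)
stationary_open_probability <- function(model) {
  stopifnot(inherits(model, "gating_model"))
  P <- model$transition_probs
  n <- nrow(P)
  # pi P = pi, sum(pi) = 1 via the eigenvector of t(P) at eigenvalue 1
  e <- eigen(t(P))
  i <- which(abs(e$values - 1) < 1e-8)
  if (length(i) == 0L)
    stop("embedded chain has no unit eigenvalue; malformed transition matrix",
         call. = FALSE)
  if (length(i) > 1L)
    stop("embedded transition chain is reducible: stationary distribution ",
         "is not unique", call. = FALSE)
  pi_ <- Re(e$vectors[, i])
  pi_ <- pi_ / sum(pi_)
  if (any(pi_ < -1e-10))
    stop("embedded transition chain is reducible or degenerate", call. = FALSE)
  pi_ <- pmax(pi_, 0)
  mu <- vapply(model$states, state_mean_dwell, 0)
  sum(pi_[model$conducting] * mu[model$conducting]) / sum(pi_ * mu)
}
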