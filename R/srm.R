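#' Spike Response Model simulation parameters
#'
#' Bundles the constants of the Spike Response Model (SRM) used throughout
#' the package. The defaults are the study settings of the design protocol:
#' membrane time constant \eqn{\tau = 9} ms, firing threshold
#' \eqn{\theta = 1} mV, evaluation grid step 0.01 ms, and an output-layer
#' decision window starting at 10 ms.
#'
#' @param tau Membrane potential time constant in ms; controls the decay of
#'   the postsynaptic potential kernel. Must be positive.
#' @param theta Firing threshold in mV. Must be positive.
#' @param t_end Simulation end time in ms. For a K-class problem this is the
#'   last class target plus 2 ms (see [class_targets()]).
#' @param dt Evaluation grid step in ms. Spike times are resolved on this
#'   grid; 0.01 ms matches the synaptic delay resolution.
#' @param decision_start Earliest admissible output-layer spike time in ms.
#'   Hidden neurons are always simulated from t = 0; only the output
#'   neuron's first spike is searched from `decision_start` onward.
#'
#' @return An object of class `"srm_params"`: a validated list with the five
#'   fields above.
#' @examples
#' srm_params(t_end = 20)
#' @export
srm_params <- function(tau = 9, theta = 1, t_end = 20, dt = 0.01,
                       decision_start = 10) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0,
            is.numeric(theta), length(theta) == 1L, theta > 0,
            is.numeric(t_end), length(t_end) == 1L,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(decision_start), length(decision_start) == 1L)
  if (!(decision_start >= 0 && decision_start < t_end))
    stop("'decision_start' must lie in [0, t_end)", call. = FALSE)
  structure(list(tau = tau, theta = theta, t_end = t_end, dt = dt,
                 decision_start = decision_start),
            class = "srm_params")
}

#' @export
print.srm_params <- function(x, ...) {
  cat("SRM parameters: tau =", x$tau, "ms, theta =", x$theta,
      "mV, window [0,", x$t_end, "] ms, dt =", x$dt,
      "ms, output decision from", x$decision_start, "ms\n")
  invisible(x)
}

#' Postsynaptic potential kernel
#'
#' The spike-response kernel
#' \eqn{\varepsilon(t) = (t/\tau)\, e^{1 - t/\tau}} for \eqn{t > 0} and 0
#' otherwise. It rises from 0, peaks at exactly 1 when \eqn{t = \tau}, and
#' decays exponentially afterwards.
#'
#' @param t Elapsed time since the (delayed) presynaptic spike, in ms.
#'   Vectorized.
#' @param tau Membrane time constant in ms; must be positive.
#' @return Kernel values in `[0, 1]`, same length as `t`.
#' @examples
#' psp_kernel(c(0, 4.5, 9, 18), tau = 9)
#' @export
psp_kernel <- function(t, tau = 9) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number", call. = FALSE)
  ifelse(t > 0, (t / tau) * exp(1 - t / tau), 0)
}

#' Membrane potential of an SRM neuron
#'
#' Linear summation of weighted, delayed postsynaptic potentials: the
#' potential at time `t` is \eqn{\sum_i w_i\, \varepsilon(t - t_i - d_i)}
#' over all impinging spikes, where \eqn{t_i} is the presynaptic spike time
#' and \eqn{d_i} the synaptic delay.
#'
#' @param t Evaluation time(s) in ms; vectorized.
#' @param spike_times Presynaptic first-spike times in ms. `NA` entries
#'   (non-firing presynaptic neurons) contribute nothing.
#' @param weights Synaptic weights, same length as `spike_times`.
#' @param delays Synaptic delays in ms, same length, all non-negative.
#' @param tau Membrane time constant in ms.
#' @return Potential at each `t` (mV scale; compared directly to the
#'   threshold).
#' @examples
#' membrane_potential(10, spike_times = 1, weights = 2, delays = 0.5)
#' @export
membrane_potential <- function(t, spike_times, weights, delays, tau = 9) {
  stopifnot(length(spike_times) == length(weights),
            length(weights) == length(delays))
  if (any(delays < 0, na.rm = TRUE))
    stop("synaptic delays must be non-negative", call. = FALSE)
  live <- !is.na(spike_times)
  if (!any(live)) return(rep(0, length(t)))
  onset <- spike_times[live] + delays[live]
  .membrane_grid(as.numeric(t), as.numeric(onset),
                 as.numeric(weights[live]), tau)
}

#' First threshold crossing of an SRM neuron
#'
#' Scans the evaluation grid `search_from, search_from + dt, ...` up to
#' `t_end` and returns the earliest time at which the membrane potential
#' reaches the threshold, or `NA` if the neuron never fires. Each neuron is
#' simulated up to its first spike only; there is no reset kernel.
#'
#' @inheritParams membrane_potential
#' @param params An [srm_params()] object.
#' @param search_from Start of the search window in ms (0 for hidden
#'   neurons; `params$decision_start` for the output neuron).
#' @return A single spike time in ms, or `NA_real_` for a non-firing neuron.
#' @examples
#' p <- srm_params(t_end = 20)
#' first_spike_time(0, 1, 0, params = p)          # peaks at tau = 9 -> 9
#' first_spike_time(0, 0.5, 0, params = p)        # subthreshold -> NA
#' @export
first_spike_time <- function(spike_times, weights, delays, params,
                             search_from = 0) {
  stopifnot(inherits(params, "srm_params"),
            length(spike_times) == length(weights),
            length(weights) == length(delays))
  if (search_from > params$t_end)
    stop("'search_from' must not exceed t_end", call. = FALSE)
  live <- !is.na(spike_times)
  if (!any(live) || all(weights[live] <= 0)) return(NA_real_)
  .first_spike_grid(as.numeric(spike_times[live] + delays[live]),
                    as.numeric(weights[live]),
                    params$tau, params$theta,
                    search_from, params$t_end, params$dt)
}

#' Construct a three-layer SNN topology
#'
#' A designed network is a set of hidden neurons, each carrying a list of
#' input synapses (presynaptic input index, weight, delay in ms) and exactly
#' one output synapse onto the single output neuron. Hidden neurons only see
#' the inputs their synapses name, so a topology implicitly selects
#' features.
#'
#' @param n_inputs Number of input neurons (= dataset features).
#' @param hidden A list of hidden neuron specifications; each element is a
#'   list with fields `presyn` (integer vector of 0-based input indices),
#'   `weight` and `delay` (numeric vectors of the same length), and
#'   `out_weight`, `out_delay` (scalars for the output synapse).
#' @return An object of class `"snn_topology"`.
#' @examples
#' snn_topology(2, list(list(presyn = c(0L, 1L), weight = c(12.5, -3),
#'                           delay = c(1.25, 0.5),
#'                           out_weight = 500, out_delay = 2)))
#' @export
snn_topology <- function(n_inputs, hidden) {
  n_inputs <- as.integer(n_inputs)
  stopifnot(length(n_inputs) == 1L, n_inputs >= 1L,
            is.list(hidden), length(hidden) >= 1L)
  hidden <- lapply(hidden, function(h) {
    presyn <- as.integer(h$presyn)
    stopifnot(length(presyn) >= 1L,
              length(h$weight) == length(presyn),
              length(h$delay) == length(presyn),
              length(h$out_weight) == 1L, length(h$out_delay) == 1L)
    if (any(presyn < 0L) || any(presyn >= n_inputs))
      stop("input synapse presynaptic index out of range", call. = FALSE)
    if (any(c(h$delay, h$out_delay) < 0))
      stop("synaptic delays must be non-negative", call. = FALSE)
    list(presyn = presyn, weight = as.numeric(h$weight),
         delay = as.numeric(h$delay),
         out_weight = as.numeric(h$out_weight),
         out_delay = as.numeric(h$out_delay))
  })
  structure(list(n_inputs = n_inputs, hidden = hidden),
            class = "snn_topology")
}

#' @export
print.snn_topology <- function(x, ...) {
  ns <- vapply(x$hidden, function(h) length(h$presyn), integer(1))
  cat("SNN topology:", x$n_inputs, "input neuron(s),",
      length(x$hidden), "hidden neuron(s), 1 output neuron\n")
  for (i in seq_along(x$hidden)) {
    h <- x$hidden[[i]]
    cat(sprintf("  hidden %d: inputs {%s} (%d synapse%s), output w=%.2f d=%.2f\n",
                i, paste(sort(unique(h$presyn)), collapse = ","),
                ns[i], if (ns[i] > 1) "s" else "",
                h$out_weight, h$out_delay))
  }
  invisible(x)
}

#' Simulate a designed SNN on one encoded pattern
#'
#' Propagates input spikes through the hidden layer to the output neuron.
#' Hidden first-spike times are searched over `[0, t_end]`; the output
#' neuron's first spike is searched over `[decision_start, t_end]`. Hidden
#' neurons that never fire contribute no postsynaptic potential to the
#' output.
#'
#' @param topology An [snn_topology()] object.
#' @param input_spikes Numeric vector of input spike times in ms, one per
#'   input neuron (an encoded pattern's spike times).
#' @param params An [srm_params()] object.
#' @return A list with `output` (output first-spike time in ms, or `NA` if
#'   the output neuron does not fire) and `hidden` (per-hidden-neuron
#'   first-spike times, `NA` marking non-firing neurons).
#' @examples
#' top <- snn_topology(1, list(list(presyn = 0L, weight = 2, delay = 0.5,
#'                                  out_weight = 2, out_delay = 1)))
#' simulate_network(top, input_spikes = 0.01, params = srm_params(t_end = 17))
#' @export
simulate_network <- function(topology, input_spikes, params) {
  stopifnot(inherits(topology, "snn_topology"), inherits(params, "srm_params"))
  if (length(input_spikes) != topology$n_inputs)
    stop("pattern dimensionality does not match topology n_inputs",
         call. = FALSE)
  nh <- length(topology$hidden)
  hidden_t <- numeric(nh)
  for (j in seq_len(nh)) {
    h <- topology$hidden[[j]]
    hidden_t[j] <- first_spike_time(input_spikes[h$presyn + 1L],
                                    h$weight, h$delay, params,
                                    search_from = 0)
  }
  out_w <- vapply(topology$hidden, `[[`, numeric(1), "out_weight")
  out_d <- vapply(topology$hidden, `[[`, numeric(1), "out_delay")
  out_t <- first_spike_time(hidden_t, out_w, out_d, params,
                            search_from = params$decision_start)
  list(output = out_t, hidden = hidden_t)
}
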