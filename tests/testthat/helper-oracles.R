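# Independent brute-force oracles and small fixture builders.

# First threshold crossing by exhaustive scan of a fine grid, computed in
# plain R from the closed-form kernel (independent of the compiled solver).
oracle_first_spike <- function(spike_times, weights, delays, tau, theta,
                               search_from, t_end, dt) {
  grid <- seq(search_from, t_end, by = dt)
  live <- !is.na(spike_times)
  if (!any(live)) return(NA_real_)
  onset <- spike_times[live] + delays[live]
  w <- weights[live]
  v <- sapply(grid, function(t) {
    s <- t - onset
    sum(w * ifelse(s > 0, (s / tau) * exp(1 - s / tau), 0))
  })
  hit <- which(v >= theta)
  if (length(hit) == 0L) NA_real_ else grid[hit[1]]
}

# A random valid topology with 2-decimal weights/delays in the stated ranges.
random_topology <- function(n_inputs = 3) {
  nh <- sample(1:3, 1)
  snn_topology(n_inputs, lapply(seq_len(nh), function(j) {
    ns <- sample(1:4, 1)
    list(presyn = sample(0:(n_inputs - 1), ns, replace = TRUE),
         weight = round(runif(ns, -999.99, 999.99), 2),
         delay = round(runif(ns, 0.01, 19.99), 2),
         out_weight = round(runif(1, -999.99, 999.99), 2),
         out_delay = round(runif(1, 0.01, 19.99), 2))
  }))
}

toy_grammar <- load_grammar("<s> ::= a | b")

# Small encoded pattern set directly in the list form used by the
# evaluators: one feature, two patterns, two classes.
tiny_encoded <- function() {
  list(spikes = matrix(c(0.01, 9), ncol = 1), y = c(0L, 1L))
}
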