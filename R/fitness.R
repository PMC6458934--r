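#' Per-class target firing times
#'
#' Each class is assigned a desired output firing time: 12 ms for the first
#' class and 3 ms more for every further class, i.e. `{12, 15, 18, ...}` ms.
#' The simulation end time is the last target plus 2 ms.
#'
#' @param n_classes Number of classes (at least 2).
#' @return An object of class `"class_targets"`: a list with `targets`
#'   (numeric vector, ms, indexed by class id + 1) and `t_end` (ms).
#' @examples
#' class_targets(3)  # {12, 15, 18} ms, t_end = 20 ms
#' @export
class_targets <- function(n_classes) {
  stopifnot(length(n_classes) == 1L, n_classes >= 2)
  targets <- 12 + 3 * (seq_len(n_classes) - 1)
  structure(list(targets = targets, t_end = targets[n_classes] + 2),
            class = "class_targets")
}

#' @export
print.class_targets <- function(x, ...) {
  cat("Class target firing times (ms):",
      paste(x$targets, collapse = ", "),
      "| simulation end:", x$t_end, "ms\n")
  invisible(x)
}

#' Decode an output spike time into a class
#'
#' Nearest-target readout: the predicted class is the one whose target
#' firing time is closest to the observed output spike time, ties broken
#' toward the smaller class id. A non-firing output (`NA`) is rejected and
#' always counted incorrect.
#'
#' @param output_time Output first-spike time(s) in ms; `NA` marks
#'   non-firing. Vectorized.
#' @param targets A [class_targets()] object.
#' @return Integer class id(s) in `0..K-1`, `NA_integer_` for rejections.
#' @examples
#' decode_spike_time(c(13.4, 13.5, NA), class_targets(2))
#' @export
decode_spike_time <- function(output_time, targets) {
  stopifnot(inherits(targets, "class_targets"))
  vapply(output_time, function(t) {
    if (is.na(t)) return(NA_integer_)
    which.min(abs(t - targets$targets)) - 1L
  }, integer(1))
}

#' Squared-error fitness over output spike times
#'
#' \eqn{E_s = \sum_p (t^a(p) - t^d(p))^2} over all patterns, with one
#' output neuron. Both arguments must already have non-firing substitutions
#' applied (see [evaluate_genotype()]).
#'
#' @param actual Observed output spike times in ms, one per pattern.
#' @param desired Target firing times in ms (the target of each pattern's
#'   true class), same length.
#' @return The squared error (to be minimized, 0 at a perfect fit).
#' @examples
#' squared_error(c(13, 16), c(12, 18))  # 1 + 4 = 5
#' @export
squared_error <- function(actual, desired) {
  if (length(actual) != length(desired))
    stop("'actual' and 'desired' must have the same length", call. = FALSE)
  sum((actual - desired)^2)
}

#' Accuracy-error fitness
#'
#' \eqn{E_a = 1 - C/T} where `C` is the number of correct predictions and
#' `T` the total. Rejected patterns (`NA` predictions) are never correct.
#'
#' @param predictions Integer class predictions (`NA` = reject).
#' @param labels True integer class labels, same length.
#' @return The accuracy error in `[0, 1]` (to be minimized).
#' @examples
#' accuracy_error(c(0L, 1L, 1L, NA), c(0L, 1L, 0L, 1L))  # 1 - 2/4
#' @export
accuracy_error <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("'predictions' and 'labels' must have the same length",
         call. = FALSE)
  if (length(labels) == 0L) stop("no predictions to score", call. = FALSE)
  correct <- !is.na(predictions) & predictions == labels
  1 - sum(correct) / length(labels)
}

#' Sentinel fitness for invalid individuals
#'
#' Genotypes whose grammar mapping does not terminate (or whose word cannot
#' be parsed) receive a fitness strictly worse than any attainable valid
#' value: 1e9 for the squared-error fitness, 2 for the accuracy-error
#' fitness.
#'
#' @param fitness One of `"squared"`, `"accuracy"`.
#' @return The sentinel value.
#' @export
sentinel_fitness <- function(fitness = c("squared", "accuracy")) {
  switch(match.arg(fitness), squared = 1e9, accuracy = 2)
}

#' Evaluate one genotype on an encoded design set
#'
#' The end-to-end fitness pipeline: map the genotype to a word, parse the
#' word into a topology, simulate every pattern, and score. A genotype whose
#' mapping fails (codon exhaustion) or whose word does not parse yields an
#' invalid record carrying the sentinel fitness. For the squared-error
#' fitness a non-firing output is substituted with `t_end` (the maximally
#' late time), giving a finite penalty; for the accuracy-error fitness a
#' non-firing output is a rejection.
#'
#' @param genotype Integer codon vector in `[0, 255]`.
#' @param grammar A `"bnf_grammar"` object.
#' @param encoded An encoded pattern set from [encode_dataset()] (fields
#'   `spikes`, `y`).
#' @param params An [srm_params()] object (its `t_end` should equal
#'   `targets$t_end`).
#' @param targets A [class_targets()] object.
#' @param fitness `"squared"` (E_s) or `"accuracy"` (E_a).
#' @return A list of class `"fitness_record"`: `value`, `valid`, `word`
#'   (or `NA`), `output_times` (per pattern, `NA` = non-firing) and
#'   `predictions`.
#' @export
evaluate_genotype <- function(genotype, grammar, encoded, params, targets,
                              fitness = c("squared", "accuracy")) {
  fitness <- match.arg(fitness)
  stopifnot(nrow(encoded$spikes) >= 1L)
  invalid <- function() {
    structure(list(value = sentinel_fitness(fitness), valid = FALSE,
                   word = NA_character_, output_times = NULL,
                   predictions = NULL),
              class = "fitness_record")
  }
  word <- map_genotype(genotype, grammar)
  if (is.na(word)) return(invalid())
  topology <- tryCatch(parse_word(word, ncol(encoded$spikes)),
                       error = function(e) NULL)
  if (is.null(topology)) return(invalid())
  rec <- evaluate_topology(topology, encoded, params, targets, fitness)
  rec$word <- word
  rec
}

#' Evaluate an already-built topology on an encoded pattern set
#'
#' The simulation-and-scoring half of [evaluate_genotype()], useful for
#' auditing a designed network against design or test patterns.
#'
#' @inheritParams evaluate_genotype
#' @param topology An [snn_topology()] object.
#' @return A `"fitness_record"` (always `valid = TRUE`).
#' @export
evaluate_topology <- function(topology, encoded, params, targets,
                              fitness = c("squared", "accuracy")) {
  fitness <- match.arg(fitness)
  stopifnot(inherits(topology, "snn_topology"))
  n <- nrow(encoded$spikes)
  times <- numeric(n)
  for (p in seq_len(n))
    times[p] <- simulate_network(topology, encoded$spikes[p, ],
                                 params)$output
  preds <- decode_spike_time(times, targets)
  value <- if (fitness == "squared") {
    actual <- ifelse(is.na(times), params$t_end, times)
    squared_error(actual, targets$targets[encoded$y + 1L])
  } else {
    accuracy_error(preds, encoded$y)
  }
  structure(list(value = value, valid = TRUE, word = NA_character_,
                 output_times = times, predictions = preds),
            class = "fitness_record")
}

#' @export
print.fitness_record <- function(x, ...) {
  if (x$valid)
    cat("Fitness record: value =", x$value, "over",
        length(x$output_times), "patterns (",
        sum(is.na(x$output_times)), "non-firing )\n")
  else
    cat("Fitness record: invalid individual, sentinel value =", x$value, "\n")
  invisible(x)
}
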