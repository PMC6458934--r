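#' Topology statistics of a designed network
#'
#' Counts used to characterize designed architectures: the number of
#' distinct input features actually wired into the network (partial
#' connectivity performs implicit feature selection), the fraction of
#' available features employed, the hidden-unit count and the total number
#' of synapses (input synapses plus one output synapse per hidden neuron).
#'
#' @param topology An [snn_topology()] object.
#' @param n_features Total number of features available in the dataset.
#' @return A list with `features_employed`, `feature_rate`, `hidden_units`
#'   and `synapses`.
#' @export
topology_stats <- function(topology, n_features = topology$n_inputs) {
  stopifnot(inherits(topology, "snn_topology"))
  used <- unique(unlist(lapply(topology$hidden, `[[`, "presyn")))
  n_in <- sum(vapply(topology$hidden, function(h) length(h$presyn),
                     integer(1)))
  list(features_employed = length(used),
       feature_rate = length(used) / n_features,
       hidden_units = length(topology$hidden),
       synapses = n_in + length(topology$hidden))
}

#' Named experiment configurations
#'
#' The study's configuration grid over third-generation networks:
#' \eqn{\beta} presets use the genetic algorithm, \eqn{\gamma} presets
#' differential evolution; subscript 1 minimizes the squared error of
#' output spike times, subscript 2 the accuracy error of the design set.
#'
#' @param name One of `"beta1"`, `"beta2"`, `"gamma1"`, `"gamma2"`.
#' @return A list with `engine` and `fitness` suitable for [gesnn()] /
#'   [run_experiment()].
#' @examples
#' configuration("gamma2")
#' @export
configuration <- function(name = c("beta1", "beta2", "gamma1", "gamma2")) {
  name <- match.arg(name)
  list(engine = if (startsWith(name, "beta")) "ga" else "de",
       fitness = if (endsWith(name, "1")) "squared" else "accuracy",
       name = name)
}

#' Run the full design/test experiment protocol
#'
#' For each repetition `i` (seed `base_seed + i - 1`): stratified half split
#' of the dataset into design and test subsets; fit of a [gesnn()] model on
#' the design half; evaluation of the designed network on both halves. The
#' full protocol uses 1,000,000 fitness evaluations and 33 repetitions per
#' configuration, which is long-running; desk-scale runs use a few thousand
#' evaluations.
#'
#' @param ds An [snn_dataset()].
#' @param configuration A preset from [configuration()], or any list with
#'   `engine` and `fitness`.
#' @param budget Fitness evaluations per repetition.
#' @param population Population size.
#' @param repetitions Number of independent repetitions.
#' @param base_seed First seed; repetition `i` uses `base_seed + i - 1` for
#'   both the split and the search.
#' @param outdir Optional directory; when given, per-repetition results
#'   (CSV), best words (text) and topologies (JSON) are written there.
#' @param ... Further arguments to [gesnn()] (e.g. `grammar`, `tau`).
#' @return An object of class `"gesnn_experiment"`: a list of per-repetition
#'   results (`fit`, `design_accuracy`, `test_accuracy`, `stats`, `word`,
#'   `seed`) plus the configuration, printable via [summary()].
#' @export
run_experiment <- function(ds, configuration = gesnn::configuration("gamma2"),
                           budget = 1e6, population = 100,
                           repetitions = 1, base_seed = 1L,
                           outdir = NULL, ...) {
  stopifnot(inherits(ds, "snn_dataset"), repetitions >= 1)
  runs <- lapply(seq_len(repetitions), function(i) {
    seed <- base_seed + i - 1L
    halves <- stratified_split(ds, seed = seed)
    fit <- gesnn(halves$design$x, halves$design$y,
                 engine = configuration$engine,
                 fitness = configuration$fitness,
                 budget = budget, population = population, seed = seed, ...)
    test_acc <- if (is.null(fit$topology)) NA_real_ else {
      pred <- predict(fit, halves$test$x, type = "id")
      1 - accuracy_error(pred, halves$test$y)
    }
    list(fit = fit, seed = seed,
         design_accuracy = fit$design$accuracy,
         test_accuracy = test_acc,
         word = fit$word,
         stats = if (is.null(fit$topology)) NULL
                 else topology_stats(fit$topology, ncol(ds$x)))
  })
  res <- structure(list(runs = runs, configuration = configuration,
                        budget = budget, population = population,
                        base_seed = base_seed),
                   class = "gesnn_experiment")
  if (!is.null(outdir)) write_experiment(res, outdir)
  res
}

# Persist an experiment: summary CSV + per-repetition word and topology.
write_experiment <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  df <- experiment_table(res)
  write.csv(df, file.path(outdir, "results.csv"), row.names = FALSE)
  for (i in seq_along(res$runs)) {
    run <- res$runs[[i]]
    if (is.null(run$fit$topology)) next
    writeLines(run$word, file.path(outdir, sprintf("best_word_%02d.txt", i)))
    write_topology_json(run$fit$topology,
                        file.path(outdir, sprintf("topology_%02d.json", i)))
  }
  invisible(outdir)
}

# One row per repetition.
experiment_table <- function(res) {
  do.call(rbind, lapply(seq_along(res$runs), function(i) {
    run <- res$runs[[i]]
    st <- run$stats
    data.frame(repetition = i, seed = run$seed,
               design_accuracy = run$design_accuracy,
               test_accuracy = run$test_accuracy,
               hidden_units = if (is.null(st)) NA else st$hidden_units,
               features_employed = if (is.null(st)) NA
                                   else st$features_employed,
               synapses = if (is.null(st)) NA else st$synapses)
  }))
}

#' Summarize an experiment as mean and standard deviation
#'
#' @param object A `"gesnn_experiment"` from [run_experiment()].
#' @param ... Ignored.
#' @return A data frame with one row per quantity (design/test accuracy and
#'   each topology statistic) and columns `mean` and `sd`, printed in the
#'   `m +- s` style with 4 decimals.
#' @export
summary.gesnn_experiment <- function(object, ...) {
  df <- experiment_table(object)
  cols <- c("design_accuracy", "test_accuracy", "hidden_units",
            "features_employed", "synapses")
  out <- data.frame(
    quantity = cols,
    mean = vapply(cols, function(cl) mean(df[[cl]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(cols, function(cl)
      if (sum(!is.na(df[[cl]])) > 1) sd(df[[cl]], na.rm = TRUE) else 0,
      numeric(1)),
    row.names = NULL)
  class(out) <- c("summary.gesnn_experiment", "data.frame")
  out
}

#' @export
print.summary.gesnn_experiment <- function(x, ...) {
  cat("Experiment summary (", nrow(x), "quantities ):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-18s %.4f \u00b1 %.4f\n",
                x$quantity[i], x$mean[i], x$sd[i]))
  invisible(x)
}

#' @export
print.gesnn_experiment <- function(x, ...) {
  cat("GE-SNN experiment:", x$configuration$name %||% "custom",
      "|", length(x$runs), "repetition(s), budget", x$budget,
      ", population", x$population, "\n")
  print(summary(x))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
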