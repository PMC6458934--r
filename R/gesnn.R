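#' Design a spiking neural network classifier by grammatical evolution
#'
#' Evolves a partially connected three-layer feedforward spiking neural
#' network for a classification problem. A BNF grammar generates network
#' words fixing the topology together with every synaptic weight and delay
#' (there is no separate weight-training phase); integer codon genotypes are
#' mapped to words depth-first and optimized by differential evolution or a
#' genetic algorithm. Features are turned into input spike times by the
#' linear temporal encoding fitted on the supplied (design) data, neurons
#' follow the Spike Response Model, and the predicted class is the one whose
#' target firing time is nearest to the output neuron's first spike.
#'
#' The data passed here play the role of the design subset: the temporal
#' encoding and every search decision are computed from them alone. Held-out
#' data should be scored with [predict()].
#'
#' @param x Numeric feature matrix or data frame (design samples in rows),
#'   or a formula.
#' @param y Class labels (factor, character or integer), one per row.
#' @param engine Search engine: `"de"` (differential evolution, the
#'   \eqn{\gamma} configurations) or `"ga"` (genetic algorithm, the
#'   \eqn{\beta} configurations).
#' @param fitness Fitness function to minimize: `"accuracy"` (the accuracy
#'   error of the design set, subscript-2 configurations) or `"squared"`
#'   (the squared error between actual and target output spike times,
#'   subscript-1 configurations).
#' @param budget Number of fitness evaluations. The default 10,000 is a
#'   desk-scale setting; the full design protocol uses 1,000,000.
#' @param population Population size (100 in the full protocol).
#' @param encoding_window Temporal encoding limits `c(a, b)` in ms.
#' @param tau,theta,dt,decision_start SRM constants, see [srm_params()]; the
#'   simulation end time is set automatically to the last class target plus
#'   2 ms.
#' @param grammar The design grammar; defaults to [snn_grammar()].
#' @param config Optional pre-built [ga_config()]/[de_config()] overriding
#'   `budget` and `population`.
#' @param seed Integer seed; fits are reproducible bit-for-bit.
#' @param ... Passed between methods.
#' @return An object of class `"gesnn"` with components including `topology`
#'   (the designed [snn_topology()]), `word` (its grammar word), `search`
#'   (engine trace with best-so-far `history`), `encoding`, `params`,
#'   `targets` and `design` (per-pattern output times, predictions and the
#'   design accuracy). Methods: [print()], [summary()], [predict()],
#'   [coef()], [plot()], [fitted()], [residuals()].
#' @examples
#' ds <- make_blobs(40, 2, 2, separation = 8, seed = 7)
#' fit <- gesnn(ds$x, ds$y, engine = "de", fitness = "accuracy",
#'              budget = 600, population = 20, seed = 7)
#' fit
#' predict(fit, ds$x[1:3, ])
#' @export
gesnn <- function(x, ...) UseMethod("gesnn")

#' @rdname gesnn
#' @param formula A formula `class ~ feature1 + ...` (or `class ~ .`).
#' @param data Data frame holding the formula's variables.
#' @export
gesnn.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  xm <- stats::model.matrix(mt, mf)
  keep <- setdiff(colnames(xm), "(Intercept)")
  fit <- gesnn.default(xm[, keep, drop = FALSE], y, ...)
  fit$terms <- mt
  fit$call <- match.call()
  fit
}

#' @rdname gesnn
#' @export
gesnn.default <- function(x, y, engine = c("de", "ga"),
                          fitness = c("accuracy", "squared"),
                          budget = 10000, population = 100,
                          encoding_window = c(0.01, 9),
                          tau = 9, theta = 1, dt = 0.01,
                          decision_start = 10,
                          grammar = snn_grammar(), config = NULL,
                          seed = 1L, ...) {
  engine <- match.arg(engine)
  fitness <- match.arg(fitness)
  ds <- snn_dataset(x, y)
  targets <- class_targets(length(ds$class_names))
  params <- srm_params(tau = tau, theta = theta, t_end = targets$t_end,
                       dt = dt, decision_start = decision_start)
  encoding <- fit_encoding(ds, a = encoding_window[1], b = encoding_window[2])
  encoded <- encode_dataset(ds, encoding)
  fitness_fn <- function(codons)
    evaluate_genotype(codons, grammar, encoded, params, targets,
                      fitness)$value
  if (is.null(config)) {
    config <- if (engine == "de")
      de_config(population = population, budget = budget)
    else ga_config(population = population, budget = budget)
  }
  search <- if (engine == "de") de_search(fitness_fn, config, seed)
            else ga_search(fitness_fn, config, seed)
  best <- evaluate_genotype(search$best_genotype, grammar, encoded, params,
                            targets, fitness)
  if (!best$valid)
    warning("the search returned an invalid individual; ",
            "no network was designed (try a larger budget)", call. = FALSE)
  topology <- if (best$valid) parse_word(best$word, ncol(ds$x)) else NULL
  design <- list(
    labels = ds$y,
    output_times = best$output_times,
    predictions = best$predictions,
    accuracy = if (best$valid)
      1 - accuracy_error(best$predictions, ds$y) else NA_real_)
  structure(list(call = match.call(), engine = engine, fitness = fitness,
                 config = config, seed = seed, grammar = grammar,
                 encoding = encoding, params = params, targets = targets,
                 class_names = ds$class_names,
                 feature_names = colnames(ds$x),
                 search = search, word = best$word, topology = topology,
                 design = design),
            class = "gesnn")
}

#' @export
print.gesnn <- function(x, ...) {
  cat("Grammatically evolved SNN classifier\n\nCall:\n ")
  print(x$call)
  cat("\nEngine:", toupper(x$engine), "| fitness:", x$fitness,
      "| evaluations:", x$search$evaluations, "\n")
  if (is.null(x$topology)) {
    cat("No valid network designed.\n")
    return(invisible(x))
  }
  st <- topology_stats(x$topology, x$topology$n_inputs)
  cat(sprintf("Designed network: %d hidden neuron(s), %d synapses, %d/%d feature(s) employed\n",
              st$hidden_units, st$synapses, st$features_employed,
              x$topology$n_inputs))
  cat(sprintf("Design accuracy: %.4f (best fitness %.6g)\n",
              x$design$accuracy, x$search$best_fitness))
  invisible(x)
}

#' @export
summary.gesnn <- function(object, ...) {
  st <- if (is.null(object$topology)) NULL
        else topology_stats(object$topology, object$topology$n_inputs)
  conf <- if (is.null(object$topology)) NULL else {
    pred <- factor(object$design$predictions,
                   levels = seq_along(object$class_names) - 1L,
                   labels = object$class_names)
    truth <- factor(object$design$labels,
                    levels = seq_along(object$class_names) - 1L,
                    labels = object$class_names)
    table(truth = truth, predicted = pred, useNA = "ifany")
  }
  structure(list(fit = object, stats = st, confusion = conf),
            class = "summary.gesnn")
}

#' @export
print.summary.gesnn <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$topology)) {
    cat("\nTargets (ms):", paste(x$fit$targets$targets, collapse = ", "),
        "| non-firing design patterns:",
        sum(is.na(x$fit$design$output_times)), "\n")
    cat("\nDesign confusion matrix:\n")
    print(x$confusion)
    cat("\nTopology:\n")
    print(x$fit$topology)
  }
  invisible(x)
}

# Rebuild the feature matrix for predict() from new data.
gesnn_newdata <- function(object, newdata) {
  if (!is.null(object$terms)) {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, as.data.frame(newdata))
    xm <- stats::model.matrix(tt, mf)
    return(xm[, setdiff(colnames(xm), "(Intercept)"), drop = FALSE])
  }
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  x
}

#' Predict classes (or spike times) for new samples
#'
#' Encodes the new feature rows with the encoding fitted on the design data
#' (values outside the design range are clamped), simulates the designed
#' network, and decodes the output neuron's first spike against the class
#' targets. A non-firing output is a rejection (`NA` class).
#'
#' @param object A fitted [gesnn()] model.
#' @param newdata Feature matrix/data frame (or data frame of formula
#'   variables for formula fits).
#' @param type `"class"` for class labels (a factor), `"time"` for the raw
#'   output spike times in ms (`NA` = non-firing), `"id"` for the integer
#'   class ids `0..K-1`.
#' @param ... Ignored.
#' @return Factor, numeric or integer vector with one entry per row.
#' @export
predict.gesnn <- function(object, newdata,
                          type = c("class", "time", "id"), ...) {
  type <- match.arg(type)
  if (is.null(object$topology))
    stop("model holds no valid network; refit with a larger budget",
         call. = FALSE)
  x <- gesnn_newdata(object, newdata)
  if (ncol(x) != object$topology$n_inputs)
    stop("newdata has ", ncol(x), " features; the model expects ",
         object$topology$n_inputs, call. = FALSE)
  spikes <- x
  for (j in seq_len(ncol(x)))
    spikes[, j] <- encode_feature(x[, j], object$encoding$a,
                                  object$encoding$b,
                                  object$encoding$m[j], object$encoding$M[j])
  times <- vapply(seq_len(nrow(spikes)), function(p)
    simulate_network(object$topology, spikes[p, ], object$params)$output,
    numeric(1))
  if (type == "time") return(times)
  ids <- decode_spike_time(times, object$targets)
  if (type == "id") return(ids)
  factor(ids, levels = seq_along(object$class_names) - 1L,
         labels = object$class_names)
}

#' @export
coef.gesnn <- function(object, ...) {
  if (is.null(object$topology)) return(NULL)
  do.call(rbind, lapply(seq_along(object$topology$hidden), function(j) {
    h <- object$topology$hidden[[j]]
    rbind(data.frame(hidden = j, synapse = "input", presyn = h$presyn,
                     weight = h$weight, delay = h$delay),
          data.frame(hidden = j, synapse = "output", presyn = NA_integer_,
                     weight = h$out_weight, delay = h$out_delay))
  }))
}

#' @export
fitted.gesnn <- function(object, ...) {
  factor(object$design$predictions,
         levels = seq_along(object$class_names) - 1L,
         labels = object$class_names)
}

#' Temporal residuals of a designed SNN
#'
#' The difference between each design pattern's actual output spike time and
#' the target firing time of its true class, in ms. Non-firing patterns give
#' `NA`.
#'
#' @param object A fitted [gesnn()] model.
#' @param ... Ignored.
#' @return Numeric vector, one residual per design pattern.
#' @export
residuals.gesnn <- function(object, ...) {
  if (is.null(object$topology)) return(NULL)
  object$design$output_times -
    object$targets$targets[object$design$labels + 1L]
}

#' Plot the search trace of a fitted model
#'
#' Best-so-far fitness against the generation counter (a non-increasing
#' step curve).
#'
#' @param x A fitted [gesnn()] model.
#' @param ... Passed to [plot.default()].
#' @export
plot.gesnn <- function(x, ...) {
  h <- x$search$history
  plot(seq_along(h) - 1, h, type = "s",
       xlab = "generation", ylab = paste0("best ", x$fitness, " fitness"),
       main = paste(toupper(x$engine), "search trace"), ...)
  invisible(x)
}
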