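#' Parse a network word into a topology
#'
#' Decodes the `{`/`(`/`@` dialect: one hidden neuron per `{`-terminated
#' block; within a block, `(`-separated synapse configs `id@weight@delay`;
#' the last config of each block is the output synapse, all earlier configs
#' are input synapses. Weights and delays are 2-decimal fixed-point;
#' input-neuron ids outside `[0, n_inputs)` are reduced modulo `n_inputs`;
#' delays are clamped into `[0.01, 19.99]` ms.
#'
#' @param word A word string, e.g. from [map_genotype()].
#' @param n_inputs Number of input neurons of the target network.
#' @return An [snn_topology()] object.
#' @examples
#' parse_word("0@12.50@1.25(1@-3.00@0.50(0@500.00@2.00{", n_inputs = 2)
#' @export
parse_word <- function(word, n_inputs) {
  stopifnot(is.character(word), length(word) == 1L, !is.na(word))
  n_inputs <- as.integer(n_inputs)
  if (!nzchar(word) || !endsWith(word, "{"))
    stop("malformed word: must consist of '{'-terminated blocks",
         call. = FALSE)
  blocks <- strsplit(word, "{", fixed = TRUE)[[1]]
  hidden <- lapply(seq_along(blocks), function(bi) {
    configs <- strsplit(blocks[bi], "(", fixed = TRUE)[[1]]
    if (length(configs) < 2L)
      stop("block ", bi, ": needs at least one input synapse and the ",
           "output synapse", call. = FALSE)
    parsed <- lapply(configs, function(cf) {
      parts <- strsplit(cf, "@", fixed = TRUE)[[1]]
      if (length(parts) != 3L || !all(nzchar(parts)) ||
          anyNA(suppressWarnings(as.numeric(parts))))
        stop("block ", bi, ": malformed synapse config '", cf, "'",
             call. = FALSE)
      w <- round(as.numeric(parts[2]), 2)
      if (abs(w) > 999.99)
        stop("block ", bi, ": weight ", w, " out of [-999.99, 999.99]",
             call. = FALSE)
      list(id = as.integer(round(as.numeric(parts[1]))), w = w,
           d = min(max(round(as.numeric(parts[3]), 2), 0.01), 19.99))
    })
    ins <- parsed[-length(parsed)]
    out <- parsed[[length(parsed)]]
    list(presyn = vapply(ins, function(s) s$id %% n_inputs, integer(1)),
         weight = vapply(ins, `[[`, numeric(1), "w"),
         delay = vapply(ins, `[[`, numeric(1), "d"),
         out_weight = out$w, out_delay = out$d)
  })
  snn_topology(n_inputs, hidden)
}

#' Serialize a topology back into a word
#'
#' Inverse of [parse_word()]: renders every weight and delay with exactly
#' two decimals, so values are pre-rounded to 0.01 precision.
#' `parse_word(serialize_topology(t), t$n_inputs)` is the identity on
#' topologies whose parameters respect that precision and the stated
#' weight/delay ranges.
#'
#' @param topology An [snn_topology()] object.
#' @return A single word string.
#' @export
serialize_topology <- function(topology) {
  stopifnot(inherits(topology, "snn_topology"))
  paste0(vapply(topology$hidden, function(h) {
    paste0(paste0(sprintf("%d@%.2f@%.2f(", h$presyn, h$weight, h$delay),
                  collapse = ""),
           sprintf("0@%.2f@%.2f{", h$out_weight, h$out_delay))
  }, character(1)), collapse = "")
}

#' Write / read a topology JSON sidecar
#'
#' Plain JSON serialization of a designed network (input count plus the
#' hidden neurons' synapse tables, weights and delays at 2-decimal
#' precision), for interchange alongside the word form.
#'
#' @param topology An [snn_topology()] object.
#' @param path Output (input) file path.
#' @return `write_topology_json()` returns `path` invisibly;
#'   `read_topology_json()` returns an [snn_topology()].
#' @export
write_topology_json <- function(topology, path) {
  stopifnot(inherits(topology, "snn_topology"))
  obj <- list(
    n_inputs = topology$n_inputs,
    hidden = lapply(topology$hidden, function(h) list(
      inputs = data.frame(presyn = h$presyn,
                          weight = round(h$weight, 2),
                          delay = round(h$delay, 2)),
      output = list(weight = round(h$out_weight, 2),
                    delay = round(h$out_delay, 2)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  hidden <- lapply(seq_len(nrow_or_len(obj$hidden)), function(i) {
    h <- pick_row(obj$hidden, i)
    list(presyn = as.integer(h$inputs$presyn),
         weight = as.numeric(h$inputs$weight),
         delay = as.numeric(h$inputs$delay),
         out_weight = as.numeric(h$output$weight),
         out_delay = as.numeric(h$output$delay))
  })
  snn_topology(as.integer(obj$n_inputs), hidden)
}

# jsonlite may simplify the hidden list to a data frame; normalize access
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
pick_row <- function(x, i) {
  if (is.data.frame(x)) {
    list(inputs = x$inputs[[i]],
         output = list(weight = x$output$weight[i],
                       delay = x$output$delay[i]))
  } else x[[i]]
}
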