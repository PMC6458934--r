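#' Parse a grammar in Backus-Naur form
#'
#' Reads rules of the form `<nt> ::= alt1 | alt2 | ...`, one rule per line
#' (continuation lines starting with `|` extend the previous rule; `#`
#' starts a comment). Symbols in an alternative are either nonterminals
#' `<name>` or terminals, optionally double-quoted. The textual order of
#' alternatives is significant: it defines the codon indexing used by
#' [map_genotype()]. The start symbol is the first rule's left-hand side.
#'
#' @param text Grammar source: a file path, or a character vector of lines.
#' @return An object of class `"bnf_grammar"`: a list with `start` and
#'   `rules` (a named list; each element is a list of alternatives, each
#'   alternative a character vector of symbols, nonterminals kept in angle
#'   brackets).
#' @examples
#' g <- load_grammar(c("<s> ::= a | b"))
#' g$rules[["<s>"]]
#' @export
load_grammar <- function(text) {
  if (length(text) == 1L && !grepl("::=", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  text <- unlist(strsplit(text, "\n", fixed = TRUE))
  if (length(text) == 0L || !any(nzchar(trimws(text))))
    stop("empty grammar text", call. = FALSE)
  text <- sub("#.*$", "", text)
  rules <- list()
  current <- NULL
  for (ln in seq_along(text)) {
    line <- trimws(text[ln])
    if (!nzchar(line)) next
    if (grepl("::=", line, fixed = TRUE)) {
      m <- regmatches(line, regexec("^<([^<>]+)>\\s*::=(.*)$", line))[[1]]
      if (length(m) == 0L)
        stop("line ", ln, ": malformed rule '", line, "'", call. = FALSE)
      current <- paste0("<", m[2], ">")
      rules[[current]] <- c(rules[[current]], .bnf_alternatives(m[3], ln))
    } else if (startsWith(line, "|")) {
      if (is.null(current))
        stop("line ", ln, ": continuation with no preceding rule",
             call. = FALSE)
      rules[[current]] <- c(rules[[current]],
                            .bnf_alternatives(sub("^\\|", "", line), ln))
    } else {
      stop("line ", ln, ": expected a rule or continuation, got '", line,
           "'", call. = FALSE)
    }
  }
  if (length(rules) == 0L) stop("grammar defines no rules", call. = FALSE)
  for (nt in names(rules)) {
    if (length(rules[[nt]]) == 0L)
      stop("nonterminal ", nt, " has an empty production list", call. = FALSE)
    for (alt in rules[[nt]]) {
      refs <- alt[grepl("^<.+>$", alt)]
      undef <- setdiff(refs, names(rules))
      if (length(undef))
        stop("undefined nonterminal ", undef[1], " referenced by ", nt,
             call. = FALSE)
    }
  }
  structure(list(start = names(rules)[1], rules = rules),
            class = "bnf_grammar")
}

# Split one right-hand side into alternatives, each a symbol vector.
.bnf_alternatives <- function(rhs, ln) {
  alts <- strsplit(rhs, "|", fixed = TRUE)[[1]]
  lapply(alts, function(a) {
    a <- trimws(a)
    if (!nzchar(a))
      stop("line ", ln, ": empty alternative", call. = FALSE)
    toks <- regmatches(a, gregexpr('<[^<>]+>|"[^"]*"|[^[:space:]"<>]+', a))[[1]]
    vapply(toks, function(tk) {
      if (startsWith(tk, "\"")) substr(tk, 2, nchar(tk) - 1) else tk
    }, character(1), USE.NAMES = FALSE)
  })
}

#' @export
print.bnf_grammar <- function(x, ...) {
  cat("BNF grammar:", length(x$rules), "nonterminals, start symbol",
      x$start, "\n")
  invisible(x)
}

#' The package's SNN design grammar
#'
#' Loads the shipped grammar whose words describe partially connected
#' three-layer SNNs in the `{`/`(`/`@` dialect: each `{`-terminated block is
#' one hidden neuron; `(`-separated configs inside a block are its synapses
#' (the last one is the output synapse); each config is
#' `id@weight@delay`. By construction weights lie in
#' `[-999.99, 999.99]` and delays (after clamping) in `[0.01, 19.99]` ms,
#' at 0.01 resolution.
#'
#' @return A `"bnf_grammar"` object with start symbol `<architecture>`.
#' @examples
#' snn_grammar()
#' @export
snn_grammar <- function() {
  load_grammar(system.file("extdata", "snn.bnf", package = "gesnn",
                           mustWork = TRUE))
}

#' Map a codon genotype to a word
#'
#' Standard grammatical-evolution depth-first mapping: the derivation always
#' rewrites the left-most nonterminal; at every choice point with `k > 1`
#' alternatives the next unconsumed codon `c` selects alternative
#' `c mod k` (0-based) and is consumed; single-alternative rules consume no
#' codon. There is no genotype wrapping: if the codons are exhausted while a
#' choice point remains, the individual is invalid and `NA` is returned.
#'
#' @param genotype Integer vector of codons, each in `[0, 255]`.
#' @param grammar A `"bnf_grammar"` object.
#' @return The derived word as a single string, or `NA_character_` for an
#'   invalid (non-terminating) genotype.
#' @examples
#' map_genotype(5, load_grammar("<s> ::= a | b"))  # 5 mod 2 = 1 -> "b"
#' @export
map_genotype <- function(genotype, grammar) {
  stopifnot(inherits(grammar, "bnf_grammar"))
  codons <- as.integer(genotype)
  if (anyNA(codons) || any(codons < 0L | codons > 255L))
    stop("codons must be integers in [0, 255]", call. = FALSE)
  rules <- grammar$rules
  ci <- 1L
  nc <- length(codons)
  # explicit symbol stack (top = last element), terminals collected in order
  stack <- grammar$start
  out <- character(0)
  nout <- 0L
  while (length(stack)) {
    sym <- stack[length(stack)]
    stack <- stack[-length(stack)]
    alts <- rules[[sym]]
    if (is.null(alts)) {            # terminal
      nout <- nout + 1L
      out[nout] <- sym
      next
    }
    k <- length(alts)
    if (k > 1L) {
      if (ci > nc) return(NA_character_)   # codons exhausted at a choice point
      choice <- codons[ci] %% k + 1L
      ci <- ci + 1L
    } else choice <- 1L
    stack <- c(stack, rev(alts[[choice]]))
  }
  paste0(out[seq_len(nout)], collapse = "")
}
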