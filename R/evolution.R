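#' Search engine configurations
#'
#' Constructors for the two engine settings. Defaults follow the design
#' protocol: 100 individuals, 8-bit codons; GA uses K-tournament selection
#' (K = 5), 10% elitism, one-point crossover and per-bit negation mutation
#' at 5%; DE searches the real box `[0, 255]^500` with DE/Rand/1 mutation,
#' binomial crossover at rate 0.10 and greedy selection. The differential
#' weight `F = 0.5` is the customary default. The evaluation `budget`
#' defaults to a desk-scale 10,000 fitness calls; the full protocol uses
#' 1,000,000.
#'
#' @param population Population size.
#' @param budget Maximum number of fitness evaluations.
#' @param bits_per_codon Codon width in bits (GA).
#' @param n_codons Genotype length in codons; the GA genome has
#'   `n_codons * bits_per_codon` bits (4000 by default).
#' @param tournament_k Tournament size (GA).
#' @param elitism_fraction Fraction of the population copied unchanged each
#'   generation (GA).
#' @param mutation_rate Independent per-bit flip probability (GA).
#' @param crossover_rate Binomial crossover rate CR (DE).
#' @param F Differential weight of DE/Rand/1.
#' @param domain Lower/upper bounds of the DE search box.
#' @return A list of class `"ga_config"` or `"de_config"`.
#' @export
ga_config <- function(population = 100, budget = 10000, bits_per_codon = 8,
                      n_codons = 500, tournament_k = 5,
                      elitism_fraction = 0.10, mutation_rate = 0.05) {
  stopifnot(population >= 2, budget >= population, bits_per_codon >= 1,
            n_codons >= 1, tournament_k >= 1,
            elitism_fraction >= 0, elitism_fraction < 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(population = as.integer(population), budget = budget,
                 bits_per_codon = as.integer(bits_per_codon),
                 n_codons = as.integer(n_codons),
                 genome_bits = as.integer(n_codons * bits_per_codon),
                 tournament_k = as.integer(tournament_k),
                 elitism_fraction = elitism_fraction,
                 mutation_rate = mutation_rate),
            class = "ga_config")
}

#' @rdname ga_config
#' @export
de_config <- function(population = 100, budget = 10000, n_codons = 500,
                      crossover_rate = 0.10, F = 0.5,
                      domain = c(0, 255)) {
  stopifnot(population >= 4, budget >= population, n_codons >= 1,
            crossover_rate > 0, crossover_rate <= 1, F > 0,
            length(domain) == 2L, domain[1] < domain[2])
  structure(list(population = as.integer(population), budget = budget,
                 n_codons = as.integer(n_codons),
                 crossover_rate = crossover_rate, F = F, domain = domain),
            class = "de_config")
}

#' K-tournament selection
#'
#' Draws `k` candidates uniformly with replacement and returns the index of
#' the minimum-fitness candidate (fitness is minimized throughout).
#'
#' @param fitnesses Numeric vector of population fitnesses.
#' @param k Tournament size.
#' @return The selected population index.
#' @export
tournament_select <- function(fitnesses, k = 5) {
  if (length(fitnesses) == 0L) stop("empty population", call. = FALSE)
  stopifnot(k >= 1)
  draws <- sample.int(length(fitnesses), k, replace = TRUE)
  draws[which.min(fitnesses[draws])]
}

# MSB-first grouping of a 0/1 bit vector into integer codons.
bits_to_codons <- function(bits, bits_per_codon = 8L) {
  m <- matrix(bits, ncol = bits_per_codon, byrow = TRUE)
  as.integer(m %*% 2^((bits_per_codon - 1L):0L))
}

#' Genetic algorithm search over bitstring genotypes
#'
#' Generational GA with elitism: each generation the top
#' `ceiling(elitism_fraction * population)` individuals are copied unchanged
#' (their cached fitness is reused, not re-evaluated); the remainder is
#' produced by K-tournament selection, one-point crossover and independent
#' per-bit negation mutation. Bits are grouped MSB-first into codons before
#' each fitness evaluation. The search stops when the evaluation budget is
#' exhausted; a final partial generation is topped up with the best
#' remaining parents so the population size is conserved.
#'
#' @param fitness_fn A function `codons -> numeric` fitness (minimized).
#'   Called exactly once per newly created individual.
#' @param config A [ga_config()].
#' @param seed Integer seed; the same seed reproduces the search
#'   bit-for-bit.
#' @return A list of class `"snn_search"`: `best_genotype` (codons),
#'   `best_fitness`, `history` (best-so-far fitness after initialization
#'   and after each generation; non-increasing), `evaluations`, `engine`.
#' @export
ga_search <- function(fitness_fn, config = ga_config(), seed = 1L) {
  stopifnot(inherits(config, "ga_config"), is.function(fitness_fn))
  with_seed(seed, {
    pop_n <- config$population
    nb <- config$genome_bits
    evals <- 0L
    eval_bits <- function(bits) {
      evals <<- evals + 1L
      fitness_fn(bits_to_codons(bits, config$bits_per_codon))
    }
    pop <- matrix(sample(0:1, pop_n * nb, replace = TRUE), nrow = pop_n)
    fit <- apply(pop, 1, eval_bits)
    history <- min(fit)
    n_elite <- ceiling(config$elitism_fraction * pop_n)
    n_child <- pop_n - n_elite
    while (evals < config$budget) {
      n_new <- min(n_child, config$budget - evals)
      ord <- order(fit)
      children <- matrix(0L, n_new, nb)
      ci <- 0L
      while (ci < n_new) {
        p1 <- pop[tournament_select(fit, config$tournament_k), ]
        p2 <- pop[tournament_select(fit, config$tournament_k), ]
        cp <- sample.int(nb - 1L, 1L)
        c1 <- c(p1[1:cp], p2[(cp + 1L):nb])
        c2 <- c(p2[1:cp], p1[(cp + 1L):nb])
        for (child in list(c1, c2)) {
          if (ci >= n_new) break
          flip <- runif(nb) < config$mutation_rate
          child[flip] <- 1L - child[flip]
          ci <- ci + 1L
          children[ci, ] <- child
        }
      }
      child_fit <- apply(children, 1, eval_bits)
      # elites (and budget-shortfall fill) carry cached fitness forward
      keep <- ord[seq_len(pop_n - n_new)]
      pop <- rbind(pop[keep, , drop = FALSE], children)
      fit <- c(fit[keep], child_fit)
      history <- c(history, min(history[length(history)], min(fit)))
    }
    best <- which.min(fit)
    structure(list(best_genotype = bits_to_codons(pop[best, ],
                                                  config$bits_per_codon),
                   best_fitness = fit[best], history = history,
                   evaluations = evals, engine = "ga", seed = seed,
                   population = t(apply(pop, 1, bits_to_codons,
                                        config$bits_per_codon)),
                   population_fitness = fit),
              class = "snn_search")
  })
}

#' Differential evolution search over real-coded genotypes
#'
#' DE/Rand/1 with binomial crossover and greedy selection: for each target
#' vector a mutant `v = x_r1 + F (x_r2 - x_r3)` is built from three distinct
#' random members, clamped into the search box, and recombined with the
#' target at rate CR (one coordinate always taken from the mutant); the
#' trial replaces the target when its fitness is better or equal (ties
#' replace, which lets the population drift across fitness plateaus). Codons
#' are obtained by flooring the real components at evaluation time.
#'
#' @inheritParams ga_search
#' @param config A [de_config()].
#' @return A list of class `"snn_search"` as in [ga_search()], with
#'   `engine = "de"`.
#' @export
de_search <- function(fitness_fn, config = de_config(), seed = 1L) {
  stopifnot(inherits(config, "de_config"), is.function(fitness_fn))
  with_seed(seed, {
    pop_n <- config$population
    d <- config$n_codons
    lo <- config$domain[1]; hi <- config$domain[2]
    evals <- 0L
    eval_vec <- function(x) {
      evals <<- evals + 1L
      fitness_fn(as.integer(floor(x)))
    }
    pop <- matrix(runif(pop_n * d, lo, hi), nrow = pop_n)
    fit <- apply(pop, 1, eval_vec)
    history <- min(fit)
    while (evals < config$budget) {
      for (i in seq_len(pop_n)) {
        if (evals >= config$budget) break
        r <- sample(seq_len(pop_n)[-i], 3L)
        v <- pop[r[1], ] + config$F * (pop[r[2], ] - pop[r[3], ])
        v <- pmin(pmax(v, lo), hi)
        jrand <- sample.int(d, 1L)
        take <- runif(d) < config$crossover_rate
        take[jrand] <- TRUE
        trial <- ifelse(take, v, pop[i, ])
        trial_fit <- eval_vec(trial)
        if (trial_fit <= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- trial_fit
        }
      }
      history <- c(history, min(history[length(history)], min(fit)))
    }
    best <- which.min(fit)
    structure(list(best_genotype = as.integer(floor(pop[best, ])),
                   best_fitness = fit[best], history = history,
                   evaluations = evals, engine = "de", seed = seed,
                   population = floor(pop),
                   population_fitness = fit),
              class = "snn_search")
  })
}

#' @export
print.snn_search <- function(x, ...) {
  cat(toupper(x$engine), "search: best fitness", x$best_fitness, "after",
      x$evaluations, "evaluations (", length(x$history) - 1, "generations )\n")
  invisible(x)
}
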