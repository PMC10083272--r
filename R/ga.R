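#' Genetic algorithm configuration
#'
#' Real-coded GA with tournament selection (size 2), arithmetic
#' crossover, per-gene Gaussian mutation clipped to the bounds, and
#' elitism of one. Defaults follow the study design: population 20 and
#' 200 generations for LS-SVM hyperparameters or 300 for ELM weights.
#'
#' @param population population size (>= 2).
#' @param generations number of generations.
#' @param lower,upper numeric vectors of per-gene bounds (recycled).
#' @param crossover_rate probability a selected pair is crossed.
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_sd mutation standard deviation as a fraction of the
#'   gene's bound width.
#' @param seed integer seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population = 20, generations = 200, lower, upper,
                      crossover_rate = 0.9, mutation_rate = 0.05,
                      mutation_sd = 0.1, seed = 1L) {
  stopifnot(population >= 2, generations >= 1,
            length(lower) == length(upper) || length(lower) == 1 ||
              length(upper) == 1)
  n_genes <- max(length(lower), length(upper))
  lower <- rep_len(lower, n_genes); upper <- rep_len(upper, n_genes)
  stopifnot(all(is.finite(lower)), all(is.finite(upper)), all(lower < upper))
  structure(list(population = population, generations = generations,
                 lower = lower, upper = upper,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Minimize a fitness function with a real-coded genetic algorithm
#'
#' @param fitness function taking a genome (numeric vector within the
#'   bounds) and returning a finite score to minimize.
#' @param config a [ga_config()].
#' @return List: `genome` (best-ever), `fitness` (its score), `path`
#'   (best-so-far fitness per generation, non-increasing by elitism).
#' @export
ga_optimize <- function(fitness, config) {
  stopifnot(inherits(config, "ga_config"))
  lo <- config$lower; hi <- config$upper
  g <- length(lo); np <- config$population
  with_seed(config$seed, {
    pop <- matrix(stats::runif(np * g, lo, hi), np, g, byrow = TRUE)
    fit <- apply(pop, 1, fitness)
    best_i <- which.min(fit)
    best <- list(genome = pop[best_i, ], fitness = fit[best_i])
    path <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      newpop <- matrix(0, np, g)
      newpop[1, ] <- best$genome                       # elitism
      for (i in seq(2, np)) {
        p1 <- tournament(fit)
        p2 <- tournament(fit)
        child <- pop[p1, ]
        if (stats::runif(1) < config$crossover_rate) {
          a <- stats::runif(g)
          child <- a * pop[p1, ] + (1 - a) * pop[p2, ]
        }
        mut <- stats::runif(g) < config$mutation_rate
        if (any(mut))
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, config$mutation_sd * (hi - lo)[mut])
        newpop[i, ] <- pmin(pmax(child, lo), hi)
      }
      pop <- newpop
      fit <- apply(pop, 1, fitness)
      gen_best <- which.min(fit)
      if (fit[gen_best] < best$fitness)
        best <- list(genome = pop[gen_best, ], fitness = fit[gen_best])
      path[gen] <- best$fitness
    }
    list(genome = best$genome, fitness = best$fitness, path = path)
  })
}

tournament <- function(fit) {
  i <- sample.int(length(fit), 2)
  i[which.min(fit[i])]
}
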