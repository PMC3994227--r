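#' Genetic algorithm parameters
#'
#' Defaults follow the standard configuration for this search: population 50,
#' 100 generations, one-point mutation probability 0.1 per position, and
#' selection/crossover exchange probabilities of 1 (crossover is always
#' applied, with a fair-coin uniform mask).
#'
#' @param order Model size `d` searched.
#' @param population_size Number of chromosomes kept (>= 2).
#' @param generations Number of generations (>= 1).
#' @param mutation_rate Per-position mutation probability in `[0, 1]`.
#' @param crossover_exchange_prob,selection_exchange_prob Exchange
#'   probabilities; retained for configurability, default 1.
#' @param top_k Size of the ranked distinct-model ledger kept by [run_ga()].
#' @param seed RNG seed; a run is fully deterministic given the seed.
#' @return An object of class `ga_params`.
#' @export
ga_params <- function(order, population_size = 50L, generations = 100L,
                      mutation_rate = 0.1, crossover_exchange_prob = 1,
                      selection_exchange_prob = 1, top_k = 10L, seed = NULL) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  stopifnot(population_size >= 2L, generations >= 1L,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_exchange_prob >= 0, crossover_exchange_prob <= 1,
            selection_exchange_prob >= 0, selection_exchange_prob <= 1)
  structure(list(order = as.integer(order),
                 population_size = population_size,
                 generations = generations, mutation_rate = mutation_rate,
                 crossover_exchange_prob = crossover_exchange_prob,
                 selection_exchange_prob = selection_exchange_prob,
                 top_k = as.integer(top_k), seed = seed),
            class = "ga_params")
}

#' Initialize a random population of valid models
#'
#' Each chromosome is a uniformly random valid model of order `d`: its SNPs
#' are drawn without replacement and each genotype code uniformly, so every
#' one of the `choose(n_snps, d) * n_genotypes^d` valid models is equally
#' likely (element order randomized by the draw).
#'
#' @param params A [ga_params()].
#' @param n_snps,n_genotypes Dimensions of the model space.
#' @return List of `population_size` [snp_model()] objects.
#' @export
initialize_population <- function(params, n_snps, n_genotypes = 3L) {
  d <- params$order
  if (d > n_snps) stop("model order exceeds number of SNPs")
  lapply(seq_len(params$population_size), function(i) {
    snp_model(sample.int(n_snps, d),
              sample.int(n_genotypes, d, replace = TRUE))
  })
}

#' Select the two parents by fitness rank
#'
#' Deterministic rank-based selection: chromosomes are ranked by fitness from
#' largest to smallest and the top two are the parents. Ties are broken by
#' population index (lower index wins).
#'
#' @param population List of [snp_model()] chromosomes.
#' @param fitnesses Numeric vector of their fitness values.
#' @return Integer vector of length 2: indices of parent 1 and parent 2.
#' @export
select_parents <- function(population, fitnesses) {
  if (length(population) < 2L) stop("population must hold at least 2 chromosomes")
  stopifnot(length(fitnesses) == length(population))
  order(-fitnesses)[1:2]                   # stable sort: ties keep index order
}

#' Uniform crossover of two parent chromosomes
#'
#' A binary mask of `d` fair-coin bits is drawn (or supplied); at every
#' position where the mask is 1 the parents' elements are exchanged.
#' Offspring may repeat a SNP — they are kept as-is and scored zero by the
#' fitness function rather than repaired.
#'
#' @param parent1,parent2 [snp_model()]s of equal order.
#' @param mask Optional integer/logical vector of length `d`; drawn from the
#'   RNG when `NULL`.
#' @return List with `offspring1`, `offspring2`, `mask`.
#' @export
uniform_crossover <- function(parent1, parent2, mask = NULL) {
  d <- model_order(parent1)
  if (model_order(parent2) != d) stop("parents must have equal order")
  if (is.null(mask)) mask <- sample(0:1, d, replace = TRUE)
  stopifnot(length(mask) == d)
  swap <- as.logical(mask)
  o1s <- parent1$snps; o1g <- parent1$genotypes
  o2s <- parent2$snps; o2g <- parent2$genotypes
  o1s[swap] <- parent2$snps[swap]; o1g[swap] <- parent2$genotypes[swap]
  o2s[swap] <- parent1$snps[swap]; o2g[swap] <- parent1$genotypes[swap]
  list(offspring1 = snp_model(o1s, o1g),
       offspring2 = snp_model(o2s, o2g),
       mask = as.integer(mask))
}

#' Eligible replacement elements for a mutation point
#'
#' When position `position` of a chromosome mutates, the replacement is drawn
#' uniformly from the (SNP, genotype) pairs whose SNP is not used at any
#' *other* position — the mutating position's own SNP stays eligible, so a
#' mutation can also just change the genotype.
#'
#' @param model The chromosome being mutated.
#' @param position Mutation point (1-based).
#' @param n_snps,n_genotypes Dimensions of the model space.
#' @return Data frame with columns `snp`, `genotype`, one row per candidate,
#'   ordered by SNP then genotype.
#' @export
mutation_candidates <- function(model, position, n_snps, n_genotypes = 3L) {
  used <- model$snps[-position]
  free <- setdiff(seq_len(n_snps), used)
  if (!length(free)) stop("no eligible replacement element")
  data.frame(snp = rep(free, each = n_genotypes),
             genotype = rep(seq_len(n_genotypes), length(free)))
}

#' One-point mutation of a chromosome
#'
#' Each position mutates independently with probability `mutation_rate` (or
#' at the explicitly supplied `points`). A mutating position is replaced by
#' an element drawn uniformly from [mutation_candidates()] at that position.
#'
#' @param model Chromosome to mutate.
#' @param mutation_rate Per-position mutation probability.
#' @param n_snps,n_genotypes Dimensions of the model space.
#' @param points Optional explicit 0/1 vector of mutation points; drawn from
#'   the RNG when `NULL`.
#' @return The (possibly) mutated [snp_model()].
#' @export
mutate_model <- function(model, mutation_rate, n_snps, n_genotypes = 3L,
                         points = NULL) {
  d <- model_order(model)
  if (is.null(points)) points <- as.integer(stats::runif(d) < mutation_rate)
  stopifnot(length(points) == d)
  for (pos in which(as.logical(points))) {
    cand <- mutation_candidates(model, pos, n_snps, n_genotypes)
    pick <- cand[sample.int(nrow(cand), 1L), ]
    model$snps[pos] <- pick$snp
    model$genotypes[pos] <- pick$genotype
  }
  model
}

#' Steady-state replacement of the worst population members
#'
#' Each offspring, taken in turn, replaces the currently worst population
#' member if the offspring's fitness is strictly higher than that member's;
#' otherwise the offspring is discarded. Population size is constant and the
#' best member can never be displaced (elitism).
#'
#' @param population List of chromosomes.
#' @param fitnesses Their fitness values.
#' @param offspring List of offspring chromosomes.
#' @param offspring_fitnesses Their fitness values.
#' @return List with updated `population` and `fitnesses`.
#' @export
replace_population <- function(population, fitnesses, offspring,
                               offspring_fitnesses) {
  for (i in seq_along(offspring)) {
    worst <- which.min(fitnesses)
    if (offspring_fitnesses[i] > fitnesses[worst]) {
      population[[worst]] <- offspring[[i]]
      fitnesses[worst] <- offspring_fitnesses[i]
    }
  }
  list(population = population, fitnesses = fitnesses)
}

#' Run the genetic algorithm search
#'
#' Executes the six-step loop: initialize, then per generation evaluate,
#' select the two best parents, uniform crossover, one-point mutation, and
#' steady-state replacement of the worst members. Population fitnesses are
#' cached, so each generation costs two fitness evaluations. The run is
#' fully deterministic given `params$seed` and leaves the caller's RNG state
#' untouched when a seed is set.
#'
#' @param dataset A [genotype_dataset()].
#' @param params A [ga_params()].
#' @return An object of class `ga_result`: `best_model` (the best *valid*
#'   model evaluated, in canonical notation with SNPs ascending),
#'   `best_fitness` (its [fitness()] value), `top_k` (data frame ledger of
#'   the best distinct valid models seen, ranked by fitness with ties broken
#'   by notation), `history` (best-so-far population fitness after each
#'   generation, non-decreasing), `evaluations` (fitness calls), `params`.
#' @export
run_ga <- function(dataset, params) {
  stopifnot(inherits(dataset, "genotype_dataset"), inherits(params, "ga_params"))
  S <- n_snps(dataset); G <- dataset$n_genotypes
  if (params$order > S) stop("model order exceeds number of SNPs")

  with_rng(params$seed, {
    evals <- 0L
    ledger <- new.env(parent = emptyenv())
    eval_model <- function(m) {
      f <- fitness(m, dataset)
      evals <<- evals + 1L
      if (f$valid) {
        key <- model_key(m)
        if (is.null(ledger[[key]]))
          ledger[[key]] <- list(model = m, fitness = f)
      }
      f$value
    }

    pop <- initialize_population(params, S, G)
    fits <- vapply(pop, eval_model, numeric(1))
    history <- numeric(params$generations)
    for (gen in seq_len(params$generations)) {
      par_idx <- select_parents(pop, fits)
      cx <- uniform_crossover(pop[[par_idx[1]]], pop[[par_idx[2]]])
      off <- list(
        mutate_model(cx$offspring1, params$mutation_rate, S, G),
        mutate_model(cx$offspring2, params$mutation_rate, S, G))
      off_fits <- vapply(off, eval_model, numeric(1))
      upd <- replace_population(pop, fits, off, off_fits)
      pop <- upd$population; fits <- upd$fitnesses
      history[gen] <- max(fits)
    }

    # Rank the distinct valid models seen; the reported best model is the
    # ledger top in canonical notation (SNPs ascending). The raw population
    # optimum can be an invalid zero-fitness chromosome when every valid
    # model scores negative; such chromosomes are not reportable models.
    entries <- as.list(ledger)
    lfit <- vapply(entries, function(e) e$fitness$value, numeric(1))
    ord <- order(-lfit, names(entries))    # fitness desc, ties by notation
    top <- ord[seq_len(min(params$top_k, length(ord)))]
    top_k <- data.frame(
      model = names(entries)[top],
      fitness = lfit[top],
      case_count = vapply(entries[top], function(e) e$fitness$case_count, integer(1)),
      control_count = vapply(entries[top], function(e) e$fitness$control_count, integer(1)),
      stringsAsFactors = FALSE)
    rownames(top_k) <- NULL
    best_model <- parse_snp_model(top_k$model[1])

    structure(list(best_model = best_model,
                   best_fitness = entries[[ord[1]]]$fitness,
                   top_k = top_k, history = history,
                   evaluations = evals, params = params),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> order %d: best %s, fitness %.4f (%d evaluations)\n",
              x$params$order, format(x$best_model), x$best_fitness$value,
              x$evaluations))
  invisible(x)
}
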