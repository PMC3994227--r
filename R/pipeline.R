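#' Pipeline run configuration
#'
#' Describes one end-to-end run: the input cohort (a file path or a
#' [synthetic_cohort_spec()]), the model orders to search, GA settings, and
#' where to write reports. Validated again against the dataset dimensions at
#' run time, before any computation.
#'
#' @param input Path to a genotype CSV/TSV, or a [synthetic_cohort_spec()].
#' @param orders Integer vector of model sizes to search (each >= 2 is
#'   typical; must not exceed the SNP count of the input).
#' @param out_dir Output directory; created if missing.
#' @param seed Master seed. Per-order GA seeds are derived as
#'   `seed + order` so that each order's search is independent and
#'   reproducible.
#' @param population_size,generations,mutation_rate,top_k GA settings,
#'   see [ga_params()].
#' @param alleles Optional allele declaration forwarded to
#'   [read_genotype_table()].
#' @param verbose Logical; per-order progress messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, orders, out_dir, seed,
                       population_size = 50L, generations = 100L,
                       mutation_rate = 0.1, top_k = 10L,
                       alleles = NULL, verbose = FALSE) {
  orders <- as.integer(orders)
  if (!length(orders)) stop("at least one order must be requested")
  if (any(orders < 1L)) stop("orders must be positive")
  structure(list(input = input, orders = sort(unique(orders)),
                 out_dir = out_dir, seed = as.integer(seed),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate, top_k = as.integer(top_k),
                 alleles = alleles, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' The file mirrors [run_config()] fields; a `synthetic:` block
#' (`n_case`, `n_control`, `snp_mafs`, optional `embedded_model` in
#' `"SNP(1,4):2-2"` notation with `target_freq_case`/`target_freq_control`)
#' may replace `input:`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- y$input
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    em <- if (!is.null(s$embedded_model)) parse_snp_model(s$embedded_model)
    input <- synthetic_cohort_spec(
      s$n_case, s$n_control, as.numeric(s$snp_mafs),
      embedded_model = em,
      target_freq_case = s$target_freq_case,
      target_freq_control = s$target_freq_control,
      seed = if (!is.null(s$seed)) s$seed else y$seed)
  }
  if (is.null(input)) stop("config needs 'input' or a 'synthetic' block")
  run_config(input,
             orders = y$orders, out_dir = y$out_dir, seed = y$seed,
             population_size = y$population_size %||% 50L,
             generations = y$generations %||% 100L,
             mutation_rate = y$mutation_rate %||% 0.1,
             top_k = y$top_k %||% 10L,
             alleles = y$alleles, verbose = y$verbose %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_input <- function(config) {
  if (inherits(config$input, "synthetic_cohort_spec")) {
    generate_synthetic_cohort(config$input)
  } else if (is.character(config$input)) {
    read_genotype_table(config$input, alleles = config$alleles)
  } else if (inherits(config$input, "genotype_dataset")) {
    config$input
  } else stop("unsupported input type")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full search-and-report pipeline
#'
#' Loads (or simulates) the cohort, runs one GA per requested order (seeded
#' `seed + order`), and writes four artifacts to `out_dir`:
#' `single_snp.tsv` (per-genotype association vs the reference genotype),
#' `top_models_order<d>.tsv` (ranked distinct models from each GA run),
#' `best_models.tsv` (formatted association summary of the best model per
#' order), and `results.json` (full-precision values, seed and parameters).
#' Outputs are a pure function of (input, config, seed); on any failure the
#' partially written files are removed and the error is re-thrown.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `dataset`, `ga_results`, `summary`, and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dataset <- resolve_input(config)
  if (max(config$orders) > n_snps(dataset))
    stop("requested order ", max(config$orders), " exceeds the ",
         n_snps(dataset), " SNPs in the input")

  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  written <- character(0)
  done <- FALSE
  on.exit(if (!done) unlink(written), add = TRUE)

  # Table 1 analog: every SNP, genotype counts and per-genotype tests
  single <- do.call(rbind, lapply(seq_len(n_snps(dataset)),
                                  function(j) single_snp_association(dataset, j)))
  written <- c(written, write_tsv(single, file.path(config$out_dir, "single_snp.tsv")))

  # One GA per order
  ga_results <- lapply(config$orders, function(d) {
    p <- ga_params(order = d, population_size = config$population_size,
                   generations = config$generations,
                   mutation_rate = config$mutation_rate,
                   top_k = config$top_k, seed = config$seed + d)
    res <- run_ga(dataset, p)
    if (config$verbose)
      message(sprintf("order %d: best %s fitness %.4f", d,
                      format(res$best_model), res$best_fitness$value))
    f <- file.path(config$out_dir, sprintf("top_models_order%d.tsv", d))
    written <<- c(written, write_tsv(res$top_k, f))
    res
  })
  names(ga_results) <- paste0("order", config$orders)

  # Table 3 analog: best model per order with association statistics
  best_models <- lapply(ga_results, function(r) r$best_model)
  summary <- summarize_best_models(dataset, best_models)
  written <- c(written,
               write_tsv(format_best_models(summary),
                         file.path(config$out_dir, "best_models.tsv")))

  json <- list(
    seed = config$seed,
    params = list(population_size = config$population_size,
                  generations = config$generations,
                  mutation_rate = config$mutation_rate,
                  orders = config$orders, top_k = config$top_k),
    n_case = n_case(dataset), n_control = n_control(dataset),
    snp_names = dataset$snp_names,
    single_snp = single,
    ga = lapply(ga_results, function(r)
      list(best_model = format(r$best_model),
           best_fitness = r$best_fitness$value,
           history = r$history, evaluations = r$evaluations,
           top_k = r$top_k)),
    best_model_summary = summary)
  jpath <- file.path(config$out_dir, "results.json")
  jsonlite::write_json(json, jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, jpath)

  done <- TRUE
  invisible(list(dataset = dataset, ga_results = ga_results,
                 summary = summary, files = written))
}

#' Compare GA results against the exhaustive oracle
#'
#' For every requested order and seed, runs the GA and checks whether its
#' best fitness equals the exhaustive-search optimum on the same dataset
#' (within numerical tolerance). Aggregates a per-order hit rate. This is
#' the acceptance harness for the GA on small panels, where the full model
#' space is enumerable.
#'
#' @param dataset A [genotype_dataset()].
#' @param orders Integer vector of model sizes.
#' @param seeds Integer vector of GA seeds tried per order.
#' @param population_size,generations,mutation_rate GA settings.
#' @param max_models Guard on the oracle's model-space size.
#' @return Data frame: `order`, `n_models`, `oracle_fitness`, `n_seeds`,
#'   `hits`, `hit_rate`, `monotone` (fraction of runs with non-decreasing
#'   best-so-far history).
#' @export
verify_against_oracle <- function(dataset, orders, seeds = 1:20,
                                  population_size = 50L, generations = 100L,
                                  mutation_rate = 0.1, max_models = 1e7) {
  rows <- lapply(as.integer(orders), function(d) {
    oracle <- exhaustive_best(dataset, d, k = 1L, max_models = max_models)
    hits <- 0L; mono <- 0L
    for (s in seeds) {
      p <- ga_params(order = d, population_size = population_size,
                     generations = generations,
                     mutation_rate = mutation_rate, seed = s)
      r <- run_ga(dataset, p)
      if (abs(r$best_fitness$value - oracle$fitness[1]) < 1e-12) hits <- hits + 1L
      if (!is.unsorted(r$history)) mono <- mono + 1L
    }
    data.frame(order = d, n_models = attr(oracle, "n_models"),
               oracle_fitness = oracle$fitness[1], n_seeds = length(seeds),
               hits = hits, hit_rate = hits / length(seeds),
               monotone = mono / length(seeds))
  })
  do.call(rbind, rows)
}
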