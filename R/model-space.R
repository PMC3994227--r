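#' Multi-SNP genotype combination model
#'
#' A model (the GA chromosome) is an ordered collection of `d` pairs
#' `(snp_index, genotype_code)` drawn from the product set of SNPs and
#' genotype classes. A model is *valid* when no SNP index is repeated;
#' invalid models are representable (crossover can create them) but score
#' fitness zero.
#'
#' @param snps Integer vector of SNP column indices.
#' @param genotypes Integer vector of genotype codes, same length as `snps`.
#' @return An object of class `snp_model` with fields `snps`, `genotypes`.
#' @examples
#' snp_model(c(1, 4), c(2, 2))   # the pair [SNP1 het, SNP4 het]
#' @export
snp_model <- function(snps, genotypes) {
  snps <- as.integer(snps); genotypes <- as.integer(genotypes)
  if (length(snps) != length(genotypes))
    stop("'snps' and 'genotypes' must have equal length")
  if (length(snps) < 1L) stop("a model needs at least one element")
  if (any(snps < 1L) || any(genotypes < 1L))
    stop("SNP indices and genotype codes are 1-based positive integers")
  structure(list(snps = snps, genotypes = genotypes), class = "snp_model")
}

#' @export
print.snp_model <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Model order (number of SNP-genotype elements)
#' @param model An [snp_model()].
#' @export
model_order <- function(model) length(model$snps)

#' Serialize a model as `"SNP(1,4):2-2"`
#'
#' The text form lists SNP indices then genotype codes, mirroring the usual
#' combined-SNP table notation. [parse_snp_model()] is its inverse and both
#' are bit-stable.
#'
#' @param x An [snp_model()].
#' @param ... Unused.
#' @export
format.snp_model <- function(x, ...) {
  sprintf("SNP(%s):%s", paste(x$snps, collapse = ","),
          paste(x$genotypes, collapse = "-"))
}

#' @rdname format.snp_model
#' @param text A string like `"SNP(1,4):2-2"`.
#' @export
parse_snp_model <- function(text) {
  m <- regmatches(text, regexec("^SNP\\(([0-9,]+)\\):([0-9-]+)$", text))[[1]]
  if (length(m) != 3L) stop("cannot parse model notation: ", text)
  snp_model(as.integer(strsplit(m[2], ",")[[1]]),
            as.integer(strsplit(m[3], "-")[[1]]))
}

# Canonical identity key: element order is irrelevant to what a model tests,
# so sort elements by SNP index.
model_key <- function(model) {
  o <- order(model$snps, model$genotypes)
  sprintf("SNP(%s):%s", paste(model$snps[o], collapse = ","),
          paste(model$genotypes[o], collapse = "-"))
}

#' Is a model valid (no repeated SNP)?
#'
#' A chromosome that selects the same SNP twice does not describe a genotype
#' combination; such models are scored zero by [fitness()].
#'
#' @param model An [snp_model()].
#' @return `TRUE` iff all SNP indices are distinct.
#' @export
is_valid_model <- function(model) {
  !anyDuplicated(model$snps)
}

#' Does an individual's genotype vector match a model?
#'
#' An individual matches (carries) a model when their genotype equals the
#' model's code at every model SNP. An empty element set matches vacuously.
#'
#' @param model An [snp_model()].
#' @param sample_genotypes Integer vector of genotype codes, indexed by SNP.
#' @return `1L` if the individual carries the model, else `0L`.
#' @export
sample_matches_model <- function(model, sample_genotypes) {
  if (max(model$snps) > length(sample_genotypes))
    stop("sample has no genotype for some model SNP")
  as.integer(all(sample_genotypes[model$snps] == model$genotypes))
}

# Logical carrier vector over all individuals; vectorized core used by
# fitness() and model_contingency().
model_match_vector <- function(dataset, model) {
  g <- dataset$genotypes
  if (max(model$snps) > ncol(g))
    stop("model references SNP index outside the dataset")
  hit <- rep(TRUE, nrow(g))
  for (i in seq_along(model$snps))
    hit <- hit & (g[, model$snps[i]] == model$genotypes[i])
  hit
}

#' Fitness of a model on a case-control dataset
#'
#' The fitness of a valid model is the difference between its carrier
#' frequency in cases and in controls: `case_count/N_case -
#' control_count/N_control`, a signed value in `[-1, 1]` (negative values
#' indicate protective combinations and are retained). A model that repeats
#' a SNP is invalid and scores exactly 0.
#'
#' @param model An [snp_model()].
#' @param dataset A [genotype_dataset()].
#' @return An object of class `fitness_value`: list with `value`,
#'   `case_freq`, `control_freq`, `case_count`, `control_count`, `valid`.
#' @examples
#' g <- matrix(c(2, 2, 1, 1, 2, 2, 2, 1), nrow = 4)
#' ds <- genotype_dataset(g, c("case", "case", "control", "control"))
#' fitness(snp_model(c(1, 2), c(2, 2)), ds)$value
#' @export
fitness <- function(model, dataset) {
  if (!is_valid_model(model)) {
    return(structure(list(value = 0, case_freq = NA_real_,
                          control_freq = NA_real_, case_count = NA_integer_,
                          control_count = NA_integer_, valid = FALSE),
                     class = "fitness_value"))
  }
  hit <- model_match_vector(dataset, model)
  is_case <- dataset$labels == "case"
  a <- sum(hit & is_case); b <- sum(hit & !is_case)
  cf <- a / sum(is_case); nf <- b / sum(!is_case)
  structure(list(value = cf - nf, case_freq = cf, control_freq = nf,
                 case_count = a, control_count = b, valid = TRUE),
            class = "fitness_value")
}

#' @export
print.fitness_value <- function(x, ...) {
  if (!x$valid) cat("<fitness> 0 (invalid model: repeated SNP)\n")
  else cat(sprintf("<fitness> %.4f (cases %d, controls %d)\n",
                   x$value, x$case_count, x$control_count))
  invisible(x)
}

#' Enumerate every valid model of a given order
#'
#' Yields each of the `choose(n_snps, order) * n_genotypes^order` valid
#' models exactly once, in lexicographic order by SNP index subset and then
#' by genotype codes.
#'
#' @param n_snps Number of SNPs available.
#' @param n_genotypes Genotype classes per SNP (default 3).
#' @param order Model size `d` with `1 <= order <= n_snps`.
#' @return List of [snp_model()] objects.
#' @export
enumerate_models <- function(n_snps, n_genotypes = 3L, order) {
  n_snps <- as.integer(n_snps); order <- as.integer(order)
  if (order < 1L || order > n_snps)
    stop("'order' must lie in 1..n_snps")
  snp_sets <- utils::combn(n_snps, order, simplify = FALSE)
  # genotype tuples in lexicographic order (first position slowest)
  gt <- as.matrix(rev(expand.grid(rev(replicate(order, seq_len(n_genotypes),
                                                simplify = FALSE)))))
  out <- vector("list", length(snp_sets) * nrow(gt))
  k <- 0L
  for (s in snp_sets) {
    for (r in seq_len(nrow(gt))) {
      k <- k + 1L
      out[[k]] <- snp_model(s, gt[r, ])
    }
  }
  out
}

#' Exhaustive search oracle: top-k models by fitness
#'
#' Scans every valid model of the given order and returns the `k` best by
#' fitness, ties broken by enumeration order. Intended as the ground-truth
#' oracle for validating the genetic algorithm on small SNP panels, and for
#' producing per-order ranked model tables.
#'
#' @param dataset A [genotype_dataset()].
#' @param order Model size.
#' @param k Number of models to return (default 10).
#' @param max_models Refuse to scan a space larger than this (default 1e7).
#' @return A data frame with columns `model` (notation string), `fitness`,
#'   `case_count`, `control_count`, sorted by fitness descending.
#' @export
exhaustive_best <- function(dataset, order, k = 10L, max_models = 1e7) {
  S <- n_snps(dataset); G <- dataset$n_genotypes
  total <- choose(S, order) * G^order
  if (total > max_models)
    stop("model space has ", format(total, big.mark = ","),
         " models, above the ceiling of ", format(max_models, big.mark = ","))
  models <- enumerate_models(S, G, order)
  fits <- vapply(models, function(m) fitness(m, dataset)$value, numeric(1))
  ord <- order(-fits)                      # stable: ties keep enumeration order
  top <- ord[seq_len(min(k, length(ord)))]
  res <- data.frame(
    model = vapply(models[top], format, character(1)),
    fitness = fits[top],
    stringsAsFactors = FALSE)
  counts <- lapply(models[top], function(m) fitness(m, dataset))
  res$case_count <- vapply(counts, `[[`, integer(1), "case_count")
  res$control_count <- vapply(counts, `[[`, integer(1), "control_count")
  attr(res, "n_models") <- length(models)
  res
}
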