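#' Specification of a synthetic case-control cohort
#'
#' Describes a simulated cohort: group sizes, per-SNP minor allele
#' frequencies in the background population, and optionally a multi-SNP risk
#' model embedded at different carrier frequencies in cases and controls.
#'
#' @param n_case,n_control Group sizes (each at least 1).
#' @param snp_mafs Numeric vector of minor-allele frequencies, one per SNP,
#'   each in (0, 0.5).
#' @param embedded_model Optional [snp_model()] to plant in the cohort.
#' @param target_freq_case,target_freq_control Carrier frequency of the
#'   embedded model in cases and controls. Required with `embedded_model`;
#'   must satisfy `0 <= target_freq_control <= target_freq_case <= 1`.
#' @param seed Optional RNG seed making generation reproducible.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_case, n_control, snp_mafs,
                                  embedded_model = NULL,
                                  target_freq_case = NULL,
                                  target_freq_control = NULL,
                                  seed = NULL) {
  n_case <- as.integer(n_case); n_control <- as.integer(n_control)
  stopifnot(n_case >= 1L, n_control >= 1L,
            all(snp_mafs > 0), all(snp_mafs < 0.5))
  if (!is.null(embedded_model)) {
    stopifnot(inherits(embedded_model, "snp_model"))
    if (is.null(target_freq_case) || is.null(target_freq_control))
      stop("embedded_model requires target_freq_case and target_freq_control")
    if (!(target_freq_control >= 0 && target_freq_case <= 1 &&
          target_freq_control <= target_freq_case))
      stop("need 0 <= target_freq_control <= target_freq_case <= 1")
    if (max(embedded_model$snps) > length(snp_mafs))
      stop("embedded model references a SNP beyond length(snp_mafs)")
  }
  structure(
    list(n_case = n_case, n_control = n_control, snp_mafs = snp_mafs,
         embedded_model = embedded_model,
         target_freq_case = target_freq_case,
         target_freq_control = target_freq_control, seed = seed),
    class = "synthetic_cohort_spec")
}

# Run expr under a seeded, isolated RNG stream; the caller's RNG state is
# untouched. With seed = NULL the global stream is consumed as usual.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a case-control genotype cohort
#'
#' Draws background genotypes per SNP from Hardy-Weinberg proportions
#' (`(1-maf)^2` major homozygote, `2*maf*(1-maf)` heterozygote, `maf^2`
#' minor homozygote). If the spec embeds a risk model, each individual's
#' genotypes at the model's SNPs are overwritten with the model's codes with
#' probability `target_freq_case` (cases) or `target_freq_control`
#' (controls). Background individuals may also match the model by chance, so
#' the realized carrier frequency slightly exceeds the target; tests account
#' for this rather than suppressing it.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return A [genotype_dataset()] (cases first, then controls). Generation is
#'   deterministic given `spec$seed` and leaves the caller's RNG state
#'   untouched.
#' @export
generate_synthetic_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  with_rng(spec$seed, {
    S <- length(spec$snp_mafs)
    N <- spec$n_case + spec$n_control
    geno <- vapply(seq_len(S), function(j) {
      maf <- spec$snp_mafs[j]
      p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
      sample.int(3L, N, replace = TRUE, prob = p)
    }, integer(N))
    labels <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
    if (!is.null(spec$embedded_model)) {
      m <- spec$embedded_model
      pr <- ifelse(labels == "case", spec$target_freq_case,
                   spec$target_freq_control)
      carrier <- stats::runif(N) < pr
      if (any(carrier))
        geno[carrier, m$snps] <- matrix(m$genotypes, sum(carrier),
                                        length(m$snps), byrow = TRUE)
    }
    genotype_dataset(geno, labels,
                     snp_names = paste0("SNP", seq_len(S)))
  })
}
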