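# Fixtures built in code. The published count tables are inputs (printed in
# the source study's report tables) and are frozen here; datasets realizing
# them are constructed so that every statistic is recomputed, not copied.

# Dataset in which exactly `a` cases and `b` controls carry `model`.
# Non-carriers differ from the model at its first SNP; all other columns are
# the reference genotype, so carrier counts are exact by construction.
make_count_dataset <- function(model, a, b, n_case = 345L, n_control = 290L,
                               S = max(model$snps)) {
  stopifnot(a <= n_case, b <= n_control)
  g <- matrix(1L, n_case + n_control, S)
  s1 <- model$snps[1]
  g[, s1] <- if (model$genotypes[1] == 1L) 2L else 1L
  carriers <- c(seq_len(a), if (b > 0) n_case + seq_len(b))
  if (length(carriers))
    g[carriers, model$snps] <- matrix(model$genotypes, length(carriers),
                                      model_order(model), byrow = TRUE)
  genotype_dataset(g, rep(c("case", "control"), c(n_case, n_control)))
}

# Dataset whose per-SNP genotype counts by group are exactly as given.
# case_counts / control_counts: list per SNP of length-3 count vectors.
make_margin_dataset <- function(case_counts, control_counts,
                                snp_names = NULL) {
  nc <- sum(case_counts[[1]]); nn <- sum(control_counts[[1]])
  g <- vapply(seq_along(case_counts), function(j) {
    c(rep(1:3, case_counts[[j]]), rep(1:3, control_counts[[j]]))
  }, integer(nc + nn))
  genotype_dataset(g, rep(c("case", "control"), c(nc, nn)),
                   snp_names = snp_names)
}

# Published single-SNP count table: genotype counts (codes 1,2,3) by group
# and the reported per-genotype percentages and Wald p-values.
table1_counts <- list(
  rs12320939 = list(case = c(97, 181, 67), control = c(79, 140, 71),
                    case_pct = c(28.12, 52.46, 19.42),
                    control_pct = c(27.24, 48.28, 24.48),
                    p = c(NA, 0.785, 0.248)),
  rs12313273 = list(case = c(183, 142, 20), control = c(161, 100, 29),
                    case_pct = c(53.04, 41.16, 5.80),
                    control_pct = c(55.52, 34.48, 10.00),
                    p = c(NA, 0.189, 0.107)),
  rs7135617  = list(case = c(103, 187, 55), control = c(94, 145, 51),
                    case_pct = c(29.86, 54.20, 15.94),
                    control_pct = c(32.41, 50.00, 17.59),
                    p = c(NA, 0.367, 0.947)),
  rs6486795  = list(case = c(137, 173, 35), control = c(121, 126, 43),
                    case_pct = c(39.71, 50.14, 10.14),
                    control_pct = c(41.72, 43.45, 14.83),
                    p = c(NA, 0.260, 0.204)),
  rs712853   = list(case = c(154, 158, 33), control = c(128, 134, 28),
                    case_pct = c(44.64, 45.80, 9.57),
                    control_pct = c(44.14, 46.21, 9.66),
                    p = c(NA, 0.904, 0.942)))

table1_dataset <- function() {
  make_margin_dataset(lapply(table1_counts, `[[`, "case"),
                      lapply(table1_counts, `[[`, "control"),
                      snp_names = names(table1_counts))
}

# Published ranked 2-SNP model table: model notation, carrier counts and the
# reported percent frequency difference (group totals 345/290).
table2_rows <- data.frame(
  model = c("SNP(1,4):2-2", "SNP(2,4):2-3", "SNP(3,4):2-2", "SNP(2,5):2-3",
            "SNP(2,4):3-2", "SNP(1,5):2-3", "SNP(4,5):2-3", "SNP(3,5):2-3",
            "SNP(2,3):3-3", "SNP(4,5):2-2", "SNP(1,3):2-2"),
  case_n = c(145, 22, 121, 83, 65, 81, 81, 78, 38, 77, 147),
  control_n = c(101, 1, 85, 54, 40, 55, 55, 53, 23, 56, 116),
  diff_pct = c(7.20, 6.03, 5.76, 5.44, 5.05, 4.51, 4.51, 4.33, 3.08, 3.01, 2.61),
  stringsAsFactors = FALSE)

# Published best-model-per-order table: counts, model-positive case percent,
# percent difference, OR with 95% CI and Wald p. The "others_pct" is the
# model-negative case percent of the complementary row.
table3_rows <- data.frame(
  order = 2:5,
  model = c("SNP(1,4):2-2", "SNP(1,2,4):2-1-2", "SNP(1,3,4,5):2-2-2-1",
            "SNP(1,2,3,4,5):1-2-3-1-1"),
  a = c(145, 58, 78, 14), b = c(101, 31, 53, 0),
  cancer_pct = c(58.94, 65.17, 59.54, 100.00),
  others_pct = c(51.41, 52.56, 52.98, 53.30),
  diff_pct = c(7.20, 6.12, 4.33, 4.06),
  or = c(1.357, 1.689, 1.306, 13.148),
  ci_low = c(0.983, 1.058, 0.884, 1.726),
  ci_high = c(1.873, 2.694, 1.930, 100.142),
  p = c(0.064, 0.028, 0.180, 0.013),
  stringsAsFactors = FALSE)

# Neutral 5-SNP benchmark cohort for GA-vs-oracle sweeps: a MAF > 10%
# tagSNP-style panel at the study's group sizes, fixed generator seed.
bench_mafs <- c(0.30, 0.25, 0.40, 0.35, 0.30)
bench_cohort <- function(seed = 42L, embedded = NULL,
                         freq_case = NULL, freq_control = NULL) {
  generate_synthetic_cohort(synthetic_cohort_spec(
    345L, 290L, bench_mafs, embedded_model = embedded,
    target_freq_case = freq_case, target_freq_control = freq_control,
    seed = seed))
}

# Independent fitness oracle: count carriers by hashing whole genotype
# tuples at the model's SNPs, never via sample_matches_model().
fitness_hash_oracle <- function(model, dataset) {
  key <- apply(dataset$genotypes[, model$snps, drop = FALSE], 1, paste,
               collapse = "/")
  want <- paste(model$genotypes, collapse = "/")
  is_case <- dataset$labels == "case"
  sum(key == want & is_case) / sum(is_case) -
    sum(key == want & !is_case) / sum(!is_case)
}
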