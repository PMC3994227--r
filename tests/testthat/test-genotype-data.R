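test_that("encode_genotypes maps unordered allele pairs to 1/2/3", {
  expect_identical(encode_genotypes(c("GG", "GT", "TG", "TT"), "G", "T"),
                   c(1L, 2L, 2L, 3L))
  expect_identical(encode_genotypes("tc", "T", "C"), 2L)
  expect_error(encode_genotypes("GA", "G", "T"), "undeclared")
  expect_error(encode_genotypes("GGT", "G", "T"), "two-character")
})

test_that("decode/encode round-trips all three genotype classes", {
  for (al in list(c("G", "T"), c("T", "C"), c("A", "C"))) {
    pairs <- decode_genotypes(1:3, al[1], al[2])
    expect_identical(encode_genotypes(pairs, al[1], al[2]), 1:3)
    # and the unordered flip of the heterozygote
    flipped <- paste0(substr(pairs[2], 2, 2), substr(pairs[2], 1, 1))
    expect_identical(encode_genotypes(flipped, al[1], al[2]), 2L)
  }
})

test_that("genotype_dataset validates codes, labels and group presence", {
  g <- matrix(c(1L, 2L, 3L, 2L), 2)
  expect_s3_class(genotype_dataset(g, c("case", "control")), "genotype_dataset")
  expect_error(genotype_dataset(matrix(c(1L, 4L), 1), "case"), "1\\.\\.3")
  expect_error(genotype_dataset(g, c("case", "sick")), "unknown status")
  expect_error(genotype_dataset(g, c("case", "case")), "at least one")
  expect_error(genotype_dataset(matrix(c(1L, NA), 1), "case"), "missing")
})

test_that("read_genotype_table handles codes, allele pairs and bad input", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("status,rs1,rs2",
               "case,1,GT", "case,2,GG", "control,3,TG", "control,1,TT"), csv)
  al <- list(rs2 = c(major = "G", minor = "T"))
  ds <- read_genotype_table(csv, alleles = al)
  expect_equal(nrow(ds$genotypes), 4L)
  expect_identical(ds$genotypes[, "rs1"], c(1L, 2L, 3L, 1L))
  expect_identical(ds$genotypes[, "rs2"], c(2L, 1L, 2L, 3L))
  expect_identical(ds$genotype_labels$rs2, c("GG", "GT", "TT"))
  expect_equal(attr(ds, "load_report"),
               list(rows_read = 4L, rows_dropped = 0L))

  # allele declaration via YAML sidecar
  side <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(rs2 = list(major = "G", minor = "T")), side)
  ds2 <- read_genotype_table(csv, alleles = side)
  expect_identical(ds2$genotypes, ds$genotypes)

  # inferred major/minor from observed allele frequency (G more common)
  ds3 <- read_genotype_table(csv)
  expect_identical(ds3$genotypes[, "rs2"], c(2L, 1L, 2L, 3L))

  # rows with missing genotypes are dropped and counted
  writeLines(c("status,rs1", "case,1", "case,", "control,2", "control,3"), csv)
  ds4 <- read_genotype_table(csv)
  expect_equal(attr(ds4, "load_report")$rows_dropped, 1L)
  expect_equal(nrow(ds4$genotypes), 3L)

  # hard failures
  writeLines(c("status,rs1", "case,4", "control,1"), csv)
  expect_error(read_genotype_table(csv), "outside 1\\.\\.3")
  writeLines(c("status,rs1", "case,GA", "control,GT"), csv)
  expect_error(read_genotype_table(csv), "more than two distinct alleles")
  writeLines(c("status,rs1", "patient,1", "control,1"), csv)
  expect_error(read_genotype_table(csv), "unknown status")
  expect_error(read_genotype_table(tempfile()), "not found")
})

test_that("write_genotype_table dumps codes bit-stably and round-trips", {
  ds <- bench_cohort(seed = 5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_genotype_table(ds, f1)
  back <- read_genotype_table(f1)
  expect_identical(back$genotypes, ds$genotypes)
  expect_identical(back$labels, ds$labels)
  write_genotype_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("genotype_frequency_table reproduces published percentages", {
  tab <- genotype_frequency_table(table1_dataset())
  for (snp in names(table1_counts)) {
    rows <- tab[tab$snp == snp, ]
    expect_equal(rows$case_n, table1_counts[[snp]]$case)
    expect_equal(rows$control_n, table1_counts[[snp]]$control)
    expect_equal(round(rows$case_pct, 2), table1_counts[[snp]]$case_pct)
    expect_equal(round(rows$control_pct, 2), table1_counts[[snp]]$control_pct)
  }
})

test_that("genotype_frequency_table counts sum to group sizes", {
  ds <- generate_synthetic_cohort(
    synthetic_cohort_spec(27, 23, c(0.2, 0.45, 0.1), seed = 3))
  tab <- genotype_frequency_table(ds)
  sums <- aggregate(cbind(case_n, control_n) ~ snp, tab, sum)
  expect_true(all(sums$case_n == 27))
  expect_true(all(sums$control_n == 23))
  # single-individual group edge: one cell is 100%
  ds1 <- genotype_dataset(matrix(c(2L, 1L), 2), c("case", "control"))
  t1 <- genotype_frequency_table(ds1)
  expect_equal(t1$case_pct[t1$genotype == 2], 100)
})

test_that("synthetic background genotypes follow Hardy-Weinberg proportions", {
  maf <- 0.4
  ds <- generate_synthetic_cohort(
    synthetic_cohort_spec(6000, 6000, rep(maf, 2), seed = 11))
  expected <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  for (j in 1:2) {
    obs <- tabulate(ds$genotypes[, j], 3) / 12000
    tol <- 3 * sqrt(expected * (1 - expected) / 12000)
    expect_true(all(abs(obs - expected) < tol))
  }
})

test_that("synthetic generation is deterministic and RNG-hygienic", {
  spec <- synthetic_cohort_spec(50, 40, bench_mafs,
                                embedded_model = snp_model(c(1, 4), c(2, 2)),
                                target_freq_case = 0.42,
                                target_freq_control = 0.35, seed = 99)
  a <- generate_synthetic_cohort(spec)
  set.seed(1); before <- .Random.seed
  b <- generate_synthetic_cohort(spec)
  expect_identical(before, .Random.seed)  # caller's stream untouched
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$labels, b$labels)
})

test_that("embedded model reaches its target carrier frequencies", {
  em <- snp_model(c(1, 4), c(2, 2))
  ds <- bench_cohort(seed = 7, embedded = em,
                     freq_case = 0.42, freq_control = 0.35)
  f <- fitness(em, ds)
  # background carriers inflate both groups; the group difference shrinks by
  # (1 - bg) where bg is the closed-form HWE match probability
  sd3 <- 3 * sqrt(0.42 * 0.58 / 345 + 0.35 * 0.65 / 290)
  expect_lt(abs(f$value - (0.42 - 0.35)), sd3)

  # Monte-Carlo-scale check of the carrier-frequency model itself:
  # P(carrier) = t + (1 - t) * bg with bg from HWE proportions
  big <- generate_synthetic_cohort(synthetic_cohort_spec(
    20000, 1000, bench_mafs, embedded_model = em,
    target_freq_case = 0.25, target_freq_control = 0.10, seed = 13))
  hwe_het <- function(maf) 2 * maf * (1 - maf)
  bg <- hwe_het(bench_mafs[1]) * hwe_het(bench_mafs[4])
  expect_expected <- 0.25 + (1 - 0.25) * bg
  obs <- fitness(em, big)$case_freq
  expect_lt(abs(obs - expect_expected),
            4 * sqrt(expect_expected * (1 - expect_expected) / 20000))
})

test_that("synthetic spec rejects inconsistent targets", {
  em <- snp_model(c(1, 2), c(2, 2))
  expect_error(synthetic_cohort_spec(10, 10, c(0.2, 0.2), embedded_model = em,
                                     target_freq_case = 0.1,
                                     target_freq_control = 0.4),
               "target_freq")
  expect_error(synthetic_cohort_spec(10, 10, c(0.2, 0.2), embedded_model = em),
               "requires")
  expect_error(synthetic_cohort_spec(10, 10, c(0.2, 0.6)), "snp_mafs")
  expect_error(synthetic_cohort_spec(0, 10, c(0.2, 0.2)))
})
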