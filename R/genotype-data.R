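#' Case-control genotype dataset
#'
#' Bundles a coded genotype matrix with per-individual case/control labels.
#' Genotypes are stored as integer codes `1..n_genotypes` per SNP, with the
#' canonical biallelic coding 1 = homozygous major allele, 2 = heterozygous,
#' 3 = homozygous minor allele.
#'
#' @param genotypes Integer matrix, individuals in rows, SNPs in columns.
#'   Every value must lie in `1..n_genotypes`; missing values are not allowed
#'   (drop incomplete rows before construction, see [read_genotype_table()]).
#' @param labels Character or factor vector of length `nrow(genotypes)` with
#'   values `"case"` or `"control"`. At least one of each is required.
#' @param snp_names Character vector of SNP identifiers; defaults to the
#'   matrix column names or `SNP1..SNPS`.
#' @param genotype_labels Optional named list mapping each SNP to a character
#'   vector of length `n_genotypes` giving the allele-pair string for each
#'   code (e.g. `c("GG", "GT", "TT")`).
#' @param n_genotypes Number of genotype classes per SNP (default 3).
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `labels`, `snp_names`, `genotype_labels`, `n_genotypes`.
#' @examples
#' g <- matrix(c(1, 2, 3, 2, 1, 2, 3, 1), nrow = 4)
#' ds <- genotype_dataset(g, c("case", "case", "control", "control"))
#' n_case(ds)
#' @export
genotype_dataset <- function(genotypes, labels, snp_names = NULL,
                             genotype_labels = NULL, n_genotypes = 3L) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  labels <- as.character(labels)
  n_genotypes <- as.integer(n_genotypes)

  if (nrow(genotypes) != length(labels))
    stop("'labels' must have one entry per row of 'genotypes'")
  if (anyNA(genotypes))
    stop("genotype matrix contains missing values; drop incomplete rows first")
  if (any(genotypes < 1L | genotypes > n_genotypes))
    stop("genotype codes must lie in 1..", n_genotypes)
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad))
    stop("unknown status value(s): ", paste(bad, collapse = ", "))
  if (!any(labels == "case") || !any(labels == "control"))
    stop("dataset needs at least one case and one control")

  if (is.null(snp_names)) snp_names <- colnames(genotypes)
  if (is.null(snp_names)) snp_names <- paste0("SNP", seq_len(ncol(genotypes)))
  colnames(genotypes) <- snp_names
  if (!is.null(genotype_labels)) {
    stopifnot(is.list(genotype_labels))
    if (!all(lengths(genotype_labels) == n_genotypes))
      stop("each genotype_labels entry must have length ", n_genotypes)
  }

  structure(
    list(genotypes = genotypes, labels = labels, snp_names = snp_names,
         genotype_labels = genotype_labels, n_genotypes = n_genotypes),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d individuals (%d cases / %d controls), %d SNPs, %d genotype codes\n",
              nrow(x$genotypes), n_case(x), n_control(x),
              ncol(x$genotypes), x$n_genotypes))
  cat("SNPs:", paste(x$snp_names, collapse = ", "), "\n")
  invisible(x)
}

#' Group sizes of a genotype dataset
#'
#' @param dataset A [genotype_dataset()].
#' @return Integer count of cases (`n_case`) or controls (`n_control`).
#' @export
n_case <- function(dataset) sum(dataset$labels == "case")

#' @rdname n_case
#' @export
n_control <- function(dataset) sum(dataset$labels == "control")

#' Number of SNPs in a dataset
#' @param dataset A [genotype_dataset()].
#' @export
n_snps <- function(dataset) ncol(dataset$genotypes)

#' Encode allele pairs as genotype codes
#'
#' Maps unordered allele-pair strings to the canonical integer coding:
#' major/major is 1 (the reference genotype), heterozygous is 2,
#' minor/minor is 3. Pair order is irrelevant (`"GT"` and `"TG"` are the
#' same heterozygote).
#'
#' @param allele_pairs Character vector of two-letter allele pairs.
#' @param major_allele,minor_allele Single characters declaring the two
#'   alleles of the SNP.
#' @return Integer vector of codes in `1:3`.
#' @examples
#' encode_genotypes(c("GG", "TG", "TT"), "G", "T")  # 1 2 3
#' @export
encode_genotypes <- function(allele_pairs, major_allele, minor_allele) {
  stopifnot(nchar(major_allele) == 1L, nchar(minor_allele) == 1L,
            major_allele != minor_allele)
  pairs <- toupper(as.character(allele_pairs))
  if (any(nchar(pairs) != 2L))
    stop("allele pairs must be two-character strings")
  a1 <- substr(pairs, 1L, 1L)
  a2 <- substr(pairs, 2L, 2L)
  ok <- a1 %in% c(major_allele, minor_allele) & a2 %in% c(major_allele, minor_allele)
  if (!all(ok))
    stop("allele pair(s) with undeclared allele: ",
         paste(unique(pairs[!ok]), collapse = ", "))
  n_minor <- (a1 == minor_allele) + (a2 == minor_allele)
  as.integer(n_minor + 1L)
}

#' Decode genotype codes to canonical allele-pair strings
#'
#' Inverse of [encode_genotypes()] up to pair order: code 1 becomes the
#' major homozygote, 2 the heterozygote written major-then-minor, 3 the
#' minor homozygote.
#'
#' @inheritParams encode_genotypes
#' @param codes Integer vector of codes in `1:3`.
#' @export
decode_genotypes <- function(codes, major_allele, minor_allele) {
  stopifnot(all(codes %in% 1:3))
  labs <- c(paste0(major_allele, major_allele),
            paste0(major_allele, minor_allele),
            paste0(minor_allele, minor_allele))
  labs[codes]
}

#' Read a case-control genotype table
#'
#' Reads a CSV/TSV file with one row per individual, a `status` column with
#' values `case`/`control`, and one column per SNP. SNP columns may hold
#' integer codes `1..n_genotypes` or allele-pair strings (e.g. `"GT"`). Rows
#' with any missing genotype are dropped; the count is reported in the
#' `load_report` attribute of the result.
#'
#' For allele-pair columns the major/minor alleles are taken from `alleles`
#' (a named list `list(rs123 = c(major = "G", minor = "T"))` or the path to a
#' YAML sidecar with the same structure). Without a declaration the major
#' allele is inferred as the more frequent allele in the file (ties broken
#' alphabetically); a column using more than two distinct alleles is an error.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; guessed from the file extension by default
#'   (`.tsv`/`.txt` are tab, otherwise comma).
#' @param status_col Name of the status column (default `"status"`).
#' @param alleles Optional allele declaration, see Details.
#' @param n_genotypes Number of genotype classes (default 3).
#' @return A [genotype_dataset()] with attribute `load_report`, a list with
#'   `rows_read` and `rows_dropped`.
#' @export
read_genotype_table <- function(path, sep = NULL, status_col = "status",
                                alleles = NULL, n_genotypes = 3L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!status_col %in% names(df))
    stop("no '", status_col, "' column in ", path)
  if (is.character(alleles) && length(alleles) == 1L)
    alleles <- yaml::read_yaml(alleles)

  status <- tolower(as.character(df[[status_col]]))
  bad <- setdiff(unique(status), c("case", "control"))
  if (length(bad))
    stop("unknown status value(s): ", paste(bad, collapse = ", "))
  snp_cols <- setdiff(names(df), status_col)
  if (!length(snp_cols)) stop("no SNP columns in ", path)

  rows_read <- nrow(df)
  complete <- stats::complete.cases(df[snp_cols]) & !is.na(status)
  df <- df[complete, , drop = FALSE]
  status <- status[complete]
  rows_dropped <- rows_read - nrow(df)

  geno <- matrix(NA_integer_, nrow(df), length(snp_cols),
                 dimnames = list(NULL, snp_cols))
  genotype_labels <- list()
  for (s in snp_cols) {
    col <- df[[s]]
    if (is.numeric(col) || all(grepl("^[0-9]+$", col))) {
      code <- as.integer(col)
      if (any(code < 1L | code > n_genotypes))
        stop("SNP '", s, "': genotype code outside 1..", n_genotypes)
      geno[, s] <- code
    } else {
      decl <- alleles[[s]]
      if (is.null(decl)) {
        obs <- sort(table(unlist(strsplit(toupper(col), ""))), decreasing = TRUE)
        if (length(obs) > 2L)
          stop("SNP '", s, "' uses more than two distinct alleles: ",
               paste(names(obs), collapse = ", "))
        als <- names(obs)
        if (length(als) == 1L) als <- c(als, als)  # monomorphic guard below
        if (length(unique(als)) < 2L)
          stop("SNP '", s, "' is monomorphic; declare alleles explicitly")
        if (obs[1] == obs[2]) als <- sort(als)
        decl <- c(major = als[1], minor = als[2])
      }
      geno[, s] <- encode_genotypes(col, decl[["major"]], decl[["minor"]])
      genotype_labels[[s]] <- decode_genotypes(seq_len(3L),
                                               decl[["major"]], decl[["minor"]])
    }
  }
  if (!length(genotype_labels)) genotype_labels <- NULL
  ds <- genotype_dataset(geno, status, snp_names = snp_cols,
                         genotype_labels = genotype_labels,
                         n_genotypes = n_genotypes)
  attr(ds, "load_report") <- list(rows_read = rows_read,
                                  rows_dropped = rows_dropped)
  ds
}

#' Write a dataset as a canonical coded CSV
#'
#' Dumps the integer genotype codes plus a `status` column, with the SNP
#' columns in dataset order. Output is byte-stable for a given dataset.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output file path.
#' @export
write_genotype_table <- function(dataset, path) {
  df <- data.frame(status = dataset$labels, dataset$genotypes,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-SNP genotype frequency table by case/control status
#'
#' For every SNP and genotype code, counts the individuals in each group and
#' expresses them as percentages of the group totals. Counts per SNP sum to
#' the case and control group sizes.
#'
#' @param dataset A [genotype_dataset()].
#' @return A data frame with columns `snp`, `genotype` (code),
#'   `genotype_label` (allele pair if known), `case_n`, `case_pct`,
#'   `control_n`, `control_pct`.
#' @export
genotype_frequency_table <- function(dataset) {
  nc <- n_case(dataset); nn <- n_control(dataset)
  is_case <- dataset$labels == "case"
  G <- dataset$n_genotypes
  out <- lapply(seq_len(n_snps(dataset)), function(j) {
    g <- dataset$genotypes[, j]
    case_n <- tabulate(g[is_case], nbins = G)
    ctrl_n <- tabulate(g[!is_case], nbins = G)
    lab <- dataset$genotype_labels[[dataset$snp_names[j]]]
    data.frame(
      snp = dataset$snp_names[j],
      genotype = seq_len(G),
      genotype_label = if (is.null(lab)) NA_character_ else lab,
      case_n = case_n,
      case_pct = 100 * case_n / nc,
      control_n = ctrl_n,
      control_pct = 100 * ctrl_n / nn,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
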