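# Fixed 97.5% normal quantile used for the Woolf 95% CI. The published
# 3-decimal CI bounds (e.g. an upper bound of 100.142 on the 5-SNP table)
# require the full-precision quantile, not the conventional 1.96.
Z975 <- 1.959964

#' 2x2 contingency table for a model in a case-control dataset
#'
#' Cell layout: `a` = model-positive cases, `b` = model-positive controls,
#' `c` = model-negative cases, `d` = model-negative controls, so that
#' `a + c = N_case` and `b + d = N_control`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(lapply(as.list(cells), as.integer), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("model+", "model-"), c("case", "control")))
  print(m)
  invisible(x)
}

#' Build the model-positive vs model-negative table for a dataset
#'
#' @param dataset A [genotype_dataset()].
#' @param model A valid [snp_model()].
#' @return A [contingency_2x2()].
#' @export
model_contingency <- function(dataset, model) {
  if (!is_valid_model(model)) stop("model repeats a SNP; no contingency table")
  hit <- model_match_vector(dataset, model)
  is_case <- dataset$labels == "case"
  contingency_2x2(sum(hit & is_case), sum(hit & !is_case),
                  sum(!hit & is_case), sum(!hit & !is_case))
}

#' Odds ratio with Woolf confidence interval and Wald p-value
#'
#' Computes `OR = (a*d)/(b*c)` with the Woolf 95% CI
#' `exp(log(OR) +/- z * SE)`, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, and a
#' two-sided Wald p-value from `log(OR)/SE` against the standard normal.
#' If any cell is zero, 1 is added to *every* cell before computing OR, CI
#' and p (`corrected = TRUE`); the model-positive case percentage
#' (`risk_pct = a/(a+b)*100`) always uses the uncorrected counts.
#'
#' Optional `p_method` alternatives: `"chisq"` (Pearson chi-square without
#' continuity correction) and `"fisher"` (Fisher exact), both computed on the
#' uncorrected table; the Wald test is the default and is what the reported
#' tables use.
#'
#' @param table A [contingency_2x2()].
#' @param p_method One of `"wald"`, `"chisq"`, `"fisher"`.
#' @return An object of class `association_result`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `corrected`, `risk_pct`, `se`, `table`.
#' @examples
#' odds_ratio_test(contingency_2x2(145, 101, 200, 189))
#' @export
odds_ratio_test <- function(table, p_method = c("wald", "chisq", "fisher")) {
  stopifnot(inherits(table, "contingency_2x2"))
  p_method <- match.arg(p_method)
  a0 <- table$a; b0 <- table$b; c0 <- table$c; d0 <- table$d
  if ((a0 + c0) == 0L || (b0 + d0) == 0L || (a0 + b0) == 0L || (c0 + d0) == 0L)
    stop("a zero margin (empty row or column) leaves the odds ratio undefined")

  corrected <- any(c(a0, b0, c0, d0) == 0L)
  a <- a0 + corrected; b <- b0 + corrected
  cc <- c0 + corrected; d <- d0 + corrected

  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * Z975 * se)
  p <- switch(p_method,
    wald = 2 * stats::pnorm(-abs(log(or)) / se),
    chisq = {
      m <- matrix(c(a0, c0, b0, d0), 2)
      suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
    },
    fisher = stats::fisher.test(matrix(c(a0, c0, b0, d0), 2))$p.value)

  structure(list(odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, corrected = corrected,
                 risk_pct = 100 * a0 / (a0 + b0), se = se, table = table),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.3f%s\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value,
              if (x$corrected) " [zero cell: +1 to all cells]" else ""))
  invisible(x)
}

#' Single-SNP genotype association against the reference genotype
#'
#' For one SNP, tests each non-reference genotype against the reference
#' (code 1, the major-allele homozygote) with [odds_ratio_test()] on the
#' 2x2 table (cases with g, controls with g, cases with reference, controls
#' with reference). Counts and group percentages are reported for every
#' genotype including the reference.
#'
#' @param dataset A [genotype_dataset()].
#' @param snp_index SNP column index.
#' @return Data frame with one row per genotype: `snp`, `genotype`,
#'   `genotype_label`, `case_n`, `case_pct`, `control_n`, `control_pct`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value` (NA on the reference row).
#' @export
single_snp_association <- function(dataset, snp_index) {
  g <- dataset$genotypes[, snp_index]
  is_case <- dataset$labels == "case"
  G <- dataset$n_genotypes
  case_n <- tabulate(g[is_case], nbins = G)
  ctrl_n <- tabulate(g[!is_case], nbins = G)
  if (case_n[1] == 0L || ctrl_n[1] == 0L)
    stop("reference genotype (code 1) absent in one group")
  lab <- dataset$genotype_labels[[dataset$snp_names[snp_index]]]

  rows <- lapply(seq_len(G), function(code) {
    base <- data.frame(
      snp = dataset$snp_names[snp_index], genotype = code,
      genotype_label = if (is.null(lab)) NA_character_ else lab[code],
      case_n = case_n[code], case_pct = 100 * case_n[code] / sum(is_case),
      control_n = ctrl_n[code],
      control_pct = 100 * ctrl_n[code] / sum(!is_case),
      stringsAsFactors = FALSE)
    if (code == 1L) {
      base$odds_ratio <- NA_real_; base$ci_low <- NA_real_
      base$ci_high <- NA_real_; base$p_value <- NA_real_
    } else {
      r <- odds_ratio_test(contingency_2x2(case_n[code], ctrl_n[code],
                                           case_n[1], ctrl_n[1]))
      base$odds_ratio <- r$odds_ratio; base$ci_low <- r$ci_low
      base$ci_high <- r$ci_high; base$p_value <- r$p_value
    }
    base
  })
  do.call(rbind, rows)
}

#' Association summary of the best model per order
#'
#' Builds the per-order report: for each model a model row and an "Others"
#' row, with case/control counts, the model-positive case percentage
#' ("Cancer %" style column), the case-control frequency difference,
#' OR with 95% CI, Wald p, and a significance flag at p < 0.05.
#'
#' @param dataset A [genotype_dataset()].
#' @param models List of valid [snp_model()]s, typically one best model per
#'   order.
#' @return Data frame with two rows per model (`row = "model"` / `"others"`):
#'   `order`, `model`, `case_n`, `control_n`, `risk_pct`, `diff_pct`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `significant`, `corrected`.
#'   Statistics are full precision; round only when formatting
#'   ([format_best_models()]).
#' @export
summarize_best_models <- function(dataset, models) {
  if (inherits(models, "snp_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    tab <- model_contingency(dataset, m)
    r <- odds_ratio_test(tab)
    f <- fitness(m, dataset)
    data.frame(
      order = model_order(m),
      model = format(m),
      row = c("model", "others"),
      case_n = c(tab$a, tab$c),
      control_n = c(tab$b, tab$d),
      risk_pct = c(r$risk_pct, 100 * tab$c / (tab$c + tab$d)),
      diff_pct = c(100 * f$value, NA_real_),
      odds_ratio = c(r$odds_ratio, NA_real_),
      ci_low = c(r$ci_low, NA_real_),
      ci_high = c(r$ci_high, NA_real_),
      p_value = c(r$p_value, NA_real_),
      significant = c(r$p_value < 0.05, NA),
      corrected = c(r$corrected, NA),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Report-layer formatting of the best-model summary
#'
#' Applies the fixed rounding rules: odds ratios and CI bounds to 3 decimals,
#' percentages to 2, p-values to 3. Internal values stay full precision;
#' this function only formats.
#'
#' @param summary A data frame from [summarize_best_models()].
#' @return Character data frame ready for printing/TSV.
#' @export
format_best_models <- function(summary) {
  fmt <- function(x, digits) ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
  data.frame(
    model = ifelse(summary$row == "model", summary$model, "Others"),
    case_control = paste0(summary$case_n, "/", summary$control_n),
    risk_pct = fmt(summary$risk_pct, 2),
    diff_pct = fmt(summary$diff_pct, 2),
    odds_ratio = fmt(summary$odds_ratio, 3),
    ci_95 = ifelse(is.na(summary$ci_low), "",
                   paste0(fmt(summary$ci_low, 3), "-", fmt(summary$ci_high, 3))),
    p_value = fmt(summary$p_value, 3),
    stringsAsFactors = FALSE)
}
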