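#' Chi-squared goodness of fit for two-class segregation counts
#'
#' Pearson goodness-of-fit test of observed two-class counts (e.g. clumpy vs
#' rosette-forming F1 isolates) against an expected segregation ratio. The
#' default 1:1 ratio is the haploid single-locus Mendelian expectation. No
#' continuity correction is applied.
#'
#' @param counts nonnegative integer vector of length 2 with positive total.
#' @param expected_ratio pair of positive weights (default `c(1, 1)`).
#' @return list with `statistic`, `df` (= 1) and `p_value` (upper tail).
#' @examples
#' chisq_goodness_of_fit(c(48, 38))  # statistic 1.163, p = 0.28
#' @export
chisq_goodness_of_fit <- function(counts, expected_ratio = c(1, 1)) {
  if (length(counts) != 2L || any(counts < 0) || sum(counts) <= 0)
    stop("counts must be two nonnegative values with a positive total")
  if (length(expected_ratio) != 2L || any(expected_ratio <= 0))
    stop("expected_ratio must be two positive weights (zero expected counts)")
  ht <- suppressWarnings(
    chisq.test(counts, p = expected_ratio / sum(expected_ratio)))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Upper-tail chi-squared p-value
#'
#' @param statistic nonnegative chi-squared statistic.
#' @param df degrees of freedom, `>= 1`.
#' @return the survival function `P(X >= statistic)`.
#' @examples
#' chisq_pvalue(1.162, 1)  # 0.281
#' @export
chisq_pvalue <- function(statistic, df) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(statistic < 0)) stop("statistic must be nonnegative")
  pchisq(statistic, df, lower.tail = FALSE)
}

#' Genotype-phenotype linkage test on a 2x2 backcross table
#'
#' Pearson chi-squared test of independence (no Yates correction) between
#' genotype at a marker and phenotype, as used to confirm tight linkage of a
#' candidate lesion in backcross progeny. For a perfectly concordant table
#' the statistic equals the grand total. Because perfectly concordant tables
#' have empty cells, Fisher's exact test is available via
#' `method = "fisher"`.
#'
#' @param table 2x2 matrix of nonnegative counts, rows = genotype,
#'   columns = phenotype; all marginal totals must be positive.
#' @param method `"pearson"` (default) or `"fisher"`.
#' @return list with `statistic` (NA for Fisher), `df`, `p_value`, `method`.
#' @examples
#' linkage_chisq(matrix(c(9, 0, 0, 12), 2))  # statistic 21 = N
#' @export
linkage_chisq <- function(table, method = c("pearson", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0))
    stop("table must be a 2x2 matrix of nonnegative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all marginal totals must be positive")
  if (method == "pearson") {
    ht <- suppressWarnings(chisq.test(table, correct = FALSE))
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), method = "pearson")
  } else {
    ht <- fisher.test(table)
    list(statistic = NA_real_, df = NA_integer_,
         p_value = unname(ht$p.value), method = "fisher")
  }
}

#' Poisson probability of clonal isolation by limiting dilution
#'
#' When cells are plated by limiting dilution, the number of cells per well
#' is Poisson; the fraction of empty wells estimates `exp(-lambda)`, so
#' `lambda = -log(wells_empty / wells_total)`. The probability that an
#' occupied well was founded by exactly one cell is
#' `lambda * exp(-lambda) / (1 - exp(-lambda))`.
#'
#' @param wells_total positive number of wells plated.
#' @param wells_empty number of choanoflagellate-free wells, strictly between
#'   0 (lambda would be infinite) and `wells_total` (no occupied wells).
#' @return list with `lambda` and `probability`.
#' @examples
#' clonal_isolation_probability(100, 80)$probability  # 0.8926
#' @export
clonal_isolation_probability <- function(wells_total, wells_empty) {
  if (wells_total <= 0) stop("wells_total must be positive")
  if (wells_empty <= 0)
    stop("no empty wells: lambda is infinite and the estimate undefined")
  if (wells_empty >= wells_total)
    stop("all wells empty: no occupied wells to assess")
  lambda <- -log(wells_empty / wells_total)
  list(lambda = lambda,
       probability = lambda * exp(-lambda) / (1 - exp(-lambda)))
}
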