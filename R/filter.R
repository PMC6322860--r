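#' Filter cascade configuration
#'
#' Thresholds for the bulk-segregant filter cascade. The defaults are the
#' published cascade: keep calls with depth strictly greater than 2, quality
#' strictly greater than 10 and a non-N reference allele; call a variant
#' segregating when strictly more than 99% of reads support the alternative
#' allele; and flag a segregating variant as coverage-robust when its depth is
#' at least 0.25 times the genome-wide mean depth.
#'
#' @param min_depth calls kept when `total_depth > min_depth` (strict).
#' @param min_qual calls kept when `qual > min_qual` (strict).
#' @param forbid_ref_n drop calls whose reference allele contains `N`.
#' @param segregation_fraction segregating when alt fraction `>` this value.
#' @param coverage_mask_ratio robust when
#'   `total_depth >= coverage_mask_ratio * genome_mean_depth`.
#' @param genome_mean_depth genome-wide average pooled coverage (X). When
#'   `NULL` it is estimated from the pool by [estimate_genome_mean_depth()].
#' @return a list of class `filter_config`.
#' @examples
#' filter_config(genome_mean_depth = 187)
#' @export
filter_config <- function(min_depth = 2, min_qual = 10, forbid_ref_n = TRUE,
                          segregation_fraction = 0.99,
                          coverage_mask_ratio = 0.25,
                          genome_mean_depth = NULL) {
  if (segregation_fraction <= 0 || segregation_fraction >= 1)
    stop("segregation_fraction must be in (0, 1)")
  if (coverage_mask_ratio <= 0 || coverage_mask_ratio > 1)
    stop("coverage_mask_ratio must be in (0, 1]")
  if (!is.null(genome_mean_depth) && genome_mean_depth <= 0)
    stop("genome_mean_depth must be > 0")
  structure(list(min_depth = min_depth, min_qual = min_qual,
                 forbid_ref_n = isTRUE(forbid_ref_n),
                 segregation_fraction = segregation_fraction,
                 coverage_mask_ratio = coverage_mask_ratio,
                 genome_mean_depth = genome_mean_depth),
            class = "filter_config")
}

#' Keep pooled calls shared with the mutant parent
#'
#' First cascade stage: a causal lesion must be present in the mutagenized
#' parent, so only pooled calls whose identity `(contig, pos, ref, alt)`
#' appears in the parent strain's variant set are kept. Row order is
#' preserved.
#'
#' @param pool pooled call table (see [pooled_calls()]).
#' @param parent a [strain_variant_set()] for the mutant parent.
#' @return the subset of `pool` shared with `parent`.
#' @export
intersect_with_parent <- function(pool, parent) {
  pool[variant_key(pool) %in% variant_key(parent), , drop = FALSE]
}

#' Remove pooled calls shared with control strains
#'
#' Second cascade stage: variants present in any rosette-competent control
#' strain (mapping strain, wild type, unmutagenized control) cannot cause the
#' mutant phenotype and are removed.
#'
#' @inheritParams intersect_with_parent
#' @param controls list of [strain_variant_set()] objects; may be empty.
#' @return the subset of `pool` absent from every control.
#' @export
subtract_control_strains <- function(pool, controls) {
  if (length(controls) == 0L) return(pool)
  ctrl_keys <- unique(unlist(lapply(controls, variant_key)))
  pool[!(variant_key(pool) %in% ctrl_keys), , drop = FALSE]
}

#' Quality-filter pooled calls
#'
#' Third cascade stage: keep calls with `total_depth > min_depth`,
#' `qual > min_qual` (both strict, as published) and, when `forbid_ref_n`,
#' no `N` in the reference allele.
#'
#' @inheritParams intersect_with_parent
#' @param config a [filter_config()].
#' @return the surviving subset of `pool`.
#' @export
quality_filter <- function(pool, config = filter_config()) {
  keep <- pool$total_depth > config$min_depth & pool$qual > config$min_qual
  if (config$forbid_ref_n) keep <- keep & !grepl("N", pool$ref, fixed = TRUE)
  keep[is.na(keep)] <- FALSE  # evidence-free calls cannot pass
  pool[keep, , drop = FALSE]
}

#' Pooled alternative-allele fraction
#'
#' The fraction of high-quality reads supporting the alternative allele,
#' `alt_depth / total_depth`. Undefined (an error, never silently zero) when
#' `total_depth` is 0.
#'
#' @inheritParams intersect_with_parent
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' alt_fraction(pooled_calls("1", 1, "A", "G", 50, 200, 199)) # 0.995
#' @export
alt_fraction <- function(pool) {
  if (any(pool$total_depth == 0))
    stop("alt fraction undefined at total_depth = 0 (no read evidence)")
  pool$alt_depth / pool$total_depth
}

#' Call variants that segregate with the phenotype
#'
#' Fourth cascade stage: a variant segregates with the pooled mutant
#' phenotype when strictly more than `segregation_fraction` (default 99%) of
#' its reads support the alternative allele, i.e. essentially every pooled F1
#' carries it.
#'
#' @inheritParams quality_filter
#' @return the segregating subset of `pool`.
#' @export
call_segregating <- function(pool, config = filter_config()) {
  pool[alt_fraction(pool) > config$segregation_fraction, , drop = FALSE]
}

#' Partition segregating variants by sequencing-coverage robustness
#'
#' Final cascade stage: segregating variants observed at depth below
#' `coverage_mask_ratio` (default 0.25) times the genome-wide mean depth are
#' liable to be spurious correlations driven by low coverage. The pool is
#' partitioned — nothing is silently discarded — into a `robust` set
#' (`total_depth >= ratio * genome_mean_depth`) and a `low_coverage` set.
#'
#' @inheritParams quality_filter
#' @return list with elements `robust` and `low_coverage`.
#' @examples
#' cfg <- filter_config(genome_mean_depth = 187)
#' coverage_mask(pooled_calls("1", 1:2, "A", "G", 50, c(187, 46),
#'                            c(187, 46)), cfg)
#' @export
coverage_mask <- function(pool, config = filter_config()) {
  mean_depth <- config$genome_mean_depth
  if (is.null(mean_depth)) {
    if (nrow(pool) == 0L)
      stop("genome_mean_depth missing and pool empty; cannot apply coverage mask")
    mean_depth <- estimate_genome_mean_depth(pool)
  }
  robust <- pool$total_depth >= config$coverage_mask_ratio * mean_depth
  list(robust = pool[robust, , drop = FALSE],
       low_coverage = pool[!robust, , drop = FALSE])
}

#' Estimate genome-wide mean depth from a pooled call table
#'
#' Arithmetic mean of `total_depth` across all calls; a fallback used only
#' when the genome-wide average coverage is not supplied externally.
#'
#' @inheritParams intersect_with_parent
#' @return mean depth (X).
#' @export
estimate_genome_mean_depth <- function(pool) {
  if (nrow(pool) == 0L) stop("cannot estimate mean depth from an empty pool")
  mean(pool$total_depth)
}
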