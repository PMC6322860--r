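#' Map causal-mutation candidates by bulk segregant analysis
#'
#' Applies the full filter cascade to a pooled-F1 variant table, in order:
#' intersection with the mutant parent's variants, subtraction of control
#' strains, quality filtering (`depth > 2`, `qual > 10`, reference not N),
#' segregation calling (alt fraction `> 0.99`) and the coverage-robustness
#' mask (`depth >= 0.25 x` genome mean). The result records, per variant, a
#' pass/fail flag for every stage (flags are nested: a variant passes a stage
#' only if it also passed all previous stages), the per-stage survivor
#' counts, and the final robust candidate set sorted by
#' `(contig, position)`.
#'
#' An empty candidate set is a valid outcome and is reported as such — it is
#' what an unmappable cross (e.g. a polygenic or low-fitness phenotype)
#' produces.
#'
#' @param pool pooled call table (see [pooled_calls()] or [read_vcf()]).
#' @param parent [strain_variant_set()] of the mutagenized parent strain.
#' @param controls list of [strain_variant_set()] objects for rosette-competent
#'   control strains (mapping strain, wild type, unmutagenized control).
#' @param config a [filter_config()]; when its `genome_mean_depth` is `NULL`
#'   the mean is estimated from the full pool.
#' @return an object of class `bsa_map` with components
#'   \describe{
#'     \item{report}{per-variant data.frame with evidence, `alt_fraction` and
#'       the five nested stage flags.}
#'     \item{stage_counts}{named survivor counts per stage.}
#'     \item{candidates}{robust candidates sorted by `(contig, pos)`.}
#'     \item{low_coverage}{segregating variants masked for low coverage.}
#'     \item{config}{the resolved `filter_config` (with the mean depth used).}
#'   }
#' @examples
#' sim <- simulate_cross(cross_sim_config(seed = 1))
#' fit <- bsa_map(sim$pool, sim$mutant_parent, sim$controls,
#'                filter_config(genome_mean_depth = 187))
#' summary(fit)
#' @seealso [simulate_cross()] to generate a synthetic cross with a known
#'   planted causal lesion.
#' @export
bsa_map <- function(pool, parent, controls = list(),
                    config = filter_config()) {
  stopifnot(is.data.frame(pool))
  if (is.null(config$genome_mean_depth) && nrow(pool) > 0L)
    config$genome_mean_depth <- estimate_genome_mean_depth(pool)

  s1 <- intersect_with_parent(pool, parent)
  s2 <- subtract_control_strains(s1, controls)
  s3 <- quality_filter(s2, config)
  s4 <- call_segregating(s3, config)
  s5 <- coverage_mask(s4, config)

  key <- variant_key(pool)
  report <- pool
  report$alt_fraction <- ifelse(pool$total_depth > 0,
                                pool$alt_depth / pool$total_depth, NA_real_)
  report$shared_with_parent <- key %in% variant_key(s1)
  report$absent_from_controls <- key %in% variant_key(s2)
  report$quality_pass <- key %in% variant_key(s3)
  report$segregating <- key %in% variant_key(s4)
  report$coverage_robust <- key %in% variant_key(s5$robust)

  ord <- function(x) x[order(x$contig, x$pos), , drop = FALSE]
  structure(list(
    report = report,
    stage_counts = c(input = nrow(pool),
                     shared_with_parent = nrow(s1),
                     absent_from_controls = nrow(s2),
                     quality_pass = nrow(s3),
                     segregating = nrow(s4),
                     coverage_robust = nrow(s5$robust)),
    candidates = ord(s5$robust),
    low_coverage = ord(s5$low_coverage),
    config = config
  ), class = "bsa_map")
}

#' @export
print.bsa_map <- function(x, ...) {
  cat("Bulk segregant mapping report\n")
  cat("Filter cascade survivors:\n")
  nm <- c("input variants", "shared with parent", "absent from controls",
          "pass quality", "segregating (alt fraction > ",
          "coverage-robust (depth >= ")
  lab <- c(nm[1:4],
           paste0(nm[5], format(x$config$segregation_fraction), ")"),
           paste0(nm[6], format(x$config$coverage_mask_ratio), " x ",
                  format(x$config$genome_mean_depth, digits = 4), "X)"))
  for (i in seq_along(x$stage_counts))
    cat(sprintf("  %-45s %d\n", lab[i], x$stage_counts[i]))
  if (nrow(x$candidates)) {
    cat("Robust causal candidates:\n")
    print(x$candidates[, c("contig", "pos", "ref", "alt", "type",
                           "total_depth", "alt_depth")], row.names = FALSE)
  } else {
    cat("No robust causal candidates.\n")
  }
  if (nrow(x$low_coverage))
    cat(nrow(x$low_coverage),
        "segregating variant(s) masked for low coverage.\n")
  invisible(x)
}

#' @export
summary.bsa_map <- function(object, ...) {
  structure(list(stage_counts = object$stage_counts,
                 n_candidates = nrow(object$candidates),
                 n_low_coverage = nrow(object$low_coverage),
                 candidates = object$candidates,
                 config = object$config),
            class = "summary.bsa_map")
}

#' @export
print.summary.bsa_map <- function(x, ...) {
  cat("bsa_map summary:", x$n_candidates, "robust candidate(s),",
      x$n_low_coverage, "low-coverage segregating variant(s)\n")
  print(x$stage_counts)
  if (x$n_candidates) print(x$candidates[, c("contig", "pos", "ref", "alt")],
                            row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.bsa_map <- function(x, ...) x$report

#' Plot pooled allele fractions along the genome
#'
#' Alt-allele fraction against genomic position, one panel strip per contig,
#' with segregating variants highlighted and robust candidates marked.
#'
#' @param x a `bsa_map` object.
#' @param ... passed to [plot()].
#' @export
plot.bsa_map <- function(x, ...) {
  rep <- x$report[x$report$total_depth > 0, , drop = FALSE]
  contigs <- sort(unique(rep$contig))
  offs <- setNames(cumsum(c(0, head(tapply(rep$pos, rep$contig, max)[contigs],
                                    -1L))), contigs)
  gx <- rep$pos + offs[rep$contig]
  col <- ifelse(rep$coverage_robust, "red",
                ifelse(rep$segregating, "orange", "grey50"))
  plot(gx, rep$alt_fraction, col = col, pch = 16, cex = 0.6,
       xlab = "genome position (bp, contigs concatenated)",
       ylab = "pooled alt-allele fraction", ylim = c(0, 1), ...)
  abline(v = offs[-1L], lty = 3, col = "grey80")
  abline(h = x$config$segregation_fraction, lty = 2)
  legend("bottomright", pch = 16, col = c("grey50", "orange", "red"),
         legend = c("background", "segregating", "robust candidate"),
         bty = "n", cex = 0.8)
  invisible(x)
}
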