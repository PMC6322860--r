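#' Configuration for a simulated mapping cross
#'
#' Parameters of the synthetic haploid cross: a mutagenized parent carrying
#' one causal lesion plus passenger lesions is crossed to a polymorphic
#' mapping strain; haploid F1 meioses recombine the two genomes; F1s with the
#' mutant phenotype are pooled and "sequenced" at the pileup level. Defaults
#' describe a scaled-down cross: a 5 x 1 Mb genome standing in for the 55 Mb
#' *S. rosetta* assembly, sparse mapping-strain markers, five
#' mutagenesis-induced lesions (the scale of lesion counts detected per
#' mutant strain), a yeast-like crossover rate of 4 per Mb per meiosis, a
#' pool of 30 mutant F1s and 187X mean pooled coverage.
#'
#' @param contig_lengths positive integer vector of contig lengths (bp).
#' @param marker_density mapping-strain markers per bp (each bp is a marker
#'   independently with this probability).
#' @param n_mutagenic_variants number of lesions private to the mutant
#'   parent, `>= 1`; exactly one is flagged causal.
#' @param n_f1_total number of haploid F1 meioses to simulate.
#' @param n_pool number of mutant-phenotype F1s pooled for sequencing
#'   (`NULL` pools every mutant F1).
#' @param mean_crossovers_per_contig Poisson mean crossover count per contig
#'   per meiosis (no interference; positions uniform).
#' @param mean_coverage expected pooled read depth per site (X).
#' @param seq_error_rate per-read miscall probability, in `[0, 0.01]`.
#' @param n_spurious_low_coverage_sites number of low-coverage artifact sites
#'   shared between parent and pool calls (perfect apparent segregation at
#'   depth below a quarter of the mean) to inject.
#' @param phenotype_linked when `TRUE` (default) the phenotype is fully
#'   penetrant and monogenic (mutant iff the F1 carries the causal allele);
#'   `FALSE` decouples phenotype from genotype, emulating an unmappable
#'   (e.g. polygenic) mutant for negative-control experiments.
#' @param seed integer RNG seed; every generator stage is a pure function of
#'   the configuration and this seed.
#' @return a list of class `cross_sim_config`.
#' @examples
#' cross_sim_config(seed = 7)
#' @export
cross_sim_config <- function(contig_lengths = rep(1e6, 5),
                             marker_density = 1e-4,
                             n_mutagenic_variants = 5,
                             n_f1_total = 100,
                             n_pool = 30,
                             mean_crossovers_per_contig = 4,
                             mean_coverage = 187,
                             seq_error_rate = 1e-3,
                             n_spurious_low_coverage_sites = 4,
                             phenotype_linked = TRUE,
                             seed = 1) {
  contig_lengths <- as.numeric(contig_lengths)
  if (length(contig_lengths) == 0L || any(contig_lengths <= 0) ||
      sum(contig_lengths) <= 0)
    stop("contig_lengths must be positive with positive total length")
  if (n_mutagenic_variants < 1) stop("n_mutagenic_variants must be >= 1")
  if (mean_coverage <= 0) stop("mean_coverage must be > 0")
  if (seq_error_rate < 0 || seq_error_rate > 0.01)
    stop("seq_error_rate must lie in [0, 0.01]")
  if (mean_crossovers_per_contig < 0)
    stop("mean_crossovers_per_contig must be nonnegative")
  if (n_f1_total < 1) stop("n_f1_total must be >= 1")
  if (n_spurious_low_coverage_sites < 0)
    stop("n_spurious_low_coverage_sites must be >= 0")
  structure(list(contig_lengths = contig_lengths,
                 marker_density = marker_density,
                 n_mutagenic_variants = as.integer(n_mutagenic_variants),
                 n_f1_total = as.integer(n_f1_total),
                 n_pool = if (is.null(n_pool)) NULL else as.integer(n_pool),
                 mean_crossovers_per_contig = mean_crossovers_per_contig,
                 mean_coverage = mean_coverage,
                 seq_error_rate = seq_error_rate,
                 n_spurious_low_coverage_sites =
                   as.integer(n_spurious_low_coverage_sites),
                 phenotype_linked = isTRUE(phenotype_linked),
                 seed = as.integer(seed)),
            class = "cross_sim_config")
}

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

random_alt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
}

#' Simulate the two parental haploid genomes
#'
#' Places mapping-strain markers uniformly at the configured density (one
#' binomial draw per contig) and mutant-parent lesions at positions disjoint
#' from the markers; exactly one lesion is flagged causal. The configured
#' number of spurious artifact sites is also created inside the mutant-parent
#' call set (flagged in the `spurious` column): these emulate shared miscalls
#' in poorly covered or repetitive regions, which is what lets them survive
#' the parent-intersection stage downstream just as the real artifacts did.
#'
#' @param config a [cross_sim_config()].
#' @return list with `mutant_parent` and `mapping_strain`
#'   ([strain_variant_set()]s; the parent set has logical `causal` and
#'   `spurious` columns) and `causal`, the single causal variant row.
#' @export
simulate_parent_strains <- function(config) {
  stopifnot(inherits(config, "cross_sim_config"))
  with_seed(config$seed + 1L, {
    L <- config$contig_lengths
    contigs <- as.character(seq_along(L))

    marker_pos <- lapply(seq_along(L), function(i) {
      n <- rbinom(1L, size = as.integer(L[i]), prob = config$marker_density)
      sort(sample.int(L[i], n))
    })
    markers <- data.frame(
      contig = rep(contigs, lengths(marker_pos)),
      pos = as.integer(unlist(marker_pos)),
      stringsAsFactors = FALSE)
    markers$ref <- random_bases(nrow(markers))
    markers$alt <- random_alt(markers$ref)

    n_extra <- config$n_mutagenic_variants + config$n_spurious_low_coverage_sites
    taken <- paste(markers$contig, markers$pos)
    lesion <- data.frame(contig = character(), pos = integer())
    while (nrow(lesion) < n_extra) {
      need <- n_extra - nrow(lesion)
      ctg <- sample(seq_along(L), need, replace = TRUE, prob = L / sum(L))
      cand <- data.frame(contig = contigs[ctg],
                         pos = as.integer(ceiling(runif(need) * L[ctg])),
                         stringsAsFactors = FALSE)
      cand <- cand[!(paste(cand$contig, cand$pos) %in% taken), , drop = FALSE]
      lesion <- rbind(lesion, cand)
      lesion <- lesion[!duplicated(paste(lesion$contig, lesion$pos)), ,
                       drop = FALSE]
      taken <- c(taken, paste(lesion$contig, lesion$pos))
    }
    lesion$ref <- random_bases(nrow(lesion))
    lesion$alt <- random_alt(lesion$ref)
    lesion$spurious <- rep(c(FALSE, TRUE),
                           c(config$n_mutagenic_variants,
                             config$n_spurious_low_coverage_sites))
    lesion$causal <- FALSE
    lesion$causal[sample.int(config$n_mutagenic_variants, 1L)] <- TRUE

    ord <- order(lesion$contig, lesion$pos)
    lesion <- lesion[ord, , drop = FALSE]
    rownames(lesion) <- NULL

    parent_sites <- variant_sites(lesion$contig, lesion$pos, lesion$ref,
                                  lesion$alt)
    parent_sites$causal <- lesion$causal
    parent_sites$spurious <- lesion$spurious
    map_sites <- variant_sites(markers$contig, markers$pos, markers$ref,
                               markers$alt)

    list(mutant_parent = strain_variant_set("mutant_parent", parent_sites),
         mapping_strain = strain_variant_set("mapping_strain", map_sites),
         causal = parent_sites[parent_sites$causal, , drop = FALSE])
  })
}

#' Simulate a cohort of recombinant haploid F1s
#'
#' Per contig and meiosis the crossover count is Poisson with the configured
#' mean and crossover positions are uniform (no interference). Each F1 is a
#' mosaic of parental segments; its phenotype is mutant iff it carries the
#' causal allele (unless `phenotype_linked` is off, in which case phenotype
#' is an independent fair coin).
#'
#' @param parents result of [simulate_parent_strains()].
#' @param config the same [cross_sim_config()].
#' @return list of F1s; each has `breakpoints` (per-contig increasing
#'   crossover positions), `start_origin` (per-contig label of the first
#'   segment: `"mutant"` or `"mapping"`), `carries_causal` and `phenotype`.
#' @export
simulate_f1_cohort <- function(parents, config) {
  stopifnot(inherits(config, "cross_sim_config"))
  causal <- parents$causal
  with_seed(config$seed + 2L, {
    L <- config$contig_lengths
    lapply(seq_len(config$n_f1_total), function(i) {
      bp <- lapply(L, function(len) {
        k <- rpois(1L, config$mean_crossovers_per_contig)
        sort(runif(k, 0, len))
      })
      start <- sample(c("mutant", "mapping"), length(L), replace = TRUE)
      f1 <- list(breakpoints = bp, start_origin = start)
      f1$carries_causal <- f1_carries_alt(f1, as.integer(causal$contig[1L]),
                                          causal$pos[1L], "mutant")
      f1$phenotype <- if (config$phenotype_linked) {
        if (f1$carries_causal) "mutant" else "wildtype"
      } else sample(c("mutant", "wildtype"), 1L)
      f1
    })
  })
}

# Does F1 carry the variant allele at positions `pos` on contig `contig_idx`?
# `origin_parent` names the parent whose haplotype carries the variant.
f1_carries_alt <- function(f1, contig_idx, pos, origin_parent) {
  seg <- findInterval(pos, f1$breakpoints[[contig_idx]])
  start <- f1$start_origin[contig_idx]
  other <- if (start == "mutant") "mapping" else "mutant"
  origin <- ifelse(seg %% 2L == 0L, start, other)
  origin == origin_parent
}

#' Pool mutant-phenotype F1s and simulate pooled sequencing
#'
#' Only mutant-phenotype F1s contribute. At every parental variant site the
#' pooled alternative-allele frequency `f` is the fraction of pooled F1s
#' carrying the variant; the site's read depth is Poisson with the configured
#' mean and the alternative read count is binomial with success probability
#' `f(1-e) + (1-f)e` where `e` is the per-read error rate. The configured
#' spurious artifact sites are emitted with depth drawn below a quarter of
#' the mean coverage (but above the default quality-filter depth cutoff) and
#' alternative fraction 1, reproducing the low-coverage artifacts that
#' perfectly but spuriously co-segregate with the phenotype.
#'
#' @param f1s cohort from [simulate_f1_cohort()].
#' @param parents result of [simulate_parent_strains()].
#' @param config the same [cross_sim_config()].
#' @param n_pool pool size; defaults to `config$n_pool`. The first `n_pool`
#'   mutant-phenotype F1s are pooled; an error is raised if fewer exist.
#' @return a [pooled_calls()] data.frame covering every parental lesion and
#'   mapping-strain marker, plus the injected artifact sites.
#' @export
pool_and_sequence <- function(f1s, parents, config, n_pool = config$n_pool) {
  stopifnot(inherits(config, "cross_sim_config"))
  mutants <- Filter(function(f) f$phenotype == "mutant", f1s)
  if (length(mutants) == 0L)
    stop("no mutant-phenotype F1s to pool; cannot sequence an empty pool")
  if (!is.null(n_pool)) {
    if (length(mutants) < n_pool)
      stop("only ", length(mutants), " mutant F1s available but n_pool = ",
           n_pool)
    mutants <- mutants[seq_len(n_pool)]
  }

  parent <- parents$mutant_parent
  real <- parent[!parent$spurious, , drop = FALSE]
  spur <- parent[parent$spurious, , drop = FALSE]
  markers <- parents$mapping_strain

  sites <- rbind(
    data.frame(contig = real$contig, pos = real$pos, ref = real$ref,
               alt = real$alt, origin = "mutant", stringsAsFactors = FALSE),
    data.frame(contig = markers$contig, pos = markers$pos, ref = markers$ref,
               alt = markers$alt, origin = "mapping", stringsAsFactors = FALSE))

  with_seed(config$seed + 3L, {
    freq <- rowMeans(vapply(mutants, function(f1) {
      carried <- logical(nrow(sites))
      for (ci in unique(as.integer(sites$contig))) {
        idx <- as.integer(sites$contig) == ci
        carried[idx] <- f1_carries_alt(f1, ci, sites$pos[idx],
                                       sites$origin[idx])
      }
      carried
    }, logical(nrow(sites))))
    # f1_carries_alt vectorizes over positions but origin varies per row, so
    # it was applied with per-row origins above; freq is the pooled allele
    # frequency per site.
    e <- config$seq_error_rate
    depth <- rpois(nrow(sites), config$mean_coverage)
    p_alt <- freq * (1 - e) + (1 - freq) * e
    alt <- rbinom(nrow(sites), depth, p_alt)
    qual <- round(runif(nrow(sites), 50, 228), 1)

    calls <- pooled_calls(sites$contig, sites$pos, sites$ref, sites$alt,
                          qual = qual, total_depth = depth, alt_depth = alt)

    if (nrow(spur) > 0L) {
      lo <- 3L
      hi <- max(lo, as.integer(ceiling(0.25 * config$mean_coverage)) - 1L)
      sdepth <- sample(lo:hi, nrow(spur), replace = TRUE)
      calls <- rbind(calls,
                     pooled_calls(spur$contig, spur$pos, spur$ref, spur$alt,
                                  qual = round(runif(nrow(spur), 50, 228), 1),
                                  total_depth = sdepth, alt_depth = sdepth))
    }
    calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
    calls
  })
}

#' Simulate a complete mapping cross
#'
#' Convenience wrapper running [simulate_parent_strains()],
#' [simulate_f1_cohort()] and [pool_and_sequence()], and assembling the
#' control strain sets (the mapping strain's own variants, plus a wild-type
#' control identical to the reference and hence variant-free).
#'
#' @param config a [cross_sim_config()].
#' @return list with `pool`, `mutant_parent`, `mapping_strain`, `controls`,
#'   `causal`, `f1s` and `config`.
#' @examples
#' sim <- simulate_cross(cross_sim_config(seed = 42))
#' fit <- bsa_map(sim$pool, sim$mutant_parent, sim$controls,
#'                filter_config(genome_mean_depth = sim$config$mean_coverage))
#' fit$stage_counts
#' @export
simulate_cross <- function(config = cross_sim_config()) {
  parents <- simulate_parent_strains(config)
  f1s <- simulate_f1_cohort(parents, config)
  pool <- pool_and_sequence(f1s, parents, config)
  wt <- strain_variant_set("wild_type",
                           variant_sites(character(), integer(),
                                         character(), character()))
  list(pool = pool,
       mutant_parent = parents$mutant_parent,
       mapping_strain = parents$mapping_strain,
       controls = list(mapping_strain = parents$mapping_strain,
                       wild_type = wt),
       causal = parents$causal,
       f1s = f1s,
       config = config)
}
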