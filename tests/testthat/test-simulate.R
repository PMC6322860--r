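small_cfg <- function(seed = 1, ...) {
  args <- list(contig_lengths = c(2e5, 2e5), marker_density = 2e-4,
               n_mutagenic_variants = 3, n_f1_total = 40,
               mean_coverage = 60, seed = seed)
  args["n_pool"] <- list(NULL)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cross_sim_config, args)
}

test_that("parent simulation is deterministic and respects its contracts", {
  cfg <- small_cfg(5)
  a <- simulate_parent_strains(cfg)
  b <- simulate_parent_strains(cfg)
  expect_identical(a, b)

  expect_equal(sum(a$mutant_parent$causal), 1L)
  expect_equal(nrow(a$mutant_parent),
               cfg$n_mutagenic_variants + cfg$n_spurious_low_coverage_sites)
  # lesions disjoint from markers
  expect_length(intersect(paste(a$mutant_parent$contig, a$mutant_parent$pos),
                          paste(a$mapping_strain$contig,
                                a$mapping_strain$pos)), 0L)

  one <- simulate_parent_strains(small_cfg(2, n_mutagenic_variants = 1,
                                           n_spurious_low_coverage_sites = 0))
  expect_equal(nrow(one$mutant_parent), 1L)
  expect_true(one$mutant_parent$causal)

  expect_error(cross_sim_config(contig_lengths = numeric()), "positive")
  expect_error(cross_sim_config(n_mutagenic_variants = 0), ">= 1")
})

test_that("marker counts follow the binomial sampling model", {
  cfg1 <- function(s) cross_sim_config(contig_lengths = 1e6,
                                       marker_density = 1e-4, seed = s)
  counts <- vapply(1:200, function(s)
    nrow(simulate_parent_strains(cfg1(s))$mapping_strain), 0)
  # mean of 200 draws from Binomial(1e6, 1e-4): SE = sqrt(100)/sqrt(200)
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(1e6 * 1e-4 * (1 - 1e-4) / 200))
})

test_that("F1 cohorts segregate the causal allele in Mendelian proportion", {
  cfg <- small_cfg(3, n_f1_total = 2000)
  parents <- simulate_parent_strains(cfg)
  f1s <- simulate_f1_cohort(parents, cfg)
  frac <- mean(vapply(f1s, function(f) f$carries_causal, TRUE))
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(frac - 0.5), 4 * se)
  # phenotype deterministically tracks the causal allele
  expect_true(all(vapply(f1s, function(f)
    identical(f$phenotype == "mutant", f$carries_causal), TRUE)))
})

test_that("zero crossovers give whole-contig parental copies", {
  cfg <- small_cfg(4, mean_crossovers_per_contig = 0)
  parents <- simulate_parent_strains(cfg)
  f1s <- simulate_f1_cohort(parents, cfg)
  expect_true(all(vapply(f1s, function(f)
    all(lengths(f$breakpoints) == 0L), TRUE)))
})

test_that("allele concordance nearby the causal site follows the Haldane expectation", {
  cfg <- cross_sim_config(contig_lengths = 1e6, marker_density = 1e-5,
                          mean_crossovers_per_contig = 4,
                          n_f1_total = 4000, seed = 9)
  parents <- simulate_parent_strains(cfg)
  f1s <- simulate_f1_cohort(parents, cfg)
  causal_pos <- parents$causal$pos
  probe <- if (causal_pos < 5e5) causal_pos + 5e4 else causal_pos - 5e4
  conc <- mean(vapply(f1s, function(f) {
    segmapper:::f1_carries_alt(f, 1L, probe, "mutant") == f$carries_causal
  }, TRUE))
  d_morgans <- 4 * 5e4 / 1e6  # crossover rate x distance
  r <- (1 - exp(-2 * d_morgans)) / 2
  se <- sqrt(r * (1 - r) / 4000)
  expect_lt(abs(conc - (1 - r)), 4 * se)
})

test_that("pooled sequencing reflects the pooled allele frequencies", {
  # causal site with zero error: every pooled read is the alt allele
  cfg0 <- small_cfg(6, seq_error_rate = 0)
  parents <- simulate_parent_strains(cfg0)
  f1s <- simulate_f1_cohort(parents, cfg0)
  pool <- pool_and_sequence(f1s, parents, cfg0)
  ck <- paste(parents$causal$contig, parents$causal$pos)
  causal_call <- pool[paste(pool$contig, pool$pos) == ck, ]
  expect_equal(causal_call$alt_depth, causal_call$total_depth)
  expect_gt(causal_call$total_depth, 0)

  # unlinked parent-private sites: mean alt fraction ~ 0.5 across seeds
  fracs <- unlist(lapply(1:40, function(s) {
    cfg <- small_cfg(s)
    parents <- simulate_parent_strains(cfg)
    f1s <- simulate_f1_cohort(parents, cfg)
    pool <- pool_and_sequence(f1s, parents, cfg)
    par <- parents$mutant_parent
    other <- par[!par$causal & !par$spurious &
                 par$contig != parents$causal$contig, ]
    m <- merge(pool, other[, c("contig", "pos")], by = c("contig", "pos"))
    m$alt_depth / m$total_depth
  }))
  expect_gt(length(fracs), 30)
  expect_lt(abs(mean(fracs) - 0.5), 0.05)
})

test_that("spurious artifact sites are emitted with low depth and perfect segregation", {
  cfg <- small_cfg(8)
  parents <- simulate_parent_strains(cfg)
  f1s <- simulate_f1_cohort(parents, cfg)
  pool <- pool_and_sequence(f1s, parents, cfg)
  spur <- parents$mutant_parent[parents$mutant_parent$spurious, ]
  sp_calls <- merge(pool, spur[, c("contig", "pos")], by = c("contig", "pos"))
  expect_equal(nrow(sp_calls), 4L)
  expect_true(all(sp_calls$total_depth < 0.25 * cfg$mean_coverage))
  expect_true(all(sp_calls$alt_depth == sp_calls$total_depth))
  expect_true(all(sp_calls$total_depth > 2))  # must survive the quality filter
})

test_that("pooling requires mutant F1s and honors the pool size", {
  cfg <- small_cfg(10)
  parents <- simulate_parent_strains(cfg)
  f1s <- simulate_f1_cohort(parents, cfg)
  wt_only <- Filter(function(f) f$phenotype == "wildtype", f1s)
  expect_error(pool_and_sequence(wt_only, parents, cfg), "empty pool")
  n_mut <- sum(vapply(f1s, function(f) f$phenotype == "mutant", TRUE))
  expect_error(pool_and_sequence(f1s, parents, cfg, n_pool = n_mut + 1),
               "n_pool")
})

test_that("decoupling phenotype from genotype removes the mapping signal", {
  cfg <- cross_sim_config(seed = 21, phenotype_linked = FALSE,
                          n_f1_total = 120)
  sim <- simulate_cross(cfg)
  fit <- bsa_map(sim$pool, sim$mutant_parent, sim$controls,
                 filter_config(genome_mean_depth = cfg$mean_coverage))
  expect_equal(nrow(fit$candidates), 0L)
})

test_that("the full simulated cross is reproducible from its seed", {
  a <- simulate_cross(small_cfg(33))
  b <- simulate_cross(small_cfg(33))
  expect_identical(a$pool, b$pool)
  expect_identical(a$causal, b$causal)
})
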