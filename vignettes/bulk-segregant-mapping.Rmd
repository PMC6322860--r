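---
title: "Mapping causal mutations in haploid crosses by bulk segregant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping causal mutations in haploid crosses by bulk segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmapper)
```

## The mapping model

A haploid mutant of *Salpingoeca rosetta* carries one causal lesion plus a
handful of passenger lesions, all private to the mutagenized parent. When
the mutant is crossed to a polymorphic Mapping Strain and haploid F1
offspring are isolated, each F1 is a recombinant mosaic of the two parental
genomes. Because the organism is haploid, genotype at the causal locus
determines phenotype directly: every mutant-phenotype F1 carries the causal
allele, while an unlinked parental lesion is inherited by only about half
of them.

Pooling the mutant-phenotype F1s converts this into a read-counting
problem. At a variant site with pooled alternative-allele frequency $f$,
per-read error rate $e$, and site depth $d \sim \mathrm{Poisson}(\mu)$
(with $\mu$ the mean pooled coverage), the alternative read count is

$$a \mid d \sim \mathrm{Binomial}\!\left(d,\; f(1-e) + (1-f)e\right).$$

At the causal site $f = 1$, so the expected alt fraction is $1 - e$; at an
unlinked parental lesion $f \approx 1/2$ and the expected fraction is
$\tfrac12(1-e) + \tfrac12 e = \tfrac12$. The filter cascade exploits this
separation:

1. **Shared with parent** — a causal mutation must be present in the
   parental mutant's own variant calls.
2. **Absent from controls** — variants also called in the Mapping Strain,
   wild type, or an unmutagenized control cannot cause the phenotype.
3. **Quality** — depth > 2, QUAL > 10, reference allele not N. All
   thresholds are strict inequalities, exactly as the procedure states
   them.
4. **Segregating** — alt fraction $a/d > 0.99$. With ~30 pooled haploids,
   even one non-carrier F1 pulls the fraction to $\le 29/30 \approx 0.967$,
   so this cutoff demands that essentially every pooled F1 carries the
   allele.
5. **Coverage mask** — segregating calls with
   $d \ge 0.25\,\bar\mu$ (a quarter of the genome-wide mean depth) are
   *robust*; the rest are reported as *low-coverage*. This stage is a
   partition rather than a filter: perfect segregation at anomalously low
   depth is the signature of a miscall in a repetitive or poorly assembled
   region, and keeping those sites visible (but masked) is what lets a
   report show, e.g., five segregating variants of which one is robust.

The two sides of the mask deserve a note: one could read "masking variants
detected with >0.25X coverage" either way around. We keep sites **at or
above** 0.25× of the mean as robust and mask those below, which is the
direction consistent with the validated outcome of the procedure (the true
causal variant sits at depth near the genome average; the spurious ones sit
far below it).

`bsa_map()` applies the stages in the order above and records, per variant,
a nested pass/fail flag per stage, the per-stage survivor counts, and the
robust candidates sorted by `(contig, position)`. Ties in reporting order
are broken lexicographically; alt fractions are reported at full precision.
Variant identity throughout is `(contig, pos, ref, alt)` — VCF semantics —
so a different alternative allele at the same position is a different
variant, and multi-allelic records are decomposed into biallelic rows on
input. An empty candidate set is a valid, reported outcome, which is what
an unmappable (polygenic or low-fitness) cross produces.

### Alt-fraction denominator

Variant callers disagree about whether "total high-quality reads" is the
`DP` field or the sum of the `AD` allele depths. `read_vcf()` uses the `AD`
sum when `AD` is present (allele depths are computed from the filtered
reads) and falls back to `DP` otherwise. This is a documented convention,
not a claim about any particular upstream pipeline.

## The cross simulator

`simulate_cross()` generates everything the cascade consumes, at the
variant/pileup level. Read alignment and variant calling are deliberately
out of scope — they belong to standard upstream tools — so the simulator
emits allele-depth tables (and VCF via `write_vcf()`), not reads.

Default study conditions, chosen once:

* **Genome**: 5 contigs × 1 Mb, a ~1/11 scale model of the 55 Mb genome.
  Positions are plain integers; nothing depends on sequence content.
* **Markers**: density $10^{-4}$ per bp (each bp independently a marker),
  i.e. ~100 markers per Mb distinguishing the Mapping Strain from the
  mutant background. The real marker map is sparse and uneven; a uniform
  density is the neutral choice.
* **Lesions**: 5 mutagenesis-induced variants private to the mutant parent,
  one flagged causal — the scale of per-strain variant counts such screens
  detect (whole-genome sequencing of the unmappable mutants found tens of
  lesions across 55 Mb, i.e. a few per 5 Mb).
* **Crossovers**: Poisson count per contig per meiosis with mean 4, uniform
  positions, no interference. No genetic map exists for *S. rosetta*; a
  yeast-like ~4 crossovers/Mb is consistent with the observation that no
  haplotype block co-segregates with the phenotype (high recombination
  decouples even nearby passengers from the causal site).
* **Pool and coverage**: 30 mutant-phenotype F1s pooled (the middle of the
  38/30/22 pool sizes used across real crosses); mean coverage defaults to
  187X (the published pooled coverage), with 150X used as the standard
  validation condition; per-read error $10^{-3}$.
* **Artifacts**: 4 spurious sites injected with alt fraction 1.0 and depth
  drawn uniformly between just above the quality-filter cutoff and just
  below $0.25\mu$. They are created *inside the parent's variant set*
  (flagged `spurious`), emulating shared miscalls in low-coverage regions —
  that is what lets them survive the parent-intersection stage and
  reproduce the observed "five segregating, one robust" structure, rather
  than being dropped at stage 1.
* **Phenotype**: fully penetrant and monogenic by default;
  `phenotype_linked = FALSE` decouples phenotype from genotype to emulate
  an unmappable cross for negative controls.

Every generator is a pure function of its configuration and seed (each
stage derives a fixed offset of the run seed), and seeds are recorded in
run manifests.

What the simulator does **not** emulate: read-level artifacts (mapping
bias, indel realignment, duplicate reads), linkage disequilibrium structure
beyond uniform Poisson crossovers, uneven marker spacing, copy-number
variation, and contamination. Passing validation therefore shows the
cascade's logic is correct under the stated read model — it does not show
robustness to upstream alignment pathologies, which the coverage mask only
partially addresses.

## Cross-genetics statistics

* `chisq_goodness_of_fit()` — Pearson $\sum (O-E)^2/E$ against an expected
  ratio (default 1:1, the haploid single-locus expectation), df = 1, upper
  tail, **no Yates correction** anywhere: the published
  $\chi^2 = 1.162 \Rightarrow p = 0.28$ is the uncorrected statistic.
* `linkage_chisq()` — Pearson 2×2 independence test on backcross
  genotype × phenotype counts. For a perfectly concordant table the
  statistic equals the grand total $N$ (21 and 89 for the two published
  backcrosses). Because such tables have empty cells, Fisher's exact test
  is available via `method = "fisher"`.
* `clonal_isolation_probability()` — limiting dilution: with empty-well
  fraction $\hat p$, $\lambda = -\ln \hat p$ and
  $P(\text{1 cell} \mid \text{occupied}) = \lambda e^{-\lambda}/(1 -
  e^{-\lambda})$, strictly increasing in $\hat p$. Well counts of 0 or
  100% empty are errors, not silent infinities.

## Clump quantification

`quantify_image()` pins the ImageJ chain's "default settings" explicitly so
results are bit-stable:

| Step | Semantics |
|---|---|
| Smooth | 3×3 mean, borders replicated |
| Find Edges | Sobel magnitude $\sqrt{G_x^2+G_y^2}$, 3×3 kernels |
| Despeckle | 3×3 median (19-exchange selection network) |
| Make Binary | IsoData iterative-intermeans global threshold, foreground strictly above |
| Dilate / Erode | 3×3 square element, one iteration each |
| Fill Holes | background unreachable from the border becomes foreground |
| Analyze Particles | 8-connected components, area strictly > 20 µm² |

Cell equivalents are particle area divided by a representative single-cell
area; the reference area is a required input (the published analysis
averaged measured wild-type cells; we do not hard-code a value).
Distributions are compared with the asymptotic two-sample
Kolmogorov–Smirnov test and summarized as median, interquartile range, and
the non-outlier range (1.5 × IQR fences) — the ingredients of a violin
boxplot.

The synthetic micrograph generator draws clumps as overlapping bright disks
(sunflower packing at ~1.6 r spacing so each clump is one connected blob)
with exact rasterized ground-truth areas, plus sub-cutoff dark bacterial
speckles and additive noise. Cells default to radius 2.6 µm (area
21.2 µm² — a single cell must clear the 20 µm² filter, as real wild-type
cells do) rendered at 0.05 µm/pixel. The resolution matters: the
edge-detect → close → fill chain systematically widens each particle by
roughly half the edge width (~2 px), so the relative area bias scales as
$\sim 2\delta/r$; at 52 px per cell radius it stays within a few percent,
comfortably inside the 10% tolerance we validate against. In real
micrographs the same bias affects numerator and denominator of the
cell-equivalent ratio alike and largely cancels.

## Fluorescence profiles

Profiles are sampled along a manually traced collar-to-collar polyline at
unit-pixel arclength spacing with bilinear sub-pixel interpolation,
normalized by the cropped image's maximum intensity, and linearly
interpolated onto 150 equally spaced points of normalized arclength
(endpoints preserved; resampling is idempotent on 150-point inputs). The
choice of *linear* interpolation is a documented convention — any
reasonable one-dimensional interpolant would serve.

The ensemble band is the pointwise t-interval
$\bar x \pm t_{0.975,\,n-1}\,s/\sqrt{n}$ at each of the 150 abscissae. This
is a per-point confidence band, not a simultaneous band; its pointwise
coverage is the nominal 95% (validated by simulation), but the probability
that the whole curve stays inside is lower. Published bands rarely state
their construction; the t-interval is our convention. Basal signal is
compared via each cell's mean over the central 20% of arclength (the basal
pole is the trace midpoint by construction of the trace) with a Welch
interval for the group difference.

## Problem sizes and numerical choices

Validation runs use a 5 × 1 Mb genome with 100 simulated crosses for the
recovery rate, 1000 random ≤100-site tables for the brute-force
equivalence check, 500 clumps per population for the K-S comparison, and
1000 simulated ensembles for band coverage — sizes chosen so the whole
suite completes in about a minute while keeping Monte-Carlo error well
below the tolerances tested. Degenerate inputs fail loudly by design:
zero-depth alt fractions, empty pools, all-empty or no-empty dilution
plates, constant images (empty mask with a warning), and fields too small
to place the requested clumps are all explicit errors.

## Known limitations

* The cascade consumes variant calls; garbage calls in, garbage out. The
  coverage mask catches low-depth artifacts but not systematically
  misaligned high-depth regions.
* The simulator's uniform-recombination, uniform-marker model understates
  the clustering of real markers and repeats.
* The K-S p-value is asymptotic; with heavy ties at small samples it is
  approximate (the published comparisons involve hundreds of clumps, where
  this is immaterial).
* Image quantification assumes phase-bright cells on a darker background;
  inverted-contrast inputs select the complementary class at thresholding.
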