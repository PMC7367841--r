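# oncomap

Comparative oncogenomics of canine mammary tumors (CMTs) in R.

Spontaneous mammary tumors of dogs share histology and molecular drivers
with human breast cancer while arising in an intact immune system, which
makes cohort-level CMT genomics a natural comparative model: which driver
mutations appear already in benign disease, what distinguishes malignant
progression (allele-frequency shifts, selection, copy-number
instability), and how do expression subtypes and their prognosis align
across species? `oncomap` implements the full analysis pipeline for such
a study as a tidyverse-native package — every user-facing function takes
a data frame and returns a tibble — together with a synthetic-cohort
generator that plants known ground truth, so the entire pipeline is
testable end to end without any sequencing data.

## What it computes

* **Variant post-filtering and landscape** — alignment-error removal by
  the pooled score rule *meanXS ≥ 0.8·meanAS*, six-class consequence
  mapping (missense / nonsense / frameshift / in-frame indel / splice /
  silent), recurrent-gene tables (strict >5% non-silent frequency),
  germline candidate filtering (depth ≥ 10, damaging annotation,
  MAF < 0.05), pathway aberration fractions.
* **Burden and selection** — TMB per Mb, purity adjustment (× 1/purity),
  hypermutation (> 10/Mb), benign-vs-malignant U tests of burden and
  mutant allele frequencies, and an opportunity-corrected dN/dS
  surrogate: dN/dS = [(n+½)/(s+½)] / (E_N/E_S) with a binomial test and
  BH correction.
* **Mutational signatures** — 96-channel trinucleotide spectra
  (pyrimidine-strand convention), de novo NMF deconvolution (generalized
  KL, multiplicative updates), cosine matching to any named catalog, and
  non-negative least-squares exposure fitting.
* **Copy number** — GC decile-median corrected log2 tumor/normal depth
  ratios, circular binary segmentation (permutation-tested recursive
  splits, C++ core), genome fraction altered, and simplified G-score
  recurrence peaks with a cyclic-shift null.
* **Cross-species projection** — UCSC chain parsing/validation, interval
  projection with exact unmapped accounting and strand reflection,
  coverage-weighted projection of copy-number profiles onto a second
  genome with re-segmentation, cross-cohort amplification/deletion
  correlation.
* **Expression subtyping** — consensus NMF with cophenetic + dispersion
  rank selection, tumor-specific metagene designation and cluster
  assignment (ties and normal-dominated samples → UNASSIGNED), preranked
  GSEA, up/down signature scores, Kaplan–Meier/log-rank survival
  stratification.
* **Cohort statistics** — exact two-sided Fisher (minimum-likelihood
  rule), exact/asymptotic Mann–Whitney U, multi-group log-rank, one-way
  ANOVA, BH FDR, and gene-set enrichment over an explicit universe.

## Worked example

Simulate a 24-sample cohort (planted drivers, an aging-like CpG>T
signature at weight 0.85, a +1 log2 amplification on chr1:20–40 kb in
malignant genomes), then run the pipeline:

```r
library(oncomap)
library(dplyr)

genome <- genome_spec(c(chr1 = 6e4, chr2 = 4e4), bin_size = 1000,
                      planted_segments = tibble(chrom = "chr1", start = 2e4,
                                                end = 4e4, true_log2 = 1))
spec   <- cohort_spec(n_samples = 24, tmb_rate = 60, seed = 1)
cohort <- simulate_mutation_cohort(spec, genome)

filt <- alignment_error_filter(cohort$variants, cohort$scores)
nrow(filt$kept)
#> [1] 1397        # 27 planted alignment-error sites removed from 1424

recurrent_gene_table(filt$kept, cohort$metadata)$recurrent |>
  filter(gene %in% spec$driver_freqs$gene)
#> # A tibble: 5 × 3
#>   gene   n_mutated frequency
#>   <chr>      <int>     <dbl>
#> 1 PIK3CA         7    0.292
#> 2 KRAS           3    0.125
#> 3 AKT1           2    0.0833
#> 4 PTEN           2    0.0833
#> 5 TP53           2    0.0833
```

PIK3CA is the most frequent driver and KRAS/TP53/AKT1 sit near their
planted malignant rates. Signature exposures recover the planted
0.85/0.15 mixture:

```r
reference <- simulate_reference(genome, spec$seed)
spectra   <- build_spectrum(filt$kept, reference)
fit       <- fit_exposures(rowSums(spectra), spec$catalog)
tidy(fit)
#> # A tibble: 2 × 3
#>   signature   exposure proportion
#>   <chr>          <dbl>      <dbl>
#> 1 Deamination     929.      0.851
#> 2 Flat            163.      0.149
```

Segmentation of a malignant genome's GC-corrected depth ratios recovers
the planted amplification with exact breakpoints:

```r
depth <- simulate_depth_bins(spec, genome)
segs  <- cbs_segment(gc_correct_ratio(filter(depth, sample_id == "CMT-024")),
                     nperm = 1000, seed = 1)
segs
#> # A tibble: 4 × 5
#>   chrom start   end n_bins seg_mean
#>   <chr> <dbl> <dbl>  <dbl>    <dbl>
#> 1 chr1      0 20000     20  -0.0450
#> 2 chr1  20000 40000     20   0.685
#> 3 chr1  40000 60000     20  -0.155
#> 4 chr2      0 40000     40  -0.0876
genome_fraction_altered(segs)
#> [1] 0.2
```

The +0.69 segment mean reflects the planted +1.0 event diluted by that
sample's purity. Benign-vs-malignant comparison shows the planted
allele-frequency shift with no burden difference:

```r
compare_burden_and_maf(filt$kept, cohort$metadata) |>
  select(measure, u, p, median_benign, median_malignant)
#> # A tibble: 3 × 5
#>   measure            u             p median_benign median_malignant
#>   <chr>          <dbl>         <dbl>         <dbl>            <dbl>
#> 1 tmb              56  0.568                  1.63             1.47
#> 2 adjusted_tmb     41  0.679                 68.3             67.1
#> 3 vaf          124860. 0.00000000128          0.27             0.31
```

Expression subtyping, cluster assignment, GSEA, signature scoring and
survival stratification work the same way from
`simulate_expression_cohort()` / `nmf_metagenes()` /
`stratify_and_survive()`; see the methods vignette
(`vignettes/oncomap-methods.Rmd`) for the models, parameter defaults and
their rationale.

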