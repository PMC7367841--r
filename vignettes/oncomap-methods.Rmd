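---
title: "Methods: comparative oncogenomics of canine mammary tumors with oncomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative oncogenomics of canine mammary tumors with oncomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncomap)
library(dplyr)
```

# Scope

`oncomap` implements the analysis pipeline of a cohort-level comparative
oncogenomics study of canine mammary tumors (CMTs): somatic-variant
post-filtering and landscape statistics, tumor mutational burden (TMB) with
purity adjustment and a dN/dS selection surrogate, trinucleotide
mutational-signature analysis, read-depth copy-number profiles with
circular binary segmentation (CBS) and recurrence peaks, cross-species
projection of copy-number profiles through UCSC chain alignments,
consensus-NMF expression subtyping with survival analysis, and the exact
and asymptotic cohort statistics used throughout. A synthetic-cohort
module generates every input with planted ground truth, so the complete
pipeline is exercised end to end by the test suite without any external
download.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and the known limitations. It states no
empirical result that the package's tests and `scripts/acceptance.R` do
not themselves compute.

# Variant post-filtering

**Alignment-error filter.** Candidate SNV sites can arise from ambiguous
read placement. For every alt-supporting read the aligner reports an
optimal alignment score (AS) and, when a secondary placement exists, a
suboptimal score (XS). Pooling all alt reads of all samples sharing a
site, the site is rejected when

$$\overline{XS} \ge 0.8 \times \overline{AS}.$$

The ratio (default 0.8) and the pooling across samples are the method's
definition; per-sample filtering is deliberately not applied. Reads with
no secondary hit contribute XS = 0 — a read that maps nowhere else is
maximal evidence against an alignment artifact, so missing XS must lower,
not raise, the site's mean.

**Consequence classes.** Annotation terms (Sequence Ontology vocabulary,
shipped as `inst/extdata/consequence_classes.tsv` so dialects can be
swapped) map deterministically onto six functional classes: missense,
nonsense, frameshift, in-frame indel, splice, silent. For indels the
annotation string is overridden by arithmetic: a net length change
divisible by 3 is in-frame, anything else a frameshift. Unknown terms map
to `other` (non-silent = FALSE) with a warning rather than an error, so a
single unexpected annotation cannot abort a cohort run.

**Recurrence and germline filtering.** A gene is recurrently mutated when
the fraction of samples with at least one *non-silent* mutation strictly
exceeds 5% (configurable). Germline candidates survive only if read depth
is at least 10 in tumor and normal (or in normal alone when no tumor
depth exists), the annotation is truncating/pathogenic/likely-pathogenic,
and both the population and cohort minor-allele frequencies are below
0.05 (missing population frequency counts as novel, i.e. passes). The
filter is idempotent by construction.

# Burden and selection

TMB is the count of exonic mutations (silent and non-silent, SNVs and
indels) per sample, normalized per megabase of callable region. There is
no canonical canine exome size; the default `target_mb = 38` is an
explicit convention, not a measurement. Hypermutation is a strict
`> 10 mutations/Mb` call.

Purity dilutes the detectable mutant fraction roughly in proportion to
the neoplastic cell content, so the purity-adjusted burden multiplies the
observed count by `1/purity`. The correction factor is pluggable
(`factor_fn`) because this linear model is an approximation: detection
sensitivity is not exactly linear in purity at fixed depth.

The selection surrogate compares observed nonsynonymous/synonymous SNV
counts to a mutational-opportunity model (per-gene expected
nonsynonymous `E_N` and synonymous `E_S` opportunity, pre-weighted by a
96-channel rate vector):

$$\mathrm{dN/dS} = \frac{(n_{obs}+0.5)/(s_{obs}+0.5)}{E_N/E_S},$$

with a two-sided binomial test of `n_obs` among all classified SNVs
against the neutral proportion `E_N/(E_N+E_S)` and BH correction within
the scope (gene or sample). The 0.5 pseudocounts keep ratios finite at
zero counts; a sample with no classifiable SNVs reports dN/dS = 1 and
p = 1 by convention. This is a deliberately simple surrogate: it corrects
for opportunity but fits no covariates and no overdispersion, so its
p-values are calibrated only under the stated binomial model (the test
suite verifies this calibration on neutral simulations).

# Mutational signatures

Spectra use the canonical 96 channels: six pyrimidine-strand substitution
classes times 16 flanking contexts, contexts alphabetical within class
(`A[C>A]A` … `T[T>G]T`). Purine-reference SNVs are reverse-complemented;
catalogs are aligned by channel *name*, never position, so any
row-stochastic catalog TSV is interchangeable.

De novo deconvolution factorizes the 96 × samples count matrix by
multiplicative updates minimizing the generalized Kullback–Leibler
divergence — the natural objective for Poisson-like counts and the one
used by the established signature-discovery frameworks — taking the best
of `restarts` random initializations (deterministic given `seed`; the
objective is non-increasing per iteration, which the tests assert on
arbitrary input). Exposure fitting against a fixed catalog instead solves
Euclidean non-negative least squares (via `pracma::lsqnonneg`): with a
known catalog the problem is convex and NNLS is exact, reproducible and
fast. This objective asymmetry (KL for discovery, Euclidean for
refitting) is intentional and documented here.

# Copy-number analysis

Tumor/normal depth ratios are median-normalized and GC-corrected by
dividing each bin's ratio by the median ratio of its GC decile
(`n_bands = 10`, configurable). Decile medians were chosen over loess for
transparency and testability; they remove any monotone multiplicative
bias exactly in expectation, as the bias-removal simulation in the test
suite checks. Zero-depth bins are masked before the log2 transform.

CBS recursively finds, per chromosome, the circular arc maximizing the
two-sample t statistic (pooled within-segment variance; prefix-sum scan
implemented in C++), and accepts the split only if a within-segment
permutation p-value is at most `alpha = 0.01` (`nperm = 1000`,
deterministic given `seed`, minimum segment width 3 bins). The "undo
splits" refinement of the reference implementation is omitted — at the
signal-to-noise ratios of binned exome depth it changes little, and
omitting it keeps the algorithm testable as a pure recursive procedure.
Segments never cross chromosome boundaries and tile the binned genome;
the weighted mean of segment means reconstructs the global mean to 1e-9.

Genome fraction altered is the length-weighted fraction of segments with
`|log2 ratio|` strictly above 0.2. The ±0.2 amplitude thresholds here and
in recurrence scoring are conventions (≈ one copy gained/lost at 70%
purity would give ~±0.5; ±0.2 catches subclonal and low-purity events)
and are exposed as arguments.

Recurrence peaks use a simplified G-score: per bin, the sum over samples
of the amplitude excess beyond the threshold (mirrored for deletions) —
frequency × amplitude, as in the established recurrence tools. The null
preserves within-sample segment structure by cyclically shifting each
sample's bin-level profile; per-bin empirical p-values (pooled null) are
BH-corrected and peaks are maximal runs with q ≤ 0.25. This replaces the
reference tool's semi-exact background model and peel-off peak
definition; it is a surrogate suited to cohort-level synthetic tests, not
a reimplementation.

# Cross-species projection

UCSC chain semantics: the "target" (t) side is the assembly projected
*from*, the "query" (q) side the assembly projected *to*; tStrand is
always `+`; negative-strand q coordinates live on the reversed sequence
and are reflected via `pos' = qSize − 1 − pos`. The parser verifies the
format invariants (block sizes and gaps summing to the stated spans)
and rejects violations with the chain id and line number.

Interval projection maps bases through aligned blocks only; gap bases are
reported as unmapped, and mapped mass is conserved exactly
(`mapped + unmapped = interval length`). Where several chains cover a
base, the highest-scoring chain wins — the common liftover convention,
configurable in principle by pre-filtering the chain set. Projected
copy-number profiles weight each target bin by mapped base pairs
(`Σ log2·bp / Σ bp`), carry missing (not zero) values in uncovered bins,
are smoothed with a centered moving median (default window 5 bins —
"smoothing" is otherwise unspecified in the source method, and a median
window is robust to single-bin projection artifacts) and re-segmented
with CBS. Per-sample projection precedes any cohort aggregation. Default
target bin size for cross-cohort correlation is 1 Mb. Cohort
amplification/deletion scores are per-bin sums of positive/negative
parts, correlated (Pearson) over bins covered in both cohorts.

# Expression subtyping

Expression input is `log2(FPKM+1)`; the `top_n = 2000` most-variable
genes are kept before factorization (gene filtering is a standard
stabilizing step the source method leaves unstated). Consensus NMF runs
`restarts = 30` Euclidean multiplicative-update factorizations per rank
in 2–10, assigns each sample to its dominant metagene per run, and
records co-assignment frequencies in a consensus matrix. Stability per
rank is the cophenetic correlation between consensus distances and the
cophenetic distances of average-linkage clustering of the consensus.

**Rank selection.** The selected rank is the largest k whose consensus is
both *hierarchical* (cophenetic ≥ 0.95) and *crisp* (dispersion
coefficient — the mean of `4(c−0.5)²` over consensus entries — ≥ 0.99).
The crispness requirement is this package's design choice: above the true
rank, duplicated factors split a real cluster and the resulting consensus
is fuzzy (within-block co-assignment near 0.5) yet still perfectly
hierarchical, so cophenetic correlation alone cannot reject inflated
ranks. If no rank qualifies, the smallest candidate is returned with a
warning (this is what a rank-1 input produces: every restart puts all
samples in one cluster, which is treated as trivial, not as stability).

Tumor-specific metagenes are those whose mean activity in tumor samples
exceeds that in adjacent-normal samples (manual override supported).
Samples are assigned to their dominant metagene when it is
tumor-specific; a dominant normal metagene or an exact tie leaves the
sample UNASSIGNED — this is the mechanism by which a subtyped cohort can
be smaller than the assayed cohort.

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum (weight
`|score|^p`, default p = 1) with a gene-label permutation null; the
two-sided p-value comes from the sign-matched tail and the normalized ES
divides by the mean absolute same-sign null. With p = 1 the ES is
invariant under positive rescaling of the scores; full invariance under
arbitrary strictly monotone transforms holds only for the rank-based
p = 0 statistic — both are verified in the tests at their own scope.

Signature scores z-score genes across samples and either correlate a
sample's z-profile with a ±1 up/down template (correlation mode, bounded
in [−1, 1]) or take `mean z(up) − mean z(down)` (mean-difference mode).
An empty down set collapses both modes to the mean expression of the up
genes, which covers single-direction scores such as EMT or metagene
averages. Zero-variance genes are dropped with a warning. Median splits
of continuous scores send samples at the median to the low group.

# Cohort statistics

The 2×2 Fisher test is the exact hypergeometric test with the two-sided
minimum-likelihood rule (all tables with probability ≤ observed ×
(1+1e-7) are summed) — the convention of the widely used reference
implementations, which the test suite verifies against an exhaustive
enumeration oracle for every table with total N ≤ 40. The Mann–Whitney U
test enumerates exactly when both groups have ≤ 20 observations and no
ties, otherwise uses the normal approximation with tie and continuity
corrections; a completely degenerate comparison (all values identical)
reports p = 1. The log-rank test is the standard multi-group chi-square
with simultaneous risk-set accounting at ties (delegated to
`survival::survdiff`); one-way ANOVA is the classical F test, returning
F = 0, p = 1 with a warning when every group is a constant and all
constants are equal. BH q-values come from `stats::p.adjust`; note that
BH step-up is *not* idempotent (re-adjusting q-values inflates them), so
only monotonicity is asserted. Pathway enrichment builds each 2×2 table
over an explicit, caller-supplied gene universe — no default universe is
assumed, because enrichment p-values are meaningless without one.

# The synthetic cohort

The generator's defaults are the study conditions, fixed once:

* cohort: `benign_fraction = 0.225` (benign tumors are roughly a quarter
  of spontaneous CMT cohorts), `tmb_rate = 43.5` exonic mutations/sample
  (Poisson), `indel_fraction = 0.21`, purity uniform on [0.7, 1] (only
  high-purity specimens pass histological review), `target_mb = 38`;
* drivers: PIK3CA (0.55 benign / 0.38 malignant), TP53 (0 / 0.11), KRAS
  (0.02 / 0.13), PTEN (0.04 / 0.07), AKT1 (0 / 0.05) — the pattern of an
  early ubiquitous PI3K driver and malignant-restricted late drivers;
* signatures: an aging-like CpG `N[C>T]G` deamination profile at weight
  0.85 plus a flat background at 0.15, mirroring a cohort dominated by a
  single age-related process;
* allele frequencies: clonal fraction uniform on (0.2, 1) for benign and
  (0.5, 1) for malignant, times purity/2, with binomial sampling noise at
  read depth 100 — malignant VAFs are therefore stochastically larger by
  construction (the planted analog of clonal sweeps during malignant
  progression);
* alignment-error sites: 2% of variant sites get suboptimal scores at
  85–100% of the optimal score; clean sites 0–40%.

Each generator call uses a single RNG stream seeded from the spec seed;
per-sample sub-streams are derived at fixed offsets (7919·i for
mutations, 104729+i for purity, 15485863+i for depth), so enlarging a
cohort never reshuffles existing samples, and purities agree across the
mutation and depth generators. Toy references are i.i.d. uniform ACGT;
mutation contexts are located by scanning the reference, never by
resampling it, and passenger mutations are excluded from the driver gene
intervals so planted driver frequencies are exactly Bernoulli. Depth bins
apply a monotone GC bias (0.6 + 0.8·GC) to tumor and normal alike and
scale tumor depth by `purity·2^log2 + (1−purity)` inside planted
segments, which are applied to malignant samples only. The default GC
profile is a deterministic short-period wave (period ≈ 7 bins) so that GC
correction bands sample bins across the genome instead of being
confounded with planted segments — real GC varies at a much finer scale
than copy-number events.

What the generator does **not** emulate: read-level data (no FASTQ/BAM),
germline haplotypes, subclonal copy number, correlated noise between
genes, platform/batch effects, or realistic gene structure (codons,
splice sites). Passing tests therefore demonstrate that the algorithms
recover *planted* parameters under their stated noise models — not that
they are robust to everything real data does.

The toy chain generator emits valid chain text from an explicit block
map and also returns a per-base source→target map computed directly from
the blocks, bypassing the chain arithmetic. That map is the oracle the
projection tests compare against, base for base.

# Problem sizes

The test suite and acceptance script run at deliberately small scale,
chosen once as adequate for the statistical checks involved: toy genomes
of ~100 kb in 100–1000 bins, cohorts of 12–40 samples (400 for the
driver-frequency calibration), ~5,000–10,000 mutations for spectrum and
exposure recovery, 1,000-bin CBS profiles at signal-to-noise 10, null
calibrations of 60–200 replicates, and 100-seed power estimates. All
randomness flows from explicit seeds.

# Known limitations

* The dN/dS surrogate ignores covariates and overdispersion; its
  q-values should not be compared numerically with covariate-based
  estimators on real cohorts.
* The recurrence-peak null (cyclic shifts, pooled empirical p) is a
  surrogate for the established semi-exact background model; peak
  boundaries are q-runs, not peel-off peaks.
* CBS omits the undo-splits refinement; on very noisy profiles it can
  oversegment relative to the reference implementation.
* On exactly separable, noiseless cluster data, consensus stability is
  degenerate above the true rank: a duplicated factor that splits a
  block *consistently* is genuinely stable, so the largest-stable-k rule
  can overshoot there. With any realistic noise (generator default
  `noise_sd = 0.5`) selection is reliable; the acceptance suite asserts
  exact-label recovery and perfect stability at the planted rank for the
  noiseless case and planted-rank selection at default noise.
* Chain projection resolves overlapping chains by score only; it does
  not implement net/level filtering of chain files.
* GC correction by decile medians assumes the altered fraction of the
  genome within any GC band is modest; a genome that is mostly aberrant
  would bias the band medians.
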