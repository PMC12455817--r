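---
title: "Models and methods: SPE complementation, heterosis variance and eQTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: SPE complementation, heterosis variance and eQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speqtl)
```

This vignette documents the models the package fits, the conventions and
tunable parameters, what the synthetic-cross generator does and does not
emulate, and the design choices made where a procedure admitted more than
one reading. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The genetic material being modelled

An intermated RIL population descends from two founder inbreds (called
B73 and Mo17 throughout) via an F1, several generations of intercrossing,
and selfing to near-homozygosity. Crossing each RIL back to both founders
yields two hybrids whose genomes are mosaics of homozygous and
heterozygous blocks: a region where the RIL carries the non-recurrent
founder's alleles is heterozygous in that backcross and homozygous in the
other. This complementary structure is what lets SPE complementation be
attributed to hetero- vs homozygosity.

## Genome mosaic classification

Input is a long genotype-call table (sample, locus, call, GQ), the shape
a joint genotyping pipeline emits. All coordinates in the package are
1-based, closed intervals, in bp; BED output converts to 0-based
half-open on disk.

The rules, all exposed as defaults of `classify_ril_regions()`:

* only biallelic calls with GQ >= 10 are used (except contamination
  flagging, which deliberately ignores GQ);
* a locus is founder-discriminating when >= 90% *and* >= 3 of the
  qualifying calls in each founder panel are the expected homozygote;
* calls matching neither founder allele are RIL-specific; such loci
  grouped at < 2.5 Mbp form a block, and blocks with >= 10 loci of which
  >= 5 homozygous are masked as third-origin regions;
* a 15-locus sliding window labels its loci Mo17 when >= 11 are
  homozygous Mo17, B73 when >= 12 are homozygous B73, else ambiguous;
* surviving same-allele loci < 0.5 Mbp apart merge into blocks whose
  first and last member loci delimit the reported region;
* a RIL whose masked length exceeds 50% of its classified-plus-masked
  length is excluded together with its hybrids (strict `>`).

**Interpretations where the procedure is underspecified.** The window
slides by one locus, and a locus survives only if *every* window covering
it is labelled and matches the locus's own call — the most conservative
reading of dropping loci "classified differently from their window".
Regions span member loci only (no extrapolation into gaps); gaps are
no-information. A gene belongs to the region containing its annotated
start; a gene whose start and end fall in differently classified regions
is set to no-information with a warning. The heterozygosity fraction of a
hybrid divides heterozygous classified length by total classified length,
excluding masked and no-information length from the denominator.

## Activity calling and normalization

Counts are normalized multiplicatively: `normalized = raw x gene_factor
x sample_factor`.

* The gene factor is the inverse of a predictive count from a penalized
  additive smoother (`mgcv::gam`, thin-plate splines, smoothness by GCV)
  of log mean count on GC fraction and log gene length. The model class
  is fixed but basis and penalty were open; GCV-tuned thin-plate splines
  are mgcv's defaults and need no per-dataset tuning. With fewer than 10
  distinct covariate values the term degrades to linear, and constant
  covariates fall back to the grand mean with a warning.
* The sample factor comes from trimmed-mean-of-M-values (TMM)
  normalization (via edgeR, trim 30% on M and 5% on A — the method's
  canonical values; the reference library is the one whose upper
  quartile is closest to the mean upper quartile). The package reports
  `1 / (library size x TMM factor)` rescaled to geometric mean one as
  the multiplicative factor, plus `ref_ratio`, the factor relative to
  the reference sample (a doubled library has `ref_ratio` 0.5).

The activity threshold tau is the empirical 0.25 quantile
(linear-interpolation convention, R quantile type 7) of the pooled
*nonzero* genotype mean expressions; a direct empirical quantile is used
rather than a density estimate because the quantile is the operative
statistic. Activity is strict: a gene is active only when its mean
exceeds tau, so ties and zeros are inactive. Scaling all counts by a
constant scales tau identically and leaves every call unchanged. Genotype
means are computed over all retained replicates.

## SPE pattern taxonomy

A gene shows SPE in a hybrid when the hybrid is active and exactly one
parent is. Patterns 1–4 apply to B73 x RIL hybrids and 5–8 to Mo17 x RIL
hybrids, crossing zygosity (heterozygous vs homozygous recurrent-founder)
with the active parent (maternal founder vs paternal RIL). SPE genes with
masked or unknown zygosity stay `UNCLASSIFIED` but still count toward
per-hybrid SPE totals. Pattern-count differences between patterns are
tested with a Gaussian mixed model (`nlme::lme`) with the hybrid as
random effect, pattern as fixed factor and a separate residual variance
per pattern (`varIdent`), followed by pairwise Wald contrasts; if the
heteroscedastic fit fails to converge the model falls back to a
homoscedastic mixed model, then to ordinary least squares.

## Heterosis variance decomposition

Plant-level trait values are analysed on a transformed scale: size-like
traits (total root length, total root volume, number of root tips) as
`sqrt(y + 0.5)`, lateral root density untransformed. The variance models
are fitted on this transformed scale.

The baseline model fits fixed genotype and block effects with nested
random effects for batch, system, triplet and row; genotype adjusted
means are the genotype coefficients plus the average block effect.

The full heterosis model replaces the genotype factor with per-parent
covariates: a parent's own covariate is 1; a hybrid carries 0.5 on each
parent (mid-parent heterosis) or 1 on the better parent (better-parent
heterosis, which requires parental means to decide "better"). Block
enters as dummies for blocks 2..k with no intercept. Four slopes
`gamma_1..gamma_4` multiply the per-hybrid counts of the four SPE
patterns (zero for parents), `phi` is the hybrid intercept, and the
genotype random effect is switched on only for hybrids via
`(0 + z | genotype)` with the hybrid dummy `z`. Fitting is REML via
`lme4::lmer`. The null model drops the four SPE slopes. Then

`p_Het = 1 - sigma2_Het / sigma2_G`

with `sigma2_Het` the hybrid-deviation variance of the full model (the
heterotic variance the SPE counts cannot explain) and `sigma2_G` that of
the null model (total genetic variance among hybrids). These names
follow the convention that reproduces the published worked examples
(e.g. `1 - 0.232/0.325 = 0.29`); the source's running text swaps the two
symbols relative to its table footnote, and the footnote is taken as
authoritative because its arithmetic checks out. `p_Het` may be
negative — the null model simply fit better — and is undefined when
`sigma2_G = 0` (an error).

Two deliberate choices: the printed model shows a single slope symbol on
all four SPE covariates, which is treated as a typo for four distinct
slopes (`shared_slope = TRUE` restores the single-slope variant); and
SPE counts enter unstandardized, in genes. Since REML likelihoods are
not comparable across different fixed effects, the package asserts
convergence and non-negative components rather than a likelihood
ordering between full and null models. Adding a constant to the trait
changes `phi` only.

## eQTL mapping

Genotypes are coded 1/2 (founder homozygotes for selfed RILs;
recurrent-homozygote/heterozygote for a backcross). Preparation drops
individuals with > 19% missing calls, duplicated individuals, and
markers with > 60% missing; markers are thinned greedily to >= 1 cM
spacing (keeping the first of each run) and pseudomarkers are inserted
on a 1-cM grid, with physical positions interpolated from the cM-bp map.
The genetic map is taken from the simulator's truth or a supplied map —
iterative map re-estimation is out of scope, and a linear cM/Mbp map
makes the two equivalent in simulation.

A two-state hidden Markov model (forward–backward, genotyping error
0.001, Haldane recombination fractions; RIL-by-selfing map expansion
`R = 2r/(1+2r)`) yields genotype probabilities at every grid position;
missing genotypes and pseudomarkers are uninformative emissions, and the
posteriors sum to one by construction. The Haley–Knott scan regresses
each phenotype on the expected genotype dosage and reports
`LOD = (n/2) log10(RSS0/RSS1)`, capped at 300 for exact fits; zero
phenotypic variance gives a flat zero curve.

Significance is permutation-based: the phenotype is reshuffled
(10,000 times in production; tests and the reproduction script use
1,000) recording each genome-wide maximum; the threshold is the 99.9th
percentile of the maxima (alpha 0.001), and the adjusted p of a peak is
the fraction of maxima at least as large, reported as `0.5/n_perm` when
the observed value exceeds every permutation. Across genes,
Benjamini–Hochberg is applied to the adjusted p-values with the
effective test count equal to the total number of genes scanned plus the
number of second-and-further peaks; peaks with q <= 0.001 are retained.

Peaks are local maxima above the threshold separated by a drop of at
least 1.5 LOD; the support interval is the contiguous region within 1.5
LOD of the peak, expanded by one grid position per side (the published
procedure says only "confidence interval"; the 1.5-LOD drop is this
package's convention, as is lowest-coordinate tie-breaking on plateaus).
Peaks of one gene from different datasets are merged unless they are
>= 25 Mbp apart or on different chromosomes *and* outside each other's
support intervals; within a merged group the shortest interval (highest
LOD on ties) survives. A peak is cis when it lies within 2.5 Mbp of its
gene's start on the same chromosome or its interval covers the start;
otherwise trans.

## Association and synteny

The per-gene TWAS is a deliberately simplified stand-in for multi-locus
mixed-model software: within each population, genes active in >= 5% of
genotypes are rescaled to [0, 2], and each gene's rescaled expression is
tested in `lm(trait ~ expression + 3 expression PCs)` with Bonferroni
control at 0.05 over the tested genes. No kinship matrix and no
multi-locus forward selection are used, so hit lists are not expected to
match multi-locus methods — the surface (inputs, filters, rescaling,
multiplicity control) is what is preserved. TWAS hits with SPE in more
than 10 hybrids are TSG candidates; activity–trait differences use an
equal-variance Student t-test; cis/trans against syntenic/non-syntenic
is a two-sided Fisher exact test.

## The synthetic-cross generator

The generator provides every input with known ground truth:

* **Meiosis** — crossovers per chromosome are Poisson with mean the map
  length in Morgans, positions uniform, no interference (Haldane); a
  linear cM/Mbp map links genetic and physical scales. The population
  goes through 4 generations of intercrossing (the study population's
  history) and 6 explicit selfing meioses, after which one gamete is
  drawn and doubled — residual heterozygosity is idealized to zero, with
  genotype-call error supplying the realism (default error rate 0.006,
  motivated by a median of 99.4% homozygous calls in real inbreds).
* **Genotype calls** — founders are homozygous reference (B73) and
  alternate (Mo17); hybrids are heterozygous where the RIL mosaic
  differs from the recurrent parent; third-origin segments emit alleles
  matching neither founder. GQ is a two-component mixture (high = 99, a
  configurable fraction below 10), since no GQ distribution was
  published. Calls flip to a random wrong genotype with the error rate
  and drop to missing with the missing rate.
* **Expression** — expected count = log-normal baseline x activity x
  artifact(GC, log length) x library size, with negative-binomial noise.
  Activity implements the regulatory model: a gene silenced by one
  founder's allele is active only when the genotype carries at least one
  copy of the other founder's allele at the gene's eQTL locus. Cis eQTL
  sit within 1 Mbp of the gene start; trans eQTL sit on another
  chromosome (83%) or >= 5 Mbp away.
* **Design and phenotypes** — an alpha design with 3 blocks x 4 batches
  x 8 systems x 12 rows x 8 plants; three consecutive rows form a
  triplet (RIL + both backcross hybrids), 2 reference triplets per
  batch, randomized per block. Phenotypes follow the full-model
  structure generatively, and the generator returns the implied true
  p_Het for recovery experiments.
* **Genome defaults** — 5 chromosomes x 50 Mbp at 20 loci/Mbp and
  2.5 cM/Mbp. This is a deliberately scaled-down genome: it preserves
  the quantities that drive the methods (marker density per cM,
  breakpoint spacing, block-length scales relative to the 2.5/0.5-Mbp
  rules) at a size where the full pipeline runs in minutes. It does
  **not** emulate read-level artifacts, alignment errors, reference
  bias, linked selection, segregation distortion or real LD structure,
  so passing recovery tests demonstrates correctness of the inference
  chain, not robustness to those real-data phenomena.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` use: 12 RILs on a 3 x 30 Mbp
genome for region-classification recovery; 6 RILs x 200 genes for the
SPE-oracle equivalence; 80 hybrids x 100 replicates per implied truth
(0, 0.15, 0.3) for p_Het recovery; 150 RILs, 500 null genes and 1,000
permutations for threshold calibration; and 100 genes (half cis, half
trans, effect 1.5 SD) for cis/trans recovery. These sizes were chosen so
each study gives stable Monte-Carlo answers while the whole validation
finishes in minutes on one CPU.

## Known limitations

* The TWAS stand-in ignores kinship; with strong population structure
  its error control is optimistic.
* `p_Het` relies on REML point estimates of two variances; no
  uncertainty interval is attached to it.
* The peak-support convention (1.5-LOD drop) and the window-label
  conflict rule are this package's interpretations of underspecified
  procedures; both are parameterized so other conventions can be tried.
* The generator's idealized homozygosity means sample-level
  heterozygosity filtering is exercised by error injection rather than
  true residual heterozygosity.
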