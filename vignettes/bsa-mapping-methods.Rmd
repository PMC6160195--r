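---
title: "Methods: bulked-segregant scans, their thresholds, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant scans, their thresholds, and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamapr)
```

This vignette explains the statistical model behind `bsamapr`, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one reasonable convention exists.

## The design and its assumptions

The package targets a classical BSA-seq design: an F2 from a cross between
two inbreds fixed for alternative alleles genome-wide, with two DNA pools
drawn from the phenotypic extremes (here 37 high-trait and 18 trait-free
plants out of 383) and sequenced together with both parents. The working
assumptions are:

* biallelic SNPs, parents fixed for different nucleotides (sites violating
  this are filtered or dropped as uninformative);
* pooled read counts reflect pool allele frequencies (equal DNA per plant,
  no amplification bias);
* a single major locus drives the phenotypic selection of the bulks, so
  away from it both pools sample the same 1:1 allele distribution.

## SNP quality filtering

Four rules are applied in a fixed order, and each rejected record is
charged to the *first* rule it fails, giving an additive rejection tally:
multi-allelic; depth below `min_depth_per_sample` (default 4, applied to
each of the four samples independently); identical pool genotypes;
parental-origin inconsistency. Two conventions needed fixing:

* **Pool "genotype".** Pools are mixtures, so exact count equality between
  pools would be vacuous. A pool's genotype is defined as the *set* of
  nucleotides whose within-pool frequency exceeds a noise floor (default
  0.1, chosen above any plausible sequencing-error rate and below the
  smallest real allele frequency a bulk of 18–37 plants can carry at
  useful depth).
* **Recessive consistency.** The rule "a pool must not carry an allele
  absent from both parents" is the testable reading of requiring recessive
  alleles to descend from the recessive parent; presence in a parent is
  judged with the same noise floor.

The identity-of-pool-genotypes rule deserves a caveat: on idealized pooled
reads at 30–50× depth, every unlinked SNP segregates near 0.5 in both
pools, so both pool genotype sets are `{ref, alt}` and the rule would
reject essentially the entire unlinked background — exactly the SNPs the
confidence thresholds are calibrated on. The rule is meaningful for
caller-issued genotype columns on real data (where pools are often called
as discrete genotypes), so it is implemented and tested in full, but the
pipeline default (`pipeline_config()`) leaves it off for simulated scans.

## The Euclidean-distance scan

At each SNP the statistic is the Euclidean distance between the two pools'
four-nucleotide frequency vectors; it ranges from 0 (identical pools) to
√2 (pools fixed for different alleles). The squared series ED² is what is
smoothed and thresholded: squaring shrinks background values (ED < 1)
and amplifies large divergences, which is the point of using it.

Numerical choices:

* **Loess span 0.3, degree 2**, per chromosome, fitting ED² against
  physical position. The span is a fraction of each chromosome's SNPs; 0.3
  is wide enough that a multi-megabase selected region survives smoothing
  while single-SNP noise does not. Both are configurable
  (`smoothing_config()`), as is fitting ED instead of ED². Chromosomes
  with fewer than 10 SNPs are left unsmoothed (raw values, with a
  warning) rather than extrapolated.
* **Threshold = genome-wide median + 3 SD of the fitted values.** The SD
  convention is the population SD (divisor *n*), pinned by a test: with
  fitted values `{0,0,0,0,10}` the threshold is `0 + 3·4 = 12`. The
  threshold is always derived from the data at run time; the value any
  particular dataset produces (0.27 in the pepper study this reproduces at
  desk scale) is an output, never a constant.
* **Region bounds are SNP-anchored**: a region runs from the first to the
  last above-threshold SNP of a run, matching how such regions are
  reported. Runs are split when two consecutive above-threshold SNPs are
  more than `max_gap` (default 1 Mb) apart, so sparse marker deserts do
  not bridge unrelated peaks.

## The ΔSNP-index scan

Pool reads are partitioned by parental origin and each pool's SNP-index is
computed. The printed formulas in the source study are asymmetric — the
low pool's index counts low-parent reads while the high pool's counts
high-parent reads — which makes Δ = 0 at a fully selected causal locus and
contradicts the stated interpretation that Δ near ±1 marks tight linkage.
The package therefore defaults to the **unified convention** (both indices
are the high-parent read fraction; Δ = index_H − index_N, the standard
QTL-seq convention, under which Δ → 1 at the causal locus for this
design); `convention = "literal"` reproduces the printed formula for
comparability.

Windowing averages Δ over 400-SNP sliding windows advanced 1 SNP at a
time, truncated at chromosome ends; a chromosome shorter than one window
becomes a single whole-chromosome window with a warning.

### Confidence thresholds

The null model is two-stage (Takagi-style): each bulk's allele frequency
is drawn by sampling `2 × bulk size` chromosomes at probability 0.5, then
read counts are binomial at the observed depth. 10,000 replicates per
depth pair give empirical two-sided quantile bounds at the 90/95/99%
levels; depths are looked up on a small log-spaced grid (nearest pair).

One design decision here departs from the obvious construction. Bounds on
the *mean of 400 independent* null draws would be the natural window-level
threshold, but window members on a real chromosome are not independent:
the bulk-frequency component of Δ is shared through linkage across the
whole window, so the iid-mean bound is anti-conservative by roughly an
order of magnitude and calls regions all over a null genome. Region
calling therefore applies the **per-SNP bound to the window average** —
exact under complete within-window linkage, conservative for unlinked
windows — which is also the convention of the QTL-seq literature. The
iid-mean bounds remain available (`scopes = "window"` in
`confidence_thresholds()`) for unlinked-marker designs. The calibration
study (`analysis/06_calibration.R`, also part of the acceptance suite)
verifies both properties: held-out null draws fall inside the 99% bounds
at 0.99 ± 0.005, and null genomes yield zero called regions in ≥ 90% of
seeds.

Both scans' candidate regions are intersected per chromosome; the
intersection is the final call. Interval size is `(end − start)/10⁶` Mb
rounded half-away-from-zero to 2 decimals — the `end − start` span (not
`+1`) and the rounding rule are pinned by tests against all ten rows of
the published worked example. Gene counting uses inclusive any-overlap (a
gene starting exactly at a region end counts); full-containment counting
is available by flag, and the choice is declared rather than inferred
since only totals on unavailable raw data could distinguish them.

## The simulator

`simulate_f2()` builds gametes per chromosome with a Haldane model
(crossover count Poisson with mean `map_length_morgans`, default 1;
breakpoints uniform; no interference) — the study gives no genetic map, so
1 Morgan per chromosome is a generic plant-genome default. Phenotype at
the causal locus is recessive-null with incomplete dominance: exactly 0
for the low homozygote, `dominance × effect_size` (default 0.75 × 6
mg/100 g) for heterozygotes, `effect_size` for high homozygotes, plus
truncated Gaussian noise (SD 0.8). The zero class makes "no measurable
trait" bulk membership exact; the numeric scale is calibrated so the F2
range resembles the reported 0.9–7.3 mg/100 g. Bulks are chosen by a
floor-then-top rule: the 37 best plants at or above 0.90 mg/100 g, and the
first 18 zero-phenotype plants.

`simulate_reads()` draws per-sample depths Poisson at the reported means
(33.83/45.74× pools, 25.77/23.45× parents), allele origins binomially from
the bulk frequency, and per-read errors uniformly to the other three
nucleotides (rate 0.001). A configurable fraction of records is corrupted
into filter-failing form for filter testing. Chromosomes default to 50 Mb
with 250 SNPs so the mean marker spacing (0.2 Mb) stays well below the
1 Mb region-merge gap — the genome is scaled down from the real
3.5 Gb/127k-SNP setting for test speed, keeping the spacing-to-gap
relation of densely markered data. The acceptance and calibration studies
use 20 seeds of this scale (plus 2 × 500-SNP null genomes), sizes chosen
so the whole suite runs in minutes.

What the generator does **not** emulate: restriction-site ascertainment of
markers (SLAF library structure), read-level artifacts (mapping error, PCR
duplicates, base-quality structure), depth overdispersion beyond Poisson,
segregation distortion, multiple or epistatic loci, and any real gene
annotation (gene models are placed uniformly at random). Passing tests
therefore demonstrate the statistical machinery under the design's own
assumptions, not robustness to those artifacts.

## The assay calculator

`anthocyanin_concentration()` implements the standard pH-differential
method: net absorbance
`A = (A520 − A700)_pH1.0 − (A520 − A700)_pH4.5`, concentration
`A·MW·DF·10³/(ε·l)` mg/L as cyanidin-3-glucoside equivalents
(MW = 449.2 g/mol). The extinction coefficient is not printed in the
source study; the standard cyanidin-3-glucoside value ε = 26,900
L·mol⁻¹·cm⁻¹ is the default and is configurable. Negative net absorbance
(possible with hazy extracts) clamps to zero with a warning.

## Known limitations

* Region bounds are SNP positions, so region size depends on marker
  density; very sparse chromosomes fragment regions (mitigated by
  `max_gap`).
* The per-SNP-bound-on-window-average rule is conservative for genuinely
  unlinked markers; power there would improve with an explicit
  linkage-aware null, which is out of scope.
* The location annotator classifies genic SNPs only as `genic_unclassified`
  unless a codon-level class is supplied on input; it does not compute
  synonymous/non-synonymous status.
* `literal` index mode is provided for comparability but its Δ is
  not interpretable as linkage strength at selected loci (see above).
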