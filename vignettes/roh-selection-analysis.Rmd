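---
title: "Autozygosity and selection signatures in a breeding cohort: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity and selection signatures in a breeding cohort: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohselect)
```

## The scientific problem

Closed breeding programs keep only a handful of top-ranked sires each round.
Over decades this raises autozygosity: both copies of a chromosomal segment
descend from the same recent ancestor, producing long runs of homozygosity
(ROH). `rohselect` quantifies that process in a cohort of sequenced animals
and asks three questions: how much has genome-wide autozygosity (F~roh~)
risen over the course of selection, which 10-Mb regions of the genome gained
ROH fastest, and whether region-level autozygosity depresses the selected
trait (body weight at 12 months) once genetic relatedness is controlled for.
A haplotype-based selection scan (EHH/iHS) complements the ROH view: sweeps
driven by selection extend haplotype homozygosity locally, whereas
inbreeding raises homozygosity everywhere.

Because cohorts of this kind are rarely public, the package ships a
forward-time pedigree simulator with exact identity-by-descent (IBD)
bookkeeping. Every analysis stage is therefore testable against known truth,
and the whole pipeline runs end-to-end without any external download.

## The simulator and its ground truth

`simulate_cohort()` implements truncation selection: each round,
`offspring_per_round` candidates are bred from the current sires and dams,
ranked on phenotype, and the top `n_sires_selected` males become both the
next round's sires and the registered bulls of the cohort (sequential KPN
numbers, round order, ties by phenotype rank). A control group is produced
by random mating within the founder pool.

Haplotypes are represented two ways at once: an allele vector over the SNP
map, and a *founder-origin mosaic* — a run-length list of (breakpoint,
founder-haplotype label) pairs. Meioses draw a Poisson crossover count at
the chromosome map length (Haldane model, no interference, sex-averaged
map, constant cM/Mb) with uniform crossover positions, and recombine both
representations. True autozygous segments are the maximal intervals where
an individual's two mosaics carry the same founder label, at breakpoint
(base-pair) resolution — no SNP-density artefacts. Pedigree inbreeding
coefficients come from the standard tabular relationship-matrix recursion,
and the test suite checks them against an independent recursive-kinship
oracle.

Two closed-form calibrations anchor the machinery:

* offspring of full-sib matings have expected pedigree F = 0.25, and the
  realized IBD fraction over many replicates centres there;
* when the two copies of a locus coalesce in an ancestor g generations back
  (2g meioses in the loop), a surviving autozygous tract has expected length
  100/(2g) cM. The tract-length experiment uses long chromosomes
  (3 x 1000 cM) so that edge censoring stays within a few percent of the
  10-cM expectation at g = 5.

Default cohort conditions were chosen once, as a desk-scale analogue of an
intensive two-stage performance-test program: 60 founders, 18 rounds of
40 candidates with the top 7 males kept (126 selected bulls), 10 unselected
controls, a 3 x 50 Mb / 50 cM genome at 50 SNPs/Mb, founder alternate-allele
frequencies uniform on [0.05, 0.5], h^2^ = 0.4 and sigma~p~ = 30 kg for
12-month weight (typical yearling-weight values for beef cattle), 3 rearing
facilities with 10-kg-SD effects, mean weight 320 kg. With so few sires the
simulated inbreeding rate is much higher than in a real national program
(hundreds of sires, thousands of dams); the simulation is a qualitative
emulation — directions and mechanisms, not magnitudes. Breeding values
follow the infinitesimal model (mid-parent plus Mendelian sampling with
constant variance; the small inbreeding correction to Mendelian-sampling
variance is omitted), so phenotypic selection response and the rising
F~roh~ trend coexist without marker-level effects.

What the simulator does **not** emulate: genotyping error and missingness
patterns of real variant calling, mutation, background LD in the founders
(founder alleles are drawn independently per SNP), sex chromosomes, and
overlapping-generation population structure. Passing tests on simulated
data therefore demonstrate correctness of the algorithms and calibration of
the statistics, not robustness to real-data artefacts.

`apply_sweep()` emulates a hard selective sweep by copy-replacement: inside
a chosen interval a fraction of haplotypes is overwritten with one template,
raising local haplotype homozygosity exactly as a swept allele would, while
leaving the rest of the genome untouched. It is used to give the iHS scan a
positive control.

## ROH calling

The caller is a transparent run-based scanner, not a hidden-Markov model:
per sample and chromosome it extends maximal runs of homozygous calls left
to right, tolerating at most `max_het_in_run` heterozygous calls (default
0) and `max_missing_in_run` missing calls (default 2) per run, and breaking
wherever consecutive SNPs are more than `max_gap` apart (default 500 kb,
guarding against deceptively long runs across SNP deserts). Segments start
and end at homozygous SNPs; runs with fewer than `min_snps` homozygous SNPs
(default 20) are dropped. Greedy left-to-right extension was chosen over
"all maximal windows" because the latter can produce overlapping runs when
the missing-call budget is split between two windows; the greedy rule keeps
per-sample segments disjoint and is exactly reproducible by a brute-force
oracle, which the test suite checks on hundreds of random tracks.

Autozygosity is then a length question: short ROH arise from ancient,
chopped-up haplotype sharing, long ROH from recent inbreeding.
`threshold_profile()` reports segment count, total length and carrier
frequency across a 0–2000 kb threshold grid (100-kb steps), and
`filter_autozygous()` applies the chosen threshold — 500 kb by default,
retaining segments exactly at the boundary. F~roh~ divides the per-sample
merged segment total by the summed autosome length; the bundled UMD3.1
table provides the 29 cattle autosome lengths (2,512 Mb in total, 269
10-Mb bins). Group contrasts use the two-sided Wilcoxon rank-sum test, with
a subsampling routine (`froh_resampling()`) that re-draws small selected
subsets to show the contrast is not a sample-size artefact.

## SNP statistics

* **QC**: SNPs with missing rate > 0.05 or MAF < 0.01 are removed (strict
  inequalities; boundary values survive).
* **F~snp~** is the method-of-moments excess-homozygosity estimator on the
  LD-pruned panel: `F = (O_hom - E_hom)/(N - E_hom)` with
  `E_hom = sum(1 - 2 p q n/(n-1))` over the sample's non-missing SNPs — the
  small-sample `n/(n-1)` correction matches the conventional `--het`-style
  estimator.
* **LD pruning** uses 50-SNP windows advancing by 5, removing the later SNP
  of any retained pair with r^2^ > 0.5. Which member of an offending pair is
  dropped differs among tools; dropping the later SNP is deterministic and
  order-stable. Pruning is per chromosome.
* **LD decay** averages all intra-chromosomal pairwise r^2^ within 20 kb in
  non-overlapping 5-kb distance bins (bin midpoints reported); a sliding
  "moving average" would differ only cosmetically at this resolution.
* **GRM**: VanRaden method 1, `G = ZZ'/(2 sum p(1-p))` with columns centred
  by `2p` and missing dosages mean-imputed per SNP. Under Hardy–Weinberg
  equilibrium the diagonal centres on 1 and the off-diagonal mean on
  `-1/(N-1)` (a consequence of estimating allele frequencies in-sample),
  both asserted in tests.

## Haplotype selection scan

EHH at offset x is the probability that two random carriers of a core
allele are identical over every SNP between the core and x, computed by
pair counting over identical extended haplotypes. iHH integrates EHH over
physical distance (trapezoid rule) outward until EHH falls below 0.05;
iHS = ln(iHH~derived~/iHH~ancestral~), with the REF allele taken as
ancestral by default (the simulator records true ancestral alleles, so
tests use truth). A core is undefined when its MAF is below 0.01, either
allele has fewer than two carriers, an inter-SNP gap exceeds 200 kb before
the cutoff is reached, or a chromosome edge is hit first. On long shared
haplotypes the integral is truncated at 1 Mb per side (the conventional
cap); without it, highly related panels would keep EHH above the cutoff
across whole chromosomes and every core would be undefined.

Raw scores are standardized within 100 equal-width derived-allele-frequency
bins (bins with fewer than two scores or zero spread are flagged and left
raw). Two flagging modes mirror common practice: per 100-kb non-overlapping
window, the proportion of SNPs with |iHS| > 2 (windows under 10 scored SNPs
dropped, top 1% of proportions flagged, inverse-ECDF quantile, ties
included — so in a degenerate all-zero scan every window ties at the
threshold); and per SNP, the top 1% of |iHS|. The antisymmetry of iHS under
allele-label swaps and the monotone decay of EHH are asserted as properties.

## Bin association models

The genome is tiled into 10-Mb bins (last bin per chromosome truncated).
Per sample and bin the ROH status (any overlap) and overlap length are
tabulated; a segment spanning a bin boundary contributes to both bins. Bins
where all samples share one length (usually all-zero) carry no information
and are removed.

**Analysis 1** regresses bin ROH status on the KPN registration number —
a proxy for selection time — with a logistic model, reporting the slope,
its Wald p-value (a likelihood-ratio option is available; Wald is the
default to parallel Analysis 2) and McFadden pseudo-R^2^ (the conventional
fit measure for logit models). Complete separation and constant status are
flagged, not estimated. Null calibration at nominal 0.01 is asserted over
1000 simulated null bins.

**Analysis 2** fits, per bin, `weight = intercept + roh_length + facility +
g + e` with `g ~ N(0, s2g G)` — a single-kinship REML mixed model. The
implementation eigendecomposes G once, profiles beta and the residual
variance out of the restricted likelihood, and maximizes over the variance
ratio `delta = s2g/s2e` by one-dimensional optimization on the log scale
(with an explicit boundary check at delta = 0, where the fit collapses
exactly to ordinary least squares). Wald chi-square tests per coefficient
make the collapse comparable to normal-theory OLS inference. Facility is an
unordered factor with reference coding; the dummy block is dropped when
only one level remains. Unselected animals (no KPN) are excluded from both
analyses; samples with missing weight from Analysis 2 only.

Raw p < 0.01 marks a bin significant, with no multiple-testing correction —
deliberate, matching the screening character of the analysis; a
Benjamini–Hochberg adjustment can be applied to the returned p-value
columns if desired. The early/late contrast (`group_mean_length_change()`)
splits selected samples at a KPN cutoff and reports the difference of group
mean bin lengths (the simple difference; scaling by the KPN range would
only rescale, not reorder, bins). Cohort-level relationships among KPN,
F~roh~ and weight use tie-corrected Spearman correlations with asymptotic
p-values (ties make the exact distribution unavailable).

## Overlap regions

A "complete overlap" region is formalized as the maximal interval attaining
the maximum distinct-sample ROH coverage depth: per-sample segments are
merged, endpoint events are swept, and all maximal intervals at the maximum
depth are returned (ties included). Group-wise characterization of a region
(`region_group_curves()`) computes, in 50-kb sliding windows (10-kb step),
the mean pairwise r^2^ among window SNPs and a window inbreeding
coefficient `F = 1 - mean(O_het)/mean(E_het)` using group allele
frequencies with the `n/(n-1)` correction; windows without SNPs polymorphic
in the group are undefined rather than zero. `confirm_overlap()` counts
carriers of a region in a second, independent cohort.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes the full chain — simulate (or read VCF/metadata),
hard-filter summary, ROH and threshold profile, F~roh~/F~snp~ with group
comparison and resampling, GRM, both bin analyses, iHS track and sweep
windows, overlap regions in the top trend bin, correlations — writing fixed
file names plus a manifest (package version, seed, parameter hash). Every
stage is a pure function of (inputs, parameters, seed): reruns are
byte-identical, and each stochastic stage derives its own sub-seed from the
run seed so stages stay reproducible independently. The VCF reader is
backed by vcfR; the writer is a small deterministic text writer so that
byte-identity under a fixed seed holds. All hard-filter criteria
(QUAL < 30, DP < 5, MQ0 > 4, FS > 200 removed) are strict inequalities,
read literally.

The test suite and the acceptance script run everything at desk scale: the
default 136-sample cohort on a 150-Mb genome (7,500 SNPs), 200-track ROH
oracle comparisons, 500 full-sib replicates, ~1000 IBD tracts for the
tract-length law, 1000 null logistic bins, 20 REML recovery seeds on a
300-animal half-sib GRM, and 10 sweep-scan seeds on a 20-Mb panel. These
sizes were chosen so the complete suite finishes in minutes on one core
while keeping every Monte-Carlo comparison comfortably inside its
tolerance.

## Known limitations

* The ROH caller is run-based; results will differ from HMM-based callers
  on noisy data, by design (auditable semantics over smoothing).
* Physical distance stands in for genetic distance in the iHS integral (no
  genetic map is assumed for real input data).
* The REML engine handles one kinship matrix; multi-component models are
  out of scope.
* Simulator founders carry no LD; LD-sensitive statistics on simulated
  founders reflect family structure only.
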