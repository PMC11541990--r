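---
title: "Methods: mosaic chromosomal alterations and MBL screening"
author: "mosaicMBL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mosaic chromosomal alterations and MBL screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicMBL)
```

# Background

Monoclonal B-cell lymphocytosis (MBL) is the asymptomatic precursor of
chronic lymphocytic leukemia (CLL): a small clonal B-cell population in
peripheral blood, classified as low-count (LC-MBL, clone below 500 cells/µL
or below 85% of B cells) or high-count (HC-MBL) by clone size. Mosaic
chromosomal alterations (mCAs) — somatic gains, losses and copy-neutral
loss-of-heterozygosity (CNN-LOH) of large chromosomal segments, detectable
in a fraction of blood cells from SNP-array data — are a second, purely
genetic readout of clonal hematopoiesis. This package implements the
inference chain that connects the two: detect mCAs from phased array
signals, estimate the fraction of cells carrying each event, classify
events against CLL-relevant genomic region lists, compare clone size with
the flow-cytometric B-cell fraction to reason about cell-of-origin, and
quantify the cohort-level association between mCA categories and MBL
status, including the use of mCAs as a flow-cytometry-free screen for
HC-MBL.

# Detection model

## The phased deviation statistic

At a heterozygous SNP the B-allele frequency (BAF) sits near 0.5; a mosaic
event present in a fraction $f$ of cells displaces it up or down depending
on which parental haplotype gained or lost material. Raw $|BAF - 0.5|$
averages to the noise level, but once sites are phased the quantity
$d_i = h_i\,(b_i - 0.5)$ — with $h_i \in \{+1,-1\}$ the phased haplotype
label — has a common sign across an event, so its mean over $n$ hets
estimates the BAF shift with standard error $\sigma_{BAF}/\sqrt{n}$. With
array noise $\sigma_{BAF} = 0.03$ and $10^4$ hets, a CNN-LOH clone at
$f = 0.01$ (shift 0.005) yields $z \approx 0.005 / (0.03/100) \approx 17$,
which is why cell fractions well below 1% are detectable on well-covered
segments.

## Segmentation, boundaries, typing

Candidate segments come from recursive binary segmentation of the $d_i$
sequence: the standardized CUSUM statistic proposes the best single change
point; splits are accepted while that statistic exceeds `splitZ` (default
5) with at least `minHets` (default 25) hets on both sides; leaf segments
whose mean-deviation $z$ reaches `zThreshold` (default 5) are emitted. Ties
in the CUSUM maximum break toward the smaller index so results are
deterministic. This deliberately replaces the hidden-Markov-model machinery
used by production mCA callers with a transparent change-point procedure;
it is a fidelity limitation (no multi-state inference, no per-site
posterior), but its operating characteristics are directly testable and
sufficient at the scale this package targets.

Boundaries are then refined by resampling: in a flanked window around each
end point, het sites are bootstrap-resampled and the change point re-located
by maximizing the CUSUM; the per-boundary median across `nBoot` resamples is
reported. The first replicate uses the unresampled data, so `nBoot = 1`
reduces to the plain CUSUM fit.

Event type uses the log R ratio (LRR, log2 total intensity): mean segment
LRR below $-0.05$ is a loss, above $+0.05$ a gain, copy-neutral LRR with a
positive BAF deviation is CNN-LOH. The margin of 0.05 is about one third of
a fully mosaic deletion's shift at $f = 0.1$ and comfortably above the LRR
standard error of any segment with dozens of probes.

## Cell-fraction algebra

A two-population mixture (fraction $f$ aberrant, $1-f$ diploid) gives the
expected het BAF deviation per type:

$$\Delta BAF_{loss} = \frac{f}{2(2-f)}, \qquad
  \Delta BAF_{gain} = \frac{f}{2(2+f)}, \qquad
  \Delta BAF_{cnnloh} = \frac{f}{2},$$

inverted by `dbafToCf()` as $f = 4\Delta/(1+2\Delta)$, $4\Delta/(1-2\Delta)$
(capped at 1; a single extra copy is assumed) and $2\Delta$. Expected LRR is
$\log_2\!\big(((1-f)\,2 + f\,c)/2\big)$ with copy number $c \in \{1,2,3\}$.
The generator injects events with exactly these shifts, so detector
estimates are comparable with truth to Monte-Carlo error; the round-trip
$f \to \Delta \to f$ is exact to machine precision and is asserted at 1e-12
in the tests.

Sex chromosomes have no usable het BAF (male X/Y), so mosaic loss of Y or X
is called from the median LRR alone, $f = 2(1 - 2^{\tilde{m}})$ clipped to
$[0,1]$, guarded by a one-sided location test.

## Call filters

Likely artifacts are removed on four axes: sample genotype call rate (default
minimum 0.97), sample baseline $|{\rm median\ BAF} - 0.5|$ (maximum 0.05),
per-call phase concordance — the fraction of hets whose deviation sign
matches the majority (minimum 0.6; 0.5 is random) — and a germline proxy:
deviation within 0.05 of the constitutional value 0.5 together with a mean
LRR within 0.1 of the matching integer-copy value ($-1$ deletion, $0$
isodisomy, $\log_2 1.5$ duplication). These thresholds are configuration
defaults, not literature claims; production callers document their own.
Phase switch errors are *not* re-phased: cumulative switches attenuate the
chromosome-wide mean deviation (the tests demonstrate the attenuation), and
segments between switches remain detectable individually.

# Taxonomy

Calls are annotated against three overlapping category systems held in a
`RegionLists` object:

* **Canonical CLL-associated**: the clinical FISH panel — del 6q, del 11q,
  trisomy 12, del 13q, del 17p, and CNN-LOH on 13q containing the
  *MIR16-1* anchor locus.
* **CLL-driver**: canonical, or fully containing a candidate driver region
  of matching type.
* **Lymphoid**: chromosome/arm + type entries associated with lymphoid
  malignancy risk.

Interpretation decisions the underlying definitions leave open, fixed here
and configurable: an arm entry matches on ≥ 1 bp overlap with matching
type; "trisomy 12" means a gain covering ≥ 80% of chr12 (`trisomyCoverage`);
driver containment is call-contains-candidate (large mCAs span focal
drivers, not the reverse) with exact type match, so a CNN-LOH over a
deletion candidate does not count; the *MIR16-1* anchor ships as a
build-tagged coordinate (GRCh38) with no lift-over inside the package.
Categories are OR-aggregated flags, never partitions — an 11q deletion is
both canonical and lymphoid, and canonical implies driver by construction.
The shipped driver and lymphoid lists are small **examples** for testing;
faithful replication of published analyses requires the published candidate
lists.

# Lineage inference

If an mCA were confined to B cells, the fraction of cells carrying it could
not exceed the flow-cytometric B-cell fraction measured on the same sample.
`assessLineage()` therefore compares, per individual and category, the
maximum cell fraction among calls in the category (the largest clone is the
informative one; non-carriers are reported with cell fraction 0) against
`bcell_fraction`, using a strict inequality so ties do **not** count as
exceeding — conservative with respect to concluding a pre-B-lineage origin.
The comparison is cleanest when DNA and flow cytometry come from the same
PBMC sample, hence the `restrictDnaSource = "pbmc"` option in
`lineageSummary()`. Both cell-fraction estimates are imprecise; the module
computes the comparison and its counts, nothing more.

# Concordance with FISH

`fishConcordance()` cross-tabulates per-locus call positivity (derived from
the canonical interval rules) against clinical FISH at 6q, 11q, 12, 13q and
17p, reporting sensitivity and specificity with `NA` on empty denominators.
Because FISH del(13q) probes also light up CNN-LOH clones homozygous for
the deleted haplotype, anchored 13q CNN-LOH calls can be counted as
13q-positive (`include13qCnnLoh`, on by default, toggleable).

# Cohort statistics

* Percentages print with **half-up** rounding to one decimal
  (`roundHalfUp`), the convention that reproduces published cohort tables
  exactly (52.108 → 52.1, 99.865 → 99.9, 14.976 → 15.0); base R's
  round-half-even does not.
* Odds ratios: `crudeOr()` is the 2×2 cross-product with a Woolf CI and
  optional Haldane–Anscombe correction; `adjustedOr()` is a
  maximum-likelihood logistic fit (via `glm`, deviance convergence,
  maximum 100 iterations) with Wald CIs. Quasi-separation — an exposure
  absent in one outcome class, as happens for del 17p among unaffected
  controls — is detected from diverging coefficients and flagged rather
  than reported as a huge finite OR. With no covariates the adjusted OR
  equals the crude OR, which the tests assert.
* Clone sizes are compared with the two-sided Mann–Whitney test
  (normal approximation, tie and continuity correction); fully tied input
  returns $p = 1$ and $U = n_1 n_2 / 2$.
* The polygenic risk score is a weighted average of risk-allele dosages
  ($\sum w_i d_i / \sum w_i$, dosages in $[0,2]$, missing values
  mean-imputed), matching the 41-SNP CLL score construction.
* HC-MBL prediction (`cvPredictAuc()`) contrasts HC-MBL against the
  combined LC-MBL/no-MBL group with seeded stratified 10-fold
  cross-validation; out-of-fold probabilities are **pooled** into one
  rank-based AUC (lower variance than averaging per-fold AUCs; published
  analyses rarely say which they used, and the choice moves the second
  decimal at most). Sex and categorical covariates enter as indicators, age
  linearly; no multiple-testing correction is applied anywhere, matching
  the raw-p-value reporting convention of the field.

# The synthetic cohort generator

Protected cohort data cannot ship, so `generateCohort()` emulates the
statistical structure the analysis assumes: the five groups at their
published sizes (2971 no-MBL, 728 LC-MBL, 332 HC-MBL, 497 CLL, 104 SLL),
group-by-category mCA prevalences set to the published carrier fractions
where printed (e.g. canonical mCAs in 52.1% of HC-MBL, 1.1% of LC-MBL,
0.13% of no-MBL; LoY in 15% of males), and phenotype distributions chosen
once as plausible stand-ins where no distributions are published: clonal
B-cell % Beta-scaled on (0, 85) for LC-MBL and Uniform(85, 100) for HC-MBL
(the definition boundaries), B-cell fractions Beta with group-appropriate
means, ALC lognormal per group, a standard-normal polygenic score with
positive group shifts, and event cell fractions from a common rescaled Beta
on (0.01, 1]. Truth events are placed on disjoint chromosomes per category
so each individual's event set is non-overlapping and classifiable by the
example region lists.

`simulateArraySignals()` shares the mixture algebra above, adds truncated
Gaussian BAF/LRR noise, and applies cumulative phase-switch errors at the
configured rate (realistic long-range phasing decay). It does **not**
emulate linkage-disequilibrium structure, germline CNVs, probe-specific
biases or raw intensity files — so passing tests demonstrate correctness of
the inference chain under its own signal model, not robustness to every
artifact of real arrays. Likewise the phenotype stand-ins are not
calibrated to real overlap between groups: synthetic ALC separates HC-MBL
from controls more cleanly than real cohorts do, so cross-validated AUCs on
synthetic cohorts overstate real-world screening performance and are
reported as internal consistency checks, not as reproductions of published
AUC values.

# Numerical choices and degenerate inputs

Deterministic tie-breaks (first CUSUM maximum), a $10^{-9}$ floor on the
CUSUM noise scale so noiseless steps are handled, BAF truncation rather
than resampling (keeps the noise model monotone in its standard deviation),
strict input validation on ranges (`dbaf` ∈ [0, 0.5], fractions ∈ [0, 1],
dosages ∈ [0, 2]), `NA`-with-warning on empty denominators, and
seed-derived child seeds below $2^{31}$ for every stochastic stage. Problem
sizes used by the test suite and the acceptance script — 200 replicates of
10,000 hets for the detection limit, 500 event-free chromosomes of 2,000
sites for null calibration, 100 cohorts of 3,000 for OR recovery — were
chosen as the smallest sizes at which the Monte-Carlo error of each check
is far below its decision margin.

# Known limitations

No HMM and no per-site posteriors; no multi-copy gains or subclonal
mixtures (gain fractions cap at 1); phasing is taken as given and switch
errors are tolerated, not corrected; shipped region lists are miniature
examples; the absolute MBL rule returns `NA` above 5000 cells/µL rather
than diagnosing CLL; and all cohort-level defaults describe a synthetic
stand-in, not any real population.
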