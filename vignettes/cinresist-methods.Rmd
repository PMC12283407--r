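---
title: "Copy-number signature biomarkers of chemotherapy resistance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number signature biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinresist)
```

This vignette explains the models implemented in `cinresist`, the
assumptions they make, the numerical choices behind them, and what the
package's synthetic-data tests do and do not demonstrate about real
data.

## The mixing model and the purity/ploidy grid search

A bulk tumor sample is a mixture of tumor cells (fraction *purity*)
and diploid normal cells. Sequencing depth in a genomic bin is
proportional to the mixture's local DNA content, so the depth-normalised
**relative copy number** of bin $j$ relates to the tumor's **absolute
copy number** $aCN_j$ through

$$ rCN_j = d \, \big( \text{purity} \cdot aCN_j + 2 (1 - \text{purity}) \big),
\qquad d = \frac{r}{\text{ploidy} \cdot \text{purity} + 2 (1 - \text{purity})} , $$

where $r$ is the genome-wide (length-weighted) mean relative copy
number and *ploidy* the tumor's mean copy number. Neither purity nor
ploidy is observed; both are estimated by exhaustive grid search
(purity 0.05–1 in steps of 0.01; ploidy 1.8–8 in steps of 0.1),
choosing the pair that makes the transformed profile most nearly
integer:

$$ e = \frac{1}{J} \sum_{j=1}^{J} \big( aCN_j - \text{round}(aCN_j) \big)^2 . $$

Two filters remove degenerate optima. A fit implying more than 10 Mb of
homozygous loss (rounded $aCN \le 0$, measured on segment lengths) is
rejected — tumors do not survive losing that much of both alleles — and
in tissue mode a fit must place at least one segment at every integer
state from 1 to the (rounded) ploidy, which suppresses whole-genome
doubled or shifted solutions that only occupy every other state. Cell
lines and organoids are treated as 100% pure (`mode = "pure_model"`),
searching over ploidy only; the integer-state filter is not applied
there because near-homogeneous lines can genuinely lack intermediate
states.

**The two forms of the transformation.** The published form of the aCN
equation carries a trailing $-2$ after the purity division. Under that
form an average bin ($rCN_j = r$) at purity 1 maps to $\text{ploidy} -
2$, which contradicts the definition of $d$: inverting the mixing model
exactly gives $aCN_j = (rCN_j/d - 2(1-\text{purity}))/\text{purity}$
with no such term, and only that inverse satisfies round-trip identity
(forward mixing followed by inversion reproduces $aCN$ to $10^{-10}$;
this is tested). Both forms are implemented —
`variant = "consistent"` (default) and `variant = "printed"` — so the
published form remains reproducible while the self-consistent one does
the work.

**Numerical choices.** Rounding is R's round-half-to-even; the fit
error is weighted by the number of bins per segment; ties on the error
surface are broken toward lower ploidy, then higher purity (the most
parsimonious genome), a rule fixed purely for determinism. "1 to
ploidy" is interpreted as $1..\text{round}(\text{ploidy})$ since grid
ploidies are not integers. The panel-anchored fit (`constrained_fit`)
intersects a ±0.2 ploidy / ±0.05 purity window with the global grid and
flags optima on the window edge as boundary solutions; the second
window is read as purity because a second ploidy window would be
redundant.

## Profile processing

**GC/mappability correction** (`correct_counts`) fits a LOESS surface
of counts on GC and mappability (span 0.65, robust `symmetric`
family) and divides it out, then median-normalises so the genome-wide
median relative copy number is 1. Bins below a mappability floor
(default 0.5) are masked. With fewer than 100 usable bins, or
degenerate covariates, a median-ratio normalisation substitutes for
LOESS.

**Segmentation** (`segment_profile`) is a penalized least-squares
changepoint search implemented as PELT with a squared-error cost, run
per chromosome. The default penalty is the BIC-type
$2\hat\sigma^2\log n$, with $\hat\sigma$ estimated from the median
absolute deviation of first differences so real changepoints do not
inflate it. On inputs of up to 200 bins the search is verified against
an exhaustive dynamic-programming oracle; a planted five-changepoint
signal at noise $\sigma = 0.05$ is recovered within one bin.

**Harmonisation** (`resegment_30kb`) re-bins high-resolution profiles
into 30 kb bins (overlap-weighted averages), merges equal-valued
neighbours, removes segments of exactly 30 kb (artifacts of bins
straddling old boundaries), and smooths with `smooth_merge`: a greedy
left-to-right pass merging neighbours within ±0.1 copies of the running
length-weighted mean, iterated to a fixed point so the output provably
contains no adjacent pair within tolerance. Comparing against the
running mean, rather than the previous raw value, stops long
near-monotone chains from being absorbed into one drifting segment.

**wGII** is the mean over chromosomes of the fraction of covered length
whose rounded copy number differs from the rounded sample ploidy
(length-weighted mean copy number). Averaging per chromosome weights
small chromosomes equally — instability of chr21 counts as much as
chr1. **`profile_difference`** is the percentage of jointly covered
genome where two profiles disagree in rounded copy number, the metric
used to compare assays of the same tumor.

## Off-target panel copy number

Capture panels sequence a small targeted fraction of the genome deeply;
the rest of the genome still receives sparse "off-target" coverage from
which 50 kb-binned copy number can be recovered. The pipeline drops
bins dominated by on-target signal (target overlap ≥ 25% of the bin, or
more than 10 distinct targets), uses a panel of normals both to flag
unreliable bins (a bin is usable when ≥ 90% of normals have nonzero
counts and the coefficient of variation is below 1 — criteria chosen
here, as the underlying workflow does not publish them) and to supply a
**similarity bias score**: regions resembling target sequence attract
excess off-target reads, and since normals carry no copy-number signal,
the standardized log panel-mean is a direct readout of that excess. A
single linear model of sample log-counts on the score removes the bias
while leaving score-0 bins untouched. Bins partially covered by targets
get a pseudocount — the panel's per-bin mean rescaled by the ratio of
sample to panel median off-target depth over overlap-free bins (the
rescaling rule is this package's choice; only the per-bin-mean basis is
prescribed). GC and replication-timing LOESS passes (span 0.75, two
sequential univariate fits, genome-wide median preserved exactly)
precede segmentation and an anchor-constrained purity/ploidy fit.

## Signature quantification

Five features are extracted from the absolute profile: segment size,
absolute copy-number change at each within-chromosome boundary,
breakpoints per 10 Mb (non-overlapping tiles; windows with no
breakpoints contribute no event, so a quiet genome has an empty
catalog), breakpoints per chromosome arm, and lengths of oscillating
chains — maximal runs of ≥ 3 consecutive segments alternating between
exactly two rounded states, broken at arm boundaries. Each event is
soft-assigned to the fixed mixture components of its feature
(posterior ∝ component weight × density; gaussian components for
continuous features, Poisson for counts), and posteriors are summed per
component. Block sums therefore equal event counts — a conservation
property the tests enforce. Events with zero density under every
component receive a uniform posterior with a warning rather than being
dropped, so the conservation property survives outliers.

Activities are the non-negative least-squares solution of
$\min_{w\ge0} \|v - M^T w\|_2$ (Lawson–Hanson, via `pracma`),
normalised to sum 1. An all-zero encoding returns all-zero activities
flagged `no_cin`. Small activities are then zeroed by per-signature
thresholds **without renormalisation** — renormalising would let one
signature's removal inflate another's activity, breaking monotonicity.
Z-scaling against a reference cohort's per-signature mean and standard
deviation makes a single decision boundary transferable across tumor
types; the package ships clearly synthetic scaling tables and accepts
real ones as TSV.

**The synthetic signature model.** The shipped 17-signature matrix and
mixture components are synthetic. Components are placed well apart
(gaussians ≥ 4 SD; Poisson rates 2/12/45-style spacing) and changepoint
components sit on integer means, since real copy-number changepoints
are near-integer; each signature concentrates most of each feature
block on one "primary" component, and the 17 rows are a greedy
minimum-coherence selection from a large random pool (maximum pairwise
cosine ≈ 0.26). This construction is what makes planted exposures
recoverable from realistic event counts (cosine ≥ 0.95 at 500 events),
which is the stated contract of the event generator. Real definition
matrices and components load from TSV in the same layout and are used
unchanged.

## Resistance classifiers

* **Platinum** — no detectable CIN ⇒ resistant; else resistant iff
  scaled CX2 > scaled CX3 (BRCA1/2-mutant reference scaling). CX2 and
  CX3 both mark impaired homologous recombination, but only the
  CX3-type defect is synthetically lethal with platinum damage.
* **Taxane** — no CIN ⇒ resistant; else resistant iff pan-cohort scaled
  CX5 < 0.
* **Anthracycline** — resistant iff CX8 > 0.01 or CX9 > 0.009 or
  CX13 > 0.009 on raw activities. These signatures mark focal
  amplification linked to extrachromosomal DNA and micronucleus
  tolerance, the proposed route to surviving anthracycline-induced
  immune signalling.

All boundary comparisons are strict, so exact ties resolve to
sensitive — one consistent convention, kept in one place. The
anthracycline rule has **no** CIN gate: a sample with all-zero
activities is called sensitive. That asymmetry is deliberate: the
source workflow states the no-CIN rule only for platinum and taxane,
and the package documents rather than guesses the missing case. The
default CIN rule is "any thresholded signature positive"; a structural
alternative (`min_segments`, default 20 post-smoothing segments) is
available because the two rules genuinely disagree on quiet genomes,
and which is wanted depends on whether the question is "is there
signature evidence" or "is there structural evidence".

Two calibration procedures mirror how the thresholds were derived:
`calibrate_threshold_response` scans activity thresholds, computing the
mean dose–response AUC of the predicted-resistant set (samples below
threshold) and maximising it subject to the predicted resistance rate
falling in an expected band (default 30–60%), ties to the smaller
threshold; `calibrate_threshold_rank` labels the top-$n$ samples by
IC50 as resistant and maximises accuracy of the strict-threshold rule,
ties to higher specificity then the larger (most conservative)
threshold. Both scan observed activity values only, so results are
exactly reproducible from the data.

## Trial emulation

Treatment-line tables are turned into emulated trials by rules, not
judgment calls. The experimental arm takes each patient's treatment
line closest to diagnosis that contains the therapy of interest and
passes the exposure filter (≥ 3 cycles **or** ≥ 28 days — the OR
matters: short intensive and long gentle schedules both count).
Optional switches restrict to biopsy-linked lines and exclude
platinum-containing lines (the relapsed-ovarian configuration, where
platinum response would confound the readout). The control arm removes
therapy-containing lines, removes whole patients who appear in the
experimental arm, keeps monotherapies (exactly one non-maintenance drug
after synonym mapping; maintenance agents — PARP inhibitors,
bevacizumab, letrozole — are covariates, not lines), and retains the
five most frequent standard-of-care drugs, frequency ties broken
lexicographically for determinism.

**TTF** (time to treatment failure) is the earliest of the next line's
start and the death/progression date, minus the line start, censored at
last follow-up; the rule is pluggable because operational TTF
definitions vary between registries. Finalisation keeps one line per
patient (first viable) and applies the late-exclusion rule: a patient
whose last treatment line shows a TTF above 730 days is excluded when
follow-up extends less than a year past that line's end — an apparently
extraordinary treatment success that nobody watched long enough to
verify. The rule is anchored at the line's end because anchoring at
diagnosis would make the two conditions mutually exclusive (a TTF over
730 days cannot coexist with under a year of total follow-up).

Stabilized inverse-probability weights balance treatment assignment
over year-of-treatment bins using empirical propensities — a saturated
model, exact in categorical covariates and free of specification
choices; a level where one arm has zero propensity is an error rather
than an infinite weight. Hazard ratios come from `survival::coxph`
(weighted, optionally stratified by age group, robust variance under
weighting), with `survival::cox.zph`'s global p-value reported as a
proportional-hazards diagnostic; none of the survival internals are
reimplemented. Required sample sizes use Schoenfeld's events formula
$(z_{1-\alpha} + z_{\beta})^2 / (\ln HR)^2 / (p(1-p))$, divided by the
expected event fraction.

## What the synthetic data emulates — and what it does not

The generators produce: absolute profiles whose length-weighted mean
lands exactly on the target ploidy (boundary fine-tuning), with every
integer state up to the ploidy present and ≥ 12 Mb at copy number 1 —
the profile shape for which the fit filters were designed, and without
which purity/ploidy would be genuinely ambiguous; binned counts under
the mixing model with Poisson or negative-binomial (overdispersion 0.1)
noise and optional GC bias; GC and replication-timing tracks that vary
on a fine (tens of bins) scale, roughly independent of the
megabase-scale segments, as in real annotation tracks; panels with
clustered targets, an exponential-decay similarity covariate with known
log-slope, and 40 synthetic normals; cohorts with exponential failure
times, a planted hazard ratio on the resistant × experimental stratum,
and exponential censoring.

The default simulation genome is 4 chromosomes × 50 Mb (4,000 bins), so
grid searches and end-to-end runs take seconds; hg19-scale profiles
work unchanged (`hg19_genome()`). The test suite exercises: 50
profiles across the purity/ploidy grid (noiseless and at 100
reads/bin), 10⁴ transformation triples, 100 NNLS instances, 20
signature-recovery seeds at 500 events, 4 off-target tumors, and
100 + 200 emulation replicates at n = 200/120 patients.

Passing these tests shows the pipeline is *self-consistent*: it inverts
its own generative models under realistic noise. It does not show that
real tumors follow those models. In particular, the synthetic signature
definitions share only their shape with real ones; real sWGS bins have
wave artifacts and blacklisted regions the generator omits; real
treatment records contain date errors, merged lines and drug-name chaos
far beyond the shipped synonym table; and exponential TTF with
proportional hazards is the friendliest possible survival model. The
thresholds and scaling tables shipped as fixtures are synthetic and
must be replaced with cohort-derived values for any real application.

## Known limitations

Allele-specific copy number (and hence LOH-aware fitting) is out of
scope; the fit filters assume aneuploid genomes with several integer
states, and near-flat diploid profiles with low purity are genuinely
hard for any integer-snapping objective; the bias-score definition for
off-target similarity is one reasonable choice isolated behind
`similarity_bias_score()`; and the emulation machinery implements the
stated eligibility and filtering rules, not a general causal-inference
framework — residual confounding beyond the year-of-treatment covariate
is untouched.
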