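---
title: "Methods: allelic-imbalance GI scoring for CSF cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic-imbalance GI scoring for CSF cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`csfgi` quantifies genomic instability in a cell-free DNA sample from the
allele fractions of shared germline heterozygous variants. The underlying
physical model is a two-population mixture: a fraction $f$ of cfDNA
molecules derive from an aberrant clone with allele-specific copy numbers
$(c_{major}, c_{minor})$ over each genomic segment, the rest from diploid
normal cells. A germline het site whose ALT allele lies on a haplotype
present in $c_{alt}$ copies then has expected ALT allele fraction

$$p = \frac{(1-f) + f\,c_{alt}}{2(1-f) + f\,(c_{major}+c_{minor})},$$

which is 0.5 at $f = 0$ and $c_{alt}/(c_{major}+c_{minor})$ at $f = 1$
(`expected_het_af()`). Allelic imbalance — $|p - 0.5| > 0$ — therefore
requires both a non-diploid clone and an appreciable tumor fraction.

The per-sample statistic is deliberately simple. Shared mutations between
an assay compartment and the patient's leukocyte reference are screened by
normalized variant key; leukocyte AF outside $[0.2, 0.8]$ removes
non-heterozygous and artifact calls; a shared mutation is a *GI mutation*
when its assay AF lies strictly outside the theoretical quartile band
$(0.25, 0.75)$; and

$$\mathrm{GI\_Score} = N_{GI}/N_{common}.$$

## Reading of "the quartile band", and boundary conventions

The band is the *theoretical* quartile band around the expected het AF of
0.5, not per-sample empirical quartiles: empirical quartiles would place
roughly half of all mutations outside the IQR by construction, forcing
every score toward 0.5 and destroying the contrast between stable scores
near 0.03 and unstable scores near 0.3 that the method relies on. Boundary
conventions: the leukocyte filter *retains* 0.2 and 0.8 (the removal rule
is a strict inequality); the GI band *excludes* its boundaries (AF exactly
0.25 or 0.75 is not GI); classification assigns a score exactly at the
cutoff to GI (the boundary goes to the unstable, clinically actionable
class, and every report records the rule). CNV records never enter the
score; tissue samples, when present, are scored identically to CSF and
plasma.

`min_common` (default 20) guards the denominator: a ratio of tiny counts
is unstable, so samples with fewer shared mutations are reported
`indeterminate` with an undefined score rather than a misleading 0.

# The cutoff

On a mixed cohort the score distribution is bimodal, and the GI/GS
threshold is estimated from it. The default method fits a two-component
Gaussian mixture on the raw score scale by EM — 50 random restarts under a
fixed seed (means initialized from sampled score pairs, SD floor $10^{-4}$,
convergence at $|\Delta\log L| < 10^{-8}$, 200 iterations maximum), best
log-likelihood kept — and returns the score where posterior membership
flips between the components, found by root-solving the log-density
difference between the two means. If the posteriors do not cross there
(heavy overlap), the weight-balanced midpoint of the means is used.

Degenerate fits fall back to Otsu's threshold (1000-point grid minimizing
within-class variance) with a warning: a component weight below 0.05,
means closer than 0.02, or a missing valley — mixture density at the flip
point at least 30% of the density at the shallower mode, the signature of
EM splitting one tight cluster in two. One exemption: a variance-floor
component whose claimed points are all tied is genuine zero-inflation
(samples with no GI mutations score exactly 0), not a spike pathology, so
the valley heuristic is skipped for it. Fewer than 10 finite scores is an
error directing the user to the fixed method. The cutoff is fitted on CSF
scores only by default — plasma scores of the same patients are near zero
regardless of status and would only dilute the unstable component — but
the compartment is configurable.

# The copy-number validation arm

Low-pass WGS bin counts are normalized to $\log_2$ ratios against the
median autosomal bin count (zero-count bins become missing; scaling all
counts by a constant leaves ratios unchanged). Segmentation is a greedy
mean-merge: a bin starts a new segment when it deviates from the running
segment mean by `merge_tol` (0.1) or more; runs shorter than `min_bins`
(3) are absorbed into the neighbor with the closer mean; adjacent segments
whose means converged below the tolerance are re-merged. A segment is
called gained or lost when $|\overline{\log_2}| >$ `call_tol`, and the
altered genome fraction (AGF) is the length fraction of called segments.
A sample is copy-number-unstable when AGF $\ge$ 0.10.

`call_tol` defaults to 0.25, chosen to align the two arms' sensitivity in
tumor fraction. For a clone state $(c, 0)$, the AF band flags sites at
$f \ge 2/(c+2)$, while a coverage threshold $t$ detects the segment at
$f \ge 2(2^t - 1)/(c - 2)$. At $t = 0.25$ the dominant amplified-LOH state
$(3,0)$ crosses both thresholds at nearly the same tumor fraction
($f \approx 0.37$ versus $0.40$), so the score-based and AGF-based status
agree except in a narrow $f$ window; at the conventional $t = 0.2$ the
coverage arm fires a full 0.1 of tumor fraction earlier and the two calls
disagree on a substantial share of moderately infiltrated samples. Median
normalization assumes the altered fraction of the genome stays below ~50%;
no GC or mappability correction is applied (the simulated data carry no
such bias, and correcting real data is out of scope).

# The synthetic-cohort generator

`simulate_cohort()` emulates the full data-generating process at the
cohort scale the package targets: 56 patients, 50 with paired plasma, 9
with tissue, GI prevalence 0.661. Per patient it draws one clone and
reuses it across compartments (same tumor, different shedding), with
compartment-specific tumor fractions: CSF $U(0.1, 0.6)$ and plasma
$U(0, 0.05)$ for GI patients — the generative source of the CSF-versus-
plasma contrast — and 0 everywhere for GS patients. Clones alter a
$U(0.2, 0.6)$ fraction of the 22 autosomes (sex chromosomes are excluded;
the AF-0.5 assumption fails for male X) using single-retained-haplotype
states — copy-neutral LOH $(2,0)$ with weight 0.3, amplified LOH $(3,0)$
with 0.6, hemizygous deletion $(1,0)$ with 0.1. These are the lesions that
generate maximal allelic imbalance, i.e. exactly the signal the score is
built to detect; balanced gains, which the score cannot see at any tumor
fraction, are deliberately absent so that the score arm and the coverage
arm measure the same lesions.

Read sampling is binomial at Poisson depths (negative-binomial
overdispersion by config) around compartment means of 800× (leukocyte),
1000× (plasma/tissue) and 1500× (CSF) over 300 het SNP sites — a panel-like
density; the real panel's het-site count is unpublished, so this is a
configurable default, not a claim. WGS tracks use 3 Mb bins at 2000
expected counts per diploid bin, keeping per-bin $\log_2$ noise
($\approx 1/(\ln 2\sqrt{\lambda}) \approx 0.03$) well below the merge
tolerance — consistent with ~10× WGS at that bin width. A somatic layer
adds driver mutations (TP53, EGFR, RB1, ERBB2, KMT2C, CDKN2A, APC, RICTOR)
with status-dependent Bernoulli probabilities so co-mutation enrichment is
exercisable; the probabilities are config entries, not biology.

The clinical layer ties covariates to the realized CSF score:
$\ln(\mathrm{ICP}) = \ln(1.3) + 1.2\,s + N(0, 0.5)$ kPa with a
lumboperitoneal shunt placed above 2.5 kPa (the clinical indication);
$\mathrm{KPS} = \mathrm{round}_{10}(\mathrm{clamp}(80 - 30 s + N(0, 10),
10, 100))$. Survival is exponential with GS-baseline medians of 2.9 years
(MFS) and 3.9 years (OS), hazards multiplied by 2.338 / 2.109 for GI
patients, under independent $U(0, 10)$-year administrative censoring
(staggered entry, fixed analysis date; ~25% censoring for MFS).

## What the generator does and does not emulate

It emulates the statistical skeleton: AF deviation driven by
allele-specific copy number at a given tumor fraction, depth-limited
binomial noise, near-diploid plasma, bimodal cohort scores, and
survival/covariate associations of the configured sizes. It does not
emulate sequencing artifacts or mapping noise — GS samples score exactly 0
here, whereas real stable samples sit near 0.03 — nor subclonal mixtures
(one clone per patient), GC/mappability bias, read-level data, or
correlated MFS/OS times (the two endpoints are drawn independently).
Consequently, passing tests demonstrate that the pipeline recovers the
signal its model generates; they do not certify performance against
artifact-heavy real panels. Two visible consequences of these study
conditions: the mixture cutoff fitted on generator cohorts lands just
above the exact-zero mass (far below the ~0.07 seen on noisier real-world
score distributions, which the bimodal-cohort recovery test mirrors
instead), and the fraction of CSF samples classified GI (~25–35%) is
bounded by the share of clones with tumor fraction above ~0.4, since no
integer copy-number state can push a het AF outside the quartile band at
lower $f$.

# Statistical layer conventions

* Categorical group tests: Pearson chi-squared *without* continuity
  correction when every expected cell count is at least 5, Fisher's exact
  otherwise. This single rule reproduces standard clinical baseline tables
  computed under mixed test footnotes.
* Continuous group tests: Wilcoxon rank-sum, summarized as median (IQR).
* Multivariate Cox entry is gated at univariate $p < 0.05$; with a single
  qualifying covariate the multivariate model is identical to the
  univariate one by construction.
* Correlations default to Pearson; Spearman by flag.
* Raw p-values are reported throughout the exploratory co-mutation scan —
  no multiplicity correction — and the tables say so.
* Gene-level somatic status is derived by subtracting the leukocyte
  variant keys from the assay table; CNV records count as gene mutations
  only by explicit flag.
* The log-rank test returns `NA` with a warning on degenerate inputs (no
  variance); groups without events flag their hazard ratios unstable.

# Reproducibility and problem sizes

Every stochastic routine consumes the ambient RNG stream; cohort
generation seeds it once from `config$seed`, and `simulate_cohort()` is
byte-deterministic given the config. The mixture EM seeds its restarts
from its own `seed` argument via an isolated RNG scope, leaving the global
stream untouched. The test suite validates at desk scale chosen to keep
Monte-Carlo error well inside the asserted margins: 500 seeds for the
stable-sample noise floor, a 7-point tumor-fraction grid × 100 seeds for
monotonicity, 100 bimodal replicates for cutoff recovery, 500 simulated
trials of 400 patients per arm for hazard-ratio recovery and CI
calibration, 200 samples for score/AGF concordance, and 20 seeds × 30
pairs for the same-clone correlation.

# Known limitations

The score saturates at tumor fractions below ~0.25–0.4 depending on the
lesion (no integer state escapes the quartile band earlier), so
moderate-infiltration unstable samples are indistinguishable from stable
ones by design of the statistic itself; the copy-number arm is aligned to
the same sensitivity rather than tuned to its (better) intrinsic one.
Indel matching trims common prefix/suffix only — full left-alignment would
need flanking reference sequence, which the tabular inputs do not carry.
The segmenter is a minimal greedy merge, adequate for chromosome-arm-scale
events at low bin noise, not a replacement for CBS-class methods on real
tracks. Survival modeling is exponential with administrative censoring;
no competing risks, landmarking or time-dependent covariates.
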