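---
title: "Methods: adhesion-assay quantification and twin heritability in twinLEA"
author: "twinLEA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adhesion-assay quantification and twin heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinLEA)
```

# The measurement model

A leukocyte–endothelial adhesion (LEA) screen loads a fixed number of
Calcein-labeled cells (50,000/well by convention) onto confluent endothelial
monolayers in 96-well plates, washes three times, and reads total-area
fluorescence (RFU) before washing and after the third wash. Two phenotype
scales are derived per well:

* **% input RFU** = 100 · RFU(wash3)/RFU(pre-wash) — a pure ratio, so any
  plate- or well-level multiplicative gain common to the two reads cancels.
  This is the primary scale: it needs no calibration and is the default fed
  to the heritability analysis.
* **% adherent cells** = 100 · f⁻¹(RFU(wash3))/cells loaded, where f is a
  four-parameter logistic (4PL) standard curve fitted to wells with known
  cell loads. This scale corrects the curvature of the fluorescence–cell
  relationship but inherits the standard curve's uncertainty. Which scale
  feeds downstream analysis is a configuration switch
  (`phenotype_scale`), since practice varies; both are always computed when
  a curve exists.

A cell line's phenotype is the **mean over its technical replicate wells**
(8 by convention) after QC, with replicates on failed plates excluded. The
mean (rather than median) is used so the reported replicate CV describes the
same statistic that is aggregated.

## The 4PL curve: fitting, inversion, numerics

`fitFourPL()` performs a deterministic least-squares fit of
f(x) = d + (a − d)/(1 + (x/c)^b) by Levenberg–Marquardt. Starting values
follow a fixed rule — `a` and `d` from the min/max observed RFU, `c` from the
geometric midpoint of the positive cell-load range, `b = 1` — so a given
dataset always yields the same curve; reproducibility of the pipeline was
preferred over adaptive initialization. At least 4 distinct concentrations
are required (4 parameters); non-convergence raises an error naming the
starting point rather than returning a silent best iterate.

Inversion uses the closed form x = c·((a − d)/(y − d) − 1)^{1/b}, the unique
preimage for a monotone curve. **No extrapolation**: RFU values at or beyond
an asymptote are refused, naming the violated asymptote. Wells that cannot be
inverted contribute `NA` to the %-adherent mean instead of a clipped value.

## Quality control

Per plate, `plateQC()` computes per-sample replicate CV (on % input RFU),
the Z′-factor 1 − 3(σ₊ + σ₋)/|μ₊ − μ₋| and SNR (μ₊ − μ₋)/σ₋ from the
control wells, and a composite Z′ that pools control wells across plates
exactly (within- plus between-plate sums of squares). Two defaulted gates
decide `passed`: Z′ ≥ 0.5 and **plate median per-sample CV ≤ 10%**. The
median was chosen deliberately: with 8 replicates the per-sample CV estimate
has a sampling sd of roughly a quarter of its value, so an "every sample
under 10%" rule would fail a substantial fraction of plates whose true
replicate noise is well under 10%; the full per-sample CV distribution is
kept in the report rather than reduced to one scalar, since conventions
differ on whether a quoted plate CV is a mean, median or worst case. The
choice of SNR denominator (negative-control sd) follows classic screening
practice; a pooled-sd alternative is available, as the definition is not
standardized.

Sample sds use the n−1 denominator throughout — replicate counts are small
(8), where the distinction matters.

# The twin design

## Estimators

Members of a twin or sibling pair are exchangeable, so intra-pair
resemblance is measured by the one-way random-effects ANOVA intraclass
correlation for k = 2: ICC = (MS_B − MS_W)/(MS_B + MS_W), which is invariant
to within-pair member order and bounded in [−1, 1]. A double-entry Pearson
estimator (correlating the pair list with its member-swapped copy) is
provided as an option; the two agree to O(1/n) and the ANOVA form is the
default because it is the classical twin-analysis estimator.

Falconer's formula h² = 2(r_MZ − r_DZ) treats full siblings as dizygotic
twins: MZ pairs share all additive genetic variance, full siblings half, and
both kinds of pair are assumed to share common environment equally (the
equal-environments assumption), so the doubled difference isolates the
additive fraction. The raw estimate is reported even outside [0, 1] — with
23 pairs per group the estimator's sd is ≈ 0.37, so out-of-range values are
an expected feature of the sampling distribution, and silently clipping them
would bias any average over studies. Truncation to [0, 1] is opt-in and the
result object flags out-of-range estimates either way.

## Permutation null

"Randomizing the samples" admits more than one concrete scheme. The default
pools all 2·n_MZ + 2·n_SIB phenotype values and re-deals them into
pseudo-pairs preserving the group sizes, which destroys both pair resemblance
and any group difference; the alternative (`scheme = "pair_label"`) keeps
pairs intact and permutes zygosity labels, testing only the MZ/SIB contrast.
The pooled values are sorted before dealing, so the null — and hence the
p-value — is invariant to pair and member order, and bit-identical under a
fixed seed. The empirical p uses the add-one rule
p = (1 + #\{h²_null ≥ h²_obs\})/(1 + n_perm), never claiming resolution finer
than 1/(n_perm + 1). Note that under the individual re-dealing null with 23
pairs per group the null distribution of h² is wide (sd ≈ 0.6), so even a
true h² near 0.7 does not generally reach small p-values at this sample
size; the permutation machinery is calibrated (type-I error at the nominal
level under the null, verified by simulation in the test suite), which is
the property the implementation guarantees.

## Confounder screening

Covariate screens follow the covariate's type: Pearson correlation for
continuous (age, transformation time), two-sample t-test for binary (sex,
growth class), one-way ANOVA for multi-level (ethnicity); equality of
variance across groups uses the two-sided F-test with the larger variance in
the numerator (pairwise with Bonferroni beyond two groups). Unadjusted
p-values are reported — each screen is a separate scientific question — with
a Bonferroni column alongside for transparency. Constant covariates are
flagged not-testable rather than forced.

# The synthetic-study generator

`simulatePairPhenotypes()` draws each subject as
y = μ + σ(√h²·A + √c²·C + √(1 − h² − c²)·E), A shared fully within MZ pairs
and with correlation ½ within sibling pairs, C shared within every pair, E
independent. The implied correlations are r_MZ = h² + c², r_SIB = h²/2 + c²,
so the Falconer estimator recovers h² in expectation — the generator and the
estimator share the additive model but no code path.

Defaults are the study conditions the package emulates: 23 MZ and 23 sibling
pairs; phenotype mean 40.25% input RFU, sd 10.37; replicate CV 8.68% over 8
replicate wells; positive-control adhesion 35%, negative-control 5% (a
7-fold dynamic range); h² = 0.6966 with c² = 0.10 (so r_MZ ≈ 0.80,
r_SIB ≈ 0.45 — c² = 0.10 is a modest shared-environment share consistent
with the twin correlations the defaults target). Phenotypes are clipped to
(1, 99) before plate simulation; at the defaults the clip rate is far below
0.1% (≈ 0.008% expected), so the genetic signal is untouched, and the
realized rate is returned and asserted in tests.

`simulatePlateReadings()` lays samples onto 96-well plates: 8 replicate
wells per line, 8 positive-control, 8 negative-control and 8 standard-curve
wells per plate (72 test wells → 9 lines/plate; extra samples paginate onto
further plates). A sample's generative phenotype is defined on the % input
RFU scale: the pre-wash signal is the generative 4PL curve at the loaded
cell count times the plate gain, and the wash3 signal is phenotype/100 times
the pre-wash signal. Each read gets multiplicative log-normal noise with
CV = replicate_cv/√2, so the post/pre **ratio** has CV ≈ replicate_cv —
fluorescence noise scales with signal, hence multiplicative. With zero noise
and unit gain, % input RFU recovers every phenotype exactly; the %-adherent
scale then differs from the generative value only through the curve's
curvature, mirroring the real assay's two scales. Per-plate gain factors
emulate batch effects that `standardizeToControl()` must cancel exactly.

What the generator does **not** emulate: wash-step kinetics (only pre-wash
and wash3 are generated), spatial plate artifacts (edge effects, drift),
fluorescence background, and any biology of EBV transformation. Passing
tests therefore demonstrate correctness of the statistical machinery under
the additive model and multiplicative noise — not robustness to spatially
structured artifacts in real plates.

# Problem sizes and determinism

Simulation-backed checks use sizes chosen to bound Monte-Carlo error well
below the tolerances they assert: 2,000 pairs per group × 20 seeds for
estimator-bias checks (MC sd of the mean ≈ 0.009 on h²), 200 replicate
studies × 500 permutations for type-I-error calibration (binomial 95% CI
half-width ≈ 0.03 around 0.05), and 10,000–20,000 pairs for implied-
correlation identities. Every stochastic step takes an explicit integer
seed; the same seed yields bit-identical results, including fixture files
and the permutation null.

# Known limitations

* The Falconer/ICC design cannot separate additive from non-additive
  genetic variance or test the equal-environments assumption; full ACE/ADE
  variance-component likelihood modelling is out of scope.
* QC has no spatial plate-effect correction; a plate with strong edge
  effects can pass the gates.
* The %-adherent scale depends on standard-curve quality; with fewer than 4
  distinct calibration loads on a plate the study-wide curve is used as a
  fallback, and with none the scale is `NA`.
* Heritability sampling error at 23 + 23 pairs is large (sd ≈ 0.37);
  single-study point estimates should be read with that in mind.
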