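---
title: "Models and methods for coculture interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for coculture interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocultr)
```

This vignette documents the statistical models behind `cocultr`, the
assumptions they make, the tunable parameters and their defaults, the
numerical choices taken where the underlying methodology leaves room, and
what the synthetic-data generator does and does not emulate.

## The measurement model

A Biolog GEN III plate couples carbon oxidation to the reduction of a
tetrazolium dye, so the 590 nm absorbance of a well is a proxy for how much
of that well's carbon source the culture has oxidised — its **carbon usage
efficiency (CUE)**. The 750 nm channel tracks turbidity and is carried
through the same interface but never used as CUE by default.

Normalisation subtracts the negative-control well A1 of the *same plate,
wavelength and timepoint* from every well (`a1_zero()`). Two choices here
deserve comment:

* **Per-timepoint zeroing.** The control could be read once (at the
  analysis endpoint) or per timepoint. We zero per timepoint: the control
  well's signal drifts with incubation just as the carbon wells' baselines
  do, and per-timepoint subtraction is the reading under which zeroing is
  idempotent and preserves within-plate contrasts at every time.
* **Negative CUEs are retained.** Wells can fall below the control after
  zeroing (a weakly oxidising culture, control drift, noise). Clamping at
  zero would bias downstream variance estimates, so negative values are
  kept and flagged (`negative_cue`); `clamp_negative_cue = TRUE` restores
  clamping for users who want the bounded scale.

The analysis timepoint defaults to 24 h — the endpoint of the design — but
`extract_cue(time_h =)` accepts any measured time, mainly for growth-curve
style displays. The 23 chemical-sensitivity wells of the GEN III plate
(columns 10–12, plus the A10 positive control) are parsed and excluded.

## qPCR quantification

Standard curves are ordinary least squares of Ct on log10 template
concentration over a serial dilution series (by default 4-fold from
10 ng/µL). Replicate standards enter as individual points rather than
being averaged first, preserving residual degrees of freedom for the
reported R²; a fit with R² < 0.98 warns. The slope of an ideal
efficiency-2 amplifier is −1/log10(2) ≈ −3.32 cycles per decade, and the
implied efficiency `10^(−1/slope)` is reported with every curve.

Quantification inverts the curve, `q = 10^((Ct − intercept)/slope)`.
Quantities extrapolated below the lowest standard are kept but flagged
`below_range`; an undetermined Ct (no amplification) propagates as a
missing final ratio rather than an infinite one. The two primer sets are
assumed to share amplification efficiency — the design was validated that
way — but `final_ratios()` accepts separate per-species curves.

From the final ratio `r` (EC quantity / PP quantity) the species fractions
are `EC% = r/(1+r)` and `PP% = 1/(1+r)`. Numerically the PP fraction is
computed as `1 − EC%`: identical to the printed formula to within one ulp,
and it makes the two fractions sum to exactly 1 in floating point, an
invariant downstream code relies on.

## Preference calls

A carbon source is EC- or PP-preferred when a two-sample t-test on the two
monocultures' replicate CUEs is significant at 0.05 and the corresponding
mean is higher; otherwise it is nonpreferential. The raw p-values are used
deliberately — the preference call is a per-carbon description, not a
family-wise discovery claim — so no multiplicity adjustment is applied
across the 71 sources.

The default test is Welch's (unequal variances): with three replicates per
group it is slightly conservative when variances are in fact equal, which
we consider the right failure mode for a labelling rule;
`var_equal = TRUE` restores Student's pooled test. Constant inputs are
handled explicitly: equal constant sets give p = 1 ("none"), unequal
constant sets p = 0.

## Final-ratio structure

Ratio statistics operate on the log10 scale throughout, which symmetrises
the EC:PP and PP:EC directions and stabilises variance across the four
orders of magnitude a coculture panel spans. Per carbon source, a one-way
ANOVA compares the three cocultures' log10 ratios; p-values are BH-adjusted
across the carbons actually tested (a carbon with an entirely missing
coculture is flagged untestable and excluded from the family, since BH is
defined over performed tests), and significance is coded from the adjusted
value (`**` < 0.01, `*` < 0.05, `ns`). Tukey HSD supplies the post hoc
pairs. Group-level contrasts of ratio distributions use pairwise Wilcoxon
rank-sum tests, BH-adjusted within each comparison family;
`stats::wilcox.test()` provides the exact-versus-normal-approximation
switching (exact for small tie-free samples, tie-corrected normal
otherwise).

## The interaction model

The package's core is a null model for the CUE of a *non-interacting*
coculture. If species A and B occupy fractions `pA` and `pB = 1 − pA` of
the coculture (measured by qPCR at the endpoint), the expected ("calculated")
CUE is the abundance-weighted mixture of the monoculture means:

$$\mu_2 = p_A\,\overline{\mathrm{CUE}}_A + p_B\,\overline{\mathrm{CUE}}_B.$$

Both the measured coculture CUE (mean $\mu_1$) and this calculated CUE are
treated as normal. The dispersion of the calculated CUE is propagated
assuming the two monoculture measurements are independent,
$\mathrm{sd}_2^2 = p_A^2\,s_A^2 + p_B^2\,s_B^2$ — the delta-method variance
of the weighted sum. A conservative alternative
(`variance_mode = "pooled"`, the unweighted pooled variance of the two
replicate sets) is available; it never shrinks the null dispersion when one
species is rare, at the cost of power.

Classification is by **sequential one-sided Welch tests** at
`alpha = 0.05`:

1. test the alternative $\mu_1 > \mu_2$; rejection ⇒ **positive**;
2. otherwise test $\mu_1 < \mu_2$; rejection ⇒ **negative**;
3. otherwise **unresolved**.

The expected CUE enters the Welch statistic as a summary-form second sample
`(mu2, sd2, n_effective)` with Welch–Satterthwaite degrees of freedom.
`n_effective` is the monoculture replicate count when the two sets are the
same size (the designed case, n = 3); for unequal sets a
Welch–Satterthwaite effective count from the weighted variance components
is used. The species fractions are averaged over the coculture's qPCR
replicates before weighting; a replicate-paired mode is not provided
because plate replicates and qPCR replicates are not physically matched
samples in this design.

Two properties of the procedure are worth stating plainly:

* **Combined null call rate.** Each branch runs one-sided at the full 0.05
  level with no correction across branches. Under the null the two
  rejection regions are the disjoint 5% tails, so the combined
  positive+negative call rate is close to $2\alpha \approx 0.10$, not
  $\alpha$. The test suite asserts exactly this ~0.10 behaviour; a user
  wanting a 5% family rate should set `alpha = 0.025`.
* **Agreement with the bounds rule.** The coarse legacy rule
  (`bounds_precheck()`: positive above both monoculture means, negative
  below both) is implied by the t-test call in the small-dispersion limit,
  because $\mu_2$ always lies between the monoculture means. The package
  reports both, the t-test call being the refinement that resolves the
  interior region.

## Profiling

**Usage groups.** Carbon sources are clustered on the replicate-level CUE
matrix (carbons × culture-replicates) by complete-linkage agglomeration on
Euclidean distances — complete linkage because usage groups should be
compact in every culture condition, Euclidean because all columns share
the CUE scale (both are arguments of `cluster_usage_groups()`). Cluster
*labels* are made reproducible by ordering clusters on ascending
within-group mean CUE: U1 is always the lowest-CUE (hardest-to-use) group.
The culture side is clustered analogously at replicate level, since
replicate columns are genuine observations of each culture's profile.

**PCA.** `pca_profiles()` is a centred, by default unscaled, principal
component decomposition (all variables are CUEs on one scale, so scaling
would only inflate noisy columns). Component signs — arbitrary in any
SVD — are fixed by making the largest-magnitude loading of each component
positive.

**Regression.** `regress_cue()` fits OLS of CUE on treatment-coded
categorical factors with reference levels chosen as the natural baselines:
usage group U1 (low everywhere), initial ratio 1:1 (the symmetric
inoculum), preference "none". The initial ratio is a 3-level factor, not a
numeric log-ratio, because its effect on CUE is not monotone — both
departures from 1:1 can lower capacity. Monocultures are excluded (no
initial ratio is defined for them). Term influence is ranked by partial
(drop-one) sums of squares, which, unlike sequential sums, do not depend
on the order the terms were written.

## The synthetic-data generator

`generate_experiment()` draws a full experiment from an explicit generative
model matching the assumptions above:

* replicate CUEs are Normal(mean, `cue_noise_sd`) per (culture, carbon);
  the default noise sd of 0.02 is a low-noise plate setting, roughly the
  replicate scatter a well-run phenotype array achieves on the 0–1 CUE
  scale;
* coculture CUE means equal the abundance-weighted expectation shifted
  additively by a planted interaction mode (±δ) — additivity is the
  natural effect model for a comparison of means on the CUE scale;
* raw absorbance at time t is `baseline + (t/t_max) · CUE`, with the
  baseline drawn once per plate (Uniform on 0.15–0.25), so A1-zeroing
  recovers the planted CUE exactly at the endpoint and zero signal at
  t = 0; control-well noise is absorbed into the plate baseline rather
  than modelled separately, so that the replicate dispersion of zeroed
  CUEs equals `cue_noise_sd` by construction;
* per-replicate final ratios are lognormal (`log10 r ~ N(mean, sd)`), a
  fixed total DNA mass is split between the species by the ratio, and Ct
  values follow the standard curve plus Normal cycle noise (sd 0.1);
* one global seed feeds independent sub-streams for plates, qPCR and
  standards, so the outputs are byte-identical under a fixed seed and
  adding an output never perturbs another.

`default_study_config()` encodes the study-scale design: 71 carbons,
5 cultures, 3 replicates; a preference partition of 18 EC / 27 PP / 26
none; usage groups of 41/14/16 whose planted CUE patterns make U2 high
only in the 1:1 and 1000:1 cocultures (via strong planted synergy,
δ = 0.6) and U3 high everywhere except the EC monoculture; coculture
ratio centres of 10^−2.5, 10^−1.44 and 10^−0.8 with preference-linked
offsets, spanning ~10⁻⁴–10 with a pooled median near 0.03; 12 carbons with
identical coculture ratio distributions (true ANOVA nulls); and planted
interaction frequencies that make the 1:1000 coculture predominantly
negative and the 1:1 coculture predominantly positive. Other planted
effects use δ = 0.1 = 5 noise sd, a clearly detectable but not degenerate
effect at n = 3.

What the generator does **not** emulate: growth kinetics (the time course
is a deterministic ramp, not a logistic curve), plate spatial effects and
edge artefacts, well-to-well optical cross-talk, differential primer
efficiencies, qPCR inhibition, or the chemical-sensitivity wells.
Consequently, passing recovery tests on synthetic data demonstrates that
the *statistical pipeline* is correct under its own assumptions — not that
those assumptions hold for any particular instrument or strain pair.

## Problem sizes and numerical conventions

The test suite exercises the pipeline at the sizes where its claims are
sharp but cheap: full 71-carbon experiments for structure-recovery checks;
1000-instance oracle sweeps for the classifier; 500–2000 draws for
calibration rates; a 10,000-well run for noise-calibration of the
generator. Monte-Carlo acceptance bands use 99% binomial intervals around
the nominal rate.

Degenerate inputs are resolved explicitly rather than left to NaN
propagation: constant t-test inputs (p of 1 or 0 by mean equality),
all-zero dispersion in the interaction test (decided by mean comparison,
p of 0/1), fractions at the closed boundary {0, 1} accepted as degenerate
weights, k = 1 clustering, and constant matrices in PCA (zero-variance
warning, no components).

## Known limitations

* Interaction calls are made per (coculture, carbon) at a fixed alpha with
  no multiplicity control across the 71 carbons; the calls are
  descriptive, and users performing discovery-style inference should
  adjust `p_pos`/`p_neg` themselves.
* The expected-CUE null assumes the monoculture CUE is the per-capita
  phenotype that scales linearly with relative abundance; strongly
  density-dependent phenotypes violate that premise.
* The summary-form Welch test treats `sd2` as if estimated from
  `n_effective` replicates; that is an approximation whenever the two
  monoculture variances differ greatly and the fractions are extreme.
* qPCR quantities below the lowest standard are linear extrapolations,
  trustworthy only as order-of-magnitude estimates (hence the
  `below_range` flag).
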