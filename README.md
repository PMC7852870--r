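# cocultr

Analysis of two-species bacterial coculture experiments run across many
carbon sources on Biolog GEN III phenotype-microarray plates.

The experimental design the package targets: *Escherichia coli* (EC) and
*Pseudomonas putida* (PP) are grown — as monocultures and as cocultures
inoculated at initial EC:PP ratios of 1:1000, 1:1 and 1000:1 — in 71
different carbon sources, in triplicate, with absorbance read at 590 and
750 nm every 4 h for 24 h. Species-specific qPCR assays quantify the two
populations after 24 h. The scientific question is how the initial inoculum
ratio and the carbon source jointly shape community structure (the final
ratio), community function (the carbon-usage profile) and the interaction
between the species.

## What the package computes

- **Carbon usage efficiency (CUE).** Raw 590 nm absorbance, normalised by
  subtracting the same plate's negative-control well (A1-zeroing), taken at
  24 h: a proxy for the extent of carbon oxidation in each well. Functions:
  `load_readings()`, `a1_zero()`, `extract_cue()`.
- **Final ratios from qPCR.** Ct values are converted to template
  quantities through an OLS standard curve (Ct on log10 concentration over
  a 4-fold dilution series), and each coculture's final ratio
  *r* = EC/PP yields species fractions EC% = *r*/(1+*r*) and
  PP% = 1/(1+*r*). Functions: `fit_standard_curve()`, `quantify()`,
  `final_ratios()`.
- **Carbon preference.** Per carbon source, a two-sample t-test (Welch by
  default) on the monoculture CUEs calls the source EC-preferred,
  PP-preferred or nonpreferential at p < 0.05. Function:
  `preference_calls()`.
- **Ratio structure.** Per-carbon one-way ANOVA of log10 final ratios
  across the three cocultures, Benjamini–Hochberg adjusted across carbons,
  with Tukey HSD post hoc pairs; pairwise Wilcoxon rank-sum comparisons
  between groups. Functions: `test_final_ratios()`, `compare_groups()`.
- **Interaction classification** (the core model). For each coculture and
  carbon source, the *expected* CUE of a non-interacting coculture is the
  abundance-weighted mixture of the monoculture CUEs,

      mu2 = pA * mean(CUE_A) + pB * mean(CUE_B),      pA + pB = 1,

  with the fractions taken from the 24-h final ratio and the variance
  propagated as `sd2^2 = pA^2 var(CUE_A) + pB^2 var(CUE_B)`. The measured
  coculture CUE (mean mu1) is compared against this null by sequential
  one-sided Welch tests at alpha = 0.05: first the positive direction
  (mu1 > mu2; rejection means a **positive** interaction), then the
  negative direction (**negative**), otherwise **unresolved**. The simple
  bounds rule (above both monoculture means / below both / between) is
  reported alongside. Functions: `expected_cue()`, `classify_interaction()`,
  `classify_interactions()`, `summarize_interactions()`.
- **Profiling.** Complete-linkage hierarchical clustering of the
  71 × 15 replicate-level CUE matrix into usage groups U1/U2/U3, PCA of the
  profiles, and an OLS regression of CUE on usage group, initial ratio and
  preference. Functions: `cluster_usage_groups()`, `pca_profiles()`,
  `regress_cue()`.
- **Synthetic experiments.** A generator that draws complete experiments
  (plate readings, qPCR tables, standards) from a configurable model with a
  ground-truth ledger, so every stage is testable end to end:
  `simulation_config()`, `default_study_config()`,
  `generate_experiment()`.

## Worked example

A complete synthetic experiment with the study's structure, analysed end to
end:

```r
library(cocultr)

cfg <- default_study_config(seed = 1)
ex  <- generate_experiment(cfg)

cue <- extract_cue(a1_zero(load_readings(ex$readings, ex$layout)), ex$layout)
cue
#> CUE matrix (590 nm, A1-zeroed, t = 24 h)
#>   71 carbon sources x 5 cultures x 3 replicates
#>   151 negative CUE values flagged

table(preference_calls(cue)$preference)
#>   EC none   PP
#>   19   25   27

std   <- ex$standards[ex$standards$species == "EC", ]
curve <- fit_standard_curve(std$concentration, std$ct)
curve
#> qPCR standard curve: Ct = 23.9793 -3.3414 * log10(conc)
#>   R^2 = 0.9993 over 18 points (0.00977-10 ng/uL), efficiency = 1.992

fr <- final_ratios(ex$qpcr, curve)
median(fr$ratio, na.rm = TRUE)
#> [1] 0.0266

summarize_interactions(classify_interactions(cue, fr))
#>   culture  n positive negative unresolved
#> 1  1:1000 71    0.085     0.63       0.28
#> 2     1:1 71    0.493     0.25       0.25
#> 3  1000:1 71    0.310     0.15       0.54

cluster_usage_groups(cue, k = 3)
#> Carbon usage groups (complete-linkage clustering, k = 3)
#> U1 U2 U3
#> 41 14 16
```

The preference table recovers the planted 18/27/26 partition to within the
t-test's resolution at three replicates; the usage-group clustering
recovers the planted 41/14/16 partition exactly; the interaction summary
shows the planted pattern — the 1:1000 coculture dominated by negative
interactions, the 1:1 coculture by positive ones. The regression of CUE on
the annotated factors (`regress_cue(regression_table(...))`) ranks their
influence usage group > initial ratio > preference with adjusted
R² = 0.84 on this draw.

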