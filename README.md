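# clpnet — cross-lagged panel networks for two-wave symptom panels

`clpnet` estimates **cross-lagged panel networks (CLPNs)** from two-wave
ordinal symptom data such as the PHQ-9, for researchers studying how
individual symptoms predict each other over time — e.g. which depressive
symptom at baseline drives which symptoms at follow-up, and whether that
differs between groups on different symptom trajectories.

## The model

Given p symptom scores measured at two waves (T1, T2), the CLPN is a
directed network over the p symptoms in which the edge *i → j* is the
regularized regression coefficient of symptom *i* at T1 predicting symptom
*j* at T2, controlling for all other T1 symptoms (and optional covariates).
For each target *j*, with all variables z-standardized within group,

&nbsp;&nbsp;&nbsp;&nbsp;minimize&nbsp; (1/2n) Σₛ ( z²ₛⱼ − Σᵢ βᵢⱼ z¹ₛᵢ − Σₖ γₖⱼ cₛₖ )² + λⱼ ( Σᵢ |βᵢⱼ| + Σₖ |γₖⱼ| )

The LASSO penalty λⱼ is selected per equation by 10-fold cross-validation;
βⱼⱼ is the **autoregressive** path, βᵢⱼ (i ≠ j) the **cross-lagged** paths,
and covariate coefficients γ never enter the edge matrix. On top of the
fitted network the package computes:

- **Trajectory stratification** — each subject's PHQ-9 totals are
  dichotomized at a cutoff (default ≥ 7) and the 2×2 pattern maps to
  *chronic* (depressed both waves), *delayed* (T2 only), *recovery*
  (T1 only), *resistance* (neither).
- **Expected influence** — out-EI(i) = Σⱼ βᵢⱼ and in-EI(j) = Σᵢ βᵢⱼ, in
  *overall*, *cross-lagged* (autoregression excluded) and *cross-construct*
  variants, raw and z-standardized. High out-EI marks priority intervention
  targets.
- **Stability diagnostics** — nonparametric bootstrap 95% CIs around each
  edge, case-drop correlation-stability (CS) coefficients for the
  centrality rank order (≥ 0.25 acceptable, ≥ 0.5 preferred), and bootstrap
  difference tests between edges and between centralities.
- **Network comparison** — Pearson correlation of vectorized edge matrices
  between groups, with and without the autoregressive diagonal.
- **Synthetic panels** — a latent-threshold generator with known cross-lag
  structure and four trajectory-scenario presets, so the whole pipeline is
  testable end to end without cohort data.

## Worked example

```r
library(clpnet)

# a synthetic cohort with elevated severity at both waves
sim <- generate_panel(generator_spec(n = 1000, t1_mean_shift = 1.3,
                                     t2_mean_shift = 1.3, seed = 42))
stratify_cohort(sim$panel)
#> Cohort stratification (n = 1000, cutoff >= 7):
#>  trajectory   n percent
#>     chronic 849    84.9
#>     delayed 100    10.0
#>    recovery  15     1.5
#>  resistance  36     3.6

fit <- clpn(sim$panel, seed = 1)
summary(fit)
#> CLPN over 9 symptoms (n = 1000)
#>   36 of 72 cross-lagged edges nonzero
#>   strongest autoregressive path: sleep (weight = 0.281)
#>   strongest cross-lagged edge: suicidal_ideation -> motor (weight = 0.245)

head(expected_influence(fit, "overall"), 3)
#>          symptom in_ei_raw out_ei_raw in_ei_z out_ei_z variant
#> 1      anhedonia     0.727      0.340   1.098   -0.568 overall
#> 2 depressed_mood     0.727      0.447   1.094   -0.200 overall
#> 3          sleep     0.438      0.587  -0.338    0.276 overall

case_drop_cs(sim$panel, "out_ei", reps_per_level = 50, seed = 1,
             refit = "fixed_lambda")
#> CS coefficient (out_ei, overall variant): 0.70
#>   (largest drop proportion keeping the 5% correlation quantile >= 0.70)
```

The stratification table shows that the chronic scenario preset indeed
yields a mostly-chronic cohort; the summary reports how sparse the selected
network is and its strongest temporal paths; the centrality table gives
each symptom's expected influence (here suicidal ideation's out-EI of 1.24,
z = 2.50, reflects the generator's built-in hub of outgoing paths from that
node); the CS value of 0.70 means the out-EI rank order survives dropping
up to 70% of cases.

The full pipeline — stratify, fit one network per trajectory group,
centralities, bootstrap/CS diagnostics, between-group comparison matrix,
reproducibility manifest — runs from one config:

```r
run_clpn_pipeline(list(input = "panel.csv", out_dir = "run1", seed = 1))
```

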