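# sempic

Phylogenetic path analysis of extra-pair paternity by structural
equation modeling on independent contrasts.

## The problem

Rates of extra-pair paternity (EPP) — the share of offspring sired
outside the social pair — vary widely across socially monogamous
passerines, and the candidate drivers (body size, longevity, paternal
care, relative testes size, breeding range, altitudinal breadth,
clutch-size range, song complexity) are themselves intercorrelated.
Single-predictor comparative regressions cannot disentangle that web.
This package implements the path-analytic alternative: each hypothesis
is a directed acyclic graph over the nine observed variables, fit by
maximum likelihood to the species covariance matrix

&nbsp;&nbsp;&nbsp;&nbsp;Σ(θ) = (I − B)⁻¹ Ψ (I − B)⁻ᵀ,

both on raw species values and on Felsenstein's phylogenetically
independent contrasts (which remove the pseudo-replication of shared
ancestry).  Models are compared by χ², AIC, CFI and RMSEA, and every
predictor's influence on EPP is decomposed into standardized direct and
indirect (mediated) effects with delta-method inference.

Six a-priori models are shipped in `inst/models/` and validated at load
time (degrees of freedom 16, 11, 10, 15, 15, 12; all eight predictors
keep a direct arrow into EPP; no model regresses testes size on body
size).  The ML covariance-structure fitter is hand-authored (analytic
gradient, quasi-Newton, closed-form OLS start values that double as an
independent test oracle); tree handling and contrasts delegate to
`ape`, path enumeration to `igraph`.

## Worked example

The package ships a seeded generator of Yule trees and
Brownian-motion trait data obeying arbitrary structural equations, so
the full pipeline runs without any download:

```r
library(sempic)

tr     <- simulate_tree(36, seed = 1)                 # 36-tip Yule tree
tab    <- simulate_structural(tr, example_truth(),    # raw-scale traits
                              seed = 2, raw_like = TRUE)
traits <- apply_transforms(tab)                       # /10, ln transforms
report <- run_analysis(shipped_models(), traits, tree = tr)
print(report)
```

```
== independent-contrast data ==
  model      aic delta_aic  chisq df chisq_df pvalue   cfi rmsea
 model4 1299.899     0.000 23.357 15    1.557  0.077 0.894 0.126
 model6 1300.445     0.547 17.904 12    1.492  0.119 0.925 0.119
 model2 1302.277     2.379 17.736 11    1.612  0.088 0.915 0.132
 model3 1305.134     5.235 18.592 10    1.859  0.046 0.891 0.157
 model5 1313.359    13.461 36.818 15    2.455  0.001 0.723 0.204
 model1 1313.773    13.874 39.231 16    2.452  0.001 0.705 0.204
best model: model4 

== raw data ==
  model      aic delta_aic  chisq df chisq_df pvalue   cfi rmsea
 model3 1409.279     0.000 21.514 10    2.151  0.018 0.890 0.179
 model6 1413.663     4.384 29.898 12    2.491  0.003 0.829 0.204
 model2 1414.928     5.649 29.163 11    2.651  0.002 0.826 0.214
 model1 1418.154     8.876 42.389 16    2.649  0.000 0.747 0.214
 model5 1419.610    10.331 41.845 15    2.790  0.000 0.743 0.223
 model4 1424.903    15.624 47.138 15    3.143  0.000 0.692 0.244
best model: model3
```

Fitting a single model and decomposing effects on EPP:

```r
ct  <- contrasts_for_table(tr, traits)
fit <- fit_ml(shipped_models()$model6, sample_moments(ct$contrasts))
print(fit)
```

```
ML path-model fit 'model6' (9 variables, N = 35)
  chisq = 17.904 on df = 12 (p = 0.119, N convention)
  AIC = 1300.45  CFI = 0.925  RMSEA = 0.119
```

```r
ee  <- effects(fit)
epp <- ee[ee$target == "epp",
          c("source", "std_direct", "std_indirect", "std_total")]
epp[-1] <- round(epp[-1], 3)
print(epp, row.names = FALSE)
```

```
          source std_direct std_indirect std_total
       body_size     -0.214       -0.128    -0.342
       longevity     -0.214       -0.131    -0.345
    male_feeding     -0.470        0.006    -0.464
 testes_residual      0.191        0.192     0.383
      range_size      0.104        0.081     0.185
  altitude_range     -0.155        0.018    -0.136
    clutch_range     -0.121        0.072    -0.049
 song_complexity      0.160        0.000     0.160
```

(The generator's ground truth puts a strong negative direct effect on
male feeding and a strong positive one on testes size; both are
recovered.  At n = 36 species, sampling noise of this magnitude on the
weaker paths is expected — the suite quantifies it with 200-replicate
coverage checks.)

Other entry points: `read_trait_csv()` / `apply_transforms()` for real
data, `species_means()` / `composite_score()` for building the song
composite from recordings, `write_report()` to export a fitted report
as CSV + JSON, and `inst/cli/sempic.R` for a command-line wrapper.

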