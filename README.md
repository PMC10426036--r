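# brandevo

Generative inference and averaging analysis for combinatorial ownership
marks (cattle brands).

Registered cattle brands are simple graphic emblems built from a finite
alphabet of components — letters, numbers and signs — with one to four
components per brand, a body-location digit and a registration zip zone.
Because brand registries are legally complete and dated, they let us ask two
questions that matter well beyond ranching:

1. **Which forces shape the designs?** Copying of components, pressure for
   distinctiveness, and pressure for complexity all compete. `brandevo`
   fits an agent-based model of yearly brand creation to registry snapshots
   by random-forest approximate Bayesian computation (ABC) and recovers two
   parameters: the copying exponent *C* in the component-adoption law
   *P(x) ∝ n(x)^C* (*C* = 1 random copying, *C* > 1 conformity, *C* < 0
   pressure for distinctiveness) and the complexity parameter *λ* of the
   truncated-Poisson distribution of components per brand.
2. **What does time- and space-averaging do to signals of copying?**
   Archaeological assemblages are almost always mixed over time and space.
   `brandevo` implements a shuffling model — a pointwise-mutual-information
   style null that predicts the prevalence *S = Π Fᵢ · N_other* of every
   component combination from component marginals — and compares its
   accuracy on structured versus deliberately time-/space-mixed datasets
   with linear mixed models (ACTUAL, MIXED, COMPLEXITY effects, ICCs, an AIC
   ladder), plus a temporal-distance analysis of pairwise edit distances.

The package is aimed at cultural-evolution and archaeology researchers who
want a tested, reproducible pipeline for component-level copying inference
and for averaging experiments on synthetic or real registry data.

## Worked example

```r
library(brandevo)

# a synthetic registry with known ground truth: lambda = 3, C = 1
cfg <- synthetic_config(lambda_true = 3, C_true = 1, seed = 42)
series <- generate_observed_series(cfg)
series[["2016"]]
#> brand_population: 2780 brands, year 2016, 103-symbol alphabet

# generative inference (a quick run; defaults are n_sims = 5000, n_trees = 500)
report <- run_generative_inference(series, n_sims = 200, n_trees = 100, seed = 7)
report$posterior_lambda
#> lambda posterior: median 2.596, 95% CI [1.182, 6.043] (100 trees)
report$posterior_C
#> C posterior: median 0.976, 95% CI [0.767, 1.214] (100 trees)
```

Even this deliberately small run pins the copying exponent near its true
value of 1 — the registry's component dynamics are consistent with random
copying — and brackets the complexity parameter's truth of 3; the full-size
reference table sharpens both posteriors considerably.

For the averaging side:

```r
tb <- generate_wholesale_copy_table(seed = 1)   # planted local copying
rep <- run_averaging_experiment(tb, seed = 1)
rep$fit_time$fixed      # ACTUAL, MIXED, COMPLEXITY, ACTUAL:MIXED estimates
rep$icc_time            # variance shares of combination / quadrant / period
rep$confusion           # per-subset TP/FP/TN/FN at the S >= 1 boundary
```

A thin command-line wrapper over the same functions lives in
`inst/cli/brandevo.R` (`synth`, `abc`, `average` subcommands).

## Package layout

* `R/brand_data.R` — 13-digit code parsing, registries, deduplication, I/O
* `R/abm.R` — the generative model (frequency-dependent sampling, truncated
  Poisson complexity, yearly turnover)
* `R/summary_stats.R` — the nine-statistic summary suite (Hill numbers,
  Jaccard / Morisita–Horn beta diversity, token Levenshtein)
* `R/abc.R` — priors, reference tables, random-forest ABC, recovery harness
* `R/shuffling.R` — prevalence predictions, 16 structured subsets,
  time-/space-mixed counterparts, confusion classification
* `R/averaging.R` — mixed models, ICCs, AIC ladder, temporal distance
* `R/synthetic_data.R` — ground-truth generators and the two illustrative
  simulations
* `R/pipeline.R` — end-to-end recipes, including inference on
  label-shuffled data
* `vignettes/brandevo-methods.Rmd` — models, assumptions, parameters and
  design decisions in detail
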