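---
title: "Models and methods in brandevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in brandevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`brandevo` studies the cultural evolution of registered ownership marks
(cattle brands): graphic emblems assembled from a finite alphabet of
components (letters, numbers, signs), each brand carrying one to four
components, a body-location digit, and a registration zip zone. Because such
registries are legally complete and dated, they are a rare system in which
one can (i) infer the forces shaping design — copying of components versus
pressure for distinctiveness, and pressure for complexity — by generative
inference, and (ii) measure what time- and space-averaging, the mixing that
archaeological deposition imposes on most other material-culture records,
does to the statistical signals of copying.

This vignette documents the models, their assumptions, the tunable
parameters, and the design choices taken where the problem was genuinely
open. It states no empirical result beyond what the package's own test suite
and acceptance script compute.

## The generative model

New brands enter the registry every year. The agent-based model assumes each
new brand draws its components from the pool of components currently in use
in the whole population, with usage probability

$$P(x) = \frac{n_x^{\,C}}{\sum_y n_y^{\,C}},$$

where $n_x$ is the token count of component $x$ (counted with multiplicity
across all active brands, see `build_frequency_table()`) and $C$ is the
copying/distinctiveness exponent:

* $C = 1$: random (unbiased) copying — components used in proportion to
  their frequency;
* $C > 1$: conformist copying — common components over-adopted;
* $C = 0$: frequency-blind assembly;
* $C < 0$: pressure for distinctiveness — the rarest components are the most
  attractive.

Components with zero count are never sampled: the component alphabet is
closed (no innovation), which also keeps negative exponents well defined.
This parameterisation matches standard conformity/anticonformity models of
cultural transmission.

The number of components in a new brand (its complexity, 1–4) is drawn from
a Poisson distribution with parameter $\lambda$, truncated to $\{1,2,3,4\}$
and renormalised (`complexity_pmf()`): $q(k) \propto \lambda^k / k!$. At
$\lambda = 3$ two- and three-component brands are exactly equally likely; at
$\lambda = 0.5$ one-component brands dominate, at $\lambda = 15$
four-component brands do.

Each simulated year, `N_new` brands are created from the frequency table
compiled *before* any of the year's additions (batch creation), each
receiving a zip drawn in proportion to the zip frequencies of the observed
data; then `N_old` brands are removed uniformly at random, with brands
created the same year removable. `N_new` and `N_old` are estimated from the
observed snapshots as average appearance/disappearance counts per calendar
year (`estimate_turnover()`), with counts divided by the gap between books
when registries are unevenly spaced. Within-brand component draws are
i.i.d. with replacement — repeated components inside one brand are legal, as
they are in real registries — and no brand-uniqueness constraint is imposed
on the simulation.

## Summary statistics

Nine statistics summarise each snapshot year
(`summarize_snapshot()`), chosen to capture common variants, rare variants,
spatial structure at two resolutions, and between-brand design distance:

1. proportion of component tokens of the most common type;
2. proportion of tokens of the most rare type;
3. Hill–Shannon diversity $\exp(-\sum p_i \ln p_i)$;
4. Hill–Simpson diversity $1 / \sum p_i^2$;
5. mean pairwise Jaccard similarity of component incidence across zips;
6. mean pairwise Morisita–Horn similarity of component abundance across zips;
7. and 8. the same two indices across counties;
9. mean token-level Levenshtein distance between brands, from a random 10%
   subsample.

Diversities are reported as Hill numbers so that all indices share the
effective-number scale, and Hill numbers are non-increasing in their order,
so statistic 3 is never below statistic 4. The paired beta indices are
complementary: Jaccard is the incidence-based index most robust to sampling
error, Morisita–Horn the standard abundance-based one. The literature offers
no canonical way to aggregate a pairwise index over many communities; we use
the mean over all unordered pairs of non-empty units, which keeps both
indices in $[0,1]$ and symmetric. Levenshtein distance operates on canonical
symbol sequences in recorded slot order, ignoring rotations (consistent with
the generative model, which excludes them); its 10% subsample is drawn with
a year-offset seed so a summary vector is reproducible from one run seed.
Four snapshot years give the 36-value vector used downstream.

## Random-forest ABC

Fitting the two parameters proceeds by approximate Bayesian computation with
random forests:

1. draw $(\lambda, C)$ from the priors — $C \sim \mathcal{N}(0, 2)$,
   $\lambda \sim \mathrm{Gamma}(\mathrm{shape}\,0.9, \mathrm{rate}\,0.2)$, a
   positive prior whose mass spreads evenly over the qualitatively distinct
   complexity regimes while allowing extremes;
2. run the generative model once per draw from the shared initial population
   and record the 36 summary statistics (the reference table), with
   $\lambda$ log-transformed as recommended for non-linear regression ABC;
3. grow one random forest of regression trees per parameter on bootstrap
   samples of 80% of the table (tuned settings: 6 candidate split features
   and minimum node size 3 for $\lambda$; 17 and 3 for $C$);
4. feed the observed summary vector to every tree; the per-tree predictions,
   back-transformed, are the posterior sample, summarised by the median and
   the 2.5%/97.5% quantiles.

The posterior is deliberately the per-tree prediction distribution, not the
leaf-weight posterior of other random-forest ABC variants. A known
limitation follows: the spread of per-tree predictions reflects
between-tree variability, not full predictive uncertainty, so the 95%
intervals can be substantially anti-conservative in well-identified regions
of parameter space even when the posterior medians are accurate. The
parameter-recovery harness (`recover_parameters()`) therefore reports both
the median error and truth coverage, and coverage should be read with this
caveat. The out-of-bag RMSE on the transformed scale is attached to each
forest as a diagnostic ($C$ is left untransformed for this diagnostic: no
logit-type transform has an unbounded natural domain for it).

### Problem sizes

The package defaults are a *desk* scale chosen so a complete
recovery experiment runs on a single CPU in minutes: a ~2,000-brand initial
population over 27 years with turnover 180/150 per year, 103 components, 10
zips in 5 counties, 5,000 reference simulations and 500 trees. The
registry-scale analysis (hundreds of thousands of simulations, 1,000 trees)
is one configuration change away (`n_sims`, `n_trees`), since rows of the
reference table are embarrassingly parallel with counter-derived seeds.

## The shuffling model

For the averaging analysis, the package predicts how prevalent each
combination of components would be if components carried no information
about one another — a pointwise-mutual-information-style null. For a
three-component combination $\{A,B,C\}$:

$$S = F_A \, F_B \, F_C \times N_\mathrm{other},$$

where $F_A$ is the frequency of brands containing $A$ among brands
containing neither $B$ nor $C$ (and cyclically), and $N_\mathrm{other}$ is
the number of brands excluding exact occurrences of the focal combination.
$S$ is set to 0 when a component repeats within the combination, when a
component occurs in exactly one brand of the dataset, or when a frequency
denominator is empty. Two conventions were open: the numerator scope of
$F_i$ (we count brands containing $i$ at least once) and what "excluding the
focal brand" means when several brands realise the same combination (we
subtract all exact matches, keeping present and absent combinations on a
comparable footing); both alternatives were considered and the defaults are
the natural readings. A scalar reference implementation
(`predicted_prevalence()`) defines the semantics; the vectorised
`shuffle_predictions()` is cross-checked against it in the tests.

Brands are split into 16 structured subsets — period (old: appears in the
earliest book; young: only later) × quadrant (four county-based regions) ×
complexity (2 or 3 components; one-component brands lack combinatorics,
four-component brands are rare). Each subset gets a time-mixed counterpart
(same quadrant and complexity, any period) and a space-mixed counterpart
(same period and complexity, any quadrant), drawn without replacement at the
structured subset's size. Predictions with $S \ge 1$ count as positive when
classified against actual presence.

## Mixed models, ICCs and the AIC ladder

Non-zero predictions are log-transformed and modelled with linear mixed
models (maximum likelihood, so AICs are comparable) with a random intercept
per combination and fixed effects added in tiers: (0) intercept, (1)
`COMPLEXITY`, (2) `+ ACTUAL + MIXED`, (3) `+ ACTUAL:MIXED`. A positive
`ACTUAL` effect means the shuffling model predicts presence better than
chance; a positive `ACTUAL:MIXED` interaction means it does so *better* on
mixed than on structured data — the averaging-boosts-copying-signals
hypothesis. `COMPLEXITY` is a control: three-component combinations carry an
extra multiplied proportion and so have systematically lower prevalence.
Intraclass correlations come from a random-intercepts-only model over
combination, quadrant and period. The original analysis refit its best
models in a Bayesian framework; this package intentionally stays with
likelihood-based fits and Wald 95% intervals for determinism and light
dependencies.

The temporal-distance analysis pools old and young brands within each
quadrant–complexity cell, computes all pairwise token Levenshtein distances
(capped at 200,000 pairs per cell with seeded subsampling), and fits
`LD ~ same_period` with crossed random intercepts for the two compared
brands; old/old and young/young pairs are collapsed into one
`same_period = 1` level. Distances are computed within complexity strata,
consistent with the subset definitions. A negative coefficient means brands
from the same period are more similar — expected when copying is local in
time.

## What the synthetic data emulates — and what it does not

`synthetic_config()` fixes the study conditions: a closed 103-symbol
alphabet, brands of 1–4 components, a skewed zip distribution
(Dirichlet-style weights), yearly turnover, and known ground truth
$(\lambda, C)$. The initial component distribution is also Dirichlet-skewed;
the real 1990 distribution's shape is unknown, so the concentration is a
parameter that tests can sweep. Quadrants are synthetic labels attached to
zip zones round-robin; no geometry of any real state is emulated.

`generate_wholesale_copy_table()` plants the averaging phenomenon for the
regression checks. Its design follows the two mechanisms that the
prevalence model reacts to:

* *component-popularity heterogeneity*: the shared Zipf base weights receive
  additive log-normal quadrant and period effects (sd 0.4 each) — regional
  fashion and temporal drift. This is what makes presence of a combination
  track its local prevalence prediction (a positive `ACTUAL` effect).
  Decomposing the heterogeneity additively matters: each mixing axis then
  only blends the *other* axis's effect, the way real mixing degrades only
  the structure along the mixed dimension.
* *wholesale copying*: with probability 0.8 a new brand copies the full
  component set of an earlier brand from its own period–quadrant cell.
  Copy clusters concentrate presence on a few combinations whose predicted
  prevalence the shuffling formula deliberately depresses (exact matches are
  excluded from the frequency factors and from $N_\mathrm{other}$); mixing
  dilutes the clusters and relieves the depression, which is what makes the
  `ACTUAL:MIXED` interaction positive.

The two mechanisms pull the interaction in opposite directions, and the
chosen parameters sit where both signs are expected but not overwhelming —
deliberately so, since the phenomenon itself is subtle in real registries
(mixing windows are narrow and innovation is absent). Passing sign-recovery
tests on these tables shows the estimation machinery detects planted
structure of realistic strength; it does not show that any real registry has
that structure.

`toy_conformity_sim()` is the two-variant illustration of why time-mixing
boosts rare variants under conformity: 30 agents, two variants starting at
equal frequency, re-adoption probability proportional to
$\mathrm{freq}^C$ with $C = 2$ over three timesteps. Updating is
simultaneous by default (the natural reading of synchronous timesteps);
sequential updating is available behind a flag. `component_mixing_demo()`
runs the full generative model at $C = 0$ and $C = 10$ and contrasts
final-year component rank-frequency distributions with equal-size subsamples
pooled over all years, against the $C = 1$ reference.

## Numerical and interface choices

* **Slot grammar.** Real 13-digit codes are four 3-character slots (a
  2-character abbreviation plus a rotation digit) and a location digit. The
  padding convention for brands with fewer than four components is not
  documented for the real registry, so the filler token (default `"___"`)
  and the rotation step per digit (default 45°, eight orientations) are
  configuration. Redundant abbreviations collapse through the registry's
  rotation offsets.
* **Deduplication** removes duplicate codes within a zip (keeping the
  earliest first year, then input order) and keeps duplicates across zips;
  it is idempotent and never grows its input.
* **Seeds.** Every stage derives independent streams from one root seed via
  a counter scheme (`seed * 48271 + i * 7919 mod 2^31 - 1`), so reference
  tables are identical regardless of execution order and all pipelines are
  bit-reproducible.
* **Degenerate inputs.** Empty populations, single-snapshot turnover
  estimation, all-identical distance sets, and single-level groupings error
  or flag explicitly (`degenerate`, `converged`) rather than returning
  silent numbers.
* **Command line.** The package is primarily a programmatic toolkit; the
  end-to-end recipes (`run_generative_inference()`,
  `run_mixed_inference()`, `run_averaging_experiment()`) are ordinary
  functions, and a thin script in `inst/cli/` exposes the common ones for
  shell use.

## Known limitations

* Per-tree ABC posteriors understate uncertainty (see above); trust the
  medians, validate coverage claims by simulation at the scale you use.
* Rotation angles are parsed and round-tripped but deliberately excluded
  from the generative model and all combination identities.
* The mean-over-pairs aggregation of beta diversity is one defensible
  choice; a multi-community Hill-overlap aggregation would weight large
  units differently.
* Synthetic spatial structure is labels-only; conclusions about real
  geographic clustering require real zip-to-county-to-region tables.
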