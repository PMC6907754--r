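# visitnet

Quantitative plant–pollinator network analysis under two measures of
interaction strength.

Most quantitative pollination network studies weight each plant–pollinator
link by the frequency of *encounters* — an individual pollinator arriving at
an individual plant. But an encounter on a plant carrying hundreds of open
flowers is not the same event as an encounter on a plant with three: the
number of flowers actually *visited* per encounter varies widely among both
plants (with floral display) and pollinators (honey bees work many flowers
per bout; many beetles sit on one). `visitnet` implements the full pipeline
for building and comparing the two resulting networks from field survey
records:

- **encounter-based strength** of the link between plant *i* and pollinator
  *j*:
  `a_ij = Σ_w (encounters_wij / flowers_surveyed_wi) × flower_abundance_wi`,
  the sum over survey weeks of the weekly encounter frequency weighted by
  the plant's weekly flower abundance;
- **visit-based strength**: `a_ij × v_ij`, where `v_ij` is the mean number
  of flowers visited per encounter for that interaction, estimated from
  4-minute pollinator follows with a documented imputation hierarchy
  (own observations → functionally similar donor species → expert value →
  excluded from both networks).

On top of the paired networks it computes the standard quantitative
descriptors from their defining formulas — species strength
(`S_i = Σ_j a_ij / A_j`, the summed dependence of partners on the focal
species), the push–pull index of interaction asymmetry
(`PP_i = (1/k_i) Σ_j (d_ji − d_ij)`), the d′ specialization index
(standardized Kullback–Leibler divergence of partner use against partner
availability), weighted NODF nestedness, H2′ network specialization,
interaction evenness, and plant/pollinator generality (marginal-weighted
effective partner numbers) — and the statistical machinery to compare the
two measures: descriptor-on-descriptor OLS regressions with slope-versus-1
tests and the study's variable transformations, ratio-of-change regressions
against floral display, and bootstrap subsampling of the encounter-event
pool with paired t-tests at 25/50/75% intensity.

A synthetic survey generator (`scenario_config()`, `simulate_survey()`)
emulates the sampling design of a Mediterranean scrubland study — 19 plant
species, 122 pollinator morphotypes in eight functional groups, ~4 × 10³
encounters over a 14-week season, heavy-tailed preferences, and a positive
log–log display-to-visits relation — so every stage of the pipeline is
testable without field data. The published 19-plant survey summary ships
with the package (`garraf_plants()`).

## Worked example

```r
library(visitnet)

## Do plants with larger floral displays receive more visits per encounter?
tab <- garraf_plants()
fit_regression(tab$floral_display, tab$visits_per_encounter,
               transform_x = "log", transform_y = "log", labels = tab$code)
#> OLS regression (n = 19; x: log, y: log)
#>   slope 0.2848 +/- 0.0671 (SE), intercept 0.1664
#>   F(1, 17) = 18.04, p = 0.000543, R2 = 0.515 (adj. 0.486)
#>   H0 slope = 1: p = 5.97e-09
```

The slope is positive and highly significant: visits per encounter scale
roughly with the 0.28 power of floral display, and display explains about
half the interspecific variance (adjusted R² 0.49).

```r
## Synthetic survey through the full pipeline
sim  <- simulate_survey(scenario_config(seed = 2026))
nets <- build_networks(sim$encounters, sim$flowers, sim$visits)
nets$encounter
#> Weighted bipartite network (encounter-based strength)
#>   19 plants x 114 pollinators, 494 links, total strength 2.093e+04
unlist(nets$imputation_report)
#>     observed        donor       expert     excluded observed_ge5
#>          494            0            0           51          288

rbind(network_metrics(nets$encounter), network_metrics(nets$visit))
#>     measure wnodf h2_prime interaction_evenness plant_generality pollinator_generality
#> 1 encounter  28.9    0.488                0.603             15.1                  3.07
#> 2     visit  29.9    0.543                0.560             14.7                  2.36
```

51 of the 545 observed interactions had no follow observations and were
excluded from both networks (no donor/expert configuration was supplied
here), so the two measures are compared on an identical 494-link set.
Switching to the visit-based measure lowers interaction evenness and
pollinator generality — the qualitative signature expected when large-display
plants absorb disproportionately many visits per encounter.

```r
## Bootstrap subsampling comparison (100 replicates at 50% of encounters)
bc <- bootstrap_compare(sim$encounters, sim$flowers, nets$estimates,
                        fractions = 0.5, n_reps = 100, seed = 2027)
bc[bc$descriptor == "plant_generality",
   c("fraction", "encounter_mean", "encounter_sd", "visit_mean", "visit_sd", "p_value")]
#>   fraction encounter_mean encounter_sd visit_mean visit_sd  p_value
#> 4      0.5           14.2        0.331       13.9    0.328 3.25e-18
```

The paired t-test shows the measure effect is stable under subsampling:
plant generality is systematically lower in the visit-based replicates.

## Package layout

- `R/bipartite-network.R`, `R/io.R` — the `bipartite_network` S3 class,
  readers/writers for survey tables and long-format strength matrices.
- `R/strength.R` — weekly frequencies, encounter strength, the
  visits-per-encounter imputation hierarchy, visit strength.
- `R/species-metrics.R`, `R/network-metrics.R` — species- and network-level
  descriptors, with dialect flags for the weighted-NODF pair rule and the
  evenness denominator.
- `R/comparison.R` — regressions, ratio-of-change analysis, bootstrap
  subsampling with paired t-tests.
- `R/synthetic.R` — the scenario generator.
- `vignettes/visitation-networks.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical conventions, limitations.
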