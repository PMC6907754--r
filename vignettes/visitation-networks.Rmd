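---
title: "Encounter- versus visit-based interaction strength: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encounter- versus visit-based interaction strength: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visitnet)
```

# The problem

A quantitative pollination network weights each plant–pollinator link by an
interaction strength. The near-universal field currency is the *encounter*:
an individual pollinator observed on an individual plant during a timed
watch. But an encounter comprises one or more flower *visits*, and the
number of visits per encounter varies over two orders of magnitude among
plant species (roughly with floral display) and among pollinator groups.
Since pollen transfer and resource extraction happen at the flower, a
visit-based currency is arguably the ecologically meaningful one. This
package implements both measures and the machinery to quantify how much the
choice changes species- and network-level structure.

# Interaction strength

For plant $i$ and pollinator $j$ the encounter-based strength is

$$a_{ij} = \sum_w \frac{n_{wij}}{F_{wi}} \, B_{wi},$$

with $n_{wij}$ the encounters observed in week $w$, $F_{wi}$ the open
flowers surveyed on plant $i$ that week, and $B_{wi}$ the plant's weekly
flower abundance. Dividing by $F_{wi}$ converts counts into per-flower
encounter frequencies (sampling effort is never proportional to floral
abundance in the field); multiplying by $B_{wi}$ scales frequencies back to
the population of flowers actually on offer; summing over weeks respects
phenology. The week is the unit of aggregation throughout; sub-weekly
information, if present, is collapsed.

The visit-based strength multiplies $a_{ij}$ by $v_{ij}$, the interaction's
mean number of flowers visited per encounter. $v_{ij}$ is resolved per
interaction in a strict priority order:

1. **observed** — the arithmetic mean over all 4-minute follows of that
   pair, pooled over years without year weighting;
2. **donor** — the observed mean of a configured functionally similar
   pollinator (same plant); "functionally similar" is a judgement call, so
   donors are supplied via a configuration file rather than inferred;
3. **expert** — a configured fixed value;
4. **excluded** — no evidence-based estimate exists; the interaction is
   removed from *both* networks, so all encounter/visit comparisons run on
   an identical link set.

The count of observed estimates based on $\ge 5$ follows is reported as a
reliability diagnostic but deliberately not used as a filter. The 4-minute
truncation of follows (which under-counts visits for slow-working taxa such
as many beetles) is a property of the data-collection protocol, not
something the pipeline models.

# Species descriptors

All species descriptors derive from the dependence matrix
$d_{ij} = a_{ij}/A_i$ (share of species $i$'s total strength involving
partner $j$; $A$ denotes a marginal total).

- **Species strength** $S_i = \sum_j d_{ji}$: summed dependence of the
  partners on the focal species. Exact conservation — one level's strengths
  sum to the size of the other level — is used as a test invariant.
- **Push–pull** $PP_i = \tfrac{1}{k_i}\sum_{j}(d_{ji}-d_{ij})$ over the
  $k_i$ realized partners. The literature contains both a summed and an
  averaged form; the averaged form is the default because it respects the
  documented $[-1,1]$ range, and the summed variant is available via
  `push_pull(..., summed = TRUE)` for sensitivity analysis.
- **d′** is the standardized Kullback–Leibler divergence between partner
  use $p'_{ij} = a_{ij}/A_i$ and partner availability $q_j = A_j/m$:
  $d_i = \sum_j p'_{ij}\ln(p'_{ij}/q_j)$, standardized by
  $d_{\max} = \ln(m/A_i)$. The classical index obtains its extremes by
  shuffling integer counts; abundance-weighted strengths are continuous
  reals, for which integer shuffling is undefined, so the continuous limits
  are used: $d_{\min} = 0$ (use proportional to availability) and the
  analytic $d_{\max}$ above, which is a true upper bound for the divergence
  under the constraint $q_j \ge p'_{ij} A_i/m$. Values are clamped to
  $[0,1]$ purely against floating-point spill. d′ values are therefore only
  compared *between the two measures under the same convention*, which is
  all the comparison analysis needs.

# Network descriptors

- **Weighted NODF.** Rows and columns are sorted by descending marginal
  totals (alphabetical tie-break, fixed so the sort is deterministic). A
  row pair (u above v) scores
  $100\,|\{c: 0 < a_{vc} < a_{uc}\}| / |\{c: a_{vc} > 0\}|$ when
  $A_u > A_v$ strictly, and 0 on ties — which makes the tie-break
  inconsequential; the index is the mean over all row and column pairs. Two
  dialects circulate: this defining formula gates pairs on marginal totals
  (`dialect = "marginal"`, default), while the `vegan`/`bipartite`
  implementations gate on *fill* (number of nonzero cells) with totals only
  as tie-break (`dialect = "fill"`). Both are provided; the test suite
  proves the fill dialect equal to `vegan::nestednodf(weighted = TRUE)` and
  the default equal to an independent pair-enumeration oracle, exhaustively
  over all 3×3 matrices with entries in {0, 1, 2}.
- **H2′** standardizes the two-dimensional Shannon entropy
  $H_2 = -\sum p_{ij}\ln p_{ij}$ ($p_{ij}=a_{ij}/m$) between extremes
  consistent with the observed marginals: $H_{2\max}$ from the independent
  outer-product allocation $A_iA_j/m$ (equivalently the sum of the two
  marginal entropies) and $H_{2\min}$ from a greedy concentration
  allocation (repeatedly place $\min$ of the largest remaining row and
  column totals in one cell). As with d′, these are continuous-marginal
  constructions chosen because the strengths are real-valued; the greedy
  minimum is a heuristic upper bound on concentration and the sandwich
  $H_{2\min} \le H_2 \le H_{2\max}$ is asserted property-style in the
  tests. The greedy loop stops when the remaining mass falls below
  $10^{-12} m$, which also breaks exact-tie cycling.
- **Interaction evenness** $IE = H_2 / \ln(RC)$, the all-potential-links
  denominator of the cited definition; `denominator = "realized"` gives the
  $\ln(\text{links})$ dialect. Both are retained because published values
  do not always state which was used.
- **Generality** of a level is $\sum_i (A_i/m)\, e^{H_i}$ with $H_i$ the
  Shannon entropy of species $i$'s partner distribution — the
  marginal-weighted mean effective partner number. Natural logarithms are
  used throughout; any base cancels in every standardized index and in
  $e^{H}$, so the choice is cosmetic.

All four descriptors, and d′, are invariant to multiplying the whole matrix
by a positive constant. Consequently only the *relative* scale of the
weekly flower-abundance column matters for them (flowers/m² versus total
transect counts is immaterial); absolute scale only affects raw strengths
and their log-regression intercepts, never slopes.

# Comparison analysis

Descriptor-on-descriptor regressions (visit-based response,
encounter-based predictor, species as replicates) use OLS with the study's
variable transformations: log–log for species strength, arcsin√ for plant
d′, untransformed otherwise. A two-sided t test of slope = 1 with $n-2$ df
operationalizes "the descriptor is unaffected by the measure"; a perfect
zero-residual fit is reported with $p_{slope=1}=1$ when the slope is
exactly 1 (exact equality, not evidence). Both $R^2$ and adjusted $R^2$
are always reported: the printed F statistic and coefficient of
determination of the 19-plant display regression are mutually consistent
only for the adjusted value, so that is what downstream checks target.
Ratio-of-change regressions divide the visit-based by the encounter-based
value per plant (log ratio for strength, √ratio for d′, raw otherwise) and
regress on log floral display; plants with a zero encounter-based value are
dropped with a warning rather than silently producing infinities.

The bootstrap comparison subsamples the pool of encounter *events* without
replacement — the natural reading of "subsample", with `replace = TRUE`
available for the resampling alternative — at $\lfloor f N \rfloor$ events
per replicate, keeping week labels and reusing the complete flower-survey
table so each replicate passes through the identical weekly weighting
pipeline as the original network. Visit multipliers are then applied and
all five descriptors computed on both networks; 100 paired replicates per
fraction are compared with two-sided paired t tests, uncorrected for
multiplicity (15 raw tests are the study design). Replicates in which a
trophic level collapses below two species are redrawn and counted. With
fraction 1.0 every replicate equals the original network; the paired
differences then have zero variance and the t statistic is reported as
`NA` rather than raising an error. Given identical inputs and seed the
output is bit-identical.

# The synthetic generator

`scenario_config()` fixes the study conditions the generator emulates:

| parameter | default | rationale |
|---|---|---|
| `n_plants`, `n_pollinators`, `n_weeks` | 19, 122, 14 | the surveyed community: 19 entomophilous plants, 122 pollinator morphotypes, a March–June (≈14-week) season |
| `group_sizes` | 39/27/20/15/9/8/3/1 | bees, Coleoptera, Diptera, Lepidoptera, wasps, ants, Heteroptera, Orthoptera |
| `encounter_total` | 4249 | the field study's encounter count, used as the expected-total anchor |
| `display_meanlog`, `display_sdlog` | 3, 1.7 | log-normal fit to the published 19-plant floral-display column (2–576 flowers) |
| `visits_slope`, `visits_intercept`, `visits_sd` | 0.285, 0.26, 0.66 | the log–log display-to-visits regression on the published table, including its residual scatter |
| `group_visit_effect` | bees +0.4 … beetles −0.4 (log scale) | qualitative field knowledge: honey bees work many flowers per bout, beetles often sit on one |
| `concentration` | 0.3 | Dirichlet concentration of pollinator preferences; < 1 gives the few-strong/many-weak link distribution typical of visitation data |
| `nb_size` | 0.8 | negative-binomial overdispersion of encounter counts |
| `samples_per_interaction`, `zero_sample_fraction` | 5, 0.1 | median follow effort per interaction; share of interactions left unobserved to exercise the imputation hierarchy |

Encounter counts are negative-binomial with mean ∝ abundance × preference ×
pollinator activity; visit samples are shifted negative binomial on
$\{1, 2, \dots\}$ (an encounter implies at least one visit) with mean
$\exp(\alpha + b\ln display + \gamma_{group} + \varepsilon)$. One global
seed governs everything; the community, encounter and visit stages draw
from `seed`, `seed + 1`, `seed + 2` so stages can be regenerated
independently.

**What the generator does and does not emulate.** It reproduces the
sampling design (weekly surveys, abundance-proportional effort, follow
observations), the scale of the data, heavy-tailed link strengths, the
display–visits relation and group-level visit behavior. It does not
reproduce the *degree* of specialization of the real community: with the
default Dirichlet preferences the synthetic network is substantially more
even and more generalized (interaction evenness ≈ 0.6–0.7, plant
generality ≈ 15–30) than the field network (0.32 and 3.53), because real
pollinator preferences are structured by phenological matching and trait
filtering, not exchangeable draws. It also omits between-year structure,
within-day bout timing, and the 4-minute follow truncation. Passing tests
therefore demonstrate that the machinery is correct and that the
qualitative measure effects (e.g. display-correlated strength change)
emerge under the assumed data-generating process — not that the synthetic
community is structurally indistinguishable from the Garraf one.

# Numerical conventions and degenerate inputs

- Zero-strength cells are absent links everywhere; species left without
  links are dropped at construction and marginals recomputed.
- Species order: descending marginal totals, alphabetical tie-break.
  Output vectors follow matrix order; exact ties can legitimately permute
  under scalar rescaling (float non-associativity), which is why tests
  compare per species, by name.
- d′ of a species facing a single opposite-level species ($d_{\max}=0$) is
  defined as 0, with a message; H2′ of a 1×1 network and evenness of a
  single-cell network are errors ("degenerate marginals").
- Strength files are written with 17 significant digits so read/write
  round-trips are exact.
- `estimate_visits` refuses donors that themselves lack an observed
  estimate on the same plant (configuration error, caught eagerly).

# Problem sizes in the shipped tests

The test suite runs the full pipeline at the study's nominal size (19 ×
122, ~4 × 10³ events) where the check concerns that scale (slope recovery,
reproducibility), and at reduced sizes (3–10 plants, 4–25 pollinators,
100 fuzzed scenarios) for property-style invariants, keeping the whole
suite around half a minute. Exhaustive oracle checks cover every 3×3
matrix over {0, 1, 2} with no empty margins (16 064 matrices).

# Known limitations

- The weighted-NODF and evenness dialect choices cannot be adjudicated
  without the deposited field dataset; both dialects are first-class and
  flagged, and checks against published values use the
  `vegan`/`bipartite`-convention flags since that is the toolchain the
  published numbers came from.
- The greedy $H_{2\min}$ is a heuristic: it is not guaranteed to be the
  global entropy minimum over matrices with the given continuous marginals,
  only an effective concentration bound (asserted, never violated in
  testing).
- The linear mixed model for among-plant differences in visits per
  encounter is outside the package's scope: it is a routine off-the-shelf
  fit whose per-observation data the pipeline does not carry.
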