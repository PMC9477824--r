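---
title: "Methods: inferring bacterial dispersal routes into surface litter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring bacterial dispersal routes into surface litter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soildispersal)
```

## The measurement problem

Bacteria reach surface soil and litter along three broad routes: deposition
from the air column above the canopy (**above**), deposition from the
canopy and near-surface vegetation (**near**), and splash or contact
transfer from the soil below (**below**). A field design that separates
these routes uses four nested exclusion treatments, each blocking one more
route than the last:

| treatment  | exposed routes          |
|------------|-------------------------|
| `Closed`   | none                    |
| `Elevated` | above                   |
| `Overhead` | above + near            |
| `Open`     | above + near + below    |

Sterile glass trap slides are deployed per block × treatment and collected
at a series of timepoints; cells on a slide are counted per cm². Because
cells also die on the slides, raw accumulation undercounts immigration,
so a parallel series of *death slides* — slides pre-loaded with a known
cell population and protected from immigration — measures mortality.

## Demographic model

Cell abundance on a trap follows an immigration–death balance

$$\frac{dN}{dt} = I - \delta N,$$

with immigration rate $I$ (cells/cm²/day) and per-capita death rate
$\delta$ (1/day). The closed-form solution from an initial count $N_0$ is

$$N(t) = N_0 e^{-\delta t} + \frac{I}{\delta}\left(1 - e^{-\delta t}\right).$$

Three estimators follow:

* **Death rate** (`fit_death_rate`): ordinary least squares of
  $\ln N$ on $t$ for the death slides; $\delta = -\text{slope}$ and the
  daily mortality fraction is $m = 1 - e^{-\delta}$. The lognormal count
  noise enters the log-linear model as an additive constant absorbed by
  the intercept, so the slope — and its 95% CI — is unbiased.
* **Cumulative inversion** (`invert_cumulative_immigration`): from an
  initially empty trap, $I = \delta N / (1 - e^{-\delta t})$.
* **Interval inversion** (`invert_interval_immigration`): between two
  collections $\Delta t$ apart,
  $I = \delta\,(N_2 - N_1 e^{-\delta \Delta t}) / (1 - e^{-\delta \Delta t})$.

Both inversions use `-expm1(-delta * t)` for the denominator, which keeps
them accurate for $\delta t$ down to zero, and take the analytic limits
$I = N/t$ and $I = (N_2 - N_1)/\Delta t$ at $\delta = 0$ rather than
dividing near-zero quantities.

## Route decomposition

Within a block, consecutive treatment differences isolate one route each:

$$
\text{above} = I_{\text{Elevated}} - I_{\text{Closed}},\qquad
\text{near} = I_{\text{Overhead}} - I_{\text{Elevated}},\qquad
\text{below} = I_{\text{Open}} - I_{\text{Overhead}}.
$$

`decompose_routes` computes these per block and tests each route's mean
against zero with a one-sample t-test. The three differences telescope
exactly to $I_{\text{Open}} - I_{\text{Closed}}$ per block — a machine
precision identity the test suite asserts. The same nested-subtraction
logic applies to litter decomposition (`route_mass_loss`), where the
`Elevated` treatment sits on a table rather than the ground and is
therefore excluded from ground-level contrasts; there the contrasts are
`above_near` (Overhead − Closed) and `below` (Open − Overhead).

## Community statistics

All multivariate statistics operate on Bray–Curtis dissimilarities of
rarefied count tables. Implementation notes:

* **Rarefaction** (`rarefy`, `rarefied_bray_curtis`) draws without
  replacement (multivariate hypergeometric), and the distance version
  averages distances across resamplings rather than resampling once.
* **PERMANOVA** (`permanova`) uses the direct sum-of-squared-distances
  partition; $p = (1 + \#\{F_\pi \ge F\}) / (1 + n_\pi)$. With
  `n_perm = "exact"` all $n!$ relabelings are enumerated ($n \le 9$),
  giving exact p-values on small designs. `strata` restricts permutations
  to within blocks.
* **PERMDISP** (`permdisp`) embeds the distances by principal coordinates
  (imaginary axes subtract from squared distances, clamped at zero) and
  compares distances to group centroids. The null distribution relabels
  the *samples* and recomputes the centroid distances per permutation.
  The more common shortcut — permuting the precomputed dispersion
  values — is anticonservative for small groups (simulated type-I error
  ≈ 0.11 for three groups of four, in this and in reference
  implementations); the recomputing scheme is exact under
  exchangeability (simulated type-I ≈ 0.047).
* **NMDS** (`nmds`) is a SMACOF majorization with monotone (isotonic)
  disparities; the stress trace is non-increasing by construction and
  multiple restarts guard against local minima.
* **Mantel** (`mantel`) aligns the two matrices by sample id before
  correlating.

## Source attribution

`estimate_mixture` models a sink community's counts as a multinomial
draw from a convex mixture of known source profiles plus an unknown
component, fitted by EM. Two deliberate choices:

* Source profiles are smoothed with a pseudocount (default `1/n_taxa`)
  *on the count scale before normalization*, so sink taxa absent from a
  source keep a small probability without distorting the profile shape.
* The unknown component's profile is **fixed** at uniform-over-observed
  taxa by default. Re-estimating it freely each M-step makes the model
  unidentifiable — the likelihood optimum is always "100% unknown with
  the sink's own empirical profile". `unknown_profile = "em"` retains the
  free variant for comparison.

`attribute_samples` pools replicate source samples by label and applies
the estimator to every sink column.

## Synthetic experiment generator

`generate_experiment` simulates the full field campaign: per-route
immigration intensities with a rain schedule (the splash route is only
active during rainy intervals), lognormal count noise, death slides,
multinomial community profiles for slides, litter and environmental
sources, litter mass loss with a first-interval decomposition boost for
litter-exposed treatments, and a JSON-serialized ground truth. Default
calibrations are chosen so that standard analyses of the default
experiment land near recognizable values: Open-treatment immigration
≈ 7900 cells/cm²/day (≈ 0.47% of the resident litter community per day),
daily mortality ≈ 3.34%, total mass loss ≈ 30%, with exposed treatments
decomposing ≈ 2.5× faster in the first interval. These are generator
settings, not fitted quantities; all estimators are validated against
closed forms, independent oracles, and unbiasedness simulations rather
than against the calibration itself.

Problem sizes in the acceptance suite (replicate counts, permutation
counts) are the package's own choices, sized so Monte-Carlo error is
small relative to each acceptance band: permutation-test null
simulations use 119 permutations, for which rejection at
$p \le 0.05$ has exact size $6/120 = 0.05$.

## Reproducibility

Every stochastic routine takes an explicit seed and runs under a
save/restore of the RNG state (`with_seed`), so seeded calls never
perturb the caller's random stream. `run_pipeline` derives per-stage
child seeds from a master seed; re-running with the same seed reproduces
byte-identical output files.

## Limitations

* The generator's noise model (independent lognormal counts, multinomial
  reads) is simpler than field data: no spatial autocorrelation within
  blocks, no taxon-specific death rates, no compositional sequencing
  artifacts.
* The immigration model assumes constant $I$ within an interval;
  real deposition is episodic.
* The fixed-uniform unknown component in the mixture model absorbs
  out-of-panel taxa well but cannot represent a *structured* unknown
  source; attribution against an incomplete panel biases toward whichever
  panel source overlaps the missing one.
* PERMANOVA assumes exchangeability under the null; with strong
  dispersion differences its p-value conflates location and spread (which
  is why `permdisp` is always reported alongside).
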