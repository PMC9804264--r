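---
title: "Models and methods: turf community dynamics under climate change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: turf community dynamics under climate change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(turflag)
```

This vignette is the package's account of its science: the data model,
the three vital-rate models and their assumptions, the simulator, the
synthetic-data generator, and the numerical and design choices made
where the design was genuinely open.

## 1. Data model: turfs, quadrants, demographic units

The observational unit is a square turf (default 1 m²) subdivided into
square quadrants (default 5 × 5 cm). Only the *inner* quadrants — those
beyond a buffer ring (default 10 cm) from the edge — are modelled
demographically; with the defaults that is the classic 16 × 16 = 256
inner quadrants. Vegetation in the buffer is allowed to exist, crowds
the inner quadrants, but is never itself updated: it mirrors the
root-barrier design of a transplanted turf, in which the edge is not
surveyed. Quadrant indices are 0-based `(row, col)` from the south-west
corner in all file formats.

All shoots of one taxon rooted in one quadrant form one *demographic
unit* with a single cover area `u ∈ (0, 25]` cm²; a taxon therefore
occupies a quadrant at most once, while different taxa overlap freely
(canopy covers are measured per species, so a quadrant's summed cover
may exceed its ground area; we impose no packing cap by default).

Cover can be recorded continuously or on a 7-class ordinal scale
(absence plus presence classes with upper bounds 2, 6, 14, 30, 60 and
100 % of the quadrant, decoded to midpoints 0.25, 1, 2.5, 5.5, 11.25
and 20 cm²). The published class table for the source field protocol is
not universal across field protocols, so this scale is the package's
own, chosen to be roughly
geometric in class width as visual cover scales usually are; every I/O
path accepts raw continuous cover to bypass it entirely.

## 2. Neighbourhood crowding

Crowding on a focal (taxon, quadrant) pair is a kernel-weighted sum of
neighbour cover with a Gaussian kernel of the distance between quadrant
centres, split into a conspecific part `w_i` (other quadrants only —
there is only one conspecific unit per quadrant) and a heterospecific
part `w_j` (which includes the focal quadrant at distance 0, weight 1).
This asymmetry follows the field data model and tends to make
heterospecific crowding stronger than conspecific crowding.

Field observations of alpine forbs suggest most crowding is exerted
within roughly a 10-cm radius, but no canonical kernel width exists. We
set σ = 5 cm — so ~95 % of kernel mass lies within 10 cm — and truncate
at 15 cm; both are configurable (`kernel_spec()`). Units are treated as concentrated
at their quadrant centre (sub-quadrant positions do not exist in the
data), and neighbours outside the turf simply do not exist: no torus,
no mirroring. The implementation precomputes a kernel "stamp" and
convolves per-taxon cover matrices; an all-pairs brute-force loop is
kept in the test suite as an independent oracle and agrees to 1e-9.

## 3. Vital-rate models

Three models drive each taxon, all functions of the previous summer's
mean temperature `T` (°C), and where noted soil moisture `M`, unit size
`u` and the crowding pair:

**Survival** (Bernoulli):
`logit(s) = λ_S(T,M) + b_S u − α_iiS(T) w_i − α_ijS(T) w_j` with
`λ_S = lam_max / (1 + exp(k_sig (T − (T_infl0 + m_moist M))))` and
`α(T) = a0 + a1 T`. This is the simplest parameterisation of a
temperature sigmoid whose inflection shifts with soil moisture — the
qualitative shape alpine survival data support — and every parameter is
explicit so an alternative shape can be swapped in. With `k_sig > 0` and `lam_max > 0`
the intrinsic rate declines with warming (a cold-adapted taxon); a
negative `lam_max` yields a warm-adapted shape. The linear-in-`T`
interaction coefficients may take either sign at a given temperature —
facilitation is allowed, as the qualitative description requires.

**Growth** (Gaussian):
`E(u′) = λ_G(T) + b_G u − exp(c_ii + d_ii T) w_i − exp(c_ij + d_ij T) w_j`
with `λ_G = g_max exp(−(T − T_opt)²/(2σ_T²))`. Exponential coefficients
keep neighbour effects on growth strictly competitive at every finite
temperature, by construction. We model the next size on the raw cm²
scale with additive Gaussian noise (SD `σ_eps`) truncated to
`[u_min, 25]`, `u_min = 0.1` cm² — the simplest noise structure
consistent with annual cover changes. A realised size at `u_min` does *not*
imply death — mortality is governed solely by the survival model.

**Recruitment** (Bernoulli per taxon × previously unoccupied quadrant):
`logit(r) = exp(r_ii0 + r_ii1 T) w_i − exp(r_ij0 + r_ij1 T) w_j + θ_R`.
Conspecific neighbours are propagule sources (positive), heterospecifics
compete, and the background rate is the fixed constant `θ_R = −5`
(probability ≈ 0.0067 in an empty neighbourhood), overridable but never
fitted. Recruitment into a quadrant the taxon already occupies is a
contract violation, which also makes intraspecific limitation emerge
naturally. Recruits start at `u_init = 0.25` cm², the smallest
presence-class midpoint.

## 4. Tracking demographic units between years

Linking demographic units across annual surveys must tolerate small
location changes from re-sprouting and observation error, and no
standard algorithm exists for cover-grid data. Ours is a deterministic
greedy two-pass assignment per taxon: pass 1 links units
that stayed in their quadrant; pass 2 links remaining pairs in order of
centre distance (within `max_displacement` quadrant widths, default 1),
breaking ties by smallest size change, then row-major order. Unlinked
old units are deaths; unlinked new units are recruits. Many-to-one
links are forbidden. The scheme is validated only against the synthetic
generator's ground truth: recovery is exact on noiseless series at
radius 0 (recruits can only appear in previously empty quadrants, so
the radius-0 problem has no ambiguity) and ≈ 98 % correct for units
with fewer than one conspecific neighbour per 3 × 3 neighbourhood when
one-quadrant displacement noise is on. In dense clumps, a death next to
a recruit is occasionally mislinked as a move — an identifiability
limit of the data, not of the matcher.

## 5. Inference

Baseline inference is MAP: the exact Bernoulli or Gaussian likelihood
plus Gaussian priors (SD 2 on intercept-like parameters, SD 1 on slopes
and log-scale positive parameters), optimised by seeded 3-start BFGS
(relative tolerance 1e-8), with standard errors from the inverse
Hessian (`numDeriv`). Full MCMC (the gold standard for these
hierarchical demographic models) is deliberately not the default:
desk-scale testing needs second-scale fits, and for these regular
likelihoods at n ≥ 1000 the curvature approximation is accurate (parameter-recovery coverage of
±3 SE intervals is ≥ 95 % in the acceptance suite).

Numerical choices that matter:

* **Centred internal coordinates.** Temperature enters far from 0 °C,
  so a coefficient's intercept and temperature slope are nearly
  collinear; likewise the survival inflection and the moisture slope.
  Internally every interaction coefficient is parameterised as (value
  at mean observed `T`, slope), and the inflection as its value at mean
  moisture; `k_sig`, `σ_T`, `σ_eps` are optimised on the log scale.
  Standard errors live on these coordinates, and
  `internalise_params()` maps natural-scale truth into them for
  recovery checks. Natural-scale estimates are recovered exactly by
  the inverse affine map.
* **Data-driven parameter scaling** (`optim`'s `parscale`) from mean
  crowding, mean size and the temperature SD, without which BFGS stalls
  on the ill-conditioned ridge.
* Separation (single outcome class, or all fitted logits beyond ±10)
  and temperature ridges (a single observed temperature, ill-conditioned
  Hessians) are flagged in diagnostics, with estimates still returned —
  the priors bound them.
* The hierarchical (partial-pooling) structure hinted at for the growth
  model is simplified to complete pooling per taxon; a known deviation,
  acceptable because the synthetic world has no turf-level heterogeneity.

**Validation** simulates each turf forward from its first map and
compares predicted (median of 20 replicates) versus observed
log-transformed final/initial cover ratios; a taxon is included when its
SSR is ≤ 80 % of the null (no-change) SSR. Zero covers are handled with
a pseudo-count of 0.25 cm² (one minimal class midpoint); the source does
not state its handling. Taxa qualify for fitting with ≥ 1000 records.

## 6. Climate drivers

Scenario generators produce yearly mean-summer-temperature series:
constant (burn-in; the default home value 12.3 °C is the home meadow's
observed summer mean), gradual with three qualitative shapes mirroring
the RCP families (plateau-after-2040 ≈ RCP 2.6, linear ≈ RCP 4.5,
accelerating ≈ RCP 8.5; default endpoint warmings 0.5/2.3/4.8 K), and
stepwise (i.i.d. draws with the mean and variance of an end-of-century
window of a source scenario — the abrupt manipulation of a transplant
experiment). Site-versus-station calibration is OLS per variable, the
simplest model consistent with its description. Moisture is a constant
per scenario (default 0.5) because the projections force temperature;
moisture paths are accepted via CSV. Synthetic "transplant sites"
default to offsets of 0, 2.2, 3.3 and 5.5 K, the printed warming
equivalents of the field elevations.

## 7. The individual-based simulator

`step_year()` advances one year *synchronously*: all survival, growth
and recruitment probabilities are computed from the start-of-year map
before any fate is realised (the source does not state an ordering;
synchronous updating avoids order artefacts). Extinction is absorbing:
a taxon with zero cover anywhere on the turf cannot recruit, because the
simulations include no immigration — the fixed background recruitment
rate is read as local propagule pressure of an extant population, not
as seed rain from outside. Note the interaction with the buffer: buffer
vegetation is static, so a taxon with buffer presence is never extinct
and may legally re-enter the inner region; invariant checks therefore
use buffer-free turfs.

`equilibrate()` iterates under constant climate until the total inner
cover is quasi-stable: growth rate `|C′/C − 1| < 0.05` *or* absolute
change below 0.5 % of turf area, between two subsequent years ("growth
rate" is the plain ratio, not a log-ratio). Each turf equilibrates separately. `run_scenario()`
projects seeded replicate ensembles (default 20) and reports per-year
medians and 5 %/95 % quantiles of each taxon's cover and of Shannon
diversity. `run_no_lag()` is the lag-free counterfactual: each year the
community is re-equilibrated to that year's climate (same criterion)
before the year's state is recorded. `run_stepwise()` shares seeds
between gradual and stepwise comparisons.

## 8. The synthetic world

`synthetic_design()` states the world the generator emulates: 8 taxa,
3 turfs at each of 4 sites offset 0/2.2/3.3/5.5 K from a 12.3 °C home
climate, 4 survey years, the 256-inner-quadrant grid, constant moisture
0.5, 22 % initial per-taxon quadrant occupancy, and a 20 % per-unit-year
probability of one-quadrant location displacement (re-sprouting /
observation error, applied inside the transition so apparent movement
is at most one quadrant). A `field_scale` switch restores the
field-campaign scale (10 turfs, 5 sites). Parameters are drawn once per
seed from documented ranges built around equilibrium reasoning (growth
persistence `b_G` 0.6–0.8, survival sigmoid inflections 1.5–3.5 K above
home so most taxa decline under +5.5 K, recruitment roughly balancing
mortality near home climate); the first taxon always has a warm growth
optimum (+2 to +4 K) and the second a cold, steep survival decline.
Initial maps are equilibrated at the home climate before
"transplanting" — the field source community is an intact meadow near
its home equilibrium — using a slightly stricter halting criterion
(growth rate 0.02) so the home-site series stays quasi-stable (< 10 %
total-cover change over the 4 years on the default seed, while the
+5.5 K site loses ~80 %).

What a green test does and does not establish: the generator produces
data from *exactly* the models the inference module fits, so parameter
recovery is well-posed by construction. Green recovery demonstrates the
estimator and simulator are correct and calibrated — it says nothing
about model adequacy for real vegetation, where growth forms creep,
surveys miss shoots, moisture varies and the true demographic surfaces
are not these parametric shapes.

## 9. The ecological-lag demonstration fixture

`make_lag_fixture()` constructs the minimal community in which lags
change a long-term outcome: a deterministic static `resident` sward
(certain survival, growth pinned at the 25-cm² cap, no recruitment,
filling all inner quadrants) plus a `warm_forb` with a +4 K growth
optimum and strongly size-dependent survival (`lam_max = −6.5`,
`b_S = 0.55`): large adults are near-immortal, small ones die. Under
the cool starting climate its adults shrink ~3 % per year, so with
annual steps it persists for over a decade — long enough for 4 K of
linear warming over 30 years to reverse the shrinkage — whereas the
lag-free run's year-1 equilibration walks the whole shrink-and-die
cascade to completion at the starting climate and extinguishes it
immediately. Both taxa have background recruitment overridden off
(`θ_R = −30`) and near-zero growth noise, and the bundled equilibrium
criterion is deliberately strict (1e-5 on both thresholds), so the
year-1 equilibration cannot halt while even one shrinking unit remains
(a single unit's yearly change ≈ 0.2 cm² exceeds the 0.1-cm² absolute
threshold) yet halts exactly at extinction, when the deterministic
resident leaves the community bit-for-bit static.

## 10. Summaries

Shannon diversity uses natural logarithms (maximum `ln S`),
configurable base. Ordination is classical metric MDS on Euclidean
distances (`cmdscale`), which for Euclidean input equals PCA of the
centred community matrix up to axis sign; signs are fixed by orienting
each axis so its largest-magnitude taxon loading is positive. Taxon
vectors are correlations of taxon cover with the first two axis scores,
and the ">90 % of cover variation" flag is the R² of the taxon's cover
regressed on those two scores — a documented convention (biplot-arrow
constructions vary across the ordination literature).
`compare_trajectories()` tabulates median first-extinction years (on
per-replicate absorbing-zero covers), each scenario's diversity minimum
and final value, and per-year median-cover differences between
scenarios.

## 11. Known limitations

* The survival sigmoid, growth noise structure, kernel width and
  tracking algorithm are documented stand-ins for unpublished details;
  all are parameterised and swappable.
* Complete pooling per taxon (no turf-level random effects); no MCMC in
  the default path.
* No immigration, dispersal between turfs, grazing, drought extremes,
  or novel low-elevation competitors — all outside the modelled world.
* Validation operates per climate series (per site); multi-site
  validation is run site by site.
* The quasi-equilibrium halting criterion is an *or* of a loose
  relative and a loose absolute test; a slowly declining population can
  satisfy it, which is faithful to its definition but means "halted"
  does not imply stationary. The lag/no-lag equivalence check
  therefore settles the community well past the halting point before
  comparing.
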