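---
title: "Methods: second-order circular analysis of taxis plate assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: second-order circular analysis of taxis plate assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magtaxis)
```

# The analysis problem

Two behavioral assays ask whether worms orient to a magnetic stimulus.
In the **horizontal-field assay**, a drop of worms is released at the
center of an agar plate inside a coil system; each worm is paralyzed
where it reaches the rim, and its heading is recorded as a compass angle
(degrees on [0, 360), 0° = magnetic North, increasing clockwise). In the
**two-target assay**, worms choose between a test circle and a sham
circle, and each plate is summarized by the preference index
$PI = (T - C)/(T + C)$.

The central statistical commitment is that **plates, not worms, are the
independent units**: worms on a plate interact (aggregation, trail
following), so pooling individual headings would overstate the sample
size. Every inferential quantity in this package is therefore computed
at the plate level.

# The second-order circular model

For plate $j$ with worm headings $\theta_{1j},\dots,\theta_{m_j j}$, the
mean vector is obtained by vector summation of unit vectors,
$(\bar S_j, \bar C_j) = \frac{1}{m_j}\sum_i (\sin\theta_{ij},
\cos\theta_{ij})$, giving the plate mean direction
$\hat\mu_j = \operatorname{atan2}(\bar S_j, \bar C_j)$ and mean
resultant length $r_j = \|(\bar S_j,\bar C_j)\|$ (`mean_vector()`). The
*second-order* sample consists of the plate mean directions, one **unit**
vector per plate; its own mean vector gives the population-level $\mu$
and $r$ ("directedness", 0 = uniform, 1 = perfect alignment).

Using unit vectors for the second-order stage — rather than the plates'
full resultant vectors — is a deliberate choice: the Rayleigh test below
assumes unit observations, and it keeps a well-sampled but weakly
oriented plate from dominating the population direction. The plate-level
$r_j$ values still matter descriptively, and plate-to-plate directedness
enters inference through the bootstrap instead.

## Rayleigh uniformity test

Uniformity of the $n$ plate mean directions is tested with the Rayleigh
statistic $Z = n r^2$ (`rayleigh_z()`) and the classical series
approximation to its p-value (`rayleigh_p()`):

$$p = e^{-Z}\left[1 + \frac{2Z - Z^2}{4n}
  - \frac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\right],$$

clipped into $[0,1]$. Among the several published approximations this
series was adopted because it reproduces the printed per-condition
p-values of the replication experiment this package models (the test
suite asserts 0.094, 0.108 and 0.234 at the published $(Z, n)$ pairs),
and because a Monte-Carlo calibration property in the suite verifies a
5% ± 1% empirical rejection rate at $\alpha = 0.05$ for
$n \in \{10, 26, 100\}$. Note one rounding subtlety: computing $p$ from
a mean resultant length already rounded to three decimals can move the
third decimal of $p$; the package always carries full precision
internally.

The test is for a *unimodal* departure from uniformity. Axial
(bimodal) preferences would require angle doubling, which is out of
scope here.

## Bootstrap comparison of directedness

Whether one condition is more directed than another is assessed with a
percentile bootstrap on the second-order sample (`bootstrap_r_ci()`):
the $n$ plate mean directions are resampled with replacement, $r$ is
recomputed, and after `n_reps` repetitions (default 100,000) the sorted
values at 1-based ranks $\lceil n_{\mathrm{reps}}(1-c)/2\rceil$ and
$\lfloor n_{\mathrm{reps}}(1+c)/2\rfloor$ give the level-$c$ limits —
ranks 2,500 and 97,500 at the defaults. A reference $r$ below the lower
limit means the bootstrapped condition is significantly more directed
(one-sided, p < 0.05 at the 95% level); `ci_contains()` reports both the
plain containment verdict and this one-sided reading, since the
published comparison can be interpreted either way. "Orientation angles"
are taken literally: angles are resampled, each contributing a unit
vector, rather than resampling plate resultants with their lengths.

Two caveats the test suite makes explicit: the interval is a resampling
interval around the *observed* sample, so it contains the observed $r$
itself nearly always (measurably more often than the nominal 95%); and
with fewer than about five plates the bootstrap distribution has few
atoms, which is why the suite checks small-$n$ endpoints directly
against exhaustive enumeration of all $n^n$ resamples (tolerance ±0.02
at $10^5$ resamples).

## Kernel density estimates

Raw headings are visualized with a von Mises kernel density
(`vonmises_kde()`):
$\hat f(\theta) = \frac{1}{m}\sum_i e^{\kappa\cos(\theta-\theta_i)} /
(2\pi I_0(\kappa))$. The `bandwidth` argument is the kernel
concentration $\kappa$ (dimensionless; larger = narrower kernel),
matching the convention of the `density.circular`-style estimators used
in this field; the default 40 is the value conventionally used for
worm-heading rose plots. Exponentially scaled Bessel evaluation keeps
$\kappa$ up to several hundred overflow-free, and the trapezoidal
integral over the circle is checked to equal 1 within $10^{-6}$.

# Two-target assay

Per-plate preference indices are compared across conditions with a
two-sided Mann–Whitney U test (`mann_whitney_u()`), with no
multiple-testing adjustment (two planned comparisons: magnet vs control
and diacetyl vs control, the latter a positive control). The p-value is
exact by full enumeration of all $\binom{n_1+n_2}{n_1}$ rank allocations
when $\min(n_1,n_2) \le 8$ and there are no ties — exactness is cheap
there — and otherwise uses the normal approximation with tie-corrected
variance and continuity correction, which is reproducible and matches
the standard reference implementation to $10^{-6}$ (asserted in the
suite). Plates where no worm reached either circle have an undefined
$PI$ and are dropped with a warning.

# Plate-inclusion filters

`filter_plates()` admits a plate only under environmental conditions
favorable to orientation behavior. Boundary semantics follow a literal
reading of the protocol wording:

| rule | threshold | boundary |
|---|---|---|
| worms scored | ≥ 30 | inclusive (29 fails) |
| relative humidity | < 50% | strict (50.0% fails) |
| temperature | ≤ 25 °C | inclusive, on max(start, end) |
| temperature drift | < 2 °C | strict, absolute difference (2.0 fails) |
| duration | 55–65 min | inclusive at both ends |

The worms-scored count is always derived from the headings table rather
than a separate column, so the two can never disagree. The temperature
rule is applied to the larger of the start and end readings (the
protocol states a single ceiling without naming the reading); humidity
is evaluated at assay start, the conventional logging point — both
choices are configurable through `filter_config()`. The exclusion log
lists *every* violated rule per excluded plate, and filtering is
idempotent. The post-filter balance check (`balance_check()`) is a
chi-square goodness-of-fit test against equal allocation at
$\alpha = 0.05$; the protocol it models states the verification without
naming a test, so this is reported as advisory, never as a gate.

# What the simulators emulate

`simulate_field_plates()` draws from the minimal hierarchical model
honoring the two explicit commitments above — plate non-independence and
a fixed preferred bearing:

$$\mu_j \sim \mathrm{vM}(\mu_{\mathrm{pop}}, \kappa_b), \qquad
  \theta_{ij} \mid \mu_j \sim \mathrm{vM}(\mu_j, \kappa_w),$$

with exact uniform draws replacing the von Mises (sampled by the
Best–Fisher rejection scheme) when a concentration is exactly 0. Key
defaults, chosen once as realistic for this assay: `worms_per_plate`
(truncated Poisson mean) 100, matching a 10 µl aliquot of 50–100 worms
plus typical scoring counts; `mu_population_deg` 305°, the bearing
reported for starved worms relative to the field lines;
`kappa_within` 1, a weak within-plate alignment that leaves plate mean
directions estimable (~10° SE at 80–100 worms) without making single
worms informative; `kappa_between` 0, the null. Metadata for
filter-passing plates is sampled uniformly well inside the pass region
(humidity 30–49%, start temperature 21.5–23 °C, drift within ±1.4 °C,
duration 56–64 min); a designated fraction of plates instead violates
exactly one randomly chosen rule, so filter bookkeeping is exercised
end to end.

`simulate_magnet_plates()` splits a truncated-Poisson plate count
(default mean 60 worms reaching the circles) between the circles by a
beta-binomial with target fraction `p_target` (0.5 = null) and
intra-plate correlation `overdispersion_rho` — plate-level environmental
idiosyncrasies make worm choices within a plate positively correlated,
so plate PIs are overdispersed relative to a binomial split.

`simulate_biased_walk()` is an optional mechanistic generator: a
correlated random walk from the plate center (wrapped-normal turns,
default SD 30°/step, vector-blended toward a target bearing with weight
`bias_weight`), recording the compass angle at first rim crossing
(default radius 45 step lengths ≈ a 9 cm scoring rim in ~1 mm steps).
Worms still inside after `max_steps` (default 10,000) are dropped with a
warning.

What the generators do **not** emulate: realistic worm locomotion
(speeds, reversals, pirouettes), worm–worm coupling mechanisms (the
clustering is carried entirely by the plate-level random direction),
paralytic kinetics, drifting environmental covariates, or any
dependence of behavior on the field itself. Passing tests therefore
show that the *statistical machinery* is correct and calibrated under
the assumed hierarchy — not that the hierarchy captures every feature
of real plates.

# Numerical and degenerate-case choices

* $r = 0$ (perfect cancellation, within $10^{-12}$): the mean direction
  is reported as *undefined* (`NA` plus a flag), never as 0°; such
  plates are excluded from a second-order sample with a warning.
* All angles are normalized into [0, 360) at construction; internal
  trigonometry uses East/North components so the compass convention is
  handled in exactly one place, and every statistic is rotationally
  equivariant (asserted as a property test).
* Every stochastic operation takes an integer seed and restores the
  caller's PRNG state; identical inputs and seed give byte-identical
  JSON reports (`render_report()` serializes at 17 significant digits,
  which round-trips doubles exactly).
* The pipeline derives one bootstrap seed per condition from the
  top-level seed, so condition results do not depend on the order in
  which conditions are processed.

# Problem sizes in the test suite

Stochastic properties are verified at sizes chosen to keep Monte-Carlo
error well below the asserted margins: type-I calibration at 1,000
pipeline replicates of 26 plates × 100 worms; detection power at 500
replicates of 24 plates × 80 worms with $\kappa_b = 2$; null p-value
uniformity by Kolmogorov–Smirnov over 600 (field) and 500 (magnet)
replicates; joint non-significance of three null conditions at 600
replicates against a two-sided band around its theoretical value
$0.95^3 \approx 0.857$; and walk-uniformity at 100 replicates of 1,000
worms. Exhaustive-enumeration oracles cover the bootstrap (all $n^n$
resamples for $n \le 4$) and the exact Mann–Whitney branch (all rank
allocations).

# Known limitations

* The Rayleigh series p-value is an approximation; for $n < 10$ its
  tail accuracy degrades (the suite calibrates it only down to
  $n = 10$).
* One recovery property worth stating precisely: with
  $\kappa_b = 2$ and ~24 plates the asymptotic SE of the second-order
  mean direction is $1/\sqrt{n\,\kappa_b A(\kappa_b)} \approx 10°$, so
  a single experiment of that size localizes the preferred bearing only
  to roughly ±20° at 95% confidence — detection of *some* orientation
  is essentially certain at those settings, but tight recovery of the
  bearing is not.
* The bootstrap comparison is between one condition's interval and
  another's point estimate; it does not propagate the reference group's
  own sampling error.
* Only unimodal alternatives are tested; axial preferences, confidence
  cones for $\mu$, and second-order tests that use plate resultant
  lengths (Hotelling/Moore-type) are out of scope.
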