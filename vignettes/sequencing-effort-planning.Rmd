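---
title: "Planning metagenome sequencing effort with seqeffort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning metagenome sequencing effort with seqeffort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqeffort)
library(dplyr)
```

## The model

How many reads does a shotgun metagenome experiment need? `seqeffort`
answers this from a deliberately minimal model. A community metagenome is a
finite population of *unique k-mers*: a genome of length $l$ bp read at
length $k$ bp exposes $K = l - k + 1$ read windows, and every window of
every genome — including identical sequences at different loci — is a
distinct member of the population $K_{MG}$. A sequencing read is one draw
from this population, with replacement, landing on k-mer $j$ with
probability $p_j$ proportional to the abundance of its host genome. No
sequence content is ever materialised: a community is fully described by
*groups* of equiprobable k-mers, each group a `size` (k-mers) and a `mass`
(total sampling probability), which is what `community_structure()` stores.

Sequencing the whole population at least once is then the classical coupon
collector problem with unequal probabilities, whose expected waiting time is

$$E = \int_0^\infty \Big(1 - \prod_{j \in K_{MG}} (1 - e^{-p_j t})\Big)\,dt.$$

Because all k-mers in a group share one probability $w_g$, the product
collapses to $\prod_g (1 - e^{-w_g t})^{m_g}$; `expected_reads_to_exhaustion()`
integrates this grouped form, so the cost is independent of $|K_{MG}|$. For
a *fraction* $q < 1$ of the population, the occupancy expectation
$\sum_g m_g (1 - e^{-w_g t})$ is inverted by monotone root finding
(`expected_reads_to_fraction()`); full exhaustion always goes through the
integral, because the occupancy curve only reaches $|K_{MG}|$ in the limit.

```{r}
expected_reads_to_exhaustion(community_even(1e6))
```

For an even population this must equal $n H_n$; the test suite holds the
integral to that closed form at relative $10^{-6}$.

### Community structures

Four standard structures span the evenness range seen in real communities:
even; 90% of sampling mass on 50% of the k-mers; 90% on 10%; and a
Preston-style lognormal, $S(R) = S_0 e^{-a^2 R^2}$ over ten equal octave
groups. The `exponent` argument of `community_lognormal()` also provides
the $e^{-a R^2}$ reading, because the parameterisation of this family is
not used consistently across the literature and neither reading reproduces
every published evenness figure from the printed $a$ ranges; the package
defaults to the literal $a^2$ form and asserts only order properties
(skewer communities are less even and need more effort), not any specific
published $(a, J)$ pair. Evenness itself is Pielou's
$J = H_{MG}/\ln|K_{MG}|$ at k-mer level, with a group-level variant
(`level = "group"`) for when octave groups are the ecological unit.

```{r}
suite <- gen_community_suite(1e5)
sapply(suite, pielou_evenness)
```

A headline property of the model: expected effort to exhaustion grows as a
power of metagenome size with exponent just above one (the coupon-collector
tail contributes a $\ln|K_{MG}|$ factor), near 1.06 over sizes
$10^6$–$10^8$ for all four structures:

```{r}
sizes <- seq(1e6, 1e8, length.out = 10)
powerlaw_slope(effort_scaling(community_even, sizes))
```

## The simulators

The theory assumes independent draws; the Monte-Carlo layer checks it and
extends it to questions the integral cannot answer. Two simulators share a
compiled core with a deterministic per-replicate RNG substream, so every
result is bit-reproducible from its seed:

* `simulate_community_sequencing()` draws reads from the weighted k-mer
  population, tracks occupancy in a bitmap, and records the read index at
  which each target fraction is first covered. The default records the
  exact crossing; `record_mode = "checkpoint"` rounds up to a fixed
  evaluation interval (e.g. every $10^7$ reads), the convention of
  pipelines that only evaluate coverage periodically.
* `simulate_genome_effort()` targets one genome making up a fraction $f$ of
  the community. Only on-target reads need simulating: coupon collection
  over the genome's $K$ k-mers gives the hit count $h$, and the off-target
  reads follow a negative binomial with $h$ successes at probability $f$.
  The test suite confirms this shortcut is distributionally identical to a
  literal two-population simulation (Kolmogorov–Smirnov at small $K$) and
  that simulated means sit within three standard errors of the theory.

Problem sizes in the tests are chosen for desk-scale runtimes:
$|K_{MG}| = 10^5$ with 30 replicates for the simulator–theory comparison,
$10^4$ and below for distributional checks. These sizes are far past the
asymptotic regime the model operates in (the power law is already stable at
$10^6$), so nothing scientific hinges on scaling them further.

## The effort surface

Planning needs the inverse question: given a target fraction $q$, genome
size $l$ and relative abundance $f$, how many bases? `run_simulation_grid()`
simulates `simulate_genome_effort()` over a lattice of
$(q, l, f)$ cells (defaults: $q \in [0.5, 1]$ linear, $f \in [0.01, 1]$
log-spaced, $l \in \{0.5, 1, 2, 3, 5, 10, 15, 20\}$ Mbp, 100 bp reads,
triplicate), and `fit_effort_surface()` smooths the replicate means with a
penalized additive P-spline regression of $\log_{10}(\text{bases})$ on
$q$, $\log_{10} l$ and $\log_{10} f$ (basis dimensions 50, 6 and 29,
clipped to the distinct values available; smoothing by GCV). The log
transforms are not cosmetic: occupancy theory gives
$\text{bases} \approx (l - k + 1)\,k \ln\tfrac{1}{1-q}/f$, which is exactly
additive and linear in $\log_{10} l$ and $\log_{10} f$, so the smooth has
almost nothing to correct. Fits on simulated grids reach $R^2 > 0.999$,
predictions match the analytic form to a few percent in the interior, and
monotonicity holds in all three directions.

Abundances below the 1% simulation floor are handled by linear
extrapolation in $(\log_{10} f, \log_{10}\text{bases})$ using the boundary
slope — theory fixes that slope at $-1$ — down to $f = 10^{-4}$, and such
predictions are flagged. `invert_effort()` bisects the surface to turn a
sequencing budget into an *abundance cutoff*: the rarest genome sequenced
to the target fraction within budget.

The package ships a surface pre-trained on a reduced grid
($9 \times 8 \times 6$, triplicate, seed 101 — recorded in the file), which
keeps installation light while spanning the full ranges;
`surface_grid_full()` reproduces the full-resolution
$100 \times 30 \times 8$ study grid when more resolution is wanted.
Serialization stores the training table at full floating-point precision
and refits on load, which is deterministic, so a reloaded surface predicts
identically to the saved one.

```{r, eval = FALSE}
surf <- default_surface()
predict_effort(surf, abundance = 0.001, genome_size = 4.3e6,
               target_fraction = 0.9)
```

## MAG rarefaction and the Gompertz curve

The model layer above describes sequencing; the recovery layer describes
what an assembly-and-binning pipeline returns. MAGs are classified by the
MIMAG-style thresholds (high: completeness > 90% and contamination < 5%;
medium: > 50% and < 10%; strict inequalities, boundaries fall down), and
"quality MAGs" — medium plus high — are counted per environment, depth and
replicate (`classify_mag()`, `count_quality_mags()`, with a CheckM table
importer). Quality-MAG yield against high-quality bases $b$ (Gbp) is
sigmoidal, not a classical collector's curve: there is a lag before enough
read overlap exists to assemble anything. The Zwietering form of the
Gompertz curve keeps the parameters interpretable,

$$g(b) = A \exp\!\Big(-\exp\big(\tfrac{\mu e}{A}(\lambda - b) + 1\big)\Big),$$

with asymptote $A$ (most quality MAGs the pipeline will ever yield),
maximum rate $\mu$ (MAGs per Gbp) and lag $\lambda$ (Gbp).
`fit_gompertz()` estimates them by Levenberg–Marquardt least squares with a
shape-based initialisation ($A_0$ the maximum count, $\mu_0$ the steepest
finite-difference slope, $\lambda_0$ the deepest near-zero depth) and two
fallback starts; standard errors come from the Jacobian. Replicate-level
points are fitted directly (fitting replicate means instead is a
`summarise()` away and gives the same estimates for balanced designs).
Yield, the saturation diagnostic, is the replicate-mean quality count at
the deepest depth divided by $A$; that aggregation choice is isolated in
`gompertz_yield()` so the alternative (a global maximum) is a one-line
change.

```{r}
counts <- gen_gompertz_counts(A = 15, mu = 2, lambda = 3, seed = 1)
fit <- fit_gompertz(counts)
glance(fit)
```

`effort_to_abundance_curve()` finally couples the two layers: sweep a
budget, convert it to an abundance cutoff through the surface (at
$q = 0.5$ by default, with 5 Mbp central and 1/20 Mbp bounding genome
sizes), and read predicted quality MAGs off the Gompertz curve. On this
axis quality MAGs rise steeply as the cutoff drops — the optics of
diminishing returns in raw bases invert when effort is expressed as reach
into the rare biosphere.

## What the synthetic data does and does not show

All test inputs are generated in code. `gen_gompertz_counts()` produces
counts from a known curve with Gaussian noise (SD 0.5 MAGs, the replicate
scatter scale of real rarefaction surveys) rounded to integers;
`gen_mag_table()` expands counts into per-MAG completeness/contamination
rows, with distractors, such that the classify-and-count pipeline
reproduces them exactly; `synthetic_mag_survey()` assembles a
four-environment survey with parameters representative of published ocean,
sediment, soil and gut data sets. A purely noiseless generator was
rejected: integer rounding alone acts as one-sided noise in the lag region
and biases fitted $\lambda$ upward, which unbiased replicate noise removes.

Passing tests on these fixtures demonstrate that the estimation machinery
recovers known truths under the model's own assumptions. They do not
demonstrate anything about real sequencing data — no read errors, no
read-length distribution, no strain microdiversity, no shared homologous
regions between genomes (each k-mer belongs to one genome; a hook for
treating homologous DNA as a shared-abundance reservoir is a documented
extension point, not implemented), and no assembler behaviour beyond the
fitted sigmoid. The declining yields some pipelines show at very deep
sequencing are likewise outside the model: the Gompertz form is monotone by
construction.

## Numerical choices

* The exhaustion integrand is evaluated in log space
  (`log1p`/`expm1`), split at $t = 1$ with the tail integrated in
  $\log t$; adaptive quadrature at relative tolerance $10^{-10}$, with an
  upper cut where the integrand falls below $10^{-16}$.
* Root solving (fractional targets, budget inversion) uses bracketed
  bisection on monotone functions; fractional-target roots are solved to
  near machine precision, budget inversion to $10^{-3}$ in $\log_{10} f$.
* Simulation RNG is xoshiro256++, seeded per replicate from R's RNG, so
  `set.seed()` semantics carry through the compiled core and replicates
  are independent substreams. Default caps: $|K_{MG}| \le 2 \times 10^8$,
  $10^{10}$ reads per replicate.
* Gompertz fitting bounds $A, \mu > 0$ and $\lambda \ge 0$; an all-zero
  count vector is rejected rather than fitted.
* When a tier or octave assignment does not divide $|K_{MG}|$ evenly, the
  remainder k-mers join the most abundant group, deterministically.

## Limitations

The model prices k-mer discovery, not assembly quality; the link from
target fraction to a usable genome runs through the empirical Gompertz
layer and inherits its pipeline dependence. Surface predictions below 1%
abundance are theory-guided extrapolation and flagged as such. The
coupon-collector expectation has no variance attached — the package
reports replicate spread where it simulates, but the theoretical layer is
expectations only.
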