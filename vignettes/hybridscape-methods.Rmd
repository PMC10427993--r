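---
title: "Methods: models, synthetic worlds, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, synthetic worlds, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hybridscape` quantifies the spatial and phylogenetic overlap between
naturalized alien plants (neophytes) and interspecific hybrids, and asks
what that overlap implies over evolutionary and ecological time. This
vignette documents the statistical machinery, the design decisions taken
where several readings were defensible, the synthetic-data generator that
makes the pipeline testable without external databases, and the
numerical details a user re-implementing or auditing the package would
need.

## Checklist integration

Two checklist dialects are read into one taxon-record schema. The WCVP
dialect identifies interspecific hybrids through its hybrid-sign column
(`"×"` natural, `"+"` artificial, empty none) and carries an optional
`introduced` flag per occurrence row that distinguishes native from alien
presences; the GloNaF dialect carries `name_status` (accepted or not),
`status` (naturalized vs. alien) and a 0/1 `hybrid` flag. The inclusion
rules are:

* **Hybrids**: accepted natural interspecific hybrids; artificial
  (cultivation-origin) hybrids and unaccepted names are removed.
* **Neophytes**: accepted, naturalized, non-hybrid taxa. Records listed
  only as aliens are removed because establishment is a precondition for
  hybridization in the wild; hybrid-flagged neophytes are removed so
  hybrid incidence is never regressed on hybrids; naturalized varieties
  are retained because their naturalizations equally present
  hybridization opportunities.
* **Region codes** must be alphabetic tokens. Purely numeric codes
  cannot be matched to a botanical country and are dropped at read time,
  with the count reported; drop counts plus retained rows always
  reconcile to the input.

Name matching is deterministic: trim, collapse internal whitespace,
case-sensitive exact joins. Live taxonomy harmonization against name
services is out of scope; the deterministic normalization is stated so
results are reproducible from the same inputs.

Two choices here were genuinely open. First, the native denominator for
incidence ratios: we count accepted species-rank, non-hybrid records
flagged native in each region from the WCVP-dialect table. Second,
per-genus accepted species counts exclude hybrids *and* all
infraspecific ranks (varieties, subvarieties, convarieties, forms,
subforms, subspecies); hybrid names therefore never inflate the richness
denominator even though they carry species rank in the source tables.

## Effort covariates

Recording effort differs enormously between botanical countries, and the
bias is stronger for hybrids (which require recognizing the parentage)
than for widespread neophytes. Two covariates proxy effort:

* **Per-capita GDP**, averaged over the available years within each
  political country, then crosswalked to botanical countries: a
  political country containing several botanical countries passes its
  value to each; a botanical country spanning several political
  countries receives their unweighted mean. Missing GDP is flagged, not
  zero-filled.
* **Range-weighted taxonomist counts**: an author who first described
  plant species is credited to every region where at least one of those
  species occurs, with weight `1 / mean(range size)` over their described
  species occurring in that region (range size = number of occupied
  regions). The reciprocal damps the spillage of wide-ranged species
  crediting an author to dozens of regions. The mean is taken over the
  author's described species *present in the focal region*, not over
  their global output — the alternative global reading is defensible but
  couples a region's score to ranges of species that never occur there.
  Every individual contribution lies in (0, 1], and shrinking ranges can
  only raise region scores.

## Congener encounters and the event projection

A naturalization event is one (neophyte, region) pair. An event offers a
hybridization opportunity when a native congener is present in that
region; genus identity is the sole criterion — no phylogenetic-distance
crossability model. Congeners are counted from natives only, not from
earlier-arriving neophytes, which is the conservative reading. The
species-level fraction counts a neophyte as soon as one of its events
meets a congener. The projection multiplies the neophyte count by the
species-level encounter fraction and a literature bracket of per-species
hybridization propensities (9–25%), rounding half-away-from-zero to
whole events.

## Diversification rates

The stem-age method-of-moments estimator
`r = ln(SR(1 - e) + e) / t_stem` uses natural logarithm — the worked
example of a 217-species genus with stem age 0.00371 Myr gives ~840
species/Myr, which only the natural-log form reproduces. log10 enters
later, as the variance-stabilizing transform of the rates before
modelling. The estimator assumes rates constant in time and across
clades; it is used for its minimal data demands, not as a birth–death
likelihood fit. Defaults: `e = 0.9`, with `e = 0.5` as the conventional
sensitivity setting.

Monotypic genera have rate exactly 0 (log10 undefined) and are excluded
from the group-mean model by default, with a toggle for robustness
checks. Extreme-rate outliers are flagged above a configurable
threshold; because no principled universal cutoff exists, the default is
the table's own 99.9th rate percentile, and the flag is carried in the
table but applied only at the modelling stage, so the rate table itself
is always complete.

Groups are assigned purely by count positivity: (1) neither hybrids nor
neophytes, (2) neophytes only, (3) hybrids only, (4) both. The group
model is fit in cell-means form (`d_i ~ Normal(m[g_i], sigma)`), which
is the same model as intercept-plus-group-offsets but mixes better; all
six pairwise posterior differences are reported with 66% and 95%
equal-tailed intervals, and back-transformed (`10^difference`) into rate
ratios.

## Phylogenetic signal

Blomberg's *K* is computed from the Brownian variance–covariance matrix
`V` of the genus-level tree: the phylogenetic (GLS) mean
`a = (1'V⁻¹x) / (1'V⁻¹1)`, the observed mean squared error about `a`
(divisor `n − 1`), the `V`-weighted mean squared error, and the Brownian
expectation `(tr(V) − n / sum(V⁻¹)) / (n − 1)` of their ratio. Traits
are the raw per-genus hybrid and neophyte counts, untransformed; tips
missing from the tally score zero (a genus with no recorded hybrids is a
genuine zero, not missing data), and tally rows absent from the tree are
dropped with a report. Solves go through a Cholesky factorization with a
relative singularity tolerance of `1e-10` on the smallest squared pivot.
An optional permutation test shuffles tip labels (≥999 shuffles
recommended) and reports the fraction of permuted datasets, observed
included, whose *K* reaches the observed value. Ultrametricity is not
required — the synthetic trees deliberately carry stem-age terminal
branches.

## Footprint comparison

Hectads are opaque 10 × 10 km grid keys with rectangle geometry supplied
separately; the package does not parse national-grid letter codes. Zonal
means assign a raster cell to a hectad when its center lies inside the
rectangle, half-open on the max edges (left/bottom inclusive) so shared
boundaries never double-count; at 1 km cells inside 10 km hectads the
difference from area-weighted overlap is at most the boundary cells.
Only hybrids occupying strictly more than 10 hectads enter the
comparison. The HFI model has a varying intercept and varying type
slopes per triplet, partially pooled; population-level type means and
the three pairwise contrasts are reported. Triplets observed for fewer
than two types are dropped with a report; at least two usable triplets
are required, since one triplet cannot identify group-level variance.

## Bayesian machinery

All models are Gaussian with weakly informative, data-scaled priors:
`Normal(0, 2.5 sd(y)/sd(x))` on slopes, `Normal(mean(y), 2.5 sd(y))` on
intercepts, half-Student-t(3, sd(y)) on all scales. Sampling is Gibbs
(JAGS), two chains by default, each chain seeded deterministically from
the user seed so fits are bit-reproducible. Convergence is enforced
post-hoc: split-chain R-hat < 1.01 and effective sample size ≥ 400 for
every monitored parameter; failures are flagged per fit and surfaced as
a diagnostic-failure count in the pipeline report.

Numerical choices that matter:

* Predictors of the non-hierarchical regressions are centered inside the
  sampler (decorrelating intercept and slopes), and the intercept is
  transformed back afterwards.
* The hierarchical HFI model uses hierarchical centering
  (`u_j ~ Normal(beta, tau)` rather than `beta + u_j` with zero-centered
  deviations), which mixes far better at this data scale; only the
  population-level quantities are monitored, as the group-level scales
  are nuisance parameters.
* Counts of zero cannot enter a log10 response or predictor; the
  regression stages therefore restrict to positive counts with a
  reported drop count (the genus regression is anyway restricted to
  genera containing both hybrids and neophytes), and an additive offset
  remains available as an explicit user choice.
* "Statistical clarity" of a coefficient means its equal-tailed 95%
  credible interval excludes zero.
* An analytic conjugate sampler (Jeffreys prior; scaled inverse-chi²
  marginal for the variance, conditional normal for coefficients) is
  exported as an independent closed-form reference for the
  non-hierarchical Gaussian case and is used as the oracle in the test
  suite, never as the production path.

## The synthetic world

The generator exists so that every stage can be validated against known
ground truth. Its defaults are the study conditions the pipeline is
designed to recover: 200 botanical countries, 800 genera, 30 included
triplets (plus 3 planted below the occupancy threshold), a cross-country
elasticity of 0.26, a cross-genus ratio elasticity of 0.64, group rate
multipliers (1, 1.6, 2.5, 2.91) on a base rate of 0.05 species/Myr, and
HFI type means 22.6 (native), 24.6 (neophyte), 28.5 (hybrid) with
between-triplet sd 1.5. At this scale a full simulate-and-fit cycle
takes under a minute on one CPU; the problem sizes were chosen so the
posterior intervals are narrow enough to be informative while the suite
stays quick.

Design decisions worth knowing:

* **Planted truth is exact, not merely in expectation.** Residual noise
  vectors are centered and made orthogonal to the planted predictors,
  per-group rate noise is centered within groups, and triplet effects
  are centered; the finite world then *realizes* its documented
  coefficients exactly, so recovery tests measure estimator behaviour
  rather than realization luck. Count noise is lognormal on the latent
  scale, matching the Gaussian-on-log10 models, so recovery is exact for
  the fitted model rather than approximately so.
* **Integer rounding lands on the response side.** Neophyte region
  memberships are drawn as integers first and the planted relations are
  conditioned on the realized predictor, so discretization never
  attenuates a planted slope; hybrid counts are then sampled to match
  each region's planted tally exactly, preferring not-yet-placed taxa so
  genus-level and country-level tallies stay mutually consistent.
* **Stem ages invert the estimator.** Each genus' terminal branch is set
  so the method-of-moments estimator at `e = 0.9` returns exactly its
  planted rate; monotypic genera occur only in the groups without
  hybrids.
* **Footprint selection.** The raster has a single-axis west-to-east
  disturbance gradient plus noise, keeping the hectad-level HFI
  distribution close to uniform over its range so that kernel-based
  habitat selection (Gaussian kernel, bandwidth 6 HFI units) recovers
  its target mean without edge bias.
* **Planted rule violations.** Known counts of artificial hybrids,
  unaccepted names, alien-status rows, hybrid-flagged neophytes and
  numeric region codes are planted so the filter tests can assert exact
  casualties. Everything is deterministic under the config seed, byte
  for byte.

What the generator does **not** emulate: real richness distributions
beyond a heavy tail, taxonomic synonymy and name drift, spatial
autocorrelation of occurrence beyond the footprint gradient, imperfect
detection, or correlated missingness between the two checklists. Passing
recovery tests therefore demonstrate that the estimators and models are
implemented correctly and identify their targets under the stated
generative assumptions — not that those assumptions hold for any real
flora.

## Scope and limitations

* Taxonomy is joined by normalized exact names; no fuzzy matching or
  synonym resolution.
* Congener opportunity is genus membership; crossability varies greatly
  within genera and is not modelled.
* The diversification analysis inherits the method-of-moments
  assumptions (constant rates, known extinction fraction) and spans far
  more time than neophyte introductions; it describes association, not
  causation.
* Raster handling covers planar ASCII grids and rectangle zones, which
  suffices for the fixture dialect; reprojection must happen upstream.
* The pipeline's interface is R functions (`sim_world()`,
  `write_world()`, `run_pipeline()`) rather than a shell executable;
  orchestration, stage toggles, per-stage error reporting and exit
  behaviour live in `run_pipeline()`.
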