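# hybridscape

Macroecology of the overlap between naturalized alien plants (neophytes)
and interspecific hybrids.

Human activity moves plant species across the geographic barriers that
once isolated them. Once a neophyte establishes alongside a native
congener, hybridization becomes possible, and the consequences — from
genetic swamping of natives to the birth of new lineages — play out over
both ecological and macroevolutionary time scales. `hybridscape` is an R
package for quantifying that overlap from checklist-scale data: it
integrates WCVP-style and GloNaF-style species checklists, builds
taxonomic-effort covariates, measures how often naturalizations meet a
congener, contrasts net diversification rates between genera with and
without hybrids and neophytes, scores phylogenetic signal, and compares
the human-footprint distributions of hybrids against their parent
species. It is aimed at macroecologists and invasion biologists who work
with botanical-country (TDWG Level 3) checklists, genus-level dated
phylogenies, and gridded occurrence data.

Every stage runs end to end on synthetic data with known ground truth, so
the whole pipeline is testable without downloading any external database.

## The models at the core

**Spatial overlap.** Counts of hybrids per botanical country are
regressed on counts of naturalized neophytes with a Bayesian Gaussian
model on the log10 scale,

    h_i ~ Normal(mu_i, sigma),   mu_i = alpha + b_n n_i + b_e e_i + b_t t_i + b_a a_i,

where `n_i`, `e_i`, `t_i`, `a_i` are (log10) neophyte count, per-capita
GDP, range-weighted taxonomist effort, and area of country *i*. The
taxonomist-effort covariate credits an author to a country when at least
one species they described occurs there, weighted by the reciprocal of
the mean range size of those species. A slope `b` on the log10–log10
scale reads as an elasticity: a 20% increase of the predictor changes the
response by `100 * (1.2^b - 1)` percent.

**Phylogenetic overlap.** The same Gaussian model links per-genus hybrid
and neophyte incidence (counts, and ratios to the number of accepted
species per genus — ratios may legitimately exceed 1). Phylogenetic
signal in the per-genus counts is summarized by Blomberg's *K*,

    K = (MSE0 / MSE) / E[MSE0 / MSE],

the ratio of the observed to the Brownian-expected mean-squared-error
ratio under the tree's variance–covariance matrix; `K = 0` means no
signal and `K = 1` matches Brownian motion.

**Diversification.** Per-genus net diversification rates come from the
stem-age method-of-moments estimator,

    r = ln(SR * (1 - e) + e) / stem_age,

with species richness `SR`, relative extinction fraction `e = 0.9`
(sensitivity `e = 0.5`), and rate 0 for monotypic genera. Genera are
grouped by incidence — (1) neither hybrids nor neophytes, (2) neophytes
only, (3) hybrids only, (4) both — and group means of the log10 rates are
compared; posterior differences back-transform to rate ratios.

**Human footprint.** Occurrences on a 10 × 10 km hectad grid are joined
to the mean human footprint index (HFI, 0–50) of each hectad, and HFI is
modelled for each triplet (hybrid, native parent, neophyte parent) with a
hierarchical varying-intercept, varying-slope model,

    f_i ~ Normal(alpha_triplet[i] + beta_type[i],triplet[i], sigma),

yielding population-level mean HFI per taxon type and pairwise posterior
contrasts. Only hybrids occupying more than 10 hectads enter the
comparison.

## Worked example

```r
library(hybridscape)

# stem-age method-of-moments rate: 217 species, stem age 0.00371 Myr
mom_rate(richness = 217, stem_age = 0.00371, extinction_fraction = 0.9)
#> [1] 840.4178

# projected hybridization events among 11,987 neophytes, 73% of which
# could meet a congener, assuming 9-25% of species hybridize
projected_hybridizations(11987, 0.73, 0.09, 0.25)
#> # A tibble: 1 × 2
#>     low  high
#>   <int> <int>
#> 1   788  2188

# elasticity reading of log10-log10 slopes at a 20% predictor increase
slope_percent_change(c(0.26, 0.64), predictor_factor = 1.2)
#> [1]  4.854512 12.376628
```

The full pipeline on a synthetic world with planted ground truth (200
botanical countries, 800 genera, 30 triplets; country slope 0.26, genus
slope 0.64, group rate multipliers 1/1.6/2.5/2.91, HFI type means
22.6/24.6/28.5):

```r
world <- sim_world(world_config())
dir <- file.path(tempdir(), "demo-world")
write_world(world, dir)
report <- run_pipeline(pipeline_config(dir, seed = 1))
print(report)
#> == hybridscape pipeline report ==
#> stages: spatial, genus, congeners, diversification, signal, footprint
#> countries tallied: 200 | genera tallied: 800
#> country model: b(neophytes) = 0.261 [0.199, 0.324]
#> genus model:   b(neophyte ratio) = 0.655 [0.499, 0.809]
#> congeners: 25.0% of events, 51.1% of species; projection 50-140 events
#> diversification: both/neither rate ratio = 2.90 [2.53, 3.33]
#> Blomberg's K (n_hybrids) = 0.178
#> Blomberg's K (n_neophytes) = 0.178
#> mean HFI: hybrid 28.5 | native 22.8 | neophyte 24.8
#> range coverage: 30/30 hybrids above native min HFI, 17/30 above both parents' max
#> MCMC diagnostic failures: 0
```

Every planted value sits inside its recovered 95% credible interval: the
country slope (0.26), the genus ratio slope (0.64), the
diversification-rate ratio between genera with both hybrids and
neophytes and those with neither (2.91), and the three HFI type means.
Fitted objects follow broom conventions (`tidy()`, `glance()`) and plot
with `autoplot()` / `plot_contrasts()`.

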