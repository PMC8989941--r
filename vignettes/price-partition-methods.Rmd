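---
title: "Partitioning functional-diversity change with the Price equation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning functional-diversity change with the Price equation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdprice)
```

fdprice links the *numerical* diversity of species assemblages (how many
species, how abundant) to their *functional* diversity (how different the
species are in what they do), and asks which environmental conditions
drive that link. It was built for site-by-species bird count data with
diet, foraging-stratum and body-mass traits, but nothing in the pipeline
is bird-specific. This vignette documents the statistical models, the
design decisions behind them, and what the synthetic-data validation does
and does not establish.

## Functional dispersion in a Gower/PCoA trait space

Each species carries nine diet percent-use categories (summing to 100),
seven foraging-stratum percent-use categories (summing to 100), and a
body mass in grams. Three trait sets are analysed: `diet`, `strata`, and
`comb` (both blocks plus body mass).

Pairwise species dissimilarity is numeric Gower: the mean over selected
traits of $|x_i - x_j| / \mathrm{range}$, with ranges taken from the
supplied table. All traits here are numeric percent-use values, so no
categorical branch is implemented (the reader keeps a column-mapping hook
for other encodings). Two numerical choices matter:

* **Zero-range traits** carry no information under range normalisation.
  They are excluded from the per-pair mean — the classic Gower weighting,
  and the only reading under which "two species differing in the single
  varying trait" have dissimilarity 1 — and flagged with a warning.
* **Body mass** enters untransformed by default; a `log_mass` switch is
  provided because mass spans two orders of magnitude and a log scale is
  a defensible alternative. The default keeps the index closest to the
  raw trait table.

Principal coordinates (classical metric scaling of the double-centred
dissimilarity matrix) turn the Gower matrix into Euclidean coordinates.
**All axes with positive eigenvalues are retained**: functional
dispersion is distance-based, and truncating axes changes the index.
Gower matrices are usually not Euclidean-embeddable, so negative
eigenvalues appear; by default no correction is applied and a warning is
raised when the negative eigenvalues exceed 5% of the absolute
eigenvalue mass — transparency over silent correction. Element-wise
square-root and Cailliez corrections are available
(`correction = "sqrt"` / `"cailliez"`).

Functional dispersion (FDis) of a site is the abundance-weighted mean
distance of its species to the abundance-weighted centroid:

$$
\mathrm{FDis} = \frac{\sum_i a_i \, \lVert x_i - c \rVert}{\sum_i a_i},
\qquad
c = \frac{\sum_i a_i x_i}{\sum_i a_i},
$$

over species with $a_i > 0$. Species absent from a site are excluded from
both centroid and dispersion, so the index is independent of species
richness and invariant to rescaling a site's abundance row. The trait
space is built **once from the full species pool per trait set**, not per
site, so site values are comparable. Empty site-years propagate as
missing FD (logged, excluded from pairwise comparisons); single-species
sites have FDis 0.

```{r fdis-example}
fdis(c(3, 1), matrix(c(0, 1), ncol = 1))  # centroid 0.25 by hand
```

## Per-species contributions and rarity

The contribution of species $i$ at a site in a year is

$$
z_i = \frac{a_i \cdot \mathrm{FD}_{\text{site,year}}}{N_{\text{year}}},
$$

where $N_{\text{year}}$ is the total number of individuals across **all**
sites in that year. Summed over a site, $\sum_i z_i = \mathrm{FD} \cdot
n_{\text{site}} / N_{\text{year}}$ — the site's FD scaled by its share of
the year's individuals, not FD itself. That is a property of the
definition (the year-wide denominator makes contributions comparable
across sites), and the conservation identity the tests check is the exact
one: yearly contributions sum to the abundance-weighted mean FD across
sites.

Species are *common* in a year when their total abundance across sites is
at or above the mean of those totals, *rare* below it; the boundary is
classed common. The year-total definition is the default because rarity
is a year-level species summary here; a per-occupied-site mean is offered
as an alternative rule. For descriptive summaries a species' modal class
across years is used, with exact ties resolving to common (the same
at-the-boundary direction).

## The five-component Price partition

For an ordered pair of sites — baseline with $s$ species and mean
contribution $\bar z$, comparison with $s'$ species and mean $\bar z'$,
sharing $s_c$ species with shared-species means $\bar z_c, \bar z'_c$ —
the difference in total contribution partitions additively into five
components:

| term | formula | reading |
|------|---------|---------|
| RICH_L | $(s_c - s)\,\bar z$ | random species loss (always $\le 0$) |
| COMP_L | $s_c(\bar z_c - \bar z)$ | non-random species loss |
| RICH_G | $(s' - s_c)\,\bar z'$ | random species gain (always $\ge 0$) |
| COMP_G | $-s_c(\bar z'_c - \bar z')$ | non-random species gain |
| ABUN | $\sum_{\text{shared}} (z'_i - z_i)$ | abundance change of shared species |

Their sum telescopes to $\sum z' - \sum z = \Delta\mathrm{FD}$ exactly;
the package verifies this identity on every record rather than trusting
the algebra, and the tests additionally check role-swap antisymmetry
(swapping baseline and comparison negates the total and maps losses onto
gains). Cumulative losses (RICH_L + COMP_L) and gains (RICH_G + COMP_G)
are carried along because the components are additive.

Design choices that were genuinely open:

* **Pairing.** The default visits every ordered pair of non-empty sites
  within each year and trait set — deterministic and exhaustive. A seeded
  `random_pairs` scheme mirrors repeated random pairwise comparison.
  Pairs are never formed across years or trait sets, since FD and
  $N_{\text{year}}$ are year-specific.
* **Presence.** A species is present in a pair when its count (hence its
  contribution) is positive; the partition's membership indicators are
  exactly the joint-presence masks.
* **Site-level response.** For environmental modelling each component is
  averaged over all pairs in which a site is the *comparison* site
  (within year and trait set): gains and losses are framed from the
  comparison site's perspective, and covariates are per-site. This
  mapping is a package decision; pair-level alternatives with other
  groupings are possible and would change regression answers.
* **"Relative" contribution.** Component summaries report both raw means
  and means scaled by the mean absolute $\Delta\mathrm{FD}$, since either
  normalisation is a reasonable reading of "relative".

## Environmental screening with mixed models

Each Price component (per trait set) is regressed on **one** covariate at
a time: a linear mixed model with a fixed slope and a random intercept
per year, fitted by maximum likelihood, compared against the
intercept-plus-year-random null by a likelihood-ratio test on 1 df. With
three year levels the random-intercept variance is weakly identified —
the package mirrors a year-as-random design deliberately, and when a fit
is singular it falls back to a flagged OLS comparison rather than
reporting a degenerate mixed model. Covariates enter unstandardised so
slopes are on raw covariate scales. No multiple-testing correction is
applied to the headline flags (a screening design); a Benjamini–Hochberg
column is emitted for reference.

Flagged models (p < 0.05) get residual diagnostics: a simulation-based
dispersion test (the observed residual variance compared two-sidedly with
an envelope of, by default, 1000 responses simulated from the fitted
model) and the mean within-year lag-1 residual autocorrelation, with 0.15
as the reporting threshold. These are documented envelope procedures, not
re-implementations of any particular diagnostics package.

## What the synthetic generator emulates

The generator's defaults are the study conditions the package targets: 82
sites, 3 years, 61 species, counts shaped like maximum point counts.

* **Abundances.** A log-normal species abundance distribution (log-series
  optional) supplies latent expected abundances via distribution
  quantiles, so species rank is well defined; counts are zero-truncated
  Poisson draws where a Bernoulli occupancy process (site-varying
  probability) puts the species. The choice of family is a
  stand-in for an unknown assemblage SAD, not an inference; the property
  that matters downstream is the right-skewed common/rare split.
* **Traits.** Dirichlet-style percent blocks with invertivore-leaning
  diet weights and a log-normal body mass spanning roughly 5–900 g.
* **Trait-linked rarity.** Because contributions are proportional to
  abundance, COMP_L responds to the *abundance gap* between shared and
  lost species, not to trait positions directly. `rare_trait_shift`
  therefore plants trait-*linked* rarity: the rarest quantile of species
  is pulled toward distinct trait poles **and** has its occupancy thinned
  (rare, distinct species are the first lost between sites). With the
  shift at 0, occupancy is independent of species identity and the mean
  COMP_L across pairs is zero in expectation — the partition's
  interpretation, checked by simulation.
* **Planted covariate effects.** A covariate targeting a component is
  built as `centre + b (c - mean c) + noise` from the per-site mean
  component `c`, with `b = rho^2 / slope` and the noise standard
  deviation chosen so the *population regression slope of the component
  on the covariate* equals the requested slope exactly
  (attenuation-corrected; `rho` defaults to 0.6). Values are clamped to
  the covariate's legal range, which at default scales essentially never
  binds. This guarantees a recoverable linear signal without using the
  downstream estimator in the construction.
* **Seeding.** One master seed spawns a fixed substream per operation, so
  adding draws to one generator never shifts another's stream, and equal
  seeds give byte-identical outputs.

What passing the synthetic validation does **not** show about real data:
no detection error or occupancy modelling (counts are true abundances),
no spatial structure or phylogenetic trait correlation, no
abundance–occupancy correlation beyond the planted rarity mechanism, and
environmental covariates that are independent by construction except for
planted effects.

## Validation design and problem sizes

The test suite checks each stage against an independent oracle (direct
per-pair Gower evaluation, naive per-site FDis recomputation, elementwise
contribution formulas, the $\sum z' - \sum z$ identity) and the whole
pipeline against the generator's planted truth: a planted NDVI to
random-gains slope of 0.7 is recovered within 2 standard errors in at
least 90% of 200 replicates at the default study size, the
likelihood-ratio screen holds its nominal 5% type-I rate under the null
generator (200 replicates of a 40-site study), and the COMP_L
interpretation check uses 100 replicates per condition at 30 sites and 40
species. These sizes were chosen to make the Monte-Carlo assertions sharp
while keeping the default validation run comfortably interactive.

## Known limitations

* The Gower/PCoA space is rebuilt from the supplied species pool;
  comparing FD across datasets with different pools is not meaningful.
* With three year levels, the mixed models' year variance is often
  estimated at zero; the flagged OLS fallback keeps the LRT
  interpretable but the random-intercept design is deliberately minimal.
* The per-site aggregation of pair-level components is one defensible
  mapping among several; regression results should be read conditional
  on it.
* The rare/common split is a within-dataset operational rule, not a
  biological rarity concept.
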