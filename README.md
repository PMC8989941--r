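# fdprice

Community ecologists routinely observe that sites differ both in *how
many* individuals and species they hold and in *how functionally diverse*
those species are — but a difference in functional diversity (FD) between
two sites says nothing, by itself, about *why*: did species get lost at
random, were functionally distinctive (often rare) species lost first,
were distinctive species gained, or did shared species just change in
abundance? fdprice answers that question for assemblages sampled as
site-by-species count matrices with species-level functional traits, and
then asks which environmental conditions drive each mechanism.

The package implements, end to end:

1. **Trait space** — numeric Gower dissimilarity over diet percent-use,
   foraging-stratum percent-use and body-mass traits, turned into
   Euclidean coordinates by principal coordinates analysis (all
   positive-eigenvalue axes retained), plus a descriptive diet/stratum
   guild classification.
2. **Functional dispersion (FDis)** per site, year and trait set:
   $\mathrm{FDis} = \sum_i a_i \lVert x_i - c\rVert / \sum_i a_i$ with
   $c$ the abundance-weighted centroid — an FD measure independent of
   species richness.
3. **Per-species contributions** $z_i = a_i\,\mathrm{FD}/N_{\mathrm{year}}$
   and a rare/common split at the mean species abundance.
4. **The five-component Price partition** of the FD difference between
   ordered site pairs:

   $$\Delta\mathrm{FD} = \underbrace{(s_c-s)\bar z}_{\text{RICH\_L}}
     + \underbrace{s_c(\bar z_c-\bar z)}_{\text{COMP\_L}}
     + \underbrace{(s'-s_c)\bar z'}_{\text{RICH\_G}}
     - \underbrace{s_c(\bar z'_c-\bar z')}_{\text{COMP\_G}}
     + \underbrace{\textstyle\sum_{\text{shared}}(z_i'-z_i)}_{\text{ABUN}}$$

   separating random from non-random species losses and gains and the
   abundance change of shared species; the five terms sum to
   $\sum z' - \sum z$ exactly, and the package verifies that identity on
   every record.
5. **Environmental screening** — each component regressed on one
   covariate at a time (forest-management intensity and its components,
   deadwood, snags, vegetation cover, tree microhabitats, NDVI) with a
   year random intercept, compared to a null model by likelihood-ratio
   test, with simulation-based residual diagnostics.
6. **A seeded synthetic-data generator** reproducing the study design the
   package targets (82 sites x 3 years x 61 species, right-skewed
   abundances, optional trait-linked rarity, plantable covariate
   effects), so the whole pipeline is validated without field data.

All user-facing functions take and return tibbles and chain with the
pipe; fitted models have `tidy()`/`glance()` methods and `autoplot()`,
and `plot_price_components()` / `plot_species_contributions()` give the
standard figures.

## Worked example

Simulate a 30-site study in which NDVI is constructed to drive the
random-gains component with slope 0.7, then recover that effect:

```r
library(fdprice)

cfg <- sim_config(n_sites = 30, n_species = 40, seed = 42,
                  env_effects = list(ndvi = list(component = "rich_g",
                                                 slope = 0.7)))
sim   <- simulate_community(cfg)
fd    <- fd_table(sim$counts, sim$traits)     # FDis per site/year/trait set
z     <- species_contributions(sim$counts, fd)
pairs <- price_all_pairs(z)                   # all ordered pairs, per year

dplyr::filter(price_summary(pairs), trait_set == "comb")
#> # A tibble: 8 × 6
#>   trait_set component          mean       sd     n mean_scaled
#>   <chr>     <fct>             <dbl>    <dbl> <int>       <dbl>
#> 1 comb      rich_l        -3.98e- 3 0.00225   2610   -1.27e+ 0
#> 2 comb      comp_l        -1.71e- 5 0.000819  2610   -5.44e- 3
#> 3 comb      rich_g         3.98e- 3 0.00225   2610    1.27e+ 0
#> 4 comb      comp_g         1.71e- 5 0.000819  2610    5.44e- 3
#> 5 comb      abun           0        0.000621  2610    0
#> 6 comb      rich_l_comp_l -4.00e- 3 0.00239   2610   -1.28e+ 0
#> 7 comb      rich_g_comp_g  4.00e- 3 0.00239   2610    1.28e+ 0
#> 8 comb      delta_fd       5.12e-21 0.00386   2610    1.63e-18
```

Over all ordered pairs the loss terms mirror the gain terms (every pair
appears in both roles), the mean `delta_fd` is numerically zero, and the
random-richness terms dominate the composition terms — random species
turnover, not trait-selective turnover, carries most of the FD difference
in this simulation. `mean_scaled` expresses each mean relative to the
mean absolute FD difference.

```r
fit <- fit_component_model(
  dplyr::select(dplyr::filter(price_site_means(pairs), trait_set == "comb"),
                site, year, value = rich_g),
  sim$env, "ndvi", component = "rich_g", trait_set = "comb")
fit
#> <fd_lmm> rich_g ~ ndvi [comb]
#>   slope 0.7483 (SE 0.1737), LRT chi2 = 17.227, p = 3.317e-05 (OLS fallback)
```

The planted slope 0.7 is recovered (0.75 ± 0.17) and flagged by the
likelihood-ratio test; the estimated year variance was zero here, so the
fit fell back — flagged — to the OLS comparison.

`run_pipeline()` drives all stages from a YAML config (input CSVs or a
`simulate` block) and writes every intermediate table, a manifest and a
summary; `inst/scripts/fdprice` wraps it for shell use.

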