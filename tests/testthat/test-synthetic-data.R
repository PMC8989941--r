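# Synthetic community generator: contracts and Monte-Carlo properties.

test_that("trait tables are complete with percent blocks summing to 100", {
  traits <- generate_traits(sim_config(n_species = 61, seed = 3))
  expect_equal(nrow(traits), 61)
  expect_false(anyNA(traits))
  expect_equal(rowSums(traits[trait_columns("diet")]), rep(100, 61),
               tolerance = 1e-12)
  expect_equal(rowSums(traits[trait_columns("strata")]), rep(100, 61),
               tolerance = 1e-12)
  expect_true(all(traits$body_mass > 0))
})

test_that("generators are deterministic under a fixed master seed", {
  cfg <- sim_config(n_sites = 12, n_species = 15, seed = 77)
  sim1 <- simulate_community(cfg)
  sim2 <- simulate_community(cfg)
  expect_identical(sim1$traits, sim2$traits)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$env, sim2$env)
})

test_that("trait profile is independent of abundance rank when shift is 0", {
  # correlation between abundance rank and distance-to-centroid,
  # averaged over seeds, should straddle 0
  cors <- vapply(1:40, function(s) {
    tr <- generate_traits(sim_config(n_species = 30, seed = s))
    d <- gower_dissimilarity(tr, "comb")
    cor(seq_len(30), colMeans(d))  # index = descending abundance rank
  }, numeric(1))
  expect_lt(abs(mean(cors)), 2 * sd(cors) / sqrt(length(cors)) + 0.05)
})

test_that("a large rare_trait_shift makes the rare quantile functionally distinct", {
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(n_species = 40, seed = s, rare_trait_shift = 1)
    tr <- generate_traits(cfg)
    # distance in the functional (range-normalized Gower/PCoA) space, to
    # the abundance-weighted community centroid (as FDis defines it)
    coords <- suppressWarnings(build_trait_space(tr, "comb"))$coordinates
    lam <- fdprice:::latent_abundances(cfg)
    cen <- colSums(lam * coords) / sum(lam)
    dist_cen <- sqrt(rowSums(sweep(coords, 2, cen)^2))
    rare <- seq_len(40) > 30  # rarest quantile is the index tail
    mean(dist_cen[rare]) > mean(dist_cen[!rare])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("species totals are right-skewed under the lognormal model", {
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(n_sites = 20, n_species = 30, seed = s,
                      meanlog = 1, sdlog = 1.2)
    counts <- generate_counts(cfg)
    totals <- counts |>
      dplyr::group_by(species) |>
      dplyr::summarise(n = sum(count), .groups = "drop")
    skew(totals$n) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("count tables have the configured shape and integer counts", {
  cfg <- sim_config(n_sites = 9, n_species = 12, n_years = 2, seed = 5)
  counts <- generate_counts(cfg, generate_traits(cfg))
  expect_setequal(unique(counts$year), 1:2)
  expect_true(all(counts$site %in% sprintf("site_%03d", 1:9)))
  expect_true(all(counts$species %in% sprintf("sp_%03d", 1:12)))
  expect_true(all(counts$count >= 1 & counts$count == round(counts$count)))
  # site pairs differ in composition
  present <- counts |>
    dplyr::filter(year == 1) |>
    dplyr::group_by(site) |>
    dplyr::summarise(sp = paste(sort(species), collapse = ","),
                     .groups = "drop")
  expect_gt(length(unique(present$sp)), 1)
})

test_that("log-series abundance model also yields valid counts", {
  cfg <- sim_config(n_sites = 8, n_species = 10, seed = 2,
                    abundance_model = "logseries", logseries_x = 0.95)
  counts <- generate_counts(cfg)
  expect_true(all(counts$count >= 1))
  expect_gt(nrow(counts), 0)
})

test_that("environmental covariates respect their field-legal ranges", {
  env <- generate_environment(sim_config(n_sites = 50, seed = 8))
  for (nm in c("formi_harvest", "formi_nonnative", "formi_dwcut")) {
    expect_true(all(env[[nm]] >= 0 & env[[nm]] <= 1))
  }
  expect_true(all(env$formi >= 0 & env$formi <= 3))
  expect_equal(env$formi,
               env$formi_harvest + env$formi_nonnative + env$formi_dwcut)
  expect_true(all(env$ndvi >= 0 & env$ndvi <= 1))
  expect_true(all(env$veg_cover >= 0 & env$veg_cover <= 100))
  expect_true(all(env$deadwood_volume >= 0))
  expect_true(all(env$snags >= 0 & env$trem_abundance >= 0))
  expect_true(all(env$trem_richness <= env$trem_abundance))
})

test_that("without planted effects, covariates are independent of counts", {
  cors <- vapply(1:30, function(s) {
    sim <- simulate_community(sim_config(n_sites = 30, n_species = 20,
                                         seed = s))
    tot <- sim$counts |>
      dplyr::group_by(site) |>
      dplyr::summarise(n = sum(count), .groups = "drop")
    cor(tot$n[match(sim$env$site, tot$site)], sim$env$ndvi)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 2 * sd(cors) / sqrt(length(cors)) + 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_sites = 0), "positive integer")
  expect_error(sim_config(rare_trait_shift = -1), ">= 0")
  expect_error(
    sim_config(env_effects = list(ndvi = list(component = "nope",
                                              slope = 1))),
    "unknown target component")
  expect_error(
    generate_environment(
      sim_config(seed = 1,
                 env_effects = list(ndvi = list(component = "rich_g",
                                                slope = 0.7)))),
    "requires")
  cfg <- sim_config(n_sites = 6, n_species = 8, seed = 1,
                    env_effects = list(bogus = list(component = "abun",
                                                    slope = 1)))
  sim_traits <- generate_traits(cfg)
  sim_counts <- generate_counts(cfg, sim_traits)
  expect_error(generate_environment(cfg, sim_counts, sim_traits),
               "unknown covariate")
})

test_that("a planted covariate effect is recoverable in a single draw", {
  cfg <- sim_config(seed = 19,
                    env_effects = list(ndvi = list(component = "rich_g",
                                                   slope = 0.7)))
  sim <- suppressWarnings(simulate_community(cfg))
  suppressWarnings({
    fd <- fd_table(sim$counts, sim$traits, trait_sets = "comb")
  })
  z <- species_contributions(sim$counts, fd)
  sm <- price_site_means(price_all_pairs(z))
  fit <- fit_component_model(
    dplyr::select(sm, site, year, value = rich_g), sim$env, "ndvi")
  expect_lt(abs(fit$slope - 0.7), 2 * fit$slope_se)
})
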