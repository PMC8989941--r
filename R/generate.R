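# Synthetic community generator: trait tables, count matrices and
# environmental covariates with the statistical structure the downstream
# analysis assumes.

# Dirichlet-style percent block: gamma draws renormalized to sum to 100.
rdirichlet_pct <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  100 * g / rowSums(g)
}

# Trait poles the rare quantile is pulled toward when rarity is
# trait-linked: vertebrate/seed diets, ground/canopy foraging. Chosen to
# move rare species away from the invertivore/mid-stratum bulk of the
# assemblage.
RARE_DIET_POLE <- c(diet_inv = 5, diet_vend = 30, diet_vect = 10,
                    diet_vfish = 5, diet_vunk = 0, diet_scav = 10,
                    diet_fruit = 5, diet_nect = 0, diet_seed = 35)
RARE_STRATA_POLE <- c(strat_watbelowsurf = 0, strat_wataroundsurf = 0,
                      strat_ground = 45, strat_understory = 5,
                      strat_midhigh = 5, strat_canopy = 45,
                      strat_aerial = 0)

#' Generate a synthetic species trait table
#'
#' Draws one row per species: nine diet percent-use categories summing to
#' 100, seven foraging-stratum percent-use categories summing to 100, and a
#' log-normal body mass in grams. When `config$rare_trait_shift > 0` the
#' rarest quantile of species (by expected abundance rank) is blended
#' toward distinct trait poles and given a heavier body mass, emulating
#' assemblages in which rare species carry distinct trait profiles.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `species`, the nine `diet_*` columns, the
#'   seven `strat_*` columns and `body_mass`.
#' @export
#' @examples
#' traits <- generate_traits(sim_config(n_species = 8, seed = 2))
#' rowSums(traits[trait_columns("diet")])
generate_traits <- function(config) {
  config <- as_sim_config(config)
  set.seed(op_seed(config$seed, "traits"))
  n <- config$n_species

  diet_alpha <- c(4, 0.5, 0.3, 0.2, 0.2, 0.3, 1, 0.3, 1)
  strata_alpha <- c(0.05, 0.05, 2, 1, 1.5, 0.8, 0.3)
  diet <- rdirichlet_pct(n, diet_alpha)
  strata <- rdirichlet_pct(n, strata_alpha)
  mass <- rlnorm(n, meanlog = config$body_meanlog, sdlog = config$body_sdlog)

  if (config$rare_trait_shift > 0) {
    rare <- rare_species_mask(config)
    w <- min(1, config$rare_trait_shift)
    diet[rare, ] <- (1 - w) * diet[rare, , drop = FALSE] +
      w * matrix(RARE_DIET_POLE, nrow = sum(rare), ncol = 9, byrow = TRUE)
    strata[rare, ] <- (1 - w) * strata[rare, , drop = FALSE] +
      w * matrix(RARE_STRATA_POLE, nrow = sum(rare), ncol = 7, byrow = TRUE)
    mass[rare] <- mass[rare] * exp(w * 1.2)  # rare species skew heavier
  }

  colnames(diet) <- DIET_COLS
  colnames(strata) <- STRATA_COLS
  out <- dplyr::bind_cols(
    tibble::tibble(species = species_ids(config)),
    tibble::as_tibble(diet),
    tibble::as_tibble(strata),
    tibble::tibble(body_mass = mass)
  )
  # renormalization is exact up to float error; force it
  out[DIET_COLS] <- 100 * out[DIET_COLS] / rowSums(out[DIET_COLS])
  out[STRATA_COLS] <- 100 * out[STRATA_COLS] / rowSums(out[STRATA_COLS])
  out
}

#' Generate synthetic site-by-species counts
#'
#' Emulates maximum point-count abundances per site and year: a latent
#' log-normal (or log-series) species abundance distribution is thinned to
#' sites by a Bernoulli occupancy process whose probability varies by site,
#' and occupied cells receive a zero-truncated Poisson count. Species total
#' abundances are right-skewed under the default configuration. When
#' `rare_trait_shift > 0`, rare-quantile species have their occupancy
#' thinned further (trait-linked rarity: the species that diverge in traits
#' are also lost first between sites).
#'
#' @param config A [sim_config()].
#' @param traits Trait table from [generate_traits()]; only used to check
#'   species alignment.
#' @return A long tibble `site`, `year`, `species`, `count` containing the
#'   positive counts (absent combinations are implicit zeros).
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 6, n_species = 10, seed = 3)
#' counts <- generate_counts(cfg, generate_traits(cfg))
generate_counts <- function(config, traits = NULL) {
  config <- as_sim_config(config)
  if (!is.null(traits) &&
      !setequal(traits$species, species_ids(config))) {
    abort("`traits` species do not match the configuration")
  }
  set.seed(op_seed(config$seed, "counts"))

  lambda <- latent_abundances(config)
  occ_sp <- rep(1, config$n_species)
  if (config$rare_trait_shift > 0) {
    occ_sp[rare_species_mask(config)] <- exp(-config$rare_trait_shift)
  }
  sites <- site_ids(config)
  species <- species_ids(config)

  out <- vector("list", config$n_years)
  for (y in seq_len(config$n_years)) {
    site_quality <- runif(config$n_sites, 0.6, 1.4)
    p_occ <- pmin(1, outer(site_quality * config$base_occupancy, occ_sp))
    present <- matrix(
      rbinom(length(p_occ), 1, as.vector(p_occ)) == 1,
      nrow = config$n_sites
    )
    counts <- matrix(0L, config$n_sites, config$n_species)
    idx <- which(present)
    lam <- lambda[((idx - 1) %/% config$n_sites) + 1]
    counts[idx] <- pmax(1L, rpois(length(idx), lam))
    dimnames(counts) <- list(sites, species)
    out[[y]] <- tibble::as_tibble(as.data.frame.table(
      counts, responseName = "count", stringsAsFactors = FALSE
    )) |>
      stats::setNames(c("site", "species", "count")) |>
      dplyr::filter(.data$count > 0) |>
      dplyr::mutate(year = y, .after = "site")
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$year, .data$site, .data$species)
}

# legal ranges used for clamping planted covariates
COVARIATE_RANGES <- list(
  formi = c(0, 3), formi_harvest = c(0, 1), formi_nonnative = c(0, 1),
  formi_dwcut = c(0, 1), deadwood_volume = c(0, Inf), snags = c(0, Inf),
  veg_cover = c(0, 100), trem_abundance = c(0, Inf),
  trem_richness = c(0, Inf), ndvi = c(0, 1)
)

#' Generate synthetic environmental covariates
#'
#' Draws one row per site: forest-management intensity (ForMI, the sum of
#' three components each in \[0, 1\]: harvested-volume proportion,
#' non-native tree proportion, and man-made vs natural deadwood ratio),
#' lying deadwood volume (m3/ha), snag count, vegetation cover (percent),
#' tree-related microhabitat (TreM) abundance and richness, and NDVI in
#' \[0, 1\].
#'
#' When `config$env_effects` plants an effect, the named covariate is
#' constructed by coupling it to the per-site Price component it targets
#' (computed by running the trait-space, dispersion, contribution and
#' partition steps on `counts`), with the coupling scaled so the population
#' regression slope of the component on the covariate equals the requested
#' slope; values are then clamped to the covariate's legal range.
#'
#' @param config A [sim_config()].
#' @param counts Long count tibble from [generate_counts()]; required when
#'   `env_effects` is non-empty.
#' @param traits Trait table; required when `env_effects` is non-empty
#'   (the planted component is computed in its trait space).
#' @return A tibble with one row per site.
#' @export
generate_environment <- function(config, counts = NULL, traits = NULL) {
  config <- as_sim_config(config)
  if (length(config$env_effects) > 0 && (is.null(counts) || is.null(traits))) {
    abort("planting env effects requires `counts` and `traits`")
  }
  set.seed(op_seed(config$seed, "environment"))
  n <- config$n_sites

  env <- tibble::tibble(
    site = site_ids(config),
    formi_harvest = rbeta(n, 2, 2),
    formi_nonnative = rbeta(n, 1.2, 4),
    formi_dwcut = rbeta(n, 2, 3),
    deadwood_volume = rgamma(n, shape = 2, scale = 15),
    snags = rpois(n, 8),
    veg_cover = runif(n, 5, 95),
    trem_abundance = rpois(n, 30),
    ndvi = rbeta(n, 12, 3)
  )
  env$trem_richness <- pmin(env$trem_abundance, rpois(n, 9))
  env$formi <- env$formi_harvest + env$formi_nonnative + env$formi_dwcut

  if (length(config$env_effects) > 0) {
    needed_sets <- unique(vapply(config$env_effects, `[[`, "", "trait_set"))
    site_comp <- planted_site_components(counts, traits, needed_sets)
    for (nm in names(config$env_effects)) {
      eff <- config$env_effects[[nm]]
      if (!nm %in% names(COVARIATE_RANGES)) {
        abort(paste0("unknown covariate in env_effects: ", nm))
      }
      comp <- site_comp |>
        dplyr::filter(.data$trait_set == eff$trait_set)
      c_site <- comp[[eff$component]][match(env$site, comp$site)]
      env[[nm]] <- plant_covariate(c_site, eff, COVARIATE_RANGES[[nm]],
                                   centre = mean(env[[nm]]))
    }
    env$formi <- env$formi_harvest + env$formi_nonnative + env$formi_dwcut
  }
  dplyr::relocate(env, "site", "formi", "formi_harvest", "formi_nonnative",
                  "formi_dwcut", "deadwood_volume", "snags", "veg_cover",
                  "trem_abundance", "trem_richness", "ndvi")
}

# Per-site Price components averaged over years: the regression response
# the planted slope must be recoverable from.
planted_site_components <- function(counts, traits, trait_sets) {
  fd <- fd_table(counts, traits, trait_sets = trait_sets)
  z <- species_contributions(counts, fd)
  pairs <- price_all_pairs(z)
  price_site_means(pairs) |>
    dplyr::group_by(.data$trait_set, .data$site) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(COMPONENT_NAMES), mean),
                     .groups = "drop")
}

# Covariate x = centre + b (c - mean c) + noise with b = rho^2 / slope and
# noise sd b sd(c) sqrt(1 - rho^2) / rho, so that the population regression
# slope of the component c on x equals `slope` exactly (the forward
# coefficient is attenuation-corrected). Clamped to the legal range, which
# at default scales almost never binds.
plant_covariate <- function(c_site, eff, range, centre) {
  sd_c <- sd(c_site)
  if (!is.finite(sd_c) || sd_c == 0) {
    abort("target component has zero variance across sites; cannot plant")
  }
  b <- eff$rho^2 / eff$slope
  noise_sd <- abs(b) * sd_c * sqrt(1 - eff$rho^2) / eff$rho
  x <- centre + b * (c_site - mean(c_site)) + rnorm(length(c_site), 0, noise_sd)
  clamped <- pmin(pmax(x, range[1]), range[2])
  if (any(clamped != x)) {
    warn("planted covariate clamped to its legal range at some sites")
  }
  clamped
}

#' Simulate a full synthetic study
#'
#' Runs [generate_traits()], [generate_counts()] and
#' [generate_environment()] under one master seed.
#'
#' @param config A [sim_config()] (or a list of its arguments).
#' @return A list of class `"fd_sim"` with elements `traits`, `counts`,
#'   `env` and `config`.
#' @export
#' @examples
#' sim <- simulate_community(sim_config(n_sites = 8, n_species = 10, seed = 4))
#' names(sim)
simulate_community <- function(config = sim_config()) {
  config <- as_sim_config(config)
  traits <- generate_traits(config)
  counts <- generate_counts(config, traits)
  env <- generate_environment(config, counts, traits)
  structure(list(traits = traits, counts = counts, env = env,
                 config = config),
            class = "fd_sim")
}

#' @export
print.fd_sim <- function(x, ...) {
  cat("<fd_sim> ", x$config$n_sites, " sites x ", x$config$n_years,
      " years; ", length(unique(x$counts$species)), " species observed of ",
      x$config$n_species, "; ", sum(x$counts$count), " individuals\n",
      sep = "")
  invisible(x)
}
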