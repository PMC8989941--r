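#' Configuration for the synthetic community generator
#'
#' Bundles and validates every knob of the synthetic-data module. The
#' defaults emulate the study design the package targets: 82 one-hectare
#' forest sites surveyed in each of 3 years, an assemblage of 61 bird
#' species with a right-skewed (log-normal) species abundance distribution,
#' diet/foraging-stratum percent-use traits with body mass spanning roughly
#' 5-900 g, and environmental covariates in their field-legal ranges.
#'
#' @param n_sites Number of sites (default 82).
#' @param n_years Number of survey years (default 3).
#' @param n_species Number of species in the pool (default 61).
#' @param abundance_model `"lognormal"` (default) or `"logseries"`; family of
#'   the latent species abundance distribution.
#' @param meanlog,sdlog Parameters of the log-normal abundance model (site
#'   scale expected counts).
#' @param logseries_x Shape parameter of the log-series alternative,
#'   in (0, 1).
#' @param base_occupancy Baseline probability that a species occurs at a
#'   site in a year; per-site quality multiplies it so site pairs differ in
#'   composition.
#' @param rare_trait_shift Magnitude (>= 0) of trait-linked rarity. At 0,
#'   trait profiles and site occupancy are independent of abundance rank.
#'   When positive, the rarest quantile of species is (a) pulled toward the
#'   configured trait poles and (b) thinned more strongly across sites, so
#'   rare, functionally distinct species are the first lost between sites.
#' @param rare_quantile Fraction of species (by expected abundance) treated
#'   as the rare quantile for the shift (default 0.25).
#' @param env_effects Named list mapping a covariate name to
#'   `list(component =, slope =, trait_set =, rho =)`: plants a recoverable
#'   linear effect of the covariate on the named Price component
#'   (one of `r paste(COMPONENT_NAMES, collapse = ", ")`). `rho` is the
#'   target covariate-component correlation (default 0.6).
#' @param body_meanlog,body_sdlog Log-normal body-mass parameters (grams).
#' @param seed Master seed; each generator operation draws from its own
#'   substream derived from it.
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 10, n_species = 12, seed = 1)
#' cfg$n_species
sim_config <- function(n_sites = 82,
                       n_years = 3,
                       n_species = 61,
                       abundance_model = c("lognormal", "logseries"),
                       meanlog = 0,
                       sdlog = 1.2,
                       logseries_x = 0.98,
                       base_occupancy = 0.22,
                       rare_trait_shift = 0,
                       rare_quantile = 0.25,
                       env_effects = list(),
                       body_meanlog = log(25),
                       body_sdlog = 1.2,
                       seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  check_pos_int <- function(x, nm) {
    if (length(x) != 1 || !is.numeric(x) || !is_whole(x) || x < 1) {
      abort(paste0("`", nm, "` must be a single positive integer"))
    }
  }
  check_pos_int(n_sites, "n_sites")
  check_pos_int(n_years, "n_years")
  check_pos_int(n_species, "n_species")
  if (rare_trait_shift < 0) abort("`rare_trait_shift` must be >= 0")
  if (rare_quantile <= 0 || rare_quantile >= 1) {
    abort("`rare_quantile` must be in (0, 1)")
  }
  if (logseries_x <= 0 || logseries_x >= 1) {
    abort("`logseries_x` must be in (0, 1)")
  }
  if (base_occupancy <= 0 || base_occupancy > 1) {
    abort("`base_occupancy` must be in (0, 1]")
  }
  if (!is.list(env_effects)) abort("`env_effects` must be a named list")
  if (length(env_effects) > 0) {
    if (is.null(names(env_effects)) || any(names(env_effects) == "")) {
      abort("every `env_effects` entry must be named by a covariate")
    }
    env_effects <- lapply(env_effects, function(e) {
      if (is.null(e$component) || is.null(e$slope)) {
        abort("each env effect needs `component` and `slope`")
      }
      e$component <- tolower(e$component)
      if (!e$component %in% COMPONENT_NAMES) {
        abort(paste0("unknown target component `", e$component,
                     "`; must be one of: ",
                     paste(COMPONENT_NAMES, collapse = ", ")))
      }
      e$trait_set <- e$trait_set %||% "comb"
      e$rho <- e$rho %||% 0.6
      if (e$rho <= 0 || e$rho >= 1) abort("env effect `rho` must be in (0, 1)")
      e
    })
  }
  structure(
    list(n_sites = as.integer(n_sites), n_years = as.integer(n_years),
         n_species = as.integer(n_species),
         abundance_model = abundance_model, meanlog = meanlog, sdlog = sdlog,
         logseries_x = logseries_x, base_occupancy = base_occupancy,
         rare_trait_shift = rare_trait_shift, rare_quantile = rare_quantile,
         env_effects = env_effects, body_meanlog = body_meanlog,
         body_sdlog = body_sdlog, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_sites, " sites x ", x$n_years, " years x ",
      x$n_species, " species; abundance: ", x$abundance_model,
      "; rare_trait_shift = ", x$rare_trait_shift, "\n", sep = "")
  if (length(x$env_effects) > 0) {
    for (nm in names(x$env_effects)) {
      e <- x$env_effects[[nm]]
      cat("  planted effect: ", nm, " -> ", e$component, " (", e$trait_set,
          "), slope ", e$slope, "\n", sep = "")
    }
  }
  invisible(x)
}

as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  if (!is.list(x)) abort("cannot interpret simulate config")
  do.call(sim_config, x)
}

# Deterministic latent expected abundances, one per species, sorted
# decreasing: species_001 is the most abundant, the tail is the rare
# quantile. Using distribution quantiles (not draws) keeps the rank
# structure identical across seeds so "rare" is well defined.
latent_abundances <- function(config) {
  p <- (seq_len(config$n_species) - 0.5) / config$n_species
  lambda <- switch(config$abundance_model,
    lognormal = exp(config$meanlog + config$sdlog * stats::qnorm(p)),
    logseries = logseries_quantile(p, config$logseries_x)
  )
  sort(lambda, decreasing = TRUE)
}

# Quantile function of the log-series distribution on {1, 2, ...},
# P(n) = -x^n / (n log(1 - x)); evaluated by direct CDF accumulation.
logseries_quantile <- function(p, x) {
  kmax <- 1000L
  k <- seq_len(kmax)
  pmf <- -x^k / (k * log(1 - x))
  cdf <- cumsum(pmf) / sum(pmf)
  vapply(p, function(pi) k[which(cdf >= pi)[1]], numeric(1))
}

# Species are indexed in decreasing expected abundance, so the rare
# quantile is the tail of the index sequence.
rare_species_mask <- function(config) {
  n_rare <- max(1L, floor(config$n_species * config$rare_quantile))
  seq_len(config$n_species) > config$n_species - n_rare
}

species_ids <- function(config) {
  sprintf("sp_%03d", seq_len(config$n_species))
}

site_ids <- function(config) {
  sprintf("site_%03d", seq_len(config$n_sites))
}
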