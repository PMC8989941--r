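# Readers and writers for the three CSV schemas, and the YAML run config.

#' Read a site-by-species count table
#'
#' Long format (canonical): columns `site`, `year`, `species`, `count`;
#' missing combinations are zeros, duplicated `(site, year, species)` keys
#' are an error (the offending rows are named), as are negative or
#' non-integer counts. Wide format: one `site` column plus one column per
#' species, for a single year given by `year`.
#'
#' @param path CSV path.
#' @param format `"long"` (default) or `"wide"`.
#' @param year Year label, required for `format = "wide"`.
#' @return Long count tibble: `site`, `year`, `species`, `count`.
#' @export
read_counts <- function(path, format = c("long", "wide"), year = NULL) {
  format <- match.arg(format)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (format == "wide") {
    if (is.null(year)) abort("`year` is required for wide count tables")
    assert_columns(raw, "site", "wide count table")
    raw <- raw |>
      tidyr::pivot_longer(-"site", names_to = "species",
                          values_to = "count") |>
      dplyr::mutate(year = year, .after = "site")
  }
  assert_columns(raw, c("site", "year", "species", "count"), "count table")
  bad <- which(raw$count < 0 | !is_whole(raw$count))
  if (length(bad) > 0) {
    abort(paste0("negative or non-integer counts at row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  dup <- duplicated(raw[c("site", "year", "species")])
  if (any(dup)) {
    abort(paste0("duplicated (site, year, species) keys at row(s): ",
                 paste(head(which(dup), 10), collapse = ", ")))
  }
  raw |>
    dplyr::mutate(count = as.integer(.data$count),
                  site = as.character(.data$site),
                  species = as.character(.data$species)) |>
    dplyr::select("site", "year", "species", "count")
}

#' Read a species trait table
#'
#' Accepts the canonical dialect (columns `species`, `diet_*`, `strat_*`,
#' `body_mass`) or the EltonTraits 1.0 dialect (`Diet-Inv` ...,
#' `ForStrat-ground` ..., `BodyMass-Value`); other dialects are handled by
#' an explicit `mapping` (named character vector, file column ->
#' canonical column). Percent blocks must each sum to 100 per species
#' within `tol`; off-sum rows are renormalized (default) or rejected.
#'
#' @param path CSV path.
#' @param dialect `"canonical"` or `"elton"`.
#' @param mapping Optional named character vector overriding the dialect's
#'   column mapping.
#' @param species_col Column holding species ids (default `"species"`;
#'   `"Scientific"` is typical for EltonTraits exports).
#' @param on_offsum `"renormalize"` (default) or `"reject"`.
#' @param tol Allowed deviation of each percent block from 100.
#' @return Canonical trait tibble.
#' @export
read_traits <- function(path, dialect = c("canonical", "elton"),
                        mapping = NULL, species_col = "species",
                        on_offsum = c("renormalize", "reject"), tol = 0.5) {
  dialect <- match.arg(dialect)
  on_offsum <- match.arg(on_offsum)
  raw <- readr::read_csv(path, show_col_types = FALSE, name_repair = "minimal")
  map <- mapping %||% switch(dialect, canonical = NULL, elton = ELTON_MAP)
  if (!is.null(map)) {
    missing <- setdiff(names(map), names(raw))
    if (length(missing) > 0) {
      abort(paste0("trait file lacks mapped column(s): ",
                   paste(missing, collapse = ", ")))
    }
    keep <- raw[c(species_col, names(map))]
    names(keep) <- c("species", unname(map))
    raw <- keep
  } else if (species_col != "species") {
    names(raw)[names(raw) == species_col] <- "species"
  }
  assert_columns(raw, c("species", DIET_COLS, STRATA_COLS), "trait table")
  if (!"body_mass" %in% names(raw)) {
    abort("trait table is missing `body_mass`")
  }
  if (any(!is.finite(raw$body_mass)) || any(raw$body_mass <= 0)) {
    abort("body mass must be present and positive for every species")
  }
  for (block in list(DIET_COLS, STRATA_COLS)) {
    sums <- rowSums(raw[block])
    off <- abs(sums - 100) > tol
    if (any(off)) {
      if (on_offsum == "reject") {
        abort(paste0("percent block off 100 for species: ",
                     paste(raw$species[off], collapse = ", ")))
      }
      warn(paste0("renormalized percent block for ", sum(off), " species"))
    }
    raw[block] <- 100 * raw[block] / sums
  }
  raw$species <- as.character(raw$species)
  raw
}

#' Read a site environment table
#'
#' One row per site; covariate columns as in [generate_environment()].
#' Values outside a covariate's legal range raise a warning naming the
#' offending sites.
#'
#' @param path CSV path.
#' @return Environment tibble.
#' @export
read_environment <- function(path) {
  env <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(env, "site", "environment table")
  if (any(duplicated(env$site))) abort("duplicated site rows")
  for (nm in intersect(names(env), names(COVARIATE_RANGES))) {
    r <- COVARIATE_RANGES[[nm]]
    bad <- env[[nm]] < r[1] | env[[nm]] > r[2]
    if (any(bad, na.rm = TRUE)) {
      warn(paste0("`", nm, "` outside [", r[1], ", ", r[2], "] at site(s): ",
                  paste(env$site[which(bad)], collapse = ", ")))
    }
  }
  env$site <- as.character(env$site)
  env
}

#' Write package tables to CSV
#'
#' Thin [readr::write_csv()] wrappers for the canonical schemas. The trait
#' writer can emit the EltonTraits 1.0 dialect.
#'
#' @param x Table to write.
#' @param path Output CSV path.
#' @param dialect Trait dialect to write (`"canonical"` or `"elton"`).
#' @return The input, invisibly.
#' @export
write_counts <- function(x, path) {
  assert_columns(x, c("site", "year", "species", "count"), "counts")
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname write_counts
#' @export
write_traits <- function(x, path, dialect = c("canonical", "elton")) {
  dialect <- match.arg(dialect)
  if (dialect == "elton") {
    out <- x[c("species", unname(ELTON_MAP))]
    names(out) <- c("species", names(ELTON_MAP))
    x <- out
  }
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname write_counts
#' @export
write_environment <- function(x, path) {
  assert_columns(x, "site", "environment table")
  readr::write_csv(x, path)
  invisible(x)
}

RUN_CONFIG_KEYS <- c("counts", "traits", "environment", "simulate",
                     "trait_sets", "trait_dialect", "pcoa_correction",
                     "log_mass", "pairing", "n_pairs", "rarity_rule",
                     "alpha", "nsim", "outdir", "seed")

#' Read and validate a pipeline run configuration
#'
#' YAML with either input paths (`counts`, `traits`, `environment`) or a
#' `simulate` block of [sim_config()] arguments — exactly one of the two —
#' plus optional analysis settings (`trait_sets`, `trait_dialect`,
#' `pcoa_correction`, `log_mass`, `pairing`, `n_pairs`, `rarity_rule`,
#' `alpha`, `nsim`, `outdir`, `seed`). Unknown keys are rejected.
#'
#' @param path YAML path.
#' @return A validated named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A named list with the same fields as the YAML.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  has_paths <- all(c("counts", "traits") %in% names(cfg))
  has_sim <- "simulate" %in% names(cfg)
  if (has_paths == has_sim) {
    abort("config must have exactly one of {counts+traits paths, simulate}")
  }
  cfg$trait_sets <- cfg$trait_sets %||% c("diet", "strata", "comb")
  cfg$trait_dialect <- cfg$trait_dialect %||% "canonical"
  cfg$pcoa_correction <- cfg$pcoa_correction %||% "none"
  cfg$log_mass <- cfg$log_mass %||% FALSE
  cfg$pairing <- cfg$pairing %||% "all_ordered"
  cfg$rarity_rule <- cfg$rarity_rule %||% "year_total"
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$nsim <- cfg$nsim %||% 1000
  cfg$seed <- cfg$seed %||% 1L
  if (has_sim) cfg$simulate$seed <- cfg$simulate$seed %||% cfg$seed
  structure(cfg, class = "run_config")
}
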