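# Per-species contributions to functional diversity and the rare/common
# split.

#' Per-species contribution to functional diversity
#'
#' For each species, site, year and trait set, the contribution is the
#' species' abundance at the site multiplied by the site-year FD value and
#' divided by the total number of individuals across all sites in that
#' year: `z_i = a_i * FD(site, year) / N_year`. Species absent from a site
#' contribute zero (such rows are implicit: only observed counts are
#' returned). Summed over species and sites within a year, contributions
#' equal the abundance-weighted mean FD across sites — the conservation
#' identity the partition relies on.
#'
#' @param counts Long count tibble: `site`, `year`, `species`, `count`.
#' @param fd FD tibble from [fd_table()].
#' @return Tibble: `species`, `site`, `year`, `trait_set`, `count`, `z`.
#' @export
species_contributions <- function(counts, fd) {
  assert_columns(counts, c("site", "year", "species", "count"), "counts")
  assert_columns(fd, c("site", "year", "trait_set", "fd"), "fd table")
  n_year <- counts |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n_year = sum(.data$count), .groups = "drop")
  if (any(n_year$n_year == 0)) {
    abort("a year has zero total abundance; contributions undefined")
  }
  counts |>
    dplyr::filter(.data$count > 0) |>
    dplyr::inner_join(fd, by = c("site", "year"),
                      relationship = "many-to-many") |>
    dplyr::left_join(n_year, by = "year") |>
    dplyr::mutate(z = .data$count * .data$fd / .data$n_year) |>
    dplyr::select("species", "site", "year", "trait_set", "count", "z") |>
    dplyr::arrange(.data$trait_set, .data$year, .data$site, .data$species)
}

#' Classify species as rare or common
#'
#' Per year, each species' total abundance across sites is compared with
#' the mean of those totals: species at or above the mean are common,
#' species below it are rare. Species recorded in the table but absent in
#' a given year enter with total 0. `rule = "site_mean"` instead compares
#' each species' mean abundance per occupied site.
#'
#' @param counts Long count tibble: `site`, `year`, `species`, `count`.
#' @param rule `"year_total"` (default) or `"site_mean"`.
#' @return Tibble: `species`, `year`, `abundance`, `class` with `class` a
#'   factor `rare`/`common`.
#' @export
classify_rarity <- function(counts, rule = c("year_total", "site_mean")) {
  rule <- match.arg(rule)
  assert_columns(counts, c("site", "year", "species", "count"), "counts")
  if (all(counts$count <= 0)) abort("no species with positive abundance")
  filled <- counts |>
    dplyr::filter(.data$count > 0) |>
    tidyr::complete(species = unique(counts$species),
                    year = unique(counts$year),
                    fill = list(count = 0))
  per_species <- filled |>
    dplyr::group_by(.data$year, .data$species) |>
    dplyr::summarise(
      abundance = if (rule == "year_total") sum(.data$count) else {
        if (any(.data$count > 0)) mean(.data$count[.data$count > 0]) else 0
      },
      .groups = "drop_last"
    ) |>
    dplyr::mutate(
      class = factor(ifelse(.data$abundance >= mean(.data$abundance),
                            "common", "rare"),
                     levels = c("rare", "common"))
    ) |>
    dplyr::ungroup()
  dplyr::select(per_species, "species", "year", "abundance", "class")
}

#' Modal rarity class across years
#'
#' Collapses the per-year rare/common classes of [classify_rarity()] to one
#' class per species (the class it held in most years; an exact tie
#' resolves to common, matching the at-or-above-mean boundary rule).
#'
#' @param rarity Output of [classify_rarity()].
#' @return Tibble: `species`, `class`.
#' @export
modal_rarity <- function(rarity) {
  assert_columns(rarity, c("species", "year", "class"), "rarity table")
  rarity |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      class = factor(
        ifelse(mean(.data$class == "common") >= 0.5, "common", "rare"),
        levels = c("rare", "common")),
      .groups = "drop"
    )
}
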