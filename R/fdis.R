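# Abundance-weighted functional dispersion (FDis).

#' Functional dispersion of one assemblage
#'
#' FDis: the abundance-weighted mean distance of species to the
#' abundance-weighted centroid of the assemblage in trait-space
#' coordinates. With centroid `c = sum(a_i x_i) / sum(a_i)` over species
#' with positive weight, returns `sum(a_i ||x_i - c||) / sum(a_i)`
#' (Euclidean norm). Species with zero weight are excluded from both the
#' centroid and the dispersion; the index is invariant to rescaling all
#' weights by a positive constant, and a single-species assemblage has
#' FDis 0.
#'
#' @param weights Non-negative numeric vector of abundances, one per row
#'   of `coords`.
#' @param coords Numeric matrix of species coordinates (species x axes).
#' @return A single non-negative number.
#' @export
#' @examples
#' fdis(c(3, 1), matrix(c(0, 1), ncol = 1))  # centroid 0.75 -> 0.625
fdis <- function(weights, coords) {
  coords <- as.matrix(coords)
  if (length(weights) != nrow(coords)) {
    abort("`weights` must have one entry per row of `coords`")
  }
  if (any(weights < 0)) abort("weights must be non-negative")
  pos <- weights > 0
  if (!any(pos)) abort("all weights are zero: empty assemblage")
  w <- weights[pos]
  x <- coords[pos, , drop = FALSE]
  centroid <- colSums(w * x) / sum(w)
  dist_c <- sqrt(rowSums(sweep(x, 2, centroid)^2))
  sum(w * dist_c) / sum(w)
}

#' Functional dispersion per site, year and trait set
#'
#' Builds one trait space per trait set from the full species pool (so all
#' sites are measured in a common space) and computes FDis for every
#' site-year from the count table. Sites with no individuals in a year get
#' `NA` (logged and excluded from pairwise comparisons downstream); sites
#' with a single species get 0.
#'
#' @param counts Long count tibble: `site`, `year`, `species`, `count`
#'   (absent combinations are zeros).
#' @param traits Trait tibble covering every species in `counts`.
#' @param trait_sets Character vector among `"diet"`, `"strata"`, `"comb"`.
#' @param correction,log_mass,tol Passed to [build_trait_space()].
#' @return Tibble: `site`, `year`, `trait_set`, `fd`.
#' @export
fd_table <- function(counts, traits,
                     trait_sets = c("diet", "strata", "comb"),
                     correction = "none", log_mass = FALSE, tol = 1e-8) {
  assert_columns(counts, c("site", "year", "species", "count"), "counts")
  assert_columns(traits, "species", "trait table")
  trait_sets <- match.arg(trait_sets, several.ok = TRUE)
  orphans <- setdiff(unique(counts$species), traits$species)
  if (length(orphans) > 0) {
    abort(paste0("species in counts but not in trait table: ",
                 paste(orphans, collapse = ", ")))
  }

  spaces <- lapply(stats::setNames(trait_sets, trait_sets), function(s) {
    build_trait_space(traits, s, correction = correction,
                      log_mass = log_mass, tol = tol)
  })

  site_years <- counts |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$site, .data$year)

  per_set <- purrr::map(trait_sets, function(s) {
    coords <- spaces[[s]]$coordinates
    site_years |>
      dplyr::summarise(
        fd = fdis(.data$count,
                  coords[match(.data$species, rownames(coords)), ,
                         drop = FALSE]),
        .groups = "drop"
      ) |>
      dplyr::mutate(trait_set = s)
  })

  out <- dplyr::bind_rows(per_set) |>
    dplyr::select("site", "year", "trait_set", "fd")
  # make empty site-years explicit as missing FD
  all_sites <- unique(counts$site)
  full <- tidyr::expand_grid(site = all_sites,
                             year = sort(unique(counts$year)),
                             trait_set = trait_sets)
  out <- dplyr::left_join(full, out, by = c("site", "year", "trait_set"))
  n_empty <- sum(is.na(out$fd)) / length(trait_sets)
  if (n_empty > 0) {
    inform(sprintf("%d empty site-year(s): FD recorded as missing", n_empty))
  }
  dplyr::arrange(out, .data$trait_set, .data$year, .data$site)
}
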