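# Small fixtures built in code, shared across test files.

# canonical trait tibble with all percent blocks valid; deterministic
make_traits <- function(n = 6, seed = 42) {
  generate_traits(sim_config(n_species = n, n_sites = 2, seed = seed))
}

# hand-sized long count tibble: `mat` is sites x species, one year
counts_from_matrix <- function(mat, year = 1) {
  tibble::as_tibble(as.data.frame.table(mat, responseName = "count",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("site", "species", "count")) |>
    dplyr::mutate(year = year, .after = "site") |>
    dplyr::filter(count > 0)
}

# 5 sites x 6 species, chosen so sites differ in richness and composition
fixture_counts <- function() {
  mat <- matrix(
    c(3, 1, 0, 2, 0, 1,
      0, 2, 2, 0, 1, 0,
      1, 1, 1, 1, 1, 1,
      5, 0, 0, 0, 2, 0,
      0, 0, 3, 1, 0, 2),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("s", 1:5), paste0("sp", 1:6))
  )
  counts_from_matrix(mat)
}

fixture_traits <- function() {
  tr <- make_traits(n = 6, seed = 9)
  tr$species <- paste0("sp", 1:6)
  tr
}

# independent scalar FDis: direct evaluation of the two-term definition
naive_fdis <- function(weights, coords) {
  keep <- weights > 0
  w <- weights[keep]
  x <- coords[keep, , drop = FALSE]
  cen <- colSums(w * x) / sum(w)
  d <- apply(x, 1, function(r) sqrt(sum((r - cen)^2)))
  sum(w * d) / sum(w)
}
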