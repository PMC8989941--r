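# Five-component Price-equation partition of pairwise FD differences.
#
# For a baseline site with s species (mean contribution zbar) and a
# comparison site with s' species (mean zbar'), sharing s_c species with
# shared-species means zbar_c / zbar'_c:
#   rich_l = (s_c - s)  * zbar          random species loss      (<= 0)
#   comp_l = s_c * (zbar_c - zbar)      non-random species loss
#   rich_g = (s' - s_c) * zbar'         random species gain      (>= 0)
#   comp_g = -s_c * (zbar'_c - zbar')   non-random species gain
#   abun   = sum over shared (z'_i - z_i)   abundance of shared species
# The five terms sum to sum(z') - sum(z) = FD' - FD exactly.

#' Price partition of one site pair
#'
#' Partitions the difference in total species contributions between a
#' baseline and a comparison assemblage into five additive components:
#' random species losses (`rich_l`), non-random species losses (`comp_l`),
#' random species gains (`rich_g`), non-random species gains (`comp_g`)
#' and abundance change of shared species (`abun`). These carry the field's
#' usual labels RICH_L, COMP_L, RICH_G, COMP_G and ABUN (context
#' dependence). Presence is defined by a positive contribution.
#'
#' @param z_baseline,z_comparison Named numeric vectors mapping species to
#'   their contribution `z` at the baseline / comparison site; species with
#'   `z > 0` count as present.
#' @return One-row tibble: `s`, `s_prime`, `s_c`, the five components,
#'   `delta_fd` (their sum, equal to `sum(z') - sum(z)`), and the two
#'   cumulative sums `rich_l_comp_l` and `rich_g_comp_g`.
#' @export
#' @examples
#' price_components(c(A = 0.1, B = 0.2, C = 0.3),
#'                  c(B = 0.25, C = 0.35, D = 0.4))
price_components <- function(z_baseline, z_comparison) {
  if (is.null(names(z_baseline)) || is.null(names(z_comparison))) {
    abort("contribution vectors must be named by species")
  }
  zb <- z_baseline[z_baseline > 0]
  zc <- z_comparison[z_comparison > 0]
  if (length(zb) == 0 || length(zc) == 0) {
    abort("both sites must have at least one present species")
  }
  shared <- intersect(names(zb), names(zc))
  s <- length(zb)
  s_prime <- length(zc)
  s_c <- length(shared)
  zbar <- mean(zb)
  zbar_p <- mean(zc)
  rich_l <- (s_c - s) * zbar
  rich_g <- (s_prime - s_c) * zbar_p
  if (s_c > 0) {
    comp_l <- s_c * (mean(zb[shared]) - zbar)
    comp_g <- -s_c * (mean(zc[shared]) - zbar_p)
    abun <- sum(zc[shared] - zb[shared])
  } else {
    comp_l <- 0
    comp_g <- 0
    abun <- 0
  }
  tibble::tibble(
    s = s, s_prime = s_prime, s_c = s_c,
    rich_l = rich_l, comp_l = comp_l, rich_g = rich_g, comp_g = comp_g,
    abun = abun,
    delta_fd = rich_l + comp_l + rich_g + comp_g + abun,
    rich_l_comp_l = rich_l + comp_l,
    rich_g_comp_g = rich_g + comp_g
  )
}

#' Price partition over site pairs
#'
#' Computes the five-component partition for ordered site pairs within
#' each year and trait set (pairs are never formed across years or trait
#' sets: FD and the yearly total abundance are year-specific). The default
#' scheme visits every ordered pair of non-empty sites; `"random_pairs"`
#' draws `n_pairs` ordered pairs uniformly without replacement under a
#' seed, mirroring repeated random pairwise comparison.
#'
#' The pairwise records are computed by a vectorized matrix formulation;
#' [price_components()] is the same arithmetic one pair at a time.
#'
#' @param contributions Tibble from [species_contributions()]; presence is
#'   `count > 0`.
#' @param scheme `"all_ordered"` (default) or `"random_pairs"`.
#' @param n_pairs Number of ordered pairs to draw per year and trait set
#'   when `scheme = "random_pairs"`.
#' @param seed Seed for the random pair draw.
#' @return Tibble: `year`, `trait_set`, `baseline`, `comparison`, `s`,
#'   `s_prime`, `s_c`, the five components, `delta_fd`, and the cumulative
#'   sums (see [price_components()]).
#' @export
price_all_pairs <- function(contributions,
                            scheme = c("all_ordered", "random_pairs"),
                            n_pairs = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  assert_columns(contributions,
                 c("species", "site", "year", "trait_set", "count", "z"),
                 "contributions")
  if (scheme == "random_pairs") {
    if (is.null(n_pairs)) abort("`n_pairs` is required for random_pairs")
    if (!is.null(seed)) set.seed(op_seed(seed, "pairs"))
  }

  groups <- contributions |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$year, .data$trait_set)

  dplyr::group_map(groups, function(df, key) {
    z_wide <- df |>
      dplyr::select("site", "species", "z") |>
      tidyr::pivot_wider(names_from = "species", values_from = "z",
                         values_fill = 0)
    sites <- z_wide$site
    if (length(sites) < 2) {
      abort(sprintf("year %s needs at least 2 non-empty sites",
                    as.character(key$year)))
    }
    z_mat <- as.matrix(z_wide[-1])
    p_wide <- df |>
      dplyr::select("site", "species", "count") |>
      tidyr::pivot_wider(names_from = "species", values_from = "count",
                         values_fill = 0)
    p_mat <- (as.matrix(p_wide[-1]) > 0) * 1

    pair_idx <- which(outer(seq_along(sites), seq_along(sites), "!="),
                      arr.ind = TRUE)
    if (scheme == "random_pairs") {
      if (n_pairs > nrow(pair_idx)) {
        abort(sprintf(
          "n_pairs = %d exceeds the %d available ordered pairs",
          n_pairs, nrow(pair_idx)))
      }
      pair_idx <- pair_idx[sample.int(nrow(pair_idx), n_pairs), ,
                           drop = FALSE]
    }
    a <- pair_idx[, 1]
    b <- pair_idx[, 2]

    s_vec <- rowSums(p_mat)
    t_vec <- rowSums(z_mat)
    sc_mat <- p_mat %*% t(p_mat)          # shared species counts
    zc_base <- z_mat %*% t(p_mat)         # sum of baseline z over shared
    zc_comp <- p_mat %*% t(z_mat)         # sum of comparison z over shared

    s_c <- sc_mat[pair_idx]
    zbar <- t_vec[a] / s_vec[a]
    zbar_p <- t_vec[b] / s_vec[b]
    sum_zc <- zc_base[pair_idx]
    sum_zcp <- zc_comp[pair_idx]
    has_shared <- s_c > 0
    comp_l <- ifelse(has_shared, sum_zc - s_c * zbar, 0)
    comp_g <- ifelse(has_shared, -(sum_zcp - s_c * zbar_p), 0)
    abun <- ifelse(has_shared, sum_zcp - sum_zc, 0)
    rich_l <- (s_c - s_vec[a]) * zbar
    rich_g <- (s_vec[b] - s_c) * zbar_p

    tibble::tibble(
      year = key$year, trait_set = key$trait_set,
      baseline = sites[a], comparison = sites[b],
      s = s_vec[a], s_prime = s_vec[b], s_c = s_c,
      rich_l = rich_l, comp_l = comp_l, rich_g = rich_g, comp_g = comp_g,
      abun = abun,
      delta_fd = rich_l + comp_l + rich_g + comp_g + abun,
      rich_l_comp_l = rich_l + comp_l,
      rich_g_comp_g = rich_g + comp_g
    )
  }) |>
    dplyr::bind_rows()
}

#' Summarise Price components across pairs
#'
#' Mean, standard deviation and pair count of each component per trait
#' set, plus the mean scaled by the mean absolute FD difference
#' (`mean_scaled`), since "relative contribution" can be read either way.
#'
#' @param pairs Tibble from [price_all_pairs()].
#' @return Long tibble: `trait_set`, `component`, `mean`, `sd`, `n`,
#'   `mean_scaled`.
#' @export
price_summary <- function(pairs) {
  comp_cols <- c(COMPONENT_NAMES, "rich_l_comp_l", "rich_g_comp_g",
                 "delta_fd")
  assert_columns(pairs, c("trait_set", comp_cols), "pairs")
  pairs |>
    dplyr::group_by(.data$trait_set) |>
    dplyr::group_modify(function(df, key) {
      scale <- mean(abs(df$delta_fd))
      df |>
        tidyr::pivot_longer(dplyr::all_of(comp_cols),
                            names_to = "component", values_to = "value") |>
        dplyr::group_by(.data$component) |>
        dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                         n = dplyr::n(), .groups = "drop") |>
        dplyr::mutate(mean_scaled = .data$mean / scale)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(component = factor(.data$component, levels = comp_cols)) |>
    dplyr::arrange(.data$trait_set, .data$component)
}

#' Per-site mean Price components
#'
#' Averages each component over all pairs in which a site is the
#' comparison site, within year and trait set. Gains and losses in the
#' partition are framed from the comparison site's perspective, so this is
#' the site-level response modelled against per-site environmental
#' covariates.
#'
#' @param pairs Tibble from [price_all_pairs()].
#' @return Tibble: `site`, `year`, `trait_set`, mean of each component and
#'   of `delta_fd`.
#' @export
price_site_means <- function(pairs) {
  assert_columns(pairs, c("year", "trait_set", "comparison",
                          COMPONENT_NAMES, "delta_fd"), "pairs")
  pairs |>
    dplyr::group_by(site = .data$comparison, .data$year, .data$trait_set) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c(COMPONENT_NAMES, "rich_l_comp_l",
                                    "rich_g_comp_g", "delta_fd")), mean),
      n_pairs = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$trait_set, .data$year, .data$site)
}
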