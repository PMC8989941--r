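# ggplot2 views of the main result types.

#' Plot Price component distributions
#'
#' Point-range plot (mean +/- sd across pairs) of the five Price
#' components and the two cumulative sums, per trait set — the usual way
#' to display the relative contribution of species losses, gains and
#' shared-species abundance change to the FD difference.
#'
#' @param pairs Tibble from [price_all_pairs()].
#' @return A ggplot object.
#' @export
plot_price_components <- function(pairs) {
  smry <- price_summary(pairs) |>
    dplyr::filter(.data$component != "delta_fd")
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$component, y = .data$mean,
                                     colour = .data$trait_set)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL, y = "contribution to ΔFD",
                  colour = "trait set") +
    ggplot2::theme_minimal()
}

#' Plot species abundance against contribution to FD
#'
#' Species ordered by ascending yearly abundance, with their mean
#' contribution to FD overlaid and the rare/common split marked.
#'
#' @param contributions Tibble from [species_contributions()].
#' @param rarity Tibble from [classify_rarity()].
#' @param trait_set Trait set to display (default `"comb"`, falling back
#'   to the first available).
#' @return A ggplot object.
#' @export
plot_species_contributions <- function(contributions, rarity,
                                       trait_set = "comb") {
  sets <- unique(contributions$trait_set)
  if (!trait_set %in% sets) trait_set <- sets[1]
  z_sp <- contributions |>
    dplyr::filter(.data$trait_set == !!trait_set) |>
    dplyr::group_by(.data$species, .data$year) |>
    dplyr::summarise(z = mean(.data$z), .groups = "drop")
  dat <- rarity |>
    dplyr::left_join(z_sp, by = c("species", "year")) |>
    dplyr::mutate(z = dplyr::coalesce(.data$z, 0)) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(abundance = mean(.data$abundance), z = mean(.data$z),
                     class = .data$class[1], .groups = "drop") |>
    dplyr::arrange(.data$abundance) |>
    dplyr::mutate(rank = dplyr::row_number())
  scale_f <- max(dat$abundance) / max(max(dat$z), 1e-12)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$abundance, fill = .data$class),
                      alpha = 0.7) +
    ggplot2::geom_point(ggplot2::aes(y = .data$z * scale_f)) +
    ggplot2::scale_y_continuous(
      "mean abundance per year",
      sec.axis = ggplot2::sec_axis(~ . / scale_f, name = "contribution to FD")
    ) +
    ggplot2::labs(x = "species (ascending abundance)", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a fitted component-covariate effect
#'
#' Scatter of the site-year component values against the covariate with
#' the fixed-effect line of the mixed model.
#'
#' @param object An `"fd_lmm"` from [fit_component_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fd_lmm <- function(object, ...) {
  dat <- object$data
  fe <- if (inherits(object$model, "lm")) coef(object$model) else
    lme4::fixef(object$model)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$.x, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$year)),
                        alpha = 0.7) +
    ggplot2::geom_abline(intercept = fe[[1]], slope = fe[[2]]) +
    ggplot2::labs(
      x = object$covariate,
      y = paste0(object$component,
                 if (!is.na(object$trait_set)) paste0(" (", object$trait_set,
                                                      ")")),
      colour = "year") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
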