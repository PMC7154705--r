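#' Plot a fitted logistic NPP-biomass relationship
#'
#' Fit points with the fitted parabola overlaid; the vertex at `K/2` marks
#' the density of maximum NPP.
#'
#' @param object A `logistic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot logistic_fit
#' @export
autoplot.logistic_fit <- function(object, ...) {
  pts <- object$points
  curve <- tibble(
    biomass_c = seq(0, max(pts$biomass_c) * 1.05, length.out = 200)
  ) %>%
    mutate(npp_c = object$r * .data$biomass_c *
             (1 - .data$biomass_c / object$K))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$biomass_c, y = .data$npp_c)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(
      x = "standing biomass (t C/ha)", y = "NPP (t C/ha/yr)",
      title = sprintf("r = %.3f /yr, K = %.0f t C/ha", object$r, object$K)
    ) +
    ggplot2::theme_minimal()
}

#' Plot simulated carbon stocks and density
#'
#' @param object A `craft_run`.
#' @param what `"stocks"` for total carbon per compartment (t C),
#'   `"density"` for per-hectare trajectories by group, or `"fluxes"` for
#'   the annual biomass fluxes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot craft_run
#' @export
autoplot.craft_run <- function(object, what = c("stocks", "density",
                                                "fluxes"), ...) {
  what <- match.arg(what)
  a <- object$annual
  if (what == "stocks") {
    df <- a %>%
      group_by(.data$year) %>%
      summarise(biomass = sum(.data$density * .data$area),
                litter = sum(.data$litter_total * .data$area),
                soil = sum(.data$soc * .data$area)) %>%
      tidyr::pivot_longer(-"year", names_to = "compartment",
                          values_to = "stock")
    ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$stock,
                                     fill = .data$compartment)) +
      ggplot2::geom_area() +
      ggplot2::labs(x = NULL, y = "C stock (t C)",
                    title = paste0(object$region_id, " (", object$mode,
                                   ")")) +
      ggplot2::theme_minimal()
  } else if (what == "density") {
    df <- a %>%
      select("year", "group", biomass = "density", soil = "soc",
             litter = "litter_total") %>%
      tidyr::pivot_longer(c("biomass", "soil", "litter"),
                          names_to = "compartment", values_to = "density")
    ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$density,
                                     colour = .data$group)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~compartment, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "t C/ha") +
      ggplot2::theme_minimal()
  } else {
    df <- a %>%
      select("year", "group", "npp", "gai", "mortality",
             "harvest_total") %>%
      tidyr::pivot_longer(c("npp", "gai", "mortality", "harvest_total"),
                          names_to = "flux", values_to = "value")
    ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$value,
                                     colour = .data$flux)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~group) +
      ggplot2::labs(x = NULL, y = "t C/ha/yr") +
      ggplot2::theme_minimal()
  }
}

#' Plot an LMDI driver decomposition
#'
#' Interval bars of the area, species-composition and density
#' contributions, with the net stock change overlaid as points.
#'
#' @param decomposition A tibble from [chain_decomposition()].
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition) {
  df <- decomposition %>%
    mutate(label = paste0(.data$year0, "-", .data$year1)) %>%
    tidyr::pivot_longer(c("delta_area", "delta_composition",
                          "delta_density"),
                        names_to = "driver", values_to = "contribution") %>%
    mutate(driver = sub("delta_", "", .data$driver))
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$contribution,
                                   fill = .data$driver)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(ggplot2::aes(y = .data$delta_b), colour = "black",
                        show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "contribution to biomass C change (t C)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
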