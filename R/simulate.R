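#' Run the coupled forest biomass and soil carbon simulation
#'
#' Full annual-step reconstruction for one region: climate forcing is
#' rebuilt from the reference climatology and the temperature-anomaly
#' series, standing biomass follows the logistic balance, and the litter
#' and humus pools receive natural mortality and felling residues, lose
#' carbon to mineralisation (climate-dependent rates) and to historical
#' litter raking, and are mixed with agricultural soil carbon where forest
#' expanded onto former agricultural land. Both the biomass and the soil
#' state start at the equilibrium implied by the first year's forcing.
#'
#' @inheritParams run_biomass
#' @param sp A [soil_params()] registry.
#' @param raking A function `year -> fraction` of foliage-litter input
#'   removed (default [raking_fraction()]); use `function(y) 0` to disable.
#' @return An object of class `craft_run`; its `$annual` element is a
#'   tibble with one row per year and group holding the biomass columns of
#'   [run_biomass()] plus the four litter pools, `humus_fast`,
#'   `humus_slow`, `soc` (t C/ha), `soil_co2` and `raked`
#'   (t C ha-1 yr-1).
#' @export
run_craft <- function(dataset, params, modifiers = growth_modifiers(),
                      mode = c("dynamic", "static"),
                      registry = organ_registry(), sp = soil_params(),
                      raking = raking_fraction) {
  mode <- match.arg(mode)
  forcing <- reconstruct_forcing(dataset$climatology, dataset$anomaly,
                                 dataset$latitude)
  bio <- run_biomass(dataset, params, modifiers, mode, registry)
  years <- dataset$years
  ny <- length(years)
  rak <- raking(years)
  eps <- dataset$epsilon$value
  ag <- dataset$ag_soc

  annual <- purrr::map_dfr(unique(bio$group), function(g) {
    bg <- bio %>% filter(.data$group == g) %>% arrange(.data$year)
    org <- registry$organs[registry$organs$group == g, ]
    # annual litter input per pool: natural mortality + felling residues,
    # mapped organ -> pool
    inputs <- matrix(0, nrow = ny, ncol = length(LITTER_POOLS),
                     dimnames = list(NULL, LITTER_POOLS))
    for (o in org$organ) {
      pool <- sp$organ_pools[[o]]
      inputs[, pool] <- inputs[, pool] +
        bg[[paste0("mort_", o)]] + bg[[paste0("res_", o)]]
    }
    eq <- equilibrium_soil(inputs[1, ], forcing$temperature[1],
                           forcing$moisture[1], rak[1], sp)
    litter <- matrix(0, nrow = ny, ncol = length(LITTER_POOLS),
                     dimnames = list(NULL, LITTER_POOLS))
    humus <- matrix(0, nrow = ny, ncol = 2,
                    dimnames = list(NULL, c("fast", "slow")))
    co2 <- numeric(ny); raked <- numeric(ny)
    litter[1, ] <- eq$litter
    humus[1, ] <- eq$humus
    for (t in seq_len(ny - 1)) {
      st <- step_soil(litter[t, ], humus[t, ], inputs[t, ],
                      forcing$temperature[t], forcing$moisture[t],
                      rak[t], sp)
      co2[t] <- st$co2; raked[t] <- st$raked
      lit <- st$litter
      hum <- st$humus
      if (eps[t] > 0) {
        # converted agricultural land brings its humus but no litter
        lit <- apply_landuse_mixing(lit, numeric(0), eps[t])
        hum <- apply_landuse_mixing(
          hum, c(fast = ag$fast[t], slow = ag$slow[t]), eps[t])
      }
      litter[t + 1, ] <- lit
      humus[t + 1, ] <- hum
    }
    dplyr::bind_cols(
      bg,
      as_tibble(litter) %>% setNames(paste0("litter_", LITTER_POOLS)),
      tibble(humus_fast = humus[, "fast"], humus_slow = humus[, "slow"],
             soc = humus[, "fast"] + humus[, "slow"],
             litter_total = rowSums(litter),
             soil_co2 = co2, raked = raked)
    )
  })
  annual <- annual %>%
    mutate(ecosystem_density = .data$density + .data$litter_total + .data$soc,
           ecosystem_stock = .data$ecosystem_density * .data$area)
  structure(list(annual = annual, region_id = dataset$region_id,
                 mode = mode, params = as_tibble(params),
                 modifiers = modifiers, forcing = forcing),
            class = "craft_run")
}

#' @export
print.craft_run <- function(x, ...) {
  a <- x$annual
  y0 <- min(a$year); y1 <- max(a$year)
  tot <- function(y) sum(a$ecosystem_stock[a$year == y])
  cat("<craft_run> ", x$region_id, " ", y0, "-", y1,
      " (", x$mode, ")\n", sep = "")
  cat(sprintf("  ecosystem C stock: %.3g -> %.3g t C (%+.0f%%)\n",
              tot(y0), tot(y1), 100 * (tot(y1) / tot(y0) - 1)))
  invisible(x)
}

#' @rdname run_craft
#' @param x A `craft_run`.
#' @param ... Unused.
#' @method tidy craft_run
#' @export
tidy.craft_run <- function(x, ...) x$annual

#' @rdname run_craft
#' @method glance craft_run
#' @export
glance.craft_run <- function(x, ...) {
  a <- x$annual
  y0 <- min(a$year); y1 <- max(a$year)
  at <- function(col, y) sum(a[[col]][a$year == y] * a$area[a$year == y])
  tibble(
    region = x$region_id, mode = x$mode, start_year = y0, end_year = y1,
    biomass_stock_start = at("density", y0),
    biomass_stock_end = at("density", y1),
    soc_stock_start = at("soc", y0),
    soc_stock_end = at("soc", y1),
    ecosystem_stock_start = sum(a$ecosystem_stock[a$year == y0]),
    ecosystem_stock_end = sum(a$ecosystem_stock[a$year == y1])
  )
}
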