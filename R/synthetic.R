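#' Configuration for the synthetic-region generator
#'
#' Defines a self-contained synthetic region with known ground truth,
#' emulating the structure of the historical inputs: sparse census-year
#' observations of forest area and commercial harvest per species group,
#' species- and class-stratified production tables, a temperate monthly
#' climatology with a 20th-century warming anomaly, agricultural
#' soil-carbon series and a small agricultural-conversion episode.
#'
#' Defaults describe a mid-latitude western European region: carrying
#' capacities of 180 (deciduous) and 140 (coniferous) t C/ha with intrinsic
#' growth rates 0.12 and 0.16 /yr (peak stand NPP near 5.5 t C ha-1 yr-1),
#' forest expanding by about half over 1850-2015, commercial extraction
#' near 0.4-0.55 t C ha-1 yr-1, and growth conditions improving after the
#' reference era (anchor scales 1 and 0.85 in 1850, 1.15 and 1.35 in 2015,
#' for deciduous and coniferous). Production tables and inventory targets
#' are noiseless by default because the sources they emulate are published
#' deterministic tables and inventory point estimates; `table_noise` and
#' `inventory_noise` (relative standard deviations) support sensitivity
#' experiments.
#'
#' @param seed Integer seed; fully determines every generated artifact.
#' @param years Simulation years.
#' @param true_r,true_K Named per-group true logistic parameters.
#' @param true_s0,true_s1 Named per-group true modifier anchors (on the 5%
#'   grid if exact grid recovery is wanted).
#' @param class_multipliers Carrying-capacity multipliers per productivity
#'   class (class 1 = poorest site).
#' @param true_class_weights Named list of integer class-weight vectors per
#'   group (the true area distribution across classes).
#' @param latitude Region latitude (degrees).
#' @param harvest_level Multiplier on the commercial-harvest trajectory
#'   (default 1; 0 gives an unharvested forest).
#' @param table_noise,inventory_noise Relative noise (sd) on table values
#'   and inventory targets; 0 by default.
#' @param target_years Inventory census years.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    years = 1850:2015,
    true_r = c(deciduous = 0.12, coniferous = 0.16),
    true_K = c(deciduous = 180, coniferous = 140),
    true_s0 = c(deciduous = 1.00, coniferous = 0.85),
    true_s1 = c(deciduous = 1.15, coniferous = 1.35),
    class_multipliers = c(0.70, 0.85, 1.00, 1.15),
    true_class_weights = list(deciduous = c(0, 0, 1, 4),
                              coniferous = c(0, 1, 1, 8)),
    latitude = 46,
    harvest_level = 1,
    table_noise = 0, inventory_noise = 0,
    target_years = c(1985, 1998, 2011)) {
  stopifnot(table_noise >= 0, inventory_noise >= 0, harvest_level >= 0)
  structure(
    list(seed = as.integer(seed), years = years, true_r = true_r,
         true_K = true_K, true_s0 = true_s0, true_s1 = true_s1,
         class_multipliers = class_multipliers,
         true_class_weights = true_class_weights, latitude = latitude,
         harvest_level = harvest_level,
         table_noise = table_noise, inventory_noise = inventory_noise,
         target_years = target_years),
    class = "synthetic_config"
  )
}

# Census years emulating sparse 19th-century statistics then regular yearbooks
synthetic_census_years <- function(years) {
  cand <- c(1862, 1878, 1882, 1892, 1908, 1910, 1915, 1920, 1925, 1929,
            1935, 1940, 1945, seq(1950, 2015, by = 5))
  sort(unique(pmin(pmax(cand[cand >= min(years) & cand <= max(years)],
                        min(years)), max(years))))
}

#' Generate a synthetic region with known ground truth
#'
#' The ground truth is the landscape-scale logistic NPP-biomass relation
#' per productivity class. Stand age curves take their biomass shape from
#' the closed-form stand growth law `db/da = r b (1 - b/K_c) - m b`; the
#' tabulated increments are then chosen so that every rotation-age mosaic
#' (equal-weight mean over ages 1..rt) lies exactly on the true logistic
#' relation, and biomass is converted back to exploitable-wood volume
#' through the organ registry. The whole parameterisation pipeline (carbon
#' conversion, rotation averaging, logistic fit) is therefore exactly
#' invertible on these tables; real yield tables satisfy no such identity.
#' Inventory targets are produced by running the biomass model forward with
#' the true parameters and modifiers. All randomness (only active when a
#' noise level is positive) derives from the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @param registry An [organ_registry()].
#' @return A list with elements `dataset` (a [regional_dataset()]),
#'   `tables` (tibble `species, group, productivity_class, age, volume,
#'   increment`), `targets` (tibble `year, group, stock`), and `truth`
#'   (true regional parameters, anchors and class weights).
#' @export
generate_synthetic_region <- function(cfg, registry = organ_registry()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)
  years <- cfg$years
  census <- synthetic_census_years(years)
  frac <- (census - min(years)) / (max(years) - min(years))

  # --- forcing series (sparse observations, as the archives report them)
  area_obs <- bind_rows(
    tibble(year = census, group = "deciduous",
           value = 3e5 * (1 + 0.50 * frac^1.3)),
    tibble(year = census, group = "coniferous",
           value = 1e5 * (1 + 1.50 * frac))
  )
  # commercial extraction per hectare: 19th-century peak then decline
  h_dec <- 0.45 + 0.10 * exp(-((census - 1900) / 35)^2) - 0.10 * frac
  h_con <- 0.55 + 0.10 * exp(-((census - 1900) / 35)^2) - 0.12 * frac
  harvest_obs <- bind_rows(
    tibble(year = census, group = "deciduous",
           value = h_dec * area_obs$value[area_obs$group == "deciduous"]),
    tibble(year = census, group = "coniferous",
           value = h_con * area_obs$value[area_obs$group == "coniferous"])
  ) %>%
    mutate(value = .data$value * cfg$harvest_level)
  anomaly <- tibble(year = years,
                    value = pmax(0, (years - 1920) / (2015 - 1920)) * 1.0)
  climatology <- tibble(month = 1:12,
                        temperature = 11 + 7.5 * sin((1:12 - 4) * pi / 6),
                        precipitation = c(65, 55, 60, 65, 75, 65, 55, 60,
                                          70, 80, 75, 70))
  ag_soc <- tibble(year = c(min(years), max(years)),
                   fast = c(28, 33), slow = c(22, 24))
  epsilon <- tibble(year = years,
                    value = ifelse(years >= 1950 & years <= 2000, 0.002, 0))
  dataset <- regional_dataset(
    region_id = paste0("synthetic-", cfg$seed), latitude = cfg$latitude,
    years = years, area = area_obs, harvest = harvest_obs,
    anomaly = anomaly, climatology = climatology, ag_soc = ag_soc,
    epsilon = epsilon)

  # --- production tables from the closed-form stand trajectory
  ages <- 1:150
  tables <- purrr::map_dfr(SPECIES_GROUPS, function(g) {
    org <- registry$organs[registry$organs$group == g, ]
    exp_share <- sum(org$share[org$extracted])
    dens <- registry$wood_density[[g]]
    cf <- registry$carbon_fraction
    m <- mortality_rate(registry, g)
    r <- cfg$true_r[[g]]
    purrr::map_dfr(seq_along(cfg$class_multipliers), function(cl) {
      K <- cfg$true_K[[g]] * cfg$class_multipliers[cl]
      keff <- K * (1 - m / r)
      b0 <- 0.02 * keff
      cc <- keff / b0 - 1
      b <- keff / (1 + cc * exp(-(r - m) * ages))
      # stand NPP series whose running means land the rotation-age mosaic
      # exactly on the true landscape relation NPP = r B (1 - B/K)
      bbar <- cumsum(b) / ages
      nbar <- r * bbar * (1 - bbar / K)
      npp <- diff(c(0, ages * nbar))
      vol <- b * exp_share / (dens * cf)
      inc <- pmax(0, npp - m * b) * exp_share / (dens * cf)
      if (cfg$table_noise > 0) {
        vol <- vol * exp(stats::rnorm(length(vol), 0, cfg$table_noise))
        inc <- inc * exp(stats::rnorm(length(inc), 0, cfg$table_noise))
      }
      tibble(species = paste0(g, "_sp"), group = g,
             productivity_class = cl, age = ages,
             volume = vol, increment = inc)
    })
  })

  # --- true regional parameters and inventory targets
  w_norm <- purrr::imap_dfr(cfg$true_class_weights, function(w, g) {
    tibble(group = g, productivity_class = seq_along(w),
           weight = w / sum(w))
  })
  truth_params <- w_norm %>%
    mutate(K_c = cfg$true_K[.data$group] *
             cfg$class_multipliers[.data$productivity_class],
           r_c = cfg$true_r[.data$group]) %>%
    group_by(.data$group) %>%
    summarise(r = sum(.data$weight * .data$r_c),
              K = sum(.data$weight * .data$K_c))
  true_mods <- growth_modifiers(cfg$true_s0, cfg$true_s1,
                                start_year = min(years),
                                end_year = max(years))
  traj <- run_biomass(dataset, truth_params, true_mods, mode = "dynamic",
                      registry = registry)
  targets <- traj %>%
    filter(.data$year %in% cfg$target_years) %>%
    select("year", "group", "stock")
  if (cfg$inventory_noise > 0) {
    targets$stock <- targets$stock *
      exp(stats::rnorm(nrow(targets), 0, cfg$inventory_noise))
  }
  list(dataset = dataset, tables = tables, targets = targets,
       truth = list(params = truth_params, s0 = cfg$true_s0,
                    s1 = cfg$true_s1,
                    class_weights = cfg$true_class_weights,
                    modifiers = true_mods))
}

#' Fit growth parameters from synthetic (or real) production tables
#'
#' Convenience pipeline: each species/class table is converted to carbon,
#' rotation-averaged over a range of rotation times and fitted; the result
#' feeds [regional_params()] or [calibrate_class_distribution()].
#'
#' @param tables A tibble as in [generate_synthetic_region()]'s `tables`.
#' @param rts Rotation times used as fit points (default `20:120`).
#' @param registry An [organ_registry()].
#' @return A tibble `species, group, productivity_class, r, K,
#'   fit_residual`.
#' @export
fit_production_tables <- function(tables, rts = 20:120,
                                  registry = organ_registry()) {
  tables %>%
    group_by(.data$species, .data$group, .data$productivity_class) %>%
    dplyr::group_modify(function(df, key) {
      cc <- stand_to_carbon(df[, c("age", "volume", "increment")],
                            key$group, registry)
      pts <- rotation_points(cc, rts)
      fit <- fit_logistic(pts %>%
                            select("biomass_c", "npp_c"))
      tibble(r = fit$r, K = fit$K, fit_residual = fit$fit_residual)
    }) %>%
    ungroup()
}
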