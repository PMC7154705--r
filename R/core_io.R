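#' Fill a sparse annual series by linear interpolation
#'
#' Historical forestry statistics report area and harvest only for scattered
#' census years; the simulation needs every year. Values between the two
#' closest documented years are linearly interpolated; years outside the
#' observed span are filled by constant extrapolation from the nearest
#' observed value. Observed values are preserved exactly and every filled
#' point is flagged.
#'
#' @param series A data frame with columns `year` and `value` (observed
#'   points; years strictly increasing).
#' @param years Integer vector of years to cover (typically a full span,
#'   e.g. `1850:2015`).
#' @return A tibble with columns `year`, `value`, `provenance`
#'   (`"observed"` or `"interpolated"`), one row per requested year.
#' @examples
#' interpolate_annual(data.frame(year = c(1900, 1910), value = c(10, 20)),
#'                    1900:1910)
#' @export
interpolate_annual <- function(series, years) {
  series <- as_tibble(series)
  if (nrow(series) == 0) abort("cannot interpolate an empty series")
  if (anyDuplicated(series$year) || is.unsorted(series$year, strictly = TRUE)) {
    series <- series %>% arrange(.data$year)
    if (anyDuplicated(series$year)) abort("duplicate observation years")
  }
  years <- sort(unique(as.integer(years)))
  if (nrow(series) == 1) {
    warn("single observed point: filling the whole span with a constant")
    out <- tibble(year = years, value = series$value[[1]])
  } else {
    out <- tibble(
      year = years,
      value = approx(series$year, series$value, xout = years, rule = 2)$y
    )
  }
  out$provenance <- ifelse(out$year %in% series$year, "observed", "interpolated")
  # exactness at observed years (approx can introduce fp noise)
  idx <- match(series$year, out$year)
  ok <- !is.na(idx)
  out$value[idx[ok]] <- series$value[ok]
  out
}

#' Split a total series into species groups by interpolated shares
#'
#' Some census years report only the total forest area or harvest without
#' the deciduous/coniferous breakdown. Group shares observed at the years
#' where the split is documented are linearly interpolated (nearest share
#' carried constant beyond the ends) and applied to the total, so the group
#' series sum back to the total in every year.
#'
#' @param total A data frame with columns `year`, `value`: the annualised
#'   total series (see [interpolate_annual()]).
#' @param shares A data frame with columns `year`, `group`, `share`: group
#'   shares at the documented years; shares must sum to 1 across groups at
#'   each year.
#' @param tol Tolerance on the share sum (default 1e-8).
#' @return A tibble with columns `year`, `group`, `value`.
#' @export
split_groups <- function(total, shares, tol = 1e-8) {
  total <- as_tibble(total)
  shares <- as_tibble(shares)
  bad <- shares %>%
    group_by(.data$year) %>%
    summarise(s = sum(.data$share)) %>%
    filter(abs(.data$s - 1) > tol)
  if (nrow(bad) > 0) {
    abort(paste0("group shares do not sum to 1 at year(s): ",
                 paste(bad$year, collapse = ", ")))
  }
  if (any(shares$share < -tol | shares$share > 1 + tol)) {
    abort("group shares must lie in [0, 1]")
  }
  groups <- unique(shares$group)
  per_group <- purrr::map_dfr(groups, function(g) {
    obs <- shares %>% filter(.data$group == g)
    sh <- interpolate_annual(obs[, c("year", "share")] %>%
                               rename(value = "share"), total$year)
    tibble(year = sh$year, group = g, share = sh$value)
  })
  # renormalise so groups sum exactly to 1 every year (guards fp drift when
  # share observation years differ between groups)
  per_group <- per_group %>%
    group_by(.data$year) %>%
    mutate(share = .data$share / sum(.data$share)) %>%
    ungroup()
  per_group %>%
    left_join(total, by = "year") %>%
    mutate(value = .data$share * .data$value) %>%
    select("year", "group", "value")
}

#' Assemble a regional forcing dataset
#'
#' Bundles every forcing series the simulator needs for one region on a
#' common annual grid: forest area and commercial harvest per species group,
#' the temperature-anomaly series, a monthly reference climatology,
#' agricultural soil-carbon series and the agricultural land-conversion
#' fraction. Sparse inputs are annualised with [interpolate_annual()].
#'
#' @param region_id Region label.
#' @param latitude Latitude in degrees (used for extraterrestrial radiation).
#' @param years Integer vector: simulation years (e.g. `1850:2015`).
#' @param area Data frame `year, group, value` (ha), sparse allowed.
#' @param harvest Data frame `year, group, value` (t C/yr commercial
#'   extraction, regional total), sparse allowed.
#' @param anomaly Data frame `year, value` (degC temperature anomaly
#'   relative to the reference climatology), sparse allowed; defaults to 0.
#' @param climatology Data frame `month, temperature, precipitation`
#'   (12 rows; degC and mm/month) for the reference period.
#' @param ag_soc Data frame `year, fast, slow` (t C/ha agricultural humus),
#'   sparse allowed; defaults to 0.
#' @param epsilon Data frame `year, value`: fraction of forest area newly
#'   converted from agricultural land; defaults to 0. Values must be >= 0.
#' @return An object of class `regional_dataset`: a list of tibbles on the
#'   annual grid plus metadata.
#' @export
regional_dataset <- function(region_id, latitude, years, area, harvest,
                             anomaly = NULL, climatology = NULL,
                             ag_soc = NULL, epsilon = NULL) {
  years <- sort(unique(as.integer(years)))
  annualise_grouped <- function(df, what) {
    df <- as_tibble(df)
    assert_group(unique(df$group))
    if (any(df$value < 0)) {
      abort(paste0("negative ", what, " at year(s) ",
                   paste(unique(df$year[df$value < 0]), collapse = ", ")))
    }
    purrr::map_dfr(unique(df$group), function(g) {
      out <- interpolate_annual(df[df$group == g, c("year", "value")], years)
      out$group <- g
      out[, c("year", "group", "value", "provenance")]
    })
  }
  area <- annualise_grouped(area, "area")
  harvest <- annualise_grouped(harvest, "harvest")
  if (is.null(anomaly)) anomaly <- tibble(year = years, value = 0)
  anomaly <- interpolate_annual(as_tibble(anomaly)[, c("year", "value")], years)
  if (is.null(climatology)) {
    climatology <- tibble(month = 1:12,
                          temperature = 10 + 8 * sin((1:12 - 4) * pi / 6),
                          precipitation = 70)
  }
  climatology <- as_tibble(climatology)
  if (!all(1:12 %in% climatology$month)) abort("climatology must cover months 1..12")
  if (is.null(ag_soc)) ag_soc <- tibble(year = years, fast = 0, slow = 0)
  ag_soc <- as_tibble(ag_soc)
  ag_fast <- interpolate_annual(ag_soc %>% select("year", value = "fast"), years)
  ag_slow <- interpolate_annual(ag_soc %>% select("year", value = "slow"), years)
  ag_soc <- tibble(year = years, fast = ag_fast$value, slow = ag_slow$value)
  if (is.null(epsilon)) epsilon <- tibble(year = years, value = 0)
  epsilon <- as_tibble(epsilon)
  epsilon <- tibble(year = years,
                    value = approx(epsilon$year, epsilon$value, xout = years,
                                   rule = 2, ties = "ordered")$y)
  if (any(epsilon$value < 0)) abort("land-conversion fraction must be >= 0")
  structure(
    list(region_id = region_id, latitude = latitude, years = years,
         area = area, harvest = harvest, anomaly = anomaly,
         climatology = climatology, ag_soc = ag_soc, epsilon = epsilon),
    class = "regional_dataset"
  )
}

#' @export
print.regional_dataset <- function(x, ...) {
  cat("<regional_dataset> ", x$region_id,
      " (", min(x$years), "-", max(x$years), ", lat ", x$latitude, ")\n",
      sep = "")
  cat("  groups:", paste(unique(x$area$group), collapse = ", "), "\n")
  cat("  area ", round(sum(x$area$value[x$area$year == max(x$years)])),
      " ha in ", max(x$years), "; harvest ",
      round(sum(x$harvest$value[x$harvest$year == max(x$years)])),
      " t C/yr\n", sep = "")
  invisible(x)
}

#' Load a regional dataset from CSV files
#'
#' Reads the long-format input tables (one row per year, region, group,
#' variable) named in a YAML configuration and assembles a
#' [regional_dataset()]. Harvest volumes given in m3 are converted to t C at
#' load time with the registry's wood density and carbon fraction.
#'
#' @param config Path to a YAML file with keys `region_id`, `latitude`,
#'   `years` (`start`, `end`), `files` (`series`, `climatology`, optional
#'   `anomaly`, `ag_soc`, `epsilon`), and `units` (`harvest`: `"tC"` or
#'   `"m3"`). Paths are resolved relative to the config file.
#' @param registry An [organ_registry()] (for unit conversion).
#' @return A `regional_dataset`.
#' @export
load_regional_dataset <- function(config, registry = organ_registry()) {
  cfg <- yaml::read_yaml(config)
  base <- dirname(config)
  path_of <- function(p) if (file.exists(p)) p else file.path(base, p)
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(paste0(file, ": missing mandatory column(s): ",
                   paste(miss, collapse = ", ")))
    }
    df
  }
  series <- readr::read_csv(path_of(cfg$files$series),
                            show_col_types = FALSE) %>%
    need(c("year", "group", "variable", "value"), cfg$files$series)
  years <- cfg$years$start:cfg$years$end
  area <- series %>% filter(.data$variable == "area") %>%
    select("year", "group", "value")
  harvest <- series %>% filter(.data$variable == "harvest") %>%
    select("year", "group", "value")
  if ((cfg$units$harvest %||% "tC") == "m3") {
    dens <- unlist(registry$wood_density)
    harvest <- harvest %>%
      mutate(value = .data$value * dens[.data$group] * registry$carbon_fraction)
  }
  read_opt <- function(key, cols) {
    if (is.null(cfg$files[[key]])) return(NULL)
    readr::read_csv(path_of(cfg$files[[key]]), show_col_types = FALSE) %>%
      need(cols, cfg$files[[key]])
  }
  regional_dataset(
    region_id = cfg$region_id, latitude = cfg$latitude, years = years,
    area = area, harvest = harvest,
    anomaly = read_opt("anomaly", c("year", "value")),
    climatology = read_opt("climatology",
                           c("month", "temperature", "precipitation")),
    ag_soc = read_opt("ag_soc", c("year", "fast", "slow")),
    epsilon = read_opt("epsilon", c("year", "value"))
  )
}

#' Write an annual trajectory to tidy CSV
#'
#' One row per region-year-group-variable, the package's standard output
#' format.
#'
#' @param trajectory A tibble as returned by [run_craft()] or
#'   [run_biomass()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  id <- intersect(c("region", "year", "group"), names(trajectory))
  long <- trajectory %>%
    tidyr::pivot_longer(cols = -all_of(id),
                        names_to = "variable", values_to = "value")
  readr::write_csv(long, path)
  invisible(path)
}
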