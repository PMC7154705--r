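DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)  # no leap
MID_MONTH_DOY <- cumsum(DAYS_IN_MONTH) - DAYS_IN_MONTH / 2

#' Monthly extraterrestrial radiation
#'
#' Daily extraterrestrial (top-of-atmosphere) solar radiation evaluated at
#' mid-month from the standard astronomical formula (solar constant,
#' inverse relative Earth-Sun distance, solar declination and sunset hour
#' angle), on a constant 365-day calendar.
#'
#' @param latitude Latitude in degrees, within `[-66, 66]` (polar latitudes
#'   unsupported).
#' @param month Integer month(s) 1..12.
#' @return Radiation in MJ m-2 day-1.
#' @export
extraterrestrial_radiation <- function(latitude, month = 1:12) {
  if (abs(latitude) > 66) abort("polar latitudes are not supported")
  if (any(!month %in% 1:12)) abort("month must be in 1..12")
  phi <- latitude * pi / 180
  j <- MID_MONTH_DOY[month]
  gsc <- 0.0820  # MJ m-2 min-1
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  delta <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Temperature-based potential evapotranspiration
#'
#' `PET = Re / (l * rho) * (T + 5) / 100` expressed in mm/day, clamped to 0
#' for `T <= -5` degC: a radiation- and temperature-only PET suitable for
#' long reconstructions where only temperature varies.
#'
#' @param temperature Air temperature (degC).
#' @param re Extraterrestrial radiation (MJ m-2 day-1).
#' @param latent_heat Latent heat of vaporisation (MJ/kg, default 2.45).
#' @param water_density Density of water (kg/m3, default 1000).
#' @return PET in mm/day (>= 0).
#' @export
pet_oudin <- function(temperature, re, latent_heat = 2.45,
                      water_density = 1000) {
  if (any(re < 0)) abort("radiation must be >= 0")
  # the /100 scaling and the m -> mm conversion leave Re/l * (T+5)/100 in mm/day
  pmax(0, re / (latent_heat * water_density) * (temperature + 5) / 100 * 1000)
}

#' Reconstruct annual climate forcing from a climatology and anomalies
#'
#' Annual mean temperature is the reference climatology mean shifted by the
#' year's temperature anomaly; monthly PET is recomputed from the shifted
#' monthly temperatures, and the May-September moisture term is
#' `M = sum(P_month - PET_month * days)` over those months, with
#' precipitation held constant at the climatology.
#'
#' @param climatology Data frame `month, temperature, precipitation`
#'   (12 rows, degC, mm/month).
#' @param anomaly Data frame `year, value`: annual temperature anomaly
#'   (degC) relative to the climatology.
#' @param latitude Latitude in degrees.
#' @return A tibble `year, temperature, moisture` (degC; mm over
#'   May-September).
#' @export
reconstruct_forcing <- function(climatology, anomaly, latitude) {
  climatology <- as_tibble(climatology) %>% arrange(.data$month)
  if (nrow(climatology) != 12) abort("climatology must have 12 monthly rows")
  re <- extraterrestrial_radiation(latitude, climatology$month)
  t_ref <- mean(climatology$temperature)
  growing <- climatology$month %in% 5:9
  purrr::map_dfr(seq_len(nrow(anomaly)), function(i) {
    a <- anomaly$value[i]
    t_m <- climatology$temperature + a
    pet_m <- pet_oudin(t_m, re) * DAYS_IN_MONTH[climatology$month]
    tibble(year = anomaly$year[i],
           temperature = t_ref + a,
           moisture = sum(climatology$precipitation[growing] - pet_m[growing]))
  })
}
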