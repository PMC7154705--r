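#' Load the tree-organ composition registry
#'
#' The registry gives, per species group, each organ's share of total
#' standing biomass, its annual turnover rate to litter, and whether it is
#' part of commercial (extracted) wood, together with wood densities and the
#' carbon fraction of dry matter. The packaged default ships as editable
#' YAML; any registry whose organ shares sum to 1 within each group is
#' accepted.
#'
#' @param path Path to a YAML registry; default is the packaged registry.
#' @return A list with elements `carbon_fraction`, `wood_density`,
#'   `branch_residue_ratio`, and `organs`, the latter a tibble with columns
#'   `group`, `organ`, `share`, `turnover`, `extracted`.
#' @export
organ_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "organ_registry.yaml", package = "craftr")
  }
  raw <- yaml::read_yaml(path)
  organs <- purrr::imap_dfr(raw$groups, function(g, gname) {
    purrr::imap_dfr(g$organs, function(o, oname) {
      tibble(group = gname, organ = oname, share = o$share,
             turnover = o$turnover, extracted = isTRUE(o$extracted))
    })
  })
  bad <- organs %>%
    group_by(.data$group) %>%
    summarise(s = sum(.data$share)) %>%
    filter(abs(.data$s - 1) > 1e-8)
  if (nrow(bad) > 0) {
    abort(paste0("organ shares must sum to 1; group(s) off: ",
                 paste(bad$group, collapse = ", ")))
  }
  if (any(organs$turnover < 0)) abort("organ turnover rates must be >= 0")
  cf <- raw$carbon_fraction
  if (!(cf > 0 && cf < 1)) abort("carbon_fraction must lie in (0, 1)")
  list(
    carbon_fraction = cf,
    wood_density = raw$wood_density,
    branch_residue_ratio = raw$branch_residue_ratio %||% 0.10,
    organs = organs
  )
}

#' Natural mortality rate implied by an organ registry
#'
#' The whole-tree biomass loss rate to litter, `sum(share * turnover)` over
#' organs (1/yr), for one species group.
#'
#' @param registry An [organ_registry()] list.
#' @param group `"deciduous"` or `"coniferous"`.
#' @return Mortality rate m (1/yr).
#' @export
mortality_rate <- function(registry, group) {
  assert_group(group)
  org <- registry$organs[registry$organs$group == group, ]
  sum(org$share * org$turnover)
}

#' Load the litter and humus decay registry
#'
#' Decay rates, humification fractions, the fast-humus temperature response,
#' the slow-humus constants (0.007 and 0.0033) with their role wiring, and
#' the organ-to-litter-pool mapping. Ships as editable YAML.
#'
#' @param path Path to a YAML registry; default is the packaged registry.
#' @return A list with components `litter` (tibble: pool, base_decay,
#'   climate_sensitive, humification), `climate_modifier_floor`,
#'   `fast_humus` (a0, t_ref, q10), `slow_humus` (decay_factor,
#'   transfer_fraction, wiring), and `organ_pools` (named character vector).
#' @export
soil_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "soil_params.yaml", package = "craftr")
  }
  raw <- yaml::read_yaml(path)
  litter <- purrr::imap_dfr(raw$litter, function(p, pname) {
    tibble(pool = pname, base_decay = p$base_decay,
           climate_sensitive = isTRUE(p$climate_sensitive),
           humification = p$humification)
  })
  if (any(litter$base_decay < 0)) abort("litter decay rates must be >= 0")
  if (any(litter$humification < 0 | litter$humification > 1)) {
    abort("humification fractions must lie in [0, 1]")
  }
  if (raw$fast_humus$a0 <= 0) abort("fast humus a0 must be > 0")
  wiring <- raw$slow_humus$wiring %||% "ratio_consistent"
  if (!wiring %in% c("ratio_consistent", "literal")) {
    abort("slow_humus wiring must be 'ratio_consistent' or 'literal'")
  }
  list(
    litter = litter,
    climate_modifier_floor = raw$climate_modifier_floor %||% 0.05,
    fast_humus = raw$fast_humus,
    slow_humus = list(decay_factor = raw$slow_humus$decay_factor,
                      transfer_fraction = raw$slow_humus$transfer_fraction,
                      wiring = wiring),
    organ_pools = unlist(raw$organ_pools)
  )
}

#' Historical litter-raking schedule
#'
#' Fraction of annual foliage-litter production removed from the forest by
#' raking and grazing: a constant plateau until `plateau_end`, a linear
#' phase-out to zero at `zero_year`, and zero after. The default plateau of
#' 0.5 until 1940 with phase-out complete by 1980 reflects the historical
#' decline of secondary forest uses after World War II.
#'
#' @param year Integer vector of calendar years.
#' @param plateau Raking fraction during the plateau (default 0.5).
#' @param plateau_end Last year of the plateau (default 1940).
#' @param zero_year First year with zero raking (default 1980).
#' @return Numeric vector of raking fractions in `[0, 1]`.
#' @export
raking_fraction <- function(year, plateau = 0.5, plateau_end = 1940,
                            zero_year = 1980) {
  stopifnot(plateau >= 0, plateau <= 1, zero_year > plateau_end)
  out <- ifelse(
    year <= plateau_end, plateau,
    ifelse(year >= zero_year, 0,
           plateau * (zero_year - year) / (zero_year - plateau_end))
  )
  as.numeric(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
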