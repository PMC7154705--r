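#' Time-varying growth-parameter scaling
#'
#' Yield tables describe growth conditions of the era when they were
#' compiled (anchored here at a reference year, 1960 by default). To
#' represent the long-term change in growth conditions, a single
#' dimensionless scale multiplies both `r` and `K`; it is piecewise linear
#' through the anchors (start year, s0), (reference year, 1), (end year,
#' s1), with constant extension outside.
#'
#' @param s0,s1 Named numeric vectors (names = species groups) or scalars:
#'   the scale at the start and end anchors. Must lie in `[0.5, 1.5]`.
#' @param start_year,end_year,ref_year Anchor years.
#' @return An object of class `growth_modifiers`.
#' @export
growth_modifiers <- function(s0 = 1, s1 = 1, start_year = 1850,
                             end_year = 2015, ref_year = 1960) {
  expand <- function(s) {
    if (is.null(names(s))) s <- setNames(rep(s, length(SPECIES_GROUPS)),
                                         SPECIES_GROUPS)
    assert_group(names(s))
    s[SPECIES_GROUPS]
  }
  s0 <- expand(s0); s1 <- expand(s1)
  if (any(s0 < 0.5 - 1e-9 | s0 > 1.5 + 1e-9 |
          s1 < 0.5 - 1e-9 | s1 > 1.5 + 1e-9)) {
    abort("modifier anchors must lie in [0.5, 1.5]")
  }
  structure(list(s0 = s0, s1 = s1, start_year = start_year,
                 end_year = end_year, ref_year = ref_year),
            class = "growth_modifiers")
}

#' Evaluate the growth scale for given years
#'
#' @param modifiers A [growth_modifiers()] object.
#' @param year Integer vector of years.
#' @param group A single species group.
#' @return Numeric vector of dimensionless scales (1 at the reference year).
#' @export
scale_at <- function(modifiers, year, group) {
  assert_group(group)
  m <- modifiers
  approx(x = c(m$start_year, m$ref_year, m$end_year),
         y = c(m$s0[[group]], 1, m$s1[[group]]),
         xout = pmin(pmax(year, m$start_year), m$end_year),
         ties = "ordered")$y
}

#' Logistic net primary production
#'
#' `NPP = r * B * (1 - B / K)` in t C ha-1 yr-1. Negative values are
#' allowed for `B > K` (overshoot decays back to the carrying capacity).
#'
#' @param b Standing biomass density (t C/ha, >= 0).
#' @param r Intrinsic growth rate (1/yr).
#' @param K Carrying capacity (t C/ha).
#' @return NPP (t C ha-1 yr-1).
#' @export
npp_logistic <- function(b, r, K) {
  if (any(b < 0)) abort("biomass density must be >= 0")
  r * b * (1 - b / K)
}

#' Expand commercial harvest into extraction and felling residues
#'
#' Harvest statistics report extracted commercial wood (stem and large
#' branches) only. Felling also transfers the non-exploited organs of the
#' felled trees (leaves, small branches, fine and large roots) to the
#' forest floor, in proportion of each organ's share relative to the
#' extracted organs' share; in addition 10% of the harvested branch
#' material is assumed left on site. The total `H` removed from standing
#' biomass is extraction plus all residues.
#'
#' @param commercial_c Commercial extraction (t C ha-1 yr-1, >= 0).
#' @param group Species group.
#' @param registry An [organ_registry()].
#' @return A list with `extracted` (t C/ha/yr leaving the site), `residues`
#'   (named numeric per organ, left on the floor), and `total` (the harvest
#'   term of the biomass balance).
#' @export
harvest_to_fluxes <- function(commercial_c, group, registry = organ_registry()) {
  if (any(commercial_c < 0)) abort("commercial harvest must be >= 0")
  assert_group(group)
  rat <- residue_ratios(registry, group)
  residues <- lapply(rat$per_organ, function(x) x * commercial_c)
  list(extracted = commercial_c,
       residues = residues,
       total = commercial_c * (1 + rat$total))
}

# Per-organ residue:extraction ratios; branch rule adds 10% of the harvested
# branch mass to the large-branch residue stream.
residue_ratios <- function(registry, group) {
  org <- registry$organs[registry$organs$group == group, ]
  exp_share <- sum(org$share[org$extracted])
  per_organ <- setNames(numeric(nrow(org)), org$organ)
  for (i in seq_len(nrow(org))) {
    if (!org$extracted[i]) {
      per_organ[org$organ[i]] <- org$share[i] / exp_share
    }
  }
  if ("large_branches" %in% org$organ) {
    lb <- org$share[org$organ == "large_branches"] / exp_share
    per_organ["large_branches"] <- per_organ["large_branches"] +
      registry$branch_residue_ratio * lb
  }
  list(per_organ = as.list(per_organ), total = sum(unlist(per_organ)))
}

#' Equilibrium biomass density under constant mortality and harvest
#'
#' Solves `r b (1 - b/K) = m b + h` for the larger (stable) root: the
#' density at which NPP compensates natural mortality and anthropogenic
#' extraction, used to initialise the simulation at its first year.
#'
#' @param r,K Logistic growth parameters (`r > m` required).
#' @param m Whole-tree mortality rate `sum(k_i * eps_i)` (1/yr).
#' @param h Total harvest rate (t C ha-1 yr-1, extraction plus residues).
#' @return Equilibrium density (t C/ha).
#' @export
equilibrium_biomass <- function(r, K, m, h = 0) {
  if (r <= m) abort("growth rate must exceed the mortality rate")
  if (h < 0) abort("harvest must be >= 0")
  disc <- (r - m)^2 - 4 * (r / K) * h
  # harvest exactly at the sustainability maximum: fp noise can push the
  # discriminant marginally negative
  if (disc < 0 && disc > -1e-9 * (r - m)^2) disc <- 0
  if (disc < 0) {
    abort(sprintf(
      "harvest %.4g t C/ha/yr is unsustainable at any density; maximum sustainable h = %.4g",
      h, K * (r - m)^2 / (4 * r)))
  }
  (K / (2 * r)) * ((r - m) + sqrt(disc))
}

# Lean density integration for one group: same arithmetic as run_biomass,
# returning only the density vector. Used by the calibration hot loop.
integrate_density <- function(years, area, h_total, r_t, K_t, m) {
  ny <- length(years)
  b <- numeric(ny)
  b[1] <- equilibrium_biomass(r_t[1], K_t[1], m, h_total[1])
  for (t in seq_len(ny - 1)) {
    b1 <- b[t] + r_t[t] * b[t] * (1 - b[t] / K_t[t]) - m * b[t] - h_total[t]
    if (b1 < 0) b1 <- 0
    dA <- area[t + 1] - area[t]
    b[t + 1] <- if (dA > 0 && area[t] > 0) b1 / (1 + dA / area[t]) else b1
  }
  b
}

#' Simulate standing biomass per species group
#'
#' Annual explicit stepping of the biomass balance: gross annual increment
#' `GAI = NPP - mortality - H` is applied to the current density, then area
#' change dilutes the stock (new forest starts with zero biomass; area loss
#' exports stock at the current density). The first year is initialised at
#' the equilibrium implied by its own forcing. Growth parameters are
#' multiplied by the time-varying scale; `mode = "static"` freezes the
#' scale at 1 (the control run with constant reference-era growth
#' conditions).
#'
#' @param dataset A [regional_dataset()].
#' @param params A data frame `group, r, K` of reference-era growth
#'   parameters (see [regional_params()]).
#' @param modifiers A [growth_modifiers()] object.
#' @param mode `"dynamic"` (use the modifiers) or `"static"` (scale = 1).
#' @param registry An [organ_registry()].
#' @return A tibble, one row per year and group, with density (t C/ha),
#'   area (ha), stock (t C), the annual fluxes (t C ha-1 yr-1: `npp`,
#'   `gai`, `mortality`, `harvest_extracted`, `harvest_residue`,
#'   `harvest_total`), per-organ mortality and residue columns
#'   (`mort_*`, `res_*`), the area-loss export (t C), and any clipping
#'   deficit.
#' @export
run_biomass <- function(dataset, params, modifiers = growth_modifiers(),
                        mode = c("dynamic", "static"),
                        registry = organ_registry()) {
  mode <- match.arg(mode)
  params <- as_tibble(params)
  years <- dataset$years
  ny <- length(years)
  purrr::map_dfr(unique(dataset$area$group), function(g) {
    p <- params[params$group == g, ]
    if (nrow(p) != 1) abort(paste0("missing growth parameters for group ", g))
    m <- mortality_rate(registry, g)
    rat <- residue_ratios(registry, g)
    area <- dataset$area$value[dataset$area$group == g]
    harv_tot <- dataset$harvest$value[dataset$harvest$group == g]
    sc <- if (mode == "static") rep(1, ny) else scale_at(modifiers, years, g)
    # commercial extraction per current hectare
    h_comm <- ifelse(area > 0, harv_tot / area, 0)
    h_total <- h_comm * (1 + rat$total)
    r_t <- p$r * sc
    K_t <- p$K * sc
    b <- integrate_density(years, area, h_total, r_t, K_t, m)
    # diagnostics recomputed from the density trajectory
    b1_all <- b + r_t * b * (1 - b / K_t) - m * b - h_total
    deficit <- c(pmax(0, -b1_all[-ny]), 0)
    dA <- diff(area)
    export <- c(ifelse(dA < 0, -dA * pmax(0, b1_all[-ny]), 0), 0)
    if (any(deficit > 0)) {
      warn(paste0("group ", g, ": harvest demand exceeded available biomass in ",
                  sum(deficit > 0), " year(s); density clipped at 0"))
    }
    npp <- r_t * b * (1 - b / K_t)
    out <- tibble(
      year = years, group = g, area = area, density = b,
      stock = b * area, scale = sc,
      npp = npp, mortality = m * b,
      harvest_extracted = h_comm,
      harvest_residue = h_comm * rat$total,
      harvest_total = h_total,
      gai = npp - m * b - h_total,
      area_loss_export = export, deficit = deficit
    )
    org <- registry$organs[registry$organs$group == g, ]
    for (i in seq_len(nrow(org))) {
      out[[paste0("mort_", org$organ[i])]] <- org$share[i] * org$turnover[i] * b
      out[[paste0("res_", org$organ[i])]] <-
        rat$per_organ[[org$organ[i]]] * h_comm
    }
    out
  })
}
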