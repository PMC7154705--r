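LITTER_POOLS <- c("foliage", "fine_roots", "coarse_woody",
                  "large_roots_branches")

#' Climate-dependent litter decay rates
#'
#' Foliage and fine-root litter, the most reactive compartments, decay at
#' base rates of 0.35/yr and 0.25/yr respectively, both multiplied by the
#' climate modifier `phi = 1 + 0.094 (T - 4) + 0.0023 (M + 50)` where `T`
#' is mean annual temperature (degC) and `M` the May-September
#' precipitation minus PET (mm). The woody pools decay at their fixed
#' registry rates. `phi` is floored at a small positive value in very cold
#' or dry climates.
#'
#' @param temperature Mean annual temperature (degC).
#' @param moisture May-September precipitation minus PET (mm; may be
#'   negative).
#' @param sp A [soil_params()] registry.
#' @return Named numeric vector of decay rates (1/yr) for pools `foliage`,
#'   `fine_roots`, `coarse_woody`, `large_roots_branches`.
#' @export
litter_decay_rates <- function(temperature, moisture, sp = soil_params()) {
  if (temperature < -20 || temperature > 30) {
    abort("temperature outside the plausible guard range [-20, 30] degC")
  }
  phi <- max(sp$climate_modifier_floor,
             1 + 0.094 * (temperature - 4) + 0.0023 * (moisture + 50))
  k <- setNames(sp$litter$base_decay, sp$litter$pool) *
    ifelse(sp$litter$climate_sensitive, phi, 1)
  k[LITTER_POOLS]
}

#' Temperature response of the fast humus decay rate
#'
#' `a(T) = a0 * Q10^((T - T_ref) / 10)`: a monotone-increasing exponential
#' response anchored at a reference temperature, with the anchor rate,
#' reference temperature and Q10 supplied by the registry.
#'
#' @inheritParams litter_decay_rates
#' @return Decay rate a (1/yr).
#' @export
fast_humus_decay_rate <- function(temperature, sp = soil_params()) {
  fh <- sp$fast_humus
  if (fh$a0 <= 0) abort("fast humus a0 must be > 0")
  fh$a0 * fh$q10^((temperature - fh$t_ref) / 10)
}

# Slow-pool constants under the chosen role wiring: decay rate multiplier on
# a, and the fraction of fast-humus decay transferred to the slow pool.
slow_pool_roles <- function(sp) {
  sh <- sp$slow_humus
  if (sh$wiring == "ratio_consistent") {
    list(decay_mult = sh$transfer_fraction, transfer = sh$decay_factor)
  } else {
    list(decay_mult = sh$decay_factor, transfer = sh$transfer_fraction)
  }
}

#' Advance the litter and humus pools by one year
#'
#' Each litter pool gains its input (after litter raking removes a fraction
#' of the foliage input stream) and loses `k * L` to decay; a humification
#' fraction of each decay flux feeds the fast humus pool and the remainder
#' is mineralised. Fast humus decays at the temperature-dependent rate `a`,
#' with a small fraction of that flux transferred to the slow pool; slow
#' humus decays at its proportional rate. Carbon is conserved exactly:
#' `delta(litter + humus) = inputs - raked - co2`.
#'
#' @param litter Named numeric: current litter pools (t C/ha).
#' @param humus Named numeric `c(fast = , slow = )` (t C/ha).
#' @param inputs Named numeric: annual litter inputs per pool
#'   (t C ha-1 yr-1), from natural mortality plus felling residues.
#' @param temperature,moisture Climate forcing for the year.
#' @param raking Fraction of the foliage-litter input removed by raking and
#'   grazing (0..1).
#' @param sp A [soil_params()] registry.
#' @return A list with `litter`, `humus` (updated pools), `co2`
#'   (mineralised t C ha-1 yr-1) and `raked` (exported t C ha-1 yr-1).
#' @export
step_soil <- function(litter, humus, inputs, temperature, moisture,
                      raking = 0, sp = soil_params()) {
  k <- litter_decay_rates(temperature, moisture, sp)
  if (any(k > 1)) {
    abort("litter decay rate exceeds 1/yr: annual explicit stepping unstable; reduce rates or the climate modifier")
  }
  a <- fast_humus_decay_rate(temperature, sp)
  roles <- slow_pool_roles(sp)
  hum_frac <- setNames(sp$litter$humification, sp$litter$pool)[LITTER_POOLS]
  inp <- setNames(numeric(length(LITTER_POOLS)), LITTER_POOLS)
  inp[names(inputs)] <- unlist(inputs)
  raked <- raking * inp[["foliage"]]
  inp[["foliage"]] <- inp[["foliage"]] - raked
  litter <- litter[LITTER_POOLS]
  decay <- k * litter
  new_litter <- litter + inp - decay
  to_fast <- sum(hum_frac * decay)
  co2_litter <- sum((1 - hum_frac) * decay)
  fast_decay <- a * humus[["fast"]]
  to_slow <- roles$transfer * fast_decay
  slow_decay <- roles$decay_mult * a * humus[["slow"]]
  new_humus <- c(fast = humus[["fast"]] + to_fast - fast_decay,
                 slow = humus[["slow"]] + to_slow - slow_decay)
  if (any(new_litter < -1e-12) || any(new_humus < -1e-12)) {
    abort("pool driven negative: decay rates too large for annual stepping")
  }
  list(litter = pmax(new_litter, 0), humus = pmax(new_humus, 0),
       co2 = co2_litter + (fast_decay - to_slow) + slow_decay,
       raked = unname(raked))
}

#' Steady-state litter and humus pools under constant forcing
#'
#' Closed-form fixed point of [step_soil()]: `L* = input / k` per litter
#' pool (after raking), `F* = humified inputs / a` for fast humus, and the
#' slow pool balancing its transfer against its decay. Used to initialise
#' the soil state at the start of the simulation, assuming soil inputs
#' compensated losses at that time.
#'
#' @inheritParams step_soil
#' @return A list with `litter` and `humus` named vectors (t C/ha).
#' @export
equilibrium_soil <- function(inputs, temperature, moisture, raking = 0,
                             sp = soil_params()) {
  k <- litter_decay_rates(temperature, moisture, sp)
  a <- fast_humus_decay_rate(temperature, sp)
  roles <- slow_pool_roles(sp)
  hum_frac <- setNames(sp$litter$humification, sp$litter$pool)[LITTER_POOLS]
  inp <- setNames(numeric(length(LITTER_POOLS)), LITTER_POOLS)
  inp[names(inputs)] <- unlist(inputs)
  inp[["foliage"]] <- (1 - raking) * inp[["foliage"]]
  if (any(k <= 0 & inp > 0)) {
    abort("zero decay rate with nonzero input: no equilibrium exists")
  }
  litter <- ifelse(k > 0, inp / k, 0)
  names(litter) <- LITTER_POOLS
  to_fast <- sum(hum_frac * k * litter)   # = sum(hum_frac * inp)
  fast <- to_fast / a
  slow <- if (roles$decay_mult > 0) {
    roles$transfer * a * fast / (roles$decay_mult * a)
  } else 0
  list(litter = litter, humus = c(fast = fast, slow = slow))
}

#' Mix forest and agricultural per-hectare pools after land conversion
#'
#' When a fraction `epsilon` of the forest area was converted from
#' agricultural land during the year, each per-hectare forest pool is
#' replaced by the convex combination
#' `C_F / (1 + eps) + C_A * eps / (1 + eps)`. Because agricultural soils
#' usually hold less carbon than forest soils, this appears as a dilution
#' of per-hectare forest SOC.
#'
#' @param forest Named numeric: forest per-hectare pools (t C/ha).
#' @param agricultural Named numeric of the same pools in agricultural land
#'   (missing entries treated as 0).
#' @param epsilon Converted-area fraction (>= 0).
#' @return Named numeric of mixed pools.
#' @export
apply_landuse_mixing <- function(forest, agricultural, epsilon) {
  if (epsilon < 0) abort("land-conversion fraction must be >= 0")
  ag <- setNames(numeric(length(forest)), names(forest))
  common <- intersect(names(forest), names(agricultural))
  ag[common] <- unlist(agricultural)[common]
  forest / (1 + epsilon) + ag * epsilon / (1 + epsilon)
}
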