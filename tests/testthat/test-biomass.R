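# minimal hand-built registry: one extracted organ with share 0.8, one
# residual organ with share 0.2, no branch rule
toy_registry <- function() {
  list(
    carbon_fraction = 0.47,
    wood_density = list(deciduous = 0.55, coniferous = 0.42),
    branch_residue_ratio = 0,
    organs = tibble::tibble(
      group = rep(c("deciduous", "coniferous"), each = 2),
      organ = rep(c("stem", "fine_roots"), 2),
      share = rep(c(0.8, 0.2), 2),
      turnover = rep(c(0.005, 0.8), 2),
      extracted = rep(c(TRUE, FALSE), 2))
  )
}

test_that("logistic NPP has its roots and vertex where expected", {
  expect_equal(npp_logistic(0, 0.1, 200), 0)
  expect_equal(npp_logistic(200, 0.1, 200), 0)
  expect_equal(npp_logistic(100, 0.1, 200), 0.1 * 200 / 4)
  # overshoot decays
  expect_lt(npp_logistic(250, 0.1, 200), 0)
  expect_error(npp_logistic(-1, 0.1, 200), ">= 0")
})

test_that("harvest expands into residues in proportion to organ shares", {
  hf0 <- harvest_to_fluxes(0, "deciduous")
  expect_equal(hf0$total, 0)
  expect_true(all(unlist(hf0$residues) == 0))

  # ratio identity: residual share 0.2 against extracted share 0.8
  hf <- harvest_to_fluxes(1, "deciduous", toy_registry())
  expect_equal(hf$residues$fine_roots, 0.25)
  expect_equal(hf$total, 1.25)

  # full default registry against a hand-computed table
  reg <- organ_registry()
  org <- reg$organs[reg$organs$group == "coniferous", ]
  exp_share <- sum(org$share[org$extracted])
  hf2 <- harvest_to_fluxes(1, "coniferous", reg)
  for (o in org$organ[!org$extracted]) {
    expect_equal(hf2$residues[[o]],
                 org$share[org$organ == o] / exp_share)
  }
  # branch rule: 10% of the harvested branch mass stays on site
  expect_equal(hf2$residues$large_branches,
               0.10 * org$share[org$organ == "large_branches"] / exp_share)
  expect_equal(hf2$total, 1 + sum(unlist(hf2$residues)))
  expect_error(harvest_to_fluxes(-0.1, "deciduous"), ">= 0")
})

test_that("equilibrium density solves the growth-mortality-harvest balance", {
  expect_equal(equilibrium_biomass(0.10, 200, 0.02, 0), 160)
  # double root at the sustainability maximum
  r <- 0.08; m <- 0.01; K <- 150
  hmax <- K * (r - m)^2 / (4 * r)
  expect_equal(equilibrium_biomass(r, K, m, hmax), K * (r - m) / (2 * r),
               tolerance = 1e-7)
  expect_error(equilibrium_biomass(r, K, m, hmax * 1.01), "unsustainable")
  expect_error(equilibrium_biomass(0.05, 200, 0.06, 0), "exceed")
  # scalar root-finding oracle
  b_eq <- equilibrium_biomass(0.08, 150, 0.01, 1.0)
  f <- function(b) 0.08 * b * (1 - b / 150) - 0.01 * b - 1.0
  oracle <- uniroot(f, c(K * (r - m) / (2 * r), 150), tol = 1e-12)$root
  expect_equal(b_eq, oracle, tolerance = 1e-9)
  # it is a root and the larger one
  expect_equal(f(b_eq), 0, tolerance = 1e-12)
})

test_that("growth modifiers interpolate through their anchors", {
  gm <- growth_modifiers(s0 = c(deciduous = 0.8, coniferous = 1.2),
                         s1 = c(deciduous = 1.4, coniferous = 0.6))
  expect_equal(scale_at(gm, 1960, "deciduous"), 1)
  expect_equal(scale_at(gm, 1850, "deciduous"), 0.8)
  expect_equal(scale_at(gm, 2015, "coniferous"), 0.6)
  expect_equal(scale_at(gm, 1905, "deciduous"), 0.9)
  # constant outside the anchor span
  expect_equal(scale_at(gm, 1800, "coniferous"), 1.2)
  expect_error(growth_modifiers(s0 = 0.4), "0.5")
})

test_that("the annual balance holds exactly at constant area", {
  ds <- constant_dataset()
  traj <- run_biomass(ds, default_params())
  for (g in c("deciduous", "coniferous")) {
    tg <- traj[traj$group == g, ]
    expect_lt(max(abs(diff(tg$density) - tg$gai[-nrow(tg)])), 1e-10)
  }
})

test_that("constant forcing at equilibrium gives a flat trajectory", {
  ds <- constant_dataset()
  traj <- run_biomass(ds, default_params())
  drift <- tapply(traj$density, traj$group,
                  function(b) max(abs(b - b[1])))
  expect_true(all(drift < 1e-8))
})

test_that("static mode equals dynamic mode when the scale is one", {
  syn <- syn_fixture()
  stat <- run_biomass(syn$dataset, syn$truth$params, mode = "static")
  dyn <- run_biomass(syn$dataset, syn$truth$params, growth_modifiers(),
                     mode = "dynamic")
  expect_equal(stat$density, dyn$density)
  expect_equal(stat$gai, dyn$gai)
})

test_that("a three-step toy run matches an explicit hand iteration", {
  years <- 1900:1903
  ds <- regional_dataset(
    "toy", 45, years,
    area = data.frame(year = c(1900, 1903), group = "deciduous",
                      value = c(1000, 1300)),
    harvest = data.frame(year = c(1900, 1903), group = "deciduous",
                         value = c(400, 400)))
  p <- tibble::tibble(group = "deciduous", r = 0.12, K = 180)
  reg <- organ_registry()
  m <- mortality_rate(reg, "deciduous")
  org <- reg$organs[reg$organs$group == "deciduous", ]
  exp_share <- sum(org$share[org$extracted])
  res_ratio <- sum(org$share[!org$extracted]) / exp_share +
    0.10 * org$share[org$organ == "large_branches"] / exp_share
  traj <- run_biomass(ds, p)

  area <- seq(1000, 1300, by = 100)
  h_tot <- (400 / area) * (1 + res_ratio)
  b <- numeric(4)
  b[1] <- equilibrium_biomass(0.12, 180, m, h_tot[1])
  for (t in 1:3) {
    b1 <- b[t] + 0.12 * b[t] * (1 - b[t] / 180) - m * b[t] - h_tot[t]
    b[t + 1] <- b1 / (1 + 100 / area[t])
  }
  expect_equal(traj$density, b)
})

test_that("area expansion dilutes density: doubling halves it", {
  years <- 1900:1901
  ds <- regional_dataset(
    "toy", 45, years,
    area = data.frame(year = c(1900, 1901), group = "deciduous",
                      value = c(1000, 2000)),
    harvest = data.frame(year = c(1900, 1901), group = "deciduous",
                         value = c(0, 0)))
  p <- tibble::tibble(group = "deciduous", r = 0.12, K = 180)
  traj <- run_biomass(ds, p)
  m <- mortality_rate(organ_registry(), "deciduous")
  b0 <- traj$density[1]
  pre_mix <- b0 + 0.12 * b0 * (1 - b0 / 180) - m * b0
  expect_equal(traj$density[2], pre_mix / 2)
})

test_that("harvest never increases next-year density; recovery is monotone", {
  p <- default_params()
  ds_lo <- constant_dataset(h_dec = 0.2, h_con = 0.2)
  ds_hi <- constant_dataset(h_dec = 0.4, h_con = 0.4)
  lo <- run_biomass(ds_lo, p)
  hi <- run_biomass(ds_hi, p)
  expect_true(all(hi$density <= lo$density + 1e-12))

  # zero harvest from below K: monotone increase toward K
  ds0 <- constant_dataset(h_dec = 0.35, h_con = 0.4)
  traj0 <- run_biomass(ds0, p)
  start <- traj0[traj0$year == min(traj0$year), ]
  ds_free <- constant_dataset(h_dec = 0, h_con = 0)
  # start the no-harvest run from the harvested equilibrium by simulating
  # the harvested first year then releasing harvest
  m_dec <- mortality_rate(organ_registry(), "deciduous")
  b <- start$density[start$group == "deciduous"]
  K_eff <- 180 * (1 - m_dec / 0.12)
  expect_lt(b, K_eff)
  bs <- numeric(120); bs[1] <- b
  for (t in 1:119) {
    bs[t + 1] <- bs[t] + 0.12 * bs[t] * (1 - bs[t] / 180) - m_dec * bs[t]
  }
  expect_true(all(diff(bs) > 0))
  expect_equal(bs[120], K_eff, tolerance = 0.01)
})

test_that("splitting a region into two half-size copies conserves totals", {
  p <- default_params()
  syn <- syn_fixture()
  whole <- run_biomass(syn$dataset, p)
  half <- syn$dataset
  half$area$value <- half$area$value / 2
  half$harvest$value <- half$harvest$value / 2
  halved <- run_biomass(half, p)
  expect_equal(2 * halved$stock, whole$stock, tolerance = 1e-12)
  expect_equal(halved$density, whole$density)
})

test_that("unsustainable harvest clips density at zero with a warning", {
  ds <- constant_dataset(h_dec = 0.3, h_con = 0.35)
  # force clipping by a harvest spike after initialization
  ds$harvest$value[ds$harvest$year > 1900] <-
    ds$harvest$value[ds$harvest$year > 1900] * 50
  w <- testthat::capture_warnings(traj <- run_biomass(ds, default_params()))
  expect_true(any(grepl("clipped", w)))
  expect_true(all(traj$density >= 0))
  expect_true(any(traj$deficit > 0))
})
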