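test_that("foliage and fine-root decay follow the climate modifier", {
  sp <- soil_params()
  # modifier-neutral point: T = 4 degC, M = -50 mm
  k <- litter_decay_rates(4, -50, sp)
  expect_equal(unname(k["foliage"]), 0.35)
  expect_equal(unname(k["fine_roots"]), 0.25)
  # warm: phi = 1 + 0.094 * 10 = 1.94
  k2 <- litter_decay_rates(14, -50, sp)
  expect_equal(unname(k2["foliage"]), 0.35 * 1.94)
  expect_equal(unname(k2["foliage"]), 0.679)
  # moist: phi = 1 + 0.0023 * 100 = 1.23
  k3 <- litter_decay_rates(4, 50, sp)
  expect_equal(unname(k3["foliage"]), 0.35 * 1.23)
  # woody pools are climate-insensitive
  expect_equal(unname(k2["coarse_woody"]), unname(k["coarse_woody"]))
  # floor in extreme cold
  k4 <- litter_decay_rates(-15, -300, sp)
  expect_gt(min(k4), 0)
  expect_error(litter_decay_rates(40, 0, sp), "guard")
})

test_that("fast humus decay is anchored and monotone in temperature", {
  sp <- soil_params()
  expect_equal(fast_humus_decay_rate(sp$fast_humus$t_ref, sp),
               sp$fast_humus$a0)
  expect_lt(fast_humus_decay_rate(5, sp), fast_humus_decay_rate(15, sp))
  # closed form of the exponential response
  expect_equal(fast_humus_decay_rate(20, sp),
               sp$fast_humus$a0 * sp$fast_humus$q10^((20 - sp$fast_humus$t_ref) / 10))
})

test_that("one soil step splits decay into humification and CO2", {
  sp <- soil_params()
  # zero inputs, zero stocks: nothing happens
  st0 <- step_soil(setNames(numeric(4), c("foliage", "fine_roots",
                                          "coarse_woody",
                                          "large_roots_branches")),
                   c(fast = 0, slow = 0),
                   list(foliage = 0), 4, -50, 0, sp)
  expect_equal(st0$co2, 0)
  expect_true(all(st0$litter == 0))

  # arithmetic split on a single pool: k = 0.5, humification 0.2, L = 10
  sp2 <- sp
  sp2$litter$base_decay[sp2$litter$pool == "foliage"] <- 0.5
  sp2$litter$climate_sensitive[sp2$litter$pool == "foliage"] <- FALSE
  sp2$litter$humification[sp2$litter$pool == "foliage"] <- 0.2
  st <- step_soil(c(foliage = 10, fine_roots = 0, coarse_woody = 0,
                    large_roots_branches = 0),
                  c(fast = 0, slow = 0), list(), 4, -50, 0, sp2)
  expect_equal(unname(st$litter["foliage"]), 5)
  expect_equal(unname(st$humus["fast"]), 1)
  expect_equal(st$co2, 4)
})

test_that("carbon is conserved to 1e-10 in every soil step", {
  sp <- soil_params()
  set.seed(21)
  litter <- c(foliage = 5, fine_roots = 3, coarse_woody = 20,
              large_roots_branches = 12)
  humus <- c(fast = 30, slow = 60)
  for (i in 1:200) {
    inputs <- as.list(setNames(runif(4, 0, 2),
                               c("foliage", "fine_roots", "coarse_woody",
                                 "large_roots_branches")))
    rakef <- runif(1, 0, 0.5)
    temp <- runif(1, 2, 14)
    moist <- runif(1, -150, 150)
    st <- step_soil(litter, humus, inputs, temp, moist, rakef, sp)
    d_stock <- sum(st$litter) + sum(st$humus) - sum(litter) - sum(humus)
    balance <- sum(unlist(inputs)) - st$raked - st$co2
    expect_lt(abs(d_stock - balance), 1e-10)
    litter <- st$litter; humus <- st$humus
  }
})

test_that("constant inputs drive pools to the closed-form steady state", {
  sp <- soil_params()
  inputs <- list(foliage = 2, fine_roots = 1, coarse_woody = 0.8,
                 large_roots_branches = 0.6)
  eq <- equilibrium_soil(inputs, 10, -20, 0.3, sp)
  # single-pool closed form: L* = input / k
  k <- litter_decay_rates(10, -20, sp)
  expect_equal(unname(eq$litter["coarse_woody"]), 0.8 / k[["coarse_woody"]])
  expect_equal(unname(eq$litter["foliage"]),
               (1 - 0.3) * 2 / k[["foliage"]])
  # steady state is a fixed point of step_soil
  st <- step_soil(eq$litter, eq$humus, inputs, 10, -20, 0.3, sp)
  expect_lt(max(abs(st$litter - eq$litter)), 1e-10)
  expect_lt(max(abs(st$humus - eq$humus)), 1e-10)
  # long-run relaxation oracle reaches the same state
  litter <- setNames(numeric(4), names(eq$litter))
  humus <- c(fast = 0, slow = 0)
  for (i in 1:10000) {
    st <- step_soil(litter, humus, inputs, 10, -20, 0.3, sp)
    litter <- st$litter; humus <- st$humus
  }
  expect_equal(litter, eq$litter, tolerance = 1e-6)
  expect_equal(unname(humus["fast"]), unname(eq$humus["fast"]),
               tolerance = 1e-6)
  # the slow pool relaxes over ~1/(0.0033 a) years; check direction only
  expect_gt(humus[["slow"]], 0)
  expect_error(equilibrium_soil(list(foliage = 1), 4, -50, 0,
                                within(sp, litter$base_decay[1] <- 0)),
               "no equilibrium")
})

test_that("the steady-state slow:fast humus ratio matches its constants", {
  sp <- soil_params()
  eq <- equilibrium_soil(list(foliage = 2, fine_roots = 1,
                              coarse_woody = 0.5,
                              large_roots_branches = 0.5), 8, 0, 0, sp)
  expect_equal(unname(eq$humus["slow"] / eq$humus["fast"]),
               0.007 / 0.0033, tolerance = 1e-9)
  # the literal wiring gives the reciprocal ratio
  sp_lit <- sp
  sp_lit$slow_humus$wiring <- "literal"
  eq2 <- equilibrium_soil(list(foliage = 2, fine_roots = 1,
                               coarse_woody = 0.5,
                               large_roots_branches = 0.5), 8, 0, 0, sp_lit)
  expect_equal(unname(eq2$humus["slow"] / eq2$humus["fast"]),
               0.0033 / 0.007, tolerance = 1e-9)
})

test_that("raking lowers the foliage and fast-humus steady states", {
  sp <- soil_params()
  inputs <- list(foliage = 2, fine_roots = 1, coarse_woody = 0.5,
                 large_roots_branches = 0.5)
  fols <- sapply(c(0, 0.25, 0.5, 0.75), function(rk) {
    eq <- equilibrium_soil(inputs, 8, 0, rk, sp)
    c(eq$litter[["foliage"]], eq$humus[["fast"]])
  })
  expect_true(all(diff(fols[1, ]) < 0))
  expect_true(all(diff(fols[2, ]) < 0))
})

test_that("the raking schedule follows plateau, phase-out, zero", {
  expect_equal(raking_fraction(c(1850, 1940)), c(0.5, 0.5))
  expect_equal(raking_fraction(1980), 0)
  expect_equal(raking_fraction(2000), 0)
  expect_equal(raking_fraction(1960), 0.25)
  expect_true(all(diff(raking_fraction(1935:1985)) <= 0))
})

test_that("land-use mixing is the epsilon-weighted convex combination", {
  expect_equal(apply_landuse_mixing(c(soc = 100), c(soc = 40), 0),
               c(soc = 100))
  expect_equal(apply_landuse_mixing(c(soc = 100), c(soc = 40), 1),
               c(soc = 70))
  expect_equal(unname(apply_landuse_mixing(c(soc = 80), c(soc = 50), 0.05)),
               80 / 1.05 + 50 * 0.05 / 1.05)
  expect_equal(unname(apply_landuse_mixing(c(soc = 80), c(soc = 50), 0.05)),
               78.57142857, tolerance = 1e-8)
  expect_error(apply_landuse_mixing(c(soc = 80), c(soc = 50), -0.1),
               ">= 0")
  # dilution: conversion from carbon-poorer agricultural soils lowers
  # per-hectare forest SOC
  mixed <- apply_landuse_mixing(c(fast = 40, slow = 60),
                                c(fast = 20, slow = 30), 0.04)
  expect_true(all(mixed < c(fast = 40, slow = 60)))
})
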