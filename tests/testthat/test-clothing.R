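# Clothing ensembles, correction factors and dynamic properties.

test_that("clothing area factor follows 1 + 0.3 Icl and rejects negative input", {
  expect_equal(fcl_ratio(1.0), 1.3)
  expect_equal(fcl_ratio(0), 1.0)       # nude limit
  expect_equal(fcl_ratio(2.01), 1.603)
  expect_error(fcl_ratio(-0.1), ">= 0")
})

test_that("ensembles validate fields and classify by insulation cutpoints", {
  expect_equal(clothing_category(c(0.2, 0.48, 0.6, 1.08, 1.4, 1.41, 2.01)),
               c("LC", "LC", "NC", "NC", "NC", "SC", "SC"))
  ens <- fixture_sc_ensemble()
  expect_s3_class(ens, "clothing_ensemble")
  expect_identical(ens$category, "SC")
  expect_error(clothing_ensemble(0, 0.03, 0.38), "icl")
  expect_error(clothing_ensemble(1, -1, 0.38), "rt_static")
  expect_error(clothing_ensemble(1, 0.03, 1.2), "imt")
  expect_error(clothing_ensemble(1, 0.03, 0.38, pr = 0.5), "pr")
  expect_error(clothing_ensemble(2.01, 0.1, 0.2, category = "NC"), "inconsistent")
})

test_that("correction formulas match an independently coded oracle to 1e-12", {
  # plain-arithmetic re-statements of the published regressions, sharing no
  # code with the implementation
  oracle <- list(
    ISO7933_NC = function(v, w, pr) c(
      exp(0.043 - 0.398 * v + 0.066 * v * v - 0.378 * w + 0.094 * w * w),
      exp(-0.472 * v + 0.047 * v * v - 0.342 * w + 0.117 * w * w)),
    ISO9920_NC = function(v, w, pr) c(
      exp(-0.281 * (v - 0.15) + 0.044 * (v - 0.15)^2 - 0.492 * w + 0.176 * w * w),
      exp(-0.533 * (v - 0.15) + 0.069 * (v - 0.15)^2 - 0.462 * w + 0.201 * w * w)),
    ISO9920_SC = function(v, w, pr) c(
      exp(-0.0512 * (v - 0.4) + 0.000794 * (v - 0.4)^2 - 0.0639 * w) * pr^0.144,
      exp(-0.533 * (v - 0.15) + 0.069 * (v - 0.15)^2 - 0.462 * w + 0.201 * w * w))
  )
  ranges <- list(ISO7933_NC = c(0, 3, 0, 1.5), ISO9920_NC = c(0.15, 3.5, 0, 1.2),
                 ISO9920_SC = c(0.4, 3.5, 0, 1.2))
  set.seed(101)
  for (algo in names(oracle)) {
    r <- ranges[[algo]]
    for (i in 1:100) {
      v <- runif(1, r[1], r[2]); w <- runif(1, r[3], r[4])
      pr <- if (algo == "ISO9920_SC") runif(1, 1, 1000) else NULL
      got <- correction_factors(algo, kinematics(v, w, var = v), pr = pr)
      want <- oracle[[algo]](v, w, pr)
      expect_equal(got$corr_tot, want[1], tolerance = 1e-12)
      expect_equal(got$corr_a, want[2], tolerance = 1e-12)
      expect_false(got$clamped)
    }
  }
  # Lu's total-insulation regression, via the LC dispatch
  ens <- fixture_lc_ensemble()
  set.seed(102)
  for (i in 1:100) {
    v <- runif(1, 0.15, 5.2); w <- runif(1, 0, 1.2)
    dyn <- dynamic_insulation(ens, kinematics(v, w, var = v), "LU")
    want <- min(exp(-0.393 * (v - 0.15) + 0.0393 * (v - 0.15)^2 -
                      0.0728 * w + 0.053 * w * w), 1)
    expect_equal(dyn$corr_tot, want, tolerance = 1e-12)
  }
})

test_that("all correction factors are 1 at their still-air reference point", {
  k0 <- kinematics(0.15, 0, var = 0.15)
  nc <- correction_factors("ISO9920_NC", k0)
  expect_equal(nc$corr_tot, 1, tolerance = 1e-12)
  expect_equal(nc$corr_a, 1, tolerance = 1e-12)
  sc <- correction_factors("ISO9920_SC", kinematics(0.4, 0, var = 0.4), pr = 1)
  expect_equal(sc$corr_tot, 1, tolerance = 1e-12)
  # ISO 7933: the boundary factor at rest, and the total factor at the root
  # of its exponent
  at_rest <- correction_factors("ISO7933_NC", kinematics(0, 0, var = 0))
  expect_equal(at_rest$corr_a, 1, tolerance = 1e-12)
  v0 <- (0.398 - sqrt(0.398^2 - 4 * 0.066 * 0.043)) / (2 * 0.066)
  expect_equal(correction_factors("ISO7933_NC", kinematics(v0, 0, var = v0))$corr_tot,
               1, tolerance = 1e-12)
  lu0 <- dynamic_insulation(fixture_lc_ensemble(), k0, "LU")
  expect_equal(lu0$corr_tot, 1, tolerance = 1e-12)
})

test_that("ISO 9920 NC factors stay below 1 and decrease with walking speed", {
  for (var in c(0.2, 0.5, 1.5, 3.4)) {
    vws <- seq(0, 1.2, by = 0.05)
    f <- t(vapply(vws, function(w) {
      cf <- correction_factors("ISO9920_NC", kinematics(var, w, var = var))
      c(cf$corr_tot, cf$corr_a)
    }, numeric(2)))
    expect_true(all(f <= 1 + 1e-12))
    # total-factor exponent is decreasing over the whole validity range
    # (-0.492 + 0.352 vw < 0 up to 1.398 m/s)
    expect_true(all(diff(f[, 1]) < 0))
    # boundary-layer exponent turns at vw = 0.462/0.402 = 1.149 m/s, so
    # monotonicity holds only below that stationary point
    expect_true(all(diff(f[, 2][vws <= 1.14]) < 0))
  }
})

test_that("out-of-range kinematics are clamped and flagged", {
  # walking faster than the ISO 9920 validity bound
  expect_message(
    cf <- correction_factors("ISO9920_NC", kinematics(0.33, 1.25, var = 0.33)),
    "clamped")
  expect_true(cf$clamped)
  at_bound <- correction_factors("ISO9920_NC", kinematics(0.33, 1.2, var = 0.33))
  expect_equal(cf$corr_tot, at_bound$corr_tot)
  # relative velocity below the ISO 9920 reference clamps up to 0.15
  expect_message(low <- correction_factors("ISO9920_NC", kinematics(0, 0, var = 0)))
  expect_equal(low$corr_tot, 1, tolerance = 1e-12)
  expect_true(low$clamped)
})

test_that("cold-weather correction needs the air permeability", {
  kin <- kinematics(0.5, 0.5)
  expect_error(correction_factors("ISO9920_SC", kin), "pr")
  # pr = 1 makes the permeability term unity
  p1 <- correction_factors("ISO9920_SC", kin, pr = 1)
  p100 <- correction_factors("ISO9920_SC", kin, pr = 100)
  expect_equal(p100$corr_tot / p1$corr_tot, 100^0.144, tolerance = 1e-12)
})

test_that("static total insulation assembles as Icl + Ia/fcl", {
  ens <- clothing_ensemble(1.0, 0.04, 0.38)
  dyn <- dynamic_insulation(ens, kinematics(0, 0, var = 0), "ISO7933")
  expect_equal(dyn$itot, 1.0 + 0.716 / 1.3, tolerance = 1e-12)
})

test_that("dynamic insulation is internally consistent for every algorithm", {
  cases <- expand.grid(icl = c(0.2, 0.48, 0.8, 1.08, 2.01), va = c(0.33, 1, 3),
                       vw = c(0, 0.5, 1.2))
  for (i in seq_len(nrow(cases))) {
    ens <- clothing_ensemble(cases$icl[i], 0.05, 0.38)
    kin <- kinematics(cases$va[i], cases$vw[i], var = cases$va[i])
    algos <- c("ISO7933", "ISO9920", if (ens$category == "LC") "LU")
    for (algo in algos) {
      dyn <- dyn_quiet(ens, kin, algo)
      # clothing + boundary-layer split recomposes the total
      expect_equal(dyn$icl_dyn + dyn$ia_dyn / dyn$fcl, dyn$itot_dyn,
                   tolerance = 1e-12)
      expect_true(all(c(dyn$itot_dyn, dyn$ia_dyn, dyn$icl_dyn, dyn$rt_dyn) > 0))
      expect_lte(dyn$corr_tot, 1 + 1e-12)
    }
  }
})

test_that("Lu's algorithm is rejected outside light clothing", {
  expect_error(dynamic_insulation(fixture_nc4_ensemble(), kinematics(1, 1), "LU"),
               "light clothing")
  expect_error(dynamic_insulation(fixture_sc_ensemble(), kinematics(1, 1), "LU"))
})

test_that("evaporative corrections reduce to the static values in still air", {
  # both quadratic multipliers equal 1 at corr_tot = 1
  expect_equal(2.6 * 1 - 6.5 + 4.9, 1.0)
  expect_equal(1.2 - 0.5 + 0.3, 1.0)
  ens <- clothing_ensemble(1.0, 0.04, 0.38)
  k0 <- kinematics(0.15, 0, var = 0.15)
  d9920 <- dynamic_clothing(ens, k0, "ISO9920")
  expect_equal(d9920$rt_dyn, ens$rt_static, tolerance = 1e-12)
  d7933 <- dynamic_clothing(ens, k0, "ISO7933")
  # double correction: imt unchanged when the total factor is 1
  expect_equal(d7933$imt_dyn, ens$imt * (2.6 * d7933$corr_tot^2 -
                                           6.5 * d7933$corr_tot + 4.9),
               tolerance = 1e-12)
})

test_that("the dynamic permeability index is capped at 0.9", {
  # strong pumping drives imt * Corr_E above the cap
  ens <- clothing_ensemble(1.0, 0.04, 0.6)
  dyn <- dyn_quiet(ens, kinematics(3, 1.2, var = 3), "ISO7933")
  expect_equal(dyn$imt_dyn, 0.9)
  expect_equal(dyn$rt_dyn, dyn$itot_dyn * 0.155 / (0.9 * 16.7), tolerance = 1e-12)
})

test_that("evaporative resistance rejects non-positive correction factors", {
  ens <- fixture_nc4_ensemble()
  dyn <- dynamic_insulation(ens, kinematics(0.5, 0.5), "ISO7933")
  dyn$corr_tot <- 0
  expect_error(dynamic_evaporative_resistance(ens, dyn), "corr_tot")
})
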