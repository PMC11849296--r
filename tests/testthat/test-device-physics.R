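test_that("areal capacitance follows eps0*eps_r/t with its scaling laws", {
  expect_equal(capacitance_per_area(ref_stack()), 4.5747e-6,
               tolerance = 1e-4)
  # doubling thickness exactly halves the capacitance
  expect_equal(capacitance_per_area(dielectric_stack(12, 3.1)),
               capacitance_per_area(ref_stack()) / 2)
  # identity case: eps_r = 1, t = 1 m reads off the vacuum permittivity
  expect_equal(capacitance_per_area(dielectric_stack(1e6, 1)),
               8.8541878128e-12)
  expect_error(dielectric_stack(-6), class = "dmf_invalid_input")
  expect_error(dielectric_stack(0), class = "dmf_invalid_input")
})

test_that("Young-Lippmann force is quadratic in V and matches the device range", {
  # the ~15-45 uN operating range corresponds to 110-140 V over 0.6-1.0 mm
  expect_equal(young_lippmann_force(actuation_state(140), 1.0, ref_stack()),
               44.83e-6, tolerance = 1e-3)
  expect_equal(young_lippmann_force(actuation_state(110), 0.6, ref_stack()),
               16.61e-6, tolerance = 1e-3)
  expect_identical(young_lippmann_force(actuation_state(0), 5, ref_stack()), 0)
  expect_identical(
    young_lippmann_force(actuation_state(120, active = FALSE), 1, ref_stack()),
    0)
  # quadratic law: halving the voltage quarters the force, for random V and L
  withr::with_seed(11, {
    for (i in 1:20) {
      v <- runif(1, 10, 300); l <- runif(1, 0.1, 5)
      expect_equal(
        young_lippmann_force(actuation_state(v), l, ref_stack()) /
          young_lippmann_force(actuation_state(v / 2), l, ref_stack()),
        4)
    }
  })
  expect_error(young_lippmann_force(actuation_state(100), -1, ref_stack()),
               class = "dmf_invalid_input")
  expect_error(actuation_state(-5), class = "dmf_invalid_input")
})

test_that("retention pressure imbalance is positive and linear in sigma at the operating point", {
  dp_ref <- retention_pressure_imbalance(ref_geom(), ref_fluid())
  expect_gt(dp_ref, 0)  # breakup-favourable at d = 1 mm, w = 2.2 mm, k = 0.6
  # exact linearity in sigma: doubling sigma doubles Delta p
  expect_equal(retention_pressure_imbalance(ref_geom(), ref_fluid(sigma_mN_m = 84)),
               2 * dp_ref)
  # lower surfactant concentration (higher sigma) raises Delta p
  expect_gt(retention_pressure_imbalance(ref_geom(), ref_fluid(sigma_mN_m = 70)),
            retention_pressure_imbalance(ref_geom(), ref_fluid(sigma_mN_m = 30)))
  expect_error(
    retention_pressure_imbalance(
      device_geometry(drive_width_mm = 1.0, densify_minor_mm = 1.0),
      ref_fluid()),
    class = "dmf_invalid_input")
})

test_that("Delta p trends: increasing in k everywhere, in sigma where breakup-favourable", {
  # k-monotonicity holds for every valid geometry (the electrowetting term
  # enters with a positive coefficient sigma * g0)
  withr::with_seed(23, {
    for (i in 1:40) {
      gf <- random_geom_fluid()
      dps <- vapply(seq(0.05, 0.95, by = 0.1), function(k)
        retention_pressure_imbalance(
          gf$geom, fluid_state(gf$fluid$sigma * 1e3,
                               gf$fluid$viscosity * 1e3, k)),
        numeric(1))
      expect_true(all(diff(dps) > 0))
    }
  })
  # sigma-monotonicity over the characterised parameter box (round d = 0.6-1.2
  # mm, k = 0.5-0.9), where the geometric bracket is breakup-favourable
  for (d in c(0.8, 1.0, 1.2)) {
    for (k in c(0.5, 0.7, 0.9)) {
      dps <- vapply(seq(30, 70, by = 10), function(s)
        retention_pressure_imbalance(device_geometry(densify_minor_mm = d),
                                     fluid_state(s, k_factor = k)),
        numeric(1))
      expect_true(all(diff(dps) > 0) || dps[1] < 0)
    }
  }
})

test_that("Delta p saturates in the destination electrode width", {
  dps <- vapply(c(1.5, 2.0, 2.5, 3.0, 3.5), function(w)
    retention_pressure_imbalance(device_geometry(drive_width_mm = w),
                                 ref_fluid()),
    numeric(1))
  expect_true(all(diff(dps) > 0))           # wider electrodes help...
  expect_true(all(diff(diff(dps)) < 0))     # ...with diminishing returns
  # gain from 2.5 -> 3.5 mm is smaller than from 1.5 -> 2.5 mm
  expect_lt(dps[5] - dps[3], dps[3] - dps[1])
})

test_that("reservoir Laplace pressure rises as the sample is used up", {
  expect_gt(reservoir_laplace_pressure(50, ref_geom(), ref_fluid()),
            reservoir_laplace_pressure(100, ref_geom(), ref_fluid()))
  vols <- c(5, 10, 20, 40, 80, 160)
  ps <- vapply(vols, reservoir_laplace_pressure, numeric(1),
               geom = ref_geom(), fluid = ref_fluid())
  expect_true(all(diff(ps) < 0))
  # at huge volumes only the gap-curvature term survives
  p_inf <- reservoir_laplace_pressure(1e15, ref_geom(), ref_fluid())
  inplane <- function(v) reservoir_laplace_pressure(v, ref_geom(), ref_fluid()) - p_inf
  # r ~ sqrt(V): halving the volume scales the in-plane term by sqrt(2)
  expect_equal(inplane(50) / inplane(100), sqrt(2), tolerance = 1e-6)
  expect_error(reservoir_laplace_pressure(0, ref_geom(), ref_fluid()),
               class = "dmf_invalid_input")
})

test_that("all pressures scale linearly with interfacial tension", {
  withr::with_seed(37, {
    for (i in 1:10) {
      gf <- random_geom_fluid()
      f2 <- fluid_state(2 * gf$fluid$sigma * 1e3, gf$fluid$viscosity * 1e3,
                        gf$fluid$k_factor)
      expect_equal(retention_pressure_imbalance(gf$geom, f2),
                   2 * retention_pressure_imbalance(gf$geom, gf$fluid))
      expect_equal(reservoir_laplace_pressure(30, gf$geom, f2),
                   2 * reservoir_laplace_pressure(30, gf$geom, gf$fluid))
    }
  })
})

test_that("domain constructors enforce their invariants", {
  expect_error(fluid_state(k_factor = 1), class = "dmf_invalid_input")
  expect_error(fluid_state(k_factor = 0), class = "dmf_invalid_input")
  expect_error(fluid_state(sigma_mN_m = -1), class = "dmf_invalid_input")
  expect_error(device_geometry(gap_um = 0), class = "dmf_invalid_input")
  expect_error(device_geometry(densify_minor_mm = 2, densify_major_mm = 1),
               class = "dmf_invalid_input")
  g <- device_geometry(densify_shape = "oval", densify_minor_mm = 0.8,
                       densify_major_mm = 1.2)
  expect_identical(g$densify_shape, "oval")
})
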