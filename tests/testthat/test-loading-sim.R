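test_that("wicking flow follows Darcy scaling and slows as the front advances", {
  w1 <- absorber_spec("paper", thickness_um = 180, pore_size_um = 11)
  fl <- ref_fluid()
  # doubling the wetted cross-section doubles the rate
  wide <- absorber_spec("paper", thickness_um = 180, pore_size_um = 11,
                        wick_width_mm = 40)
  expect_equal(wicking_flow_rate(wide, fl), 2 * wicking_flow_rate(w1, fl))
  # imbibition: rate strictly decreasing in time for paper
  q <- wicking_flow_rate(w1, fl, t_s = c(0, 10, 30, 60, 120))
  expect_true(all(diff(q) < 0))
  # SAP acts as a constant sink scaling with its mass
  sap <- absorber_spec("SAP", sap_mass_mg = 25)
  expect_equal(wicking_flow_rate(sap, fl, t_s = c(0, 50, 500)),
               rep(2, 3))
  expect_error(wicking_flow_rate(w1, fl, t_s = -1), class = "dmf_invalid_input")
})

# time to absorb `vol` uL through an absorber, by integrating the rate
load_time <- function(absorber, vol = 100, dt = 0.25) {
  t <- 0; loaded <- 0
  while (loaded < vol) {
    loaded <- loaded + wicking_flow_rate(absorber, ref_fluid(), t_s = t) * dt
    t <- t + dt
  }
  t
}

test_that("absorber calibration reproduces the loading-time orderings", {
  # thicker paper (390 um) loads 100 uL faster than thinner (180 um)
  t_thick <- load_time(absorber_spec("paper", 390, 6))
  t_thin <- load_time(absorber_spec("paper", 180, 11))
  expect_lt(t_thick, t_thin)
  expect_gt(t_thin, 120)   # the slow paper takes minutes, not seconds
  # a 15-ply stack roughly halves the single-ply loading time
  t_1 <- load_time(absorber_spec("paper", 200, 2.5))
  t_15 <- load_time(absorber_spec("paper_stack", 200, 2.5, layers = 15))
  expect_gt(t_15 / t_1, 0.3)
  expect_lt(t_15 / t_1, 0.7)
})

test_that("bead retention against flow follows the Stokes force balance", {
  beads <- bead_population(1000)
  fl <- ref_fluid()
  expect_identical(bead_retained_fraction(0, beads, fl), 1)
  # no magnetic force: every bead washes away at any positive velocity
  loose <- bead_population(1000, force_median_nN = 0)
  expect_identical(bead_retained_fraction(0.01, loose, fl), 0)
  # retention passes through 1/2 at the median threshold velocity
  v_star <- beads$force_median / (6 * pi * fl$viscosity * beads$diameter / 2)
  expect_equal(bead_retained_fraction(v_star, beads, fl), 0.5)
  # monotone: non-increasing in velocity, non-decreasing in force scale
  v <- seq(0, 5 * v_star, length.out = 30)
  expect_true(all(diff(bead_retained_fraction(v, beads, fl)) <= 0))
  strong <- bead_population(1000, force_median_nN = 0.4)
  expect_true(all(bead_retained_fraction(v, strong, fl) >=
                  bead_retained_fraction(v, beads, fl)))
  expect_error(bead_retained_fraction(-1, beads, fl),
               class = "dmf_invalid_input")
})

test_that("passive loading loses a substantial bead fraction at high flow", {
  sap25 <- absorber_spec("SAP", sap_mass_mg = 25)
  res <- simulate_passive(100, bead_population(5000), sap25, seed = 101)
  expect_lt(res$beads_retained / res$input_beads, 0.90)
  expect_gt(res$beads_retained / res$input_beads, 0.60)
  expect_equal(res$waste_total + res$retained_droplet, res$input_volume)
  # zero flow: no drag, full retention
  dry <- simulate_passive(100, bead_population(500),
                          absorber_spec("SAP", sap_mass_mg = 0), seed = 1)
  expect_identical(dry$beads_retained, 500L)
  # degenerate: no beads at all, volumes still conserved
  none <- simulate_passive(50, bead_population(0), sap25, seed = 1)
  expect_identical(none$beads_retained + none$beads_lost, 0L)
  expect_equal(none$waste_total + none$retained_droplet, 50)
})

test_that("parallel loading at DMF-limited velocity retains essentially all beads", {
  res <- simulate_parallel(100, 4, bead_population(5272), seed = 7)
  expect_gte(res$beads_retained / res$input_beads, 0.99)
  expect_equal(res$waste_total + res$retained_droplet, 100)
  # a single sub-volume is the same computation as the explicit vector form
  a <- simulate_parallel(60, 1, bead_population(800), seed = 5)
  b <- simulate_parallel(60, c(60), bead_population(800), seed = 5)
  expect_identical(a$beads_retained, b$beads_retained)
  # unequal sub-volumes: conservation still exact
  u <- simulate_parallel(100, c(40, 35, 25), bead_population(1000), seed = 9)
  expect_equal(u$waste_total + u$retained_droplet, 100)
  expect_identical(u$beads_retained + u$beads_lost, 1000L)
  expect_error(simulate_parallel(100, c(30, 30), bead_population(10)),
               class = "dmf_invalid_input")
})

test_that("stepwise loading runs 12 closed-loop cycles on a 100 uL sample", {
  sw <- simulate_stepwise(100, 9, bead_population(5000), seed = 17)
  expect_length(sw$result$segments, 12)
  expect_identical(max(sw$log$cycle), 12L)
  expect_gte(sw$result$beads_retained / 5000, 0.98)
  expect_equal(sw$result$waste_total + sw$result$retained_droplet, 100)
  # loading time is the final waste-removal transition
  expect_equal(sw$result$loading_time, max(sw$log$t_transition))
  # a sample of exactly one nominal segment runs a single cycle
  one <- simulate_stepwise(9, 9, bead_population(100), seed = 2)
  expect_length(one$result$segments, 1)
  expect_identical(max(one$log$cycle), 1L)
})

test_that("stepwise simulation is bit-identical under a fixed seed", {
  a <- simulate_stepwise(36, 9, bead_population(500), noise_sd = 0.5, seed = 77)
  b <- simulate_stepwise(36, 9, bead_population(500), noise_sd = 0.5, seed = 77)
  expect_identical(a$trace$capacitance, b$trace$capacitance)
  expect_identical(unclass(a$result), unclass(b$result))
  expect_identical(a$log$t_transition, b$log$t_transition)
  c <- simulate_stepwise(36, 9, bead_population(500), noise_sd = 0.5, seed = 78)
  expect_false(identical(a$trace$capacitance, c$trace$capacitance))
})

test_that("trace synthesizer honours its calibration", {
  # no segments: flat 100 pF baseline
  flat <- synth_capacitance_trace(numeric(0))
  expect_true(all(flat$capacitance == 100))
  # 4.5 uL: load plateau at 175 pF (150 pF per 9 uL slope)
  half <- synth_capacitance_trace(4.5)
  ev <- attr(half, "events")
  expect_equal(ev$plateau_level[ev$phase == "LOAD"], 175)
  # determinism of the noise stream
  s1 <- synth_capacitance_trace(c(9, 9), noise_sd = 1, seed = 4)
  s2 <- synth_capacitance_trace(c(9, 9), noise_sd = 1, seed = 4)
  expect_identical(s1$capacitance, s2$capacitance)
  expect_error(synth_capacitance_trace(9, noise_sd = -1),
               class = "dmf_invalid_input")
})

test_that("volume and bead conservation hold across randomized runs of all strategies", {
  withr::with_seed(55, {
    for (i in 1:20) {
      vol <- sample(20:120, 1)
      nb <- sample(0:2000, 1)
      beads <- bead_population(nb)
      res <- switch(sample(c("passive", "parallel", "stepwise"), 1),
        passive = simulate_passive(vol, beads,
                                   absorber_spec("SAP", sap_mass_mg = 25)),
        parallel = simulate_parallel(vol, sample(1:5, 1), beads),
        stepwise = simulate_stepwise(vol, 9, beads)$result)
      expect_equal(res$waste_total + res$retained_droplet, vol,
                   tolerance = 1e-12)
      expect_identical(res$beads_retained + res$beads_lost, as.integer(nb))
    }
  })
})

test_that("retention ordering across strategies matches the device comparison", {
  beads <- function() bead_population(5000)
  r_pass <- simulate_passive(100, beads(),
                             absorber_spec("SAP", sap_mass_mg = 25),
                             seed = 201)
  r_par <- simulate_parallel(100, 4, beads(), seed = 202)
  r_step <- simulate_stepwise(100, 9, beads(), seed = 203)$result
  f <- function(r) r$beads_retained / r$input_beads
  expect_gt(f(r_par), f(r_pass))
  expect_gt(f(r_step), f(r_pass))
  expect_lt(abs(f(r_step) - f(r_par)), 0.02)  # stepwise ~ parallel
})
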