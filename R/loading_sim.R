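# Physics-driven simulators of the three sample-loading strategies
# (passive, parallel, stepwise) with magnetic-bead retention accounting,
# and the synthetic capacitance-trace generator that feeds the closed-loop
# controller.

#' Waste-absorber specification
#'
#' Describes the absorptive medium in the waste collection area: a single
#' paper wick, a multi-ply paper stack, or superabsorbent polymer (SAP, e.g.
#' sodium polyacrylate) fed by a wick.
#'
#' @param kind `"paper"`, `"paper_stack"` or `"SAP"`.
#' @param thickness_um paper thickness per ply, um.
#' @param pore_size_um nominal pore size, um.
#' @param layers number of plies (>= 1).
#' @param sap_mass_mg SAP mass in mg (used when `kind = "SAP"`).
#' @param permeability_m2 Darcy permeability, m^2; by default derived from
#'   the pore size via a Kozeny-type relation `pore^2 / 500`.
#' @param wick_width_mm in-plane width of the absorbing strip, mm
#'   (default 20).
#' @param porosity void fraction of the paper (default 0.7).
#' @param interply_efficiency fractional contribution of each ply beyond the
#'   first to the effective cross-section (default 0.03). Stacked plies share
#'   one line source, so inter-ply contact resistance makes the gain from
#'   stacking strongly sub-linear; the default is calibrated once so a
#'   15-ply stack roughly halves the single-ply loading time.
#' @param sap_rate_ul_s_mg SAP sink strength, uL/s per mg (default 0.08).
#' @return an object of class `absorber_spec`.
#' @export
absorber_spec <- function(kind = c("paper", "paper_stack", "SAP"),
                          thickness_um = 180, pore_size_um = 11, layers = 1,
                          sap_mass_mg = 0, permeability_m2 = NULL,
                          wick_width_mm = 20, porosity = 0.7,
                          interply_efficiency = 0.03,
                          sap_rate_ul_s_mg = 0.08) {
  kind <- match.arg(kind)
  if (layers < 1) stop_invalid("invalid absorber: layers must be >= 1")
  if (thickness_um <= 0 || pore_size_um <= 0 || wick_width_mm <= 0)
    stop_invalid("invalid absorber: dimensions must be positive")
  if (sap_mass_mg < 0) stop_invalid("invalid absorber: sap_mass_mg must be >= 0")
  if (is.null(permeability_m2))
    permeability_m2 <- (pore_size_um * 1e-6)^2 / 500
  structure(list(kind = kind, thickness = thickness_um * 1e-6,
                 pore_size = pore_size_um * 1e-6, layers = as.integer(layers),
                 sap_mass = sap_mass_mg, permeability = permeability_m2,
                 wick_width = wick_width_mm * 1e-3, porosity = porosity,
                 interply_efficiency = interply_efficiency,
                 sap_rate = sap_rate_ul_s_mg),
            class = "absorber_spec")
}

#' Magnetic bead population
#'
#' @param count number of beads (>= 0).
#' @param diameter_um bead diameter, um (default 2.7, superparamagnetic
#'   assay beads).
#' @param force_median_nN median of the per-bead maximum magnetic trapping
#'   force, nN (default 0.22, calibrated so passive loading at the fast
#'   25 mg-SAP operating point loses ~15% of beads).
#' @param force_sdlog log-scale dispersion of the per-bead force
#'   (log-normal; default 0.4). Captures bead-to-bead and positional
#'   variation of the trapping force over the magnetic lens.
#' @return an object of class `bead_population`.
#' @export
bead_population <- function(count, diameter_um = 2.7, force_median_nN = 0.22,
                            force_sdlog = 0.4) {
  if (!is.finite(count) || count < 0)
    stop_invalid("invalid beads: count must be >= 0")
  if (diameter_um <= 0) stop_invalid("invalid beads: diameter must be positive")
  if (force_median_nN < 0 || force_sdlog < 0)
    stop_invalid("invalid beads: force parameters must be >= 0")
  structure(list(count = as.integer(round(count)),
                 diameter = diameter_um * 1e-6,
                 force_median = force_median_nN * 1e-9,
                 force_sdlog = force_sdlog),
            class = "bead_population")
}

#' Per-cycle loading ledger
#'
#' Conservation-checked record of a loading run: volumes are conserved to
#' float tolerance (waste + retained droplet = input volume) and bead counts
#' exactly (retained + lost = input count).
#'
#' @param strategy `"passive"`, `"parallel"` or `"stepwise"`.
#' @param loading_time_s total loading time, s.
#' @param segments_ul per-cycle (or per-sub-volume) volumes, uL.
#' @param waste_total_ul total waste volume, uL.
#' @param retained_droplet_ul final retained droplet volume, uL.
#' @param beads_retained,beads_lost integer bead counts.
#' @param input_volume_ul,input_beads the inputs, for the conservation check.
#' @return an object of class `loading_result`.
#' @export
loading_result <- function(strategy, loading_time_s, segments_ul,
                           waste_total_ul, retained_droplet_ul,
                           beads_retained, beads_lost,
                           input_volume_ul, input_beads) {
  if (abs(waste_total_ul + retained_droplet_ul - input_volume_ul) > 1e-9)
    stop_invalid("conservation violation: waste + retained != input volume")
  if (beads_retained + beads_lost != input_beads)
    stop_invalid("conservation violation: bead counts do not sum to input")
  structure(list(strategy = strategy, loading_time = loading_time_s,
                 segments = segments_ul, waste_total = waste_total_ul,
                 retained_droplet = retained_droplet_ul,
                 beads_retained = as.integer(beads_retained),
                 beads_lost = as.integer(beads_lost),
                 input_volume = input_volume_ul,
                 input_beads = as.integer(input_beads)),
            class = "loading_result")
}

#' @export
print.loading_result <- function(x, ...) {
  cat(sprintf("<loading_result> strategy: %s\n", x$strategy))
  cat(sprintf("  input %.2f uL in %d segment(s); loading time %.1f s\n",
              x$input_volume, length(x$segments), x$loading_time))
  cat(sprintf("  waste %.2f uL, retained droplet %.2f uL\n",
              x$waste_total, x$retained_droplet))
  ret <- if (x$input_beads > 0) 100 * x$beads_retained / x$input_beads else NA
  cat(sprintf("  beads: %d retained / %d lost of %d (%.1f%% retention)\n",
              x$beads_retained, x$beads_lost, x$input_beads, ret))
  invisible(x)
}

#' Wicking flow rate into the waste absorber
#'
#' Darcy/Washburn model of capillary imbibition. For paper, the wetted front
#' advances as `l(t) = sqrt(l0^2 + 2 K pc t / (phi mu))` (capillary pressure
#' `pc = 4 sigma / pore`), and the volumetric uptake is
#' `Q(t) = A_eff K pc / (mu l(t))`, decreasing in time; the effective
#' cross-section `A_eff` grows with ply thickness and (sub-linearly, through
#' inter-ply contact resistance) with the number of plies. SAP acts as a
#' near-constant sink whose strength scales with its mass.
#'
#' @param absorber an [absorber_spec()].
#' @param fluid a [fluid_state()].
#' @param geom a [device_geometry()] (unused by the absorber model itself;
#'   kept for interface symmetry with the loading simulators).
#' @param t_s elapsed time since imbibition began, s (>= 0); vectorised.
#' @param l0_mm initial wetted length (wick penetration into the device), mm.
#' @return volumetric flow rate in uL/s.
#' @export
wicking_flow_rate <- function(absorber, fluid, geom = device_geometry(),
                              t_s = 0, l0_mm = 5) {
  stopifnot(inherits(absorber, "absorber_spec"), inherits(fluid, "fluid_state"))
  if (any(t_s < 0)) stop_invalid("invalid input: t_s must be >= 0")
  if (absorber$kind == "SAP")
    return(rep(absorber$sap_rate * absorber$sap_mass, length(t_s)))
  eff_layers <- 1 + absorber$interply_efficiency * (absorber$layers - 1)
  a_eff <- absorber$wick_width * absorber$thickness * eff_layers
  pc <- 4 * fluid$sigma / absorber$pore_size
  l0 <- l0_mm * 1e-3
  b <- 2 * absorber$permeability * pc / (absorber$porosity * fluid$viscosity)
  l <- sqrt(l0^2 + b * t_s)
  q_m3 <- a_eff * absorber$permeability * pc / (fluid$viscosity * l)
  q_m3 * 1e9
}

# Stokes drag on a bead of radius r at velocity v in fluid mu: 6 pi mu r v.
stokes_drag <- function(viscosity, radius, velocity) {
  6 * pi * viscosity * radius * velocity
}

#' Fraction of a bead population retained against flow
#'
#' A bead stays on the magnetic trap iff its maximum magnetic force is at
#' least the Stokes drag `6 pi mu r v`. With per-bead forces log-normally
#' distributed, the retained fraction is the survival function of that
#' distribution evaluated at the drag: 1 at zero velocity, non-increasing in
#' velocity, dropping through 0.5 at the threshold velocity
#' `v* = F_median / (6 pi mu r)`.
#'
#' @param flow_velocity_m_s flow velocity over the trap, m/s (>= 0);
#'   vectorised.
#' @param beads a [bead_population()].
#' @param fluid a [fluid_state()].
#' @return expected retained fraction in [0, 1].
#' @export
bead_retained_fraction <- function(flow_velocity_m_s, beads, fluid) {
  stopifnot(inherits(beads, "bead_population"), inherits(fluid, "fluid_state"))
  if (any(flow_velocity_m_s < 0))
    stop_invalid("invalid input: velocity must be >= 0")
  drag <- stokes_drag(fluid$viscosity, beads$diameter / 2, flow_velocity_m_s)
  if (beads$force_median <= 0) return(as.numeric(drag <= 0))
  if (beads$force_sdlog == 0) return(as.numeric(beads$force_median >= drag))
  ifelse(drag <= 0, 1,
         plnorm(drag, log(beads$force_median), beads$force_sdlog,
                lower.tail = FALSE))
}

# Draw per-bead maximum magnetic forces (N).
draw_bead_forces <- function(beads) {
  if (beads$count == 0) return(numeric(0))
  if (beads$force_median <= 0) return(rep(0, beads$count))
  if (beads$force_sdlog == 0) return(rep(beads$force_median, beads$count))
  rlnorm(beads$count, log(beads$force_median), beads$force_sdlog)
}

#' Device-specific capacitance calibration of the trace synthesizer
#'
#' The pF values are calibration fixtures of the instrument, not physics
#' predictions: an empty channel reads ~100 pF, a fully loaded ~9 uL segment
#' ~250 pF (hence the slope of 150 pF per 9 uL), and the split event ~320 pF.
#' Dwell (plateau) durations are compressed relative to real runs; ramps use
#' a fixed slew rate because liquid covers the final sensing electrode
#' quickly compared with the 15-sample stability window.
#'
#' @param baseline_pF empty-channel capacitance (default 100).
#' @param slope_pF_per_ul capacitance rise per uL loaded (default 150/9).
#' @param split_pF capacitance at the split event (default 320).
#' @param sample_rate sampling rate, Hz (default 40).
#' @param ramp_rate_pF_s slew rate of capacitance ramps (default 500).
#' @param load_hold_s,split_hold_s,baseline_hold_s plateau dwell times, s.
#' @param lead_in_s baseline samples emitted before the first cycle, s.
#' @return an object of class `trace_calibration`.
#' @export
trace_calibration <- function(baseline_pF = 100, slope_pF_per_ul = 150 / 9,
                              split_pF = 320, sample_rate = 40,
                              ramp_rate_pF_s = 500, load_hold_s = 2,
                              split_hold_s = 2, baseline_hold_s = 2,
                              lead_in_s = 0.5) {
  structure(list(baseline = baseline_pF, slope = slope_pF_per_ul,
                 split = split_pF, sample_rate = sample_rate,
                 ramp_rate = ramp_rate_pF_s, load_hold = load_hold_s,
                 split_hold = split_hold_s, baseline_hold = baseline_hold_s,
                 lead_in = lead_in_s),
            class = "trace_calibration")
}

# Ramp from `prev` to `level`, anchored at the end so the final ramp sample
# sits one full per-sample step away from the plateau; this keeps the rolling
# stability index above threshold until the window lies fully in the plateau.
.ramp_samples <- function(prev, level, step) {
  a <- level - prev
  if (a == 0) return(numeric(0))
  m <- floor(abs(a) / step)
  if (m == 0) return(numeric(0))
  level - sign(a) * step * (m:1)
}

#' Synthesize a closed-loop capacitance trace for a segment plan
#'
#' Per segment: baseline -> ramp to `baseline + slope * volume` (load
#' plateau) -> ramp to the split level -> fall back to baseline. Optional
#' additive Gaussian noise; seeded for reproducibility. The true plateau
#' onset times are attached as `attr(trace, "events")` (a data frame with
#' `cycle`, `phase`, `plateau_time`, `plateau_level`), which is what the
#' closed-loop timing oracle consumes.
#'
#' @param segments_ul numeric vector of segment volumes, uL (may be empty:
#'   a flat baseline trace results).
#' @param calib a [trace_calibration()].
#' @param noise_sd additive Gaussian noise SD, pF (>= 0; default 0).
#' @param seed optional integer seed.
#' @return a [capacitance_trace()] with an `events` attribute.
#' @examples
#' tr <- synth_capacitance_trace(c(9, 9, 9))
#' attr(tr, "events")
#' @export
synth_capacitance_trace <- function(segments_ul, calib = trace_calibration(),
                                    noise_sd = 0, seed = NULL) {
  stopifnot(inherits(calib, "trace_calibration"))
  if (noise_sd < 0) stop_invalid("invalid input: noise_sd must be >= 0")
  dt <- 1 / calib$sample_rate
  step <- calib$ramp_rate * dt
  hold <- function(level, dur) rep(level, max(1L, round(dur / dt)))
  vals <- hold(calib$baseline, calib$lead_in)
  ev <- list()
  for (i in seq_along(segments_ul)) {
    load_level <- calib$baseline + calib$slope * segments_ul[i]
    prev <- calib$baseline
    vals <- c(vals, .ramp_samples(prev, load_level, step))
    ev[[length(ev) + 1L]] <- c(i, 1, length(vals) + 1L, load_level)
    vals <- c(vals, hold(load_level, calib$load_hold))
    vals <- c(vals, .ramp_samples(load_level, calib$split, step))
    ev[[length(ev) + 1L]] <- c(i, 2, length(vals) + 1L, calib$split)
    vals <- c(vals, hold(calib$split, calib$split_hold))
    vals <- c(vals, .ramp_samples(calib$split, calib$baseline, step))
    ev[[length(ev) + 1L]] <- c(i, 3, length(vals) + 1L, calib$baseline)
    vals <- c(vals, hold(calib$baseline, calib$baseline_hold))
  }
  if (noise_sd > 0)
    vals <- with_seed_opt(seed, vals + rnorm(length(vals), 0, noise_sd))
  vals <- pmax(vals, 0)
  times <- (seq_along(vals) - 1) * dt
  tr <- capacitance_trace(times, vals, sample_rate = calib$sample_rate)
  if (length(ev)) {
    em <- do.call(rbind, ev)
    events <- data.frame(cycle = as.integer(em[, 1]),
                         phase = c("LOAD", "SPLIT", "WASTE_REMOVAL")[em[, 2]],
                         plateau_time = times[em[, 3]],
                         plateau_level = em[, 4])
  } else {
    events <- data.frame(cycle = integer(), phase = character(),
                         plateau_time = numeric(), plateau_level = numeric())
  }
  attr(tr, "events") <- events
  tr
}

# Channel flow velocity (m/s) for a volumetric rate in uL/s.
channel_velocity <- function(q_ul_s, geom) {
  (q_ul_s * 1e-9) / (geom$gap * geom$drive_width)
}

#' Simulate passive loading through a virtual channel
#'
#' The sample is stretched across the device as a virtual channel and waste
#' is continuously pulled into the absorber; the channel flow velocity over
#' the magnetic trap follows the wicking rate (with multiplicative log-normal
#' variability, reflecting the flow-rate variation observed in the channel)
#' and each bead is retained iff its magnetic force beats the Stokes drag at
#' its moment of passage.
#'
#' @param volume_ul sample volume, uL.
#' @param beads a [bead_population()].
#' @param absorber an [absorber_spec()].
#' @param geom a [device_geometry()].
#' @param fluid a [fluid_state()].
#' @param retained_droplet_ul residual droplet left on the densifying
#'   electrode, uL (default 0.2).
#' @param flow_noise_sdlog log-SD of the multiplicative flow variability
#'   (default 0.3).
#' @param dt_s integration step, s (default 0.5).
#' @param seed optional integer seed.
#' @return a [loading_result()].
#' @export
simulate_passive <- function(volume_ul, beads, absorber,
                             geom = device_geometry(), fluid = fluid_state(),
                             retained_droplet_ul = 0.2,
                             flow_noise_sdlog = 0.3, dt_s = 0.5, seed = NULL) {
  stopifnot(inherits(beads, "bead_population"))
  if (volume_ul <= 0) stop_invalid("invalid input: volume must be positive")
  retained_droplet_ul <- min(retained_droplet_ul, volume_ul)
  with_seed_opt(seed, {
    n <- beads$count
    if (wicking_flow_rate(absorber, fluid, geom, 0) <= 0) {
      # zero-flow sink: nothing moves, no drag, every bead stays trapped
      return(loading_result("passive", Inf, volume_ul,
                            volume_ul - retained_droplet_ul,
                            retained_droplet_ul, n, 0L, volume_ul, n))
    }
    # integrate the wicking flow until the sample is loaded
    t_cur <- 0; loaded <- 0
    tgrid <- numeric(0); qgrid <- numeric(0); cumv <- numeric(0)
    while (loaded < volume_ul) {
      q <- wicking_flow_rate(absorber, fluid, geom, t_cur)
      if (flow_noise_sdlog > 0) q <- q * rlnorm(1, 0, flow_noise_sdlog)
      loaded <- min(volume_ul, loaded + q * dt_s)
      t_cur <- t_cur + dt_s
      tgrid <- c(tgrid, t_cur); qgrid <- c(qgrid, q); cumv <- c(cumv, loaded)
    }
    if (n > 0) {
      # each bead crosses the trap when its (uniform) share of volume passes
      u <- runif(n) * volume_ul
      idx <- findInterval(u, cumv) + 1L
      idx[idx > length(qgrid)] <- length(qgrid)
      v_bead <- channel_velocity(qgrid[idx], geom)
      forces <- draw_bead_forces(beads)
      kept <- sum(forces >= stokes_drag(fluid$viscosity, beads$diameter / 2,
                                        v_bead))
    } else kept <- 0L
    loading_result("passive", t_cur, volume_ul,
                   volume_ul - retained_droplet_ul, retained_droplet_ul,
                   kept, n - kept, volume_ul, n)
  })
}

#' Simulate parallel loading of off-chip sub-volumes
#'
#' The sample is split off-chip into sub-volumes small enough to load fully
#' without simultaneous waste extraction; each is processed at the
#' DMF-limited transport velocity (which can be kept low), and the retained
#' droplets are merged and re-densified into a single final droplet.
#'
#' @param volume_ul total sample volume, uL.
#' @param sub_volumes either a count (equal split) or a numeric vector of
#'   sub-volumes summing to `volume_ul`.
#' @param beads a [bead_population()].
#' @param geom,fluid device and fluid descriptions.
#' @param dmf_velocity_m_s DMF-limited transport velocity (default 1e-3,
#'   i.e. 1 mm/s).
#' @param retained_droplet_ul final residual droplet, uL (default 0.2).
#' @param seed optional integer seed.
#' @return a [loading_result()].
#' @export
simulate_parallel <- function(volume_ul, sub_volumes = 4, beads,
                              geom = device_geometry(), fluid = fluid_state(),
                              dmf_velocity_m_s = 1e-3,
                              retained_droplet_ul = 0.2, seed = NULL) {
  stopifnot(inherits(beads, "bead_population"))
  if (volume_ul <= 0) stop_invalid("invalid input: volume must be positive")
  if (length(sub_volumes) == 1 && sub_volumes == round(sub_volumes) &&
      sub_volumes >= 1) {
    subs <- rep(volume_ul / sub_volumes, sub_volumes)
  } else {
    subs <- as.numeric(sub_volumes)
    if (abs(sum(subs) - volume_ul) > 1e-9)
      stop_invalid("invalid input: sub-volumes must sum to the total volume")
  }
  retained_droplet_ul <- min(retained_droplet_ul, volume_ul)
  with_seed_opt(seed, {
    n <- beads$count
    kept <- 0L
    if (n > 0) {
      alloc <- as.vector(rmultinom(1, n, subs / sum(subs)))
      forces <- draw_bead_forces(beads)
      drag <- stokes_drag(fluid$viscosity, beads$diameter / 2, dmf_velocity_m_s)
      split_f <- split(forces, rep(seq_along(subs), alloc))
      kept <- sum(vapply(split_f, function(f) sum(f >= drag), numeric(1)))
    }
    # sub-volumes run two at a time through the paired reservoirs
    transit <- (subs * 1e-9) / (geom$gap * geom$drive_width) / dmf_velocity_m_s
    batches <- split(transit, ceiling(seq_along(transit) / 2))
    load_time <- sum(vapply(batches, max, numeric(1)))
    loading_result("parallel", load_time, subs,
                   volume_ul - retained_droplet_ul, retained_droplet_ul,
                   kept, n - kept, volume_ul, n)
  })
}

#' Simulate stepwise loading under closed-loop capacitance control
#'
#' Plans ~9 uL segments with [plan_segments()], synthesizes the per-cycle
#' capacitance trace, runs the closed-loop controller against it, and
#' accounts bead retention segment by segment at the DMF-limited velocity.
#' Segments too small to produce a detectable capacitance rise
#' (below `rise_delta / slope` uL) are folded into the preceding segment, the
#' in-silico counterpart of over-sizing the final hard-to-split segments.
#'
#' @param volume_ul total sample volume, uL.
#' @param nominal_segment_ul nominal segment volume, uL (default 9).
#' @param beads a [bead_population()].
#' @param geom,fluid device and fluid descriptions.
#' @param config a [controller_config()].
#' @param calib a [trace_calibration()].
#' @param noise_sd capacitance noise SD, pF (default 0.5).
#' @param dmf_velocity_m_s DMF-limited transport velocity (default 1 mm/s).
#' @param retained_droplet_ul final residual droplet, uL (default 0.2).
#' @param policy segment-planning policy (see [plan_segments()]).
#' @param seed optional integer seed (fanned out to trace synthesis and bead
#'   accounting substreams).
#' @return a list with elements `result` (a [loading_result()]), `trace`
#'   (the synthesized [capacitance_trace()]) and `log` (the controller's
#'   `cycle_log`).
#' @export
simulate_stepwise <- function(volume_ul, nominal_segment_ul = 9, beads,
                              geom = device_geometry(), fluid = fluid_state(),
                              config = controller_config(),
                              calib = trace_calibration(), noise_sd = 0.5,
                              dmf_velocity_m_s = 1e-3,
                              retained_droplet_ul = 0.2,
                              policy = "default", seed = NULL) {
  stopifnot(inherits(beads, "bead_population"))
  if (volume_ul <= 0) stop_invalid("invalid input: volume must be positive")
  plan <- plan_segments(volume_ul, nominal_segment_ul, policy)
  min_detectable <- config$rise_delta / calib$slope
  while (length(plan) > 1 && plan[length(plan)] < min_detectable) {
    plan <- c(plan[seq_len(length(plan) - 2)],
              plan[length(plan) - 1] + plan[length(plan)])
  }
  retained_droplet_ul <- min(retained_droplet_ul, volume_ul)
  trace <- synth_capacitance_trace(plan, calib, noise_sd = noise_sd,
                                   seed = if (is.null(seed)) NULL else seed + 1L)
  log <- run_closed_loop(trace, plan, config)
  kept <- 0L
  n <- beads$count
  if (n > 0) {
    kept <- with_seed_opt(if (is.null(seed)) NULL else seed + 2L, {
      alloc <- as.vector(rmultinom(1, n, plan / sum(plan)))
      forces <- draw_bead_forces(beads)
      drag <- stokes_drag(fluid$viscosity, beads$diameter / 2, dmf_velocity_m_s)
      sum(forces >= drag)
    })
  }
  res <- loading_result("stepwise", max(log$t_transition), plan,
                        volume_ul - retained_droplet_ul, retained_droplet_ul,
                        kept, n - kept, volume_ul, n)
  list(result = res, trace = trace, log = log)
}
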