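# Small builders used across tests. The default stack/geometry/fluid are the
# device operating point; helpers only shorten call sites.

ref_stack <- function() dielectric_stack(6, 3.1)
ref_geom <- function(...) device_geometry(...)
ref_fluid <- function(...) fluid_state(...)

# A random but valid geometry/fluid pair in the experimentally relevant box
# (densifying electrode smaller than the drive electrode).
random_geom_fluid <- function() {
  w <- runif(1, 1.5, 3.5)
  d <- runif(1, 0.4, 0.9 * w)
  list(geom = device_geometry(gap_um = runif(1, 120, 260),
                              drive_width_mm = w, densify_minor_mm = d),
       fluid = fluid_state(sigma_mN_m = runif(1, 25, 72),
                           viscosity_mPa_s = runif(1, 0.8, 1.5),
                           k_factor = runif(1, 0.05, 0.95)))
}

# Manual rolling population SD oracle (direct evaluation of the formula).
rolling_pop_sd <- function(x, w) {
  vapply(seq_along(x), function(i) {
    if (i < w) return(NA_real_)
    win <- x[(i - w + 1):i]
    sqrt(mean((win - mean(win))^2))
  }, numeric(1))
}
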