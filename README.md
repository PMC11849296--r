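# dmfsimoa

Physics-based simulators and statistics for digital-microfluidic (DMF)
front-end processing of single-molecule array (Simoa) bead assays.

## The problem

Digital immunoassays count single molecules captured on antibody-coated
magnetic beads: each bead is read out as on/off, and the mean label number
per bead is recovered from the positive fraction by Poisson inversion. High
sensitivity needs *large samples* (at 1 aM, a 1 µL sample contains < 1
molecule in expectation; 100 µL contains ~60, since `E[N] = c·V·N_A`) and
*few beads* (~5000, to concentrate molecules per bead) — but DMF devices
hold ~1 µL per electrode, and magnetic retention of so few beads is
fragile. This package implements, as tested simulators, the computational
core of a DMF sample-processing method that closes that gap:

- **Electrowetting/pressure models** — areal capacitance
  `c = ε₀εᵣ/t`, Young–Lippmann driving force `F = ½cV²L`, the
  densifying-electrode pressure imbalance
  `Δp = σ[k·g₀ − 2/d − 1/(w−d)]` (with `g₀ = −2cosθ₀/h`) that governs
  whether a small droplet is retained over the bead pellet at splitting,
  and the reservoir Laplace pressure that makes final cycles hard.
- **Closed-loop capacitance controller** — the rolling-SD *stability index*
  (15 samples, 2 pF threshold at ~40 Hz) driving the
  LOAD → SPLIT → WASTE_REMOVAL state machine, plus the ~9 µL segment
  planner (12 cycles for 100 µL).
- **Loading-strategy simulators** — passive (Darcy/Washburn wicking into
  paper or superabsorbent-polymer waste absorbers; beads lost when Stokes
  drag `6πμrv` beats the log-normal per-bead magnetic force), parallel
  (off-chip sub-volumes at DMF-limited velocity), and stepwise (segments
  under the real closed-loop controller, fed by a synthetic capacitance
  trace with the 100/250/320 pF cycle signature).
- **Digital counting statistics** — expected molecule numbers, multinomial
  molecule-to-bead distribution, the Poisson-corrected readout
  `AEB = −ln(1 − f_on)`, bead-retention percentages, and the bead-number
  sensitivity trade-off.
- **Bead imaging** — a synthetic brightfield renderer and a counting
  pipeline (Otsu threshold, connected components, area filter with cluster
  splitting).

Everything is generated in-package; no hardware or external data is
required. See `vignettes/dmf-simoa-methods.Rmd` for the models, defaults,
and their rationale.

## Worked example

```r
library(dmfsimoa)

# DMF driving force at the upper operating corner:
# 140 V_RMS over a 1.0 mm contact line, 6 um parylene, eps_r = 3.1
f <- young_lippmann_force(actuation_state(140), 1.0, dielectric_stack(6, 3.1))
sprintf("force: %.1f uN", f * 1e6)
#> "force: 44.8 uN"   # the top of the ~15-45 uN retention window

# Droplet-retention pressure imbalance at the operating point
# (round 1.0 mm densifying electrode, w = 2.2 mm, sigma = 42 mN/m, k = 0.6)
retention_pressure_imbalance(device_geometry(), fluid_state())
#> 13.6   # Pa; positive = breakup-favourable, the droplet is retained

# Stepwise-load 100 uL carrying 5000 beads under closed-loop control
sw <- simulate_stepwise(100, 9, bead_population(5000), seed = 1)
sw$result
#> <loading_result> strategy: stepwise
#>   input 100.00 uL in 12 segment(s); loading time 81.1 s
#>   waste 99.80 uL, retained droplet 0.20 uL
#>   beads: 5000 retained / 0 lost of 5000 (100.0% retention)

# Digital counting: 500 molecules on 5000 beads -> lambda = 0.1
st <- distribute_molecules(500, 5000, seed = 1)
c(f_on = mean(st$counts >= 1), AEB = aeb_estimate(st))
#>   f_on    AEB
#> 0.0940 0.0987   # -ln(1 - f_on) recovers the mean labels per bead
```

The 12 cycles are decided by the controller replaying the synthesized
capacitance trace, not by the plan; the 0.2 µL retained droplet is the
residual volume a 1 mm densifying electrode leaves over the bead pellet
(0.2% of the original sample).

A thin command-line wrapper is installed at `inst/cli/dmf-sim`
(`dmf-sim simulate-loading --strategy stepwise --seed 1 --out DIR`, plus
`run-controller`, `gen-trace`, `assay-sim`, `count-beads`); configuration
is YAML with unit-suffixed keys (see `default_run_config()`).

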