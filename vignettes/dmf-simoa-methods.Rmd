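---
title: "Models and methods behind the DMF bead-processing simulators"
author: "dmfsimoa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the DMF bead-processing simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmfsimoa)
```

## The problem

Ultrasensitive digital immunoassays count single analyte molecules captured
on antibody-coated magnetic beads. At attomolar concentrations a 1 µL sample
holds less than one molecule in expectation, so useful sensitivity requires
processing ~100 µL of sample onto a small bead population (~5000 beads) —
two orders of magnitude more liquid than a digital-microfluidic (DMF)
electrode can hold, and two orders of magnitude fewer beads than a magnet
can pellet reliably. This package simulates the front-end that bridges that
gap: pulling a large sample through a two-plate DMF device over a magnetic
trap while a small *densifying electrode* holds a residual droplet over the
bead pellet, with waste drawn off by an absorber or split away cycle by
cycle under closed-loop capacitance feedback. Every component is synthetic:
no hardware, images, or recorded traces are needed.

## Electrowetting and pressure models

**Young–Lippmann force.** The areal capacitance of the dielectric stack is
$c = \varepsilon_0 \varepsilon_r / t$; an energized electrode pulls on the
droplet edge with $F = \tfrac12 c V^2 L$ over an actuated contact line of
length $L$. With the device stack (6 µm parylene, $\varepsilon_r = 3.1$) the
110–140 V$_\mathrm{RMS}$ range over 0.6–1.0 mm contact lines spans roughly
15–45 µN, which is the force window in which droplet retention on the
densifying electrode goes from never to always.

**Retention pressure imbalance.** During the splitting stroke the retained
droplet (pressure $p_1$, over the active densifying electrode of minor
diameter $d$) connects through a necking region (pressure $p_2$) to the
moving droplet on the destination electrode of width $w$. Each pressure is a
pancake-droplet Laplace pressure
$p = \sigma\,(\kappa_\parallel - (\cos\theta_b + \cos\theta_t)/h)$. We model
the retained droplet with in-plane curvature $2/d$ and an electrowetting
gap term reduced by the factor $(1-k)$, $k \in (0,1)$ being the fractional
contact-angle shift on actuated surfaces (larger at higher voltage, smaller
at higher surfactant concentration); the neck is a saddle with in-plane
radius $a\,(w-d)$ over unactuated surface. This gives

$$\Delta p = p_2 - p_1
  = \sigma\left[k\,g_0 - \frac{2}{d} - \frac{1}{a\,(w-d)}\right],
  \qquad g_0 = -\frac{2\cos\theta_0}{h},$$

which is exactly linear in $\sigma$, strictly increasing in $k$, and
increasing in $w$ with diminishing increments — the three trends the model
must reproduce. A positive $\Delta p$ drains the neck and favours clean
breakup.

Two defaults deserve comment, because the closed-form supplement defining
$k$ and the neck geometry is not reproduced here and the decomposition is a
reconstruction. We take the baseline contact angle on the fluoropolymer
coating as $\theta_0 = 120^\circ$ (within the usual advancing-angle range
for such coatings; $\cos\theta_0 = -1/2$) and the neck in-plane radius as
the full footprint-to-electrode-edge separation ($a = 1$). With a notably
smaller angle (~115°) or a neck radius of half the separation, the model
would put $\Delta p < 0$ at the characterised operating point
($\sigma = 42$ mN/m, $k = 0.6$, $w = 2.2$ mm, round $d = 1.0$ mm,
$h = 190$ µm), contradicting the observation that this point gives reliable
breakup; the chosen defaults give $\Delta p \approx +14$ Pa there while
changing no trend. Only trends and the sign at the operating point are
asserted — the absolute scale of $\Delta p$ is not calibrated against
measurements.

Because $\Delta p$ is linear in $\sigma$, monotonicity in $\sigma$ holds
exactly where the geometric bracket is positive (breakup-favourable
geometries) and reverses where it is negative (e.g. very small densifying
electrodes). The $k$-monotonicity, by contrast, holds for *every* valid
geometry, and is property-tested over randomized geometries; the
$\sigma$-trend is tested over the characterised parameter box.

**Reservoir pressure.** The on-chip reservoir is a pancake droplet of
footprint radius $r = \sqrt{V/(\pi h)}$ and pressure
$\sigma(1/r - (\cos\theta_b+\cos\theta_t)/h)$: as the sample is consumed the
pressure rises, which is why the final splitting cycles of stepwise loading
are the hard ones and why the planner can merge small final segments.

## The closed-loop controller

Liquid covering the actuated electrode path raises the measured capacitance
(~40 samples/s). The controller's only statistic is the *stability index*:
the rolling standard deviation of the last 15 samples (population
convention by default — the streaming-friendly choice; the sample convention
is available and the two differ by the fixed factor
$\sqrt{14/15}$). Each sub-step (LOAD → SPLIT → WASTE_REMOVAL) completes
when, after the capacitance has moved at least `rise_delta` from the
phase-entry baseline, the stability index falls below 2 pF; waste removal
instead requires the capacitance to return to within `rise_delta` of the
global baseline.

`rise_delta` defaults to 10 pF. The guard must sit well above the 2 pF
noise threshold but below the smallest phase excursion it has to detect;
with the device's 150 pF per 9 µL calibration, the default 100 µL plan ends
with a 1 µL segment whose load plateau is only ~17 pF above baseline, so a
20 pF guard would starve the controller on precisely the nominal run while
10 pF detects every plannable segment with a 5× noise margin.

On noiseless synthesized traces the controller admits an exact timing
oracle: a transition fires at the first sample whose 15-sample window lies
wholly inside a plateau, i.e. at the plateau onset plus 14 samples (0.35 s
at 40 Hz). The trace synthesizer guarantees this by slewing ramps at
500 pF/s (≥ 12.5 pF per sample, so any window straddling a ramp keeps its
SD above threshold) and anchoring ramps at the plateau end. Truncated
streams raise an error naming the interrupted phase; a stream whose index
never stabilizes is reported as starvation, never skipped.

**Segment planning.** The default policy takes
$n = \lceil V/V_\mathrm{seg} \rceil$ segments ($n-1$ nominal plus the
remainder; 12 for 100 µL at 9 µL). The `merge-final` policy folds a
remainder below half the nominal into the final segment, mirroring the
practice of over-sizing the final, hardest-to-split segments. Both conserve
volume exactly.

## Loading-strategy simulators

**Bead retention.** A bead stays on the trap iff its maximum magnetic force
exceeds the Stokes drag $6\pi\mu r v$. Per-bead forces are log-normal
(median 0.22 nN, log-SD 0.4 by default) — two parameters that capture
bead-to-bead and positional variation of the trapping force and reproduce
partial-loss behaviour. The median is calibrated once so that passive
loading at the fast-absorber operating point (25 mg of superabsorbent
polymer, ~2 µL/s, ~4.8 mm/s channel velocity) loses ~15% of the beads on
average, while the DMF-limited transport velocity
(default 1 mm/s) loses essentially none — the core quantitative contrast
between the strategies. Note the source reports both "~15%" and "~85%" for
passive-loading bead loss in different passages; the simulator is
calibrated to the 15%-loss reading, which is consistent with the recovered
bead counts, and the discrepancy is documented rather than resolved.

**Wicking (passive loading).** Paper absorbers follow a
Darcy/Lucas–Washburn model: permeability $K = d_\mathrm{pore}^2/500$
(Kozeny-type, the constant calibrated once so a 180 µm / 11 µm-pore paper
loads 100 µL in minutes while a 390 µm / 6 µm-pore paper takes about one),
capillary pressure $4\sigma/d_\mathrm{pore}$, front position
$l(t) = \sqrt{l_0^2 + 2 K p_c t/(\phi\mu)}$ and uptake
$Q = A_\mathrm{eff} K p_c / (\mu\, l(t))$, decreasing in time. Plies beyond
the first contribute only a fraction (default 0.03) of their cross-section
— stacked plies share one line source and inter-ply contact resistance
makes stacking strongly sub-linear — calibrated once so a 15-ply stack
roughly halves the single-ply loading time (pure Darcy linearity would
predict ~15×, and the $t \propto l^2$ imbibition law would amplify it
further). SAP is a near-constant sink of 0.08 µL/s per mg. Flow variability
in the virtual channel is multiplicative log-normal noise (log-SD 0.3) on
the wicking rate.

**Parallel and stepwise loading** both transport beads at the DMF-limited
velocity; parallel splits the sample off-chip (default 4 × 25 µL, loaded in
pairs), stepwise plans segments, synthesizes the capacitance trace, and
runs the actual closed-loop controller against it — the returned ledger's
cycle count and loading time come from the controller, not from the plan.
All strategies conserve volume to 1e-9 µL and bead counts integer-exactly;
the final retained droplet (default 0.2 µL, the residual volume on a 1 mm
densifying electrode) is a configurable fixture.

The capacitance levels (100/250/320 pF, 150 pF per 9 µL) and dwell times in
`trace_calibration()` are device-specific calibration fixtures, not physics
predictions; dwell times are compressed relative to real runs so the
simulated loading time (~80 s for 12 cycles) is shorter than a real ~4 min
run while preserving every controller-visible feature.

## Digital counting statistics

Expected molecule number is $E[N] = c V N_A$, carried as a real expectation
(realized counts are Poisson-sampled only inside simulations). Molecules
distribute over beads multinomially; at molecule-to-bead ratios well below
1 the per-bead occupancy is Poisson to excellent approximation. The digital
readout is the average number of enzyme labels per bead,
$\mathrm{AEB} = -\ln(1 - f_\mathrm{on})$, inverting the Poisson zero class
from the fraction of signal-positive beads ($\mathrm{AEB} \approx
f_\mathrm{on}$ when $f_\mathrm{on}$ is small); it errors at saturation
($f_\mathrm{on} = 1$). Retention percentages implement both counting
conventions (from the waste droplet and from the recovered droplet), which
are exact complements.

The bead-number trade-off table uses a saturating capture model
$\eta(n) = 1 - e^{-n/n_0}$ (default scale $n_0 = 10^4$ beads) with
molecules per bead $E[N]\,\eta(n)/n$. The functional form is a
reconstruction: only the two monotone trends (efficiency rises with bead
number, per-bead signal falls) are asserted, not the location of any
optimum.

## Synthetic bead images

The renderer places non-overlapping dark anti-aliased disks (linear edge
coverage) on a bright background, with optional Gaussian noise — it
emulates monodisperse 2.7 µm beads in brightfield at ~0.325 µm/px and
nothing else (no illumination gradients, focus blur, debris, or clusters
beyond what the separation limit allows). The counter normalises
intensities (making it invariant to global offsets), applies an Otsu
threshold, labels connected components (via `EBImage`), and filters by
area: objects within ±40% of the expected single-bead area count as one
bead, objects near $k$× that area count as $k$ (default cap 3; both the
tolerance and the cap are configurable, and cluster splitting can be
disabled). Passing tests on these images shows the pipeline recovers
ground truth under its own imaging model; it says nothing about microscopy
artifacts the renderer does not emulate.

## Randomness, units, and problem sizes

Every stochastic operation takes a `seed` and restores the caller's RNG
state; compound simulations fan a single seed out to fixed per-stage
offsets, so adding a stage never perturbs an earlier stage's randomness.
Interfaces accept laboratory units (µm, mm, µL, mN/m, pF, V) and convert to
SI at the boundary; all internal state is SI.

The test-suite problem sizes are the package's own choices for a
desk-scale, reproducible run: 1000 randomized conservation simulations at
5–150 µL and up to 500 beads; AEB recovery at 5000 beads × 200 replicates;
image recovery at up to 400 beads in a 1024² frame. Larger runs only
tighten the same Monte-Carlo comparisons.

## Known limitations

No electrohydrodynamics, contact-angle saturation, AC-frequency effects, or
droplet shape relaxation; no spatially resolved bead trajectories or
magnetic field maps; no absorber swelling or evaporation; the $\Delta p$
scale and the capture-efficiency scale are uncalibrated reconstructions;
experimental quantities (measured loading times, measured retention of real
beads, retained-volume measurements, immunoassay calibration curves) are
out of scope and enter only as labelled calibration fixtures.
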