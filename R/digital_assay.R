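# Poisson statistics of digital single-molecule counting: expected molecule
# numbers, molecule-to-bead distribution, the Poisson-corrected
# average-enzymes-per-bead (AEB) readout, bead-retention percentages and the
# bead-number sensitivity trade-off.

#' Assay sample description
#'
#' @param concentration_M analyte concentration, mol/L (>= 0).
#' @param volume_ul sample volume, uL (> 0).
#' @return an object of class `assay_sample`.
#' @examples
#' assay_sample(1e-18, 100)   # 1 aM in 100 uL: ~60 molecules
#' @export
assay_sample <- function(concentration_M, volume_ul) {
  if (!is.finite(concentration_M) || concentration_M < 0)
    stop_invalid("invalid sample: concentration must be >= 0")
  if (!is.finite(volume_ul) || volume_ul <= 0)
    stop_invalid("invalid sample: volume must be positive")
  structure(list(concentration = concentration_M, volume = volume_ul * 1e-6),
            class = "assay_sample")
}

#' Expected number of analyte molecules in a sample
#'
#' `E[N] = c * V * N_A`, returned as a real-valued expectation (not
#' rounded). At 1 aM, a 1 uL sample holds less than one molecule in
#' expectation while 100 uL holds ~60 — the quantitative reason ultrasensitive
#' assays need large sample volumes.
#'
#' @param sample an [assay_sample()].
#' @return expected molecule count (dimensionless, real-valued).
#' @examples
#' expected_molecules(assay_sample(1e-18, 100))  # ~60.2
#' expected_molecules(assay_sample(1e-18, 1))    # ~0.602
#' @export
expected_molecules <- function(sample) {
  stopifnot(inherits(sample, "assay_sample"))
  sample$concentration * sample$volume * .AVOGADRO
}

#' Per-bead captured-molecule state
#'
#' @param counts non-negative integer vector: captured molecules per bead.
#' @return an object of class `bead_assay_state` with fields `counts` and
#'   `n_beads`.
#' @export
bead_assay_state <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) < 1) stop_invalid("invalid state: need at least one bead")
  if (any(is.na(counts)) || any(counts < 0))
    stop_invalid("invalid state: counts must be non-negative integers")
  structure(list(counts = counts, n_beads = length(counts)),
            class = "bead_assay_state")
}

#' Distribute captured molecules over beads
#'
#' Each molecule is captured by a uniformly random bead (a multinomial
#' partition); when molecules are scarcer than beads the per-bead counts are
#' Poisson-distributed to excellent approximation, which is the basis of
#' digital (on/off) counting.
#'
#' @param n_molecules number of molecules (non-negative integer).
#' @param n_beads number of beads (>= 1).
#' @param seed optional integer seed.
#' @return a [bead_assay_state()]; the counts sum to `n_molecules` exactly.
#' @export
distribute_molecules <- function(n_molecules, n_beads, seed = NULL) {
  if (!is.finite(n_beads) || n_beads < 1)
    stop_invalid("invalid input: n_beads must be >= 1")
  if (!is.finite(n_molecules) || n_molecules < 0)
    stop_invalid("invalid input: n_molecules must be >= 0")
  n_molecules <- as.integer(round(n_molecules))
  n_beads <- as.integer(n_beads)
  counts <- with_seed_opt(seed, {
    if (n_molecules == 0) integer(n_beads)
    else tabulate(sample.int(n_beads, n_molecules, replace = TRUE),
                  nbins = n_beads)
  })
  bead_assay_state(counts)
}

#' Average enzymes per bead (AEB), Poisson-corrected
#'
#' The digital readout of a single-molecule array: with `f_on` the fraction
#' of signal-positive beads (>= 1 label), the mean label number per bead is
#' estimated as \deqn{\mathrm{AEB} = -\ln(1 - f_{on}),} the inversion of the
#' Poisson zero class `P(0) = e^{-\lambda}`. In the low-`f_on` regime
#' AEB ~ `f_on`. Undefined (saturated) when every bead is positive.
#'
#' @param state a [bead_assay_state()] (or an integer vector of per-bead
#'   counts).
#' @return AEB estimate (dimensionless).
#' @export
aeb_estimate <- function(state) {
  if (!inherits(state, "bead_assay_state")) state <- bead_assay_state(state)
  f_on <- mean(state$counts >= 1)
  if (f_on >= 1)
    stop(structure(class = c("dmf_saturation", "error", "condition"),
                   list(message = "saturation: every bead is positive; AEB undefined",
                        call = sys.call())))
  -log(1 - f_on)
}

#' Bead retention percentage
#'
#' Two conventions, matching how the waste or the recovered (densified)
#' droplet is counted:
#' `from_waste`: `100 * (1 - count / expected)` with `count` the beads found
#' in the waste; `from_recovered`: `100 * count / expected` with `count` the
#' beads in the densified droplet.
#'
#' @param count observed bead count (>= 0).
#' @param expected expected number of beads (> 0).
#' @param mode `"from_waste"` or `"from_recovered"`.
#' @return retention in percent.
#' @examples
#' retention_percentage(5240, 5272, "from_recovered")  # > 99%
#' @export
retention_percentage <- function(count, expected,
                                 mode = c("from_waste", "from_recovered")) {
  mode <- match.arg(mode)
  if (!is.finite(expected) || expected <= 0)
    stop_invalid("invalid input: expected bead count must be positive")
  if (!is.finite(count) || count < 0)
    stop_invalid("invalid input: count must be >= 0")
  if (mode == "from_waste") 100 * (1 - count / expected)
  else 100 * count / expected
}

#' Bead-number sensitivity trade-off
#'
#' Fewer beads concentrate the captured molecules (raising the per-bead
#' signal, the quantity digital detection responds to) but capture a smaller
#' fraction of them. Capture efficiency is modelled with the saturating form
#' `1 - exp(-n / capture_scale)`; molecules per bead is
#' `E[N] * efficiency / n`. Efficiency is strictly increasing and molecules
#' per bead strictly decreasing in `n`.
#'
#' @param sample an [assay_sample()].
#' @param bead_grid positive numeric vector of bead numbers to tabulate.
#' @param capture_scale bead number at which capture efficiency reaches
#'   `1 - 1/e` (default 10000).
#' @return a data frame with columns `n_beads`, `capture_efficiency`,
#'   `molecules_per_bead`.
#' @export
bead_number_tradeoff <- function(sample, bead_grid, capture_scale = 1e4) {
  stopifnot(inherits(sample, "assay_sample"))
  if (length(bead_grid) < 1 || any(bead_grid <= 0))
    stop_invalid("invalid input: bead_grid must be positive and non-empty")
  if (!is.finite(capture_scale) || capture_scale <= 0)
    stop_invalid("invalid input: capture_scale must be positive")
  eff <- 1 - exp(-bead_grid / capture_scale)
  data.frame(n_beads = bead_grid,
             capture_efficiency = eff,
             molecules_per_bead = expected_molecules(sample) * eff / bead_grid)
}
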