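# Capacitance-feedback closed-loop control of stepwise sample loading.
#
# The instrument reports the capacitance of the actuated electrode path at
# ~40 Hz; liquid covering the electrodes raises it (baseline ~100 pF, ~250 pF
# once a ~9 uL segment has loaded, ~320 pF at the split). Sub-steps
# LOAD -> SPLIT -> WASTE_REMOVAL advance when, after an initial change in
# capacitance, a rolling-standard-deviation stability index falls below a
# threshold (defaults: 15 samples, 2 pF).

#' Capacitance time series
#'
#' @param time_s sample times in seconds, strictly increasing.
#' @param capacitance_pF capacitance readings in pF, non-negative.
#' @param sample_rate nominal sampling rate in Hz (default 40).
#' @return an object of class `capacitance_trace`: a list with fields
#'   `time`, `capacitance`, `sample_rate`.
#' @export
capacitance_trace <- function(time_s, capacitance_pF, sample_rate = 40) {
  if (length(time_s) == 0)
    stop_invalid("invalid trace: empty")
  if (length(time_s) != length(capacitance_pF))
    stop_invalid("invalid trace: time and capacitance lengths differ")
  if (any(diff(time_s) <= 0))
    stop_invalid("invalid trace: times must be strictly increasing")
  if (any(!is.finite(capacitance_pF)) || any(capacitance_pF < 0))
    stop_invalid("invalid trace: capacitance must be finite and >= 0")
  structure(list(time = as.numeric(time_s),
                 capacitance = as.numeric(capacitance_pF),
                 sample_rate = sample_rate),
            class = "capacitance_trace")
}

#' @export
print.capacitance_trace <- function(x, ...) {
  cat(sprintf("<capacitance_trace> %d samples, %.3f-%.3f s, %.0f Hz nominal\n",
              length(x$time), x$time[1], x$time[length(x$time)], x$sample_rate))
  cat(sprintf("  capacitance %.1f-%.1f pF\n",
              min(x$capacitance), max(x$capacitance)))
  invisible(x)
}

#' @export
plot.capacitance_trace <- function(x, window = 15, ...) {
  op <- par(mar = c(4, 4, 1, 4))
  on.exit(par(op))
  plot(x$time, x$capacitance, type = "l", xlab = "time (s)",
       ylab = "capacitance (pF)", ...)
  if (length(x$capacitance) >= window) {
    si <- stability_index(x, window)
    par(new = TRUE)
    plot(x$time, si, type = "l", col = "darkorange", axes = FALSE,
         xlab = "", ylab = "")
    graphics::axis(4, col.axis = "darkorange")
    graphics::mtext("stability index (pF)", side = 4, line = 2.5,
                    col = "darkorange")
  }
  invisible(x)
}

#' Write / read a capacitance trace as two-column delimited text
#'
#' Format: a one-line header `time_s<TAB>capacitance_pF`, then one sample per
#' line. The nominal sample rate is recovered from the median time step on
#' read.
#'
#' @param trace a [capacitance_trace()].
#' @param path file path.
#' @return `write_capacitance_trace` returns `path` invisibly;
#'   `read_capacitance_trace` returns a [capacitance_trace()].
#' @export
write_capacitance_trace <- function(trace, path) {
  stopifnot(inherits(trace, "capacitance_trace"))
  df <- data.frame(time_s = trace$time, capacitance_pF = trace$capacitance)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_capacitance_trace
#' @export
read_capacitance_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "capacitance_pF") %in% names(df)))
    stop_invalid("invalid trace file: expected columns time_s, capacitance_pF")
  rate <- if (nrow(df) > 1) 1 / stats::median(diff(df$time_s)) else 40
  capacitance_trace(df$time_s, df$capacitance_pF, sample_rate = rate)
}

#' Closed-loop controller configuration
#'
#' @param window number of samples in the rolling stability window
#'   (default 15).
#' @param stability_threshold_pF stability-index threshold in pF (default 2):
#'   a sub-step completes when the index falls below this value.
#' @param rise_delta_pF minimum capacitance change (pF) above the phase-entry
#'   baseline that counts as the "initial increase" arming the stability
#'   check (default 10: below the load rise of even a ~1 uL final segment
#'   at the 150 pF / 9 uL calibration, and well above the 2 pF noise
#'   threshold). For WASTE_REMOVAL it instead bounds the distance from the
#'   global baseline that counts as "returned".
#' @param sd_convention `"population"` (divide by the window length; default)
#'   or `"sample"` (divide by window - 1) for the rolling SD.
#' @return an object of class `controller_config`.
#' @export
controller_config <- function(window = 15, stability_threshold_pF = 2,
                              rise_delta_pF = 10,
                              sd_convention = c("population", "sample")) {
  if (!is.finite(window) || window < 2)
    stop_invalid("invalid config: window must be >= 2")
  if (!is.finite(stability_threshold_pF) || stability_threshold_pF <= 0)
    stop_invalid("invalid config: stability_threshold_pF must be positive")
  if (!is.finite(rise_delta_pF) || rise_delta_pF <= 0)
    stop_invalid("invalid config: rise_delta_pF must be positive")
  structure(list(window = as.integer(window),
                 stability_threshold = stability_threshold_pF,
                 rise_delta = rise_delta_pF,
                 sd_convention = match.arg(sd_convention),
                 phases = c("LOAD", "SPLIT", "WASTE_REMOVAL")),
            class = "controller_config")
}

#' Capacitance stability index (rolling standard deviation)
#'
#' Element `i` (for `i >= window - 1 + 1`) is the standard deviation of
#' samples `i - window + 1 ... i`; earlier elements, where the window is not
#' yet full, are `NA`. A low index signals that droplet motion has completed
#' and the actuated electrodes are fully covered.
#'
#' @param trace a [capacitance_trace()] or a numeric vector of capacitance
#'   readings (pF).
#' @param window window length in samples (default 15).
#' @param convention `"population"` (default) or `"sample"` SD normalisation.
#' @return numeric vector of the same length as the trace, in pF, with `NA`
#'   for the first `window - 1` positions.
#' @export
stability_index <- function(trace, window = 15,
                            convention = c("population", "sample")) {
  convention <- match.arg(convention)
  x <- if (inherits(trace, "capacitance_trace")) trace$capacitance else
    as.numeric(trace)
  n <- length(x)
  if (n < window)
    stop_invalid("insufficient data: trace has ", n,
                 " samples but the stability window needs ", window)
  out <- rep(NA_real_, n)
  idx <- seq.int(window, n)
  out[idx] <- vapply(idx, function(i) sd(x[(i - window + 1L):i]), numeric(1))
  if (convention == "population")
    out <- out * sqrt((window - 1) / window)
  out
}

# Latest stability-index value of a history vector, or NA if too short.
.latest_stability <- function(x, config) {
  n <- length(x)
  if (n < config$window) return(NA_real_)
  s <- sd(x[(n - config$window + 1L):n])
  if (config$sd_convention == "population")
    s <- s * sqrt((config$window - 1) / config$window)
  s
}

#' Is the controller ready to advance to the next sub-step?
#'
#' For LOAD and SPLIT: true iff some sample since phase entry exceeds the
#' phase baseline by at least `rise_delta_pF` (the "initial increase") and
#' the most recent stability-index value is below the threshold. For
#' WASTE_REMOVAL the rise condition is replaced by a fall condition: the
#' latest capacitance must be within `rise_delta_pF` of the global baseline.
#' Returns `FALSE` (never errors) while there is insufficient data.
#'
#' @param history a [capacitance_trace()] or numeric vector: the samples
#'   observed since the current phase began (plus enough pre-history to fill
#'   the stability window).
#' @param config a [controller_config()].
#' @param phase_baseline capacitance (pF) at phase entry.
#' @param phase one of `"LOAD"`, `"SPLIT"`, `"WASTE_REMOVAL"`.
#' @param global_baseline dry/empty-channel capacitance (pF); defaults to the
#'   phase baseline (only used for WASTE_REMOVAL).
#' @return logical scalar.
#' @export
phase_transition_ready <- function(history, config, phase_baseline,
                                   phase = "LOAD",
                                   global_baseline = phase_baseline) {
  x <- if (inherits(history, "capacitance_trace")) history$capacitance else
    as.numeric(history)
  if (length(x) == 0) stop_invalid("invalid input: empty history")
  armed <- if (identical(phase, "WASTE_REMOVAL")) {
    x[length(x)] <= global_baseline + config$rise_delta
  } else {
    any(x >= phase_baseline + config$rise_delta)
  }
  if (!armed) return(FALSE)
  s <- .latest_stability(x, config)
  !is.na(s) && s < config$stability_threshold
}

#' Run the closed-loop load/split/waste-removal state machine over a trace
#'
#' Consumes the capacitance stream sample by sample, advancing through the
#' sub-steps LOAD -> SPLIT -> WASTE_REMOVAL once per planned segment, using
#' [phase_transition_ready()] as the feedback rule. The stability window
#' always spans the most recent `window` samples of the stream; the rise
#' condition is evaluated on samples since phase entry.
#'
#' @param trace a [capacitance_trace()] (the full recorded or synthesized
#'   stream).
#' @param plan numeric vector of planned segment volumes (uL); one cycle is
#'   emitted per element.
#' @param config a [controller_config()].
#' @return an object of class `cycle_log`: a data frame with one row per
#'   (cycle, phase) holding `cycle`, `phase`, `t_start`, `t_transition` and
#'   `cap_transition` (pF). Phases occur in order and transition times are
#'   non-decreasing.
#' @export
run_closed_loop <- function(trace, plan, config = controller_config()) {
  stopifnot(inherits(trace, "capacitance_trace"),
            inherits(config, "controller_config"))
  if (length(plan) == 0) stop_invalid("invalid input: empty segment plan")
  x <- trace$capacitance
  tt <- trace$time
  n <- length(x)
  si <- if (n >= config$window)
    stability_index(x, config$window, config$sd_convention) else rep(NA_real_, n)
  global_baseline <- x[1]
  n_cycles <- length(plan)
  rows <- vector("list", 3L * n_cycles)
  r <- 0L
  cycle <- 1L
  phase_i <- 1L
  phase_start <- 1L
  phase_baseline <- x[1]
  i <- 1L
  while (cycle <= n_cycles) {
    if (i > n) {
      stop(structure(class = c("dmf_incomplete_cycle", "error", "condition"),
        list(message = sprintf(
          "incomplete cycle: stream ended during %s of cycle %d (controller starved: stability criterion never met)",
          config$phases[phase_i], cycle), call = sys.call())))
    }
    ready <- {
      # rise guard on phase-local samples only; stability on the raw stream
      armed <- if (config$phases[phase_i] == "WASTE_REMOVAL") {
        x[i] <= global_baseline + config$rise_delta
      } else {
        any(x[phase_start:i] >= phase_baseline + config$rise_delta)
      }
      armed && !is.na(si[i]) && si[i] < config$stability_threshold
    }
    if (ready) {
      r <- r + 1L
      rows[[r]] <- data.frame(cycle = cycle, phase = config$phases[phase_i],
                              t_start = tt[phase_start], t_transition = tt[i],
                              cap_transition = x[i])
      phase_i <- phase_i + 1L
      if (phase_i > 3L) {
        phase_i <- 1L
        cycle <- cycle + 1L
      }
      phase_start <- i + 1L
      phase_baseline <- x[i]
    }
    i <- i + 1L
  }
  log <- do.call(rbind, rows[seq_len(r)])
  class(log) <- c("cycle_log", "data.frame")
  attr(log, "global_baseline") <- global_baseline
  log
}

#' @export
print.cycle_log <- function(x, ...) {
  cat(sprintf("<cycle_log> %d cycles, %d phase transitions, %.2f s total\n",
              max(x$cycle), nrow(x), max(x$t_transition) - min(x$t_start)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plan the segment volumes of a stepwise loading run
#'
#' Splits a total sample volume into segments of a nominal size (the amount
#' the virtual channel holds before each split, ~9 uL on this device).
#'
#' Policies:
#' \describe{
#'   \item{`"default"`}{`n = ceiling(total/nominal)` segments: `n - 1` at the
#'     nominal size plus the remainder (a full nominal segment when the
#'     division is exact). 100 uL at 9 uL nominal gives 12 cycles.}
#'   \item{`"merge-final"`}{as above, but a small remainder (under half the
#'     nominal size) is folded into the final segment, allowing the last one
#'     or two segments to exceed the nominal size — mirroring the practice of
#'     over-sizing the hardest-to-split final segments.}
#' }
#'
#' @param total_volume_ul total sample volume, uL (> 0).
#' @param nominal_segment_ul nominal segment volume, uL (> 0, default 9).
#' @param policy `"default"` or `"merge-final"`.
#' @return numeric vector of segment volumes (uL) summing exactly to
#'   `total_volume_ul`.
#' @examples
#' plan_segments(100, 9)                  # 12 segments
#' plan_segments(20, 9, "merge-final")    # c(9, 11)
#' @export
plan_segments <- function(total_volume_ul, nominal_segment_ul = 9,
                          policy = c("default", "merge-final")) {
  policy <- match.arg(policy)
  if (!is.finite(total_volume_ul) || total_volume_ul <= 0)
    stop_invalid("invalid input: total volume must be positive")
  if (!is.finite(nominal_segment_ul) || nominal_segment_ul <= 0)
    stop_invalid("invalid input: nominal segment volume must be positive")
  n <- ceiling(total_volume_ul / nominal_segment_ul)
  last <- total_volume_ul - nominal_segment_ul * (n - 1)
  segs <- c(rep(nominal_segment_ul, n - 1), last)
  if (policy == "merge-final" && n >= 2 && last < nominal_segment_ul / 2) {
    segs <- c(segs[seq_len(n - 2)], segs[n - 1] + segs[n])
  }
  segs
}
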