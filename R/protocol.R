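# Stimulation protocols: rectangular glutamate pulse trains plus a
# piecewise-constant extracellular Mg2+ schedule.

#' Glutamate pulse-train stimulation protocol
#'
#' Describes the synaptic drive of a simulation: a rectangular glutamate
#' pulse train (pulse `k` starts at `stim_start + k * 1000/freq` and lasts
#' `pulse_width` ms at `pulse_amp` mM; a pulse is emitted only if it ends at
#' or before `stim_end`) together with a piecewise-constant extracellular
#' Mg2+ schedule.
#'
#' @param freq pulse frequency (Hz).
#' @param pulse_width pulse duration (ms), default 2; must be shorter than
#'   the inter-pulse period `1000/freq`.
#' @param pulse_amp glutamate concentration during a pulse (mM), default 1.
#' @param stim_start,stim_end stimulation span (ms).
#' @param t_end total simulated time (ms), `>= stim_end`.
#' @param mg constant extracellular Mg2+ (mM); shorthand for a one-row
#'   schedule starting at t = 0.
#' @param mg_schedule data frame with columns `time` (ms, non-decreasing,
#'   first row at 0) and `mg` (mM, `>= 0`): Mg2+ steps instantaneously to
#'   `mg[i]` at `time[i]`. Overrides `mg` when given.
#' @return Object of class `"rgc_protocol"`.
#' @examples
#' pr <- stim_protocol(freq = 80, stim_end = 3000, t_end = 3000, mg = 0.2)
#' glutamate_at(pr, c(0, 1.9, 2.1, 12.5))
#' @export
stim_protocol <- function(freq, pulse_width = 2, pulse_amp = 1,
                          stim_start = 0, stim_end = 3000, t_end = stim_end,
                          mg = 0.2, mg_schedule = NULL) {
  stopifnot(is.numeric(freq), length(freq) == 1L, freq > 0,
            is.numeric(pulse_width), pulse_width > 0,
            is.numeric(pulse_amp), pulse_amp >= 0)
  period <- 1000 / freq
  if (pulse_width >= period)
    stop("invalid protocol: pulse_width (", pulse_width,
         " ms) must be shorter than the inter-pulse period (", period,
         " ms at ", freq, " Hz)", call. = FALSE)
  if (!(stim_start < stim_end && stim_end <= t_end))
    stop("require stim_start < stim_end <= t_end", call. = FALSE)
  if (is.null(mg_schedule)) {
    stopifnot(is.numeric(mg), length(mg) == 1L)
    mg_schedule <- data.frame(time = 0, mg = mg)
  }
  if (!is.data.frame(mg_schedule) ||
      !all(c("time", "mg") %in% names(mg_schedule)) ||
      nrow(mg_schedule) < 1L)
    stop("'mg_schedule' must be a data frame with columns time, mg",
         call. = FALSE)
  if (is.unsorted(mg_schedule$time))
    stop("mg_schedule times must be non-decreasing", call. = FALSE)
  if (mg_schedule$time[1L] > 0)
    stop("mg_schedule must define Mg from t = 0", call. = FALSE)
  if (any(mg_schedule$mg < 0))
    stop("Mg concentrations must be >= 0", call. = FALSE)
  structure(list(freq = freq, period = period, pulse_width = pulse_width,
                 pulse_amp = pulse_amp, stim_start = stim_start,
                 stim_end = stim_end, t_end = t_end,
                 mg_schedule = mg_schedule[, c("time", "mg")]),
            class = "rgc_protocol")
}

#' @export
print.rgc_protocol <- function(x, ...) {
  cat("Glutamate pulse-train protocol\n")
  cat("  ", x$freq, " Hz, ", x$pulse_width, " ms pulses of ", x$pulse_amp,
      " mM, stimulation ", x$stim_start, "-", x$stim_end, " ms, t_end ",
      x$t_end, " ms\n", sep = "")
  mgs <- x$mg_schedule
  if (nrow(mgs) == 1L) {
    cat("  Mg2+ constant at", mgs$mg, "mM\n")
  } else {
    cat("  Mg2+ schedule:",
        paste(sprintf("%g mM @ %g ms", mgs$mg, mgs$time), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Glutamate concentration at given times
#'
#' @param protocol an [stim_protocol()] object.
#' @param t time or vector of times (ms).
#' @return Glutamate concentration (mM) at each time.
#' @export
glutamate_at <- function(protocol, t) {
  p <- protocol
  k <- floor((t - p$stim_start) / p$period + 1e-9)
  tk <- p$stim_start + k * p$period
  inpulse <- t >= p$stim_start & t < p$stim_end &
    (t - tk) < p$pulse_width - 1e-9 &
    tk + p$pulse_width <= p$stim_end + 1e-9
  ifelse(inpulse, p$pulse_amp, 0)
}

#' Extracellular Mg2+ concentration at given times
#'
#' @inheritParams glutamate_at
#' @return Mg2+ concentration (mM) at each time.
#' @export
mg_at <- function(protocol, t) {
  mgs <- protocol$mg_schedule
  idx <- findInterval(t + 1e-9, mgs$time)
  mgs$mg[pmax(idx, 1L)]
}

#' Expected number of stimulus pulses in a window
#'
#' Counts emitted pulses whose onset lies in `[window[1], window[2])`; this
#' is the denominator of the spike-probability metric (e.g. 200 pulses for
#' 80 Hz over a 2.5 s analysis window).
#'
#' @inheritParams glutamate_at
#' @param window numeric length-2, analysis window (ms).
#' @return Integer pulse count.
#' @examples
#' pr <- stim_protocol(freq = 80, stim_end = 3000, t_end = 3000)
#' expected_pulses(pr, c(500, 3000))  # 200
#' @export
expected_pulses <- function(protocol, window) {
  p <- protocol
  stopifnot(length(window) == 2L, window[1] < window[2])
  onsets <- seq(p$stim_start, p$stim_end, by = p$period)
  onsets <- onsets[onsets + p$pulse_width <= p$stim_end + 1e-9]
  sum(onsets >= window[1] - 1e-9 & onsets < window[2] - 1e-9)
}
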