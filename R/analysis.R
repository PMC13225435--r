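# Analysis metrics: spike detection, calcium metrics, therapeutic-window
# classification, protection efficacy, calcium progress, and the mechanistic
# NMDA-charge / mean-unblock decompositions.

# window helpers --------------------------------------------------------------

check_window <- function(trace, window) {
  stopifnot(is.numeric(window), length(window) == 2L)
  if (window[1] >= window[2])
    stop("analysis window must satisfy window[1] < window[2]", call. = FALSE)
  t <- trace$time
  if (window[1] < min(t) - 1e-9 || window[2] > max(t) + 1e-9)
    stop("analysis window [", window[1], ", ", window[2],
         "] lies outside the trace span [", min(t), ", ", max(t), "]",
         call. = FALSE)
  idx <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  if (!length(idx)) stop("analysis window contains no samples", call. = FALSE)
  idx
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# spikes ----------------------------------------------------------------------

#' Detect spikes by threshold crossing
#'
#' A spike is an upward crossing of the voltage threshold (default -20 mV):
#' the spike time is the first supra-threshold sample of each crossing, and a
#' new spike requires the voltage to fall back below threshold first (which
#' de-bounces multi-sample excursions). Spike probability is the ratio of
#' detected spikes to expected stimulus pulses in the window (capped at 1),
#' and spike loss is `100 * (1 - probability)`.
#'
#' @param trace an `rgc_trace` (or any data frame with `time` and `V`).
#' @param window analysis window (ms), e.g. `c(500, 3000)`.
#' @param threshold spike threshold (mV), default -20.
#' @param n_expected expected pulse count; defaults to
#'   [expected_pulses()] of the trace's protocol over `window`.
#' @return A list of class `"spike_metrics"`: `spike_times` (ms),
#'   `n_spikes`, `n_expected`, `spike_probability`, `spike_loss_pct`.
#' @export
detect_spikes <- function(trace, window, threshold = -20,
                          n_expected = NULL) {
  idx <- check_window(trace, window)
  v <- trace$V[idx]
  t <- trace$time[idx]
  up <- which(v > threshold & c(-Inf, v[-length(v)]) <= threshold)
  if (is.null(n_expected)) {
    proto <- attr(trace, "protocol")
    if (is.null(proto))
      stop("trace carries no protocol; supply 'n_expected'", call. = FALSE)
    n_expected <- expected_pulses(proto, window)
  }
  prob <- if (n_expected > 0) min(1, length(up) / n_expected) else NA_real_
  structure(list(spike_times = t[up], n_spikes = length(up),
                 n_expected = n_expected, spike_probability = prob,
                 spike_loss_pct = 100 * (1 - prob)),
            class = "spike_metrics")
}

#' @export
print.spike_metrics <- function(x, ...) {
  cat("Spikes: ", x$n_spikes, " / ", x$n_expected, " expected pulses ",
      "(probability ", round(x$spike_probability, 3), ", loss ",
      round(x$spike_loss_pct, 1), "%)\n", sep = "")
  invisible(x)
}

# calcium ---------------------------------------------------------------------

#' Peak intracellular calcium in a window
#'
#' @inheritParams detect_spikes
#' @return Maximum `Ca` (uM) over the window samples.
#' @export
peak_calcium <- function(trace, window) {
  idx <- check_window(trace, window)
  max(trace$Ca[idx])
}

# therapeutic window ----------------------------------------------------------

#' Dual therapeutic criteria
#'
#' Neuroprotection: peak intracellular calcium strictly below the toxicity
#' threshold (default 1.0 uM). Function preservation: spike reduction
#' relative to the low-Mg2+ baseline (default 0.2 mM) at most
#' `max_spike_loss_pct` (default 20%).
#'
#' @param ca_toxicity_threshold calcium toxicity threshold (uM), `> 0`.
#' @param max_spike_loss_pct maximum tolerated spike loss (%), in `[0, 100]`.
#' @param baseline_mg baseline Mg2+ concentration (mM).
#' @return A list of class `"therapeutic_criteria"`.
#' @export
therapeutic_criteria <- function(ca_toxicity_threshold = 1.0,
                                 max_spike_loss_pct = 20,
                                 baseline_mg = 0.2) {
  stopifnot(ca_toxicity_threshold > 0,
            max_spike_loss_pct >= 0, max_spike_loss_pct <= 100,
            baseline_mg >= 0)
  structure(list(ca_toxicity_threshold = ca_toxicity_threshold,
                 max_spike_loss_pct = max_spike_loss_pct,
                 baseline_mg = baseline_mg),
            class = "therapeutic_criteria")
}

#' Therapeutic-window classification at one frequency
#'
#' Classifies each Mg2+ concentration of a dose-response row by the dual
#' criteria and reports the maximal contiguous run of concentrations
#' satisfying both (the therapeutic window). Concentrations failing the
#' calcium criterion are labelled `fails_protection`, those exceeding the
#' spike-loss limit `fails_function` (`fails_both` if both), and window
#' members `optimal`. Window boundaries are reported at grid resolution.
#'
#' @param mg sorted (strictly increasing) Mg2+ grid (mM).
#' @param peak_ca peak calcium (uM) per concentration.
#' @param spike_loss spike loss relative to baseline (%) per concentration.
#' @param criteria a [therapeutic_criteria()] object.
#' @param frequency optional stimulation frequency (Hz), carried through for
#'   labelling.
#' @return A list of class `"therapeutic_window"`: `frequency`, `exists`,
#'   `lower`, `upper`, `width` (mM; `NA`/0-width handling per grid),
#'   `classification` (factor aligned with `mg`).
#' @export
find_window <- function(mg, peak_ca, spike_loss,
                        criteria = therapeutic_criteria(),
                        frequency = NA_real_) {
  stopifnot(length(mg) == length(peak_ca), length(mg) == length(spike_loss))
  if (length(mg) < 1L || is.unsorted(mg, strictly = TRUE))
    stop("'mg' must be a strictly increasing grid", call. = FALSE)
  prot_ok <- peak_ca < criteria$ca_toxicity_threshold
  func_ok <- spike_loss <= criteria$max_spike_loss_pct
  cls <- ifelse(prot_ok & func_ok, "optimal",
         ifelse(!prot_ok & !func_ok, "fails_both",
         ifelse(!prot_ok, "fails_protection", "fails_function")))
  ok <- prot_ok & func_ok
  lower <- upper <- width <- NA_real_
  exists <- any(ok)
  if (exists) {
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    cand <- which(runs$values)
    best <- cand[which.max(runs$lengths[cand])]
    lower <- mg[starts[best]]
    upper <- mg[ends[best]]
    width <- upper - lower
  }
  structure(list(frequency = frequency, exists = exists, lower = lower,
                 upper = upper, width = width, mg = mg,
                 classification = factor(cls, levels = c("fails_protection",
                   "optimal", "fails_function", "fails_both"))),
            class = "therapeutic_window")
}

#' @export
print.therapeutic_window <- function(x, ...) {
  hz <- if (is.na(x$frequency)) "" else paste0(" at ", x$frequency, " Hz")
  if (x$exists) {
    cat("Therapeutic window", hz, ": [", x$lower, ", ", x$upper,
        "] mM (width ", x$width, " mM)\n", sep = "")
  } else {
    cat("No therapeutic window", hz, "\n", sep = "")
  }
  invisible(x)
}

#' Sensitivity of the therapeutic window to the toxicity threshold
#'
#' Re-runs the window classification for a series of calcium toxicity
#' thresholds (the spike-loss criterion unchanged). Window width is
#' non-decreasing in the threshold.
#'
#' @param mg,peak_ca,spike_loss as in [find_window()].
#' @param thresholds sorted ascending toxicity thresholds (uM).
#' @param criteria base criteria (supplies the spike-loss limit).
#' @return Data frame with columns `threshold`, `exists`, `lower`, `upper`,
#'   `width`.
#' @export
threshold_sensitivity <- function(mg, peak_ca, spike_loss,
                                  thresholds = seq(0.6, 1.4, by = 0.1),
                                  criteria = therapeutic_criteria()) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be sorted ascending", call. = FALSE)
  rows <- lapply(thresholds, function(thr) {
    w <- find_window(mg, peak_ca, spike_loss,
                     therapeutic_criteria(thr, criteria$max_spike_loss_pct,
                                          criteria$baseline_mg))
    data.frame(threshold = thr, exists = w$exists, lower = w$lower,
               upper = w$upper, width = ifelse(w$exists, w$width, 0))
  })
  do.call(rbind, rows)
}

# timing metrics --------------------------------------------------------------

#' Protection efficacy of a Mg2+ intervention
#'
#' Linear score of peak-calcium reduction relative to the two reference runs:
#' `100 * (peak_noMg - peak_intervention) / (peak_noMg - peak_pretreated)`.
#' An intervention matching the pre-treated run scores 100%, one matching the
#' untreated run scores 0%.
#'
#' @param peak_noMg peak calcium of the untreated (baseline Mg2+) run (uM).
#' @param peak_pre peak calcium of the pre-treated run (uM); must be below
#'   `peak_noMg`.
#' @param peak_intervention peak calcium of the intervention run (uM).
#'   Vectorised.
#' @return Efficacy in percent.
#' @examples
#' protection_efficacy(4, 1, 2.5)  # 50
#' @export
protection_efficacy <- function(peak_noMg, peak_pre, peak_intervention) {
  if (!(peak_noMg > peak_pre))
    stop("degenerate references: require peak_noMg > peak_pre", call. = FALSE)
  100 * (peak_noMg - peak_intervention) / (peak_noMg - peak_pre)
}

#' Normalized calcium progress of the untreated trace
#'
#' Fraction of the untreated run's peak calcium accumulation reached at a
#' given time: `(Ca(t) - Ca_rest) / (Ca_peak - Ca_rest)`, where the peak is
#' taken from the untreated trace over the analysis window. This is a
#' treatment-independent measure of how far the excitotoxic calcium rise has
#' progressed when an intervention is applied.
#'
#' @param trace untreated `rgc_trace`.
#' @param t_eval time (ms) at which to evaluate progress; linearly
#'   interpolated. Must lie within the trace.
#' @param window analysis window (ms) over which the peak is taken.
#' @param ca_rest resting calcium (uM); defaults to the trace's parameter set.
#' @return Progress fraction (0 at rest, 1 at the untreated peak).
#' @export
ca_progress <- function(trace, t_eval, window = c(500, 4500),
                        ca_rest = NULL) {
  if (is.null(ca_rest)) {
    p <- attr(trace, "params")
    ca_rest <- if (is.null(p)) .rgc_defaults$Ca_rest else p$Ca_rest
  }
  if (any(t_eval < min(trace$time) - 1e-9) ||
      any(t_eval > max(trace$time) + 1e-9))
    stop("'t_eval' lies outside the trace", call. = FALSE)
  peak <- peak_calcium(trace, window)
  ca_t <- stats::approx(trace$time, trace$Ca, xout = t_eval)$y
  (ca_t - ca_rest) / (peak - ca_rest)
}

# mechanistic metrics ---------------------------------------------------------

#' Integrated NMDA charge
#'
#' Trapezoidal integral of `|INMDA|` over the analysis window, a measure of
#' the total NMDA-receptor charge transfer driving calcium entry.
#'
#' @inheritParams detect_spikes
#' @return Charge density (uA*ms/cm^2), non-negative.
#' @export
nmda_charge <- function(trace, window) {
  idx <- check_window(trace, window)
  trapz(trace$time[idx], abs(trace$INMDA[idx]))
}

#' Time-averaged NMDA unblocked fraction
#'
#' Time average of the Jahr-Stevens block factor `B(V(t), Mg(t))` over the
#' analysis window.
#'
#' @inheritParams detect_spikes
#' @return Mean unblocked fraction in `(0, 1]`.
#' @export
mean_unblock <- function(trace, window) {
  idx <- check_window(trace, window)
  t <- trace$time[idx]
  trapz(t, trace$B[idx]) / (t[length(t)] - t[1])
}
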