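# Experiment drivers: the frequency x Mg2+ dose-response sweep and the
# intervention-timing protocol.

#' Dose-response sweep over frequency and extracellular Mg2+
#'
#' Simulates the glutamate pulse-train protocol for every combination of
#' stimulation frequency and Mg2+ concentration, computes per-cell spike and
#' calcium metrics on the steady-state analysis window (the first 500 ms are
#' excluded to remove initialisation transients), and classifies each
#' frequency's therapeutic window under the dual criteria.
#'
#' Spike loss is reported both in absolute terms
#' (`100 * (1 - spike probability)`) and relative to the baseline Mg2+ run
#' at the same frequency (`spike_loss_vs_baseline_pct`, the quantity used by
#' the function-preservation criterion). Calcium reduction is relative to
#' the same baseline.
#'
#' @param frequencies stimulation frequencies (Hz).
#' @param mg_values Mg2+ grid (mM), sorted ascending; must contain the
#'   criteria's `baseline_mg`.
#' @param params model parameters.
#' @param criteria a [therapeutic_criteria()] object.
#' @param t_end simulated time per cell (ms).
#' @param window steady-state analysis window (ms).
#' @param dt integration step (ms).
#' @param verbose print one line per completed cell.
#' @return A list of class `"rgc_sweep"`: `summary` (one data-frame row per
#'   cell with columns `frequency`, `mg`, `n_spikes`, `n_expected`,
#'   `spike_prob`, `spike_loss_pct`, `spike_loss_vs_baseline_pct`,
#'   `peak_ca_uM`, `ca_reduction_pct`, `in_window`, `error`), `windows`
#'   (one [find_window()] result per frequency), plus the settings used.
#'   Cells whose integration fails are flagged via `error`, not fatal.
#' @export
run_dose_response <- function(frequencies = c(10, 30, 60, 80, 90, 100),
                              mg_values = seq(0.2, 2.5, by = 0.1),
                              params = rgc_params(),
                              criteria = therapeutic_criteria(),
                              t_end = 3000, window = c(500, 3000),
                              dt = 0.02, verbose = FALSE) {
  params <- as_rgc_params(params)
  mg_values <- round(mg_values, 10)
  if (is.unsorted(mg_values, strictly = TRUE))
    stop("'mg_values' must be strictly increasing", call. = FALSE)
  if (!any(abs(mg_values - criteria$baseline_mg) < 1e-9))
    stop("'mg_values' must contain the baseline concentration (",
         criteria$baseline_mg, " mM)", call. = FALSE)
  stopifnot(window[1] >= 0, window[2] <= t_end)

  cell <- function(f, mg) {
    pr <- stim_protocol(freq = f, stim_end = t_end, t_end = t_end, mg = mg)
    tr <- rgc_integrate(pr, params, dt = dt)
    sp <- detect_spikes(tr, window)
    list(n_spikes = sp$n_spikes, n_expected = sp$n_expected,
         spike_prob = sp$spike_probability,
         spike_loss_pct = sp$spike_loss_pct,
         peak_ca = peak_calcium(tr, window))
  }

  rows <- list()
  for (f in frequencies) {
    base <- NULL
    res_f <- vector("list", length(mg_values))
    for (j in seq_along(mg_values)) {
      mg <- mg_values[j]
      res_f[[j]] <- tryCatch(cell(f, mg), error = function(e)
        structure(list(msg = conditionMessage(e)), class = "cell_error"))
      if (verbose)
        message(sprintf("  cell %g Hz / %.1f mM done", f, mg))
      if (abs(mg - criteria$baseline_mg) < 1e-9 &&
          !inherits(res_f[[j]], "cell_error"))
        base <- res_f[[j]]
    }
    if (is.null(base))
      stop("baseline cell failed at ", f, " Hz", call. = FALSE)
    for (j in seq_along(mg_values)) {
      r <- res_f[[j]]
      if (inherits(r, "cell_error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          frequency = f, mg = mg_values[j], n_spikes = NA_integer_,
          n_expected = NA_integer_, spike_prob = NA_real_,
          spike_loss_pct = NA_real_, spike_loss_vs_baseline_pct = NA_real_,
          peak_ca_uM = NA_real_, ca_reduction_pct = NA_real_,
          in_window = NA, error = r$msg)
      } else {
        loss_vs_base <- if (base$n_spikes > 0)
          100 * max(0, 1 - r$n_spikes / base$n_spikes) else r$spike_loss_pct
        rows[[length(rows) + 1L]] <- data.frame(
          frequency = f, mg = mg_values[j], n_spikes = r$n_spikes,
          n_expected = r$n_expected, spike_prob = r$spike_prob,
          spike_loss_pct = r$spike_loss_pct,
          spike_loss_vs_baseline_pct = loss_vs_base,
          peak_ca_uM = r$peak_ca,
          ca_reduction_pct = 100 * (1 - r$peak_ca / base$peak_ca),
          in_window = NA, error = NA_character_)
      }
    }
  }
  summary <- do.call(rbind, rows)

  windows <- lapply(frequencies, function(f) {
    s <- summary[summary$frequency == f & is.na(summary$error), ]
    find_window(s$mg, s$peak_ca_uM, s$spike_loss_vs_baseline_pct,
                criteria, frequency = f)
  })
  names(windows) <- as.character(frequencies)
  for (f in frequencies) {
    w <- windows[[as.character(f)]]
    sel <- summary$frequency == f & is.na(summary$error)
    summary$in_window[sel] <-
      w$classification[match(summary$mg[sel], w$mg)] == "optimal"
  }
  structure(list(summary = summary, windows = windows, criteria = criteria,
                 params = params, window = window, t_end = t_end, dt = dt),
            class = "rgc_sweep")
}

#' @export
print.rgc_sweep <- function(x, ...) {
  cat("Dose-response sweep:", length(unique(x$summary$frequency)),
      "frequencies x", length(unique(x$summary$mg)), "Mg2+ values\n")
  for (w in x$windows) print(w)
  invisible(x)
}

#' Intervention-timing experiment
#'
#' Simulates the excitotoxic stress protocol (80 Hz glutamate train during
#' the stress window) with the extracellular Mg2+ concentration stepped
#' instantaneously from the baseline to the treated level at a series of
#' delays relative to stress onset, plus the two reference conditions:
#' untreated (baseline Mg2+ throughout) and pre-treated (treated Mg2+
#' throughout). Protection efficacy is computed per
#' [protection_efficacy()] against those references, and calcium progress
#' at each intervention time is read off the untreated trace.
#'
#' @param delays_s intervention delays in seconds after stress onset.
#' @param baseline_mg,treated_mg Mg2+ concentrations (mM).
#' @param freq stress stimulation frequency (Hz).
#' @param stress stress window (ms); glutamate pulses run only inside it.
#' @param t_end simulated time (ms).
#' @param window analysis window for peak calcium (ms); the stress window.
#' @param params model parameters.
#' @param dt integration step (ms).
#' @return A list of class `"rgc_timing"`: `table` (one row per condition:
#'   `label`, `delay_s`, `t_intervention`, `peak_ca_uM`, `efficacy_pct`,
#'   `ca_progress_at_intervention`), `peak_untreated`, `peak_pretreated`,
#'   and the untreated calcium trace (`untreated_ca`: `time`, `Ca`) for
#'   progress reanalysis.
#' @export
run_timing_experiment <- function(delays_s = c(0, 0.1, 0.2, 0.3, 0.4, 0.5,
                                               0.75, 1, 2, 3),
                                  baseline_mg = 0.2, treated_mg = 1.8,
                                  freq = 80, stress = c(500, 4500),
                                  t_end = 6000, window = stress,
                                  params = rgc_params(), dt = 0.02) {
  params <- as_rgc_params(params)
  if (any(delays_s < 0) ||
      any(stress[1] + delays_s * 1000 > stress[2]))
    stop("delays must lie within the stress window", call. = FALSE)

  proto <- function(mg_schedule) {
    stim_protocol(freq = freq, stim_start = stress[1], stim_end = stress[2],
                  t_end = t_end, mg_schedule = mg_schedule)
  }
  run_peak <- function(mg_schedule, keep_ca = FALSE) {
    tr <- rgc_integrate(proto(mg_schedule), params, dt = dt)
    out <- list(peak = peak_calcium(tr, window))
    if (keep_ca) out$ca <- data.frame(time = tr$time, Ca = tr$Ca)
    out
  }

  untreated <- run_peak(data.frame(time = 0, mg = baseline_mg),
                        keep_ca = TRUE)
  pretreated <- run_peak(data.frame(time = 0, mg = treated_mg))
  untreated_trace <- structure(untreated$ca,
                               class = c("rgc_trace", "data.frame"),
                               params = params)

  eff <- function(peak) protection_efficacy(untreated$peak, pretreated$peak,
                                            peak)
  rows <- list(data.frame(label = "pretreat", delay_s = NA_real_,
                          t_intervention = 0,
                          peak_ca_uM = pretreated$peak,
                          efficacy_pct = eff(pretreated$peak),
                          ca_progress_at_intervention = 0))
  for (d in delays_s) {
    t_int <- stress[1] + d * 1000
    r <- run_peak(data.frame(time = c(0, t_int),
                             mg = c(baseline_mg, treated_mg)))
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("+%g s", d), delay_s = d, t_intervention = t_int,
      peak_ca_uM = r$peak, efficacy_pct = eff(r$peak),
      ca_progress_at_intervention =
        ca_progress(untreated_trace, t_int, window))
  }
  structure(list(table = do.call(rbind, rows),
                 peak_untreated = untreated$peak,
                 peak_pretreated = pretreated$peak,
                 untreated_ca = untreated$ca,
                 baseline_mg = baseline_mg, treated_mg = treated_mg,
                 freq = freq, stress = stress, window = window,
                 t_end = t_end, dt = dt, params = params),
            class = "rgc_timing")
}

#' @export
print.rgc_timing <- function(x, ...) {
  cat("Intervention-timing experiment (", x$freq, " Hz stress ",
      x$stress[1], "-", x$stress[2], " ms, Mg ", x$baseline_mg, " -> ",
      x$treated_mg, " mM)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
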