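# One-call reproduction of the study's figure/table quantities as CSV/JSON.
# Outputs are data tables (figures are derived views of these).

.reproduce_targets <- c("fig1", "fig2", "fig3", "fig4", "fig5", "fig6",
                        "s1_table", "s2_fig", "s3_fig")

write_csv_out <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Reproduce a figure or table of the study
#'
#' Runs the protocol behind one of the study's displays and writes the
#' underlying data table(s) plus a JSON manifest to `out_dir`. Repeated
#' invocation is byte-identical (the model is deterministic).
#'
#' Targets: `fig1` (Mg block curves, 80 Hz example metrics per Mg2+),
#' `fig2`/`fig3` (full dose-response grid and therapeutic windows per
#' frequency), `fig4`/`fig5` (intervention timing and calcium-progress
#' reanalysis), `fig6` (mechanistic comparison 0.2 vs 1.8 mM at 80 Hz),
#' `s1_table` (high-resolution 80 Hz scan with dual-criteria stars),
#' `s2_fig` (toxicity-threshold sensitivity), `s3_fig` (step-size
#' convergence).
#'
#' @param target one of the ids above.
#' @param out_dir output directory (created if needed).
#' @param params model parameters.
#' @param dt integration step (ms).
#' @return Character vector of files written, invisibly.
#' @export
reproduce <- function(target, out_dir = ".", params = rgc_params(),
                      dt = 0.02) {
  target <- match.arg(target, .reproduce_targets)
  params <- as_rgc_params(params)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- function(name) file.path(out_dir, name)
  files <- character()

  sweep80 <- function() {
    run_dose_response(frequencies = 80, params = params, dt = dt)
  }

  if (target == "fig1") {
    V <- seq(-90, 40, by = 1)
    bcurves <- data.frame(V = V,
                          B_0.2 = mg_block(V, 0.2, params),
                          B_1.0 = mg_block(V, 1.0, params),
                          B_2.0 = mg_block(V, 2.0, params))
    files <- c(files, write_csv_out(bcurves, out("fig1_mg_block_curves.csv")))
    sw <- sweep80()
    files <- c(files, write_csv_out(sw$summary, out("fig1_80hz_metrics.csv")))
  } else if (target %in% c("fig2", "fig3")) {
    sw <- run_dose_response(params = params, dt = dt)
    files <- c(files, write_csv_out(sw$summary, out(paste0(target,
      "_dose_response_grid.csv"))))
    wtab <- do.call(rbind, lapply(sw$windows, function(w)
      data.frame(frequency = w$frequency, exists = w$exists, lower = w$lower,
                 upper = w$upper, width = ifelse(w$exists, w$width, NA))))
    files <- c(files, write_csv_out(wtab, out(paste0(target,
      "_therapeutic_windows.csv"))))
    wjson <- out(paste0(target, "_therapeutic_windows.json"))
    jsonlite::write_json(wtab, wjson, auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <- c(files, wjson)
  } else if (target %in% c("fig4", "fig5")) {
    tm <- run_timing_experiment(params = params, dt = dt)
    files <- c(files, write_csv_out(tm$table, out(paste0(target,
      "_timing_summary.csv"))))
    if (target == "fig5") {
      prog <- tm$untreated_ca[seq(1, nrow(tm$untreated_ca), by = 50), ]
      prog$progress <- (prog$Ca - params$Ca_rest) /
        (tm$peak_untreated - params$Ca_rest)
      files <- c(files, write_csv_out(prog, out("fig5_ca_progress_trace.csv")))
    }
  } else if (target == "fig6") {
    rows <- lapply(c(0.2, 1.8), function(mg) {
      pr <- stim_protocol(freq = 80, stim_end = 3000, t_end = 3000, mg = mg)
      tr <- rgc_integrate(pr, params, dt = dt)
      win <- c(500, 3000)
      sp <- detect_spikes(tr, win)
      idx <- which(tr$time >= win[1] & tr$time <= win[2])
      data.frame(mg = mg,
                 peak_ca_uM = peak_calcium(tr, win),
                 q_nmda = nmda_charge(tr, win),
                 mean_unblock = mean_unblock(tr, win),
                 peak_inmda = max(abs(tr$INMDA[idx])),
                 peak_iampa = max(abs(tr$IAMPA[idx])),
                 n_spikes = sp$n_spikes)
    })
    tab <- do.call(rbind, rows)
    tab$q_reduction_pct <- 100 * (1 - tab$q_nmda / tab$q_nmda[1])
    files <- c(files, write_csv_out(tab, out("fig6_mechanistic_metrics.csv")))
  } else if (target == "s1_table") {
    sw <- sweep80()
    s <- sw$summary
    s$star <- ifelse(s$in_window, "*", "")
    files <- c(files, write_csv_out(s, out("s1_table_80hz_fine_grid.csv")))
  } else if (target == "s2_fig") {
    sw <- sweep80()
    s <- sw$summary
    sens <- threshold_sensitivity(s$mg, s$peak_ca_uM,
                                  s$spike_loss_vs_baseline_pct)
    files <- c(files, write_csv_out(sens, out("s2_threshold_sensitivity.csv")))
  } else if (target == "s3_fig") {
    pr <- stim_protocol(freq = 80, stim_end = 3000, t_end = 3000, mg = 0.2)
    cr <- convergence_report(pr, params)
    files <- c(files, write_csv_out(cr, out("s3_convergence.csv")))
  }

  man <- run_manifest(params, integration = list(dt = dt, method = "euler",
                                                 record_stride = 1))
  mpath <- out(paste0(target, ".manifest.json"))
  jsonlite::write_json(unclass(man), mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mpath))
}
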