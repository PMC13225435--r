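sw_small <- cached("sw_small", run_dose_response(
  frequencies = 80, mg_values = c(0.2, 1.0, 1.8), verbose = FALSE))

test_that("dose-response summaries carry consistent per-cell metrics", {
  s <- sw_small$summary
  expect_equal(nrow(s), 3)
  expect_equal(s$n_expected, rep(200, 3))
  # spike-loss/probability identity in every cell
  expect_equal(s$spike_loss_pct, 100 * (1 - s$spike_prob))
  # the baseline cell is its own reference
  base <- s[s$mg == 0.2, ]
  expect_equal(base$spike_loss_vs_baseline_pct, 0)
  expect_equal(base$ca_reduction_pct, 0)
  # peak calcium decreases with Mg, reductions increase
  expect_true(all(diff(s$peak_ca_uM) < 0))
  expect_true(all(diff(s$ca_reduction_pct) > 0))
  expect_true(all(is.na(s$error)))
})

test_that("sweep cells are independent of the surrounding grid", {
  s <- sw_small$summary
  cell <- s[s$mg == 1.8, ]
  tr <- trace80(1.8)
  sp <- detect_spikes(tr, c(500, 3000))
  expect_equal(cell$n_spikes, sp$n_spikes)
  expect_equal(cell$peak_ca_uM, peak_calcium(tr, c(500, 3000)))
})

test_that("the baseline concentration must be on the grid", {
  expect_error(run_dose_response(frequencies = 80, mg_values = c(1, 2)),
               "baseline")
})

test_that("timing experiment scores interventions against both references", {
  tm <- cached("tm_small", run_timing_experiment(delays_s = c(0.2, 2)))
  tab <- tm$table
  expect_equal(tab$label, c("pretreat", "+0.2 s", "+2 s"))
  # pre-treatment is the 100% reference by construction
  expect_equal(tab$efficacy_pct[1], 100)
  # efficacy declines with delay; late intervention is nearly useless
  expect_true(all(diff(tab$efficacy_pct) < 0))
  expect_lt(tab$efficacy_pct[3], 5)
  # calcium progress at the intervention moment increases with delay
  expect_true(all(diff(tab$ca_progress_at_intervention) > 0))
  expect_true(all(tab$ca_progress_at_intervention >= 0 &
                    tab$ca_progress_at_intervention <= 1))
  # an intervention identical to the untreated run scores 0
  expect_equal(protection_efficacy(tm$peak_untreated, tm$peak_pretreated,
                                   tm$peak_untreated), 0)
})

test_that("pre-treated timing run matches the dose-response plateau", {
  tm <- cached("tm_small", run_timing_experiment(delays_s = c(0.2, 2)))
  # steady-state peak under constant 1.8 mM: stress protocol (window
  # restricted to late steady state) vs the dose-response cell
  cell_peak <- peak_calcium(trace80(1.8), c(1500, 3000))
  tr_pre <- rgc_integrate(
    stim_protocol(freq = 80, stim_start = 500, stim_end = 4500,
                  t_end = 6000, mg = 1.8))
  expect_equal(peak_calcium(tr_pre, c(2000, 4500)), cell_peak,
               tolerance = 0.01)
})

test_that("delays outside the stress window are rejected", {
  expect_error(run_timing_experiment(delays_s = c(0.2, 5)), "stress window")
})
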