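test_that("an unstimulated cell stays at rest for 3 seconds", {
  p <- rgc_params()
  tr <- trace_rest()
  expect_true(all(abs(tr$V - p$Vrest) < 1))
  expect_true(all(abs(tr$Ca - p$Ca_rest) / p$Ca_rest < 0.01))
})

test_that("gating and synaptic variables stay in [0, 1] during stimulation", {
  tr <- trace80(0.2)
  for (v in c("m", "h", "n", "a", "b", "sCaL", "sAMPA", "sNMDA")) {
    expect_true(all(tr[[v]] >= 0 & tr[[v]] <= 1), label = v)
  }
  expect_true(all(tr$Ca >= 0))
})

test_that("integration is deterministic (bit-identical reruns)", {
  pr <- proto_short(t_end = 300)
  t1 <- rgc_integrate(pr)
  t2 <- rgc_integrate(pr)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  r1 <- rgc_integrate(pr, method = "rk4")
  r2 <- rgc_integrate(pr, method = "rk4")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("the pure-R integration path reproduces the compiled path", {
  pr <- proto_short(t_end = 50)
  tc <- rgc_integrate(pr, dt = 0.02)
  tr <- rgc_integrate(pr, dt = 0.02, kinetics = default_kinetics())
  expect_equal(tc$V, tr$V, tolerance = 1e-8)
  expect_equal(tc$Ca, tr$Ca, tolerance = 1e-8)
  expect_equal(tc$INMDA, tr$INMDA, tolerance = 1e-8)
})

test_that("calcium relaxes to rest with the nominal time constant", {
  p <- rgc_params()
  init <- resting_state(p)
  init["Ca"] <- 1.0
  pr <- stim_protocol(freq = 10, pulse_amp = 0, stim_end = 800, t_end = 800,
                      mg = 1.0)
  tr <- rgc_integrate(pr, init = init)
  # fit log-linear decay of (Ca - Ca_rest) over the first 400 ms
  sel <- tr$time <= 400
  fit <- stats::lm(log(tr$Ca[sel] - p$Ca_rest) ~ tr$time[sel])
  tau_fit <- -1 / coef(fit)[2]
  expect_lt(abs(tau_fit - p$tau_Ca) / p$tau_Ca, 0.05)
})

test_that("numerical guards abort with a named variable and time", {
  # Euler far above the stable step for the Na gate trips the gating guard
  expect_error(rgc_integrate(proto_short(t_end = 50), dt = 0.5),
               "left \\[0,1\\].*t = ")
  # an absurd initial state trips the blow-up guard
  init <- resting_state()
  init["Ca"] <- 2000
  expect_error(rgc_integrate(proto_short(mg = 0, t_end = 50), init = init),
               "blowup")
})

test_that("record_stride subsamples the grid without changing dynamics", {
  pr <- proto_short(t_end = 100)
  full <- rgc_integrate(pr)
  coarse <- rgc_integrate(pr, record_stride = 10L)
  expect_equal(diff(coarse$time[1:2]), 0.2)
  expect_identical(coarse$V, full$V[seq(1, nrow(full), by = 10)])
})

test_that("Euler error versus the RK4 reference shrinks with the step", {
  pr <- proto80(0.2, t_end = 600)
  cr <- convergence_report(pr, dt_values = c(0.05, 0.02, 0.01),
                           ref_dt = 0.005, window = c(100, 600))
  expect_true(all(diff(cr$rel_error_pct) < 0))
  # identical step and method give zero error against itself
  ref <- attr(cr, "reference")
  tr <- rgc_integrate(pr, dt = ref[["dt"]], method = "rk4")
  expect_equal(peak_calcium(tr, c(100, 600)), ref[["peak_ca_uM"]])
})
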