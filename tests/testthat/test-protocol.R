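test_that("glutamate pulse trains have the stated timing and bookkeeping", {
  pr <- stim_protocol(freq = 80, stim_end = 3000, t_end = 3000)
  expect_equal(pr$period, 12.5)
  expect_equal(expected_pulses(pr, c(500, 3000)), 200)
  # pulse values: amplitude inside [t_k, t_k + width), zero outside
  expect_equal(glutamate_at(pr, c(0, 1.99, 2.01, 12.5, 14.6)),
               c(1, 1, 0, 1, 0))
  # onset-aligned to the pulse grid
  expect_equal(glutamate_at(pr, 500), 1)
  # pulse count matches floor(f * span) for all default grid frequencies
  for (f in c(10, 30, 60, 80, 90, 100)) {
    prf <- stim_protocol(freq = f, stim_end = 3000, t_end = 3000)
    expect_equal(expected_pulses(prf, c(500, 3000)), floor(f * 2.5))
  }
})

test_that("degenerate protocols are rejected", {
  expect_error(stim_protocol(freq = 600, pulse_width = 2), "pulse_width")
  expect_error(stim_protocol(freq = 80, stim_start = 100, stim_end = 50),
               "stim_start")
  expect_error(stim_protocol(freq = 80, stim_end = 400, t_end = 300),
               "stim_start")
  expect_error(stim_protocol(freq = 80, mg = -0.5), ">= 0")
  expect_error(stim_protocol(freq = 80,
    mg_schedule = data.frame(time = c(0, 100, 50), mg = c(1, 1, 1))),
    "non-decreasing")
})

test_that("no pulses fall outside the stimulation span", {
  pr <- stim_protocol(freq = 80, stim_start = 500, stim_end = 4500,
                      t_end = 6000)
  t <- seq(0, 6000, by = 0.25)
  glu <- glutamate_at(pr, t)
  expect_true(all(glu[t < 500 | t >= 4500] == 0))
  expect_equal(expected_pulses(pr, c(500, 4500)), 320)
  # a window with no pulses
  expect_equal(expected_pulses(pr, c(4600, 5600)), 0)
})

test_that("Mg schedules step at the stated times", {
  pr <- stim_protocol(freq = 80, stim_end = 3000, t_end = 3000,
    mg_schedule = data.frame(time = c(0, 700), mg = c(0.2, 1.8)))
  expect_equal(mg_at(pr, c(0, 699.9, 700, 2999)), c(0.2, 0.2, 1.8, 1.8))
  # constant shorthand
  expect_equal(mg_at(proto80(1.4), c(0, 1500)), c(1.4, 1.4))
})
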