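test_that("spike detection counts upward threshold crossings", {
  # synthetic sawtooth with a known number of crossings
  t <- seq(0, 99.9, by = 0.1)
  k <- 7
  V <- -60 + 50 * (sin(2 * pi * k * t / 100) > 0)  # k square pulses above -20
  tr <- data.frame(time = t, V = V)
  sp <- detect_spikes(tr, c(0, 99.9), n_expected = k)
  expect_equal(sp$n_spikes, k)
  expect_equal(sp$spike_probability, 1)
  expect_equal(sp$spike_loss_pct, 0)
  # flat sub-threshold trace: no spikes, total loss
  flat <- data.frame(time = t, V = rep(-65, length(t)))
  spf <- detect_spikes(flat, c(0, 99.9), n_expected = 10)
  expect_equal(spf$n_spikes, 0)
  expect_equal(spf$spike_loss_pct, 100)
  # the identity loss = 100 * (1 - n/n_expected)
  sp2 <- detect_spikes(tr, c(0, 99.9), n_expected = 10)
  expect_equal(sp2$spike_loss_pct, 100 * (1 - k / 10))
  # 160 of 200 expected pulses is 20% loss
  expect_equal(100 * (1 - 160 / 200), 20)
  # probability caps at 1 when bursting yields extra crossings
  sp3 <- detect_spikes(tr, c(0, 99.9), n_expected = 5)
  expect_equal(sp3$spike_probability, 1)
  expect_equal(sp3$spike_loss_pct, 0)
  # a sustained supra-threshold plateau counts once (de-bounce)
  Vp <- rep(-65, length(t)); Vp[200:500] <- 10
  spp <- detect_spikes(data.frame(time = t, V = Vp), c(0, 99.9),
                       n_expected = 1)
  expect_equal(spp$n_spikes, 1)
})

test_that("window arguments are validated against the trace", {
  t <- seq(0, 100, by = 1)
  tr <- data.frame(time = t, V = rep(-65, 101), Ca = rep(0.05, 101))
  expect_error(detect_spikes(tr, c(50, 150), n_expected = 1), "outside")
  expect_error(peak_calcium(tr, c(80, 20)), "window")
  expect_error(detect_spikes(tr, c(0, 100)), "n_expected")
})

test_that("peak calcium is the window maximum", {
  t <- seq(0, 100, by = 1)
  tr <- data.frame(time = t, Ca = 0.05 + 0.01 * t)
  expect_equal(peak_calcium(tr, c(0, 100)), 1.05)
  expect_equal(peak_calcium(tr, c(0, 50)), 0.55)
  const <- data.frame(time = t, Ca = rep(0.42, 101))
  expect_equal(peak_calcium(const, c(10, 90)), 0.42)
})

test_that("therapeutic window classification honours both criteria", {
  mg <- seq(1.0, 2.5, by = 0.1)
  peak <- seq(1.5, 0.6, length.out = length(mg))   # monotone decreasing
  loss <- c(rep(0, 6), rep(20, 6), rep(25, 4))     # plateau then failure
  w <- find_window(mg, peak, loss, therapeutic_criteria(), frequency = 80)
  expect_true(w$exists)
  inside <- mg >= w$lower & mg <= w$upper
  expect_true(all(peak[inside] < 1 & loss[inside] <= 20))
  # every concentration just outside violates at least one criterion
  for (i in which(!inside))
    expect_true(peak[i] >= 1 || loss[i] > 20)
  expect_equal(w$width, w$upper - w$lower)
  # all-pass grid spans everything
  w2 <- find_window(mg, rep(0.5, 16), rep(0, 16))
  expect_equal(c(w2$lower, w2$upper), c(1.0, 2.5))
  # no-pass grid is empty
  w3 <- find_window(mg, rep(2, 16), rep(50, 16))
  expect_false(w3$exists)
  expect_error(find_window(rev(mg), peak, loss), "increasing")
})

test_that("window width grows with the toxicity threshold", {
  mg <- seq(1.0, 2.5, by = 0.1)
  peak <- seq(1.5, 0.6, length.out = length(mg))
  loss <- c(rep(0, 6), rep(20, 6), rep(25, 4))
  sens <- threshold_sensitivity(mg, peak, loss,
                                thresholds = seq(0.6, 1.4, by = 0.1))
  expect_true(all(diff(sens$width) >= 0))
  # an effectively unbounded threshold leaves only the spike-loss criterion
  loose <- threshold_sensitivity(mg, peak, loss, thresholds = c(1, 1e6))
  w_loss_only <- find_window(mg, rep(0, 16), loss)
  expect_equal(loose$width[2], w_loss_only$width)
  expect_error(threshold_sensitivity(mg, peak, loss, thresholds = c(1, 0.5)),
               "ascending")
})

test_that("protection efficacy is the linear peak-reduction score", {
  expect_equal(protection_efficacy(4, 1, 2.5), 50)
  expect_equal(protection_efficacy(4, 1, 1), 100)
  expect_equal(protection_efficacy(4, 1, 4), 0)
  expect_equal(protection_efficacy(4, 1, c(4, 2.5, 1)), c(0, 50, 100))
  expect_error(protection_efficacy(1, 1, 1), "degenerate")
  expect_error(protection_efficacy(0.8, 1, 0.9), "degenerate")
})

test_that("calcium progress normalises against the untreated peak", {
  t <- seq(0, 1000, by = 1)
  ca <- 0.05 + 4.5 * (1 - exp(-t / 200))
  tr <- structure(data.frame(time = t, Ca = ca),
                  class = c("rgc_trace", "data.frame"))
  expect_equal(ca_progress(tr, 0, window = c(0, 1000)), 0)
  t_peak <- t[which.max(ca)]
  expect_equal(ca_progress(tr, t_peak, window = c(0, 1000)), 1)
  # non-decreasing along the rise
  pv <- ca_progress(tr, seq(0, 1000, by = 50), window = c(0, 1000))
  expect_true(all(diff(pv) >= 0))
  expect_error(ca_progress(tr, -5, window = c(0, 1000)), "outside")
})

test_that("NMDA charge and mean unblock integrate the recorded trace", {
  t <- seq(0, 100, by = 0.5)
  tr <- data.frame(time = t, INMDA = rep(-2, length(t)),
                   B = rep(0.25, length(t)))
  expect_equal(nmda_charge(tr, c(0, 100)), 2 * 100)
  expect_equal(mean_unblock(tr, c(0, 100)), 0.25)
  zero <- data.frame(time = t, INMDA = 0, B = 1)
  expect_equal(nmda_charge(zero, c(0, 100)), 0)
  expect_equal(mean_unblock(zero, c(0, 100)), 1)
  # clamped V at fixed Mg equals the closed-form block factor
  trv <- data.frame(time = t, B = mg_block(-65, 0.2) + 0 * t)
  expect_equal(mean_unblock(trv, c(0, 100)), mg_block(-65, 0.2))
})
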