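p <- rgc_params()

test_that("Mg block factor matches closed-form values and rejects bad input", {
  # resting-potential block at the three reference concentrations
  expect_equal(round(100 * mg_block(-65, c(0.2, 1, 2))), c(24, 6, 3))
  expect_equal(mg_block(-30, 0), 1)
  expect_equal(mg_block(0, 1), 1 / 1.28)
  expect_error(mg_block(-65, -0.1), "Mg")
  expect_error(mg_block(-65, NA_real_), "Mg")
})

test_that("Mg block factor is monotone in voltage and concentration", {
  V <- seq(-90, 40, by = 5)
  for (mg in c(0.1, 0.5, 1, 2.5))
    expect_true(all(diff(mg_block(V, mg)) > 0))
  mg <- seq(0.1, 3, by = 0.1)
  for (v in c(-80, -65, -40, 0))
    expect_true(all(diff(mg_block(v, mg)) < 0))
})

test_that("intrinsic currents follow their conductance equations", {
  st <- resting_state()
  ii <- intrinsic_currents(st, p)
  # KCa half-saturates at Ca = Kd
  st2 <- st; st2["Ca"] <- p$Kd_KCa
  act <- intrinsic_currents(st2, p)$IKCa / (p$gKCa * (st2["V"] - p$EK))
  expect_equal(unname(act), 0.5)
  # zero driving force at the potassium reversal
  st3 <- st; st3["V"] <- p$EK
  ii3 <- intrinsic_currents(st3, p)
  expect_equal(ii3$IKdr, 0)
  expect_equal(ii3$IKA, 0)
  # maximal Na activation at 0 mV
  st4 <- st; st4["V"] <- 0; st4["m"] <- 1; st4["h"] <- 1
  expect_equal(intrinsic_currents(st4, p)$INa, 120 * (0 - 50))
  # leak is linear
  expect_equal(ii$IL, p$gL * (st[["V"]] - p$EL))
})

test_that("synaptic currents compose conductance, gate and Mg block", {
  st <- resting_state()
  st["V"] <- -65
  # closed NMDA gate conducts nothing
  st["sNMDA"] <- 0; st["sAMPA"] <- 0.5
  si <- synaptic_currents(st, 0.2, p)
  expect_equal(si$INMDA, 0)
  expect_equal(si$IAMPA, p$gAMPA * 0.5 * (-65))
  # both vanish at the excitatory reversal potential
  st2 <- st; st2["V"] <- p$Eexc; st2["sNMDA"] <- 1
  si2 <- synaptic_currents(st2, 0.2, p)
  expect_equal(si2$IAMPA, 0)
  expect_equal(si2$INMDA, 0)
  # open NMDA gate at rest: inward, scaled by the block factor
  st3 <- st; st3["sNMDA"] <- 1
  si3 <- synaptic_currents(st3, 0.2, p)
  expect_equal(si3$INMDA, p$gNMDA * mg_block(-65, 0.2, p) * (-65))
  expect_lt(si3$INMDA, 0)
})

test_that("synaptic gate kinetics have the stated fixed points", {
  expect_equal(syn_gate_deriv(0, 0, 0.5, 0.3, 3), 0)
  # half-maximal activation at Glu = EC50
  expect_equal(syn_gate_deriv(0, 0.5, 0.5, 1, 10), 0.5)
  # NMDA nearly saturated at cleft glutamate
  a_nmda <- 1 / (1 + 0.002)
  expect_equal(syn_gate_deriv(0, 1, 0.002, 5, 80), a_nmda / 5)
  # analytic fixed point: A(1-s)/tr = s/td
  A <- 1 / 1.5; tr <- 0.3; td <- 3
  s_star <- A * td / (A * td + tr)
  expect_equal(syn_gate_deriv(s_star, 1, 0.5, tr, td), 0, tolerance = 1e-12)
})

test_that("calcium dynamics: fixed point, decay and influx terms", {
  expect_equal(ca_deriv(p$Ca_rest, 0, 0, p), 0)
  expect_equal(ca_deriv(0.25, 0, 0, p), -(0.25 - 0.05) / 200)
  expect_equal(ca_deriv(p$Ca_rest, -10, 0, p), 0.012 * 0.15 * 10)
  # inward currents always produce non-negative influx terms
  expect_gte(ca_deriv(p$Ca_rest, -1, -1, p), 0)
})

test_that("full right-hand side decomposes into the component currents", {
  pr <- proto_short()
  st <- resting_state()
  st["V"] <- -48; st["sAMPA"] <- 0.4; st["sNMDA"] <- 0.6; st["Ca"] <- 1.2
  d <- rgc_rhs(1.0, st, pr, p)
  ii <- intrinsic_currents(st, p)
  si <- synaptic_currents(st, mg_at(pr, 1.0), p)
  itot <- sum(unlist(ii)) + si$IAMPA + si$INMDA
  expect_equal(unname(d["V"]), -itot / p$Cm)
  expect_equal(unname(d["Ca"]), ca_deriv(st[["Ca"]], si$INMDA, ii$ICaL, p))
  # determinism: identical inputs give identical derivatives
  expect_identical(d, rgc_rhs(1.0, st, pr, p))
  expect_error(rgc_rhs(0, replace(st, 1, NaN), pr, p), "non-finite")
})

test_that("compiled right-hand side matches the pure-R reference", {
  pr <- proto80(0.7)
  set.seed(42)
  for (i in 1:25) {
    st <- c(V = runif(1, -90, 40), m = runif(1), h = runif(1), n = runif(1),
            a = runif(1), b = runif(1), sCaL = runif(1), sAMPA = runif(1),
            sNMDA = runif(1), Ca = runif(1, 0.05, 5))
    t <- runif(1, 0, 3000)
    dR <- rgc_rhs(t, st, pr, p)
    dC <- rgcmg:::rhs_cpp(unname(st), unclass(p), glutamate_at(pr, t),
                          mg_at(pr, t))
    expect_equal(dR, dC$deriv, tolerance = 1e-12)
  }
})
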