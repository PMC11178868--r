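ip_step <- induction_params(U = 0, r = 1e4, d = 0)  # near-instant induction

test_that("RNP activity is anchored at 1e-6 and saturates at the intact pool", {
  ip <- induction_params(U = 0, r = 5, d = 0)
  expect_equal(rnp_activity(0, 1, ip), 1e-6, tolerance = 1e-2)
  expect_equal(rnp_activity(100, 1, ip), 1, tolerance = 1e-6)
  expect_equal(rnp_activity(100, 0.4, ip), 0.4, tolerance = 1e-6)
  expect_error(rnp_activity(-1, 1, ip), "non-negative")
  # monotone non-decreasing in the intact fraction
  a <- vapply(seq(0, 1, 0.1), function(x) rnp_activity(10, x, ip), numeric(1))
  expect_true(all(diff(a) >= 0))
  # clipped at zero when most molecules are no longer intact
  expect_identical(rnp_activity(100, 0, induction_params(U = 0.5, r = 5)), 0)
})

test_that("3-state derivatives match direct substitution and conserve mass", {
  z <- ode_rhs_3(c(1, 0, 0), 10, rates3(0, 0, 0), ip_step)
  expect_equal(unname(z), c(0, 0, 0))
  d1 <- ode_rhs_3(c(1, 0, 0), 10, rates3(0.01, 0.05, 0.03), ip_step)
  expect_equal(unname(d1), c(-0.01, 0, 0.01), tolerance = 1e-6)
  set.seed(21)
  for (i in 1:25) {
    st <- runif(3); st <- st / sum(st)
    r3 <- rates3(runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 5))
    expect_equal(sum(ode_rhs_3(st, runif(1, 0, 72), r3, ip_step)), 0,
                 tolerance = 1e-12)
    st4 <- runif(4); st4 <- st4 / sum(st4)
    r4 <- rates4(runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 5),
                 runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 5))
    expect_equal(sum(ode_rhs_4(st4, runif(1, 0, 72), r4, ip_step)), 0,
                 tolerance = 1e-12)
  }
})

test_that("the 4-state RHS nests the 3-state RHS at k_processing = 0", {
  st <- c(0.7, 0.1, 0.2)
  d3 <- ode_rhs_3(st, 12, rates3(0.02, 0.06, 0.04), ip_step)
  d4 <- ode_rhs_4(c(st, 0), 12, rates4(0.02, 0, 0.06, 0.04, 0.9, 0.9),
                  ip_step)
  expect_equal(unname(d4[1:3]), unname(d3), tolerance = 1e-14)
  expect_equal(unname(d4[4]), 0)
  # processing feeds the processed pool at k_processing * dsb
  d4b <- ode_rhs_4(c(0.7, 0.1, 0.1, 0.1), 12,
                   rates4(0, 0.02, 0, 0, 0, 0), ip_step)
  expect_equal(unname(d4b[4]), 0.002, tolerance = 1e-12)
})

test_that("integration conserves mass and is step-size converged", {
  r3 <- rates3(0.05, 0.06, 0.08, 0.2)
  tr <- integrate_model("3state", r3, ip_step, times = 0:72,
                        steps_per_hour = 500)
  expect_equal(rowSums(tr[, c("intact", "indel", "dsb")]), rep(1, 73),
               tolerance = 1e-8)
  # zero rates: nothing moves
  tr0 <- integrate_model("3state", rates3(0, 0, 0), ip_step, times = c(0, 72))
  expect_equal(tr0$intact, c(1, 1))
  # halving the step changes no component by more than 1e-4
  tr2 <- integrate_model("3state", r3, ip_step, times = 0:72,
                         steps_per_hour = 1000)
  expect_lt(max(abs(as.matrix(tr[, -1]) - as.matrix(tr2[, -1]))), 1e-4)
})

test_that("the 4-state trajectory reproduces the 3-state one when nested", {
  r3 <- rates3(0.05, 0.06, 0.08)
  r4 <- rates4(0.05, 0, 0.06, 0.08, 1, 2)
  t3 <- integrate_model("3state", r3, ip_step, times = c(0, 6, 24, 72))
  t4 <- integrate_model("4state", r4, ip_step, times = c(0, 6, 24, 72))
  expect_equal(t4$intact, t3$intact, tolerance = 1e-12)
  expect_equal(t4$indel, t3$indel, tolerance = 1e-12)
  expect_equal(t4$dsb, t3$dsb, tolerance = 1e-12)
  expect_equal(t4$processed_dsb, rep(0, 4))
})

test_that("flux identities hold on random parameter draws", {
  set.seed(31)
  for (i in 1:30) {
    r3 <- rates3(runif(1, 0.001, 0.3), runif(1, 0.001, 0.3),
                 runif(1, 0.001, 0.3))
    ip <- induction_params(U = runif(1, 0, 0.5), r = 10^runif(1, -1, 4),
                           d = runif(1, 0, 0.05))
    fl <- compute_flows("3state", r3, ip, T = 48)
    # accounting: everything cut is now broken, an indel, or precisely repaired
    expect_equal(fl$cutting,
                 fl$end_state$indel + fl$precise_repair + fl$end_state$dsb,
                 tolerance = 1e-8)
    expect_equal(fl$end_state$indel, fl$error_repair, tolerance = 1e-8)
    # both repair fluxes integrate the same DSB trajectory
    if (fl$precise_repair > 0)
      expect_equal(fl$error_repair / fl$precise_repair, r3$E / r3$P,
                   tolerance = 1e-8)
    r4 <- rates4(r3$k_cut, runif(1, 0.001, 0.1), r3$P, r3$E,
                 runif(1, 0.001, 0.3), runif(1, 0.001, 0.3))
    fl4 <- compute_flows("4state", r4, ip, T = 48)
    expect_equal(fl4$cutting,
                 fl4$end_state$indel + fl4$precise_direct +
                   fl4$precise_processed + fl4$end_state$dsb +
                   fl4$end_state$processed_dsb,
                 tolerance = 1e-8)
    if (fl4$precise_direct > 0)
      expect_equal(fl4$error_direct / fl4$precise_direct,
                   r4$E_direct / r4$P_direct, tolerance = 1e-8)
    if (fl4$precise_processed > 0)
      expect_equal(fl4$error_processed / fl4$precise_processed,
                   r4$E_processed / r4$P_processed, tolerance = 1e-8)
  }
})

test_that("cutting flow is monotone in the cutting rate", {
  ip <- induction_params(U = 0.1, r = 50, d = 0.01)
  fls <- vapply(c(0.005, 0.02, 0.05, 0.2, 1),
                function(k) compute_flows("3state", rates3(k, 0.05, 0.05),
                                          ip, T = 72)$cutting,
                numeric(1))
  expect_true(all(diff(fls) > 0))
})

test_that("indels are absorbing: final indel fraction equals error flow", {
  # previously reported Psy1 72 h estimates
  r3 <- rates3(0.0092, 0.0791, 0.0335, 0.2052)
  ip <- induction_params(U = 0, r = 9402.089, d = 0)
  tr <- integrate_model("3state", r3, ip, times = c(0, 72))
  fl <- compute_flows("3state", r3, ip, T = 72)
  expect_equal(tr$indel[2], fl$error_repair, tolerance = 1e-10)
  expect_equal(tr$indel[2], 0.1518, tolerance = 0.02)
})

test_that("degenerate inputs are rejected", {
  expect_error(compute_flows("3state", rates3(0.1, 0.1, 0.1), ip_step, T = 0),
               "positive")
  expect_error(rates3(-0.1, 0, 0))
  expect_error(rates3(11, 0, 0))
  expect_error(rates4(0.1, 0.1, 0.1, 0.1, 0.1, 12))
})
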