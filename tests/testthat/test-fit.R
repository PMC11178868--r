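test_that("fits are deterministic given a seed", {
  counts <- sim_3state_counts(seed = 3, n = 2000L, times = c(0, 12, 36, 72))
  f1 <- fit_kinetics(counts, "3state", n_starts = 50L, n_refine = 3L,
                     seed = 7)
  f2 <- fit_kinetics(counts, "3state", n_starts = 50L, n_refine = 3L,
                     seed = 7)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(f1$aic, 2 * f1$n_params - 2 * f1$loglik)
})

test_that("all-intact data drives the cutting rate to zero", {
  cats <- dsb_categories()
  counts <- do.call(rbind, lapply(c(0, 6, 24, 48, 72), function(t) {
    data.frame(sample_id = paste0("s", t), time_h = t, replicate = 1L,
               is_control = FALSE, intact = 5000L, indel = 0L,
               dsb_direct = 0L, dsb_processed = 0L, n_na = 0L)
  }))
  f <- fit_kinetics(counts, "3state", n_starts = 100L, n_refine = 5L,
                    fixed_induction = induction_params(U = 0, r = 1e4, d = 0),
                    seed = 11)
  expect_lt(f$estimates$k_cut, 1e-3)
})

test_that("simulated 3-state rates are recovered within 15 percent", {
  counts <- sim_3state_counts(seed = 101)
  f <- fit_kinetics(counts, "3state", n_starts = 200L, n_refine = 10L,
                    seed = 1)
  expect_lt(abs(f$estimates$k_cut - 0.02) / 0.02, 0.15)
  expect_lt(abs(f$estimates$P - 0.06) / 0.06, 0.15)
  expect_lt(abs(f$estimates$E - 0.04) / 0.04, 0.15)
  expect_lt(abs(f$estimates$e - 0.1), 0.05)
  expect_true(f$converged)
})

test_that("a fixed induction curve reduces the parameter count", {
  counts <- sim_3state_counts(seed = 5, n = 2000L, times = c(0, 12, 36, 72))
  ipf <- induction_params(U = 0, r = 1e4, d = 0)
  f <- fit_kinetics(counts, "3state", fixed_induction = ipf,
                    n_starts = 100L, n_refine = 5L, seed = 3)
  expect_identical(f$n_params, 4L)
  expect_identical(f$induction$r, 1e4)
  # no-precise variant drops P as well
  f0 <- fit_kinetics(counts, "3state_no_precise", fixed_induction = ipf,
                     n_starts = 100L, n_refine = 5L, seed = 3)
  expect_identical(f0$n_params, 3L)
  expect_null(f0$estimates$P)
  expect_identical(f0$rates$P, 0)
})

test_that("single-time-point or empty data is rejected", {
  counts <- sim_3state_counts(seed = 6, n = 500L, times = c(12, 12))
  expect_error(fit_kinetics(counts, "3state"), "2 distinct time points")
})

test_that("AIC comparison reports delta and relative likelihood", {
  counts <- sim_3state_counts(seed = 31, n = 5000L,
                              times = c(0, 6, 24, 48, 72))
  ipf <- induction_params(U = 0, r = 1e4, d = 0)
  f3 <- fit_kinetics(counts, "3state", fixed_induction = ipf,
                     n_starts = 150L, n_refine = 6L, seed = 2)
  f0 <- fit_kinetics(counts, "3state_no_precise", fixed_induction = ipf,
                     n_starts = 150L, n_refine = 6L, seed = 2)
  cmp <- aic_compare(f3, f0)
  expect_identical(nrow(cmp), 2L)
  expect_equal(min(cmp$delta_aic), 0)
  expect_equal(cmp$rel_likelihood, exp(-cmp$delta_aic / 2))
  # the data carry real precise repair, so the 3-state fit must win
  expect_identical(cmp$model[1], "3state")
  # comparing fits of different data is an error
  other <- fit_kinetics(sim_3state_counts(seed = 32, n = 500L,
                                          times = c(0, 24, 72)),
                        "3state", fixed_induction = ipf,
                        n_starts = 50L, n_refine = 3L, seed = 2)
  expect_error(aic_compare(f3, other), "same data")
})

test_that("FACS induction parameters are recovered from exact curve data", {
  truth <- induction_params(U = 0.3, r = 5, d = 0.01, t_offset = 0.5)
  times <- c(0, 0.5, 1, 2, 4, 8, 16, 24, 48)
  tt <- times + truth$t_offset
  t0 <- log(1e6) / (truth$r + 1e-12)
  p <- (1 - truth$U) * 2^(-truth$d * tt) / (1 + exp(-truth$r * (tt - t0)))
  facs <- data.frame(time_h = times, positive_fraction = p, n_cells = 1e6L)
  ip <- fit_induction_from_facs(facs, t_offset = 0.5)
  expect_equal(ip$U, truth$U, tolerance = 1e-3)
  expect_equal(ip$r, truth$r, tolerance = 1e-3)
  expect_equal(ip$d, truth$d, tolerance = 1e-2)
})

test_that("degenerate FACS data hit the expected boundaries", {
  zero <- data.frame(time_h = c(0, 6, 24), positive_fraction = 0,
                     n_cells = 1000L)
  expect_warning(ip0 <- fit_induction_from_facs(zero), "degenerate")
  expect_gt(ip0$U, 0.99)
  one <- data.frame(time_h = c(0, 6, 24), positive_fraction = 1,
                    n_cells = 1000L)
  expect_warning(ip1 <- fit_induction_from_facs(one), "degenerate")
  expect_gt(ip1$r, 50)  # pushed into step-like induction
})
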