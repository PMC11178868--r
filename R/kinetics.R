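# Kinetic compartment models of DSB induction, processing and repair.
#
# Latent states are fractions of the molecule pool: (intact, indel, dsb)
# for the 3-state model, plus processed_dsb for the 4-state model. Rates are
# per-hour; the cut rate is modulated by a time-dependent ribonucleoprotein
# activity curve RNP(t).

#' Induction-curve parameters
#'
#' The effective nuclease (RNP) activity is modeled as a logistic rise with
#' speed `r`, scaled by the transfectable fraction `1 - U` and decaying with
#' half-life `1/d`. The curve is anchored so that activity is ~1e-6 at time 0
#' (logistic midpoint `t0 = log(1e6) / (r + 1e-12)`). Because only intact
#' molecules can be cut, the momentary activity additionally subtracts the
#' fraction of molecules no longer intact, and is clipped at 0; see
#' [rnp_activity()].
#'
#' @param U Uncuttable fraction in `[0, 1]` (e.g. untransfected cells).
#' @param r Induction speed (per hour, >= 0).
#' @param d Activity decay rate (per hour, >= 0); half-life `1/d`.
#' @param t_offset Hours between transfection and the nominal time 0 of the
#'   sampling clock (default 0; 0.5 accounts for a 30 min handling time).
#'   Implemented by shifting the induction clock, not the observation times.
#' @return Object of class `induction_params`.
#' @export
induction_params <- function(U = 0, r = 1e4, d = 0, t_offset = 0) {
  stopifnot(U >= 0, U <= 1, r >= 0, d >= 0, t_offset >= 0)
  structure(list(U = U, r = r, d = d, t_offset = t_offset),
            class = "induction_params")
}

#' Momentary RNP activity
#'
#' `max(0, (1 - U) * 2^(-d*t) * plogis(r * (t - t0)) - (1 - intact))` with
#' `t0 = log(1e6) / (r + 1e-12)`, evaluated on the induction clock
#' (`t + t_offset`). The subtraction of `1 - intact` makes the activity the
#' fraction of the pool that active RNPs can still act on, so the model's
#' cutting term is `k_cut * RNP(t)` directly.
#'
#' @param t Time in hours (vectorized, must be >= 0).
#' @param intact Current intact fraction in `[0, 1]`.
#' @param ip An [induction_params()] object.
#' @return Activity fraction(s), clipped at 0.
#' @export
rnp_activity <- function(t, intact, ip) {
  if (any(t < 0)) stop("t must be non-negative")
  stopifnot(intact >= 0, intact <= 1)
  tt <- t + ip$t_offset
  t0 <- log(1e6) / (ip$r + 1e-12)
  a <- (1 - ip$U) * 2^(-ip$d * tt) /
    (1 + exp(-ip$r * (tt - t0))) - (1 - intact)
  pmax(0, a)
}

#' Rate constants of the 3-state model
#'
#' @param k_cut Cutting rate (per hour, in `[0, 10]`).
#' @param P Precise-repair rate DSB -> intact (per hour).
#' @param E Error-repair rate DSB -> indel (per hour).
#' @param e Probability in `[0, 1]` that a DSB is observed at an unexpected
#'   end position (recorded as processed); an observation-level parameter,
#'   not a kinetic rate.
#' @return Object of class `rates3`.
#' @export
rates3 <- function(k_cut, P, E, e = 0) {
  stopifnot(k_cut >= 0, k_cut <= 10, P >= 0, E >= 0, e >= 0, e <= 1)
  structure(list(k_cut = k_cut, P = P, E = E, e = e), class = "rates3")
}

#' Rate constants of the 4-state model
#'
#' @param k_cut Cutting rate (per hour).
#' @param k_processing Direct-DSB to processed-DSB conversion rate.
#' @param P_direct,E_direct Precise/error repair rates of direct DSBs.
#' @param P_processed,E_processed Precise/error repair rates of processed
#'   DSBs.
#' @return Object of class `rates4`.
#' @export
rates4 <- function(k_cut, k_processing, P_direct, E_direct,
                   P_processed, E_processed) {
  v <- c(k_cut, k_processing, P_direct, E_direct, P_processed, E_processed)
  stopifnot(all(v >= 0), all(v <= 10))
  structure(list(k_cut = k_cut, k_processing = k_processing,
                 P_direct = P_direct, E_direct = E_direct,
                 P_processed = P_processed, E_processed = E_processed),
            class = "rates4")
}

rates_vector <- function(rates) {
  if (inherits(rates, "rates3")) c(rates$k_cut, rates$P, rates$E)
  else c(rates$k_cut, rates$k_processing, rates$P_direct, rates$E_direct,
         rates$P_processed, rates$E_processed)
}

state_names <- function(model) {
  if (model == "4state") c("intact", "indel", "dsb", "processed_dsb")
  else c("intact", "indel", "dsb")
}

flux_names <- function(model) {
  if (model == "4state")
    c("cutting", "processing", "precise_direct", "error_direct",
      "precise_processed", "error_processed")
  else c("cutting", "precise_repair", "error_repair")
}

#' Right-hand side of the 3-state model
#'
#' `d[intact] = -k_cut*RNP(t) + P*[dsb]`, `d[indel] = E*[dsb]`,
#' `d[dsb] = k_cut*RNP(t) - (P+E)*[dsb]`; the intact-pool dependence of the
#' cutting term is carried by [rnp_activity()]. Derivatives sum to zero
#' (molecule conservation).
#'
#' @param state Named or unnamed numeric vector `(intact, indel, dsb)`.
#' @param t Time in hours.
#' @param rates A [rates3()] object.
#' @param ip An [induction_params()] object.
#' @return Derivative vector of length 3.
#' @export
ode_rhs_3 <- function(state, t, rates, ip) {
  cut <- rates$k_cut * rnp_activity(t, state[[1]], ip)
  prec <- rates$P * state[[3]]
  err <- rates$E * state[[3]]
  c(intact = -cut + prec, indel = err, dsb = cut - prec - err)
}

#' Right-hand side of the 4-state model
#'
#' As [ode_rhs_3()] with a fourth, processed-DSB pool: direct DSBs convert to
#' processed DSBs at `k_processing`, and each pool has its own precise and
#' error repair rates.
#'
#' @param state Numeric vector `(intact, indel, dsb, processed_dsb)`.
#' @param t Time in hours.
#' @param rates A [rates4()] object.
#' @param ip An [induction_params()] object.
#' @return Derivative vector of length 4.
#' @export
ode_rhs_4 <- function(state, t, rates, ip) {
  cut <- rates$k_cut * rnp_activity(t, state[[1]], ip)
  proc <- rates$k_processing * state[[3]]
  pd <- rates$P_direct * state[[3]]
  ed <- rates$E_direct * state[[3]]
  pp <- rates$P_processed * state[[4]]
  ep <- rates$E_processed * state[[4]]
  c(intact = -cut + pd + pp, indel = ed + ep,
    dsb = cut - pd - ed - proc, processed_dsb = proc - pp - ep)
}

#' Integrate a kinetic model over a time course
#'
#' Fixed-step classical Runge-Kutta (RK4) integration from an all-intact
#' initial state, at `steps_per_hour` intervals per hour. Requested times are
#' snapped to the step grid.
#'
#' @param model `"3state"` or `"4state"` (`"3state_no_precise"` is accepted
#'   and treated as 3-state).
#' @param rates A [rates3()] or [rates4()] object matching `model`.
#' @param ip An [induction_params()] object.
#' @param times Sorted non-negative times (hours) at which to report.
#' @param steps_per_hour Integration resolution (default 500).
#' @return `data.frame` with `time_h` and one column per latent state
#'   fraction; the cumulative per-rate fluxes up to each time are attached as
#'   attribute `"fluxes"`.
#' @export
integrate_model <- function(model = c("3state", "3state_no_precise", "4state"),
                            rates, ip, times, steps_per_hour = 500L) {
  model <- match.arg(model)
  stopifnot(!is.unsorted(times), all(times >= 0), steps_per_hour >= 1)
  mod_id <- if (model == "4state") 4L else 3L
  res <- tryCatch(
    integrate_kinetics_cpp(mod_id, rates_vector(rates), ip$U, ip$r, ip$d,
                           ip$t_offset, as.numeric(times),
                           as.integer(steps_per_hour)),
    error = function(e)
      stop("integration failed for rates [",
           paste(signif(rates_vector(rates), 4), collapse = ", "),
           "]: ", conditionMessage(e)))
  states <- as.data.frame(res$states)
  names(states) <- state_names(model)
  out <- cbind(time_h = as.numeric(times), states)
  fluxes <- as.data.frame(res$fluxes)
  names(fluxes) <- flux_names(model)
  attr(out, "fluxes") <- cbind(time_h = as.numeric(times), fluxes)
  out
}

#' Cumulative molecule flow through each rate
#'
#' Integrates the model to time `T` and reports, for every rate term, the
#' cumulative fraction of the initial molecule pool that passed through it
#' (e.g. cutting flow = integral of `k_cut * RNP(t) dt`). Flows can exceed 1
#' because precisely repaired molecules re-enter the cuttable pool. Repair
#' accuracy is the precise-repair flow divided by total repair flow.
#'
#' @inheritParams integrate_model
#' @param T End of the time course in hours (> 0).
#' @return Object of class `dsb_flows`: a list with per-rate flows, the end
#'   state, `repair_accuracy`, `model` and `T`.
#' @export
compute_flows <- function(model, rates, ip, T, steps_per_hour = 500L) {
  if (T <= 0) stop("T must be positive")
  traj <- integrate_model(model, rates, ip, times = c(0, T),
                          steps_per_hour = steps_per_hour)
  fl <- attr(traj, "fluxes")[2L, -1L, drop = TRUE]
  fl <- as.list(fl)
  if (identical(match.arg(model, c("3state", "3state_no_precise", "4state")),
                "4state")) {
    precise <- fl$precise_direct + fl$precise_processed
    error <- fl$error_direct + fl$error_processed
  } else {
    precise <- fl$precise_repair
    error <- fl$error_repair
  }
  acc <- if (precise + error > 0) precise / (precise + error) else NA_real_
  structure(
    c(fl, list(repair_accuracy = acc,
               end_state = traj[2L, -1L, drop = FALSE],
               model = model, T = T)),
    class = "dsb_flows")
}

#' @export
print.dsb_flows <- function(x, ...) {
  cat("<dsb_flows>", x$model, "model, T =", x$T, "h\n")
  nm <- setdiff(names(x), c("repair_accuracy", "end_state", "model", "T"))
  for (n in nm) cat(sprintf("  %-18s %8.4f\n", n, x[[n]]))
  cat(sprintf("  %-18s %8.4f\n", "repair_accuracy", x$repair_accuracy))
  invisible(x)
}
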