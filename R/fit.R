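# Box-constrained multi-start maximum likelihood for the kinetic models,
# stratified bootstrap uncertainty, and AIC model comparison.
#
# Parameter boxes: all kinetic rates in [0, max_rate] (default 10 cuts/hour,
# well above any reported CRISPR cutting rate), e and U in [0, 1], decay d in
# [0, 10], induction speed r optimized as log10(r) in [-2, 5].

par_layout <- function(model, co_estimate_induction) {
  rate_names <- switch(model,
    "3state" = c("k_cut", "P", "E", "e"),
    "3state_no_precise" = c("k_cut", "E", "e"),
    "4state" = c("k_cut", "k_processing", "P_direct", "E_direct",
                 "P_processed", "E_processed"))
  nm <- rate_names
  if (co_estimate_induction) nm <- c(nm, "U", "log10_r", "d")
  nm
}

par_bounds <- function(nm, max_rate) {
  lower <- vapply(nm, function(n) switch(n,
    e = 0, U = 0, log10_r = -2, d = 0, 0), numeric(1))
  upper <- vapply(nm, function(n) switch(n,
    e = 1, U = 1, log10_r = 5, d = 10, max_rate), numeric(1))
  list(lower = lower, upper = upper)
}

# Exponential(mean 0.01) starting draws for rates and proportions (truncated
# to the box); log-uniform for the induction speed.
draw_starts <- function(nm, n, bounds) {
  m <- matrix(0, nrow = n, ncol = length(nm), dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    m[, j] <- if (nm[j] == "log10_r") runif(n, bounds$lower[j], bounds$upper[j])
              else pmin(rexp(n, rate = 100), bounds$upper[j])
  }
  m
}

# Negative log-likelihood as a function of the packed parameter vector,
# built on the precompiled likelihood core (no per-call object construction).
make_negll <- function(counts, model, error_matrix, steps_per_hour, nm,
                       bounds, fixed_induction, t_offset) {
  core <- loglik_core(counts, model, error_matrix, steps_per_hour)
  idx <- setNames(seq_along(nm), nm)
  rate_sel <- switch(model,
    "3state" = idx[c("k_cut", "P", "E")],
    "3state_no_precise" = c(idx[["k_cut"]], NA_integer_, idx[["E"]]),
    "4state" = idx[c("k_cut", "k_processing", "P_direct", "E_direct",
                     "P_processed", "E_processed")])
  has_e <- "e" %in% nm
  free_induction <- is.null(fixed_induction)
  function(theta) {
    theta <- pmin(pmax(theta, bounds$lower), bounds$upper)
    rv <- ifelse(is.na(rate_sel), 0, theta[rate_sel])
    e <- if (has_e) theta[idx[["e"]]] else 0
    if (free_induction) {
      ll <- core(rv, e, U = theta[idx[["U"]]], r = 10^theta[idx[["log10_r"]]],
                 d = theta[idx[["d"]]], t_offset = t_offset)
    } else {
      ll <- core(rv, e, U = fixed_induction$U, r = fixed_induction$r,
                 d = fixed_induction$d, t_offset = fixed_induction$t_offset)
    }
    if (!is.finite(ll)) 1e10 else -ll
  }
}

unpack_params <- function(theta, nm, model, fixed_induction, t_offset) {
  g <- function(n, default = 0) if (n %in% nm) theta[[which(nm == n)]] else default
  rates <- switch(model,
    "3state" = rates3(g("k_cut"), g("P"), g("E"), g("e")),
    "3state_no_precise" = rates3(g("k_cut"), 0, g("E"), g("e")),
    "4state" = rates4(g("k_cut"), g("k_processing"), g("P_direct"),
                      g("E_direct"), g("P_processed"), g("E_processed")))
  ip <- if (is.null(fixed_induction)) {
    induction_params(U = g("U"), r = 10^g("log10_r"), d = g("d"),
                     t_offset = t_offset)
  } else fixed_induction
  list(rates = rates, ip = ip)
}

#' Fit a kinetic model to category counts by maximum likelihood
#'
#' Maximizes the exact multinomial log-likelihood over the model's rate
#' constants (box `[0, max_rate]`), the processed-DSB observation probability
#' `e` (3-state models) and, unless `fixed_induction` is given, the induction
#' parameters `U`, `r`, `d`. Optimization is multi-start: `n_starts` points
#' are drawn from an exponential(mean 0.01) start distribution (log-uniform
#' for `r`), the likelihood is evaluated at all of them, and L-BFGS-B is run
#' from the best `n_refine`. The error matrix is estimated from `controls`
#' when supplied.
#'
#' @param counts `category_counts` data.frame with at least 2 distinct time
#'   points (experimental samples only).
#' @param model `"3state"`, `"3state_no_precise"` (precise repair fixed at 0)
#'   or `"4state"`.
#' @param controls Optional control `category_counts` for the error matrix;
#'   alternatively pass a 4x4 matrix as `error_matrix`.
#' @param error_matrix Optional explicit 4x4 error matrix (identity if
#'   neither this nor `controls` given).
#' @param n_starts Number of random starting points screened (default 5000).
#' @param n_refine Number of best starts refined with L-BFGS-B (default 25).
#' @param max_rate Upper box bound for rates (default 10 per hour).
#' @param fixed_induction Optional [induction_params()] to hold fixed
#'   (e.g. from [fit_induction_from_facs()]).
#' @param t_offset Induction clock offset in hours (ignored when
#'   `fixed_induction` is given).
#' @param steps_per_hour Integration resolution inside the likelihood
#'   (default 50).
#' @param seed Optional integer seed; fits are deterministic given it.
#' @return Object of class `dsb_fit`: estimates, loglik, aic, n_params,
#'   convergence flag, start count, and the data/options needed for
#'   [stratified_bootstrap()] and [aic_compare()].
#' @export
fit_kinetics <- function(counts,
                         model = c("3state", "3state_no_precise", "4state"),
                         controls = NULL, error_matrix = NULL,
                         n_starts = 5000L, n_refine = 25L, max_rate = 10,
                         fixed_induction = NULL, t_offset = 0,
                         steps_per_hour = 50L, seed = NULL) {
  model <- match.arg(model)
  if (length(unique(counts$time_h)) < 2L)
    stop("need counts at >= 2 distinct time points")
  if (sum(counts[dsb_categories()]) == 0)
    stop("counts are all zero")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(error_matrix) && !is.null(controls))
    error_matrix <- estimate_error_matrix(controls)

  nm <- par_layout(model, is.null(fixed_induction))
  bounds <- par_bounds(nm, max_rate)
  negll <- make_negll(counts, model, error_matrix, steps_per_hour, nm,
                      bounds, fixed_induction, t_offset)

  starts <- draw_starts(nm, n_starts, bounds)
  screen <- apply(starts, 1L, negll)
  ord <- order(screen)[seq_len(min(n_refine, n_starts))]

  best <- NULL
  converged <- FALSE
  for (i in ord) {
    opt <- tryCatch(
      optim(starts[i, ], negll, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = 200, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      converged <- opt$convergence == 0
    }
  }
  if (is.null(best))
    stop("no optimization start converged; screened best -loglik = ",
         signif(min(screen), 6))

  theta <- setNames(pmin(pmax(best$par, bounds$lower), bounds$upper), nm)
  pr <- unpack_params(theta, nm, model, fixed_induction, t_offset)
  est <- as.list(theta)
  if ("log10_r" %in% nm) {
    est$r <- 10^est$log10_r
    est$log10_r <- NULL
  }
  n_params <- length(nm)
  ll <- -best$value
  structure(
    list(model = model,
         estimates = est,
         rates = pr$rates, induction = pr$ip,
         loglik = ll, n_params = n_params,
         aic = 2 * n_params - 2 * ll,
         converged = converged, start_count = n_starts,
         error_matrix = error_matrix,
         counts = counts,
         options = list(n_starts = n_starts, n_refine = n_refine,
                        max_rate = max_rate, t_offset = t_offset,
                        steps_per_hour = steps_per_hour,
                        fixed_induction = fixed_induction)),
    class = "dsb_fit")
}

#' @export
print.dsb_fit <- function(x, ...) {
  cat("<dsb_fit>", x$model, "model:",
      sprintf("loglik = %.2f, AIC = %.2f (%d parameters)%s\n",
              x$loglik, x$aic, x$n_params,
              if (x$converged) "" else " [not converged]"))
  est <- unlist(x$estimates)
  for (n in names(est)) cat(sprintf("  %-14s %g\n", n, est[n]))
  invisible(x)
}

#' Stratified bootstrap confidence intervals for a fit
#'
#' Resamples molecules with replacement within each (time point, replicate)
#' stratum (a multinomial redraw of each sample's counts at its own total),
#' refits the model on every resample, and reports 1 and 99 percentile
#' confidence intervals plus a one-sided p-value per parameter: the
#' proportion of re-estimates equal to 0 (the lower box bound), reported as
#' `< 1/B` when none.
#'
#' Bootstrap refits start from the original point estimate plus the best of
#' a small random screen.
#'
#' @param fit A [fit_kinetics()] result.
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Optional integer seed.
#' @param n_starts Random starts screened per refit (default 200).
#' @param n_refine Local optimizations per refit (default 2; the original
#'   estimate is always one of them).
#' @return Object of class `dsb_boot`: matrix of re-estimates (`B` rows),
#'   `ci` (1%/99% bounds), `p_values`, `p_labels`, number of failed refits.
#' @export
stratified_bootstrap <- function(fit, B = 100L, seed = NULL,
                                 n_starts = 200L, n_refine = 2L) {
  stopifnot(inherits(fit, "dsb_fit"))
  if (!is.null(seed)) set.seed(seed)
  counts <- fit$counts
  cats <- dsb_categories()
  opts <- fit$options
  draws <- list()
  failures <- 0L
  warm <- unlist(fit$estimates)
  for (b in seq_len(B)) {
    boot <- counts
    for (i in seq_len(nrow(counts))) {
      x <- as.numeric(counts[i, cats])
      n <- sum(x)
      if (n > 0) boot[i, cats] <- as.numeric(rmultinom(1L, n, x / n))
    }
    refit <- tryCatch(
      refit_warm(boot, fit, n_starts, n_refine, warm),
      error = function(e) NULL)
    if (is.null(refit)) { failures <- failures + 1L; next }
    draws[[length(draws) + 1L]] <- unlist(refit$estimates)
  }
  if (length(draws) == 0L) stop("all bootstrap refits failed")
  est <- do.call(rbind, draws)
  ci <- apply(est, 2L, quantile, probs = c(0.01, 0.99), names = FALSE)
  rownames(ci) <- c("ci_low", "ci_high")
  pz <- colMeans(est <= 1e-8)
  p_lab <- ifelse(pz == 0, sprintf("<%.2g", 1 / B), sprintf("%.2g", pz))
  unreliable <- failures > 0.1 * B
  if (unreliable)
    warning(failures, " of ", B, " bootstrap refits failed; CIs unreliable")
  structure(list(estimates = est, ci = ci, p_values = pz, p_labels = p_lab,
                 B = B, failures = failures, unreliable = unreliable),
            class = "dsb_boot")
}

# warm-started refit used by the bootstrap: original MLE plus a small screen
refit_warm <- function(counts, fit, n_starts, n_refine, warm) {
  opts <- fit$options
  model <- fit$model
  nm <- par_layout(model, is.null(opts$fixed_induction))
  warm_theta <- vapply(nm, function(n) {
    if (n == "log10_r") log10(max(warm[["r"]], 1e-2)) else warm[[n]]
  }, numeric(1))
  bounds <- par_bounds(nm, opts$max_rate)
  negll <- make_negll(counts, model, fit$error_matrix, opts$steps_per_hour,
                      nm, bounds, opts$fixed_induction, opts$t_offset)
  starts <- draw_starts(nm, n_starts, bounds)
  screen <- apply(starts, 1L, negll)
  cand <- rbind(warm_theta,
                starts[order(screen)[seq_len(max(1L, n_refine - 1L))], ,
                       drop = FALSE])
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    opt <- tryCatch(
      optim(cand[i, ], negll, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = 150, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("refit failed")
  theta <- setNames(pmin(pmax(best$par, bounds$lower), bounds$upper), nm)
  est <- as.list(theta)
  if ("log10_r" %in% nm) {
    est$r <- 10^est$log10_r
    est$log10_r <- NULL
  }
  list(estimates = est, loglik = -best$value,
       aic = 2 * length(nm) + 2 * best$value)
}

#' Compare fitted models by AIC
#'
#' Reports AIC, delta-AIC and the relative likelihood
#' `exp((AIC_min - AIC) / 2)` for fits of different models to the same data.
#'
#' @param ... Two or more [fit_kinetics()] results on identical counts.
#' @return `data.frame` with one row per model, sorted by AIC.
#' @export
aic_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], "dsb_fit")) fits <- fits[[1L]]
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "dsb_fit")))
  ref <- fits[[1L]]$counts
  for (f in fits[-1L]) {
    if (!isTRUE(all.equal(f$counts[dsb_categories()], ref[dsb_categories()],
                          check.attributes = FALSE)))
      stop("fits were not obtained on the same data")
  }
  out <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE)
  out$delta_aic <- out$aic - min(out$aic)
  out$rel_likelihood <- exp(-out$delta_aic / 2)
  out[order(out$aic), ]
}

#' Bootstrap stability of a model comparison
#'
#' Refits two nested models on shared stratified-bootstrap resamples and
#' reports the proportion of resamples in which the more complex model (more
#' parameters) attains the lower AIC. A proportion above 0.95 flags a stable
#' preference.
#'
#' @param fit_simple,fit_complex [fit_kinetics()] results on the same data.
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Optional integer seed.
#' @param n_starts,n_refine Refit effort per resample (see
#'   [stratified_bootstrap()]).
#' @return List with `support` (proportion preferring the complex model),
#'   `stable` (`support > 0.95`), `B`, and the per-resample AIC matrix.
#' @export
bootstrap_compare <- function(fit_simple, fit_complex, B = 100L, seed = NULL,
                              n_starts = 200L, n_refine = 2L) {
  stopifnot(inherits(fit_simple, "dsb_fit"), inherits(fit_complex, "dsb_fit"))
  if (fit_complex$n_params <= fit_simple$n_params)
    stop("fit_complex must have more parameters than fit_simple")
  if (!isTRUE(all.equal(fit_simple$counts[dsb_categories()],
                        fit_complex$counts[dsb_categories()],
                        check.attributes = FALSE)))
    stop("fits were not obtained on the same data")
  if (!is.null(seed)) set.seed(seed)
  counts <- fit_simple$counts
  cats <- dsb_categories()
  aics <- matrix(NA_real_, nrow = B, ncol = 2L,
                 dimnames = list(NULL, c("simple", "complex")))
  warm_s <- unlist(fit_simple$estimates)
  warm_c <- unlist(fit_complex$estimates)
  for (b in seq_len(B)) {
    boot <- counts
    for (i in seq_len(nrow(counts))) {
      x <- as.numeric(counts[i, cats]); n <- sum(x)
      if (n > 0) boot[i, cats] <- as.numeric(rmultinom(1L, n, x / n))
    }
    rs <- tryCatch(refit_warm(boot, fit_simple, n_starts, n_refine, warm_s),
                   error = function(e) NULL)
    rc <- tryCatch(refit_warm(boot, fit_complex, n_starts, n_refine, warm_c),
                   error = function(e) NULL)
    if (!is.null(rs) && !is.null(rc)) aics[b, ] <- c(rs$aic, rc$aic)
  }
  ok <- stats::complete.cases(aics)
  support <- mean(aics[ok, "complex"] < aics[ok, "simple"])
  list(support = support, stable = support > 0.95, B = B, aic = aics)
}

#' Fit the induction curve to FACS transfection proportions
#'
#' Binomial maximum likelihood fit of the uncoupled induction curve
#' `(1-U) * 2^(-d*t) * plogis(r*(t - t0))` to per-time positive-cell
#' fractions (the intact-pool term of [rnp_activity()] plays no role here).
#'
#' @param facs `data.frame` with columns `time_h`, `positive_fraction`,
#'   `n_cells`; at least 3 time points.
#' @param t_offset Hours between transfection and the first sorting time
#'   (default 0.5).
#' @return An [induction_params()] object with the fitted `U`, `r`, `d`.
#' @export
fit_induction_from_facs <- function(facs, t_offset = 0.5) {
  stopifnot(all(c("time_h", "positive_fraction", "n_cells") %in% names(facs)),
            nrow(facs) >= 3L)
  pos <- round(facs$positive_fraction * facs$n_cells)
  if (all(pos == 0) || all(pos == facs$n_cells))
    warning("degenerate FACS data (all-negative or all-positive); ",
            "boundary estimate returned")
  nm <- c("U", "log10_r", "d")
  bounds <- par_bounds(nm, 10)
  negll <- function(theta) {
    theta <- pmin(pmax(theta, bounds$lower), bounds$upper)
    U <- theta[1]; r <- 10^theta[2]; d <- theta[3]
    t0 <- log(1e6) / (r + 1e-12)
    tt <- facs$time_h + t_offset
    p <- (1 - U) * 2^(-d * tt) / (1 + exp(-r * (tt - t0)))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(pos, facs$n_cells, p, log = TRUE))
  }
  starts <- rbind(
    expand.grid(U = c(0, 0.3, 0.7), log10_r = c(-1, 0, 1, 3), d = c(0, 0.05)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(as.numeric(starts[i, ]), negll, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("induction fit failed")
  th <- pmin(pmax(best$par, bounds$lower), bounds$upper)
  induction_params(U = th[1], r = 10^th[2], d = th[3], t_offset = t_offset)
}
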