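# Observation model: latent state fractions -> probabilities over the four
# observation categories, and the exact multinomial likelihood of category
# counts.

#' Estimate the category error matrix from control time courses
#'
#' Control samples (no guide) contain only intact molecules, so their pooled
#' category frequencies estimate the probability that a truly intact molecule
#' is recorded in each category. Indel-bearing molecules are structurally
#' intact and are assumed to misread at the same rates (with the intact/indel
#' roles swapped); the chance of a broken molecule being read as intact is
#' taken as negligible.
#'
#' @param controls A `category_counts` data.frame of control samples (rows
#'   pooled), or `NULL`/empty for an identity matrix (with a warning).
#' @return 4x4 matrix over [dsb_categories()]; `entry[obs, true]` is the
#'   probability that a molecule of true category `true` is recorded as
#'   `obs`. Columns sum to 1.
#' @export
estimate_error_matrix <- function(controls = NULL) {
  cats <- dsb_categories()
  em <- diag(4)
  dimnames(em) <- list(obs = cats, true = cats)
  if (is.null(controls) || nrow(controls) == 0L) {
    warning("no control samples supplied; using identity error matrix")
    return(em)
  }
  pooled <- vapply(cats, function(k) sum(controls[[k]]), numeric(1))
  if (sum(pooled) == 0) {
    warning("control samples have zero total count; using identity error matrix")
    return(em)
  }
  p <- pooled / sum(pooled)
  em[, "intact"] <- p
  # indel molecules mirror intact error rates with roles swapped
  em[, "indel"] <- p[c(2L, 1L, 3L, 4L)]
  validate_error_matrix(em)
  em
}

validate_error_matrix <- function(em) {
  if (!is.matrix(em) || !all(dim(em) == c(4L, 4L)))
    stop("error matrix must be 4x4 over ", paste(dsb_categories(), collapse = ", "))
  if (any(em < 0) || any(em > 1))
    stop("error matrix entries must lie in [0, 1]")
  if (any(abs(colSums(em) - 1) > 1e-8))
    stop("error matrix columns must sum to 1")
  invisible(em)
}

#' Map latent state fractions to observation-category probabilities
#'
#' For the 3-state model the latent DSB pool is split into observed direct
#' and processed DSBs with probability `e` (`dsb_direct = (1-e)*dsb`,
#' `dsb_processed = e*dsb`); the 4-state model maps its four pools
#' one-to-one. The error matrix is then applied.
#'
#' @param latent Numeric vector of latent fractions: `(intact, indel, dsb)`
#'   or `(intact, indel, dsb, processed_dsb)`.
#' @param e Processed-DSB observation probability (3-state only).
#' @param error_matrix 4x4 error matrix (default identity); see
#'   [estimate_error_matrix()].
#' @param model `"3state"`, `"3state_no_precise"` or `"4state"`.
#' @return Named probability vector over [dsb_categories()], summing to 1.
#' @export
observation_probs <- function(latent, e = 0, error_matrix = NULL,
                              model = "3state") {
  if (is.null(error_matrix)) {
    error_matrix <- diag(4)
    dimnames(error_matrix) <- list(obs = dsb_categories(),
                                   true = dsb_categories())
  }
  validate_error_matrix(error_matrix)
  if (model == "4state") {
    stopifnot(length(latent) == 4L)
    true4 <- as.numeric(latent)
  } else {
    stopifnot(length(latent) == 3L, e >= 0, e <= 1)
    true4 <- c(latent[[1]], latent[[2]],
               (1 - e) * latent[[3]], e * latent[[3]])
  }
  p <- as.numeric(error_matrix %*% true4)
  # guard tiny negative round-off from the solver
  p[p < 0 & p > -1e-12] <- 0
  setNames(p / sum(p), dsb_categories())
}

# multinomial log-pmf; written out so stats::dmultinom can serve as an
# independent oracle in tests
multinom_logpmf <- function(x, prob) {
  keep <- x > 0
  if (any(prob[keep] <= 0)) return(-Inf)
  lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(x[keep] * log(prob[keep]))
}

# Precompiled likelihood evaluator: extracts the count matrix and constant
# multinomial coefficients once, so repeated evaluation inside the optimizer
# costs one ODE integration plus a few matrix operations.
loglik_core <- function(counts, model, error_matrix, steps_per_hour) {
  cats <- dsb_categories()
  X <- as.matrix(as.data.frame(counts)[cats])
  ut <- sort(unique(counts$time_h))
  ti <- match(counts$time_h, ut)
  const <- sum(lgamma(rowSums(X) + 1)) - sum(lgamma(X + 1))
  if (!is.null(error_matrix)) validate_error_matrix(error_matrix)
  emt <- if (is.null(error_matrix)) NULL else t(error_matrix)
  mod_id <- if (model == "4state") 4L else 3L
  pos <- X > 0
  function(rates_vec, e, U, r, d, t_offset) {
    res <- tryCatch(
      integrate_kinetics_cpp(mod_id, rates_vec, U, r, d, t_offset, ut,
                             as.integer(steps_per_hour)),
      error = function(err) NULL)
    if (is.null(res)) return(-Inf)
    S <- res$states
    T4 <- if (mod_id == 4L) S
          else cbind(S[, 1L], S[, 2L], (1 - e) * S[, 3L], e * S[, 3L])
    P <- if (is.null(emt)) T4 else T4 %*% emt
    P[P < 0] <- 0
    P <- P / rowSums(P)
    Pn <- P[ti, , drop = FALSE]
    if (any(Pn[pos] <= 0)) return(-Inf)
    ll <- const + sum(X[pos] * log(Pn[pos]))
    if (is.nan(ll)) -Inf else ll
  }
}

#' Exact multinomial log-likelihood of a category-count time course
#'
#' Each sample's counts over the four observation categories are multinomial
#' with probabilities given by the model trajectory at the sample's time,
#' passed through the observation model. Samples (time-point x replicate) are
#' independent.
#'
#' @param counts `category_counts` data.frame of experimental samples.
#' @param model `"3state"`, `"3state_no_precise"` or `"4state"`.
#' @param rates A [rates3()] or [rates4()] object.
#' @param ip An [induction_params()] object.
#' @param error_matrix Optional 4x4 error matrix.
#' @param steps_per_hour Integration resolution (default 50; the likelihood
#'   needs state values only at the sampled times).
#' @return Log-likelihood (may be `-Inf` when a zero-probability category has
#'   a nonzero count).
#' @export
loglik_counts <- function(counts, model, rates, ip, error_matrix = NULL,
                          steps_per_hour = 50L) {
  stopifnot(nrow(counts) > 0L)
  core <- loglik_core(counts, model, error_matrix, steps_per_hour)
  core(rates_vector(rates), e = if (model == "4state") 0 else rates$e,
       U = ip$U, r = ip$r, d = ip$d, t_offset = ip$t_offset)
}
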