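# Synthetic data generation: multinomial category-count time courses drawn
# from an integrated kinetic model, and synthetic consensus reads with
# planted footprints for exercising the classifier.

# deterministic substream seed for one (time index, replicate)
substream_seed <- function(seed, time_index, replicate) {
  as.integer((seed * 1009 + time_index * 101 + replicate * 7919) %% 2147483647)
}

#' Simulate a category-count time course from a kinetic model
#'
#' Integrates the model, maps the latent state to observation-category
#' probabilities (including the processed-DSB observation probability `e`
#' and the error matrix), and draws one multinomial sample of size
#' `n_molecules` per (time point, replicate). Each sample uses a substream
#' seed derived deterministically from `(seed, time, replicate)`, so draws
#' are reproducible regardless of evaluation order.
#'
#' @param model `"3state"` or `"4state"`.
#' @param rates A [rates3()] or [rates4()] object.
#' @param ip An [induction_params()] object.
#' @param times Sampling times in hours (sorted, nonempty).
#' @param n_molecules Molecules per sample (> 0).
#' @param replicates Replicates per time point (default 2).
#' @param error_matrix Optional 4x4 error matrix (identity when `NULL`).
#' @param seed Integer seed.
#' @param steps_per_hour Integration resolution (default 50).
#' @return List with `counts` (a `category_counts` data.frame) and `truth`
#'   (noiseless latent proportions and observation probabilities per time).
#' @export
simulate_counts <- function(model = c("3state", "4state"), rates, ip, times,
                            n_molecules, replicates = 2L, error_matrix = NULL,
                            seed = 1L, steps_per_hour = 50L) {
  model <- match.arg(model)
  stopifnot(length(times) >= 1L, !is.unsorted(times), n_molecules > 0)
  traj <- integrate_model(model, rates, ip, times = times,
                          steps_per_hour = steps_per_hour)
  nst <- state_names(model)
  cats <- dsb_categories()
  probs <- t(vapply(seq_along(times), function(i) {
    observation_probs(as.numeric(traj[i, nst]),
                      e = if (model == "4state") 0 else rates$e,
                      error_matrix = error_matrix, model = model)
  }, numeric(4)))
  rows <- list()
  for (i in seq_along(times)) {
    for (rep in seq_len(replicates)) {
      set.seed(substream_seed(seed, i, rep))
      x <- as.numeric(rmultinom(1L, n_molecules, probs[i, ]))
      cc <- data.frame(
        sample_id = sprintf("sim_t%g_r%d", times[i], rep),
        time_h = times[i], replicate = rep, is_control = FALSE,
        intact = x[1], indel = x[2], dsb_direct = x[3], dsb_processed = x[4],
        n_na = 0L, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- cc
    }
  }
  counts <- do.call(rbind, rows)
  class(counts) <- c("category_counts", "data.frame")
  truth <- cbind(traj,
                 setNames(as.data.frame(probs), paste0("p_", cats)))
  list(counts = counts, truth = truth)
}

parse_footprint_spec <- function(spec, window) {
  if (spec == "WT") return(list(kind = "WT"))
  if (grepl("^ins:", spec)) {
    body <- sub("^ins:", "", spec)
    parts <- strsplit(body, "@", fixed = TRUE)[[1]]
    pos <- if (length(parts) > 1L) as.integer(parts[2]) else 50L
    return(list(kind = "ins", bases = toupper(parts[1]), pos = pos))
  }
  if (grepl("^del:", spec)) {
    body <- sub("^del:", "", spec)
    parts <- strsplit(body, "@", fixed = TRUE)[[1]]
    len <- as.integer(parts[1])
    pos <- if (length(parts) > 1L) as.integer(parts[2])
           else 50L - len %/% 2L
    return(list(kind = "del", len = len, pos = pos))
  }
  if (grepl("^dsb@", spec)) {
    return(list(kind = "dsb", pos = as.integer(sub("^dsb@", "", spec))))
  }
  if (grepl("^dsbext@", spec)) {
    return(list(kind = "dsbext", pos = as.integer(sub("^dsbext@", "", spec))))
  }
  stop("unrecognized footprint spec '", spec, "'")
}

#' Generate synthetic consensus reads with planted footprints
#'
#' Builds reads from the target amplicon according to a composition over
#' footprint specs, recording each read's intended truth. Specs (positions
#' are 0-based reference-window coordinates; the expected cut is at 50):
#' `"WT"`; `"ins:SEQ"` or `"ins:SEQ@P"` (insertion of `SEQ` at boundary `P`,
#' default the cut); `"del:L@P"` (deletion of `L` bases starting at `P`;
#' default start centers the deletion on the cut); `"dsb@P"` (molecule
#' truncated at boundary `P`); `"dsbext@P"` (`P > 50`: truncated at the cut
#' and extended to boundary `P` with non-reference filler bases). Read counts
#' follow the composition fractions
#' deterministically (largest-remainder rounding); `N` noise is applied
#' uniformly per base.
#'
#' @param target A [target_spec()].
#' @param composition Named numeric vector of fractions summing to 1; names
#'   are footprint specs.
#' @param n_reads Total number of reads.
#' @param n_rate Per-base probability of replacing a base with `N`.
#' @param seed Integer seed (used only for `N` noise placement).
#' @return List with `reads` (named character vector) and `truth`
#'   (`data.frame`: read_id, spec, expected state and category, expected
#'   footprint name for indels).
#' @export
generate_reads <- function(target, composition, n_reads, n_rate = 0,
                           seed = 1L) {
  stopifnot(inherits(target, "target_spec"),
            abs(sum(composition) - 1) < 1e-8, n_reads > 0)
  ct <- canonicalize_target(target)
  window <- extract_reference_window(ct)
  off <- ct$cut_index - 50L  # 0-based amplicon offset of the window start
  amp <- ct$amplicon

  # largest-remainder allocation so planted composition is exact
  alloc <- diff(c(0L, round(cumsum(composition) * n_reads)))
  specs <- rep(names(composition), alloc)

  set.seed(seed)
  reads <- character(length(specs))
  truth <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- parse_footprint_spec(specs[i], window)
    if (sp$kind == "WT") {
      seq <- amp
      tr <- list(state = "INTACT", category = "intact", footprint = "")
    } else if (sp$kind == "ins") {
      if (sp$pos < 0L || sp$pos > 100L) stop("insertion outside the window")
      at <- off + sp$pos
      seq <- paste0(substr(amp, 1L, at), sp$bases,
                    substr(amp, at + 1L, nchar(amp)))
      tr <- list(state = "NHEJ", category = "indel",
                 footprint = paste0("+", sp$bases))
    } else if (sp$kind == "del") {
      if (sp$pos < 0L || sp$pos + sp$len > 100L)
        stop("deletion outside the window")
      at <- off + sp$pos
      deleted <- substr(amp, at + 1L, at + sp$len)
      seq <- paste0(substr(amp, 1L, at),
                    substr(amp, at + sp$len + 1L, nchar(amp)))
      tr <- list(state = "NHEJ", category = "indel",
                 footprint = paste0("-", deleted))
    } else if (sp$kind == "dsb") {
      if (sp$pos < 12L || sp$pos > 100L)
        stop("DSB end outside the window")
      seq <- substr(amp, 1L, off + sp$pos)
      cat <- if ((sp$pos - 50L) %in% ct$direct_positions) "dsb_direct"
             else "dsb_processed"
      tr <- list(state = "DSB", category = cat, footprint = "")
    } else {  # dsbext: end past the cut with non-reference filler bases
      if (sp$pos <= 50L || sp$pos > 100L)
        stop("extended DSB end outside the window")
      ref_tail <- strsplit(substr(amp, off + 51L, off + sp$pos), "",
                           fixed = TRUE)[[1]]
      filler <- chartr("ACGT", "TGCA", paste(ref_tail, collapse = ""))
      seq <- paste0(substr(amp, 1L, off + 50L), filler)
      tr <- list(state = "DSB", category = "dsb_processed", footprint = "")
    }
    if (n_rate > 0) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      hit <- runif(length(chars)) < n_rate
      chars[hit] <- "N"
      seq <- paste(chars, collapse = "")
    }
    reads[i] <- seq
    truth[[i]] <- data.frame(
      read_id = sprintf("sim%06d", i), spec = specs[i], state = tr$state,
      category = tr$category, footprint = tr$footprint,
      stringsAsFactors = FALSE)
  }
  names(reads) <- sprintf("sim%06d", seq_along(reads))
  # reads for flipped targets are emitted in sequencing orientation
  if (target$pam_side == "left") reads <- setNames(revcomp(reads), names(reads))
  list(reads = reads, truth = do.call(rbind, truth))
}
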