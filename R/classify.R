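# State calling, footprint characterization and DSB-end typing for
# single-molecule consensus reads.
#
# All coordinates are 0-based half-open; "position 50" in the reference
# window means the molecule's captured end abuts the boundary between
# offsets 49 and 50.

# Ungapped sliding-window match of a 12 bp indicator against a read.
# Score: +1 match, -1 mismatch ('N' counts as mismatch). Ties at the maximal
# score resolve to the leftmost hit for the left indicator and the rightmost
# for the right indicator, maximizing the spanned window deterministically.
scan_indicator <- function(read_chars, ind_chars, side) {
  L <- length(read_chars); k <- length(ind_chars)
  if (L < k) return(NULL)
  no <- L - k + 1L
  sc <- rep.int(0L, no)
  for (j in seq_len(k)) {
    sc <- sc + ifelse(read_chars[j:(j + no - 1L)] == ind_chars[j], 1L, -1L)
  }
  best <- max(sc)
  pos <- which(sc == best)
  pos <- if (side == "left") pos[1L] else pos[length(pos)]
  list(score = best, start = pos, end = pos + k - 1L)  # 1-based inclusive
}

# Gapped fallback through Biostrings local alignment (match +1, mismatch -1,
# each gapped position -2), used only when the ungapped scan misses the
# threshold; rescues indicators carrying a single indel.
align_indicator <- function(read, indicator) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(indicator),
    subject = Biostrings::DNAString(read),
    type = "local", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = 2)
  list(score = as.numeric(Biostrings::score(pa)),
       start = BiocGenerics::start(Biostrings::subject(pa)),
       end = BiocGenerics::end(Biostrings::subject(pa)))
}

find_indicator <- function(read, read_chars, indicator, min_score, side) {
  hit <- scan_indicator(read_chars, strsplit(indicator, "", fixed = TRUE)[[1]],
                        side)
  if (!is.null(hit) && hit$score >= min_score) return(hit)
  if (nchar(read) >= 4L) {
    hit2 <- align_indicator(read, indicator)
    if (hit2$score >= min_score) return(hit2)
  }
  NULL
}

# TRUE when the read terminates in the primer (or its reverse complement),
# allowing one mismatch: a PCR-contamination artifact rather than a captured
# restriction/DSB end.
ends_in_primer <- function(read_chars, primer) {
  np <- nchar(primer); L <- length(read_chars)
  if (L < np) return(FALSE)
  tail_chars <- read_chars[(L - np + 1L):L]
  for (p in c(primer, revcomp(primer))) {
    mism <- sum(tail_chars != strsplit(p, "", fixed = TRUE)[[1]])
    if (mism <= 1L) return(TRUE)
  }
  FALSE
}

#' Call the state of a consensus read
#'
#' A read is `INTACT` when both the left and right 12 bp indicators of the
#' reference window align with score at least `min_indicator_score` (ungapped
#' +1/-1 scoring, so the default 10 admits one mismatch), `DSB` when only the
#' left indicator does, and `NA` otherwise. Reads with more than 4 `N`s, or
#' ending in the target primer sequence (PCR contamination), are `NA` as well.
#'
#' @param read Read sequence (character).
#' @param window A [extract_reference_window()] result.
#' @param primer Target-specific primer sequence used for the contamination
#'   filter (`NULL` to skip).
#' @param min_indicator_score Minimum indicator alignment score (default 10,
#'   i.e. 10 of 12 bases).
#' @return A list with `state` (`"INTACT"`, `"DSB"` or `"NA"`) and
#'   `seq_window`: for `INTACT`, the read substring spanning both indicator
#'   matches inclusive; for `DSB`, from the left indicator match to the read
#'   end; otherwise `NA`.
#' @export
classify_state <- function(read, window, primer = NULL,
                           min_indicator_score = 10) {
  stopifnot(nzchar(read))
  read <- toupper(read)
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  if (sum(chars == "N") > 4L)
    return(list(state = "NA", seq_window = NA_character_))
  if (!is.null(primer) && nzchar(primer) && ends_in_primer(chars, toupper(primer)))
    return(list(state = "NA", seq_window = NA_character_))
  left <- find_indicator(read, chars, window$left_indicator,
                         min_indicator_score, "left")
  if (is.null(left)) return(list(state = "NA", seq_window = NA_character_))
  right <- find_indicator(read, chars, window$right_indicator,
                          min_indicator_score, "right")
  if (!is.null(right) && right$start > left$end) {
    return(list(state = "INTACT",
                seq_window = substr(read, left$start, right$end)))
  }
  list(state = "DSB", seq_window = substr(read, left$start, nchar(read)))
}

# Global (Needleman-Wunsch, affine gaps) alignment of a sequence window to
# the reference, returning the two gapped strings.
align_window <- function(seq_window, wt_ref) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq_window),
    subject = Biostrings::DNAString(wt_ref),
    type = "global", substitutionMatrix = submat,
    gapOpening = 2, gapExtension = 1)
  list(pattern = as.character(Biostrings::alignedPattern(pa)),
       subject = as.character(Biostrings::alignedSubject(pa)))
}

# Shift an indel event left while the base preceding it equals its last base
# (standard left normalization); makes microhomology detection independent of
# the aligner's gap placement.
left_normalize <- function(ref_chars, pos, bases) {
  # pos: 0-based ref offset at which the event starts
  b <- strsplit(bases, "", fixed = TRUE)[[1]]
  while (pos > 0L && ref_chars[pos] == b[length(b)]) {
    b <- c(ref_chars[pos], b[-length(b)])
    pos <- pos - 1L
  }
  list(pos = pos, bases = paste(b, collapse = ""))
}

#' Characterize the repair footprint of an intact read
#'
#' The extracted sequence window of an `INTACT` read is globally aligned to
#' the 100 bp reference. No gap on either side gives a `WT` call; a gap opened
#' in the reference is an `Insertion` (name `"+"` plus the inserted bases); a
#' gap opened in the read is a `Deletion` (name `"-"` plus the deleted bases).
#' Deletions flanked by at least `mh_min_len` bp of repeated sequence are
#' annotated `MH_Del` with the microhomology reported. Indel positions are
#' left-normalized before naming. Reads with both an insertion and a deletion
#' are named by concatenating the events in reference order and typed by the
#' net length change (`Insertion` when >= 0).
#'
#' @param seq_window Sequence window from [classify_state()] (INTACT reads).
#' @param window A [extract_reference_window()] result.
#' @param mh_min_len Minimum flanking-repeat length for `MH_Del` (default 2).
#' @return List with `footprint_type` (`"WT"`, `"Insertion"`, `"Deletion"`,
#'   `"MH_Del"`), `footprint_name` and `microhomology` (empty strings when
#'   not applicable).
#' @export
characterize_indel <- function(seq_window, window, mh_min_len = 2L) {
  al <- align_window(seq_window, window$wt_ref)
  p <- strsplit(al$pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(al$subject, "", fixed = TRUE)[[1]]
  ref_chars <- strsplit(window$wt_ref, "", fixed = TRUE)[[1]]

  # walk the alignment collecting gap runs; ref_pos is 0-based in wt_ref
  events <- list()
  i <- 1L; ref_pos <- 0L
  while (i <= length(p)) {
    if (s[i] == "-") {         # gap in reference -> inserted bases in read
      j <- i
      while (j <= length(p) && s[j] == "-") j <- j + 1L
      events[[length(events) + 1L]] <-
        list(kind = "ins", pos = ref_pos,
             bases = paste(p[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (p[i] == "-") {  # gap in read -> deleted reference bases
      j <- i
      while (j <= length(p) && p[j] == "-") j <- j + 1L
      events[[length(events) + 1L]] <-
        list(kind = "del", pos = ref_pos,
             bases = paste(s[i:(j - 1L)], collapse = ""))
      ref_pos <- ref_pos + (j - i)
      i <- j
    } else {
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    }
  }

  if (length(events) == 0L)
    return(list(footprint_type = "WT", footprint_name = "",
                microhomology = ""))

  events <- lapply(events, function(ev) {
    norm <- left_normalize(ref_chars, ev$pos, ev$bases)
    ev$pos <- norm$pos; ev$bases <- norm$bases
    ev
  })
  name <- paste(vapply(events, function(ev) {
    paste0(if (ev$kind == "ins") "+" else "-", ev$bases)
  }, character(1)), collapse = "")

  kinds <- vapply(events, `[[`, character(1), "kind")
  if (all(kinds == "ins")) {
    return(list(footprint_type = "Insertion", footprint_name = name,
                microhomology = ""))
  }
  if (all(kinds == "del") && length(events) == 1L) {
    ev <- events[[1L]]
    mh <- flanking_microhomology(ref_chars, ev$pos, ev$bases)
    if (nchar(mh) >= mh_min_len)
      return(list(footprint_type = "MH_Del", footprint_name = name,
                  microhomology = mh))
    return(list(footprint_type = "Deletion", footprint_name = name,
                microhomology = ""))
  }
  if (all(kinds == "del"))
    return(list(footprint_type = "Deletion", footprint_name = name,
                microhomology = ""))
  # mixed insertion + deletion: type by net length change
  net <- sum(vapply(events, function(ev)
    (if (ev$kind == "ins") 1L else -1L) * nchar(ev$bases), integer(1)))
  list(footprint_type = if (net >= 0L) "Insertion" else "Deletion",
       footprint_name = name, microhomology = "")
}

# Longest repeat shared between the deleted bases and the sequence flanking
# the deletion (checked on both sides; after left normalization the repeat
# surfaces on the right flank).
flanking_microhomology <- function(ref_chars, pos, deleted) {
  d <- strsplit(deleted, "", fixed = TRUE)[[1]]
  L <- length(d)
  right <- ref_chars[seq.int(pos + L + 1L, length.out = min(L, length(ref_chars) - pos - L))]
  k_right <- 0L
  while (k_right < length(right) && k_right < L &&
         d[k_right + 1L] == right[k_right + 1L]) k_right <- k_right + 1L
  left <- if (pos > 0L) ref_chars[seq_len(pos)] else character(0)
  k_left <- 0L
  while (k_left < length(left) && k_left < L &&
         d[L - k_left] == left[length(left) - k_left]) k_left <- k_left + 1L
  if (k_right >= k_left && k_right > 0L)
    paste(d[seq_len(k_right)], collapse = "")
  else if (k_left > 0L)
    paste(d[(L - k_left + 1L):L], collapse = "")
  else ""
}

#' Type a captured DSB end by its position
#'
#' Trailing `N`s (adaptor fill) are trimmed, the remaining window is locally
#' aligned to the reference, and the end position is the reference coordinate
#' where the captured molecule terminates (aligned end plus any unaligned
#' trailing bases). Ends at `50 + delta` for `delta` in the target's
#' `direct_positions` are `direct`; ends short of every direct position are
#' `guide` (guide-side resection/deletion intermediates); longer ends are
#' `pam` when the extra bases match the reference past the cut and `extended`
#' when they do not (filler DNA).
#'
#' @param seq_window DSB sequence window from [classify_state()].
#' @param window A [extract_reference_window()] result.
#' @param target The [target_spec()] (supplies `direct_positions`).
#' @return List with `dsb_end_pos` (0-based reference boundary coordinate)
#'   and `dsb_type` (`"direct"`, `"guide"`, `"pam"` or `"extended"`), or
#'   `dsb_type = "NA"` for windows shorter than the left indicator.
#' @export
classify_dsb <- function(seq_window, window, target) {
  sw <- sub("N+$", "", toupper(seq_window))
  if (nchar(sw) < nchar(window$left_indicator))
    return(list(dsb_end_pos = NA_integer_, dsb_type = "NA"))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(sw),
    subject = Biostrings::DNAString(window$wt_ref),
    type = "local", substitutionMatrix = submat,
    gapOpening = 2, gapExtension = 1)
  ref_end <- BiocGenerics::end(Biostrings::subject(pa))      # 1-based = boundary
  pat_end <- BiocGenerics::end(Biostrings::pattern(pa))
  extra <- nchar(sw) - pat_end
  end_pos <- as.integer(ref_end + extra)
  direct_set <- window$cut_pos + target$direct_positions
  type <-
    if (end_pos %in% direct_set) "direct"
    else if (end_pos < min(direct_set)) "guide"
    else if (extra == 0L) "pam"
    else "extended"
  list(dsb_end_pos = end_pos, dsb_type = type)
}

#' Classify a set of consensus reads against one target
#'
#' Runs the full per-molecule pipeline: state calling ([classify_state()]),
#' footprint characterization of intact reads ([characterize_indel()], which
#' promotes non-WT footprints to state `NHEJ`), and positional typing of DSB
#' ends ([classify_dsb()]). Targets whose PAM lies left of the cut are
#' reverse-complemented internally (reads included) so classification always
#' runs with the captured side on the left.
#'
#' @param reads Named character vector or `Biostrings::DNAStringSet` of
#'   consensus read sequences (names become `read_id`).
#' @param target A [target_spec()].
#' @param min_indicator_score Indicator score threshold (default 10/12).
#' @param mh_min_len Minimum microhomology length; defaults to the target's.
#' @return A `data.frame` with one row per read: `read_id`, `state`
#'   (`INTACT`, `NHEJ`, `DSB`, `NA`), `footprint_type`, `footprint_name`,
#'   `microhomology`, `dsb_end_pos`, `dsb_type`.
#' @export
classify_molecules <- function(reads, target, min_indicator_score = 10,
                               mh_min_len = NULL) {
  stopifnot(inherits(target, "target_spec"))
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  mh_min_len <- mh_min_len %||% target$mh_min_len
  flipped <- target$pam_side == "left"
  target <- canonicalize_target(target)
  if (flipped) reads <- setNames(revcomp(reads), names(reads))
  window <- extract_reference_window(target)

  out <- data.frame(
    read_id = names(reads), state = "NA", footprint_type = "none",
    footprint_name = "", microhomology = "", dsb_end_pos = NA_integer_,
    dsb_type = "none", stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    st <- classify_state(reads[[i]], window, target$primer,
                         min_indicator_score)
    if (st$state == "INTACT") {
      fp <- characterize_indel(st$seq_window, window, mh_min_len)
      out$footprint_type[i] <- fp$footprint_type
      out$footprint_name[i] <- fp$footprint_name
      out$microhomology[i] <- fp$microhomology
      out$state[i] <- if (fp$footprint_type == "WT") "INTACT" else "NHEJ"
    } else if (st$state == "DSB") {
      db <- classify_dsb(st$seq_window, window, target)
      if (db$dsb_type == "NA") {
        out$state[i] <- "NA"
      } else {
        out$state[i] <- "DSB"
        out$dsb_end_pos[i] <- db$dsb_end_pos
        out$dsb_type[i] <- db$dsb_type
      }
    }
  }
  out
}

#' Aggregate classified molecules into category counts
#'
#' Pools guide-side, PAM-side and extended DSBs into `dsb_processed`; direct
#' DSBs count as `dsb_direct`; `NA` molecules are excluded from the totals and
#' reported in `n_na`.
#'
#' @param molecules Output of [classify_molecules()] (one sample).
#' @param sample_id,time_h,replicate,is_control Sample metadata.
#' @return One-row `data.frame` of class `category_counts` with columns
#'   `sample_id`, `time_h`, `replicate`, `is_control`, `intact`, `indel`,
#'   `dsb_direct`, `dsb_processed`, `n_na`.
#' @export
aggregate_counts <- function(molecules, sample_id = "sample", time_h = 0,
                             replicate = 1L, is_control = FALSE) {
  cc <- data.frame(
    sample_id = sample_id, time_h = as.numeric(time_h),
    replicate = as.integer(replicate), is_control = isTRUE(is_control),
    intact = sum(molecules$state == "INTACT"),
    indel = sum(molecules$state == "NHEJ"),
    dsb_direct = sum(molecules$state == "DSB" &
                       molecules$dsb_type == "direct"),
    dsb_processed = sum(molecules$state == "DSB" &
                          molecules$dsb_type %in% c("guide", "pam", "extended")),
    n_na = sum(molecules$state == "NA"),
    stringsAsFactors = FALSE)
  class(cc) <- c("category_counts", "data.frame")
  cc
}
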