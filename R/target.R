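#' Describe a CRISPR target amplicon
#'
#' A target specification records the geometry of one amplicon: the guide
#' (sgRNA) protospacer, the target-specific primer used for capture, the full
#' amplicon sequence, and the expected blunt-cut position. SpCas9 cleaves 3 bp
#' upstream of the PAM; when `cut_index` is not supplied it is derived by
#' locating the protospacer on either strand of the amplicon and applying that
#' rule. For targets where the nuclease produces two adjacent blunt ends
#' (dual cleavage, e.g. both the -3 and -4 positions from the PAM),
#' `direct_positions` lists the expected end offsets relative to the cut.
#'
#' @param name Target name (unique within a sample sheet).
#' @param sgrna Protospacer sequence (DNA, typically 20 nt, no PAM).
#' @param primer Target-specific primer sequence used in capture; reads ending
#'   in this sequence are discarded as PCR contamination.
#' @param amplicon Full amplicon sequence containing the protospacer.
#' @param cut_index Integer, 0-based offset of the expected blunt cut within
#'   `amplicon` (the cut falls between `cut_index - 1` and `cut_index`).
#'   Derived from `sgrna` when `NULL`.
#' @param pam_side `"right"` or `"left"`: which side of the cut the PAM lies
#'   on in the amplicon's written orientation. Derived when `cut_index` is.
#' @param direct_positions Integer offsets (relative to the cut) at which a
#'   captured end counts as a direct, nuclease-made DSB. Default `0`; use
#'   `c(0, -1)` for dual-cleavage targets.
#' @param mh_min_len Minimum flanking-repeat length (bp) for a deletion to be
#'   annotated as microhomology-associated. Default 2.
#' @return An object of class `target_spec`.
#' @examples
#' amp <- paste(rep("ACGT", 60), collapse = "")
#' # explicit cut site
#' ts <- target_spec("toy", sgrna = substr(amp, 81, 100),
#'                   primer = substr(amp, 1, 20), amplicon = amp,
#'                   cut_index = 97)
#' @export
target_spec <- function(name, sgrna, primer, amplicon, cut_index = NULL,
                        pam_side = NULL, direct_positions = 0L,
                        mh_min_len = 2L) {
  stopifnot(is.character(name), nzchar(name))
  sgrna <- toupper(sgrna); primer <- toupper(primer); amplicon <- toupper(amplicon)
  if (!grepl("^[ACGTN]+$", amplicon))
    stop("amplicon for target '", name, "' contains non-DNA characters")
  if (is.null(cut_index)) {
    loc <- locate_cut_site(sgrna, amplicon)
    if (is.null(loc))
      stop("sgRNA of target '", name,
           "' not found in amplicon on either strand")
    cut_index <- loc$cut_index
    pam_side <- loc$pam_side
  } else {
    pam_side <- pam_side %||% "right"
    # the guide must still be present on one strand
    if (!grepl(sgrna, amplicon, fixed = TRUE) &&
        !grepl(revcomp(sgrna), amplicon, fixed = TRUE))
      stop("sgRNA of target '", name,
           "' not found in amplicon on either strand")
  }
  pam_side <- match.arg(pam_side, c("right", "left"))
  direct_positions <- sort(unique(as.integer(direct_positions)))
  if (length(direct_positions) == 0L)
    stop("direct_positions must be nonempty for target '", name, "'")
  mh_min_len <- as.integer(mh_min_len)
  if (mh_min_len < 2L) stop("mh_min_len must be >= 2")
  structure(
    list(name = name, sgrna = sgrna, primer = primer, amplicon = amplicon,
         cut_index = as.integer(cut_index), pam_side = pam_side,
         direct_positions = direct_positions, mh_min_len = mh_min_len),
    class = "target_spec")
}

# Brute-force localization of the protospacer; the blunt cut sits 3 bp
# 5' of the PAM (i.e. between protospacer positions 17|18 for a 20-mer).
locate_cut_site <- function(sgrna, amplicon) {
  fwd <- regexpr(sgrna, amplicon, fixed = TRUE)
  if (fwd > 0) {
    s <- as.integer(fwd) - 1L  # 0-based start
    return(list(cut_index = s + nchar(sgrna) - 3L, pam_side = "right"))
  }
  rev <- regexpr(revcomp(sgrna), amplicon, fixed = TRUE)
  if (rev > 0) {
    s <- as.integer(rev) - 1L
    return(list(cut_index = s + 3L, pam_side = "left"))
  }
  NULL
}

# Orient a target so the captured (primed) side is to the left of the cut and
# the PAM to the right; classification always runs in this frame. Reads for a
# flipped target must be reverse-complemented with `revcomp()` as well.
canonicalize_target <- function(target) {
  if (target$pam_side == "right") return(target)
  n <- nchar(target$amplicon)
  target$amplicon <- revcomp(target$amplicon)
  target$sgrna <- revcomp(target$sgrna)
  target$primer <- revcomp(target$primer)
  target$cut_index <- n - target$cut_index
  target$pam_side <- "right"
  target
}

#' @export
print.target_spec <- function(x, ...) {
  cat("<target_spec>", x$name, "\n")
  cat("  amplicon:", nchar(x$amplicon), "bp, cut at", x$cut_index,
      "(PAM", x$pam_side, ")\n")
  cat("  direct end offsets:", paste(x$direct_positions, collapse = ", "),
      " mh_min_len:", x$mh_min_len, "\n")
  invisible(x)
}

#' Extract the 100 bp reference window around the cut
#'
#' The classifier works inside a 100 bp wild-type reference window (`wt_ref`)
#' centred on the expected blunt cut: 50 bp on each side, so the expected DSB
#' end sits at position 50 (0-based boundary coordinate). The outermost 12 bp
#' on each side serve as left/right indicator sequences for state calling.
#'
#' @param target A [target_spec()].
#' @return An object of class `reference_window` with fields `wt_ref` (100 bp),
#'   `left_indicator` (`wt_ref[0:12)`), `right_indicator` (`wt_ref[88:100)`)
#'   and `cut_pos = 50`.
#' @export
extract_reference_window <- function(target) {
  stopifnot(inherits(target, "target_spec"))
  target <- canonicalize_target(target)
  n <- nchar(target$amplicon)
  ci <- target$cut_index
  if (ci < 50L || ci > n - 50L)
    stop("cut site of target '", target$name,
         "' is closer than 50 bp to an amplicon end (cut_index=", ci,
         ", amplicon length=", n, ")")
  wt_ref <- substr(target$amplicon, ci - 50L + 1L, ci + 50L)
  structure(
    list(wt_ref = wt_ref,
         left_indicator = substr(wt_ref, 1L, 12L),
         right_indicator = substr(wt_ref, 89L, 100L),
         cut_pos = 50L),
    class = "reference_window")
}
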