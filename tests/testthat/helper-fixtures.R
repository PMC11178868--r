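# Shared fixtures: a synthetic CRISPR target whose reference window embeds a
# microhomology-bearing motif around the cut, plus small oracles.
#
# Amplicon layout (0-based): 103 random bp, then "A", then "TGTTGCCTTGTT",
# then random bp starting with "A". The blunt cut sits at amplicon offset
# 110, i.e. window coordinate 50, which falls inside the TGTTGCCT motif.
# Deleting window offsets [44, 52) removes "TGTTGCCT" and leaves the "TGTT"
# flank: a 4 bp microhomology-associated deletion. The preceding "A" and the
# "A" after the motif pin left-normalization and the microhomology length.

make_test_amplicon <- function(seed = 7202) {
  set.seed(seed)
  left <- paste(sample(c("A", "C", "G", "T"), 103, TRUE), collapse = "")
  right <- paste0("A", paste(sample(c("A", "C", "G", "T"), 103, TRUE),
                             collapse = ""))
  paste0(left, "A", "TGTTGCCTTGTT", right)
}

make_test_target <- function(direct_positions = 0L, mh_min_len = 2L,
                             seed = 7202) {
  amp <- make_test_amplicon(seed)
  ci <- 110L
  sgrna <- substr(amp, ci - 17L + 1L, ci + 3L)  # protospacer, cut at -3
  target_spec("synthetic_psy1_like", sgrna = sgrna,
              primer = substr(amp, 1L, 20L), amplicon = amp,
              cut_index = ci, direct_positions = direct_positions,
              mh_min_len = mh_min_len)
}

# reverse-complement a character DNA string (independent of the package's
# internal helper)
rc <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# rewrite a target with the amplicon on the opposite strand; the guide
# sequence itself is strand-specific and stays as-is (it now matches the
# reverse complement of the amplicon)
flip_target <- function(target) {
  n <- nchar(target$amplicon)
  target_spec(paste0(target$name, "_flipped"),
              sgrna = target$sgrna, primer = rc(target$primer),
              amplicon = rc(target$amplicon),
              cut_index = n - target$cut_index, pam_side = "left",
              direct_positions = target$direct_positions,
              mh_min_len = target$mh_min_len)
}

# Brute-force check that a reported footprint name is a valid single edit
# transforming wt_ref into seq_window: tries every position exhaustively.
edit_explains_window <- function(wt_ref, footprint_name, seq_window) {
  if (startsWith(footprint_name, "+")) {
    ins <- substring(footprint_name, 2L)
    for (p in 0:nchar(wt_ref)) {
      cand <- paste0(substr(wt_ref, 1, p), ins,
                     substr(wt_ref, p + 1, nchar(wt_ref)))
      if (cand == seq_window) return(TRUE)
    }
    return(FALSE)
  }
  if (startsWith(footprint_name, "-")) {
    del <- substring(footprint_name, 2L)
    L <- nchar(del)
    for (p in 0:(nchar(wt_ref) - L)) {
      if (substr(wt_ref, p + 1, p + L) != del) next
      cand <- paste0(substr(wt_ref, 1, p),
                     substr(wt_ref, p + L + 1, nchar(wt_ref)))
      if (cand == seq_window) return(TRUE)
    }
    return(FALSE)
  }
  FALSE
}

# mutate the i-th (1-based) character of a string
mutate_at <- function(s, i, to) {
  substr(s, i, i) <- to
  s
}

# pick a substitution different from the current base
other_base <- function(b) c(A = "C", C = "G", G = "T", T = "A", N = "A")[[b]]

# quick 3-state simulated dataset for fitting tests
sim_3state_counts <- function(seed, k_cut = 0.02, P = 0.06, E = 0.04,
                              e = 0.1, n = 10000L,
                              times = c(0, 6, 12, 24, 36, 48, 72)) {
  simulate_counts("3state", rates3(k_cut, P, E, e),
                  induction_params(U = 0, r = 1e4, d = 0),
                  times = times, n_molecules = n, replicates = 2L,
                  seed = seed)$counts
}
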