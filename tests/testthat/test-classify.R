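target <- make_test_target()
window <- extract_reference_window(target)
wt <- window$wt_ref

test_that("state calling follows the two-indicator rule", {
  expect_identical(classify_state(wt, window)$state, "INTACT")
  expect_identical(classify_state(substr(wt, 1, 50), window)$state, "DSB")
  # neither indicator present
  expect_identical(classify_state(strrep("A", 80), window)$state, "NA")
})

test_that("indicator threshold admits one mismatch and rejects two", {
  # one mismatch in the left indicator: score 10, still intact
  r1 <- mutate_at(wt, 5, other_base(substr(wt, 5, 5)))
  expect_identical(classify_state(r1, window)$state, "INTACT")
  # two mismatches in the left indicator: score 8 -> left fails -> NA
  r2 <- mutate_at(r1, 9, other_base(substr(wt, 9, 9)))
  expect_identical(classify_state(r2, window)$state, "NA")
  # two mismatches in the right indicator: right fails -> DSB call
  r3 <- mutate_at(mutate_at(wt, 92, other_base(substr(wt, 92, 92))),
                  96, other_base(substr(wt, 96, 96)))
  expect_identical(classify_state(r3, window)$state, "DSB")
  # threshold is configurable: score 8 passes at min_indicator_score 8
  expect_identical(classify_state(r2, window, min_indicator_score = 8)$state,
                   "INTACT")
})

test_that("more than 4 Ns makes a read NA; 4 Ns does not", {
  r5 <- paste0(substr(wt, 1, 40), strrep("N", 5), substr(wt, 46, 100))
  expect_identical(classify_state(r5, window)$state, "NA")
  r4 <- paste0(substr(wt, 1, 40), strrep("N", 4), substr(wt, 45, 100))
  expect_identical(classify_state(r4, window)$state, "INTACT")
})

test_that("reads ending in the primer are filtered as PCR contamination", {
  contaminated <- paste0(wt, target$primer)
  expect_identical(classify_state(contaminated, window, target$primer)$state,
                   "NA")
  # one mismatch in the primer tail is still filtered
  n <- nchar(contaminated)
  cm <- mutate_at(contaminated, n - 3,
                  other_base(substr(contaminated, n - 3, n - 3)))
  expect_identical(classify_state(cm, window, target$primer)$state, "NA")
  # without the primer argument the read is classified normally
  expect_identical(classify_state(contaminated, window)$state, "INTACT")
})

test_that("footprints are named +/- with inserted or deleted bases", {
  expect_identical(
    characterize_indel(wt, window),
    list(footprint_type = "WT", footprint_name = "", microhomology = ""))
  ins <- paste0(substr(wt, 1, 50), "AG", substr(wt, 51, 100))
  fp <- characterize_indel(ins, window)
  expect_identical(fp$footprint_type, "Insertion")
  expect_identical(fp$footprint_name, "+AG")
  del <- paste0(substr(wt, 1, 48), substr(wt, 51, 100))  # remove "GC" at 48,49
  fp <- characterize_indel(del, window)
  expect_identical(fp$footprint_type, "Deletion")
  expect_identical(fp$footprint_name, "-GC")
  expect_identical(fp$microhomology, "")
})

test_that("the TGTTGCCT deletion is annotated with its TGTT microhomology", {
  # window offsets [44, 52) hold TGTTGCCT, flanked on the right by TGTT
  expect_identical(substr(wt, 45, 52), "TGTTGCCT")
  del <- paste0(substr(wt, 1, 44), substr(wt, 53, 100))
  fp <- characterize_indel(del, window)
  expect_identical(fp$footprint_type, "MH_Del")
  expect_identical(fp$footprint_name, "-TGTTGCCT")
  expect_identical(fp$microhomology, "TGTT")
  # raising the threshold above the repeat length demotes it to Deletion
  fp5 <- characterize_indel(del, window, mh_min_len = 5L)
  expect_identical(fp5$footprint_type, "Deletion")
})

test_that("footprint names are valid edits under exhaustive brute force", {
  cases <- list()
  for (p in c(20L, 47L, 50L, 70L)) {
    for (ins in c("T", "AG", "CTA")) {
      cases[[length(cases) + 1L]] <-
        paste0(substr(wt, 1, p), ins, substr(wt, p + 1, 100))
    }
    for (len in c(1L, 3L, 8L)) {
      cases[[length(cases) + 1L]] <-
        paste0(substr(wt, 1, p), substr(wt, p + len + 1, 100))
    }
  }
  for (sw in cases) {
    fp <- characterize_indel(sw, window)
    expect_true(fp$footprint_type %in%
                  c("Insertion", "Deletion", "MH_Del"))
    expect_true(edit_explains_window(wt, fp$footprint_name, sw),
                info = fp$footprint_name)
  }
})

test_that("DSB ends are typed direct/guide/pam/extended by position", {
  direct <- classify_dsb(substr(wt, 1, 50), window, target)
  expect_identical(direct, list(dsb_end_pos = 50L, dsb_type = "direct"))
  guide <- classify_dsb(substr(wt, 1, 47), window, target)
  expect_identical(guide, list(dsb_end_pos = 47L, dsb_type = "guide"))
  pam <- classify_dsb(substr(wt, 1, 54), window, target)
  expect_identical(pam, list(dsb_end_pos = 54L, dsb_type = "pam"))
  # same length but the 4 extra bases contradict the reference
  tail4 <- vapply(strsplit(substr(wt, 51, 54), "")[[1]], other_base,
                  character(1))
  ext <- classify_dsb(paste0(substr(wt, 1, 50),
                             paste(tail4, collapse = "")), window, target)
  expect_identical(ext$dsb_end_pos, 54L)
  expect_identical(ext$dsb_type, "extended")
  # trailing Ns are trimmed before the end is measured
  withN <- classify_dsb(paste0(substr(wt, 1, 50), "NNN"), window, target)
  expect_identical(withN, list(dsb_end_pos = 50L, dsb_type = "direct"))
})

test_that("dual-cleavage targets accept both -3 and -4 ends as direct", {
  dual <- make_test_target(direct_positions = c(0L, -1L))
  at49 <- classify_dsb(substr(wt, 1, 49), window, dual)
  expect_identical(at49$dsb_type, "direct")
  single <- classify_dsb(substr(wt, 1, 49), window, target)
  expect_identical(single$dsb_type, "guide")
  # below both direct positions: guide-side
  expect_identical(classify_dsb(substr(wt, 1, 48), window, dual)$dsb_type,
                   "guide")
})

test_that("classification is idempotent and partitions every read", {
  comp <- c(WT = 0.4, "ins:AG" = 0.15, "del:8@44" = 0.15, "dsb@50" = 0.15,
            "dsb@46" = 0.15)
  gr <- generate_reads(target, comp, n_reads = 40L, n_rate = 0.002, seed = 5)
  m1 <- classify_molecules(gr$reads, target)
  m2 <- classify_molecules(gr$reads, target)
  expect_identical(m1, m2)
  expect_true(all(m1$state %in% c("INTACT", "NHEJ", "DSB", "NA")))
  cc <- aggregate_counts(m1)
  expect_identical(sum(cc$intact, cc$indel, cc$dsb_direct, cc$dsb_processed,
                       cc$n_na), nrow(m1))
})

test_that("opposite-strand targets yield identical category counts", {
  comp <- c(WT = 0.5, "ins:AG" = 0.1, "del:8@44" = 0.2, "dsb@50" = 0.1,
            "dsb@54" = 0.1)
  gr_f <- generate_reads(target, comp, n_reads = 50L, seed = 9)
  cc_f <- aggregate_counts(classify_molecules(gr_f$reads, target))
  fl <- flip_target(target)
  gr_r <- generate_reads(fl, comp, n_reads = 50L, seed = 9)
  cc_r <- aggregate_counts(classify_molecules(gr_r$reads, fl))
  expect_identical(cc_f[dsb_categories()], cc_r[dsb_categories()])
})

test_that("aggregation pools processed DSB subtypes and excludes NA", {
  mols <- data.frame(
    read_id = sprintf("r%d", 1:8),
    state = c("INTACT", "INTACT", "INTACT", "NHEJ", "NHEJ", "DSB", "DSB", "NA"),
    footprint_type = c("WT", "WT", "WT", "Deletion", "Deletion",
                       "none", "none", "none"),
    footprint_name = "", microhomology = "",
    dsb_end_pos = c(NA, NA, NA, NA, NA, 50L, 47L, NA),
    dsb_type = c("none", "none", "none", "none", "none",
                 "direct", "guide", "none"),
    stringsAsFactors = FALSE)
  cc <- aggregate_counts(mols, "s1", 6, 1L, FALSE)
  expect_identical(as.integer(cc[dsb_categories()]), c(3L, 2L, 1L, 1L))
  expect_identical(cc$n_na, 1L)
  # empty input: all-zero counts are valid
  cc0 <- aggregate_counts(mols[0, ])
  expect_true(all(as.integer(cc0[c(dsb_categories(), "n_na")]) == 0L))
})
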