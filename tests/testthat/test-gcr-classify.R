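combined_panel <- function() {
  rbind(as.data.frame(fx_telomeric()), as.data.frame(fx_centromeric()))
}

calls_of <- function(panel, overrides = list()) {
  calls <- stats::setNames(rep(1L, nrow(panel)), panel$probe_id)
  for (nm in names(overrides)) calls[nm] <- overrides[[nm]]
  calls
}

test_that("an all-ones isolate has no events and is CLASSIFIED", {
  panel <- combined_panel()
  calls <- calls_of(panel)
  flags <- stats::setNames(rep("OK", nrow(panel)), panel$probe_id)
  cl <- classify_isolate(calls, flags, panel)
  expect_false(cl$has_chrV_L_deletion)
  expect_length(cl$arm_duplications, 0L)
  expect_length(cl$whole_chromosome_duplications, 0L)
  expect_equal(cl$status, "CLASSIFIED")
})

test_that("deletion plus single-arm duplication is recognized", {
  panel <- combined_panel()
  calls <- calls_of(panel, list("chrV-L_tel" = 0L, "chrXIII-L_tel" = 2L))
  flags <- stats::setNames(rep("OK", nrow(panel)), panel$probe_id)
  cl <- classify_isolate(calls, flags, panel)
  expect_true(cl$has_chrV_L_deletion)
  expect_equal(cl$arm_duplications, "chrXIII-L")
  expect_equal(cl$status, "CLASSIFIED")
})

test_that("simultaneous duplication of all probed loci is a whole-chromosome event", {
  panel <- combined_panel()
  ov <- as.list(stats::setNames(
    rep(2L, sum(panel$chrom %in% c("chrVIII", "chrIX"))),
    panel$probe_id[panel$chrom %in% c("chrVIII", "chrIX")]))
  ov[["chrV-L_tel"]] <- 0L
  cl <- classify_isolate(calls_of(panel, ov),
                         stats::setNames(rep("OK", nrow(panel)),
                                         panel$probe_id), panel)
  expect_setequal(cl$whole_chromosome_duplications, c("chrVIII", "chrIX"))
  expect_length(cl$arm_duplications, 0L)  # arms subsumed by the whole event
})

test_that("ambiguous cells propagate to isolate status", {
  panel <- combined_panel()
  calls <- calls_of(panel, list("chrV-L_tel" = 0L, "chrVII-L_tel" = 2L))
  flags <- stats::setNames(rep("OK", nrow(panel)), panel$probe_id)
  flags["chrVII-L_tel"] <- "AMBIGUOUS"
  cl <- classify_isolate(calls, flags, panel)
  expect_equal(cl$status, "AMBIGUOUS")
  # deletion-only isolates are NO_DUPLICATION
  cl2 <- classify_isolate(calls_of(panel, list("chrV-L_tel" = 0L)),
                          stats::setNames(rep("OK", nrow(panel)),
                                          panel$probe_id), panel)
  expect_equal(cl2$status, "NO_DUPLICATION")
  # a missing assay probe is an error
  bad <- panel[panel$probe_id != "chrV-L_tel", ]
  expect_error(classify_isolate(calls_of(bad),
                                stats::setNames(rep("OK", nrow(bad)),
                                                bad$probe_id), bad),
               "chrV-L")
})

test_that("duplications at fallback probes carry a caveat", {
  panel <- combined_panel()
  calls <- calls_of(panel, list("chrV-L_tel" = 0L, "chrII-L_tel" = 2L))
  cl <- classify_isolate(calls, stats::setNames(rep("OK", nrow(panel)),
                                                panel$probe_id), panel)
  expect_equal(cl$arm_duplications, "chrII-L")
  expect_match(cl$caveats, "fallback")
})

test_that("breakpoints localize to the elements between flanking probes", {
  ann <- fx_annotation()
  aps3 <- fx_arm_panel("chrIII", "R")
  # no duplication
  empty <- localize_breakpoint(
    stats::setNames(rep(1L, nrow(aps3)), aps3$probe_id), aps3, ann)
  expect_true(empty$no_duplication)

  # FS1: duplicated from the second probe on -> delta8/9/10 cluster
  calls <- stats::setNames(c(1L, 2L, 2L), aps3$probe_id)
  bp <- localize_breakpoint(calls, aps3, ann)
  expect_setequal(bp$target_ids, c("YCRWdelta8", "YCRWdelta9", "YCRWdelta10"))
  expect_equal(bp$validity, "SIMPLE")
  expect_equal(bp$geometry, "MONOCENTRIC")

  # FS2: only the most telomeric probe duplicated -> delta11
  bp2 <- localize_breakpoint(stats::setNames(c(1L, 1L, 2L), aps3$probe_id),
                             aps3, ann)
  expect_equal(bp2$target_ids, "YCRWdelta11")

  # chrX-R: the tandem Ty1 pair
  apsX <- fx_arm_panel("chrX", "R")
  bpx <- localize_breakpoint(
    stats::setNames(c(1L, 2L), apsX$probe_id), apsX, ann)
  expect_setequal(bpx$target_ids, c("YJRWTy1-1", "YJRWTy1-2"))
})

test_that("a duplication starting at the most centromeric probe has unknown target", {
  ann <- fx_annotation()
  aps3 <- fx_arm_panel("chrIII", "R")
  bp <- localize_breakpoint(stats::setNames(c(2L, 2L, 2L), aps3$probe_id),
                            aps3, ann)
  expect_length(bp$target_ids, 0L)
  expect_true(is.na(bp$geometry))
})

test_that("non-monotone call profiles are COMPLEX but still summarized", {
  ann <- fx_annotation()
  apsV <- fx_arm_panel("chrV", "R")
  calls <- stats::setNames(rep(1L, nrow(apsV)), apsV$probe_id)
  calls[c(3, 6, 7)] <- 2L  # two separate steps
  bp <- localize_breakpoint(calls, apsV, ann)
  expect_equal(bp$validity, "COMPLEX")
  expect_equal(bp$first_dup_probe, apsV$probe_id[3])
})

test_that("dicentric-intermediate geometry follows target orientation", {
  ann <- fx_annotation()
  apsV <- fx_arm_panel("chrV", "R")
  # duplication bounded by the centromere-oriented YERCdelta14/15/16 cluster
  idx <- which(apsV$anchor_bp > 434000)[1]
  calls <- stats::setNames(rep(1L, nrow(apsV)), apsV$probe_id)
  calls[idx:nrow(apsV)] <- 2L
  bp <- localize_breakpoint(calls, apsV, ann)
  expect_setequal(bp$target_ids, c("YERCdelta14", "YERCdelta15", "YERCdelta16"))
  expect_equal(bp$geometry, "DICENTRIC_INTERMEDIATE")
})

test_that("cohort summaries count mutually exclusive statuses", {
  ann <- fx_annotation()
  truth <- fixture_cohort(ann, "wildtype")
  cl <- classify_truth(truth, ann)
  s <- summarize_cohort(cl)
  expect_equal(s$n, 112L)
  expect_equal(s$n_chrV_L_deletion, 112L)
  expect_equal(s$n_arm_duplication, 106L)
  expect_equal(s$n_no_duplication, 5L)
  expect_equal(s$n_ambiguous, 1L)
  expect_equal(s$n_arm_duplication + s$n_no_duplication + s$n_ambiguous, s$n)
})

test_that("per-arm target percentages sum to 100 within each arm", {
  ann <- fx_annotation()
  truth <- fixture_cohort(ann, "wildtype")
  bps <- c(localize_truth_arm(truth, ann, "chrIII", "R"),
           localize_truth_arm(truth, ann, "chrV", "R"))
  s <- summarize_cohort(classify_truth(truth, ann), bps)
  tt <- s$target_table
  sums <- tapply(tt$percent, tt$arm, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("an empty cohort summarizes to zero counts", {
  s <- summarize_cohort(data.frame())
  expect_equal(s$n, 0L)
  expect_equal(s$n_arm_duplication, 0L)
})
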