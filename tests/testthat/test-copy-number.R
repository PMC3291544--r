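# handcrafted 3-probe panel on one arm for normalization arithmetic
toy_panel <- function() {
  el <- data.frame(id = "d1", chrom = "chrA", start = 60000L, end = 60334L,
                   class = "SOLO_DELTA", orientation = "TELOMERE")
  design_probe_set(toy_annotation(el), "ARM_SPECIFIC", chrom = "chrA",
                   arm = "R")
}

peaks_from_areas <- function(areas_by_sample, panel, controls = character(0)) {
  do.call(rbind, lapply(names(areas_by_sample), function(sid) {
    data.frame(sample_id = sid, size_bp = panel$product_length_bp,
               height = areas_by_sample[[sid]],
               area = areas_by_sample[[sid]],
               is_control = sid %in% controls, stringsAsFactors = FALSE)
  }))
}

test_that("within-sample normalization matches hand arithmetic", {
  panel <- toy_panel()
  expect_equal(nrow(panel), 2L)
  # extend to 3 probes for the (10, 10, 20) example
  p3 <- assign_product_lengths(rbind(as.data.frame(panel),
                                     transform(as.data.frame(panel)[2, ],
                                               probe_id = "extra")))
  v <- normalize_within_sample(stats::setNames(c(10, 10, 20), p3$probe_id),
                               p3, "GLOBAL_SUM")
  expect_equal(unname(v), c(0.25, 0.25, 0.5))
  # scale invariance
  v2 <- normalize_within_sample(stats::setNames(7 * c(10, 10, 20),
                                                p3$probe_id),
                                p3, "GLOBAL_SUM")
  expect_equal(v, v2)
  # anchor mode divides by the most centromeric probe
  va <- normalize_within_sample(stats::setNames(c(5, 10, 10), p3$probe_id),
                                p3, "ANCHOR")
  expect_equal(unname(va), c(1, 2, 2))
  expect_error(normalize_within_sample(stats::setNames(c(0, 10, 10),
                                                       p3$probe_id),
                                       p3, "ANCHOR"), "anchor")
  expect_error(normalize_within_sample(stats::setNames(c(0, 0), panel$probe_id),
                                       panel, "GLOBAL_SUM"), "zero")
})

test_that("samples identical to controls call copy number 1 everywhere", {
  panel <- toy_panel()
  pk <- peaks_from_areas(list(s1 = c(100, 200), c1 = c(100, 200),
                              c2 = c(100, 200)), panel, c("c1", "c2"))
  cn <- call_copy_numbers(pk, panel)
  expect_equal(unname(cn$ratio["s1", ]), c(1, 1))
  expect_equal(unname(cn$call["s1", ]), c(1L, 1L))
  expect_true(all(cn$flag == "OK"))
})

test_that("borderline ratios are flagged AMBIGUOUS", {
  panel <- toy_panel()
  # controls normalized (0.25, 0.75); sample (0.5, 0.5) -> ratios (2, 0.667)
  pk <- peaks_from_areas(list(s1 = c(50, 50), c1 = c(25, 75), c2 = c(25, 75)),
                         panel, c("c1", "c2"))
  cn <- call_copy_numbers(pk, panel)
  expect_equal(unname(cn$ratio["s1", ]), c(2, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(cn$call["s1", 1]), 2L)
  expect_equal(unname(cn$flag["s1", ]), c("OK", "AMBIGUOUS"))
  # the .5 tie rounds half away from zero and is ambiguous at default tol
  pk2 <- peaks_from_areas(list(s1 = c(100, 150), c1 = c(100, 100),
                               c2 = c(100, 100)), panel, c("c1", "c2"))
  cn2 <- call_copy_numbers(pk2, panel, mode = "ANCHOR")
  expect_equal(unname(cn2$call["s1", 2]), 2L)
  expect_equal(unname(cn2$flag["s1", 2]), "AMBIGUOUS")
})

test_that("deletion and duplication pattern is called from peak areas", {
  # genome-wide panel; one isolate with chrV-L lost and chrXIII-L doubled
  ann <- fx_annotation()
  tel <- fx_telomeric()
  truth <- data.frame(isolate = "iso1", category = "dup", region = "chrXIII-L",
                      chrom = "chrXIII", arm = "L", target_element = NA,
                      whole_dups = "", stringsAsFactors = FALSE)
  ct <- true_copy_numbers(truth, tel, ann)
  pk <- simulate_peaks(ct, tel, noise_model(cv = 0.02), n_controls = 3,
                       seed = 5)
  cn <- call_copy_numbers(pk, tel)
  expect_equal(unname(cn$call["iso1", "chrV-L_tel"]), 0L)
  expect_equal(unname(cn$call["iso1", "chrXIII-L_tel"]), 2L)
  expect_true(all(cn$call["iso1", setdiff(colnames(cn$call),
                                          c("chrV-L_tel", "chrXIII-L_tel"))] == 1L))
})

test_that("calls are invariant to per-sample scaling of raw areas", {
  panel <- toy_panel()
  pk <- peaks_from_areas(list(s1 = c(90, 210), c1 = c(100, 200),
                              c2 = c(110, 190)), panel, c("c1", "c2"))
  pk_scaled <- pk
  pk_scaled$area[pk_scaled$sample_id == "s1"] <-
    pk_scaled$area[pk_scaled$sample_id == "s1"] * 13
  cn1 <- call_copy_numbers(pk, panel)
  cn2 <- call_copy_numbers(pk_scaled, panel)
  expect_equal(cn1$ratio, cn2$ratio)
})

test_that("call accuracy is high at 5% CV and degrades with noise", {
  ann <- fx_annotation()
  tel <- fx_telomeric()
  truth <- simulate_cohort(ann, wildtype_event_model(ann), 200, seed = 7)
  ct <- true_copy_numbers(truth, tel, ann)
  acc <- function(cv, seed) {
    pk <- simulate_peaks(ct, tel, noise_model(cv = cv), n_controls = 4,
                         seed = seed)
    cn <- call_copy_numbers(pk, tel)
    mean(cn$call == round(ct))
  }
  a05 <- acc(0.05, 8)
  expect_gte(a05, 0.99)
  a30 <- acc(0.30, 8)
  expect_lte(a30, a05)
})

test_that("anchor mode reproduces global-sum calls when the anchor is clean", {
  ann <- fx_annotation()
  aps <- fx_arm_panel("chrV", "R")
  truth <- data.frame(isolate = "iso1", category = "dup",
                      region = "chrV-R:YERCTy1-2", chrom = "chrV",
                      arm = "R", target_element = "YERCTy1-2",
                      whole_dups = "", stringsAsFactors = FALSE)
  ct <- true_copy_numbers(truth, aps, ann)
  expect_equal(unname(ct[1, 1]), 1)  # anchor probe truly single copy
  # duplicated fraction small enough that the global sum is not distorted
  # past the rounding boundary (needs < 1/3 of probes duplicated)
  expect_lt(mean(ct >= 2), 1 / 3)
  pk <- simulate_peaks(ct, aps, noise_model(cv = 0.02), n_controls = 3,
                       seed = 9)
  cn_anchor <- call_copy_numbers(pk, aps, mode = "ANCHOR")
  cn_global <- call_copy_numbers(pk, aps, mode = "GLOBAL_SUM")
  expect_equal(cn_anchor$call, cn_global$call)
})

test_that("peak matching tolerates 1 bp sizing error and flags strays", {
  panel <- toy_panel()
  pk <- data.frame(sample_id = "s1",
                   size_bp = c(panel$product_length_bp[1] + 0.8,
                               panel$product_length_bp[2] - 0.5, 250),
                   height = 1, area = c(100, 100, 50), is_control = FALSE)
  expect_warning(m <- match_peaks(pk, panel), "ignored")
  expect_equal(nrow(m), 2L)
  expect_equal(m$probe_id, panel$probe_id)
})
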