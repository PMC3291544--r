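#' Generate a synthetic S288C-like genome annotation
#'
#' Builds a 16-chromosome annotation whose repeat landscape matches the
#' published aggregate features of the S288C reference: by default 254
#' potential Ty-related translocation targets in `TY1_PLUS_DELTA` counting
#' (each Ty2 contributing two delta targets), 13 Ty2 elements, and a mixed
#' orientation distribution (~52% centromere-oriented).  Chromosome sizes
#' and centromere positions follow the real karyotype.  The fixture is
#' synthetic: per-arm element counts other than the constrained aggregates
#' are allocated proportionally to arm length, with seeded jitter on
#' element positions.
#'
#' Four structural motifs of the real genome are reproduced exactly because
#' downstream behaviour depends on them:
#' \itemize{
#'   \item the four arms whose terminal element sits too close to the
#'     telomere for a unique probe window (chrII-L, chrIV-R, chrIX-R,
#'     chrXV-L), forcing `FALLBACK_CENTROMERIC` telomeric probes;
#'   \item the chrIII-R fragile-site loci: the collocated
#'     YCRWdelta8/9/10 cluster (FS1) and the separate YCRWdelta11 (FS2);
#'   \item the chrV-R hotspot clusters YERCdelta14/15/16 and
#'     YERWdelta17/YERWdelta21/YERCTy1-1, plus the singleton
#'     YERWdelta22 and YERCTy1-2 loci;
#'   \item the chrX-R tandem YJRWTy1-1/YJRWTy1-2 pair and the chrXIV-L
#'     YNLCTy1-1 / YNLWTy1-2 / YNLCTy2-1 loci.
#' }
#'
#' @param n_chrom number of chromosomes (16 for the full landscape; smaller
#'   values give a bare annotation without elements and require
#'   `target_total = 0`).
#' @param n_ty2 number of Ty2 elements (default 13).
#' @param target_total total `TY1_PLUS_DELTA` target count (default 254).
#' @param n_ty1_extra number of full-length Ty1 elements outside the fixed
#'   hotspot loci (default 26, giving ~30 Ty1 total).
#' @param p_telomere_oriented probability that a randomly placed element is
#'   telomere-oriented (default 0.476).
#' @param seed RNG seed; the annotation is deterministic given all
#'   arguments.
#' @return A `genome_annotation`.
#' @export
make_fixture_annotation <- function(n_chrom = 16, n_ty2 = 13,
                                    target_total = 254, n_ty1_extra = 26,
                                    p_telomere_oriented = 0.476, seed = 1) {
  chroms <- fixture_chromosomes()
  if (n_chrom < 1 || n_chrom > 16) stop("n_chrom must be in 1..16")
  chroms <- chroms[seq_len(n_chrom), , drop = FALSE]
  cen <- fixture_centromeres()
  cen <- cen[cen$chrom %in% chroms$chrom, , drop = FALSE]
  tel <- rbind(
    data.frame(chrom = chroms$chrom, side = "L", start = 1L, end = 5000L),
    data.frame(chrom = chroms$chrom, side = "R",
               start = chroms$length - 4999L, end = chroms$length)
  )

  if (target_total == 0)
    return(genome_annotation(chroms, cen, tel, NULL))
  if (n_chrom < 16)
    stop("infeasible constraints: the full element landscape needs 16 chromosomes")

  fixed <- fixture_fixed_elements()
  fixed_targets <- sum(ifelse(fixed$class == "TY2", 2L, 1L))
  n_ty2_fixed <- sum(fixed$class == "TY2")
  if (n_ty2 < n_ty2_fixed) stop("infeasible constraints: n_ty2 too small")
  extra_ty2 <- n_ty2 - n_ty2_fixed
  remaining <- target_total - fixed_targets - 2L * extra_ty2
  if (remaining < n_ty1_extra)
    stop("infeasible constraints: target_total too small for the requested mix")
  n_delta_extra <- remaining - n_ty1_extra

  # eligible arms for random placement: everything except the hotspot arms
  hotspot_arms <- c("chrIII R", "chrV R", "chrX R", "chrXIV L")
  arms <- arm_table(genome_annotation(chroms, cen, tel, NULL))
  arms$key <- paste(arms$chrom, arms$arm)
  # usable interior zone of each arm, clear of telomere tract, centromere
  # and the fixed terminal deltas
  arms$zone_lo <- ifelse(arms$arm == "L", 5000L + 20000L, arms$start + 20000L)
  arms$zone_hi <- ifelse(arms$arm == "L", arms$end - 20000L,
                         arms$end - 5000L - 20000L)
  elig <- arms[!arms$key %in% hotspot_arms, , drop = FALSE]
  elig$zone_len <- elig$zone_hi - elig$zone_lo

  # one extra Ty2 on each of the longest eligible arms
  ty2_arms <- elig$key[order(-elig$zone_len)][seq_len(extra_ty2)]

  # allocate the remaining Ty1 + delta items proportionally to zone length
  n_items <- n_ty1_extra + n_delta_extra
  w <- elig$zone_len / sum(elig$zone_len)
  alloc <- floor(w * n_items)
  shortfall <- n_items - sum(alloc)
  if (shortfall > 0) {
    resid <- w * n_items - alloc
    alloc[order(-resid)[seq_len(shortfall)]] <- alloc[order(-resid)[seq_len(shortfall)]] + 1L
  }
  # global Ty1 positions among the pooled items
  ty1_slots <- if (n_ty1_extra > 0)
    unique(round(seq(1, n_items, length.out = n_ty1_extra))) else integer(0)
  while (length(ty1_slots) < n_ty1_extra)  # guard against rounding collisions
    ty1_slots <- union(ty1_slots, setdiff(seq_len(n_items), ty1_slots)[1L])

  el <- with_seed(seed, {
    rows <- list(fixed)
    item <- 0L
    for (i in seq_len(nrow(elig))) {
      a <- elig[i, ]
      k <- alloc[i] + as.integer(a$key %in% ty2_arms)
      if (k == 0L) next
      spacing <- (a$zone_hi - a$zone_lo) / (k + 1L)
      centers <- a$zone_lo + spacing * seq_len(k) +
        stats::runif(k, -0.2, 0.2) * spacing
      is_ty2 <- rep(FALSE, k)
      if (a$key %in% ty2_arms) is_ty2[ceiling(k / 2)] <- TRUE
      for (j in seq_len(k)) {
        if (is_ty2[j]) {
          cls <- "TY2"; len <- 5918L
        } else {
          item <- item + 1L
          cls <- if (item %in% ty1_slots) "TY1" else "SOLO_DELTA"
          len <- if (cls == "TY1") 5918L else 334L
        }
        s <- as.integer(round(centers[j] - len / 2))
        ori <- if (stats::runif(1) < p_telomere_oriented) "TELOMERE" else "CENTROMERE"
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s%s_%s%02d", a$chrom, a$arm,
                       c(TY1 = "Ty1_", TY2 = "Ty2_", SOLO_DELTA = "delta")[cls], j),
          chrom = a$chrom, start = s, end = s + len - 1L, class = cls,
          orientation = ori, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  ann <- genome_annotation(chroms, cen, tel, el)
  total <- build_target_catalog(ann, "TY1_PLUS_DELTA")$total
  if (total != target_total)
    stop("internal error: fixture catalog has ", total, " targets, expected ",
         target_total)
  ann
}

# real S288C karyotype (chromosome sizes and centromere midpoint intervals)
fixture_chromosomes <- function() {
  data.frame(
    chrom = paste0("chr", c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                            "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")),
    length = c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L,
               1090940L, 562643L, 439888L, 745751L, 666816L, 1078177L,
               924431L, 784333L, 1091291L, 948066L),
    stringsAsFactors = FALSE)
}

fixture_centromeres <- function() {
  mid <- c(151465L, 238207L, 114385L, 449711L, 151987L, 148510L, 496920L,
           105586L, 355629L, 436307L, 440129L, 150828L, 268031L, 628758L,
           326584L, 555957L)
  data.frame(chrom = fixture_chromosomes()$chrom,
             start = mid, end = mid + 116L, stringsAsFactors = FALSE)
}

# named elements reproduced exactly (hotspot loci and fallback-arm terminal
# deltas); coordinates are synthetic but preserve order, clustering and the
# sub-minimum telomeric windows
fixture_fixed_elements <- function() {
  d <- function(id, chrom, start, ori = "TELOMERE", class = "SOLO_DELTA",
                len = if (class == "SOLO_DELTA") 334L else 5918L)
    data.frame(id = id, chrom = chrom, start = as.integer(start),
               end = as.integer(start + len - 1L), class = class,
               orientation = ori, stringsAsFactors = FALSE)
  rbind(
    # chrIII-R: FS1 cluster and FS2
    d("YCRWdelta8",  "chrIII", 160000), d("YCRWdelta9", "chrIII", 160900),
    d("YCRWdelta10", "chrIII", 161800), d("YCRWdelta11", "chrIII", 170000),
    # chrV-R: singleton deltas, two hotspot clusters, distal singletons
    d("YERCdelta5",  "chrV", 350000, "CENTROMERE"),
    d("YERCdelta7",  "chrV", 380000),
    d("YERCdelta14", "chrV", 432000, "CENTROMERE"),
    d("YERCdelta15", "chrV", 432800, "CENTROMERE"),
    d("YERCdelta16", "chrV", 433600, "CENTROMERE"),
    d("YERWdelta17", "chrV", 440000),
    d("YERWdelta21", "chrV", 440900),
    d("YERCTy1-1",   "chrV", 441800, "CENTROMERE", "TY1"),
    d("YERWdelta22", "chrV", 470000),
    d("YERCTy1-2",   "chrV", 490000, "CENTROMERE", "TY1"),
    # chrX-R tandem Ty1 pair
    d("YJRWTy1-1", "chrX", 590000, "TELOMERE", "TY1"),
    d("YJRWTy1-2", "chrX", 596200, "TELOMERE", "TY1"),
    # chrXIV-L loci (left arm: lower coordinate = more telomeric)
    d("YNLCTy1-1", "chrXIV", 90000,  "CENTROMERE", "TY1"),
    d("YNLWTy1-2", "chrXIV", 520000, "TELOMERE",   "TY1"),
    d("YNLCTy2-1", "chrXIV", 585000, "CENTROMERE", "TY2"),
    # terminal deltas abutting the telomere on the four fallback arms
    d("YBLWdelta-term", "chrII", 5080),
    d("YDRWdelta-term", "chrIV", 1526500),
    d("YIRWdelta-term", "chrIX", 434450),
    d("YOLWdelta-term", "chrXV", 5100)
  )
}

#' Event models for cohort simulation
#'
#' An `event_model` specifies, conditional on an isolate carrying a
#' duplication, the probabilities of each duplication "region" (a hotspot
#' target locus or a whole non-hotspot arm), plus the per-isolate
#' probabilities of having no duplication, of being unassignable
#' (ambiguous), and of carrying an independent whole-chromosome
#' duplication.
#'
#' `wildtype_event_model()` encodes the wild-type regime: six hotspot
#' target regions and four singleton loci on the four hotspot arms at their
#' observed maximum-likelihood fractions (67 + 6 of 106 duplications), the
#' rest spread over the remaining arms in proportion to their target
#' catalog share; 5/112 duplication-free and 1/112 ambiguous isolates.
#' `rad52_event_model()` encodes the recombination-deficient regime: 68%
#' of isolates carry only the assay deletion and 32% a single duplication.
#'
#' @param ann a `genome_annotation` from [make_fixture_annotation()].
#' @return An `event_model` list: `regions` (data.frame `region`, `chrom`,
#'   `arm`, `target_element`, `prob`), `p_no_duplication`, `p_ambiguous`,
#'   `p_whole_chromosome`.
#' @export
wildtype_event_model <- function(ann) {
  hs <- hotspot_region_counts()
  other <- other_arm_probabilities(ann)
  other$count <- NA_real_
  regions <- rbind(hs[, c("region", "chrom", "arm", "target_element")],
                   other[, c("region", "chrom", "arm", "target_element")])
  regions$prob <- c(hs$count / 106, (33 / 106) * other$prob)
  structure(list(regions = regions, p_no_duplication = 5 / 112,
                 p_ambiguous = 1 / 112, p_whole_chromosome = 0),
            class = "event_model")
}

#' @rdname wildtype_event_model
#' @export
rad52_event_model <- function(ann) {
  hs <- hotspot_region_counts()
  other <- other_arm_probabilities(ann)
  regions <- rbind(hs[, c("region", "chrom", "arm", "target_element")],
                   other[, c("region", "chrom", "arm", "target_element")])
  # dispersed target use: hotspot regions flattened to equal weight, the
  # rest by catalog share
  w <- c(rep(1 / 4, nrow(hs)) / nrow(hs) * 4, 3 * other$prob)
  regions$prob <- w / sum(w)
  structure(list(regions = regions, p_no_duplication = 0.68,
                 p_ambiguous = 0, p_whole_chromosome = 0),
            class = "event_model")
}

# Table-style hotspot regions with observed wild-type counts (of 106)
hotspot_region_counts <- function() {
  data.frame(
    region = c("chrIII-R:FS1", "chrIII-R:FS2",
               "chrV-R:YERCdelta5", "chrV-R:YERCdelta7",
               "chrV-R:YERCdelta14-16", "chrV-R:YERWdelta17-Ty1-1",
               "chrV-R:YERWdelta22", "chrV-R:YERCTy1-2",
               "chrXIV-L:YNLCTy1-1", "chrXIV-L:YNLWTy1-2",
               "chrXIV-L:YNLCTy2-1", "chrX-R:YJRWTy1"),
    chrom = c("chrIII", "chrIII", rep("chrV", 6), rep("chrXIV", 3), "chrX"),
    arm = c("R", "R", rep("R", 6), rep("L", 3), "R"),
    target_element = c("YCRWdelta9", "YCRWdelta11", "YERCdelta5",
                       "YERCdelta7", "YERCdelta15", "YERWdelta21",
                       "YERWdelta22", "YERCTy1-2", "YNLCTy1-1",
                       "YNLWTy1-2", "YNLCTy2-1", "YJRWTy1-1"),
    count = c(17, 11, 1, 1, 5, 18, 1, 1, 1, 1, 6, 10),
    stringsAsFactors = FALSE)
}

# catalog-share probabilities over the non-hotspot arms (excluding the
# assay arm chrV-L, which cannot be recovered as a duplication)
other_arm_probabilities <- function(ann) {
  cat <- build_target_catalog(ann, "TY1_PLUS_DELTA")
  pa <- cat$per_arm
  pa$key <- paste0(pa$chrom, "-", pa$arm)
  drop <- c("chrIII-R", "chrV-R", "chrX-R", "chrXIV-L", "chrV-L")
  pa <- pa[!pa$key %in% drop & pa$count > 0, , drop = FALSE]
  data.frame(region = pa$key, chrom = pa$chrom, arm = pa$arm,
             target_element = NA_character_,
             prob = pa$count / sum(pa$count), stringsAsFactors = FALSE)
}

#' Simulate a GCR cohort with known ground truth
#'
#' Every isolate carries the assay-selected chrV-L deletion.  Conditional
#' on the event model, it additionally carries either one chromosome-arm
#' duplication (drawn from the model's region probabilities), no
#' duplication, or an engineered ambiguous dosage (an intermediate copy
#' number emulating a mixed colony).  Whole-chromosome duplications are
#' drawn independently at the model's per-isolate rate.
#'
#' @param ann a `genome_annotation`.
#' @param model an `event_model`.
#' @param n number of isolates.
#' @param seed RNG seed.
#' @return A `cohort_truth` data.frame: `isolate`, `category`
#'   (`dup`/`none`/`ambiguous`), `region`, `chrom`, `arm`,
#'   `target_element`, `whole_dups` (comma-separated chromosomes).
#' @export
simulate_cohort <- function(ann, model, n, seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    cats <- sample(c("dup", "none", "ambiguous"), n, replace = TRUE,
                   prob = c(1 - model$p_no_duplication - model$p_ambiguous,
                            model$p_no_duplication, model$p_ambiguous))
    reg <- model$regions
    ridx <- sample.int(nrow(reg), n, replace = TRUE, prob = reg$prob)
    chroms_all <- setdiff(unique(ann$chromosomes$chrom), "chrV")
    whole <- vapply(seq_len(n), function(i) {
      if (stats::runif(1) < model$p_whole_chromosome)
        sample(chroms_all, 1L) else ""
    }, character(1))
    out <- data.frame(
      isolate = sprintf("iso%03d", seq_len(n)), category = cats,
      region = ifelse(cats == "dup", reg$region[ridx], NA_character_),
      chrom = ifelse(cats == "dup", reg$chrom[ridx], NA_character_),
      arm = ifelse(cats == "dup", reg$arm[ridx], NA_character_),
      target_element = ifelse(cats == "dup", reg$target_element[ridx],
                              NA_character_),
      whole_dups = whole, stringsAsFactors = FALSE)
    class(out) <- c("cohort_truth", "data.frame")
    out
  })
}

#' Deterministic fixture cohorts
#'
#' Cohorts with exact (not sampled) event counts, used as worked examples
#' and regression anchors: `"wildtype"` is a 112-isolate cohort encoding
#' the observed wild-type hotspot counts (17 + 11 on chrIII-R, 27 on
#' chrV-R, 8 on chrXIV-L, 10 on chrX-R, 33 spread over other arms, 5
#' duplication-free, 1 ambiguous); `"rad52"` is a 50-isolate cohort with 34
#' deletion-only isolates and 16 single duplications; `"rtt109"` is a
#' 49-isolate cohort in which every isolate carries a duplication and 11
#' additionally carry whole-chromosome duplications (one of them two:
#' chrVIII and chrIX).
#'
#' @param ann a `genome_annotation` (16-chromosome fixture).
#' @param regime `"wildtype"`, `"rad52"` or `"rtt109"`.
#' @return A `cohort_truth` data.frame (see [simulate_cohort()]).
#' @export
fixture_cohort <- function(ann, regime = c("wildtype", "rad52", "rtt109")) {
  regime <- match.arg(regime)
  hs <- hotspot_region_counts()
  other <- other_arm_probabilities(ann)

  expand_regions <- function(counts_df) {
    idx <- rep(seq_len(nrow(counts_df)), counts_df$count)
    counts_df[idx, c("region", "chrom", "arm", "target_element")]
  }

  rows <- switch(regime,
    wildtype = {
      hot <- expand_regions(hs)  # 73 isolates
      # 33 further duplications round-robin over the non-hotspot arms
      oidx <- rep(seq_len(nrow(other)), length.out = 33)
      oth <- other[sort(oidx), c("region", "chrom", "arm", "target_element")]
      dup <- rbind(hot, oth)
      data.frame(category = c(rep("dup", nrow(dup)), rep("none", 5), "ambiguous"),
                 region = c(dup$region, rep(NA, 6)),
                 chrom = c(dup$chrom, rep(NA, 6)),
                 arm = c(dup$arm, rep(NA, 6)),
                 target_element = c(dup$target_element, rep(NA, 6)),
                 whole_dups = "", stringsAsFactors = FALSE)
    },
    rad52 = {
      named <- hs[match(c("chrIII-R:FS1", "chrV-R:YERWdelta17-Ty1-1",
                          "chrX-R:YJRWTy1", "chrX-R:YJRWTy1"), hs$region),
                  c("region", "chrom", "arm", "target_element")]
      oidx <- rep(seq_len(nrow(other)), length.out = 12)
      oth <- other[sort(oidx), c("region", "chrom", "arm", "target_element")]
      dup <- rbind(named, oth)  # 16 duplications
      data.frame(category = c(rep("dup", 16), rep("none", 34)),
                 region = c(dup$region, rep(NA, 34)),
                 chrom = c(dup$chrom, rep(NA, 34)),
                 arm = c(dup$arm, rep(NA, 34)),
                 target_element = c(dup$target_element, rep(NA, 34)),
                 whole_dups = "", stringsAsFactors = FALSE)
    },
    rtt109 = {
      oidx <- rep(seq_len(nrow(other)), length.out = 37)
      oth <- other[sort(oidx), c("region", "chrom", "arm", "target_element")]
      hot_hs <- hs[hs$region %in%
        c("chrIII-R:FS1", "chrV-R:YERWdelta17-Ty1-1", "chrX-R:YJRWTy1",
          "chrXIV-L:YNLCTy2-1"), ]
      hot_hs$count <- 3L
      hot <- expand_regions(hot_hs)
      dup <- rbind(hot, oth)  # 49 duplications
      whole <- rep("", 49)
      # 11 aneuploid isolates among the non-hotspot-dup ones; one carries two
      aneu_chrom <- c("chrVIII,chrIX", "chrVIII", "chrVIII", "chrXII",
                      "chrXII", "chrXII", "chrIX", "chrX", "chrXIII",
                      "chrII", "chrVII")
      whole[13:23] <- aneu_chrom
      data.frame(category = "dup", region = dup$region, chrom = dup$chrom,
                 arm = dup$arm, target_element = dup$target_element,
                 whole_dups = whole, stringsAsFactors = FALSE)
    })
  rows$isolate <- sprintf("%s%03d", substr(regime, 1, 2), seq_len(nrow(rows)))
  rows <- rows[, c("isolate", "category", "region", "chrom", "arm",
                   "target_element", "whole_dups")]
  rownames(rows) <- NULL
  class(rows) <- c("cohort_truth", "data.frame")
  rows
}

#' True copy numbers implied by a cohort's events
#'
#' Maps ground-truth events onto a probe panel: every isolate has copy
#' number 0 at the chrV-L telomeric probe (the assay deletion), an arm
#' duplication raises the probes telomeric to the target element on the
#' duplicated arm (for a telomeric panel, the arm's telomeric probe) to 2,
#' a whole-chromosome duplication adds one copy at every probe of the
#' chromosome, and an ambiguous isolate carries an intermediate dosage of
#' 1.5 at a designated marker probe (default: the chrVII-L telomeric
#' probe), emulating a mixed colony.
#'
#' @param truth a `cohort_truth`.
#' @param probeset a `probe_set` (telomeric, centromeric or arm-specific).
#' @param ann the `genome_annotation`.
#' @param gcr_chrom,gcr_arm the assay deletion arm.
#' @return Numeric matrix isolates x probes of true copy numbers.
#' @export
true_copy_numbers <- function(truth, probeset, ann,
                              gcr_chrom = "chrV", gcr_arm = "L") {
  ps <- as.data.frame(probeset)
  n <- nrow(truth)
  cn <- matrix(1, n, nrow(ps), dimnames = list(truth$isolate, ps$probe_id))

  tel_role <- ps$role == "TELOMERIC"
  vl <- tel_role & ps$chrom == gcr_chrom & ps$arm == gcr_arm
  cn[, vl] <- 0

  el <- ann$elements
  for (i in seq_len(n)) {
    tr <- truth[i, ]
    if (tr$category == "dup" && !is.na(tr$chrom)) {
      on_arm <- ps$chrom == tr$chrom & ps$arm == tr$arm
      if (any(on_arm & ps$role == "ARM_SPECIFIC")) {
        # duplication runs from the target element to the telomere
        e <- el[el$id == tr$target_element, ]
        if (nrow(e)) {
          dup_probes <- on_arm & ps$role == "ARM_SPECIFIC" &
            (if (tr$arm == "R") ps$anchor_bp > e$end else ps$anchor_bp < e$start)
        } else {
          dup_probes <- on_arm & ps$role == "ARM_SPECIFIC" &
            seq_len(nrow(ps)) == max(which(on_arm))
        }
        cn[i, dup_probes] <- cn[i, dup_probes] + 1
      }
      cn[i, on_arm & tel_role] <- cn[i, on_arm & tel_role] + 1
    }
    if (nzchar(tr$whole_dups)) {
      for (ch in strsplit(tr$whole_dups, ",", fixed = TRUE)[[1]])
        cn[i, ps$chrom == ch] <- cn[i, ps$chrom == ch] + 1
    }
    if (tr$category == "ambiguous") {
      marker <- which(tel_role & ps$chrom == "chrVII" & ps$arm == "L")
      if (!length(marker)) marker <- which(tel_role)[1L]
      cn[i, marker[1L]] <- 1.5
    }
  }
  cn
}

#' Default multiplicative noise model for peak simulation
#'
#' @param cv multiplicative measurement coefficient of variation
#'   (lognormal sigma, default 0.05).
#' @param sigma_probe lognormal sd of per-probe ligation/amplification
#'   efficiency (default 0.3; cancels in control normalization).
#' @param sigma_sample lognormal sd of per-sample scale (default 0.2;
#'   cancels in within-sample normalization).
#' @param background fraction of a one-copy signal emitted by a
#'   zero-copy locus (default 0.02).
#' @return A `noise_model` list.
#' @export
noise_model <- function(cv = 0.05, sigma_probe = 0.3, sigma_sample = 0.2,
                        background = 0.02) {
  stopifnot(cv >= 0, sigma_probe >= 0, sigma_sample >= 0, background >= 0)
  structure(list(cv = cv, sigma_probe = sigma_probe,
                 sigma_sample = sigma_sample, background = background),
            class = "noise_model")
}

#' Simulate capillary peak tables from true copy numbers
#'
#' Peak areas follow `area = scale_sample * efficiency_probe *
#' max(CN, background) * exp(eps)` with `eps ~ Normal(0, cv^2)`.
#' Probe efficiencies are drawn once and shared by all samples (as in a
#' real probe mix); control samples carry copy number 1 everywhere.
#'
#' @param true_cn matrix isolates x probes from [true_copy_numbers()].
#' @param probeset the `probe_set` (provides product lengths).
#' @param noise a `noise_model`.
#' @param n_controls number of euploid control samples (>= 1).
#' @param seed RNG seed.
#' @return Long data.frame `sample_id`, `size_bp`, `height`, `area`,
#'   `is_control` suitable for [call_copy_numbers()].
#' @export
simulate_peaks <- function(true_cn, probeset, noise = noise_model(),
                           n_controls = 3, seed = 1) {
  if (n_controls < 1) stop("need at least one control sample")
  ps <- as.data.frame(probeset)
  stopifnot(ncol(true_cn) == nrow(ps))
  ctrl <- matrix(1, n_controls, nrow(ps),
                 dimnames = list(sprintf("control%02d", seq_len(n_controls)),
                                 ps$probe_id))
  cn <- rbind(true_cn, ctrl)
  is_ctrl <- c(rep(FALSE, nrow(true_cn)), rep(TRUE, n_controls))

  with_seed(seed, {
    eff <- exp(stats::rnorm(nrow(ps), 0, noise$sigma_probe))
    scl <- exp(stats::rnorm(nrow(cn), 0, noise$sigma_sample))
    eps <- matrix(stats::rnorm(length(cn), 0, noise$cv), nrow(cn))
    dose <- pmax(cn, noise$background)
    area <- sweep(sweep(dose * exp(eps), 2, eff, "*"), 1, 1000 * scl, "*")
    data.frame(
      sample_id = rep(rownames(cn), times = ncol(cn)),
      size_bp = rep(ps$product_length_bp, each = nrow(cn)),
      height = as.vector(area), area = as.vector(area),
      is_control = rep(is_ctrl, times = ncol(cn)),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a Luria-Delbruck fluctuation assay
#'
#' Each culture grows clonally from a single cell to `final_population`
#' cells.  The number of mutational events is Poisson with mean
#' `mutation_rate * final_population` (one opportunity per cell division);
#' each event is assigned to a division drawn uniformly over the growth
#' history, so a mutation arising when the population had size `s` leaves
#' `final_population / s` descendants.  This reproduces the heavy-tailed
#' "jackpot" distribution of mutant counts.
#'
#' @param mutation_rate events per cell per division, in (0, 1).
#' @param final_population final cells per culture (>= 1000).
#' @param n_cultures number of parallel cultures.
#' @param seed RNG seed.
#' @param method per-culture rate transform passed to
#'   [per_culture_rates()] (default `"frequency"`).
#' @return data.frame `culture`, `count`, `rate`.
#' @export
simulate_fluctuation <- function(mutation_rate, final_population, n_cultures,
                                 seed = 1, method = "frequency") {
  stopifnot(mutation_rate >= 0, mutation_rate < 1, final_population >= 1000)
  counts <- with_seed(seed, {
    m <- stats::rpois(n_cultures, mutation_rate * final_population)
    vapply(m, function(k) {
      if (k == 0) return(0)
      s <- ceiling(stats::runif(k) * final_population)  # size at mutation
      min(final_population, sum(floor(final_population / s)))
    }, numeric(1))
  })
  data.frame(culture = sprintf("c%04d", seq_len(n_cultures)),
             count = counts,
             rate = per_culture_rates(counts, final_population, method),
             stringsAsFactors = FALSE)
}

#' Per-culture rate values from mutant counts
#'
#' `"frequency"` reports the naive mutant frequency `count / N`.
#' `"lea_coulson"` inverts the Lea-Coulson median relation
#' `r / m - ln(m) = 1.24` for each culture's count `r` and reports
#' `m / N`; applied at the cohort median count this recovers the true rate,
#' so the median of the transformed values is a consistent rate estimator,
#' unlike the frequency, which inflates with `ln(mN)`.
#'
#' @param counts integer vector of per-culture mutant counts.
#' @param population final cells per culture.
#' @param method `"frequency"` or `"lea_coulson"`.
#' @return Numeric vector of per-culture rate values.
#' @export
per_culture_rates <- function(counts, population,
                              method = c("frequency", "lea_coulson")) {
  method <- match.arg(method)
  if (method == "frequency") return(counts / population)
  vapply(counts, function(r) {
    if (r <= 0) return(0)
    f <- function(m) r / m - log(m) - 1.24
    m <- stats::uniroot(f, lower = 1e-10, upper = 1e12, tol = 1e-12)$root
    m / population
  }, numeric(1))
}

#' Simulate paired aneuploidy indicators
#'
#' For each fluctuation culture a matched pair of isolates is screened for
#' whole-chromosome duplications: one colony from nonselective medium and
#' one GCR-selected colony.  Indicators are independent Bernoulli draws
#' per isolate; the discordant counts feed [paired_exact_test()].
#'
#' @param n number of culture pairs.
#' @param p_selective,p_nonselective aneuploidy probabilities for the
#'   selected and nonselected isolate of a pair.
#' @param seed RNG seed.
#' @return data.frame `culture`, `selective`, `nonselective` (logical),
#'   with attribute `discordant` = c(b, c).
#' @export
simulate_paired_aneuploidy <- function(n, p_selective, p_nonselective,
                                       seed = 1) {
  stopifnot(p_selective >= 0, p_selective <= 1,
            p_nonselective >= 0, p_nonselective <= 1)
  with_seed(seed, {
    sel <- stats::runif(n) < p_selective
    non <- stats::runif(n) < p_nonselective
    out <- data.frame(culture = sprintf("c%03d", seq_len(n)),
                      selective = sel, nonselective = non,
                      stringsAsFactors = FALSE)
    attr(out, "discordant") <- c(b = sum(sel & !non), c = sum(!sel & non))
    out
  })
}
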