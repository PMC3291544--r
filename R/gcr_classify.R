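#' Classify one isolate's copy-number calls into GCR events
#'
#' The selection assay recovers cells that lost the nonessential terminal
#' segment of chromosome V-L, so every informative isolate is expected to
#' show copy number 0 at the chrV-L telomeric probe.  On top of that the
#' classifier reports: whole-chromosome duplications (call >= 2 at every
#' probed locus of a chromosome, across the telomeric and, when present,
#' centromeric panels), and chromosome-arm duplications (telomeric call >= 2
#' on an arm not already part of a whole-chromosome duplication) -- the
#' signature of a nonreciprocal translocation that captured the terminal
#' segment of the target arm.
#'
#' An isolate is `AMBIGUOUS` when any contributing cell carries the
#' `AMBIGUOUS` (or `MISSING`, other than unprobed loci) QC flag,
#' `NO_DUPLICATION` when the chrV-L deletion is present but no duplication
#' was found, and `CLASSIFIED` otherwise.  A duplication detected at a
#' `FALLBACK_CENTROMERIC` telomeric probe is reported with a caveat because
#' the terminal element(s) of that arm are unprobed.
#'
#' @param calls named integer vector of copy-number calls for one isolate
#'   (names = probe ids), covering the telomeric panel and optionally the
#'   centromeric panel.
#' @param flags named character vector of QC flags matching `calls`.
#' @param probeset the combined `probe_set` (telomeric plus optional
#'   centromeric rows) describing the probes in `calls`.
#' @param gcr_chrom,gcr_arm chromosome and arm whose loss defines the assay
#'   (defaults `"chrV"`, `"L"`).
#' @return An `isolate_classification`: list with `isolate`,
#'   `has_chrV_L_deletion`, `arm_duplications` (character vector
#'   `"chrom-arm"`), `whole_chromosome_duplications` (character vector of
#'   chromosomes), `status`, `caveats`.
#' @export
classify_isolate <- function(calls, flags, probeset,
                             gcr_chrom = "chrV", gcr_arm = "L") {
  probeset <- as.data.frame(probeset)
  idx <- match(probeset$probe_id, names(calls))
  if (anyNA(idx)) stop("calls are missing probe(s): ",
                       paste(probeset$probe_id[is.na(idx)], collapse = ", "))
  calls <- calls[idx]
  flags <- flags[idx]

  tel <- probeset$role == "TELOMERIC"
  vl <- tel & probeset$chrom == gcr_chrom & probeset$arm == gcr_arm
  if (!any(vl)) stop("missing ", gcr_chrom, "-", gcr_arm, " telomeric probe")
  if (flags[vl] == "MISSING")
    stop("no peak for the ", gcr_chrom, "-", gcr_arm, " telomeric probe")

  has_del <- !is.na(calls[vl]) && calls[vl] == 0L

  # whole-chromosome duplication: every probed locus on the chromosome >= 2
  whole <- character(0)
  for (ch in unique(probeset$chrom)) {
    on_ch <- probeset$chrom == ch
    if (ch == gcr_chrom) next  # the assay chromosome is structurally rearranged
    if (all(!is.na(calls[on_ch]) & calls[on_ch] >= 2L)) whole <- c(whole, ch)
  }

  arm_dup <- character(0)
  caveats <- character(0)
  for (i in which(tel)) {
    if (probeset$chrom[i] %in% whole) next
    if (!is.na(calls[i]) && calls[i] >= 2L) {
      armname <- paste0(probeset$chrom[i], "-", probeset$arm[i])
      arm_dup <- c(arm_dup, armname)
      if (probeset$placement_flag[i] == "FALLBACK_CENTROMERIC")
        caveats <- c(caveats, paste0(armname,
          ": duplication at fallback probe; terminal element(s) unprobed"))
    }
  }

  status <- if (any(flags %in% c("AMBIGUOUS", "MISSING"))) "AMBIGUOUS"
            else if (has_del && !length(arm_dup) && !length(whole)) "NO_DUPLICATION"
            else "CLASSIFIED"

  structure(list(isolate = NA_character_, has_chrV_L_deletion = has_del,
                 arm_duplications = arm_dup,
                 whole_chromosome_duplications = whole,
                 status = status, caveats = caveats),
            class = "isolate_classification")
}

#' Classify every isolate of a cohort
#'
#' Applies [classify_isolate()] to each row of one or more
#' `copy_number_matrix` objects (e.g. the telomeric and centromeric panel
#' runs of the same isolates) after aligning them on isolate ids.
#'
#' @param cn a `copy_number_matrix` or list of them sharing isolates.
#' @param gcr_chrom,gcr_arm see [classify_isolate()].
#' @return data.frame with one row per isolate: `isolate`,
#'   `has_chrV_L_deletion`, `arm_duplications` and
#'   `whole_chromosome_duplications` (comma-separated), `status`, `events`
#'   (compact `-chrV-L/+chrX-R/+chrVIII` notation), `caveats`.
#' @export
classify_cohort <- function(cn, gcr_chrom = "chrV", gcr_arm = "L") {
  if (inherits(cn, "copy_number_matrix")) cn <- list(cn)
  isolates <- rownames(cn[[1]]$ratio)
  for (m in cn) stopifnot(setequal(rownames(m$ratio), isolates))
  probeset <- do.call(rbind, lapply(cn, function(m) as.data.frame(m$probeset)))
  calls <- do.call(cbind, lapply(cn, function(m) m$call[isolates, , drop = FALSE]))
  flags <- do.call(cbind, lapply(cn, function(m) m$flag[isolates, , drop = FALSE]))

  rows <- lapply(isolates, function(id) {
    cl <- classify_isolate(calls[id, ], flags[id, ], probeset,
                           gcr_chrom = gcr_chrom, gcr_arm = gcr_arm)
    data.frame(
      isolate = id,
      has_chrV_L_deletion = cl$has_chrV_L_deletion,
      arm_duplications = paste(cl$arm_duplications, collapse = ","),
      whole_chromosome_duplications =
        paste(cl$whole_chromosome_duplications, collapse = ","),
      status = cl$status,
      events = event_notation(cl, gcr_chrom, gcr_arm),
      caveats = paste(cl$caveats, collapse = "; "),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# "-chrV-L/+chrXIII-L/+chrVIII" event string
event_notation <- function(cl, gcr_chrom, gcr_arm) {
  parts <- character(0)
  if (cl$has_chrV_L_deletion)
    parts <- c(parts, paste0("-", gcr_chrom, "-", gcr_arm))
  parts <- c(parts, paste0("+", cl$arm_duplications),
             paste0("+", cl$whole_chromosome_duplications))
  if (cl$status == "AMBIGUOUS") parts <- c(parts, "?")
  paste(parts, collapse = "/")
}

#' Localize an arm duplication breakpoint to candidate Ty targets
#'
#' Scans the arm-specific copy-number calls in centromere-to-telomere order
#' for the step from copy number 1 to >= 2.  The candidate recombination
#' targets are the annotated repeat elements lying strictly between the
#' last non-duplicated probe and the first duplicated probe.  Predicted
#' product geometry follows target orientation: all telomere-oriented
#' targets give a `MONOCENTRIC` product, all centromere-oriented targets a
#' `DICENTRIC_INTERMEDIATE`, otherwise `MIXED`.  Non-monotone call
#' profiles (more than one step) are flagged `COMPLEX` but still summarized
#' at their most centromeric step, as expected for products of dicentric
#' intermediates that underwent secondary rearrangements.
#'
#' @param arm_calls named integer vector of calls for the arm-specific
#'   panel, ordered centromere to telomere (the panel's design order).
#' @param arm_probeset the `ARM_SPECIFIC` `probe_set` (single arm).
#' @param ann the `genome_annotation`.
#' @return A `breakpoint_call`: list with `chrom`, `arm`,
#'   `first_dup_probe`, `flanking_probe`, `target_ids` (character; empty
#'   means no annotated element in the interval, reported as `UNKNOWN`),
#'   `geometry`, `validity`, `no_duplication`.
#' @export
localize_breakpoint <- function(arm_calls, arm_probeset, ann) {
  ps <- as.data.frame(arm_probeset)
  stopifnot(length(unique(ps$chrom)) == 1L, length(unique(ps$arm)) == 1L)
  calls <- arm_calls[match(ps$probe_id, names(arm_calls))]
  chrom <- ps$chrom[1L]; arm <- ps$arm[1L]

  dup <- !is.na(calls) & calls >= 2L
  if (!any(dup)) {
    return(structure(list(chrom = chrom, arm = arm,
                          first_dup_probe = NA_character_,
                          flanking_probe = NA_character_,
                          target_ids = character(0),
                          geometry = NA_character_, validity = NA_character_,
                          no_duplication = TRUE),
                     class = "breakpoint_call"))
  }
  k <- which(dup)[1L]
  flank <- if (k > 1L) ps$probe_id[k - 1L] else NA_character_

  # expected simple pattern: 1..1 then >=2 to the telomeric end
  expected <- c(rep(FALSE, k - 1L), rep(TRUE, length(calls) - k + 1L))
  validity <- if (identical(unname(dup), expected)) "SIMPLE" else "COMPLEX"

  # interval between the flanking probe (or centromere edge) and the first
  # duplicated probe, in chromosome coordinates
  a1 <- ps$anchor_bp[k]
  a0 <- if (k > 1L) ps$anchor_bp[k - 1L] else {
    cen <- ann$centromeres[ann$centromeres$chrom == chrom, ]
    if (arm == "R") cen$end else cen$start
  }
  lo <- min(a0, a1); hi <- max(a0, a1)
  el <- ann$elements
  inside <- el$chrom == chrom & el$arm == arm & el$start > lo & el$end < hi
  targets <- el[inside, , drop = FALSE]

  geometry <- if (!nrow(targets)) NA_character_
    else if (all(targets$orientation == "TELOMERE")) "MONOCENTRIC"
    else if (all(targets$orientation == "CENTROMERE")) "DICENTRIC_INTERMEDIATE"
    else "MIXED"

  structure(list(chrom = chrom, arm = arm,
                 first_dup_probe = ps$probe_id[k], flanking_probe = flank,
                 target_ids = targets$id, geometry = geometry,
                 validity = validity, no_duplication = FALSE),
            class = "breakpoint_call")
}

#' @export
print.breakpoint_call <- function(x, ...) {
  if (x$no_duplication) {
    cat("breakpoint_call:", x$chrom, x$arm, "- no duplication\n")
  } else {
    tg <- if (length(x$target_ids)) paste(x$target_ids, collapse = "/") else "UNKNOWN"
    cat("breakpoint_call:", paste0(x$chrom, "-", x$arm), "step at",
        x$first_dup_probe, "targets", tg,
        paste0("(", x$geometry, ", ", x$validity, ")\n"))
  }
  invisible(x)
}

#' Summarize a classified cohort
#'
#' Aggregates per-isolate classifications (and, optionally, breakpoint
#' calls) into the cohort-level counts used for hotspot statistics: the
#' number of assay deletions, duplication-bearing isolates, isolates with
#' no duplication, ambiguous isolates, per-arm duplication counts,
#' whole-chromosome duplication counts, and a per-arm table of predicted
#' recombination targets with the percentage of that arm's duplications
#' each target accounts for.
#'
#' @param classifications data.frame from [classify_cohort()].
#' @param breakpoints optional list of `breakpoint_call` objects (one per
#'   localized isolate).
#' @return A `cohort_summary` list: `n`, `n_chrV_L_deletion`,
#'   `n_arm_duplication` (isolates with >= 1 arm duplication),
#'   `n_no_duplication`, `n_ambiguous`, `arm_counts` (named vector),
#'   `whole_chromosome_counts`, `target_table` (data.frame `arm`, `targets`,
#'   `n`, `percent`).
#' @export
summarize_cohort <- function(classifications, breakpoints = NULL) {
  cl <- classifications
  if (!nrow(cl)) {
    return(structure(list(n = 0L, n_chrV_L_deletion = 0L,
                          n_arm_duplication = 0L, n_no_duplication = 0L,
                          n_ambiguous = 0L, arm_counts = integer(0),
                          whole_chromosome_counts = integer(0),
                          target_table = NULL),
                     class = "cohort_summary"))
  }
  amb <- cl$status == "AMBIGUOUS"
  arms <- strsplit(cl$arm_duplications[!amb], ",", fixed = TRUE)
  arms <- unlist(lapply(arms, function(x) x[nzchar(x)]))
  whole <- strsplit(cl$whole_chromosome_duplications[!amb], ",", fixed = TRUE)
  whole <- unlist(lapply(whole, function(x) x[nzchar(x)]))

  has_arm_dup <- !amb & nzchar(cl$arm_duplications)

  target_table <- NULL
  if (!is.null(breakpoints)) {
    bp <- Filter(function(b) !b$no_duplication, breakpoints)
    if (length(bp)) {
      df <- do.call(rbind, lapply(bp, function(b) data.frame(
        arm = paste0(b$chrom, "-", b$arm),
        targets = if (length(b$target_ids))
          paste(b$target_ids, collapse = "/") else "UNKNOWN",
        stringsAsFactors = FALSE)))
      agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                              by = df[, c("arm", "targets")], FUN = sum)
      arm_tot <- tapply(agg$n, agg$arm, sum)
      agg$percent <- 100 * agg$n / as.vector(arm_tot[agg$arm])
      agg <- agg[order(agg$arm, -agg$n), ]
      rownames(agg) <- NULL
      target_table <- agg
    }
  }

  structure(list(
    n = nrow(cl),
    n_chrV_L_deletion = sum(cl$has_chrV_L_deletion),
    n_arm_duplication = sum(has_arm_dup),
    n_no_duplication = sum(cl$status == "NO_DUPLICATION"),
    n_ambiguous = sum(amb),
    arm_counts = if (length(arms)) sort(table(arms), decreasing = TRUE)
                 else integer(0),
    whole_chromosome_counts = if (length(whole)) table(whole) else integer(0),
    target_table = target_table
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort_summary: n =", x$n, "\n")
  cat("  chrV-L deletions:     ", x$n_chrV_L_deletion, "\n")
  cat("  arm duplications:     ", x$n_arm_duplication, "\n")
  cat("  no duplication:       ", x$n_no_duplication, "\n")
  cat("  ambiguous:            ", x$n_ambiguous, "\n")
  if (length(x$whole_chromosome_counts))
    cat("  whole-chromosome dups:",
        paste(names(x$whole_chromosome_counts), x$whole_chromosome_counts,
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$target_table)) {
    cat("  breakpoint targets:\n")
    print(x$target_table, row.names = FALSE)
  }
  invisible(x)
}

#' Write classification report TSV
#'
#' @param classifications data.frame from [classify_cohort()].
#' @param path output path.
#' @export
write_classification <- function(classifications, path) {
  utils::write.table(classifications, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
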