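#' Design an MLPA probe panel from a genome annotation
#'
#' Places ligation-probe anchor points in unique (repeat-free) windows of the
#' genome.  Because the package carries no sequence, "unique sequence
#' suitable for a probe" is abstracted to a window of at least `min_window`
#' bp containing no repeat element.
#'
#' Three panel roles are supported:
#' \describe{
#'   \item{TELOMERIC}{one probe per chromosome arm, placed between the most
#'     telomere-distal repeat element and the telomere.  When that window is
#'     shorter than `min_window` the probe is instead placed immediately
#'     centromeric to the terminal element(s) and flagged
#'     `FALLBACK_CENTROMERIC`; duplications bounded by the skipped terminal
#'     element(s) are then invisible to the panel.}
#'   \item{CENTROMERIC}{one probe per arm, centromeric to the arm's
#'     innermost repeat element, so that a terminal arm duplication never
#'     covers it.  Used together with the telomeric panel to call
#'     whole-chromosome duplications.}
#'   \item{ARM_SPECIFIC}{one probe in every inter-element gap along a single
#'     arm, including the (centromere, innermost element) and (outermost
#'     element, telomere) gaps.  Elements closer than `collocate` bp are
#'     treated as one cluster sharing flanking probes.}
#' }
#'
#' @param ann a `genome_annotation`.
#' @param role `"TELOMERIC"`, `"CENTROMERIC"` or `"ARM_SPECIFIC"`.
#' @param chrom,arm chromosome name and arm ("L"/"R"); required for
#'   `ARM_SPECIFIC`, ignored otherwise.
#' @param min_window minimum repeat-free window (bp) accepted for a probe
#'   (default 300).
#' @param collocate gap threshold (bp) below which adjacent elements share
#'   one flanking probe (default 1000).
#' @param start_length,min_gap passed to [assign_product_lengths()];
#'   amplification products start at `start_length` bp and adjacent product
#'   lengths differ by at least `min_gap` bp (default 2).
#' @return A `probe_set`: data.frame with columns `probe_id`, `chrom`, `arm`,
#'   `anchor_bp`, `role`, `product_length_bp`, `placement_flag`.
#' @export
design_probe_set <- function(ann, role = c("TELOMERIC", "CENTROMERIC",
                                           "ARM_SPECIFIC"),
                             chrom = NULL, arm = NULL,
                             min_window = 300, collocate = 1000,
                             start_length = 100L, min_gap = 2L) {
  role <- match.arg(role)
  arms <- arm_table(ann)
  if (role == "ARM_SPECIFIC") {
    if (is.null(chrom) || is.null(arm))
      stop("ARM_SPECIFIC design requires 'chrom' and 'arm'")
    arms <- arms[arms$chrom == chrom & arms$arm == arm, , drop = FALSE]
    if (!nrow(arms)) stop("unknown arm: ", chrom, "-", arm)
  }

  rows <- list()
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    tel <- ann$telomeres[ann$telomeres$chrom == a$chrom &
                           ann$telomeres$side == a$arm, ]
    # usable arm interval excludes the telomere repeat tract itself
    lo <- a$start; hi <- a$end
    if (nrow(tel)) {
      if (a$arm == "L") lo <- max(lo, tel$end + 1L) else hi <- min(hi, tel$start - 1L)
    }
    el <- ann$elements[ann$elements$chrom == a$chrom &
                         ann$elements$arm == a$arm, , drop = FALSE]
    # order centromere -> telomere
    el <- el[order(el$start, decreasing = (a$arm == "L")), , drop = FALSE]

    placed <- switch(role,
      TELOMERIC = place_telomeric(a, lo, hi, el, min_window),
      CENTROMERIC = place_centromeric(a, lo, hi, el, min_window),
      ARM_SPECIFIC = place_arm_specific(a, lo, hi, el, min_window, collocate)
    )
    rows[[i]] <- placed
  }
  probes <- do.call(rbind, rows)
  probes$role <- role
  # deterministic order: chromosome, L before R, centromere->telomere
  co <- chrom_order(ann$chromosomes$chrom)
  probes <- probes[order(match(probes$chrom, ann$chromosomes$chrom[co]),
                         match(probes$arm, c("L", "R")),
                         probes$within_arm_rank), , drop = FALSE]
  probes$within_arm_rank <- NULL
  probes$probe_id <- make_probe_ids(probes, role)
  rownames(probes) <- NULL
  assign_product_lengths(probes, start_length = start_length,
                         min_gap = min_gap)
}

make_probe_ids <- function(probes, role) {
  base <- paste0(probes$chrom, "-", probes$arm)
  if (role == "ARM_SPECIFIC") {
    idx <- stats::ave(seq_len(nrow(probes)), base, FUN = seq_along)
    sprintf("%s_arm%02d", base, idx)
  } else {
    paste0(base, "_", tolower(substr(role, 1, 3)))
  }
}

# telomeric placement for one arm; returns a one-row skeleton data.frame
place_telomeric <- function(a, lo, hi, el, min_window) {
  skel <- function(anchor, flag, rank = 1L)
    data.frame(probe_id = NA_character_, chrom = a$chrom, arm = a$arm,
               anchor_bp = as.integer(round(anchor)), placement_flag = flag,
               within_arm_rank = rank, stringsAsFactors = FALSE)
  if (!nrow(el)) return(skel((lo + hi) / 2, "PREFERRED"))
  # window between the most distal element and the telomere
  if (a$arm == "R") {
    w_lo <- max(el$end) + 1L; w_hi <- hi
  } else {
    w_lo <- lo; w_hi <- min(el$start) - 1L
  }
  if (w_hi - w_lo + 1L >= min_window)
    return(skel((w_lo + w_hi) / 2, "PREFERRED"))
  # fallback: walk centromeric past terminal elements until a gap fits
  # el is ordered cen->tel; scan gaps from the telomeric end inward
  n <- nrow(el)
  for (k in seq(n, 1L)) {
    if (k == 1L) {
      g_lo <- if (a$arm == "R") lo else el$end[1L] + 1L
      g_hi <- if (a$arm == "R") el$start[1L] - 1L else hi
    } else {
      if (a$arm == "R") { g_lo <- el$end[k - 1L] + 1L; g_hi <- el$start[k] - 1L }
      else { g_lo <- el$end[k] + 1L; g_hi <- el$start[k - 1L] - 1L }
    }
    if (g_hi - g_lo + 1L >= min_window) {
      # sit immediately centromeric to the skipped element(s): anchor at the
      # telomeric end of this gap
      anchor <- if (a$arm == "R") g_hi - min_window / 2 else g_lo + min_window / 2
      return(skel(anchor, "FALLBACK_CENTROMERIC"))
    }
  }
  stop("no placeable telomeric probe window on arm ", a$chrom, "-", a$arm)
}

place_centromeric <- function(a, lo, hi, el, min_window) {
  if (!nrow(el)) {
    anchor <- (lo + hi) / 2
  } else {
    if (a$arm == "R") { g_lo <- lo; g_hi <- min(el$start) - 1L }
    else { g_lo <- max(el$end) + 1L; g_hi <- hi }
    if (g_hi - g_lo + 1L < min_window)
      stop("no placeable centromeric probe window on arm ", a$chrom, "-", a$arm)
    anchor <- (g_lo + g_hi) / 2
  }
  data.frame(probe_id = NA_character_, chrom = a$chrom, arm = a$arm,
             anchor_bp = as.integer(round(anchor)),
             placement_flag = "PREFERRED", within_arm_rank = 1L,
             stringsAsFactors = FALSE)
}

# cluster elements closer than `collocate` and put one probe per usable gap
place_arm_specific <- function(a, lo, hi, el, min_window, collocate) {
  if (!nrow(el)) {
    return(data.frame(probe_id = NA_character_, chrom = a$chrom, arm = a$arm,
                      anchor_bp = as.integer(round((lo + hi) / 2)),
                      placement_flag = "PREFERRED", within_arm_rank = 1L,
                      stringsAsFactors = FALSE))
  }
  # el ordered cen->tel; build clusters along that direction
  cl <- integer(nrow(el))
  cl[1L] <- 1L
  if (nrow(el) > 1L) for (k in 2L:nrow(el)) {
    gap <- if (a$arm == "R") el$start[k] - el$end[k - 1L] - 1L
           else el$start[k - 1L] - el$end[k] - 1L
    cl[k] <- if (gap < collocate) cl[k - 1L] else cl[k - 1L] + 1L
  }
  ncl <- max(cl)
  # cluster extents in cen->tel direction
  cen_edge <- vapply(seq_len(ncl), function(j) {
    if (a$arm == "R") min(el$start[cl == j]) else max(el$end[cl == j])
  }, numeric(1))
  tel_edge <- vapply(seq_len(ncl), function(j) {
    if (a$arm == "R") max(el$end[cl == j]) else min(el$start[cl == j])
  }, numeric(1))

  anchors <- numeric(0)
  for (g in seq_len(ncl + 1L)) {
    if (a$arm == "R") {
      g_lo <- if (g == 1L) lo else tel_edge[g - 1L] + 1L
      g_hi <- if (g == ncl + 1L) hi else cen_edge[g] - 1L
    } else {
      g_hi <- if (g == 1L) hi else tel_edge[g - 1L] - 1L
      g_lo <- if (g == ncl + 1L) lo else cen_edge[g] + 1L
    }
    if (g_hi - g_lo + 1L >= min_window)
      anchors <- c(anchors, (g_lo + g_hi) / 2)
  }
  if (!length(anchors))
    stop("no placeable arm-specific probe window on arm ", a$chrom, "-", a$arm)
  # order anchors cen->tel
  anchors <- sort(anchors, decreasing = (a$arm == "L"))
  data.frame(probe_id = NA_character_, chrom = a$chrom, arm = a$arm,
             anchor_bp = as.integer(round(anchors)),
             placement_flag = "PREFERRED",
             within_arm_rank = seq_along(anchors), stringsAsFactors = FALSE)
}

#' Assign unique amplification-product lengths to probes
#'
#' Product lengths identify probes on the capillary trace, so they must be
#' unique and separated by a minimum gap (2 bp by default).  Assignment is
#' deterministic: probes are taken in panel order (chromosome, then arm L
#' before R, then centromere-to-telomere within an arm) and given the
#' arithmetic sequence `start_length, start_length + min_gap, ...`.
#'
#' @param probes a `probe_set` or skeleton data.frame of probes.
#' @param start_length product length (bp) of the first probe; must be > 0.
#' @param min_gap minimum difference (bp) between adjacent product lengths;
#'   must be >= 1.
#' @return The `probe_set` with `product_length_bp` filled in.
#' @export
assign_product_lengths <- function(probes, start_length = 100L, min_gap = 2L) {
  stopifnot(start_length > 0, min_gap >= 1)
  probes <- as.data.frame(probes)
  probes$product_length_bp <-
    as.integer(start_length + min_gap * (seq_len(nrow(probes)) - 1L))
  probes <- probes[, c("probe_id", "chrom", "arm", "anchor_bp", "role",
                       "product_length_bp", "placement_flag")]
  class(probes) <- c("probe_set", "data.frame")
  attr(probes, "min_gap") <- as.integer(min_gap)
  probes
}

#' Theoretical target coverage of a telomeric probe panel
#'
#' A catalog target is detectable ("covered") by the panel iff its arm's
#' telomeric probe lies telomeric to the target, so that a duplication
#' bounded by the target also duplicates the probe locus.  Probes placed
#' with the `FALLBACK_CENTROMERIC` flag sit centromeric to the terminal
#' element(s) of their arm and therefore do not cover them.
#'
#' @param catalog a `target_catalog` (typically `TY1_PLUS_DELTA` mode).
#' @param probeset a TELOMERIC `probe_set` over the same annotation.
#' @return list with `covered`, `total`, and `percent`
#'   (`100 * covered / total`, rounded to 1 decimal).
#' @export
theoretical_coverage <- function(catalog, probeset) {
  if (!inherits(probeset, "probe_set") || probeset$role[1] != "TELOMERIC")
    stop("theoretical_coverage requires a TELOMERIC probe_set")
  tg <- catalog$targets
  if (!nrow(tg)) stop("empty target catalog")
  key <- paste(tg$chrom, tg$arm)
  pkey <- paste(probeset$chrom, probeset$arm)
  idx <- match(key, pkey)
  if (anyNA(idx))
    stop("probe panel does not cover arm(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  anchor <- probeset$anchor_bp[idx]
  covered <- ifelse(tg$arm == "R", anchor > tg$end, anchor < tg$start)
  list(covered = sum(covered), total = nrow(tg),
       percent = round(100 * sum(covered) / nrow(tg), 1))
}

#' Read / write probe-set TSV
#'
#' Probe panels are exchanged as tab-separated tables with columns
#' `probe_id`, `chrom`, `arm`, `anchor_bp`, `role`, `product_length_bp`,
#' `placement_flag`.
#'
#' @param path file path.
#' @return `read_probe_set` returns a `probe_set`; `write_probe_set` returns
#'   `path` invisibly.
#' @export
read_probe_set <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "arm", "anchor_bp", "role",
            "product_length_bp", "placement_flag")
  if (!all(need %in% names(p)))
    stop("probe TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(p$product_length_bp))
    stop("duplicated product lengths in probe set")
  class(p) <- c("probe_set", "data.frame")
  p
}

#' @rdname read_probe_set
#' @param probeset a `probe_set`.
#' @export
write_probe_set <- function(probeset, path) {
  utils::write.table(as.data.frame(probeset), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
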