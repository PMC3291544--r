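#' Match capillary peaks to a probe panel
#'
#' Peaks are matched to panel probes by nearest product length within
#' +/- `size_tolerance` bp; peaks matching no probe are dropped with a
#' warning, and two peaks claiming the same probe within one sample is an
#' error.
#'
#' @param peaks data.frame with columns `sample_id`, `size_bp`, `area` (and
#'   optionally `height`, `is_control`).
#' @param probeset a `probe_set`.
#' @param size_tolerance maximum |size - product length| accepted (default 1).
#' @return data.frame `sample_id`, `probe_id`, `area` (one row per matched
#'   peak).
#' @export
match_peaks <- function(peaks, probeset, size_tolerance = 1) {
  stopifnot(all(c("sample_id", "size_bp", "area") %in% names(peaks)))
  if (any(peaks$area < 0)) stop("negative peak area")
  d <- abs(outer(peaks$size_bp, probeset$product_length_bp, "-"))
  j <- apply(d, 1L, which.min)
  ok <- d[cbind(seq_len(nrow(peaks)), j)] <= size_tolerance
  if (any(!ok))
    warning(sum(!ok), " peak(s) matched no probe and were ignored")
  out <- data.frame(sample_id = peaks$sample_id[ok],
                    probe_id = probeset$probe_id[j[ok]],
                    area = peaks$area[ok], stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("sample_id", "probe_id")])
  if (any(dup))
    stop("multiple peaks matched to probe(s) ",
         paste(unique(out$probe_id[dup]), collapse = ", "),
         " within one sample")
  out
}

#' Within-sample normalization of peak areas
#'
#' Two schemes are provided.  `GLOBAL_SUM` divides each probe's raw area by
#' the total area of all probes in the sample, making values invariant to
#' per-sample amplification/loading scale; it is the scheme used for the
#' genome-wide telomeric and centromeric panels.  `ANCHOR` divides every
#' probe by the most centromeric probe of the panel (or an explicit
#' `anchor`), on the assumption that the anchor locus is never duplicated;
#' it is used for arm-specific panels where a duplication can span a large
#' fraction of the probes and would distort the global sum.
#'
#' @param areas named numeric vector of raw areas (names = probe ids), or a
#'   data.frame with `probe_id` and `area`.
#' @param probeset the `probe_set`, used to determine panel order and the
#'   default anchor (most centromeric probe = first in
#'   centromere-to-telomere order).
#' @param mode `"GLOBAL_SUM"` or `"ANCHOR"`.
#' @param anchor probe id of the anchor for `ANCHOR` mode; defaults to the
#'   panel's most centromeric probe.
#' @return Named numeric vector of normalized values in panel order; probes
#'   with no peak are `NA`.
#' @export
normalize_within_sample <- function(areas, probeset,
                                    mode = c("GLOBAL_SUM", "ANCHOR"),
                                    anchor = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(areas)) {
    v <- areas$area
    names(v) <- areas$probe_id
    areas <- v
  }
  x <- areas[match(probeset$probe_id, names(areas))]
  names(x) <- probeset$probe_id
  if (sum(!is.na(x)) < 2L) stop("need at least 2 matched probes per sample")
  if (mode == "GLOBAL_SUM") {
    tot <- sum(x, na.rm = TRUE)
    if (tot <= 0) stop("zero total peak area in sample")
    return(x / tot)
  }
  if (is.null(anchor)) {
    # most centromeric probe: smallest distance from its arm's centromere.
    # For a single-arm panel in design order the first probe is the most
    # centromeric one.
    anchor <- probeset$probe_id[1L]
  }
  a <- x[[anchor]]
  if (is.na(a) || a <= 0) stop("anchor probe '", anchor, "' has no usable area")
  x / a
}

#' Call integer copy numbers for a set of samples against controls
#'
#' Implements the two-step MLPA quantification: raw areas are first
#' normalized within each sample ([normalize_within_sample()]), then each
#' probe value is divided by the mean normalized value of that probe over
#' the control samples, giving a dimensionless dosage ratio whose
#' expectation equals the locus copy number when controls are euploid.
#' Copy number is the nearest integer (ties at .5 round half away from
#' zero); a cell is flagged `AMBIGUOUS` when the ratio deviates from its
#' nearest integer by more than `tolerance`, and `MISSING` when the sample
#' shows no peak for the probe.
#'
#' @param peaks long data.frame of peaks (`sample_id`, `size_bp`, `area`,
#'   `is_control` logical), as read by [read_peak_table()] or simulated by
#'   [simulate_peaks()].
#' @param probeset the `probe_set` the peaks were generated with.
#' @param mode,anchor normalization scheme, see [normalize_within_sample()].
#' @param tolerance maximum |ratio - round(ratio)| for an unambiguous call
#'   (default 0.3).
#' @param size_tolerance peak-to-probe matching window, see [match_peaks()].
#' @return A `copy_number_matrix`: list with matrices `ratio`, `call`,
#'   `flag` (isolates x probes; controls excluded), the `probeset`, and the
#'   control sample ids.
#' @export
call_copy_numbers <- function(peaks, probeset,
                              mode = c("GLOBAL_SUM", "ANCHOR"),
                              anchor = NULL, tolerance = 0.3,
                              size_tolerance = 1) {
  mode <- match.arg(mode)
  stopifnot("is_control" %in% names(peaks))
  m <- match_peaks(peaks, probeset, size_tolerance)
  ctrl_ids <- unique(peaks$sample_id[peaks$is_control])
  if (!length(ctrl_ids)) stop("no control samples in peak table")
  samp_ids <- setdiff(unique(peaks$sample_id), ctrl_ids)

  norm_one <- function(sid) {
    normalize_within_sample(m[m$sample_id == sid, c("probe_id", "area")],
                            probeset, mode = mode, anchor = anchor)
  }
  ctrl <- do.call(rbind, lapply(ctrl_ids, norm_one))
  ctrl_mean <- colMeans(ctrl, na.rm = TRUE)
  bad <- is.na(ctrl_mean) | ctrl_mean <= 0
  if (any(bad))
    stop("control mean is zero/undefined for probe(s): ",
         paste(probeset$probe_id[bad], collapse = ", "))

  n <- length(samp_ids)
  p <- nrow(probeset)
  ratio <- matrix(NA_real_, n, p,
                  dimnames = list(samp_ids, probeset$probe_id))
  for (sid in samp_ids) ratio[sid, ] <- norm_one(sid) / ctrl_mean

  call <- round_half_away(ratio)
  call[!is.na(call) & call < 0] <- 0L
  flag <- matrix("OK", n, p, dimnames = dimnames(ratio))
  flag[is.na(ratio)] <- "MISSING"
  dev <- abs(ratio - call)
  flag[!is.na(dev) & dev > tolerance] <- "AMBIGUOUS"

  structure(list(ratio = ratio, call = call, flag = flag,
                 probeset = probeset, controls = ctrl_ids,
                 mode = mode, tolerance = tolerance),
            class = "copy_number_matrix")
}

# round half away from zero (R's round() rounds half to even)
round_half_away <- function(x) {
  out <- sign(x) * floor(abs(x) + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' @export
print.copy_number_matrix <- function(x, ...) {
  cat("copy_number_matrix:", nrow(x$ratio), "isolates x", ncol(x$ratio),
      "probes (", x$mode, "normalization,", length(x$controls), "controls )\n")
  fl <- table(x$flag)
  cat("  flags:", paste(names(fl), fl, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a copy-number matrix as TSV
#'
#' One row per isolate x probe with the normalized ratio, integer call and
#' QC flag.
#'
#' @param cn a `copy_number_matrix`.
#' @param path output path.
#' @export
write_copy_number_matrix <- function(cn, path) {
  long <- expand.grid(isolate = rownames(cn$ratio),
                      probe_id = colnames(cn$ratio),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$ratio <- as.vector(cn$ratio)
  long$call <- as.vector(cn$call)
  long$flag <- as.vector(cn$flag)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
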