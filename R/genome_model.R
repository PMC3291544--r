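#' Construct a validated genome annotation
#'
#' A `genome_annotation` bundles chromosome sizes, centromere and telomere
#' intervals, and the repeat elements (full-length Ty1/Ty2 retrotransposons
#' and solo delta LTRs) that act as potential translocation targets.  All
#' coordinates are 1-based and inclusive (SGD convention).
#'
#' Each element is assigned to the chromosome arm (`L` or `R`) flanking the
#' centromere that fully contains it.  Element `orientation` is its
#' transcriptional direction relative to the arm's telomere: `TELOMERE` means
#' transcription points toward the nearer telomere, `CENTROMERE` toward the
#' centromere.  Orientation matters because a translocation into a
#' centromere-oriented element produces a dicentric intermediate whereas a
#' telomere-oriented element yields a stable monocentric product.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`.
#' @param centromeres data.frame with columns `chrom`, `start`, `end`.
#' @param telomeres data.frame with columns `chrom`, `side` ("L"/"R"),
#'   `start`, `end`.  If `NULL`, default 1 bp telomere points at the
#'   chromosome ends are used.
#' @param elements data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `class` (`TY1`, `TY2`, `SOLO_DELTA`) and `orientation` (`TELOMERE`,
#'   `CENTROMERE`).  May have zero rows.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, centromeres, telomeres = NULL,
                              elements = NULL) {
  chromosomes <- as.data.frame(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes <- chromosomes[chrom_order(chromosomes$chrom), , drop = FALSE]
  rownames(chromosomes) <- NULL

  centromeres <- as.data.frame(centromeres)
  stopifnot(all(c("chrom", "start", "end") %in% names(centromeres)))

  if (is.null(telomeres)) {
    telomeres <- rbind(
      data.frame(chrom = chromosomes$chrom, side = "L", start = 1L, end = 1L),
      data.frame(chrom = chromosomes$chrom, side = "R",
                 start = chromosomes$length, end = chromosomes$length)
    )
  }
  telomeres <- as.data.frame(telomeres)

  if (is.null(elements) || nrow(as.data.frame(elements)) == 0L) {
    elements <- data.frame(id = character(), chrom = character(),
                           arm = character(), start = integer(),
                           end = integer(), class = character(),
                           orientation = character(),
                           stringsAsFactors = FALSE)
  } else {
    elements <- as.data.frame(elements)
  }

  ann <- structure(
    list(chromosomes = chromosomes, centromeres = centromeres,
         telomeres = telomeres, elements = elements),
    class = "genome_annotation"
  )
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  chroms <- ann$chromosomes
  cen <- ann$centromeres
  tel <- ann$telomeres
  el <- ann$elements

  if (anyDuplicated(chroms$chrom))
    stop("duplicated chromosome names in annotation")
  missing_cen <- setdiff(chroms$chrom, cen$chrom)
  if (length(missing_cen))
    stop("no centromere for chromosome(s): ", paste(missing_cen, collapse = ", "))

  for (i in seq_len(nrow(cen))) {
    len <- chroms$length[match(cen$chrom[i], chroms$chrom)]
    if (is.na(len)) stop("centromere on unknown chromosome: ", cen$chrom[i])
    if (cen$start[i] <= 1 || cen$end[i] >= len || cen$start[i] > cen$end[i])
      stop("centromere not strictly inside chromosome: ", cen$chrom[i])
  }

  for (i in seq_len(nrow(tel))) {
    len <- chroms$length[match(tel$chrom[i], chroms$chrom)]
    if (is.na(len)) stop("telomere on unknown chromosome: ", tel$chrom[i])
    if (tel$start[i] < 1 || tel$end[i] > len)
      stop("telomere outside chromosome: ", tel$chrom[i], "-", tel$side[i])
    ci <- cen[cen$chrom == tel$chrom[i], ]
    if (tel$end[i] >= ci$start && tel$start[i] <= ci$end)
      stop("telomere overlaps centromere on ", tel$chrom[i])
  }

  if (nrow(el)) {
    if (anyDuplicated(el$id))
      stop("duplicated element id(s): ",
           paste(unique(el$id[duplicated(el$id)]), collapse = ", "))
    bad_class <- !el$class %in% ELEMENT_CLASSES
    if (any(bad_class))
      stop("unknown element class for record(s): ",
           paste(el$id[bad_class], collapse = ", "))
    bad_ori <- !el$orientation %in% ORIENTATIONS
    if (any(bad_ori))
      stop("unknown orientation for record(s): ",
           paste(el$id[bad_ori], collapse = ", "))
    len <- chroms$length[match(el$chrom, chroms$chrom)]
    out <- is.na(len) | el$start < 1 | el$end > len | el$start > el$end
    if (any(out))
      stop("element outside its chromosome: ",
           paste(el$id[out], collapse = ", "))
    # assign arms if absent, check if present
    arm <- character(nrow(el))
    for (i in seq_len(nrow(el))) {
      ci <- cen[cen$chrom == el$chrom[i], ]
      if (el$end[i] < ci$start) arm[i] <- "L"
      else if (el$start[i] > ci$end) arm[i] <- "R"
      else stop("element overlaps centromere: ", el$id[i])
    }
    el$arm <- arm
    # sort by chromosome then coordinate
    el <- el[order(match(el$chrom, chroms$chrom), el$start), , drop = FALSE]
    rownames(el) <- NULL
    ann$elements <- el[, c("id", "chrom", "arm", "start", "end",
                           "class", "orientation")]
  }
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$elements), "repeat elements\n")
  if (nrow(x$elements)) {
    tab <- table(x$elements$class)
    cat("  ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Arm intervals of an annotation
#'
#' Returns one row per chromosome arm with the interval between the
#' centromere and the telomere-proximal chromosome end.
#'
#' @param ann a `genome_annotation`.
#' @return data.frame with columns `chrom`, `arm`, `start`, `end`.
#' @export
arm_table <- function(ann) {
  chroms <- ann$chromosomes
  out <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    ci <- ann$centromeres[ann$centromeres$chrom == chroms$chrom[i], ]
    data.frame(chrom = chroms$chrom[i], arm = c("L", "R"),
               start = c(1L, ci$end + 1L),
               end = c(ci$start - 1L, chroms$length[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# strand -> orientation convention: on a right arm "+" transcribes toward the
# right telomere; on a left arm "-" transcribes toward the left telomere.
strand_to_orientation <- function(strand, arm) {
  ifelse((arm == "R") == (strand == "+"), "TELOMERE", "CENTROMERE")
}

orientation_to_strand <- function(orientation, arm) {
  ifelse((orientation == "TELOMERE") == (arm == "R"), "+", "-")
}

#' Load a genome annotation from disk
#'
#' Two dialects are supported.  `tsv` reads a simplified element table
#' (columns `chrom`, `start`, `end`, `class`, `orientation`, `id`) together
#' with companion tables for chromosome sizes, centromeres and optional
#' telomeres.  `gff3` reads a GFF3 file carrying `centromere`, `telomere`,
#' `LTR_retrotransposon` (attribute `class=Ty1|Ty2`) and
#' `long_terminal_repeat` (solo delta) features; element orientation is taken
#' from the strand column under the convention that "+" on a right arm (and
#' "-" on a left arm) is telomere-oriented.
#'
#' @param path path to the element TSV or the GFF3 file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param chrom_sizes for `dialect = "tsv"`, path to a two-column TSV
#'   (`chrom`, `length`); for `gff3` sizes come from `##sequence-region`
#'   pragmas or region features.
#' @param centromeres for `dialect = "tsv"`, path to a TSV with `chrom`,
#'   `start`, `end`.
#' @param telomeres optional TSV path (`chrom`, `side`, `start`, `end`).
#' @return A `genome_annotation`.
#' @export
read_genome_annotation <- function(path, dialect = c("tsv", "gff3"),
                                   chrom_sizes = NULL, centromeres = NULL,
                                   telomeres = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "tsv") {
    read_annotation_tsv(path, chrom_sizes, centromeres, telomeres)
  } else {
    read_annotation_gff3(path)
  }
}

read_annotation_tsv <- function(path, chrom_sizes, centromeres, telomeres) {
  if (is.null(chrom_sizes) || is.null(centromeres))
    stop("tsv dialect requires 'chrom_sizes' and 'centromeres' companion files")
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "class", "orientation", "id")
  if (!all(need %in% names(el)))
    stop("element TSV must have columns: ", paste(need, collapse = ", "))
  chroms <- utils::read.delim(chrom_sizes, stringsAsFactors = FALSE)
  cen <- utils::read.delim(centromeres, stringsAsFactors = FALSE)
  tel <- if (!is.null(telomeres))
    utils::read.delim(telomeres, stringsAsFactors = FALSE) else NULL
  genome_annotation(chroms, cen, tel, el)
}

read_annotation_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the 'rtracklayer' package")
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  g$seqid <- as.character(g$seqid)
  g$type <- as.character(g$type)
  g$strand <- as.character(g$strand)

  # chromosome sizes from ##sequence-region pragmas
  lines <- readLines(path)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(sr)) stop("GFF3 lacks ##sequence-region pragmas")
  parts <- strsplit(trimws(sr), "\\s+")
  chroms <- data.frame(
    chrom = vapply(parts, `[[`, "", 2L),
    length = as.integer(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )

  cen <- g[g$type == "centromere", c("seqid", "start", "end")]
  names(cen) <- c("chrom", "start", "end")
  telg <- g[g$type == "telomere", , drop = FALSE]
  tel <- NULL
  if (nrow(telg)) {
    cen_start <- cen$start[match(telg$seqid, cen$chrom)]
    tel <- data.frame(chrom = telg$seqid,
                      side = ifelse(telg$end < cen_start, "L", "R"),
                      start = telg$start, end = telg$end,
                      stringsAsFactors = FALSE)
  }

  elg <- g[g$type %in% c("LTR_retrotransposon", "long_terminal_repeat"), ,
           drop = FALSE]
  el <- NULL
  if (nrow(elg)) {
    cls <- ifelse(elg$type == "long_terminal_repeat", "SOLO_DELTA",
                  ifelse(!is.null(elg$class) & !is.na(elg$class) &
                           elg$class == "Ty2", "TY2", "TY1"))
    cen_start <- cen$start[match(elg$seqid, cen$chrom)]
    cen_end <- cen$end[match(elg$seqid, cen$chrom)]
    arm <- ifelse(elg$end < cen_start, "L",
                  ifelse(elg$start > cen_end, "R", NA))
    id <- if ("ID" %in% names(elg)) as.character(elg$ID) else
      paste0("el", seq_len(nrow(elg)))
    el <- data.frame(id = id, chrom = elg$seqid, start = elg$start,
                     end = elg$end, class = cls,
                     orientation = strand_to_orientation(elg$strand, arm),
                     stringsAsFactors = FALSE)
  }
  genome_annotation(chroms, cen, tel, el)
}

#' Write a genome annotation to disk
#'
#' Inverse of [read_genome_annotation()].  The `tsv` dialect writes the
#' element table to `path` and companion tables next to it
#' (`<path>.sizes.tsv`, `<path>.cen.tsv`, `<path>.tel.tsv`); `gff3` writes a
#' single GFF3 file with `##sequence-region` pragmas.
#'
#' @param ann a `genome_annotation`.
#' @param path output path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.  For `tsv` the companion paths are attached as
#'   attributes `chrom_sizes`, `centromeres`, `telomeres`.
#' @export
write_genome_annotation <- function(ann, path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    el <- ann$elements[, c("chrom", "start", "end", "class", "orientation", "id")]
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
    sizes <- paste0(path, ".sizes.tsv")
    cenp <- paste0(path, ".cen.tsv")
    telp <- paste0(path, ".tel.tsv")
    utils::write.table(ann$chromosomes, sizes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ann$centromeres, cenp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ann$telomeres, telp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- path
    attr(out, "chrom_sizes") <- sizes
    attr(out, "centromeres") <- cenp
    attr(out, "telomeres") <- telp
    return(invisible(out))
  }
  # gff3
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(ann$chromosomes)))
    writeLines(sprintf("##sequence-region %s 1 %d",
                       ann$chromosomes$chrom[i], ann$chromosomes$length[i]), con)
  row9 <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\tmlpaGCR\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attrs)
  cen <- ann$centromeres
  for (i in seq_len(nrow(cen)))
    writeLines(row9(cen$chrom[i], "centromere", cen$start[i], cen$end[i], ".",
                    sprintf("ID=CEN_%s", cen$chrom[i])), con)
  tel <- ann$telomeres
  for (i in seq_len(nrow(tel)))
    writeLines(row9(tel$chrom[i], "telomere", tel$start[i], tel$end[i], ".",
                    sprintf("ID=TEL_%s_%s", tel$chrom[i], tel$side[i])), con)
  el <- ann$elements
  for (i in seq_len(nrow(el))) {
    type <- if (el$class[i] == "SOLO_DELTA") "long_terminal_repeat"
            else "LTR_retrotransposon"
    attrs <- sprintf("ID=%s", el$id[i])
    if (el$class[i] != "SOLO_DELTA")
      attrs <- paste0(attrs, ";class=",
                      if (el$class[i] == "TY2") "Ty2" else "Ty1")
    strand <- orientation_to_strand(el$orientation[i], el$arm[i])
    writeLines(row9(el$chrom[i], type, el$start[i], el$end[i], strand, attrs),
               con)
  }
  invisible(path)
}

#' Build the catalog of potential Ty-mediated translocation targets
#'
#' Enumerates the repeat elements that can serve as homology targets for a
#' Ty-mediated nonreciprocal translocation.  In `TY1_ONLY` mode only
#' full-length Ty1 elements count (one target each).  In `TY1_PLUS_DELTA`
#' mode Ty1 and solo delta elements each count once and every Ty2 element
#' contributes two separate delta targets, one at each LTR end of the
#' element, because the Ty2 LTRs carry most of the Ty1-Ty2 homology.
#'
#' @param ann a `genome_annotation`.
#' @param mode `"TY1_PLUS_DELTA"` (default) or `"TY1_ONLY"`.
#' @param orientation_filter `"ALL"` or `"TELOMERE_ORIENTED"` to keep only
#'   telomere-oriented targets (those yielding monocentric products).
#' @param ty2_ltr_length length in bp of the Ty2 terminal repeats used to
#'   place the two expanded delta targets (default 334).
#' @return An object of class `target_catalog` with components `targets`
#'   (data.frame: `target_id`, `element_id`, `chrom`, `arm`, `start`, `end`,
#'   `class`, `orientation`), `per_arm` (counts per chromosome arm over all
#'   arms of the annotation), `total`, `mode`, `orientation_filter`.
#' @export
build_target_catalog <- function(ann, mode = c("TY1_PLUS_DELTA", "TY1_ONLY"),
                                 orientation_filter = c("ALL", "TELOMERE_ORIENTED"),
                                 ty2_ltr_length = 334L) {
  mode <- match.arg(mode)
  orientation_filter <- match.arg(orientation_filter)
  el <- ann$elements

  rows <- list()
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    if (mode == "TY1_ONLY") {
      if (e$class != "TY1") next
      rows[[length(rows) + 1L]] <-
        data.frame(target_id = e$id, element_id = e$id, chrom = e$chrom,
                   arm = e$arm, start = e$start, end = e$end, class = e$class,
                   orientation = e$orientation, stringsAsFactors = FALSE)
    } else {
      if (e$class == "TY2") {
        # two delta targets at the element's two LTR ends
        for (side in c("5p", "3p")) {
          s <- if (side == "5p") e$start else max(e$start, e$end - ty2_ltr_length + 1L)
          en <- if (side == "5p") min(e$end, e$start + ty2_ltr_length - 1L) else e$end
          rows[[length(rows) + 1L]] <-
            data.frame(target_id = paste0(e$id, "_", side), element_id = e$id,
                       chrom = e$chrom, arm = e$arm, start = s, end = en,
                       class = "TY2", orientation = e$orientation,
                       stringsAsFactors = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(target_id = e$id, element_id = e$id, chrom = e$chrom,
                     arm = e$arm, start = e$start, end = e$end, class = e$class,
                     orientation = e$orientation, stringsAsFactors = FALSE)
      }
    }
  }
  targets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(), element_id = character(),
               chrom = character(), arm = character(), start = integer(),
               end = integer(), class = character(), orientation = character(),
               stringsAsFactors = FALSE)

  if (orientation_filter == "TELOMERE_ORIENTED")
    targets <- targets[targets$orientation == "TELOMERE", , drop = FALSE]

  arms <- arm_table(ann)
  key <- paste(targets$chrom, targets$arm)
  per_arm <- data.frame(chrom = arms$chrom, arm = arms$arm,
                        count = as.integer(
                          tabulate(match(key, paste(arms$chrom, arms$arm)),
                                   nbins = nrow(arms))),
                        stringsAsFactors = FALSE)
  structure(list(mode = mode, orientation_filter = orientation_filter,
                 targets = targets, per_arm = per_arm,
                 total = nrow(targets)),
            class = "target_catalog")
}

#' @export
print.target_catalog <- function(x, ...) {
  cat("target_catalog (", x$mode, ", ", x$orientation_filter, "): ",
      x$total, " targets on ", sum(x$per_arm$count > 0), " arms\n", sep = "")
  invisible(x)
}

#' Per-arm target probabilities under the equal-frequency null
#'
#' Converts a target catalog into the per-arm multinomial probabilities used
#' as the null expectation that every catalog target recombines at equal
#' frequency: `p_arm = count_arm / total`.
#'
#' @param catalog a `target_catalog` with `total > 0`.
#' @return Named numeric vector (names `"chrom-arm"`, e.g. `"chrIII-R"`)
#'   summing to 1, over all arms of the annotation.
#' @export
arm_target_probabilities <- function(catalog) {
  if (catalog$total <= 0) stop("empty target catalog")
  p <- catalog$per_arm$count / catalog$total
  names(p) <- paste0(catalog$per_arm$chrom, "-", catalog$per_arm$arm)
  p
}
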