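#' Read a capillary peak table
#'
#' Reads a GeneMapper-export-like CSV with columns `sample_id`, `size_bp`,
#' `height`, `area`, `is_control`.
#'
#' @param path CSV path.
#' @return data.frame of peaks (zero rows allowed).
#' @export
read_peak_table <- function(path) {
  pk <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "size_bp", "height", "area", "is_control")
  miss <- setdiff(need, names(pk))
  if (length(miss))
    stop("peak CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(pk)) {
    bad <- which(pk$area < 0)
    if (length(bad))
      stop("negative peak area at row(s): ", paste(bad, collapse = ", "))
    dup <- which(duplicated(pk[, c("sample_id", "size_bp")]))
    if (length(dup))
      stop("duplicate (sample_id, size_bp) at row(s): ",
           paste(dup, collapse = ", "))
    pk$is_control <- as.logical(pk$is_control)
  }
  pk
}

#' @rdname read_peak_table
#' @param peaks data.frame of peaks.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full MLPA GCR analysis pipeline
#'
#' Executes call -> classify -> (localize) -> summarize over peak tables on
#' disk and writes the copy-number matrix, the per-isolate classification
#' table and a JSON cohort summary to `out_dir`.  Every output embeds the
#' seed and an md5 digest of the configuration, so reruns with the same
#' config are reproducible and traceable.
#'
#' @param config a list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{annotation}{list with `path`, `dialect` and, for the `tsv`
#'       dialect, `chrom_sizes`, `centromeres`, optional `telomeres`.}
#'     \item{peaks}{list with `telomeric` (CSV path, required), optional
#'       `centromeric`, and optional `arm_specific` (named list
#'       `"chrom-arm" = path`).}
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{mode}{normalization for genome-wide panels
#'       (default `"GLOBAL_SUM"`).}
#'     \item{arm_mode}{normalization for arm panels (default `"ANCHOR"`).}
#'     \item{tolerance}{ambiguity tolerance (default 0.3).}
#'     \item{seed}{seed recorded in outputs (default 1).}
#'   }
#' @return Invisibly, a list with the annotation, probe sets, copy-number
#'   matrices, classification data.frame, breakpoint calls and
#'   `cohort_summary`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (field in c("annotation", "peaks", "out_dir"))
    if (is.null(config[[field]])) stop("config is missing '", field, "'")
  mode <- config$mode %||% "GLOBAL_SUM"
  arm_mode <- config$arm_mode %||% "ANCHOR"
  tolerance <- config$tolerance %||% 0.3
  seed <- config$seed %||% 1L

  cfg_hash <- config_digest(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ac <- config$annotation
  ann <- stage("annotation", read_genome_annotation(
    ac$path, dialect = ac$dialect %||% "tsv", chrom_sizes = ac$chrom_sizes,
    centromeres = ac$centromeres, telomeres = ac$telomeres))

  tel_ps <- stage("probe_design", design_probe_set(ann, "TELOMERIC"))
  cen_ps <- stage("probe_design",
                  design_probe_set(ann, "CENTROMERIC", start_length = 300L))

  read_validated <- function(path) {
    pk <- read_peak_table(path)
    if (!nrow(pk) || !any(pk$is_control))
      stop("no control samples in ", path)
    pk
  }
  cn_list <- list()
  cn_list$telomeric <- stage("copy_number", call_copy_numbers(
    read_validated(config$peaks$telomeric), tel_ps, mode = mode,
    tolerance = tolerance))
  if (!is.null(config$peaks$centromeric))
    cn_list$centromeric <- stage("copy_number", call_copy_numbers(
      read_validated(config$peaks$centromeric), cen_ps, mode = mode,
      tolerance = tolerance))

  classifications <- stage("classify", classify_cohort(cn_list))

  breakpoints <- list()
  for (armkey in names(config$peaks$arm_specific %||% list())) {
    parts <- strsplit(armkey, "-", fixed = TRUE)[[1]]
    arm_ps <- stage("probe_design", design_probe_set(
      ann, "ARM_SPECIFIC", chrom = parts[1], arm = parts[2]))
    arm_cn <- stage("copy_number", call_copy_numbers(
      read_validated(config$peaks$arm_specific[[armkey]]), arm_ps,
      mode = arm_mode, tolerance = tolerance))
    bps <- stage("localize", lapply(rownames(arm_cn$call), function(id)
      localize_breakpoint(arm_cn$call[id, ], arm_ps, ann)))
    breakpoints <- c(breakpoints, bps)
  }

  summary <- stage("summarize", summarize_cohort(
    classifications, if (length(breakpoints)) breakpoints else NULL))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- sprintf("# mlpaGCR %s | seed=%s | config_md5=%s",
                    as.character(utils::packageVersion("mlpaGCR")),
                    seed, cfg_hash)
  out_tsv <- function(obj, file, writer) {
    path <- file.path(config$out_dir, file)
    writeLines(header, path)
    tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
    writer(obj, tmp)
    file.append(path, tmp)
    path
  }
  out_tsv(cn_list$telomeric, "copy_number_telomeric.tsv",
          write_copy_number_matrix)
  out_tsv(classifications, "classification.tsv", write_classification)
  summary_json <- c(list(seed = seed, config_md5 = cfg_hash),
                    cohort_summary_list(summary))
  jsonlite::write_json(summary_json,
                       file.path(config$out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(annotation = ann, telomeric_probes = tel_ps,
                 centromeric_probes = cen_ps, copy_number = cn_list,
                 classifications = classifications,
                 breakpoints = breakpoints, summary = summary,
                 config_md5 = cfg_hash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

# cohort_summary as plain lists for JSON serialization
cohort_summary_list <- function(s) {
  list(n = s$n,
       n_chrV_L_deletion = s$n_chrV_L_deletion,
       n_arm_duplication = s$n_arm_duplication,
       n_no_duplication = s$n_no_duplication,
       n_ambiguous = s$n_ambiguous,
       arm_counts = as.list(stats::setNames(as.integer(s$arm_counts),
                                            names(s$arm_counts))),
       whole_chromosome_counts =
         as.list(stats::setNames(as.integer(s$whole_chromosome_counts),
                                 names(s$whole_chromosome_counts))),
       target_table = s$target_table)
}

#' Write a strain rate table TSV
#'
#' One row per strain in `"median [lo-hi]e-08 (fold)"` style.
#'
#' @param estimates named list of `rate_estimate` objects.
#' @param reference name of the reference strain for fold columns.
#' @param path output path.
#' @export
write_rate_table <- function(estimates, reference, path) {
  ref <- estimates[[reference]]
  rows <- do.call(rbind, lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(strain = nm, rate = format_rate(e),
               fold = as.numeric(fold_change(e, ref)),
               n_cultures = e$n, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
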