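# shared fixtures, built once per test run
.fx <- new.env()

fx_annotation <- function() {
  if (is.null(.fx$ann)) .fx$ann <- make_fixture_annotation(seed = 1)
  .fx$ann
}

fx_telomeric <- function() {
  if (is.null(.fx$tel)) .fx$tel <- design_probe_set(fx_annotation(), "TELOMERIC")
  .fx$tel
}

fx_centromeric <- function() {
  if (is.null(.fx$cen))
    .fx$cen <- design_probe_set(fx_annotation(), "CENTROMERIC",
                                start_length = 300L)
  .fx$cen
}

fx_arm_panel <- function(chrom, arm) {
  key <- paste0(chrom, arm)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- design_probe_set(fx_annotation(), "ARM_SPECIFIC",
                                   chrom = chrom, arm = arm)
  .fx[[key]]
}

# minimal two-chromosome annotation for handcrafted unit tests
toy_annotation <- function(elements = NULL) {
  genome_annotation(
    chromosomes = data.frame(chrom = c("chrA", "chrB"),
                             length = c(100000L, 200000L)),
    centromeres = data.frame(chrom = c("chrA", "chrB"),
                             start = c(40000L, 90000L),
                             end = c(40116L, 90116L)),
    elements = elements
  )
}

# classify a truth cohort through simulated peaks (telomeric + centromeric)
classify_truth <- function(truth, ann, cv = 0.03, seed = 101) {
  tel <- design_probe_set(ann, "TELOMERIC")
  cen <- design_probe_set(ann, "CENTROMERIC", start_length = 300L)
  pk_t <- simulate_peaks(true_copy_numbers(truth, tel, ann), tel,
                         noise_model(cv = cv), n_controls = 4, seed = seed)
  pk_c <- simulate_peaks(true_copy_numbers(truth, cen, ann), cen,
                         noise_model(cv = cv), n_controls = 4, seed = seed + 1)
  classify_cohort(list(call_copy_numbers(pk_t, tel),
                       call_copy_numbers(pk_c, cen)))
}

# localize breakpoints for all isolates of `truth` duplicated on one arm
localize_truth_arm <- function(truth, ann, chrom, arm, cv = 0.03, seed = 201) {
  aps <- fx_arm_panel(chrom, arm)
  sub <- truth[truth$category == "dup" & !is.na(truth$chrom) &
                 truth$chrom == chrom & truth$arm == arm, , drop = FALSE]
  if (!nrow(sub)) return(list())
  cta <- true_copy_numbers(sub, aps, ann)
  pka <- simulate_peaks(cta, aps, noise_model(cv = cv), n_controls = 4,
                        seed = seed)
  cna <- call_copy_numbers(pka, aps, mode = "ANCHOR")
  lapply(rownames(cna$call), function(id)
    localize_breakpoint(cna$call[id, ], aps, ann))
}
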