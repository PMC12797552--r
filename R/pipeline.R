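# Family-level orchestration: QC -> phasing -> fetal haplotyping -> optional
# screening arm, consolidated into one machine-readable report.

#' Run the full diagnosis pipeline on one family
#'
#' Evaluates the QC gate first (fetal fraction and sequencing error), then
#' phases the parents (PAHP via the proband or RAHP via relatives), decodes
#' fetal inheritance over the target regions with the two-chain HMM, applies
#' the no-call policy, and — when bin counts are supplied — runs the
#' aneuploidy/MMS screening arm.
#'
#' @param panel A `snp_panel`.
#' @param plasma A `plasma_depths`.
#' @param father_gt Father's `genotype_table`.
#' @param target_regions Data frame `chrom`, `start`, `end` (and optional
#'   `name`) of clinically targeted regions.
#' @param variant_loci Data frame `chrom`, `pos`, `parent` of pathogenic
#'   loci (alt allele pathogenic).
#' @param inheritance `"AR"`, `"AD"` or `"XL"`.
#' @param variant_parent For AD: the carrier parent.
#' @param fetal_sex `"male"` or `"female"` (chrX handling; for XL calls).
#' @param mother_gt Optional maternal gDNA genotypes; inferred from plasma
#'   when `NULL`.
#' @param proband_gt Proband genotypes (required for PAHP).
#' @param relatives Relative list for RAHP (see [phase_rahp()]).
#' @param phasing_mode `"PAHP"` or `"RAHP"`.
#' @param map Genetic map (constant 1.2 cM/Mb fallback).
#' @param bins Optional `bin_matrix` containing this family's plasma sample
#'   (named per `screen_sample`) plus a reference cohort.
#' @param screen_sample Sample name inside `bins` to screen.
#' @param policy A [nocall_policy()].
#' @param lod_threshold Region-call evidence threshold (log10 odds).
#' @return A `family_report` list with blocks `qc`, `haplotype` (per-region
#'   calls, clinical call, crossovers), and `screening` (or `NULL`), plus
#'   `status` in `"pass"`, `"no-call"`, `"fail"`.
#' @export
run_family <- function(panel, plasma, father_gt, target_regions, variant_loci,
                       inheritance = c("AR", "AD", "XL"),
                       variant_parent = "father", fetal_sex = "female",
                       mother_gt = NULL, proband_gt = NULL, relatives = NULL,
                       phasing_mode = c("PAHP", "RAHP"), map = NULL,
                       bins = NULL, screen_sample = "test",
                       policy = nocall_policy(), lod_threshold = 1) {
  inheritance <- match.arg(inheritance)
  phasing_mode <- match.arg(phasing_mode)

  if (is.null(mother_gt)) mother_gt <- infer_maternal_genotypes(plasma)
  qc <- run_qc(plasma, father_gt, mother_gt)

  report <- list(qc = qc, haplotype = NULL, screening = NULL)
  if (qc$overall == "fail") {
    report$status <- "fail"
    class(report) <- "family_report"
    return(report)
  }

  isnps <- classify_isnps(father_gt, mother_gt)
  phased <- if (phasing_mode == "PAHP") {
    if (is.null(proband_gt)) stop("PAHP phasing requires a proband genotype table")
    phase_pahp(isnps, proband_gt, variant_loci, inheritance,
               father_gt = father_gt, mother_gt = mother_gt)
  } else {
    if (is.null(relatives)) stop("RAHP phasing requires relatives")
    phase_rahp(isnps, relatives)
  }

  fits <- infer_fetal_haplotypes(phased, isnps, plasma, ff = qc$ff_snp,
                                 err = qc$err, map = map,
                                 fetal_sex = fetal_sex)
  calls <- apply_nocall(fits, qc$ff_snp, target_regions, policy = policy,
                        lod_threshold = lod_threshold)
  # one clinical call per target region
  clin <- vapply(unique(calls$name), function(nm) {
    pc <- calls$call[calls$name == nm & calls$parent == "paternal"]
    mc <- calls$call[calls$name == nm & calls$parent == "maternal"]
    clinical_call(pc, mc, inheritance, variant_parent, fetal_sex)
  }, character(1))

  report$haplotype <- list(
    phasing_mode = phasing_mode,
    region_calls = calls,
    clinical_calls = data.frame(name = unique(calls$name), call = unname(clin),
                                row.names = NULL),
    crossovers = list(paternal = fits$paternal$crossovers,
                      maternal = fits$maternal$crossovers),
    fits = fits)

  if (!is.null(bins)) {
    prep <- screen_prepare(bins)
    report$screening <- list(
      aneuploidy = screen_one(prep, screen_sample, ff_snp = qc$ff_snp),
      mms = screen_mms(prep, screen_sample))
  }

  report$status <- if (qc$overall == "no-call" ||
                       any(calls$call == "no-call")) "no-call" else "pass"
  class(report) <- "family_report"
  report
}

#' Write a family report as JSON
#'
#' Serializes the report's QC, per-region calls, clinical calls, crossover
#' and screening blocks (model internals are dropped).
#'
#' @param report A `family_report`.
#' @param path Output path.
#' @export
write_family_report <- function(report, path) {
  out <- list(status = report$status,
              qc = report$qc[c("ff_snp", "err", "err_pass", "ff_pass", "overall")])
  if (!is.null(report$haplotype)) {
    h <- report$haplotype
    out$haplotype <- list(
      phasing_mode = h$phasing_mode,
      region_calls = h$region_calls,
      clinical_calls = h$clinical_calls,
      crossovers = h$crossovers)
  }
  if (!is.null(report$screening)) {
    a <- report$screening$aneuploidy
    out$screening <- list(
      z = as.list(a$z), y_ratio = a$y_ratio, ff_chry = a$ff_chry,
      r_value = a$r_value, fetal_sex = a$fetal_sex, call = a$call,
      mms = report$screening$mms)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
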