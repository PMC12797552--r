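# Plasma QC: SNP- and chrY-based fetal-fraction estimation, pooled
# sequencing-error estimation from Mendelian-impossible reads, depth/recall
# theory, and the pass / no-call / fail gate.

#' Select Group-1 loci (parents homozygous for different alleles)
#'
#' At these loci the father's allele is absent from the mother, so every
#' fetal-specific read is paternal in origin; they anchor the SNP-based
#' fetal-fraction estimate.
#'
#' @param father_gt,mother_gt `genotype_table`s (the mother's may be
#'   plasma-inferred).
#' @return Data frame `chrom`, `pos`, `father_dosage`, `mother_dosage`.
#' @export
select_group1_loci <- function(father_gt, mother_gt) {
  m <- merge_dosages(father_gt, mother_gt)
  keep <- !is.na(m$d1) & !is.na(m$d2) &
    ((m$d1 == 2 & m$d2 == 0) | (m$d1 == 0 & m$d2 == 2))
  out <- m[keep, c("chrom", "pos", "d1", "d2")]
  names(out)[3:4] <- c("father_dosage", "mother_dosage")
  rownames(out) <- NULL
  out
}

#' Select Group-2 loci (parents homozygous for the same allele)
#'
#' Reads of the opposite allele cannot exist under Mendelian inheritance and
#' therefore measure the sequencing error rate.
#'
#' @inheritParams select_group1_loci
#' @return Data frame `chrom`, `pos`, `dosage` (the shared parental dosage).
#' @export
select_group2_loci <- function(father_gt, mother_gt) {
  m <- merge_dosages(father_gt, mother_gt)
  keep <- !is.na(m$d1) & !is.na(m$d2) & m$d1 == m$d2 & m$d1 %in% c(0, 2)
  out <- m[keep, c("chrom", "pos", "d1")]
  names(out)[3] <- "dosage"
  rownames(out) <- NULL
  out
}

#' @keywords internal
merge_dosages <- function(gt1, gt2) {
  a <- data.frame(chrom = gt1$chrom, pos = gt1$pos, d1 = gt1$dosage)
  b <- data.frame(chrom = gt2$chrom, pos = gt2$pos, d2 = gt2$dosage)
  order_loci(merge(a, b, by = c("chrom", "pos")))
}

#' SNP-based fetal fraction: median of 2p/(p+q) over Group-1 loci
#'
#' At each Group-1 locus, `p` is the read count of the fetal-specific allele
#' (the father's homozygous allele, absent from the mother) and `q` the
#' count of the shared maternal allele; the per-locus estimate is
#' `ff_i = 2p/(p+q)` and the sample estimate is the median over loci.
#'
#' @param depths A `plasma_depths`.
#' @param group1 Output of [select_group1_loci()].
#' @return List `ff_snp`, `n_loci_used`, and the per-locus estimates `ff_i`.
#' @export
estimate_ff_snp <- function(depths, group1) {
  if (!nrow(group1)) stop("no Group-1 loci available for ff estimation")
  i <- match(locus_key(group1$chrom, group1$pos), locus_key(depths$chrom, depths$pos))
  g1 <- group1[!is.na(i), , drop = FALSE]
  d <- depths[i[!is.na(i)], , drop = FALSE]
  # fetal-specific allele is the father's homozygous allele
  p <- ifelse(g1$father_dosage == 2, d$alt_depth, d$ref_depth)
  q <- ifelse(g1$father_dosage == 2, d$ref_depth, d$alt_depth)
  tot <- p + q
  ok <- tot > 0
  if (!any(ok)) stop("all Group-1 loci have zero depth")
  ff_i <- 2 * p[ok] / tot[ok]
  list(ff_snp = stats::median(ff_i), n_loci_used = sum(ok), ff_i = ff_i)
}

#' chrY-based fetal fraction
#'
#' Rescales the sample's chrY read proportion between the female-control
#' mean (0% fetal male DNA) and the adult-male baseline (100%). Negative
#' estimates from noise are clipped to zero with a warning.
#'
#' @param y_ratio chrY read proportion of the sample.
#' @param female_mean,male_mean Control means; `male_mean > female_mean`.
#' @return Fetal fraction estimate (>= 0).
#' @export
estimate_ff_chry <- function(y_ratio, female_mean, male_mean) {
  if (male_mean <= female_mean)
    stop("male control mean must exceed female control mean")
  ff <- (y_ratio - female_mean) / (male_mean - female_mean)
  if (ff < 0) {
    warning("negative chrY fetal-fraction estimate clipped to 0")
    ff <- 0
  }
  ff
}

#' Pooled sequencing error rate from Group-2 loci
#'
#' `err = sum(p) / sum(p + q)` where `p` pools reads of the Mendelian-
#' impossible allele over all Group-2 loci and `q` the expected allele.
#'
#' @param depths A `plasma_depths`.
#' @param group2 Output of [select_group2_loci()].
#' @return Error-rate fraction.
#' @export
estimate_error_rate <- function(depths, group2) {
  if (!nrow(group2)) stop("no Group-2 loci available for error estimation")
  i <- match(locus_key(group2$chrom, group2$pos), locus_key(depths$chrom, depths$pos))
  g2 <- group2[!is.na(i), , drop = FALSE]
  d <- depths[i[!is.na(i)], , drop = FALSE]
  p <- ifelse(g2$dosage == 0, d$alt_depth, d$ref_depth)
  q <- ifelse(g2$dosage == 0, d$ref_depth, d$alt_depth)
  if (sum(p + q) == 0) stop("zero total depth over Group-2 loci")
  sum(p) / sum(p + q)
}

#' Minimum supporting-read threshold for calling a fetal allele
#'
#' The tiered default reproduces the published depth-tier table (2 reads up
#' to 150x, 3 reads at 200x and above). `method = "poisson"` instead returns
#' the smallest `t` such that error-only reads, `X ~ Poisson(depth * err)`,
#' satisfy `P(X >= t) <= 1 - confidence`.
#'
#' @param depth Mean sequencing depth.
#' @param err Per-read error rate.
#' @param confidence Probability that error-only loci stay below threshold.
#' @param method `"tiered"` (default) or `"poisson"`.
#' @return Integer threshold (reads).
#' @export
min_support_threshold <- function(depth, err = 0.001, confidence = 0.999,
                                  method = c("tiered", "poisson")) {
  method <- match.arg(method)
  stopifnot(depth > 0)
  if (method == "tiered") return(if (depth >= 200) 3L else 2L)
  if (err <= 0) return(1L)
  lambda <- depth * err
  t <- 1L
  while (stats::ppois(t - 1, lambda, lower.tail = FALSE) > 1 - confidence)
    t <- t + 1L
  t
}

#' Theoretical recall of fetal-specific alleles at a given depth
#'
#' The fetal-specific allele is present at frequency `ff / 2` of the reads,
#' so its read count is Poisson(`depth * ff / 2`) and the recall is the
#' upper tail at the supporting-read threshold.
#'
#' @param depth Mean sequencing depth.
#' @param ff Fetal fraction.
#' @param threshold Minimum supporting reads (see [min_support_threshold()]).
#' @return Recall probability.
#' @export
theoretical_recall <- function(depth, ff, threshold) {
  if (threshold <= 0) return(1.0)
  stats::ppois(threshold - 1, depth * ff / 2, lower.tail = FALSE)
}

#' QC gate: pass / no-call / fail
#'
#' A sample fails (resequencing advised) when the sequencing error rate
#' exceeds 0.5%; it is a haplotyping no-call when the fetal fraction is
#' below 5%; otherwise it passes.
#'
#' @param ff_snp SNP-based fetal-fraction estimate.
#' @param err Sequencing error rate.
#' @param err_max Error gate (default 0.005).
#' @param ff_min Fetal-fraction gate (default 0.05).
#' @return A `qc_report` list: `err`, `ff_snp`, `err_pass`, `ff_pass`,
#'   `overall` in `"pass"`, `"no-call"`, `"fail"`.
#' @export
qc_gate <- function(ff_snp, err, err_max = 0.005, ff_min = 0.05) {
  err_pass <- err <= err_max
  ff_pass <- ff_snp >= ff_min
  overall <- if (!err_pass) "fail" else if (!ff_pass) "no-call" else "pass"
  structure(list(err = err, ff_snp = ff_snp, err_pass = err_pass,
                 ff_pass = ff_pass, overall = overall),
            class = "qc_report")
}

#' Full plasma QC in one call
#'
#' Infers maternal genotypes from plasma when no maternal gDNA is given,
#' derives Group-1/Group-2 loci, estimates ff and err, and applies the gate.
#'
#' @param depths A `plasma_depths`.
#' @param father_gt Father's `genotype_table`.
#' @param mother_gt Optional maternal `genotype_table`; plasma-inferred when
#'   `NULL`.
#' @inheritParams qc_gate
#' @return A `qc_report` with `n_group1`, `n_group2` attached.
#' @export
run_qc <- function(depths, father_gt, mother_gt = NULL,
                   err_max = 0.005, ff_min = 0.05) {
  if (is.null(mother_gt)) mother_gt <- infer_maternal_genotypes(depths)
  g1 <- select_group1_loci(father_gt, mother_gt)
  g2 <- select_group2_loci(father_gt, mother_gt)
  ff <- estimate_ff_snp(depths, g1)
  err <- estimate_error_rate(depths, g2)
  rep <- qc_gate(ff$ff_snp, err, err_max = err_max, ff_min = ff_min)
  rep$n_group1 <- ff$n_loci_used
  rep$n_group2 <- nrow(g2)
  rep
}
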