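# Aneuploidy and microdeletion/microduplication screening from 250-kb bin
# counts: GC LOESS normalization, PCA correction against a euploid reference
# cohort, chromosome-proportion Z scores, male-fetus X/Y logic with the R
# value, and CBS segmentation with bootstrap confidence.

## ---- normalization ---------------------------------------------------------

#' GC LOESS normalization of bin counts
#'
#' Per sample, a LOESS curve of count versus bin GC is fitted and each bin
#' is rescaled by `global median / fitted value`. A degenerate GC
#' distribution leaves the counts unchanged with a warning.
#'
#' @param counts Samples x bins count matrix.
#' @param gc Per-bin GC fraction.
#' @param span LOESS span (default 0.3).
#' @param min_bins Minimum number of GC-valid bins required.
#' @param fit_mask Logical per-bin vector selecting the bins the curve is
#'   fitted on (typically autosomes: sex-chromosome bins are at half or
#'   near-zero dosage and would distort the curve at their GC values); the
#'   correction itself is applied to every bin. `NULL` fits on all bins.
#' @return Corrected matrix of the same shape.
#' @export
normalize_gc <- function(counts, gc, span = 0.3, min_bins = 100,
                         fit_mask = NULL) {
  ok <- !is.na(gc)
  if (is.null(fit_mask)) fit_mask <- rep(TRUE, length(gc))
  if (sum(ok & fit_mask) < min_bins)
    stop("need at least ", min_bins, " bins with valid GC")
  if (stats::sd(gc[ok & fit_mask]) < 1e-6) {
    warning("degenerate GC distribution; returning counts unchanged")
    return(counts)
  }
  out <- counts
  for (i in seq_len(nrow(counts))) {
    use <- ok & fit_mask
    fit <- stats::loess(y ~ g, data = data.frame(y = counts[i, use],
                                                 g = gc[use]),
                        span = span, degree = 2,
                        control = stats::loess.control(surface = "interpolate"))
    f <- stats::predict(fit, newdata = data.frame(g = gc[ok]))
    f[!is.na(f) & f <= 0] <- NA
    corr <- counts[i, ok] * stats::median(counts[i, use]) / f
    corr[is.na(corr)] <- counts[i, ok][is.na(corr)]
    out[i, ok] <- corr
  }
  out
}

#' PCA correction against the reference cohort
#'
#' Fits a PCA on the reference samples' centered log2 values of the
#' autosomal bins and projects the top `k` components out of every sample,
#' removing shared assay/batch structure. Sex-chromosome bins are excluded
#' from the fit and left unprojected: the fetal-sex difference is the
#' dominant variance direction across any mixed reference cohort and must
#' not be regressed out, and downstream X/Y statistics assume a linear
#' copy-number mixture. `k = 0` is the identity.
#'
#' @param corrected GC-corrected samples x bins matrix.
#' @param is_reference Logical vector flagging reference-cohort rows.
#' @param k Number of components to remove (default 3; must be smaller than
#'   the reference size).
#' @param autosomal Logical per-bin vector; `NULL` treats all bins as
#'   autosomal.
#' @return List `residual` (samples x bins log2 deviations from the
#'   reference mean, PCA components removed on autosomes), `values`
#'   (corrected counts with the PCA projection removed multiplicatively,
#'   linear scale) and `rotation`.
#' @export
pca_correct <- function(corrected, is_reference, k = 3, autosomal = NULL) {
  if (!any(is_reference)) stop("no reference samples flagged")
  if (k >= sum(is_reference)) stop("k must be smaller than the reference cohort size")
  if (is.null(autosomal)) autosomal <- rep(TRUE, ncol(corrected))
  lr <- log2(corrected + 0.5)
  lr <- lr - rowMeans(lr[, autosomal, drop = FALSE]) # per-sample scale out
  center <- colMeans(lr[is_reference, , drop = FALSE])
  dev <- sweep(lr, 2, center)
  if (k == 0) return(list(residual = dev, values = corrected, rotation = NULL))
  pc <- stats::prcomp(dev[is_reference, autosomal, drop = FALSE],
                      center = FALSE, rank. = k)
  rot <- pc$rotation # autosomal bins x k
  scores <- dev[, autosomal, drop = FALSE] %*% rot
  proj <- scores %*% t(rot)
  dev[, autosomal] <- dev[, autosomal, drop = FALSE] - proj
  values <- corrected
  values[, autosomal] <- corrected[, autosomal, drop = FALSE] * 2^(-proj)
  list(residual = dev, values = values, rotation = rot)
}

## ---- chromosome-level statistics -------------------------------------------

# denominator: all autosomes except chr13, chr18, chr19 and chr21
#' @keywords internal
denominator_bins <- function(bins) {
  excl <- c("chr13", "chr18", "chr19", "chr21", "chrX", "chrY")
  !(bins$chrom %in% excl)
}

#' Chromosome read proportions
#'
#' `p = chromosome counts / counts on all autosomes except chr13, chr18,
#' chr19 and chr21`.
#'
#' @param values Samples x bins matrix (corrected counts).
#' @param bins Bin table with `chrom`.
#' @param chrom Target chromosome.
#' @return Numeric vector, one proportion per sample.
#' @export
chromosome_proportion <- function(values, bins, chrom) {
  chrom <- normalize_chrom(chrom)
  num <- rowSums(values[, bins$chrom == chrom, drop = FALSE])
  den <- rowSums(values[, denominator_bins(bins), drop = FALSE])
  num / den
}

#' Chromosome-proportion Z score
#'
#' `Z = (p1 - p0) / SD` where `p0` and `SD` are the mean and standard
#' deviation of the proportion in the reference cohort; Z > 3 indicates a
#' trisomy of the target chromosome.
#'
#' @param p1 Observed proportion(s).
#' @param reference Proportions of the reference samples.
#' @return Z score(s).
#' @export
chromosome_z <- function(p1, reference) {
  s <- stats::sd(reference)
  if (!is.finite(s) || s == 0) stop("reference SD is zero; cannot standardize")
  (p1 - mean(reference)) / s
}

#' Aneuploidy screen of one sample against the reference cohort
#'
#' Computes Z for chr13/18/21, classifies fetal sex from the chrY ratio
#' (female-control mean + 3 SD gate), and applies the sex-chromosome logic:
#' female fetuses are tested on chrX against female-fetus plasma controls
#' (45,X below Z = -3, XXX above Z = +3); male fetuses use the
#' ff.chrY-transformed X expectation plus the R value (`ff.chrY / ff.snp`):
#' Z > 3 with R <= 2 is XXY, Z > 3 with R > 2 is XYY.
#'
#' @param bm A `bin_matrix` (see [simulate_bin_cohort()]); reference rows
#'   are taken from `bm$samples$is_reference` and fetal sex of the
#'   references from their karyotype. gDNA baseline rows (type "gdna")
#'   provide the male/female chrY baselines.
#' @param sample Sample name to screen.
#' @param ff_snp SNP-based fetal fraction of the sample (for the R value).
#' @param k PCA components to remove.
#' @param span LOESS span.
#' @return A `screen_result` list: `z` (chr13/18/21/X), `y_ratio`,
#'   `ff_chry`, `r_value`, `fetal_sex`, `call` and the proportions used.
#' @export
screen_aneuploidy <- function(bm, sample, ff_snp = NA_real_, k = 3, span = 0.3) {
  prep <- screen_prepare(bm, k = k, span = span)
  screen_one(prep, sample, ff_snp = ff_snp)
}

#' Precompute normalization and reference statistics for screening
#'
#' Runs GC LOESS and PCA correction once for a whole cohort so that many
#' samples can be screened against the same reference.
#'
#' @inheritParams screen_aneuploidy
#' @return A `screen_reference` list used by [screen_one()].
#' @export
screen_prepare <- function(bm, k = 3, span = 0.3) {
  counts <- bm$counts
  bins <- bm$bins
  samples <- bm$samples
  autosomal <- !(bins$chrom %in% c("chrX", "chrY"))
  corrected <- normalize_gc(counts, bins$gc, span = span,
                            fit_mask = autosomal)
  pca <- pca_correct(corrected, samples$is_reference, k = k,
                     autosomal = autosomal)
  # chromosome proportions use the GC-corrected counts: projecting out
  # reference-fitted components treats reference and test samples
  # asymmetrically (the references' own noise is partly removed), which
  # shifts p0 relative to test samples by a sizable fraction of the tiny
  # proportion SD; shared batch structure cancels in the Z denominator
  # anyway. The PCA residuals drive the bin-level MMS statistics.
  values <- corrected
  ref <- which(samples$is_reference)
  ref_sex <- vapply(samples$karyotype[ref], function(x) parse_karyotype(x)$fetal_sex,
                    character(1))
  y_ratio <- chromosome_proportion(values, bins, "chrY")
  prep <- list(bm = bm, values = values, residual = pca$residual, ref = ref,
               ref_sex = ref_sex, y_ratio = y_ratio)
  prep$p <- lapply(c("chr13", "chr18", "chr21", "chrX"), function(ch)
    chromosome_proportion(values, bins, ch))
  names(prep$p) <- c("chr13", "chr18", "chr21", "chrX")
  gd <- which(samples$type == "gdna")
  prep$male_baseline <- mean(y_ratio[gd][grepl("XY", samples$karyotype[gd])])
  prep$female_baseline_gdna <- mean(y_ratio[gd][!grepl("Y", samples$karyotype[gd])])
  fem_ref <- ref[ref_sex == "female"]
  prep$female_ref_y_mean <- mean(y_ratio[fem_ref])
  prep$female_ref_y_sd <- stats::sd(y_ratio[fem_ref])
  class(prep) <- "screen_reference"
  prep
}

#' Screen one sample using precomputed reference statistics
#'
#' @param prep A [screen_prepare()] result.
#' @param sample Sample name.
#' @param ff_snp SNP-based fetal fraction (for the R value).
#' @return A `screen_result` (see [screen_aneuploidy()]).
#' @export
screen_one <- function(prep, sample, ff_snp = NA_real_) {
  samples <- prep$bm$samples
  i <- match(sample, samples$sample)
  if (is.na(i)) stop("unknown sample: ", sample)
  ref <- prep$ref
  fem_ref <- ref[prep$ref_sex == "female"]
  z <- c(chr13 = unname(chromosome_z(prep$p$chr13[i], prep$p$chr13[ref])),
         chr18 = unname(chromosome_z(prep$p$chr18[i], prep$p$chr18[ref])),
         chr21 = unname(chromosome_z(prep$p$chr21[i], prep$p$chr21[ref])))
  call <- character(0)
  if (z["chr13"] > 3) call <- c(call, "T13")
  if (z["chr18"] > 3) call <- c(call, "T18")
  if (z["chr21"] > 3) call <- c(call, "T21")

  # fetal sex from the chrY ratio against female-fetus plasma controls
  y <- prep$y_ratio[i]
  male <- y > prep$female_ref_y_mean + 3 * prep$female_ref_y_sd
  ff_chry <- NA_real_
  r_value <- NA_real_
  p0x <- mean(prep$p$chrX[fem_ref])
  sdx <- stats::sd(prep$p$chrX[fem_ref])
  if (!male) {
    zx <- unname((prep$p$chrX[i] - p0x) / sdx)
    if (zx < -3) call <- c(call, "45X")
    if (zx > 3) call <- c(call, "XXX")
  } else {
    ff_chry <- estimate_ff_chry(y, prep$female_ref_y_mean, prep$male_baseline)
    zx <- unname((prep$p$chrX[i] - p0x * (1 - ff_chry / 2)) / sdx)
    if (zx > 3) {
      if (is.na(ff_snp) || ff_snp == 0) {
        call <- c(call, "XXY or XYY (R undefined)")
      } else {
        r_value <- ff_chry / ff_snp
        call <- c(call, if (r_value > 2) "XYY" else "XXY")
      }
    } else if (!is.na(ff_snp) && ff_snp > 0) {
      r_value <- ff_chry / ff_snp
    }
  }
  structure(list(
    sample = sample, z = c(z, chrX = zx), y_ratio = y, ff_chry = ff_chry,
    ff_snp = ff_snp, r_value = r_value,
    fetal_sex = if (male) "male" else "female",
    call = if (length(call)) paste(call, collapse = "+") else "low-risk",
    p1 = vapply(prep$p, `[`, numeric(1), i)), class = "screen_result")
}

## ---- segmentation and MMS calls --------------------------------------------

#' Circular binary segmentation of a bin-value profile
#'
#' Recursive CBS: within each segment the maximal circular two-sample t
#' statistic is located, its significance assessed by permutation, and the
#' segment split while significant. Adjacent segments whose means differ by
#' less than `merge_sd` global standard deviations are re-merged.
#'
#' @param x Numeric profile (one chromosome's residual log ratios).
#' @param n_perm Permutations per split test (default 1000).
#' @param alpha Split significance level (default 0.01).
#' @param merge_sd Merge threshold in global-SD units.
#' @param seed Seed for the permutation shuffles.
#' @param min_width Smallest segment the recursion may produce.
#' @return Data frame `start`, `end` (1-based bin indices), `mean`.
#' @export
segment_cbs <- function(x, n_perm = 1000, alpha = 0.01, merge_sd = 0.5,
                        seed = 1L, min_width = 2L) {
  n <- length(x)
  breaks <- c(0L, n)
  segment_rec <- function(lo, hi, depth) {
    # lo, hi: 0-based segment bounds (]
    if (hi - lo < 2L * min_width || depth > 20L) return(NULL)
    res <- .cbs_scan(x[(lo + 1):hi], n_perm, alpha,
                     seed + lo * 131L + hi)
    if (res$p > alpha) return(NULL)
    b <- sort(unique(c(lo + res$i, lo + res$j)))
    b <- b[b > lo & b < hi]
    if (!length(b)) return(NULL)
    breaks <<- sort(unique(c(breaks, b)))
    pts <- c(lo, b, hi)
    for (k in seq_len(length(pts) - 1)) segment_rec(pts[k], pts[k + 1], depth + 1L)
  }
  segment_rec(0L, n, 1L)
  # merge small mean differences
  s <- stats::sd(x)
  repeat {
    b <- breaks
    if (length(b) <= 2) break
    means <- vapply(seq_len(length(b) - 1), function(k)
      mean(x[(b[k] + 1):b[k + 1]]), numeric(1))
    d <- abs(diff(means))
    if (!length(d) || all(d >= merge_sd * s)) break
    drop <- which.min(d) + 1L
    breaks <- b[-drop]
  }
  b <- breaks
  data.frame(start = b[-length(b)] + 1L, end = b[-1],
             mean = vapply(seq_len(length(b) - 1), function(k)
               mean(x[(b[k] + 1):b[k + 1]]), numeric(1)))
}

#' Segment a whole residual profile chromosome by chromosome
#'
#' @param residual_row One sample's residual log2 ratios over all bins.
#' @param bins Bin table.
#' @inheritParams segment_cbs
#' @return Data frame `chrom`, `start_bin`, `end_bin`, `start`, `end`,
#'   `n_bins`, `mean`.
#' @export
segment_sample <- function(residual_row, bins, n_perm = 1000, alpha = 0.01,
                           merge_sd = 0.5, seed = 1L) {
  out <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    if (length(idx) < 10) next
    seg <- segment_cbs(residual_row[idx], n_perm = n_perm, alpha = alpha,
                       merge_sd = merge_sd, seed = seed)
    out[[ch]] <- data.frame(
      chrom = ch,
      start_bin = idx[seg$start], end_bin = idx[seg$end],
      start = bins$start[idx[seg$start]], end = bins$end[idx[seg$end]],
      n_bins = seg$end - seg$start + 1L, mean = seg$mean)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call microdeletion/microduplication segments with bootstrap confidence
#'
#' Per segment, the sample's segment-mean residual is standardized against
#' the reference samples' means over the same bins (Z). The segment's bins
#' are then resampled with replacement `B` times; the bootstrap confidence
#' is the fraction of replicates with |Z| > 3 and the original sign. A
#' segment is called when |Z| > 3 and confidence > 0.95. Segments under
#' `min_bins` bins (sub-Mb) are not evaluated.
#'
#' @param segments Output of [segment_sample()].
#' @param residual_row The sample's residual profile.
#' @param ref_residual Reference samples x bins residual matrix.
#' @param B Bootstrap replicates (default 1000).
#' @param min_bins Smallest evaluable segment (default 4 bins = 1 Mb).
#' @param z_threshold,conf_threshold Call thresholds.
#' @return `segments` with `z`, `confidence`, `direction`, `called` added.
#' @export
call_mms <- function(segments, residual_row, ref_residual, B = 1000,
                     min_bins = 4L, z_threshold = 3, conf_threshold = 0.95) {
  segments$z <- NA_real_
  segments$confidence <- NA_real_
  segments$direction <- NA_character_
  segments$called <- FALSE
  for (k in seq_len(nrow(segments))) {
    idx <- segments$start_bin[k]:segments$end_bin[k]
    if (length(idx) < min_bins) next
    ref_means <- rowMeans(ref_residual[, idx, drop = FALSE])
    mu <- mean(ref_means); s <- stats::sd(ref_means)
    if (!is.finite(s) || s == 0) next
    z <- (mean(residual_row[idx]) - mu) / s
    segments$z[k] <- z
    segments$direction[k] <- if (z < 0) "del" else "dup"
    bz <- vapply(seq_len(B), function(b) {
      ridx <- sample(idx, length(idx), replace = TRUE)
      (mean(residual_row[ridx]) - mu) / s
    }, numeric(1))
    conf <- mean(abs(bz) > z_threshold & sign(bz) == sign(z))
    segments$confidence[k] <- conf
    segments$called[k] <- abs(z) > z_threshold && conf > conf_threshold
  }
  segments
}

#' Screen one sample for MMS events
#'
#' Segments the sample's residual profile and applies the Z/bootstrap rule.
#'
#' @param prep A [screen_prepare()] result.
#' @param sample Sample name.
#' @param ... Passed to [segment_sample()] and [call_mms()].
#' @inheritParams call_mms
#' @param n_perm,alpha,merge_sd CBS parameters.
#' @param seed Seed for permutations and bootstrap.
#' @return The annotated segment table (see [call_mms()]).
#' @export
screen_mms <- function(prep, sample, B = 1000, n_perm = 1000, alpha = 0.01,
                       merge_sd = 0.5, seed = 1L) {
  i <- match(sample, prep$bm$samples$sample)
  if (is.na(i)) stop("unknown sample: ", sample)
  auto <- !(prep$bm$bins$chrom %in% c("chrX", "chrY"))
  bins <- prep$bm$bins[auto, , drop = FALSE]
  row <- prep$residual[i, auto]
  ref_res <- prep$residual[prep$ref, auto, drop = FALSE]
  # bin indices below refer to the autosomal subset
  seg <- segment_sample(row, bins, n_perm = n_perm, alpha = alpha,
                        merge_sd = merge_sd, seed = seed)
  set.seed(seed)
  call_mms(seg, row, ref_res, B = B)
}
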