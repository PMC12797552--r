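# Genome-wide SNP panel design: candidate filtering, systematic 25-kb
# sampling, and density boosting within 2 Mb of target genes.

#' Panel design configuration
#'
#' Filters and sampling geometry for panel construction: candidate SNPs must
#' have a population minor-allele frequency and a GC fraction of the +/-120 bp
#' flank inside the configured ranges (inclusive) and a mappability strictly
#' above `mappability_min`; survivors are sampled systematically at an
#' average `target_spacing`, with the sampling grid densified by
#' `boost_factor` within `boost_halfwidth` of each target gene.
#'
#' @param maf_range,gc_range Inclusive \[lo, hi\] filters in \[0,1\].
#' @param mappability_min Strict lower bound on mappability.
#' @param target_spacing Average inter-SNP distance of the sampling grid (bp).
#' @param boost_halfwidth Half-width of the boosted window around each gene (bp).
#' @param boost_factor Grid densification factor (>= 1) inside boost regions.
#' @param gene_list Optional data frame `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive) of target genes.
#' @return A `panel_design_config` list.
#' @export
panel_design_config <- function(maf_range = c(0.30, 0.70),
                                gc_range = c(0.30, 0.70),
                                mappability_min = 0.85,
                                target_spacing = 25000,
                                boost_halfwidth = 2e6,
                                boost_factor = 5,
                                gene_list = NULL) {
  stopifnot(length(maf_range) == 2, length(gc_range) == 2,
            all(maf_range >= 0 & maf_range <= 1),
            all(gc_range >= 0 & gc_range <= 1),
            maf_range[1] <= maf_range[2], gc_range[1] <= gc_range[2],
            mappability_min >= 0, mappability_min <= 1,
            target_spacing > 0, boost_halfwidth >= 0, boost_factor >= 1)
  if (!is.null(gene_list))
    stopifnot(all(c("chrom", "start", "end") %in% names(gene_list)))
  structure(list(maf_range = maf_range, gc_range = gc_range,
                 mappability_min = mappability_min,
                 target_spacing = target_spacing,
                 boost_halfwidth = boost_halfwidth,
                 boost_factor = boost_factor,
                 gene_list = gene_list),
            class = "panel_design_config")
}

#' Filter candidate SNPs on allele frequency, flank GC and mappability
#'
#' Retains exactly the candidates with `maf` and `gc_flank` inside the
#' configured ranges (inclusive) and `mappability` strictly greater than
#' `mappability_min`. Candidates with missing metadata are dropped and
#' counted.
#'
#' @param candidates A `snp_panel` carrying `maf`, `gc_flank`, `mappability`.
#' @param cfg A [panel_design_config()].
#' @return Filtered `snp_panel`; `attr(, "n_dropped_missing")` counts loci
#'   dropped for missing metadata.
#' @export
filter_candidates <- function(candidates, cfg = panel_design_config()) {
  need <- c("maf", "gc_flank", "mappability")
  miss <- setdiff(need, names(candidates))
  if (length(miss)) stop("candidates lack metadata column(s): ",
                         paste(miss, collapse = ", "))
  complete <- stats::complete.cases(candidates[, need])
  n_missing <- sum(!complete)
  if (n_missing) message(n_missing, " candidate(s) dropped for missing metadata")
  df <- candidates[complete, , drop = FALSE]
  keep <- df$maf >= cfg$maf_range[1] & df$maf <= cfg$maf_range[2] &
    df$gc_flank >= cfg$gc_range[1] & df$gc_flank <= cfg$gc_range[2] &
    df$mappability > cfg$mappability_min
  out <- new_snp_panel(df[keep, , drop = FALSE])
  attr(out, "n_dropped_missing") <- n_missing
  out
}

# boost intervals (gene +/- halfwidth), merged per chromosome
#' @keywords internal
boost_intervals <- function(cfg) {
  gl <- cfg$gene_list
  if (is.null(gl) || !nrow(gl)) return(NULL)
  iv <- data.frame(chrom = normalize_chrom(gl$chrom),
                   start = pmax(1, gl$start - cfg$boost_halfwidth),
                   end = gl$end + cfg$boost_halfwidth)
  iv <- iv[order(chrom_factor(iv$chrom), iv$start), , drop = FALSE]
  out <- list()
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    s <- sub$start[1]; e <- sub$end[1]; rows <- list()
    if (nrow(sub) > 1) for (k in 2:nrow(sub)) {
      if (sub$start[k] <= e) e <- max(e, sub$end[k])
      else { rows[[length(rows) + 1]] <- c(s, e); s <- sub$start[k]; e <- sub$end[k] }
    }
    rows[[length(rows) + 1]] <- c(s, e)
    m <- do.call(rbind, rows)
    out[[ch]] <- data.frame(chrom = ch, start = m[, 1], end = m[, 2])
  }
  do.call(rbind, out)
}

#' @keywords internal
in_intervals <- function(chrom, pos, iv) {
  if (is.null(iv)) return(rep(FALSE, length(pos)))
  res <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(iv))) {
    res <- res | (chrom == iv$chrom[k] & pos >= iv$start[k] & pos <= iv$end[k])
  }
  res
}

#' Systematic sampling of a filtered candidate set
#'
#' Walks each chromosome with a grid of average step `target_spacing`,
#' dividing the step by `boost_factor` inside gene boost regions, and keeps
#' the candidate nearest to each grid point (ties broken toward the smaller
#' position). Grid points with no candidate within half the local step on
#' either side are skipped. The procedure is deterministic; `seed` is kept
#' in the signature for interface stability with stochastic thinning
#' variants.
#'
#' @param filtered A filtered, sorted `snp_panel`.
#' @param cfg A [panel_design_config()].
#' @param seed Unused by the deterministic grid sampler.
#' @return A `snp_panel` subset of `filtered`, sorted and deduplicated, with
#'   an `in_boost_region` column.
#' @export
sample_panel <- function(filtered, cfg = panel_design_config(), seed = 1L) {
  if (!nrow(filtered)) {
    warning("empty candidate set; returning empty panel")
    return(filtered)
  }
  iv <- boost_intervals(cfg)
  picked <- integer(0)
  n_skipped <- 0L
  for (ch in unique(filtered$chrom)) {
    idx <- which(filtered$chrom == ch)
    pos <- filtered$pos[idx]
    g <- pos[1]
    last <- pos[length(pos)]
    while (g <= last + cfg$target_spacing / 2) {
      boosted <- in_intervals(ch, g, iv)
      step <- if (boosted) cfg$target_spacing / cfg$boost_factor else cfg$target_spacing
      j <- findInterval(g, pos)
      cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(pos)))
      d <- abs(pos[cand] - g)
      best <- cand[order(d, pos[cand])][1] # tie -> smaller position
      if (abs(pos[best] - g) <= step / 2) picked <- c(picked, idx[best])
      else n_skipped <- n_skipped + 1L
      g <- g + step
    }
  }
  if (n_skipped) message(n_skipped, " grid window(s) had no candidate and were skipped")
  picked <- sort(unique(picked))
  out <- filtered[picked, , drop = FALSE]
  out$in_boost_region <- in_intervals(out$chrom, out$pos, iv)
  new_snp_panel(out)
}

#' Design a panel in one call: filter then sample
#'
#' @inheritParams filter_candidates
#' @inheritParams sample_panel
#' @return A `snp_panel`.
#' @export
design_panel <- function(candidates, cfg = panel_design_config(), seed = 1L) {
  sample_panel(filter_candidates(candidates, cfg), cfg, seed)
}
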