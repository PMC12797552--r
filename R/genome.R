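# Reference genome geometry and genetic maps.
#
# All coordinates in the package are 1-based inclusive (VCF convention);
# BED ingestion/emission converts exactly once in the I/O layer.

# GRCh38 chromosome lengths (bp)
.HG_LENGTHS <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415
)

#' Chromosome lengths for the human genome
#'
#' Returns a named vector of chromosome lengths (bp, GRCh38). `scale` shrinks
#' every chromosome proportionally; the simulator uses this to run the same
#' pipeline on a length-scaled genome when a full-size run is not needed.
#'
#' @param scale Multiplicative length factor in (0, 1].
#' @param chroms Chromosome names to keep (default: 22 autosomes, X and Y).
#' @return Named numeric vector of lengths in bp.
#' @export
default_genome <- function(scale = 1, chroms = names(.HG_LENGTHS)) {
  stopifnot(scale > 0, scale <= 1)
  bad <- setdiff(chroms, names(.HG_LENGTHS))
  if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  round(.HG_LENGTHS[chroms] * scale)
}

#' @keywords internal
chrom_levels <- function(x = NULL) {
  lv <- names(.HG_LENGTHS)
  if (is.null(x)) return(lv)
  extra <- setdiff(unique(as.character(x)), lv)
  c(lv, sort(extra))
}

#' Normalize chromosome names to the "chrN" convention
#'
#' Accepts "1"/"chr1"/"X" etc.; returns "chr1", "chrX", ...
#'
#' @param x Character vector of chromosome names.
#' @return Character vector with the "chr" prefix.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' @keywords internal
chrom_factor <- function(x) {
  factor(normalize_chrom(x), levels = chrom_levels(normalize_chrom(x)))
}

# order rows of a locus table by (chrom, pos) using the canonical
# chromosome ordering
#' @keywords internal
order_loci <- function(df) {
  df[order(chrom_factor(df$chrom), df$pos), , drop = FALSE]
}

#' @keywords internal
locus_key <- function(chrom, pos) paste(normalize_chrom(chrom), pos, sep = ":")

## ---- genetic maps ----------------------------------------------------------

#' Build a constant-rate genetic map
#'
#' A genetic map is a per-chromosome table of physical position (bp),
#' local recombination rate (cM/Mb) and cumulative genetic position (cM).
#' The constant-rate map applies one genome-wide rate, the usual fallback
#' when no empirical map is supplied (default 1.2 cM/Mb, close to the
#' sex-averaged human mean).
#'
#' @param genome Named vector of chromosome lengths (bp).
#' @param rate_cm_per_mb Recombination rate in cM/Mb.
#' @return A `genetic_map` object.
#' @export
constant_genetic_map <- function(genome = default_genome(), rate_cm_per_mb = 1.2) {
  stopifnot(rate_cm_per_mb >= 0)
  tabs <- lapply(names(genome), function(ch) {
    L <- genome[[ch]]
    data.frame(
      chrom = ch,
      pos = c(1, L),
      rate = rate_cm_per_mb,
      cum = c(0, (L - 1) / 1e6 * rate_cm_per_mb)
    )
  })
  new_genetic_map(do.call(rbind, tabs))
}

#' Construct/validate a genetic map from a position/rate/cumulative table
#'
#' @param df Data frame with columns `chrom`, `pos` (bp, 1-based), `rate`
#'   (cM/Mb) and optionally `cum` (cM, recomputed if absent).
#' @return A `genetic_map` object (a data frame, rows ordered by chrom/pos).
#' @export
new_genetic_map <- function(df) {
  stopifnot(all(c("chrom", "pos", "rate") %in% names(df)))
  df$chrom <- normalize_chrom(df$chrom)
  df <- order_loci(df)
  if (any(df$rate < 0)) stop("genetic map rates must be >= 0")
  by_ch <- split(seq_len(nrow(df)), df$chrom)
  for (idx in by_ch) {
    p <- df$pos[idx]
    if (any(diff(p) <= 0)) stop("genetic map positions must be strictly increasing per chromosome")
  }
  if (!"cum" %in% names(df)) {
    df$cum <- NA_real_
    for (idx in by_ch) {
      p <- df$pos[idx]; r <- df$rate[idx]
      # integrate rate piecewise (rate applies on the interval starting at pos)
      cm <- c(0, cumsum(diff(p) / 1e6 * r[-length(r)]))
      df$cum[idx] <- cm
    }
  } else {
    for (idx in by_ch) {
      if (any(diff(df$cum[idx]) < 0)) stop("cumulative genetic positions must be non-decreasing")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Read a genetic map from a 3+ column TSV (chrom, pos, rate[, cum])
#'
#' @param path Path to a tab-separated file.
#' @return A `genetic_map` object.
#' @export
read_genetic_map <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  names(df)[1:3] <- c("chrom", "pos", "rate")
  if (ncol(df) >= 4) names(df)[4] <- "cum"
  new_genetic_map(df)
}

#' Cumulative genetic position (cM) at physical positions
#'
#' Linear interpolation of the map's cumulative cM; positions beyond the
#' mapped range are extrapolated at the terminal local rate's flat value
#' (rule-2 clamping).
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome (scalar or vector recycled against `pos`).
#' @param pos Physical positions (bp).
#' @return Numeric vector of cM positions.
#' @export
genetic_cm <- function(map, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  if (length(chrom) == 1) chrom <- rep(chrom, length(out <- pos)) # recycle
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- map[map$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) stop("chromosome ", ch, " absent from genetic map")
    if (nrow(sub) == 1) {
      out[sel] <- sub$cum
    } else {
      out[sel] <- stats::approx(sub$pos, sub$cum, xout = pos[sel], rule = 2)$y
    }
  }
  out
}

# inverse map: physical position at cumulative cM (used to place crossovers)
#' @keywords internal
genetic_cm_inverse <- function(map, chrom, cm) {
  chrom <- normalize_chrom(chrom)
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(sub) < 2 || max(sub$cum) == min(sub$cum)) {
    # degenerate (zero-rate) map: place uniformly in physical space
    return(stats::runif(length(cm), min(sub$pos), max(sub$pos)))
  }
  stats::approx(sub$cum, sub$pos, xout = cm, rule = 2, ties = "ordered")$y
}
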