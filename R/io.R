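# Readers/writers for the package's external formats:
#   panel BED (+ metadata columns), genotype VCF/TSV, plasma allele-depth
#   VCF/TSV, bin-count TSV, JSON reports.

## ---- SNP panel -------------------------------------------------------------

.PANEL_COLS <- c("chrom", "pos", "ref", "alt", "maf", "gc_flank",
                 "mappability", "gene", "in_boost_region")

#' Construct and validate a SNP panel
#'
#' A panel is an ordered table of biallelic SNP loci with optional
#' allele-frequency/GC/mappability metadata and target-gene annotations.
#' Positions are 1-based. Loci are sorted by (chrom, pos) and must be unique.
#'
#' @param df Data frame with at least `chrom`, `pos`, `ref`, `alt`; optional
#'   `maf`, `gc_flank`, `mappability` (all in \[0,1\]), `gene`,
#'   `in_boost_region`.
#' @return An object of class `snp_panel`.
#' @export
new_snp_panel <- function(df) {
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  df$chrom <- normalize_chrom(df$chrom)
  if (nrow(df)) {
    if (any(df$pos < 1)) stop("panel positions must be >= 1")
    same <- !is.na(df$ref) & !is.na(df$alt) & df$ref == df$alt
    if (any(same)) stop("ref and alt alleles must differ (first offender row ",
                        which(same)[1], ")")
  }
  for (col in c("maf", "gc_flank", "mappability")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1)))
        stop("panel column '", col, "' must lie in [0, 1]")
    }
  }
  o <- order(chrom_factor(df$chrom), df$pos)
  if (any(o != seq_along(o))) {
    warning("panel loci were not sorted by (chrom, pos); sorting")
    df <- df[o, , drop = FALSE]
  }
  if (anyDuplicated(locus_key(df$chrom, df$pos)))
    stop("panel contains duplicated loci")
  rownames(df) <- NULL
  structure(df, class = c("snp_panel", "data.frame"))
}

#' Read a SNP panel from a BED-like table
#'
#' Expects whitespace/tab-separated columns
#' `chrom start end ref alt [maf gc_flank mappability [gene in_boost_region]]`
#' with 0-based half-open intervals of width 1 (the usual BED encoding of a
#' SNP). `start + 1` becomes the internal 1-based position. Lines starting
#' with `#` are ignored. Unsorted input is sorted with a warning.
#'
#' @param path Path to the BED-like file.
#' @return A `snp_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- readLines(path)
  raw <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  if (!length(raw)) {
    warning("empty panel file: ", path)
    return(new_snp_panel(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character())))
  }
  fields <- strsplit(raw, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 5)) {
    stop("malformed panel line ", which(nf < 5)[1], ": expected >= 5 fields")
  }
  ncol_use <- min(nf)
  m <- t(vapply(fields, function(f) f[seq_len(ncol_use)], character(ncol_use)))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  cn <- c("chrom", "start", "end", "ref", "alt", "maf", "gc_flank",
          "mappability", "gene", "in_boost_region")
  names(df) <- cn[seq_len(ncol_use)]
  for (col in intersect(c("start", "end", "maf", "gc_flank", "mappability"), names(df))) {
    raw_na <- df[[col]] %in% c("NA", ".")
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !raw_na
    if (any(bad)) stop("malformed panel line ", which(bad)[1],
                       ": non-numeric '", col, "'")
    df[[col]] <- v
  }
  bad <- df$end - df$start != 1
  if (any(bad)) stop("malformed panel line ", which(bad)[1],
                     ": expected width-1 interval (SNP)")
  df$pos <- as.integer(df$start + 1) # 0-based half-open -> 1-based
  if ("gene" %in% names(df)) df$gene[df$gene == "."] <- NA_character_
  if ("in_boost_region" %in% names(df))
    df$in_boost_region <- df$in_boost_region %in% c("1", "TRUE", "true")
  df$start <- NULL; df$end <- NULL
  new_snp_panel(df[, intersect(.PANEL_COLS, names(df)), drop = FALSE])
}

#' Write a SNP panel as a BED-like table
#'
#' Inverse of [read_panel()]: positions are emitted as 0-based half-open
#' width-1 intervals; the read -> write -> read round trip is the identity
#' on canonical files.
#'
#' @param panel A `snp_panel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  out <- data.frame(chrom = df$chrom, start = df$pos - 1L, end = df$pos,
                    ref = df$ref, alt = df$alt)
  for (col in c("maf", "gc_flank", "mappability", "gene", "in_boost_region")) {
    if (col %in% names(df)) out[[col]] <- df[[col]]
  }
  if ("gene" %in% names(out)) out$gene[is.na(out$gene)] <- "."
  if ("in_boost_region" %in% names(out)) out$in_boost_region <- as.integer(out$in_boost_region)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- genotypes -------------------------------------------------------------

.ROLES <- c("father", "mother", "proband", "relative-paternal-side",
            "relative-maternal-side", "fetus-truth")

#' Construct a genotype table
#'
#' Per-locus alternate-allele dosages in \{0, 1, 2, NA\} for one individual,
#' with a family-role label.
#'
#' @param df Data frame with `chrom`, `pos`, `dosage`.
#' @param id Individual identifier.
#' @param role One of `r paste(.ROLES, collapse = ", ")`.
#' @return A `genotype_table`.
#' @export
new_genotype_table <- function(df, id = "sample", role = "father") {
  role <- match.arg(role, .ROLES)
  stopifnot(all(c("chrom", "pos", "dosage") %in% names(df)))
  df$chrom <- normalize_chrom(df$chrom)
  ok <- is.na(df$dosage) | df$dosage %in% 0:2
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA (first offender row ",
                     which(!ok)[1], ")")
  df <- order_loci(df[, c("chrom", "pos", "dosage")])
  rownames(df) <- NULL
  structure(df, id = id, role = role, class = c("genotype_table", "data.frame"))
}

# GT string ("0/1", "1|1", "./.") -> alt dosage or NA
#' @keywords internal
gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (any(a == "." | is.na(a))) return(NA_real_)
    sum(as.numeric(a) > 0)
  }, numeric(1))
}

#' Read genotypes from a VCF or a chrom/pos/dosage TSV
#'
#' VCF input uses the GT field of the (single) sample; phased and unphased
#' separators are accepted and missing genotypes propagate as `NA`. TSV
#' input needs a header with columns `chrom`, `pos`, `dosage`. When a panel
#' is supplied, off-panel loci are dropped with a message.
#'
#' @param path Path to a `.vcf` or TSV file.
#' @param role Family-role label (see [new_genotype_table()]).
#' @param id Individual id; defaults to the VCF sample name or the file name.
#' @param panel Optional `snp_panel` used to restrict loci.
#' @return A `genotype_table`.
#' @export
read_genotypes <- function(path, role, id = NULL, panel = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix)) # single-variant VCF
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(id)) id <- colnames(gt)[1]
    df <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     dosage = gt_to_dosage(gt[, 1]))
  } else {
    df <- data.table::fread(path, data.table = FALSE)
    stopifnot(all(c("chrom", "pos", "dosage") %in% names(df)))
    if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (!is.null(panel)) {
    keep <- locus_key(df$chrom, df$pos) %in% locus_key(panel$chrom, panel$pos)
    if (any(!keep)) message(sum(!keep), " locus/loci not in panel skipped")
    df <- df[keep, , drop = FALSE]
  }
  new_genotype_table(df, id = id, role = role)
}

#' Write a genotype table as a minimal single-sample VCF
#'
#' @param gt A `genotype_table`.
#' @param path Output path.
#' @param panel `snp_panel` supplying REF/ALT alleles.
#' @export
write_genotypes_vcf <- function(gt, path, panel) {
  key <- locus_key(panel$chrom, panel$pos)
  i <- match(locus_key(gt$chrom, gt$pos), key)
  if (anyNA(i)) stop("genotype loci absent from panel")
  gts <- c("0/0", "0/1", "1/1")[gt$dosage + 1]
  gts[is.na(gts)] <- "./."
  id <- attr(gt, "id") %||% "sample"
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", id))
  body <- paste(gt$chrom, gt$pos, ".", panel$ref[i], panel$alt[i], ".", ".", ".",
                "GT", gts, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- plasma allele depths --------------------------------------------------

#' Construct plasma allele depths
#'
#' Per-locus reference/alternate read counts from maternal plasma cfDNA.
#'
#' @param df Data frame with `chrom`, `pos`, `ref_depth`, `alt_depth`.
#' @param sample_id Sample identifier.
#' @return A `plasma_depths` object; `attr(, "mean_depth")` holds the mean
#'   total depth over loci.
#' @export
new_plasma_depths <- function(df, sample_id = "plasma") {
  stopifnot(all(c("chrom", "pos", "ref_depth", "alt_depth") %in% names(df)))
  if (any(df$ref_depth < 0 | df$alt_depth < 0, na.rm = TRUE))
    stop("allele depths must be non-negative")
  df$chrom <- normalize_chrom(df$chrom)
  df <- order_loci(df)
  rownames(df) <- NULL
  structure(df, sample_id = sample_id,
            mean_depth = mean(df$ref_depth + df$alt_depth),
            class = c("plasma_depths", "data.frame"))
}

#' Read plasma allele depths from a TSV or an AD-annotated VCF
#'
#' TSV input needs columns `chrom`, `pos`, `ref_depth`, `alt_depth`
#' (allele columns, if present, are carried along). VCF input takes the
#' sample's `AD` field as `ref,alt`.
#'
#' @inheritParams read_genotypes
#' @param sample_id Sample identifier (defaults to VCF sample/file name).
#' @return A `plasma_depths` object.
#' @export
read_plasma_depths <- function(path, sample_id = NULL, panel = NULL) {
  if (!file.exists(path)) stop("plasma depth file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix)) # single-variant VCF
    ad <- vcfR::extract.gt(v, element = "AD")
    if (is.null(sample_id)) sample_id <- colnames(ad)[1]
    parts <- strsplit(ad[, 1], ",")
    df <- data.frame(
      chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
      ref_depth = as.numeric(vapply(parts, `[`, character(1), 1)),
      alt_depth = as.numeric(vapply(parts, `[`, character(1), 2))
    )
  } else {
    df <- data.table::fread(path, data.table = FALSE)
    stopifnot(all(c("chrom", "pos", "ref_depth", "alt_depth") %in% names(df)))
    if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (!is.null(panel)) {
    keep <- locus_key(df$chrom, df$pos) %in% locus_key(panel$chrom, panel$pos)
    if (any(!keep)) message(sum(!keep), " locus/loci not in panel skipped")
    df <- df[keep, , drop = FALSE]
  }
  new_plasma_depths(df, sample_id = sample_id)
}

#' Write plasma allele depths to TSV
#' @param depths A `plasma_depths`.
#' @param path Output path.
#' @export
write_plasma_depths <- function(depths, path) {
  data.table::fwrite(as.data.frame(depths), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
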