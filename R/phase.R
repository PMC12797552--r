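# Maternal genotype inference from plasma, informative-SNP classification,
# and parental haplotype phasing through a proband (PAHP) or through
# relatives (RAHP), linking the pathogenic allele to Hap0.

#' Infer maternal genotypes from plasma allele depths
#'
#' The ref-total-ratio `r = ref_depth / (ref_depth + alt_depth)` is banded:
#' `r < 0.15` homozygous-alt (dosage 2), `r > 0.85` homozygous-ref (0),
#' `0.3 <= r <= 0.7` heterozygous (1); ratios in the ambiguous zones
#' (0.15-0.3, 0.7-0.85) and zero-depth loci are missing.
#'
#' @param depths A `plasma_depths`.
#' @return A `genotype_table` with role `"mother"`.
#' @export
infer_maternal_genotypes <- function(depths) {
  tot <- depths$ref_depth + depths$alt_depth
  r <- ifelse(tot > 0, depths$ref_depth / tot, NA_real_)
  dosage <- rep(NA_real_, length(r))
  dosage[!is.na(r) & r < 0.15] <- 2
  dosage[!is.na(r) & r > 0.85] <- 0
  dosage[!is.na(r) & r >= 0.3 & r <= 0.7] <- 1
  new_genotype_table(
    data.frame(chrom = depths$chrom, pos = depths$pos, dosage = dosage),
    id = paste0(attr(depths, "sample_id"), "_inferred"), role = "mother")
}

#' Classify panel loci into iSNP groups
#'
#' Group 1: parents homozygous for different alleles; Group 2: homozygous
#' for the same allele; Group 3 (paternal iSNPs): father heterozygous,
#' mother homozygous; Group 4 (maternal iSNPs): mother heterozygous, father
#' homozygous. Loci with a missing genotype in either parent are excluded.
#' The groups are disjoint by construction.
#'
#' @inheritParams select_group1_loci
#' @return An `isnp_set`: data frame `chrom`, `pos`, `father_dosage`,
#'   `mother_dosage`, `group` (1-4; loci with both parents het are dropped).
#' @export
classify_isnps <- function(father_gt, mother_gt) {
  m <- merge_dosages(father_gt, mother_gt)
  m <- m[!is.na(m$d1) & !is.na(m$d2), , drop = FALSE]
  grp <- rep(NA_integer_, nrow(m))
  hom1 <- m$d1 %in% c(0, 2); hom2 <- m$d2 %in% c(0, 2)
  grp[hom1 & hom2 & m$d1 != m$d2] <- 1L
  grp[hom1 & hom2 & m$d1 == m$d2] <- 2L
  grp[m$d1 == 1 & hom2] <- 3L
  grp[m$d2 == 1 & hom1] <- 4L
  out <- m[!is.na(grp), , drop = FALSE]
  names(out)[3:4] <- c("father_dosage", "mother_dosage")
  out$group <- grp[!is.na(grp)]
  rownames(out) <- NULL
  structure(out, class = c("isnp_set", "data.frame"))
}

# deduce the transmitted allele of the heterozygous parent at iSNP loci:
# the homozygous parent contributes its allele, so the child's remaining
# allele came from the het parent. Returns alt indicator (0/1) or NA on
# Mendelian inconsistency.
#' @keywords internal
deduce_transmitted <- function(child_dosage, other_hom_dosage) {
  t <- child_dosage - other_hom_dosage / 2
  t[!(t %in% c(0, 1))] <- NA_real_
  t
}

#' @keywords internal
new_phased_parents <- function(father, mother, mode, n_mendel_err = 0L,
                               n_total = NA_integer_) {
  structure(list(father = father, mother = mother, phasing_mode = mode,
                 n_mendelian_errors = n_mendel_err, n_loci = n_total),
            class = "phased_parents")
}

#' Proband-assisted haplotype phasing (PAHP)
#'
#' At each paternal iSNP (Group 3) the mother is homozygous, so the allele
#' the proband did not receive from her identifies the paternally
#' transmitted allele; symmetrically for maternal iSNPs (Group 4). The
#' proband-transmitted haplotype of a carrier parent is labeled Hap0 when
#' the proband inherited that parent's pathogenic allele (deduced by the
#' same Mendelian logic at the variant locus), otherwise Hap1. Loci with a
#' Mendelian inconsistency are flagged and excluded; a rate above
#' `max_mendel_rate` aborts with a sample-swap warning.
#'
#' For X-linked families the proband is hemizygous on chrX (dosage coded
#' 0/2) and the maternally transmitted allele is read directly.
#'
#' @param isnps An [classify_isnps()] result.
#' @param proband_gt Proband `genotype_table`.
#' @param variant_loci Data frame `chrom`, `pos`, `parent`
#'   (`"father"`/`"mother"`/`"both"`) of pathogenic panel loci (alt allele =
#'   pathogenic).
#' @param inheritance `"AR"`, `"AD"` or `"XL"`.
#' @param father_gt,mother_gt Optional parent genotype tables, consulted at
#'   variant loci that fall outside the iSNP groups (e.g. an AR variant
#'   locus where both parents are heterozygous).
#' @param max_mendel_rate Abort threshold on the Mendelian-error fraction.
#' @return A `phased_parents` object: per parent a data frame `chrom`,
#'   `pos`, `hap0`, `hap1` (alt indicators) over that parent's phased iSNPs.
#' @export
phase_pahp <- function(isnps, proband_gt, variant_loci,
                       inheritance = c("AR", "AD", "XL"),
                       father_gt = NULL, mother_gt = NULL,
                       max_mendel_rate = 0.01) {
  inheritance <- match.arg(inheritance)
  key_p <- locus_key(proband_gt$chrom, proband_gt$pos)
  n_err <- 0L; n_tot <- 0L
  xl <- inheritance == "XL"

  phase_side <- function(group, het_col, hom_col) {
    sub <- isnps[isnps$group == group, , drop = FALSE]
    i <- match(locus_key(sub$chrom, sub$pos), key_p)
    sub <- sub[!is.na(i), , drop = FALSE]
    pd <- proband_gt$dosage[i[!is.na(i)]]
    x <- sub$chrom == "chrX"
    if (group == 4L && xl) {
      # hemizygous male proband on chrX: his single allele is maternal
      t <- ifelse(x, pd / 2, deduce_transmitted(pd, sub[[hom_col]]))
      t[x & !(t %in% c(0, 1))] <- NA_real_
    } else {
      t <- deduce_transmitted(pd, sub[[hom_col]])
    }
    n_tot <<- n_tot + nrow(sub)
    n_err <<- n_err + sum(is.na(t) & !is.na(pd))
    keep <- !is.na(t)
    data.frame(chrom = sub$chrom[keep], pos = sub$pos[keep],
               transmitted = t[keep],
               untransmitted = 1 - t[keep])
  }

  pat <- phase_side(3L, "father_dosage", "mother_dosage")
  mat <- phase_side(4L, "mother_dosage", "father_dosage")

  if (n_tot > 0 && n_err / n_tot > max_mendel_rate)
    stop("Mendelian inconsistency at ", signif(100 * n_err / n_tot, 3),
         "% of iSNP loci; check for a sample swap")

  # carrier-status linkage: did the proband inherit the variant from this
  # parent? If yes the proband-transmitted haplotype is Hap0. A homozygous
  # proband settles both parents at once; a heterozygous proband needs the
  # other parent homozygous at the locus (Mendel).
  other_dosage_at <- function(parent, chrom, pos) {
    j <- which(isnps$chrom == chrom & isnps$pos == pos)
    if (length(j)) {
      return(if (parent == "father") isnps$mother_dosage[j[1]]
             else isnps$father_dosage[j[1]])
    }
    gt <- if (parent == "father") mother_gt else father_gt
    if (is.null(gt)) return(NA_real_)
    j <- which(gt$chrom == chrom & gt$pos == pos)
    if (length(j)) gt$dosage[j[1]] else NA_real_
  }
  carrier_hap0 <- function(parent) {
    vl <- variant_loci[variant_loci$parent %in% c(parent, "both"), , drop = FALSE]
    if (!nrow(vl)) return(NULL) # non-carrier parent: arbitrary labels
    i <- match(locus_key(vl$chrom, vl$pos), key_p)
    if (anyNA(i)) stop("variant locus missing from proband genotypes")
    inherited <- vapply(seq_len(nrow(vl)), function(k) {
      pd <- proband_gt$dosage[i[k]]
      if (is.na(pd)) return(NA)
      if (xl && parent == "mother" && normalize_chrom(vl$chrom[k]) == "chrX")
        return(pd / 2 == 1) # hemizygous male proband: allele is maternal
      if (pd == 2) return(TRUE)
      if (pd == 0) return(FALSE)
      oh <- other_dosage_at(parent, vl$chrom[k], vl$pos[k])
      if (is.na(oh) || !(oh %in% c(0, 2))) return(NA)
      (pd - oh / 2) == 1
    }, logical(1))
    if (all(is.na(inherited)))
      stop("cannot link the ", parent, " variant: transmission undeducible ",
           "from the proband at the variant locus/loci")
    all(inherited, na.rm = TRUE)
  }

  label <- function(phased, hap0_is_transmitted) {
    if (is.null(hap0_is_transmitted) || isTRUE(hap0_is_transmitted)) {
      data.frame(chrom = phased$chrom, pos = phased$pos,
                 hap0 = phased$transmitted, hap1 = phased$untransmitted)
    } else {
      data.frame(chrom = phased$chrom, pos = phased$pos,
                 hap0 = phased$untransmitted, hap1 = phased$transmitted)
    }
  }

  new_phased_parents(
    father = label(pat, carrier_hap0("father")),
    mother = label(mat, carrier_hap0("mother")),
    mode = "PAHP", n_mendel_err = n_err, n_total = n_tot)
}

#' Relative-assisted haplotype phasing (RAHP)
#'
#' At loci where a parent is heterozygous and a relative on that side is
#' homozygous, the relative's allele marks the parental haplotype descending
#' from that relative's lineage. When the relative is a carrier whose
#' lineage transmitted the pathogenic allele, that lineage haplotype is
#' Hap0; otherwise it is Hap1.
#'
#' @param isnps An [classify_isnps()] result.
#' @param relatives List of relatives, each a list with `gt`
#'   (`genotype_table`), `side` (`"paternal"`/`"maternal"`) and `carrier`
#'   (logical: does the pathogenic lineage pass through this relative?).
#' @return A `phased_parents` object (sides without an informative relative
#'   raise an error).
#' @export
phase_rahp <- function(isnps, relatives) {
  sides <- vapply(relatives, `[[`, character(1), "side")
  phase_side <- function(side, group) {
    rels <- relatives[sides == side]
    if (!length(rels)) stop("no relative supplied for the ", side, " side")
    sub <- isnps[isnps$group == group, , drop = FALSE]
    hap0 <- rep(NA_real_, nrow(sub))
    for (rel in rels) {
      i <- match(locus_key(sub$chrom, sub$pos), locus_key(rel$gt$chrom, rel$gt$pos))
      rd <- rel$gt$dosage[i]
      informative <- !is.na(rd) & rd %in% c(0, 2)
      lineage_allele <- rd / 2 # the allele carried by the relative's lineage
      h0 <- if (isTRUE(rel$carrier)) lineage_allele else 1 - lineage_allele
      fill <- informative & is.na(hap0)
      hap0[fill] <- h0[fill]
      conflict <- informative & !is.na(hap0) & hap0 != h0
      hap0[conflict] <- NA_real_ # inconsistent relatives: leave unphased
    }
    keep <- !is.na(hap0)
    if (!any(keep)) stop("relative(s) uninformative genome-wide on the ",
                         side, " side")
    data.frame(chrom = sub$chrom[keep], pos = sub$pos[keep],
               hap0 = hap0[keep], hap1 = 1 - hap0[keep])
  }
  new_phased_parents(
    father = phase_side("paternal", 3L),
    mother = phase_side("maternal", 4L),
    mode = "RAHP")
}
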