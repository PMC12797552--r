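# Family and plasma simulator with known truth: parental haplotypes drawn at
# panel allele frequencies, map-driven meioses, plasma allele depths as a
# maternal+fetal binomial mixture with sequencing error, and 250-kb bin
# counts with GC bias, batch structure and aneuploidy/CNV effects.

#' Simulation configuration
#'
#' Study-condition defaults: cfDNA depth 150x, gDNA depth 50x, per-read
#' error 0.001, constant 1.2 cM/Mb genetic map with maternal/paternal rate
#' multipliers 1.4/0.85 (reproducing the maternal excess of crossovers),
#' binomial allele-depth emissions (optional beta-binomial overdispersion).
#'
#' @param seed Integer RNG seed.
#' @param ff Fetal fraction in (0, 1).
#' @param mean_depth_cfdna,mean_depth_gdna Mean per-locus read depths.
#' @param err Per-read substitution error probability (< 0.01).
#' @param map A `genetic_map`, or `NULL` for a constant `rate_cm_per_mb` map.
#' @param rate_cm_per_mb Rate of the fallback constant map.
#' @param maternal_rate_mult,paternal_rate_mult Sex-specific multipliers of
#'   the map rate used in maternal/paternal meioses.
#' @param phasing_mode `"PAHP"` (proband-assisted) or `"RAHP"`
#'   (relative-assisted): controls which family members are generated.
#' @param inheritance `"AR"`, `"AD"` or `"XL"`.
#' @param variant_parent For AD: `"father"` or `"mother"`. Ignored otherwise
#'   (AR uses both, XL uses the mother).
#' @param variant_loci Optional data frame `chrom`, `pos`, `parent` placing
#'   pathogenic alleles at panel loci; defaults are chosen automatically.
#' @param karyotype Fetal karyotype string, e.g. `"46,XX"`, `"47,XY,+21"`,
#'   `"45,X"`, `"47,XXY"`, `"47,XYY"`, `"47,XXX"`.
#' @param cnv_events Optional data frame `chrom`, `start`, `end`, `cn` of
#'   fetal copy-number events (used by the bin simulator).
#' @param overdispersion Beta-binomial intraclass correlation rho (0 =
#'   pure binomial).
#' @param genome Named chromosome-length vector.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ff = 0.10, mean_depth_cfdna = 150,
                       mean_depth_gdna = 50, err = 0.001, map = NULL,
                       rate_cm_per_mb = 1.2, maternal_rate_mult = 1.4,
                       paternal_rate_mult = 0.85,
                       phasing_mode = c("PAHP", "RAHP"),
                       inheritance = c("AR", "AD", "XL"),
                       variant_parent = "father", variant_loci = NULL,
                       karyotype = "46,XX", cnv_events = NULL,
                       overdispersion = 0, genome = default_genome()) {
  phasing_mode <- match.arg(phasing_mode)
  inheritance <- match.arg(inheritance)
  stopifnot(ff > 0, ff < 1, mean_depth_cfdna > 0, mean_depth_gdna > 0,
            err >= 0, err < 0.01, overdispersion >= 0, overdispersion < 1)
  if (is.null(map)) map <- constant_genetic_map(genome, rate_cm_per_mb)
  kar <- parse_karyotype(karyotype)
  structure(list(seed = as.integer(seed), ff = ff,
                 mean_depth_cfdna = mean_depth_cfdna,
                 mean_depth_gdna = mean_depth_gdna, err = err, map = map,
                 maternal_rate_mult = maternal_rate_mult,
                 paternal_rate_mult = paternal_rate_mult,
                 phasing_mode = phasing_mode, inheritance = inheritance,
                 variant_parent = variant_parent, variant_loci = variant_loci,
                 karyotype = karyotype, kar = kar, cnv_events = cnv_events,
                 overdispersion = overdispersion, genome = genome),
            class = "sim_config")
}

#' Parse a karyotype string
#'
#' @param x E.g. `"46,XY"`, `"47,XX,+21"`, `"45,X"`, `"47,XXY"`.
#' @return List with `n_x`, `n_y`, `trisomy` (autosome number or `NA`) and
#'   `fetal_sex` (`"male"` iff a Y is present).
#' @export
parse_karyotype <- function(x) {
  parts <- strsplit(gsub(" ", "", x), ",")[[1]]
  sex <- parts[2]
  if (!grepl("^[XY]+$", sex)) stop("cannot parse karyotype: ", x)
  tri <- NA_integer_
  if (length(parts) >= 3) {
    if (!grepl("^\\+(13|18|21)$", parts[3])) stop("unsupported karyotype: ", x)
    tri <- as.integer(sub("\\+", "", parts[3]))
  }
  n_x <- sum(strsplit(sex, "")[[1]] == "X")
  n_y <- sum(strsplit(sex, "")[[1]] == "Y")
  list(n_x = n_x, n_y = n_y, trisomy = tri,
       fetal_sex = if (n_y > 0) "male" else "female")
}

## ---- haplotypes and meiosis ------------------------------------------------

#' Generate a synthetic SNP panel at fixed average spacing
#'
#' Loci are placed on a jittered regular grid; minor-allele frequencies are
#' uniform on `maf_range`, flank GC uniform on (0.3, 0.7) and mappability
#' uniform on (0.86, 1), i.e. all loci pass the design filters.
#'
#' @param genome Named chromosome-length vector.
#' @param spacing Average inter-SNP distance (bp).
#' @param chroms Chromosomes to cover (default: autosomes + chrX).
#' @param maf_range Range of simulated allele frequencies.
#' @return A `snp_panel`.
#' @export
simulate_panel <- function(genome = default_genome(), spacing = 25000,
                           chroms = setdiff(names(genome), "chrY"),
                           maf_range = c(0.30, 0.70)) {
  tabs <- lapply(chroms, function(ch) {
    L <- genome[[ch]]
    grid <- seq(spacing / 2, L, by = spacing)
    pos <- round(grid + stats::runif(length(grid), -0.25, 0.25) * spacing)
    pos <- sort(unique(pmin(pmax(pos, 1), L)))
    n <- length(pos)
    ra <- matrix(c("A", "G", "C", "T")[cbind(sample(1:4, n, TRUE),
                                             sample(1:4, n, TRUE))], ncol = 2)
    flip <- ra[, 1] == ra[, 2]
    ra[flip, 2] <- c(A = "G", C = "T", G = "A", T = "C")[ra[flip, 1]]
    data.frame(chrom = ch, pos = pos, ref = ra[, 1], alt = ra[, 2],
               maf = stats::runif(n, maf_range[1], maf_range[2]),
               gc_flank = stats::runif(n, 0.30, 0.70),
               mappability = stats::runif(n, 0.86, 1))
  })
  new_snp_panel(do.call(rbind, tabs))
}

#' Draw parental haplotypes at panel allele frequencies
#'
#' Four haplotypes (`F0`, `F1`, `M0`, `M1`; alt-allele indicators) are drawn
#' independently Bernoulli(maf) per locus. Pathogenic alleles are placed on
#' the Hap0 of each carrier parent at `variant_loci` (Hap1 and the
#' non-carrier parent forced wild-type there), per the inheritance mode.
#'
#' @param panel A `snp_panel` with `maf`.
#' @param cfg A [sim_config()].
#' @return A partial truth list with the haplotype matrix `H` (loci x 4),
#'   the panel and the variant table.
#' @export
simulate_parent_haplotypes <- function(panel, cfg) {
  n <- nrow(panel)
  H <- matrix(stats::rbinom(4L * n, 1L, rep(panel$maf, 4)), ncol = 4,
              dimnames = list(NULL, c("F0", "F1", "M0", "M1")))
  vl <- cfg$variant_loci
  if (is.null(vl)) vl <- default_variant_loci(panel, cfg)
  if (nrow(vl)) {
    i <- match(locus_key(vl$chrom, vl$pos), locus_key(panel$chrom, panel$pos))
    if (anyNA(i)) stop("variant locus absent from panel: ",
                       paste(locus_key(vl$chrom, vl$pos)[is.na(i)], collapse = ", "))
    for (k in seq_len(nrow(vl))) {
      H[i[k], ] <- 0L
      if (vl$parent[k] %in% c("father", "both")) H[i[k], "F0"] <- 1L
      if (vl$parent[k] %in% c("mother", "both")) H[i[k], "M0"] <- 1L
    }
    vl$idx <- i
  }
  list(panel = panel, H = H, variant_loci = vl)
}

# default variant placement: a mid-chromosome panel locus (chr1 for
# autosomal modes, chrX for XL); AR uses one shared locus for both parents
#' @keywords internal
default_variant_loci <- function(panel, cfg) {
  ch <- if (cfg$inheritance == "XL") "chrX" else "chr1"
  idx <- which(panel$chrom == ch)
  if (!length(idx)) stop("panel has no loci on ", ch, " for variant placement")
  i <- idx[which.min(abs(panel$pos[idx] - stats::median(panel$pos[idx])))]
  parent <- switch(cfg$inheritance,
                   AR = "both", AD = cfg$variant_parent, XL = "mother")
  data.frame(chrom = panel$chrom[i], pos = panel$pos[i], parent = parent,
             stringsAsFactors = FALSE)
}

#' Simulate one meiosis over the panel loci
#'
#' Crossover counts per chromosome are Poisson(genetic length in Morgans);
#' positions are placed by inverting the cumulative map. The transmitted
#' haplotype starts from a random parental haplotype and switches source at
#' each crossover (no interference).
#'
#' @param hapA,hapB Alt-indicator vectors over the panel loci.
#' @param panel The `snp_panel` the haplotypes live on.
#' @param map A `genetic_map`.
#' @param rate_mult Sex-specific multiplier of the map's genetic length.
#' @return List with `allele` (transmitted alt indicators), `source`
#'   (0 = hapA, 1 = hapB per locus) and `crossovers` (chrom, pos).
#' @export
simulate_meiosis <- function(hapA, hapB, panel, map, rate_mult = 1) {
  n <- nrow(panel)
  source <- integer(n)
  xo <- list()
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    cm <- genetic_cm(map, ch, c(1, max(panel$pos[idx])))
    L_cm <- (cm[2] - cm[1]) * rate_mult
    n_xo <- stats::rpois(1, L_cm / 100)
    start <- stats::rbinom(1, 1, 0.5)
    if (n_xo > 0) {
      xo_cm <- sort(stats::runif(n_xo, cm[1], cm[2]))
      xo_pos <- genetic_cm_inverse(map, ch, xo_cm)
      nbelow <- findInterval(panel$pos[idx], xo_pos)
      source[idx] <- (start + nbelow) %% 2L
      xo[[length(xo) + 1]] <- data.frame(chrom = ch, pos = xo_pos)
    } else {
      source[idx] <- start
    }
  }
  allele <- ifelse(source == 0L, hapA, hapB)
  crossovers <- if (length(xo)) do.call(rbind, xo) else
    data.frame(chrom = character(), pos = numeric())
  list(allele = allele, source = source, crossovers = crossovers)
}

# relabel which parental haplotype counts as the meiosis start so that the
# transmitted source at `idx` equals `want` (0 = first hap). Label swapping
# maps a meiosis to an equally probable one, so conditioning this way is
# exact.
#' @keywords internal
orient_meiosis <- function(meio, hapA, hapB, idx, want = 0L) {
  if (length(idx) && meio$source[idx[1]] != want) {
    meio$source <- 1L - meio$source
    meio$allele <- ifelse(meio$source == 0L, hapA, hapB)
  }
  meio
}

## ---- whole families --------------------------------------------------------

#' Simulate a complete family with plasma cfDNA
#'
#' Generates parental haplotypes, a proband (PAHP) or genotyped grandparents
#' (RAHP), a fetus via map-driven meioses, and maternal plasma allele depths.
#' The proband is conditioned (by haplotype-label symmetry, which is exact)
#' to carry the pathogenic parental haplotypes implied by the inheritance
#' mode; the fetal meioses are unconditioned.
#'
#' @param panel A `snp_panel`.
#' @param cfg A [sim_config()]; `cfg$seed` seeds the whole family.
#' @return A `sim_family` list: `truth` (haplotypes, fetal transmitted
#'   sources/alleles per parent, crossovers, variant table, fetal sex),
#'   genotype tables (`father_gt`, `mother_gt`, `proband_gt`, `relatives`)
#'   and `plasma`.
#' @export
simulate_family <- function(panel, cfg) {
  force(panel) # evaluate before seeding: the promise may itself use the RNG
  set.seed(cfg$seed)
  truth <- simulate_parent_haplotypes(panel, cfg)
  H <- truth$H
  vl <- truth$variant_loci
  map <- cfg$map
  male_fetus <- cfg$kar$fetal_sex == "male"
  x_loci <- panel$chrom == "chrX"

  pat_idx <- vl$idx[vl$parent %in% c("father", "both")]
  mat_idx <- vl$idx[vl$parent %in% c("mother", "both")]

  relatives <- NULL
  if (cfg$phasing_mode == "RAHP") {
    # grandparents: each parental haplotype descends from one grandparent's
    # meiosis; the genotyped relative is the grandfather on each side and the
    # pathogenic lineage passes through him when that side carries a variant
    relatives <- list()
    for (side in c("paternal", "maternal")) {
      gf <- matrix(stats::rbinom(2L * nrow(panel), 1L, rep(panel$maf, 2)), ncol = 2)
      gm <- matrix(stats::rbinom(2L * nrow(panel), 1L, rep(panel$maf, 2)), ncol = 2)
      vidx <- if (side == "paternal") pat_idx else mat_idx
      carrier <- length(vidx) > 0
      gf_meio <- simulate_meiosis(gf[, 1], gf[, 2], panel, map, 1)
      gm_meio <- simulate_meiosis(gm[, 1], gm[, 2], panel, map, 1)
      if (carrier) {
        gf_meio <- orient_meiosis(gf_meio, gf[, 1], gf[, 2], vidx, 0L)
        gf[vidx, 1] <- 1L; gf[vidx, 2] <- 0L
        gf_meio$allele[vidx] <- 1L
      }
      # overwrite this parent's haplotypes with the grandparental descent:
      # Hap0 (carrier lineage) from the grandfather, Hap1 from the grandmother
      cols <- if (side == "paternal") c("F0", "F1") else c("M0", "M1")
      H[, cols[1]] <- gf_meio$allele
      H[, cols[2]] <- gm_meio$allele
      if (length(vidx)) { H[vidx, cols[1]] <- 1L; H[vidx, cols[2]] <- 0L }
      role <- paste0("relative-", side, "-side")
      relatives[[side]] <- list(
        gt = new_genotype_table(
          data.frame(chrom = panel$chrom, pos = panel$pos,
                     dosage = gf[, 1] + gf[, 2]),
          id = paste0(side, "_grandfather"), role = role),
        side = side, carrier = carrier)
    }
    truth$H <- H
  }

  # proband meioses, conditioned on transmitting Hap0 at carrier variant loci
  pat_p <- simulate_meiosis(H[, "F0"], H[, "F1"], panel, map, cfg$paternal_rate_mult)
  mat_p <- simulate_meiosis(H[, "M0"], H[, "M1"], panel, map, cfg$maternal_rate_mult)
  pat_p <- orient_meiosis(pat_p, H[, "F0"], H[, "F1"], pat_idx, 0L)
  mat_p <- orient_meiosis(mat_p, H[, "M0"], H[, "M1"], mat_idx, 0L)

  # fetal meioses, unconditioned
  pat_f <- simulate_meiosis(H[, "F0"], H[, "F1"], panel, map, cfg$paternal_rate_mult)
  mat_f <- simulate_meiosis(H[, "M0"], H[, "M1"], panel, map, cfg$maternal_rate_mult)

  # the father is hemizygous on chrX: his single X (stored as F0) is what a
  # daughter receives; sons receive no paternal X
  if (any(x_loci)) {
    for (m in c("pat_p", "pat_f")) {
      mm <- get(m)
      mm$allele[x_loci] <- H[x_loci, "F0"]
      mm$source[x_loci] <- 0L
      mm$crossovers <- mm$crossovers[mm$crossovers$chrom != "chrX", , drop = FALSE]
      assign(m, mm)
    }
  }

  father_dos <- H[, "F0"] + H[, "F1"]
  mother_dos <- H[, "M0"] + H[, "M1"]

  # hemizygous chrX encoded as {0, 2} for males (single allele doubled)
  proband_male <- cfg$inheritance == "XL"
  proband_dos <- pat_p$allele + mat_p$allele
  if (proband_male && any(x_loci)) proband_dos[x_loci] <- 2L * mat_p$allele[x_loci]
  if (any(x_loci)) father_dos[x_loci] <- 2L * H[x_loci, "F0"]

  fetal_dos <- pat_f$allele + mat_f$allele
  fetal_ploidy <- rep(2L, nrow(panel))
  if (male_fetus && any(x_loci)) {
    fetal_dos[x_loci] <- mat_f$allele[x_loci]
    fetal_ploidy[x_loci] <- 1L
  }

  truth$fetal <- list(
    pat_source = pat_f$source, mat_source = mat_f$source,
    pat_allele = pat_f$allele, mat_allele = mat_f$allele,
    dosage = fetal_dos, ploidy = fetal_ploidy,
    crossovers = list(paternal = pat_f$crossovers, maternal = mat_f$crossovers))
  truth$proband <- list(
    pat_source = pat_p$source, mat_source = mat_p$source,
    crossovers = list(paternal = pat_p$crossovers, maternal = mat_p$crossovers))
  truth$fetal_sex <- cfg$kar$fetal_sex
  truth$mother_dosage <- mother_dos

  gt <- function(dos, id, role) new_genotype_table(
    data.frame(chrom = panel$chrom, pos = panel$pos, dosage = dos),
    id = id, role = role)

  fam <- list(
    panel = panel, cfg = cfg, truth = truth,
    father_gt = gt(father_dos, "father", "father"),
    mother_gt = gt(mother_dos, "mother", "mother"),
    proband_gt = gt(proband_dos, "proband", "proband"),
    relatives = relatives,
    variant_loci = vl)
  fam$plasma <- simulate_plasma(fam, cfg)
  class(fam) <- "sim_family"
  fam
}

#' Simulate maternal plasma allele depths
#'
#' Per locus: total depth ~ Poisson(`mean_depth_cfdna`); the expected
#' alt-read fraction is `f = ((1 - ff) g_m + ff g_f (2 / ploidy_f)) / 2`
#' (maternal dosage `g_m`, fetal dosage `g_f`, fetal ploidy 1 on male chrX),
#' mixed with symmetric sequencing error `f' = f (1 - err) + (1 - f) err`;
#' alt depth ~ Binomial(depth, f') (beta-binomial under overdispersion).
#'
#' @param fam A `sim_family` (or a list with `panel` and `truth` as built by
#'   [simulate_family()]).
#' @param cfg A [sim_config()].
#' @return A `plasma_depths` object.
#' @export
simulate_plasma <- function(fam, cfg) {
  panel <- fam$panel
  g_m <- fam$truth$mother_dosage
  g_f <- fam$truth$fetal$dosage
  ploidy <- fam$truth$fetal$ploidy
  f <- ((1 - cfg$ff) * g_m + cfg$ff * g_f * (2 / ploidy)) / 2
  fp <- f * (1 - cfg$err) + (1 - f) * cfg$err
  n <- nrow(panel)
  depth <- stats::rpois(n, cfg$mean_depth_cfdna)
  alt <- rbinom_od(n, depth, fp, cfg$overdispersion)
  new_plasma_depths(
    data.frame(chrom = panel$chrom, pos = panel$pos,
               ref = panel$ref, alt = panel$alt,
               ref_depth = depth - alt, alt_depth = alt),
    sample_id = "plasma_sim")
}

# binomial or beta-binomial (icc rho) draws
#' @keywords internal
rbinom_od <- function(n, size, prob, rho = 0) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  s <- (1 - rho) / rho
  p <- stats::rbeta(n, prob * s, (1 - prob) * s)
  stats::rbinom(n, size, p)
}

## ---- bin counts for the screening arm --------------------------------------

#' Tile a genome into fixed-width bins
#'
#' @param genome Named chromosome-length vector.
#' @param bin_size Bin width in bp (default 250 kb).
#' @return Data frame `chrom`, `start`, `end` (1-based inclusive), `gc`
#'   (smooth synthetic per-bin GC fraction).
#' @export
genome_bins <- function(genome = default_genome(), bin_size = 250e3) {
  tabs <- lapply(names(genome), function(ch) {
    nb <- floor(genome[[ch]] / bin_size)
    if (nb < 1) return(NULL)
    s <- (seq_len(nb) - 1) * bin_size + 1
    data.frame(chrom = ch, start = s, end = s + bin_size - 1)
  })
  bins <- do.call(rbind, tabs)
  t <- seq_len(nrow(bins))
  bins$gc <- pmin(0.65, pmax(0.30,
    0.45 + 0.06 * sin(2 * pi * t / 47) + 0.04 * sin(2 * pi * t / 301) +
      stats::rnorm(nrow(bins), 0, 0.01)))
  bins
}

#' Simulate a cohort of binned read-count profiles
#'
#' Per-bin counts are Poisson with a rate combining a shared per-bin
#' baseline, a sample-specific smooth GC-bias curve, a shared batch
#' direction with sample-specific scores, and the copy-number mixture
#' `c_mix = (1 - ff) c_maternal + ff c_fetal` (plasma samples) or the
#' sample's own copy number (gDNA baselines). chrY carries a small
#' mismapping background so female samples have a nonzero Y ratio.
#'
#' @param samples Data frame with columns `sample`, `type` ("plasma" or
#'   "gdna"), `karyotype`, `ff` (`NA` for gDNA), `is_reference` (logical).
#' @param cnv_events Optional data frame `sample`, `chrom`, `start`, `end`,
#'   `cn` of fetal copy-number events; events overlapping within a sample
#'   are an error.
#' @param genome,bin_size Bin tiling (see [genome_bins()]).
#' @param mean_bin_count Mean reads per bin at copy number 2.
#' @param gc_amp Scale of the per-sample GC-bias slopes.
#' @param batch_sd SD of the batch scores.
#' @param chry_background Mismapping background rate on chrY (fraction of an
#'   autosomal haploid-equivalent).
#' @param chrom_disp Per-sample, per-chromosome multiplicative noise SD
#'   (log scale). Real cfDNA chromosome proportions have CVs of 0.3-1.5%,
#'   far above Poisson counting noise, from residual library/GC effects;
#'   the default 0.005 reproduces that regime (and the moderate Z scores
#'   clinical sex-chromosome aneuploidies show).
#' @param seed RNG seed.
#' @return A `bin_matrix`: list with `bins`, `counts` (samples x bins) and
#'   `samples`.
#' @export
simulate_bin_cohort <- function(samples, cnv_events = NULL,
                                genome = default_genome(0.25),
                                bin_size = 250e3, mean_bin_count = 2000,
                                gc_amp = 1.0, batch_sd = 0.03,
                                chry_background = 0.002, chrom_disp = 0.005,
                                seed = 1L) {
  force(samples); force(cnv_events); force(genome)
  set.seed(seed)
  stopifnot(all(c("sample", "type", "karyotype", "ff", "is_reference") %in% names(samples)))
  bins <- genome_bins(genome, bin_size)
  nb <- nrow(bins)
  ns <- nrow(samples)
  baseline <- exp(stats::rnorm(nb, 0, 0.05))
  batch_dir <- as.numeric(stats::filter(stats::rnorm(nb), rep(1 / 15, 15),
                                        circular = TRUE))
  gcc <- bins$gc - mean(bins$gc)
  counts <- matrix(0L, ns, nb, dimnames = list(samples$sample, NULL))
  if (!is.null(cnv_events)) {
    stopifnot(all(c("sample", "chrom", "start", "end", "cn") %in% names(cnv_events)))
    cnv_events$chrom <- normalize_chrom(cnv_events$chrom)
    for (s in unique(cnv_events$sample)) {
      ev <- cnv_events[cnv_events$sample == s, , drop = FALSE]
      for (ch in unique(ev$chrom)) {
        e <- ev[ev$chrom == ch, , drop = FALSE]
        e <- e[order(e$start), , drop = FALSE]
        if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
          stop("overlapping CNV events for sample ", s, " on ", ch)
      }
    }
  }
  for (i in seq_len(ns)) {
    kar <- parse_karyotype(samples$karyotype[i])
    cn_f <- rep(2, nb)
    if (!is.na(kar$trisomy))
      cn_f[bins$chrom == paste0("chr", kar$trisomy)] <- 3
    cn_f[bins$chrom == "chrX"] <- kar$n_x
    cn_f[bins$chrom == "chrY"] <- kar$n_y
    if (!is.null(cnv_events)) {
      ev <- cnv_events[cnv_events$sample == samples$sample[i], , drop = FALSE]
      for (k in seq_len(nrow(ev))) {
        hit <- bins$chrom == ev$chrom[k] & bins$start >= ev$start[k] &
          bins$end <= ev$end[k]
        cn_f[hit] <- ev$cn[k]
      }
    }
    if (samples$type[i] == "plasma") {
      ff <- samples$ff[i]
      cn_m <- rep(2, nb)
      cn_m[bins$chrom == "chrY"] <- 0
      c_mix <- (1 - ff) * cn_m + ff * cn_f
    } else {
      c_mix <- cn_f
    }
    a <- stats::rnorm(1, 0, gc_amp)
    b <- stats::rnorm(1, -1, 0.5)
    gc_bias <- pmax(0.2, 1 + a * gcc + b * gcc^2)
    batch <- exp(stats::rnorm(1, 0, batch_sd) * batch_dir)
    chrom_noise <- exp(stats::rnorm(length(unique(bins$chrom)), 0, chrom_disp))
    names(chrom_noise) <- unique(bins$chrom)
    rate <- mean_bin_count * baseline * gc_bias * batch *
      chrom_noise[bins$chrom] *
      (c_mix / 2 + chry_background * (bins$chrom == "chrY"))
    counts[i, ] <- stats::rpois(nb, rate)
  }
  structure(list(bins = bins, counts = counts, samples = samples),
            class = "bin_matrix")
}

#' Simulate bins for one test sample plus a euploid reference cohort
#'
#' Convenience wrapper around [simulate_bin_cohort()]: emits `n_ref_samples`
#' euploid plasma references (alternating fetal sex, ff uniform 0.08-0.15),
#' adult male/female gDNA baselines, and one test sample drawn from
#' `cfg$karyotype` / `cfg$cnv_events` at `cfg$ff`.
#'
#' @param cfg A [sim_config()].
#' @param n_ref_samples Reference cohort size (default 126).
#' @param ... Passed to [simulate_bin_cohort()].
#' @return A `bin_matrix`; the test sample is named `"test"`.
#' @export
simulate_bins <- function(cfg, n_ref_samples = 126, ...) {
  ref <- data.frame(
    sample = sprintf("ref%03d", seq_len(n_ref_samples)),
    type = "plasma",
    karyotype = rep(c("46,XX", "46,XY"), length.out = n_ref_samples),
    ff = stats::runif(n_ref_samples, 0.08, 0.15),
    is_reference = TRUE)
  base <- data.frame(
    sample = c("gdna_female", "gdna_male"), type = "gdna",
    karyotype = c("46,XX", "46,XY"), ff = NA_real_, is_reference = FALSE)
  test <- data.frame(sample = "test", type = "plasma",
                     karyotype = cfg$karyotype, ff = cfg$ff,
                     is_reference = FALSE)
  cnv <- cfg$cnv_events
  if (!is.null(cnv)) cnv$sample <- "test"
  simulate_bin_cohort(rbind(ref, base, test), cnv_events = cnv,
                      genome = cfg$genome, seed = cfg$seed, ...)
}

#' Simulate a 4-Mb window containing one crossover
#'
#' Builds a single-chain decoding problem for one parent: `n_isnp`
#' informative SNPs placed uniformly in a window, one crossover at a
#' uniform position, parental haplotypes random at each het locus, plasma
#' depths from the mixture model. Used for the recombination-region
#' accuracy experiments behind the iSNP no-call thresholds.
#'
#' @param n_isnp Number of informative SNPs in the window.
#' @param ff Fetal fraction.
#' @param parent `"paternal"` or `"maternal"` chain.
#' @param depth Mean read depth.
#' @param err Sequencing error rate.
#' @param width Window width in bp (default 4 Mb).
#' @param rate_cm_per_mb Constant recombination rate for the transition model.
#' @return List: `chain` (ready for [decode_chain()]), `p_switch`,
#'   `truth_state` (0 = Hap0 transmitted per locus) and `xo_pos`.
#' @export
simulate_recomb_window <- function(n_isnp, ff, parent = c("paternal", "maternal"),
                                   depth = 200, err = 0.001, width = 4e6,
                                   rate_cm_per_mb = 1.2) {
  parent <- match.arg(parent)
  pos <- sort(sample.int(width, n_isnp))
  hap0 <- stats::rbinom(n_isnp, 1, 0.5) # het parent: hap1 is the complement
  hap1 <- 1 - hap0
  g_other <- 2 * stats::rbinom(n_isnp, 1, 0.5) # other parent homozygous
  xo_pos <- stats::runif(1, 0.1 * width, 0.9 * width)
  start <- stats::rbinom(1, 1, 0.5)
  state <- (start + (pos > xo_pos)) %% 2 # 0 = Hap0 transmitted
  transmitted <- ifelse(state == 0, hap0, hap1)
  if (parent == "paternal") {
    g_m <- g_other
    a_m <- g_other / 2
    f_true <- expected_alt_fraction(g_m, transmitted, a_m, ff, err)
    f0 <- expected_alt_fraction(g_m, hap0, a_m, ff, err)
    f1 <- expected_alt_fraction(g_m, hap1, a_m, ff, err)
  } else {
    a_p <- g_other / 2
    f_true <- expected_alt_fraction(1, a_p, transmitted, ff, err)
    f0 <- expected_alt_fraction(1, a_p, hap0, ff, err)
    f1 <- expected_alt_fraction(1, a_p, hap1, ff, err)
  }
  total <- stats::rpois(n_isnp, depth)
  alt <- stats::rbinom(n_isnp, total, f_true)
  chain <- data.frame(chrom = "chr1", pos = pos, total = total, alt = alt,
                      f0 = f0, f1 = f1)
  d_morgan <- diff(pos) / 1e6 * rate_cm_per_mb / 100
  list(chain = chain, p_switch = 0.5 * (1 - exp(-2 * d_morgan)),
       truth_state = state, xo_pos = xo_pos)
}

#' Recombination-window decoding accuracy at a distance from the crossover
#'
#' Repeatedly simulates a 4-Mb window containing one crossover (see
#' [simulate_recomb_window()]), decodes it, and scores decoding accuracy
#' over the iSNPs whose rank-distance from the true crossover is at least
#' `min_dist`. This is the quantity behind the recombination-region iSNP
#' minima in [nocall_policy()]: within a few iSNPs of the breakpoint the
#' switch cannot be localized exactly by any decoder, so the clinically
#' relevant question is how reliably loci are assigned once at least
#' `min_dist` informative SNPs separate them from the crossover.
#'
#' @param parent `"paternal"` or `"maternal"` chain.
#' @param n_windows Number of simulated windows.
#' @param n_isnp iSNPs per window (a single count, recycled).
#' @param ff_range Length-2 numeric; per-window ff is drawn uniformly.
#' @param min_dist Minimum iSNP rank-distance from the true crossover for a
#'   locus to be scored.
#' @param depth Mean read depth per iSNP.
#' @param err Sequencing error rate.
#' @return List: `accuracy` (pooled over scored loci), `n_loci` (number
#'   scored), `n_windows`, and `per_window` accuracies (NA when a window
#'   has no locus at the required distance).
#' @export
recomb_window_accuracy <- function(parent = c("paternal", "maternal"),
                                   n_windows = 200, n_isnp = 55,
                                   ff_range = c(0.07, 0.15), min_dist = 10,
                                   depth = 200, err = 0.001) {
  parent <- match.arg(parent)
  correct <- 0L; scored <- 0L
  per_window <- rep(NA_real_, n_windows)
  for (w in seq_len(n_windows)) {
    ff <- stats::runif(1, ff_range[1], ff_range[2])
    win <- simulate_recomb_window(n_isnp, ff, parent, depth = depth, err = err)
    fit <- decode_chain(win$chain, win$p_switch)
    dec <- match(fit$loci$state, c("Hap0", "Hap1")) - 1L
    # crossover sits between two iSNP ranks; distance measured in ranks
    xo_rank <- sum(win$chain$pos < win$xo_pos) + 0.5
    far <- abs(seq_len(n_isnp) - xo_rank) >= min_dist
    if (any(far)) {
      hits <- dec[far] == win$truth_state[far]
      correct <- correct + sum(hits)
      scored <- scored + sum(far)
      per_window[w] <- mean(hits)
    }
  }
  list(accuracy = correct / scored, n_loci = scored, n_windows = n_windows,
       per_window = per_window)
}
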