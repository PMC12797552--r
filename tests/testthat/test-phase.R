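test_that("maternal genotype banding follows the ref-total-ratio rules exactly", {
  d <- 100
  mk <- function(r) new_plasma_depths(data.frame(
    chrom = "chr1", pos = seq_along(r) * 1000,
    ref_depth = round(r * d), alt_depth = d - round(r * d)))
  ratios <- c(0.50, 0.95, 0.20, 0.10, 0.30, 0.70, 0.80, 0.86)
  got <- infer_maternal_genotypes(mk(ratios))$dosage
  expect_equal(got, c(1, 0, NA, 2, 1, 1, NA, 0))
  # zero depth -> missing
  pd0 <- new_plasma_depths(data.frame(chrom = "chr1", pos = 1,
                                      ref_depth = 0, alt_depth = 0))
  expect_true(is.na(infer_maternal_genotypes(pd0)$dosage))
})

test_that("iSNP groups are assigned by parental genotype pattern and are disjoint", {
  father <- new_genotype_table(data.frame(chrom = "chr1", pos = 1:6 * 1000,
                                          dosage = c(1, 2, 0, 2, 1, NA)),
                               role = "father")
  mother <- new_genotype_table(data.frame(chrom = "chr1", pos = 1:6 * 1000,
                                          dosage = c(0, 1, 2, 2, 1, 0)),
                               role = "mother")
  is <- classify_isnps(father, mother)
  expect_equal(is$group[match(c(1000, 2000, 3000, 4000),  is$pos)],
               c(3L, 4L, 1L, 2L))
  expect_false(5000 %in% is$pos) # both het: no group
  expect_false(6000 %in% is$pos) # missing genotype excluded
  expect_equal(anyDuplicated(is$pos), 0L)
})

test_that("PAHP deduces transmitted alleles by Mendel and links Hap0 to the variant", {
  # father A/B (het), mother A/A: proband's non-maternal allele is paternal
  father <- new_genotype_table(data.frame(chrom = "chr1", pos = 1:3 * 1000,
                                          dosage = c(1, 1, 1)), role = "father")
  mother <- new_genotype_table(data.frame(chrom = "chr1", pos = 1:3 * 1000,
                                          dosage = c(0, 2, 0)), role = "mother")
  proband <- new_genotype_table(data.frame(chrom = "chr1", pos = 1:3 * 1000,
                                           dosage = c(1, 1, 0)), role = "proband")
  is <- classify_isnps(father, mother)
  vl <- data.frame(chrom = "chr1", pos = 1000, parent = "father")
  ph <- phase_pahp(is, proband, vl, "AD")
  # locus 1: mother hom-ref, proband het -> father sent alt; variant there -> Hap0 = alt
  expect_equal(ph$father$hap0[ph$father$pos == 1000], 1)
  # locus 2: mother hom-alt, proband het -> father sent ref; same haplotype
  expect_equal(ph$father$hap0[ph$father$pos == 2000], 0)
  # locus 3: proband hom-ref with mother hom-ref -> father sent ref
  expect_equal(ph$father$hap0[ph$father$pos == 3000], 0)
})

test_that("Mendelian inconsistencies are excluded and a high rate aborts", {
  father <- new_genotype_table(data.frame(chrom = "chr1", pos = 1:2 * 1000,
                                          dosage = c(1, 1)), role = "father")
  mother <- new_genotype_table(data.frame(chrom = "chr1", pos = 1:2 * 1000,
                                          dosage = c(0, 0)), role = "mother")
  # proband 2 with mother hom-ref is impossible
  proband <- new_genotype_table(data.frame(chrom = "chr1", pos = 1:2 * 1000,
                                           dosage = c(2, 1)), role = "proband")
  is <- classify_isnps(father, mother)
  vl <- data.frame(chrom = "chr1", pos = 2000, parent = "father")
  expect_error(phase_pahp(is, proband, vl, "AD"), "sample swap")
  ph <- phase_pahp(is, proband, vl, "AD", max_mendel_rate = 0.6)
  expect_false(1000 %in% ph$father$pos)
  expect_equal(ph$n_mendelian_errors, 1L)
})

test_that("PAHP reproduces the simulator's parental haplotypes", {
  fam <- small_family()
  mo <- infer_maternal_genotypes(fam$plasma)
  isnps <- classify_isnps(fam$father_gt, mo)
  ph <- phase_pahp(isnps, fam$proband_gt, fam$variant_loci, "AR")
  key <- paste(fam$panel$chrom, fam$panel$pos)
  # AR proband carries both variants: Hap0 is the proband-transmitted
  # haplotype, a mosaic of the true haplotypes along proband crossovers
  ip <- match(paste(ph$father$chrom, ph$father$pos), key)
  truth_pat <- ifelse(fam$truth$proband$pat_source[ip] == 0,
                      fam$truth$H[ip, "F0"], fam$truth$H[ip, "F1"])
  expect_gte(mean(ph$father$hap0 == truth_pat), 0.999)
  im <- match(paste(ph$mother$chrom, ph$mother$pos), key)
  truth_mat <- ifelse(fam$truth$proband$mat_source[im] == 0,
                      fam$truth$H[im, "M0"], fam$truth$H[im, "M1"])
  expect_gte(mean(ph$mother$hap0 == truth_mat), 0.999)
})

test_that("RAHP phases from homozygous relatives with carrier linkage", {
  # mother het at all loci; maternal grandfather homozygous at 1, 3
  isnps <- structure(data.frame(chrom = "chr1", pos = 1:3 * 1000,
                                father_dosage = c(0, 0, 2),
                                mother_dosage = c(1, 1, 1),
                                group = c(4L, 4L, 4L)),
                     class = c("isnp_set", "data.frame"))
  gf <- new_genotype_table(data.frame(chrom = "chr1", pos = 1:3 * 1000,
                                      dosage = c(2, 1, 0)),
                           role = "relative-maternal-side")
  # paternal side: make father's groups empty but side must still phase
  isnps_p <- structure(data.frame(chrom = "chr1", pos = 4000,
                                  father_dosage = 1, mother_dosage = 0,
                                  group = 3L),
                       class = c("isnp_set", "data.frame"))
  rels <- list(list(gt = gf, side = "maternal", carrier = TRUE),
               list(gt = new_genotype_table(
                 data.frame(chrom = "chr1", pos = 4000, dosage = 2),
                 role = "relative-paternal-side"),
                 side = "paternal", carrier = FALSE))
  ph <- phase_rahp(rbind(isnps, isnps_p), rels)
  # carrier grandfather hom-alt at locus 1 -> maternal Hap0 carries alt there
  expect_equal(ph$mother$hap0[ph$mother$pos == 1000], 1)
  expect_equal(ph$mother$hap0[ph$mother$pos == 3000], 0)
  expect_false(2000 %in% ph$mother$pos) # relative het: uninformative
  # non-carrier paternal relative hom-alt -> that lineage is Hap1
  expect_equal(ph$father$hap0[ph$father$pos == 4000], 0)
  # sides without relatives fail
  expect_error(phase_rahp(isnps, rels[1]), "paternal")
})

test_that("RAHP on a simulated family recovers Hap0 = the carrier lineage", {
  cfg <- sim_config(seed = 19, ff = 0.12, mean_depth_cfdna = 200,
                    genome = small_genome(), inheritance = "AR",
                    phasing_mode = "RAHP")
  fam <- simulate_family(small_panel(), cfg)
  mo <- infer_maternal_genotypes(fam$plasma)
  isnps <- classify_isnps(fam$father_gt, mo)
  rels <- list(
    list(gt = fam$relatives$paternal$gt, side = "paternal",
         carrier = fam$relatives$paternal$carrier),
    list(gt = fam$relatives$maternal$gt, side = "maternal",
         carrier = fam$relatives$maternal$carrier))
  ph <- phase_rahp(isnps, rels)
  key <- paste(fam$panel$chrom, fam$panel$pos)
  ip <- match(paste(ph$father$chrom, ph$father$pos), key)
  expect_gte(mean(ph$father$hap0 == fam$truth$H[ip, "F0"]), 0.999)
  im <- match(paste(ph$mother$chrom, ph$mother$pos), key)
  expect_gte(mean(ph$mother$hap0 == fam$truth$H[im, "M0"]), 0.999)
})

test_that("plasma-inferred maternal genotypes agree with truth at depth 150+", {
  fam <- small_family()
  mo <- infer_maternal_genotypes(fam$plasma)
  classified <- !is.na(mo$dosage)
  expect_gt(mean(classified), 0.9)
  expect_gte(mean(mo$dosage[classified] ==
                    fam$truth$mother_dosage[classified]), 0.99)
})
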