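test_that("parental haplotypes follow panel allele frequencies and variants sit on Hap0", {
  panel <- new_snp_panel(data.frame(chrom = "chr1", pos = 1:4 * 1e6,
                                    ref = "A", alt = "G",
                                    maf = c(1, 0, 0.5, 0.5)))
  cfg <- sim_config(seed = 3, inheritance = "AR",
                    variant_loci = data.frame(chrom = "chr1", pos = 3e6,
                                              parent = "both"),
                    genome = c(chr1 = 5e6))
  set.seed(3)
  tr <- simulate_parent_haplotypes(panel, cfg)
  expect_true(all(tr$H[1, ] == 1)) # maf 1 -> all alt
  expect_true(all(tr$H[2, ] == 0)) # maf 0 -> all ref
  expect_equal(unname(tr$H[3, ]), c(1, 0, 1, 0)) # variant on F0/M0 only
  expect_error(
    simulate_parent_haplotypes(panel, sim_config(
      variant_loci = data.frame(chrom = "chr1", pos = 999, parent = "both"),
      genome = c(chr1 = 5e6))),
    "absent")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_family_cfg()
  fam2 <- simulate_family(small_panel(), cfg)
  expect_identical(fam2$truth$H, small_family()$truth$H)
  expect_identical(fam2$plasma$alt_depth, small_family()$plasma$alt_depth)
})

test_that("zero-rate maps give crossover-free meioses", {
  panel <- small_panel()
  map0 <- constant_genetic_map(small_genome(), rate_cm_per_mb = 0)
  set.seed(5)
  hapA <- rbinom(nrow(panel), 1, 0.5)
  hapB <- 1 - hapA
  m <- simulate_meiosis(hapA, hapB, panel, map0)
  expect_equal(nrow(m$crossovers), 0L)
  for (ch in unique(panel$chrom)) {
    src <- m$source[panel$chrom == ch]
    expect_true(all(src == src[1])) # whole chromosome from one haplotype
  }
})

test_that("crossover counts are Poisson with mean = genetic length / 100", {
  g <- c(chr1 = 1e8)
  map <- constant_genetic_map(g, rate_cm_per_mb = 1) # 100 cM -> mean 1
  panel <- new_snp_panel(data.frame(chrom = "chr1", pos = c(1, 1e8),
                                    ref = "A", alt = "G", maf = 0.5))
  set.seed(11)
  counts <- replicate(2000, nrow(simulate_meiosis(c(0, 0), c(1, 1), panel, map)$crossovers))
  expect_lt(abs(mean(counts) - 1), 0.08) # MC error ~ 0.022
  # chi-square against Poisson(1) on binned counts
  obs <- table(factor(pmin(counts, 4), levels = 0:4))
  pexp <- c(dpois(0:3, 1), ppois(3, 1, lower.tail = FALSE))
  expect_gt(stats::chisq.test(obs, p = pexp)$p.value, 0.001)
})

test_that("plasma depths follow the maternal+fetal mixture formula", {
  # expected alt fractions from the documented formula
  expect_equal(expected_alt_fraction(0, 1, 0, ff = 0.10), 0.05)
  expect_equal(expected_alt_fraction(1, 0, 0, ff = 0.10), 0.45)
  expect_equal(expected_alt_fraction(1, 0, 1, ff = 0), 0.5)

  # empirical check on a constructed family where all truth is forced
  panel <- new_snp_panel(data.frame(chrom = "chr1", pos = 1:2000 * 1000,
                                    ref = "A", alt = "G", maf = 0.5))
  fam <- list(panel = panel,
              truth = list(mother_dosage = rep(0L, 2000),
                           fetal = list(dosage = rep(1L, 2000),
                                        ploidy = rep(2L, 2000))))
  cfg <- sim_config(seed = 1, ff = 0.10, mean_depth_cfdna = 150, err = 0,
                    genome = c(chr1 = 3e6))
  set.seed(1)
  pl <- simulate_plasma(fam, cfg)
  frac <- sum(pl$alt_depth) / sum(pl$alt_depth + pl$ref_depth)
  expect_lt(abs(frac - 0.05), 0.002)

  # g_m = 0, g_f = 0, err = 0 -> no alt reads at all
  fam$truth$fetal$dosage <- rep(0L, 2000)
  set.seed(1)
  pl0 <- simulate_plasma(fam, cfg)
  expect_equal(sum(pl0$alt_depth), 0)
})

test_that("bin counts scale with the fetal copy-number mixture", {
  g <- default_genome(0.2)
  samples <- data.frame(
    sample = c("eup", "t21", "x45", "cnv"), type = "plasma",
    karyotype = c("46,XX", "47,XX,+21", "45,X", "46,XX"),
    ff = 0.10, is_reference = FALSE)
  cnv <- data.frame(sample = "cnv", chrom = "chr5", start = 1e6, end = 7e6, cn = 1)
  # nuisance biases off: this test isolates the copy-number mixture itself
  bm <- simulate_bin_cohort(samples, cnv_events = cnv, genome = g,
                            mean_bin_count = 5000, gc_amp = 0, batch_sd = 0,
                            chrom_disp = 0, seed = 2)
  ratio21 <- sum(bm$counts["t21", bm$bins$chrom == "chr21"]) /
    sum(bm$counts["eup", bm$bins$chrom == "chr21"])
  expect_lt(abs(ratio21 - 1.05), 0.02) # 1 + ff/2
  ratioX <- sum(bm$counts["x45", bm$bins$chrom == "chrX"]) /
    sum(bm$counts["eup", bm$bins$chrom == "chrX"])
  expect_lt(abs(ratioX - 0.95), 0.02) # 1 - ff/2
  hit <- bm$bins$chrom == "chr5" & bm$bins$start >= 1e6 & bm$bins$end <= 7e6
  ratio_cnv <- sum(bm$counts["cnv", hit]) / sum(bm$counts["eup", hit])
  expect_lt(abs(ratio_cnv - 0.95), 0.02)
  expect_error(
    simulate_bin_cohort(samples[1, ],
                        cnv_events = data.frame(sample = "eup", chrom = "chr5",
                                                start = c(1e6, 3e6),
                                                end = c(5e6, 8e6), cn = c(1, 3)),
                        genome = g),
    "overlapping")
})

test_that("karyotype strings parse into chromosome counts", {
  expect_equal(parse_karyotype("47,XY,+21")$trisomy, 21L)
  expect_equal(parse_karyotype("47,XY,+21")$fetal_sex, "male")
  expect_equal(parse_karyotype("45,X")$n_x, 1L)
  expect_equal(parse_karyotype("47,XXY")[c("n_x", "n_y")], list(n_x = 2L, n_y = 1L))
  expect_error(parse_karyotype("46,ZZ"), "parse")
})
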