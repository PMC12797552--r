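gt <- function(dosages, role = "father") {
  new_genotype_table(data.frame(chrom = "chr1", pos = seq_along(dosages) * 1000,
                                dosage = dosages), role = role)
}

test_that("Group-1 and Group-2 locus selection follows parental homozygosity", {
  father <- gt(c(2, 1, 2, 0, 2, NA))
  mother <- gt(c(0, 0, 2, 2, 2, 0), role = "mother")
  g1 <- select_group1_loci(father, mother)
  expect_equal(g1$pos, c(1000, 4000)) # {2,0} and {0,2}; het and hom-same excluded
  g2 <- select_group2_loci(father, mother)
  expect_equal(g2$pos, c(3000, 5000))
})

test_that("ff estimator is 2p/(p+q) per locus, median across loci", {
  father <- gt(c(2, 2, 0))
  mother <- gt(c(0, 0, 2), role = "mother")
  g1 <- select_group1_loci(father, mother)
  pd <- new_plasma_depths(data.frame(
    chrom = "chr1", pos = c(1000, 2000, 3000),
    ref_depth = c(190, 180, 12), alt_depth = c(10, 20, 188)))
  est <- estimate_ff_snp(pd, g1)
  # per-locus: 0.10, 0.20, and (father hom-ref) 2*12/200 = 0.12
  expect_equal(sort(est$ff_i), c(0.10, 0.12, 0.20))
  expect_equal(est$ff_snp, 0.12)
  # no fetal-specific reads anywhere -> ff 0
  pd0 <- new_plasma_depths(data.frame(chrom = "chr1", pos = c(1000, 2000),
                                      ref_depth = c(100, 100),
                                      alt_depth = c(0, 0)))
  expect_equal(estimate_ff_snp(pd0, g1[1:2, ])$ff_snp, 0)
})

test_that("ff estimator recovers the simulated fetal fraction", {
  fam <- small_family()
  qc <- run_qc(fam$plasma, fam$father_gt)
  expect_lt(abs(qc$ff_snp - 0.11), 0.01)
  expect_gt(qc$n_group1, 100)
})

test_that("ff estimator is median-unbiased across the clinical ff range", {
  # true maternal genotypes: plasma-inferred banding censors Group-1 loci
  # near its 0.85 ratio edge once ff reaches ~2*(1-0.85), biasing the
  # estimate low at the top of the range (a property of the banding
  # thresholds, covered by the genotype-inference tests)
  panel <- small_panel()
  for (ff in c(0.03, 0.08, 0.15, 0.25)) {
    cfg <- sim_config(seed = round(1000 * ff), ff = ff,
                      mean_depth_cfdna = 150, genome = small_genome())
    fam <- simulate_family(panel, cfg)
    est <- run_qc(fam$plasma, fam$father_gt, fam$mother_gt)$ff_snp
    expect_lt(abs(est - ff), 0.01)
  }
})

test_that("chrY-based ff rescales between female and male baselines", {
  expect_equal(estimate_ff_chry(0.002, 0.002, 0.102), 0)
  expect_equal(estimate_ff_chry(0.102, 0.002, 0.102), 1)
  expect_equal(estimate_ff_chry(0.052, 0.002, 0.102), 0.5)
  expect_warning(ff <- estimate_ff_chry(0.001, 0.002, 0.102), "clipped")
  expect_equal(ff, 0)
  expect_error(estimate_ff_chry(0.05, 0.1, 0.1), "exceed")
})

test_that("error rate pools Mendelian-impossible reads over Group-2 loci", {
  father <- gt(c(0, 0, 2))
  mother <- gt(c(0, 0, 2), role = "mother")
  g2 <- select_group2_loci(father, mother)
  pd <- new_plasma_depths(data.frame(
    chrom = "chr1", pos = c(1000, 2000, 3000),
    ref_depth = c(4999, 4999, 1), alt_depth = c(1, 1, 4999)))
  expect_equal(estimate_error_rate(pd, g2), 3 / 15000)
  # error-free
  pd0 <- new_plasma_depths(data.frame(chrom = "chr1", pos = 1000,
                                      ref_depth = 100, alt_depth = 0))
  expect_equal(estimate_error_rate(pd0, g2[1, ]), 0)
})

test_that("simulated error rate is recovered within a factor of two", {
  fam <- small_family() # err = 0.001, >1e5 Group-2 reads at this panel size
  mo <- infer_maternal_genotypes(fam$plasma)
  g2 <- select_group2_loci(fam$father_gt, mo)
  expect_gt(sum(fam$plasma$ref_depth[g2$pos %in% fam$plasma$pos]), 1e5)
  err <- estimate_error_rate(fam$plasma, g2)
  expect_gt(err, 0.0005)
  expect_lt(err, 0.002)
})

test_that("min support threshold: published tiers and Poisson computation", {
  expect_equal(min_support_threshold(150), 2L)
  expect_equal(min_support_threshold(50), 2L)
  expect_equal(min_support_threshold(250), 3L)
  expect_equal(min_support_threshold(200), 3L)
  expect_equal(min_support_threshold(150, err = 0, method = "poisson"), 1L)
  # Poisson route agrees with direct tail enumeration
  for (depth in c(50, 150, 250)) {
    t <- min_support_threshold(depth, err = 0.001, confidence = 0.999,
                               method = "poisson")
    lambda <- depth * 0.001
    tail_at <- function(k) 1 - sum(dpois(0:(k - 1), lambda))
    expect_lte(tail_at(t), 0.001)
    if (t > 1) expect_gt(tail_at(t - 1), 0.001)
  }
})

test_that("theoretical recall matches brute-force Poisson summation", {
  brute <- function(depth, ff, thr) {
    lambda <- depth * ff / 2
    1 - sum(dpois(0:(thr - 1), lambda))
  }
  for (depth in c(50, 150, 250)) for (ff in c(0.03, 0.07, 0.15)) {
    expect_equal(theoretical_recall(depth, ff, 2), brute(depth, ff, 2),
                 tolerance = 1e-12)
    expect_equal(theoretical_recall(depth, ff, 3), brute(depth, ff, 3),
                 tolerance = 1e-12)
  }
  expect_equal(theoretical_recall(150, 0.07, 0), 1.0)
  # monotone in depth and ff
  d <- sapply(c(50, 100, 150, 200, 250), theoretical_recall, ff = 0.07, threshold = 2)
  expect_true(all(diff(d) > 0))
  f <- sapply(c(0.03, 0.05, 0.07, 0.1), theoretical_recall, depth = 150, threshold = 2)
  expect_true(all(diff(f) > 0))
})

test_that("QC gate distinguishes pass, no-call and fail", {
  expect_equal(qc_gate(0.11, 0.0002)$overall, "pass")
  expect_equal(qc_gate(0.0392, 0.0002)$overall, "no-call")
  expect_equal(qc_gate(0.11, 0.006)$overall, "fail")
  expect_equal(qc_gate(0.03, 0.006)$overall, "fail") # err failure dominates
  expect_equal(qc_gate(0.05, 0.005)$overall, "pass") # boundary values pass
})
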