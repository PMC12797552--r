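test_that("Haldane switch probabilities follow the map function", {
  g <- c(chr1 = 1e8, chr2 = 1e8)
  map <- constant_genetic_map(g, rate_cm_per_mb = 1)
  # d = 0
  expect_equal(build_transition(c("chr1", "chr1"), c(5e6, 5e6), map), 0)
  # 1 cM = 1 Mb at this rate: closed form (1 - e^{-0.02})/2
  p <- build_transition(c("chr1", "chr1"), c(5e6, 6e6), map)
  expect_equal(p, 0.5 * (1 - exp(-0.02)), tolerance = 1e-12)
  # large genetic distance saturates at 1/2 (independence limit)
  map_hot <- constant_genetic_map(g, rate_cm_per_mb = 10)
  p_far <- build_transition(c("chr1", "chr1"), c(1, 1e8), map_hot)
  expect_lt(abs(p_far - 0.5), 1e-3)
  # chromosome boundary restarts the chain
  expect_equal(build_transition(c("chr1", "chr2"), c(5e6, 5e6), map), 0.5)
  expect_true(all(diff(sapply(c(1e5, 1e6, 1e7), function(d)
    build_transition(c("chr1", "chr1"), c(1, 1 + d), map))) > 0))
})

test_that("emission fractions cover the documented transmission cases", {
  # paternal chain, mother hom-ref, transmitted hap carries alt
  expect_equal(expected_alt_fraction(0, 1, 0, ff = 0.10, err = 0), 0.05)
  # maternal chain, father hom-ref, mother het, maternal ref hap transmitted
  expect_equal(expected_alt_fraction(1, 0, 0, ff = 0.10, err = 0), 0.45)
  # no fetal signal: state-independent maternal background
  expect_equal(expected_alt_fraction(1, 0, 1, ff = 0), 0.5)
  expect_equal(expected_alt_fraction(1, 0, 0, ff = 0), 0.5)
  # male chrX: hemizygous fetus contributes its single maternal allele
  expect_equal(expected_alt_fraction(1, 0, 1, ff = 0.10, ploidy = 1),
               0.45 + 0.10)
  # error mixing
  expect_equal(expected_alt_fraction(0, 0, 0, ff = 0.10, err = 0.001), 0.001)
})

test_that("Viterbi and posteriors match exhaustive path enumeration", {
  for (seed in 1:8) {
    n <- sample(6:12, 1)
    rc <- random_chain(n, seed)
    fit <- decode_chain(rc$chain, rc$p_switch)
    e <- cbind(dbinom(rc$chain$alt, rc$chain$total, rc$chain$f0, log = TRUE),
               dbinom(rc$chain$alt, rc$chain$total, rc$chain$f1, log = TRUE))
    bf <- brute_force_hmm(e, rc$p_switch)
    expect_equal(match(fit$loci$state, c("Hap0", "Hap1")),
                 unname(bf$best_path), info = paste("seed", seed))
    expect_equal(fit$viterbi_loglik, bf$best_ll, tolerance = 1e-9)
    expect_equal(fit$loglik, bf$loglik, tolerance = 1e-9)
    expect_equal(fit$loci$posterior_hap0, bf$posterior_hap0, tolerance = 1e-9)
  }
})

test_that("forward and backward recursions agree and posteriors normalize", {
  rc <- random_chain(200, 99)
  fit <- decode_chain(rc$chain, rc$p_switch)
  expect_true(all(abs(fit$loci$posterior_hap0 +
                        (1 - fit$loci$posterior_hap0) - 1) < 1e-10))
  # total likelihood computed from the backward side must match the forward
  e <- fit$emissions
  n <- nrow(e)
  lp <- log(rc$p_switch); lq <- log1p(-rc$p_switch)
  b <- matrix(0, n, 2)
  for (t in (n - 1):1) {
    b[t, 1] <- haplodose:::.lse2(b[t + 1, 1] + lq[t] + e[t + 1, 1],
                                 b[t + 1, 2] + lp[t] + e[t + 1, 2])
    b[t, 2] <- haplodose:::.lse2(b[t + 1, 1] + lp[t] + e[t + 1, 1],
                                 b[t + 1, 2] + lq[t] + e[t + 1, 2])
  }
  ll_back <- haplodose:::.lse2(log(0.5) + e[1, 1] + b[1, 1],
                               log(0.5) + e[1, 2] + b[1, 2])
  expect_equal(ll_back, fit$loglik, tolerance = 1e-10)
})

test_that("symmetric emissions leave the chain undecided", {
  n <- 30
  chain <- data.frame(chrom = "chr1", pos = 1:n * 1e5, total = 100,
                      alt = 50, f0 = 0.5, f1 = 0.5)
  fit <- decode_chain(chain, rep(0.01, n - 1))
  expect_true(all(abs(fit$loci$posterior_hap0 - 0.5) < 1e-12))
  lod <- region_log_odds(fit, list(chrom = "chr1", start = 1, end = 2e6))
  expect_equal(lod, 0, tolerance = 1e-10)
})

test_that("region log-odds is antisymmetric and monotone in evidence", {
  rc <- random_chain(30, 7)
  fit <- decode_chain(rc$chain, rc$p_switch)
  region <- list(chrom = "chr1", start = rc$chain$pos[10], end = rc$chain$pos[20])
  lod <- region_log_odds(fit, region)
  # swap the state labels: f0 <-> f1
  swapped <- rc$chain
  swapped$f0 <- rc$chain$f1; swapped$f1 <- rc$chain$f0
  fit_sw <- decode_chain(swapped, rc$p_switch)
  expect_equal(region_log_odds(fit_sw, region), -lod, tolerance = 1e-9)

  # appending a strongly Hap0-favoring iSNP inside the region raises the odds
  add <- data.frame(chrom = "chr1", pos = rc$chain$pos[15] + 1, total = 100,
                    alt = 10, f0 = 0.10, f1 = 0.01)
  chain2 <- rbind(rc$chain[1:15, ], add, rc$chain[16:30, ])
  p2 <- c(rc$p_switch[1:14], 0.01, rc$p_switch[15:29])
  fit2 <- decode_chain(chain2, p2)
  expect_gt(region_log_odds(fit2, region), lod)
  # no iSNP in region -> undefined
  expect_true(is.na(region_log_odds(fit, list(chrom = "chr9", start = 1, end = 2))))
})

test_that("crossovers are reported as inter-iSNP intervals", {
  chain <- data.frame(chrom = "chr1", pos = 1:6 * 1e6, total = 200,
                      alt = c(0, 0, 0, 10, 10, 10),
                      f0 = 0.001, f1 = 0.05)
  fit <- decode_chain(chain, rep(0.01, 5))
  expect_equal(fit$loci$state, c(rep("Hap0", 3), rep("Hap1", 3)))
  expect_equal(nrow(fit$crossovers), 1L)
  expect_equal(fit$crossovers$start, 3e6)
  expect_equal(fit$crossovers$end, 4e6)
  expect_equal(fit$crossovers$resolution, 1e6)
  expect_equal(fit$candidate_regions$start, 3.5e6 - 2e6)
  # constant path: none
  flat <- data.frame(chrom = "chr1", pos = 1:6 * 1e6, total = 200,
                     alt = rep(0, 6), f0 = 0.001, f1 = 0.05)
  expect_equal(nrow(decode_chain(flat, rep(0.01, 5))$crossovers), 0L)
})

test_that("the no-call policy gates on ff and recombination iSNP counts", {
  mk_fit <- function(n, xo_at, spacing = 1e5) {
    alt <- c(rep(0, xo_at), rep(10, n - xo_at))
    chain <- data.frame(chrom = "chr1", pos = 1:n * spacing, total = 200,
                        alt = alt, f0 = 0.001, f1 = 0.05)
    decode_chain(chain, rep(0.001, n - 1))
  }
  tr <- data.frame(chrom = "chr1", start = 1, end = 6e6, name = "gene")
  # ff below 5%: sample no-call regardless of evidence
  fits <- list(paternal = mk_fit(40, 20), maternal = mk_fit(40, 20))
  out <- apply_nocall(fits, 0.04, tr)
  expect_true(all(out$call == "no-call"))
  expect_true(all(grepl("fetal fraction", out$reason)))
  # maternal target in a recombination region with 15 iSNPs at ff 0.12 (< 20);
  # the target itself sits on one side of the crossover (clear local evidence)
  # but overlaps the 4-Mb candidate recombination region
  tr <- data.frame(chrom = "chr1", start = 1, end = 1.2e6, name = "gene")
  fits2 <- list(paternal = mk_fit(12, 6, spacing = 3e5),
                maternal = mk_fit(15, 7, spacing = 2.5e5))
  out2 <- apply_nocall(fits2, 0.12, tr)
  expect_equal(out2$call[out2$parent == "maternal"], "no-call")
  expect_match(out2$reason[out2$parent == "maternal"], "iSNP")
  # paternal needs only 10: 12 iSNPs pass
  expect_false(out2$call[out2$parent == "paternal"] == "no-call")
  # maternal minimum relaxes to 10 at high ff
  out3 <- apply_nocall(fits2, 0.16, tr)
  expect_false(out3$call[out3$parent == "maternal"] == "no-call")
})

test_that("clinical calls map chain states under each inheritance mode", {
  expect_equal(clinical_call("Hap0", "Hap0", "AR"), "Affected")
  expect_equal(clinical_call("Hap0", "Hap1", "AR"), "Carrier (P)")
  expect_equal(clinical_call("Hap1", "Hap0", "AR"), "Carrier (M)")
  expect_equal(clinical_call("Hap1", "Hap1", "AR"), "Normal")
  expect_equal(clinical_call("Hap0", "no-call", "AR"), "Affected or Carrier (P)")
  expect_equal(clinical_call("Hap0", "Hap1", "AD", variant_parent = "father"),
               "Affected")
  expect_equal(clinical_call("Hap1", "Hap0", "AD", variant_parent = "father"),
               "Normal")
  expect_equal(clinical_call("no-call", "Hap0", "XL", fetal_sex = "male"),
               "Affected")
  expect_equal(clinical_call("no-call", "Hap0", "XL", fetal_sex = "female"),
               "Carrier (M)")
  expect_equal(clinical_call("Hap1", "no-call", "XL", fetal_sex = "female"),
               "Carrier (M) or Normal")
})

test_that("accuracy evaluation matches transmitted alleles against truth", {
  fam <- small_family()
  cfg <- small_family_cfg()
  fits <- decode_family(fam, cfg)
  tp <- truth_alleles(fam, "paternal")
  acc <- evaluate_accuracy(fits$paternal, tp)
  expect_gte(acc$accuracy, 0.99)
  # complemented truth gives the complementary accuracy
  flipped <- tp
  flipped$allele <- 1 - flipped$allele
  acc_f <- evaluate_accuracy(fits$paternal, flipped)
  expect_equal(acc$accuracy + acc_f$accuracy, 1)
  expect_error(evaluate_accuracy(fits$paternal,
                                 data.frame(chrom = "chr9", pos = 1, allele = 0)),
               "disjoint")
})

test_that("decoding accuracy does not degrade with higher ff or depth", {
  panel <- small_panel()
  acc_at <- function(ff, depth) {
    cfg <- sim_config(seed = 77, ff = ff, mean_depth_cfdna = depth,
                      genome = small_genome())
    fam <- simulate_family(panel, cfg)
    fits <- decode_family(fam, cfg, ff = ff, err = 0.001)
    evaluate_accuracy(fits$maternal, truth_alleles(fam, "maternal"))$accuracy
  }
  # same meioses (same seed), increasing signal
  a_low <- acc_at(0.05, 100)
  a_mid <- acc_at(0.11, 150)
  a_high <- acc_at(0.20, 250)
  expect_lte(a_low, a_mid + 0.005)
  expect_lte(a_mid, a_high + 0.005)
  expect_gt(a_high, 0.99)
})
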