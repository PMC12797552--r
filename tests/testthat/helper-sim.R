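# Shared fixtures: a small 3-chromosome genome keeps the per-test cost low
# while preserving the multi-chromosome structure of real runs. Expensive
# objects are built once and cached for the whole suite.

.fixtures <- new.env(parent = emptyenv())

small_genome <- function() default_genome(0.05, chroms = c("chr1", "chr2", "chrX"))

small_panel <- function() {
  if (is.null(.fixtures$panel)) {
    set.seed(424242)
    .fixtures$panel <- simulate_panel(small_genome(), spacing = 25e3)
  }
  .fixtures$panel
}

# a standard AR PAHP family at ff 0.11, depth 200
small_family <- function() {
  if (is.null(.fixtures$fam)) {
    cfg <- sim_config(seed = 7, ff = 0.11, mean_depth_cfdna = 200,
                      genome = small_genome(), inheritance = "AR")
    .fixtures$fam <- simulate_family(small_panel(), cfg)
    .fixtures$fam_cfg <- cfg
  }
  .fixtures$fam
}

small_family_cfg <- function() {
  small_family()
  .fixtures$fam_cfg
}

# shared screening cohort: 40 euploid references, gDNA baselines, one test
# slot per karyotype class and one CNV carrier
screen_cohort <- function() {
  if (is.null(.fixtures$bm)) {
    set.seed(55)
    samples <- data.frame(
      sample = c(sprintf("ref%02d", 1:40), "gdna_female", "gdna_male",
                 "t21", "t18", "eup_f", "eup_m", "x45", "xxx", "xxy", "xyy",
                 "del5", "dup7"),
      type = c(rep("plasma", 40), "gdna", "gdna", rep("plasma", 10)),
      karyotype = c(rep(c("46,XX", "46,XY"), 20), "46,XX", "46,XY",
                    "47,XY,+21", "47,XX,+18", "46,XX", "46,XY", "45,X",
                    "47,XXX", "47,XXY", "47,XYY", "46,XX", "46,XY"),
      ff = c(stats::runif(40, 0.08, 0.15), NA, NA, rep(0.10, 10)),
      is_reference = c(rep(TRUE, 40), rep(FALSE, 12)))
    cnv <- data.frame(sample = c("del5", "dup7"),
                      chrom = c("chr5", "chr7"),
                      start = c(2e6, 5e6), end = c(8e6, 10e6),
                      cn = c(1, 3))
    .fixtures$bm <- simulate_bin_cohort(samples, cnv_events = cnv,
                                        genome = default_genome(0.2),
                                        seed = 31)
    .fixtures$prep <- screen_prepare(.fixtures$bm)
  }
  .fixtures$bm
}

screen_prep <- function() {
  screen_cohort()
  .fixtures$prep
}

# truth tables in the shape evaluate_accuracy() expects
truth_alleles <- function(fam, parent = c("paternal", "maternal")) {
  parent <- match.arg(parent)
  allele <- if (parent == "paternal") fam$truth$fetal$pat_allele
            else fam$truth$fetal$mat_allele
  data.frame(chrom = fam$panel$chrom, pos = fam$panel$pos, allele = allele)
}

# run phasing + decoding on a simulated family with plasma-inferred
# maternal genotypes (the default clinical situation)
decode_family <- function(fam, cfg, ff = NULL, err = NULL) {
  mo <- infer_maternal_genotypes(fam$plasma)
  isnps <- classify_isnps(fam$father_gt, mo)
  qc <- run_qc(fam$plasma, fam$father_gt, mo)
  ph <- phase_pahp(isnps, fam$proband_gt, fam$variant_loci, cfg$inheritance,
                   father_gt = fam$father_gt)
  infer_fetal_haplotypes(ph, isnps, fam$plasma,
                         ff = ff %||% qc$ff_snp, err = err %||% qc$err,
                         map = cfg$map, fetal_sex = fam$truth$fetal_sex)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force HMM oracles (independent of the package's recursions):
# enumerate all 2^n state paths
brute_force_hmm <- function(e, p_switch) {
  n <- nrow(e)
  lp <- log(p_switch); lq <- log1p(-p_switch)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  ll <- apply(paths, 1, function(s) {
    x <- log(0.5) + e[1, s[1]]
    if (n > 1) for (t in 2:n) {
      x <- x + (if (s[t] == s[t - 1]) lq[t - 1] else lp[t - 1]) + e[t, s[t]]
    }
    x
  })
  tot <- max(ll) + log(sum(exp(ll - max(ll))))
  post1 <- vapply(1:n, function(t) {
    sel <- paths[, t] == 1
    exp(max(ll[sel]) + log(sum(exp(ll[sel] - max(ll[sel])))) - tot)
  }, numeric(1))
  list(best_path = paths[which.max(ll), ], best_ll = max(ll),
       loglik = tot, posterior_hap0 = post1)
}

# random small chain for HMM property tests
random_chain <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample(1e6:5e7, n))
  total <- rpois(n, 80)
  f0 <- runif(n, 0.02, 0.5)
  f1 <- runif(n, 0.02, 0.5)
  truth <- rbinom(n, 1, 0.5)
  alt <- rbinom(n, total, ifelse(truth == 0, f0, f1))
  list(chain = data.frame(chrom = "chr1", pos = pos, total = total,
                          alt = alt, f0 = f0, f1 = f1),
       p_switch = runif(n - 1, 0.001, 0.3))
}
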