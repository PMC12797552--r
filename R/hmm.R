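# Fetal haplotype inference by relative haplotype dosage: two independent
# 2-state HMMs (paternal chain on Group-3 iSNPs, maternal chain on Group-4),
# binomial allele-depth emissions with error mixing, Haldane map-function
# transitions, Viterbi decoding, forward-backward posteriors, constrained
# region log-odds, crossover detection and the ff/iSNP no-call policy.

## ---- model components ------------------------------------------------------

#' Expected plasma alt-read fraction under a transmission state
#'
#' `f = ((1 - ff) g_m + ff (a_p + a_m) (2 / ploidy)) / 2` mixed with
#' symmetric sequencing error: `f' = f (1 - err) + (1 - f) err`. `a_p`/`a_m`
#' are the alt indicators of the transmitted paternal/maternal alleles (one
#' of them fixed by the homozygous parent, the other set by the HMM state).
#'
#' @param g_m Maternal alt dosage (0/1/2).
#' @param a_p,a_m Transmitted paternal/maternal alt indicators (0/1; `a_p`
#'   is ignored when `ploidy = 1`, the male-chrX case).
#' @param ff Fetal fraction.
#' @param err Sequencing error rate.
#' @param ploidy Fetal ploidy at the locus (2, or 1 on male chrX).
#' @return Error-mixed expected alt fraction in \[0, 1\].
#' @export
expected_alt_fraction <- function(g_m, a_p, a_m, ff, err = 0, ploidy = 2) {
  n <- max(length(g_m), length(a_p), length(a_m), length(ploidy))
  g_m <- rep_len(g_m, n); a_p <- rep_len(a_p, n)
  a_m <- rep_len(a_m, n); ploidy <- rep_len(ploidy, n)
  a <- a_p + a_m
  hemi <- ploidy == 1
  a[hemi] <- a_m[hemi]
  f <- ((1 - ff) * g_m + ff * a * (2 / ploidy)) / 2
  f * (1 - err) + (1 - f) * err
}

#' Per-gap switch probabilities from a genetic map (Haldane)
#'
#' For adjacent iSNPs at genetic distance `d` Morgans the probability that
#' the transmitted parental haplotype switches is `(1 - exp(-2d)) / 2`
#' (Haldane map function, no interference). Chromosome boundaries restart
#' the chain (switch probability 1/2, i.e. independence).
#'
#' @param chrom,pos Sorted iSNP coordinates.
#' @param map A `genetic_map`.
#' @return Numeric vector of length `length(pos) - 1`.
#' @export
build_transition <- function(chrom, pos, map) {
  n <- length(pos)
  if (n < 2) return(numeric(0))
  cm <- genetic_cm(map, chrom, pos)
  d <- diff(cm) / 100 # Morgans
  p <- 0.5 * (1 - exp(-2 * d))
  p[chrom[-1] != chrom[-n]] <- 0.5
  p
}

# assemble one parent's chain: loci with per-state emission fractions
#' @keywords internal
build_chain <- function(parent = c("paternal", "maternal"), phased, isnps,
                        depths, ff, err, fetal_sex = "female") {
  parent <- match.arg(parent)
  hp <- if (parent == "paternal") phased$father else phased$mother
  grp <- if (parent == "paternal") 3L else 4L
  sub <- isnps[isnps$group == grp, , drop = FALSE]
  m <- merge(hp, sub[, c("chrom", "pos", "father_dosage", "mother_dosage")],
             by = c("chrom", "pos"))
  i <- match(locus_key(m$chrom, m$pos), locus_key(depths$chrom, depths$pos))
  m <- m[!is.na(i), , drop = FALSE]
  d <- depths[i[!is.na(i)], , drop = FALSE]
  m$total <- d$ref_depth + d$alt_depth
  m$alt <- d$alt_depth
  male_x <- fetal_sex == "male" & m$chrom == "chrX"
  if (parent == "paternal") {
    m <- m[!male_x, , drop = FALSE] # no paternal X in a male fetus
    a_m <- m$mother_dosage / 2
    m$f0 <- expected_alt_fraction(m$mother_dosage, m$hap0, a_m, ff, err)
    m$f1 <- expected_alt_fraction(m$mother_dosage, m$hap1, a_m, ff, err)
  } else {
    ploidy <- ifelse(male_x, 1, 2)
    a_p <- ifelse(male_x, 0, m$father_dosage / 2)
    m$f0 <- expected_alt_fraction(1, a_p, m$hap0, ff, err, ploidy)
    m$f1 <- expected_alt_fraction(1, a_p, m$hap1, ff, err, ploidy)
  }
  m <- order_loci(m)
  rownames(m) <- NULL
  m
}

## ---- decoding --------------------------------------------------------------

#' @keywords internal
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

# scalar version for the recursion hot loops
#' @keywords internal
.lse2 <- function(a, b) {
  m <- if (a > b) a else b
  if (m == -Inf) return(-Inf)
  m + log(exp(a - m) + exp(b - m))
}

#' Decode one parental chain
#'
#' Runs Viterbi (most probable state path) and forward-backward (per-locus
#' posteriors) on a two-state chain in log space, with a uniform initial
#' distribution and restarts at chromosome boundaries.
#'
#' @param chain Data frame with `chrom`, `pos`, `total`, `alt`, `f0`, `f1`
#'   (per-state expected alt fractions), as built internally from phased
#'   parents, iSNP classes and plasma depths.
#' @param p_switch Per-gap switch probabilities ([build_transition()]).
#' @return A `chain_fit` list: `loci` (the chain with `state` = "Hap0"/
#'   "Hap1" and `posterior_hap0`), `loglik`, `crossovers` and
#'   `candidate_regions` (crossover midpoints +/- 2 Mb), plus the per-state
#'   log emissions used.
#' @export
decode_chain <- function(chain, p_switch) {
  n <- nrow(chain)
  if (n == 0) stop("empty chain: no informative SNPs with depth")
  if (all(chain$total == 0)) stop("all chain loci have zero depth")
  e <- cbind(stats::dbinom(chain$alt, chain$total, chain$f0, log = TRUE),
             stats::dbinom(chain$alt, chain$total, chain$f1, log = TRUE))
  lp <- log(p_switch); lq <- log1p(-p_switch)

  # Viterbi
  v <- c(log(0.5), log(0.5)) + e[1, ]
  bp <- matrix(1L, n, 2)
  if (n > 1) for (t in 2:n) {
    s0 <- c(v[1] + lq[t - 1], v[2] + lp[t - 1]) # into Hap0
    s1 <- c(v[1] + lp[t - 1], v[2] + lq[t - 1]) # into Hap1
    bp[t, 1] <- which.max(s0); bp[t, 2] <- which.max(s1)
    v <- c(max(s0), max(s1)) + e[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(v)
  if (n > 1) for (t in (n - 1):1) path[t] <- bp[t + 1, path[t + 1]]

  # forward-backward
  a <- matrix(NA_real_, n, 2); b <- matrix(NA_real_, n, 2)
  a[1, ] <- log(0.5) + e[1, ]
  if (n > 1) for (t in 2:n) {
    a[t, 1] <- .lse2(a[t - 1, 1] + lq[t - 1], a[t - 1, 2] + lp[t - 1]) + e[t, 1]
    a[t, 2] <- .lse2(a[t - 1, 1] + lp[t - 1], a[t - 1, 2] + lq[t - 1]) + e[t, 2]
  }
  b[n, ] <- 0
  if (n > 1) for (t in (n - 1):1) {
    b[t, 1] <- .lse2(b[t + 1, 1] + lq[t] + e[t + 1, 1],
                     b[t + 1, 2] + lp[t] + e[t + 1, 2])
    b[t, 2] <- .lse2(b[t + 1, 1] + lp[t] + e[t + 1, 1],
                     b[t + 1, 2] + lq[t] + e[t + 1, 2])
  }
  loglik <- .lse2(a[n, 1], a[n, 2])
  post0 <- exp(a[, 1] + b[, 1] - loglik) /
    (exp(a[, 1] + b[, 1] - loglik) + exp(a[, 2] + b[, 2] - loglik))

  loci <- chain
  loci$state <- c("Hap0", "Hap1")[path]
  loci$posterior_hap0 <- post0
  fit <- list(loci = loci, p_switch = p_switch, emissions = e,
              loglik = loglik, viterbi_loglik = max(v))
  fit$crossovers <- detect_crossovers(fit)
  fit$candidate_regions <- candidate_regions(fit$crossovers)
  class(fit) <- "chain_fit"
  fit
}

#' Detect crossovers as state switches in the Viterbi path
#'
#' Each switch between consecutive iSNPs on the same chromosome is a
#' crossover localized to the inter-iSNP interval; the interval width is
#' the crossover resolution.
#'
#' @param fit A `chain_fit`.
#' @return Data frame `chrom`, `start`, `end`, `mid`, `resolution`.
#' @export
detect_crossovers <- function(fit) {
  l <- fit$loci
  n <- nrow(l)
  if (n < 2) return(data.frame(chrom = character(), start = numeric(),
                               end = numeric(), mid = numeric(),
                               resolution = numeric()))
  sw <- which(l$state[-1] != l$state[-n] & l$chrom[-1] == l$chrom[-n])
  data.frame(chrom = l$chrom[sw], start = l$pos[sw], end = l$pos[sw + 1],
             mid = (l$pos[sw] + l$pos[sw + 1]) / 2,
             resolution = l$pos[sw + 1] - l$pos[sw])
}

# 4-Mb candidate recombination regions (crossover midpoint +/- 2 Mb)
#' @keywords internal
candidate_regions <- function(crossovers, flank = 2e6) {
  if (!nrow(crossovers)) return(data.frame(chrom = character(),
                                           start = numeric(), end = numeric()))
  data.frame(chrom = crossovers$chrom,
             start = pmax(1, crossovers$mid - flank),
             end = crossovers$mid + flank)
}

#' Region log-odds of Hap0 versus Hap1 inheritance
#'
#' log10 ratio of constrained forward likelihoods: the chain's state is
#' fixed to Hap0 across all iSNPs in the region versus fixed to Hap1, with
#' transitions outside the region free. Positive values favor fetal
#' inheritance of Hap0.
#'
#' @param fit A `chain_fit`.
#' @param region List or one-row data frame with `chrom`, `start`, `end`.
#' @return log10 odds (`NA` when the region contains no iSNP).
#' @export
region_log_odds <- function(fit, region) {
  l <- fit$loci
  inr <- l$chrom == normalize_chrom(region$chrom[1]) &
    l$pos >= region$start[1] & l$pos <= region$end[1]
  if (!any(inr)) return(NA_real_)
  (constrained_loglik(fit, inr, 1L) - constrained_loglik(fit, inr, 2L)) / log(10)
}

#' @keywords internal
constrained_loglik <- function(fit, mask, state) {
  e <- fit$emissions
  n <- nrow(e)
  lp <- log(fit$p_switch); lq <- log1p(-fit$p_switch)
  block <- function(t, s) if (mask[t] && s != state) -Inf else e[t, s]
  a <- c(log(0.5) + block(1, 1), log(0.5) + block(1, 2))
  if (n > 1) for (t in 2:n) {
    a <- c(.lse2(a[1] + lq[t - 1], a[2] + lp[t - 1]) + block(t, 1),
           .lse2(a[1] + lp[t - 1], a[2] + lq[t - 1]) + block(t, 2))
  }
  .lse2(a[1], a[2])
}

## ---- calls and QC ----------------------------------------------------------

#' No-call policy thresholds
#'
#' Sample-level: fetal fraction below `ff_min` is a no-call. Region-level: a
#' target region overlapping a 4-Mb candidate recombination region is a
#' no-call unless the region's iSNP count reaches the parent- and ff-specific
#' minimum (paternal 10; maternal 10 at ff >= 0.15, 20 at 0.10-0.15, 30 at
#' 0.05-0.10).
#'
#' @param ff_min Sample fetal-fraction gate.
#' @param flank Candidate-region half-width (bp).
#' @param paternal_min Paternal iSNP minimum.
#' @param maternal_min Named vector of maternal minima by ff band.
#' @return A `nocall_policy` list.
#' @export
nocall_policy <- function(ff_min = 0.05, flank = 2e6, paternal_min = 10,
                          maternal_min = c(high = 10, mid = 20, low = 30)) {
  structure(list(ff_min = ff_min, flank = flank, paternal_min = paternal_min,
                 maternal_min = maternal_min), class = "nocall_policy")
}

#' @keywords internal
isnp_minimum <- function(parent, ff, policy) {
  if (parent == "paternal") return(policy$paternal_min)
  if (ff >= 0.15) policy$maternal_min[["high"]]
  else if (ff >= 0.10) policy$maternal_min[["mid"]]
  else policy$maternal_min[["low"]]
}

#' Apply the no-call policy to target regions
#'
#' @param fits List with `paternal` and `maternal` `chain_fit`s.
#' @param ff Sample fetal-fraction estimate.
#' @param target_regions Data frame `chrom`, `start`, `end` (and optionally
#'   `name`) of clinically targeted regions.
#' @param policy A [nocall_policy()].
#' @param lod_threshold Minimum |log10 odds| for a region call.
#' @return Data frame with one row per region x parent: `name`, `parent`,
#'   `log_odds`, `n_isnp_recomb`, `in_recomb_region`, `call` in
#'   `"Hap0"`/`"Hap1"`/`"no-call"`, and `reason` for no-calls.
#' @export
apply_nocall <- function(fits, ff, target_regions, policy = nocall_policy(),
                         lod_threshold = 1) {
  if (!"name" %in% names(target_regions))
    target_regions$name <- sprintf("region%d", seq_len(nrow(target_regions)))
  target_regions$chrom <- normalize_chrom(target_regions$chrom)
  rows <- list()
  for (k in seq_len(nrow(target_regions))) {
    tr <- target_regions[k, ]
    for (parent in c("paternal", "maternal")) {
      fit <- fits[[parent]]
      if (ff < policy$ff_min) {
        rows[[length(rows) + 1]] <- data.frame(
          name = tr$name, parent = parent, log_odds = NA_real_,
          n_isnp_recomb = NA_integer_, in_recomb_region = NA,
          call = "no-call", reason = "fetal fraction below 5%")
        next
      }
      lod <- region_log_odds(fit, tr)
      cr <- fit$candidate_regions
      hit <- which(cr$chrom == tr$chrom & cr$start <= tr$end & cr$end >= tr$start)
      n_isnp <- NA_integer_
      reason <- ""
      call <- if (is.na(lod)) "no-call"
      else if (lod >= lod_threshold) "Hap0"
      else if (lod <= -lod_threshold) "Hap1"
      else "no-call"
      if (is.na(lod)) reason <- "no iSNP in target region"
      else if (call == "no-call") reason <- "insufficient log-odds evidence"
      if (length(hit) && !is.na(lod)) {
        # iSNP support inside the overlapping candidate recombination regions
        n_isnp <- min(vapply(hit, function(h) {
          sum(fit$loci$chrom == cr$chrom[h] & fit$loci$pos >= cr$start[h] &
                fit$loci$pos <= cr$end[h])
        }, numeric(1)))
        if (n_isnp < isnp_minimum(parent, ff, policy)) {
          call <- "no-call"
          reason <- sprintf("recombination region with %d iSNPs (< %d required)",
                            n_isnp, isnp_minimum(parent, ff, policy))
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        name = tr$name, parent = parent, log_odds = lod,
        n_isnp_recomb = n_isnp, in_recomb_region = length(hit) > 0,
        call = call, reason = reason)
    }
  }
  do.call(rbind, rows)
}

#' Clinical interpretation of region haplotype calls
#'
#' Maps the paternal/maternal Hap0/Hap1 region calls to a clinical label
#' under the family's inheritance mode. Constituent no-calls produce a
#' partial label enumerating the remaining possibilities.
#'
#' @param paternal_call,maternal_call `"Hap0"`, `"Hap1"` or `"no-call"`.
#' @param inheritance `"AR"`, `"AD"` or `"XL"`.
#' @param variant_parent For AD: which parent carries the variant.
#' @param fetal_sex For XL: `"male"` or `"female"`.
#' @return A label such as `"Affected"`, `"Carrier (P)"`, `"Carrier (M)"`,
#'   `"Normal"`, or a partial `"Normal or Carrier (M)"` form.
#' @export
clinical_call <- function(paternal_call, maternal_call,
                          inheritance = c("AR", "AD", "XL"),
                          variant_parent = "father", fetal_sex = "female") {
  inheritance <- match.arg(inheritance)
  states <- function(call) switch(call, Hap0 = "Hap0", Hap1 = "Hap1",
                                  c("Hap0", "Hap1"))
  labs <- character(0)
  if (inheritance == "AR") {
    for (p in states(paternal_call)) for (m in states(maternal_call)) {
      labs <- c(labs,
                if (p == "Hap0" && m == "Hap0") "Affected"
                else if (p == "Hap0") "Carrier (P)"
                else if (m == "Hap0") "Carrier (M)"
                else "Normal")
    }
  } else if (inheritance == "AD") {
    call <- if (variant_parent == "father") paternal_call else maternal_call
    labs <- vapply(states(call), function(s)
      if (s == "Hap0") "Affected" else "Normal", character(1))
  } else { # XL: maternal chain decides
    labs <- vapply(states(maternal_call), function(s) {
      if (fetal_sex == "male") { if (s == "Hap0") "Affected" else "Normal" }
      else { if (s == "Hap0") "Carrier (M)" else "Normal" }
    }, character(1))
  }
  labs <- unique(labs)
  if (length(labs) == 1) labs else paste(labs, collapse = " or ")
}

## ---- top level and evaluation ---------------------------------------------

#' Infer fetal inheritance of parental haplotypes from plasma
#'
#' Builds and decodes the paternal (Group-3) and maternal (Group-4) chains.
#'
#' @param phased A `phased_parents` object.
#' @param isnps An [classify_isnps()] result.
#' @param depths A `plasma_depths`.
#' @param ff Fetal-fraction estimate.
#' @param err Sequencing error rate.
#' @param map A `genetic_map` (constant 1.2 cM/Mb fallback when `NULL`).
#' @param fetal_sex `"male"` or `"female"` (controls chrX handling).
#' @return A `fetal_haplotype_result`: list with `paternal` and `maternal`
#'   `chain_fit`s, plus `ff` and `err`.
#' @export
infer_fetal_haplotypes <- function(phased, isnps, depths, ff, err = 0.001,
                                   map = NULL, fetal_sex = "female") {
  if (is.null(map)) map <- constant_genetic_map()
  fits <- list()
  for (parent in c("paternal", "maternal")) {
    chain <- build_chain(parent, phased, isnps, depths, ff, err, fetal_sex)
    p_sw <- build_transition(chain$chrom, chain$pos, map)
    fits[[parent]] <- decode_chain(chain, p_sw)
  }
  fits$ff <- ff
  fits$err <- err
  class(fits) <- "fetal_haplotype_result"
  fits
}

#' Haplotype accuracy against truth
#'
#' Fraction of chain iSNPs whose inferred transmitted allele (the phased
#' Hap0/Hap1 allele selected by the Viterbi state) matches the truly
#' transmitted allele, overall and stratified by candidate recombination
#' regions.
#'
#' @param fit A `chain_fit`.
#' @param truth Data frame `chrom`, `pos`, `allele` of truly transmitted
#'   alt indicators (e.g. from [simulate_family()]).
#' @return List `accuracy`, `n`, `accuracy_recomb`, `accuracy_outside`.
#' @export
evaluate_accuracy <- function(fit, truth) {
  l <- fit$loci
  i <- match(locus_key(l$chrom, l$pos), locus_key(truth$chrom, truth$pos))
  if (all(is.na(i))) stop("truth and chain loci are disjoint")
  keep <- !is.na(i)
  inferred <- ifelse(l$state[keep] == "Hap0", l$hap0[keep], l$hap1[keep])
  match_ok <- inferred == truth$allele[i[keep]]
  cr <- fit$candidate_regions
  in_cr <- in_intervals(l$chrom[keep], l$pos[keep], cr)
  list(accuracy = mean(match_ok), n = sum(keep),
       accuracy_recomb = if (any(in_cr)) mean(match_ok[in_cr]) else NA_real_,
       accuracy_outside = if (any(!in_cr)) mean(match_ok[!in_cr]) else NA_real_)
}
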