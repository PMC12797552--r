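---
title: "Statistical methods behind haplodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind haplodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodose)
```

`haplodose` infers which parental haplotypes a fetus inherited — and screens
for chromosomal abnormalities — from targeted SNP sequencing of maternal
plasma cell-free DNA (cfDNA), in which a minority *fetal fraction* (ff) of
fragments is fetal. This vignette documents the statistical model, every
tunable parameter and its default, the design of the built-in simulator
that the package's results are computed on, and the numerical choices made
along the way.

## 1. The measurement model

At a biallelic SNP, plasma is a mixture of maternal and fetal genomes. With
maternal genotype dosage $g_m \in \{0,1,2\}$ (alt-allele count), fetal
transmitted alleles $a_p, a_m \in \{0,1\}$, fetal ploidy $c$ at the locus
(2 autosomal, 1 for male chrX), and fetal fraction $\mathit{ff}$, the
expected alt-read fraction is

$$f = \frac{(1-\mathit{ff})\,g_m + \mathit{ff}\,(a_p + a_m)\,(2/c)}{2},$$

mixed with a symmetric per-read error rate $e$: $f' = f(1-e) + (1-f)e$.
Observed alt depth is Binomial(total depth, $f'$). For male chrX the
paternal term is absent ($a_p = 0$, $c = 1$), so a hemizygous fetal allele
contributes its full $\mathit{ff}$ weight. `expected_alt_fraction()`
implements exactly this formula and is shared by the simulator and the
decoder, so emission correctness is tested against closed-form cases rather
than against itself.

## 2. Informative SNP groups and QC

Comparing the father's genotypes with the mother's (supplied as gDNA, or
inferred from plasma ref-ratio banding: ratio $< 0.15$ hom-alt, $> 0.85$
hom-ref, $0.3\text{–}0.7$ het, otherwise missing), SNPs split into four
groups (`classify_isnps()`):

* **Group 1** — parents homozygous for opposite alleles. The father's
  allele is fetal-specific; its plasma fraction is $\mathit{ff}/2$, so
  $\widehat{\mathit{ff}} = \mathrm{median}\,2p/(p+q)$ over these loci
  (`estimate_ff_snp()`). The median resists outlier loci; the estimator is
  median-unbiased to $<1\%$ across ff 3–25% (tested).
* **Group 2** — both parents homozygous for the same allele. Any
  minor-allele reads are errors or (rarely) de novo events:
  $\hat e = \sum p / \sum (p+q)$ pooled (`estimate_error_rate()`).
* **Group 3** — father het, mother hom: paternal-inheritance informative.
* **Group 4** — mother het, father hom: maternal-inheritance informative.

The QC gate (`qc_gate()`) fails a run at $\hat e > 0.005$ and no-calls it
at $\widehat{\mathit{ff}} < 0.05$; both bounds are the operating limits
below which the dosage signal is unreliable. A male-fetus cross-check,
$\widehat{\mathit{ff}}_{chrY} = (y - \bar f)/(\bar m - \bar f)$, rescales
the chrY read share between female-pregnancy and adult-male baselines.

The minimum alt-read support for counting a fetal-specific allele as
detected is depth-tiered (`min_support_threshold()`): 2 below 200×, 3 at
200× and above. A Poisson alternative (`method = "poisson"`, smallest $t$
with $P(\mathrm{Pois}(d\,e) \ge t) < 10^{-3}$) is provided; note the tiered
default is deliberately *not* identical to it (the Poisson rule gives 3
already at 150×) — the tiers are the validated operating table, kept
as-is. Expected per-locus recall is
$P(\mathrm{Pois}(d \cdot \mathit{ff}/2) \ge t)$ (`theoretical_recall()`);
at 150×, ff 7%, threshold 2 it is `r round(theoretical_recall(150, 0.07, 2), 3)`.

## 3. Parental phasing

The pathogenic (Hap0) versus wild-type (Hap1) labelling of each parent's
haplotypes comes from family structure, not population panels:

* **Proband-assisted** (`phase_pahp()`): at each Group-3/4 locus the het
  parent's transmitted allele is deduced from the proband's dosage minus
  the other (homozygous) parent's contribution. Whether the transmitted
  haplotype is Hap0 follows from the proband's genotype at the pathogenic
  loci under the stated inheritance mode (for a het proband, the other
  parent's genotype settles which parent transmitted the variant; for male
  X-linked probands the chrX dosage is hemizygous). Mendelian
  inconsistencies above 1% of deduced loci abort with a sample-swap error.
* **Relative-assisted** (`phase_rahp()`): a homozygous genotyped relative
  on a known lineage pins the lineage allele at each locus; carrier status
  of the relative decides whether that lineage is Hap0. Conflicting
  relatives leave loci unphased rather than guessing.

## 4. The fetal-inheritance HMM

Each parent is decoded independently with a two-state HMM over that
parent's informative SNPs ordered along the genome; states are "fetus
inherited Hap0/Hap1". Emissions are the binomial model of §1 with
state-specific $f$; transitions follow Haldane's map function
$p_{\text{switch}} = \tfrac12(1 - e^{-2d})$ with $d$ the inter-SNP genetic
distance in Morgans; chromosome boundaries restart the chain at
probability $\tfrac12$. The default map is a constant 1.2 cM/Mb scaled by
meiosis-specific factors (maternal ×1.4, paternal ×0.85), replaceable by
any position-indexed map (`read_genetic_map()`).

`decode_chain()` runs Viterbi (backpointer form) and forward–backward in
log space. All pairwise log-sums use a hand-inlined scalar
$\mathrm{logsumexp}$ (`.lse2`) — two states never need more — and the
recursions are exact to $10^{-10}$ against brute-force path enumeration
(tested for all chains up to $2^{12}$ paths). State switches within a
chromosome are reported as crossovers with the inter-SNP interval as their
resolution; ±2 Mb around each midpoint forms a *candidate recombination
region*.

Per target region, evidence is summarized as a constrained log-odds:
the difference in total data log-likelihood between forcing the region's
loci to Hap0 versus Hap1 (all other loci marginalized), reported in
$\log_{10}$ units (`region_log_odds()`). Calls require $|\mathrm{LOD}| >
1$ (10:1 odds); weaker evidence is a no-call.

**No-call policy** (`nocall_policy()`): samples below ff 5% are not called
at all. A region overlapping a candidate recombination region needs a
minimum number of informative SNPs in that region: 10 (paternal), and
for the maternal chain 10/20/30 for ff ≥ 15% / 10–15% / < 10% — the
maternal signal is a $\mathit{ff}/2$ shift around 0.5 rather than
presence/absence, so it needs more loci at low ff. §8 quantifies these
thresholds. Clinical genotype calls then follow the inheritance mode
(`clinical_call()`), with partial "A or B" labels when only one chain is
callable.

## 5. Aneuploidy and segmental screening

The screening arm works on 250-kb bin counts of shallow whole-genome
plasma sequencing against a euploid reference cohort.

1. **GC correction** (`normalize_gc()`): per-sample LOESS (degree 2, span
   0.3) of count versus bin GC, *fitted on autosomal bins only* but
   applied to all bins — sex-chromosome bins sit at half or zero dosage
   and would otherwise drag the curve at their GC values.
2. **PCA correction** (`pca_correct()`): principal components of the
   reference samples' log-ratio profiles (k = 3, autosomal bins only)
   capture residual batch structure; projections onto them are removed.
   Components are restricted to autosomes because fetal sex is the
   dominant cross-sample direction on chrX/chrY and must not be removed.
3. **Chromosome proportions**: each test chromosome's share of the
   denominator (all autosomes except the screened 13/18/21 and 19, the
   most GC-extreme autosome) is compared with the reference distribution:
   $Z = (p_1 - p_0)/\mathrm{SD}_0$. Proportions are computed from the
   GC-corrected counts, *not* the PCA residuals: reference-fitted
   components absorb part of the references' own noise but none of a test
   sample's, which would shift the null by about one SD at a 40-sample
   reference. PCA residuals are used only for segmentation (step 5).
4. **Sex-chromosome logic** (`screen_one()`): fetal sex is gated on the
   chrY share exceeding the female-reference mean + 3 SD. Female fetuses:
   X-proportion Z against female references (±3 → 45,X / 47,XXX). Male
   fetuses: the X baseline is rescaled by $(1 - \mathit{ff}_{chrY}/2)$,
   and X-excess ($Z > 3$) splits into XXY versus XYY by
   $R = \mathit{ff}_{chrY}/\mathit{ff}_{SNP} > 2$. Note $R$ has
   expectation exactly 2.0 for XYY under the ideal mixture model, so the
   subtype label sits on a knife edge and the reliable statement is
   "sex-chromosome count abnormality"; detection itself rests on $Z$.
5. **Segmental events** (`screen_mms()`): circular binary segmentation
   with the max circular-t scan implemented in C++ (`src/cbs.cpp`),
   permutation p-values (early-exit at the decision boundary), recursive
   splitting, and merging of adjacent segments within 0.5 SD. A segment
   is called when its Z against reference segment means exceeds 3 *and*
   a bin-bootstrap confidence exceeds 95%, with a 4-bin (1 Mb) minimum.

## 6. SNP panel design

`design_panel()` filters candidate SNPs to minor-allele frequency and
flanking GC in [0.30, 0.70] and mappability > 0.85, then walks a 25-kb
grid and takes the candidate nearest each grid point (ties to the smaller
position; empty windows skipped), giving near-uniform spacing rather than
clumps. Inside ±2 Mb of targeted genes the grid step shrinks by a factor
of 5, boosting local informative-SNP density where diagnostic calls and
recombination exclusion actually happen.

## 7. The simulator: realism and limits

All results in this package are computed on its own generative model —
that is deliberate: truth is exactly known, and every component is
exercised end to end.

* **Families** (`simulate_family()`): parental haplotypes are Bernoulli
  draws from panel allele frequencies; pathogenic variants are placed on
  Hap0. Meioses draw Poisson(genetic length / 100 cM) crossovers via the
  genetic map with the maternal/paternal rate multipliers; the proband is
  conditioned to carry the required pathogenic haplotypes by relabelling
  haplotypes (exact, because labels are exchangeable), never by rejection.
  Fathers are hemizygous on chrX (one X, no crossovers, always
  transmitted to daughters). Plasma depths are Poisson around the mean
  depth with binomial alt counts from the §1 model, optionally
  beta-binomial overdispersed (default off).
* **Bin cohorts** (`simulate_bin_cohort()`): per-bin expected counts get
  a smooth per-sample GC bias (quadratic, amplitude `gc_amp = 1`), a
  batch factor (`batch_sd = 0.03`), a chrY mismapping background
  (0.002) so female pregnancies have nonzero chrY share, and per-sample
  per-chromosome log-normal dispersion `chrom_disp = 0.005`. The last is
  essential: pure Poisson binning gives chromosome-proportion CVs of
  ~0.2%, which would make every trisomy a $Z \approx 25$ event;
  clinically observed screening CVs are 0.3–1.5%, and 0.005 places the
  simulator inside that range (euploid Z is then close to standard
  normal, which the tests check).
* **Known limits**: no fragment-length information, no maternal CNVs or
  mosaicism, symmetric errors, mappability as a given number, crossovers
  without interference, and banding-based maternal genotyping censors
  Group-1 loci once $\mathit{ff}/2$ approaches the 0.15 band margin
  (visible as a slight downward ff bias above ff ≈ 0.25). De novo
  variants are out of scope: the HMM infers transmission of parental
  haplotypes only.

## 8. Study-scale results and problem sizes

The problem sizes below are this package's own choices, set to exercise
full-scale behaviour where it matters and to keep everything runnable on
one CPU inside minutes.

`scripts/acceptance.R` (see README) recomputes, from a single seed:

* **Genome-wide accuracy** (t2/t3): a full ~121k-SNP genome-wide panel
  (25-kb grid over a GRCh38-length genome), 5 families at ff 10–12% and
  200× target depth, full pipeline from plasma-inferred maternal
  genotypes onward. Typical results: paternal ≈ 100%, maternal ≈ 99.6%
  over ~150k informative SNPs each.
* **Crossover windows** (t4/t5): 500 4-Mb windows per parent, each
  containing one crossover, at the per-window median informative-SNP
  densities (55 paternal, 101 maternal per 4 Mb). Accuracy is measured
  on SNPs at rank-distance ≥ 10 (paternal, ff 7–15%) or ≥ 30 (maternal,
  ff 5–10%) from the true crossover — the exact quantity the no-call
  iSNP minima of §4 control. Within a few SNPs of a breakpoint *no*
  decoder can place the switch exactly (the window-wide mean accuracy is
  bounded near $1 - k/n$ regardless of depth), so the clinically
  meaningful guarantee is conditional on distance; both exceed 99%
  (`recomb_window_accuracy()`).
* **Screening** (t6/t7): a 126-sample euploid plasma reference plus gDNA
  baselines, 50 euploid tests, two each of T13/T18/T21/45,X/XXX/XXY/XYY
  at ff ≈ 10%, and 8 CNV carriers (4–20 Mb deletions and duplications)
  on a length-scaled genome (factor 0.25, keeping ~3,100 250-kb bins) so
  LOESS + PCA + CBS over ~200 samples stay fast. Sensitivity is 100% on
  both arms with 50/50 euploid specificity.

The unit/property suite runs the same machinery at smaller scale (a
3-chromosome 5%-length genome) with brute-force HMM enumeration, closed
forms, and constructed edge cases as oracles.

## 9. Numerical and implementation notes

* All HMM arithmetic is in log space; posteriors normalize to $10^{-10}$.
* `loess` failures on degenerate strata fall back to uncorrected counts
  rather than dropping samples; fits need ≥ 100 bins.
* The CBS permutation loop exits as soon as the p-value decision is
  determined, and uses a seeded `mt19937` so segmentation is reproducible.
* Seed handling: every simulator entry point takes an explicit seed and
  forces its arguments *before* seeding (lazy argument evaluation could
  otherwise interleave a caller's RNG use into the stream).
* File formats: SNP panels are BED (0-based half-open, converted to
  1-based once on read, byte-identical on round-trip); genotypes and
  plasma allele depths come from VCF (via `vcfR`, `GT` and `AD` fields)
  or plain TSV.
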