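---
title: "Detecting and validating functional variants for feed efficiency"
author: "PFVcattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating functional variants for feed efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PFVcattle)
```

## The problem

Residual feed intake (RFI) is the standard feed-efficiency measure in
beef cattle: the residual of daily dry-matter intake (DMI) after
regressing out the energy sinks of growth and maintenance.  Animals with
low RFI eat less than expected for their gain and size, which matters
both economically and environmentally.  RFI is expensive to measure, so
a marker panel enriched for variants that actually drive the trait —
*potential functional variants* (PFVs) — is attractive for selection.

`PFVcattle` implements a two-stage pipeline:

1. **Detection.** Variants called per organ from RNA-seq of
   physiologically relevant tissues (liver, muscle, hypothalamus,
   pituitary, adrenal) are quality-filtered, merged into a unique-variant
   table, tested for allele-frequency differences between extreme
   high- and low-efficiency groups, and classified by their predicted
   consequence on the protein.  Significant variants with high (or
   moderate) impact are the PFVs.
2. **Validation.** In an independent population, chip SNPs adjacent to
   the PFVs are up-weighted in the genomic relationship matrix of a
   single-step GBLUP evaluation, and the gain in prediction accuracy for
   young genotyped animals is measured.

Everything runs against a synthetic herd generator, so each stage is
testable end to end without external data.

## Phenotype stage

Average daily gain is the OLS slope of the body-weight series on days in
test (DIT): $y_{ij} = \alpha + \beta\,\mathrm{DIT} + \varepsilon$.
Metabolic weight is the mid-test weight raised to the 0.75 power,
$MW = [\alpha + \beta\,(\mathrm{DIT}/2)]^{0.75}$.  RFI is the residual
of the within-contemporary-group multiple regression

$$\mathrm{DMI}_i = \beta_0 + \beta_1\,\mathrm{ADG}_i + \beta_2\,MW_i +
  \beta_3\,\mathrm{CG} + \varepsilon_i,$$

fitted by `computeRFI()`.  Numerical choices:

* Contemporary groups with fewer than 4 animals are dropped
  (configurable down to 2 for toy examples).
* Records beyond ±3.5 SD of their CG mean are excluded once, before
  fitting.  The rule is applied to DMI — the regressand — since that is
  the variable whose outliers distort the residuals.
* The model is exactly ADG + MW + CG; age is used later in the animal
  model, not here.
* Residuals centre to zero within every retained CG and are orthogonal
  to the regressors by construction; the tests assert this to 1e-10.

`selectExtremeGroups()` labels the *lowest*-RFI animals HFE (efficient)
and the highest LFE; boundary ties break by ascending animal id.

## Variant filtering and association

Record-level QC follows GATK-style thresholds, all strict inequalities:
QUAL > 30, DP > 4, QD > 3, and — in the default mode — FS < 30 and
MQ > 35, because high strand bias and low mapping quality are evidence
*against* a call.  A `literal = TRUE` switch flips the last two
directions for compatibility with pipelines that publish the thresholds
the other way around.

Per-tissue call sets are merged by the key (chrom, pos, ref, alt).  A
sample genotyped in several tissues is resolved by majority vote over
its non-missing calls; ties become missing — a conservative choice given
that no tissue is a priori more trustworthy.  Minor-allele frequency
(folded to ≤ 0.5) and call rate are computed over the pooled extreme
animals after merging.

The default variant filter retains MAF ≥ 0.40 and call rate > 0.50.
Retaining *high*-MAF variants is deliberate: a difference in allele
frequency between two 9-animal groups is only detectable for common
variants, and the filter direction is exposed (`keepAboveMaf`) for the
opposite convention.

The association test compares allele frequencies between HFE and LFE
without assuming Hardy–Weinberg equilibrium.  `method = "allelic"` is
the 1-df chi-square on the 2×2 allele-count table; `method = "trend"`
is the Cochran–Armitage trend statistic on genotype counts with scores
(0, 1, 2).  Significance is declared at raw p < 0.05; a
Benjamini–Hochberg option exists but is off by default, since the
detection stage is intentionally permissive and the downstream impact
filter provides the specificity.  Monomorphic variants return
chi² = 0, p = 1 rather than an error.

**Calibration.**  The chi-square reference is asymptotic.  By exact
enumeration, at 9 vs 9 animals and MAF 0.4 the true level of the
allelic test at nominal 0.05 is 0.0602 — discreteness makes the test
slightly anticonservative at the study's group size.  The calibration
test therefore runs at 50 animals per group (exact level 0.0514), where
the reference applies, and a separate property test checks the 9v9
simulated rejection rate against the enumeration oracle rather than
against the nominal level.

## Consequence classification

`classifyVariants()` implements a compact VEP-style classifier against a
toy gene model (GFF3 + FASTA, 1-based, indels left-anchored as in VCF):

* coding SNVs are translated with the standard genetic code →
  missense / synonymous / stop_gained / stop_lost / start_lost /
  start_retained;
* CDS indels are frameshift iff their length is not a multiple of 3,
  otherwise inframe insertion/deletion; indels overlapping the start
  codon are start_retained when the mutated CDS still begins ATG;
* the first/last two intronic bases are splice_donor / splice_acceptor
  (strand-aware: the donor is the 5′ side of the intron in transcription
  direction); splice_region covers 3–8 bases into the intron and 1–3
  bases into the exon;
* everything else inside a transcript is intron_variant, outside is
  intergenic.

Impact follows the Ensembl severity map (HIGH ⊇ stop_gained,
frameshift, splice_donor/acceptor, stop_lost, start_lost; MODERATE ⊇
missense, inframe indels; LOW ⊇ synonymous, splice_region,
start_retained; MODIFIER ⊇ non-coding), with multi-term and
multi-transcript calls taking the maximum severity.  Only the first
(canonical) transcript per gene is consulted unless
`allTranscripts = TRUE`.  The classifier is property-tested for strand
symmetry: every variant classified on a minus-strand transcript equals
the reverse-complemented variant on the equivalent plus-strand copy.

PFVs are the intersection of significant variants with the chosen
impact classes (`impactSet = "HIGH"` by default; add MODERATE for the
permissive set).

## Single-step GBLUP and WssGWAS

The animal model is $y = X\beta + Zu + e$ with contemporary group and
age as fixed effects, $u \sim N(0, H\sigma_a^2)$,
$e \sim N(0, I\sigma_e^2)$.  Variance components are inputs (no REML).
The combined relationship inverse is

$$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\
  0 & G^{-1} - A_{22}^{-1} \end{bmatrix},$$

with $A$ from the tabular method with inbreeding and the VanRaden
genomic matrix $G = ZDZ'\lambda$, $Z = M - P$,
$\lambda = 1/\sum_j 2p_j(1-p_j)$, allele frequencies observed in the
genotyped animals.  Henderson's equations are solved by dense Cholesky;
PEV comes from the explicit inverse diagonal — exactness over
scalability, which is the right trade-off at the few-thousand-animal
scale this package targets.  Rank-deficient fixed-effect designs (CG
nested in the intercept) drop aliased columns via the QR pivot.

Numerical choices worth knowing:

* With observed-frequency centring the rows of $G$ sum to zero, so $G$
  is singular by construction.  Before inversion it is blended,
  $G^* = 0.95\,G + 0.05\,A_{22}$ (industry default, exposed as
  `blend`).  The SNP back-solve
  $\hat u = \lambda DZ'(ZDZ'\lambda)^{-1}\hat a_g$ reuses the blended
  inverse for the same reason; the exact reconstruction identity
  $Z\hat u = \hat a_g$ is asserted on invertible fixtures.
* The WssGWAS loop starts at $D = I$, and per iteration: build
  $G = ZDZ'\lambda$, solve for GEBVs, back-solve SNP effects, reweight
  $d_i = \hat u_i^2\,2p_i(1-p_i)$, then normalise.  Two iterations are
  the default.
* "Keep the total genetic variance constant" is implemented as
  conserving $\sum_i d_i\,2p_i(1-p_i)$ (a $\sum d_i = m$ variant is
  available); $\lambda$ itself is held fixed across iterations — it is
  the weights that are normalised, not the scaling constant.
* A weight floor of 1e-8 × mean prevents markers from locking at zero
  across iterations.

PFV fold-weighting (`applyPfvWeights()`) sets every chip SNP within
50 kb of a PFV — or, when the window is empty, the nearest flanking SNP
on each side — to 1×, 2× or 3× the maximum D diagonal obtained after
the two WssGWAS iterations, then re-applies the conservation
normalisation.  The 50 kb adjacency window is a package choice (exposed
as `windowBp`): adjacency is otherwise undefined, and 50 kb is the
scale over which chip LD with a causal variant is typically strong.

Prediction quality per scenario is summarised by the Beef Improvement
Federation accuracy
$\mathrm{Acc} = 1 - \sqrt{\mathrm{PEV}/((1+F_i)\sigma_a^2)}$ averaged
over validation animals, and by the inflation slope $b$ of the
whole-data unweighted-G GEBVs regressed on the scenario GEBVs
(b < 1 = over-dispersed).  Because "prediction ability" is ambiguous
between model-internal accuracy and realised accuracy, the synthetic
diagnostic cor(GEBV, TBV) is reported alongside.

## The synthetic herd generator

`simulateHerd()` produces one realisation of: pedigree (founders plus
discrete generations, matings capped at half the founder count so
cohorts stay constant), genotypes, trait architecture, feedlot records
and a toy genome/gene model.  What it emulates, and how:

* **Gene dropping with block cosegregation.**  Founder gametes draw
  alleles independently per locus (frequencies uniform on
  `founderMafRange`); offspring inherit whole 100-kb block haplotypes
  from each parent, independently per block.  There is no recombination
  within a block and free recombination between blocks.  Because
  founder alleles are independent, cosegregation alone creates no LD in
  expectation — so the linkage that chip-based prediction needs is
  induced explicitly: each of the `nQtl` causal variants gets three tag
  SNPs within 10 kb (same block) whose founder alleles copy the causal
  allele with probability 0.9 (r² ≈ 0.64).  This mimics a dense chip
  tagging a causal variant without a recombination-map dependency.
* **Trait.**  The causal variants are transcribed (exonic) variants;
  the true breeding value is the centred sum of effect × allele count.
  Default effects are rescaled so the founder phenotypic variance of
  true RFI is 0.64 (SD 0.8 kg DM/day — a realistic RFI scale); the
  residual SD then satisfies the configured heritability exactly on the
  founder cohort.  Explicitly supplied effects are never rescaled.
* **Feedlot records.**  Body weight is linear growth (start 376 ± 29 kg,
  ADG 1.1 ± 0.15 kg/day) weighed fortnightly over a 70-day test with
  4 kg weighing noise.  DMI = intercept + 1.5 × ADG + 0.09 × MW +
  CG effect + tbv + residual, so the genetic component enters intake
  only and true RFI ≡ tbv + residual — which is what makes RFI recovery
  and parameter-recovery tests well defined.
* **Tissues.**  Each organ exposes a fixed Bernoulli(callability)
  subset of the transcribed variants (default 0.5 per organ, giving an
  all-five-organs overlap near 0.5⁵), sampled on 18/17/18/18/15 extreme
  animals, with 10% per-genotype missingness, and 5% of records written
  with one deliberately failing QC field.

What it does **not** model: read-level data (FASTQ/BAM), within-block
recombination, allele-specific expression, imputation error, and any
dependence of call rate on expression depth (a single per-sample
missing rate stands in).  Consequently, passing tests demonstrate the
*statistical machinery* — filtering arithmetic, test calibration,
mixed-model algebra, weighting dynamics — not robustness to real
RNA-seq artefacts.

## Problem sizes and what the simulation study shows

The replicated prediction study used by the test suite runs 20 seeds of
a 2,040-animal herd (120 founders, 4 generations), 3,000 chip SNPs,
5 QTLs, h² = 0.3, with the youngest generation (480 animals) as
genotyped validation and all sires genotyped in training; the
acceptance script reports the same grid over 5 seeds.  Calibration uses
10⁴ null replicates.  These sizes keep a full run in minutes on one
core while leaving the orderings statistically resolvable by sign test.

Directional results the tests compute: genomic information, validation
records, and their combination each raise BIF accuracy over plain
ssGBLUP; WssGWAS weight mass concentrates on the QTL-adjacent tag SNPs;
fold-weighting at the true QTLs is monotone 1-fold ≤ 2-fold ≤ 3-fold;
weighting SNPs adjacent to *random* non-causal variants does not
improve on the weighted-G baseline; and weighted scenarios are the more
inflated ones (b < 1).

## Known limitations

* **Oligogenic architecture inverts one ordering.**  With five large
  QTLs, weighting G by estimated SNP variances captures most of the
  genetic variance, and Acc(ssGBLUP+wG) exceeds Acc(ssGBLUP+records) on
  essentially every replicate.  In polygenic real data the ranking is
  typically the reverse (own records beat weighted genomic
  information).  This is a property of the simulated architecture, not
  of the solver; the test suite records the inversion rather than
  hiding it.
* PEV-based BIF accuracy treats the estimated SNP weights as known,
  so weighted-G accuracies are optimistic relative to cor(GEBV, TBV);
  both are reported.
* The fold-weighting scenarios operate on a 3,000-SNP panel where
  boosting a handful of SNPs to the maximum weight materially rescales
  the whole D; on a dense chip the same operation is a small
  perturbation.  Fold effects should be read as orderings, not
  magnitudes.
* The classifier handles the listed consequence terms only — no UTR
  classes, no regulatory consequences, no SIFT/PolyPhen scores.
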