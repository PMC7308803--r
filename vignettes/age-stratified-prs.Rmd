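---
title: "Age-stratified APOE and polygenic risk analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stratified APOE and polygenic risk analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prsage` implements an age-stratified polygenic-risk analysis of Alzheimer's
disease: variant quality control, linkage-disequilibrium (LD) pruning,
polygenic risk scores (PRS) with APOE-region exclusion, APOE
&epsilon;-diplotype calling, pathway-restricted scores, and logistic/Poisson
association models compared by likelihood-ratio tests, stratified at an age
cutoff (80 years by default). Because the cohorts this design is used on
(case-control clinical cohorts; biobanks with parental family history) are
access-controlled, the package ships a synthetic-data generator that
reproduces the statistical structure the analysis assumes, so every stage is
testable end to end.

## The association model

Let $d_4, d_2 \in \{0,1,2\}$ be the counts of APOE &epsilon;4 and
&epsilon;2 alleles, called from the unphased genotypes of rs429358 and
rs7412, and let $S$ be the standardized PRS computed from all variants with
discovery p-value $p \le p_T$ (default $p_T = 0.5$) outside the APOE region
(chromosome 19, 44.4--46.5 Mb). For a case-control phenotype $Y$ the joint
model is the logistic regression

$$\mathrm{logit}\, P(Y=1) = \alpha + \beta_4 d_4 + \beta_2 d_2 + \beta_S S,$$

fitted separately in the full cohort and in the two age strata (below /
at-or-above the cutoff; age exactly at the cutoff goes to the upper
stratum). For the family-history ("proxy") design the outcome is the number
of affected parents coded 0/1/2 and the model is Poisson with log link;
maternal and paternal status are additionally analysed by separate logistic
regressions. Three blocks are fitted per stratum — APOE doses only, PRS
only, and the joint model — and the likelihood-ratio test of the joint
model against the APOE-only model asks whether the polygenic component
explains variation over and above APOE. Each fit reports Wald tests from the
observed information, the model log-likelihood, and the AUC of the linear
predictor computed exactly as the normalized Mann-Whitney $U$ statistic (for
the count outcome the AUC binarizes at "any affected parent", a choice
recorded in the fit object since no standard AUC exists for counts).

The scores themselves are plain weighted allele sums
$S_i^{raw} = \sum_j \hat\beta_j \, g_{ij}$ over the pruned, thresholded
variant set, with the panel dose reflected ($g \to 2-g$) whenever the panel
counts the non-effect allele. Raw scores are adjusted by ordinary
least-squares regression on covariates (age, sex, principal components) and
standardized to mean 0, SD 1, the form in which they enter the models. The
&epsilon;4 and &epsilon;2 doses always enter as two separate count
covariates rather than being folded into the score, so their coefficients
are directly interpretable per allele.

## QC, pruning and APOE calling conventions

Variant QC removes variants with minor-allele frequency $< 0.01$,
missingness $> 0.02$ (array profile; $> 0.05$ for imputed data), exact
Hardy-Weinberg $p \le 10^{-6}$, and — for imputed data — INFO $\le 0.4$,
after setting hard calls with implied genotype posterior $\le 0.4$ to
missing. The comparison senses (strict for MAF and missingness, non-strict
for HWE and INFO) are part of the contract and tested at the boundaries. The
HWE test is the standard two-sided exact test (no mid-p correction),
computed on all samples by default with a controls-only option; a variant
failing several filters is attributed to each, with a separate deduplicated
total, so the attrition report is unambiguous.

LD pruning is clumping-style: variants are visited by ascending discovery
p-value (ties broken by chromosome, position, id — fully deterministic) and
kept only if their $r^2$ with every already-kept variant on the same
chromosome within a symmetric 1000-kb window is at most 0.1. $r^2$ is the
squared Pearson correlation of dosages on the target panel or on a seeded
reference subsample (`ref_n`, e.g. 1000 individuals). The window is
interpreted as a pairwise physical distance $|pos_i - pos_j| \le$ 1,000,000
bp; anchoring it per kept variant rather than per candidate is the standard
distance-based convention and the symmetric reading makes the result
independent of scan direction.

APOE diplotypes are called from rs429358/rs7412 via the standard haplotype
table (&epsilon;2 = T/T, &epsilon;3 = T/C, &epsilon;4 = C/C on the
rs429358/rs7412 alleles). Six of the nine unphased genotype combinations
resolve uniquely; the double heterozygote is returned as
&epsilon;2&epsilon;4 with an ambiguity flag because the alternative
&epsilon;1&epsilon;3 phase is vanishingly rare; the three combinations
that require an &epsilon;1 haplotype are returned as `ambiguous` with
missing doses rather than silently miscalled.

## What the generator simulates

The generator is the package's stand-in for the study conditions, not a
test fixture; its defaults are the conditions the analysis assumes.

* **Genotypes.** Biallelic variants in contiguous LD blocks. Within a
  block, haplotype alleles come from a latent-Gaussian AR(1) copula whose
  latent correlations are *tetrachorically calibrated*: the naive choice of
  setting the latent correlation to the target genotype correlation
  attenuates badly after thresholding (a pre-build Monte Carlo put adjacent
  $r^2$ near 0.35 for a 0.9 target), so the generator solves for the latent
  value that delivers the requested genotype correlation, up to the ceiling
  unequal allele frequencies impose. Allele frequencies are uniform on
  (0.1, 0.5) by default — common variants, consistent with a post-QC panel.
* **APOE.** The two SNPs are drawn at the haplotype level from the
  worldwide &epsilon;2/&epsilon;3/&epsilon;4 frequencies 0.084/0.779/0.137,
  which guarantees phase-consistency: no impossible rs429358/rs7412
  genotype pair can arise.
* **Phenotype.** A liability-threshold model: standardized causal dosages
  with Gaussian weights, rescaled so the polygenic term explains `h2_poly`
  of the non-APOE liability variance; an APOE term whose per-&epsilon;4
  effect is a step function of age (`beta_e4_young` below the cutoff,
  `beta_e4_old` at or above it — matching the two-stratum analysis; a
  continuous decline would be an alternative but the step is what the
  stratified fits estimate); Gaussian noise; disease above the empirical
  $1-K$ liability quantile, so the realized case fraction equals the
  prevalence $K$ up to ties. Defaults $\beta_{4,young} = 0.5$,
  $\beta_{4,old} = 0.2$, $\beta_2 = -0.15$, $K = 0.2$, `h2_poly` $= 0.15$
  encode the qualitative structure the analysis targets: a strong,
  age-declining APOE effect, a protective &epsilon;2, and a moderate
  polygenic background.
* **Discovery cohort.** An independent cohort on the same variant map (no
  sample overlap, mirroring the argument that overlap between discovery and
  target is negligible) with per-variant marginal logistic fits providing
  the scoring weights, standard errors and p-values.
* **Parents.** Block-wise Mendelian transmission: each parent contributes
  one of the child's haplotypes and receives a fresh population haplotype
  for the other (one recombination-free block = one transmitted unit),
  giving the expected parent-child dosage correlation of 0.5 without full
  recombination modelling. Parental status is simulated under the same
  liability model at parental ages; parental age at death is shifted by
  `survival_shift_e4` years per parental &epsilon;4 allele (default -1,
  i.e. twelve months earlier per allele); parents alive at recording
  contribute a last-recorded age instead. Parental-history weighting is the
  plain 0/1/2 affected-parent count; single- and both-parent histories are
  not weighted differently, since the proxy coding is a count.
* **Covariates.** Sex is Bernoulli(0.5) with a configurable liability
  effect defaulting to 0; the "principal components" are independent
  standard normals. The generator has no population structure, so these are
  pure noise covariates — they exercise the adjustment code, not the
  confounding it would absorb in real data.

What the generator does **not** emulate: realistic human LD maps and
recombination hotspots, population structure (hence genuine PCs),
imputation error, X-chromosome inheritance, assortative mating, or
dementia-subtype misclassification in family history. Passing tests
therefore demonstrate that the analysis machinery recovers the effects it
is pointed at under its own assumptions — not that those assumptions hold
in any particular cohort.

## Numerical choices

GLMs are fitted by IRLS (`stats::glm`) with relative log-likelihood
tolerance $10^{-8}$ and at most 100 iterations; non-convergence, rank
deficiency (aliased columns are named) and suspected separation (any
$|\hat\beta| > 30$) are errors, not warnings. The exact HWE distribution is
computed by the ratio recurrence anchored at the modal heterozygote count
with final renormalization, and the two-sided tail uses a $1 + 10^{-12}$
relative tolerance when comparing point probabilities so ties are not lost
to rounding; the test agrees with brute-force enumeration to at least ten
significant figures for all tables up to $n = 200$. Monomorphic variants
inside `genotype_r2` are warned about and treated as uncorrelated (they
should not survive QC). Missing dosages in scoring default to cohort-mean
substitution, the common scoring convention; the `omit` policy instead
rescales each sample's score by the ratio of total to observed variant
count. Standardization refuses to divide by a residual SD below
$10^{-12}$ and returns a flagged missing score. Strata with fewer than 10
outcome events are skipped with a warning rather than fitted unstably.
All simulation operations re-seed deterministically from the configuration
seed (with fixed offsets per operation and per cohort), so identical
configurations give bit-identical panels, phenotypes, families and
pipeline reports.

## Scale of the shipped checks

The package's test suite exercises the design at desk scale, chosen so the
statistical assertions have the power they need: the age-reversal property
uses 100 replicates of a 40,000-sample target cohort (about 20,000 per age
stratum, mean age 80) with an independent 5,000-sample discovery GWAS per
replicate; proxy attenuation and the survival shift use a single 25,000
-family cohort (50,000 parents); null calibration of Wald and
likelihood-ratio p-values uses 200 replicates at $n = 10{,}000$. At these
sizes the attenuation ratio is estimated with a standard error of a few
hundredths and the carrier-level death-age shift with about 0.12 years.
The parent-level survival contrast is asserted at carrier level because the
&epsilon;2&epsilon;2 child stratum is only ~0.7% of families, making the
homozygote-stratum mean contrast an order of magnitude noisier; the
stratum table is instead checked for its ordering (&epsilon;4&epsilon;4
parents die youngest, &epsilon;2&epsilon;2 oldest).

## A worked example

```{r, eval = FALSE}
library(prsage)

cfg <- sim_config(seed = 1, n_variants = 80, n_blocks = 10,
                  n_discovery = 5000, n_target = 40000,
                  beta_e4_young = 0.5, beta_e4_old = 0.2,
                  age_distribution = c(80, 8))
panel    <- attach_apoe(simulate_genotypes(cfg), cfg)
sumstats <- simulate_discovery_sumstats(cfg)
pheno    <- simulate_phenotype(panel, cfg)

qc       <- qc_filter(panel, qc_metrics(panel))
keep     <- ld_prune(qc$panel, sumstats)          # r^2 <= 0.1, 1000-kb window
raw      <- compute_prs(qc$panel, sumstats, keep = keep,
                        exclude_regions = apoe_region())
scores   <- adjust_standardize(raw, pheno[, c("age", "sex", "PC1", "PC2",
                                              "PC3", "PC4")])
apoe     <- call_apoe_panel(panel)
stratified_assoc(pheno, scores, apoe, cutoff = 80)
```

The printed table mirrors the three-block schema (APOE-only, PRS-only,
joint; per stratum) with $\beta$, SE, Wald $p$, AUC and the LRT p-value of
joint-vs-APOE. Under the default generator the fitted &epsilon;4
coefficient is visibly larger below 80 than above while the PRS coefficient
is equal or slightly larger above 80 — the age-reversal pattern the
analysis is designed to detect.

## Known limitations

Only biallelic variants are handled; PLINK binary formats and BGEN are out
of scope (the text dialects cover simulated and exported data); the `.raw`
dialect does not carry the non-effect allele, so orientation is recovered
from the `.map` sidecar only up to allele relabelling; Cox/survival
modelling of age at onset, genetic-correlation estimation between strata
and meta-analysis across cohorts are outside the package's remit. Pathway
scores depend entirely on the supplied gene intervals; the package maps
variants to intervals by position and does not attempt gene-model curation.
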