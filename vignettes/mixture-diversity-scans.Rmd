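---
title: "Genome-wide diversity association scans for varietal mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide diversity association scans for varietal mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixscan)
library(dplyr)
```

## The question mixscan addresses

Sowing several genotypes of one crop together — a varietal mixture — changes
the plot's performance relative to its components, and the direction of that
change varies wildly between mixtures and environments. `mixscan` takes a
locus-level view of the problem: instead of asking whether a *mixture* is
good, it asks, SNP by SNP, whether the *genetic diversity within the plot at
that locus* is associated with a plot-level trait, and whether that
association shifts under water stress.

The experimental design the package models is an incomplete balanced set of
k-way mixtures of inbred lines: each of 96 mixtures combines k = 12 of 96
lines, no two mixtures share a composition, and every line appears in
exactly 12 mixtures. The 96 mixtures are grown once each, 48 under rainfed
conditions (R) and 48 under a controlled water deficit (CWD), in 4 blocks
per regime.

Because the components are inbred and contribute equally to the plot, the
allele frequency of SNP i in mixture j is imputed from the component
dosages \(G \in \{0, 1, 2\}\):

\[
F_{i,j} = \frac{1}{2k} \sum_{c=1}^{k} G_{i,c},
\]

and within-plot diversity is the Nei expected heterozygosity
\(H_{E} = 2F(1-F)\), maximal (0.5) at \(F = 0.5\) and zero at fixation.

## Eligibility: separating diversity from frequency

\(H_E\) is a deterministic, concave function of \(F\), so a frequency effect
at a locus where one allele is rare masquerades as a diversity effect. A SNP
enters the diversity scan only when, across the mixtures, its minimum
frequency is strictly below 0.5, its maximum strictly above 0.5, and the
spread between them is at least 0.5 (`eligible_snps()`; the boundary case
min = 0.25 / max = 0.75 qualifies). Only such SNPs carry enough frequency
variation on both sides of 0.5 for the quadratic \(H_E\) term to be
distinguishable from the linear \(F\) term. The inequalities at 0.5 are
strict, and the spread inequality is non-strict, reading the rule's
wording — "below", "above", "at least" — literally.

## The association model

For every SNP k, trait values at the plot level are regressed on

\[
y = \mu + \text{Block} + T + X_k + T{\times}X_k + e,
\]

with \(X_k = H_{E,k}\) for the diversity scan (GWDA, `gwda_scan()`) or
\(X_k = F_k\) for the frequency scan (GWFA, `gwfa_scan()`). Terms are tested
by sequential (type-I) sums of squares in exactly that order, each F-ratio
formed against the full model's residual mean square, and p-values are
reported as \(-\log_{10} p\).

Two modelling choices deserve comment:

* **Block coding.** The default (`block_coding = "shared"`) treats the four
  block labels as shared across regimes and fits them *before* the
  treatment term. With fully nested blocks fitted first (8 dummies), the
  treatment term would be absorbed and receive 0 sequential df; the shared
  coding is the only one under which the stated term order leaves the
  treatment term testable. The alternative (`"nested"`) fits treatment
  first and then block-within-treatment; it is also the parameterisation
  under which the fitted \(T{\times}H_E\) coefficient equals
  \(\beta_{CWD} - \beta_R\) from the per-regime fits, an identity the test
  suite checks to 1e-6.
* **No mixture factor.** The genetic regressor is a mixture-level quantity
  mapped to plots; since each mixture occupies a single plot, a mixture
  factor would be saturated and is not fitted.

SNPs whose regressor is constant across the design (relative projection
norm below 1e-10) are flagged `degenerate` and skipped, not tested at 0 df.

## Multiplicity: the Galwey effective number of tests

Neighbouring SNPs are correlated through linkage disequilibrium, so the
scan's tests are not independent. `effective_tests_galwey()` summarises,
chromosome by chromosome, the eigenvalues \(\lambda\) of the Pearson
correlation matrix of mixture allele frequencies into

\[
M_{\text{eff}} = \frac{\left(\sum_i \sqrt{\lambda_i}\right)^2}{\sum_i \lambda_i},
\]

floors negative eigenvalues at zero (finite-sample correlation matrices can
be numerically indefinite), sums over chromosomes (a one-SNP chromosome
contributes exactly 1), and rounds half-up. The genome-wide threshold is
then \(-\log_{10}(\alpha / M_{\text{eff}})\): with \(\alpha = 0.05\) and
1774 effective tests this is 4.55; with 30 tests, 2.78; with one test,
1.301. Correlations are taken across the 96 mixtures — the unit entering
the regressions — rather than across lines; this is an interpretation, and
the package exposes the per-chromosome contributions so either convention
can be audited.

**Limitation (quantified by the test suite's null study).** With n mixtures
and m SNPs per chromosome, the sample correlation matrix has rank at most
n − 1, so \(M_{\text{eff}}\) can never exceed \((n-1) \times\) the number
of chromosomes, and sample eigenvalue spreading shrinks it further whenever
m is not small relative to n. For 2,000 mutually independent eligible SNPs
over 96 mixtures and 14 chromosomes the estimator returns roughly 830, so
the corrected threshold is anti-conservative: the package's own 100-genome
null calibration measures a family-wise false-positive rate of about
11–14% at nominal 5%. This is a structural property of eigenvalue-based
effective-test estimates at this shape of data, not an implementation
artifact; thresholds derived this way should be read as approximate, and
the corresponding calibration check in the test suite is deliberately left
failing rather than loosened. The Kolmogorov–Smirnov uniformity of null
p-values sits at about a 91% per-genome pass rate at \(\alpha = 0.01\):
marginally each p-value is exactly uniform, but 2,000 statistics
constrained to a ≤ 95-dimensional response space are mutually dependent,
which inflates the KS statistic in a fraction of genomes.

## The HE-vs-F test

A significant diversity association might still be an allele-frequency
effect in disguise. For each detected diversity QTL peak,
`he_vs_f_test()` fits a reference model containing blocks, treatment,
\(F_k\) and \(T{\times}F_k\), then adds \(H_{E,k}\) (and \(T{\times}H_{E,k}\)
when the QTL was detected on the interaction term) and performs the
incremental F-test. Because \(H_E\) is quadratic in \(F\), the augmented
model nests the reference one; this nested reading is the package's
interpretation of comparing the two single-regressor models, which are
non-nested with equal df and admit no standard test. Interaction-detected
QTLs are tested jointly on both added columns. The threshold is Bonferroni
over the number of detected diversity QTLs (e.g. \(-\log_{10}(0.05/30) =
2.78\) for 30). When fewer than three distinct frequency values exist, the
quadratic is collinear with the linear term and the test is flagged
undefined rather than computed.

## QTL intervals from LD blocks

Significant SNPs on a chromosome are grouped into LD blocks
(`cluster_significant_snps()`): pairwise Hill–Robertson
\(r^2 = D^2 / (p_A p_a q_B q_b)\) is computed from line haplotypes (inbred
dosages 0/2 map to haplotypes; heterozygous lines are excluded pairwise),
distances \(d = 1 - \sqrt{r^2}\) are clustered by average linkage, and the
tree is cut at \(1 - \sqrt{r^2_c}\). The square-root transform makes LD
closer to normally distributed; the package applies it to the distances
*and* the cutoff so both live on one scale (`transform = "raw"` disables
both consistently). The critical value \(r^2_c\) is the 99.9th percentile
of \(r^2\) between marker pairs sampled from different chromosomes
(`critical_r2()`, default 10,000 pairs — enough for a stable 99.9th
percentile at the problem sizes the package targets).

Each cluster becomes one QTL: bounds are the min/max member positions
(1-based inclusive bp), the peak is the most significant member (ties
broken by smaller position, then SNP id), and the peak's slope sign and
minor allele frequency \(\min(\bar F, 1-\bar F)\) represent the QTL. Two
QTLs of different traits overlap when they share at least one significant
marker *and* their peaks lie within one tenth of the chromosome length —
peak-to-peak distance, the stricter of the two readings of "physical
distance", is used deliberately.

## Genome-wide slope census and the stress-gradient test

The locus-by-locus scan is complemented by a census of diversity's global
direction. Within each regime, `per_treatment_slopes()` fits
\(P = \mu + \beta_k H_{E,k} + \text{Block} + e\) per SNP; `sign_census()`
counts positive and negative \(\beta_k\) and applies a one-sample Wilcoxon
signed-rank test of the slope vector against zero (exact zeros excluded
from the statistic and reported separately; significance read at 1.301,
i.e. p = 0.05). The stress-gradient hypothesis — diversity helps more under
stress — predicts \(\Delta_k = \beta_{CWD,k} - \beta_{R,k} > 0\);
`stress_gradient_test()` applies the signed-rank test to the paired
\(\Delta\) vector and reports the direction of the median shift. The
default is two-sided with the direction reported, a one-sided option being
available for the directional reading. SNPs are deliberately *not* pruned
for LD at this stage, so the census p-values are anti-conservative under
linkage and should be read as descriptive summaries, not calibrated tests.

## The synthetic-data generator

All validation runs on synthetic experiments (`sim_config()`,
`simulate_line_genotypes()`, `simulate_phenotypes()`), designed to carry
exactly the statistical structure the analysis assumes:

* **Genotypes.** Inbred lines are haploid Bernoulli draws doubled to
  dosages {0, 2} (optional residual heterozygosity produces 1s). SNPs sit
  on 14 chromosomes — the durum wheat karyotype (1A–7B) — with strictly
  increasing positions, partitioned into blocks of `ld_block_length`
  consecutive SNPs. Within a block, each SNP copies the previous SNP's
  allele per line with probability `within_block_r` and redraws otherwise,
  giving adjacent correlation ≈ `within_block_r` with geometric decay and
  independent blocks. This copy-with-mutation scheme is chosen over
  coalescent simulation because it exercises the multiplicity and
  clustering stages while keeping LD exactly controllable.
* **Phenotypes** follow the association model generatively: grand mean
  (default 100 trait units), block effects drawn once per (regime, block)
  pair (sd 3), a CWD shift (default −24 units, i.e. a ~24% depression of
  the default mean, the order of the stress response of kernel number per
  m²), planted per-locus effects evaluated on the *actual* mixture
  \(F\)/\(H_E\) (interaction effects acting in CWD only), and Gaussian
  residual noise (sd 5). Defaults are free parameters of the simulator —
  the field experiment publishes no variance-component estimates — chosen
  once so that the default planted slopes (40 units per unit \(F\), 80 per
  unit \(H_E\), 120 for interactions) clear the genome-wide threshold with
  a comfortable margin.

What the generator does **not** emulate: realistic demography or
coalescent LD decay, spatial field trends, non-additive architectures,
seed-contribution imbalance, or frequency drift between sowing and
harvest. Passing tests therefore certify the statistical machinery under
its own assumptions, not the field realism of those assumptions.

## Numerical and degenerate-input conventions

* Frequencies are means of per-line allele frequencies \(G/2\), so
  \(F \in [0,1]\) and \(H_E = 2F(1-F)\) is well defined; the equivalent
  raw-dosage sum would live on [0, 2].
* Missing genotype calls are rejected at load; scans abort when a trait is
  missing for more than 10% of plots (no imputation).
* Degenerate regressors: relative squared-norm tolerance 1e-10 after
  projection on the base design.
* Sequential SS conservation (terms + residual = total) is enforced in
  tests at 1e-8 relative.
* \(M_{\text{eff}}\) rounding is half-up; eigenvalues floored at 0.
* Ties at QTL peaks break by position then SNP id; output ordering is
  (trait, chromosome, lower bound) so runs are byte-reproducible.
* All randomness flows through explicit integer seeds; derived stage seeds
  stay below 2^31.

## Problem sizes used in the test suite

The packaged validation works at desk scale: null calibration uses 100
genomes of 2,100 SNPs (2,000 eligible) over 96 mixtures; parameter-recovery
studies use 50 seeds at 120–300 SNPs; clustering oracles enumerate up to 6
SNPs by brute force. These sizes were chosen so the full suite exercises
every stage in a few minutes while keeping Monte-Carlo margins wide; the
pipeline itself scales to the 10^4–10^5 SNP range the design targets.

## A complete run

```{r pipeline, eval = FALSE}
cfg <- sim_config(
  n_snps = 2000, seed = 42,
  effect_table = data.frame(snp = 101, type = "diversity",
                            trait = "Y", slope = 80))
panel <- simulate_line_genotypes(cfg)
design <- build_mixture_design(rownames(panel$geno), 96, 12, seed = 42) |>
  assign_layout(seed = 42)
pheno <- simulate_phenotypes(panel, design, cfg)

res <- run_pipeline(panel, design, pheno, traits = "Y", seed = 42)
res$multiplicity
res$qtl
res$stress_gradient
plot_manhattan(filter(res$scans, scan_kind == "GWDA"),
               threshold = res$multiplicity$threshold_minus_log10)
```
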