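---
title: "Scanning imputed complex traits with GWAS summary statistics"
author: "scorescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning imputed complex traits with GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scorescan)
```

## The problem

Genome-wide association studies of a disease trait $Y$ publish per-SNP
summary statistics but rarely individual-level data. Meanwhile, linear
trait-imputation models — polygenic scores $\hat T = XW$, with $W$ a
SNP-by-trait weight vector — exist for thousands of complex traits. The
question this package answers is: *is the disease associated with an
imputed trait*, i.e. what is the z-score for $\gamma$ in
$Y = \alpha + \hat T \gamma + \delta$, when the only inputs are (i) the
weights $W$, (ii) SNP-level z-scores $\tilde Z$ from the GWAS of $Y$, and
(iii) an external reference genotype panel $\tilde X$ of the same ancestry?

## The statistic

Writing the OLS estimator for $\gamma$ in terms of per-SNP covariances and
substituting the standard GWAS approximations
$\mathrm{cov}(X_j, Y) = \mathrm{var}(X_j)\hat\beta_j$ and
$\mathrm{se}(\hat\beta_j) \approx \sqrt{\mathrm{var}(Y)/(N\,\mathrm{var}(X_j))}$
gives

$$Z \;=\; \frac{\hat\gamma}{\mathrm{se}(\hat\gamma)} \;\approx\;
  \sum_j W_j \,\frac{\mathrm{sd}(X_j)}{\mathrm{sd}(\hat T)}\, \tilde Z_j
  \;=\; W^\top \Gamma \tilde Z .$$

Note the *standard-deviation* ratio: carrying the $\hat\beta/\mathrm{se}$
algebra through forces $\Gamma_{jj} = \mathrm{sd}(X_j)/\mathrm{sd}(\hat T)$,
and the package's tests prove this form against an individual-level OLS
oracle (a variance-ratio form fails those tests by construction). Both
$\mathrm{var}(X_j)$ and $\mathrm{var}(\hat T)$ are estimated on the
reference panel; $\mathrm{var}(\hat T)$ as the sample variance of the
panel-imputed score $\tilde T = \tilde X W$, which avoids ever forming the
SNP covariance matrix.

For $K$ imputed traits tested jointly (a conditional analysis), with
$U = \mathrm{cov}(\tilde T_1, \dots, \tilde T_K)^{-1}$ estimated on the
panel,

$$Z_k \;=\; U_{kk}^{-1/2}\; e_k^\top\, U\, (W^*)^\top\,
   \mathrm{diag}\!\big(\mathrm{sd}(X_j)\big)\, \tilde Z ,$$

which reduces exactly to the univariate statistic at $K = 1$ and to the
marginal statistics when the panel covariance is diagonal. The
approximation behind the joint form assumes the $K$ imputed traits jointly
explain little of $\mathrm{var}(Y)$ — reasonable for complex traits and
moderate $K$, and conservative otherwise.

### Effect-size scale

$\mathrm{var}(Y)$ is not identifiable from z-score summary statistics, so
the package adopts the standardised-outcome convention
$\mathrm{var}(Y) = 1$:
$\mathrm{se}(\hat\gamma) = 1/\sqrt{N\,\mathrm{var}(\tilde T)}$. This leaves
$z$ and $p$ untouched; `gamma_hat` is per unit of the imputed trait and
`gamma_std` ($= Z/\sqrt{N}$) per standard deviation of it, both on the
standardised-$Y$ scale, and results are labelled accordingly. $N$ defaults
to the per-variant median of the GWAS sample sizes over the variants a
trait actually uses (meta-analysed GWAS have heterogeneous $N$), and can
be overridden.

## The pipeline around the statistic

* **Harmonisation** (`harmonize()`): variants are matched across sources on
  (chromosome, position) — rsIDs drift between builds — then allele pairs
  are verified. A swapped effect allele flips the sign of beta/z/weights;
  an opposite-strand pair is complemented first; strand-ambiguous A/T and
  C/G variants are dropped by default because their orientation is
  undecidable without allele frequencies (which the supported input formats
  do not carry uniformly). When both a swap and a strand interpretation fit
  (only possible for palindromic pairs), swap is preferred — relevant only
  with `strict_ambiguous = FALSE`. Duplicate variants within a source are
  dropped, not guessed at.
* **Score construction** (`build_prs()`): keep variants with $p \le$
  threshold (0.01 by default; "removing SNPs with p greater than" the cutoff
  retains equality), then greedy LD clumping with $r^2 > 0.1$ within 1 Mb,
  both against a user-chosen panel. "LD cutoff" is interpreted as squared
  Pearson correlation of dosages, the semantics of the standard clumping
  tools; $r^2$ is always computed against the current index variant, never
  transitively; ties on $p$ break by ascending (chromosome, position) so
  the result is order-independent. Weights are the marginal betas (z-scores
  for z-only tables, flagged `standardized_weight`).
* **Region exclusion** (`exclude_region()`): intervals are 1-based and
  inclusive on both ends internally; BED input is converted at the
  boundary. The motivating use is removing a dominant locus — e.g. the
  extended APOE region chr19:45,147,340–45,594,595 (hg19) in Alzheimer's
  scans — before re-running a scan.
* **Post-processing**: fixed-effects inverse-variance-weighted
  meta-analysis across cohorts (the two-study design needs no
  heterogeneity model); Bonferroni (strict $p < \alpha/m$) and
  Benjamini–Hochberg step-up flags; hierarchical clustering of the
  panel-score correlation matrix at distance $1 - |r|$ with average
  linkage, cut at $k$ clusters, minimal-$p$ representative per cluster.
  $1 - |r|$ rather than $1 - r$ because strongly anti-correlated traits
  (a diagnosis and its medication-use counterpart) belong to one family;
  linkage and distance are configurable since no canonical choice exists.
  Replication enrichment is the observed/expected overlap
  $(k/n)/(K/m)$ with an upper-tail hypergeometric p-value; all four counts
  are explicit arguments, never defaults, because the correct universe is
  analysis-specific.

## The simulation engine, and what a green test establishes

Real cohorts in this field are access-controlled, so validation runs on a
generated world. Genotypes come from a latent Gaussian with exchangeable
within-block correlation, thresholded to allele counts at per-variant MAFs
drawn uniformly from `maf_range`, two gametes summed: $O(nm)$ cost,
controllable LD, Binomial(2, MAF) marginals. Blocks are laid out 2 Mb apart
so a 1 Mb clumping radius never spans blocks. This emulates block LD and
allele-frequency spread; it does **not** emulate realistic human LD decay,
population structure, relatedness, or case-control ascertainment — so green
tests establish the *estimator algebra and calibration*, not cohort-specific
published numbers (which the stated design treats as out of reach).

Four trait settings mirror the validation designs:

1. i.i.d. N(0,1) traits independent of genotype (type-I error);
2. heritable traits, $Y = X\beta + \varepsilon$ rescaled so realised
   $h^2 = 0.1$, with no direct score effect (type-I error under
   heritability);
3. $Y = B + \rho P$ with the polygenic background $B$ and the standardized
   score $P$ normalised separately, $\rho \in \{0.005, 0.008, 0.01, 0.015,
   0.02\}$ (power and effect recovery);
4. paired half-cohorts: exposure traits $T_i$ ($h^2 = 0.1$) scanned in one
   half, responses $Y_i = \gamma_i T_i + \varepsilon_i$ with
   $\gamma_i \sim N(0, 2)$, $\varepsilon_i \sim N(0, \mathrm{Var}(T_i))$
   scanned in the other, so weight-training and outcome GWAS are
   independent (effect-size recovery across traits).

### Scale-dependent confounding, and the geometry choices

One desk-scale artifact deserves emphasis. A random score $P = XW$ and a
polygenic background $X\beta$ share the genotype space, so their chance
correlation inflates the null z by
$\mathrm{var}(z) \approx 1 + n h^2 / M_{\mathrm{eff}}$. At biobank scale
($n \sim 6\times 10^4$, $M_{\mathrm{eff}} \sim 10^5$) this is negligible
(~1.1); on a small simulated cohort with a few hundred effective variants
it dominates, and it affects the individual-level oracle identically — it
is a property of the simulated world, not of the summary-statistics
approximation. The validation suite therefore works in the regime the
method actually targets:

* calibration runs use $n = 400$, $M = 8000$
  ($n h^2 / M_{\mathrm{eff}} \approx 0.03$);
* the power study passes `exclude_score_blocks = TRUE` to `sim_setting3()`,
  drawing each trait's background off the score's LD blocks, which
  reproduces the large-$M$ limit where background and score are effectively
  orthogonal.

Power curves over the $\rho$ grid use common random numbers:
`sim_setting3()` consumes its seed before $\rho$ enters, so calls differing
only in $\rho$ share every draw. This makes the monotone-power property
testable at 200 replicates; it changes no distributional assumption.
Reduced cohort sizes (e.g. $n = 8000$, $M = 400$ for power; $n = 4000$
split in half for the paired design) keep the suite inside desk runtime;
absolute power values are therefore smaller than any full-scale figures
and are never asserted — only monotonicity and agreement with the oracle
(within 3 percentage points) are.

## Numerical choices

* p-values from the two-sided standard normal, computed in log space;
  `neglog10_p` stays exact far beyond $|z| \approx 38$, where `p` itself
  underflows (it is floored at the smallest positive double).
* Near-singular score covariance in the joint test (condition number
  $> 10^{10}$, e.g. duplicated traits): a ridge of $10^{-6} \times$ mean
  diagonal is added with a message; with `ridge = 0` it is an error naming
  the most collinear trait pair.
* Missing panel dosages are mean-imputed per variant (preserves the variant
  mean, keeps variances well-defined); all-missing variants are dropped.
* Zero-variance dosage pairs count as $r^2 = 0$ in clumping; zero-variance
  variants in a GWAS scan yield beta 0, infinite se, p 1, flagged.
* Exact zero-residual OLS fits report $|z|$ capped at $10^8$ and flagged.
* All randomness flows from a single integer seed per simulation config.

## Known limitations

* No correction for sample overlap between the weight-training GWAS and
  the outcome GWAS; the framework assumes they are independent, and
  overlap biases associations.
* No allele-frequency-based rescue of strand-ambiguous variants; they are
  simply dropped under the default policy.
* No genome-build liftover; coordinates must already agree across inputs.
* Effect sizes are treated as scale-agnostic linear coefficients; log-odds
  inputs are accepted as-is and reported on the standardised-outcome scale.
* The CLI config file is flat JSON (no YAML parser is assumed on the host).
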