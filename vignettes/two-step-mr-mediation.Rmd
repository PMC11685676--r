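---
title: "Two-sample MR screening and two-step mediation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR screening and two-step mediation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

# The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone: per-SNP effects on
the exposure ($\gamma_j$, SE $\sigma_{Xj}$) come from one study, per-SNP
effects on the outcome ($\Gamma_j$, SE $\sigma_{Yj}$) from another, and under
the instrumental-variable assumptions (relevance, exclusion, independence)
each SNP provides a Wald ratio $\hat\theta_j = \Gamma_j / \gamma_j$ for the
causal effect $\theta$.

mrpath implements this machinery for screening studies in which hundreds of
molecular exposures (e.g. plasma metabolites, immune-cell traits measured by
flow cytometry) are tested against one disease outcome, and for *two-step
mediation*: decomposing an exposure → outcome effect into the part flowing
through a measured mediator (exposure → mediator → outcome) and a direct
remainder.

# Instrument selection

Instruments are selected by a cascade whose thresholds are all exposed in
`mr_params()`:

1. **Association**: $p < 10^{-5}$ for molecular exposures (the conventional
   relaxation used when few SNPs reach $5\times10^{-8}$); $p < 5\times10^{-8}$
   when the disease GWAS itself supplies instruments (reverse MR).
2. **LD clumping**: greedy index-SNP selection, visiting SNPs in ascending
   p-value order (ties broken lexicographically by SNP id for determinism)
   and discarding neighbours with $r^2 \ge 0.001$ within 10,000 kb on the
   same chromosome. LD comes from a user-supplied local $r^2$ matrix (square
   or long/plink-style TSV); SNP pairs absent from it are treated as
   unlinked and this is the package's replacement for remote LD-panel
   lookups — no network service is consulted.
3. **Outcome-association exclusion**: SNPs with outcome $p < 5\times10^{-8}$
   are removed, since they plausibly act on the outcome directly. The spec
   order (clump, then exclude) is the default; `exclude_before_clump`
   reverses it.
4. **Strength**: per-SNP variance explained
   $R^2 = 2\,\mathrm{maf}(1-\mathrm{maf})\beta^2$ (standardized-trait
   approximation) and $F = R^2 (n-2) / (1-R^2)$, retaining $F > 10$ and
   $\mathrm{MAF} > 0.01$. When the frequency or sample size is missing the
   Wald fallback $F = (\beta/\mathrm{se})^2$ is used and recorded per SNP
   in `f_method`.

`find_proxy()` implements LD-proxy substitution ($r^2 > 0.8$, ties by higher
$r^2$ then lower p) but is not wired into the default pipeline: substitution
is only appropriate when a variant is missing or of poor quality in one
study, a situation the caller must judge.

**Harmonization** aligns the outcome effects to the exposure's effect allele:
direct match, swapped match (sign flip), then complementary-strand
relabeling before declaring a SNP incompatible. Palindromic SNPs (A/T, C/G)
are removed outright by default because their strand cannot be resolved from
alleles; an opt-in `palindromic = "infer"` mode retains them when both
effect-allele frequencies are available and both MAFs are below 0.42,
aligning by frequency. The blanket-removal default is deliberately
conservative; frequency inference near MAF 0.5 is unreliable, hence the
0.42 ceiling.

# The five estimators

All operate on the harmonized quadruples and weight by the outcome precision
$w_j = 1/\sigma_{Yj}^2$ (the first-order choice; the $\sigma_{Xj}$ term is
deliberately omitted from ratio variances, the simplest defensible
convention, so weights are reproducible from the reported columns alone):

* **IVW** — weighted regression of $\Gamma$ on $\gamma$ through the origin:
  $\hat\theta = \sum w_j\gamma_j\Gamma_j / \sum w_j\gamma_j^2$. The default
  standard-error model is *multiplicative random effects*, scaling the
  fixed-effects SE by $\max(1, \sqrt{Q/(n-1)})$ — the dominant convention in
  two-sample MR software; `model = "fixed"` is one flag away, and the fixed
  SE is never larger by construction.
* **MR-Egger** — the same regression with a free intercept. The slope is the
  pleiotropy-adjusted effect; the intercept estimates the average direct
  (pleiotropic) effect and its test is the pleiotropy gate used in
  screening. Inference uses the t distribution with $n-2$ df (regression
  convention) and the analogous $\max(1,\sqrt{Q_E/(n-2)})$ scaling.
* **Weighted median** — the interpolated weighted quantile of the per-SNP
  ratios at 0.5, consistent while valid instruments carry $\ge 50\%$ of
  weight.
* **Weighted and simple mode** — the argmax of a Gaussian-kernel density
  over the ratios (inverse-variance or equal weights), bandwidth
  $\varphi \cdot 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)\, m^{-1/5}$,
  evaluated on a 512-point grid spanning the ratio range ± 3 bandwidths;
  grid ties resolve to the midpoint of the tied points. "Simple mode" is the
  unweighted variant (sometimes labelled *sample mode* in applied reports).

Median and mode standard errors come from a parametric bootstrap (1000
seeded replicates by default) that redraws both effect vectors from normals
with their reported SEs; `n_boot = 0` skips the bootstrap when only point
estimates are needed, which is how the large validation simulations keep
their runtimes down. p-values are two-sided normal except Egger's t. All
confidence intervals use the same quantile as the corresponding test, so
"CI excludes 0" and "p < 0.05" can never disagree.

`run_all_methods()` derives an independent seed substream per stochastic
estimator, so output is bit-reproducible from `(data, seed)` and changing
one method's draws never perturbs another's. With two SNPs the set degrades
to IVW alone, with one to the Wald ratio, and the degradation is recorded.

# Sensitivity suite

* **Cochran's Q** at the fixed-effects IVW estimate (which minimizes the
  weighted RSS), $\chi^2_{n-1}$ under homogeneity.
* **Egger intercept test** as above.
* **MR-PRESSO**: the observed statistic is the leave-one-out weighted RSS
  $\sum_j w_j (\Gamma_j - \gamma_j \hat\theta_{(-j)})^2$; its null
  distribution is built by parametric simulation (both effect vectors
  redrawn, default 1000 replicates). The global p carries an add-one
  correction so it is bounded below by $1/(n_{sim}+1)$ and can never be
  exactly zero. Per-SNP outlier p-values are raw empirical proportions
  (no add-one) Bonferroni-corrected by the SNP count, as in the reference
  algorithm — with an add-one floor no outlier could ever clear a 0.05
  Bonferroni bar at moderate simulation counts. The outlier-corrected
  estimate is IVW on the unflagged SNPs, and the optional distortion test
  compares the raw-vs-corrected shift with the shift from removing equally
  many random non-outliers.
* **Leave-one-out** IVW per SNP, plus the full-set row.

# Strict screening and mediation

An exposure is *strongly supported* when four independent gates all pass:
IVW $p < 0.05$; all five estimators agree in sign (a zero estimate fails);
MR-PRESSO global $p > 0.05$; Egger intercept $p > 0.05$. Both the PRESSO and
Egger gates are applied because "pleiotropy test" is ambiguous between them;
applying both is the stricter and safer reading. A gate whose statistic is
unavailable (e.g. PRESSO with < 4 SNPs) fails conservatively.

Two-step mediation for exposure X, mediator M, outcome Y:

1. $\beta_T$: X → Y total effect (IVW on X's instruments);
2. $\beta_A$: X → M (IVW on X's instruments against the mediator GWAS);
3. $\beta_B$: M → Y, where M's instruments are first purged of every SNP
   used in step 2 *and* (by default) any SNP in LD $r^2 \ge 0.001$ with one.
   This SNP-set exclusion is the package's reading of "adjusting for the
   exposure"; it is deliberately not multivariable MR, which answers a
   different question and needs joint instrument modelling.

The indirect effect is the product of coefficients
$\beta_A\beta_B$ with first-order delta-method (Sobel) SE
$\sqrt{\beta_A^2\mathrm{se}_B^2 + \beta_B^2\mathrm{se}_A^2}$; the mediated
proportion is $100\,\beta_A\beta_B/\beta_T$ (signed, unclamped — negative or
\>100% values indicate inconsistent mediation and are flagged, not hidden).
Because the delta method can disagree with printed CI/Z pairs in applied
papers, a Monte-Carlo CI (normal draws of $\beta_A$, $\beta_B$) is available
via `mc_ci = TRUE` and both conventions are recorded in the output. A
pathway is excluded when reverse MR (outcome as exposure, instruments at
$5\times10^{-8}$) yields IVW $p < 0.05$; when no reverse instruments exist
the check is recorded as not assessed rather than silently passing.

`run_screen_stage()` / `run_mediation_stage()` orchestrate catalogs,
degrading per-exposure failures to logged skips — a screen over hundreds of
traits must survive individual dropouts. No multiplicity correction is
applied to the pass/fail logic (the screening convention is raw 0.05);
`fdr = TRUE` appends a Benjamini–Hochberg column for information only.

# The synthetic GWAS generator

`simulate_pair()` / `simulate_mediation_triple()` emulate the statistical
skeleton the estimators assume: per-SNP MAF uniform on [0.05, 0.5], true
instrument effects half-normal $|N(0, 0.03^2)|$, GWAS sample sizes 100,000,
sampling SEs from the standardized-trait approximation
$1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$, independent noise in the two
samples, Wald p-values. Defaults are strong enough that instruments
typically clear the $10^{-5}$ threshold. Pleiotropy modes plant direct
effects on an `invalid_fraction` of SNPs: `balanced` (mean 0) preserves the
Egger intercept truth of zero, `directional` (non-zero mean) biases IVW.
The mediation triple plants two disjoint instrument blocks (X-instruments
and M-instruments) with total effect
$\theta_{XM}\theta_{MY} + \theta_{direct}$.

Design choices worth stating:

* **Orientation**: true effects are drawn half-normal (all positive), the
  standard orientation in MR simulation studies. With zero-mean instrument
  effects, directional pleiotropy averages out of the IVW numerator and the
  robustness ordering one wants to demonstrate (median beats IVW under
  directional pleiotropy) would be vacuous.
* **Seeding**: one master seed expands into named substreams (MAF, effects,
  pleiotropy, per-sample noise), so changing e.g. the outcome sample size
  leaves the exposure draws bit-identical.
* **Not modelled**: individual-level genotypes, realistic LD (the LD module
  generates block-diagonal matrices), winner's-curse selection of the
  discovery GWAS, or a case-control likelihood for binary outcomes (the
  log-odds scale reuses the same SE approximation). Passing tests therefore
  validate estimator algebra and pipeline logic, not robustness to those
  real-data complications.

# Validation results, and one deliberate failure

The test suite validates the pipeline end-to-end on generated data: oracle
equivalence of every estimator against independent closed forms (weighted
least squares via `stats::lm`, brute-force weighted-quantile and
kernel-grid scans) to ten significant digits; IVW type-I error and CI
coverage at nominal level over 500 replicates; Egger-intercept calibration
under balanced pleiotropy (invalid fraction 0.3, pleiotropy SD 0.005) and
\>80% power against directional pleiotropy of mean 0.01 at 50 SNPs;
MR-PRESSO null global-p uniformity (KS) and \>90% detection of a planted
10-SE outlier among 30 valid SNPs; recovery of a planted mediated
proportion of 13.04% ($\theta_{XM}=0.3$, $\theta_{MY}=0.2$, direct 0.4)
within two Monte-Carlo SEs over 200 replicates. Problem sizes (500/200
replicates, 300 PRESSO simulations in the planted-outlier study, bootstrap
disabled where only point estimates are compared) are the package's chosen
validation scale; all run single-threaded in a few minutes.

One check fails by design of the study conditions, and is kept failing
rather than loosened: *mean bias within two Monte-Carlo SEs of zero for
every estimator* at the generator defaults. With `gamma_sd = 0.03` and
n = 100,000 the mean instrument F is ≈ 33, and all ratio-based estimators
carry the classical finite-sample weak-instrument attenuation
$E[\hat\theta] \approx \theta \cdot F/(F+1)$ — about −0.006 on
$\theta = 0.2$ for IVW (Egger, which amplifies instrument noise, about
−0.017). That is 4–8 Monte-Carlo SEs at 500 replicates, far larger than the
Monte-Carlo noise the tolerance budgets for, and no correct implementation
of these estimators is unbiased at that order. The assertion documents the
attenuation rather than hiding it behind a wider tolerance; coverage,
type-I error and every other property pass at their stated levels.

# Worked example

```{r example}
sim <- simulate_pair(sim_config(m_snps = 25, seed = 42, theta_xy = 0.2))
h <- harmonize(sim$exposure, sim$outcome)
est <- run_all_methods(h, seed = 1, n_boot = 200)
tidy(est)
glance(full_sensitivity(h, est, seed = 1, n_sim = 300))
```

```{r plot, fig.width = 6, fig.height = 3}
autoplot(est)
```

# Known limitations

* First-order ratio variances and delta-method mediation SEs understate
  uncertainty when instruments are weak; the bootstrap and Monte-Carlo CI
  options mitigate but do not remove this.
* The palindromic-SNP policy discards information that frequency inference
  could sometimes rescue; that mode exists but is off by default.
* No multivariable MR, Steiger filtering, or winner's-curse correction;
  exposures selected and estimated in the same GWAS will show the
  attenuation quantified above.
* Per-SNP ratios with near-zero instrument effects are extreme, and the
  unweighted (simple) mode — which cannot down-weight them — occasionally
  chases such a ratio; its replicate distribution is heavy-tailed and
  summaries of it should be robust (median rather than mean). The weighted
  variants are not affected.
* The LD interface expects precomputed $r^2$; the package never estimates
  LD from genotypes.
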