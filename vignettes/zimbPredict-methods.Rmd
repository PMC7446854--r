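---
title: "Predictive analysis of zero-inflated microbiome counts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive analysis of zero-inflated microbiome counts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

zimbPredict implements three strategies for predicting a phenotype from an
OTU count table with zero-inflation, over-dispersion and grouped samples:

1. **LASSO** — an L1-penalised multinomial logistic regression on all
   transformed taxa plus covariates;
2. **screening+GLM** — a per-taxon likelihood-ratio screen with count
   mixed models, followed by an unpenalised logistic model on the selected
   taxa;
3. **screening+LASSO** — the same screen followed by a penalised fit on
   the selected subset.

A Dirichlet-multinomial simulator generates benchmark datasets with a known
signal so the strategies can be compared against an oracle that is told the
true signal taxa.

# Count models for the screen

Each taxon's counts $Z_i$ are modelled conditional on covariates and an
offset $\log T_i$ (total reads), so the mean model describes relative
abundance. The negative binomial pmf is parameterised by mean $\mu_i$ and
inverse dispersion $\theta$; $\theta \to \infty$ recovers Poisson, small
$\theta$ gives the heavy right tail typical of 16S data. Three models are
available:

* **NB**: $\log \mu_i = \log T_i + X_i\beta + W_i b$, with random
  intercepts $b \sim N(0, \sigma_b^2)$ per group of the random factor.
* **ZINB**: a mixture of a point mass at zero (probability $\phi_i$,
  logit-linked) and an NB; under the alternative the phenotype enters both
  the mean and the zero component.
* **TPNB** (two-part NB): the model is chosen per taxon by its zero
  proportion (ZP): plain NB when ZP $\le$ 10%, a hurdle
  (logistic presence + zero-truncated NB) for 10% < ZP $\le$ 80%, a
  presence/absence logistic regression for 80% < ZP < 90%, and the taxon is
  dropped (p-value set to 1) at ZP $\ge$ 90%. Boundary values resolve to
  the lower-numbered rule.

Random intercepts are integrated out with a Laplace approximation: a
safeguarded one-dimensional Newton finds each group's conditional mode and
the marginal likelihood uses the curvature correction
$-\tfrac12\log(\sigma_b^2 H_g)$. The outer parameters are maximised by
BFGS with analytic gradients (envelope theorem plus the implicit
derivative of the log-determinant term; the dispersion direction is
differenced). The tests verify the marginal log-likelihood against a
64-node adaptive Gauss–Hermite quadrature oracle (within $10^{-3}$ on
small instances) and against glmmTMB on simulated data. Dispersion is
estimated jointly and bounded below at $10^{-3}$; fits stuck at the
dispersion floor are restarted once from moderate dispersion, because that
boundary is a known flat trap for quasi-Newton methods. Non-convergence is
never an exception: the taxon is reported with p = 1 and a flag.

The likelihood-ratio statistic $T_n = 2(\log L_1 - \log L_0)$ is referred
to a chi-square whose degrees of freedom equal the parameter difference:
$K-1$ when the phenotype (with $K$ levels) enters only the mean (NB and
the logistic regime), $2(K-1)$ when it enters both components (ZINB,
hurdle). q-values use the conservative Benjamini–Hochberg step-up
($\hat\pi_0 = 1$); a Storey variant with the $\hat\pi_0(\zeta)$ estimator
is available. Taxa with q $\le$ 0.05 are selected by default.

# Transforms and classifiers

Counts enter the classifiers either as the variance-stabilising
$\tilde Z = \arcsin\sqrt{Z/T}$ or as the presence indicator $I(Z>0)$.
The design matrix holds an intercept, the transformed taxa, fixed factors
(categorical ones dummy-coded with $k-1$ columns, reference = first sorted
level) and, optionally, dummy columns for the random-factor groups. All
non-intercept columns are standardised with *training-set* statistics; the
same centres and scales are applied to test samples, so no held-out
information leaks into the fit. Constant columns are left unscaled and
flagged.

The penalised fit minimises the soft-max negative log-likelihood plus
$\lambda \sum_k \lVert\beta_k\rVert_1$ in the symmetric all-classes
parameterisation (identifiability is resolved by the penalty; intercepts
are unpenalised). Fitting is delegated to glmnet's coordinate descent; the
objective equivalence with an independent proximal-gradient solver and the
KKT conditions are asserted in the tests. $\lambda$ runs over a 200-point
geometric grid from the data-driven $\lambda_{\max}$ (the smallest penalty
with an all-null penalised fit, computed from the score at the
intercept-only model) down to $10^{-4}\lambda_{\max}$; the user-facing
objective is the unscaled log-likelihood, so glmnet's per-observation
penalty is ours divided by $n$. Cross-validation is stratified by class,
scores candidate $\lambda$ by held-out error rate under the argmax rule,
and breaks ties toward the largest (sparsest) $\lambda$. Where an
unpenalised multinomial GLM is called for (screening+GLM, the oracle), a
fixed tiny ridge of $10^{-6}$ guards against separation, which is routine
when tens of selected taxa meet a few hundred samples.

Evaluation uses the misclassification error rate ER, the baseline
$ER^{(0)} = 1-\max_k f_k$, the relative reduction
$R^2_{ER} = (ER^{(0)}-ER)/ER^{(0)}$, rank-based AUC (ties counted one
half) and a step-interpolated AUPRC (right-continuous in recall; linear
interpolation is avoided as optimistic). Argmax ties break toward the
majority training class; the positive class defaults to the second sorted
level.

For simulation studies each replicate is split 80/20 with stratification,
and screening, $\lambda$ selection and standardisation use the training
portion only. For user data, `externalCV()` re-runs the *entire* strategy
(screening included) inside every fold — the leakage-safe protocol — and
assembles out-of-fold predictions.

# The synthetic benchmark

`generateDataset()` draws, per replicate: total reads
$T_i \sim$ Unif(10 000, 300 000); taxon proportions
$p_i \sim$ Dirichlet($\alpha$); counts $Z_i \sim$ Multinomial($T_i, p_i$);
a continuous covariate $X^{(1)} \sim$ Unif(20, 50) with effect $-1$; a
3-level factor $X^{(2)}$ with effects (10, 15); a balanced 5-group random
factor $W$ with effects $(-100,-50,0,50,100)$; 20 signal taxa with effects
drawn from Unif(1.5, 2) (ten taxa) and Unif($-2,-1.5$) (ten taxa), all
other taxa 0; and the phenotype
$Y \sim$ Bernoulli$(p)$, $p = 1/(1+\exp(\eta))$,
$$\eta = \beta_0 + c\,\tilde Z \beta_Z + X\beta_X + W\beta_W + \epsilon,
\qquad \epsilon \sim N(0, 10),$$
with $\beta_0 = 1$. Design 2 omits $W\beta_W$ from $\eta$ (the factor is
still generated); design 3 uses $n = 262$ instead of 500. Note the sign
convention as printed: large $\eta$ favours class "0". All randomness
flows from a master seed through counter-based substreams
(`derivedSeed()`), so replicates are reproducible and order-independent.

Three quantities are not derivable from the published design and are the
package's own, documented choices:

* **The Dirichlet parameters.** The source cohort's fitted parameters are
  unpublished, so a stand-in is used: log-normal base weights
  ($\sigma_{\log} = 1.5$) normalised to total concentration 300. This was
  chosen once to mimic a prevalence-filtered gut census: median per-taxon
  zero proportion around 0.3–0.5 at the simulated depths, roughly 10% of
  taxa beyond the 90%-zeros drop rule, and variance far above multinomial
  (the DM inflation factor $(T+\!\sum\alpha)/(1+\!\sum\alpha)$ is in the
  hundreds). It does not attempt phylogenetic correlation among taxa.
* **The scale of the OTU term.** The design never states the scale on
  which counts enter $\eta$; raw counts with effects near $\pm 1.75$ would
  saturate the logit by orders of magnitude. Taxa therefore enter as
  standardised (zero-mean, unit-variance within the replicate)
  arcsine-square-root proportions times a single multiplier $c$.
* **The two calibrated scalars.** `calibrateSignal()` adjusts an additive
  intercept offset and the multiplier $c$ so that (i) the majority class
  has prevalence $0.6 \pm 0.03$ (baseline error 0.4) and (ii) the oracle
  model's held-out error is $0.04 \pm 0.02$. The oracle-ER response to
  $c$ is not monotone: when $c$ is small the printed covariate effects
  ($\pm 100$ group effects against noise with variance 10) classify most
  samples deterministically, a regime in which screening has essentially
  no power and the penalised models ignore the taxa entirely —
  behaviour inconsistent with the benchmark's published character.
  The design states the group-effect gap (50) was chosen to be comparable
  in scale to the simulated OTU term, which pins the per-taxon
  contribution near that gap: $c_0 = 50/\overline{|\beta_Z|} \approx 28.6$.
  Calibration therefore starts at $c_0$ and bisects along the
  signal-dominant branch only if the oracle band is missed there; the
  intercept offset is then re-centred. Calibrated values are stored in the
  config and can be persisted as plain text.

At this operating point (and with the package's defaults) the benchmark
reproduces the qualitative structure of the published study: the oracle
sits near 0.04 error, the full-LASSO strategy recovers essentially all 20
signal taxa, two-part-NB screening recovers about 11 of them at q ≤ 0.05
with power near 0.5–0.6 and is at least as powerful as ZINB/NB, the
variance-stabilising transform clearly beats the binary transform, and
power drops at $n = 262$. Two quantitative points deviate: the full-LASSO
error rate here is lower (about 0.11–0.13 against a published 0.21) and
its AUC correspondingly higher, because standardised features are easier
to estimate than whatever raw-scale features produced the published gap
between oracle and LASSO; the deviation is intrinsic to the standardised
reading of the phenotype model and is reported, not tuned away.

What passing the synthetic tests does **not** show: the generator has no
phylogenetic or ecological correlation structure beyond compositional
coupling, no batch effects, and its signal taxa act additively on the
logit — real microbiome signals need not behave this way.

# Numerical choices and degenerate inputs

* Zero-proportion dispatch boundaries are closed toward the
  lower-numbered rule (10% → NB, 80% → hurdle).
* Fits that do not converge, and taxa dropped by the ZP rule, propagate
  p = 1 (conservative) rather than halting a 587-taxon screen.
* $\sigma_b^2$ at the boundary is handled by comparing against the
  fixed-effects profile; a single observed group degenerates to the GLM.
* Empty screening selections fall back to covariates-only models; designs
  that lose all taxa remain valid.
* CV folds that lose a class are re-drawn (up to 10 attempts) before
  erroring; LASSO tie-breaks go to the sparser model.
* The simulation evaluation uses one stratified 80/20 split per replicate;
  nested CV is reserved for the real-data path.

# Problem sizes

The shipped tests and the acceptance script run the full-size generator
($n = 500$ or 262, $m = 587$) with 10 replicates for screening arms and 20
for prediction arms — reduced from the study's 100 — which keeps a
complete run in the tens of minutes on a single core while leaving
Monte-Carlo error well inside the stated tolerances.

# Real data

`readCounts()`/`readMetadata()` ingest TSV tables (samples × taxa plus a
metadata sheet); `filterMinReads()` (default 10 000 reads) and
`filterPrevalence()` (default 20%) apply the usual quality-control rules,
depth filter first. Totals are sequencing depths and are deliberately not
recomputed after taxon filtering, so the relative-abundance offset keeps
its meaning. The published case study's cohort is not redistributed with
the package; the real-data path is exercised on synthetic stand-ins in the
tests.
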