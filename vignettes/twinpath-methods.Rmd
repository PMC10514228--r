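---
title: "Liability-threshold twin models by two-stage weighted least squares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold twin models by two-stage weighted least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpath)
```

## The scientific problem

Lifetime use or misuse of a drug, recorded as a yes/no interview item, is
the visible tail of a continuum of risk. The classical twin design
identifies the sources of that risk by contrasting monozygotic (MZ) pairs,
who share all segregating genes, with same-sex dizygotic (DZ) pairs, who
share half on average: additive genetic liability (A) correlates 1 across
MZ and 0.5 across DZ co-twins, the common environment (C) is shared within
any pair, and the unique environment (E, which absorbs measurement error)
is individual. With many substances measured at once, the further question
is *structure*: is the familial liability one general propensity that all
substances tap, or do clusters of substances (for example prescription
misuse versus illicit use) carry separable genetic and environmental
factors, and how much of each substance's risk is drug-specific?

## Model family

All models live on the liability scale. A binary phenotype $y_j$ is
$\mathbb{1}\{\ell_j > \tau_j\}$ with $\ell_j$ standard normal; the
threshold is fixed by the prevalence, $\tau_j = \Phi^{-1}(1-p_j)$, and is
estimated separately for men and women (the groups are same-sex, so sex
never enters the correlation structure directly).

With loading matrices $\Lambda_a, \Lambda_c, \Lambda_e$ for general
factors and specific variances on the diagonal, the within-twin
correlation block is

$$\Sigma_W \;=\; \Lambda_a\Lambda_a' + \Lambda_c\Lambda_c' +
\Lambda_e\Lambda_e' + \mathrm{diag}(v_{sa} + v_{sc} + s_e^2),$$

and the cross-twin block is

$$\Sigma_X \;=\; \kappa\,(\Lambda_a\Lambda_a' + \mathrm{diag}(v_{sa}))
+ \Lambda_c\Lambda_c' + \mathrm{diag}(v_{sc}),
\qquad \kappa = 1\ (\mathrm{MZ}),\ \tfrac12\ (\mathrm{DZ}).$$

The packaged specifications are the univariate ACE model, the bivariate
Cholesky (for cross-trait correlations), independent pathway models
(IPM; general A/C/E factors loading on every phenotype, named by factor
counts such as 2-2-2 or 1-0-1, with either echelon identification or a
prescription-vs-illicit split driven by the codebook's class tags), and
the one-factor common pathway model (CPM; general loadings
$\lambda_j$ with the factor itself decomposed as
$a_F^2 + c_F^2 + e_F^2 = 1$, so the general a/c/e mix is proportionally
identical across phenotypes — the CPM is exactly the 1-1-1 IPM with its
three loading columns constrained proportional, hence nested).

### Parameterization choices

Three decisions here were genuinely open and matter downstream:

* **Unit variance by construction.** The specific-E coefficient is never a
  free parameter: $s_{e,j} = \sqrt{\max(0,\ 1 - \text{explained}_j)}$,
  with a smooth quadratic penalty once the explained variance exceeds 1
  (and the same device for $e_F$ in the CPM). Every admissible parameter
  vector therefore yields an exactly standardized solution, without
  constrained optimization. Solutions with any residual below $10^{-6}$
  are flagged as boundary solutions.
* **Signed variance components for specific A and C.** Specific A and C
  enter as free *variances* $v_{sa}, v_{sc}$, allowed to go modestly
  negative, rather than as path coefficients. The moment structure depends
  on a path coefficient only through its square, so a Wald test of a
  true-zero specific path has a degenerate null distribution ($4z^2$
  rather than $\chi^2_1$, roughly tripling the nominal size). With signed
  variances the moment map is locally linear at zero and the drop-test is
  calibrated — the classical unbounded-variance device of twin modelling.
  Estimated proportions are reported raw; a small negative specific
  variance is a boundary phenomenon, not an error.
* **Regularizing the flat ridge.** When a general loading is truly zero
  *and* its same-component specific variance is free, the trade-off
  $\lambda^2 + v = \text{const}$ is locally flat; soft box constraints
  (squared loadings at most 1, specific variances at least $-0.3$) and a
  minuscule ridge on the signed variances ($10^{-6}\times$ the largest
  weight — orders of magnitude below the data curvature of any identified
  direction) keep the optimizer from wandering along it. Sandwich
  covariances drop exactly-flat directions by pseudo-inversion with a
  warning, which makes Wald restrictions touching them conservative; a
  flat direction carried by a large estimate still raises, since that
  indicates genuine non-identification. Wald tests of dropping *entire
  general factors* whose loadings are truly zero sit on the boundary of
  the identified set in any parameterization and are reported but not
  claimed to be calibrated (commercial estimators show the same behaviour,
  printing either nonconvergence or hyper-conservative p-values for such
  drops); factor-count selection is better judged by the fit indices.

### Identification bookkeeping

Distinct fitted moments are the $p(p-1)/2$ within-person and $p(p+1)/2$
cross-twin correlations per group ($4p^2$ over the four groups;
thresholds are fixed at stage 1 and cancel from the degrees of freedom).
Free parameters are the general loadings (echelon zeros identify
rotations when a component has two factors), the retained specific A/C
variances, and for the CPM the loadings plus $a_F, c_F$. Under this rule
the packaged IPM ladder has df $484 - 85 = 399$ (2-2-2), $429$ (1-1-1),
$440$ (1-0-1), and $457$ (reduced 1-0-1) for eleven phenotypes. The same
rule gives the one-factor CPM df 449; estimators that count residual-E
paths as free in common-pathway models (but not in independent-pathway
models) arrive at 438 — no single consistent rule reproduces both
families, so the package keeps the consistent one.

## Estimation

**Stage 1.** Per zygosity-sex group: thresholds from all observed
individuals (both twins pooled); within-person tetrachorics from all
individuals (twins pooled, so the twin-1 and twin-2 blocks are equal by
construction); cross-twin tetrachorics from complete pairs with both
orderings averaged (exchangeability holds exactly). Each tetrachoric
fixes its thresholds at the table's margins; the MLE then solves the
monotone cell-matching equation $P_{11}(\rho) = \hat p_{11}$ by
safeguarded Newton iteration on a 64-node Gauss–Legendre orthant
integral, clamped at $|\rho| \le 1-10^{-8}$. Tables containing a zero
cell get $+0.5$ on every cell and are flagged — unavoidable at realistic
sample sizes when a phenotype has 1–2% prevalence. The observed
information has a closed form at the matching solution,
$-\ell'' = N\,\phi_2^2 \sum_{ij} p_{ij}^{-1}$, which supplies the default
(diagonal) weights. The full asymptotic covariance of a group's moment
vector — needed by the mean-adjusted test statistic and the sandwich — is
estimated by a pair-level nonparametric bootstrap (default 200
replicates), vectorized over replicates via multinomial resampling of
pair-level cell counts; this is algebraically identical to resampling
pairs and re-estimating, and automatically propagates threshold noise.
An independent brute-force verifier (`tetrachoric_oracle()`: staged dense
grid search with two-dimensional tensor quadrature of the raw density)
shares no code with the production estimator and agrees with it to
$10^{-6}$ over randomized tables.

Missingness is handled available-case per moment, mirroring the design in
which incomplete pairs still inform thresholds and within-person
correlations. Masking of second twins in the generator is completely at
random; nothing in the estimators assumes a missingness mechanism beyond
that.

**Stage 2.** Minimize
$F(\theta) = \sum_g (s_g - \sigma_g(\theta))' W_g^{-1} (s_g - \sigma_g(\theta))$
with $W_g$ the diagonal of the stage-1 acov (robust/DWLS default), the
full bootstrap acov (flagged unstable for eleven phenotypes, where the
weight matrix dimension grows with the square of the moment count), or
the identity. Structural parameters are shared across the four groups;
sex-specific fits duplicate them by sex. Optimization is multi-start
quasi-Newton (`nlminb`, five jittered starts by default, sub-seeds
derived from the user seed, crude start from Falconer decompositions of
the same-trait cross-twin correlations), followed by a polishing pass.
Convergence requires a scaled gradient norm below tolerance, a positive
semidefinite Hessian, and no active penalty; nonconvergence is an
ordinary reportable outcome (model-ladder tables print "No convergence"
rows rather than raising). Factor signs are canonicalized so the first
free loading of each factor is nonnegative. For the exactly identified
univariate model the bootstrap path uses a closed-form weighted
least-squares solve (the objective is linear in $a^2, c^2$), verified to
agree with the general optimizer.

## Inference

* **Fit statistic.** $df = \#\text{moments} - \#\text{free parameters}$;
  $T = df \cdot F_{\min} / \mathrm{tr}(U\Gamma)$ with
  $U = W^{-1} - W^{-1}\Delta(\Delta'W^{-1}\Delta)^{-1}\Delta'W^{-1}$.
  Since $E[F_{\min}] = \mathrm{tr}(U\Gamma)$ under the model, $T$ is
  mean-calibrated and referred to $\chi^2_{df}$ (single scaling; the
  empirical size is verified by simulation rather than by formula
  pedigree).
* **Fit indices.** Multi-group convention
  $\mathrm{RMSEA} = \sqrt{G\,\max(T-df,0)/(df\,N)}$ with $N$ the number
  of individuals and a 90% interval from the noncentral chi-square;
  $\mathrm{TLI} = ((T_b/df_b)-(T/df))/((T_b/df_b)-1)$;
  $\mathrm{CFI} = 1 - \max(T-df,0)/\max(T_b-df_b, T-df, 0)$. The baseline
  keeps the thresholds and fixes every correlation at zero. Conventional
  cutoffs (RMSEA < 0.05, TLI > 0.95, CFI > 0.95) are attached as flags.
  At $T=424.58$, $df=399$, $N=7164$, $G=4$ this convention gives
  RMSEA 0.006.
* **Wald tests** on the fuller model,
  $W = (R\hat\theta - r)'(RVR')^{-1}(R\hat\theta - r)$ with $V$ the
  sandwich
  $(\Delta'W^{-1}\Delta)^{-1}\Delta'W^{-1}\Gamma W^{-1}\Delta(\Delta'W^{-1}\Delta)^{-1}$.
  Nested comparisons restrict the parameters absent from the reduced
  spec; likelihood-ratio differences are deliberately not offered for
  DWLS fits without a proper scaling correction.
* **Sex differences** are tested by fitting the univariate ACE model with
  sex-specific structural parameters and Wald-testing the cross-sex
  equalities (2 df; *e* is determined by the unit-variance constraint).
  **Sex as a covariate** enters as a per-phenotype probit threshold shift
  $\beta_j$; the liability variance explained by sex is
  $\beta_j^2 v_s/(\beta_j^2 v_s + 1)$. Because all groups are same-sex,
  within-group correlations already condition on sex and the structural
  stage is unchanged.
* **Bootstrap intervals.** Pairs (and singletons) are resampled with
  replacement within groups; both stages are refitted per replicate, warm
  started at the point estimate; BCa intervals use the bias-correction
  from the replicate distribution and acceleration from a pair-level
  jackknife (delete-block jackknife above 2000 pairs). Intervals use
  converged replicates only, with reliability warnings past 10% failures.

## The synthetic generator

No individual-level data from the motivating study design are
distributable, so the generator is a first-class module: it draws factor
scores per pair (A with cross-twin correlation $\kappa$, C shared, E
individual, specifics likewise), forms liabilities from a fully
standardized `generating_model`, thresholds them per sex, and masks twin 2
completely at random to create incomplete pairs. `atr_preset()` emulates
a large volunteer-registry study of drug (mis)use: 11 phenotypes with the
published lifetime prevalences (7.79% prescription-opioid misuse down to
1.31% heroin and 1.86% dissociatives), group sizes derived from the
published individual counts (MZ male 1555, MZ female 2405, DZ male 1324,
DZ female 1880), and per-group completeness reproducing 84.12% of
individuals in complete pairs. Its loading structure is the reduced
1-0-1 IPM; per-phenotype cells that were not published numerically are
synthetic fill-ins consistent with every published fragment (e.g. POM
14/41/39/0/6 percent across general-a/general-e/specific-a/specific-c/
specific-e, heroin 64/15/0/0/21). `shrunken_preset()` is a five-phenotype
analogue (one general A, one general E, specific A on the two
prescription phenotypes, complete pairs, moderate prevalences) used for
recovery and calibration experiments at desk scale.

What passing tests on these data do and do not show: the generator
satisfies the liability-threshold ACE assumptions *exactly* — multivariate
normal liability, MCAR incompleteness, no assortative mating, no
dominance, no sex difference in structure. Real interview data violate
several of these (at minimum measurement non-invariance and non-random
nonresponse), so recovery and calibration results certify the estimator,
not the model's adequacy for any particular dataset.

## Numerical choices and problem sizes

Tolerances: Newton cell-matching to $10^{-12}$; optimizer relative
tolerance $10^{-12}$ with a $10^{-14}$ polish; gradient check via central
differences; correlation clamp $1-10^{-8}$; acov smoothing floor
$10^{-6}$ of the mean diagonal when a full weight matrix is inverted.
The simulation-based checks in the test suite use sizes chosen to give
stable Monte-Carlo verdicts on a single CPU: recovery at 2000 pairs per
group over 100 replicates, test-size calibration at 1000 pairs per group
over 300 replicates, bootstrap coverage at 800 pairs per group over 200
datasets with 400 replicates each, and generator fidelity at ten times
the registry scale. The acceptance script reruns the same experiments at
reduced replicate counts.

## Known limitations

Full-weight WLS is exposed but not recommended beyond a handful of
phenotypes. Ordinal (more than two category) items, opposite-sex pairs,
dominance (ADE) decompositions, and assortative-mating corrections are
out of scope. The mean-adjusted statistic uses a single scaling constant,
not mean-and-variance adjustment, so its tail behaviour is verified
empirically rather than guaranteed: under the calibration design (three
phenotypes, 1000 pairs per group) its empirical size at nominal 0.05 is
roughly 0.06–0.10 across simulation streams — a slightly heavy upper
tail, the recognised cost of mean-only scaling at moderate degrees of
freedom; degrees-of-freedom bookkeeping
follows the single consistent rule described above. BCa acceleration from
a delete-block jackknife is an approximation whose block count trades
accuracy for time.
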