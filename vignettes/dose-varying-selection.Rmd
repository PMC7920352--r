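---
title: "Dose-varying coefficient modelling and two-stage gene selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-varying coefficient modelling and two-stage gene selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large cancer cell-line screens measure viability of a cell line under a drug
at a short dilution series of doses (here: 9-point 2-fold or 5-point 4-fold
series down from a per-drug maximum concentration), together with baseline
gene expression of the cell line. The usual analysis collapses each dilution
series into a single summary (an IC50 or an area under the curve) and
regresses that summary on expression, which discards how a gene's influence
changes with dose. `dosevc` instead models the whole normalized response
curve and lets every covariate effect be a smooth function of the dose
fraction:

$$ y_{ij} \;=\; \sum_{k=0}^{p} z_{ik}\,\beta_k(d_{ij})
   \;+\; \sum_{g=1}^{G} x_{ig}\,\gamma_g(d_{ij}) \;+\; \varepsilon_{ij}, $$

where unit $i$ is one cell line-drug pair, $d_{ij} \in (0, 1]$ its $j$-th
dose as a fraction of the drug's maximum, $z_i$ a short vector of design
covariates (intercept, drug, tissue dummies), and $x_i$ the
(standardized) expression vector with $G$ in the thousands. Errors are
independent across units, dependent within a unit, with dose-varying
variance $V(d)$. Sparsity is assumed: only a small set of genes has
$\gamma_g \neq 0$.

With $G \gg n$ the joint fit is infeasible, so selection is done in two
stages: a weighted *marginal screen* ranks genes by how much each one alone
improves the fit, and a *group-SCAD* penalized regression on the screened
set makes the final selection.

## Basis, weights, and the whitened objective

**Spline basis.** Every coefficient function is expanded in clamped cubic
B-splines. The default uses one interior knot at the median observed dose
and boundary knots at the observed dose range, giving $L = K + q + 1 = 5$
basis functions. The rate-rule `interior_knot_count(n, q)` =
$\lfloor n^{1/(2q+3)} \rfloor$ is exposed, but the one-knot default is
deliberate: dilution designs have at most 9 distinct doses, and the basis
dimension must stay well below that. (The dimension count $L = K + q + 1$
is the standard clamped-boundary convention; it is what the partition of
unity test pins down.)

**Variance function.** $V(d)$ is estimated from the residuals of the
unweighted z-only fit: squared residuals are averaged within each distinct
dose fraction — the design is discrete, so binning by dose is exact — then
smoothed by unpenalized projection onto the same spline basis and floored
at $10^{-8}$.

**Working correlation.** Within-unit dependence is modelled either as
independence or as a rational quadratic function of the dose lag,
$R(h) = \bigl(1 + h^2/(2a\ell^2)\bigr)^{-a}$. Residuals standardized by
$\hat V$ are multiplied pairwise within units, pooled by dose lag, and
$(a, \ell)$ fitted by pair-count-weighted least squares from several
Nelder-Mead starts. The shape parameter $a$ is weakly identified (a known
property of this family); the length scale $\ell$ is what the recovery
tests check.

**Weights.** Each unit contributes
$W_i = n_i^{-1} \hat V_i^{-1/2} R_i(\hat\phi)^{-1} \hat V_i^{-1/2}$, and
every weighted objective in the package is the whitened sum
$\sum_i r_i^{\mathsf T} W_i r_i$ computed through the Cholesky factor of
$W_i$. With the independence structure and unit variance this reduces to
per-unit-normalized least squares.

## Stage one: marginal screening

For each gene the marginal model (z-blocks plus that gene's spline block)
is fitted by whitened least squares and scored by the utility
$u_g = n^{-1}\sum_i (y_i - \hat y_i^{(g)})^{\mathsf T} W_i
(y_i - \hat y_i^{(g)})$; smaller is stronger. Genes are ranked by ascending
utility (ties broken by gene index) and the first
$\tau_n = \lfloor \nu\, n / \log n \rfloor$ retained — the natural
logarithm, under which the reference screen of 3805 units at $\nu = 2$
retains 923 genes. $n$ counts experimental units, not observations. The
weight model is estimated once from the z-only residuals and shared across
genes.

## Stage two: group-SCAD selection

On the screened set the package minimizes half the whitened residual sum of
squares plus $\sum_g p_{\lambda,\alpha}(\lVert\eta_g\rVert_2)$, where
$\eta_g$ are the $L$ spline coefficients of gene $g$ and
$p_{\lambda,\alpha}$ is the SCAD penalty (linear to $\lambda$, quadratic to
$\alpha\lambda$, constant beyond). Grouping the spline coefficients makes
selection all-or-nothing per gene; SCAD's flat tail leaves large effects
essentially unbiased. The z-blocks are never penalized. $\alpha$ defaults
to the conventional 3.7.

The optimizer iterates the local linear approximation: per-group weights
$p'_{\lambda,\alpha}(\lVert\eta_g^{(t)}\rVert)$ define a weighted
group-lasso surrogate, solved by block coordinate descent. Because the
penalty is on the *unweighted* Euclidean norm of the original coefficients
(no basis-Gram re-weighting), the per-block update is not a plain
soft-threshold; it is computed exactly from the eigendecomposition of the
block Gram matrix and a safeguarded Newton solve of the monotone scalar
equation $c\,s(c) = w$. Initialization is the weighted ridge solution
(ridge $10^{-4}$); convergence is declared when the largest coefficient
change falls below $10^{-6}$, with a 500-iteration cap and a recorded,
non-increasing objective trace.

$\lambda$ is chosen by 5-fold cross-validation over units (a unit's doses
never split across folds), stratified by drug so each fold sees every drug.
The grid is 50 log-spaced values from $\lambda_{\max}$ (the smallest value
that zeroes every group at the first LLA step) down to
$10^{-3}\lambda_{\max}$, fitted with warm starts along the path; ties in
the CV curve resolve to the larger $\lambda$. Path fits use a looser
optimizer tolerance ($10^{-4}$) than the final refit — the CV curve is
insensitive to coefficient noise that far below fold-to-fold variability.

## Effect summaries

Selected genes are summarized exactly as a practitioner would read them
off: the coefficient curve on a 101-point dose grid; its area
$\int |\hat\gamma_g|\,dd$ by trapezoid (the absolute value keeps mixed-sign
curves rankable); a sign class (+ if positive over the whole grid, − if
negative, 0 if mixed); and the Spearman correlation between dose and curve
value as a monotonicity index. Uncertainty comes from resampling units with
replacement ($B = 200$ by default) and refitting the *unpenalized* weighted
model on the fixed selected set — re-running selection inside the bootstrap
is deliberately avoided; the bands therefore describe estimation
uncertainty given the selection. Predictive accuracy is scored by MAE plus
four argmin-matching scenarios (best drug-dose pair and best drug per cell
line; best dose and best dose range — split at 31.25% of the maximum dose —
per unit), with "best" meaning lowest predicted (resp. observed)
viability. A four-parameter logistic fit extracts an IC50 from any
predicted curve, flagged when the curve never crosses half-viability inside
the dose domain.

## What the synthetic generator emulates

`simulate_panel()` draws panels that look like a subsample of a large
screen: a cell-line pool of $\lceil 0.9\,n\rceil$ lines (nearly every unit
a distinct cell line, some lines recurring across drugs), five drugs and
three tissues by default, 66% of units on the 9-point 2-fold series and the
rest on the 5-point 4-fold series, expression multivariate normal with
exchangeable gene-gene correlation $\rho_x = 0.2$, errors with
$V(d) = \sigma^2(1+d)^2$ ($\sigma = 0.1$) and rational quadratic
within-unit correlation ($a = 2$, $\ell = 0.3$) by default.

The true effect library (constant, linear, sine, bump) is normalized so
each shape has unit root-mean-square over the design's pooled dose
distribution: dilution series concentrate doses near zero, and without the
normalization "amplitude 1" would mean a strong constant effect but a
nearly invisible linear one. Amplitude $a$ therefore always means: one SD
of expression shifts the response by $a$ response-units RMS over the tested
doses. The default active set is three *sign-balanced pairs*
(constant, linear, sine, each once up- and once down-regulating). Balance
is a deliberate design choice: with exchangeable expression correlation, a
same-sign active set creates an aggregate association that every inactive
gene proxies through the shared expression factor, and the spread of those
proxies — not noise — then dominates marginal screening. Real panels
contain both resistance- and sensitization-type effects, and the balanced
default keeps the screening problem about individual genes rather than a
global confound.

What the generator does *not* emulate: real expression covariance (block
structure, skewness), batch effects, plate artefacts, heteroscedasticity
beyond the $(1+d)^2$ profile, or replicate assays. Passing the Monte Carlo
suite therefore shows the procedure works under the model's own
assumptions at realistic sizes — not that it is robust to everything real
data does.

## Numerical choices

* **Condition cap on $R_i^{-1}$.** Neighbouring doses in a dilution series
  are very close on the dose-fraction scale, so a strongly correlated
  working structure makes $R_i$ near-singular (smallest eigenvalues
  $10^{-10}$–$10^{-6}$ arise routinely when the low-dimensional residuals
  are dominated by gene effects). The inverse is computed from the
  eigendecomposition with eigenvalues floored at (leading eigenvalue /
  100), bounding the whitener's amplification of near-duplicate dose
  contrasts; well-conditioned correlations are untouched.
* **Variance floor** $10^{-8}$; **ridge** $10^{-10}$ in the variance
  projection; group Grams get eigenvalues clipped at 0.
* **Ties**: utility ties break by gene index; CV ties by larger $\lambda$;
  argmin ties in the evaluation harness by first row in input order.
* **Degenerate inputs**: units with control ≤ blank or fewer than two
  positive doses are dropped with a warning; a constant curve returns
  Spearman 0 with a `constant` flag; a flat predicted curve returns an
  IC50 clipped to the domain with an `extrapolated` flag.
* **Determinism**: one master seed governs fold assignment (seed + 1) and
  the bootstrap (seed + 2); the simulation harness draws per-replicate
  seeds once from its master seed, so replicates are reproducible and
  shareable across scenarios.

## Problem sizes used by the test-suite studies

The shipped studies run at the sizes the methods are meant for, scaled to
what a single desk machine fits comfortably: the selection-recovery study
uses $n = 190$ units and $G = 886$ genes with 6 active at 25 replicates;
effect-curve error is compared at $n = 100$ vs $n = 400$ (constant/linear
truths, which the basis spans exactly, so the comparison isolates
estimation error from approximation bias); correlation recovery uses 1000
units with no active genes (the clean regime the estimator is defined
for). These sizes are the package's own study design choices.

## Known limitations

* The working weights are estimated from z-only residuals, exactly as the
  two-stage procedure prescribes; when gene effects are large relative to
  noise those residuals contaminate both $\hat V$ and $\hat R$, and the
  weights drift from the true error covariance. Screening ranks are robust
  to this (they are relative), but single-gene marginal *estimates* under
  heavily contaminated weights can be distorted — the condition cap bounds,
  but does not remove, this effect.
* The shape parameter $a$ of the rational quadratic family trades off
  against $\ell$; only $\ell$ should be interpreted.
* The bootstrap conditions on the selected set; its bands do not account
  for selection uncertainty.
* Sign-balance in the generator's default truth is a property of the
  default, not of the method; users studying same-sign regimes can and
  should set `amplitude` accordingly and expect harder screening.
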