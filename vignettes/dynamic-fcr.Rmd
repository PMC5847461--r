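---
title: "Dynamic functional concurrent regression: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional concurrent regression: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfcr)
```

## The model

`dynfcr` fits a functional concurrent regression (FCR) model for outcomes
observed at irregular, subject-specific times. With subjects $i = 1, \dots,
N$ observed at visit times $t_{ij}$, $j = 1, \dots, m_i$,

$$Y_{ij} = f_0(t_{ij}) + \sum_{p=1}^P z_{p,ij}\, f_p(t_{ij}) + b_i(t_{ij}) +
\epsilon_{ij}, \qquad \epsilon_{ij} \sim N(0, \sigma^2_\epsilon),$$

where the $f_p$ are smooth time-varying coefficient functions, the $z_{p,ij}$
are covariate values (time-invariant covariates broadcast across visits;
time-varying covariates observed concurrently with the outcome), and $b_i$ is
a smooth, zero-mean subject-specific deviation curve — a *functional random
intercept* — with covariance $\mathrm{cov}\{b_i(s), b_i(t)\} = C(s, t)$. The
motivating setting is growth-curve modeling: predicting a child's
length-for-age z-score trajectory from sex, concurrent weight-for-age
z-scores, and the child's own partial history. A scalar random
intercept/slope is a special case (the `amm` competitor) but is usually too
rigid for standardized growth trajectories, which rise and fall nonlinearly.

Time-varying covariates are themselves measured sparsely and with error:
$Z_{i,\mathrm{obs}}(t_{ij}) = Z_i(t_{ij}) + \epsilon^z_{ij}$, with
$Z_i = \mu_z + b_{iz}$ a smooth latent process. Before entering the outcome
model, each such covariate is denoised by sparse functional principal
component analysis: the package estimates $\mu_z$, the covariance surface
$C_z$, and the noise variance $\sigma^2_{\epsilon z}$, and substitutes the
best linear unbiased predictor (BLUP)
$$\tilde Z_i(t) = \hat\mu_z(t) + \hat C_z(t, \mathbf t_i)'
\{\hat C_z(\mathbf t_i, \mathbf t_i) + \hat\sigma^2_{\epsilon z} I\}^{-1}
\{Z_{i,\mathrm{obs}} - \hat\mu_z(\mathbf t_i)\}.$$

## Basis and penalty

Every coefficient function and the random intercept use one shared cubic
B-spline basis $B(t) = \{B_1(t), \dots, B_c(t)\}'$, with interior knots at
the empirical quantiles of the pooled observed times, so knot density follows
visit density. Sharing the basis keeps the design block-structured and the
penalty block-diagonal. The default is 6 interior knots, i.e. $c = 10$ basis
functions per block — for a two-year domain this resolves features a few
months wide while keeping the random-intercept covariance ($c \times c$)
estimable from moderate samples; it is configurable via `n_interior`.

The random intercept can optionally use its own, smaller basis
(`n_interior_cov`): its covariance has $c(c+1)/2$ free parameters, so a
reduced basis (e.g. $c = 6$, 21 parameters, the benchmark default) keeps the
plug-in GLS weights stable in moderate samples, at the price of a smoother
subject-deviation space. The fitting default shares the coefficient basis.

Smoothness is enforced by a second-order difference penalty $\lambda_p D'D$
on each coefficient block (the Eilers–Marx P-spline device). The null space
of $D'D$ consists of coefficient sequences linear in the index; under
infinite smoothing each $f_p$ collapses to an (interior-)affine function.
Note a boundary subtlety: with repeated boundary knots, "linear in the
coefficient index" corresponds to an exactly affine function of $t$ only away
from the boundary knots, where the Greville abscissae are uniform. The test
suite asserts exactly this: vanishing second coefficient differences, and
affineness on the interior knot region.

## Penalized generalized least squares

Writing $X_i = [B_i, \mathrm{diag}(z_{1,i}) B_i, \dots]$ and
$V_i = B_i \Gamma B_i' + \sigma^2_\epsilon I_{m_i}$ (where $\Gamma$ is the
coefficient covariance of $b_i$, so $C(s,t) = B(s)'\Gamma B(t)$), the stacked
coefficient vector is estimated by

$$\hat\theta = \Big(N^{-1}\textstyle\sum_i X_i' V_i^{-1} X_i + P\Big)^{-1}
N^{-1}\textstyle\sum_i X_i' V_i^{-1} y_i, \qquad
P = \mathrm{blockdiag}(\lambda_p D'D),$$

with the sandwich covariance
$\mathrm{Cov}(\hat\theta) = M^{-1} (A/N) M^{-1}$, $A = N^{-1}\sum_i X_i'
V_i^{-1} X_i$, $M = A + P$. Both this sandwich form and the model-based
(Bayesian) covariance $M^{-1}/N$ are computed and stored. Pointwise 95%
confidence bands for $\hat f_p(t) = B(t)'\hat\theta_p$ use the normal
multiplier 1.96 and, by default, the Bayesian covariance: under a difference
penalty the sandwich form ignores penalty-induced bias and its bands shrink
to zero under heavy smoothing, while the Bayesian form includes the
squared-bias term and delivers near-nominal across-the-function coverage —
the standard choice for penalized-spline inference and the behavior of the
REML-based smoothing software this class of models is usually fit with.
`interval = "sandwich"` selects the frequentist form. Even so, bands for a
between-subject covariate can undercover in smaller samples because the
plug-in $\hat\Gamma$ (55 free parameters at $c = 10$) adds sampling noise to
the GLS weights that the formulas do not see; the effect fades as $N$ grows
(the suite documents it at $N = 100$ versus $N = 200$). The
covariance of the plug-in $\tilde Z$ is *not* propagated — a known
limitation shared with the plug-in convention of the estimation procedure;
in simulations this shows up as below-nominal coverage for the time-varying
coefficient while the intercept and time-invariant coefficients remain near
nominal.

Variance components follow a 4-step procedure: (1) penalized GLS under
working independence ($V_i = I$); (2) sparse-FPCA covariance smoothing of the
residuals to get $(\hat\Gamma, \hat\sigma^2_\epsilon)$; (3) penalized GLS
under the estimated $V_i$; (4) re-estimation of the variance components from
the updated residuals. `cycles` controls how many (3)–(4) passes are run;
one pass is the default, and the suite checks that a second pass changes the
estimates by well under 1% of the coefficient scale.

## Smoothing-parameter selection

Each $\lambda_p$ is selected by REML in the equivalent variance-components
formulation after pre-whitening by $V_i^{-1/2}$ (GCV is available via
`selector = "gcv"`). The criterion
$$ (n - M_0)\,\log(\mathrm{RSS}_{pen}) + \log\lvert S + S_\lambda\rvert -
\log\lvert S_\lambda\rvert_+ $$
(with $S$ the whitened information, $S_\lambda = N\,P$, $M_0$ the total
penalty null-space dimension) is minimized by cyclic coordinate descent: a
log$_{10}$ grid search on $\lambda \in 10^{-6..8}$ per block, refined by
golden-section search, for two sweeps. The search range covers everything
from effective interpolation to the affine limit; the criterion is evaluated
from pre-accumulated sufficient statistics, so each evaluation is a single
$O(((P{+}1)c)^3)$ Cholesky factorization.

## Sparse FPCA: covariance smoothing and the error variance

The covariance surface is expanded as $C(s,t) = \sum_{k\ell} \gamma_{k\ell}
B_k(s) B_\ell(t)$ and $\Gamma = (\gamma_{k\ell})$ is estimated by regressing
the off-diagonal residual cross-products $r_{ij} r_{ik}$ ($j \neq k$) on the
symmetrized tensor-product basis, with penalty $\lambda (D'D \otimes I + I
\otimes D'D)$ on a symmetric (half-vectorized) parameterization and GCV
selection of $\lambda$. The estimate is then projected to positive
semidefiniteness in the $L^2$ geometry of the basis: with Gram matrix
$G = U'U$, negative eigenvalues of $U \Gamma U'$ are set to zero.
Eigenvalues/eigenfunctions of the covariance operator come from the same
decomposition, with eigenfunctions orthonormal in $L^2$; the truncation keeps
the smallest number of components reaching a 0.9999 cumulative share.

The white-noise error variance is estimated by a **local variogram (nugget)
regression**: for within-subject pairs with time gap $d$ below 10% of the
domain, $\tfrac12 E\{(r_{ij} - r_{ik})^2\} = \sigma^2_\epsilon + \gamma(d)$
with $\gamma$ smooth and $\gamma(0) = 0$, so the intercept of a quadratic
(or, with too few distinct gaps, linear) fit in $d$ estimates
$\sigma^2_\epsilon$, clamped at zero. We chose this over the more common
"smoothed raw diagonal minus fitted surface diagonal" gap because the latter
compares two independently smoothed estimates of a large common quantity to
extract a small difference: pointwise clamping biases it upward, the PSD
projection inflates the fitted diagonal by roughly the size of the nugget
itself, and the noise floor of the difference is far above a small
$\sigma^2_\epsilon$. In the package's recovery benchmark (two-eigenfunction
truth, curve variance roughly eighty times the nugget) the variogram
intercept achieves a few percent relative error where surface-gap variants
and even likelihood refinements given the smoothed surface sit at 25–75%.

## Dynamic prediction

For a new subject with history $\{t_j, Y_j, Z_{j,\mathrm{obs}}\}$ up to a
cutoff, the BLUP of the random-intercept coefficients is
$$\tilde u = \Gamma B_*'(B_* \Gamma B_*' + \sigma^2_\epsilon I_m)^{-1}
(y - X\theta),$$
and the predicted trajectory is $\tilde Y(t) = X(t)\theta + B(t)'\tilde u$
with pointwise variance
$$B(t)'\{\Gamma - \Gamma B_*'(B_* \Gamma B_*' + \sigma^2_\epsilon
I_m)^{-1} B_* \Gamma\} B(t) + \sigma^2_\epsilon$$
and $\pm 2\,\mathrm{sd}$ prediction limits (the multiplier 2 is used for
prediction intervals, as distinct from the 1.96 used for coefficient
confidence bands — the two conventions are kept deliberately). Future values
of time-varying covariates are replaced by the covariate-process BLUP
conditioned on the subject's covariate history up to the cutoff; this is a
design choice (the natural alternative, the population mean, discards
subject information), and `future_covariates` lets the user supply a known
future path instead. Estimation uncertainty in $\hat\theta$ and
$\hat\Gamma$ is not propagated (plug-in prediction).

Prediction is refused beyond $T_{\max}$, the latest observed outcome time in
the training data: beyond all observed data there is no information about
trajectory shape. Benchmark windows are clipped to $T_{\max}$ for the same
reason.

Numerical safeguards: every $m \times m$ conditioning matrix is factored by
Cholesky with escalating jitter ($10^{-8} \times \mathrm{trace}/m$ and up) on
failure; a near-zero pivot (ratio below $10^{-6}$) with zero error variance
raises an error suggesting jitter rather than returning garbage.

## Competitor models

* `fit_am` — the same penalized mean structure with independent errors
  ($\Gamma = 0$); its residual variance uses an effective-degrees-of-freedom
  correction. Its confidence bands ignore within-subject correlation and are
  expected to undercover badly on correlated data.
* `fit_amm` — random intercept + slope: $V_i = Z_i \Psi Z_i' +
  \sigma^2_\epsilon I$ with $Z_i = [1, t_i]$ and unstructured $2 \times 2$
  $\Psi$, estimated by direct REML (Nelder–Mead on a log-Cholesky
  parameterization, started from method-of-moments values from residual
  cross-products). This keeps the module self-contained rather than
  delegating to a general mixed-model backend; the test suite cross-checks
  it against `lme4` on a correctly specified instance.
* `fit_fri` — the covariate-free functional random intercept model; it is
  literally `fit_fcr` with an empty covariate list.

All three share the dynamic-prediction machinery (the AMM via $[1, t]$ in
place of $B(t)$).

## The synthetic-data generator

`sim_scenario()`/`generate_dataset()` emulate sparse growth-cohort z-score
data: $N$ subjects with discrete-uniform visit counts (e.g. 15–25 or 25–35),
visit times drawn without replacement from a 500-point equispaced grid on
the unit interval (rescaled to 0–24 months in reports), sex from
Bernoulli(0.5), a latent covariate process from a truncated eigenfunction
expansion observed with white noise (sd 0.16), and outcomes from the
concurrent model with residual sd 0.18 (or 0.37).

The surrogate truth is calibrated to the magnitudes of the motivating
application: intercept function $f_0(t) = -1 + 0.5\cos(2\pi t)$ (negative
everywhere, order-one scale), sex effect $f_1 \equiv 0$ (z-scores already
standardize for sex), covariate effect $f_2(t) = 0.25 + 0.15\cos(2\pi t)$
(positive, strongest at the domain ends); outcome eigenvalues $(0.30, 0.10,
0.03)$ summing to $0.43$, so that with $\sigma_\epsilon = 0.18$ the random
functions account for about 93% of residual variation; eigenfunctions are a
Gram–Schmidt orthonormalization of $\{\sin \pi t, 1, 2t - 1\}$, putting the
variance peak mid-domain. The covariate process uses mean $\mu_w(t) = 0.6 -
0.4t$, shifted-Legendre eigenfunctions with eigenvalues $(0.80, 0.25,
0.05)$, and noise sd 0.16: population variance near 1 (a z-score scale),
12-month-lag within-subject autocorrelation around 0.55, and concurrent
outcome–covariate correlation around 0.3–0.4. These covariate-process values
were fixed once on realism grounds and are not tuned to benchmark outcomes.

What the generator does *not* emulate: covariate-dependent or nonstationary
noise, dropout or informative visit timing, more than three eigenfunctions,
and cross-covariance between the outcome deviation and the covariate process
beyond what the concurrent term induces. Passing benchmarks here therefore
demonstrates correctness of the machinery under a smooth low-rank truth, not
performance on any particular real cohort.

One consequence deserves emphasis. With a rank-3, very smooth random
function, a subject's deviation curve is largely pinned down by a handful of
observations, so absolute prediction errors are small — and the *relative*
advantage of FCR over the covariate-free FRI model (which comes from the
covariate history predicting the covariate's future path) is
correspondingly amplified, to 25–50% in late cells even for an oracle that
knows the true covariances. Empirically estimated growth-curve covariances
have slower eigenvalue decay and larger irreducible prediction error, which
dilutes that same absolute gain to under 10%. The FCR-vs-FRI relative gap is
therefore a quantity whose magnitude is specific to the generating truth;
the FCR-vs-AMM comparison and the coverage behavior are robust to it.

## Benchmark metrics and problem sizes

`run_experiment()` reports, per model: median and IQR of $100 \times$ ISE
for each coefficient function (trapezoidal quadrature on a 500-point grid);
average pointwise coverage of the 95% bands at the same 500 points; and
median and IQR of $10 \times$ MISE for dynamic prediction over the six
(cutoff ∈ {6, 12, 18} months) × (window ∈ {8–12, 14–18, 20–24} months) cells
with the window after the cutoff, evaluated on 50 held-out subjects per
replicate, squared error integrated on the month scale. All randomness
descends from one master seed; identical seeds give bit-identical reports.

The package's own test suite runs the recovery benchmark at $N = 200$ with
20 replicates, the coverage comparison at $N = 100$ with 100 replicates, and
the prediction comparison at $N = 100$ with 100 replicates; the acceptance
script uses 120 and 100 replicates for the same two scenarios. These sizes
give stable medians while keeping a full run in the minutes range; the
original full-scale design (500 replicates) is available by raising
`n_reps`.

## Known limitations

* Plug-in covariate denoising: $\tilde Z$ uncertainty is ignored in both
  coefficient bands (below-nominal coverage for $f_2$) and predictions.
* Pointwise, not simultaneous, bands.
* Gaussian outcomes only; no historical-effect kernels
  ($\int \beta(s,t) Z(s)\,ds$ terms are out of scope by design).
* The default random-intercept basis equals the mean basis; with moderate
  samples the covariance plug-in noise then widens the realized spread of
  between-subject contrasts beyond the reported bands (use
  `n_interior_cov` to reduce it, as the benchmark does).
* REML/GCV selection is per-block coordinate descent; a joint optimization
  could in principle find better minima in pathological cases.
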