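---
title: "Selecting biomarkers by simultaneous one-sided AUC inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting biomarkers by simultaneous one-sided AUC inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucselect)
```

## The problem

Early diagnostic trials — biomarker panels, imaging modalities — often
measure several candidate tests on the *same* subjects, together with a
binary gold standard (case / control). The task is not to compare the tests
with each other but to decide, for each test individually, whether its
diagnostic accuracy clears a pre-specified bar. Because measurements may be
continuous, discrete, or ordered categorical and no cut-off has been chosen
yet, the natural accuracy measure is the area under the ROC curve,

$$\mathrm{AUC}^{(\ell)} \;=\; P\!\left(X_0^{(\ell)} < X_1^{(\ell)}\right)
  + \tfrac12\, P\!\left(X_0^{(\ell)} = X_1^{(\ell)}\right),$$

the probability that a random case measures higher than a random control,
with ties counted half. It is invariant under monotone transformations of
each marker's scale, so markers on entirely different scales are comparable.
Marker $\ell$ is *selected* when the one-sided null hypothesis
$H_0^{(\ell)}: \mathrm{AUC}^{(\ell)} \le \mathrm{AUC}_0$ is rejected, and
the familywise error rate over all $d$ markers must be controlled at a
one-sided level $\alpha$ (default $0.025$, the conventional non-inferiority
level corresponding to one-sided 97.5% confidence intervals).

## Estimation: midranks and placements

All estimators are rank-based and fully nonparametric. Per marker, the
pooled midranks $R_{is}$ over all $N = n_0 + n_1$ subjects and the internal
midranks $R^{(i)}_{is}$ within each status group yield the *placements*

$$Z_{is} \;=\; \frac{R_{is} - R^{(i)}_{is}}{N - n_i},$$

i.e. the empirical distribution function of the *opposite* group evaluated
at the observation (midranks implement the tie convention exactly). The mean
of the case placements is the AUC estimate; the groupwise sample covariance
matrices of the placement vectors combine into the covariance estimate of
the AUC vector,

$$\widehat V = N\left(\widehat V_0 / n_0 + \widehat V_1 / n_1\right),$$

which for a single continuous marker reduces to the classical
components-of-variance (DeLong-type) estimator — the test suite verifies
this identity against an independent implementation. Computation is
$O(N \log N)$ per marker via the rank-difference identity; no pairwise scan
is ever performed.

## Testing: multiple contrast tests and transformations

Studentized statistics $T^{(\ell)} = (\widehat{\mathrm{AUC}}^{(\ell)} -
\mathrm{AUC}_0)\sqrt{N / \widehat v^{(\ell,\ell)}}$ are asymptotically
jointly multivariate normal with correlation matrix $R$ (estimated by
$\widehat R$ from $\widehat V$). The single-step multiple contrast test
rejects $H_0^{(\ell)}$ when $T^{(\ell)}$ reaches the one-sided
*equicoordinate* quantile $z_{1-\alpha}(\widehat R)$ — the scalar $z$ with
$P(\text{all components} \le z) = 1 - \alpha$ under $N(0, \widehat R)$ —
which exploits the correlation between markers instead of paying the full
Bonferroni price. Compatible one-sided simultaneous confidence intervals
subtract $z_{1-\alpha}(\widehat R)\sqrt{\widehat v^{(\ell,\ell)}/N}$ from
the estimate; selection by interval and by test coincide by construction,
and an invariant test asserts this for every method.

The logit transformation $g(p) = \log\{p/(1-p)\}$ with the delta-method
variance $\widehat s^{(\ell,\ell)} = \widehat v^{(\ell,\ell)} /
\{\widehat{\mathrm{AUC}}^{(\ell)}(1 - \widehat{\mathrm{AUC}}^{(\ell)})\}^2$
improves the normal approximation in small samples and keeps bounds inside
$(0,1)$; back-transforming with $\operatorname{expit}$ gives the `"logit"`
method. Four asymptotic methods are available — `unadjusted`, `bonferroni`,
`mcp` (raw scale), `logit` — whose lower bounds always order as
unadjusted $\ge$ MCP $\ge$ Bonferroni.

### Numerical choices

The equicoordinate quantile is found by bracketing root search between the
closed-form bounds $z_{1-\alpha}$ (comonotone limit) and $z_{1-\alpha/d}$
(independence/Bonferroni limit). Rectangle probabilities come from the
quasi-Monte-Carlo routine in **mvtnorm**, always run under a fixed internal
seed so quantiles are bit-reproducible and the caller's RNG stream is never
disturbed; the default absolute tolerance on the coverage probability is
$10^{-6}$. Perfectly correlated duplicate markers are collapsed before
integration (the singular comonotone limit is handled by reduction), while
non-symmetric or non-positive-semidefinite inputs are an error — no silent
"nearest correlation" repair is applied. Inside the Monte-Carlo engine the
tolerance is relaxed to $10^{-5}$ with at most 2000 integration points per
probability: a quantile error of order $10^{-4}$ moves rejection
probabilities by $\approx \varphi(z)\cdot 10^{-4}$, orders of magnitude
below Monte-Carlo noise, at a tenth of the cost.

### Degenerate markers

A marker estimated at AUC $= 1$ (or $0$) has constant placements: zero
estimated variance, infinite logit. The default policy is an explicit error
naming the marker. Opting in to `boundary_fix = TRUE` applies the minimal
conservative repair: the largest control measurement is replaced by the
smallest case measurement (mirrored at AUC $= 0$), which strictly decreases
the estimated effect and increases its variance. The fitted object records
which markers were repaired.

## Small samples: the Wild Bootstrap

For $N \lesssim 100$ and accuracies $\ge 0.8$ the asymptotic methods drift:
the raw-scale MCP becomes markedly liberal, the logit method conservative.
The Wild Bootstrap approximates the joint null law of the max statistic
directly: i.i.d. weights $W_{is}$ with mean 0 and variance 1 multiply the
centered placements, $Z^{*}_{is} = W_{is}(Z_{is} - \bar Z_{i\cdot})$, and
each draw yields studentized statistics

$$T^{*(\ell)} = \frac{\bar Z^{*(\ell)}_{1\cdot} - \bar Z^{*(\ell)}_{0\cdot}}
 {\sqrt{\widehat v^{*(\ell,\ell)}_0 / n_0 + \widehat v^{*(\ell,\ell)}_1 / n_1}},$$

whose conditional joint distribution mimics that of the observed statistics
under the null *and* the alternative. The max over markers is recorded per
draw; the logit-scale statistics $\widetilde T^{(\ell)}$ are compared with
the empirical $(1-\alpha)$ quantile $z^*$ of the `nboot` max draws (the
$\lceil (1-\alpha)\,\mathrm{nboot} \rceil$-th order statistic, so the test
never rejects more often than the interval implies at finite `nboot`).
Per-marker p-values are one minus the retention proportion
$\tfrac1{nboot}\sum_j \mathbf 1\{\widetilde T^{(\ell)} \ge A^*_j\}$, with
ties counting as retention, so small p means strong evidence and
"$p \le \alpha$" is identical to the quantile decision. Confidence bounds
back-transform $g(\widehat{\mathrm{AUC}}^{(\ell)}) - z^* \sqrt{\widehat
s^{(\ell,\ell)}/N}$ through $\operatorname{expit}$.

Weight schemes: Rademacher signs, standard normal (the default and the
recommended choice), and uniform on $[-\sqrt{12}/2, \sqrt{12}/2]$. A single
RNG stream per analysis is seeded from the `seed` argument; within each
draw, weights are assigned in subject order (controls first, then cases),
which makes results bit-reproducible and equivariant to marker reordering.
Draws in which some marker's bootstrap variance vanishes are rejected and
redrawn (with a hard cap); with continuous weights this is a
measure-zero event.

The bootstrap denominator pairs each group's variance with its own sample
size ($\widehat v^*_0/n_0 + \widehat v^*_1/n_1$): this is the only pairing
under which the statistic is conditionally standardized (unit conditional
variance) and consistent with how $\widehat V$ combines the groupwise
covariances. The alternative cross-pairing
($\widehat v^*_1/n_0 + \widehat v^*_0/n_1$) is exposed as
`wb_denominator = "crossed"` for comparison; with balanced groups the two
coincide.

A conventional casewise (Efron-type) bootstrap — groupwise resampling with
replacement, studentized logit max statistic centered at the original
estimates, degenerate resamples redrawn — is included as
`method = "efron"` purely as a comparison procedure. Its resampling
distribution does not track the statistic's null law at high accuracies and
it is demonstrably liberal there (the test suite checks this direction);
it is not recommended for selection.

## The Monte-Carlo engine

`sim_scenario()` + `run_study()` drive the package's simulation study of
familywise error and power. The *standard scenario* is multivariate normal
data,
compound-symmetric correlation $\rho = 0.9$, $d = 5$ markers, $N = 100$
subjects at a 1:1 case-control ratio, $\alpha = 0.025$; grids vary the true
AUC (0.5–0.9), $d$ (5, 10, 20), $N$ (50–200), the ratio (1:1 to 1:9),
$\rho$ (0.3–0.9), the covariance structure, and the distribution family.
Under the least favorable null all true AUCs sit exactly at the threshold;
the empirical rejection rate of the global hypothesis is then the
familywise type-I error, otherwise the global power.

Generation details:

* **Normal family.** Controls are centered $d$-variate normal with the
  scenario covariance; cases are shifted marker-wise by
  $\delta^{(\ell)} = \Phi^{-1}(\mathrm{AUC}^{(\ell)})
  \sqrt{\sigma_0^2 + \sigma_1^2}$ — the exact binormal identity, so the
  calibration is closed-form.
* **Log-normal.** The elementwise exponential of the normal draws. Ranks are
  unchanged, so this isolates the effect of skewness on nothing but the
  normality of the *statistics* — a pure robustness check.
* **Ordinal (5-point scale).** Both groups are cut at the shared thresholds
  $\{-1.5, -0.5, 0.5, 1.5\}$ on the control scale; the latent case shift is
  found by monotone root search so that the *discretised* AUC (ties counted
  half) equals the target to $10^{-6}$. Targets outside the attainable
  post-discretisation range are a calibration error.
* **Covariance structures.** Compound symmetry; a fixed seeded
  "unstructured" correlation (orthogonal rotation of spread eigenvalues
  `seq(0.2, 2, length.out = d)`, shipped as a reproducible constant);
  heterogeneous diagonal
  variances `seq(1, 2, length.out = d)` with a $\times 2$ group scale,
  positive pairing giving the larger scale to the larger group and negative
  pairing the reverse. The heterogeneity magnitudes are this package's own
  documented defaults.
* **Case-control ratio 1:k.** $n_1 = \mathrm{round}(N/(k+1))$ cases (the
  smaller group, as in the motivating trial's 26 vs 41), $n_0 = N - n_1$.
* **Seeding.** Replication $r$ of a scenario with master seed $s$ uses the
  child seed $(1000003\,s + 7919\,r) \bmod (2^{31}-1)$: replications are
  independent of `nsim`, reproducible individually, and trivially
  parallelizable.
* **Degenerate replications** (a marker at AUC 0 or 1, increasingly likely
  at AUC 0.9 with small groups) are repaired by the conservative boundary
  fix before testing, mirroring the recommended analysis path.

All methods requested for a scenario are evaluated on the *same* simulated
datasets (common random numbers), which makes method contrasts sharper at
no extra generation cost.

### What the generator does and does not emulate

The generator reproduces the *structure* the study varied: marginal
location shifts calibrated to a target AUC, equi- or heterogeneous
covariance, skewness via a monotone transform, heavy ties via
discretisation, and group imbalance. It does not emulate features of real
biomarker panels such as measurement error correlated with disease
severity, batch effects, non-monotone marker–disease relationships, or
missing measurements. Passing the simulation suite therefore demonstrates
correct error control under the stated sampling models, not robustness to
those further complications; the rank basis does, however, make every
result invariant to each marker's measurement scale.

### Problem sizes used in the shipped checks

The package's shipped simulation checks run 1000–4000 simulation runs per
cell with 500–2000 bootstrap draws, sizes chosen so the whole suite
completes in minutes on a single core while keeping the binomial
Monte-Carlo standard error of a 2.5% rate near or below 0.5 percentage
points; assertions use three standard errors plus a 0.3 point allowance for
the reduced bootstrap size. The synthetic example fixture mirrors the
motivating intestinal-current-measurement trial's shape (67 subjects,
26 cases / 41 controls, four strongly correlated markers, one separating
perfectly) but is generated from seeded normals — it is a synthetic
stand-in, not the unpublished original data.

## Worked example

```{r}
fix <- make_icm_like_fixture(seed = 20150501)
auc_estimate(fix, status, control = "control", case = "case")
```

Marker 4 separates perfectly; the Wild Bootstrap analysis with the
boundary fix:

```{r}
fit <- auc_select(fix, status,
  control = "control", case = "case",
  auc0 = 0.8, method = "wb", weights = "normal",
  nboot = 10000, seed = 1, boundary_fix = TRUE
)
tidy(fit)
glance(fit)
```

```{r, fig.width = 6, fig.height = 3}
autoplot(fit)
```

A marker is selected exactly when its simultaneous lower bound clears the
dashed threshold. `write_report()` renders the same table as a diffable
TSV, and the command-line wrappers under `inst/cli/` expose the analysis
and the simulation engine to shell pipelines.

## Known limitations

* Single-step procedures only: no step-down refinement, by design, so that
  intervals and tests stay compatible.
* Two-group gold standard only; no clustered or weighted sampling; no
  missing data.
* The raw-scale MCP should not be used at high accuracies (it is liberal
  there — the simulation engine reproduces this); the Wild Bootstrap with
  normal weights is the recommended default.
* At case-control imbalance beyond about 1:4 combined with AUC near 0.9,
  even the Wild Bootstrap becomes liberal; rates there should be read with
  care.
* p-values are single-step adjusted against the max-null; they are
  compatible with the selection decisions but are not closed-testing
  p-values.
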