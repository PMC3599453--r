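---
title: "Normal-gamma background correction: model, estimation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal-gamma background correction: model, estimation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammabg)
```

## The model

Single-channel microarray platforms such as Illumina BeadArrays report, for
every probe, an observed fluorescence intensity that mixes true
hybridization signal with background noise. The additive decomposition

$$X_j = S_j + B_j, \qquad S_j \perp B_j$$

treats the signal $S_j$ of a regular probe as a draw from a signal
distribution and the noise $B_j$ as $N(\mu, \sigma^2)$. The platform's
negative control probes target no transcript, so for them $S_j = 0$ and
their observed intensities are a pure noise sample — this is what makes
per-array noise estimation possible without replicates.

The established normexp model takes $S_j \sim \mathrm{Exp}(\alpha)$.
`gammabg` implements the more flexible **normal-gamma** model,

$$S_j \sim \Gamma(k, \theta) \quad (\text{shape } k,\ \text{scale } \theta),$$

which contains normexp as the special case $k = 1$, $\theta = \alpha$. The
extra shape parameter lets the fitted intensity distribution track the
sharp peak and heavy right tail seen on real arrays, which a single
exponential rate cannot do. The marginal density of an observed intensity
is the gamma–normal convolution

$$f^{\mathrm{ng}}_{\mu,\sigma,k,\theta}(x)
  = \int f^{\mathrm{gam}}_{k,\theta}(t)\, f^{\mathrm{norm}}_{\mu,\sigma}(x-t)\,dt,$$

which has no closed form; everything downstream rests on computing it
accurately.

## Computing the convolution density

`dnormgamma_grid()` evaluates $f^{\mathrm{ng}}$ on an equispaced grid by
discrete convolution via FFT with zero-padding to twice the grid length, so
no circular wrap-around can alias mass from one tail into the other.

Numerical choices that matter:

* **Grid.** Default length $2^{16}$; origin $\mu - 8\sigma$; upper end
  $\max(\mu + 8\sigma,\ \mu + Q_{\mathrm{gam}}(1 - 10^{-8}; k, \theta))$,
  covering essentially all mass of both factors. A grid that holds less
  than $1 - 10^{-6}$ of the mass raises an error rather than returning a
  silently truncated density.
* **Cell masses, not ordinates.** The gamma factor enters through exact
  per-cell probability masses (`pgamma` increments). For $k < 1$ the gamma
  density is infinite at 0; the first cell's mass is finite and exact, so
  the singularity never touches the numerics.
* **Moment corrections.** Each cell additionally carries its exact first
  and second partial moments about the cell centre (closed forms via
  `pgamma` at shapes $k+1$ and $k+2$), paired with the normal kernel's
  first two derivatives. This second-order scheme brings the node-level
  error below $10^{-7}$ relative against adaptive quadrature across
  $\mu \in \{0, 100\}$, $\sigma \in \{5, 50\}$, $k \in \{0.3, 1, 3\}$,
  $\theta \in \{50, 500\}$ — the accuracy the test suite asserts.
* **Floor.** Density values are clipped below at $10^{-300}$ so
  log-likelihoods stay finite during optimization.
* **Off-grid evaluation.** `interp_density()` interpolates linearly
  (positivity-preserving; a spline could undershoot zero between nodes).
  Left of the grid the normal factor dominates and $f \approx
  f^{\mathrm{norm}}_{\mu,\sigma}$; right of it the gamma factor dominates
  and $f \approx f^{\mathrm{gam}}_{k,\theta}(x - \mu)$.

The normexp density (`dnormexp()`) has a closed form involving
$\exp(\sigma^2/2\alpha^2 - (x-\mu)/\alpha)\,\Phi(\bar x)$. Evaluated
naively this overflows and cancels catastrophically once
$\sigma^2/\alpha^2$ is large; for $\bar x < -30$ the implementation
rewrites the exponent through the normal log-density plus a log Mills-ratio
term, which is algebraically identical and stable for arbitrary parameters
— this matters because a likelihood optimizer will visit such regions.

## Estimation

`fit_normgamma()` maximizes the joint likelihood of one array,

$$L(\mu,\sigma,k,\theta) =
  \prod_{j \in J} f^{\mathrm{ng}}(X_j) \prod_{j \in J_0} f^{\mathrm{norm}}_{\mu,\sigma}(X_j),$$

over $(\mu, \log\sigma, \log k, \log\theta)$ with Nelder–Mead. The log
reparametrization keeps the positive parameters unconstrained; a
derivative-free method is used because the FFT-interpolated likelihood has
slightly noisy numerical gradients. Details:

* **Initializer.** $\mu_0, \sigma_0$ from the robust normal fit of the
  negatives (median and $1.4826 \times$ MAD); then method of moments on the
  convolution: $m_1 = \bar X - \mu_0$, $v = \widehat{\mathrm{Var}}(X) -
  \sigma_0^2$, $\theta_0 = v / m_1$, $k_0 = m_1^2 / v$, falling back to
  $k_0 = 1$, $\theta_0 = m_1$ when $v \le 0$. Closed-form and consistent,
  so the search starts near the optimum.
* **Two stages plus a restart.** A coarse $2^{12}$-point grid with loose
  tolerance approaches the optimum cheaply; the default $2^{14}$ fitting
  grid with objective tolerance $10^{-8}$ finishes; one fresh-simplex
  restart guards against the premature collapse Nelder–Mead is prone to in
  four dimensions. One density grid is rebuilt at every objective
  evaluation (the parameters move), but the grid specification is fixed
  within a stage so the objective stays smooth. The reported log-likelihood
  is recomputed on a $2^{16}$ grid.
* **Robustness.** Parameter proposals outside $e^{\pm 25}$ on the log
  scale, or whose grid construction fails, score $-10^{300}$ instead of
  erroring; non-convergence is reported in the `bg_fit` object, never as an
  exception.

The normexp baselines (`fit_normexp()`) mirror the published estimator
family: `mle` (same joint likelihood with the closed-form density), `np`
(negative-probe moments plus mean excess of regulars), and `rma` (mode of a
kernel density estimate of the regulars, half-normal reflection below the
mode for $\sigma$, mean excess above it for $\alpha$ — the single-channel
adaptation of the classic convention; it uses no negatives and is known to
be biased, which the package reproduces rather than repairs).

A note on tolerances: with $n \approx 26{,}000$ probes, an objective
tolerance of $10^{-8}$ on a log-likelihood of magnitude $2 \times 10^5$
pins parameters only to $\sim 3 \times 10^{-4}$ relative. The model-nesting
test (normexp MLE versus the $k = 1$-constrained normal-gamma fit)
therefore runs both fits at `reltol = 1e-12`, where they agree to
$10^{-5}$.

## Background correction

The corrected intensity is the conditional expectation
$\hat S(x) = E[S \mid X = x]$ — strictly positive for all finite $x$, which
is the point of model-based correction over subtraction. For the
normal-gamma model the shape-shift identity
$s\,f^{\mathrm{gam}}_{k,\theta}(s) = k\theta\,f^{\mathrm{gam}}_{k+1,\theta}(s)$
gives

$$\hat S^{\mathrm{ng}}(x) = k\theta\,
  \frac{f^{\mathrm{ng}}_{\mu,\sigma,k+1,\theta}(x)}{f^{\mathrm{ng}}_{\mu,\sigma,k,\theta}(x)},$$

computed from two densities on one shared grid (sized for shape $k + 1$) so
interpolation errors largely cancel in the ratio. Two regimes need care:

* **Far right tail.** The FFT carries an absolute roundoff floor around
  $10^{-14}$; where the density itself is that small the ratio is noise.
  Beyond the point where the denominator falls to $10^{-6}$ of its peak —
  far outside any observable intensity — the correction switches to the
  Laplace (normally tilted gamma) limit
  $\hat S \approx x - \mu + \sigma^2\!\left(\frac{k-1}{x-\mu} -
  \frac{1}{\theta}\right)$, with a one-$\sigma$ linear blend so the
  composite stays monotone. At $k = 1$ this limit is the exact normexp
  asymptote.
* **Far left tail.** Below the grid the posterior is an exponentially
  tilted gamma and $\hat S \approx k\theta / (1 + \theta(\mu - x)/\sigma^2)$,
  decreasing smoothly to 0 as $x \to -\infty$.

The normexp correction $\hat S^{\mathrm{nexp}}(x) = \sigma(\bar x +
\phi(\bar x)/\Phi(\bar x))$ uses log-space $\phi/\Phi$ (stable to
$\bar x \approx -37$) and the asymptotic series $1/t - 2/t^3 + 10/t^5$,
$t = -\bar x$, beyond; for $\bar x > 10^8$ the exact limit
$x - \mu - \sigma^2/\alpha$ avoids overflow. Both corrections match direct
quadrature of the conditional expectation to $10^{-6}$ ($10^{-8}$ for
normexp) at bulk intensities, which the acceptance tests verify.

Detection p-value utilities round out the module: `detection_pvalues()` is
the counting definition (fraction of negatives strictly above a probe), and
`infer_negatives()` inverts it when a public data set ships p-values but no
negative intensities. The r-th negative order statistic is read off by
piecewise-linear interpolation of sorted intensity against p at level
$(n_{\mathrm{neg}} - r)/n_{\mathrm{neg}}$, each p plateau represented by
its smallest intensity, with clamping to the regular range. The
reconstruction is validated by a round trip: parameters fitted from
inferred negatives agree with the true-negative fit to $10^{-2}$ relative
on a full-scale synthetic array. `quantile_normalize()` (mean of order
statistics, ties sharing their block mean — delegated to
`limma::normalizeQuantiles`) and `offset_log()` support the operating
characteristics analyses; negatives are pooled with regulars into one rank
pool, the common convention.

## The simulator

`simulate_arrays()` generates the study designs the evaluation machinery
consumes. Defaults are one array's worth of $n_{\mathrm{reg}} = 25{,}000$
regular and $n_{\mathrm{neg}} = 1{,}000$ negative probes, $N = 100$ arrays.
Because the original calibration sets are not published, the package ships
two named presets with Illumina-plausible values, documented as stand-ins:
preset A, a non-degenerate normal-gamma set
($\mu = 900, \sigma = 140, k = 0.64, \theta = 500$ — weak-signal-heavy,
signal mean 320) and preset B, its normexp counterpart
($\mu = 900, \sigma = 140, \alpha = 320$). The headline excess-risk ratios
are parameter-robust (the matched-model ratio is 1.00 across every
published set), so the choice of stand-in does not drive the acceptance
results.

Design knobs:

* **Replicate mode** draws one signal vector under the master seed and
  shares it bitwise across arrays, with fresh noise per array — technical
  replicates of one sample, the setting in which per-probe absolute
  deviation and operating characteristics are defined.
* **Mixture noise** replaces the normal by a normal/$\chi^2_4$ mixture:
  with probability $p$ a draw is $\mu + \sigma (C - 4)/\sqrt{8}$,
  $C \sim \chi^2_4$. The affine adjustment pins the first two moments for
  every $p$, so $p$ moves only tail weight (skewness $\sqrt{8/4} \approx
  1.41$ at $p = 1$) — a controlled departure from noise normality.
* **Empirical noise** resamples a supplied vector with replacement, e.g.
  pooled quantile-normalized negatives from a real experiment.
* **Seeds.** Array $\ell$ uses stream `seed + l`, so enlarging a design
  never reshuffles earlier arrays and every result is reproducible from the
  design object alone.

What the simulator does *not* emulate: bead-level replicates and their
robust summarization, spatial artifacts, probe-sequence effects, scanner
saturation (the reason real dilution data bend at high concentration), and
cross-probe dependence from co-regulation. Tests passing on these synthetic
arrays therefore certify the estimator and correction machinery under the
model's own assumptions — they do not certify the model against real
arrays, which is exactly the question the irregular-histogram L1 diagnostic
is for.

## Evaluation machinery

* **Irregular histogram** (`irregular_histogram()`): penalized-likelihood
  histogram with unequal bins; candidates at $2^7$ data quantiles, dynamic
  program over partitions, penalty $(D - 1) + \log\binom{n-1}{D-1}$. The DP
  provably equals exhaustive partition search (tested up to 12 candidate
  edges). Its purpose is the $\ell_1$ distance (`l1_fit()`) between a
  plug-in parametric density and the data — the lack-of-fit statistic that
  motivates the gamma signal model in the first place. Because the
  penalized-MLE histogram targets Kullback–Leibler rather than $L_1$ risk,
  its $L_1$ distance to a smooth truth at $n = 10^5$ plateaus near 0.06;
  the tests assert that measured level.
* **MAD and excess-risk ratios** (`mad_ratios()`):
  $\mathrm{MAD} = \frac{1}{N}\sum_\ell \frac{1}{n_{\mathrm{reg}}}\sum_j
  |\hat S(X_{j\ell}) - S_{j\ell}|$, and $R(i)$ divides method $i$'s MAD by
  that of the oracle — the normal-gamma correction evaluated at the *true*
  generating parameters, i.e. a perfect first (estimation) step. $R = 1$
  means estimating the parameters costs nothing. The log-scale variant
  applies $|\log \hat S - \log S|$ with probes of true signal $< 1$
  excluded and zero corrected values excluded — background subtraction's
  clamped zeros would otherwise make the log undefined, which is why
  published log-scale tables omit the subtraction column.
* **AD profiles and operating characteristics** (`ad_profile()`,
  `operating_chars()`): per-probe deviation against log signal on
  replicate designs, and the bias/precision summary — per-reference-bin
  mean and SD of log2 corrected intensities (25 equal-count bins), the
  innate offset (mean corrected intensity of zero-reference probes), and
  the response slope fitted below the top two bins, where saturation bends
  real spike-in curves.
* **Rank utilities** (`auc_rank()`, `spearman_scores()`): mid-rank
  Mann–Whitney AUC and per-probe Spearman correlation against a design
  gradient; both invariant under any increasing transform, so offset
  choices cannot influence them.

## Problem sizes and reproducibility

The test suite runs the full parameter-recovery study at array scale
($n_{\mathrm{reg}} = 25{,}000$, $n_{\mathrm{neg}} = 1{,}000$, 20 replicate
fits, against 20 at $n_{\mathrm{reg}} = 2{,}500$ to verify errors shrink
with $n$) and the excess-risk comparison at $N = 6$ arrays per model;
`scripts/acceptance.R` recomputes the four headline ratios at $N = 20$
arrays per model, rounding to two decimals as printed. One normal-gamma fit
takes a few seconds on one core; the acceptance script completes in about
six minutes. All randomness flows from one `--seed` argument through the
per-array counter scheme.

## Known limitations

* The correction assumes the fitted array's parameters; arrays are never
  pooled. This matches per-array processing practice but forgoes shrinkage
  across arrays.
* The gamma signal model shares the normexp model's independence
  assumption across probes; co-expression violates it, mildly.
* The noise model is exactly normal. The mixture and empirical noise modes
  exist to probe robustness to that assumption, not to fit non-normal
  noise.
* `fit_normexp(method = "rma")` is a convention-faithful heuristic; its
  bias is a property of the convention, and no attempt is made to improve
  it.
* The FFT density's absolute accuracy floor ($\sim 10^{-14}$) limits
  log-density accuracy only beyond the $10^{-6}$-of-peak threshold where
  the analytic tail rules take over.
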