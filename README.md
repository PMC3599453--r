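# gammabg

Normal-gamma background correction for single-channel microarray
intensities.

## The problem

On single-channel platforms such as Illumina BeadArrays, the observed
intensity of every probe is signal plus noise,

```
X = S + B,    S ⊥ B,    B ~ N(μ, σ²),
```

and the platform's **negative control probes** (S = 0) provide a pure noise
sample on every array. Background correction means estimating S from X. The
default subtraction rule `max(X − median(negatives), 0)` zeroes out every
weak probe and throws information away; model-based correction instead
returns the conditional expectation `E[S | X = x]`, which is strictly
positive for all x.

The established **normexp** model takes S ~ Exp(α). This package implements
the more flexible **normal-gamma** model,

```
S ~ Γ(k, θ)        (shape k, scale θ; normexp is the special case k = 1),
```

whose extra shape parameter lets the fitted density match the sharp peak
and heavy right tail of real intensity distributions. The package provides:

* the gamma⊗normal convolution density, computed by an FFT scheme with
  exact per-cell gamma masses and moment corrections (node accuracy ~1e−7
  relative against adaptive quadrature);
* joint maximum-likelihood estimation of (μ, σ, k, θ) from regular **and**
  negative probes, `L = Π_J f_ng(X_j) · Π_J₀ f_norm(X_j)`;
* the correction `Ŝ(x) = kθ · f_ng(x; k+1) / f_ng(x; k)` plus the normexp
  baselines (MLE / RMA / NP) and background subtraction;
* detection-p-value utilities, including reconstruction of unpublished
  negative-probe intensities from detection p-values;
* a synthetic-array simulator (fresh or replicated signal, normal /
  χ²-mixture / empirical noise) and the evaluation toolkit used to compare
  corrections: penalized irregular histograms and L1 fit distance,
  relative-L1 parameter errors, MAD excess-risk ratios, absolute-deviation
  profiles, operating characteristics (bias / precision / innate offset),
  and rank-based AUC.

Everything is tidyverse-shaped: probe tables are tibbles, fitted models have
`tidy()` / `glance()` methods, result objects have `autoplot()` methods, and
the simulator returns a nested tibble.

## Worked example

Simulate one full-scale array, fit the model, and correct it:

```r
library(gammabg)

arrays <- simulate_arrays(sim_design(params = preset_params("A"),
                                     n_reg = 25000, n_neg = 1000,
                                     n_arrays = 1, seed = 42))
array1 <- arrays$data[[1]]

fit <- fit_background(array1, model = "normal-gamma")
fit
#> <bg_fit: ng-mle | loglik -186560.724 | converged after 272 evaluations>
#> <normal-gamma parameters>
#>   mu    901.183
#>   sigma 141.523
#>   k     0.638949
#>   theta 492.819

corrected <- bg_correct(array1, method = "normal-gamma", fit = fit)
dplyr::select(corrected, probe_id, probe_type, intensity, signal, signal_hat)[c(1:3, 25001), ]
#> # A tibble: 4 × 5
#>   probe_id  probe_type intensity signal signal_hat
#>   <chr>     <chr>          <dbl>  <dbl>      <dbl>
#> 1 reg_00001 regular         812.   49.0       52.7
#> 2 reg_00002 regular        1407.  355.       446.
#> 3 reg_00003 regular         810.   77.9       52.3
#> 4 neg_0001  negative        938.    0         80.6
```

The array was generated with (μ = 900, σ = 140, k = 0.64, θ = 500); the MLE
recovers (901.2, 141.5, 0.639, 492.8) from 26,000 observed intensities. In
the corrected table, `signal` is the simulator's hidden truth and
`signal_hat` the model's conditional-expectation estimate: a probe observed
at 812 — barely above the noise mean — is pulled to 52.7 rather than the
subtraction rule's 0 (its true signal is 49.0), while a clearly expressed
probe at 1407 is corrected to 446 (truth 355). The correlation between
`signal_hat` and the true signal on this array is 0.957.

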