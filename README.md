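# metaif

Maximum-entropy estimation of the arterial input function (AIF) density
and two-compartment pharmacokinetic parameters for DCE-MRI.

## What problem this solves, and for whom

Quantitative analysis of dynamic contrast-enhanced MRI fits the
two-compartment (Tofts) exchange model

    dC_T/dt = Ka C_p(t) - Kb C_T(t)

to tissue concentration–time curves, where C_p(t) is the AIF and Ka, Kb
(1/min) are the exchange rate constants. When no artery is in the field of
view the AIF cannot be measured directly, and the Murase-linearized system
C_T = A·K, with A built from cumulative integrals of both curves, is an
ill-conditioned inverse problem under noise. This package is for imaging
scientists who want to (a) estimate the *probability density* of the AIF
concentration values by the maximum-entropy technique (MET) and (b) carry
that density into regularized / Bayesian estimation of (Ka, Kb).

The maximum-entropy density under moment constraints
E_p[phi_i(X)] = mu_i has the form

    p(x) = exp( - sum_i lambda_i phi_i(x) ),   phi_i in {1, ln x, x, x ln x, x^a}

and the package solves for the multipliers three ways:

* **Newton** — damped Newton on the convex dual ln Z(lambda) + lambda'mu;
* **TLBO** — teaching–learning-based optimization of the moment residual;
* **MET/REG** — a soft-constrained variant minimizing
  `||mu - E_p[phi]||^2 + w * KL(p, g)` against a kernel-density reference
  g, solved through its low-dimensional convex dual (and, independently,
  a primal simplex solver used for cross-checking).

Closed-form dictionaries map multipliers to the exponential, Weibull,
gamma and Erlang families and back. Classical Weibull baselines (moment
estimator, MLE, frequency-weighted MLE) are included for comparison, and
an evaluation suite scores any fit against the empirical reference (KL
divergence, differential entropy, RMSE, chi-square, R²). A synthetic
cohort generator emulates the 46-frame × 11.9 s acquisition so the whole
pipeline runs end to end without clinical data.

## Worked example

```r
library(metaif)

subject <- generate_subject(ka_per_min = 0.6, kb_per_min = 1.2, seed = 7)
result  <- run_pipeline(subject$aif, subject$tissue,
                        aif_method = "met_reg", pk_method = "map")
result
#> AIF density fit [met_reg] on 42 values (4 dropped)
#>   gamma(alpha = 2.62461, beta = 0.247543)
#>   KL to reference = 0.0116, entropy = 0.3657
#> PK fit (map): ka = 0.6226 /min, kb = 1.2375 /min
#>   residual SS = 5.060e-03, sigma2 = 1.150e-04 (n = 46)
```

Reading the output: the AIF value density is fitted as a gamma with shape
2.62 and scale 0.248 mmol/L (the four zero baseline frames are dropped
before fitting); its Kullback–Leibler divergence from the kernel-density
reference is 0.012 nats (small = close to the empirical density); and MAP
estimation with that density as prior recovers the generating rates
Ka = 0.6, Kb = 1.2 /min to within a few percent at the default 2 % noise.
Everything is a tibble or has `tidy()`/`glance()` methods:

```r
glance(result)         # one row: family, alpha, beta, KL, entropy, Ka, Kb
tidy(fit_aif(sample_aif_values(5000, seed = 1), method = "met_newton"))
#> # A tibble: 2 × 2
#>   term  estimate
#> 1 alpha    2.74
#> 2 beta     0.238
```

`autoplot()` methods exist for curves, fitted densities and TLBO traces.
A thin command-line wrapper over the same functions ships at
`inst/cli/metaif.R` (subcommands `simulate`, `fit-aif`, `fit-pk`,
`evaluate`, `run`).

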