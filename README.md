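# rsdcm

Directed (effective) connectivity analysis of resting-state fMRI for
seizure networks.  `rsdcm` fits a two-node **cross-spectral dynamic causal
model** (DCM) to region-wise BOLD time series, classifies the
**seizure-onset zone (SOZ)** against the **propagation zone (pZ)** from the
polarity of the estimated directed couplings, and quantifies
pre-to-post-operative network change with recovery indices and the
**Boerwinkle Neuroplasticity Index (BNI)**.

## The model

Neural activity in the two regions follows a stable linear stochastic
system

    dx/dt = A x + v,

where the off-diagonals of `A` (Hz) are the directed couplings and the
diagonal self-decays are parameterized as `-0.5 * exp(a_self)` to keep the
system stable.  Endogenous fluctuations `v` and observation noise have
power-law spectra `amp * f^(-exp)`.  BOLD observation goes through a
balloon-type haemodynamic model.  The model is fit not to the time series
but to its **cross-spectral density**

    G_y(f) = H(f) G_v(f) H(f)* + G_e(f),   H(f) = diag(h(f)) (2*pi*i*f*I - A)^-1,

estimated from the data with a multivariate autoregression (order 8,
32 frequency bins from 1/128 Hz to the Nyquist frequency).  Inversion is
by variational Laplace (Gauss–Newton with Levenberg damping on a
free-energy bound), followed by exhaustive Bayesian model reduction and
averaging (BMA) over on/off configurations of the couplings, thresholded
at posterior probability 0.9.

The decision layer applies the directionality rule — the SOZ *emits
excitatory (positive)* coupling toward the pZ and *receives inhibitory
(negative)* coupling back — and, for operated patients, computes per
connection

    recovery index = 100 * (pre - post) / pre     (percent)

with `BNI = SOZ index + pZ index`; `BNI > 70%` (or an obliterated SOZ with
no extractable signal) predicts sub-seizure-threshold residual activity.
Group analyses use parametric empirical Bayes (PEB) with Engel-class and
age covariates, leave-one-out cross-validation, and a three-level
pre/post hierarchy.  Diagnostic accuracy is evaluated with exact binomial
confidence intervals and the prevalence-adjusted bias-adjusted kappa
(PABAK).

## Worked example

```r
library(rsdcm)

# simulate a 20-minute resting-state acquisition (2 runs x 300 volumes,
# TR 2 s) from a network with known directed coupling:
# SOZ -> pZ +0.22 Hz (excitatory), pZ -> SOZ -0.73 Hz (inhibitory)
ds  <- simulate_dataset(soz_network(), acquisition_spec(seed = 42))
csd <- estimate_csd_mar(concatenate_runs(ds$runs))
fit <- invert_dcm(csd)
fit
#> <inversion_result> 2 regions, F = -860.84, 40 iterations (converged)
#>             estimate     sd    pp
#> a[pZ<-SOZ]    0.3756 0.0463 1.000
#> a[SOZ<-pZ]   -0.6911 0.0590 1.000
#> a_self[SOZ]   0.0626 0.0469 0.909
#> a_self[pZ]   -0.1989 0.0565 1.000

rep <- threshold_connections(reduce_and_average(fit), 0.9)
call <- classify_direction(
  connection_estimate("SOZ", "pZ", rep$value[rep$source == "SOZ" & !rep$self],
                      rep$pp[rep$source == "SOZ" & !rep$self], "pre"),
  connection_estimate("pZ", "SOZ", rep$value[rep$source == "pZ" & !rep$self],
                      rep$pp[rep$source == "pZ" & !rep$self], "pre"))
call$soz
#> [1] "SOZ"
```

The fitted couplings have the correct signs and high posterior
probability: the positive outgoing and negative incoming coupling identify
the first node as the seizure-onset zone.  The magnitudes are shrunk
relative to the simulation truth by the deliberate coupling priors.

Recovery indices reproduce the reference cohort exactly:

```r
recovery_record("subject-2", 0.28, 0.08, -0.97, -0.26)[
  c("soz_recovery_index", "pz_recovery_index", "bni")]
#> $soz_recovery_index [1] 71
#> $pz_recovery_index  [1] 73
#> $bni                [1] 144

diagnostic_metrics(contingency_counts(55, 8, 3, 22))$percent
#> [1] 88 95 73 87 88   # accuracy, sensitivity, specificity, ppv, npv
```

A thin command-line wrapper is installed as `exec/rsdcm`
(`rsdcm simulate|run|evaluate`).

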