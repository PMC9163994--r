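---
title: "Seizure-network directionality from resting-state cross-spectral DCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure-network directionality from resting-state cross-spectral DCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsdcm)
```

## The problem and the model

Drug-resistant focal epilepsy surgery needs the seizure-onset zone (SOZ)
distinguished from the region seizures propagate to (pZ).  `rsdcm`
implements a resting-state approach: estimate the *directed* coupling
between two candidate regions from rs-fMRI alone and read the roles off
the coupling polarity — the SOZ sends excitatory (positive) influence to
the pZ and receives inhibitory (negative) influence back.

Neural dynamics are linear and stable,

$$\dot x = A x + v,$$

with off-diagonal couplings of $A$ in Hz and self-connections
parameterized on a log scale, decoded as $-0.5\,e^{a}$ Hz so that the
decay is always negative (at $a = 0$, exactly $-0.5$ Hz).  The endogenous
fluctuations $v$ and the measurement noise are modelled as power laws
$\alpha f^{-\beta}$, each region contributing a log-amplitude and an
exponent deviation around 1.  Observation goes through the balloon
haemodynamic model (signal decay 0.64 s⁻¹, autoregulation 0.32 s⁻¹,
transit 2 s, stiffness 0.32, resting extraction 0.4); only a per-region
log-gain is estimated, because two-node spectra cannot constrain the full
haemodynamic parameterization.

The data feature is the second-order statistic, not the time series: a
multivariate autoregression (MAR) of order 8, fit by ridge-regularized
least squares to the standardized, run-concatenated series, evaluated as
a cross-spectral matrix on 32 linear frequency bins spanning 1/128 Hz to
Nyquist.  The generative model predicts the same quantity as
$G_y(f) = H G_v H^* + G_e$ with
$H(f) = \mathrm{diag}(h_r(f))\,(2\pi i f I - A)^{-1}$, where $h_r$ is the
small-signal balloon frequency response.  Because the same integrator
that simulates BOLD also produces $h_r$, the synthetic-data generator and
the model are consistent by construction.

## Inversion

Variational Laplace: Gauss–Newton steps with Levenberg damping maximize a
free-energy bound; the residual log-precision is updated by EM under a
tight $\mathcal N(4, 1/128)$ prior; steps that destabilize $A$ or lower
the objective are rejected with doubled damping.  Priors shrink:
off-diagonal couplings $\mathcal N(0, 1/64)$, self log-scales and
haemodynamic log-gains $\mathcal N(0, 1/256)$, spectral log-amplitudes
and exponent deviations $\mathcal N(0, 1/64)$.  Two numerical choices
matter in practice:

* **Data scaling.**  The observed CSD is rescaled by one scalar so its
  mean diagonal power matches the prior prediction; per-region scale ends
  up in the haemodynamic log-gains.  Coupling estimates are therefore
  invariant to rescaling the input series.
* **Deterministic multistart.**  The spectral-fit objective is multimodal
  in the coupling signs: from a zero start, roughly half of noisy
  datasets converge into the sign-flipped mode even though the true mode
  has higher free energy.  `invert_dcm()` therefore starts from the prior
  mean and from the two opposed coupling quadrants ($\pm 0.15$ Hz) — the
  two directed hypotheses a two-node network admits — and returns the
  highest-evidence fit.  This is deterministic and adds no randomness.

Convergence is declared at $|\Delta F| < 10^{-3}$ nats (at most 128
iterations).  The recorded free energies of accepted steps are monotone
up to the small wobble introduced when the Jacobian is refreshed between
iterations; tests allow 0.05 nats for it.

Magnitudes are deliberately conservative: with couplings of $+0.22$ and
$-0.73$ Hz the posterior means are biased toward zero by the tight
priors.  Signs and posterior probabilities — all the decision layer
uses — are recovered reliably (≈90% of synthetic datasets at the default
acquisition).

## Model reduction, averaging, thresholds

Exhaustive Bayesian model reduction switches each coupling (including
self-connections, which clinical results show can be pruned) on or off —
"off" being a reduced prior variance of $10^{-8}$, since an exact zero
breaks the precision algebra — over all $2^4$ configurations, analytic
and without refitting.  Model probabilities are the softmax of the free
energies; the averaged posterior is the moment-matched Gaussian mixture.
A connection's posterior probability is the summed probability of models
containing it; individual-level reports threshold at 0.9, group effects
at 0.95, the pre/post hierarchy at 0.9.  Two Pp conventions coexist by
design: the full-model report uses the Gaussian sign-probability of each
parameter, the reduced report uses model-based probabilities.

## Group level

PEB places $\theta_i \sim \mathcal N(X_i\beta,\ \Gamma)$ over the
first-level coupling posteriors, with design columns ordered intercept,
Engel class (1a = +1, 1b = −1), age, covariates mean-centred.  Group
coefficients have $\mathcal N(0,1)$ priors.  The between-subject
covariance is $\Gamma = (\text{first-level prior variance}/16)\,
e^{-\gamma}$ with $\gamma \sim \mathcal N(0, 1/16)$: the log-precision
modulates a base scaled to the parameters' own prior — without that
scaling the tight $\gamma$ prior would pin the between-subject variance
near 1 Hz², swamping couplings of 0.1–0.7 Hz and erasing group effects.
$\gamma$ is optimized on the marginal evidence (one-dimensional, exact
conditional $\beta$ posterior), which keeps the group level deterministic.

Because the group-effect prior is informative, the intercept does not
converge exactly to the arithmetic mean of first-level means even as
first-level uncertainty vanishes; with a vague group prior it does (this
is how the property is tested).

Leave-one-out validation refits the PEB without each subject and infers
the left-out covariate from its first-level posterior mean by generalized
least squares with a Gaussian prior taken from the training spread; the
fold predictions are correlated with the true covariate
($df = n - 2$, one-tailed).

The pre/post hierarchy is three levels: sessions inverted separately
without reduction; one PEB per subject with columns common $[1,1]$ and
difference $[0.5,-0.5]$ (so the difference coefficient is literally pre
minus post); a PEB of PEBs across subjects; then BMR+BMA at 0.9.
Subjects whose post-operative SOZ yields no extractable signal cannot
enter (a one-node "pair" cannot be inverted) and are routed to the
evaluation as obliterated records.

## Decision layer and evaluation

`classify_direction()` lets each significant connection vote for an SOZ
candidate (positive coupling nominates its source, negative its target);
consistent votes give the call, conflicting or absent votes give
"indeterminate".  "Reversed" means the called SOZ is not the clinically
presumed node; reversed calls still count as calls so that evaluation can
score them as false positives.

Recovery indices are $100(\mathrm{pre}-\mathrm{post})/\mathrm{pre}$,
rounded half-away-from-zero to integers only at reporting; the BNI is the
sum of the two *reported* integers — the convention that reproduces the
reference cohort's table exactly (e.g. 71 + 73 = 144).  Indices are
scale-free but explode as $|\mathrm{pre}| \to 0$; only
$|\mathrm{pre}| < 10^{-6}$ Hz is treated as undefined, since genuinely
small printed couplings (−0.03 Hz) legitimately produce four-digit
indices.  Contingency aggregation counts each pre-operative connection
once (expected polarity TP, reversed FP, non-significant FN by default —
an FP routing is configurable because the published table splits five
such connections 3/2 without a stated rule) and each post-operative
subject twice (BNI > 70% or obliteration TN, otherwise FP).  Metrics use
the published footer formulas with Clopper–Pearson intervals from beta
quantiles; PABAK is $2P_o-1$.  The published PPV (88%) is not encoded:
the footer formula on the published counts gives 55/63 = 87.3%, which
this package reports as 87.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions: two runs of 300
volumes at TR 2 s; couplings $+0.22$/$-0.73$ Hz (the cohort's
pre-operative means); Euler–Maruyama integration at $dt = 0.1$ s with 60 s
burn-in; power-law fluctuation synthesis in the frequency domain with a
low-frequency floor at 1/duration and exponents clamped to $[0, 2]$;
balloon haemodynamics; decimation to the TR grid; additive power-law
observation noise; per-run intensity offsets $\mathcal N(0, 1)$ to
exercise concatenation correction.

Chosen conventions (the study reports none): fluctuation exponent 1
(canonical $1/f$), amplitude $10^{-5}$ — small enough (neural sd ≈ 0.02)
that the balloon stays in its small-signal regime, where generator and
spectral model agree within ~10% mid-band; at 100× that drive the balloon
nonlinearity distorts the spectra outright.  Noise amplitude
$2\times10^{-7}$ with exponent 0.5 puts the BOLD-to-noise sd ratio near
4, typical of denoised ROI series.  What the generator does *not*
emulate: head motion, physiological confounds, spatially varying
haemodynamics, registration error, nonlinear neural dynamics.  Passing
recovery tests on this generator therefore shows the estimation chain is
correct and well-calibrated under the model's assumptions — not that real
ablation data behave this way.

## Problem sizes and determinism

Unit tests run on short series (150–300 volumes) and toy conjugate
models; the recovery studies use 200 synthetic datasets at the full
acquisition and 50 replicate 9-subject pre/post groups; the acceptance
script estimates the same rates from 60 datasets and 10 groups.  Every
stochastic stage takes an explicit seed derived from the master seed by a
documented label-hash scheme, so the full pipeline is bit-reproducible.

## Known limitations

* Coupling magnitudes are shrunk by the priors; only signs and posterior
  probabilities are calibrated.  This matches the decision layer's needs.
* The MAR data feature at 600 volumes is noisy; ~10% of synthetic
  datasets at the default SNR land in the wrong sign mode even with
  multistart, consistent with the reversed/indeterminate rates observed
  clinically.
* The PEB level assumes a diagonal between-subject covariance with one
  shared log-precision; no covariate-specific random-effect structure.
* Exhaustive reduction is limited to 20 switchable parameters (2^k model
  space).
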