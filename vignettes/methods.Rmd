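---
title: "Information dynamics of epoched two-site recordings: models, estimators, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information dynamics of epoched two-site recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(infodyn)
```

# The measures

`infodyn` quantifies three aspects of information processing in a pair of
simultaneously recorded continuous neural signals (say sites $X$ and $Y$,
each cut into epochs):

* **Differential entropy** $H(Y_t)$ — how much information is locally
  available in new samples of a site.
* **Active information storage**
  $AIS(Y) = I(Y_t ; \mathbf{Y}_{t-1})$ — how much of each new sample is
  predictable from the site's own past state
  $\mathbf{Y}_{t-1} = (Y_{t-1}, Y_{t-1-\tau}, \dots, Y_{t-1-(d-1)\tau})$.
* **Transfer entropy with an explicit transfer delay**
  $TE(X \to Y, u) = I(Y_t ; \mathbf{X}_{t-u} \mid \mathbf{Y}_{t-1})$ —
  directed information transfer that is *new* with respect to the
  target's own past. Because the conditional mutual information is
  maximal when the assumed delay $u$ matches the physical coupling delay
  $\delta$, scanning $u$ and keeping the argmax (`scan_delay()`)
  reconstructs $\delta$; the bidirectional asymmetry index
  `te_net()` is only meaningful with per-direction optimized delays.

Useful bounds connect the three: $AIS(Y) \le H(Y_t)$ and
$TE(X \to Y, u) \le H(\mathbf{X}_{t-u})$ — transfer can never exceed the
information the source states make available. These inequalities hold
exactly for plug-in estimates on a common discretization and are enforced
as property tests.

# Estimators

**Continuous (nearest-neighbour) route.** Differential entropy uses the
Kozachenko-Leonenko estimator
$\hat H = -\psi(k) + \psi(N) + \frac{d}{N}\sum_i \log \epsilon_i$ with
$\epsilon_i$ twice the max-norm distance to the $k$-th neighbour. Mutual
information uses the Kraskov-Stögbauer-Grassberger (KSG) estimator in its
"algorithm 2" form ($\psi(k) - 1/k + \psi(N) - \langle\psi(n_x) +
\psi(n_y)\rangle$, marginal radii from the $k$ nearest joint-space
neighbours, inclusive counts); conditional mutual information uses the
"algorithm 1" conditional form ($\psi(k) + \langle\psi(n_c + 1) -
\psi(n_{ac} + 1) - \psi(n_{bc} + 1)\rangle$, joint radius, strict
counts). The two forms carry slightly different biases; because the bias
depends only on data geometry and parameters, all comparative statistics
(conditions, directions, surrogates) are unaffected. Everything uses the
maximum norm and $k = 4$, balancing estimator bias (falls with $k$) and
variance (rises with $k$). Neighbour searches run on a C++ max-norm k-d
tree; distance ties are broken toward the smaller time index so results
are reproducible. Exact duplicate points (possible after storage round
trips) receive a deterministic, seeded jitter of relative amplitude
`1e-10` — configurable off, in which case duplicates are an error.

KSG-type estimates have a data-dependent bias and must not be read at
face value; significance comes from epoch-shuffle surrogates
(`surrogate_test()`): target epochs are permuted, source order kept,
destroying coupling while preserving the within-epoch structure that
drives the bias.

**Discrete (Bayesian) route.** Signals are binned into `n_inner_bins`
equal-width bins spanning ±3 SD around the mean plus two overflow bins
(default alphabet 12); delay-embedded words over this alphabet are
counted, and word entropies are estimated with the
Nemenman-Shafee-Bialek (NSB) estimator — a mixture of symmetric Dirichlet
priors, mixed so the prior is nearly flat in expected entropy. TE
decomposes into four word entropies, AIS into three, each estimated
separately. The NSB integral runs over the prior-expected-entropy
coordinate $\xi \in (0, \log K)$: the evidence is located on a coarse
grid, then integrated by 64-node Gauss-Legendre quadrature over the
region within 35 log-units of the peak. Two numerical hazards are handled
explicitly: for large concentrations the difference
$\log\Gamma(\kappa) - \log\Gamma(N + \kappa)$ cancels catastrophically
and is replaced by its stable expansion, and likewise the count-sum term
switches to an exact product form for large $\beta$. The working support
is capped at $K' = 10^{12}$ (valid for sparse word distributions;
estimates must be, and are tested to be, support-independent). The
`subsample_robustness()` check re-estimates entropies on nested
subsamples; the default stability rule — relative deviation below 5%
over the top half of the curve — is this package's choice, since no
printed tolerance exists. Heavy-tailed, undersampled distributions are
exactly where NSB drifts with sample size, and such recordings should be
excluded rather than trusted.

A scale caveat: the ±3 SD binning adapts to the signal's amplitude, so
the Bayesian route is blind to condition effects carried purely by
variance. The cross-backend agreement flag of the pipeline therefore
compares AIS and TE only.

# Embedding optimization

Past states use the Ragwitz criterion: for each candidate $(d, \tau)$,
each point's next sample is predicted as the mean next sample of its
$k = 4$ nearest embedded neighbours, and the candidate minimizing the MSE
wins. Decisions fixed here: prediction horizon is one sample; ties go to
smaller $d$, then smaller $\tau$; $\tau$ candidates default to fractions
{0.2, 0.4, 0.6, 0.8, 1.0} of the epoch's autocorrelation decay time
(ACT, the first lag below $e^{-1}$), with a floor of one sample; the
default $d$ grid is intentionally small (1–5) for desk use and should be
widened for real analyses. Because estimator bias grows with $d$, the
pipeline embeds every epoch with the *maximum* optimized $d$ across
conditions and directions (`common_dimension()`), while $\tau$ stays
per-recording. One empirical note: on smooth narrowband signals the MSE
local predictor is only weakly sensitive to $\tau$, and adjacent-sample
embeddings often predict best; the often-expected preference for
$\tau > 1$ on oversampled oscillations does not reliably materialize, so
no test asserts it.

# The synthetic world

Real recordings are not packaged, so every downstream stage is exercised
on a generator (`synth_params()`, `generate_recording()`) whose defaults
state the world the analysis assumes: two channels at 1000 Hz, 4.81-s
epochs generated independently (estimation never crosses epoch
boundaries), several hundred epochs per recording, a handful of
recordings per condition.

* **Source** = AR(1) broadband background (coefficient `storage_gain`,
  default 0.5) + narrowband stochastic oscillations + white innovations,
  all scaled by `source_entropy_scale` (the entropy knob; 1 = awake-like).
* **Oscillations** are AR(2) resonators with pole radius 0.99 (theta
  4 Hz, amplitude 0.5; alpha 10 Hz, amplitude 1 by default), not
  deterministic sinusoids: real LFP rhythms have finite bandwidth and
  phase diffusion, and a phase-locked sine is fully predictable from the
  target's past, so it could carry no transferable information. With
  these defaults the source ACT lands at roughly 7–16 ms, inside the
  range typical of cortical LFP.
* **Target** = its own AR(1) background plus `coupling_gain` times a
  Gaussian-smoothed (kernel SD `smooth_samples = 10`), delayed
  (`coupling_delay`, default 5 samples) copy of the source — the same
  injection recipe as the in-package source-entropy study. For
  delay-reconstruction experiments `smooth_samples = 0` concentrates the
  coupling at a single lag (the filtering-study design).
* **Nesting**: a per-recording log-normal jitter (`intercept_sd`) on the
  entropy and storage knobs gives recordings distinct intercepts, so
  epoch-level estimates are genuinely dependent within recordings
  (intraclass correlation > 0) and the mixed-model stage has something
  to model.

What a green test on this world does **not** establish: realism of the
LFP spectrum beyond the stated components, artifacts other than optional
amplitude spikes, burst suppression or other shape changes of the
amplitude distribution, nonstationarity within epochs, or volume
conduction. In particular, condition effects on *entropy* are injected
through variance; in real anesthesia data they partly come from
distribution shape.

# The two simulation studies

**Filtering study** (`sim_filter_effect()`): two uniform-noise series,
the second receiving a 0.2-scaled copy of the first delayed by 10
samples; TE with one-sample histories and $k = 4$ over $u = 1..20$,
before and after causal fourth-order Butterworth band-passes (0.1–300,
0.1–200, 12–30, 4–8 Hz; the band edges presuppose the 1000-Hz analysis
rate). The filters are designed in-package (bilinear transform,
second-order sections) because no DSP package is available in the target
environment; the design was verified against an independent reference
implementation during development. Expected pattern, reproduced by the
acceptance suite at the scaled profile (20,000 samples, 10 runs; full
profile 100,000/50): exact recovery unfiltered; modal recovery at
0.1–300 Hz; a one-sample underestimation at 0.1–200 Hz; reconstruction
failure with errors up to the grid maximum of 10 samples in the beta and
theta bands. Note the scan grid itself bounds the error at 10.

**Source-entropy study** (`sim_source_entropy()`): two base recordings
whose sources differ only in `source_entropy_scale` (1.0 vs 0.5); target
epochs are permuted to destroy genuine transfer, then an identical
coupling (gain 0.2, Gaussian SD 10 samples, delay 5) is injected into
both. Per-epoch TE is compared with a permutation t-test. The smoothing
makes the per-sample transferred information genuinely small (a smooth
signal delivers little *new* information per sample), so the effect size
is of order $10^{-3}$ nats per epoch; with 4.81-s epochs the study needs
a few hundred epochs per case — matching the recording scale it
emulates (~200–530 epochs) — to resolve it at $p < 0.01$. The Gaussian
"smoothing of 10 samples" is read as the kernel SD. The d = 1,
$\tau$ = 1 histories are a desk-scale simplification; source and target
state entropies are reported so the mechanism (source entropy falls,
target entropy stays) is visible directly.

# Inference

* Surrogate p-values, permutation-ANOVA p-values, restricted Spearman
  and permutation t-tests all use the $+1$ correction
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$ — never exactly
  zero, differing from the raw fraction by at most $1/(n+1)$.
* The two-factor permutation ANOVA computes Type II F-ratios (residual
  mean square from the full interaction model, supporting unbalanced
  cells). Main effects permute observations only within the levels of
  the other factor — an assertion verifies on every draw that the
  stratifying factor is untouched; the interaction requires full
  permutation and is approximative. Epoch-level estimates are first
  aggregated to per-recording medians.
* The mixed-model stage fits, by maximum likelihood (not REML, so
  likelihood ratios are valid), a random-intercept-per-recording model
  with direction coded ±1 and condition as treatment contrasts against
  the reference level, plus its nested submodels; mains are tested
  against the null model, the interaction against the additive model,
  with $\chi^2$ likelihood-ratio tests and BIC reported. The one-way
  random-effects ICC is the intercept-variance share from the
  intercept-only fit.
* All four procedures are calibration-tested: over 500 null simulations
  each, the type-I error rate must fall inside the central 95% binomial
  interval around $\alpha = 0.05$ (surrogate and permutation counts are
  chosen so that $\alpha$ is exactly attainable: 39 surrogates, 199
  permutations).

# Numerical and interface decisions

* Units: nats internally for continuous estimators, bits for the
  discrete route; conversions are explicit (`units` arguments), and a
  z-normalization-across-conditions output mode exists for figure-style
  reporting.
* The pipeline z-normalizes epochs before AIS/TE estimation (both are
  invariant to channel-wise affine maps) but estimates $H$ on the raw
  epochs: differential entropy is exactly *not* scale-invariant, and the
  synthetic world carries its entropy differences in amplitude.
* The assumed-delay grid is 1–20 samples at 1000 Hz; $u = 0$ is excluded
  because a physical delay is at least one sample.
* No Theiler exclusion window is applied within epochs (epochs are
  short and pooled across independent realizations); neighbour searches
  may pool states across epochs of one recording, and per-epoch
  estimates remain available because the mixed models operate on them.
* Epoch QC only flags epochs (strictly-greater-than 30% relative delta
  power for the rejection rule; an amplitude z-score hook with a
  deliberately permissive default of 8 SD stands in for manual artifact
  inspection); samples are never altered.
* Multitaper band power uses Slepian tapers computed from the canonical
  tridiagonal eigenproblem via LAPACK, $K = \lfloor 2TW - 1 \rfloor$
  tapers for smoothing half-bandwidth $W$ (1 Hz default).
* Known limitations: no GPU ensemble estimator (the pooling contract is
  honored, serially); no Pitman-Yor entropy estimator (left as an
  extension point; NSB's drift on heavy-tailed undersampled data is the
  symptom that would motivate it); single-source TE only; no symbolic
  TE.
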