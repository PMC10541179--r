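---
title: "Models and methods behind cogchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cogchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogchain)
```

cogchain implements an analysis chain for developmental cognitive
neuroscience: two-choice behavior is decomposed into cognitive, decision,
and visuomotor components with the EZ-diffusion model; magnetic resonance
spectroscopy (MRS) concentrations are corrected for voxel composition and
relaxation; resting-state visuomotor connectivity is scored from ROI time
series; and moderated regressions and moderated mediations relate the
three levels across age. A synthetic-cohort generator reproduces the
statistical structure the analyses assume, so the whole chain can be
exercised and validated without any external data. This vignette explains
the models, the tunable parameters, and the design decisions.

## The EZ-diffusion decomposition

In a two-alternative task, evidence is assumed to accumulate as a Wiener
process with drift $v$ (evidence units/s) between absorbing boundaries at
$0$ and $a$, starting unbiased at $a/2$, with diffusion scale $s$
(evidence units/$\sqrt{s}$). The reaction time adds a non-decision
component $T_{er}$ (perceptual encoding plus motor execution) to the
first-passage time. The EZ estimator maps three observed moments — the
proportion correct $P_c$, and the mean (MRT) and unbiased variance (VRT)
of correct-trial reaction times — to the three parameters in closed form.
With $L = \mathrm{logit}(P_c)$:

$$x = \frac{L\,(L P_c^2 - L P_c + P_c - \tfrac12)}{VRT}, \qquad
v = \mathrm{sign}(P_c - \tfrac12)\, s\, x^{1/4}, \qquad
a = \frac{s^2 L}{v},$$

$$MDT = \frac{a}{2v}\cdot\frac{1 - e^{-va/s^2}}{1 + e^{-va/s^2}}, \qquad
T_{er} = MRT - MDT.$$

Choices made here:

* **Scaling.** $s = 0.1$, the conventional diffusion scaling. Scaling is
  arbitrary in this model class; only the products $v a / s^2$ and so on
  are identified.
* **Edge correction.** $P_c \in \{0, \tfrac12, 1\}$ makes the logit or
  the sign rule degenerate. The half-count rule is applied: $P_c = 1
  \mapsto 1 - 1/(2n)$, $P_c = 0 \mapsto 1/(2n)$, $P_c = \tfrac12 \mapsto
  \tfrac12 + 1/(2n)$. This keeps all-correct participants (common in
  easy child-friendly tasks) usable, at a known cost of mild shrinkage.
* **Variance estimator.** VRT uses the $n-1$ denominator. A participant
  with a single correct trial has no defined VRT and is excluded for
  that task rather than imputed.
* **Trial screening.** Anticipations (< 200 ms by default) are removed
  first; then a single pass removes trials beyond 3 SD of the
  individual's mean RT across *all* conditions. The band rule is not
  iterated: re-screening the screened sample would progressively trim
  any heavy-tailed RT distribution.

`ez_forward()` is the exact algebraic inverse of the estimator (moments
from parameters), which gives a machine-precision round-trip identity —
the primary correctness oracle — and provides the noiseless path through
which the generator's truth values reach the estimator exactly.

## The Wiener first-passage simulator

`simulate_wiener_trials()` is the independent stochastic oracle. Because
drift and diffusion are constant, increments over a step $\Delta t$ are
*exactly* $N(v\Delta t, s^2\Delta t)$; the only discretisation error in a
fixed-step simulation is the chance that the path touched a boundary
inside a step while both endpoints are interior. Ignoring that event
biases accuracy and first-passage times (the effective boundaries widen
by $\approx 0.583\, s\sqrt{\Delta t}$). The simulator therefore evaluates
the Brownian-bridge crossing probabilities
$\exp(-2(a-x_t)(a-x_{t+\Delta t})/(s^2\Delta t))$ and
$\exp(-2 x_t x_{t+\Delta t}/(s^2\Delta t))$ each step and resolves them
with an auxiliary uniform draw (`bridge = TRUE`, the default). At
$\Delta t = 1$ ms this removes the leading-order bias; the remaining
within-step timing quantisation (RTs recorded at step ends) is an order
of magnitude below Monte-Carlo error at the trial counts used in the
tests. Setting `bridge = FALSE` recovers naive fixed-step sampling for
comparison.

## Spectroscopy corrections

`tissue_correct()` rescales a raw metabolite-to-water ratio for the
voxel's gray-matter, white-matter and CSF fractions using water
concentrations 43300, 35880 and 55556 mmol/L and the $1/(1-f_{CSF})$
metabolite-free-CSF correction. `t2_correct()` applies
$\exp(-TE/T_2)$ *multiplicatively*, exactly as in the quantification
chain this package mirrors; note that a conventional relaxation
correction would divide by the attenuation factor — the function
documentation flags this so cross-pipeline comparisons are not
surprised.

The tissue-water $T_2$ comes from a biexponential fit of unsuppressed
water integrals over a 13-point echo-time grid (32–4040 ms), with the
CSF water $T_2$ fixed at 740 ms and three free parameters (tissue $T_2$,
tissue amplitude, CSF amplitude). The fit uses Levenberg–Marquardt least
squares with bounds $T_{2,t} \in [10, 300]$ ms and non-negative
amplitudes, initialised from a log-linear fit of the earliest six
echoes (where the tissue pool dominates) and a CSF back-extrapolation
from the longest echo. On noiseless grids the fit is exact to $10^{-6}$
relative; bounded trust-region steps keep 1%-noise replicates stable.

Quality exclusions: metabolites with CRLB > 50% are flagged not
detectable (that metabolite only — the rest of the spectrum is kept);
spectra with SNR beyond 3 SD of their region's distribution are removed.
CRLB flagging runs first, but the two rules do not interact: the SNR
distribution is computed over unique spectra, not metabolite rows.

## Visuomotor connectivity

The within-network score is the mean Fisher $z = \mathrm{atanh}(r)$ over
the 21 pairs of the seven visuomotor network nodes (four visual, three
sensorimotor). Each series is high-pass filtered at 0.01 Hz (sampling
interval 0.933 s) with a zero-phase Butterworth filter (a second-order
design applied forward and backward, i.e. fourth-order magnitude
response); supplied nuisance regressors are removed by least squares
before correlation. Frames with framewise displacement above 2 mm are
censored after filtering; participants lose their score when strictly
more than 5% of frames are censored (removing exactly 5% is retained).
The pairwise-mean definition of "within-network connectivity averaged
across ROIs" follows the ROI-to-ROI convention of common connectivity
toolboxes; a network-level summary (average time series first, then
correlate) would weight shared variance differently, and the ambiguity
is resolved here in favour of the pairwise mean.

## The moderated-regression engine

All continuous dependent variables and predictor components are z-scored
on each model's analysis sample, and product terms are formed **after**
z-scoring the components (not by z-scoring the product). This makes the
reported coefficients standardized betas and makes simple-slope probing
exact: the slope of the focal predictor at moderator level $k$ SD is
$\beta_{focal} + k\,\beta_{interaction}$, and the crossover point is
$-\beta_{focal}/\beta_{interaction}$.

Inference is by case bootstrap: participants are resampled with
replacement, the full standardize-and-fit procedure is rerun per
resample, and percentile intervals are reported together with a
two-sided sign-crossing p-value $p_{BO} = 2\min(\#\{\beta^* \le 0\},
\#\{\beta^* \ge 0\})/B$, floored at $2/B$ (an honest resolution limit:
a bootstrap cannot certify a p-value below its own granularity). The
default is $B = 5000$ resamples and 95% intervals. After the initial
fit, rows with |standardized residual| > 3 are removed once, the sample
re-standardized, and the model (and its bootstrap) rerun — a single
pass, since iterating residual trimming on re-standardized samples has
no natural fixed point.

Hypothesis families are enumerated as Cartesian products of design
factors — 3 diffusion parameters × 3 neurochemicals × 2 voxel regions ×
2 effect types = 36 hypotheses for the main assessment, × 5 cognitive
functions = 180 for the condition-based supplementary family — and
corrected with Benjamini–Hochberg (the step-up FDR procedure; the
generic label "FDR" is resolved to BH as the field default). Age in
years is the continuous moderator everywhere; the five recruitment
bands (6–7, 10–11, 14–15, 16–17, 18+) are used *only* for the
per-age-group 3-SD screening of analysis variables.

## Moderated mediation (model 59)

Both the $X \to M$ path, the $M \to Y$ path and the direct path are
moderated by $W$ (age): two OLS equations on z-scored variables give
paths $(a_1, a_2, a_3)$ and $(c_1', c_2', c_3', b_1, b_2)$, and the
conditional indirect effect at moderator value $w$ is
$\omega(w) = (a_1 + a_3 w)(b_1 + b_2 w)$, probed at $w \in \{-1, 0, +1\}$
SD. Significance is judged by whether the case-bootstrap percentile
interval of $\omega(w)$ excludes zero, at 90% by convention for
mediation chains. Percentile (not bias-corrected) intervals are used:
they are reproducible without acceleration constants, at the cost of a
known divergence risk from macro implementations that default to
bias-correction — a caveat worth remembering when comparing numerical
output across tools. Moderator levels are computed on the analysis
sample after exclusions. Note that at a *complete* null (both paths
zero) the product statistic is sharply peaked at zero and the interval
test is very conservative; its nominal 10% size is approached on the
partial null where one path is real, which is what the test suite
checks.

## The synthetic cohort

The generator emulates the study conditions end to end:

* **Design facts**: five age bands (defaults 60/60/60/57/56
  participants, ages uniform within bands), a 96-trial/12-condition
  attention block (4 cue × 3 flanker cells of 8 trials), 72
  digit-comparison trials covering all 36 unordered digit pairs twice,
  and 72 animal-figure rotation trials (24 per figure, angles
  45/90/135°).
* **Structure**: standardized age trends (drift +0.5, boundary −0.4,
  non-decision −0.5; glutamate −0.4, GABA +0.4, NAA +0.15),
  neurochemical-by-age interactions on non-decision time (glutamate
  −0.22, GABA +0.23, IPS only), a connectivity latent carrying the
  neurochemical-by-age structure (glutamate −0.18, GABA +0.15), and an
  intelligence outcome with the model-59 path set. These values are the
  packaged study-like calibration; every one of them is a config field.
* **Observation models**: trials are drawn by the Wiener simulator from
  natural-scale parameters (e.g. non-decision 0.32 ± 0.05 s, floored at
  0.1 s with truncations counted); raw MRS values are constructed by
  *inverting* the tissue correction from truth concentrations and
  sampled tissue fractions, so the correction chain recovers truth
  exactly at zero noise; water-reference series come from the
  biexponential model; ROI series are latent-factor Gaussian with the
  factor loading set so the pairwise correlation tracks the
  connectivity truth; framewise-displacement traces plant high-motion
  participants preferentially in the youngest band; intelligence is a
  monotone integer link of the latent outcome onto the 0–30 item
  support.

For the recovery simulations the generator works at the participant
level with all analysis variables at unit population variance: the
residual SD of each structural equation is solved in closed form from
the generating coefficients (for the mediation generator this uses the
exact moments of the $MW$ regressor under independent standard-normal
$X$ and $W$). That is what makes a generating coefficient directly
comparable to the mean recovered standardized beta. Two approximations
are documented rather than hidden: banded (mixture-of-uniform) ages
have sub-Gaussian kurtosis, which perturbs the product-term variance by
well under 1% at the calibrated effect sizes; and the mediation
generator draws the neurochemical independent of age, since the
closed-form variance normalization assumes independence.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: BOLD autocorrelation and scanner
drift (ROI noise is white), item-level difficulty structure in the
intelligence test (no IRT; the discontinue rule is emulated only as the
bounded support), RT contaminants other than the planted anticipations,
MRS lineshape or baseline artifacts (quality covariates are sampled,
not derived from spectra), and selective attrition at follow-up
(retention is random). The follow-up wave itself is a latent-stability
emulation (autocorrelation 0.7, +1.75 years, ~70% retention), suitable
for exercising the replication and longitudinal-prediction model
patterns, not for calibrating retest statistics.

## Problem sizes and reproducibility

The packaged recovery simulations use 200 replicate cohorts of n = 258
(moderated regression) and n = 250 (moderated mediation), which puts
the Monte-Carlo standard error of the mean recovered coefficient near
0.003 — an order of magnitude below the 0.02 agreement band used in the
tests. Oracle checks use 50,000 simulated trials (stochastic) and 1,000
random parameter sets (algebraic identity). Pipeline demonstrations in
the test suite run on 45–70 participant cohorts with reduced bootstrap
counts; all inferential defaults remain B = 5000. Every stochastic
function takes an explicit seed, the cohort generator regenerates
bit-identically from `(config, seed)`, and the pipeline records stage
order, exclusion tallies and seeds in its manifest.

## Known limitations

The EZ decomposition ignores inter-trial variability parameters and
starting-point bias; tasks with strong fast-guess contamination violate
it. The multiplicative form of the T2 correction is a fidelity choice,
not the physical convention. The pairwise-mean connectivity score and
the percentile bootstrap are each one of two defensible conventions
(network-summary scores; bias-corrected intervals), chosen for
transparency and reproducibility. The SNARC effect appears in the
supplementary family enumeration (its multiplicity is a design fact)
but no behavioral construction for it is implemented.
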