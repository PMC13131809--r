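---
title: "Models and analyses for trans-saccadic visual-stability judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and analyses for trans-saccadic visual-stability judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdprior)
```

## The task and the scientific question

In a saccadic suppression of displacement (SSD) experiment a subject
fixates, makes an instructed saccade, and reports whether a peripheral
probe jumped during the movement. The probability that the probe jumps is
cued trial-by-trial (priors of 0.2 or 0.8, plus a neutral 0.5 used only for
model fitting), and two kinds of sensory uncertainty are manipulated on
interleaved trials: *saccade-driven* noise (an intervening saccade versus
steady fixation) and external *image* noise (the width of the Gaussian
probe: 0.5, 1.25, and 2 degrees — 1.75 as an alternative high level for one
subject). The with-saccade, low-image-noise condition is shared between the
two manipulations and serves as the **common condition**; **prior use** is
the difference in "jumped" report rates between the high and low prior
cues, averaged over displacements of 0–2 degrees, where both cue conditions
have appreciable trial mass.

A Bayesian observer should lean on the prior more whenever sensory evidence
gets worse, regardless of the noise source. The empirical pattern is more
interesting: prior use grows with saccade-driven noise but *shrinks* with
image noise ("anti-Bayesian"). This package implements the two models whose
combination reproduces that pattern, the maximum-likelihood machinery to
fit it to binary session data, the firing-rate analyses that ask which
pattern a neural population follows, and synthetic-data generators so that
every analysis runs end to end with known ground truth.

## The Bayesian ideal observer

The observer sees a percept $\hat{x} \sim N(x, \sigma_t^2)$ of the true
displacement $x$ and knows the two hypothesis distributions
$x \mid J \sim N(0, \sigma_J^2)$ and
$x \mid \neg J \sim N(0, \sigma_{\neg J}^2)$. Reporting "jumped" whenever
the posterior favors a jump reduces to a threshold on $\hat{x}^2$:

$$\hat{x}^2 \; > \; \hat{x}_C^2 \;=\;
\frac{\log\frac{\sigma_J^2 + \sigma_t^2}{\sigma_{\neg J}^2 + \sigma_t^2}
      \; + \; 2 \log\frac{1 - P(J)}{P(J)}}
     {\frac{1}{\sigma_{\neg J}^2 + \sigma_t^2} -
      \frac{1}{\sigma_J^2 + \sigma_t^2}}$$

Because $\hat{x}^2/\sigma_t^2$ is non-central chi-square with one degree of
freedom and non-centrality $x^2/\sigma_t^2$, the report probability is the
upper tail of that distribution above $\hat{x}_C^2/\sigma_t^2$
(`jump_probability()`). Numerical notes:

* A strong jump prior can make $\hat{x}_C^2$ negative. Every percept then
  exceeds the criterion and the probability is exactly 1; the package
  returns 1 rather than evaluating the distribution at a negative bound.
* For one degree of freedom the non-central tail has the exact closed form
  $\Phi(\delta - \sqrt{c}) + \Phi(-\delta - \sqrt{c})$ with
  $\delta = |x|/\sigma_t$ and $c = \hat{x}_C^2/\sigma_t^2$. The compiled
  fitting kernel uses this form (the series evaluation of the distribution
  function becomes the bottleneck at non-centralities in the thousands);
  the R path uses `pchisq(..., ncp)` and the two are cross-checked to
  machine precision in the tests, alongside a Monte-Carlo oracle.
* $\sigma_J = \sigma_{\neg J}$ makes the criterion undefined (zero
  denominator) and is rejected at parameter construction; the constraint
  $\sigma_{\neg J} < \sigma_J$ is also enforced inside the likelihood,
  because the criterion silently changes sense when the widths invert.

Saccade-driven noise is modeled as a wider internal non-jump distribution
(it takes a larger displacement to be noticed across a saccade); image
noise widens $\sigma_t$. With the illustration parameters
($\sigma_J = 5$; $\sigma_{\neg J} = 0.1$ without and $0.75$ with a saccade;
$\sigma_t \in \{0.4, 0.65, 0.9\}$) prior use is monotone nondecreasing
across the four conditions — the purely Bayesian prediction.

## The category-learning network

The alternative account is a two-layer perceptron-like network that learns
to map displacements onto "jump"/"no jump" categories, with a separate
input bank per prior cue. Displacement magnitude is encoded by 75 input
units tiling 0–7.5 degrees in 0.1-degree bins; activation is a Gaussian
profile over bin centers, truncated to the range and renormalized so the
total input activation is always 1 (`encode_input()`). Output activations
are weighted sums, normalized so the two outputs sum to 1, and weights are
updated by the error rule
$\Delta w_{ij} = \beta \, a_i (d_j - o_j)$ with desired outputs $(1,0)$ on
jump trials and $(0,1)$ otherwise.

Design choices where the construction was open:

* **Magnitude coding.** The grid is nonnegative, so the network encodes
  $|x|$; both displacement distributions are centered on zero, making all
  model computation symmetric (signs are retained in stored trial tables).
* **Initialization.** All weights start at the same positive constant
  (0.5). Any symmetric constant gives the identical first output (0.5,
  0.5), and the normalization makes the subsequent trajectory invariant to
  the constant's scale; the constant is a constructor argument.
* **Unclamped learning.** The update rule is applied without clamping, so
  weights may go negative for rarely visited bins and the normalized
  output can transiently leave $[0,1]$ there. Consumers that need a
  probability (response sampling, the combined output) clamp at use; the
  raw forward pass is left untouched so the property is visible in tests.
* **Evaluate-then-renormalize truncation**, with the Gaussian evaluated at
  bin centers rather than integrated over bins; at bin width 0.1 degrees
  the difference is negligible for encoding widths of 0.1 degrees and up.

The mechanism behind the anti-Bayesian pattern is *blur at test time*:
after training at low image noise, wider test-time encoding mixes bins
across the learned category boundary, so the two priors' learned
associations collapse toward each other — the prior gap in the output,
averaged over 0–2 degrees, decreases as encoding noise rises through 0.1,
1, and 2 degrees.

## The combined model and the simulation protocol

The combined observer is the convex mixture
$O_C = w_B O_B + w_P O_P$, $w_B + w_P = 1$, with saccade-driven noise
inside the Bayesian component (non-jump width 0.5 degrees without, 1.0
degree with a saccade; Bayesian image noise pinned at 0.1 degrees in all
conditions) and image noise inside the perceptron (encoding widths 0.1, 1,
2 degrees). A simulation (`simulate_experiment()`) runs 2000 trials: the
first 1000 train the network in the common condition only (learning rate
0.5), the remaining 1000 interleave the four noise conditions with frozen
weights. True displacements are drawn from the task distributions
($N(0, 2.5^2)$ for jumps, $N(0, 0.2^2)$ otherwise), binary responses are
Bernoulli draws from $O_C$, and $O_C$ itself is retained per trial for
deterministic checks. The 2000-trial budget is split evenly and randomly
over the test cells, and trial types are i.i.d. categorical draws, the
simplest reading of uniformly interleaved trial types. At $w_B = 0.1$,
$w_P = 0.9$ the mean prior use over seeded simulations rises from the
no-saccade to the common condition and falls monotonically across image
noise — the inverted-V that matches behavior. Two parameter sets coexist
deliberately: the pure-Bayesian illustration uses $\sigma_J = 5$ while the
combined protocol uses $\sigma_J = 2.5$; both are kept as configurations
since they serve different figures.

## Fitting the combined model to sessions

`fit_combined()` estimates 12 free parameters by maximum likelihood on the
binary responses: image noise $\sigma_t$ and non-jump width
$\sigma_{\neg J}$ for each of the four conditions, the jump width
$\sigma_J$, and the three priors. The perceptron component is not retrained
during fitting; each prior's input-to-jump association is set to the value
of a psychometric curve fitted to that prior's trials (cumulative Gaussian
in $|x|$ with guess and lapse rates — a standard monotone choice for yes/no
detection), evaluated at the bin centers, and the condition's $\sigma_t$
then blurs it through the population code. Two decisions deserve emphasis:

* **Association curves come from the low-image-noise conditions only.**
  Fitting them to all conditions pooled would bake the condition-specific
  blur into the association and then blur it again at prediction time;
  measured on synthetic sessions this double-counting costs roughly 90
  log-likelihood units at the generating parameters and wrecks parameter
  interpretability.
* **The mixture weight is fixed** at $w_B = 0.1$ (argument-overridable),
  since the free-parameter list does not include it.

Optimization is bounded L-BFGS-B on log-$\sigma$/logit-prior scale
($\sigma \in [0.01, 10]$, priors $\in [0.01, 0.99]$), from one canonical
start at protocol defaults plus seeded random restarts (eight starts in
total by default), followed by a Nelder-Mead polish constrained to the same
box. The likelihood kernel is compiled; a pure-R reference path is kept and
the two are compared in the tests.

**Identifiability caveat.** With $w_B = 0.1$ the three priors influence
only a tenth of the predicted probability, through near-step changes of the
Bayesian component. On 2000-trial synthetic sessions the likelihood
surface around the priors is shallow (often only a few log-likelihood units
across the admissible range), and the global optimum can sit a tenth or
more away from the generating value — verified by polishing from the truth,
which lands in a *worse* point than the fitted optimum. Median fitted
priors across ten sessions do recover the cued ordering (0.2 < 0.5 < 0.8)
and the fitted image-noise widths recover their generating rank order, but
individual-session prior estimates should be read with that caution; the
corresponding recovery test records the tight error bound as currently not
met rather than relaxing it.

## Synthetic neurons and the dissociation analyses

`gen_neuron()` produces per-trial inhomogeneous-Poisson spike trains
aligned to fixation acquisition and to the reafferent event (the
post-saccadic arrival of the probe in the receptive field). The baseline
rate (20 spikes/s) applies everywhere; inside the 0–800 ms reafferent
window the rate adds a displacement term (1 spike/s per degree, capped at
5 degrees, echoing displacement-tuned visual responses) and a prior term of
$\pm$ half the modulation depth (5 spikes/s at default). The prior term is
scaled per condition by the neuron's pattern:

* `bayesian` — gain 0.3 without a saccade, 1 elsewhere;
* `anti_bayesian` — gain 1, 1, 0.6, 0.2 across no-saccade/common/medium/
  high: **linear in the image-noise level**, so that under the regression's
  numeric level coding the collapse loads entirely on the prior-by-image
  interaction (a convex profile would leak curvature into the
  prior-by-saccade term through the lone no-saccade cell);
* `prior_only` — gain 1 everywhere;
* `output_mirroring` — gains equal to the session's behavioral prior use
  normalized to the common condition.

Prior modulation starts at the reafferent event and is over by +800 ms;
the fixation period carries none, matching the observation that the prior
signal emerges only once sensory evidence is available. Poisson spiking is
the simplest count model consistent with rate-based analyses.

Behavioral sessions can be generated two ways: from the combined model
(the mechanistic route), or from a logistic model with explicit
interaction strengths (`ground_truth(behavioral_model = "logistic")`).
The logistic route is the generative model for the mixed-effects recovery
experiments, because there the injected coefficients are exactly the
estimands. Its default coefficients echo the scale of a combined-model
cohort's fitted coefficients, with a prior-by-saccade strength (+1.4 on
the log-odds scale) chosen so a cohort-scale recovery experiment has high
power, and a prior-by-image strength of −1.2 whose implied prior-use
profile across conditions (roughly 0.29, 1, 0.59, 0.12 after normalizing
to the common condition) also gives the output-mirroring pattern a
signature distinct from the anti-Bayesian one.

The firing-rate analyses mirror standard practice: pooled z-score
normalization in 20 ms bins with Gaussian smoothing (interpreted as
kernel SD 20 ms, truncated at three SDs) for visualization series only;
epoch rates (fixation 0–250 ms, reafferent 0–800 ms) feeding all
statistics; high-versus-low-prior contrasts with the rank-sum test and the
effect size $z/\sqrt{n}$, signed positive when high-prior rates are
larger. The text of the source protocol names both the rank-sum and the
signed-rank test for this contrast; the samples are independent trial
groups, so rank-sum is implemented. The per-neuron screen corrects for
two epochs ($\alpha = 0.025$) and the 15 sliding 100 ms bins (50 ms steps
over 0–800 ms) for 15 comparisons ($\alpha = 0.025/15$). Per-condition
values are normalized to the common condition as a ratio (with a floor of
0.01 on the common value's magnitude; sessions below it are flagged out),
and neuronal versus behavioral prior use is compared by Pearson
correlation across sessions.

One structural fact about the regression design is worth knowing: with a
single no-saccade cell (which exists only at low image noise), the
image-by-saccade product is an exact linear combination of the intercept,
saccade, and image columns for *any* numeric coding. That fixed effect is
therefore unidentifiable by design; the formula keeps the printed term,
the design object flags it, and the mixed-model machinery drops it at fit
time. The two prior interactions — the terms the Bayesian/anti-Bayesian
dissociation rests on — are unaffected. Image noise enters as the numeric
level 1/2/3, the prior as a 0/1 indicator of the high cue, and 0.5-prior
trials are excluded from the contrast. The behavioral model is a binomial
mixed model grouped by session, the neural model a linear one grouped by
neuron; both carry random intercepts and (uncorrelated) slopes for the
four main effects by default — slopes for all seven terms are available
but routinely singular at desk-scale cohort sizes. Linear-model p-values
use the Wald normal approximation, appropriate at these row counts.

`classify_pattern()` reduces a neuron's per-condition effects to two
common-normalized features — the no-saccade ratio and the mean
medium/high-image ratio — and applies a 0.3 threshold on their departure
from 1 (both changed: output-mirroring; saccade only: Bayesian; image
only: anti-Bayesian; neither: prior-only; ratios far outside any
signature's range: unclassified).

## What the synthetic world does and does not establish

The generators reproduce the protocol's condition algebra, the displacement
mixtures, Poisson spiking with programmed condition gains, and behavioral
patterns with known interaction structure. They do not emulate real
recordings' firing-rate heterogeneity, burstiness and autocorrelation,
session-to-session electrode differences, eye-movement kinematics, or
reaction-time structure (a lognormal response latency with median 611 ms is
drawn only to place the response event). A green dissociation-recovery test
therefore establishes that the analysis pipeline recovers injected effects
of realistic size through the full alignment/epoch/regression chain — not
that any particular brain area behaves this way. Inclusion filters (10
valid trials per condition; 5 for displacement-zero controls) are the
stated eligibility rules and are applied by `filter_sessions()`.

## Reproducibility

Every stochastic stage takes an explicit integer seed; cohorts consume a
single RNG stream so different cohort seeds give independent cohorts.
`run_pipeline()` persists its configuration with a content hash into the
output directory and stamps every table with that hash; rerunning with the
same configuration and seed reproduces every numeric output byte for byte.
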