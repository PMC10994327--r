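---
title: "Modelling reciprocity under hidden endowments: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reciprocity under hidden endowments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetg)
```

## The task and the scientific question

In the Trust Game an Investor receives an endowment $E$, transfers an
investment $I \le E$ to a Trustee, the transfer is multiplied by $M = 4$,
and the Trustee decides how much of the pot $I \times M$ to return. The
ratio $I/E$ — *bestowed trust* — is the main driver of reciprocation. In
the hidden-endowment variant the Trustee is not shown $E$; instead three
candidate endowments are displayed, whose implied trust ratios fall one
per band: low (0.05–0.25), medium (0.35–0.50) and high (0.70–1.00). The
question the analysis answers is *how people impute the hidden bestowed
trust* — their ambiguity-resolution strategy — from nothing but their
observed returns.

A session is 120 trials: 40 standard (unambiguous) rounds followed by 80
hidden-endowment rounds in three fixed blocks ($I = 2$ with candidates
$\{2,5,10\}$; $I \in \{4,5\}$ with $\{5,10,20\}$; $I \in \{7,\dots,10\}$
with $\{10,20,50\}$). The unambiguous block always comes first so that
every participant carries the same prior experience into the ambiguous
block; it also calibrates the reciprocity model per participant.

## The reciprocity (inequity-aversion) model

A Trustee with fairness norm $\Delta \in [0,1]$ returns

$$R_2 = \max\!\big(0,\; (E - I + I M)\,\Delta - (E - I)\big),$$

i.e. the share of all money in the game they deem fair for the Investor
to end with, minus what the Investor already has, floored at zero
(returns cannot be negative). $\Delta = 0$ returns nothing, $\Delta = 0.5$
equalizes final payouts, $\Delta = 1$ returns the whole pot. `fit_delta()`
estimates $\Delta$ per participant on the unambiguous trials by grid
search (101 points by default) on the residual sum of squares in returned
*amounts* — the scale on which the model is stated; a proportion option
exists. Minimizing SSE is identical to minimizing the Gaussian deviance
with the maximum-likelihood plug-in scale $\hat\sigma^2 = SSE/n$, which is
also the convention that makes the SSE-based AIC below coherent.

## Reverse inference of the hidden endowment

For $R_2 > 0$ the forward model is linear in $E$ and inverts exactly at
$M = 4$:

$$E = \frac{R_2 - I - 3 I \Delta}{\Delta - 1}.$$

A widely circulated shortcut form of this inverse omits the $-I$ term in
the numerator and therefore differs from the exact inverse by
$I/(\Delta-1)$ at every input; it is kept behind
`method = "uncorrected"` purely so results under either convention can be
compared. The default is the exact inverse, whose round trip through the
forward model is an acceptance-tested invariant (recovery to $10^{-9}$
over the whole printed design).

Three practical details:

* **Clamping.** The inferred endowment is clamped to the candidate range:
  values outside the displayed candidates are impossible in the task. Only
  the upper clamp at $E_{max}$ is part of the classical formula; the lower
  clamp is this package's choice.
* **Censoring.** A returned amount of 0 makes the $\max(0,\cdot)$ floor
  bind, so $E$ is only boundable: every candidate above
  $I(1+3\Delta)/(1-\Delta)$ predicts exactly 0. Such trials are flagged
  `censored` and assigned the largest candidate — the one most consistent
  with a zero return — and retained for strategy fitting.
* **Snapping.** The candidate a participant is taken to have acted on is
  the one whose *predicted return* is nearest the observed return (ties
  toward the larger endowment, consistent with the censoring rule). Away
  from the zero floor the forward model is linear in $E$, so this is
  identical to snapping to the candidate nearest the inferred endowment;
  at the floor it treats returns of $0$ and $\varepsilon$ consistently,
  where nearest-endowment snapping would jump discontinuously between
  candidates. This continuity matters: low-$\Delta$ agents produce many
  near-zero returns, and the discontinuous rule systematically
  mis-assigned half of them, ruining recovery of the lowest-assumed-trust
  strategy.

## The ambiguity-resolution-strategy (ARS) model

Candidate endowments are scored by

$$p_2(E) = \big(1 - \lvert I/E - \tau\rvert\big)(1-\psi)
         + \big(1 - \lvert I/E - I/10\rvert\big)\,\psi,$$

a mixture of (a) how well the implied trust ratio matches the
participant's default assumed trustingness $\tau$ and (b) how well it
matches a magnitude heuristic that reads the investment as a share of the
modal endowment 10. Four archetypes span the corners: LAT
($\tau=0$), MT ($\tau=0.5$), HAT ($\tau=1$) — all with $\psi=0$ — and HR
($\psi=1$, $\tau$ inert). An agent resolves ambiguity by taking the
$p_2$-argmax candidate (ties toward the smaller endowment; a softmax
temperature is deliberately out of scope).

### Fitting construction

`fit_ars_grid()` enumerates the full $101 \times 101$ grid on
$(\tau,\psi) \in [0,1]^2$ (10 201 points) and minimizes deviance, with the
same plug-in-scale Gaussian convention as above, so the minimizer is the
SSE minimizer. What the per-trial residual should be is the one genuinely
open methodological question, and the package's answer is deliberate:

* The *naive* residual — the preference gap
  $p_2(\text{model's candidate}) - p_2(\text{observed candidate})$ — is
  degenerate as an estimating objective. Trials where the model's
  preferred candidate matches the observed one contribute exactly zero
  across the entire matching parameter plateau, so the grid minimum is
  governed solely by the deviating trials; their gap vanishes at the
  preference *crossover* between two candidates, so the estimate is
  attracted to decision boundaries ($\hat\tau \approx 0.70$ for
  highest-assumed-trust agents, $\approx 0.30$ for lowest-assumed-trust
  agents) the moment any trial deviates. Under midpoint classification
  thresholds, archetype agents are then misclassified at *any* positive
  noise level. This construction is retained as `loss = "preference"`
  for audit.
* The default residual (`loss = "choice"`) compares predicted and
  observed preference at the level of the implied candidate choice:
  residual 1 when the model's preferred candidate is not the observed
  one, 0 otherwise, so SSE counts mismatched trials. Eq-style preferences
  still drive everything (they define each grid point's preferred
  candidate); the objective now rewards parameters that reproduce the
  observed resolutions most often. A perfectly strategy-consistent
  participant yields a zero-SSE plateau that contains the generating
  archetype, and noisy agents are recovered because the per-trial-type
  majority pattern decides the fit.

### Ties

Zero-SSE plateaus are a structural feature, not an edge case, so the
tie-break is part of the estimator: among deviance-minimizing grid
points, an archetype point lying on the plateau is preferred (LAT, MT,
HAT, then HR — ascending $(\psi,\tau)$ order); otherwise the tie breaks
to the smallest $\psi$, then the smallest $\tau$. This makes noiseless
archetype recovery exact (`tau_hat` 0.5 for a modal-trust agent, `psi_hat`
1 for a heuristic agent) — a plain smallest-coordinate rule would return
the plateau edge (e.g. $\hat\tau = 0.38$ for modal trust, $0.71$ for
highest assumed trust) and misclassify.

## Model comparison and classification

Models are scored with the SSE form of the Akaike Information Criterion,
$AIC = n\,\ln(SSE/n) + 2k$, with $k = 2$ for the ARS model and $k = 0$
for the fixed archetypes. Because the grid contains all four archetype
points, the ARS SSE can never exceed an archetype's, and ARS AIC can
never exceed an archetype AIC by more than the $2k = 4$ penalty — both
are enforced as tests. A perfect fit ($SSE = 0$) sends AIC to $-\infty$;
such participants are excluded from paired tests (and from the mean-AIC
summary), the package's mechanical version of excluding perfectly
predicted participants.

Cohort comparisons are uncorrected one-tailed paired t-tests of the ARS
model against each archetype, in the direction "ARS has lower AIC", with
paired Cohen's $d = \lvert\bar d\rvert / s_d$. The lack of correction is
deliberate and inherited from the analysis being reproduced: one
archetype is expected to fit best, so the ARS model is effectively tested
against that single competitor. The paired (not pooled) $d$ convention is
an assumption, documented here because it is not derivable from the
reproduced analysis.

Classification reads the fitted $(\hat\tau,\hat\psi)$ through thresholds:
$\hat\psi > 0.5$ is Heuristic; otherwise $\hat\tau < 0.25$ is Lowest
Assumed Trust, $\hat\tau > 0.75$ Highest Assumed Trust, Modal Trust in
between. Only the archetypes themselves ("close to 0 / 0.5 / 1") are
pinned by the verbal rule, so the thresholds are interval midpoints,
exposed in the configuration.

## The synthetic world

`simulate_cohort()` generates trustees with known $(\Delta, \tau, \psi)$
and additive Gaussian response noise of scale `noise_sd` $\times$ pot,
*clipped* to $[0, \text{pot}]$. Clipping (rather than a renormalized
truncated density) is intentional: a response slider produces exact zero
returns, and the censoring machinery above exists precisely for them.
Defaults, fixed once:

* **Cohort mixture**: 24 modal-trust, 8 lowest-assumed-trust and 2
  highest-assumed-trust agents — a 34-participant cohort matching the
  71% / 23% / 6% prevalence pattern the task was designed around.
* **Fairness norms**: drawn per agent uniformly from $[0.3, 0.7]$
  (rounded to the 0.01 grid) — equal-split-centred norms typical of
  trust-game trustees.
* **Noise**: `noise_sd = 0.05` of the pot.
* **Unambiguous trial table**: the exact original condition list is not
  publicly available, so the shipped default emulates its stated
  constraints (modal endowment 10, modal transfer $E/2$, all three trust
  bands present over endowments 5/10/20); it is a frequency-table
  configuration and can be replaced wholesale by the user.

What the generator does *not* emulate: within-session strategy switching
(one fixed strategy per agent, matching the default-strategy framing),
Investor behaviour (scripted by design), learning across trials
(conditions are blocked precisely to exclude it), slider granularity
(returns are continuous) and any real-data heteroscedasticity. A green
recovery test therefore establishes that *the estimator inverts its own
generative assumptions* at task-realistic noise — not that human data
satisfy those assumptions.

## Numerical choices and degenerate inputs

* Grid resolutions: 101 points per axis everywhere, mirroring the
  10 201-point parameter space; SSE ties on the $\Delta$ grid break to the
  smallest value.
* $\hat\Delta = 1$ makes endowment inference singular (every endowment
  predicts a full-pot return); affected participants are emitted with
  missing inferences and a warning rather than an error.
* Zero-variance return sequences make $R^2$ undefined; it is returned as
  `NA` with a warning.
* $SSE \le 10^{-12}$ is treated as a perfect fit throughout (residuals
  are exact zeros in the relevant cases).
* Trust bands use closed intervals with a $10^{-9}$ tolerance; ratios in
  the gaps are labelled `unbanded`, never coerced.
* Per-participant RNG substreams are keyed by participant index, so
  enlarging a cohort never reshuffles existing participants' data.

## Known limitations

* The preference-gap objective is exposed but unsuitable for estimation
  (see above); it exists for audit only.
* Strategy identification is weak for low-$\Delta$ lowest-assumed-trust
  agents, whose predicted returns are zero on many trials: a zero return
  carries only an inequality's worth of information about the hidden
  endowment. The censoring-aware snapping recovers most of this, but it
  is the structurally hardest corner of the design.
* The mixed-effects condition analysis of the original task is out of
  scope; the report prints descriptive condition means so the qualitative
  medium-vs-ambiguous pattern can be inspected on synthetic data.
* Alternative division norms (e.g. norms over the multiplied investment
  alone) are not modelled; the reciprocity model is an extension point.
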