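---
title: "Methods: adaptive coherence thresholding, the group plan, and rank-based overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive coherence thresholding, the group plan, and rank-based overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpmotion)
```

This vignette documents the models implemented in `mlpmotion`, the
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic generators do and do not emulate.

## The psychometric model and the adaptive procedure

Motion-direction discrimination in an eight-alternative forced-choice
(8AFC) task is modelled by a logistic psychometric function of motion
coherence $x$ (percent, 0–100):

$$p(x) = \gamma + \frac{1-\gamma}{1 + e^{-\beta (x - \alpha)}}.$$

The guess rate is fixed at $\gamma = 1/8 = 0.125$ (8AFC chance), the
slope at $\beta = 1/2$ per percentage point of coherence, and only the
midpoint $\alpha$ varies. Note the parenthesisation: this is the standard
logistic with asymptotes $\gamma$ and $1$ — the only form in which the
lower asymptote equals the 8AFC chance level — and it gives
$p(\alpha) = \gamma + (1-\gamma)/2 = 0.5625$.

The maximum-likelihood procedure (MLP) is *selection over a fixed grid*,
not curve fitting. The grid holds 150 candidate functions differing only
in $\alpha$, spaced linearly so that their 70 %-accuracy levels
$x_{70} = \alpha + \tfrac{1}{\beta}\ln\tfrac{p-\gamma}{1-p}\big|_{p=0.7}
= \alpha + 1.3012$ span exactly $[0, 100]$ — any presentable coherence
can be some hypothesis's 70 % level. After each trial the Bernoulli
log-likelihood of the full response history is evaluated for every grid
member and the maximiser is selected; the next stimulus of that track is
placed at its 70 % level. Likelihood along the grid is not assumed
unimodal: the argmax is a full scan (cached incrementally, which is
algebraically identical because the grid is fixed and per-trial terms
are additive; the test suite verifies exact agreement with brute-force
recomputation). Exact likelihood ties are broken toward the lowest
midpoint, deterministically.

Decisions taken where the procedure description was open:

* **No lapse or false-alarm hypotheses.** Some MLP variants track a
  family of false-alarm rates; here the grid varies only in midpoint.
  Simulated observers can still *have* a lapse rate, which lets the
  tests measure how the midpoint-only selection copes with it.
* **First trial at 100 % coherence** (maximally visible), configurable
  via `session_config(initial_level = )`.
* **Interleaving** of the two hemifield tracks is a seeded random
  shuffle of 32 left + 32 right trials within each of five blocks. One
  session seed derives three independent streams (left responses, right
  responses, interleave order), so a track's likelihood trajectory is a
  function of its own history only.
* **Threshold read-out** is the 70 % level of the finally selected
  hypothesis, not the last presented level (both are logged). The
  default thresholds across all five blocks combined
  (`threshold_mode = "all-blocks"`); the per-block variant, which resets
  the grid each block and averages five read-outs, is provided for
  comparison with the earlier single-block-MLP design.
* **Timeouts** are treated as incorrect responses in simulation.

## The RDK stimulus generator

Defaults follow the stimulus specification: 150 dots in an 8-deg
circular aperture (≈ 3 dots/deg²), speed 13.3 deg/s, 47 ms lifetime,
106 ms duration at 60 Hz. Derived discrete quantities: 6 frames per
stimulus (`round(0.106 × 60)`), a per-frame step of 13.3/60 = 0.2217 deg,
and a lifetime of `floor(47/16.7)` = 2 coherent displacement steps, so
coherent travel is bounded by speed × lifetime ≈ 0.625 deg (short motion
streaks). Dots exceeding their lifetime or exiting the aperture reappear
at a uniform random position, keeping the per-frame dot count — and
hence density — exactly constant. Initial dot ages are uniformly
staggered so replacements are spread asynchronously over frames.

The phrase "equal probability of being selected as a signal dot or noise
dot" cannot literally mean $P = 0.5$ (that would pin coherence at 50 %);
it is read as the standard anti-streak rule: signal identity is redrawn
independently every frame with $P(\text{signal}) = \text{coherence}/100$.
That is the default (`signal_rule = "different"`); the fixed-identity
alternative is available as `signal_rule = "same"` but is not the
default, since per-frame reassignment is what "minimize motion streaks"
implies.

## The group-level statistical plan

The design is three within-subject stimulation conditions (active
hf-tRNS over left hMT+, sham over hMT+, active over the forehead) ×
two hemifields, one session per condition, condition order
counterbalanced. The registered tests are three *one-tailed* paired
t-tests at α = 0.02 on ipsilateral − contralateral difference scores
(positive difference = contralateral facilitation): (1) the difference
itself under active hMT+ stimulation, (2) its excess over sham, (3) its
excess over the forehead control. The exploratory ANOVA first averages
the two hemifields per participant and fits the one-way within-subject
decomposition, $F$ on $(2, 2(n-1))$ df, no sphericity correction. SEMs
use the $n-1$ sample SD. No multiplicity correction beyond the per-test
α = 0.02 is applied; direction conventions are explicit function
arguments, never implicit.

**Power analysis.** The planned effect size is
$d = (10.51 - 2.59)/14.8 = 0.5351$ (mean active minus sham
difference-of-differences over the difference SD). `required_n()`
searches for the smallest $n$ with
$1 - F_{n-1,\,d\sqrt n}(t_{1-\alpha,\,n-1}) \ge 0.9$ using the exact
noncentral-t distribution. The boundary is genuinely tight — power is
0.89996 at $n = 41$ and 0.9072 at $n = 42$ — which is why the exact
distribution, with the unrounded $d$, is used rather than a normal
approximation. The test suite brackets the analytic power at both $n$
with a 10,000-replicate simulation.

## The cohort generator

`generate_cohort()` draws
$y_{pch} = \mu + b_p + \delta (s_{pc} - 1) + \tau_{ch} +
\varepsilon_{pch}$ with $b_p \sim N(0, \sigma_b^2)$ and
$\varepsilon \sim N(0, \sigma_e^2)$, full counterbalancing of the six
condition orders (42 participants → 7 per order), and truncation of
thresholds to $[0, 100]$ (truncation count recorded as an attribute).
Default calibration, chosen once:

* $\sigma_e = 14.8/\sqrt 2 = 10.47\,\%$, so the within-condition
  ipsi − contra difference score has SD
  $\sqrt{2}\sigma_e = 14.8\,\%$ — the SD the sampling plan was powered
  on. The study reports cell SEMs rather than variance components, so
  the partition between participant and residual variance is free; it
  defaults to an even split ($\sigma_b = \sigma_e$). Participant effects
  cancel from all difference scores, so this choice does not affect the
  registered tests.
* Grand mean 71 % coherence, near the observed cell means (70.7–71.9 %).
* Learning drift $\delta = -2\,\%$ per session: a modest practice
  improvement, linear in session order because the design only
  stipulates that counterbalancing accounts for learning. It cancels
  from ipsi − contra scores and, by counterbalancing, from expected
  condition contrasts.
* The effect of interest is injected as
  $\tau_{\text{hMT active, contra}} = -7.92\,\%$ (contralateral
  facilitation), which makes the hypothesis-1 contrast an exact
  $d = 7.92/14.8 = 0.535$ at the difference-score level — the simulated
  power at $n = 42$ then matches the analytic 0.907 (checked over 2,000
  cohorts). The difference-of-differences contrast has SD
  $2\sigma_e = 20.9\,\%$ under independent residuals, so matching $d$
  on that contrast instead would require a different $\sigma_e$; the
  calibration ties the generator to the power analysis through the
  contrast the plan's SD refers to.

What the generator does *not* emulate: session-to-session autocorrelated
noise, floor/ceiling clustering of poor performers, non-normal residuals,
and any true stimulation effect heterogeneity across participants.
Passing calibration and power tests therefore show that the *pipeline*
is correct under the stated model, not that real data meet its
assumptions.

## The overlap statistic

Both volumes are rank-transformed within the shared mask (descending,
average ranks for ties — invariant to any strictly monotone rescaling of
either map), discretised into `bins` equal-count bins (default 10), and
the mutual information of the joint bin histogram is computed in natural
log units and normalised by $\min(H(A), H(B))$, the maximum attainable
for the binned marginals:

$$\text{MI\%} = 100 \cdot \frac{H(A) + H(B) - H(A,B)}{\min(H(A), H(B))}.$$

With equal-count bins and no ties the normaliser is $\log(\text{bins})$;
tie structure and the in-mask voxel count make the attainable maximum
specific to each volume pair, which is why the statistic is reported as
a participant-specific percentage. Identical maps give exactly 100 %;
independent maps give a small positive finite-sample bias of order
$(\text{bins}-1)^2 / (2N)$ nats — about 0.2 % of the normaliser at
$N = 10^4$ voxels and 10 bins — kept below 5 % in the property tests. Sensitivity to the bin count (5/10/20) can be examined by passing
`bins =`; the default 10 balances histogram occupancy against resolution
at typical in-mask voxel counts.

The synthetic volume pairs place a principal Gaussian activation blob
(plus weaker secondaries and low-amplitude noise) in an ellipsoidal
mask, and an exponential-decay e-field whose source interpolates from an
*independently drawn* mask-edge point (overlap 0) to the principal blob
(overlap 1). The independent anchor matters: anchoring the zero-overlap
source at the blob's antipode would make the two fields strongly
*anti*-aligned, and mutual information — being sign-agnostic — would
score that as high overlap, destroying monotonicity of MI in the overlap
dial. With the independent anchor, mean MI rises monotonically with
overlap strength (verified over 50 seeds in the tests).

Supplementary measures: `voxel_rank_correlation()` (Pearson correlation
of the two rank fields, i.e. a Spearman-type correlation of the raw
values), `correlate_overlap_behavior()` (Pearson r and two-sided p
between per-participant MI and behavioural modulation), and
`mni_distance()` (Euclidean distance between MNI coordinates in mm).

## Numerical choices

* Incorrect-response log-likelihood terms use `log1p(-p)`;
  likelihoods stay finite for all grid members because $\gamma > 0$ and
  $p < 1$ at any finite level.
* `which.max` on the cached log-likelihood vector implements the
  lowest-midpoint tie-break (first maximum on an ascending-α grid).
* Presented levels and threshold read-outs are clipped to $[0, 100]$;
  with the default grid and $p = 0.70$ the read-out lands in
  $[0, 100]$ by construction.
* Rank bins are assigned by `ceiling(bins · r / n)`, which yields exact
  equal counts whenever `n` is a multiple of `bins` and near-equal
  otherwise.
* `required_n()` is an ascending integer search; power is monotone
  nondecreasing in $n$, so the first hit is the minimum.
* Seeds: every stochastic entry point takes an explicit integer seed;
  a session seed derives its three sub-streams by drawing stream seeds
  from the seeded RNG.

## Problem sizes used in the test suite

Simulation-based checks run at sizes chosen to give stable Monte-Carlo
estimates while keeping the full suite in the low minutes on one CPU:
1,000 random histories for the selection-vs-brute-force equivalence;
500 simulated tracks per trial count (20/40/80/160) for threshold
recovery; 2,000 synthetic cohorts each for type-I calibration and for
power at the planned effect; 50 seeds per overlap level at 16³ voxels;
200 seeds for the realised-coherence check (180,000 Bernoulli labels).

## Known limitations

* The MLP models no lapse hypotheses, so a lapsing observer biases the
  selected midpoint upward slightly; the recovery tests quantify this.
* The RDK generator models dot kinematics only — no luminance, display
  timing, or rendering; the realised-coherence check concerns labels
  and displacements, not photometric output.
* The ANOVA reports the uncorrected within-subject F; with three
  conditions, sphericity violations are possible and no
  Greenhouse–Geisser correction is applied (matching the registered
  analysis).
* The overlap percentage depends on the bin count; comparisons should
  hold `bins` fixed across participants.
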