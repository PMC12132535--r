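# mlpmotion

Adaptive motion-coherence thresholding and the statistical pipeline of a
within-subject brain-stimulation study of global motion perception.

The package is for visual psychophysicists and non-invasive brain
stimulation researchers who need (i) a tested implementation of the
maximum-likelihood procedure (MLP) for adaptive coherence thresholding,
(ii) the group-level analysis of a three-condition (active / sham /
control-site) hemifield design, and (iii) a rank-based mutual-information
measure of spatial overlap between functional activation maps and
simulated stimulation e-fields.

## What it computes

**Adaptive thresholding (MLP).** Responses in an 8-alternative
forced-choice motion-direction task are modelled with a logistic
psychometric function

p(x) = γ + (1 − γ) / (1 + exp(−β(x − α))),

with guess rate γ = 1/8 (8AFC chance), fixed slope β = 1/2 per percent
coherence, and midpoint α. A fixed grid of 150 such functions, differing
only in α and spaced so their 70 %-accuracy levels span 0–100 % coherence,
forms the hypothesis set. After every trial the procedure selects the grid
member maximising the Bernoulli likelihood of all responses so far and
places the next stimulus at that member's 70 % level. Two hemifield tracks
(left / right of fixation) run interleaved, 160 trials each over five
blocks; the threshold is the 70 % level of the finally selected
hypothesis. A frame-level random-dot-kinematogram (RDK) simulator (150
dots, 8-deg aperture, 13.3 deg/s, 47 ms lifetime, 106 ms stimulus)
validates that nominal coherence is realised in the displayed dot
statistics.

**Group statistics.** Per-participant ipsilateral − contralateral
difference scores feed three one-tailed paired t-tests at α = 0.02
(facilitation under active hMT+ stimulation; active vs sham; active vs
control site), plus a hemifield-collapsed one-way within-subject ANOVA.
Sample-size planning uses exact noncentral-t power: with
d = (10.51 − 2.59)/14.8 = 0.535, power 0.9 and one-tailed α = 0.02 the
smallest adequate n is 42 (power at n = 41 is 0.89996 — a normal
approximation gets this boundary wrong).

**Overlap analysis.** Two co-registered volumes (a functional t-map and
an e-field magnitude map) are rank-transformed within a shared brain
mask, discretised into equal-count rank bins, and their mutual
information is reported as a percentage of the attainable maximum
min(H(A), H(B)).

Synthetic generators (simulated observers, cohorts with subject effects,
counterbalanced session-order learning drift, and volume pairs with a
controllable co-localisation dial) stand in for participants and imaging
data throughout the tests.

## Worked example

```r
library(mlpmotion)

# adaptive threshold estimation for two simulated observers
obs_l <- sim_observer(psychfun(alpha = 38.7))   # true 70% level: 40.0
obs_r <- sim_observer(psychfun(alpha = 46.2))   # true 70% level: 47.5
fit <- mlp_session(obs_l, obs_r, session_config(seed = 11))
fit
#> Adaptive MLP thresholding session
#>   160 trials per hemifield over 5 blocks (mode: all-blocks)
#>   threshold (70% accuracy): left 39.60%, right 46.98% coherence

# the registered group analysis on a synthetic null cohort
tab <- generate_cohort(cohort_effects(n_participants = 42, seed = 7))
analyze_group(tab)
#> One-tailed paired t-tests (alpha = 0.02):
#>   hMT+ active: ipsi > contra                 t(41) =  0.39, p = 0.351
#>   ipsi-contra diff: hMT+ active > sham       t(41) =  1.21, p = 0.116
#>   ipsi-contra diff: hMT+ active > forehead   t(41) =  1.01, p = 0.159
#> Conditions collapsed across hemifield: F(2, 82) = 1.77, p = 0.177

# sampling plan: exact noncentral-t sample size
required_n(cohens_d(10.51, 2.59, 14.8))
#> [1] 42

# rank-based mutual information of a synthetic t-map / e-field pair
vp <- generate_volume_pair(c(24, 24, 24), overlap_strength = 0.8, seed = 3)
mutual_information_percent(vp)
#> Rank-based mutual information: 12.84% of maximum (0.2957 / 2.3026 nats, 5232 voxels, 10 bins)
```

The session estimates (39.60 %, 46.98 %) sit within half a grid step of
the observers' true 70 % levels (40.0, 47.5). On a null cohort all three
registered tests are non-significant at α = 0.02, as they should be about
98 % of the time. The overlap percentage is the share of the maximum
attainable mutual information (log 10 nats for 10 equal-count bins)
carried jointly by the two maps.

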