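---
title: "Models and methods behind icnum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icnum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icnum)
```

`icnum` simulates and analyses a 2AFC numerosity-discrimination paradigm
in which Kanizsa-type illusory contours (ICs) connect pairs of Pac-Man
inducers. This vignette is the package's own account of the science it
implements: the stimulus-construction constraints, the observer model,
the psychometric and inferential machinery, the numerical choices, and
what the simulations do and do not show about real data.

## 1. Stimulus synthesis

### Geometry and constraints

A stimulus is a 240 × 240 px mid-grey panel containing N Pac-Man
inducers: 20 px discs with a rectangular notch 4 px wide extending
10 px from the centre to the rim. Test panels carry 9–15 items, the
reference always 12. Constraints (all defaults of
`pattern_geometry()`):

* centre-to-centre distance ≥ 22 px for every pair (items never touch:
  the diameter is 20 px);
* centres at least 20 px from every panel edge, so every item lies
  fully inside the panel. (The margin could also be read as rim-to-edge;
  centre-to-edge is the stricter and simpler reading and we apply it
  everywhere, including to reference patterns.)
* four disjoint *candidate pairs* planted per pattern at distances
  drawn from {22, 25, 28, 31} px. Planting four lets one base pattern
  serve both the 2-IC clone (first two pairs aligned — a fixed,
  deterministic choice) and the 4-IC clone (all four), so the three
  connectedness levels of one pattern are rotations of the *same*
  placement.

Placement is rejection sampling: pair midpoints and free items are
proposed uniformly, with budgets of 10,000 proposals per item and 100
restarts per pattern; exhausting the budget raises an explicit
generation error rather than returning an invalid pattern. Rejection
sampling was chosen over constructive layouts because it is simple,
auditable, and trivially reproducible from a seed.

### The alignment predicate

"Two inducers complete an illusory contour" is operationalised as: both
notch axes within ±10° of the line joining the centres, each opening
towards the other, at centre distance ≤ 40 px. The 40 px ceiling sits
just above the largest planted distance (31 px) and below the scale at
which this illusion is reported to weaken; the ±10° tolerance is the
collinearity window within which contour completion is typically
obtained psychophysically. The same predicate serves three roles:
cloning *targets* it (aligned pairs are set antiparallel along the pair
axis, exactly 0° error), generation *avoids* it (orientations are
re-drawn until no accidental pair passes it — in the base pattern and
in every clone configuration, since re-orienting a pair member could
otherwise create a spurious third alignment in one clone), and
validation *counts* it (a k-IC pattern must contain exactly k passing
pairs, found by brute force over all C(N, 2) pairs).

### Continuous features

Because clones only rotate items, the features known to confound
numerosity — convex hull, density, total surface, occupancy — are
identical across connectedness levels by construction.
`continuous_features()` makes this checkable: the item area is computed
analytically (disc minus the notch rectangle's intersection with the
disc, `r round(icnum:::inducer_area(20, 4, 10), 2)` px² for the default
geometry), and the hull is taken over sampled points of
each item's circular rim. The notch is a concave cavity, so ignoring it
can only matter along the small mouth arc; the discrepancy is far below
the 5% rasterisation tolerance at which the rendered pixel count is
tied back to the analytic surface.

### Orientation and rendering conventions

Orientations are degrees counterclockwise from the +x axis; image
coordinates put the origin top-left, x rightward, y downward, pixel
centres at integer + 0.5. Rendering is deliberately un-anti-aliased
(every pixel is exactly −1, 0 or +1) so that geometric invariants are
exact and test oracles need no tolerance for blending; PNG export maps
−1/0/+1 to 0/128/255. The notch is half-open at the vertex (the centre
pixel belongs to the body), matching the wedge-like Pac-Man mouth whose
vertex has zero width. Closed inducers gain a sealing arc: notch pixels
within 1 px of the rim take the item's polarity, completing the
circular outline that blocks contour completion.

### Polarity schemes

Experiment 1 draws whole panels all-black or all-white (half the
pattern pairs each). Experiments 2–3 use the reverse-contrast scheme:
every candidate pair gets one black and one white member — applied to
all four *planted* pairs, not only currently aligned ones, so a base
and its clones can share one polarity assignment and the
"aligned pairs are always opposite-polarity" constraint holds at every
connectedness level. Remaining items are balanced to N/2 each colour;
odd numerosities carry one excess item whose colour is counterbalanced
four/four across the eight patterns of each numerosity.

## 2. The synthetic observer

The paradigm's behavioural signature is simulated by a deliberately
minimal observer:

* **Weber noise.** The internal estimate of an array with effective
  numerosity E is Gaussian with mean E and SD w·E (default w = 0.20,
  in the typical adult range for this numerosity regime; per-subject
  w is log-normal around the cohort value with log-SD 0.15).
* **Grouping.** Each IC-connected pair contributes `pair_weight`
  effective items instead of 2: E = N − k·(2 − pair_weight). The
  default `pair_weight = 1.8` loses 0.2 items per contour — a 0.8-item
  PSE shift at four contours, matching the modest underestimation this
  manipulation produces (pairwise differences between adjacent contour
  levels are small; only the cumulative 0-vs-4 contrast is reliably
  large). Stronger fusion would also make the fitted CoV fall
  appreciably with k (the Weber noise acts on the *reduced* effective
  numerosity, so grouping steepens the psychometric curve while raising
  the PSE), contradicting the Weber-law constancy the paradigm shows;
  at the default the structural CoV variation across contour levels
  stays under 15%.
* **Polarity blindness.** The grouping parameter never reads polarity —
  this is the boundary-completion account reduced to its behavioural
  consequence. The package models no brightness filling-in at all.
* **Closed-inducer null.** With `applies_to_closed = FALSE` (default),
  sealed inducers yield E = N regardless of k.
* **Lapses.** With probability 0.02 a response is replaced by a fair
  coin flip, inside the [0, 0.05] band the fitting stage allows for.

A trial compares independent draws for test and reference (no
inter-trial learning, adaptation or sequential effects); the larger
draw is chosen. The analytic choice probability
Φ((E_t − E_r)/√(w²E_t² + w²E_r²)), lapse-mixed, is exported as
`choice_probability()` and doubles as a simulation oracle. Whether
grouping should scale with the contour length (pair distances 22–31 px)
is an open empirical question; with no basis to calibrate it, the pair
weight is constant.

Trial tables reproduce the published bookkeeping exactly: 16 trials per
condition cell (42 cells in experiment 1 — 3 contour levels × 7
numerosities × 2 colours — for 672 trials; 21 cells in experiments 2
and 3), test side balanced 8/8 within each cell and split evenly over
two blocks, order randomised within block, 24 training trials (12 vs 9,
both orders) enumerated by the design but excluded from analysis.
Reference patterns never carry contours.

## 3. Psychometric fitting

Each subject × condition cell is fitted with
ψ(x) = γ + (1 − γ − λ)·Φ((x − μ)/σ) by maximising the binomial
log-likelihood over grouped counts, with γ, λ ∈ [0, 0.05] (the
conventional band that absorbs finger errors without letting the
asymptotes eat the slope) and σ ≥ 0.05 items (so step-like data pin σ
at a finite bound instead of overflowing). Optimisation evaluates a
4 × 4 × 5 × 5 start grid (γ, λ ∈ {0, 0.0167, 0.033, 0.05}; μ over the
stimulus range; σ ∈ {0.5, 1, 2, 4, 8}) in one vectorised pass and
polishes the best three points with L-BFGS-B using the analytic
gradient; ties break towards the smallest σ. Convergence and boundary
flags are reported honestly rather than silently cleaned.

The PSE solves ψ(x) = 0.5 on the *full* function including asymptotes —
μ + σ·Φ⁻¹((0.5 − γ)/(1 − γ − λ)) — matching the operational "50% of
test choices" definition literally; it equals μ whenever γ̂ = λ̂, and
under the 0–0.05 bounds the two readings differ by at most a few
hundredths of an item. CoV = σ/PSE.

Confidence intervals use a parametric bootstrap by default: counts are
resampled from Binomial(n, ψ_fit(x)) at each level, refitted (started
from the point estimate), and percentile intervals taken over 200
resamples; a nonparametric flavour (resampling the observed
proportions) is available behind a flag. Failed refits are dropped and
counted, with a warning past 20%. In simulation at the experiment's
per-condition trial counts (7 levels × 16 trials) the 95% interval
covers the true PSE at about 94%.

## 4. Repeated-measures inference

`rm_anova()` implements the classical univariate decomposition for one
or two within factors on complete balanced tables (unbalanced input is
an error, never silently imputed): each effect is tested against its
subject-by-effect interaction, with partial η² = SS_eff/(SS_eff +
SS_err). The Greenhouse–Geisser ε is always computed — from the
covariance of subject scores projected onto orthonormal contrasts
spanning the effect, which for two-level factors gives ε = 1 exactly —
and both uncorrected and ε-corrected p values are reported, the
corrected one flagged as primary when ε < 0.95. Always computing both
is deterministic and strictly more informative than a binary
"correct when needed" rule.

Post hocs are all pairwise comparisons with Bonferroni multiplication.
The default error term is the pooled subject-by-factor mean square with
its shared degrees of freedom ((a−1)(n−1): t(54) at 28 subjects and 3
levels, the df convention used when these designs are reported); a
per-pair paired-t option is available since the two differ under
sphericity violations. The trend contrasts use weights (−1, 0, +1) and
(1, −2, 1) over the three equally spaced contour levels; with the
pooled error term the linear-trend t equals minus the 0-vs-4 post hoc
t, reproducing the characteristic identity between those two reported
statistics. A per-subject contrast-score version (one-sample t,
df = n − 1) is available via `error = "per_subject"`.

## 5. What the simulations show — and what they cannot

The end-to-end property the package reproduces at experiment scale
(28-subject cohorts, 100 replicates in the test suite): fitted PSEs
increase monotonically in the number of contours with a GG-corrected
significant main effect in well over 90% of replicates; the
contour-by-colour interaction and the closed-inducer (experiment 3)
contour effect reject at nominal type-I rates; and mean CoV varies by
less than 15% across contour levels. Problem sizes in the suite —
100 seeded patterns for the stimulus oracles, 200 simulated datasets
for bootstrap coverage, 100 cohort replicates for power and type-I
behaviour — were chosen as the smallest runs at which these rates are
stable to a few percent.

The generator emulates the *trial structure and decision statistics* of
the paradigm, not the humans: there are no reaction times, no
sequential dependencies, no subitizing mechanism, no attentional or
fatigue drift, and the grouping strength is a fixed constant rather
than a latent per-subject trait. Passing tests therefore certify that
the pipeline — stimuli, trial bookkeeping, fitting, inference — is
correct and recovers known ground truth at realistic noise levels; they
cannot certify that real observers obey the linear pair-fusion model,
and the published human F and t statistics are not reproducible targets
because the underlying responses are not public. Rendering is
deliberately binary (no anti-aliasing), so pixel-level outputs are
idealisations of the displayed stimuli.
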