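---
title: "Capacity models for dual-task letter-string perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacity models for dual-task letter-string perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualcap)
```

## The problem

In a dual-task letter-string experiment an observer fixates between two
briefly flashed five-letter strings (one above, one below fixation) and
categorizes each independently — e.g. "does it contain a vowel?" or "is it
pronounceable?" — on a four-key confidence scale. Comparing *single-task*
blocks (attend one precued side) with *dual-task* blocks (judge both sides)
asks how much processing capacity the two strings must share. Three
standard models make quantitative predictions:

* **All-or-none serial**: exactly one string is processed per trial (the
  top one with probability $p_{top}$); the report for the other string is a
  guess. Dual-task accuracy pays a severe cost.
* **Fixed-capacity parallel** (sample-size model): both strings are
  processed but share a fixed resource; with share $w$ on the top side,
  sensitivity scales as $d'\sqrt{w}$ and $d'\sqrt{1-w}$.
* **Independent (unlimited-capacity) parallel**: dividing attention costs
  nothing; dual-task accuracy equals single-task accuracy on both sides.

This package simulates observers under each regime, measures accuracy with
the rating-ROC area $A_g$, places dual-task performance on an attention
operating characteristic (AOC) against each model's prediction, and runs
the accompanying inference: signed distances to the model loci,
the serial bias estimate $\hat p_{top}$, stimulus-processing trade-offs,
congruency and response-order analyses, bootstrap CIs and JZS Bayes
factors.

## Accuracy measure

Each response is a confidence rating 1–4 (1 = sure absent, 4 = sure
present; binary correctness is rating $\ge 3$ iff signal-present). `ag()`
computes the trapezoidal area under the empirical ROC built from the
cumulative hit and false-alarm rates across the three rating criteria,
with (0,0) and (1,1) appended. That area equals the concordance
probability $P(R_{present} > R_{absent}) + \tfrac12 P(\text{tie})$ — the
tests verify this identity exhaustively — and reads as a bias-corrected
proportion correct (0.5 = chance, 1 = perfect). Values below 0.5 are
returned as computed, not clipped, so that group means near chance are not
biased upward. No parametric (z-ROC) smoothing is applied.

## The observer model

Evidence for a processed stimulus is equal-variance Gaussian,
$X \sim N(\pm d'/2, 1)$, cut by three criteria (default $-1, 0, +1$) into
the four ratings. Under the symmetric default criteria, binary single-task
accuracy is $\Phi(d'/2)$; `dprime_for_pc()` inverts this, and the study
conditions used throughout the package set $d'$ for 80% single-task
accuracy, the level the adaptive staircase in such experiments targets
(accepted window 70–90%).

Key parameters of `observer_params()`:

| parameter | meaning | default |
|---|---|---|
| `dprime_top`, `dprime_bottom` | sensitivity per side (unitless) | `dprime_for_pc(0.8)` ≈ 1.68 |
| `p_top` | serial probability of processing the top side on a dual trial | 0.74 |
| `w_top` | fixed-capacity attention share for the top side | 0.5 |
| `criteria` | rating criteria on the evidence axis | (−1, 0, 1) |
| `guess_dist` | rating distribution for unprocessed stimuli | marginal (see below) |
| `selection_error_rate` | probability of reporting the wrong side | 0 |
| `fixation_break_rate` | probability a trial is flagged for exclusion | 0 |

The default `p_top = 0.74` is the top-side bias observed for letter tasks;
the 1:1:2 block mix, 20-trial blocks and 60-block sessions in
`trial_design()` mirror the standard procedure (1,200 trials per observer,
600 of them dual-task).

### What guessed responses look like

The guessing distribution for unprocessed stimuli is a genuinely open
modeling choice — behavioral data do not pin down the confidence of
guesses. We default to the **marginal rating distribution of a processed
stimulus** (the average of its signal-present and signal-absent rating
distributions). This choice has a decisive property: concordance is
bilinear in the two rating distributions, and when the guess distribution
$g$ equals $\tfrac12(f + h)$ (with $f, h$ the processed present/absent
distributions), $C(f,g) + C(g,h) = \tfrac12 + C(f,h)$ exactly, so the
serial observer's dual-task $A_g$ is *linear* in $p_{top}$:
$A_g(p) = p\,A_{single} + (1-p)\,0.5$. The simulated serial observer then
lies exactly on the straight serial AOC segment that the analysis draws —
the defining geometry of the all-or-none serial model in $A_g$ space.
Low-confidence-only alternatives (e.g. guessing only with the two middle
keys) are still unbiased in binary accuracy but break this linearity and
push the simulated serial observer measurably *outside* its own model
line (by ~0.04 accuracy units at $p_{top} = 0.74$, 80% accuracy), which
would misrepresent the model being simulated. `guess_dist` remains a user
parameter for exploring such variants. It is also behaviorally sensible:
an observer who guesses emulates their typical confidence usage.

Selection errors (attending/reporting the side opposite the cue) are
applied as a full swap of the two sides' reports on dual-task trials; on
single-task trials the observer processes the uncued stimulus and reports
it in the cued slot. This reproduces the classic congruency signature:
zero congruency effect for an error-free serial observer, and a positive
effect once selection errors occur (about 7% is enough to produce a clear
single-task congruency effect).

## Stimulus generators

Experiment-1 strings are five lowercase letters, never containing 'y',
with at least four unique letters. Vowel-present strings have exactly one
vowel; vowel-absent strings are all consonants and always include one of
q, j, c, n, s (consonants visually similar to vowels, so that the task
cannot be solved by coarse shape cues). Experiment-2 strings all contain
exactly one vowel; pronounceable items are built from a deterministic
onset + vowel + coda template over whitelists of legal English
word-initial and word-final clusters ("crult" = cr+u+lt), unpronounceable
items violate the template ("crtul"), and the two categories are matched
one-to-one on starting letter. The whitelist replaces corpus-derived
bigram/trigram statistics: it is reproducible without external databases,
and the analyses only require a deterministic, documented legality rule.
Generation is rejection sampling under a fixed seed; duplicate strings
within a category never occur.

## AOC construction and model distances

Per subject, the single-task $A_g$ values anchor the axes and the
dual-task $(A_{g,bottom}, A_{g,top})$ point is compared with three loci:

* serial: $\big((1-p)\,a_b + p/2,\; p\,a_t + (1-p)/2\big)$, $p \in [0,1]$;
* fixed-capacity: $\big(\Phi(\sqrt{1-w}\,z_b), \Phi(\sqrt{w}\,z_t)\big)$
  with $z = \Phi^{-1}(a)$, $w \in [0,1]$ (an accuracy of 1 is clamped to
  $1 - 10^{-6}$ with a warning, since it implies infinite $d'$);
* independent: the point $(a_b, a_t)$.

Because $A_g$ is bias-corrected we treat it as the accuracy entering the
equal-variance mapping. The serial and fixed-capacity loci share both
endpoints exactly, and the fixed-capacity curve dominates the serial
segment whenever the anchors exceed chance.

`signed_distance()` minimizes the Euclidean distance over the locus with a
1001-point parameter grid refined by local optimization (the loci are
smooth one-dimensional curves; a closed form exists only for the line).
The sign is positive when the dual-task point lies on the far side of the
locus from chance (0.5, 0.5) — the observer outperforms the model — and
negative when it falls short. For the serial model, the locus parameter of
the nearest point is $\hat p_{top}$, clamped to [0, 1]. Distances reported
for real and simulated observers should be read by magnitude and sign
together; a serial observer sits near zero on the serial line and clearly
negative on the two parallel loci.

## Trade-off analysis

All dual-task responses of a subject (both sides, regardless of report
order) are partitioned by whether the *other* side's response on the same
trial was correct, and $A_g$ is computed within each set. Pooling both
sides before computing the conditional $A_g$ (rather than averaging
per-side values) maximizes the counts in each partition. The serial model
predicts higher accuracy when the other side was wrong; at
$p_{top} = 0.5$ and single-task proportion correct $PC$, the conditional
proportions correct are $0.25/(0.75 - 0.5\,PC)$ and
$0.5\,PC/(0.5\,PC + 0.25)$ (5/7 ≈ 0.714 and 8/13 ≈ 0.615 at $PC = 0.8$).
Parallel observers show no trade-off. `serial_tradeoff_curve()` traces the
prediction across single-task difficulty by simulation (with the package's
guess-distribution default, documented above); the gap from the identity
line grows with single-task accuracy and vanishes toward chance.

## Exclusions

`apply_exclusions()` drops fixation-break trials first. It then removes
runs of at least four consecutive blocks (per subject and session —
sessions are approximated by contiguous block numbering unless a `session`
column is supplied) whose single-task accuracy sits outside the 70–90%
window: a removable run is anchored by out-of-window single-task blocks on
the same side of the window, carries the dual-task-only blocks lying
between the anchors (the stimulus timing was off for that whole period),
and must have pooled single-task proportion correct outside the window.
Block accuracy uses binary correctness, matching how such experiments
track accuracy online, not $A_g$.

## Inference

Group tests are one-sample/paired t tests on per-subject effects, with
percentile bootstrap 95% CIs (1,000 resampled means; plain percentile, not
BCa, matching the resampled-means description) and JZS Bayes factors.
`jzs_bf()` integrates the Cauchy($0, \sqrt{2}/2$) effect-size prior via
the inverse-gamma mixture representation with adaptive quadrature
(relative tolerance $10^{-10}$); the prior scale is the default of the
MATLAB toolbox commonly used with these designs. The tests cross-check the
integral against an independent noncentral-t formulation. Side-by-cue and
congruency-by-cue interactions use a two-factor repeated-measures ANOVA
(`aov` with a within-subject error stratum), reporting the interaction
$F(1, n-1)$; linear mixed-effects variants are deliberately out of scope
because their random-effects structure is a free choice that the
repeated-measures F approximates at these balanced designs.

## Problem sizes and numerical choices

The replicate studies in the tests and `analysis/` scripts use the study's
own scale — 11 subjects, 600 dual + 600 single trials — with 20 replicates
for parameter recovery and 40 per regime for model identification; these
sizes give stable win rates while keeping a full run in minutes.
Trade-off conditional-probability checks use 60,000 dual trials so that
the simulation error (~0.003) is far below the 0.01 assertion tolerance.
Degenerate cells (a subject with no signal-absent trials in a partition,
an empty congruency cell) flag the subject and exclude them from the group
test with a warning rather than failing the run. All randomness flows
through explicit integer seeds; seeded runs are bit-reproducible.

## Limitations

The simulator emulates the generative skeleton of the paradigm — block
structure, independent binary categories, rating production, selection
errors, fixation-break contamination — not sequential dependencies,
learning/fatigue, criterion drift, or response-time structure. Passing
recovery tests therefore shows the analysis pipeline is consistent and
identifiable under the stated models, not that real data satisfy those
models. Pronounceability is a template rule, not a corpus statistic, so
generated pseudowords are a cleaner category boundary than
database-derived stimuli. The independent-parallel model is a point
prediction; observers with mild dual-task costs will sit between loci, and
the distance tests then reject all three models rather than interpolating.
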