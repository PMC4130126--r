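---
title: "Nudged decision aids: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nudged decision aids: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcida)
```

## The problem this package models

Patient decision aids present the facts of a preference-sensitive treatment
choice — options, their benefits and harms, event probabilities — and ask the
patient to deliberate. Even a well-informed patient can end up choosing an
option that does not match their own values, because of well-documented
cognitive biases: unstable values, order effects (primacy), overweighting of
rare events, and information overload. This package implements a *nudging*
layer over such aids: the patient's importance weights are elicited first,
and the summary screen is then restructured around them — rows ordered and
sized by weight, cells shaded by score, and the option maximizing the
weighted additive total pre-selected as a default that remains freely
changeable. The package also implements the quantitative usability battery
used to evaluate such a tool (fixation analysis, SUS, the DCS uncertainty
subscale) and a parametric agent simulation of the four biases the nudges
target.

## The weighted additive model

Each option $o$ receives a total
$$T_o = \frac{1}{B}\sum_a w_a \, s_{o,a},$$
where $w_a \ge 0$ is the importance weight of attribute $a$ (constant-sum,
$\sum_a w_a = B$ with budget $B = 100$ by default), and $s_{o,a} \in [0,100]$
is the option's score on the attribute. Dividing by the budget keeps totals
on the same 0–100 scale as the scores; the raw weighted sum is recovered by
multiplying by $B$. The default option is the argmax; exact ties go to the
option listed earliest and are flagged (`tie = TRUE`) so a front-end can
disclose them rather than feign a unique optimum.

Scores come from 5-point ratings through the anchored linear map
$1\to0,\;2\to25,\;3\to50,\;4\to75,\;5\to100$. Linearity is the minimal
assumption connecting the two scales and sits behind the single function
`rating_to_score()` so an alternative map can be swapped without touching
anything else. Ratings are collected per option–attribute *pair* (not per
attribute), since cell shading and option totals both require scores that
vary across options. For harm attributes the rating wording asks for the
desirability of the option's harm profile, so no sign flip is applied
downstream; direction is authored metadata on the attribute, never inferred.

## The budget pie

`set_weight()` models one slider movement on the constant-sum exercise: the
moved attribute takes its new value and the remaining budget is spread over
the untouched attributes *in proportion to their prior weights*, preserving
the user's relative judgments; when the untouched weights are all zero the
pool is split uniformly. Integer mode (the default, matching a "100 points"
budget) rounds the redistribution by the largest-remainder method, so the
budget is conserved exactly, with fractional-part ties resolved to the
earlier attribute for determinism. Allocations are immutable values; a
session that lets the user return to the pie keeps a history of allocations
rather than mutating one.

`rank_attributes()` orders by descending weight with ties broken by the
authored `document_order` — the same order the conventional aid uses — which
keeps the ranking stable and reproducible.

## The summary layout

Three transformations, all driven by the weights and scores alone:

* **Order**: rows follow `rank_attributes()`.
* **Size**: row heights are proportional to weights, with a floor of 5% of
  the summary region so a 1-point attribute is still legible. When flooring
  breaks the unit sum, below-floor rows are fixed at the floor and the
  remaining rows renormalized, iterating until stable (water-filling). The
  result is the unique vector $h$ with $\sum h_i = 1$, $h_i \ge f$, and
  $h_i = \max(f, \lambda\,\mathrm{raw}_i)$ for a common $\lambda$ — the
  characterization the test suite checks against.
* **Shade**: cell luminance is linear in score, $0.25 + 0.70\,s/100$, lighter
  meaning more preferred. The anchors 0.25/0.95 (rather than 0/1) keep text
  readable on both the darkest and lightest cells.

The default option is both marked visually and pre-selected as a radio
control in the HTML rendering; doing both covers either way a front-end may
interpret "default". Conventional mode renders the same data with rows in
document order, uniform heights, no shading and no default, so paired
nudged-vs-conventional comparisons are built into the layout engine. A
formal consequence, tested as a property: permuting the authoring order of
attributes never changes the nudged layout but always permutes the
conventional one.

Each row's area of interest (AOI) spans the full row width, label included.
The rows tile the part of the page below a header band occupying the top
20% of normalized page coordinates (`region_top = 0.2`); fixations in the
band — titles, instructions — are classed as `other_screen`. The 20% figure
is a package choice for a summary page with a modest header; it is a
parameter of `compute_layout()`.

## Fixation analytics

`detect_fixations()` implements dispersion-threshold identification (I-DT):
within each run of valid samples, the earliest maximal window whose
x-range + y-range stays within the dispersion threshold and whose span
reaches the minimum duration becomes a fixation at the window centroid.
Defaults are 0.02 normalized units and 100 ms — deliberately below the
200–500 ms of a typical reading fixation so short fixations are kept and the
minimum acts as a noise gate; both are arguments. Eye trackers usually
export fixations directly, and that fixation-level CSV is the primary input
path; the detector serves raw gaze logs.

AOI assignment is point-in-rectangle on the fixation centroid with
half-open boxes $[x_0,x_1)\times[y_0,y_1)$, so a centroid exactly on a
shared row boundary belongs to the lower row, unambiguously.

`relative_fixation()` buckets attribute AOIs into most important, second,
least, and the remaining ("other") attributes, given the weight ranking.
The share of a bucket is its fixation time divided by **on-attribute time
only** — time on other areas of the screen is excluded from the denominator.
This convention is validated by a round-trip test: the published group mean
durations reproduce the published percentages for both presentation modes
under it, and do not under a whole-screen denominator. Shares are reported
to the nearest percent and scores to one decimal, matching the display
precision of the source measures.

## Questionnaire scoring

SUS uses the standard arithmetic: over the 10 items on 1..5, odd items
contribute (item − 1), even items (5 − item), scaled by 2.5 onto 0–100. The
DCS uncertainty subscale (clear / sure / easy, 1..5 coding) is scored
$(\bar{x} - 1) \times 25$ on 0–100, lower meaning less conflict. This
aggregate formula reproduces the published subscale value exactly from the
published item means for the nudged condition; for the conventional
condition it computes 50.8 where 50.4 was printed, a 0.4-point gap
attributable to the printed item means themselves being rounded to one
decimal. The package documents this rather than adjusting the formula.
Fractional item values are accepted so group-level item means can be scored
directly.

## The bias simulator

The simulator is the computational statement of *why* the nudges should
work. An agent has true weights (summing to the budget) and true scores,
and four bias parameters, each behind one function so alternative forms can
be swapped:

| Parameter | Bias | Form | Default in the study conditions |
|---|---|---|---|
| `weight_noise_sd` | unstable values | Gaussian noise on elicited weights, clamped at 0 and rescaled to the budget | 5 points |
| `primacy_decay` (d) | order effects | row at display position $j$ weighted by $d^{\,j-1}$ | 0.7 |
| `prob_weight_gamma` (γ) | rare-event overweighting | Tversky–Kahneman 1992 $\pi(p) = p^\gamma/(p^\gamma+(1-p)^\gamma)^{1/\gamma}$ | 0.61 |
| `attention_capacity` (k) | information overload | rows beyond position $k$ get zero effective weight | 3 of 5 |
| `default_adherence` | status-quo pull of a default | adopt the presented default with this probability when the top two perceived totals are within the indifference margin | 0.8 |

The indifference margin is 5 points on the 0–100 total scale — an agent
whose perceived best and second options differ by less than that is treated
as near-indifferent, the situation where defaults are known to act.

Perception (noisy weights, probability-weighted risk scores) is drawn once
per agent and seed; the presentation mode then only changes the display
order the decay and truncation act through, and whether a default exists.
This makes the two modes a *paired, within-agent* comparison, mirroring a
within-subject protocol and reducing variance. Concordance is the fraction
of agents choosing the option that maximizes their own *true* weighted
values. In the bias-free limit (sd = 0, d = 1, γ = 1, k ≥ n) both modes
reach concordance exactly 1 on any problem without ties — a tested
invariant. Risk attributes tie their true scores to the event probability
(100(1−p) for harms, 100p for benefits), so the undistorted perception
reproduces them exactly and γ is the only wedge between true and perceived
risk.

Agent populations draw weights uniformly from the simplex and scores
uniformly on [0, 100]; with 2000 agents the paired design resolves
concordance differences of a few percentage points, and the whole
experiment runs in seconds. A percentile bootstrap (1000 replicates) gives
the interval on the paired difference. The simulator measures concordance
*by construction*; whether observed preference changes in human users are
improvements is exactly what such a measure cannot decide from choice data
alone, and no claim of reproducing human effect sizes is made.

## Synthetic data

`fixture_problems()` ships three worked problems (knee osteoarthritis
medications, obstructive sleep apnea devices, late-stage lung cancer
chemotherapy), each with five attributes including a rare-event risk
attribute (probability ≤ 2%) so the probability-weighting bias is
exercised. All clinical numbers are invented, labelled non-clinical in file
headers, and chosen only to be structurally plausible.

`generate_gaze_log()` emulates the robust positional gradient of summary
reading — about 23% of time on the first row falling linearly to 13% on the
last, remainder on the header — with log-normal fixation durations (median
250 ms). It reproduces positional attention shares and durations; it does
**not** emulate saccade dynamics, reading order within a row,
content-driven attention, or drift/calibration error. Passing analytics
tests on these logs therefore demonstrates correct *accounting*, not that
real gaze data would show any particular effect.

`generate_responses()` jitters a persona's weights (projected back onto the
budget), ratings and questionnaire items, guaranteeing every generated file
passes the package's validators — a closure property the tests check over
many seeds.

## Numerical choices and degenerate inputs

* Budget conservation: exact in integer mode, 1e-9 elsewhere; the MCDA
  total is tested against a naive double loop at 1e-12.
* Ties: maximizer ties in totals use a 1e-9 tolerance and resolve to the
  earliest option, flagged; ranking ties resolve by document order;
  largest-remainder ties by position.
* Degenerate inputs: empty gaze logs yield empty fixation sets (not
  errors); zero on-attribute time flags shares as undefined rather than
  dividing by zero; an all-zero remainder in the budget pie falls back to a
  uniform split; `sensitivity_to_default()` returns `NA` for attributes
  whose slider can never flip the default (identical or dominated options).
* `sensitivity_to_default()` is analytic — totals are linear in the moved
  weight under proportional redistribution, so flip points are pairwise
  line crossings — and is verified against a 1-point grid search.

## Known limitations

* The linear rating map and the greyscale anchors are conventions, not
  fitted to perception data.
* The simulator's bias forms are one reasonable parameterization each;
  the package exposes them as arguments precisely because the underlying
  theory motivates the phenomena, not the functional forms.
* Group-level questionnaire scoring from item means inherits the rounding
  of those means (see the 0.4-point note above).
* The HTML rendering is a static artifact for inspection and AOI export,
  not an interactive front-end.
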