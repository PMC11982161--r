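---
title: "Quantifying dyadic speech coordination with categorical cross-recurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic speech coordination with categorical cross-recurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two people in conversation coordinate without copying each other: a
well-attuned dialogue is one where one partner speaks while the other is
silent, and the roles trade off with a shared rhythm. `dyadcrqa` quantifies
that complementary structure from the simplest possible observable — a
binary speech(1)/silence(0) series per partner at 1-second resolution — and
carries the resulting dyad-level measures through to the statistical models
a dyadic-interaction study needs: task effects, personality moderation, and
post-conversation appraisals.

```{r}
library(dyadcrqa)
```

## From annotations to series

Voice-activity annotations arrive as interval tiers (Praat TextGrid or plain
onset/offset/label CSV). `binarize()` grids them into 1-second bins over
`[t, t+1)`. The aggregation rule for sub-second intervals is genuinely
underdetermined by common practice, so both options are exposed:

* `majority` (default): a bin is speech when speech covers at least 0.5 s of
  it, ties counting as speech;
* `any_speech`: any positive overlap makes the bin speech.

A trailing partial bin is dropped rather than padded, keeping every bin
exactly one second wide. Within a dyad the two series are truncated to the
shorter length so the cross-recurrence plot is square.

```{r}
ann <- interval_annotation(data.frame(
  onset = c(0, 1.6, 3.0), offset = c(1.6, 3.0, 4.2),
  label = c("sounding", "silent", "sounding")))
binarize(ann)$values
```

## The recurrence measures

With partner A's series $a_i$ on the horizontal axis and partner B's $b_j$
on the vertical, a cell $(j, i)$ of the categorical cross-recurrence plot is
recurrent when the states are complementary, $a_i \neq b_j$ (one speaks, the
other is silent). No Theiler window is excluded. Five dyad-level measures
follow:

* $RR_{global}$: recurrent cells over the full $n \times n$ plot —
  coordination pooled over all lags. For binary series under XOR matching
  this depends only on the two speech totals,
  $RR_{global} = (n_1^a n_0^b + n_0^a n_1^b)/n^2$, so for independent
  partners with speech probabilities $p$ and $q$ its expectation is the
  chance level $p(1-q) + q(1-p)$.
* $RR_{LOS}$: the same proportion on the line of synchrony only (lag zero) —
  simultaneous complementarity.
* $Q_{DCRP} = |RR_{right} - RR_{left}| / (RR_{right} + RR_{left})$, where
  $RR_{left}$ and $RR_{right}$ are the mean per-lag recurrence rates on the
  two sides of the LOS within a $\pm L$ window: 0 for balanced
  leading/following, 1 when one partner leads throughout. It is defined as 0
  when both sides are empty.
* $LAM_{ARD}$ and $TT_{ARD}$: the absolute relative differences
  $|x_{ver}-x_{hor}|/(x_{ver}+x_{hor})$ of directional laminarity (share of
  recurrent points on vertical/horizontal lines of length $\ge \ell_{min}$)
  and trapping time (mean length of those lines). Vertical lines are runs in
  which one momentary state of partner A co-occurs with a sustained run in
  partner B — one partner "trapping" the other — and the ARDs measure how
  asymmetric that influence is.

Numerical conventions worth stating explicitly:

* Each diagonal at offset $k$ is normalized by its own length $n - |k|$, so
  short series and large lags remain comparable.
* The profile window defaults to $L = 30$ s; positive lags mean partner B's
  matching behavior follows partner A. The window choice matters: reaction
  delays of a few seconds concentrate the asymmetric mass near the LOS, and
  wider windows average it against symmetric far-lag mass.
* $\ell_{min} = 2$ by recurrence-analysis convention; border-touching lines
  count with their visible length; a direction with no qualifying lines has
  trapping time 0 so the ARD stays defined; all the ratio measures return 0
  on an all-zero numerator-and-denominator.
* The quotient measures are absolute, so none of the dyad-level outputs
  depends on which partner is placed on which axis; swapping partners only
  exchanges the directional raw values.

For complementary matching the line structure factorizes: the vertical runs
in column $i$ are exactly the maximal runs of $b$ equal to $1 - a_i$.
`line_statistics()` exploits this for an $O(n)$ computation and the test
suite verifies exact agreement with a literal cell-by-cell scan of the
materialized plot.

```{r}
d <- simulate_dyad(dyad_sim_config(seed = 11), task = "introduction")
dyad_measures(d)[, c("rr_global", "rr_los", "q_dcrp", "lam_ard", "tt_ard")]
```

## Pseudosynchrony baselines

Shuffling each partner's 1-second bins (keeping the real pairing and series
lengths — the dyadic structure) destroys temporal alignment while preserving
each partner's total speech seconds. `compare_to_chance()` then runs a
paired t-test across dyads of the real measure against each dyad's mean
surrogate value. Two consequences of the design deserve emphasis:

* $RR_{global}$ is *invariant* under bin shuffling (it only depends on the
  totals), so the paired surrogate test is degenerate for it and the
  function raises the zero-variance error. Chance comparison for the global
  rate is instead meaningful against the analytic level above. Lag-specific
  and line measures are the ones a shuffle baseline genuinely tests.
* Bin-level shuffling destroys run-length (dwell) structure along with
  alignment. A `block` mode that permutes whole speech/silence runs is
  provided for baselines that should retain the dwell distribution.

The surrogate count defaults to 100 per dyad and every replicate loop is
seedable.

## The synthetic study generator

Real recordings are not required anywhere: `simulate_dyad()` produces
coupled binary turn-taking via two two-state chains in 1-second steps. Each
partner has a start hazard `p_start` (silent → speaking) and a stop hazard
`p_stop` (speaking → silent), and coupling acts multiplicatively on the
hazards from the partner's state `delay_d` seconds earlier: `yield_gain > 1`
makes a speaker stop sooner when the partner was speaking, and
`initiative_gain > 1` makes a silent partner start sooner when the partner
was silent. States are finally flipped with probability `noise_eps`.

Defaults, chosen once as the study conditions the pipeline targets:

* `n_seconds = 300` (a 5-minute task), three tasks per dyad, 50 dyads;
* `p_start = 0.07`, `p_stop = 0.13`: stationary speech fraction
  $p_{start}/(p_{start}+p_{stop}) = 0.35$ per partner, i.e. mean speaking
  turns of ~7.7 s and silences of ~14 s. This puts the uncoupled chance
  level at $2 \times 0.35 \times 0.65 \approx 0.455$, the regime typical of
  dyadic conversation where each partner holds the floor roughly a third of
  the time, and it places the speech fraction *below* one half so that
  stronger initiative coupling raises both the speech fraction and the
  global recurrence rate together;
* `yield_gain = initiative_gain = 3`, `delay_d = 1`, `noise_eps = 0.02`:
  clearly coupled but noisy dyads, with lag-zero coordination well above the
  chance level (around 0.65) while leaving the asymmetry measures in the
  small ranges observed for unselected dyads;
* task coupling multipliers 1 / 1.15 / 1.30 for introduction,
  self-disclosure, argumentative, so later conversations are somewhat more
  coordinated;
* trait effects: a participant's initiative gain is scaled by
  $\exp(0.3\,E)$ and the yield gain by $\exp(0.2\,A)$, with $E$, $A$
  standardized Extraversion and Agreeableness scores;
* appraisal items: 1–5 scores generated as item mean plus trait terms plus a
  term in the *computed* dyad-mean lag-zero coordination plus Gaussian
  noise, clipped to the scale — computed measures rather than latent
  parameters feed the items so the appraisal stage can be tested
  end-to-end.

What the generator deliberately does not emulate: conversational content,
longer-range nonstationarity (topic changes, fatigue), overlapping
back-channels shorter than a second, and the measurement path from audio to
annotations. Passing tests therefore demonstrate that the *measures and
models* behave correctly on series with the right coupling structure, not
that any specific psychological effect size in real data is reproduced.

### Recovering asymmetries

The generator's knobs map onto the measures as the design intends, and the
test suite checks the trends:

* raising both partners' gains raises median $RR_{LOS}$ against the
  uncoupled control;
* redistributing a fixed total coupling unevenly between the partners
  (partner A's gains scaled by $f$, partner B's by $1/f$) raises the median
  profile quotient. Holding the total fixed isolates asymmetry: raising one
  partner's gain alone also deepens overall coupling, which *reduces*
  profile noise and with it the median of the absolute quotient, masking the
  signed shift. The quotient trend is assessed on series of 900 s — the
  full-conversation length at which diagonal profiles are computed — where
  the finite-sample noise floor of $|RR_{right}-RR_{left}|$ sits below the
  induced signal; the response saturates for $f \gtrsim 2$, so the sweep
  spans $f \in [1, 2]$;
* lowering partner A's stop hazard (longer speaking turns) raises the median
  trapping-time asymmetry.

## The statistical stage

`assemble_measures_table()` produces the long dyad-task table: one row per
dyad and task, task as a factor with introduction as baseline, and the
chosen trait standardized across all participants then split by within-dyad
role — partner "A" is the higher scorer (ties go to the first-listed
partner). The descriptive dyad typing at ±0.5 SD (`"++"`, `"--"`, `"+-"`,
`"mid"`) is attached for plotting only.

`fit_mixed_model()` fits a maximum-likelihood linear mixed model with a
dyad random intercept via `lmerTest` (Satterthwaite degrees of freedom) and
reports raw estimates, standardized betas (obtained by refitting after
z-scoring the response and continuous predictors; task dummies stay binary —
whether the response should be included in the standardization is a
convention choice, and including it makes the betas directly comparable
across responses), ICC (between-dyad variance over total), marginal and
conditional $R^2$ (fixed-effects variance share, and fixed plus random), and
AIC. Singular fits are flagged, not hidden; a response with essentially no
between-dyad variance (common for the asymmetry quotients) legitimately
estimates a zero random-intercept variance. Degenerate designs whose
deviance surface defeats the curvature-based covariance (e.g. an exactly
linear response) fall back to point estimates with `NA` inference rather
than failing.

`fit_appraisal_model()` fits per-item ordinary linear models on standardized
predictors; `adjust_model_family()` applies Benjamini–Hochberg across the
pooled non-intercept p-values of an item family. BH family boundaries are a
reporting choice, not a mathematical one, so they are explicit: within-model
by default for the mixed models, across the full item family for the
appraisal stage.

## Problem sizes and what the tests do

The test suite works at the study's own scale where that is cheap (150
dyad-task series of 300 s; profile trends at 900 s) and at reduced scale for
replicated calibration studies (200 null studies of 10 dyads for the type-I
rates of the surrogate test and the appraisal terms; 100 replicates for ICC
recovery). Exactness checks (vectorized measures against literal double-loop
recounting) run on 200 random dyads of up to 64 s, where the naive oracle is
affordable. `scripts/acceptance.R` recomputes the definitional extremes of
the profile quotient from freshly constructed inputs at every run.

## Known limitations

* The 1 Hz grid cannot represent sub-second turn-taking phenomena
  (back-channels, micro-pauses); the binarization rule is a modeling choice
  with two defensible variants, both exposed.
* The profile quotient is an absolute imbalance: it identifies *that* one
  partner leads, not *who*, and near-balanced dyads have a positive noise
  floor that shrinks with series length.
* The generator's coupling is first-order (a single delayed state); real
  conversations carry longer memory and content-driven structure.
* The mixed-model stage treats the dyad as the only grouping level;
  actor–partner interdependence modeling is out of scope.
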