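---
title: "Analysing distraction during licking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing distraction during licking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickdistract)
```

## The experimental paradigm

Rats licking freely for a palatable solution produce highly stereotyped
behaviour: runs ("bursts") of licks at roughly 6–8 Hz separated by pauses of
seconds. `lickdistract` analyses a closed-loop distraction task built on this
microstructure. Whenever the animal makes three consecutive licks within
1 s — after having paused for more than 1 s — the rig delivers a 1-s
audiovisual distractor (a cue light, flashing light, tone, white noise, or a
combination). If the animal then pauses licking for more than 1 s it is
classed as *distracted* on that trial; otherwise it is not. Because the
trigger is a pattern in the animal's own behaviour, the same rule applied
offline to a session recorded *without* stimuli yields *modelled
distractors*: times at which a distractor would have been delivered. These
provide the behavioural null — the spontaneous probability that a qualifying
burst is followed by a long pause anyway.

Simultaneously, bulk calcium signals are recorded by fibre photometry from
neurons expressing GCaMP6s, giving a population proxy of neural activity
around each (real or modelled) distractor.

## The trigger rule

The delivered rule is stated in two slightly different ways in common
protocol descriptions — "three consecutive licks within 1 s" versus "3–5
consecutive licks". The package implements a single rule that reproduces
both readings:

* a *burst* is a maximal run of licks whose every inter-lick interval (ILI)
  is at most the eligibility pause (1 s); maximality means each burst is
  preceded by a pause longer than 1 s or by session start;
* within a burst the trigger fires at the first lick $j \ge 3$ (counting
  within the burst) such that $L_j - L_{j-2} \le 1$ s;
* after a delivery the trigger is re-armed only once an ILI exceeds 1 s,
  i.e. at most one distractor per burst.

When the first triple of a burst is slow the trigger slides to lick 4 or 5,
which is why delivered trigger positions naturally fall in the 3–5 range.
`detect_trigger_events()` records `burst_position` so this distribution can
be audited. The implementation is checked, exactly, against an independent
quadratic brute-force scan on a thousand random lick trains.

## Trials, pauses and censoring

For each event, the *post-distractor pause* is the time to the next lick and
the trial is distracted when it exceeds the 1-s threshold (strict `>`). When
no lick follows the event the pause is right-censored at session end; such a
trial counts as distracted (the animal never resumed), but censored pauses
are excluded by default from pause-duration statistics (medians, the
log-pause ANOVA) because their value reflects session length, not behaviour.
The *pre-distractor pause* runs from the last lick before the triggering
burst to the burst's first lick and is left-censored when the burst is the
session's first licking. Duplicate lick timestamps — a contact-lickometer
artefact — are collapsed with a warning. All time bins throughout the
package are half-open, `[t, t + 1)`, with times in seconds from session
start.

## Photometry processing

The calcium-modulated (470 nm) channel is corrected with the
calcium-independent isosbestic (405 nm) channel: an ordinary least-squares
fit of the isosbestic signal onto the calcium signal over the whole session
gives a reference trace, and

$$\Delta F/F = \frac{\mathrm{ca} - \widehat{\mathrm{ca}}}{\widehat{\mathrm{ca}}}.$$

Any component of the calcium channel that is an affine function of the
isosbestic channel — bleaching and shared movement artefacts — is removed
*exactly* by this construction (the package asserts a residual below
$10^{-10}$ on affine inputs). The fit is computed once over the full
session, not piecewise; the signals are treated as acquired (the hardware
lowpass is part of acquisition, not of analysis). Fitted references that
cross zero abort with advice to re-baseline, since $\Delta F/F$ is undefined
there.

Corrected traces are cut into snips spanning 5 s before to 15 s after each
event, decimated by block averaging to a configurable rate (default 10 Hz —
the kHz acquisition rate is redundant under a 3-Hz lowpass and small arrays
keep tests fast), z-scored row-wise to the 5-s pre-event baseline, and
averaged into twenty 1-s bins. Rows whose baseline SD is zero cannot be
z-scored and are dropped with a warning. Epoch summaries use the main-text
epochs — baseline $(-5,-1)$, early post $(1,4)$, late post $(5,15)$ s —
with the figure-caption variant $(1,3)/(4,15)$ available through
`epoch_defs("caption")`; the two conventions genuinely disagree in the
source literature, so the package exposes both rather than resolving the
inconsistency. "Non-z-scored" analyses (session RMS, baseline comparisons)
operate on the $\Delta F/F$ snips without normalisation.

## Statistics

Bin-wise group comparisons use the area under the ROC curve,
$\mathrm{AUC} = P(b > a) + \tfrac12 P(b = a)$, computed from the rank-sum
statistic. Per-bin p-values come, by default, from the Mann–Whitney U test —
the test whose normalised statistic the AUC *is* — exact for small samples
without ties and tie-corrected otherwise; Welch t and label-permutation
p-values are available because the original per-bin procedure is not
documented and the deposited analysis scripts are the only authority. The
twenty bins of a panel form one comparison family and are Bonferroni
corrected ($m = 20$). A bin in which every trial of both groups has the same
value (e.g. zero licks everywhere) carries no evidence and is assigned
$p = 1$. Monte-Carlo calibration (2,000 null replicates at 15 trials/group)
confirms the family-wise error stays at or below $\alpha = 0.05$.

Day- and epoch-level contrasts use within-subject ANOVAs computed by
`stats::aov()` with `Error()` strata — one-way with
$F_{(k-1),\,(k-1)(n-1)}$ and Bonferroni-corrected paired post-hocs, two-way
reporting the epoch-by-condition interaction with Šidák-adjusted condition
contrasts within each epoch ($p_\text{adj} = 1-(1-p)^m$). The test-suite
oracle recomputes both from the raw sums-of-squares decomposition.
Sphericity corrections are not applied. Trial-level ROC analyses pool trials
across rats, matching the original pooled design; no mixed-model nesting is
attempted (a deliberate non-goal). Degenerate inputs — identical conditions,
zero-variance differences — return $F = 0$, $p = 1$ rather than `NaN`, with
the threshold set relative to the table's total variance.

## The synthetic-data generator

Because the in-vivo recordings live in an external archive, every stage is
exercised against a closed-loop generator whose defaults *are* the study
conditions:

* **Licking**: alternating burst/pause renewal process. Intra-burst ILIs are
  lognormal with median 0.14 s (≈7 Hz licking, sdlog 0.2); burst lengths are
  $1 + \mathrm{Geom}(p = 0.035)$; inter-burst pauses are lognormal with
  median 4 s (sdlog 0.6), inside the 3–6 s range typical of trained rats.
* **Closed loop**: the generator runs the trigger detector online, lick by
  lick, so its delivered-distractor log is *exactly* reproduced by
  `detect_trigger_events()` offline — an identity the tests assert for every
  fixture seed.
* **Distraction response**: a Bernoulli gate. With probability `p_distract`
  a delivered distractor interrupts the burst and the next pause is drawn
  from a lognormal (median 5 s, sdlog 0.8) truncated above the 1-s
  threshold; otherwise the burst simply continues, and can still end in a
  long pause by chance.
* **Photometry**: isosbestic = operating level + double-exponential bleach +
  shared negative artefacts + band-limited noise; calcium = affine function
  of the same shared structure + event-locked two-exponential transients
  (rise 0.2 s, decay 1.5 s, GCaMP6s-like) + independent noise.

The geometric parameter 0.035 was chosen so that the spontaneous chance of a
trigger landing on a burst's final lick — and hence being followed by a long
pause — matches the observed modelled-day distraction probability of about
0.035; it implies long lick runs (mean ≈29 licks/burst), consistent with
trained animals consuming avidly. Given that baseline, gate probabilities of
0.465 (first distraction day) and 0.21 (habituation day) produce *measured*
probabilities of ≈0.484 and ≈0.238 via
$p_\text{meas} = p + (1-p)\,q$ with $q \approx 0.035$; the estimator
inverted from this relation recovers `p_distract` with bias below 0.03 in
the package's recovery checks. Habituation is modelled as the drop in
`p_distract` with *unchanged* transient amplitudes, mirroring the
dissociation between behavioural and neural habituation. Transient
amplitudes (1.2% ΔF/F on distracted trials, 0.5% on non-distracted) and
noise (raw SD 2 on an operating level of ~400, band-limited at 3 Hz) were
set to give peak evoked z-scores around 5 and 2 — the magnitude typical of
population photometry — rather than an unrealistically clean signal.

What the generator does *not* emulate, and what passing tests therefore do
not establish about real data: the distraction gate is independent of recent
lick rate, so the empirical association between fast pre-event licking and
non-distraction is absent; there is no satiety drift, no hardware clock
jitter, and no hemodynamic or spectral structure in the noise beyond the
lowpass. Snips of nearby events overlap in time, so pooled trials are not
fully independent — exactly as in the real task, where a majority of
baselines contain the tail of a previous distractor response. One visible
consequence: with amplitudes held fixed across days, the pooled
day-1-versus-day-2 ROC can still flag an occasional bin, because the two
days differ in their *composition* of distracted versus non-distracted
trials.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run on desk-scale versions of
the design: six simulated rats, 600–1,200-s sessions, 50-Hz photometry
decimated to 10 Hz — sizes the package's authors consider ample for the
properties being checked (oracle identities are size-independent; Monte-Carlo
checks use 500–2,000 replicates). All generators are seeded; identical
configuration and seed give byte-identical sessions, and
`scripts/acceptance.R --seed N --out f.json` recomputes every reported
quantity from scratch.

## Known limitations

* The isosbestic fit is global; slow non-shared drifts (e.g. differential
  bleaching of the two fluorophore states) would leak into ΔF/F.
* Censored-pause policy (include in probabilities, exclude from durations)
  is a convention; the original analysis scripts are the only authority on
  what was done, and the choice is configurable.
* ROC p-values assume exchangeable trials within group; pooled designs
  ignore the rat as a grouping factor, as did the original pooled analyses.
* The stimulus-label vocabulary includes the single-modality labels; source
  protocol descriptions are internally inconsistent on whether every
  delivered stimulus was audiovisual, and the three-class grouping
  (white-noise-containing / tone-only / other) follows the supplementary
  analysis that needs all three classes non-empty.
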