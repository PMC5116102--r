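---
title: "Scoring actigraphy sleep and predicting sleep quality: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring actigraphy sleep and predicting sleep quality: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`actisleep` implements a complete analysis chain for minute-epoch wrist
actigraphy: rule-based scoring of sleep periods, construction of a labeled
awake-activity/sleep-quality dataset, a suite of six sequence classifiers
trained on the raw activity counts, and confusion-matrix/ROC evaluation. A
synthetic cohort generator with per-night ground truth makes the whole chain
testable end to end. This vignette explains the procedures, the tunable
parameters, and the design decisions taken where the design was genuinely
open.

## The scoring model

The substrate is a contiguous series of non-negative vertical-axis activity
counts, one per minute. All indices are 0-based and all intervals half-open
`[start, end)`, so every duration is `end - start`.

**Candidate rows.** A minute is a *candidate* (potentially asleep) when its
count is at or below `movement_threshold` (default 100 counts/min). The
threshold is deliberately above zero: sleepers generate micro-movements,
whereas runs of exact zeros indicate a removed device.

**State machine.** Scanning the candidate classification:

* while awake, a candidate run of at least `onset_run_min` minutes
  (default 15) opens a sleep period at the run's first minute — the *sleep
  onset*;
* while asleep, movement runs shorter than `close_movement_min` minutes
  (default 30) are wake bouts *inside* the period;
* a movement run of at least `close_movement_min` minutes closes the period;
  the *awakening* is the end of the last candidate run of at least
  `awakening_run_min` minutes (default 15, a knob separate from the onset
  run although the two share a default);
* the end of the recording closes an open period at its last candidate
  minute and marks it `truncated`, since the last night of a wear can never
  be followed by a 30-minute movement confirmation.

The 15/30 constants reconcile two requirements: awakenings must be robust to
brief arousals, yet wake bouts of intermediate length (6–29 min) must be
able to exist *inside* a period, otherwise the wake-after-sleep-onset
statistic below could never be positive.

**Bedtime and latency.** With no self-reported bedtime available, bedtime is
inferred as the start of the maximal *sedentary* run (counts at or below
`sedentary_threshold`) immediately preceding and adjacent to onset, clipped
at the previous period's awakening; its length is the *latency*. If the
minute before onset is active, latency is zero. When a candidate run could
belong either to sleep or to the pre-onset sedentary tail, sleep wins: onset
is the earliest qualifying minute.

`sedentary_threshold` defaults to 250 counts/min, strictly above the
movement threshold. The two cut-offs must differ for latency to be a
meaningful quantity at all: any pre-bed minute at or below the movement
threshold is itself a sleep candidate, so with equal thresholds the state
machine would absorb the whole sedentary run into the sleep period and every
latency would be identically zero. The band (100, 250] operationalises
quiet wakefulness — reading, screen use — which produces wrist counts above
the micro-movement range of sleep but well below ambulatory activity.

**WASO.** Wake after sleep onset is the summed length of all maximal
within-period wake bouts strictly longer than `waso_bout_exclusive_min`
minutes (default 5); a bout of exactly 5 minutes contributes nothing.

**Sleep efficiency and quality.** With period duration `D` (awakening −
onset), latency `L` and WASO `W`:

* total sleep time `TST = D - W`;
* time in bed `TIB = L + D`;
* sleep efficiency `SE = TST / TIB = (D - W) / (L + D)`.

A period with `SE >= efficiency_good_threshold` (default 0.85, boundary
inclusive) is labelled *good*, otherwise *poor*.

**Nonwear.** Maximal runs of exact-zero counts of at least
`nonwear_zero_run_min` minutes (default 90) are flagged as device removal.
Two modes exist. In `"naive"` mode the flags are reported but ignored: a
full-night zero block is scored as one uninterrupted candidate run and comes
out with a perfect efficiency of 1 — a real hazard of naive scoring that the
package reproduces deliberately, and that the tests probe. In `"exclude"`
mode, periods overlapping a flagged interval are marked and dropped from
dataset construction. `"exclude"` is the recommended mode for any practical
analysis; `"naive"` exists so the consequences of skipping nonwear handling
remain observable.

**Degenerate inputs.** A series shorter than the onset run yields an empty
period list, not an error. Epoch recordings with a trailing partial minute
lose that minute with a warning; gaps and irregular sampling are hard errors
because every rule above assumes contiguity. Metrics with empty denominators
are `NA`, never silently zero.

## The synthetic cohort generator

No public minute-epoch adolescent cohort with scored sleep exists, so the
generator is the package's source of ground truth. Each subject-day is
assembled as daytime activity, a pre-bed sedentary run, a sleep block with
planted wake bouts, and a forced 30-minute active tail after awakening. The
construction guarantees that the scoring rules recover the planted night
exactly: sedentary counts sit strictly inside the (movement, sedentary]
band, the minute before bedtime is active, sleep micro-movements stay at or
below the movement threshold, planted bouts exceed it, bouts are 6–25
minutes long (long enough to count towards WASO, short enough not to close
the period) and keep clear of the first and last 15 minutes of the block.
Short decoy bouts of 1–5 minutes are planted occasionally; they are wake
but, by the strict >5 rule, contribute nothing to WASO.

Defaults describe a one-week wrist-actigraphy study of 92 adolescents:
7 days per subject, nightly sleep of 360–540 minutes, latencies of 10–45
minutes, and a 62.5% share of good nights — a moderately good-heavy mix
typical of a healthy cohort. Good nights realize an efficiency in
[0.85, 0.98], poor nights in [0.55, 0.85); the generator chooses the WASO
total from the feasible set {0, 6, 7, ...} that lands the realized
efficiency inside the night's class band, erroring if duration and latency
make the band unreachable. Daytime minutes follow a zero-inflated negative
binomial (mean 350 counts/min, dispersion 1.2, 15% low/zero minutes). With
probability `p_nonwear` (default 0.05) a night is replaced by an exact-zero
block — the subject took the device off at bedtime.

The class signal available to the predictive models enters through three
interpretable daytime channels, each scaled by `coupling_strength`: total
activity volume (higher before good sleep), fragmentation (fewer low-count
minutes before good sleep) and evening activity (a calmer final two hours
before good sleep). At coupling 0 the daytime distributions of the two
classes are identical, so any classifier is at chance by construction; the
tests use this as a negative control and a strong coupling of 2 as a
positive one.

What the generator does **not** emulate: clock-time circadian structure
(sleep is placed inside the day cycle without regard to realistic bed
hours), naps, weekday/weekend differences, postural artifacts, device
calibration drift, and partial-day nonwear. Passing recovery tests
therefore demonstrates that the scoring rules are implemented exactly and
that the models can extract a planted daytime signal — not that either
would attain any particular accuracy on a real cohort.

## Dataset construction

Each scored, non-excluded sleep period yields one instance: the activity
between the previous awakening (or the series start) and this period's
bedtime, labelled with the following night's quality. Awake windows shorter
than 60 minutes are dropped. A subject contributes several instances per
week.

The split is 70/15/15 train/validation/test, randomised per class with
largest-remainder rounding so the class mix is even across partitions, and
seed-reproducible. The default partition unit is the instance; a
`unit = "subject"` option assigns whole subjects to one partition for
leakage-safe practice, at the price of approximate ratios.

Fixed-input models consume a 960-minute (16 h) window: shorter instances
are left-padded with zeros, longer ones keep their most recent 960 minutes,
on the view that activity closest to bedtime is the plausibly informative
tail. Recurrent models consume the variable-length sequence directly (with
left-padding and masking inside a mini-batch). The time-batched LSTM merges
`time_batch_window = 15` consecutive minutes into one step vector, cutting a
16-hour sequence from 960 steps to 64; the window length is a free knob.

## The classifier suite

Six architectures, each ending in a single sigmoid unit whose output is the
confidence (0–1) that the following sleep is good; 0.5 is the decision
threshold. Structural defaults are each architecture's tuned optimum:

| architecture | structure | mini-batch | dropout |
|---|---|---|---|
| `lr` | logits directly from the input window | 5 | 0.5 |
| `mlp` | one fully connected hidden layer, 15 units | 20 | 0.1 |
| `cnn` | 25 filters of length 5, max-pooling length 4, flatten | 5 | 0.0 |
| `rnn` | Elman recurrence, hidden size 75 | 5 | 0.1 |
| `lstm` | LSTM memory cells, hidden size 100 | 5 | 0.5 |
| `tb_lstm` | LSTM over 15-minute step vectors, hidden size 100 | 5 | 0.5 |

Design notes:

* "25 hidden nodes" for the convolutional model is read as 25 filters
  (the minimal structure consistent with a stated filter length and pooling
  length), not a 25-unit dense layer after pooling.
* Hidden units are rectified-linear in the feed-forward models. The
  recurrent models use tanh state updates and the canonical sigmoid/tanh
  LSTM gates: a rectified-linear recurrence iterated over ~1000 steps is
  numerically explosive, and the gated architectures are defined by their
  saturating nonlinearities.
* An MLP with `hidden_size = 0` is *exactly* logistic regression — same
  parameters, same forward pass — and the tests assert this equivalence.
* Dropout is applied (inverted, training only) to the feature vector
  feeding the output unit; for logistic regression, which has no hidden
  layer, that vector is the input window itself.
* Inputs are standardized by the training set's global mean and standard
  deviation, stored on the model and reapplied at prediction. Raw counts
  reach the thousands; without this the sigmoid saturates at initialisation
  and gradients vanish. This is a property of the training engine, not of
  the data contract.
* Weight initialisation is fan-in-scaled Gaussian under the model seed; the
  LSTM forget-gate bias starts at 1 so the memory path is open.

Training minimises mean binary cross-entropy with RMSprop (decay 0.9,
epsilon 1e-8, learning rate 0.001 by default — the rate is the one training
constant left free) over shuffled mini-batches, for at most 50 epochs.
After each epoch the model is scored on the validation set; the first epoch
whose validation accuracy falls below the previous epoch's stops training
and the previous epoch's parameters are restored (patience 1; ties
continue). Because accuracy is non-decreasing up to the stopping point, the
returned parameters are never dominated by an earlier epoch. All of
initialisation, shuffling and dropout are driven by explicit seeds, and the
gradients of every architecture are checked against central finite
differences in the test suite.

## Evaluation

Good sleep is the positive class. From the confusion matrix the package
reports accuracy, precision, recall/sensitivity, specificity and F1 (the
harmonic mean of precision and recall), each as an exact rational, `NA`
when a denominator is empty, and displayed at 4 decimal places with R's
round-half-even. The ROC curve sweeps every distinct confidence as a
threshold; AUC is the trapezoidal area, which with ties grouped equals the
rank statistic — the probability a random positive outranks a random
negative, ties counted one half — and the tests require agreement to 1e-12.

`reconstruct_confusion()` addresses a reporting situation common in
published evaluations: only rounded metrics are printed, but over a test
set of known class sizes (here 56 instances: 35 positive, 21 negative) the
rounded sensitivity and specificity pin down unique integer cell counts.
The function enumerates the candidates, errors when the printed precision
is insufficient for uniqueness, and the acceptance tests verify that each
of six published metric rows is reproduced cell-for-cell from its implied
matrix.

## Test problem sizes

The suite chooses sizes that keep a full run in a few minutes on one CPU:
state-machine and WASO oracle equivalence on 1000 random series each
(length ≤ 200); ROC/rank-AUC agreement on 1000 random score sets;
parameter recovery on cohorts of 203 nights (noise-free: onset and
awakening exact, efficiency within ±0.01; default noise: efficiency within
±0.02 on ≥95% of nights); learning checks on ~300-instance cohorts with
five seeds averaged, at reduced epoch caps (10 for the strong-signal runs,
3–5 for the shuffled-label controls) since early stopping ends most runs
within a handful of epochs anyway.

## Known limitations

* The scoring rules are definitional, not validated against
  polysomnography; the package reproduces a scoring convention, it does not
  certify it.
* Every period is scored as sleep — naps and main sleep are not
  distinguished, matching the convention adopted here.
* The generator's realism limits are listed above; in particular, measured
  model performance on synthetic cohorts says nothing quantitative about
  real adolescents.
* A minute-resolution Elman RNN over ~1000-step sequences trains poorly
  (vanishing gradients); that is expected, is the motivation for the
  time-batched variant, and is why the learnability ordering checks target
  the convolutional and gated models.
* Timezones and daylight-saving transitions are out of scope: timestamps
  are treated as UTC.
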