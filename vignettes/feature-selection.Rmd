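---
title: "Evolutionary wrapper feature selection for EEG event detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary wrapper feature selection for EEG event detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A brain-computer interface watches a multichannel EEG stream and must decide,
window by window, whether a target event just occurred. Doing this with the
full signal is wasteful: at 250 Hz, a one-second window over eight channels is
2000 input values, most of which carry no information about the event. This
package treats the choice of *which* values matter as a single optimization
problem: a genetic algorithm (GA) searches jointly over

* the sliding-window **overlap** used to segment the stream,
* the subset of **active channels**, and
* the subset of **sample points within the window, per channel**,

and scores every candidate by actually training and validating a small neural
network on the data that candidate admits (*wrapper* selection). The reference
task throughout is eye-blink detection: the blink artifact is a large,
low-frequency deflection concentrated on the prefrontal electrodes Fp1 and
Fp2, which makes ground truth unambiguous and lets a selection method prove it
can find the right channels on its own.

## Pipeline

`eegselect()` runs the whole pipeline:

1. **Preprocessing** (`preprocess()`): a mains notch filter (60 Hz, band-stop
   Butterworth of order 2, quality factor 30), a 1-12 Hz band-pass
   (Butterworth, order 4), and per-channel min-max scaling onto $[0,1]$,
   $x' = (x - x_{\min})/(x_{\max} - x_{\min})$. Both filters are applied
   forward-backward (`signal::filtfilt`), because a causal IIR filter would
   delay the waveforms relative to their event markers and silently corrupt
   the event-centred training windows. The band 1-12 Hz is where blink energy
   lives. Scaling constants are computed over the full channel by default
   (`normalize_scope = "train_only"` restricts them to the training portion
   for users who care about the mild leakage).
2. **Event-based split** (`split_by_events()`): the leading segment holding
   the first $\operatorname{round}(0.7\,E)$ of the $E$ markers becomes the
   training recording, the rest the validation recording; the cut falls at the
   midpoint between the last training marker and the first validation marker.
3. **Segmentation** (`make_training_set()`, `make_sliding_set()`): training
   positives are one window centred on each marker; those ranges are removed
   and the leftover runs are cut into negatives with stride
   $\operatorname{round}(w(1 - \text{overlap}))$. Validation and test data are
   plain sliding windows over the whole recording, labelled by marker
   containment. Window intervals are half-open and all sample indices are
   1-based, the R convention, everywhere in the package.
4. **Classifier** (`mlp_train()`): a multilayer perceptron with two hidden
   ReLU layers and one sigmoid output, sized by the geometric-pyramid rule
   below, trained by minibatch gradient descent on the mean squared error for
   10 epochs.
5. **Search** (`ga_run()`): the GA described below, with the validation
   $F_1$ of the trained classifier as fitness.

## Classifier sizing

With $IL$ inputs and $OL = 1$ output, a proportion factor
$\kappa = (IL/OL)^{1/3}$ places the hidden layers on the geometric progression
from $IL$ down to $OL$:

$$HL_1 = \operatorname{round}(OL\,\kappa^2), \qquad
  HL_2 = \operatorname{round}(OL\,\kappa),$$

so e.g. $IL = 1000$ gives a 1000-100-10-1 network. After rounding, sizes are
clamped so $IL \ge HL_1 \ge HL_2 \ge OL$ always holds. An alternative reading
of the sizing rule with $\kappa = \sqrt{IL/OL}$ makes $HL_1 = IL$, which
contradicts the strict pyramid the design calls for; it remains available as
`sizing_rule = "sqrt"` but the cube-root rule is the default.

## Training the classifier

The loss is the mean squared error
$\mathrm{MSE} = \tfrac1n \sum_i (y_i - \hat y_i)^2$ with $\hat y$ the sigmoid
output, minimized by plain minibatch gradient descent (batch size 32) for a
fixed 10 epochs. Only "backpropagation, 10 epochs" is inherent to the design;
the optimizer settings are this package's own:

* **learning rate 0.1.** With the vanishing factor $\hat y(1-\hat y)$ in the
  MSE-sigmoid gradient and only 10 epochs, a step of 0.01 leaves the network
  near its initialization (validation $F_1 \approx 0.3$ even on the true
  blink features), while 0.5 occasionally diverges. 0.1 was stable across
  seeds, overlaps, and feature subsets and is the default.
* **initialization**: symmetric uniform per layer with limit
  $\sqrt{6/(n_\text{in}+n_\text{out})}$, seeded; minibatch order is reshuffled
  each epoch from the same seed, so training is bit-reproducible and never
  perturbs the caller's RNG stream.
* the decision threshold on the sigmoid output is 0.5, inclusive.

## The genetic algorithm

Each individual is a bitstring of $7 + n + n\,m$ bits ($n$ channels, $m$
candidate sample points per channel; 2015 bits at the defaults $n=8$,
$m=250$):

* a 7-bit **Gray-coded overlap gene**, decoded by rescaling the Gray integer
  onto the 81 integer-percent levels of $[0.10, 0.90]$
  ($\text{overlap} = 0.10 + \operatorname{round}(g/127 \cdot 80)/100$). Gray
  coding makes single-bit mutations mostly small phenotypic moves. The
  rescaling map was chosen over a modulo wrap deliberately: a wrap of the 47
  surplus codes onto the low levels would double-cover overlaps below 57% and
  bias a random population 2:1 toward low overlap, a bias that reduced-scale
  runs cannot recover from.
* one **activation bit per channel** and $m$ **feature bits per channel**; a
  feature enters the classifier input iff its own bit *and* its channel's bit
  are 1, so a channel bit acts as a hard gate.

Fitness is the validation $F_1$ after regenerating both window sets at the
decoded overlap, selecting the decoded feature columns, sizing and training
the MLP, and scoring it. Phenotypes with no active features score 0 without
training. Fitness values are cached by genotype, and the MLP seed is derived
from the run seed and the genotype, so a chromosome always re-evaluates to the
same number.

Operators: binary tournament selection (with replacement; ties break toward
fewer selected features), uniform crossover with probability 0.9, uniform
mutation whose per-bit rate decays linearly from $10/\eta$ to $1/\eta$ across
generations with $\eta$ the chromosome length, and $\mu+\lambda$ survivor
selection with $\mu = \lambda = $ population size, which makes the best
fitness non-decreasing. The secondary sort toward fewer features implements
the preference for sparse solutions among equal-$F_1$ ones.

**Initial population.** Channel and feature bits are uniform random. The
overlap gene, however, is initialized stratified: the population's levels are
spread evenly across $[10\%, 90\%]$. The overlap gene is 7 bits out of 2015,
so under the mutation schedule it flips roughly once per three generations in
the whole population; with a uniform-bits init, a small population can easily
contain no competitive high-overlap lineage, and short runs then stall at
whatever overlap the early best individual carried. Stratification fixes the
coverage problem without touching the operators or the schedule.

## Scoring sliding windows

`score_windows()` reports the confusion counts and
$\mathrm{PPV} = \frac{TP}{TP+FP}$, $\mathrm{TPR} = \frac{TP}{TP+FN}$,
$F_1 = \frac{2\,\mathrm{PPV}\,\mathrm{TPR}}{\mathrm{PPV}+\mathrm{TPR}}$, with
zero-denominator cases reported as 0 and flagged.

With overlapped sliding windows, one event appears in many consecutive
windows. In the default **event mode**, positive windows that share a marker
collapse into a single detection instance — the event counts as caught if any
of its windows fires — while every no-event window stays an individual
instance (a spurious alarm is a false positive each time). This mirrors how a
detector is judged in deployment (an event is caught or missed once, however
finely the stream is sliced) and is the scoring under which high overlap is
genuinely beneficial: a finer window grid guarantees some window sits nearly
centred on each event. Window mode (`mode = "window"`), in which every window
is an instance, is available for users who want the raw picture; under it an
event-centred classifier is structurally punished for off-centre windows that
merely graze an event.

## The synthetic generator

`generate_eeg()` produces the test bed: 8 channels at 250 Hz with

* white Gaussian background (sd 10 µV) plus a 10 Hz oscillation (10 µV) per
  channel, and a common 60 Hz mains sinusoid (20 µV) — so the notch filter has
  real work to do;
* blinks: positive half-sine deflections (400 ms, 200 µV) added on Fp1 and
  Fp2 only, a marker at each peak, at least 2 s apart (defaults: 40 events in
  120 s, matching the event density of the reference capture sessions);
* single-electrode transients: blink-sized half-sines (150-400 ms,
  120-240 µV) on one random channel at a time, at 1 per second. These emulate
  electrode pops and motion artifacts, and they are what makes the two
  frontal channels *jointly* informative: without them, either frontal
  channel alone is a perfect blink detector and a sparsity-seeking search is
  right to drop the other one, which would make channel-recovery experiments
  meaningless rather than hard.

`make_problem_suite()` emits four session pairs whose event and sample counts
match the reference acquisition campaign (e.g. 183 events in 183114 samples),
for scaled reruns of the two experiments.

What the generator does **not** emulate: volume-conducted blink residue on
non-frontal channels, marker-placement jitter from hand labelling,
non-stationary background rhythms, drifting electrode impedance, and other
artifact families (ECG, EMG, chewing). Passing the recovery experiments on
this data therefore shows the search machinery works — it recovers planted
structure through the full preprocessing/segmentation/training stack — not
that the method meets any particular performance bar on real recordings.

## Numerical conventions and degenerate inputs

* stride is $\max(1, \operatorname{round}(w(1-\text{overlap})))$; sliding
  segmentation refuses an overlap whose stride rounds to 0.
* markers closer than $w/2$ to a recording edge cannot be centred; they are
  skipped with a warning and their clipped neighbourhood is still removed
  from the negative runs, so no negative window contains an event.
* constant channels make min-max scaling undefined and raise an error naming
  the channel.
* a single-class training set trains anyway with a warning (the wrapper
  treats the resulting degenerate classifier like any other candidate; its
  flagged zero metrics give it the worst fitness).
* all ties in selection and survival break toward fewer selected features,
  then toward draw order.

## Problem sizes used by the tests and experiments

The default experiment scale in this package is deliberately desk-sized:
population 20, 30 generations, 120-second synthetic sessions with 40 events
(the reference configuration — population 50, 200 generations, 31 repetitions
on 8-12-minute recordings — is a few thousand times more classifier
trainings, and nothing about the machinery changes with scale). The recovery
experiment in the test suite runs ten seeded reduced-scale searches and asks
that at least eight select both frontal channels with validation
$F_1 \ge 0.9$; a brute-force amplitude-threshold oracle is checked alongside
to certify the planted signal is recoverable at all, so a failure there would
indict the algorithm, not the data.

## Known limitations

* The classifier input is positional, and training positives are always
  event-centred, so single windows far off-centre are inherently hard; event
  mode plus high overlap is the intended operating regime.
* MSE-with-sigmoid saturates: reported MSE approaches but never reaches 0 on
  memorizable data.
* The wrapper fitness re-trains one small MLP per candidate; at paper scale
  this is the dominant cost (~10⁴ trainings per run). The per-overlap dataset
  cache and the per-genotype fitness cache in `ga_run()` remove the two most
  common redundancies.
* `split_by_events()` assumes markers are sparse relative to the recording;
  sessions whose markers are so dense that the 70% cut falls inside a blink
  get the whole blink on the training side.
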