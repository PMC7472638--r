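---
title: "Decoding contrast-driven valence shifts from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding contrast-driven valence shifts from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the chain of methods

Does changing the *contrast* of a visual scene change the emotion its
viewer feels? `eegcontrast` implements the full analysis chain behind that
question: manipulate scene contrast with a linear operator in HSV space,
decode each viewer's affective state — valence (pleasantness) and arousal
(activation), the two axes of Russell's circumplex — from their EEG with a
multi-column convolutional recognizer, and compare the decoded scores
between conditions with Welch t-tests. The expected outcome, which the
synthetic study reproduces end to end, is that contrast enhancement raises
decoded valence, contrast reduction lowers it, and arousal is untouched.

Because the benchmark EEG corpus that the recognizer is trained on (DEAP:
32 participants, 40 rated trials each) is access-restricted, the package
ships a synthetic-data module that emulates DEAP's *layout* and injects
known spectral structure. Every downstream stage is therefore testable
against ground truth, and nothing in the package depends on restricted
data.

```{r, eval = FALSE}
library(eegcontrast)
report <- run_experiment(run_config(seed = 1), out_dir = "results")
```

## The contrast operator

Scenes are converted from RGB to HSV and the saturation and value planes
are each transformed by the linear map

$$X' = X + (X - \bar X)\,\alpha,$$

where $\bar X$ is the plane mean over the image and $\alpha$ is the control
parameter ($+0.1$ for enhancement, $-0.1$ for reduction, the defaults
throughout). Hue is untouched, so the manipulation changes vividness, not
color identity. The operator has convenient algebra: the plane mean is
preserved exactly until clipping ($\mathbb E[X'] = \mathbb E[X]$), constant
images are fixed points, $\alpha = 0$ is the identity, and $\alpha' =
-\alpha/(1+\alpha)$ inverts the map. Planes are clipped to $[0,1]$ after
adjustment; the package's tests assert the mean-preservation identity
exactly in the no-clipping regime and bound the shift by the clipped mass
otherwise.

Contrast change is quantified by a decile spread: sort pixels by intensity
and subtract the mean of the darkest decile from the mean of the brightest
(decile size $\max(1,\lfloor N/10\rfloor)$). *Intensity* here is the HSV
value plane, consistent with the plane the operator manipulates; a luma
option (0.299R + 0.587G + 0.114B) exists because the choice is not forced
by anything upstream. Mean intensity is reported alongside, since the
operator's known side effect is a small mean-intensity drift — on
color-diverse scenes the contrast change dominates it by an order of
magnitude, which is the package's argument (mirrorable on any generated
scene) that valence shifts track contrast, not brightness.

## The synthetic EEG generator

The generator is the study's ground-truth machine, not a noise source. Each
trial is `baseline + content` seconds (3 s + 60 s by default) of 40-channel
signal at 512 Hz — DEAP's native rate, so the preprocessing path is
exercised realistically — with 32 EEG channels in DEAP's montage order and
8 peripheral channels of slow drift noise that exist purely so channel
exclusion has something to do.

Each EEG channel is synthesized as one random Hermitian spectrum shaped as
$1/f$ (exponent 1 by default, amplitudes set to 5 µV RMS background), and
two bands are then rescaled *exactly* on the half-spectrum before the
inverse FFT:

* **valence carrier** — the alpha band (8–13 Hz) of the frontal pair
  F3/F4 is set to total power $P_\alpha e^{\pm x/2}$ with
  $x = \beta_V \cdot \text{latent valence} + \text{participant offset} +
  \text{trial noise}$, so the left-minus-right alpha log-power difference
  equals $x$ by construction ($P_\alpha$ = (8 µV)², default slope
  $\beta_V = 3$; see the calibration note below). Frontal alpha asymmetry
  is the standard EEG valence correlate, which is why it is the carrier.
* **arousal carrier** — the beta band (13–30 Hz) of every EEG channel is
  set to power $P_\beta e^{y}$ with $y$ built the same way from latent
  arousal ($P_\beta$ = (5 µV)²); elevated beta power tracks activation.

Because the rescaling is exact, a periodogram band-power estimate recovers
the injected slopes to within a few percent, and the package asserts
recovery within 20% before preprocessing and 25% after.

Latents: the three emotion categories map to latent valence $-0.7 / 0 /
+0.7$ (negative / neutral / positive), and the contrast conditions shift
latent valence by $\pm 0.15$ — an encoding of the study's finding that
contrast moves valence without overtaking the adjacent emotion class —
while latent arousal stays 0 in every protocol condition ("condition-level
arousal null"). The arousal *slope* stays active (default 1), so a trained
recognizer genuinely learns to decode arousal from the rated corpus; it
simply finds nothing varying between conditions. Ratings on the 1–9 scale
are $5 + 4\cdot\text{latent} + \mathcal N(0, 0.5)$, clipped.

Noise and effect scales are conditions of the synthetic study, calibrated
so that its *decoded* statistical separations match the magnitude the
study design implies: trial-level noise SD 0.05 on both log-power
carriers, and participant-level offsets with SD 0.03 on the asymmetry (a
difference of homologous channels cancels most individual broadband
differences) and SD 0.3 on absolute beta power (which varies substantially
between people). The default valence slope is 3, and the reason it is not
smaller is informational, not cosmetic: a recognizer that sees 0.25 s
windows estimates a trial's alpha log-power asymmetry with an irreducible
SD of roughly 0.18 (a 5 Hz band carries barely more than one spectral
degree of freedom per window, and 48 windows tile the trial), so the
contrast conditions' $\pm 0.15$ latent shift must correspond to an
asymmetry shift well above that floor for the per-content contrast
comparisons to separate the way the full-length-trial feature does.
Two further consequences are deliberate: emotion contrasts separate at
$t$-statistics in the double digits, contrast contrasts at p between
~1e-3 and 1e-6; and because every participant contributes scores to
*both* sides of each comparison while the unpaired test treats them as
independent, the large between-participant beta variance makes the
arousal tests conservative — exactly the regime in which a real study
reports "no arousal effect".

The protocol module emits 27-trial sessions (three contrast blocks ×
three contents × three emotions, in block order: all nine original clips,
then nine contrast-enhanced, then nine reduced), each trial with a 3 s
baseline prefix. The generator also accepts per-content gains on the
contrast shift, which the pipeline derives from the scenes' contrast-metric
deltas — the mechanism by which color-diverse contents change more than
monotone ones.

What the generator does **not** emulate: eye blinks, muscle artifacts,
volume conduction, non-stationarity, or any neural dynamics beyond
stationary band power. Passing tests therefore demonstrate that the
pipeline recovers the structure it is pointed at, not that it would
perform identically on recorded EEG.

## Preprocessing

The DEAP-style chain, in order: downsample to 128 Hz, band-pass 4.0–45.0
Hz, keep the 32 EEG channels in canonical order, drop the 3 s baseline and
exactly the next 60 s (7680 samples; clips of 60–90 s are truncated).
Output is always a 32 × 7680 matrix.

Numerical choices:

* **Resampling** is done in the frequency domain (spectral truncation at
  the new Nyquist), i.e. the ideal anti-alias filter; it is zero-phase,
  exact for band-limited content, and handles any ratio that yields an
  integer output length. Edge wrap-around is masked by the discarded
  baseline.
* **Band-pass** applies the squared magnitude response of an order-4
  Butterworth — the steady-state response of the forward–backward
  (zero-phase) cascade — in the frequency domain, vectorized over
  channels. Only the response is normative: gain within 1 dB at 10 Hz,
  at least 20 dB attenuation at 1 Hz and at 60 Hz, which the tests assert
  with sinusoid oracles.
* The baseline is **discarded, not subtracted** — nothing upstream defines
  a baseline correction — but `baseline_subtract = TRUE` performs
  per-channel baseline-mean subtraction for sensitivity analyses.
* One printed source gives the band as "4.0–4.5 Hz" where its companion
  text and DEAP's published pipeline say 4.0–45.0 Hz; the package
  implements 4.0–45.0 Hz and treats the former as a typo.

The whole chain is linear, which the tests exploit:
`pipeline(a·x + b·y) = a·pipeline(x) + b·pipeline(y)` to 1e-6 relative.

## Input construction and the split

One model input is $k$ consecutive, non-overlapping 32-sample windows of
all 32 channels (32 × 32 each); inputs tile the trial with stride $32k$,
giving $\lfloor 7680/(32k)\rfloor$ inputs per trial — 48 at the default
$k = 5$, 240 at $k = 1$. Tiling is chosen because it exactly reproduces the
canonical sample counts of the 22/5/5 participant split over a 32 × 40
corpus: 880/200/200 trials and 42,240/9,600/9,600 inputs. Ratings map to
targets by $(r-5)/4$, nudged into the open interval $(-1,1)$ by $10^{-6}$
because a tanh output cannot reach $\pm 1$. The split is by participant,
never by trial, and every dataset build asserts the no-leakage invariant.

## The recognizer

Each of the $k = 5$ columns consumes one window and is the smallest
faithful reading of a "four convolutional layers, one max-pooling layer,
four fully connected layers" module: conv 3×3 ×(8, 8), max-pool 2×2,
conv 3×3 ×(16, 16), then FC 64–32–16–2. Hidden units are ReLU; the output
stage is tanh, which confines each (valence, arousal) estimate to
$(-1,1)$. Band power is an even function of the signal, and rectifying
units express even functions immediately, whereas all-odd hidden
nonlinearities must first learn biases to break symmetry — in pilot runs
the all-tanh variant needed several times more epochs to leave its
plateau. The five column outputs are fused by arithmetic mean (a
learned-weight fusion hook exists but is off by default), and a trial-level
estimate averages the fused outputs of all 48 inputs.

All convolution/backprop code is in RcppArmadillo with an im2col + GEMM
layout; its correctness oracle is a central finite-difference gradient
check (max deviation ~1e-11 on random coordinates), run in the test suite.

Training: Adam (lr 1e-3, batch 64), MSE on the (valence, arousal) pair —
the recognizer is a regressor whose outputs are binarized at 0 (the image
of rating 5) only for classification metrics — early stopping on
validation loss, best-validation checkpoint returned, every random draw
seeded. Inputs are standardized by the training set's global mean/SD,
stored in the model. The widths above are deliberately modest: the model
is sized for single-CPU training in minutes, and every width is a
constructor argument for anyone who wants the larger variant. Because
training inputs from one trial share that trial's injected band powers,
the experiment drivers thin the training tiling (keep every third input)
to spend the epoch budget on trial diversity rather than redundancy;
evaluation always uses the full tiling.

One spec-level invariant is implemented in a weaker but honest form:
training is bit-reproducible for a fixed (data, seed) pair, but permuting
the training rows changes mini-batch composition and hence the trajectory.
Order-invariance would require full-batch training, which nothing here
uses.

## The statistics

Trial-level decoded scores are aggregated to participant × content ×
condition means — the participant mean is the inferential unit — and
compared with two-sided Welch (unequal-variance) t-tests at significance
threshold 0.01: neutral-vs-positive and neutral-vs-negative per content
(the emotion table), and original-vs-up / original-vs-down per content ×
emotion (the contrast table), each on both valence and arousal. Raw p
values are reported, matching the analysis style the package reproduces; a
Bonferroni column is emitted alongside for the reader. A pooled-variance
Student variant is a flag. The ordering analysis checks, per content, that
shifted valence never crosses the adjacent original emotion (neutral+up
stays below positive, positive−down stays above neutral, negative+up stays
below neutral). The ranking analysis orders contents by
|mean valence(up) − mean valence(down)|, ties broken by content id, with
each content's contrast-metric delta attached.

Null calibration: with both injected effects at zero, the measured
asymmetry of a generated trial is *exactly* its Gaussian trial noise (a
consequence of the exact band rescaling), so group Welch tests on
generator output are exactly calibrated; 500 replicates of 6-vs-6 trials
put the empirical rejection rate at 0.01 within binomial error.

## Problem sizes and orchestration

`run_experiment()` executes scene generation → contrast reports → corpus
generation → preprocessing → input construction → training → protocol
decoding → statistics as one seeded run; a single master seed fans out to
per-stage, per-participant and per-trial seeds through a mixing function,
so any stage can be regenerated independently and two runs with the same
config are byte-identical. There is no intermediate-resume mechanism;
re-entry is deterministic re-execution, which the seed fan-out makes
equivalent.

The experiment drivers run at sizes chosen to keep a full single-CPU
analysis in minutes while leaving the statistical conclusions
unambiguous: the recognizer benchmark uses 200 trials per class (10/4/6
participants of 20 × 20), six training epochs and a label-shuffled
control; the protocol analysis uses a 16 × 15 training corpus (10/3/3
split) and 12 protocol participants (324 session trials); the calibration
uses 500 replicates of short (5 s) trials, since type-I error depends on
neither trial length nor group size. The full-size corpus arithmetic (1280 trials,
42,240 training inputs) is verified structurally via the manifest path,
which computes counts without materializing gigabytes of windows.

## Known limitations

* The generator's band-power world is far simpler than cortical EEG; in
  particular there are no artifacts, so the pipeline's robustness to real
  contamination is untested by design.
* The recognizer's internals beyond the stage counts (widths, pooling
  position) are package choices; the upstream description pins only the
  module structure and the output nonlinearity.
* Welch tests treat condition samples as independent although the protocol
  is within-participant; with the generator's participant-effect structure
  this is conservative, and a paired analysis would only sharpen the
  valence conclusions.
* Scene generation is a patchwork model of "diverse" vs "monotone" color
  statistics, sufficient to drive the contrast metric and the ranking
  mechanism, not a model of natural images.
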