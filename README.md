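# eegcontrast

Does turning up the *contrast* of a visual scene change the emotion its
viewer feels? This package implements, as a tested R analysis chain, a
study design that answers that question with EEG: scenes are manipulated by
a linear contrast operator in HSV space, viewers' affective state is
decoded from their EEG by a multi-column convolutional recognizer, and the
decoded scores are compared between conditions with Welch t-tests. The
expected result — reproduced end to end on synthetic data — is that
contrast enhancement raises decoded **valence** (pleasantness), reduction
lowers it, and **arousal** (activation) is untouched.

It is written for researchers in affective computing / EEG analysis who
want a fully inspectable, dependency-light reimplementation of this kind
of pipeline, with every stage testable against known ground truth.

## The core methods

**Contrast operator.** Images are converted RGB → HSV and the saturation
and value planes are transformed by

&nbsp;&nbsp;&nbsp;&nbsp;X′ = X + (X − X̄)·α,

with α = +0.1 for enhancement and −0.1 for reduction (hue untouched,
planes clipped to [0,1]). Contrast change is measured by the decile
spread: mean intensity of the brightest 10% of pixels minus that of the
darkest 10%.

**EEG pipeline (DEAP-style).** Trials are downsampled to 128 Hz,
band-passed 4.0–45.0 Hz, reduced to the 32 EEG channels of the DEAP
montage, trimmed of their 3 s baseline and cropped to 60 s (32 × 7680).
Each model input stacks k = 5 consecutive non-overlapping 32-channel ×
32-sample windows; a 32-participant × 40-trial corpus under the standard
22/5/5 participant split yields 880/200/200 trials and
42,240/9,600/9,600 inputs.

**Recognizer.** k = 5 structurally identical columns (4 convolutions, one
max-pool, 4 fully connected stages; ReLU hidden, tanh output), one window
per column, fused by arithmetic mean into a (valence, arousal) pair in
(−1, 1); trained by Adam on an MSE regression loss against rating targets
(r − 5)/4, with binarization at 0 only for classification metrics. The
convolution/backprop core is RcppArmadillo, verified by a
finite-difference gradient check.

**Synthetic ground truth.** Because the DEAP corpus is access-restricted,
a generator emulates its layout and injects label-linked spectral
structure over a 1/f floor: latent valence as frontal (F3−F4) alpha-band
(8–13 Hz) log-power asymmetry, latent arousal as beta-band (13–30 Hz)
power. Band powers are rescaled exactly in the frequency domain, so every
injected effect is recoverable by construction. The 27-trial session
protocol (3 contrast blocks × 3 contents × 3 emotions) and the condition
latents (−0.7/0/+0.7 per emotion, ±0.15 for contrast up/down on valence
only) encode the study design.

**Statistics.** Decoded trial scores are aggregated to participant ×
content × condition means and compared by two-sided Welch t-tests at
α = 0.01: emotion pairs (neutral–positive, neutral–negative) and contrast
pairs (original–up, original–down), on both valence and arousal; plus an
ordering analysis (shifted valence must not cross the adjacent original
emotion) and a ranking of contents by |valence(up) − valence(down)|.

## Worked example

```r
library(eegcontrast)

# contrast-enhance a synthetic color-diverse scene
scene <- generate_scene("diverse", 64, 64, seed = 7)
rep <- contrast_report(scene, adjust_contrast(scene, 0.1))
rep$contrast_before; rep$contrast_after; rep$mean_intensity_delta
#> [1] 0.6417762
#> [1] 0.7059538
#> [1] 0

# one positive-emotion, contrast-up trial through the EEG chain
cfg <- synth_config(seed = 7)
tr <- generate_trial(cfg, seed = 42,
                     condition = list(emotion = "positive", contrast = "up"))
tr$latent_valence                       # 0.7 (positive) + 0.15 (contrast up)
#> [1] 0.85
pt <- preprocess_trial(tr)              # 32 x 7680 at 128 Hz
alpha_asymmetry(pt)                     # ~ slope (3) x latent valence
#> [1] 2.64196

# Welch comparison of two score samples
welch_ttest(c(2.1, 2.5, 1.9, 2.3), c(1.1, 1.4, 0.9, 1.2))
#> $t [1] 6.331738   $df [1] 5.741652   $p [1] 0.0008610337   $significant TRUE
```

The contrast metric rises by +0.064 while mean intensity does not move —
the operator changes spread, not brightness. The processed trial's alpha
asymmetry (2.64) tracks slope × latent valence (3 × 0.85 = 2.55) up to
trial noise, which is exactly the structure the recognizer learns.

The numbered scripts under `analysis/` run the full studies and write
their tables to `results/`: scene contrast reports (`01`), the high-SNR
recognizer benchmark (`02`), the protocol analysis with the emotion and
contrast t-test tables, orderings and ranking (`03`), the scene-diversity
ranking study (`04`), and the null calibration (`05`). The heavier ones
take a few minutes each on one CPU.

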