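---
title: "Multimodal drowsiness detection: models, parameters, and design choices"
author: "DrowsyFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal drowsiness detection: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DrowsyFusion)
```

# The problem

A driver slipping into drowsiness shows coordinated changes across several
observable channels: the eyelids droop and stay closed longer (visible both
in eye images and in the eye-aspect-ratio of facial landmarks), spontaneous
blinking slows or stops (visible in periocular EOG electrodes), and the EEG
shifts toward alpha-band (8--12 Hz) activity. No single channel is reliable
in a moving vehicle — image analysis suffers from lighting and head motion,
electrode signals from noise and discomfort — so this package scores each
channel independently on a sliding window and fuses the three scores with a
Mamdani fuzzy inference system into a crisp drowsy/alert decision.

This vignette documents each stage's model, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data generators do
and do not emulate.

# Eye aspect ratio

Six landmarks trace one eye: corners $p_1$ (outer) and $p_4$ (inner), upper
lid $p_2, p_3$, lower lid $p_6, p_5$. The metric is

$$\mathrm{EAR} = \frac{\lVert p_2 - p_6\rVert + \lVert p_3 - p_5\rVert}
                     {2\,\lVert p_1 - p_4\rVert},$$

a ratio of Euclidean distances, hence invariant to translation, rotation and
uniform scaling of the face in the image — the property that makes it usable
without camera calibration. Open eyes give values around 0.2--0.4; a closed
lid gives 0.

Conventions fixed by this package (the underlying method leaves them open):

* **Threshold 0.2** (configurable) separates open from closed; this is the
  customary value in the EAR literature. Equality counts as *open*, so
  `value < threshold` means closed.
* Closed intervals are reported as **half-open, 0-based frame index ranges**
  `[start, end)`.
* **Blink duration gate**: closures lasting 0.04--0.5 s are blinks; longer
  closures are *prolonged closure*, deliberately excluded from blink
  statistics because the fusion stage must see absent blinking and sustained
  closure as distinct evidence. The event time is the interval midpoint.

The EAR channel score for fusion is the open-frame fraction of the window,
which complements the closed-frame fraction exactly to 1.

# EOG blink signature

Three periocular electrodes each record one of two pulse waveform classes:
S1, a biphasic pulse, and S2, a monophasic hump. A blink is identified by
the per-channel configuration **EOG1 = S2, EOG2 = S1, EOG3 = S1**, a
configuration no other eye movement produces; triples of coincident pulses
of exactly those kinds, one per channel, are therefore blinks.

The recorded pulse shapes are only available graphically, so the package
uses parametric stand-ins: S1 is a derivative-of-Gaussian, S2 a Gaussian
hump, both with a default 150 ms nominal width. Detection is matched
filtering: normalized cross-correlation against both templates, local
maxima above `minCorr = 0.7`, non-maximum suppression within one template
length (so the same samples never yield two overlapping pulses, and the
best-matching template decides the kind). Because Pearson correlation is
scale-invariant, shape alone cannot reject a smooth noise wiggle; an
amplitude gate therefore additionally requires the local excursion to reach
`minAmp = 3.5` robust (MAD-based) noise standard deviations.

Triple matching is **greedy earliest-first** with single-use pulses: it is
deterministic and cheap, and the test suite verifies on every synthetic
stream that it finds as many blinks as an exhaustive enumeration of disjoint
candidate triples. Coincidence tolerance defaults to 50 ms; preprocessing is
detrending plus a zero-phase Butterworth band-pass, 0.5--20 Hz at a default
250 Hz sampling rate. Electrode montage polarity is a configuration matter
(the sign convention of the amplifier is not part of the method).

The EOG channel score maps the window's blink rate $r$ linearly by its
departure from an alert baseline $r_0$ (default 15 blinks/min, a typical
relaxed adult rate): $\mathrm{score} = \max(0, 1 - |r - r_0|/r_0)$. Both
absent blinking ($r = 0$) and strongly elevated blinking score 0; this
operationalization of "blink behavior departs from baseline" is the
package's own, as the published system does not state one.

# EEG spectral criterion

The PSD of each epoch is estimated by Welch's averaged modified periodogram:
mean removal, 1 s Hann-windowed segments, 50% overlap. With these defaults
the grid spacing is 1 Hz and the integral of the density matches the
time-domain variance within windowing tolerance (checked as a Parseval-style
property test). Band powers integrate the density over delta (0.5--4 Hz),
theta (4--7 Hz), alpha (8--12 Hz) and beta (13--30 Hz); the (7, 8) Hz gap
between the stated theta and alpha edges is left **unassigned on purpose**,
matching the band definitions as printed rather than smoothing them.

Drowsiness is flagged by a peak in the 10--12 Hz domain. The package
operationalizes "peak amplitude" as a **prominence ratio**: the PSD maximum
over 10--12 Hz divided by the median PSD over 0.5--30 Hz excluding 8--12 Hz.
White noise gives a ratio near 1; an alpha-dominant epoch gives a ratio far
above 1. The classification threshold defaults to 3.0 (configurable); the
published criterion is qualitative, so both the ratio and its threshold are
documented package decisions. The EEG fusion score maps the ratio linearly,
$\mathrm{score} = \mathrm{clip}(1 - \mathrm{ratio}/2\,\mathrm{threshold})$,
placing the classification boundary at score 0.5.

Either EOG blink rate or EEG alpha prominence can feed the first fusion
input; which one is a pipeline configuration (`channel1Source`), not a code
change.

# Eye-state image classifiers

Images are cropped and down-sampled to **51 × 51** pixels by area averaging
(each output pixel is the mean of the source area it covers, which
anti-aliases; upsampling is refused), rescaled into $[0,1]$ by the image
maximum when they arrive on a wider scale, and flattened **row by row** into
the 2601-element input vector.

Two variants are implemented:

* **MLP**: 2601 inputs, 10 logistic hidden units, 2-way softmax output
  (open-or-half vs. closed), full-batch training on the cross-entropy
  objective with an L2 penalty of $10^{-4}$.
* **Stacked autoencoder**: greedy layer-wise pretraining — a 100-unit code
  autoencoder on the pixels, a 50-unit code autoencoder on the first codes,
  a softmax layer on the second codes — then end-to-end fine-tuning. The
  hidden widths 100/50 are package defaults; the published structure shows
  two hidden layers without sizes.

The original training used a numerical toolbox whose optimizer, activations
and output encoding are not stated; this package fixes them as: logistic
hidden units, softmax/cross-entropy output, seeded Glorot-uniform
initialization, and L-BFGS on the analytic full-batch gradient. Training is
bit-reproducible given (data, seed, hyperparameters). Iteration caps default
to 500 for the MLP and 15 (per pretraining stage) / 40 (fine-tuning) for the
stacked autoencoder — on the separable 140-image synthetic corpus both
converge to zero training error well inside these caps, and the caps keep a
10-seed training sweep to roughly a minute of CPU.

The corpus design mirrors the published experiment: 200 images, 70 + 70 for
training, 60 (30 + 30 balanced) held out. The published account does not
say whether its two evaluations used distinct holdouts, so the package
reuses one 60-image holdout for both variants. An internal validation split
is unnecessary under full-batch training to a cap, so none is made beyond
the 140/60 division. The face-recognition fusion score is the fraction of
window frames predicted open.

# Fuzzy fusion

Three unit-interval scores (channel 1 = EEG or EOG, channel 2 = face
recognition, channel 3 = EAR; high = alert evidence) enter a Mamdani system:

* Input terms: L = trapezoid $(0, 0, 0.5, 0.9)$, H = $(0.1, 0.5, 1, 1)$.
* Output terms: DR = $(0, 0, 0.3, 0.5)$, AL = $(0.5, 0.7, 1, 1)$.
* Rule base: all eight L/H corners, consequent **DR iff at least two
  antecedents are L** — the majority rule, of which four rows are explicitly
  tabulated in the source material and the other four follow from the same
  sentence.
* AND = min, implication = clip, aggregation = max, defuzzification =
  centroid (trapezoidal integration on a 501-point grid).

The published membership functions are shown graphically without
breakpoints, so the defaults are package decisions, made under two
constraints. First, **symmetry**: L mirrors onto H and DR onto AL, so the
eight corner decisions are forced by the rule base alone and the system is
exactly invariant under permutation of its inputs. Second, **overlapping
plateaus meeting at 0.5**, so that every score is a full member of at least
one input term ($\max(L, H) = 1$ everywhere). The second constraint is what
makes the crisp surface *exactly* monotone non-decreasing in each input —
more alert evidence never increases the drowsiness reading, verified on a
$21^3$ grid. With narrower term overlap (e.g. L falling to 0 at 0.6 and H
rising from 0.4), mid-range scores belong only weakly to both terms, every
rule under-fires, and the min/max Mamdani stack with a mixed-consequent
majority rule base produces non-monotone ripples around 0.5: a DR-consequent
rule containing one H antecedent (say L, L, H) *gains* firing strength as
that input rises toward 1, and nothing absorbs the gain unless the paired
rule (L, L, L) can fire fully on its side of the crossover. Every breakpoint
remains configurable for recalibration. Consequences of the symmetry:
scores $(0.5, 0.5, 0.5)$ defuzzify to exactly 0.5, and the documented
tie-break labels that ALERT (drowsy requires `crisp < 0.5`, consistent with
DR sitting below AL on the output axis).

The source material mentions logistic regression once as a decision method
but specifies only the fuzzy system (rules, membership shapes, surfaces);
the fuzzy system is implemented as the decision stage and logistic
regression is not.

# Pipeline

`runPipeline()` scores each modality over sliding windows (default 10 s
window, 5 s hop — long enough for blink-rate statistics to be meaningful)
and fuses per window; no state crosses windows. The published system
describes the three evidences as arriving simultaneously but not how they
are time-aligned; the windowed-score design is this package's explicit
resolution of that gap. `emitWarnings()` opens a warning after
`persistence = 2` consecutive drowsy windows and closes it at the next alert
window; vehicle intervention beyond the warning event is out of scope.

# Synthetic data

The generators replace in-vehicle sensors; all are pure functions of
(parameters, seed).

* **Eye images** are schematic (lid aperture + iris disk vs. lid crease,
  plus seeded noise and mild geometry jitter), not photorealistic. This is
  the honest target: the classifiers consume 51 × 51 rasters in which only
  coarse structure survives down-sampling anyway. Passing tests show the
  training and evaluation machinery reproduces the published all-correct
  results *on separable data*; they do not show the networks would separate
  real in-car imagery.
* **Landmarks** follow a parametric eye geometry whose EAR is strictly
  increasing in the openness parameter, giving an analytic handle for
  monotonicity tests.
* **EOG streams** embed the S2/S1/S1 blink signature with per-channel
  timing jitter below half the coincidence tolerance, optional distractor
  triples (e.g. S1/S1/S1) that must *not* be detected as blinks, and noise
  at a configurable amplitude SNR. Distractor movements are modeled only at
  the pulse-configuration level, since the signature — not the waveform
  detail — is what distinguishes movements.
* **EEG epochs**: drowsy = a seeded oscillation in 10--12 Hz over pink-ish
  background noise; alert = beta-weighted (13--30 Hz) broadband over the
  same background. Real EEG nonstationarity, artifacts and inter-subject
  variability are not modeled.
* The default session scale mirrors the published experiment: a 200-image
  corpus and 60 s sequences. Video defaults to an integer 25 fps
  (configurable); the published sequences imply a non-integer ~32.9 fps
  (1975 frames per 60 s), which the integer default trades for exact
  frame/time arithmetic.

Problem sizes used in the test suite and the acceptance script — 10
training seeds per classifier variant, 20 EOG streams, 200 EEG epochs, one
60 s end-to-end session — are the package's chosen desk-scale design; they
mirror the published counts where those exist (image corpus and splits) and
otherwise are large enough for the stochastic checks to be stable.

# Known limitations

* Landmarks are an input format, not detected from images; face detection
  and tracking are upstream of this package.
* The EOG S1/S2 templates, the EEG prominence criterion, the channel-score
  maps, the membership breakpoints, and the windowing are all documented
  package decisions where the published method is qualitative; each is
  configurable so recalibration against real recordings is a configuration
  exercise, not a code change.
* Per-driver calibration (the published system notes biological parameters
  differ between people) is not implemented; thresholds are global.
* The published on-road recordings are unavailable, so no claim is made
  about on-road performance; all quantitative results in this package are
  on synthetic data.
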