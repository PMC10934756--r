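# DrowsyFusion

Multimodal driver-drowsiness detection with Mamdani fuzzy sensor fusion,
for R.

A driver slipping into drowsiness shows coordinated changes across several
channels: the eyelids droop and stay closed longer, spontaneous blinking
slows or stops, and the EEG shifts toward alpha-band activity. None of
these channels is reliable alone in a vehicle, so this package scores each
one independently over sliding windows and fuses the scores into a crisp
drowsy/alert decision. It is aimed at researchers prototyping driver-state
monitoring and at anyone who needs a tested, fully synthetic-data-driven
reference implementation of the individual detection stages.

## What it implements

* **Eye aspect ratio (EAR)** over six eye-contour landmarks
  ($p_1$/$p_4$ corners, $p_2,p_3$ upper lid, $p_6,p_5$ lower lid):

  $$\mathrm{EAR} = \frac{\lVert p_2-p_6\rVert + \lVert p_3-p_5\rVert}
                        {2\lVert p_1-p_4\rVert}$$

  with threshold segmentation of closed-eye intervals, blink extraction
  (duration-gated), and blink statistics.
* **EOG blink signature**: matched-filter detection of S1 (biphasic) and S2
  (monophasic) pulses on three periocular channels; a blink is the
  coincident configuration EOG1 = S2, EOG2 = S1, EOG3 = S1, which no other
  eye movement produces.
* **EEG spectral analysis**: Welch PSD, delta/theta/alpha/beta band powers
  (0.5–4, 4–7, 8–12, 13–30 Hz), and a drowsiness criterion based on the
  prominence of the spectral peak in the 10–12 Hz domain.
* **Eye-state image classifiers**: 51 × 51 grayscale eye rasters flattened
  to 2601 inputs, classified open-or-half vs. closed by (a) a 2601–10–2
  feed-forward network and (b) a stacked autoencoder (100/50 code layers,
  greedy pretraining + fine-tuning). Training is seeded and
  bit-reproducible.
* **Mamdani fuzzy fusion**: three unit-interval channel scores, L/H input
  trapezoids, DR/AL output trapezoids, the 8-corner majority rule base
  (drowsy iff at least two inputs are low), min/clip/max inference and
  centroid defuzzification.
* **Synthetic generators** for every modality (images, landmarks, EOG,
  EEG, whole sessions) with ground truth, so the entire pipeline is
  testable without sensor recordings.

## Worked example

```r
library(DrowsyFusion)

# a 60 s synthetic session: regular blinking and open eyes, except a
# drowsy episode from t = 20 s to t = 40 s (no blinks, closed eyes,
# alpha-dominant EEG)
blinks <- setdiff(seq(2, 58, by = 4), seq(22, 38, by = 4))
scen <- SessionScenario(60, blinkTimes = blinks,
                        drowsyWindows = matrix(c(20, 40), 1), seed = 3)
sess <- genSession(scen)

# train the eye-state network on the standard 200-image corpus
# (70 + 70 train, 60 held out)
sp <- splitEyeCorpus(genEyeCorpus(100, seed = 42), 70)
model <- trainEyeStateMLP(sp$train, seed = 1)
evaluateModel(model, sp$test)
#>               predicted
#> actual         OPEN_OR_HALF CLOSED
#>   OPEN_OR_HALF           30      0
#>   CLOSED                  0     30

tl <- runPipeline(sess, model)
timelineWindows(tl)
#>    start end score1 score2 score3     crisp  label
#> 1      0  10    0.8   0.96  0.972 0.7958350  ALERT
#> 2      5  15    0.8   0.94  0.964 0.7958350  ALERT
#> 3     10  20    0.8   0.96  0.968 0.7958350  ALERT
#> 4     15  25    0.4   0.50  0.488 0.4959947 DROWSY
#> 5     20  30    0.0   0.00  0.000 0.2041650 DROWSY
#> 6     25  35    0.0   0.00  0.000 0.2041650 DROWSY
#> 7     30  40    0.0   0.00  0.000 0.2041650 DROWSY
#> 8     35  45    0.4   0.48  0.488 0.4932473 DROWSY
#> 9     40  50    0.8   0.96  0.972 0.7958350  ALERT
#> 10    45  55    0.8   0.94  0.964 0.7958350  ALERT
#> 11    50  60    0.8   0.94  0.968 0.7958350  ALERT

emitWarnings(tl, persistence = 2)
#>   start end nWindows
#> 1    15  45        5
```

Reading the output: `score1` is the EOG blink-rate score (1 at the alert
baseline of 15 blinks/min, 0 when blinking stops), `score2` the fraction of
frames the image classifier calls open, `score3` the open-eye fraction of
the EAR trace. The fused `crisp` value is the centroid of the aggregated
fuzzy output; values below 0.5 are labeled DROWSY. The drowsy episode
embedded at 20–40 s is flagged (including the two windows straddling its
edges), everything else is ALERT, and the persistence rule converts the
drowsy run into a single warning event.

Single-modality use is just as direct: `computeEAR()` on a landmark
matrix, `detectBlinkSignature(detectStreamPulses(preprocessEog(stream)))`
for EOG, `classifyEpoch(computePsd(epoch))` for EEG, and
`fuzzyDecide(fuzzySystem(), c(s1, s2, s3))` for fusion. A command-line
front end with `simulate` / `train` / `detect` / `fuse` / `run` /
`evaluate` subcommands is installed at `inst/scripts/drowsyfusion`.

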