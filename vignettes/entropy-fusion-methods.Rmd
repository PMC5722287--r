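---
title: "Multiple-entropy fusion for EEG fatigue detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-entropy fusion for EEG fatigue detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrofuse)
```

## The problem

Sustained driving induces a fatigue state whose EEG signature is a build-up
of low-frequency (delta/theta) rhythmic activity: the signal becomes more
*regular*. Entropy statistics quantify exactly this regularity, so a fused
vector of several entropy measures per channel makes a natural feature set
for classifying 1-second EEG epochs as alert ("normal") or fatigued.
`entrofuse` implements that pipeline end to end: zero-phase filtering,
epoching, four entropy measures plus an autoregressive-coefficient baseline,
per-subject min-max normalisation, four classifiers under leave-one-out
(LOO) cross-validation, and an accuracy-based electrode-ranking statistic
for reduced-montage operation.

## Feature definitions

For a series $x_1,\dots,x_N$ (one channel of one epoch), with embedding
dimension $m = 2$ and tolerance $r = 0.2\,\mathrm{SD}(x)$ recomputed per
channel per epoch:

* **Spectral entropy (PE)** — Shannon entropy of the normalised periodogram,
  DC bin excluded and bins restricted to the 0.15–45 Hz analysis band,
  divided by $\log$(bin count) so $PE \in [0,1]$. A 1 s epoch at 1000 Hz
  has 1 Hz bin spacing, so the band holds 45 bins.
* **Approximate entropy (AE)** — Pincus'
  $\Phi^m(r) - \Phi^{m+1}(r)$ with Chebyshev distance, self-matches
  included.
* **Sample entropy (SE)** — Richman–Moorman $-\ln(A/B)$, self-matches
  excluded, both template lengths drawn from the same $N-m$ templates.
* **Fuzzy entropy (FE)** — Chen's graded variant: templates are
  mean-centred and the hard threshold is replaced by membership
  $e^{-(d/r)^{n}}$ with gradient $n = 2$.
* **AR baseline** — the $p$ Yule–Walker coefficients (order 10 by default),
  innovation variance excluded.

Features are concatenated channel-major (channel 1: PE, AE, SE, FE;
channel 2: …), giving $30 \times 4 = 120$ columns for the full montage (or
$30 p$ columns in AR mode; with $p = 10$ that is 300 — the AR feature space
is deliberately larger than the fusion space and is used only as a
baseline). Each feature column is rescaled per subject by
$x' = (\mathrm{newMax}-\mathrm{newMin})\,
\frac{x - x_{\min}}{x_{\max} - x_{\min}} + \mathrm{newMin}$
with target range $[-1, 1]$; a constant column maps to the midpoint.

Numerical conventions worth stating: the SE sentinel for $A = 0$ is the
finite $\ln B$ rather than infinity, so feature matrices stay finite; AE,
SE and FE return exactly 0 on constant input; the Chebyshev metric and the
shared-template convention for SE/FE follow the canonical definitions, and
all three kernels are verified against independent brute-force
$O(N^2)$ enumeration oracles to $10^{-10}$ in the test suite.

## Evaluation protocol

Epoch-level LOO is the protocol of record: each epoch is held out once, the
classifier is refitted, and pooled predictions form one confusion matrix
(fatigue is the positive class; Acc/Sn/Sp are reported as percentages,
curves as ROC and PR with trapezoidal areas). Two guards differ from a
naive implementation and deserve explanation:

* **Per-fold normalisation.** Min-max statistics are refitted on each
  fold's training rows only and applied to the held-out rows. Fitting on
  all rows would leak the held-out epoch's amplitude into training.
* **Class-balance corrections.** An LOO training fold is always one sample
  short in the held-out class. The SVM uses inverse-frequency class
  weights and the random forest a balanced stratified bootstrap so that an
  uninformative fit does not systematically favour the majority class.

A subtler estimator artifact matters for interpreting near-chance results:
when the SVM cost is so small that every training point is a bound support
vector, the decision threshold is calibrated on training points whose
kernel self-similarity term a held-out point lacks, and LOO accuracy on
uninformative features collapses *below* chance. Such degenerate operating
points score poorly in LOO, which is precisely why the pipeline's
hyperparameter step — a grid search over a $\log_2$ lattice of
$(c, g)$ maximising LOO accuracy, ties broken towards the smallest values —
never selects them. The full protocol is therefore grid search followed by
evaluation at the selected operating point, and that is what the
end-to-end checks run. On strongly separable synthetic cohorts the search
reproducibly selects $c = 2^{-1}$, $g = 2^{-5}$.

Classifier defaults: feedforward network with 20 logistic hidden units
(fitted by `nnet`, a quasi-Newton analogue of the reference
Levenberg–Marquardt configuration), random forest with 500 trees and 22
candidate variables per split, nearest-neighbour vote with $k = 5$ (the
reference protocol does not state $K$; 5 is a conventional small odd
choice). Stochastic classifiers are seeded and run with 5 restarts by
default, combined by majority vote (predictions) and averaging (scores),
which keeps pooled confusion counts integral.

## Electrode ranking

With per-electrode accuracy $\mathrm{Acc}(i)$ (classifier restricted to
that electrode's four entropy columns) and pairwise accuracy
$\mathrm{Acc}(ij)$ (union of both electrodes' columns),

$$V_i = \mathrm{Acc}(i) + \frac{1}{N}\sum_{j \ne i}
\bigl(\mathrm{Acc}(ij) + \mathrm{Acc}(i) - \mathrm{Acc}(j)\bigr),$$

where the divisor is generalised from the fixed 30 of the original
formulation to the electrode count $N$. Accuracies enter as fractions in
$[0,1]$. The statistic rewards electrodes that are informative alone and
that improve their partners in pairs; the antisymmetric
$\mathrm{Acc}(i)-\mathrm{Acc}(j)$ terms cancel when summed over all
electrodes. For topographic display, weights are min-max rescaled to
$[0,1]$, values below 0.8 are zeroed, 0.8 is subtracted from the rest, and
one decimal is retained. Ranking ties preserve montage order. The four
scalp regions shipped as defaults (A = TP7, T5, P3, CP3; B = FCz; C = T4;
D = O1, Oz, T6) are a configuration mapping, not a geometric inference.

Note an internal-scale caveat: with uniform accuracies near 0.9 the formula
yields $V \approx 1.77$ for $N = 30$, so $V$ is *not* confined to $[0,1]$;
the statistic is used only for ranking and thresholded display, where the
absolute scale is irrelevant.

## The synthetic cohort generator

No public recordings accompany the protocol this package implements, so a
generator stands in for the cohort, defaulting to the study geometry:
12 subjects, 30 channels (10–20 montage), 1000 Hz, 5 minutes per state.
Each channel is the unit-variance mixture

$$x(t) = a\left(\sqrt{\rho}\,\mathrm{osc}(t) +
\sqrt{1-\rho}\,\varepsilon(t)\right),$$

where `osc` is band-limited delta/theta activity (frequency and phase
redrawn every 1 s block, so the signal is rhythmic but not periodic),
$\varepsilon$ is white noise, $a = 40\,\mu V$, and $\rho$ — the oscillatory
regularity — is $0.15$ in the normal state, rising in the fatigue state by
`effect_size` $\times\ w_{ch} \times (0.85 - 0.15)$. Planted electrodes
(default T6, P3, TP7, O1, the reference ranking's top four) carry weight
$w = 1$; all others $w = 0.2$, so fatigue is global but strongest at the
planted sites. Raising $\rho$ lowers all four entropies, which is the
signal property the features measure — the generator encodes the
*mechanism* (regularity change), not merely a mean shift.

What the generator does **not** emulate: $1/f$ background spectra, volume
conduction and inter-channel correlation, ocular/muscle artifacts,
non-stationary drift of the fatigue level, and between-subject variability
beyond independent noise draws. Passing the end-to-end checks therefore
demonstrates that the pipeline recovers a planted regularity contrast, not
that it would reach the same numbers on real road-simulator EEG.

Every recording is drawn from a seed derived deterministically from
`(cohort seed, subject, state)`, so cohorts are reproducible and
recordings pairwise distinct; at `effect_size = 0` the two states are
exchangeable draws.

## Problem sizes used by the checks

Segmentation counts use the full study geometry (1000 Hz, 5 min,
12 subjects — 300 epochs per recording, 3600 per state). The
classification and electrode-recovery checks run on scaled-down cohorts —
1 subject, 200 Hz, 30 s per state (60 epochs), 20 seeds per condition,
with a coarse 3 × 3 grid lattice and the holdout estimator for the
30-electrode pairwise accuracy matrix — sizes chosen so the whole battery
runs on a desk machine in minutes while leaving the per-condition means
stable to a few percent. At these sizes the grid-searched SVM reaches 100%
LOO accuracy at `effect_size = 0.8` and chance level at 0, and the planted
electrodes are recovered in the top six of the weight ranking in well over
90% of seeded runs.

## Known limitations

* Filter design is a package choice (order-2 high-pass + order-4 low-pass
  Butterworth cascade and a Q = 30 biquad notch, all zero-phase); the
  reference preprocessing software does not document its filters, so
  attenuation tests are oracle-derived from this design's frequency
  response, not from published values.
* Epoch-level LOO treats epochs of one recording as exchangeable samples;
  temporally adjacent epochs are weakly dependent in real EEG, which
  epoch-level LOO optimistically ignores. Subject-level LOO is available
  (`unit = "subject"`).
* The AR baseline's 300-dimensional feature space differs from the fused
  entropy space in dimension, so baseline comparisons confound feature
  *content* with feature *count*.
* The pairwise accuracy matrix costs $\binom{N}{2}$ classifier evaluations;
  for 30 electrodes under strict LOO this is the pipeline's dominant cost,
  and the holdout estimator is the practical alternative at scale.
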