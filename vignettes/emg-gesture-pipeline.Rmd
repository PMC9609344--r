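---
title: "From electrode to servo: the emgpipe gesture-classification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From electrode to servo: the emgpipe gesture-classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgpipe)
```

## The problem

A myoelectric hand prosthesis is driven by surface electromyographic (EMG)
signals: bipolar potentials of at most a few millivolts recorded over the
forearm, with usable energy below 500 Hz and dominant energy between 50 and
150 Hz. Turning those signals into finger commands requires a chain of
stages — analog conditioning, digitization, feature extraction,
classification, and decoding into servo angles. `emgpipe` implements that
entire chain in software, with a seeded synthetic EMG generator standing in
for subject recordings, so every stage can be exercised, verified and
benchmarked reproducibly.

Five gestures are classified: closed hand, grip, and individual index,
middle and ring finger movements.

## The synthetic generator

No public recordings accompany the acquisition protocol this package
emulates, so the generator reproduces the *statistics* the downstream
pipeline relies on rather than any individual's physiology:

* **Carrier**: Gaussian white noise shaped in the frequency domain to a
  class-specific band inside 50–150 Hz (squared-cosine tapers, 5 Hz wide,
  inside the band edges), normalized to unit peak.
* **Envelope**: a raised-cosine contraction envelope with a class-specific
  burst count and peak amplitude (0.7–2.4 mV across classes, well under the
  10 mV physiological ceiling), plus a 5 %-of-peak tonic floor so the trace
  is not exactly silent between bursts — and exactly zero when the peak is
  zero.
* **Contamination** (optional): additive mains interference at 50/60 Hz and
  sub-20 Hz baseline wander, the two disturbances the conditioning chain is
  designed around. Both are purely additive and hence recoverable.

Class separability is encoded through envelope amplitude, burst count and
band tilt. These per-class parameters were fixed once, before any
classifier was trained, with band edges kept inside [50, 150] Hz so the
spectral-peak contract holds with margin. Everything is a pure function of
`(class, seed)` — two calls with the same arguments return bit-identical
traces.

What the generator deliberately does **not** model: motor-unit action
potentials, electrode placement and skin-impedance variability, fatigue,
inter-subject variability, or multi-channel geometry. Classification
accuracies measured on these signals therefore demonstrate that the
pipeline is implemented correctly and can learn well-separated classes;
they are not predictions of accuracy on human subjects.

```{r}
sig <- generate_trial("grip", synth_params(seed = 7))
sig
```

## The conditioning chain

The emulated front end mirrors a five-stage analog design:

1. **Instrumentation pre-amplifier**, gain \((R_4/R_3)(2R_2/R_1 + 1)\);
   the tuned configuration uses gain 31.
2. **3rd-order Butterworth low-pass**, 500 Hz design cutoff, 471 Hz as
   realized by the simulated component values.
3. **3rd-order Butterworth high-pass**, 20 Hz design / 22.7 Hz realized,
   removing electrode-cable motion artefacts.
4. **Non-inverting amplifier**, gain \(1 + r_{fb}/r_{in}\), design range
   1–30, tuned to 21. The two tuned gains give a combined 31 × 21 = 651.
5. **Offset** to 2.5 V (ADC mid-scale; 1.5 V available as the alternative
   tuned preset) and a **10-bit, 0–5 V, 1 kHz ADC** with clip-and-count
   saturation.

The 1 kHz rate respects the Nyquist bound for the realized 472 Hz upper
band edge (`nyquist_min_rate(472)` = 944 Hz).

### Filter realization

Two digital realizations of the Butterworth stages are provided. The
default applies the exact analog prototype response
\(|H(f)| = (1 + (f/f_c)^6)^{-1/2}\) in the FFT domain, so the realized
magnitude equals the analytic curve at every resolvable frequency — the
property the test suite checks to 0.2 dB over two decades. A causal IIR
variant (`method = "bilinear"`, via the bilinear transform at the 10 kHz
internal rate) is kept for sample-by-sample streaming emulation; its
frequency warping above roughly 1/20 of the sampling rate makes it
deliberately *not* the default, since fidelity to the analog magnitude is
the contract the rest of the pipeline is verified against. Resampling from
the 10 kHz simulation rate to the 1 kHz ADC rate is plain decimation: the
low-pass has already bounded the content below 500 Hz.

ADC quantization uses round-half-up (2.5 V maps to code 512 of 1023) and
saturates out-of-range samples, counting rather than failing on clips — a
real converter does the same.

## Acquisition and windowing

The acquisition protocol collects 50 trials per gesture, 250 in total.
Each digitized trial is restored to volts (offset removed, mean-centered —
sign-based features are meaningless on unsigned ADC codes) and cut to the
500-sample region of interest: sample energies are smoothed with a
25-sample centered moving average (partial frames at the edges, so bursts
at the trial boundary are not penalized) and the 500-sample window with
maximal total smoothed energy is kept, ties breaking to the earliest
start. A flat trial — no discernible burst — yields the centered window
and a `no_burst` flag rather than an arbitrary one.

Splits are stratified by class with largest-remainder rounding (50 trials
per class make unstratified splits noisy) and seeded: 250 vectors at 60/40
give 150/100, at 60/20/20 give 150/50/50.

## The 20-element feature vector

Per windowed trial, in fixed order:

| # | Feature | Notes |
|---|---------|-------|
| 1 | MAV | \(\frac{1}{N}\sum_k \lvert x_k \rvert\) |
| 2 | ZC | strict-inequality zero crossings, deadband \(\epsilon = 0\) by default |
| 3 | SSC | strict local extrema count |
| 4 | WL | \(\sum_k \lvert x_k - x_{k-1} \rvert\) |
| 5–7 | AR(5) coefficients 1–3 | Burg's method, no demeaning |
| 8–9 | FFT energy, mean power | \(E = \frac{1}{N}\sum_k \lvert X_k \rvert^2\), \(P = E/N\) |
| 10–15 | STFT windows 1–3 | energy and mean power per rectangular third |
| 16–20 | \(v_1 \ldots v_5\) | variances of db5 approximation coefficients, levels 1–5 |

Numerical conventions worth stating:

* **Energy** is fixed to the Parseval-consistent \(\frac{1}{N}\sum|X_k|^2
  = \sum x_n^2\), so the time-domain sum serves as an independent oracle
  in the tests.
* **STFT** uses three contiguous rectangular windows with the remainder
  appended to the last; disjointness makes the window energies sum exactly
  to the total.
* **AR estimation** uses Burg's lattice method (stable, no windowing
  bias); the convention is \(x(k) = \sum_i a_i x(k-i) + e(k)\). A
  zero-variance segment returns zero coefficients with a degenerate flag.
* **DWT**: "Daubechies 5" is read as db5 (10 taps), five decomposition
  levels, Mallat pyramid with half-sample symmetric extension and
  per-level lengths recorded so reconstruction is exact for any input
  length (verified to < 1e-8 relative). Variances are sample variances
  (denominator N−1) of the *approximation* branch; the detail branch is
  available as an option.
* **ZC/SSC deadband** defaults to 0 (the literal strict-inequality
  definitions); practical EMG work uses \(\epsilon > 0\), so it is an
  argument, not a constant.

Features are z-scored using training-split statistics only — sigmoid
networks need inputs on a common scale — and the scaler travels with the
trained model.

## The classifier

A 20-15-5 multilayer perceptron (395 parameters) with logistic sigmoid
hidden and output activations, MSE loss against one-hot targets, and
argmax decoding (ties to the lowest class id). The output layer is sigmoid
+ MSE rather than softmax + cross-entropy to stay consistent with the
residual-based training rule; layer sizes and activations are free
parameters, which lets tiny nets be verified against finite differences
and an identity-activation single-layer network be checked against the
closed-form least-squares solution.

**Levenberg-Marquardt** is the primary trainer: per epoch the damped
Gauss-Newton system \((J^\top J + \mu I)\Delta = J^\top e\) is solved with
the per-residual Jacobian from backpropagation; \(\mu\) is multiplied by
10 while the proposed step fails to reduce the training MSE and by 0.1 on
acceptance (defaults \(\mu_0 = 10^{-3}\), ceiling \(10^{10}\) — the
conventional damping schedule for this optimizer family). Accepted steps
never increase the training MSE, a property the suite asserts.

Four comparison algorithms run in the same epoch loop: BFGS quasi-Newton
and Polak-Ribière conjugate gradient (restarts every `n_params`
iterations) and one-step secant, all with backtracking Armijo line
searches, plus gradient descent with momentum and an adaptive rate (rate
× 1.05 on improvement; step rejected and rate × 0.7 when the MSE grows by
more than 4 %).

All five share early stopping: training halts after 6 consecutive
validation-error increases since the best epoch, and the returned model is
the best-validation snapshot. Initialization, splits and every other
stochastic choice are seeded.

Two split modes are supported — 60/40 train/validation for the headline
run and 60/20/20 when comparing training algorithms — because both
protocols are legitimate uses; neither is hard-coded as canonical.

## Evaluation and decoding

`confusion_matrix()`/`accuracy()` give the 5 × 5 class table and its
normalized trace. `random_trial_protocol()` emulates the physical
assertiveness test: 90 fresh trials with uniformly random labels are drawn
and pushed through the *complete* pipeline (conditioning chain → window →
features → classifier). `decode_gesture()` maps each class to five servo
angles (degrees, 0 = extended, 180 = flexed): closed hand flexes all five,
grip is a partial whole-hand flexion, and each finger gesture flexes only
its finger. The map is a package constant chosen for legibility — real
hardware would recalibrate it, which is why it is a total, documented,
deterministic function rather than anything learned.

## Problem sizes and runtime

The default study conditions are 5 gestures × 50 trials × 500 points
(a 20 × 250 feature matrix), 1 s trials simulated at 10 kHz, and a
300-epoch LM budget; the whole protocol plus training and the 90-trial
evaluation completes in a few seconds on one CPU. Property tests run the
feature oracles on 1000 random segments and the filter-fidelity checks on
15-point logarithmic frequency grids per filter.

```{r}
run <- run_acquisition_protocol(per_class = 50, seed = 1)
split <- split_dataset(run$features$labels, c(0.6, 0.4), seed = 2)
fit <- train_gesture_classifier(run$features, split,
                                hyper = train_hyper("lm", max_epochs = 300),
                                seed = 3)
fit$report
round(fit$report$accuracy, 1)
```

```{r}
proto <- random_trial_protocol(fit$model, synth_params(seed = 99),
                               n = 90, seed = 42)
proto$assertiveness_pct
stream_commands(proto$predicted[1:3])
```

## Known limitations

* Single channel only; no electrode-placement or skin-condition effects.
* The generator's class structure is a stand-in: nothing constrains real
  gestures to differ by burst count or band tilt, so accuracy here bounds
  implementation correctness, not clinical performance.
* The analog emulation is at the transfer-function level — no op-amp
  nonidealities, noise figures or saturation inside the chain (only the
  ADC saturates).
* Training is full-batch; dataset sizes beyond a few thousand vectors
  would make the LM Jacobian memory-heavy (it is (5·n) × 395 at the
  default architecture).
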