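---
title: "Classifying sleep states from 40-Hz auditory steady-state responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sleep states from 40-Hz auditory steady-state responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assrfuse)
```

## The signal and the additive model

A 40-Hz auditory steady-state response (ASSR) is the phase-locked brain
potential evoked by an acoustic stimulus repeating at roughly 40 Hz. Its
amplitude tracks the subject's arousal: in wakefulness (`W0`) the response
is about twice as large as in deep slow-wave sleep (`N3`). Because the
response is orders of magnitude smaller than the background EEG, it must
be extracted by ensemble averaging many stimulus-locked sweeps.

Everything in this package rests on the additive sweep model. The recorded
signal in stimulus cycle $i$ is

$$x_i[n] = s[n] + r_i[n],$$

where $s[n]$ is the deterministic, stimulus-phase-locked ASSR waveform and
$r_i[n]$ is everything else (ongoing EEG, instrumentation noise), assumed
zero-mean with constant variance $\sigma^2$ and uncorrelated between
sweeps. Under these assumptions the ensemble average of $N$ sweeps is an
unbiased estimator of $s[n]$ whose residual noise power falls as $1/N$;
with the 900-sweep windows used here the noise standard deviation drops by
a factor of 30.

At the default amplifier rate of 12 kHz and stimulus rate of 40.68 Hz one
stimulus cycle spans 294.985 samples, which is not a whole number; the
pipeline therefore works with the nearest whole-sample cycle of
`sweep_samples(12000, 40.68)` = 295 samples and, like the original
acquisition, keeps only cycles containing all 295 samples
(`segment_sweeps()` drops markers whose sweep would overrun the record).

## The synthetic generator

The human recordings the method was developed on are not redistributable,
so the package ships a generator (`make_subject_params()`,
`simulate_sweeps()`, `simulate_dataset()`) that produces data with exactly
the statistical structure the averaging model assumes:

* a periodic unit-peak template per subject — a fundamental at the
  stimulus rate plus a second harmonic. The harmonic's relative amplitude
  (uniform in 0.15–0.35 around a nominal 0.25) and phase (uniform in
  ±0.3 rad) vary slightly between subjects so that distinct subjects have
  distinct morphologies, as observed in real recordings;
* a wake amplitude drawn log-uniformly in 0.7–1.4 times nominal, with the
  deep-sleep amplitude exactly half of it (the 2:1 wake/sleep ratio is the
  documented default and is configurable via `state_ratio`);
* a per-subject latency expressed as a circular shift of up to ±10 samples
  (±0.83 ms, about 12 degrees of the 40-Hz cycle);
* per-channel gains (the first channel is the 1.0 reference; further
  channels draw gains in 0.7–1);
* additive white Gaussian sweep noise, independent between sweeps, with
  optional AR(1) colouring along the sweep (`noise_ar1`), scaled to keep
  the marginal standard deviation at `noise_sigma`.

The default single-sweep noise standard deviation is `noise_sigma = 6`
against a signal of peak amplitude near 1 — a single-sweep SNR around
−19 dB, typical for raw ASSR sweeps, and low enough that individual sweeps
look like noise. After a 900-sweep average the residual noise sd is 0.2,
so ensemble-averaged wake and sleep sweeps of one subject are cleanly
separable, which is the regime the published same-subject experiments
describe. The defaults were fixed from these considerations (SNR realism,
clean 900-sweep separability, and recoverability of the 2:1 amplitude
ratio from averages to within a few percent) and are not fitted to any
test outcome.

What the generator deliberately does *not* model: the N1/N2/REM stages,
latency-structured AEP components (brainstem and late responses),
artifacts (eye movements, electrode pops), non-stationary noise, or any
dependence of morphology on stimulus level. Consequently, passing tests on
this fixture demonstrate that the pipeline implements the method
correctly under the model's assumptions — not that the method reaches any
particular accuracy on real polysomnography.

## Weighted ensemble averaging

`windowed_averages()` slides a 900-sweep window in steps of 150 sweeps, so
adjacent windows share 750/900 ≈ 83% of their sweeps; the step size
realizes the documented overlap, which fixes windows in sweep units rather
than seconds. Each window is reduced to one 295-sample ensemble-averaged
sweep.

Weights come from a scalar Kalman-gain recursion (`kalman_weights()`).
Each sweep's noise variance $R_i$ is estimated as the sample variance of
its residual against the window's ensemble mean; with prior variance
$P_0 = \overline{R}$ the recursion

$$K_i = \frac{P_{i-1}}{P_{i-1} + R_i}, \qquad P_i = (1 - K_i)\,P_{i-1}$$

yields the weight each sweep carries in the final recursive estimate,
$w_i = K_i \prod_{j>i}(1-K_j)$, normalized to sum to one. Two properties
motivated this exact form: when all $R_i$ are equal the gains collapse to
$K_i = 1/(i+1)$ and the weights are exactly uniform — weighted averaging
degrades gracefully to the plain mean on homoscedastic data — and a sweep
with inflated noise variance is down-weighted *wherever* it sits in the
window (the prior $P_0$ ensures even the first sweep's weight depends on
its own variance). The residual is taken against the window ensemble mean
rather than a running mean so the variance estimates treat all sweeps
symmetrically.

## The LVQ classifier

The classifier is a learning vector quantization network of the simplest
(LVQ1) kind: a competitive layer of `hn` prototype vectors in the
295-dimensional sweep space, each hard-assigned to one of the two classes,
and a linear layer that reads off the winner's class. Classification is
nearest-prototype by Euclidean distance with ties to the lowest index.
Training presents the inputs in a seeded random order each epoch and moves
only the winning prototype $W$:

$$W \leftarrow W + \alpha\,(x - W) \quad \text{(same class)}, \qquad
  W \leftarrow W - \alpha\,(x - W) \quad \text{(different class)},$$

which contracts or dilates the winner-to-input distance by exactly
$(1-\alpha)$ or $(1+\alpha)$ per update — a property the test suite checks
to machine precision. The learning rate defaults to a constant
$\alpha = 0.1$ with an optional linear decay to 0.01; the epoch cap
defaults to 2,500 with an optional training-error stop (`error_limit`),
and the experiment harness stops at the first errorless epoch. The inner
presentation loop is compiled (Rcpp) because a non-converging run touches
3.5 million presentations; the presentation orders are still drawn in R
under the caller's seed, so results are reproducible from the seed alone.

**Architecture.** Recognizing `NC` classes needs at least `NC` hidden
prototypes; capturing per-subject variability motivates the compact rule
`hn = S × NC` — one prototype per (subject, class) — which the experiment
harness uses for subject-independent designs. Prototypes that never win on
the training data ("blind neurons") contribute nothing to any decision and
`lvq_prune_blind()` removes them, by construction without changing a
single prediction on that data; a class's last prototype is never pruned.

**Initialization.** The default `"stratified"` strategy starts each
class's prototypes at the per-subject class means, cycling through the
training subjects. This follows directly from the compact architecture's
rationale: if each hidden neuron is to own one subject's cluster, it
should start there. The superficially natural alternative — every
prototype initialized to the mean of a random 20% subsample of its class —
collapses all same-class prototypes onto nearly the same point (each
subsample mean approximates the global class mean), leaving all but one of
them blind from the start and reducing the effective architecture to one
prototype per class; it is kept as `"class-mean"` for comparison, along
with `"sample"` (random training examples) and `"random"`.

## Feature-level fusion

To combine two electrodes without doubling storage, the ensemble-averaged
sweeps of two channels for the same (subject, state, window) are fused by
a single-prototype LVQ network (295 inputs, 1 hidden neuron, learning rate
0.01, 700 epochs): both sweeps carry the same target class, so every
presentation is an attractive update, and the converged prototype is a mix
of the two signals with the same dimensionality as the originals.

With the strict alternation $a, b, a, b, \dots$ used here, one epoch maps
$w \mapsto \beta^2 w + \alpha\beta\,a + \alpha\,b$ with $\beta = 1-\alpha$,
so after $E$ epochs, starting from the midpoint $(a+b)/2$,

$$w_E = \beta^{2E}\,\frac{a+b}{2} +
        \bigl(1-\beta^{2E}\bigr)\,\frac{\beta a + b}{1+\beta}.$$

`fuse_pair()` evaluates this closed form (the tests verify it against the
explicit presentation loop). All coefficients are non-negative and sum to
one, so every fused component lies in the per-sample envelope
$[\min(a_n,b_n), \max(a_n,b_n)]$; at the defaults the result is within
$5\times10^{-3}|a-b|$ of the midpoint, fusing identical inputs returns
them unchanged, and swapping the presentation order moves the result by at
most $\alpha\beta|a-b|/(1+\beta) \approx 0.005\,|a-b|$. Midpoint
initialization and strict alternation remove all run-to-run variance. A
literal concatenation of the two sweeps (doubling the length to 590) is
available behind `method = "concatenate"` for comparison.

## Evaluation

`confusion_and_rates()` scores the two-state classifier like a
verification system with wakefulness as the valid/accept class (a
convention, exposed as `valid_class`): FAR is the fraction of sleep inputs
incorrectly accepted as wake, FRR the fraction of wake inputs incorrectly
rejected. `compute_eer()` sweeps an accept threshold over classifier
scores — for the LVQ, the signed margin between the nearest other-class
and nearest valid-class prototype distances; for the SVM, the decision
value — making FAR non-increasing and FRR non-decreasing by construction,
and reports the crossing rate with linear interpolation between adjacent
thresholds.

`run_experiment()` replays three designs: *same-subject* (per subject,
train on the first 50 windows per state, test on the disjoint next 50),
*loso* (train on all subjects but the held-out one), and *fused-loso*
(LOSO on the fused two-channel dataset). The SVM baseline delegates to
libsvm (package e1071) with a linear kernel and $C = 1$ and is evaluated
through the same harness.

## Problem sizes and numerical choices

The bundled experiments and tests use an 8-subject fixture with 100
ensemble-averaged windows per state and subject (15,750 raw sweeps per
subject, channel and state), chosen to mirror the same-subject design of
the original tables at a size a laptop handles comfortably. Windowed
averaging shares cumulative sums across the heavily overlapping windows;
weighted and per-window reference computations agree to machine precision.
Sweep files are plain text with full double precision (`%.17g`), and LVQ
models serialize prototypes as base64-encoded little-endian doubles, so
both round-trip bit-exactly. All randomness flows from integer seeds
through a string-context hash, so every (seed, subject, channel, state)
combination has an independent, reproducible stream, and all derived seeds
stay below $2^{31}$.

Degenerate inputs are rejected rather than guessed at: single-sweep
windows (per-sweep variance undefined), empty classification batches
(rather than a vacuous 100%), windows larger than the available sweeps,
negative weights, single-class training sets, and LOSO with one subject
all raise errors naming the constraint.

## Known limitations

* The generator's inter-subject variability is low-dimensional (amplitude,
  latency, harmonic shape). Real inter-subject ASSR structure is richer,
  and relative classifier rankings can differ on it. In particular,
  because the synthetic classes are close to globally linearly separable
  by amplitude, the linear SVM baseline is stronger here than on the
  original recordings, where it reportedly failed badly across subjects;
  on this fixture the prototype classifier does not consistently beat it.
  A subject whose wake amplitude lands near the bottom of the drawn range
  (0.7× nominal, exactly the ceiling of the sleep range) is intrinsically
  ambiguous to any subject-independent classifier, and the winner-take-all
  prototype rule fails on such subjects in blocks rather than gracefully.
* Windows are counted in sweeps, not seconds; the "30-s window"
  bookkeeping sometimes quoted for 900 sweeps does not match 900 cycles at
  40.68 Hz (≈22 s) and is not enforced.
* The stated effect of averaging on noise is implemented (and tested) as
  the $1/N$ variance *reduction* an unbiased average provides.
* EDF input is not supported; continuous records and sweep matrices travel
  in the package's documented plain-text dialect.
* Sleep scoring itself (deciding which stretches of an overnight recording
  are `W0` or `N3`) is out of scope; state labels are taken as given.
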