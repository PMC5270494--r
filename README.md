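# assrfuse

Sleep-state classification from 40-Hz auditory steady-state responses
(ASSR) in R.

A 40-Hz ASSR is the phase-locked brain potential evoked by an acoustic
stimulus repeating at about 40 Hz. Its amplitude tracks arousal: in
wakefulness (*W0*) the response is roughly twice as large as in deep
slow-wave sleep (*N3*), which makes the extracted ASSR a compact signature
for telling the two states apart — of interest both for sleep monitoring
and, because *N3* resembles the surgical level of general anesthesia, for
anesthesia-depth research. The response is buried far below the ongoing
EEG, so it must first be pulled out of the noise by ensemble averaging
many stimulus-locked sweeps.

`assrfuse` implements that full pipeline for researchers in auditory
neurophysiology and biosignal classification:

* **Sweep model and extraction.** Each recorded stimulus cycle is modelled
  as `x_i[n] = s[n] + r_i[n]` with a phase-locked component `s[n]` and
  zero-mean, sweep-uncorrelated noise `r_i[n]`. Continuous records are
  band-limited 20–100 Hz with zero-phase third-order Butterworth filters,
  segmented into 295-sample stimulus-locked sweeps (the nearest
  whole-sample stimulus cycle: 12 kHz / 40.68 Hz → 295), and
  reduced by **weighted ensemble averaging** over sliding 900-sweep
  windows with 83% overlap. Weights come from a scalar Kalman-gain
  recursion over per-sweep noise-variance estimates: `K_i =
  P_{i-1}/(P_{i-1}+R_i)`, uniform in the homoscedastic limit, smaller for
  noisier sweeps.
* **Compact LVQ classifier.** A learning vector quantization (LVQ1)
  network over the 295-sample ensemble-averaged sweeps: nearest-prototype
  classification by Euclidean distance, winner-only updates
  `W <- W ± α(x − W)`, a compact hidden layer of `subjects × classes`
  prototypes for subject-independent designs, and pruning of "blind"
  prototypes that never win (provably without changing any decision on
  the data they were censused on).
* **Feature-level two-channel fusion.** Ensemble-averaged sweeps from two
  electrodes are fused by a single-prototype LVQ (295 inputs, 1 hidden
  neuron, α = 0.01, 700 epochs) into a mixed sweep with the *same*
  dimensionality — two channels of evidence at single-channel storage
  cost.
* **Evaluation harness.** Same-subject, leave-one-subject-out (LOSO) and
  fused-LOSO designs; per-subject error tables; FAR/FRR with wake as the
  accept class; equal-error-rate estimation by threshold sweep; and a
  linear-SVM baseline (libsvm via e1071) run through the same harness.
* **Synthetic generator.** The original eight-subject recordings are not
  redistributable, so a seeded generator produces stimulus-locked sweeps
  with the model's exact statistical structure (2:1 wake/sleep amplitude
  ratio, per-subject morphology/latency/amplitude variability, −19 dB
  single-sweep SNR). It is first-class, tested code — not a fixture dump.

Everything is tibble-first: ensemble sweeps travel as a tibble with a
`values` list-column, experiment results have `tidy()`/`glance()` methods,
and `autoplot()`/`plot_ensemble()` give quick ggplot2 views.

## Worked example

```r
library(assrfuse)

# 4 synthetic subjects; 20 ensemble-averaged 900-sweep windows per state
ens <- simulate_ensemble_dataset(n_subjects = 4, channels = "Fz-A1A2",
                                 windows_per_state = 20, seed = 1)
ens
#> # A tibble: 160 × 6
#>   subject_id channel state window_index n_averaged values
#>   <chr>      <chr>   <chr>        <int>      <int> <list>
#> 1 A          Fz-A1A2 W0               0        900 <dbl [295]>
#> 2 A          Fz-A1A2 W0               1        900 <dbl [295]>
#> 3 A          Fz-A1A2 W0               2        900 <dbl [295]>
#> 4 A          Fz-A1A2 W0               3        900 <dbl [295]>
#> # ℹ 156 more rows

# per subject: train LVQ on half of each state's windows, test the rest
report <- run_experiment(ens, design = "same-subject", classifier = "lvq",
                         seed = 1)
glance(report)
#> # A tibble: 1 × 9
#>   design       classifier n_subjects mean_error_pct mean_accuracy_pct   far   frr
#>   <chr>        <chr>           <int>          <dbl>             <dbl> <dbl> <dbl>
#> 1 same-subject lvq                 4              0               100     0     0
```

Every subject's held-out windows classify perfectly — wake averages are
about twice the sleep averages, and at 900-sweep noise levels the two
clusters are cleanly separated, matching the published same-subject
behaviour. The published per-subject LOSO error table summarizes the same
way the original study reports it:

```r
summarize_table(assr_reference_errors)
#> # A tibble: 1 × 2
#>   mean_error_pct mean_accuracy_pct
#>            <dbl>             <dbl>
#> 1           2.39              97.6
```

A command-line surface wraps the same operations
(`simulate`, `preprocess`, `average`, `train`, `fuse`, `evaluate`,
`reproduce-tables`):

```sh
Rscript inst/cli/assrfuse.R reproduce-tables --seed 0 --out reports/
```

## Scope notes

Sleep *scoring* (labelling stretches of an overnight EEG as W0/N3) is out
of scope — state labels are taken as given. EDF input is not supported;
records and sweeps travel in a documented plain-text format
(`write_sweeps()`/`read_sweeps()`). See the methods vignette
(`vignettes/assr-sleep-classification.Rmd`) for the model, parameter
choices, numerical details and known limitations of the synthetic
fixture.
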