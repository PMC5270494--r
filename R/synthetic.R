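# Synthetic stimulus-locked ASSR generator.
#
# The generative model mirrors the additive sweep model used by ensemble
# averaging: each recorded sweep is x_i[n] = s[n] + r_i[n], where s[n] is a
# periodic, phase-locked ASSR waveform whose amplitude depends on the sleep
# state (wake roughly twice deep sleep), and r_i[n] is zero-mean EEG-like
# noise with constant variance, uncorrelated from one sweep to the next.

default_channels <- c("Fz-A1A2", "C4-A1A2")

#' Generative parameters for one synthetic subject
#'
#' Draws a reproducible set of per-subject parameters: a unit-peak periodic
#' ASSR template (fundamental at the stimulus rate plus a second harmonic
#' whose size and phase vary slightly between subjects), state amplitudes
#' with a wake/deep-sleep ratio of 2 by default, a per-subject latency
#' shift, per-channel gains, and the standard deviation of the additive
#' sweep noise. The same `subject_id` and `seed` always reproduce the same
#' parameters bit for bit; distinct subjects under one seed get distinct
#' templates and amplitudes.
#'
#' Default ranges: the wake amplitude is log-uniform in 0.7 to 1.4 times the
#' nominal unit amplitude; the deep-sleep amplitude is the wake amplitude
#' divided by `state_ratio` (default 2); the latency shift is uniform on
#' -10..10 samples; the second-harmonic relative amplitude is uniform on
#' 0.15 to 0.35; gains of channels after the first are uniform on 0.7 to 1.
#'
#' @param subject_id Character label for the subject.
#' @param seed Non-negative integer seed.
#' @param overrides Named list overriding any drawn field (e.g.
#'   `list(noise_sigma = 0)`); unknown names are an error.
#' @param channels Character vector of channel labels to assign gains to.
#' @return An object of class `subject_params`.
#' @examples
#' p <- make_subject_params("A", seed = 7)
#' p$amp_w0 / p$amp_n3 # 2
#' @export
make_subject_params <- function(subject_id, seed = 0,
                                overrides = list(),
                                channels = default_channels) {
  stopifnot(is.character(subject_id), length(subject_id) == 1)
  if (!is.numeric(seed) || length(seed) != 1 || seed < 0 || seed != floor(seed)) {
    stop_assr("`seed` must be a non-negative integer.", class = "assr_parameter_error")
  }
  if (length(channels) < 1) stop_assr("`channels` must be non-empty.")

  fs <- 12000
  stim_rate <- 40.68
  n_samples <- sweep_samples(fs, stim_rate)

  drawn <- withr::with_seed(derive_seed(seed, "subject-params", subject_id), {
    list(
      amp_w0 = exp(stats::runif(1, log(0.7), log(1.4))),
      harm_amp = stats::runif(1, 0.15, 0.35),
      harm_phase = stats::runif(1, -0.3, 0.3),
      latency_shift = sample(-10:10, 1),
      gains = c(1, stats::runif(max(0, length(channels) - 1), 0.7, 1))
    )
  })

  params <- list(
    subject_id = subject_id,
    fs = fs,
    stim_rate = stim_rate,
    n_samples = n_samples,
    amp_w0 = drawn$amp_w0,
    amp_n3 = NA_real_, # filled from state_ratio below
    state_ratio = 2.0,
    harm_amp = drawn$harm_amp,
    harm_phase = drawn$harm_phase,
    noise_sigma = 6.0,
    noise_ar1 = 0.0,
    latency_shift = drawn$latency_shift,
    channel_gains = stats::setNames(as.list(drawn$gains), channels),
    seed = as.integer(seed)
  )

  allowed <- c("fs", "stim_rate", "amp_w0", "amp_n3", "state_ratio", "harm_amp",
               "harm_phase", "noise_sigma", "noise_ar1", "latency_shift",
               "channel_gains", "template")
  unknown <- setdiff(names(overrides), allowed)
  if (length(unknown) > 0) {
    stop_assr(paste0("Unknown override key(s): ", paste(unknown, collapse = ", "),
                     ". Allowed: ", paste(allowed, collapse = ", ")),
              class = "assr_config_error")
  }
  params[names(overrides)] <- overrides
  params$n_samples <- sweep_samples(params$fs, params$stim_rate)
  if (is.na(params$amp_n3)) params$amp_n3 <- params$amp_w0 / params$state_ratio

  if (is.null(overrides$template)) {
    n <- params$n_samples
    t_idx <- 0:(n - 1)
    f <- params$stim_rate / params$fs
    tpl <- sin(2 * pi * f * t_idx) +
      params$harm_amp * sin(4 * pi * f * t_idx + params$harm_phase)
    params$template <- tpl / max(abs(tpl)) # unit peak
  } else {
    params$template <- as.numeric(overrides$template)
  }

  if (params$amp_w0 <= 0 || params$amp_n3 <= 0) {
    stop_assr("State amplitudes must be positive.", class = "assr_parameter_error")
  }
  if (params$noise_sigma < 0) {
    stop_assr("`noise_sigma` must be non-negative.", class = "assr_parameter_error")
  }
  structure(params, class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("<subject_params %s> amp W0 %.3f / N3 %.3f, noise sd %.2f, shift %+d samples, %d channels\n",
              x$subject_id, x$amp_w0, x$amp_n3, x$noise_sigma,
              x$latency_shift, length(x$channel_gains)))
  invisible(x)
}

#' Noise-free stimulus-locked sweep for one subject, state and channel
#'
#' The deterministic part of every simulated sweep: channel gain times state
#' amplitude times the subject template, circularly shifted by the subject's
#' latency.
#'
#' @param params A [make_subject_params()] object.
#' @param state `"W0"` (wake) or `"N3"` (deep sleep).
#' @param channel Channel label present in `params$channel_gains`.
#' @return Numeric vector of length `params$n_samples`.
#' @export
deterministic_sweep <- function(params, state, channel) {
  stopifnot(inherits(params, "subject_params"))
  state <- match.arg(state, c("W0", "N3"))
  if (!channel %in% names(params$channel_gains)) {
    stop_assr(paste0("Unknown channel '", channel, "'. Valid channels: ",
                     paste(names(params$channel_gains), collapse = ", ")),
              class = "assr_parameter_error")
  }
  amp <- if (state == "W0") params$amp_w0 else params$amp_n3
  gain <- params$channel_gains[[channel]]
  gain * amp * circ_shift(params$template, params$latency_shift)
}

new_sweep_matrix <- function(data, fs, stim_rate, subject_id, channel, state) {
  structure(list(data = data, n_samples = ncol(data), fs = fs,
                 stim_rate = stim_rate, subject_id = subject_id,
                 channel = channel, state = state),
            class = "sweep_matrix")
}

#' @export
print.sweep_matrix <- function(x, ...) {
  cat(sprintf("<sweep_matrix> %d sweeps x %d samples | subject %s, channel %s, state %s, fs %g Hz\n",
              nrow(x$data), ncol(x$data), x$subject_id, x$channel,
              x$state, x$fs))
  invisible(x)
}

#' Simulate stimulus-locked single sweeps for one subject
#'
#' Each row is the deterministic stimulus-locked waveform
#' ([deterministic_sweep()]) plus an independent zero-mean noise draw with
#' standard deviation `params$noise_sigma` (optionally AR(1)-coloured along
#' the sweep when `params$noise_ar1 > 0`; sweeps remain mutually
#' independent).
#'
#' @inheritParams deterministic_sweep
#' @param n_sweeps Number of sweeps (rows) to simulate.
#' @param seed Integer seed; results are reproducible from
#'   (`params`, `state`, `channel`, `n_sweeps`, `seed`).
#' @return A `sweep_matrix` object.
#' @export
simulate_sweeps <- function(params, state, channel, n_sweeps, seed = 0) {
  stopifnot(inherits(params, "subject_params"))
  if (!is.numeric(n_sweeps) || n_sweeps < 1) {
    stop_assr("`n_sweeps` must be >= 1.", class = "assr_parameter_error")
  }
  n_sweeps <- as.integer(n_sweeps)
  det <- deterministic_sweep(params, state, channel)
  n <- length(det)
  noise <- withr::with_seed(
    derive_seed(seed, "sweeps", params$subject_id, channel, state, n_sweeps), {
      z <- matrix(stats::rnorm(n_sweeps * n, sd = 1), nrow = n_sweeps)
      rho <- params$noise_ar1
      if (rho > 0) {
        # AR(1) along the sweep, scaled back to unit marginal sd
        z <- t(apply(z, 1, function(row) {
          as.numeric(stats::filter(row, rho, method = "recursive"))
        })) * sqrt(1 - rho^2)
      }
      z * params$noise_sigma
    })
  data <- sweep(noise, 2, det, FUN = "+")
  new_sweep_matrix(data, params$fs, params$stim_rate,
                   params$subject_id, channel, state)
}

#' Simulate a multi-subject, multi-channel sweep dataset
#'
#' One `sweep_matrix` per (subject, channel, state) combination; subject
#' parameters are consistent across channels and the whole collection is
#' reproducible from `seed`.
#'
#' @param n_subjects Number of subjects (labelled `"A"`, `"B"`, ...).
#' @param channels Character vector of channel labels.
#' @param sweeps_per_state Sweeps simulated per (subject, channel, state).
#' @param seed Integer seed.
#' @param overrides Named list of [make_subject_params()] overrides applied
#'   to every subject.
#' @return A tibble with columns `subject_id`, `channel`, `state` and a
#'   `sweeps` list-column of `sweep_matrix` objects.
#' @export
simulate_dataset <- function(n_subjects, channels = default_channels,
                             sweeps_per_state = 900, seed = 0,
                             overrides = list()) {
  if (n_subjects < 1) stop_assr("`n_subjects` must be >= 1.")
  if (length(channels) < 1) stop_assr("`channels` must be non-empty.")
  if (sweeps_per_state < 1) stop_assr("`sweeps_per_state` must be >= 1.")
  subjects <- make_subject_labels(n_subjects)
  grid <- tidyr::expand_grid(subject_id = subjects, channel = channels,
                             state = c("W0", "N3"))
  grid$sweeps <- purrr::pmap(grid, function(subject_id, channel, state) {
    params <- make_subject_params(subject_id, seed = seed,
                                  overrides = overrides, channels = channels)
    simulate_sweeps(params, state, channel, sweeps_per_state, seed = seed)
  })
  grid
}

make_subject_labels <- function(n_subjects) {
  if (n_subjects <= 26) LETTERS[seq_len(n_subjects)] else
    paste0("S", seq_len(n_subjects))
}

#' Simulate ensemble-averaged sweeps directly
#'
#' Convenience wrapper that simulates raw sweeps per (subject, channel,
#' state), extracts sliding-window (weighted) ensemble averages, and
#' discards the raw sweeps, keeping memory bounded. `windows_per_state`
#' windows require `window + (windows_per_state - 1) * step` raw sweeps.
#'
#' @inheritParams simulate_dataset
#' @param windows_per_state Number of ensemble-averaged sweeps per state.
#' @param window,step,weighted Passed to [windowed_averages()].
#' @return An ensemble tibble (see [windowed_averages()]).
#' @export
simulate_ensemble_dataset <- function(n_subjects, channels = "Fz-A1A2",
                                      windows_per_state = 100,
                                      window = 900, step = 150,
                                      weighted = TRUE, seed = 0,
                                      overrides = list()) {
  if (windows_per_state < 1) stop_assr("`windows_per_state` must be >= 1.")
  n_sweeps <- window + (windows_per_state - 1) * step
  subjects <- make_subject_labels(n_subjects)
  grid <- tidyr::expand_grid(subject_id = subjects, channel = channels,
                             state = c("W0", "N3"))
  out <- purrr::pmap(grid, function(subject_id, channel, state) {
    params <- make_subject_params(subject_id, seed = seed,
                                  overrides = overrides, channels = channels)
    sm <- simulate_sweeps(params, state, channel, n_sweeps, seed = seed)
    windowed_averages(sm, window = window, step = step, weighted = weighted)
  })
  dplyr::bind_rows(out)
}
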