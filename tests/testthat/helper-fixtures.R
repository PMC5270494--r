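# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# Ensemble-level toy fixture: deterministic per-subject waveforms plus
# Gaussian noise applied directly at the ensemble-average level (noise sd
# `noise` emulates the residual sigma/sqrt(N) of an N-sweep average).
# Much cheaper than simulating raw sweeps when a test only needs labelled
# 295-sample vectors.
make_toy_ensemble <- function(n_subjects = 3, windows_per_state = 10,
                              channels = "Fz-A1A2", noise = 0.2, seed = 1) {
  subjects <- LETTERS[seq_len(n_subjects)]
  grid <- expand.grid(subject_id = subjects, channel = channels,
                      state = c("W0", "N3"),
                      window_index = seq_len(windows_per_state) - 1L,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject_id, grid$channel, grid$state,
                     grid$window_index), ]
  withr::with_seed(seed, {
    grid$values <- lapply(seq_len(nrow(grid)), function(i) {
      p <- make_subject_params(grid$subject_id[i], seed = seed,
                               channels = channels)
      det <- deterministic_sweep(p, grid$state[i], grid$channel[i])
      det + stats::rnorm(length(det), sd = noise)
    })
  })
  grid$n_averaged <- 900L
  tibble::as_tibble(grid[c("subject_id", "channel", "state", "window_index",
                           "n_averaged", "values")])
}

# Noise-only sweep matrix (no stimulus-locked component).
make_noise_sweeps <- function(n_sweeps, n_samples = 295, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    assrfuse:::new_sweep_matrix(
      matrix(stats::rnorm(n_sweeps * n_samples, sd = sd), nrow = n_sweeps),
      fs = 12000, stim_rate = 40.68, subject_id = "A",
      channel = "Fz-A1A2", state = "W0")
  })
}

# Two well-separated Gaussian clusters as an ensemble tibble.
make_cluster_ensemble <- function(n_per_class = 20, dim = 10, gap = 6,
                                  noise = 0.5, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(center, state) {
      lapply(seq_len(n_per_class),
             function(i) center + stats::rnorm(dim, sd = noise))
    }
    tibble::tibble(
      subject_id = "A",
      channel = "Fz-A1A2",
      state = rep(c("W0", "N3"), each = n_per_class),
      window_index = rep(seq_len(n_per_class) - 1L, 2),
      n_averaged = 900L,
      values = c(mk(rep(gap, dim), "W0"), mk(rep(0, dim), "N3"))
    )
  })
}
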