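# Weighted ensemble averaging of stimulus-locked sweeps.
#
# Under the additive model x_i[n] = s[n] + r_i[n] with zero-mean,
# sweep-uncorrelated noise of constant variance, the ensemble average is an
# unbiased estimator of s[n] and an N-sweep average reduces the residual
# noise power by a factor of N. When per-sweep noise levels differ, a
# recursive Kalman-gain estimator down-weights noisier sweeps.

#' Kalman-gain-derived per-sweep averaging weights
#'
#' Per-sweep noise variance `R_i` is estimated as the sample variance of
#' (sweep_i - ensemble mean) over the sweep's samples. A scalar Kalman
#' recursion with prior variance `P_0 = mean(R)` then runs over the sweeps:
#' gain `K_i = P_{i-1} / (P_{i-1} + R_i)`, `P_i = (1 - K_i) P_{i-1}`. The
#' weight each sweep carries in the final state estimate,
#' `w_i = K_i * prod_{j>i} (1 - K_j)`, is returned normalized to sum 1.
#'
#' When all `R_i` are equal the gains reduce to `K_i = 1/(i+1)` and the
#' weights are exactly uniform, so weighted averaging degrades gracefully
#' to the plain ensemble mean on homoscedastic data; a sweep with larger
#' estimated noise variance receives a smaller weight at any position in
#' the window.
#'
#' @param window A `sweep_matrix` (or bare numeric matrix) with at least
#'   two sweeps.
#' @return Numeric vector of positive weights summing to 1.
#' @export
kalman_weights <- function(window) {
  data <- if (inherits(window, "sweep_matrix")) window$data else as.matrix(window)
  n <- nrow(data)
  if (n < 2) {
    stop_assr("Kalman weights need at least 2 sweeps (per-sweep variance is undefined for one).",
              class = "assr_parameter_error")
  }
  center <- colMeans(data)
  resid <- sweep(data, 2, center)
  R <- rowSums(resid^2) / (ncol(data) - 1)
  kalman_weights_from_variances(R)
}

# Kalman recursion over per-sweep noise variances R_i -> normalized weights.
kalman_weights_from_variances <- function(R) {
  n <- length(R)
  if (max(R) < 1e-300) return(rep(1 / n, n)) # noiseless: plain mean
  R <- pmax(R, 1e-12 * max(R))
  K <- numeric(n)
  P <- mean(R)
  for (i in seq_len(n)) {
    K[i] <- P / (P + R[i])
    P <- (1 - K[i]) * P
  }
  # weight of sweep i in the final recursive estimate
  w <- K * rev(cumprod(rev(c(1 - K[-1], 1))))
  w / sum(w)
}

new_ensemble_sweep <- function(values, n_averaged, window_index,
                               subject_id, channel, state, weights_used) {
  structure(list(values = values, n_averaged = n_averaged,
                 window_index = window_index, subject_id = subject_id,
                 channel = channel, state = state,
                 weights_used = weights_used),
            class = "ensemble_sweep")
}

#' @export
print.ensemble_sweep <- function(x, ...) {
  cat(sprintf("<ensemble_sweep> %d samples, average of %d sweeps | subject %s, channel %s, state %s, window %d\n",
              length(x$values), x$n_averaged, x$subject_id, x$channel,
              x$state, x$window_index))
  invisible(x)
}

#' (Weighted) ensemble average of a window of sweeps
#'
#' `values[n] = sum_i weights[i] * window[i, n]`. With `weights = NULL` a
#' uniform `1/N` average is used. Weights must be non-negative and are
#' normalized to sum 1.
#'
#' @param window A `sweep_matrix`.
#' @param weights Optional numeric weights, one per sweep.
#' @param window_index Index stored in the result (0-based).
#' @return An `ensemble_sweep` object.
#' @export
ensemble_average <- function(window, weights = NULL, window_index = 0L) {
  stopifnot(inherits(window, "sweep_matrix"))
  n <- nrow(window$data)
  if (is.null(weights)) {
    weights <- rep(1 / n, n)
  } else {
    if (length(weights) != n) {
      stop_assr(sprintf("Got %d weights for %d sweeps.", length(weights), n),
                class = "assr_parameter_error")
    }
    if (any(weights < 0)) {
      stop_assr("Weights must be non-negative.", class = "assr_parameter_error")
    }
    weights <- weights / sum(weights)
  }
  values <- as.numeric(crossprod(window$data, weights))
  new_ensemble_sweep(values, n, as.integer(window_index),
                     window$subject_id, window$channel, window$state, weights)
}

#' Sliding-window ensemble averages over a sweep matrix
#'
#' Windows of `window` consecutive sweeps start at sweep 0, `step`,
#' `2 * step`, ...; the number of windows is
#' `floor((n_sweeps - window) / step) + 1` and adjacent windows overlap by
#' a fraction `(window - step) / window`. The defaults (900-sweep windows,
#' step 150) give the 83% overlap used when extracting 40-Hz ASSR signals.
#'
#' @param sweeps A `sweep_matrix`.
#' @param window Window length in sweeps.
#' @param step Window step in sweeps.
#' @param weighted If `TRUE`, use [kalman_weights()] per window; otherwise
#'   the plain mean.
#' @return A tibble with one row per window: `subject_id`, `channel`,
#'   `state`, `window_index` (0-based), `n_averaged` and a `values`
#'   list-column of numeric vectors.
#' @export
windowed_averages <- function(sweeps, window = 900, step = 150,
                              weighted = TRUE) {
  stopifnot(inherits(sweeps, "sweep_matrix"))
  if (step < 1) stop_assr("`step` must be >= 1.", class = "assr_parameter_error")
  n <- nrow(sweeps$data)
  if (n < window) {
    stop_assr(sprintf("Need at least %d sweeps for one window; got %d.",
                      window, n), class = "assr_parameter_error")
  }
  starts <- seq(0L, n - window, by = step)
  # Shared precomputations across overlapping windows: cumulative column
  # sums give each window's mean in O(p); row norms give each sweep's
  # residual variance via ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2.
  data <- sweeps$data
  p <- ncol(data)
  if (weighted && window < 2) {
    stop_assr("Weighted averaging needs windows of at least 2 sweeps.",
              class = "assr_parameter_error")
  }
  cs <- apply(data, 2, cumsum)
  rs2 <- rowSums(data^2)
  vals <- lapply(seq_along(starts), function(k) {
    rows <- (starts[k] + 1):(starts[k] + window)
    sub <- data[rows, , drop = FALSE]
    w <- if (weighted) {
      top <- cs[rows[window], ]
      bottom <- if (starts[k] > 0) cs[starts[k], ] else numeric(p)
      center <- (top - bottom) / window
      R <- (rs2[rows] - 2 * drop(sub %*% center) + sum(center^2)) / (p - 1)
      kalman_weights_from_variances(pmax(R, 0))
    } else {
      rep(1 / window, window)
    }
    as.numeric(crossprod(sub, w))
  })
  tibble::tibble(
    subject_id = sweeps$subject_id,
    channel = sweeps$channel,
    state = sweeps$state,
    window_index = seq_along(starts) - 1L,
    n_averaged = as.integer(window),
    values = vals
  )
}

#' Ensemble averages for every sweep matrix in a simulated dataset
#'
#' Maps [windowed_averages()] over the `sweeps` list-column of a
#' [simulate_dataset()] tibble and binds the results.
#'
#' @param dataset Tibble with a `sweeps` list-column of `sweep_matrix`
#'   objects.
#' @inheritParams windowed_averages
#' @return An ensemble tibble (see [windowed_averages()]).
#' @export
ensemble_dataset <- function(dataset, window = 900, step = 150,
                             weighted = TRUE) {
  stopifnot(is.data.frame(dataset), "sweeps" %in% names(dataset))
  dplyr::bind_rows(purrr::map(dataset$sweeps, windowed_averages,
                              window = window, step = step,
                              weighted = weighted))
}
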