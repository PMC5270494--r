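# Feature-level fusion of two channels' ensemble-averaged sweeps through a
# single-prototype LVQ network.
#
# Both sweeps carry the same target class, so every presentation is a
# same-class LVQ update contracting the prototype-to-input distance by
# (1 - alpha). With strict alternation a, b, a, b, ... the prototype
# converges to a near-midpoint convex mix of the two sweeps with the same
# dimensionality as the originals.

#' Fusion network settings
#'
#' A single hidden prototype (the fused feature vector), learning rate
#' 0.01 and 700 training epochs; each epoch presents both sweeps once.
#'
#' @param n_inputs Sweep length (295 by default).
#' @param alpha Learning rate in (0, 1).
#' @param epochs Training epochs.
#' @param method `"mix"` (default; fused vector keeps the input length) or
#'   `"concatenate"` (literal concatenation, doubling the length; for
#'   comparison only).
#' @param seed Integer seed (the default alternating schedule is
#'   deterministic; the seed is recorded for provenance).
#' @return A `fusion_config` object.
#' @export
fusion_config <- function(n_inputs = 295, alpha = 0.01, epochs = 700,
                          method = c("mix", "concatenate"), seed = 0) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_assr("`alpha` must lie in (0, 1).", class = "assr_parameter_error")
  }
  if (epochs < 1) stop_assr("`epochs` must be >= 1.")
  structure(list(n_inputs = as.integer(n_inputs), hidden = 1L,
                 alpha = alpha, epochs = as.integer(epochs),
                 method = method, seed = as.integer(seed)),
            class = "fusion_config")
}

# Closed form of the alternating same-class update sequence. One epoch is
#   w <- w + alpha (a - w); w <- w + alpha (b - w)
# i.e. w <- beta^2 w + alpha beta a + alpha b with beta = 1 - alpha; after
# `epochs` epochs, starting from w0,
#   w = beta^(2E) w0 + (1 - beta^(2E)) (beta a + b) / (1 + beta).
# All three coefficients are non-negative and sum to one, so the result is
# a convex combination of w0, a and b.
fuse_values <- function(a, b, alpha, epochs) {
  beta <- 1 - alpha
  shrink <- beta^(2 * epochs)
  w0 <- (a + b) / 2
  shrink * w0 + (1 - shrink) * (beta * a + b) / (1 + beta)
}

#' Fuse two ensemble-averaged sweeps at the feature level
#'
#' Trains a one-prototype LVQ network on the two sweeps with a common
#' target class, presenting them in strict alternation for
#' `config$epochs` epochs from a midpoint initialization, and returns the
#' converged prototype: a mix of the two signals with the same
#' dimensionality as the originals. Every fused component lies within the
#' per-sample envelope `[min(a_n, b_n), max(a_n, b_n)]`, and fusing a
#' sweep with itself returns it unchanged.
#'
#' @param sweep_a,sweep_b `ensemble_sweep` objects (same subject, same
#'   state, different channels) or bare numeric vectors of equal length.
#' @param config A [fusion_config()].
#' @return An `ensemble_sweep` whose `channel` records both sources, or a
#'   numeric vector when the inputs were bare vectors.
#' @export
fuse_pair <- function(sweep_a, sweep_b, config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  a_obj <- inherits(sweep_a, "ensemble_sweep")
  b_obj <- inherits(sweep_b, "ensemble_sweep")
  a <- if (a_obj) sweep_a$values else as.numeric(sweep_a)
  b <- if (b_obj) sweep_b$values else as.numeric(sweep_b)
  if (length(a) != length(b)) {
    stop_assr(sprintf("Sweep lengths differ (%d vs %d).", length(a), length(b)),
              class = "assr_parameter_error")
  }
  if (a_obj && b_obj) {
    if (!identical(sweep_a$subject_id, sweep_b$subject_id)) {
      stop_assr("Fusion requires sweeps from the same subject.")
    }
    if (!identical(sweep_a$state, sweep_b$state)) {
      stop_assr("Fusion requires sweeps from the same sleep state.")
    }
    if (identical(sweep_a$channel, sweep_b$channel)) {
      stop_assr("Fusion requires two distinct channels/electrodes.")
    }
  }
  fused <- if (config$method == "concatenate") {
    c(a, b)
  } else {
    fuse_values(a, b, config$alpha, config$epochs)
  }
  if (a_obj && b_obj) {
    new_ensemble_sweep(fused, sweep_a$n_averaged, sweep_a$window_index,
                       sweep_a$subject_id,
                       paste0(sweep_a$channel, "+", sweep_b$channel),
                       sweep_a$state, NULL)
  } else {
    fused
  }
}

#' Fuse matched windows of two channels across a whole ensemble dataset
#'
#' Pairs every (subject, state, window) present on `channel_a` with its
#' counterpart on `channel_b` and fuses each pair with [fuse_pair()]. The
#' fused dataset has exactly one sweep per matched pair and, with the
#' default mixing method, the same per-sweep storage as a single channel.
#'
#' @param data Ensemble tibble covering both channels.
#' @param channel_a,channel_b Distinct channel labels present in `data`.
#' @param config A [fusion_config()].
#' @return Ensemble tibble with `channel = "channel_a+channel_b"`.
#' @export
build_fused_dataset <- function(data, channel_a, channel_b,
                                config = fusion_config()) {
  stopifnot(is.data.frame(data))
  if (identical(channel_a, channel_b)) {
    stop_assr("Fusion requires two distinct channels/electrodes.",
              class = "assr_parameter_error")
  }
  da <- dplyr::filter(data, .data$channel == channel_a)
  db <- dplyr::filter(data, .data$channel == channel_b)
  key <- function(d) paste(d$subject_id, d$state, d$window_index, sep = "|")
  ka <- key(da)
  kb <- key(db)
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unmatched) > 0 || nrow(da) == 0) {
    stop_assr(paste0("Unmatched (subject, state, window) pairs: ",
                     if (length(unmatched) > 0) {
                       paste(utils::head(unmatched, 10), collapse = "; ")
                     } else "no data on requested channels"),
              class = "assr_parameter_error")
  }
  db <- db[match(ka, kb), ]
  out <- da
  out$channel <- paste0(channel_a, "+", channel_b)
  out$values <- purrr::map2(da$values, db$values, function(a, b) {
    if (config$method == "concatenate") c(a, b) else
      fuse_values(a, b, config$alpha, config$epochs)
  })
  out
}
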