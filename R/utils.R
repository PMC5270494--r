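# Internal helpers shared across modules.

# Deterministic 32-bit sub-seed from a base seed plus string context.
# Keeps every derived seed strictly below 2^31 so it is a valid R integer.
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  parts <- paste(c(...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(parts)) h <- (h * 131 + cp) %% 1987654321
  as.integer((h + (seed %% 2147483587) * 7919 + 1) %% 2147483587)
}

stop_assr <- function(msg, class = "assr_error") {
  rlang::abort(msg, class = class)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop_assr(sprintf("`%s` must be a single finite number in [%s, %s].",
                      name, format(lower), format(upper)),
              class = "assr_parameter_error")
  }
  invisible(x)
}

# Circular shift of a vector by k samples (positive k delays the waveform).
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Number of samples in one stimulus cycle
#'
#' One sweep spans a single cycle of the periodic auditory stimulus. A
#' cycle rarely contains a whole number of samples (at 12 kHz a 40.68-Hz
#' cycle is 294.985 samples), so the sweep length is the nearest whole
#' number of samples per cycle: `round(fs / stim_rate)`. At the default
#' amplifier rate of 12 kHz and stimulus rate of 40.68 Hz this gives the
#' 295-sample sweeps used throughout; acquisition keeps only cycles that
#' contain the full 295 samples.
#'
#' @param fs Sampling rate of the amplifier in Hz.
#' @param stim_rate Stimulus repetition rate in Hz.
#' @return Integer number of samples per sweep.
#' @examples
#' sweep_samples(12000, 40.68) # 295
#' @export
sweep_samples <- function(fs = 12000, stim_rate = 40.68) {
  check_scalar_number(fs, "fs", lower = 1e-9)
  check_scalar_number(stim_rate, "stim_rate", lower = 1e-9)
  as.integer(round(fs / stim_rate))
}

# Validate an ensemble-sweep tibble and extract an input matrix + labels.
ensemble_xy <- function(data, classes = NULL) {
  if (is.matrix(data)) {
    stop_assr("A bare matrix needs labels; pass an ensemble tibble with a `state` column.")
  }
  req <- c("values", "state")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop_assr(paste0("Ensemble data is missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) stop_assr("Ensemble data is empty.")
  x <- do.call(rbind, data$values)
  if (!all(is.finite(x))) stop_assr("Non-finite values in ensemble sweeps.")
  classes <- classes %||% sort(unique(as.character(data$state)))
  y <- match(as.character(data$state), classes)
  if (anyNA(y)) {
    stop_assr(paste0("Unknown state label(s): ",
                     paste(setdiff(unique(data$state), classes), collapse = ", ")))
  }
  list(x = x, y = y, classes = classes)
}
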