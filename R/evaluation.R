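# Classification metrics: confusion counts, error rate, FAR/FRR, EER, and
# the SVM baseline.
#
# The two-state classifier is scored like a verification system: one state
# is the "valid" (accept) class -- wakefulness W0 by convention -- and the
# other is "invalid". FAR is the fraction of invalid inputs incorrectly
# accepted; FRR is the fraction of valid inputs incorrectly rejected.

#' Confusion counts, error rate and FAR/FRR
#'
#' Fills the four possible outcomes (valid correctly / incorrectly
#' classified, invalid correctly / incorrectly classified), the overall
#' error percentage, and the accept/reject error rates with the valid
#' class treated as the accept decision.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param valid_class Label of the valid/accept class (default `"W0"`).
#' @return An object of class `assr_rates`: counts `valid_accepted`,
#'   `valid_rejected`, `invalid_accepted`, `invalid_rejected`, plus
#'   `error_pct`, `far`, `frr` and `n`.
#' @export
confusion_and_rates <- function(predicted, truth, valid_class = "W0") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop_assr("`predicted` and `truth` lengths differ.",
              class = "assr_parameter_error")
  }
  if (length(truth) < 1) stop_assr("Need at least one item.")
  labels <- unique(c(predicted, truth))
  if (length(labels) > 2 || !valid_class %in% c(labels, valid_class)) {
    stop_assr(paste0("Unknown label(s): expected two states, got ",
                     paste(labels, collapse = ", ")),
              class = "assr_parameter_error")
  }
  is_valid <- truth == valid_class
  acc <- predicted == valid_class
  counts <- list(
    valid_accepted = sum(is_valid & acc),
    valid_rejected = sum(is_valid & !acc),
    invalid_accepted = sum(!is_valid & acc),
    invalid_rejected = sum(!is_valid & !acc)
  )
  n <- length(truth)
  n_valid <- sum(is_valid)
  n_invalid <- n - n_valid
  structure(c(counts, list(
    error_pct = 100 * (counts$valid_rejected + counts$invalid_accepted) / n,
    far = if (n_invalid > 0) counts$invalid_accepted / n_invalid else NA_real_,
    frr = if (n_valid > 0) counts$valid_rejected / n_valid else NA_real_,
    n = n, valid_class = valid_class
  )), class = "assr_rates")
}

#' @export
print.assr_rates <- function(x, ...) {
  cat(sprintf("<assr_rates> n = %d | error %.2f%%, FAR %.4f, FRR %.4f (valid class %s)\n",
              x$n, x$error_pct, x$far, x$frr, x$valid_class))
  invisible(x)
}

# FAR/FRR staircase over candidate thresholds (accept iff score >= theta).
far_frr_curve <- function(scores, truth, valid_class = "W0") {
  is_valid <- as.character(truth) == valid_class
  if (!any(is_valid) || all(is_valid)) {
    stop_assr("Both classes must be present to sweep thresholds.",
              class = "assr_parameter_error")
  }
  thr <- c(-Inf, sort(unique(scores)), Inf)
  far <- vapply(thr, function(t) mean(scores[!is_valid] >= t), numeric(1))
  frr <- vapply(thr, function(t) mean(scores[is_valid] < t), numeric(1))
  tibble::tibble(threshold = thr, far = far, frr = frr)
}

#' Equal error rate by threshold sweep
#'
#' Accepts an input when its score is at or above the threshold. Sweeping
#' the threshold over the observed scores makes FAR non-increasing and FRR
#' non-decreasing; the EER is the common rate at the crossing, linearly
#' interpolated between adjacent thresholds when the staircases do not
#' meet exactly.
#'
#' @param scores Numeric scores, larger meaning more like the valid class.
#' @param truth Labels; both classes must be present.
#' @param valid_class Label of the valid/accept class.
#' @return List with `eer` and the crossing `threshold`.
#' @export
compute_eer <- function(scores, truth, valid_class = "W0") {
  curve <- far_frr_curve(scores, truth, valid_class)
  d <- curve$far - curve$frr # non-increasing in the threshold
  hit <- which(d == 0)
  if (length(hit) > 0) {
    i <- hit[1]
    return(list(eer = curve$far[i], threshold = curve$threshold[i]))
  }
  i <- which(d[-nrow(curve)] > 0 & d[-1] < 0)[1]
  if (is.na(i)) { # degenerate: curves never bracket; take closest point
    i <- which.min(abs(d))
    return(list(eer = (curve$far[i] + curve$frr[i]) / 2,
                threshold = curve$threshold[i]))
  }
  # linear interpolation between candidate thresholds i and i + 1
  t <- d[i] / (d[i] - d[i + 1])
  eer <- curve$far[i] + t * (curve$far[i + 1] - curve$far[i])
  thr <- if (is.finite(curve$threshold[i]) && is.finite(curve$threshold[i + 1])) {
    curve$threshold[i] + t * (curve$threshold[i + 1] - curve$threshold[i])
  } else {
    curve$threshold[i + 1]
  }
  list(eer = eer, threshold = thr)
}

#' SVM baseline classifier
#'
#' Fits a two-class support vector machine on the ensemble-averaged sweep
#' vectors through an established implementation (libsvm via e1071).
#' Deterministic given the data, settings and seed.
#'
#' @param train Ensemble tibble with `values` and `state` covering both
#'   classes.
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param cost Soft-margin cost parameter C.
#' @param seed Integer seed.
#' @return An `assr_svm` classifier handle with a [predict()] method
#'   returning a tibble of `.pred` and `.score` like [lvq_classify()].
#' @export
train_svm_baseline <- function(train, kernel = c("linear", "rbf"),
                               cost = 1, seed = 0) {
  kernel <- match.arg(kernel)
  xy <- ensemble_xy(train)
  if (length(unique(xy$y)) < 2) {
    stop_assr("SVM training needs both classes present.",
              class = "assr_parameter_error")
  }
  fit <- withr::with_seed(derive_seed(seed, "svm"), {
    e1071::svm(xy$x, factor(xy$classes[xy$y], levels = xy$classes),
               kernel = if (kernel == "rbf") "radial" else "linear",
               cost = cost, scale = FALSE)
  })
  structure(list(fit = fit, classes = xy$classes, kernel = kernel,
                 cost = cost, seed = as.integer(seed)),
            class = "assr_svm")
}

#' @export
print.assr_svm <- function(x, ...) {
  cat(sprintf("<assr_svm> %s kernel, C = %g, %d support vectors\n",
              x$kernel, x$cost, x$fit$tot.nSV))
  invisible(x)
}

#' @rdname train_svm_baseline
#' @param object An `assr_svm`.
#' @param newdata Ensemble tibble.
#' @param valid_class Class the decision score is oriented toward.
#' @param ... Unused.
#' @export
predict.assr_svm <- function(object, newdata, valid_class = "W0", ...) {
  if (!is.data.frame(newdata) || nrow(newdata) == 0) {
    stop_assr("Cannot classify an empty input set.", class = "assr_empty_error")
  }
  x <- do.call(rbind, newdata$values)
  pred <- stats::predict(object$fit, x, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # orient the libsvm decision value toward the valid class
  dv_name <- colnames(attr(pred, "decision.values"))[1]
  first <- strsplit(dv_name, "/")[[1]][1]
  score <- if (identical(first, valid_class)) dv else -dv
  out <- newdata[setdiff(names(newdata), "values")]
  out$.pred <- as.character(pred)
  out$.score <- as.numeric(score)
  out <- tibble::as_tibble(out)
  attr(out, "pcc") <- if ("state" %in% names(newdata)) {
    100 * mean(out$.pred == as.character(newdata$state))
  } else {
    NA_real_
  }
  out
}
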