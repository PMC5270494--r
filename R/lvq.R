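# Learning vector quantization (LVQ1) with a compact architecture and
# blind-neuron pruning.
#
# The network is a nearest-prototype classifier: a competitive layer of HN
# prototype vectors (one winner per input, Euclidean distance, ties to the
# lowest index) and a linear layer mapping each prototype to one of NC
# classes. Training moves only the winning prototype: toward the input when
# the classes agree, away when they differ,
#   W <- W + alpha * (x - W)   (same class)
#   W <- W - alpha * (x - W)   (different class)
# so each update changes the winner-to-input distance by exactly a factor
# (1 - alpha) or (1 + alpha). Prototypes that never win on the training
# data ("blind neurons") can be pruned without changing any decision.

new_lvq_model <- function(prototypes, proto_class, classes, seed) {
  structure(list(
    prototypes = prototypes,
    proto_class = as.integer(proto_class),
    classes = classes,
    n_inputs = ncol(prototypes),
    n_classes = length(classes),
    alpha = NA_real_,
    epochs = 0L,
    epochs_run = 0L,
    win_counts = integer(nrow(prototypes)),
    trained = FALSE,
    seed = as.integer(seed),
    history = NULL
  ), class = "lvq_model")
}

#' @export
print.lvq_model <- function(x, ...) {
  cat(sprintf("<lvq_model> %d prototypes x %d inputs, %d classes (%s)%s\n",
              nrow(x$prototypes), x$n_inputs, x$n_classes,
              paste(x$classes, collapse = ", "),
              if (x$trained) {
                sprintf(" | trained %d epochs, alpha %g, final error %.2f%%",
                        x$epochs_run, x$alpha,
                        utils::tail(x$history$error_pct, 1))
              } else " | untrained"))
  invisible(x)
}

#' Initialize an LVQ classifier
#'
#' Allocates `hn` prototype vectors and assigns them to classes round-robin
#' so every class owns at least one prototype (a network recognizing NC
#' classes needs at least NC hidden-layer prototypes). Initialization
#' strategies:
#'
#' * `"stratified"` (default): the prototypes of each class start at the
#'   per-subject class means, cycling through the training subjects. This
#'   matches the compact architecture's rationale — with `hn` equal to
#'   subjects x classes each hidden neuron can own one subject's cluster —
#'   and guarantees same-class prototypes start at distinct positions.
#'   Falls back to `"sample"` when the data carry no `subject_id`.
#' * `"class-mean"`: each prototype is the mean of a seeded random 20%
#'   subsample of its class's training examples (with several prototypes
#'   per class these means nearly coincide, so most start blind; kept for
#'   comparison).
#' * `"sample"`: each prototype is a random training example of its class;
#' * `"random"`: standard normal entries (no data needed).
#'
#' @param n_inputs Input dimensionality (295 for default ASSR sweeps).
#' @param hn Number of hidden-layer prototypes, `hn >= n_classes`.
#' @param n_classes Number of classes (2: wake and deep sleep).
#' @param strategy Initialization strategy, see above.
#' @param data Ensemble tibble with `values` and `state` columns; required
#'   for `"class-mean"` and `"sample"`.
#' @param classes Optional class labels; defaults to the sorted distinct
#'   states in `data`, or `c("W0", "N3")` order sorted when absent.
#' @param seed Integer seed.
#' @return An untrained `lvq_model`.
#' @export
lvq_init <- function(n_inputs = 295, hn = 2, n_classes = 2,
                     strategy = c("stratified", "class-mean", "sample", "random"),
                     data = NULL, classes = NULL, seed = 0) {
  strategy <- match.arg(strategy)
  if (n_classes < 2) stop_assr("`n_classes` must be >= 2.")
  if (hn < n_classes) {
    stop_assr(sprintf(
      "hn (%d) < n_classes (%d): recognizing NC classes requires at least NC hidden-layer prototypes.",
      hn, n_classes), class = "assr_parameter_error")
  }
  if (hn < 2) stop_assr("`hn` must be >= 2.")
  proto_class <- ((seq_len(hn) - 1L) %% n_classes) + 1L

  if (strategy %in% c("stratified", "class-mean", "sample")) {
    if (is.null(data)) {
      stop_assr(sprintf("strategy '%s' requires `data`.", strategy),
                class = "assr_parameter_error")
    }
    xy <- ensemble_xy(data, classes = classes)
    classes <- xy$classes
    if (length(classes) != n_classes) {
      stop_assr(sprintf("`data` has %d classes but n_classes = %d.",
                        length(classes), n_classes))
    }
    n_inputs <- ncol(xy$x)
    subjects <- if ("subject_id" %in% names(data)) {
      as.character(data$subject_id)
    } else {
      NULL
    }
    if (strategy == "stratified" && is.null(subjects)) strategy <- "sample"
    # position of each prototype within its own class (1, 2, ... per class)
    within_class_rank <- stats::ave(proto_class, proto_class, FUN = seq_along)
    subj_levels <- unique(subjects)
    prototypes <- withr::with_seed(derive_seed(seed, "lvq-init"), {
      t(vapply(seq_len(hn), function(p) {
        idx <- which(xy$y == proto_class[p])
        if (length(idx) == 0) {
          stop_assr(sprintf("No training examples for class '%s'.",
                            classes[proto_class[p]]))
        }
        if (strategy == "sample") {
          xy$x[idx[sample.int(length(idx), 1)], ]
        } else if (strategy == "stratified") {
          s <- subj_levels[((within_class_rank[p] - 1L) %% length(subj_levels)) + 1L]
          sub <- idx[subjects[idx] == s]
          if (length(sub) == 0) sub <- idx
          colMeans(xy$x[sub, , drop = FALSE])
        } else {
          sub <- idx[sample.int(length(idx), max(1L, round(0.2 * length(idx))))]
          colMeans(xy$x[sub, , drop = FALSE])
        }
      }, numeric(n_inputs)))
    })
  } else {
    classes <- classes %||% if (n_classes == 2) c("N3", "W0") else
      paste0("C", seq_len(n_classes))
    if (length(classes) != n_classes) {
      stop_assr("`classes` length must equal `n_classes`.")
    }
    prototypes <- withr::with_seed(derive_seed(seed, "lvq-init"),
                                   matrix(stats::rnorm(hn * n_inputs),
                                          nrow = hn))
  }
  new_lvq_model(prototypes, proto_class, classes, seed)
}

#' Index of the winning prototype
#'
#' Returns `argmin_i ||x - W_i||` (Euclidean distance); ties are broken by
#' the lowest prototype index.
#'
#' @param model An `lvq_model`.
#' @param x Numeric input vector of length `model$n_inputs`.
#' @return Integer prototype index.
#' @export
lvq_winner <- function(model, x) {
  stopifnot(inherits(model, "lvq_model"))
  if (length(x) != model$n_inputs) {
    stop_assr(sprintf("Input length %d != network input size %d.",
                      length(x), model$n_inputs))
  }
  d2 <- rowSums(model$prototypes^2) - 2 * drop(model$prototypes %*% x)
  which.min(d2) # which.min returns the first (lowest-index) minimum
}

#' One LVQ1 update step
#'
#' The winning prototype moves toward the input when its class matches the
#' label and away from it otherwise; all other prototypes are unchanged and
#' the winner's win count is incremented.
#'
#' @param model An `lvq_model`.
#' @param x Input vector.
#' @param label Class label (one of `model$classes`) or class index.
#' @param alpha Learning rate in `[0, 1]`.
#' @return The updated model.
#' @export
lvq_update <- function(model, x, label, alpha = 0.1) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop_assr("`alpha` must lie in [0, 1].", class = "assr_parameter_error")
  }
  y <- if (is.character(label) || is.factor(label)) {
    match(as.character(label), model$classes)
  } else {
    as.integer(label)
  }
  if (is.na(y) || y < 1 || y > model$n_classes) {
    stop_assr("Unknown class label.")
  }
  i <- lvq_winner(model, x)
  s <- if (model$proto_class[i] == y) alpha else -alpha
  model$prototypes[i, ] <- model$prototypes[i, ] + s * (x - model$prototypes[i, ])
  model$win_counts[i] <- model$win_counts[i] + 1L
  model
}

# Batch squared distances (n x hn) between rows of x and the prototypes.
lvq_dist2 <- function(prototypes, x) {
  pw <- rowSums(prototypes^2)
  d2 <- matrix(pw, nrow = nrow(x), ncol = length(pw), byrow = TRUE) -
    2 * x %*% t(prototypes)
  d2 + rowSums(x^2) # non-negative; constant per row, irrelevant to argmin
}

lvq_batch_winners <- function(prototypes, x) {
  max.col(-lvq_dist2(prototypes, x), ties.method = "first")
}

#' Train an LVQ classifier
#'
#' Presents the training inputs in a seeded random order each epoch,
#' applying [lvq_update()] per presentation. Training stops after `epochs`
#' epochs or as soon as the end-of-epoch training error drops to
#' `error_limit` or below (when an error limit is given). With
#' `decay = TRUE` the learning rate decreases linearly from `alpha` to
#' 0.01 over the scheduled epochs; by default it is constant.
#'
#' @param model An initialized `lvq_model`.
#' @param data Ensemble tibble with `values` and `state` columns covering
#'   every class.
#' @param alpha Learning rate in `[0, 1]`.
#' @param epochs Maximum number of training epochs.
#' @param error_limit Optional training-error stop threshold in percent
#'   (e.g. `0` stops at the first errorless epoch); `NULL` runs all epochs.
#' @param decay Linearly decay the learning rate.
#' @param seed Integer seed controlling presentation order.
#' @return The trained model; `model$history` is a tibble of per-epoch
#'   training error percentages.
#' @export
lvq_train <- function(model, data, alpha = 0.1, epochs = 2500,
                      error_limit = NULL, decay = FALSE, seed = 0) {
  stopifnot(inherits(model, "lvq_model"))
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop_assr("`alpha` must lie in [0, 1].", class = "assr_parameter_error")
  }
  xy <- ensemble_xy(data, classes = model$classes)
  missing_classes <- setdiff(seq_len(model$n_classes), unique(xy$y))
  if (length(missing_classes) > 0) {
    stop_assr(paste0("Training data lacks class(es): ",
                     paste(model$classes[missing_classes], collapse = ", ")))
  }
  x <- xy$x
  y <- xy$y
  n <- nrow(x)
  alphas <- if (decay) seq(alpha, 0.01, length.out = epochs) else rep(alpha, epochs)
  # presentation orders are drawn in R so seeding semantics stay here;
  # the per-presentation update loop runs compiled
  orders <- withr::with_seed(derive_seed(seed, "lvq-train"), {
    t(vapply(seq_len(epochs), function(ep) sample.int(n), integer(n)))
  })
  res <- lvq_train_loop(model$prototypes, model$proto_class, x, y,
                        alphas, orders,
                        error_limit %||% 0, !is.null(error_limit),
                        model$win_counts)

  model$prototypes <- res$W
  model$win_counts <- res$wins
  model$alpha <- alpha
  model$epochs <- as.integer(epochs)
  model$epochs_run <- as.integer(res$epochs_run)
  model$trained <- TRUE
  model$history <- tibble::tibble(epoch = seq_len(res$epochs_run),
                                  error_pct = res$error_pct)
  model
}

#' Remove blind prototypes
#'
#' A prototype that never wins over one full pass of `data` is "blind": it
#' plays no role in any decision on that data and can be removed without
#' changing predictions. A class's last prototype is never pruned; if all
#' of a class's prototypes are blind, an error identifies the class.
#'
#' @param model A trained `lvq_model`.
#' @param data Ensemble tibble the win census is taken over.
#' @return The pruned model (win counts and class map re-indexed).
#' @export
lvq_prune_blind <- function(model, data) {
  stopifnot(inherits(model, "lvq_model"))
  if (!model$trained) stop_assr("Model must be trained before pruning.")
  xy <- ensemble_xy(data, classes = model$classes)
  winners <- lvq_batch_winners(model$prototypes, xy$x)
  wins <- tabulate(winners, nbins = nrow(model$prototypes))
  keep <- wins > 0
  for (cls in seq_len(model$n_classes)) {
    members <- model$proto_class == cls
    if (!any(keep & members)) {
      stop_assr(sprintf("Pruning would remove every prototype of class '%s'.",
                        model$classes[cls]), class = "assr_prune_error")
    }
  }
  model$prototypes <- model$prototypes[keep, , drop = FALSE]
  model$proto_class <- model$proto_class[keep]
  model$win_counts <- model$win_counts[keep]
  model
}

#' Classify ensemble sweeps with a trained LVQ model
#'
#' Each input is assigned the class of its winning prototype. The returned
#' tibble carries the metadata columns of `data` plus `.pred` and `.score`,
#' where `.score` is the signed margin `d(nearest other-class prototype) -
#' d(nearest valid-class prototype)` toward `valid_class` (larger means
#' more confidently that class), used for threshold sweeps. When `data`
#' has a `state` column, the percentage of correct classification is
#' attached as attribute `"pcc"` and printed summaries use it.
#'
#' @param model A trained `lvq_model`.
#' @param data Ensemble tibble (non-empty) with a `values` list-column.
#' @param valid_class Class the score is oriented toward (default `"W0"`
#'   when present).
#' @return Tibble of predictions with attribute `"pcc"` (percent correct,
#'   `NA` without truth labels).
#' @export
lvq_classify <- function(model, data, valid_class = NULL) {
  stopifnot(inherits(model, "lvq_model"))
  if (!model$trained) stop_assr("Model is untrained; call lvq_train() first.")
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop_assr("Cannot classify an empty input set.", class = "assr_empty_error")
  }
  x <- do.call(rbind, data$values)
  if (ncol(x) != model$n_inputs) {
    stop_assr(sprintf("Input length %d != network input size %d.",
                      ncol(x), model$n_inputs))
  }
  valid_class <- valid_class %||% if ("W0" %in% model$classes) "W0" else model$classes[1]
  v <- match(valid_class, model$classes)
  if (is.na(v)) stop_assr("`valid_class` is not one of the model's classes.")
  d2 <- lvq_dist2(model$prototypes, x)
  winners <- max.col(-d2, ties.method = "first")
  pred <- model$classes[model$proto_class[winners]]
  d_valid <- apply(d2[, model$proto_class == v, drop = FALSE], 1, min)
  d_other <- apply(d2[, model$proto_class != v, drop = FALSE], 1, min)
  score <- sqrt(pmax(d_other, 0)) - sqrt(pmax(d_valid, 0))
  out <- data[setdiff(names(data), "values")]
  out$.pred <- pred
  out$.score <- score
  out <- tibble::as_tibble(out)
  pcc <- if ("state" %in% names(data)) {
    100 * mean(pred == as.character(data$state))
  } else {
    NA_real_
  }
  attr(out, "pcc") <- pcc
  out
}

#' @rdname lvq_classify
#' @param object A trained `lvq_model`.
#' @param newdata Ensemble tibble.
#' @param ... Passed to [lvq_classify()].
#' @export
predict.lvq_model <- function(object, newdata, ...) {
  lvq_classify(object, newdata, ...)
}

#' Percentage of correct classification from a prediction tibble
#'
#' @param predictions Result of [lvq_classify()] (or any tibble carrying a
#'   `"pcc"` attribute).
#' @return Percent correct, or `NA` if truth labels were absent.
#' @export
pcc <- function(predictions) {
  attr(predictions, "pcc") %||% NA_real_
}
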