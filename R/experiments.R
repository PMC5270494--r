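# Experiment harnesses: same-subject, leave-one-subject-out (LOSO) and
# fused-LOSO designs, with per-subject error tables and summary rates.

#' Reference leave-one-subject-out error rates
#'
#' Per-subject LOSO error percentages reported for the compact LVQ
#' classifier on the original eight-subject 40-Hz ASSR recordings
#' (channel Fz-A1A2; 500 wake + 500 deep-sleep ensemble-averaged sweeps
#' tested per held-out subject). The mean accuracy over these eight rows,
#' `100 - mean(error)`, is 97.6% to one decimal. The recordings themselves
#' are not redistributable; the synthetic generator in this package stands
#' in for them.
#'
#' @format Named numeric vector, one error percentage per held-out subject.
#' @export
assr_reference_errors <- c(H = 7, G = 0, F = 0, E = 6.6,
                           D = 0, C = 0, B = 0, A = 5.5)

default_experiment_config <- function() {
  list(
    alpha = 0.1,          # LVQ learning rate
    epochs = 2500,        # LVQ epoch cap
    error_limit = 0,      # stop at the first errorless epoch
    decay = FALSE,
    hn = NULL,            # NULL: NC per subject (same-subject), S x NC (LOSO)
    init = "stratified",
    prune = FALSE,
    svm_kernel = "linear",
    svm_cost = 1,
    valid_class = "W0",
    train_frac = 0.5,     # same-subject split
    channel_a = NULL,     # fused designs; default: first two channels
    channel_b = NULL,
    fusion = NULL         # fusion_config(); default built per run
  )
}

fit_and_predict <- function(classifier, train, test, config, seed) {
  if (classifier == "lvq") {
    n_subj <- length(unique(train$subject_id))
    n_cls <- length(unique(train$state))
    hn <- config$hn %||% max(n_cls, n_subj * n_cls) # compactness rule S x NC
    model <- lvq_init(hn = hn, n_classes = n_cls, strategy = config$init,
                      data = train, seed = seed)
    model <- lvq_train(model, train, alpha = config$alpha,
                       epochs = config$epochs,
                       error_limit = config$error_limit,
                       decay = config$decay, seed = seed)
    if (isTRUE(config$prune)) model <- lvq_prune_blind(model, train)
    lvq_classify(model, test, valid_class = config$valid_class)
  } else {
    fit <- train_svm_baseline(train, kernel = config$svm_kernel,
                              cost = config$svm_cost, seed = seed)
    predict(fit, test, valid_class = config$valid_class)
  }
}

#' Run a sleep-pattern classification experiment
#'
#' Replays one of three designs on an ensemble-averaged sweep dataset:
#'
#' * `"same-subject"`: per subject, train on the first half of each
#'   state's windows and test on the disjoint second half;
#' * `"loso"`: for each held-out subject, train on all other subjects and
#'   test on the held-out one;
#' * `"fused-loso"`: LOSO on the two-channel fused dataset built by
#'   [build_fused_dataset()].
#'
#' Single-channel designs require `data` restricted to one channel. The
#' LVQ hidden-layer size defaults to the compact rule: the number of
#' classes per subject in the same-subject design and (training subjects)
#' x (classes) in the LOSO designs.
#'
#' @param data Ensemble tibble (see [windowed_averages()]).
#' @param design `"same-subject"`, `"loso"` or `"fused-loso"`.
#' @param classifier `"lvq"` or `"svm"`.
#' @param config Named list overriding the defaults (learning rate,
#'   epochs, error limit, `hn`, init strategy, SVM kernel/cost,
#'   `valid_class`, `train_frac`, fused channels).
#' @param seed Integer seed; identical seeds give identical reports.
#' @return An `eval_report`: per-subject rows, mean error/accuracy,
#'   pooled confusion counts, FAR/FRR, EER, and the effective config.
#' @export
run_experiment <- function(data, design = c("same-subject", "loso", "fused-loso"),
                           classifier = c("lvq", "svm"),
                           config = list(), seed = 0) {
  design <- match.arg(design)
  classifier <- match.arg(classifier)
  config <- utils::modifyList(default_experiment_config(), config)
  stopifnot(is.data.frame(data))

  if (design == "fused-loso") {
    chans <- unique(data$channel)
    channel_a <- config$channel_a %||% chans[1]
    channel_b <- config$channel_b %||% chans[2]
    if (is.na(channel_b)) {
      stop_assr("fused-loso needs two channels in the data.",
                class = "assr_parameter_error")
    }
    fcfg <- config$fusion %||% fusion_config(seed = seed)
    data <- build_fused_dataset(data, channel_a, channel_b, fcfg)
    design_run <- "loso"
  } else {
    if (length(unique(data$channel)) != 1) {
      stop_assr(paste0("Design '", design, "' expects a single channel; got: ",
                       paste(unique(data$channel), collapse = ", "),
                       ". Filter the data first."),
                class = "assr_parameter_error")
    }
    design_run <- design
  }

  subjects <- sort(unique(data$subject_id))
  if (design_run == "loso" && length(subjects) < 2) {
    stop_assr("LOSO is undefined with a single subject.",
              class = "assr_parameter_error")
  }

  folds <- if (design_run == "same-subject") {
    purrr::map(subjects, function(s) {
      d <- dplyr::filter(data, .data$subject_id == s)
      d <- dplyr::arrange(d, .data$state, .data$window_index)
      idx_train <- unlist(purrr::map(split(seq_len(nrow(d)), d$state),
                                     function(ix) ix[seq_len(floor(config$train_frac * length(ix)))]))
      list(test_subject = s, train = d[idx_train, ],
           test = d[setdiff(seq_len(nrow(d)), idx_train), ])
    })
  } else {
    purrr::map(subjects, function(s) {
      list(test_subject = s,
           train = dplyr::filter(data, .data$subject_id != s),
           test = dplyr::filter(data, .data$subject_id == s))
    })
  }

  rows <- list()
  preds <- list()
  for (f in folds) {
    fold_seed <- derive_seed(seed, design, classifier, f$test_subject)
    p <- fit_and_predict(classifier, f$train, f$test, config, fold_seed)
    rows[[length(rows) + 1]] <- tibble::tibble(
      test_subject = f$test_subject,
      train_subjects = paste(sort(unique(f$train$subject_id)), collapse = ","),
      n_train = nrow(f$train),
      n_test = nrow(f$test),
      error_pct = 100 - attr(p, "pcc"),
      accuracy_pct = attr(p, "pcc")
    )
    preds[[length(preds) + 1]] <- p
  }
  rows <- dplyr::bind_rows(rows)
  all_pred <- dplyr::bind_rows(preds)
  rates <- confusion_and_rates(all_pred$.pred, all_pred$state,
                               valid_class = config$valid_class)
  eer <- tryCatch(
    compute_eer(all_pred$.score, all_pred$state, config$valid_class)$eer,
    error = function(e) NA_real_)

  structure(list(
    design = design,
    classifier = classifier,
    rows = rows,
    mean_error_pct = mean(rows$error_pct),
    mean_accuracy_pct = 100 - mean(rows$error_pct),
    rates = rates,
    eer = eer,
    config = config,
    config_hash = rlang::hash(config),
    seed = as.integer(seed),
    predictions = all_pred
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s design, %s classifier | mean error %.2f%% (accuracy %.2f%%), FAR %.4f, FRR %.4f, EER %s\n",
              x$design, x$classifier, x$mean_error_pct, x$mean_accuracy_pct,
              x$rates$far, x$rates$frr,
              if (is.na(x$eer)) "NA" else sprintf("%.4f", x$eer)))
  print(x$rows)
  invisible(x)
}

#' Mean error and mean accuracy of per-subject error rates
#'
#' @param errors Numeric vector of per-subject error percentages in
#'   `[0, 100]`.
#' @return One-row tibble with `mean_error_pct` and `mean_accuracy_pct`
#'   (`100 - mean_error_pct`).
#' @examples
#' summarize_table(assr_reference_errors)
#' @export
summarize_table <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) == 0) stop_assr("`errors` must be non-empty.")
  if (any(!is.finite(errors)) || any(errors < 0) || any(errors > 100)) {
    stop_assr("Error percentages must lie in [0, 100].",
              class = "assr_parameter_error")
  }
  tibble::tibble(mean_error_pct = mean(errors),
                 mean_accuracy_pct = 100 - mean(errors))
}

#' Write an evaluation report to CSV + JSON
#'
#' Emits `<design>-<classifier>.csv` (per-subject rows in the layout of
#' the per-design error tables: training subjects, test subject, sizes,
#' error %) and `<design>-<classifier>.json` (summary rates plus the
#' effective config, its hash and the seed) into `dir`.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, paste0(report$design, "-", report$classifier))
  csv_path <- paste0(stem, ".csv")
  json_path <- paste0(stem, ".json")
  utils::write.csv(report$rows, csv_path, row.names = FALSE)
  jsonlite::write_json(list(
    design = report$design,
    classifier = report$classifier,
    mean_error_pct = report$mean_error_pct,
    mean_accuracy_pct = report$mean_accuracy_pct,
    far = report$rates$far,
    frr = report$rates$frr,
    eer = report$eer,
    seed = report$seed,
    config_hash = report$config_hash,
    package_version = as.character(utils::packageVersion("assrfuse")),
    config = report$config[!vapply(report$config, is.null, logical(1))]
  ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv_path, json_path))
}
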