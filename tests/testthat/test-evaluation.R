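# Metrics, EER estimation, the SVM baseline and experiment harnesses.

test_that("confusion counts, error rate and FAR/FRR follow the four-outcome definitions", {
  truth <- rep(c("W0", "N3"), each = 50)
  perfect <- confusion_and_rates(truth, truth)
  expect_equal(perfect$error_pct, 0)
  expect_equal(perfect$far, 0)
  expect_equal(perfect$frr, 0)

  flipped <- confusion_and_rates(ifelse(truth == "W0", "N3", "W0"), truth)
  expect_equal(flipped$error_pct, 100)

  r <- confusion_and_rates(c("W0", "N3", "N3", "N3"),
                           c("W0", "W0", "N3", "N3"))
  expect_equal(r$error_pct, 25)
  expect_equal(r$valid_accepted, 1)
  expect_equal(r$valid_rejected, 1)
  expect_equal(r$invalid_rejected, 2)
  expect_equal(r$invalid_accepted, 0)
  expect_equal(r$frr, 0.5)
  expect_equal(r$far, 0)
  expect_equal(r$valid_accepted + r$valid_rejected + r$invalid_accepted +
                 r$invalid_rejected, r$n)

  expect_error(confusion_and_rates(c("W0"), c("W0", "N3")), "lengths differ")
})

test_that("EER is 0 for separated scores, 0.5 for exchangeable scores, and counts swapped pairs", {
  truth <- rep(c("W0", "N3"), each = 100)
  sep <- c(stats::rnorm(100, 10), stats::rnorm(100, -10))
  expect_equal(compute_eer(sep, truth)$eer, 0)

  exch <- withr::with_seed(10, stats::rnorm(4000))
  truth_big <- rep(c("W0", "N3"), each = 2000)
  expect_equal(compute_eer(exch, truth_big)$eer, 0.5, tolerance = 0.03)

  # one swapped pair in otherwise separated data
  w0_scores <- c(rep(10, 99), -5)
  n3_scores <- c(rep(-10, 99), 5)
  est <- compute_eer(c(w0_scores, n3_scores), truth)
  expect_equal(est$eer, 0.01)

  expect_error(compute_eer(1:5, rep("W0", 5)), "Both classes")
})

test_that("FAR is non-increasing and FRR non-decreasing along the threshold sweep", {
  withr::with_seed(12, {
    scores <- stats::rnorm(300)
    truth <- sample(c("W0", "N3"), 300, replace = TRUE)
    curve <- assrfuse:::far_frr_curve(scores, truth)
    expect_true(all(diff(curve$far) <= 1e-12))
    expect_true(all(diff(curve$frr) >= -1e-12))
    expect_equal(curve$far[1], 1)
    expect_equal(curve$frr[1], 0)
  })
})

test_that("the SVM baseline separates clusters, is seed-deterministic, and is near chance under label shuffling", {
  train <- make_cluster_ensemble(n_per_class = 30, seed = 1)
  test <- make_cluster_ensemble(n_per_class = 20, seed = 2)
  fit <- train_svm_baseline(train, seed = 0)
  pred <- predict(fit, test)
  expect_equal(pcc(pred), 100)

  fit2 <- train_svm_baseline(train, seed = 0)
  expect_identical(predict(fit2, test)$.pred, pred$.pred)

  # permutation null: labels carry no signal -> ~50% cross-validated error
  big <- make_cluster_ensemble(n_per_class = 100, noise = 1, seed = 3)
  shuffled <- big
  shuffled$state <- withr::with_seed(4, sample(big$state))
  errs <- purrr::map_dbl(0:4, function(f) {
    test_idx <- seq_len(nrow(big)) %% 5 == f
    fit <- train_svm_baseline(shuffled[!test_idx, ], seed = f)
    100 - pcc(predict(fit, shuffled[test_idx, ]))
  })
  expect_equal(mean(errs), 50, tolerance = 10)

  expect_error(train_svm_baseline(dplyr::filter(train, state == "W0")),
               "both classes")
})

test_that("summarize_table returns mean error and its complement accuracy", {
  expect_equal(summarize_table(c(0, 0, 0))$mean_accuracy_pct, 100)
  expect_equal(summarize_table(100)$mean_accuracy_pct, 0)
  expect_equal(summarize_table(c(4, 6))$mean_error_pct, 5)
  expect_error(summarize_table(numeric(0)), "non-empty")
  expect_error(summarize_table(c(5, 120)), "0, 100")
})

test_that("experiment designs validate their inputs and reproduce from seeds", {
  toy <- make_toy_ensemble(n_subjects = 3, windows_per_state = 8, seed = 7)
  one_subject <- dplyr::filter(toy, subject_id == "A")
  expect_error(run_experiment(one_subject, "loso", "lvq"), "single subject")

  two_channel <- make_toy_ensemble(n_subjects = 2, windows_per_state = 4,
                                   channels = c("Fz-A1A2", "C4-A1A2"),
                                   seed = 8)
  expect_error(run_experiment(two_channel, "loso", "lvq"), "single channel")

  r1 <- run_experiment(toy, "same-subject", "lvq", seed = 5)
  r2 <- run_experiment(toy, "same-subject", "lvq", seed = 5)
  expect_identical(r1$rows, r2$rows)
  expect_identical(glance(r1), glance(r2))
  expect_equal(nrow(r1$rows), 3) # one row per subject
  expect_equal(r1$rates$n, sum(r1$rows$n_test))
})

test_that("the fused-LOSO design runs on matched two-channel data", {
  toy <- make_toy_ensemble(n_subjects = 3, windows_per_state = 6,
                           channels = c("Fz-A1A2", "C4-A1A2"), seed = 9)
  rep <- run_experiment(toy, "fused-loso", "lvq", seed = 1)
  expect_equal(rep$design, "fused-loso")
  expect_equal(nrow(rep$rows), 3)
  expect_true(all(rep$rows$error_pct >= 0 & rep$rows$error_pct <= 100))
})

test_that("evaluation reports tidy, glance and serialize to CSV/JSON", {
  toy <- make_toy_ensemble(n_subjects = 2, windows_per_state = 6, seed = 10)
  rep <- run_experiment(toy, "same-subject", "lvq", seed = 2)
  td <- tidy(rep)
  expect_equal(td$design[1], "same-subject")
  g <- glance(rep)
  expect_equal(g$n_subjects, 2)
  expect_true(g$far >= 0 && g$far <= 1)

  dir <- withr::local_tempdir()
  paths <- write_eval_report(rep, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(back$error_pct, rep$rows$error_pct)
  js <- jsonlite::read_json(paths[2])
  expect_equal(js$mean_error_pct, rep$mean_error_pct)
  expect_true(nzchar(js$config_hash))
})
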