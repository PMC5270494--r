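# LVQ1 classifier: initialization, winner selection, updates, training,
# pruning and serialization.

test_that("initialization balances prototypes across classes and validates hn", {
  toy <- make_cluster_ensemble()
  m <- lvq_init(hn = 2, n_classes = 2, data = toy)
  expect_equal(m$proto_class, c(1L, 2L))
  expect_equal(sort(m$classes), c("N3", "W0"))

  m28 <- lvq_init(hn = 28, n_classes = 2, data = toy)
  expect_equal(as.numeric(table(m28$proto_class)), c(14, 14))

  expect_error(lvq_init(hn = 1, n_classes = 2, data = toy), "NC")
  expect_error(lvq_init(hn = 4, n_classes = 2, strategy = "class-mean"),
               "requires `data`")
})

test_that("class-mean initialization on noiseless data recovers the class templates", {
  tpl_a <- rep(1, 8)
  tpl_b <- rep(-1, 8)
  toy <- tibble::tibble(
    subject_id = "A", channel = "Fz-A1A2",
    state = rep(c("W0", "N3"), each = 5),
    window_index = rep(0:4, 2), n_averaged = 900L,
    values = c(replicate(5, tpl_a, simplify = FALSE),
               replicate(5, tpl_b, simplify = FALSE)))
  m <- lvq_init(hn = 2, n_classes = 2, data = toy, strategy = "class-mean")
  expect_equal(m$prototypes[m$proto_class == match("W0", m$classes), ], tpl_a)
  expect_equal(m$prototypes[m$proto_class == match("N3", m$classes), ], tpl_b)
})

test_that("stratified initialization places same-class prototypes at distinct subject means", {
  toy <- make_toy_ensemble(n_subjects = 3, windows_per_state = 6, seed = 2)
  m <- lvq_init(hn = 6, n_classes = 2, data = toy, seed = 2)
  for (cls in 1:2) {
    protos <- m$prototypes[m$proto_class == cls, ]
    pair_dists <- stats::dist(protos)
    expect_true(all(pair_dists > 0.1)) # one prototype per subject cluster
  }
  # each prototype sits at the class mean of one subject
  xy <- assrfuse:::ensemble_xy(toy)
  subj <- as.character(toy$subject_id)
  for (p in seq_len(6)) {
    dists <- purrr::map_dbl(unique(subj), function(s) {
      idx <- which(subj == s & xy$y == m$proto_class[p])
      sqrt(sum((colMeans(xy$x[idx, , drop = FALSE]) - m$prototypes[p, ])^2))
    })
    expect_lt(min(dists), 1e-10)
  }
})

test_that("winner selection is the argmin of Euclidean distance with lowest-index ties", {
  toy <- make_cluster_ensemble()
  m <- lvq_init(hn = 2, n_classes = 2, strategy = "random", seed = 1,
                n_inputs = 3)
  m$prototypes <- rbind(c(0, 0, 0), c(10, 10, 10))
  expect_equal(lvq_winner(m, c(0.1, 0.1, 0.1)), 1)
  expect_equal(lvq_winner(m, c(5, 5, 5)), 1) # exact tie -> lowest index
  expect_equal(lvq_winner(m, c(10, 10, 10)), 2) # zero distance wins
  expect_error(lvq_winner(m, c(1, 2)), "length")
})

test_that("winner agrees with an exhaustive distance scan on 1000 seeded instances", {
  withr::with_seed(42, {
    for (trial in 1:1000) {
      hn <- sample(2:10, 1)
      d <- sample(2:8, 1)
      m <- lvq_init(hn = hn, n_classes = 2, strategy = "random",
                    n_inputs = d, seed = trial)
      x <- stats::rnorm(d)
      brute <- which.min(apply(m$prototypes, 1,
                               function(w) sqrt(sum((x - w)^2))))
      expect_identical(lvq_winner(m, x), brute)
    }
  })
})

test_that("the update rule moves only the winner, by exactly the attract/repel amounts", {
  m <- lvq_init(hn = 2, n_classes = 2, strategy = "random", n_inputs = 2,
                seed = 0)
  m$prototypes <- rbind(c(0, 0), c(100, 100))
  x <- c(1, 1)

  same <- lvq_update(m, x, m$classes[m$proto_class[1]], alpha = 0.1)
  expect_equal(same$prototypes[1, ], c(0.1, 0.1))
  expect_equal(same$prototypes[2, ], c(100, 100)) # untouched
  expect_equal(same$win_counts, c(1L, 0L))

  diff <- lvq_update(m, x, m$classes[m$proto_class[2]], alpha = 0.1)
  expect_equal(diff$prototypes[1, ], c(-0.1, -0.1))

  expect_error(lvq_update(m, x, "W0", alpha = 1.5), "alpha")
})

test_that("each update rescales the winner-to-input distance by exactly (1 -/+ alpha)", {
  withr::with_seed(7, {
    for (trial in 1:50) {
      alpha <- stats::runif(1)
      m <- lvq_init(hn = 3, n_classes = 3, strategy = "random",
                    n_inputs = 6, seed = trial)
      x <- stats::rnorm(6)
      i <- lvq_winner(m, x)
      d0 <- sqrt(sum((x - m$prototypes[i, ])^2))
      same <- lvq_update(m, x, m$classes[m$proto_class[i]], alpha = alpha)
      expect_equal(sqrt(sum((x - same$prototypes[i, ])^2)), (1 - alpha) * d0,
                   tolerance = 1e-12)
      other <- m$classes[(m$proto_class[i] %% 3) + 1]
      repel <- lvq_update(m, x, other, alpha = alpha)
      expect_equal(sqrt(sum((x - repel$prototypes[i, ])^2)), (1 + alpha) * d0,
                   tolerance = 1e-12)
    }
  })
})

test_that("training separates well-separated clusters and respects degenerate rates", {
  toy <- make_cluster_ensemble(n_per_class = 15)
  m <- lvq_init(hn = 2, n_classes = 2, data = toy, seed = 1)
  fit <- lvq_train(m, toy, alpha = 0.1, epochs = 50, seed = 1)
  expect_equal(utils::tail(fit$history$error_pct, 1), 0)
  expect_equal(sum(fit$win_counts), fit$epochs_run * nrow(toy))

  frozen <- lvq_train(m, toy, alpha = 0, epochs = 5, seed = 1)
  expect_equal(frozen$prototypes, m$prototypes)

  # the error-limit stop ends training at the first errorless epoch
  early <- lvq_train(m, toy, alpha = 0.1, epochs = 2500, error_limit = 0,
                     seed = 1)
  expect_lt(early$epochs_run, 2500)
  expect_equal(utils::tail(early$history$error_pct, 1), 0)

  only_w0 <- dplyr::filter(toy, state == "W0")
  expect_error(lvq_train(m, only_w0, epochs = 2), "lacks class")
})

test_that("single-subject ensemble sweeps train to zero error within the epoch budget", {
  toy <- make_toy_ensemble(n_subjects = 1, windows_per_state = 50, seed = 5)
  m <- lvq_init(hn = 2, n_classes = 2, data = toy, seed = 5)
  fit <- lvq_train(m, toy, alpha = 0.1, epochs = 2500, error_limit = 0,
                   seed = 5)
  expect_equal(utils::tail(fit$history$error_pct, 1), 0)
})

test_that("learning-rate decay trains at a falling rate and still separates", {
  toy <- make_cluster_ensemble(n_per_class = 10)
  m <- lvq_init(hn = 2, n_classes = 2, data = toy, seed = 2)
  fit <- lvq_train(m, toy, alpha = 0.1, epochs = 30, decay = TRUE, seed = 2)
  expect_equal(utils::tail(fit$history$error_pct, 1), 0)
})

test_that("blind prototypes are pruned without changing any prediction", {
  toy <- make_cluster_ensemble(n_per_class = 15)
  m <- lvq_init(hn = 4, n_classes = 2, data = toy, seed = 3)
  fit <- lvq_train(m, toy, alpha = 0.05, epochs = 30, seed = 3)
  # plant a prototype that can never win
  fit$prototypes[3, ] <- rep(1e6, ncol(fit$prototypes))
  before <- lvq_classify(fit, toy)
  pruned <- lvq_prune_blind(fit, toy)
  expect_equal(nrow(pruned$prototypes), 3)
  after <- lvq_classify(pruned, toy)
  expect_identical(before$.pred, after$.pred)

  # all-winning model is unchanged
  m2 <- lvq_init(hn = 2, n_classes = 2, data = toy, seed = 3)
  fit2 <- lvq_train(m2, toy, alpha = 0.05, epochs = 10, seed = 3)
  expect_equal(lvq_prune_blind(fit2, toy)$prototypes, fit2$prototypes)

  # refuse to empty a class
  broken <- fit2
  broken$prototypes[match("N3", broken$classes[broken$proto_class]), ] <- 1e6
  expect_error(lvq_prune_blind(broken, toy), "class 'N3'")
})

test_that("classification reports pcc and rejects degenerate inputs", {
  toy <- make_cluster_ensemble(n_per_class = 10)
  m <- lvq_init(hn = 2, n_classes = 2, data = toy, seed = 1)
  fit <- lvq_train(m, toy, alpha = 0.1, epochs = 20, seed = 1)

  protos <- tibble::tibble(
    subject_id = "A", channel = "Fz-A1A2",
    state = fit$classes[fit$proto_class],
    window_index = 0:1, n_averaged = 900L,
    values = lapply(1:2, function(i) fit$prototypes[i, ]))
  expect_equal(pcc(lvq_classify(fit, protos)), 100)

  flipped <- protos
  flipped$state <- rev(flipped$state)
  expect_equal(pcc(lvq_classify(fit, flipped)), 0)

  expect_error(lvq_classify(fit, protos[0, ]), "empty")
  expect_error(lvq_classify(lvq_init(hn = 2, n_classes = 2, data = toy), toy),
               "untrained")
})

test_that("inference is invariant to input ordering", {
  toy <- make_cluster_ensemble(n_per_class = 12)
  m <- lvq_init(hn = 2, n_classes = 2, data = toy, seed = 1)
  fit <- lvq_train(m, toy, alpha = 0.1, epochs = 20, seed = 1)
  perm <- withr::with_seed(8, sample.int(nrow(toy)))
  straight <- lvq_classify(fit, toy)
  shuffled <- lvq_classify(fit, toy[perm, ])
  expect_identical(straight$.pred[perm], shuffled$.pred)
})

test_that("the compact HN = S x NC rule reaches zero training error; HN = NC stays above chance", {
  toy <- make_toy_ensemble(n_subjects = 3, windows_per_state = 10, seed = 11)
  compact <- lvq_init(hn = 3 * 2, n_classes = 2, data = toy, seed = 11)
  fit <- lvq_train(compact, toy, alpha = 0.1, epochs = 200, error_limit = 0,
                   seed = 11)
  expect_equal(utils::tail(fit$history$error_pct, 1), 0)

  minimal <- lvq_init(hn = 2, n_classes = 2, data = toy, seed = 11)
  fit_min <- lvq_train(minimal, toy, alpha = 0.1, epochs = 50, seed = 11)
  expect_lte(utils::tail(fit_min$history$error_pct, 1), 50)
})

test_that("model serialization round-trips bit-exactly", {
  toy <- make_cluster_ensemble(n_per_class = 8)
  m <- lvq_init(hn = 4, n_classes = 2, data = toy, seed = 9)
  fit <- lvq_train(m, toy, alpha = 0.1, epochs = 15, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_lvq_model(fit, path)
  back <- read_lvq_model(path)
  expect_identical(back$prototypes, fit$prototypes)
  expect_identical(back$proto_class, fit$proto_class)
  expect_identical(back$classes, fit$classes)
  expect_identical(back$win_counts, fit$win_counts)
  expect_equal(back$alpha, fit$alpha)
  # predictions carry over exactly
  expect_identical(lvq_classify(back, toy)$.pred, lvq_classify(fit, toy)$.pred)
})

test_that("tidy and glance summarize the competitive layer", {
  toy <- make_cluster_ensemble(n_per_class = 8)
  m <- lvq_init(hn = 4, n_classes = 2, data = toy, seed = 9)
  fit <- lvq_train(m, toy, alpha = 0.1, epochs = 10, seed = 9)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_setequal(unique(td$class), c("W0", "N3"))
  g <- glance(fit)
  expect_equal(g$hn, 4)
  expect_true(g$trained)
})
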