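# Synthetic stimulus-locked ASSR generator.

test_that("subject parameters are reproducible, subject-distinct, and keep the 2:1 state ratio", {
  p1 <- make_subject_params("A", seed = 7)
  p2 <- make_subject_params("A", seed = 7)
  expect_identical(p1, p2)

  pb <- make_subject_params("B", seed = 7)
  expect_gt(max(abs(p1$template - pb$template)), 0)
  expect_false(isTRUE(all.equal(p1$amp_w0, pb$amp_w0)))

  expect_equal(p1$amp_w0 / p1$amp_n3, 2.0)
  expect_equal(max(abs(p1$template)), 1) # unit peak
  expect_gt(p1$amp_w0, 0)
  expect_gt(p1$amp_n3, 0)
  expect_gte(p1$noise_sigma, 0)
})

test_that("unknown override keys and unknown channels are configuration errors", {
  expect_error(make_subject_params("A", seed = 1,
                                   overrides = list(bogus = 1)),
               "Unknown override")
  p <- make_subject_params("A", seed = 1)
  expect_error(simulate_sweeps(p, "W0", "Pz-XX", 5),
               "Valid channels")
})

test_that("noiseless sweeps equal the deterministic part and scale 2:1 between states", {
  p <- make_subject_params("C", seed = 3, overrides = list(noise_sigma = 0))
  sw_w <- simulate_sweeps(p, "W0", "Fz-A1A2", 4, seed = 5)
  det_w <- deterministic_sweep(p, "W0", "Fz-A1A2")
  for (i in 1:4) expect_equal(sw_w$data[i, ], det_w, tolerance = 0)

  sw_n <- simulate_sweeps(p, "N3", "Fz-A1A2", 1, seed = 5)
  p2p <- function(x) max(x) - min(x)
  expect_equal(p2p(sw_w$data[1, ]), 2 * p2p(sw_n$data[1, ]))

  # channel gain scales the waveform
  det_c4 <- deterministic_sweep(p, "W0", "C4-A1A2")
  expect_equal(det_c4, det_w * p$channel_gains[["C4-A1A2"]] /
                 p$channel_gains[["Fz-A1A2"]])
})

test_that("sweep noise is zero-mean, sweep-independent, and averages out at the CLT rate", {
  p <- make_subject_params("A", seed = 2, overrides = list(noise_sigma = 1))
  sm <- simulate_sweeps(p, "W0", "Fz-A1A2", 10000, seed = 11)
  det <- deterministic_sweep(p, "W0", "Fz-A1A2")
  resid_mean <- colMeans(sm$data) - det
  expect_gte(mean(abs(resid_mean) <= 0.05), 0.99) # sigma/sqrt(n) = 0.01

  # lag-0 cross-sweep correlations of the noise are near zero on average
  sm2 <- simulate_sweeps(p, "N3", "Fz-A1A2", 120, seed = 13)
  resid <- sweep(sm2$data, 2, deterministic_sweep(p, "N3", "Fz-A1A2"))
  cors <- stats::cor(t(resid))
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.05)
})

test_that("simulate_dataset produces one matrix per (subject, channel, state), reproducibly", {
  ds <- simulate_dataset(1, channels = "Fz-A1A2", sweeps_per_state = 900,
                         seed = 0)
  expect_equal(nrow(ds), 2)
  expect_true(all(purrr::map_int(ds$sweeps, ~ nrow(.x$data)) == 900))
  expect_true(all(purrr::map_int(ds$sweeps, ~ ncol(.x$data)) == 295))

  ds8 <- simulate_dataset(8, channels = c("Fz-A1A2", "C4-A1A2"),
                          sweeps_per_state = 5, seed = 0)
  expect_equal(nrow(ds8), 8 * 2 * 2)

  expect_identical(ds8, simulate_dataset(8, channels = c("Fz-A1A2", "C4-A1A2"),
                                         sweeps_per_state = 5, seed = 0))
  expect_error(simulate_dataset(2, sweeps_per_state = 0), "sweeps_per_state")
})

test_that("AR(1) noise colouring keeps the marginal noise scale", {
  p <- make_subject_params("A", seed = 4,
                           overrides = list(noise_sigma = 2, noise_ar1 = 0.6))
  sm <- simulate_sweeps(p, "W0", "Fz-A1A2", 400, seed = 1)
  resid <- sweep(sm$data, 2, deterministic_sweep(p, "W0", "Fz-A1A2"))
  expect_equal(stats::sd(as.numeric(resid)), 2, tolerance = 0.05)
  # successive samples within a sweep are positively correlated
  lag1 <- mean(resid[, -1] * resid[, -ncol(resid)]) / mean(resid^2)
  expect_gt(lag1, 0.4)
})

test_that("state amplitude ratio is recoverable from 900-sweep ensemble averages", {
  ratios <- purrr::map_dbl(c("A", "B"), function(s) {
    p <- make_subject_params(s, seed = 0)
    est <- purrr::map_dbl(c("W0", "N3"), function(st) {
      sm <- simulate_sweeps(p, st, "Fz-A1A2", 900, seed = 21)
      avg <- ensemble_average(sm)$values
      base <- deterministic_sweep(p, st, "Fz-A1A2") /
        (if (st == "W0") p$amp_w0 else p$amp_n3)
      sum(avg * base) / sum(base^2) # least-squares amplitude
    })
    est[1] / est[2]
  })
  expect_true(all(abs(ratios - 2) / 2 < 0.10))
})
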