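test_that("matching counts exact hits, misses and far spurious detections", {
  truth <- place_events(simulation_params(n_events = 100, seed = 6))
  det <- truth
  m <- match_detections(det, truth)
  expect_equal(m$tp, 100L); expect_equal(m$fp, 0L)

  m0 <- match_detections(det[0, ], truth)
  expect_equal(m0$tp, 0L); expect_equal(m0$fp, 0L)

  spurious <- tibble::tibble(frame = 500L,
                             row = truth$row[1] + 40,
                             col = truth$col[1] + 40, contrast = 1e-3)
  m1 <- match_detections(dplyr::bind_rows(det, spurious), truth)
  expect_equal(m1$tp, 100L); expect_equal(m1$fp, 1L)
})

test_that("matching is one-to-one and unambiguous under the exclusion radii", {
  truth <- place_events(simulation_params(n_events = 100, seed = 8))
  set.seed(61)
  det <- truth
  det$row <- det$row + rnorm(100, sd = 1)
  det$col <- det$col + rnorm(100, sd = 1)
  det$frame <- det$frame + sample(-3:3, 100, TRUE)
  m <- match_detections(det, truth)
  expect_equal(anyDuplicated(m$pairs$detection), 0L)
  expect_equal(anyDuplicated(m$pairs$truth), 0L)
  expect_true(all(m$pairs$dist_px <= 5 & m$pairs$dframes <= 10))
})

test_that("noiseless benchmarks are complete: TP 100%, FP 0%", {
  p <- simulation_params(n_frames = 300, n_events = 10, field_px = 64,
                         noise_sigma = 0, speckle_amp = 0)
  b <- run_benchmark(p, n_replicates = 2L, seeds = c(4, 9))
  expect_equal(b$tp_percent, 100)
  expect_equal(b$fp_percent, 0)
  expect_equal(b$tp_sd, 0)
})

test_that("true-positive rates rise with contrast on paired seeds", {
  seeds <- c(3, 14)
  run_at <- function(ct) {
    p <- simulation_params(n_frames = 400, n_events = 20, field_px = 96,
                           contrast = ct, noise_sigma = op_noise_sigma)
    run_benchmark(p, n_replicates = 2L, seeds = seeds)$tp_percent
  }
  tp_mono <- run_at(2.2e-3)
  tp_dimer <- run_at(4.3e-3)
  expect_gte(tp_dimer, tp_mono)
})

test_that("noise calibration brackets and hits a high target", {
  p <- simulation_params(n_frames = 300, n_events = 15, field_px = 64)
  sig <- calibrate_noise(target_tp_percent = 90, params = p,
                         seeds = c(2, 5), lower = 5e-4, upper = 8e-3,
                         tol_pp = 5, max_iter = 8)
  expect_gt(as.numeric(sig), 5e-4)
  expect_lt(as.numeric(sig), 8e-3)
  expect_lt(abs(attr(sig, "tp_percent") - 90), 5)
  expect_error(
    calibrate_noise(50, p, seeds = 2, lower = 6e-3, upper = 8e-3,
                    max_iter = 2),
    "not bracketed")
})

test_that("a single-point sweep reproduces run_benchmark", {
  p <- simulation_params(n_frames = 300, n_events = 10, field_px = 64,
                         noise_sigma = op_noise_sigma)
  seeds <- c(1, 2)
  sw <- sweep_parameters(data.frame(navg = 21, t1 = 1.2, t2 = 0.15),
                         p, n_replicates = 2L, seeds = seeds)
  b <- run_benchmark(p, n_replicates = 2L, seeds = seeds)
  expect_equal(sw$tp_percent, b$tp_percent)
  expect_equal(sw$fp_percent, b$fp_percent)
})

test_that("sweep TP is non-increasing along rising T1", {
  p <- simulation_params(n_frames = 300, n_events = 10, field_px = 64,
                         noise_sigma = op_noise_sigma)
  sw <- sweep_parameters(data.frame(navg = 21, t1 = c(1.2, 20, 200),
                                    t2 = 0.15),
                         p, n_replicates = 1L, seeds = 7)
  expect_true(all(diff(sw$tp_percent) <= 0))
})
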