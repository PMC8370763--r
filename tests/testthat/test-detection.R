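test_that("ttest_score matches an independent Welch computation", {
  before <- c(0.0, 0.1, -0.1, 0.05, -0.05)
  after <- c(0.3, 0.4, 0.25, 0.35, 0.3)
  # independent oracle: stats::t.test
  p_oracle <- stats::t.test(after, before, var.equal = FALSE)$p.value
  expect_equal(ttest_score(before, after), -log(p_oracle),
               tolerance = 1e-6)
  set.seed(41)
  for (i in 1:20) {
    b <- rnorm(21); a <- rnorm(21, mean = runif(1, -1, 1))
    expect_equal(ttest_score(b, a),
                 -log(stats::t.test(a, b, var.equal = FALSE)$p.value),
                 tolerance = 1e-6)
  }
})

test_that("identical samples score zero and strong shifts exceed T1", {
  expect_equal(ttest_score(rep(2, 21), rep(2, 21)), 0)
  expect_equal(ttest_score(rep(0, 5), rep(0, 5)), 0)
  expect_equal(ttest_score(rep(0, 5), rep(1, 5)), Inf)
  set.seed(42)
  b <- rnorm(21, sd = 1)
  expect_gt(ttest_score(b, b + 10), 1.2 * 20)
  expect_error(ttest_score(1, c(1, 2)), "at least 2")
})

test_that("radial symmetry scores spots high, ramps and noise low", {
  xy <- outer(-6:6, -6:6, function(a, b) a^2 + b^2)
  bump <- exp(-xy / 6)
  expect_gt(radial_symmetry_score(bump), 0.95)
  expect_gt(radial_symmetry_score(-2e-3 * bump), 0.95)  # polarity-blind
  ramp <- outer(1:13, 1:13, function(a, b) 0.3 * a + 0.1 * b)
  expect_lt(radial_symmetry_score(ramp), 0.4)
  set.seed(43)
  noise <- sapply(1:50, function(i)
    radial_symmetry_score(matrix(rnorm(169), 13, 13)))
  expect_lt(mean(noise), 0.15)
  expect_error(radial_symmetry_score(matrix(0, 12, 12)), "odd")
  expect_error(radial_symmetry_score(matrix(0, 3, 3)), "small")
})

test_that("patch score equals a brute-force per-pixel oracle", {
  # independent double-loop recomputation of the definition
  brute_rs <- function(patch) {
    pr <- (nrow(patch) - 1) / 2
    num <- 0; den <- 0
    for (i in 2:(nrow(patch) - 1)) for (j in 2:(ncol(patch) - 1)) {
      gr <- (patch[i + 1, j] - patch[i - 1, j]) / 2
      gc <- (patch[i, j + 1] - patch[i, j - 1]) / 2
      dr <- i - (pr + 1); dc <- j - (pr + 1)
      rad <- sqrt(dr^2 + dc^2)
      if (rad > 0) num <- num + (gr * dr + gc * dc) / rad
      den <- den + sqrt(gr^2 + gc^2)
    }
    abs(num) / den
  }
  ev <- list(row = 7, col = 7, contrast = 2.2e-3)
  rendered <- render_event(13, ev)
  expect_equal(radial_symmetry_score(rendered), brute_rs(rendered),
               tolerance = 1e-10)
  set.seed(44)
  for (i in 1:5) {
    patch <- matrix(rnorm(169), 13, 13)
    expect_equal(radial_symmetry_score(patch), brute_rs(patch),
                 tolerance = 1e-10)
  }
})

test_that("the FFT score image agrees with per-patch evaluation", {
  set.seed(45)
  R <- matrix(rnorm(40 * 40), 40, 40)
  f2 <- filter2_frame(R, 6L)
  for (k in 1:20) {
    i <- sample(8:32, 1); j <- sample(8:32, 1)
    expect_equal(f2[i, j],
                 radial_symmetry_score(R[(i - 6):(i + 6), (j - 6):(j + 6)]),
                 tolerance = 1e-10)
  }
})

test_that("filter-1 stack is zero on constant movies, peaked on events", {
  m <- mp_movie(array(1, c(6, 6, 50)), movie_metadata(500, 70.2))
  for (stat in c("jump", "welch")) {
    sc <- filter1_stack(m, detection_params(navg = 10, statistic = stat))
    expect_true(all(sc$frames == 0))
  }
  tm <- tiny_event_movie()
  sc <- filter1_stack(tm$movie, detection_params())
  peak <- which(sc$frames == max(sc$frames), arr.ind = TRUE)
  expect_equal(unname(peak[1, 1:2]), c(24, 24))
  expect_equal(unname(peak[1, 3]) + sc$t_first - 1L, 40)
})

test_that("noiseless single events yield exactly one candidate at truth", {
  tm <- tiny_event_movie()
  ratio <- ratiometric_contrast(tm$movie, 21)
  cd <- detect_candidates(tm$movie, ratio, detection_params())
  expect_equal(nrow(cd), 1L)
  expect_equal(cd$row, 24L)
  expect_equal(cd$col, 24L)
  expect_equal(cd$frame, 40L)
  expect_true(cd$score1 >= 1.2 && cd$score2 >= 0.15)
})

test_that("empty masks yield empty candidate tables", {
  m <- mp_movie(array(5, c(16, 16, 60)), movie_metadata(500, 70.2))
  ratio <- ratiometric_contrast(m, 21)
  cd <- detect_candidates(m, ratio, detection_params())
  expect_equal(nrow(cd), 0L)
})

test_that("well-separated simultaneous events stay distinct", {
  p <- simulation_params(n_frames = 80, n_events = 0, field_px = 64,
                         noise_sigma = 0, speckle_amp = 0)
  bg <- simulate_movie(p)$movie
  truth <- tibble::tibble(frame = c(40L, 40L), row = c(22, 42),
                          col = c(22, 42), contrast = 2.2e-3)
  mv <- inject_events(bg, truth)   # 20 px apart > merge radius
  cd <- detect_candidates(mv, ratiometric_contrast(mv, 21),
                          detection_params())
  expect_equal(nrow(cd), 2L)
})

test_that("detection is equivariant under whole-pixel translation", {
  tm <- tiny_event_movie(field_px = 48, row = 22, col = 25)
  tm2 <- tiny_event_movie(field_px = 48, row = 25, col = 20)
  dp <- detection_params()
  cd1 <- detect_candidates(tm$movie, ratiometric_contrast(tm$movie, 21), dp)
  cd2 <- detect_candidates(tm2$movie, ratiometric_contrast(tm2$movie, 21), dp)
  expect_equal(cd1$row + 3L, cd2$row)
  expect_equal(cd1$col - 5L, cd2$col)
})

test_that("candidate counts are monotone in both thresholds", {
  p <- simulation_params(n_frames = 400, n_events = 30, field_px = 64,
                         noise_sigma = op_noise_sigma, seed = 17)
  sim <- simulate_movie(p)
  ratio <- suppressWarnings(ratiometric_contrast(sim$movie, 21))
  n_at <- function(t1, t2) nrow(detect_candidates(
    sim$movie, ratio, detection_params(t1 = t1, t2 = t2)))
  counts_t1 <- sapply(c(0.6, 1.2, 3, 8), n_at, t2 = 0.15)
  expect_true(all(diff(counts_t1) <= 0))
  counts_t2 <- sapply(c(0.05, 0.15, 0.4, 0.7), function(t2) n_at(1.2, t2))
  expect_true(all(diff(counts_t2) <= 0))
})

test_that("filter 1 is invariant under affine intensity rescaling", {
  p <- simulation_params(n_frames = 120, n_events = 5, field_px = 48,
                         noise_sigma = op_noise_sigma, seed = 18,
                         edge_margin_px = 8)
  sim <- simulate_movie(p)
  scaled <- mp_movie(sim$movie$stack * 3.7, sim$movie$metadata)
  affine <- mp_movie(sim$movie$stack * 3.7 + 0.5, sim$movie$metadata)
  dp <- detection_params()
  s1 <- filter1_stack(sim$movie, dp)$frames
  expect_equal(s1, filter1_stack(scaled, dp)$frames, tolerance = 1e-9)
  expect_equal(s1, filter1_stack(affine, dp)$frames, tolerance = 1e-9)
  cd1 <- detect_candidates(sim$movie,
                           suppressWarnings(ratiometric_contrast(sim$movie, 21)), dp)
  cd2 <- detect_candidates(scaled,
                           suppressWarnings(ratiometric_contrast(scaled, 21)), dp)
  expect_equal(cd1[c("frame", "row", "col")], cd2[c("frame", "row", "col")])
})
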