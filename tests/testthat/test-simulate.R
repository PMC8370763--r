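test_that("benchmark placement satisfies the pairwise exclusion predicate", {
  p <- simulation_params(seed = 5)   # 1000 frames, 100 events, 12 px / 26 fr
  ev <- place_events(p)
  expect_equal(nrow(ev), 100L)
  # O(n^2) brute-force check of the exclusion rule
  expect_true(check_exclusion(ev, 12, 26))
  # full temporal guard band on both sides
  expect_true(all(ev$frame > 26 & ev$frame <= 1000 - 26))
})

test_that("single-event placement is trivially valid and seeds reproduce", {
  p <- simulation_params(n_events = 1L, seed = 2)
  expect_equal(nrow(place_events(p)), 1L)
  expect_identical(place_events(p), place_events(p))

  s1 <- simulate_movie(simulation_params(n_frames = 100, n_events = 3,
                                         noise_sigma = 1e-3, seed = 7))
  s2 <- simulate_movie(simulation_params(n_frames = 100, n_events = 3,
                                         noise_sigma = 1e-3, seed = 7))
  expect_identical(s1$movie$stack, s2$movie$stack)
  expect_identical(s1$truth, s2$truth)
})

test_that("infeasible exclusion constraints fail after bounded retries", {
  p <- simulation_params(n_frames = 60, n_events = 50, field_px = 16,
                         min_sep_px = 100, min_sep_frames = 3,
                         edge_margin_px = 1, seed = 1)
  expect_error(place_events(p, max_tries = 2000), "infeasible")
})

test_that("a landed particle persists: post minus pre frame is the PSF", {
  tm <- tiny_event_movie()
  st <- tm$movie$stack
  rendered <- render_event(48, tm$truth)
  for (t_post in c(40, 55, 80))
    expect_equal(st[, , t_post] - st[, , 10], rendered)
  # frames before the landing are flat
  expect_equal(st[, , 39], st[, , 1])
})

test_that("no noise, no speckle, no events gives a constant unit stack", {
  p <- simulation_params(n_frames = 50, n_events = 0, noise_sigma = 0,
                         speckle_amp = 0)
  expect_true(all(simulate_movie(p)$movie$stack == 1))
})

test_that("inject_events matches simulate_movie and ignores empty lists", {
  p <- simulation_params(n_frames = 120, n_events = 4, noise_sigma = 0,
                         speckle_amp = 0, seed = 9)
  sim <- simulate_movie(p)
  bg <- mp_movie(array(1, dim(sim$movie$stack)), sim$movie$metadata)
  expect_equal(inject_events(bg, sim$truth)$stack, sim$movie$stack)
  expect_identical(inject_events(bg, sim$truth[0, ])$stack, bg$stack)
  expect_error(inject_events(bg, tibble::tibble(
    frame = 1000L, row = 5, col = 5, contrast = 1e-3)), "outside")
})

test_that("placement is uniform over the allowed region", {
  p <- simulation_params(n_frames = 50, n_events = 10000, field_px = 128,
                         min_sep_px = 0, min_sep_frames = 0,
                         edge_margin_px = 10, seed = 21)
  ev <- place_events(p)
  # coarse 4x4 grid chi-square against uniformity
  cuts <- seq(11, 118, length.out = 5)
  tab <- table(cut(ev$row, cuts), cut(ev$col, cuts))
  expect_gt(stats::chisq.test(as.vector(tab))$p.value, 0.01)
})

test_that("event tables round-trip through CSV", {
  ev <- place_events(simulation_params(n_events = 5, seed = 3))
  path <- file.path(withr::local_tempdir(), "truth.csv")
  write_events_csv(ev, path)
  expect_equal(read_events_csv(path), ev, tolerance = 1e-12)
})
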