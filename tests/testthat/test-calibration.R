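test_that("two exact points on the study line recover its constants", {
  sl <- 5.023e-5; ic <- 1.261e-4
  std <- calibration_standards(c("a", "b"), c(42, 224),
                               sl * c(42, 224) + ic)
  fit <- fit_calibration(std)
  expect_equal(fit$slope, sl, tolerance = 1e-12)
  expect_equal(fit$intercept, ic, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("the bundled synthetic standards file sits on the study line", {
  std <- tibble::as_tibble(utils::read.csv(
    system.file("extdata", "standards_synthetic.csv", package = "mpdetect")))
  fit <- fit_calibration(std)
  expect_equal(fit$slope, 5.023e-5, tolerance = 1e-10)
  expect_equal(fit$intercept, 1.261e-4, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
})

test_that("noisy standards recover the slope within 2%", {
  set.seed(51)
  masses <- c(42, 73.5, 112, 147, 224)
  ok <- replicate(20, {
    std <- calibration_standards(letters[1:5], masses,
                                 5.023e-5 * masses + 1.261e-4 +
                                   rnorm(5, sd = 1e-5))
    abs(fit_calibration(std)$slope - 5.023e-5) / 5.023e-5 < 0.02
  })
  expect_gt(mean(ok), 0.9)
  expect_error(fit_calibration(calibration_standards("a", 42, 1e-3)),
               "at least 2")
  expect_error(fit_calibration(calibration_standards(c("a", "b"),
                                                     c(42, 42),
                                                     c(1e-3, 2e-3))),
               "distinct")
})

test_that("contrast/mass conversions follow the printed constants", {
  cal <- calibration_model()
  expect_equal(signif(mass_to_contrast(42, cal), 2), 2.2e-3)
  expect_equal(signif(mass_to_contrast(84, cal), 2), 4.3e-3)
  expect_equal(mass_to_contrast(42, cal), 2.23576e-3, tolerance = 1e-10)
  expect_equal(mass_to_contrast(84, cal), 4.34542e-3, tolerance = 1e-10)
  expect_equal(mass_to_contrast(0, cal), cal$intercept)
  expect_equal(contrast_to_mass(cal$intercept, cal), 0)
  expect_equal(contrast_to_mass(2.2e-3, cal), 41.288, tolerance = 1e-4)
  # round trip to machine precision
  m <- c(0.1, 42, 84, 500)
  expect_equal(contrast_to_mass(mass_to_contrast(m, cal), cal), m,
               tolerance = 1e-12)
  expect_error(calibration_model(slope = 0), "positive")
})

test_that("n-mer assignment follows the 0.3-monomer tolerance rule", {
  cal <- calibration_model()
  ev <- tibble::tibble(contrast = mass_to_contrast(c(84.1, 83.2, 168.9), cal))
  md <- build_mass_distribution(ev, cal, monomer_mass_kda = 42)
  expect_equal(md$species$n_mer, c(2L, 4L))
  expect_equal(md$species$count, c(2L, 1L))

  ev2 <- tibble::tibble(contrast = mass_to_contrast(c(41.3, 63), cal))
  md2 <- build_mass_distribution(ev2, cal, 42)
  expect_equal(md2$species$n_mer, 1L)    # 41.3 -> 1-mer; 63 unassigned
  expect_equal(md2$n_unassigned, 1L)
})

test_that("histograms conserve events; edge and negative masses excluded", {
  cal <- calibration_model()
  ev <- tibble::tibble(
    contrast = c(mass_to_contrast(c(42, 84, 84, 126), cal), 1e-5),
    edge = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  md <- build_mass_distribution(ev, cal, 42)
  expect_equal(md$n_events, 4L)               # edge event dropped
  expect_equal(sum(md$counts), 4L)            # histogram covers all masses
  expect_equal(sum(md$species$count) + md$n_unassigned, 4L)
  expect_true(any(md$masses_kda < 0))         # sub-intercept contrast kept
  expect_lte(sum(md$species$fraction), 1)
  expect_error(build_mass_distribution(ev[0, ], cal), "no events")
})
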