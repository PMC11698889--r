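make_standard <- function(element, conc, intensity, n = 50, measured = conc)
  standard_measurement(element, conc, measured,
                       list(rep(intensity, n), rep(intensity, n)))

test_that("noiseless affine standards are fitted exactly", {
  stds <- list(make_standard("Fe", 0, 0),
               make_standard("Fe", 5, 50),
               make_standard("Fe", 10, 100))
  cur <- fit_calibration(stds)
  expect_equal(cur$slope, 10, tolerance = 1e-9)
  expect_equal(cur$intercept, 0, tolerance = 1e-9)
  expect_equal(cur$r_squared, 1, tolerance = 1e-9)
  expect_equal(cur$blank_sd, 0)
  expect_equal(cur$loq, 0)
  expect_equal(cur$range, c(0, 10))
})

test_that("calibration fitting enforces its preconditions", {
  s5 <- make_standard("Fe", 5, 50)
  s10 <- make_standard("Fe", 10, 100)
  expect_error(fit_calibration(list(s5, s10)), "at least 3")
  expect_error(fit_calibration(list(s5, s10, make_standard("Fe", 15, 150))),
               "blank")
  # negative slope is uninterpretable
  expect_error(fit_calibration(list(make_standard("Fe", 0, 100),
                                    make_standard("Fe", 5, 50),
                                    make_standard("Fe", 10, 0))),
               "not positive")
  # mixed elements refused
  expect_error(fit_calibration(list(make_standard("Fe", 0, 0), s5,
                                    make_standard("Cu", 10, 100))),
               "mix")
  # a sloppy curve warns
  set.seed(2)
  noisy <- list(make_standard("Fe", 0, 0),
                make_standard("Fe", 5, 80),
                make_standard("Fe", 10, 90),
                make_standard("Fe", 20, 160))
  expect_warning(fit_calibration(noisy), "R-squared")
})

test_that("loq follows the ten-sigma-over-slope closed form to machine precision", {
  expect_identical(loq(0, 10), 0)
  expect_identical(loq(1, 10), 1)
  set.seed(4)
  for (i in 1:20) {
    s <- runif(1, 1e-3, 1e4)
    b <- runif(1, 0, 1e3)
    expect_identical(loq(b, s), 10 * b / s)
  }
  expect_error(loq(1, 0), "positive")
  expect_error(loq(-1, 10), "nonnegative")
})

test_that("applying a calibration inverts the affine detector response", {
  meta <- acq_meta(isotopes = "56Fe")
  cur <- fit_calibration(list(make_standard("56Fe", 0, 7),
                              make_standard("56Fe", 5, 57),
                              make_standard("56Fe", 10, 107)))
  # intensity equal to the intercept maps to zero everywhere
  img0 <- element_image("56Fe", matrix(cur$intercept, 4, 4), meta)
  expect_equal(apply_calibration(img0, cur)$data, matrix(0, 4, 4),
               tolerance = 1e-12)
  # affine identity: scaling the blank-corrected signal scales the output
  set.seed(9)
  base <- matrix(rexp(64, 0.01), 8, 8)
  img1 <- element_image("56Fe", base + cur$intercept, meta)
  img2 <- element_image("56Fe", 3 * base + cur$intercept, meta)
  expect_equal(apply_calibration(img2, cur)$data,
               3 * apply_calibration(img1, cur)$data, tolerance = 1e-10)
  # below-LOQ flagging and negative-value counting
  low <- element_image("56Fe", matrix(c(0, cur$intercept + cur$slope * 100),
                                      1, 2), meta)
  cm <- apply_calibration(low, cur)
  expect_identical(cm$below_loq[1, ], c(TRUE, FALSE))
  expect_identical(cm$n_negative, 1L)
  expect_error(apply_calibration(element_image("66Zn", base, acq_meta(isotopes = "66Zn")), cur),
               "mismatch")
})

test_that("slope recovery on noisy synthetic standards is unbiased within 2%", {
  sens <- c(slope = 1000, intercept = 20)
  noise <- phantom_config()$noise
  slopes <- vapply(1:25, function(s) {
    stds <- lapply(seq_along(c(0, 2, 8, 16, 33)), function(i)
      generate_standard_block("56Fe", c(0, 2, 8, 16, 33)[i], sens, noise,
                              seed = s * 100 + i))
    fit_calibration(stds)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) / 1000 - 1), 0.02)
  # and the stored LOQ always equals the closed form recomputed from parts
  stds <- lapply(1:4, function(i)
    generate_standard_block("88Sr", c(0, 2, 8, 19)[i],
                            c(slope = 10000, intercept = 10), noise,
                            seed = i))
  cur <- fit_calibration(stds)
  blank_px <- unlist(stds[[1]]$lines)
  expect_identical(cur$loq, 10 * sd(blank_px) / cur$slope)
})

test_that("response-factor normalization is a homogeneous rescaling", {
  meta <- acq_meta(isotopes = "138Ba")
  np <- normalization_params("88Sr", reference_conc = 1.31,
                             reference_intensity = 2620)
  # fixed point: the reference intensity maps to the reference concentration
  img <- element_image("138Ba", matrix(2620, 3, 3), meta)
  expect_equal(normalize_by_standard(img, np)$data, matrix(1.31, 3, 3))
  # homogeneity: doubling the signal doubles the pseudo-concentration
  img2 <- element_image("138Ba", matrix(2 * 2620, 3, 3), meta)
  expect_equal(normalize_by_standard(img2, np)$data, matrix(2 * 1.31, 3, 3))
  expect_match(normalize_by_standard(img, np)$unit, "88Sr")
  expect_error(normalization_params("88Sr", 1.31, 0), "positive")
})

test_that("standards survive the long-CSV round trip", {
  set.seed(5)
  stds <- list("56Fe" = lapply(c(0, 8, 33), function(conc)
    generate_standard_block("56Fe", conc, c(slope = 1000, intercept = 20),
                            seed = conc + 1, n_lines = 2, n_pixels = 30)))
  f <- file.path(withr::local_tempdir(), "standards.csv")
  write_standards_csv(stds, f)
  back <- read_standards_csv(f)
  expect_equal(back, stds, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(read_standards_csv({
    f2 <- file.path(withr::local_tempdir(), "bad.csv")
    write.csv(data.frame(a = 1), f2, row.names = FALSE)
    f2
  }), "missing column")
})
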