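test_that("standard blocks honor the deterministic limit and blank contract", {
  sens <- c(slope = 1000, intercept = 0)
  quiet <- list(poisson = FALSE, pixel_time_s = 0.1, spike_prob = 0,
                spike_factor = 1, glass_frac = 0)
  blk <- generate_standard_block("56Fe", 0, sens, quiet, seed = 1)
  expect_true(all(unlist(blk$lines) == 0))
  expect_identical(blk$measured_conc, 0)

  det <- generate_standard_block("56Fe", 8, c(slope = 1000, intercept = 20),
                                 quiet, seed = 1, cross_quant_cv = 0)
  expect_true(all(unlist(det$lines) == 1000 * 8 + 20))
  expect_identical(det$measured_conc, 8)
  expect_identical(length(det$lines), 5L)
  expect_identical(lengths(det$lines), rep(200L, 5))
})

test_that("lognormal region fields converge to the configured median and spread", {
  set.seed(41)
  x <- generate_region_field(2e4, median = 4.74, q1 = 2.62, q3 = 13.39)
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
  expect_lt(abs(q[[2]] / 4.74 - 1), 0.03)
  # the lognormal matches the quartile *ratio* (its sdlog is set from it);
  # asymmetric printed quartiles around the median cannot both be hit
  expect_lt(abs((q[[3]] / q[[1]]) / (13.39 / 2.62) - 1), 0.05)
  expect_error(generate_region_field(10, 5, 6, 4), "q1 < median")
})

test_that("phantoms are reproducible and structurally complete", {
  cfg <- phantom_config(shape = c(60L, 80L))
  p1 <- generate_tissue_phantom(cfg, "NM", seed = 5)
  p2 <- generate_tissue_phantom(cfg, "NM", seed = 5)
  expect_identical(p1$stack$images[["56Fe"]]$data,
                   p2$stack$images[["56Fe"]]$data)
  expect_identical(p1$annotation$labels, p2$annotation$labels)

  expect_setequal(names(p1$stack$images),
                  c("56Fe", "63Cu", "66Zn", "88Sr", "138Ba"))
  expect_true(all(vapply(p1$truth_conc, function(m) all(m >= 0), logical(1))))
  # cancer sample with stroma: niche and stroma split the epithelium
  expect_true(all(c("tumor_niche", "stroma") %in% names(p1$annotation$legend)))
  # healthy sample: no tumor sub-compartments
  ph <- generate_tissue_phantom(cfg, "H", seed = 5)
  expect_false(any(c("tumor_niche", "stroma") %in% names(ph$annotation$legend)))
  # no-stroma cancer sample: the whole epithelium is niche
  pn <- generate_tissue_phantom(cfg, "M", seed = 5, with_stroma = FALSE)
  expect_false("stroma" %in% names(pn$annotation$legend))
  expect_gt(sum(region_pixels(pn$annotation, "tumor_niche")), 0)
})

test_that("the noiseless forward model is exactly affine in the truth", {
  cfg <- phantom_config(shape = c(40L, 50L))
  cfg$noise <- list(poisson = FALSE, pixel_time_s = 0.1, spike_prob = 0,
                    spike_factor = 1, glass_frac = 0)
  ph <- generate_tissue_phantom(cfg, "H", seed = 9)
  sens <- cfg$elements[["66Zn"]]$sensitivity
  tissue <- ph$annotation$labels != 0L
  expect_equal(ph$stack$images[["66Zn"]]$data[tissue],
               sens[["slope"]] * ph$truth_conc[["66Zn"]][tissue] +
                 sens[["intercept"]],
               tolerance = 1e-12)
  # and calibration inverts it: apply_calibration o forward = identity
  cur <- structure(list(element = "66Zn", slope = sens[["slope"]],
                        intercept = sens[["intercept"]], r_squared = 1,
                        blank_sd = 0, loq = 0, range = c(0, 19)),
                   class = "calibration_curve")
  cm <- apply_calibration(ph$stack$images[["66Zn"]], cur)
  expect_equal(cm$data[tissue], ph$truth_conc[["66Zn"]][tissue],
               tolerance = 1e-10)
})

test_that("the Sr-Ba copula hits the configured rank correlation on the truth", {
  cfg <- phantom_config(shape = c(100L, 120L), sr_ba_rank_correlation = 0.9)
  # iid pixels isolate the copula itself from spatial-correlation noise in
  # the rank-correlation estimate
  cfg$regions$smooth_sigma_px <- 0
  ph <- generate_tissue_phantom(cfg, "NM", seed = 13)
  epi <- region_pixels(ph$annotation, "epithelial")
  expect_gte(sum(epi), 5000)
  rho <- cor(ph$truth_conc[["88Sr"]][epi], ph$truth_conc[["138Ba"]][epi],
             method = "spearman")
  expect_lt(abs(rho - 0.9), 0.02)
})

test_that("metastatic phantoms carry iron hot spots, healthy ones do not", {
  cfg <- phantom_config(shape = c(80L, 100L))
  base <- cfg
  base$noise$poisson <- FALSE
  nospot <- base
  nospot$regions$hot_spot_count <- 0L
  pm <- generate_tissue_phantom(base, "M", seed = 3)
  pm0 <- generate_tissue_phantom(nospot, "M", seed = 3)
  # same seed, same fields: the only difference is the amplified spot discs
  delta <- pm$truth_conc[["56Fe"]] != pm0$truth_conc[["56Fe"]]
  expect_gt(sum(delta), 0)
  expect_true(all(pm$truth_conc[["56Fe"]] >= pm0$truth_conc[["56Fe"]]))
  expect_equal(pm$truth_conc[["56Fe"]][delta],
               pm0$truth_conc[["56Fe"]][delta] *
                 base$regions$hot_spot_amplitude)
  # healthy samples never receive hot spots
  phh <- generate_tissue_phantom(base, "H", seed = 3)
  ph0 <- generate_tissue_phantom(nospot, "H", seed = 3)
  expect_identical(phh$truth_conc[["56Fe"]], ph0$truth_conc[["56Fe"]])
})

test_that("cohorts have the configured sizes, stroma counts and determinism", {
  cfg <- phantom_config(shape = c(40L, 50L))
  co <- generate_cohort(cfg, n_h = 4, n_nm = 7, n_m = 11, seed = 2)
  expect_identical(length(co$phantoms), 22L)
  expect_identical(as.vector(table(co$records$group)[c("H", "NM", "M")]),
                   c(4L, 7L, 11L))
  has_stroma <- vapply(co$phantoms, function(p)
    "stroma" %in% names(p$annotation$legend), logical(1))
  expect_identical(sum(has_stroma[co$records$group == "NM"]), 5L)
  expect_identical(sum(has_stroma[co$records$group == "M"]), 8L)
  expect_identical(sum(has_stroma[co$records$group == "H"]), 0L)

  co2 <- generate_cohort(cfg, n_h = 4, n_nm = 7, n_m = 11, seed = 2)
  expect_identical(co$phantoms[[9]]$stack$images[["88Sr"]]$data,
                   co2$phantoms[[9]]$stack$images[["88Sr"]]$data)
})
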