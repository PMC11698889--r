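#' Default phantom configuration
#'
#' Ground-truthed synthetic data emulating the study conditions: gelatine
#' calibration standards, tissue sections on a glass slide with adipose and
#' epithelial compartments, an optional tumor-niche/stroma split, iron hot
#' spots in metastatic samples, Poisson counting noise and sparse spike
#' noise, and a Gaussian-copula rank correlation between Sr and Ba.
#'
#' Concentration levels (ug/g) are parameterised as median with (Q1, Q3) of
#' lognormal distributions at two levels: `epithelial` gives the per-group
#' distribution of per-sample epithelial medians, while `within_qr` is the
#' Q3/Q1 ratio of the pixel field around a sample's median. `adipose` is the
#' pixel-field spec of the adipose compartment (identical across groups).
#' Sensitivities are detector responses in cps per ug/g with a background
#' intercept in cps; shot noise is Poisson on expected counts over the
#' effective per-pixel integration time.
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param seed Master seed.
#' @param sr_ba_rank_correlation Target Spearman correlation of the Sr and Ba
#'   concentration fields in tissue (default 0.90, the upper end of the
#'   moderate-to-strong range the analysis is designed to detect).
#' @return Nested list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(120L, 160L), seed = 0L,
                           sr_ba_rank_correlation = 0.90) {
  grp <- function(med, q1, q3) c(median = med, q1 = q1, q3 = q3)
  elements <- list(
    "56Fe" = list(
      epithelial = list(H = grp(2.9, 0.9, 4.4), NM = grp(12.6, 5.2, 26.1),
                        M = grp(6.6, 4.1, 34.1)),
      adipose = grp(0.79, 0.46, 1.26),
      within_qr = 2.0,
      stroma_ratio = 0.9,             # near parity: Fe niche/stroma contrast is weak
      sensitivity = c(slope = 1000, intercept = 20),
      hot_spots = TRUE),
    "63Cu" = list(
      epithelial = list(H = grp(0.04, 0.03, 0.06), NM = grp(0.06, 0.05, 0.20),
                        M = grp(0.07, 0.05, 0.20)),
      adipose = grp(0.03, 0.01, 0.06),
      within_qr = 2.0,
      stroma_ratio = 0.6,
      sensitivity = c(slope = 20000, intercept = 10),
      hot_spots = FALSE),
    "66Zn" = list(
      epithelial = list(H = grp(0.12, 0.08, 0.30), NM = grp(0.78, 0.50, 0.93),
                        M = grp(0.63, 0.30, 1.14)),
      adipose = grp(0.06, 0.02, 0.19),
      within_qr = 2.0,
      stroma_ratio = 0.5,
      sensitivity = c(slope = 5000, intercept = 15),
      hot_spots = FALSE),
    "88Sr" = list(
      epithelial = list(H = grp(0.5, 0.4, 0.8), NM = grp(1.8, 1.2, 3.0),
                        M = grp(1.4, 0.8, 2.8)),
      adipose = grp(0.13, 0.08, 0.18),
      within_qr = 2.0,
      stroma_ratio = 0.7,
      sensitivity = c(slope = 10000, intercept = 10),
      hot_spots = FALSE),
    "138Ba" = list(
      epithelial = list(H = grp(0.05, 0.04, 0.14), NM = grp(0.12, 0.06, 0.22),
                        M = grp(0.20, 0.10, 0.31)),
      adipose = grp(0.02, 0.01, 0.04),
      within_qr = 2.0,
      stroma_ratio = 0.7,
      sensitivity = c(slope = 10000, intercept = 10),
      hot_spots = FALSE)
  )
  structure(list(
    shape = as.integer(shape), seed = as.integer(seed),
    regions = list(tissue_semiaxes = c(0.42, 0.45),  # fractions of shape
                   adipose_blobs = 3L, adipose_radius_frac = 0.09,
                   tumor_niche_fraction = 0.35,
                   hot_spot_count = 3L, hot_spot_radius = 2L,
                   hot_spot_amplitude = 10,
                   smooth_sigma_px = 2.5),  # latent-field correlation length
    elements = elements,
    noise = list(poisson = TRUE, pixel_time_s = 0.1,
                 spike_prob = 0.002, spike_factor = 20,
                 glass_frac = 0.005),  # glass signal as fraction of epithelial level
    sr_ba_rank_correlation = sr_ba_rank_correlation,
    cross_quant_cv = 0.02,
    standard_concs = list("56Fe" = c(0, 2, 8, 16, 33),
                          "63Cu" = c(0, 2, 6, 12, 19),
                          "66Zn" = c(0, 2, 6, 12, 19),
                          "88Sr" = c(0, 2, 6, 12, 19))),
    class = "phantom_config")
}

# sdlog of a lognormal from its quartile ratio: exact relation
# log(q3/q1) = 2 * sdlog * qnorm(0.75)
.sdlog_from_qr <- function(qr) {
  if (qr <= 1) stop("infeasible quartiles: q3/q1 must exceed 1")
  log(qr) / (2 * qnorm(0.75))
}

# draw one lognormal value / field with given median and quartiles
.rlnorm_med <- function(n, median, q1, q3) {
  qlnorm(runif(n), meanlog = log(median), sdlog = .sdlog_from_qr(q3 / q1))
}

#' Lognormal concentration field from median and quartiles
#'
#' Draws an iid lognormal pixel field whose population median and quartiles
#' equal the given values (sdlog = log(q3/q1) / (2 qnorm(0.75)), exact for
#' the lognormal).
#'
#' @param n Number of pixels.
#' @param median,q1,q3 Target median and quartiles (q1 < median < q3).
#' @return Numeric vector of length `n`.
#' @export
generate_region_field <- function(n, median, q1, q3) {
  if (!(q1 < median && median < q3)) stop("need q1 < median < q3")
  .rlnorm_med(n, median, q1, q3)
}

# forward detector model: cps -> Poisson counts over pixel_time -> cps
.detect <- function(cps, noise) {
  if (!noise$poisson) return(cps)
  t <- noise$pixel_time_s
  counts <- rpois(length(cps), lambda = pmax(cps, 0) * t)
  out <- counts / t
  if (noise$spike_prob > 0) {
    hit <- runif(length(out)) < noise$spike_prob
    out[hit] <- (out[hit] + 1 / t) * noise$spike_factor
  }
  dim(out) <- dim(cps)
  out
}

#' Generate one gelatine calibration-standard block
#'
#' Simulates ablating `n_lines` lines of `n_pixels` pixels from a spiked
#' gelatine standard: expected signal slope * conc + intercept cps, Poisson
#' counting noise over the effective per-pixel integration time. The
#' digestion cross-quantification step is emulated by perturbing the nominal
#' concentration with a relative error of `cross_quant_cv`.
#'
#' @param element Element label.
#' @param conc Nominal spike concentration, ug/g (>= 0).
#' @param sensitivity Named vector `c(slope =, intercept =)` in cps per ug/g
#'   and cps.
#' @param noise Noise list as in [phantom_config()] (set `poisson = FALSE`
#'   for the deterministic limit).
#' @param n_lines,n_pixels Standard ablation geometry (default 5 x 200).
#' @param seed RNG seed.
#' @param cross_quant_cv Relative SD of the cross-quantification (default 2%).
#' @return A [standard_measurement()].
#' @export
generate_standard_block <- function(element, conc, sensitivity,
                                    noise = phantom_config()$noise,
                                    n_lines = 5L, n_pixels = 200L, seed = 0L,
                                    cross_quant_cv = 0.02) {
  stopifnot(conc >= 0)
  .with_seed(seed, {
    cps <- sensitivity[["slope"]] * conc + sensitivity[["intercept"]]
    lines <- lapply(seq_len(n_lines), function(i)
      as.numeric(.detect(rep(cps, n_pixels),
                         modifyList(noise, list(spike_prob = 0)))))
    measured <- conc * (1 + rnorm(1, 0, cross_quant_cv))
    standard_measurement(element, conc, max(measured, 0), lines)
  })
}

#' Generate the full set of calibration standards for a configuration
#'
#' @param config A [phantom_config()].
#' @param seed RNG seed.
#' @return Named list (per element) of lists of [standard_measurement()]s.
#' @export
generate_standards <- function(config = phantom_config(), seed = config$seed) {
  out <- list()
  i <- 0L
  for (el in names(config$standard_concs)) {
    out[[el]] <- lapply(config$standard_concs[[el]], function(conc) {
      i <<- i + 1L
      generate_standard_block(el, conc, config$elements[[el]]$sensitivity,
                              config$noise, seed = seed + i,
                              cross_quant_cv = config$cross_quant_cv)
    })
  }
  out
}

# Gaussian band matrix for separable smoothing (rows of weights
# dnorm((i-j)/sigma), truncated at 3 sigma)
.gauss_band <- function(n, sigma) {
  w <- outer(seq_len(n), seq_len(n),
             function(i, j) ifelse(abs(i - j) <= ceiling(3 * sigma),
                                   exp(-(i - j)^2 / (2 * sigma^2)), 0))
  w
}

# Spatially correlated standard-normal field: separable Gaussian smoothing
# of iid normals, rescaled so every pixel is exactly N(0, 1) marginally
# (variance of a weighted sum of iid normals is the sum of squared weights).
# Monotone per-pixel transforms of these latents therefore keep both the
# configured marginal law and the cross-element copula.
.smooth_field <- function(z, sigma) {
  if (sigma <= 0) return(z)
  A <- .gauss_band(nrow(z), sigma)
  B <- .gauss_band(ncol(z), sigma)
  out <- A %*% z %*% t(B)
  scale <- sqrt(outer(rowSums(A^2), rowSums(B^2)))
  out / scale
}

# disc mask helper
.disc <- function(shape, centre, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - centre[1])^2 + (c - centre[2])^2 <= radius^2
}

# procedural geometry: tissue ellipse on glass, adipose discs, optional
# tumor-niche discs within the epithelium, remainder = stroma
.build_annotation <- function(config, group, with_stroma) {
  shape <- config$shape
  rg <- config$regions
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
  a <- rg$tissue_semiaxes[1] * shape[1]
  b <- rg$tissue_semiaxes[2] * shape[2]
  tissue <- ((r - cy) / a)^2 + ((c - cx) / b)^2 <= 1
  labels <- matrix(0L, shape[1], shape[2])          # 0 = background (glass)
  labels[tissue] <- 2L                              # epithelial
  rad <- rg$adipose_radius_frac * min(shape)
  for (i in seq_len(rg$adipose_blobs)) {
    ctr <- c(cy + runif(1, -0.6, 0.6) * a, cx + runif(1, -0.6, 0.6) * b)
    blob <- .disc(shape, ctr, rad) & tissue
    labels[blob] <- 1L                              # adipose
  }
  legend <- c(background = 0L, adipose = 1L, epithelial = 2L)
  if (group %in% c("NM", "M")) {
    epi <- labels == 2L
    if (with_stroma) {
      target <- rg$tumor_niche_fraction * sum(epi)
      niche <- matrix(FALSE, shape[1], shape[2])
      guard <- 0L
      while (sum(niche & epi) < target && guard < 50L) {
        ctr <- c(cy + runif(1, -0.5, 0.5) * a, cx + runif(1, -0.5, 0.5) * b)
        niche <- niche | .disc(shape, ctr, 0.22 * min(a, b))
        guard <- guard + 1L
      }
      labels[epi & niche] <- 3L                     # tumor_niche
      labels[epi & !niche] <- 4L                    # stroma
      legend <- c(legend, tumor_niche = 3L, stroma = 4L)
      if (!any(labels == 2L)) legend <- legend[names(legend) != "epithelial"]
    } else {
      labels[epi] <- 3L                             # cancer widespread: all niche
      legend <- c(legend["background"], legend["adipose"], tumor_niche = 3L)
    }
  }
  region_annotation(labels, legend)
}

#' Generate one ground-truthed tissue phantom
#'
#' Builds a procedural tissue section (glass background, adipose blobs,
#' epithelial compartment, optional tumor-niche/stroma split), draws
#' per-region lognormal concentration fields whose median and quartiles are
#' set by the configuration, couples the Sr and Ba fields through a Gaussian
#' copula with the configured rank correlation, adds iron hot spots for
#' metastatic samples, and pushes the truth through the detector forward
#' model (intensity = Poisson(slope * conc + background) over the pixel
#' integration time, plus sparse spikes).
#'
#' @param config A [phantom_config()].
#' @param group `"H"`, `"NM"` or `"M"`.
#' @param seed RNG seed (default: config seed).
#' @param with_stroma Whether the sample retains a stroma region (cancer
#'   groups only; default TRUE).
#' @param sample_medians Optional named list (per element) fixing the
#'   sample's epithelial median instead of drawing it from the group
#'   distribution — used for controlled recovery experiments.
#' @return List of class `synthetic_phantom`: `stack` ([image_stack()]),
#'   `truth_conc` (named list of ug/g matrices), `annotation`, `config`,
#'   `group`, `sample_medians`.
#' @export
generate_tissue_phantom <- function(config = phantom_config(), group = "NM",
                                    seed = config$seed, with_stroma = TRUE,
                                    sample_medians = NULL) {
  group <- match.arg(group, c("H", "NM", "M"))
  .with_seed(seed, {
    ann <- .build_annotation(config, group, with_stroma)
    shape <- config$shape
    epi <- region_pixels(ann, "epithelial")
    adi <- region_pixels(ann, "adipose")
    els <- names(config$elements)

    # per-sample epithelial medians: one draw from the group distribution
    med <- lapply(els, function(el) {
      if (!is.null(sample_medians[[el]])) return(sample_medians[[el]])
      g <- config$elements[[el]]$epithelial[[group]]
      .rlnorm_med(1, g[["median"]], g[["q1"]], g[["q3"]])
    })
    names(med) <- els

    # Latent standard-normal fields, spatially smoothed so that, like real
    # elemental maps, concentrations vary over a correlation length of a
    # few pixels rather than pixel to pixel. Sr and Ba share a Gaussian
    # copula; the Pearson correlation of the latents that yields the target
    # Spearman rank correlation is r = 2 sin(pi * rho_s / 6). Smoothing is
    # linear and applied to each independent component, so the latent
    # correlation (and hence the copula) is preserved exactly.
    n_px <- prod(shape)
    sig <- config$regions$smooth_sigma_px
    rho_s <- config$sr_ba_rank_correlation
    r_lat <- 2 * sin(pi * rho_s / 6)
    z1 <- .smooth_field(matrix(rnorm(n_px), shape[1], shape[2]), sig)
    e2 <- .smooth_field(matrix(rnorm(n_px), shape[1], shape[2]), sig)
    z2 <- r_lat * z1 + sqrt(1 - r_lat^2) * e2
    u <- lapply(els, function(el)
      pnorm(.smooth_field(matrix(rnorm(n_px), shape[1], shape[2]), sig)))
    names(u) <- els
    u[["88Sr"]] <- pnorm(z1)
    u[["138Ba"]] <- pnorm(z2)

    truth <- list()
    for (el in els) {
      cfg <- config$elements[[el]]
      sd_w <- .sdlog_from_qr(cfg$within_qr)
      conc <- matrix(0, shape[1], shape[2])
      # epithelial field around the sample median; stroma scaled down
      fld <- qlnorm(u[[el]], meanlog = log(med[[el]]), sdlog = sd_w)
      dim(fld) <- shape
      if ("stroma" %in% names(ann$legend)) {
        str_px <- ann$labels == ann$legend[["stroma"]]
        fld[str_px] <- fld[str_px] * cfg$stroma_ratio
      }
      conc[epi] <- fld[epi]
      # adipose field: printed adipose median, same within-sample pixel
      # spread as the epithelium (the printed adipose quartiles pool
      # between-sample variance and would overstate single-section spread)
      ad <- cfg$adipose
      conc[adi] <- qlnorm(u[[el]][which(adi)],
                          meanlog = log(ad[["median"]]), sdlog = sd_w)
      truth[[el]] <- conc
    }

    # iron hot spots in metastatic samples
    if (group == "M") {
      rg <- config$regions
      for (el in els) {
        if (!isTRUE(config$elements[[el]]$hot_spots)) next
        for (i in seq_len(rg$hot_spot_count)) {
          ctr <- c(runif(1, 1, shape[1]), runif(1, 1, shape[2]))
          spot <- .disc(shape, ctr, rg$hot_spot_radius) & epi
          truth[[el]][spot] <- truth[[el]][spot] * rg$hot_spot_amplitude
        }
      }
    }

    # detector forward model per element
    meta <- acq_meta(isotopes = els)
    images <- list()
    for (el in els) {
      sens <- config$elements[[el]]$sensitivity
      g <- config$elements[[el]]$epithelial[[group]]
      glass_cps <- config$noise$glass_frac * sens[["slope"]] * g[["median"]]
      cps <- sens[["slope"]] * truth[[el]] + sens[["intercept"]]
      cps[ann$labels == 0L] <- sens[["intercept"]] + glass_cps
      images[[el]] <- element_image(el, .detect(cps, config$noise), meta)
    }
    structure(list(stack = image_stack(images,
                                       sample_id = paste0(group, "_", seed)),
                   truth_conc = truth, annotation = ann, config = config,
                   group = group, sample_medians = med),
              class = "synthetic_phantom")
  })
}

#' Generate a cohort of phantoms with sample records
#'
#' Per-sample seeds are derived deterministically from the master seed. By
#' default a fraction of the cancer samples lacks a stroma region (the tumor
#' occupies the whole epithelial compartment), mirroring cohorts where
#' widespread cancer leaves no stroma to annotate: with the default sizes
#' (4, 7, 11), 5 non-metastatic and 8 metastatic samples retain stroma.
#'
#' @param config A [phantom_config()].
#' @param n_h,n_nm,n_m Group sizes (defaults 4, 7, 11).
#' @param seed Master seed (default: config seed).
#' @param stroma_absent_frac Named fractions of NM/M samples lacking stroma
#'   (defaults 2/7 and 3/11).
#' @return List with `phantoms` (list of `synthetic_phantom`) and `records`
#'   (tibble of sample records).
#' @export
generate_cohort <- function(config = phantom_config(), n_h = 4L, n_nm = 7L,
                            n_m = 11L, seed = config$seed,
                            stroma_absent_frac = c(NM = 2 / 7, M = 3 / 11)) {
  groups <- c(rep("H", n_h), rep("NM", n_nm), rep("M", n_m))
  n <- length(groups)
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  no_stroma <- rep(FALSE, n)
  idx_nm <- which(groups == "NM"); idx_m <- which(groups == "M")
  if (length(idx_nm))
    no_stroma[utils::tail(idx_nm, round(stroma_absent_frac[["NM"]] * n_nm))] <- TRUE
  if (length(idx_m))
    no_stroma[utils::tail(idx_m, round(stroma_absent_frac[["M"]] * n_m))] <- TRUE
  phantoms <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_tissue_phantom(config, groups[i], seed = seeds[i],
                                  with_stroma = !no_stroma[i])
    sid <- sprintf("S%02d_%s", i, groups[i])
    ph$stack$sample_id <- sid
    phantoms[[i]] <- ph
    records[[i]] <- sample_record(sid, groups[i])
  }
  list(phantoms = phantoms, records = dplyr::bind_rows(records))
}
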