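#' One gelatine-standard measurement
#'
#' A matrix-matched calibration standard ablated like tissue: several line
#' scans of raw intensities plus the standard's nominal spike concentration
#' and the concentration actually measured by independent digestion
#' cross-quantification (the latter is used as the regression abscissa).
#'
#' @param element Element/isotope label.
#' @param nominal_conc Nominal spike concentration, ug/g.
#' @param measured_conc Cross-quantified concentration, ug/g.
#' @param lines List of numeric vectors, one intensity trace per ablated line
#'   (target geometry: 5 lines of 200 pixels).
#' @return An object of class `standard_measurement`.
#' @export
standard_measurement <- function(element, nominal_conc, measured_conc, lines) {
  stopifnot(length(lines) >= 1, measured_conc >= 0, nominal_conc >= 0)
  lines <- lapply(lines, as.numeric)
  if (!all(vapply(lines, function(l) all(is.finite(l)), logical(1))))
    stop("standard line scans must be finite")
  structure(list(element = element, nominal_conc = nominal_conc,
                 measured_conc = measured_conc, lines = lines),
            class = "standard_measurement")
}

#' Fit a per-element external calibration curve
#'
#' Averages the intensity of each standard over all of its line pixels and
#' regresses mean intensity on the cross-quantified concentration by ordinary
#' least squares. The blank standard deviation is computed over all pooled
#' blank pixels, and the limit of quantification follows [loq()]. A warning
#' is issued when R-squared falls below 0.98, which flags a curve markedly
#' worse than what matrix-matched gelatine standards normally achieve.
#'
#' @param standards List of [standard_measurement()]s for one element; at
#'   least 3, including a blank (nominal concentration 0).
#' @return An object of class `calibration_curve` with fields `element`,
#'   `slope` (intensity per ug/g), `intercept`, `r_squared`, `blank_sd`,
#'   `loq` (ug/g), and `range` (ug/g span of the standards).
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.list(standards))
  if (length(standards) < 3)
    stop("need at least 3 standards (including a blank)")
  if (!all(vapply(standards, inherits, logical(1), "standard_measurement")))
    stop("standards must be standard_measurement objects")
  el <- unique(vapply(standards, function(s) s$element, character(1)))
  if (length(el) != 1) stop("standards mix elements: ",
                            paste(el, collapse = ", "))
  blanks <- Filter(function(s) s$nominal_conc == 0, standards)
  if (!length(blanks)) stop("no blank (zero-concentration) standard present")
  conc <- vapply(standards, function(s) s$measured_conc, numeric(1))
  mean_int <- vapply(standards,
                     function(s) mean(unlist(s$lines)), numeric(1))
  fit <- lm(mean_int ~ conc)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope is not positive; curve is uninterpretable")
  ss_tot <- sum((mean_int - mean(mean_int))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  if (r2 < 0.98)
    warning(sprintf("calibration R-squared %.4f below 0.98 for %s", r2, el))
  blank_px <- unlist(lapply(blanks, function(s) unlist(s$lines)))
  blank_sd <- sd(blank_px)
  structure(list(element = el, slope = slope, intercept = intercept,
                 r_squared = r2, blank_sd = blank_sd,
                 loq = loq(blank_sd, slope),
                 range = range(conc)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: slope %.4g, intercept %.4g, R2 %.4f, LOQ %.4g ug/g (range %.3g-%.3g ug/g)\n",
    x$element, x$slope, x$intercept, x$r_squared, x$loq,
    x$range[1], x$range[2]))
  invisible(x)
}

#' Limit of quantification
#'
#' Ten times the standard deviation of the blank signal divided by the
#' calibration slope.
#'
#' @param blank_sd Standard deviation of the blank-standard intensities.
#' @param slope Calibration slope (intensity per ug/g), > 0.
#' @return LOQ in ug/g.
#' @export
loq <- function(blank_sd, slope) {
  if (!is.numeric(slope) || slope <= 0) stop("slope must be positive")
  if (blank_sd < 0) stop("blank_sd must be nonnegative")
  10 * blank_sd / slope
}

#' Convert an intensity image to a concentration map
#'
#' Applies the inverse calibration per pixel: conc = (intensity - intercept)
#' / slope. Pixels below the LOQ are retained but flagged in a companion
#' logical mask; negative concentrations are retained (clipping would bias
#' low-concentration medians upward) and counted.
#'
#' @param image An [element_image()] whose isotope contains the curve's
#'   element label (e.g. image "56Fe" with curve element "56Fe" or "Fe").
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @return An object of class `conc_map`: `data` (ug/g matrix), `element`,
#'   `unit = "ug/g"`, `below_loq` (logical matrix), `n_negative`.
#' @export
apply_calibration <- function(image, curve) {
  stopifnot(inherits(image, "element_image"),
            inherits(curve, "calibration_curve"))
  if (!grepl(curve$element, image$isotope, fixed = TRUE) &&
      !grepl(image$isotope, curve$element, fixed = TRUE))
    stop("element mismatch: image '", image$isotope, "' vs curve '",
         curve$element, "'")
  conc <- (image$data - curve$intercept) / curve$slope
  structure(list(data = conc, element = image$isotope, unit = "ug/g",
                 below_loq = conc < curve$loq,
                 n_negative = sum(conc < 0)),
            class = "conc_map")
}

#' Response-factor normalization parameters
#'
#' For an element without its own calibration (here Ba), the signal is scaled
#' by the response of a reference element's spiked gelatine standard — a
#' single-point response-factor estimate, not a matrix-matched calibration.
#' The study design uses the Sr standard at 1.31 ug/g.
#'
#' @param reference_element Reference element label (default `"88Sr"`).
#' @param reference_conc Concentration of the spiked reference standard, ug/g.
#' @param reference_intensity Mean intensity of that standard (> 0).
#' @return An object of class `normalization_params`.
#' @export
normalization_params <- function(reference_element = "88Sr",
                                 reference_conc = 1.31,
                                 reference_intensity) {
  if (!is.numeric(reference_conc) || reference_conc <= 0)
    stop("reference_conc must be positive")
  if (!is.numeric(reference_intensity) || reference_intensity <= 0)
    stop("reference_intensity must be positive")
  structure(list(reference_element = reference_element,
                 reference_conc = reference_conc,
                 reference_intensity = reference_intensity),
            class = "normalization_params")
}

#' Normalize an uncalibrated element against a spiked-standard response
#'
#' Per pixel: value = intensity * reference_conc / reference_intensity. The
#' unit is reference-element-equivalent ug/g.
#'
#' @param image An [element_image()].
#' @param params A [normalization_params()].
#' @return A `conc_map` with `unit = "ug/g (<ref>-equivalent)"`; no LOQ flags.
#' @export
normalize_by_standard <- function(image, params) {
  stopifnot(inherits(image, "element_image"),
            inherits(params, "normalization_params"))
  conc <- image$data * params$reference_conc / params$reference_intensity
  structure(list(data = conc, element = image$isotope,
                 unit = paste0("ug/g (", params$reference_element,
                               "-equivalent)"),
                 below_loq = matrix(FALSE, nrow(conc), ncol(conc)),
                 n_negative = sum(conc < 0)),
            class = "conc_map")
}

#' Read/write calibration standards as a long CSV
#'
#' Columns: element, standard_id, nominal_conc, measured_conc, line_id,
#' pixel_index, intensity.
#'
#' @param standards Named list (per element) of lists of
#'   [standard_measurement()]s, or a flat list for one element.
#' @param path CSV path.
#' @return `write_standards_csv` the path, invisibly; `read_standards_csv` a
#'   named list (per element) of lists of standards.
#' @export
write_standards_csv <- function(standards, path) {
  if (inherits(standards[[1]], "standard_measurement"))
    standards <- split(standards,
                       vapply(standards, function(s) s$element, character(1)))
  rows <- list()
  for (el in names(standards)) {
    for (i in seq_along(standards[[el]])) {
      s <- standards[[el]][[i]]
      for (l in seq_along(s$lines)) {
        rows[[length(rows) + 1L]] <- data.frame(
          element = s$element, standard_id = i,
          nominal_conc = s$nominal_conc, measured_conc = s$measured_conc,
          line_id = l, pixel_index = seq_along(s$lines[[l]]),
          intensity = s$lines[[l]])
      }
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_standards_csv
#' @export
read_standards_csv <- function(path) {
  df <- read.csv(path)
  need <- c("element", "standard_id", "nominal_conc", "measured_conc",
            "line_id", "pixel_index", "intensity")
  if (!all(need %in% names(df)))
    stop("standards CSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- lapply(split(df, df$element), function(de) {
    lapply(split(de, de$standard_id), function(ds) {
      lines <- lapply(split(ds, ds$line_id),
                      function(dl) dl$intensity[order(dl$pixel_index)])
      standard_measurement(ds$element[1], ds$nominal_conc[1],
                           ds$measured_conc[1], unname(lines))
    })
  })
  lapply(out, unname)
}
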