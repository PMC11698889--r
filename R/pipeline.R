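#' Run configuration for the full analysis pipeline
#'
#' Collects every analysis parameter in one auditable object: despike window
#' and deviation multiplier (size 5, k = 3.0), per-element k-means
#' segmentation (k = 3, t = 1), the calibrated element list, response-factor
#' normalization of Ba against the 1.31 ug/g Sr gelatine standard, and the
#' significance level (0.05).
#'
#' @param denoise A [denoise_params()].
#' @param segment A [segment_params()]; per-element overrides may be given in
#'   `segment_overrides` as a named list.
#' @param segment_overrides Named list (isotope -> [segment_params()]).
#' @param calibrate_elements Isotopes quantified by external calibration.
#' @param normalize_element Isotope normalized by response factor (Ba).
#' @param normalize_reference Reference isotope for normalization (Sr).
#' @param normalize_reference_conc Spiked reference standard concentration,
#'   ug/g.
#' @param alpha Significance level for all tests.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(denoise = denoise_params(5, 3.0),
                       segment = segment_params(k = 3, t = 1),
                       segment_overrides = list(),
                       calibrate_elements = c("56Fe", "63Cu", "66Zn", "88Sr"),
                       normalize_element = "138Ba",
                       normalize_reference = "88Sr",
                       normalize_reference_conc = 1.31,
                       alpha = 0.05, seed = 0L) {
  stopifnot(inherits(denoise, "denoise_params"),
            inherits(segment, "segment_params"),
            alpha > 0, alpha < 1)
  structure(list(denoise = denoise, segment = segment,
                 segment_overrides = segment_overrides,
                 calibrate_elements = calibrate_elements,
                 normalize_element = normalize_element,
                 normalize_reference = normalize_reference,
                 normalize_reference_conc = normalize_reference_conc,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

# mean intensity of the reference standard closest in measured concentration
# to the requested spike level
.reference_intensity <- function(standards_ref, conc) {
  concs <- vapply(standards_ref, function(s) s$measured_conc, numeric(1))
  nonblank <- which(vapply(standards_ref,
                           function(s) s$nominal_conc > 0, logical(1)))
  if (!length(nonblank)) stop("no non-blank reference standard available")
  i <- nonblank[which.min(abs(concs[nonblank] - conc))]
  s <- standards_ref[[i]]
  list(intensity = mean(unlist(s$lines)), conc = s$measured_conc)
}

#' Process one sample: denoise, calibrate/normalize, mask, summarise
#'
#' Applies the stage order of the analysis: rolling-median despike, then
#' conversion to concentration (external calibration, or response-factor
#' normalization for the designated element), then per-element k-means
#' background masking. The epithelial (whole-tissue) summary used for group
#' comparison is computed on the k-means-retained pixels; the
#' annotation-driven compartments (adipose, tumor niche, stroma) are
#' summarised directly on their H&E-derived pixels without the k-means mask,
#' since those regions are already histologically delimited.
#'
#' @param stack An [image_stack()].
#' @param annotation A [region_annotation()] congruent with the stack.
#' @param curves Named list of `calibration_curve`s (per isotope).
#' @param config A [run_config()].
#' @param norm_params A [normalization_params()] for the normalized element,
#'   or NULL to skip it.
#' @return List: `summaries` (tibble), `conc_maps`, `masks`, `thresholds`
#'   (per-element tibble), `colocalization` (Sr-Ba `correlation_result` on
#'   the masked epithelial pixels, or NULL).
#' @export
process_sample <- function(stack, annotation, curves, config = run_config(),
                           norm_params = NULL) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(annotation, "region_annotation"))
  sid <- stack$sample_id
  conc_maps <- list(); masks <- list(); thr_rows <- list(); sums <- list()
  regions <- unique(c(intersect(names(annotation$legend),
                                c("adipose", "tumor_niche", "stroma")),
                      "epithelial"))
  for (iso in names(stack$images)) {
    den <- rolling_median_filter(stack$images[[iso]], config$denoise)
    if (iso %in% config$calibrate_elements) {
      if (is.null(curves[[iso]]))
        stop("no calibration curve for element ", iso)
      cm <- apply_calibration(den, curves[[iso]])
    } else if (identical(iso, config$normalize_element) &&
               !is.null(norm_params)) {
      cm <- normalize_by_standard(den, norm_params)
    } else next
    sp <- config$segment_overrides[[iso]] %||% config$segment
    msk <- kmeans_threshold(den, sp)
    conc_maps[[iso]] <- cm
    masks[[iso]] <- msk
    thr_rows[[iso]] <- tibble::tibble(
      sample_id = sid, element = iso,
      threshold = attr(msk, "threshold"),
      centroids = paste(signif(attr(msk, "centroids"), 6), collapse = ";"))
    for (rg in regions) {
      rg_mask <- if (rg == "epithelial") msk else NULL
      sel_ok <- tryCatch({
        sums[[paste(iso, rg)]] <- region_summary(cm, annotation, rg,
                                                 mask = rg_mask,
                                                 sample_id = sid,
                                                 element = iso)
        TRUE
      }, error = function(e) FALSE)
      if (!sel_ok) next
    }
  }
  coloc <- NULL
  ref <- config$normalize_reference; nel <- config$normalize_element
  if (!is.null(conc_maps[[ref]]) && !is.null(conc_maps[[nel]])) {
    epi <- region_pixels(annotation, "epithelial") &
      masks[[ref]]$data & masks[[nel]]$data
    coloc <- tryCatch(
      spearman_colocalization(conc_maps[[ref]], conc_maps[[nel]],
                              pixel_mask(epi), sample_id = sid),
      error = function(e) NULL)
  }
  list(summaries = dplyr::bind_rows(sums), conc_maps = conc_maps,
       masks = masks, thresholds = dplyr::bind_rows(thr_rows),
       colocalization = coloc)
}

#' Process a cohort of samples
#'
#' Fits one calibration curve per calibrated element from the standards,
#' derives the normalization response factor from the reference standard
#' set, and runs [process_sample()] over the cohort. A failing sample is
#' logged and skipped; it does not abort the run.
#'
#' @param cohort List with `phantoms` and `records` as from
#'   [generate_cohort()], or a list of `list(stack =, annotation =)` pairs
#'   plus a `records` tibble.
#' @param standards Named list (per element) of standard lists, as from
#'   [generate_standards()] or [read_standards_csv()].
#' @param config A [run_config()].
#' @return List: `summaries`, `curves`, `colocalization` (tibble),
#'   `thresholds`, `failed` (character vector of skipped sample ids).
#' @export
run_process <- function(cohort, standards, config = run_config()) {
  missing_std <- setdiff(config$calibrate_elements, names(standards))
  if (length(missing_std))
    stop("no standards for calibrated element(s): ",
         paste(missing_std, collapse = ", "))
  if (!is.null(config$normalize_element) &&
      !config$normalize_reference %in% names(standards))
    stop("normalization requested but no ", config$normalize_reference,
         " standard set is present")
  curves <- lapply(standards[config$calibrate_elements], fit_calibration)
  ref <- .reference_intensity(standards[[config$normalize_reference]],
                              config$normalize_reference_conc)
  norm <- normalization_params(config$normalize_reference,
                               reference_conc = ref$conc,
                               reference_intensity = ref$intensity)
  sums <- list(); cols <- list(); thrs <- list(); failed <- character()
  for (i in seq_along(cohort$phantoms)) {
    ph <- cohort$phantoms[[i]]
    res <- tryCatch(
      process_sample(ph$stack, ph$annotation, curves, config, norm),
      error = function(e) {
        warning("sample ", ph$stack$sample_id, " failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(res)) { failed <- c(failed, ph$stack$sample_id); next }
    sums[[i]] <- res$summaries
    thrs[[i]] <- res$thresholds
    if (!is.null(res$colocalization))
      cols[[i]] <- tibble::tibble(
        sample_id = res$colocalization$sample_id,
        elements = paste(res$colocalization$elements, collapse = "-"),
        rho = res$colocalization$rho,
        n_pixels = res$colocalization$n_pixels,
        strength = res$colocalization$strength)
  }
  list(summaries = dplyr::bind_rows(sums), curves = curves,
       colocalization = dplyr::bind_rows(cols),
       thresholds = dplyr::bind_rows(thrs), failed = failed)
}

#' Statistical stage: group and paired comparisons plus colocalization table
#'
#' @param processed Output of [run_process()].
#' @param records Sample-record tibble.
#' @param config A [run_config()].
#' @return List: the [group_comparison_report()] tables plus the per-sample
#'   Sr-Ba `colocalization` tibble.
#' @export
run_stats <- function(processed, records, config = run_config()) {
  rep <- group_comparison_report(processed$summaries, records,
                                 alpha = config$alpha)
  c(rep, list(colocalization = processed$colocalization))
}

#' Run simulate -> calibrate -> process -> stats end to end
#'
#' @param phantom_cfg A [phantom_config()].
#' @param config A [run_config()].
#' @param n_h,n_nm,n_m Cohort sizes.
#' @return List: `cohort`, `processed`, `report`.
#' @export
run_pipeline <- function(phantom_cfg = phantom_config(),
                         config = run_config(), n_h = 4L, n_nm = 7L,
                         n_m = 11L) {
  cohort <- generate_cohort(phantom_cfg, n_h, n_nm, n_m,
                            seed = config$seed)
  standards <- generate_standards(phantom_cfg, seed = config$seed + 1L)
  processed <- run_process(cohort, standards, config)
  report <- run_stats(processed, cohort$records, config)
  list(cohort = cohort, processed = processed, report = report)
}
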