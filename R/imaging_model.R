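#' Acquisition metadata for an LA-ICP-ToF-MS image
#'
#' Describes the pixel grid and detector settings shared by every element
#' image in a stack. The dwell time is the storage interval of the mass
#' spectra; the effective per-pixel integration time (after spectral binning)
#' is a property of the synthetic forward model, not of the metadata.
#'
#' @param pixel_size_um Edge length of a (square) pixel in micrometres.
#' @param isotopes Character vector of unique isotope labels, e.g.
#'   `c("56Fe", "63Cu", "66Zn", "88Sr", "138Ba")`.
#' @param spot_shape `"square"` or `"circle"` laser spot.
#' @param dwell_ms Time in milliseconds per stored spectrum.
#' @param intensity_unit `"cps"` (counts per second) or `"counts"`.
#' @return An object of class `acq_meta`.
#' @export
acq_meta <- function(pixel_size_um = 35, isotopes = character(),
                     spot_shape = c("square", "circle"), dwell_ms = 1.03,
                     intensity_unit = c("cps", "counts")) {
  spot_shape <- match.arg(spot_shape)
  intensity_unit <- match.arg(intensity_unit)
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1,
            pixel_size_um > 0, is.numeric(dwell_ms), dwell_ms > 0)
  isotopes <- as.character(isotopes)
  if (anyDuplicated(isotopes)) stop("isotope labels must be unique")
  structure(list(pixel_size_um = pixel_size_um, spot_shape = spot_shape,
                 dwell_ms = dwell_ms, isotopes = isotopes,
                 intensity_unit = intensity_unit),
            class = "acq_meta")
}

#' Single-element intensity image
#'
#' A 2-D grid of nonnegative, finite intensities for one isotope. Row is the
#' slow axis (one laser line per row), column the fast axis along the line;
#' the origin is the top-left pixel.
#'
#' @param isotope Isotope label, e.g. `"56Fe"`.
#' @param data Numeric matrix of intensities.
#' @param meta An [acq_meta()] object.
#' @return An object of class `element_image`.
#' @export
element_image <- function(isotope, data, meta = acq_meta(isotopes = isotope)) {
  stopifnot(is.character(isotope), length(isotope) == 1, is.matrix(data))
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("element image must be finite everywhere")
  if (any(data < 0)) stop("element image intensities must be nonnegative")
  structure(list(isotope = isotope, data = data, meta = meta),
            class = "element_image")
}

#' Multi-element image stack
#'
#' A named collection of congruent [element_image()]s from one tissue section.
#'
#' @param images Named list of `element_image` objects (names = isotopes).
#' @param sample_id Sample identifier string.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(images, sample_id = "sample") {
  if (length(images) < 1) stop("an image stack needs at least one element")
  if (is.null(names(images)))
    names(images) <- vapply(images, function(im) im$isotope, character(1))
  dims <- vapply(images, function(im) dim(im$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all element images in a stack must share one pixel grid; got ",
         paste(apply(dims, 2, paste, collapse = "x"), collapse = ", "))
  structure(list(images = images, sample_id = sample_id),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$images[[1]]$data)
  cat(sprintf("<image_stack> sample '%s': %d element(s) [%s], %d x %d pixels\n",
              x$sample_id, length(x$images),
              paste(names(x$images), collapse = ", "), d[1], d[2]))
  invisible(x)
}

#' Pixel retention mask
#'
#' @param data Logical matrix; `TRUE` marks a retained pixel.
#' @return An object of class `pixel_mask`.
#' @export
pixel_mask <- function(data) {
  stopifnot(is.matrix(data), is.logical(data))
  if (anyNA(data)) stop("mask must not contain NA")
  structure(list(data = data), class = "pixel_mask")
}

.region_levels <- c("background", "adipose", "epithelial", "tumor_niche",
                    "stroma")

#' Region annotation label map
#'
#' Integer label grid (typically derived from an H&E-stained consecutive
#' section) plus a legend mapping each integer to a region name. The
#' `tumor_niche` and `stroma` regions are sub-compartments of the epithelial
#' tissue; [region_pixels()] resolves `"epithelial"` to their union.
#'
#' @param labels Integer matrix of region labels.
#' @param legend Named integer vector: names are region names drawn from
#'   `background, adipose, epithelial, tumor_niche, stroma`; values are the
#'   integers used in `labels`.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(labels, legend) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("label map must not contain NA")
  if (is.null(names(legend)) || anyDuplicated(names(legend)) ||
      anyDuplicated(legend))
    stop("legend must be a named vector with unique names and unique codes")
  bad <- setdiff(names(legend), .region_levels)
  if (length(bad))
    stop("unknown region name(s) in legend: ", paste(bad, collapse = ", "))
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(present, legend)
  if (length(missing))
    stop("label(s) present in grid but absent from legend: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, legend = legend),
            class = "region_annotation")
}

#' Logical mask of the pixels belonging to a named region
#'
#' `"epithelial"` resolves to the union of the `epithelial`, `tumor_niche`
#' and `stroma` labels, since the latter two subdivide the epithelial
#' compartment.
#'
#' @param annotation A [region_annotation()].
#' @param region Region name.
#' @return Logical matrix congruent with the label grid.
#' @export
region_pixels <- function(annotation, region) {
  stopifnot(inherits(annotation, "region_annotation"))
  if (!region %in% .region_levels)
    stop("unknown region name: ", region)
  legend <- annotation$legend
  wanted <- if (region == "epithelial")
    intersect(c("epithelial", "tumor_niche", "stroma"), names(legend))
  else intersect(region, names(legend))
  if (!length(wanted))
    stop("region '", region, "' not present in annotation legend")
  matrix(annotation$labels %in% legend[wanted], nrow = nrow(annotation$labels))
}

#' Clinical sample record
#'
#' @param sample_id Sample identifier.
#' @param group Patient group: `"H"` (healthy), `"NM"` (non-metastatic) or
#'   `"M"` (metastatic).
#' @param er,pr,her2 Receptor status, 0/1 or `NA` (carried as metadata only).
#' @return One-row tibble of class `sample_record`.
#' @export
sample_record <- function(sample_id, group, er = NA_integer_,
                          pr = NA_integer_, her2 = NA_integer_) {
  group <- match.arg(group, c("H", "NM", "M"))
  chk <- function(x) {
    if (!is.na(x) && !x %in% c(0L, 1L)) stop("receptor status must be 0/1/NA")
    as.integer(x)
  }
  out <- tibble::tibble(sample_id = as.character(sample_id), group = group,
                        er = chk(er), pr = chk(pr), her2 = chk(her2))
  class(out) <- c("sample_record", class(out))
  out
}

# ---- readers / writers ------------------------------------------------------

.read_matrix_csv <- function(path) {
  rows <- readLines(path)
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, ",", fixed = TRUE)
  lens <- lengths(parts)
  if (length(unique(lens)) != 1)
    stop("non-rectangular CSV '", basename(path), "': row ",
         which(lens != lens[1])[1], " has ", lens[lens != lens[1]][1],
         " fields, expected ", lens[1])
  matrix(as.numeric(unlist(parts)), nrow = length(parts), byrow = TRUE)
}

.write_matrix_csv <- function(data, path) {
  # full precision so write -> read round-trips bitwise for finite doubles
  txt <- apply(data, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, path)
}

#' Read a multi-element image stack from a directory
#'
#' Expects one CSV intensity matrix per isotope, named `<isotope>.csv`, plus
#' a YAML metadata file listing the isotopes and acquisition settings. `NaN`
#' or empty cells are zero-filled; the number of filled cells is reported via
#' a warning and stored in the `n_nan_filled` attribute.
#'
#' @param path Directory containing the per-isotope CSV files.
#' @param meta_path Path to the metadata YAML (default `meta.yaml` in `path`).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, meta_path = file.path(path, "meta.yaml")) {
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  m <- yaml::read_yaml(meta_path)
  meta <- acq_meta(pixel_size_um = m$pixel_size_um,
                   isotopes = unlist(m$isotopes),
                   spot_shape = m$spot_shape, dwell_ms = m$dwell_ms,
                   intensity_unit = m$intensity_unit)
  n_filled <- 0L
  images <- lapply(meta$isotopes, function(iso) {
    f <- file.path(path, paste0(iso, ".csv"))
    if (!file.exists(f))
      stop("missing intensity file for isotope '", iso, "': ", f)
    dat <- .read_matrix_csv(f)
    bad <- !is.finite(dat)
    if (any(bad)) {
      n_filled <<- n_filled + sum(bad)
      dat[bad] <- 0
    }
    element_image(iso, dat, meta)
  })
  names(images) <- meta$isotopes
  if (n_filled > 0)
    warning(n_filled, " non-finite cell(s) zero-filled on read")
  stk <- image_stack(images, sample_id = m$sample_id %||% basename(path))
  attr(stk, "n_nan_filled") <- n_filled
  stk
}

#' Write an image stack to a directory
#'
#' One CSV per isotope (`<isotope>.csv`, full double precision, lossless for
#' finite values) plus `meta.yaml`.
#'
#' @param stack An [image_stack()].
#' @param path Target directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  meta <- stack$images[[1]]$meta
  files <- character(0)
  for (iso in names(stack$images)) {
    f <- file.path(path, paste0(iso, ".csv"))
    .write_matrix_csv(stack$images[[iso]]$data, f)
    files <- c(files, f)
  }
  mf <- file.path(path, "meta.yaml")
  yaml::write_yaml(list(sample_id = stack$sample_id,
                        pixel_size_um = meta$pixel_size_um,
                        spot_shape = meta$spot_shape,
                        dwell_ms = meta$dwell_ms,
                        isotopes = as.list(names(stack$images)),
                        intensity_unit = meta$intensity_unit), mf)
  invisible(c(files, mf))
}

#' Read a region annotation (label CSV + YAML legend)
#'
#' @param path Path to the integer-label CSV.
#' @param legend_path Path to the YAML legend mapping region names to label
#'   integers (default `<path without .csv>_legend.yaml`).
#' @return A [region_annotation()].
#' @export
read_annotation <- function(path,
                            legend_path = sub("\\.csv$", "_legend.yaml", path)) {
  if (!file.exists(legend_path)) stop("legend file not found: ", legend_path)
  leg <- unlist(yaml::read_yaml(legend_path))
  labels <- .read_matrix_csv(path)
  region_annotation(labels, setNames(as.integer(leg), names(leg)))
}

#' Write a region annotation (label CSV + YAML legend)
#'
#' @param annotation A [region_annotation()].
#' @param path Target path for the label CSV.
#' @param legend_path Target path for the YAML legend.
#' @return Invisibly, the files written.
#' @export
write_annotation <- function(annotation, path,
                             legend_path = sub("\\.csv$", "_legend.yaml", path)) {
  stopifnot(inherits(annotation, "region_annotation"))
  txt <- apply(annotation$labels, 1, paste, collapse = ",")
  writeLines(txt, path)
  yaml::write_yaml(as.list(annotation$legend), legend_path)
  invisible(c(path, legend_path))
}

.congruent <- function(a, b) identical(dim(a), dim(b))

`%||%` <- function(a, b) if (is.null(a)) b else a

.image_data <- function(x) {
  if (inherits(x, "element_image") || inherits(x, "conc_map")) x$data
  else if (is.matrix(x)) x
  else stop("expected an element_image, conc_map or matrix")
}
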