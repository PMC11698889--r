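#' Rolling-median despike parameters
#'
#' @param size Odd window edge length in pixels (>= 3). Default 5.
#' @param k Nonnegative deviation multiplier: a pixel further than `k` scaled
#'   median absolute deviations (1.4826 * MAD) from its window median is
#'   replaced by that median. Default 3.0.
#' @return An object of class `denoise_params`.
#' @export
denoise_params <- function(size = 5L, k = 3.0) {
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L) stop("window size must be odd and >= 3")
  if (!is.numeric(k) || length(k) != 1 || k < 0) stop("k must be >= 0")
  structure(list(size = size, k = k), class = "denoise_params")
}

#' Rolling-median outlier filter
#'
#' For each pixel, the median m and the scaled median absolute deviation
#' s = 1.4826 * MAD are computed over the `size` x `size` window centred on
#' the pixel (truncated at the image border, no padding). If
#' |x - m| > k * s, the pixel is replaced by m; otherwise it is returned
#' bit-identical to the input. Removes isolated spikes (detector salt noise)
#' while leaving structured signal untouched.
#'
#' @param image An [element_image()], `conc_map`, or plain numeric matrix.
#' @param params A [denoise_params()].
#' @return Same type as `image`, with outlier pixels replaced.
#' @export
rolling_median_filter <- function(image, params = denoise_params()) {
  stopifnot(inherits(params, "denoise_params"))
  dat <- .image_data(image)
  if (!all(is.finite(dat))) stop("image must be finite")
  out <- .rolling_median_cpp(dat, params$size, params$k)
  if (is.matrix(image)) return(out)
  image$data <- out
  image
}
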