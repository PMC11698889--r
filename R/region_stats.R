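#' Median and quartiles of one element in one annotated region
#'
#' Summarises the concentration (or intensity) of the pixels belonging to a
#' named region, optionally intersected with a retention mask. Quantiles use
#' the linear-interpolation convention (R type 7). When `map` is a `conc_map`
#' with LOQ flags, the fraction of selected pixels below the LOQ is reported.
#'
#' @param map A `conc_map`, [element_image()], or numeric matrix.
#' @param annotation A [region_annotation()] congruent with the map.
#' @param region Region name; `"epithelial"` includes the tumor-niche and
#'   stroma sub-compartments.
#' @param mask Optional [pixel_mask()]; only pixels retained by the mask are
#'   summarised.
#' @param sample_id,element Identifiers carried into the output row.
#' @return One-row tibble: sample_id, element, region, median, q1, q3,
#'   n_pixels, pct_below_loq.
#' @export
region_summary <- function(map, annotation, region, mask = NULL,
                           sample_id = NA_character_,
                           element = NA_character_) {
  dat <- .image_data(map)
  if (!.congruent(dat, annotation$labels))
    stop("map and annotation are not congruent")
  sel <- region_pixels(annotation, region)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "pixel_mask"))
    if (!.congruent(dat, mask$data)) stop("map and mask are not congruent")
    sel <- sel & mask$data
  }
  if (!any(sel))
    stop("empty selection: region '", region, "' in sample '", sample_id, "'")
  x <- dat[sel]
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  if (is.na(element) && inherits(map, "conc_map")) element <- map$element
  if (is.na(element) && inherits(map, "element_image")) element <- map$isotope
  pct_bl <- if (inherits(map, "conc_map") && !is.null(map$below_loq))
    100 * mean(map$below_loq[sel]) else NA_real_
  tibble::tibble(sample_id = sample_id, element = element, region = region,
                 median = q[2], q1 = q[1], q3 = q[3],
                 n_pixels = sum(sel), pct_below_loq = pct_bl)
}

.test_result <- function(test_name, statistic, p_value, n1, n2, alternative,
                         alpha = 0.05) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n1 = n1, n2 = n2,
                 alternative = alternative,
                 significant = p_value <= alpha),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s (%s): statistic %.4g, p = %.4g, n = (%d, %d)%s\n",
              x$test_name, x$alternative, x$statistic, x$p_value, x$n1, x$n2,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' One-tailed Mann-Whitney U test on per-sample medians
#'
#' Compares two independent groups of per-sample region medians. The p-value
#' is exact when the combined sample size is at most 20 and there are no
#' ties, and otherwise uses the normal approximation with tie and continuity
#' corrections. The statistic reported is the U of the group stated as
#' greater under the alternative.
#'
#' @param group_a,group_b Numeric vectors of per-sample medians (n >= 2 each).
#' @param alternative `"b_greater"` (default) tests whether `group_b` is
#'   stochastically greater than `group_a`; `"a_greater"` the reverse.
#' @param alpha Significance level (default 0.05).
#' @return A `test_result`.
#' @export
mann_whitney_one_tailed <- function(group_a, group_b,
                                    alternative = c("b_greater", "a_greater"),
                                    alpha = 0.05) {
  alternative <- match.arg(alternative)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 samples")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  x <- if (alternative == "b_greater") b else a
  y <- if (alternative == "b_greater") a else b
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "greater", exact = exact,
                correct = TRUE))
  .test_result("mann_whitney_one_tailed", ht$statistic, ht$p.value,
               length(a), length(b),
               paste0(alternative, if (exact) " (exact)" else " (normal approx.)"),
               alpha)
}

#' Two-tailed Wilcoxon signed-rank test on paired per-sample medians
#'
#' Pairs with zero difference are dropped (documented convention). For up to
#' 25 retained pairs the p-value is computed from the exact sign-flip
#' permutation distribution of the signed-rank statistic, using average
#' ranks — so tied absolute differences are handled exactly rather than
#' forcing an approximation (on tie-free inputs this coincides with the
#' classical signed-rank distribution). Beyond 25 pairs the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param paired_a,paired_b Numeric vectors of equal length; at least 3
#'   nonzero differences must remain.
#' @param alpha Significance level (default 0.05).
#' @return A `test_result`.
#' @export
wilcoxon_signed_rank_two_tailed <- function(paired_a, paired_b,
                                            alpha = 0.05) {
  a <- as.numeric(paired_a); b <- as.numeric(paired_b)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- b - a
  if (all(d == 0)) stop("degenerate pairing: all differences are zero")
  nz <- d[d != 0]
  n <- length(nz)
  if (n < 3)
    stop("need at least 3 nonzero differences, got ", n)
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (n <= 25) {
    p <- .wsr_exact_two_sided(r, v)
    method <- "two-sided (exact sign-flip)"
  } else {
    ht <- suppressWarnings(
      wilcox.test(nz, alternative = "two.sided", exact = FALSE,
                  correct = TRUE))
    p <- ht$p.value
    method <- "two-sided (normal approx.)"
  }
  .test_result("wilcoxon_two_tailed", v, p, n, n, method, alpha)
}

# Exact two-sided p-value of the signed-rank statistic under independent
# random sign flips. Average ranks are half-integers, so the distribution
# of the doubled statistic is an integer convolution (one 0-or-2r term per
# pair); symmetric about n(n+1)/2 on the doubled scale.
.wsr_exact_two_sided <- function(r, v_obs) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (x in r2) {
    g <- f
    g[(x + 1):(total + 1)] <- g[(x + 1):(total + 1)] + f[1:(total + 1 - x)]
    f <- g / 2
  }
  ev <- total / 2
  dev <- abs(2 * v_obs - ev)
  sum(f[abs(seq(0, total) - ev) >= dev - 1e-9])
}

#' Spearman colocalization of two element maps within a mask
#'
#' Quantifies pixelwise spatial co-variation (e.g. Sr vs Ba in epithelial
#' tissue) by the Spearman rank correlation, i.e. the Pearson correlation of
#' average ranks. Strength classes: strong rho >= 0.8, moderate
#' 0.4 <= rho < 0.8, weak rho < 0.4.
#'
#' @param map_a,map_b `conc_map`s, [element_image()]s or matrices.
#' @param mask [pixel_mask()] or logical matrix selecting the pixels to use
#'   (>= 10 pixels).
#' @param sample_id Identifier carried into the result.
#' @return An object of class `correlation_result`: `sample_id`, `elements`,
#'   `rho`, `n_pixels`, `strength`.
#' @export
spearman_colocalization <- function(map_a, map_b, mask,
                                    sample_id = NA_character_) {
  da <- .image_data(map_a); db <- .image_data(map_b)
  msk <- if (inherits(mask, "pixel_mask")) mask$data else mask
  stopifnot(is.logical(msk))
  if (!.congruent(da, db) || !.congruent(da, msk))
    stop("maps and mask are not congruent")
  if (sum(msk) < 10) stop("need at least 10 masked pixels")
  x <- da[msk]; y <- db[msk]
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("rank-degenerate input: constant map within mask")
  rho <- cor(x, y, method = "spearman")
  lab <- function(m, default) {
    if (is.list(m) && !is.null(m$element)) m$element
    else if (is.list(m) && !is.null(m$isotope)) m$isotope
    else default
  }
  el <- c(lab(map_a, "a"), lab(map_b, "b"))
  structure(list(sample_id = sample_id, elements = el, rho = rho,
                 n_pixels = sum(msk),
                 strength = classify_correlation(rho)),
            class = "correlation_result")
}

#' Correlation strength class
#'
#' @param rho Spearman coefficient in \[-1, 1\].
#' @param thresholds Named vector with `strong` and `moderate` lower bounds
#'   (on the absolute coefficient).
#' @return `"strong"`, `"moderate"` or `"weak"`.
#' @export
classify_correlation <- function(rho,
                                 thresholds = c(strong = 0.8, moderate = 0.4)) {
  stopifnot(abs(rho) <= 1 + 1e-12)
  if (abs(rho) >= thresholds[["strong"]]) "strong"
  else if (abs(rho) >= thresholds[["moderate"]]) "moderate"
  else "weak"
}
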