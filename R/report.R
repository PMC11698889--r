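#' Group-level comparison report
#'
#' The statistical unit is the per-sample region median — never pooled
#' pixels. For every element x region the report gives the per-group median
#' (Q1-Q3) of per-sample medians; for the epithelial compartment it runs
#' pairwise one-tailed Mann-Whitney tests (H vs NM, H vs M, NM vs M, each
#' with the later-stage group as the "greater" alternative); and, where the
#' annotations provide them, paired two-tailed Wilcoxon tests of adipose vs
#' epithelial and tumor-niche vs stroma medians. Samples lacking a stroma
#' region are excluded from the stroma comparison and their number is
#' reported. A group with fewer than 2 samples makes its comparisons be
#' skipped with a warning, not an error.
#'
#' @param summaries Tibble of region summaries as returned by
#'   [region_summary()] (rows for several samples/elements/regions).
#' @param records Tibble of sample records ([sample_record()] rows) with
#'   `sample_id` and `group`.
#' @param alpha Significance level (default 0.05).
#' @param group_test_region Region on which group comparisons are run
#'   (default `"epithelial"`).
#' @return List with tibbles `group_medians`, `group_tests`, `paired_tests`,
#'   and `n_excluded_stroma`.
#' @export
group_comparison_report <- function(summaries, records, alpha = 0.05,
                                    group_test_region = "epithelial") {
  stopifnot(all(c("sample_id", "element", "region", "median") %in%
                  names(summaries)),
            all(c("sample_id", "group") %in% names(records)))
  df <- dplyr::left_join(tibble::as_tibble(summaries),
                         tibble::as_tibble(records)[, c("sample_id", "group")],
                         by = "sample_id")
  if (anyNA(df$group))
    stop("summaries contain sample_id(s) without a sample record")
  groups_present <- unique(df$group)

  group_medians <- df %>%
    dplyr::group_by(.data$element, .data$region, .data$group) %>%
    dplyr::summarise(
      n_samples = dplyr::n_distinct(.data$sample_id),
      group_median = stats::median(.data$median),
      group_q1 = unname(quantile(.data$median, 0.25, type = 7)),
      group_q3 = unname(quantile(.data$median, 0.75, type = 7)),
      .groups = "drop")

  # pairwise one-tailed Mann-Whitney on the group-comparison region;
  # the second (later-stage) group is the "greater" alternative
  pairs <- list(c("H", "NM"), c("H", "M"), c("NM", "M"))
  gt_rows <- list()
  gdf <- df[df$region == group_test_region, ]
  for (el in unique(gdf$element)) {
    de <- gdf[gdf$element == el, ]
    for (pr in pairs) {
      if (!all(pr %in% groups_present)) next
      a <- de$median[de$group == pr[1]]
      b <- de$median[de$group == pr[2]]
      if (length(a) < 2 || length(b) < 2) {
        warning("skipping ", el, " ", pr[1], "-vs-", pr[2],
                ": a group has fewer than 2 samples")
        next
      }
      tr <- mann_whitney_one_tailed(a, b, "b_greater", alpha)
      gt_rows[[length(gt_rows) + 1L]] <- tibble::tibble(
        element = el, region = group_test_region,
        comparison = paste0(pr[1], "_vs_", pr[2]),
        test = tr$test_name, statistic = tr$statistic,
        p_value = tr$p_value, n1 = tr$n1, n2 = tr$n2,
        significant = tr$significant)
    }
  }
  group_tests <- if (length(gt_rows)) dplyr::bind_rows(gt_rows) else
    tibble::tibble(element = character(), region = character(),
                   comparison = character(), test = character(),
                   statistic = numeric(), p_value = numeric(),
                   n1 = integer(), n2 = integer(), significant = logical())
  if (!nrow(group_tests) && length(groups_present) < 2)
    warning("fewer than 2 groups present; no group comparisons performed")

  # paired Wilcoxon comparisons across regions, within samples
  paired_specs <- list(c("adipose", "epithelial"), c("tumor_niche", "stroma"))
  pt_rows <- list()
  n_excl_stroma <- 0L
  for (el in unique(df$element)) {
    de <- df[df$element == el, ]
    for (ps in paired_specs) {
      wide <- merge(de[de$region == ps[1], c("sample_id", "median")],
                    de[de$region == ps[2], c("sample_id", "median")],
                    by = "sample_id", suffixes = c("_a", "_b"))
      if (identical(ps, c("tumor_niche", "stroma"))) {
        n_with_niche <- dplyr::n_distinct(
          de$sample_id[de$region == ps[1]])
        n_excl_stroma <- max(n_excl_stroma, n_with_niche - nrow(wide))
      }
      if (nrow(wide) < 3) next
      tr <- tryCatch(
        wilcoxon_signed_rank_two_tailed(wide$median_b, wide$median_a,
                                        alpha),
        error = function(e) NULL)
      if (is.null(tr)) next
      pt_rows[[length(pt_rows) + 1L]] <- tibble::tibble(
        element = el, comparison = paste0(ps[1], "_vs_", ps[2]),
        test = tr$test_name, statistic = tr$statistic,
        p_value = tr$p_value, n_pairs = tr$n1,
        significant = tr$significant)
    }
  }
  paired_tests <- if (length(pt_rows)) dplyr::bind_rows(pt_rows) else
    tibble::tibble(element = character(), comparison = character(),
                   test = character(), statistic = numeric(),
                   p_value = numeric(), n_pairs = integer(),
                   significant = logical())

  list(group_medians = group_medians, group_tests = group_tests,
       paired_tests = paired_tests, n_excluded_stroma = n_excl_stroma)
}
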