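#' Poisson background rate per bin
#'
#' Estimates the expected per-bin count of a category under the background
#' mutation process, from mutations distant from the focal points: category
#' mutations with `|offset|` in `[min_dist, max_dist)` are summed over focal
#' occurrences and scaled by the ratio of one bin's span to the background
#' annulus span (`2 * (max_dist - min_dist)` bp per focal point). When the
#' annulus holds no mutations, a pseudo-count of 0.5 is used and flagged.
#'
#' @param mutations mutation catalog tibble.
#' @param points focal points from [focal_points()].
#' @param category one of [sbs_categories()], or `"all"`.
#' @param grid a [bin_grid()].
#' @param bg_window numeric `(min_dist, max_dist)` in bp; `min_dist` must be
#'   at least `grid$flank` so the annulus excludes the profiled window.
#' @return list with `lambda_bg` (expected count per bin), `n_background`
#'   (annulus occurrences used), and `pseudo_count` (flag).
#' @export
poisson_background <- function(mutations, points, category = "all",
                               grid = bin_grid(), bg_window = c(5000, 50000)) {
  stopifnot(length(bg_window) == 2, bg_window[1] < bg_window[2])
  if (bg_window[1] < grid$flank)
    stop("background min_dist (", bg_window[1],
         ") must be >= the profiling flank (", grid$flank, ")", call. = FALSE)
  if (!identical(category, "all")) {
    category <- match.arg(category, sbs_categories())
    keep <- classify_sbs(mutations$ref, mutations$alt)$category == category
    mutations <- mutations[keep, , drop = FALSE]
  }
  occ <- focal_offsets(mutations, points, flank = bg_window[1],
                       max_dist = bg_window[2])
  n_bg <- nrow(occ)
  pseudo <- n_bg == 0L
  eff <- if (pseudo) 0.5 else n_bg
  span_ratio <- grid$bin_width / (2 * (bg_window[2] - bg_window[1]))
  list(lambda_bg = eff * span_ratio, n_background = n_bg,
       pseudo_count = pseudo)
}

#' Poisson test of the extreme bins against the background
#'
#' The maximum-count bin is tested with the upper Poisson tail
#' `P(X >= obs | lambda_bg)` for a peak and the minimum-count bin with the
#' lower tail `P(X <= obs | lambda_bg)` for a dip; both candidates are
#' reported and a direction is called only when its tail probability falls
#' below the nominal threshold. Ties on the extreme count are broken toward
#' the bin closest to the focal point.
#'
#' @param profile a `density_profile` from [bin_counts()].
#' @param lambda_bg positive background rate per bin (the `lambda_bg` from
#'   [poisson_background()]).
#' @param category category whose pooled bin counts are tested; `"all"`
#'   pools everything.
#' @param alpha_nominal nominal significance threshold (default `1e-5`).
#' @return tibble with one row per candidate (`peak`, `dip`): `anchor`,
#'   `category`, `candidate`, `bin`, `bin_start_offset`, `observed`,
#'   `lambda_bg`, `p_nominal`, `significant`, `direction` (the candidate
#'   label when significant, otherwise `"none"`).
#' @export
detect_peak_dip <- function(profile, lambda_bg, category = "all",
                            alpha_nominal = 1e-5) {
  stopifnot(lambda_bg > 0)
  cnt <- category_bin_counts(profile, category)
  offs <- bin_offsets(profile$grid)
  pick <- function(cands) cands[which.min(abs(offs[cands] +
                                              profile$grid$bin_width / 2))]
  b_max <- pick(which(cnt == max(cnt)))
  b_min <- pick(which(cnt == min(cnt)))
  p_peak <- stats::ppois(cnt[b_max] - 1, lambda_bg, lower.tail = FALSE)
  p_dip <- stats::ppois(cnt[b_min], lambda_bg, lower.tail = TRUE)
  out <- tibble::tibble(
    anchor = profile$anchor,
    category = if (identical(category, "all")) "all" else category,
    candidate = c("peak", "dip"),
    bin = c(b_max, b_min) - 1L,
    bin_start_offset = offs[c(b_max, b_min)],
    observed = as.numeric(cnt[c(b_max, b_min)]),
    lambda_bg = lambda_bg,
    p_nominal = c(p_peak, p_dip)
  )
  out$significant <- out$p_nominal < alpha_nominal
  out$direction <- ifelse(out$significant, out$candidate, "none")
  out
}

.region_bins <- function(grid, region) {
  half <- grid$n_bins %/% 2L
  switch(region,
         left = seq_len(half),
         right = half + seq_len(half),
         whole = seq_len(grid$n_bins))
}

#' Wilcoxon signed-rank test of strand bias
#'
#' Pairs the per-bin MPKM of a category's pyrimidine form with its purine
#' form over the selected bins (left = upstream half of the grid, right =
#' downstream half, whole = all bins) and applies a two-sided Wilcoxon
#' signed-rank test. Zero differences are dropped (signed-rank convention);
#' the exact null distribution is used when the informative sample size is
#' at most 25, the normal approximation with continuity correction
#' otherwise. With no informative pairs the test is vacuous: p = 1,
#' statistic NA.
#'
#' @param profile a normalized `density_profile` (after [normalize_mpkm()]).
#' @param category one of [sbs_categories()].
#' @param region `"left"`, `"right"`, or `"whole"`.
#' @return one-row tibble: `anchor`, `category`, `region`, `statistic`
#'   (signed-rank V of the pyrimidine-minus-purine differences),
#'   `n_informative`, `p`.
#' @export
strand_bias_test <- function(profile, category,
                             region = c("right", "left", "whole")) {
  region <- match.arg(region)
  category <- match.arg(category, sbs_categories())
  if (is.null(profile$mpkm))
    stop("profile is not normalized; run normalize_mpkm() first", call. = FALSE)
  forms <- sbs_forms()
  bins <- .region_bins(profile$grid, region)
  x <- profile$mpkm[which(forms$category == category & forms$pyrimidine_form),
                    bins]
  y <- profile$mpkm[which(forms$category == category & !forms$pyrimidine_form),
                    bins]
  d <- x - y
  n_inf <- sum(d != 0)
  if (n_inf == 0L) {
    res <- list(statistic = NA_real_, p = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, paired = TRUE, alternative = "two.sided",
      exact = n_inf <= 25L, correct = TRUE))
    res <- list(statistic = unname(wt$statistic), p = wt$p.value)
  }
  tibble::tibble(anchor = profile$anchor, category = category, region = region,
                 statistic = res$statistic, n_informative = n_inf, p = res$p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, pooled over whatever
#' family of tests is passed in (one pipeline run pools all
#' cohort x source x anchor x category x region tests).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Strand-bias scan over all categories and regions
#'
#' Runs [strand_bias_test()] for each of the six categories in each of the
#' three regions and adjusts the 18 p-values jointly with [bh_adjust()].
#'
#' @param profile a normalized `density_profile`.
#' @param regions regions to scan (default all three).
#' @return tibble of test rows with a pooled `p_adjusted` column.
#' @export
strand_bias_scan <- function(profile, regions = c("left", "right", "whole")) {
  rows <- lapply(sbs_categories(), function(cat)
    lapply(regions, function(r) strand_bias_test(profile, cat, r)))
  out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  out$p_adjusted <- bh_adjust(out$p)
  out
}

#' Peak/dip scan over all categories
#'
#' Estimates a per-category Poisson background and tests each category's
#' extreme bins (plus the pooled `"all"` track).
#'
#' @param mutations mutation catalog tibble.
#' @param points focal points.
#' @param profile a `density_profile` over the same points.
#' @param bg_window background annulus, as in [poisson_background()].
#' @param alpha_nominal nominal threshold (default `1e-5`).
#' @return tibble of [detect_peak_dip()] rows with `n_background` and
#'   `pseudo_count` columns.
#' @export
peak_dip_scan <- function(mutations, points, profile,
                          bg_window = c(5000, 50000), alpha_nominal = 1e-5) {
  cats <- c("all", sbs_categories())
  dplyr::bind_rows(lapply(cats, function(cat) {
    bg <- poisson_background(mutations, points, cat, profile$grid, bg_window)
    res <- detect_peak_dip(profile, bg$lambda_bg, cat, alpha_nominal)
    res$n_background <- bg$n_background
    res$pseudo_count <- bg$pseudo_count
    res
  }))
}
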