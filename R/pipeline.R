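#' One-call density analysis around an anchor
#'
#' Ties the pipeline together for a single cohort and interval set: focal
#' points at the requested anchor, optional size selection, binned counts,
#' MPKM normalization against the cohort's genome-wide total, the Poisson
#' peak/dip scan, and the strand-bias scan with pooled BH adjustment.
#'
#' @param mutations mutation catalog tibble.
#' @param intervals an [interval_set()].
#' @param anchor `"midpoint"` (default), `"start"`, or `"end"`.
#' @param grid a [bin_grid()]; `bin_grid(6000, 100)` gives the extended
#'   120-bin view.
#' @param bg_window background annulus for [poisson_background()].
#' @param max_erna_size optional strict size cutoff applied first
#'   ([filter_by_size()]); 2000 selects the bidirectional-eRNA proxy.
#' @param f per-category composition factors for [normalize_mpkm()].
#' @param alpha_nominal peak/dip nominal threshold.
#' @return list with `points`, `profile`, `peak_dip` (tibble), and
#'   `strand_bias` (tibble with `p_adjusted`).
#' @export
density_analysis <- function(mutations, intervals,
                             anchor = c("midpoint", "start", "end"),
                             grid = bin_grid(),
                             bg_window = c(5000, 50000),
                             max_erna_size = NULL,
                             f = default_composition_factors(),
                             alpha_nominal = 1e-5) {
  anchor <- match.arg(anchor)
  if (!is.null(max_erna_size))
    intervals <- filter_by_size(intervals, max_erna_size)
  points <- focal_points(intervals, anchor)
  profile <- bin_counts(mutations, points, grid)
  profile <- normalize_mpkm(profile, cohort_total = nrow(mutations), f = f)
  list(points = points,
       profile = profile,
       peak_dip = peak_dip_scan(mutations, points, profile, bg_window,
                                alpha_nominal),
       strand_bias = strand_bias_scan(profile))
}
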