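#' Binning grid around focal points
#'
#' The profiling window spans `flank` bp on each side of a focal point and
#' is divided into bins of `bin_width` bp. The defaults (2000 / 100) give
#' the 40-bin grid; a 6000 bp flank gives 120 bins.
#'
#' @param flank window half-width in bp; must be divisible by `bin_width`.
#' @param bin_width bin size in bp.
#' @return a `bin_grid` list with fields `flank`, `bin_width`, `n_bins`.
#' @export
bin_grid <- function(flank = 2000L, bin_width = 100L) {
  flank <- as.integer(flank); bin_width <- as.integer(bin_width)
  stopifnot(flank > 0, bin_width > 0)
  if (flank %% bin_width != 0L)
    stop("flank (", flank, ") must be divisible by bin_width (", bin_width, ")",
         call. = FALSE)
  structure(list(flank = flank, bin_width = bin_width,
                 n_bins = 2L * flank %/% bin_width),
            class = "bin_grid")
}

#' Start offsets of the grid bins
#'
#' @param grid a [bin_grid()].
#' @return integer vector of each bin's start offset relative to the focal
#'   point (bin 0 starts at `-flank`; offset 0 opens the first downstream
#'   bin).
#' @export
bin_offsets <- function(grid) {
  seq(-grid$flank, grid$flank - grid$bin_width, by = grid$bin_width)
}

#' Signed offsets of mutations from focal points, per occurrence
#'
#' For every (mutation, focal point) pair on the same chromosome with offset
#' `d = (pos - 1) - position` inside `[-flank, +flank)` — half-open, so
#' `d = 0` (the focal base itself) belongs to the first downstream bin — one
#' row is emitted. A mutation near several focal points contributes once per
#' point (per-occurrence tallying).
#'
#' @param mutations mutation catalog tibble.
#' @param points focal points from [focal_points()].
#' @param flank window half-width in bp.
#' @param max_dist optional outer distance; when given, pairs with
#'   `|d|` in `[flank, max_dist)` are returned instead (the background
#'   annulus used by [poisson_background()]), using `flank` as the inner
#'   exclusion radius.
#' @return tibble with columns `mut_idx`, `point_idx`, `offset`.
#' @export
focal_offsets <- function(mutations, points, flank, max_dist = NULL) {
  empty <- tibble::tibble(mut_idx = integer(), point_idx = integer(),
                          offset = numeric())
  if (!nrow(mutations) || !nrow(points)) return(empty)
  outer <- if (is.null(max_dist)) flank else max_dist
  # windows are [position - outer, position + outer - 1] in 0-based closed
  # coordinates; shift both sides by +1 to live in IRanges' 1-based world
  gr_mut <- GenomicRanges::GRanges(mutations$chrom,
                                   IRanges::IRanges(mutations$pos, width = 1L))
  gr_win <- GenomicRanges::GRanges(points$chrom,
                                   IRanges::IRanges(points$position + 1L - outer,
                                                    points$position + outer))
  hits <- GenomicRanges::findOverlaps(gr_mut, gr_win, ignore.strand = TRUE)
  mi <- S4Vectors::queryHits(hits); pi <- S4Vectors::subjectHits(hits)
  d <- (mutations$pos[mi] - 1) - points$position[pi]
  keep <- if (is.null(max_dist)) d < outer            # [-flank, +flank)
          else abs(d) >= flank & abs(d) < outer       # annulus, half-open
  tibble::tibble(mut_idx = mi[keep], point_idx = pi[keep], offset = d[keep])
}

#' Bin mutation counts around focal points
#'
#' Tallies mutations of each of the 12 complementary forms in each grid bin,
#' per occurrence of a focal point. The bin of an offset `d` is
#' `floor((d + flank) / bin_width)`.
#'
#' @param mutations mutation catalog tibble.
#' @param points focal points from [focal_points()]; must be non-empty.
#' @param grid a [bin_grid()].
#' @return a `density_profile`: list with `grid`, `anchor`, `n_focal`,
#'   `counts` (12 x n_bins matrix, rows = forms in [sbs_forms()] order),
#'   `mpkm` (`NULL` until [normalize_mpkm()]), and `counting` metadata
#'   (`"per_occurrence"`).
#' @export
bin_counts <- function(mutations, points, grid = bin_grid()) {
  if (!nrow(points)) stop("focal point set is empty", call. = FALSE)
  forms <- sbs_forms()
  counts <- matrix(0L, nrow = 12L, ncol = grid$n_bins,
                   dimnames = list(forms$form, NULL))
  occ <- focal_offsets(mutations, points, grid$flank)
  if (nrow(occ)) {
    cl <- classify_sbs(mutations$ref[occ$mut_idx], mutations$alt[occ$mut_idx])
    bin <- (occ$offset + grid$flank) %/% grid$bin_width
    tab <- table(factor(cl$form, levels = forms$form),
                 factor(bin, levels = 0:(grid$n_bins - 1L)))
    counts[] <- as.integer(tab)
  }
  structure(list(grid = grid,
                 anchor = points$anchor[1] %||% NA_character_,
                 n_focal = nrow(points),
                 counts = counts,
                 mpkm = NULL,
                 f = NULL, K = NULL,
                 counting = "per_occurrence"),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("density_profile: ", x$grid$n_bins, " bins of ", x$grid$bin_width,
      " bp around ", x$n_focal, " focal point(s) [anchor: ", x$anchor, "]\n",
      "  binned mutations: ", sum(x$counts),
      if (is.null(x$mpkm)) "  (counts only; run normalize_mpkm())" else
        paste0("  K = ", x$K, " kilo mutations"),
      "\n", sep = "")
  invisible(x)
}

#' Default base-composition adjusting factors
#'
#' A substitution category can only arise on its substrate base pair: C-rooted
#' categories on C:G pairs, T-rooted on T:A pairs. In the human reference
#' roughly 40% of bases are G or C, so the per-strand substrate fraction is
#' 0.2 for C-rooted and 0.3 for T-rooted categories. These constants are
#' applied genome-agnostically unless recomputed from a reference.
#'
#' @return named numeric vector over [sbs_categories()].
#' @export
default_composition_factors <- function() {
  c("C>A" = 0.2, "C>G" = 0.2, "C>T" = 0.2,
    "T>A" = 0.3, "T>C" = 0.3, "T>G" = 0.3)
}

#' Composition factors from a reference over profiled windows
#'
#' Recomputes the adjusting factors from observed base fractions in the
#' `[-flank, +flank]` windows around the focal points: the C-rooted factor is
#' the per-strand C:G substrate fraction `(C + G) / 2`, the T-rooted factor
#' `(A + T) / 2`.
#'
#' @param points focal points.
#' @param reference DNAStringSet or FASTA path.
#' @param flank window half-width in bp.
#' @return named numeric vector over [sbs_categories()].
#' @export
composition_factors <- function(points, reference, flank = 2000) {
  prof <- nucleotide_profile(points, reference, flank = flank)
  w <- prof$n
  gc <- sum(prof$GC * w, na.rm = TRUE) / sum(w[!is.na(prof$GC)])
  c("C>A" = gc / 2, "C>G" = gc / 2, "C>T" = gc / 2,
    "T>A" = (1 - gc) / 2, "T>C" = (1 - gc) / 2, "T>G" = (1 - gc) / 2)
}

#' Normalize binned counts to MPKM densities
#'
#' MPKM — mutations per kilo total mutations per megabase — at bin
#' granularity: each form's bin count is divided by the bin's total profiled
#' span in Mb (`n_focal * bin_width / 1e6`), the category's composition
#' adjusting factor `f`, and the cohort's total mutation count in kilos
#' `K = cohort_total / 1000`.
#'
#' @param profile a `density_profile` from [bin_counts()].
#' @param cohort_total total number of cohort mutations (genome-wide), > 0.
#' @param f named per-category factors; default
#'   [default_composition_factors()].
#' @return the profile with `mpkm` (12 x n_bins matrix), `f`, and `K` filled.
#' @export
normalize_mpkm <- function(profile, cohort_total,
                           f = default_composition_factors()) {
  stopifnot(inherits(profile, "density_profile"))
  if (cohort_total <= 0)
    stop("cohort_total must be positive: MPKM is undefined for an empty cohort",
         call. = FALSE)
  if (!all(sbs_categories() %in% names(f)))
    stop("f must name all six categories", call. = FALSE)
  K <- cohort_total / 1000
  span_mb <- profile$n_focal * profile$grid$bin_width / 1e6
  f_row <- f[sbs_forms()$category]
  profile$mpkm <- profile$counts / (span_mb * K) / f_row
  profile$f <- f[sbs_categories()]
  profile$K <- K
  profile
}

#' Long-format table of a density profile
#'
#' @param profile a `density_profile`.
#' @return tibble with `category`, `pyrimidine_form`, `form`,
#'   `bin`, `bin_start_offset`, `count`, and `mpkm` (NA until normalized).
#' @export
profile_table <- function(profile) {
  forms <- sbs_forms()
  nb <- profile$grid$n_bins
  tibble::tibble(
    category = rep(forms$category, times = nb),
    pyrimidine_form = rep(forms$pyrimidine_form, times = nb),
    form = rep(forms$form, times = nb),
    bin = rep(0:(nb - 1L), each = 12L),
    bin_start_offset = rep(bin_offsets(profile$grid), each = 12L),
    count = as.vector(profile$counts),
    mpkm = if (is.null(profile$mpkm)) NA_real_ else as.vector(profile$mpkm)
  )
}

#' Per-category bin counts (both forms pooled)
#'
#' @param profile a `density_profile`.
#' @param category one of [sbs_categories()], or `"all"` to pool everything.
#' @return integer vector of length `n_bins`.
#' @export
category_bin_counts <- function(profile, category = "all") {
  if (identical(category, "all")) return(colSums(profile$counts))
  rows <- sbs_forms()$category == match.arg(category, sbs_categories())
  colSums(profile$counts[rows, , drop = FALSE])
}
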