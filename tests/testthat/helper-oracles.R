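# Independent brute-force oracles and small fixture builders used across the
# suite. Everything here is deliberately naive: per-base membership vectors,
# per-pair linear scans, full sign enumeration.

make_catalog <- function(chrom, pos, ref = "C", alt = "A", donor = "D1") {
  n <- max(length(chrom), length(pos), length(ref), length(alt), length(donor))
  tibble::tibble(donor_id = rep_len(donor, n),
                 chrom = rep_len(as.character(chrom), n),
                 pos = rep_len(as.integer(pos), n),
                 ref = rep_len(ref, n), alt = rep_len(alt, n))
}

random_interval_set <- function(n, chrom_len = 10000, chroms = "1",
                                label = "rand") {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len - 2L, n, replace = TRUE) - 1L
  len <- sample.int(200L, n, replace = TRUE)
  interval_set(chrom, start, pmin(start + len, chrom_len), label = label)
}

# per-base membership oracle for overlap proportions on one toy chromosome
brute_overlap_prop <- function(a, b, chrom_len = 10000) {
  cover <- function(s) {
    v <- logical(chrom_len)
    for (i in seq_len(nrow(s))) v[(s$start[i] + 1):s$end[i]] <- TRUE
    v
  }
  ca <- cover(a); cb <- cover(b)
  sum(ca & cb) / sum(ca)
}

# linear-scan oracle: region-overlapping mutations per donor and category
brute_count_overlaps <- function(mutations, intervals) {
  out <- list()
  for (i in seq_len(nrow(mutations))) {
    p0 <- mutations$pos[i] - 1
    hit <- any(intervals$chrom == mutations$chrom[i] &
               intervals$start <= p0 & p0 < intervals$end)
    if (hit) {
      cl <- classify_sbs(mutations$ref[i], mutations$alt[i])
      key <- paste(mutations$donor_id[i], cl$category)
      out[[key]] <- (out[[key]] %||% 0L) + 1L
    }
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force mutation-focal co-occurrence count within [-flank, +flank)
brute_cooccurrence <- function(mutations, points, flank) {
  total <- 0L
  for (i in seq_len(nrow(mutations))) {
    sel <- points$chrom == mutations$chrom[i]
    d <- (mutations$pos[i] - 1) - points$position[sel]
    total <- total + sum(d >= -flank & d < flank)
  }
  total
}

# full sign-enumeration oracle for the two-sided Wilcoxon signed-rank p-value
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# direct step-up evaluation of the BH definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# build a normalized density_profile whose pyrimidine/purine rows of one
# category carry the given per-bin values (all other cells zero)
profile_from_forms <- function(x, y, category = "C>T") {
  n_bins <- length(x)
  grid <- bin_grid(flank = n_bins * 50L, bin_width = 100L)
  forms <- sbs_forms()
  mpkm <- matrix(0, 12L, n_bins, dimnames = list(forms$form, NULL))
  mpkm[forms$category == category & forms$pyrimidine_form, ] <- x
  mpkm[forms$category == category & !forms$pyrimidine_form, ] <- y
  structure(list(grid = grid, anchor = "midpoint", n_focal = 1L,
                 counts = matrix(0L, 12L, n_bins,
                                 dimnames = list(forms$form, NULL)),
                 mpkm = mpkm, f = default_composition_factors(), K = 1,
                 counting = "per_occurrence"),
            class = "density_profile")
}
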