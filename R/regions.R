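#' Focal points of an interval set
#'
#' Extracts one anchor coordinate per interval: `start` is the first covered
#' base, `end` the last covered base (`end - 1` in half-open coordinates),
#' and `midpoint` is `floor((start + end - 1) / 2)` — the floor of the two
#' covered endpoints' mean, deterministic for even-length intervals. eRNAs
#' are transcribed bidirectionally from near their midpoint, so `midpoint`
#' is the TSS proxy used throughout.
#'
#' @param intervals an [interval_set()].
#' @param anchor one of `"start"`, `"midpoint"`, `"end"`.
#' @return tibble with columns `chrom`, `position` (0-based), `anchor`,
#'   `strand`.
#' @export
focal_points <- function(intervals, anchor = c("midpoint", "start", "end")) {
  anchor <- match.arg(anchor)
  if (!nrow(intervals)) stop("empty interval set has no focal points", call. = FALSE)
  pos <- switch(anchor,
    start    = intervals$start,
    end      = intervals$end - 1,
    midpoint = floor((intervals$start + intervals$end - 1) / 2))
  tibble::tibble(chrom = intervals$chrom, position = pos, anchor = anchor,
                 strand = intervals$strand)
}

#' Total merged size of an interval set, in bases
#'
#' Overlapping intervals are merged before summation, so the result is the
#' number of distinct covered bases (the `M` of the MPKM burden formula,
#' before conversion to Mb).
#'
#' @param intervals an [interval_set()].
#' @return integer-valued numeric, 0 for an empty set.
#' @export
region_size <- function(intervals) {
  if (!nrow(intervals)) return(0)
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(as_granges(intervals), ignore.strand = TRUE))))
}

#' Keep intervals strictly shorter than a size cutoff
#'
#' Mirrors the bidirectional-eRNA proxy selection (size < 2000 bp): an
#' interval is kept iff `end - start < max_len` (strict).
#'
#' @param intervals an [interval_set()].
#' @param max_len positive length cutoff in bp.
#' @return the filtered [interval_set()].
#' @export
filter_by_size <- function(intervals, max_len = 2000) {
  stopifnot(max_len > 0)
  out <- intervals[(intervals$end - intervals$start) < max_len, , drop = FALSE]
  attr(out, "source_label") <- attr(intervals, "source_label")
  out
}

#' Pairwise overlap proportions between interval sets
#'
#' Entry (A, B) is the fraction of A's merged bases covered by B — an
#' asymmetric, row-normalized proportion. A symmetric Jaccard mode
#' (intersection over union) is available. Off-diagonal means over ordered
#' and unordered pairs are attached as attributes, since a single "average
#' overlap" can be read either way.
#'
#' @param sets named list of [interval_set()] objects (>= 2).
#' @param mode `"asymmetric"` (default) or `"jaccard"`.
#' @return square numeric matrix of proportions with set labels as
#'   dimnames; rows/columns of empty sets are `NA`. Attributes
#'   `mean_offdiag_ordered` and `mean_offdiag_unordered` hold the summary
#'   means.
#' @export
pairwise_overlap <- function(sets, mode = c("asymmetric", "jaccard")) {
  mode <- match.arg(mode)
  stopifnot(length(sets) >= 2)
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(seq_along(sets), function(i)
      attr(sets[[i]], "source_label") %||% paste0("set", i), "")
  reduced <- lapply(sets, function(s)
    if (nrow(s)) GenomicRanges::reduce(as_granges(s), ignore.strand = TRUE)
    else NULL)
  sizes <- vapply(reduced, function(g)
    if (is.null(g)) NA_real_ else sum(as.numeric(GenomicRanges::width(g))), 0)
  n <- length(sets)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (is.null(reduced[[i]]) || is.null(reduced[[j]])) next
    inter <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(reduced[[i]], reduced[[j]], ignore.strand = TRUE))))
    m[i, j] <- if (mode == "asymmetric") inter / sizes[i]
               else inter / (sizes[i] + sizes[j] - inter)
  }
  off <- m[row(m) != col(m)]
  attr(m, "mean_offdiag_ordered") <- mean(off, na.rm = TRUE)
  up <- m[upper.tri(m)]; lo <- t(m)[upper.tri(m)]
  attr(m, "mean_offdiag_unordered") <- mean((up + lo) / 2, na.rm = TRUE)
  m
}

#' Per-offset nucleotide composition around focal points
#'
#' For every offset in `[-flank, +flank]` relative to each focal point, the
#' fraction of each base across points, plus derived GC and AT fractions.
#' When `strand_aware = TRUE`, minus-strand points contribute with offsets
#' negated and bases complemented (the protein-coding-TSS comparison mode);
#' eRNA analyses run unstranded. Offsets that fall off a chromosome end are
#' excluded from that offset's denominator; points on chromosomes absent
#' from the reference are skipped with a warning.
#'
#' @param points focal points from [focal_points()].
#' @param reference a [Biostrings::DNAStringSet] or path to a FASTA file;
#'   names are normalized with [normalize_chrom()].
#' @param flank positive window half-width in bp.
#' @param strand_aware flip minus-strand points? Default `FALSE`.
#' @return tibble with columns `offset`, `n` (points covering that offset),
#'   `A`, `C`, `G`, `T`, `GC`, `AT` fractions.
#' @export
nucleotide_profile <- function(points, reference, flank = 2000,
                               strand_aware = FALSE) {
  stopifnot(flank > 0)
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- normalize_chrom(sub("\\s.*$", "", names(reference)))
  known <- points$chrom %in% names(reference)
  if (any(!known)) {
    warning(sum(!known), " focal point(s) on chromosomes absent from the ",
            "reference were skipped", call. = FALSE)
    points <- points[known, , drop = FALSE]
  }
  if (!nrow(points)) stop("no focal points covered by the reference", call. = FALSE)
  offsets <- -flank:flank
  width <- 2L * flank + 1L
  counts <- matrix(0, nrow = 4L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (chr in unique(points$chrom)) {
    seqlen <- Biostrings::width(reference[chr])
    pos0 <- points$position[points$chrom == chr]
    strands <- points$strand[points$chrom == chr]
    from <- pos0 + 1L - flank          # 1-based window start
    for (k in seq_along(pos0)) {
      lo <- max(1L, from[k]); hi <- min(seqlen, from[k] + width - 1L)
      if (lo > hi) next
      bases <- strsplit(as.character(
        Biostrings::subseq(reference[[chr]], lo, hi)), "")[[1]]
      cols <- (lo - from[k] + 1L):(hi - from[k] + 1L)
      if (strand_aware && !is.na(strands[k]) && strands[k] == "-") {
        bases <- unname(.base_complement[bases])
        cols <- width + 1L - rev(cols)
        bases <- rev(bases)
      }
      ok <- bases %in% c("A", "C", "G", "T")
      idx <- cbind(match(bases[ok], c("A", "C", "G", "T")), cols[ok])
      # accumulate one window; duplicated cells cannot occur within a window
      counts[idx] <- counts[idx] + 1
    }
  }
  tot <- colSums(counts)
  frac <- sweep(counts, 2, pmax(tot, 1), "/")
  frac[, tot == 0] <- NA_real_
  tibble::tibble(offset = offsets, n = as.integer(tot),
                 A = frac["A", ], C = frac["C", ], G = frac["G", ],
                 T = frac["T", ], GC = frac["C", ] + frac["G", ],
                 AT = frac["A", ] + frac["T", ])
}
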