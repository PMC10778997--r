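#' The six SBS mutation categories
#'
#' Because the two DNA strands are complementary, the 12 possible single-base
#' substitutions collapse into six categories, each written with a pyrimidine
#' reference base: C>A (pooling C>A and G>T), C>G (C>G and G>C), C>T (C>T and
#' G>A), T>A (T>A and A>T), T>C (T>C and A>G), and T>G (T>G and A>C).
#'
#' @return character vector of the six category labels, in canonical order.
#' @export
sbs_categories <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.base_complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement single bases
#'
#' @param base character vector of bases in `{A,C,G,T}`.
#' @return the complementary bases.
#' @export
complement_base <- function(base) {
  out <- .base_complement[toupper(base)]
  if (anyNA(out)) stop("non-ACGT base: ",
                       paste(unique(base[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  unname(out)
}

#' Classify a substitution into category and complementary form
#'
#' Pyrimidine-reference substitutions (ref C or T) map to their own category
#' in pyrimidine form; purine-reference substitutions (ref A or G) map to the
#' category of their reverse complement, flagged as the purine form. For
#' example G>T is the purine form of C>A, and A>G the purine form of T>C.
#'
#' @param ref,alt character vectors of single bases in `{A,C,G,T}`,
#'   elementwise distinct.
#' @return a tibble with columns `category` (one of [sbs_categories()]),
#'   `pyrimidine_form` (logical), and `form` (the substitution as observed,
#'   e.g. `"G>T"`).
#' @export
classify_sbs <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (length(ref) != length(alt)) stop("ref and alt lengths differ", call. = FALSE)
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("malformed substitution: ref/alt must be single ACGT bases",
                     call. = FALSE)
  if (any(ref == alt)) stop("malformed substitution: ref == alt", call. = FALSE)
  pyr <- ref %in% c("C", "T")
  cat_ref <- ifelse(pyr, ref, unname(.base_complement[ref]))
  cat_alt <- ifelse(pyr, alt, unname(.base_complement[alt]))
  tibble::tibble(category = paste0(cat_ref, ">", cat_alt),
                 pyrimidine_form = pyr,
                 form = paste0(ref, ">", alt))
}

#' Labels of the 12 complementary forms
#'
#' @return tibble with one row per form: `category`, `pyrimidine_form`,
#'   `form` (e.g. the purine form of C>A is G>T).
#' @export
sbs_forms <- function() {
  cats <- sbs_categories()
  ref <- substr(cats, 1, 1); alt <- substr(cats, 3, 3)
  tibble::tibble(
    category = rep(cats, each = 2L),
    pyrimidine_form = rep(c(TRUE, FALSE), times = 6L),
    form = as.vector(rbind(cats, paste0(complement_base(ref), ">",
                                        complement_base(alt))))
  )
}

#' Tally the 12-cell mutation spectrum
#'
#' Counts mutations per (category, form) cell, optionally restricted to
#' records whose position falls inside an interval set (membership in the
#' merged region).
#'
#' @param mutations a mutation catalog (tibble with `chrom`, `pos`, `ref`,
#'   `alt`), e.g. from [read_mutations()].
#' @param scope optional [interval_set()]; when given, only mutations inside
#'   it are tallied.
#' @return a 12-row tibble (`category`, `pyrimidine_form`, `form`, `n`) with
#'   attribute `total`; category totals are the sum of the two form cells.
#' @export
tally_spectrum <- function(mutations, scope = NULL) {
  if (!is.null(scope) && nrow(mutations)) {
    mutations <- mutations[overlaps_region(mutations, scope), , drop = FALSE]
  }
  grid <- sbs_forms()
  if (nrow(mutations)) {
    cl <- classify_sbs(mutations$ref, mutations$alt)
    key <- paste(cl$category, cl$pyrimidine_form)
    tab <- table(factor(key, levels = paste(grid$category, grid$pyrimidine_form)))
    grid$n <- as.integer(tab)
  } else {
    grid$n <- 0L
  }
  attr(grid, "total") <- sum(grid$n)
  grid
}

#' Which mutations fall inside a region set
#'
#' A mutation at 1-based position `pos` overlaps a 0-based half-open interval
#' `[start, end)` iff `start <= pos - 1 < end`. Membership, not multiplicity:
#' duplicated or overlapping intervals count a mutation once.
#'
#' @param mutations mutation catalog tibble.
#' @param intervals an [interval_set()].
#' @return logical vector along `mutations`.
#' @export
overlaps_region <- function(mutations, intervals) {
  if (!nrow(mutations)) return(logical(0))
  if (!nrow(intervals)) return(rep(FALSE, nrow(mutations)))
  gr_mut <- GenomicRanges::GRanges(mutations$chrom,
                                   IRanges::IRanges(mutations$pos, width = 1L))
  gr_int <- GenomicRanges::reduce(as_granges(intervals), ignore.strand = TRUE)
  IRanges::overlapsAny(gr_mut, gr_int, ignore.strand = TRUE)
}
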