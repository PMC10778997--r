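#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix (any case), uppercases the remainder, and
#' unifies the mitochondrial aliases `"M"`/`"MT"` to `"MT"`, so that mutation
#' catalogs (ICGC-style, usually unprefixed) and interval annotations
#' (UCSC-style, usually `chr`-prefixed) meet on a single dialect.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names.
#' @examples
#' normalize_chrom(c("chr7", "X", "chrM", "MT"))
#' @export
normalize_chrom <- function(chrom) {
  out <- toupper(sub("^[Cc][Hh][Rr]", "", as.character(chrom)))
  out[out == "M"] <- "MT"
  out
}

#' Column mapping for mutation tables
#'
#' Describes which columns of a tab-separated somatic-mutation export hold
#' the five fields the pipeline needs. Values may be column names or
#' 1-based column indices.
#'
#' @param donor_id,chromosome,position,ref,alt column name or index.
#' @return a named list usable as the `dialect` argument of
#'   [read_mutations()].
#' @export
mutation_dialect <- function(donor_id = "donor_id", chromosome = "chromosome",
                             position = "position", ref = "ref", alt = "alt") {
  list(donor_id = donor_id, chromosome = chromosome, position = position,
       ref = ref, alt = alt)
}

#' ICGC simple-somatic-mutation column mapping
#'
#' Preset [mutation_dialect()] for the column names used by ICGC
#' `simple_somatic_mutation` exports.
#'
#' @return a dialect list for [read_mutations()].
#' @export
icgc_dialect <- function() {
  mutation_dialect(donor_id = "icgc_donor_id",
                   chromosome = "chromosome",
                   position = "chromosome_start",
                   ref = "mutated_from_allele",
                   alt = "mutated_to_allele")
}

.pick_column <- function(df, key, what) {
  if (is.numeric(key)) {
    if (key < 1 || key > ncol(df))
      stop("dialect maps '", what, "' to column ", key, " but the table has ",
           ncol(df), " columns", call. = FALSE)
    return(df[[key]])
  }
  if (!key %in% names(df))
    stop("dialect maps '", what, "' to column '", key,
         "' which is absent from the table header", call. = FALSE)
  df[[key]]
}

#' Read a somatic SBS mutation catalog
#'
#' Reads a tab-separated mutation table, keeps only single base substitutions
#' (single-character ref and alt, both in `{A,C,G,T}`, ref != alt), and
#' normalizes chromosome names with [normalize_chrom()]. Indels,
#' multi-nucleotide variants, records with non-ACGT alleles, and rows whose
#' position does not parse as a positive integer are dropped and tallied,
#' never fatal. Counts are reported on standard error and attached as
#' attributes.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect a [mutation_dialect()] mapping table columns to fields.
#' @return a tibble with columns `donor_id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`, carrying attributes `n_kept` and `n_dropped`.
#' @export
read_mutations <- function(path, dialect = mutation_dialect()) {
  if (!file.exists(path)) stop("mutation file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) {
    out <- tibble::tibble(donor_id = character(), chrom = character(),
                          pos = integer(), ref = character(), alt = character())
    attr(out, "n_kept") <- 0L
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  df <- tibble::tibble(
    donor_id = as.character(.pick_column(raw, dialect$donor_id, "donor_id")),
    chrom    = normalize_chrom(.pick_column(raw, dialect$chromosome, "chromosome")),
    pos_raw  = as.character(.pick_column(raw, dialect$position, "position")),
    ref      = toupper(as.character(.pick_column(raw, dialect$ref, "ref"))),
    alt      = toupper(as.character(.pick_column(raw, dialect$alt, "alt")))
  )
  pos <- suppressWarnings(as.integer(df$pos_raw))
  ok_pos <- !is.na(pos) & pos >= 1L
  ok_sbs <- df$ref %in% c("A", "C", "G", "T") &
    df$alt %in% c("A", "C", "G", "T") & df$ref != df$alt
  keep <- ok_pos & ok_sbs
  out <- tibble::tibble(donor_id = df$donor_id[keep], chrom = df$chrom[keep],
                        pos = pos[keep], ref = df$ref[keep], alt = df$alt[keep])
  n_drop <- sum(!keep)
  message(sprintf("[%s] read_mutations: %d records kept, %d non-SBS/malformed dropped (%s)",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), nrow(out), n_drop,
                  basename(path)))
  attr(out, "n_kept") <- nrow(out)
  attr(out, "n_dropped") <- n_drop
  out
}

#' Construct an interval set
#'
#' An interval set is a tibble of 0-based half-open genomic intervals,
#' sorted by (chrom, start, end), with a `source_label` attribute. It is the
#' package's in-memory form of a BED annotation (eRNA spans or any other
#' feature set).
#'
#' @param chrom,start,end vectors defining the intervals; `start` 0-based
#'   inclusive, `end` exclusive.
#' @param name,strand optional per-interval annotation (BED columns 4 and 6).
#' @param label source label recorded on the set.
#' @return a sorted `interval_set` tibble.
#' @export
interval_set <- function(chrom, start, end, name = NA_character_,
                         strand = NA_character_, label = "intervals") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("interval start < 0", call. = FALSE)
  bad <- which(start >= end)
  if (length(bad))
    stop("interval start >= end at row ", bad[1L], call. = FALSE)
  out <- tibble::tibble(chrom = normalize_chrom(chrom), start = start,
                        end = end,
                        name = rep_len(as.character(name), length(start)),
                        strand = rep_len(as.character(strand), length(start)))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  attr(out, "source_label") <- label
  class(out) <- c("interval_set", class(tibble::tibble()))
  out
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set '", attr(x, "source_label") %||% "?", "': ",
      nrow(x), " intervals on ", length(unique(x$chrom)),
      " chromosome(s)\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a BED3/BED6 interval file
#'
#' BED coordinates are 0-based half-open and are kept that way internally.
#' Overlapping rows are retained (no merging on read); the output is sorted
#' by (chrom, start, end). A strand column, when present (BED6), is kept for
#' optional strand-aware profiling. Lines starting with `track`, `browser`
#' or `#` are skipped.
#'
#' @param path path to a BED file.
#' @param label source label stored on the set.
#' @return an [interval_set()].
#' @export
read_bed <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(interval_set(character(), numeric(), numeric(), label = label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED row ", which(nf < 3L)[1L], " has fewer than 3 columns",
         call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("BED row ", which(is.na(start) | is.na(end))[1L],
         " has a non-numeric coordinate", call. = FALSE)
  bad <- which(start >= end)
  if (length(bad))
    stop("BED row ", bad[1L], ": start >= end (", start[bad[1L]], " >= ",
         end[bad[1L]], ")", call. = FALSE)
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""),
                   NA_character_)
  strand[!strand %in% c("+", "-")] <- NA_character_
  interval_set(chrom, start, end, name = name, strand = strand, label = label)
}

#' Write a result table as TSV
#'
#' Tab-separated UTF-8 with a header row, stable column order, and full
#' numeric precision so that a write/read round trip reproduces values to
#' well beyond 12 significant digits.
#'
#' @param x a data frame of results.
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(x)
}

#' Read back a TSV written by [write_table()]
#'
#' @param path path to a tab-separated file with a header.
#' @return a tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Convert an interval set to GRanges (1-based, closed)
#'
#' The single conversion point between the package's 0-based half-open
#' intervals and GenomicRanges' 1-based closed ranges; all interval
#' arithmetic (merging, overlap counting, binning) goes through here so the
#' off-by-one shift happens exactly once.
#'
#' @param x an [interval_set()].
#' @return a [GenomicRanges::GRanges] object.
#' @export
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(is.na(x$strand), "*", x$strand)
  )
}
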