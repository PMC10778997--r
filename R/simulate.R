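#' Configuration of a synthetic somatic-mutation cohort
#'
#' Defines everything needed to generate a reproducible cohort: synthetic
#' chromosomes, non-overlapping eRNA-like intervals, and per-donor SBS
#' catalogs whose positions follow a configurable spatial intensity around
#' the intervals. The intensity at a position x is
#' `baseline * (1 - dip_depth * g(x; mid, dip_halfwidth)
#'            + peak_height * (g(x; start, peak_halfwidth) + g(x; end, peak_halfwidth)))`
#' with `g` a triangular kernel of unit height and compact support, so the
#' injected effects provably never reach the background annulus. Strand
#' asymmetry: within `strand_window` bp of an interval midpoint, a mutation
#' is assigned the pyrimidine form with probability `0.5 + strand_beta/2`
#' downstream of the midpoint and `0.5 - strand_beta/2` upstream; elsewhere
#' the two forms are equally likely.
#'
#' @param seed integer master seed; all randomness flows from it.
#' @param n_chroms,chrom_length genome shape (chromosomes of equal length).
#' @param n_ernas number of non-overlapping intervals to place.
#' @param erna_length `(min, max)` uniform interval length in bp.
#' @param n_donors number of donors.
#' @param donor_total_median,donor_total_sigma log-normal per-donor total
#'   mutation counts (median and log-sd).
#' @param category_weights 6-vector over [sbs_categories()], summing to 1.
#'   Default: a published ovarian-donor genome-wide spectrum, normalized.
#' @param dip_depth in `[0, 1]`: relative intensity removed at the interval
#'   midpoint.
#' @param dip_halfwidth triangular kernel half-width of the dip, bp.
#' @param peak_height >= 0: relative intensity added at interval start/end.
#' @param peak_halfwidth triangular kernel half-width of the peaks, bp.
#' @param strand_beta in `[-1, 1]`: pyrimidine-form excess downstream of
#'   interval midpoints (0.3 gives a 65/35 split).
#' @param strand_window half-width (bp) of the midpoint-centred window in
#'   which the strand asymmetry applies; defaults to the 2000 bp profiling
#'   flank.
#' @param gc_fraction G+C fraction of the synthetic reference, in (0, 1).
#' @param margin bp kept interval-free at chromosome ends (and implicitly
#'   available for background annuli); must be at least the background
#'   `max_dist` you intend to use.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_chroms = 1L, chrom_length = 3e6,
                         n_ernas = 40L, erna_length = c(500, 1999),
                         n_donors = 25L,
                         donor_total_median = 3000, donor_total_sigma = 0.4,
                         category_weights = NULL,
                         dip_depth = 0, dip_halfwidth = 200,
                         peak_height = 0, peak_halfwidth = 150,
                         strand_beta = 0, strand_window = 2000,
                         gc_fraction = 0.4, margin = 50000) {
  if (is.null(category_weights)) {
    w <- c(1342, 1178, 1770, 912, 1160, 503)   # realistic genome-wide spectrum
    category_weights <- w / sum(w)
  }
  stopifnot(length(category_weights) == 6,
            abs(sum(category_weights) - 1) < 1e-9,
            all(category_weights >= 0),
            dip_depth >= 0, dip_depth <= 1, peak_height >= 0,
            strand_beta >= -1, strand_beta <= 1,
            gc_fraction > 0, gc_fraction <= 1,
            erna_length[1] >= 1, erna_length[1] <= erna_length[2])
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = chrom_length, n_ernas = as.integer(n_ernas),
                 erna_length = erna_length, n_donors = as.integer(n_donors),
                 donor_total_median = donor_total_median,
                 donor_total_sigma = donor_total_sigma,
                 category_weights = stats::setNames(category_weights,
                                                    sbs_categories()),
                 dip_depth = dip_depth, dip_halfwidth = dip_halfwidth,
                 peak_height = peak_height, peak_halfwidth = peak_halfwidth,
                 strand_beta = strand_beta, strand_window = strand_window,
                 gc_fraction = gc_fraction, margin = margin),
            class = "synth_config")
}

#' Generate synthetic reference chromosomes
#'
#' i.i.d. bases with `P(G) = P(C) = gc_fraction / 2`, deterministic under
#' the config seed. Chromosomes are named `"1"`, `"2"`, ...
#'
#' @param config a [synth_config()].
#' @return a [Biostrings::DNAStringSet].
#' @export
generate_reference <- function(config) {
  set.seed(config$seed + 101L)
  p <- c(A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
         G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2)
  seqs <- vapply(seq_len(config$n_chroms), function(i)
    paste(sample(names(p), config$chrom_length, replace = TRUE, prob = p),
          collapse = ""), "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- as.character(seq_len(config$n_chroms))
  out
}

#' Generate non-overlapping eRNA-like intervals
#'
#' Interval lengths are uniform in `erna_length`; placement is uniform
#' subject to non-overlap and a `margin` kept free at each chromosome end,
#' via a stick-breaking allotment of the free space between intervals.
#' Intervals are distributed over chromosomes proportionally to length.
#'
#' @param config a [synth_config()].
#' @return an [interval_set()] labelled `"synthetic_ernas"`.
#' @export
generate_ernas <- function(config) {
  set.seed(config$seed + 202L)
  n_per <- as.vector(table(factor(
    sample.int(config$n_chroms, config$n_ernas, replace = TRUE),
    levels = seq_len(config$n_chroms))))
  chroms <- integer(0); starts <- numeric(0); ends <- numeric(0)
  for (chr in seq_len(config$n_chroms)) {
    n <- n_per[chr]
    if (n == 0L) next
    lens <- floor(stats::runif(n, config$erna_length[1],
                               config$erna_length[2] + 1))
    usable <- config$chrom_length - 2 * config$margin
    free <- usable - sum(lens)
    if (free < 0)
      stop("requested interval density is infeasible: ", sum(lens),
           " bp of intervals in ", usable, " usable bp", call. = FALSE)
    # stick-breaking: split the free space into n + 1 gaps uniformly
    cuts <- sort(stats::runif(n, 0, free))
    gaps <- diff(c(0, cuts, free))
    s <- config$margin + cumsum(gaps[seq_len(n)]) + cumsum(c(0, lens[-n]))
    chroms <- c(chroms, rep(chr, n))
    starts <- c(starts, floor(s))
    ends <- c(ends, floor(s) + lens)
  }
  interval_set(as.character(chroms), starts, ends,
               name = sprintf("erna_%04d", seq_along(starts)),
               label = "synthetic_ernas")
}

# triangular kernel of unit height, half-width h, centred at 0
.tri_kernel <- function(d, h) pmax(0, 1 - abs(d) / h)

# per-bp relative intensity over [from, to] (0-based closed) near one interval
.interval_intensity <- function(x, start, end, config) {
  mid <- floor((start + end - 1) / 2)
  1 - config$dip_depth * .tri_kernel(x - mid, config$dip_halfwidth) +
    config$peak_height * (.tri_kernel(x - start, config$peak_halfwidth) +
                          .tri_kernel(x - (end - 1), config$peak_halfwidth))
}

#' Generate a per-donor SBS mutation catalog
#'
#' Donor totals are log-normal; positions follow the spatial intensity of
#' the config (uniform background plus compact-support dips/peaks at the
#' intervals); categories are drawn from `category_weights`; the
#' complementary form encodes the configured strand asymmetry around
#' interval midpoints; `ref`/`alt` are set from category and form, so the
#' catalog is self-consistent without a reference (use
#' [harmonize_reference()] to patch a generated reference to match).
#'
#' @param config a [synth_config()].
#' @param ernas the [interval_set()] from [generate_ernas()].
#' @return a mutation catalog tibble (`donor_id`, `chrom`, `pos`, `ref`,
#'   `alt`), 1-based positions, sorted by donor then position.
#' @export
generate_mutations <- function(config, ernas) {
  set.seed(config$seed + 303L)
  totals <- pmax(0L, round(stats::rlnorm(config$n_donors,
                                         log(config$donor_total_median),
                                         config$donor_total_sigma)))
  N <- sum(totals)
  donor_ids <- sprintf("D%03d", seq_len(config$n_donors))
  if (N == 0L)
    return(tibble::tibble(donor_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character()))
  # --- positions: two-component mixture (affected zones vs flat background)
  has_shape <- config$dip_depth > 0 || config$peak_height > 0
  genome_len <- config$n_chroms * config$chrom_length
  if (has_shape && nrow(ernas)) {
    reach <- max(config$peak_halfwidth, config$dip_halfwidth)
    zone_from <- pmax(0, ernas$start - reach)
    zone_to <- pmin(config$chrom_length - 1, ernas$end - 1 + reach)
    zone_chrom <- ernas$chrom
    zx <- unlist(lapply(seq_len(nrow(ernas)), function(i)
      zone_from[i]:zone_to[i]))
    zc <- rep(zone_chrom, zone_to - zone_from + 1)
    zw <- unlist(lapply(seq_len(nrow(ernas)), function(i)
      .interval_intensity(zone_from[i]:zone_to[i], ernas$start[i],
                          ernas$end[i], config)))
    zw <- pmax(0, zw)
    zone_len <- length(zx)
    mass_zone <- sum(zw)
    mass_bg <- genome_len - zone_len        # flat background at rate 1
    n_zone <- stats::rbinom(1L, N, mass_zone / (mass_zone + mass_bg))
    idx <- sample.int(zone_len, n_zone, replace = TRUE, prob = zw)
    pos_zone <- zx[idx]; chrom_zone <- zc[idx]
    bg <- .sample_background(N - n_zone, config, zone_chrom, zone_from, zone_to)
    pos0 <- c(pos_zone, bg$pos)
    chrom <- c(chrom_zone, bg$chrom)
    ord <- sample.int(length(pos0))        # interleave components
    pos0 <- pos0[ord]; chrom <- chrom[ord]
  } else {
    chrom_i <- sample.int(config$n_chroms, N, replace = TRUE)
    chrom <- as.character(chrom_i)
    pos0 <- floor(stats::runif(N, 0, config$chrom_length))
  }
  # --- category and form
  category <- sample(sbs_categories(), N, replace = TRUE,
                     prob = config$category_weights)
  p_pyr <- rep(0.5, N)
  if (config$strand_beta != 0 && nrow(ernas)) {
    mids <- focal_points(ernas, "midpoint")
    occ <- focal_offsets(tibble::tibble(chrom = chrom, pos = pos0 + 1),
                         mids, flank = config$strand_window)
    occ <- occ[!duplicated(occ$mut_idx), , drop = FALSE]  # nearest-window tie-break
    downstream <- occ$offset >= 0
    p_pyr[occ$mut_idx[downstream]] <- 0.5 + config$strand_beta / 2
    p_pyr[occ$mut_idx[!downstream]] <- 0.5 - config$strand_beta / 2
  }
  pyr <- stats::runif(N) < p_pyr
  ref_p <- substr(category, 1, 1); alt_p <- substr(category, 3, 3)
  ref <- ifelse(pyr, ref_p, complement_base(ref_p))
  alt <- ifelse(pyr, alt_p, complement_base(alt_p))
  out <- tibble::tibble(donor_id = rep(donor_ids, totals),
                        chrom = chrom, pos = as.integer(pos0 + 1),
                        ref = ref, alt = alt)
  out[order(out$donor_id, out$chrom, out$pos), , drop = FALSE]
}

# n uniform background draws outside the affected zones (rejection sampling)
.sample_background <- function(n, config, zone_chrom, zone_from, zone_to) {
  pos <- integer(0); chrom <- character(0)
  if (n <= 0) return(list(pos = pos, chrom = chrom))
  zr <- split(IRanges::IRanges(zone_from + 1, zone_to + 1), zone_chrom)
  while (length(pos) < n) {
    m <- ceiling((n - length(pos)) * 1.3) + 10L
    ci <- as.character(sample.int(config$n_chroms, m, replace = TRUE))
    px <- floor(stats::runif(m, 0, config$chrom_length))
    drop <- logical(m)
    for (chr in names(zr)) {
      sel <- ci == chr
      if (any(sel))
        drop[sel] <- IRanges::overlapsAny(IRanges::IRanges(px[sel] + 1, px[sel] + 1),
                                          zr[[chr]])
    }
    pos <- c(pos, px[!drop]); chrom <- c(chrom, ci[!drop])
  }
  list(pos = pos[seq_len(n)], chrom = chrom[seq_len(n)])
}

#' Patch a reference so mutated sites carry the catalog's ref base
#'
#' Overwrites the base at every mutated position with the catalog's `ref`
#' allele, so that downstream composition profiling and classification see a
#' consistent genome.
#'
#' @param reference a [Biostrings::DNAStringSet].
#' @param mutations a mutation catalog tibble.
#' @return the patched DNAStringSet; attribute `n_patched` counts rewritten
#'   bases.
#' @export
harmonize_reference <- function(reference, mutations) {
  n_patched <- 0L
  for (chr in intersect(unique(mutations$chrom), names(reference))) {
    sel <- mutations$chrom == chr & !duplicated(paste(mutations$chrom,
                                                      mutations$pos))
    at <- IRanges::IRanges(mutations$pos[sel], width = 1L)
    cur <- as.character(Biostrings::extractAt(reference[[chr]], at))
    diff <- cur != mutations$ref[sel]
    if (any(diff)) {
      reference[[chr]] <- Biostrings::replaceAt(
        reference[[chr]], at[diff],
        as(mutations$ref[sel][diff], "DNAStringSet"))
      n_patched <- n_patched + sum(diff)
    }
  }
  attr(reference, "n_patched") <- n_patched
  reference
}

#' Simulate a full cohort
#'
#' Convenience wrapper: intervals plus mutation catalog (and optionally a
#' harmonized reference) from one config.
#'
#' @param config a [synth_config()].
#' @param with_reference also generate and harmonize a reference? Default
#'   `FALSE` (sequence is only needed for composition profiling).
#' @return list with `config`, `ernas`, `mutations`, and optionally
#'   `reference`.
#' @export
simulate_cohort <- function(config, with_reference = FALSE) {
  ernas <- generate_ernas(config)
  mutations <- generate_mutations(config, ernas)
  out <- list(config = config, ernas = ernas, mutations = mutations)
  if (with_reference)
    out$reference <- harmonize_reference(generate_reference(config), mutations)
  out
}

#' Per-replicate configs for a null batch
#'
#' Derives `n_replicates` independent sub-seeds deterministically from the
#' master seed and returns one config per replicate with every effect
#' parameter (dip, peaks, strand asymmetry) zeroed. Materialize each with
#' [simulate_cohort()]; keeping the batch as configs makes 500-replicate
#' null studies memory-flat.
#'
#' @param config the template [synth_config()].
#' @param n_replicates number of replicates (>= 1).
#' @return list of `synth_config`, one per replicate.
#' @export
generate_null_batch <- function(config, n_replicates) {
  stopifnot(n_replicates >= 1)
  set.seed(config$seed + 404L)
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    cfg$dip_depth <- 0; cfg$peak_height <- 0; cfg$strand_beta <- 0
    cfg
  })
}

#' Write a cohort to disk in the pipeline's on-disk dialects
#'
#' Mutations as a TSV consumable by [read_mutations()], intervals as BED6,
#' the reference (if present) as FASTA, and the resolved config (including
#' the seed) as a flat key-value file.
#'
#' @param cohort a list from [simulate_cohort()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mut <- cohort$mutations
  write_table(tibble::tibble(donor_id = mut$donor_id, chromosome = mut$chrom,
                             position = mut$pos, ref = mut$ref, alt = mut$alt),
              file.path(dir, "mutations.tsv"))
  bed <- cohort$ernas
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", bed$chrom, bed$start, bed$end,
                     ifelse(is.na(bed$name), ".", bed$name),
                     ifelse(is.na(bed$strand), ".", bed$strand)),
             file.path(dir, "ernas.bed"))
  if (!is.null(cohort$reference))
    Biostrings::writeXStringSet(cohort$reference,
                                file.path(dir, "reference.fa"))
  cfg <- cohort$config
  flat <- vapply(cfg, function(v) paste(format(v, digits = 15), collapse = ","), "")
  writeLines(paste0(names(cfg), "=", flat), file.path(dir, "config.txt"))
  invisible(dir)
}
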