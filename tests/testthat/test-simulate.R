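test_that("generate_reference honours gc_fraction and the seed", {
  cfg <- synth_config(seed = 51, chrom_length = 1e6, gc_fraction = 0.4)
  ref <- generate_reference(cfg)
  gc <- Biostrings::letterFrequency(ref[[1]], "GC", as.prob = TRUE)
  expect_lt(abs(gc - 0.4), 0.002)     # 3 binomial s.e. at n = 1e6
  expect_identical(as.character(generate_reference(cfg)[[1]]),
                   as.character(ref[[1]]))

  all_gc <- generate_reference(synth_config(seed = 52, chrom_length = 1e4,
                                            gc_fraction = 1))
  expect_equal(unname(Biostrings::letterFrequency(all_gc[[1]], "GC")), 1e4)
})

test_that("generate_ernas places disjoint, size-bounded, reproducible intervals", {
  cfg <- synth_config(seed = 53, n_ernas = 100, chrom_length = 1e7,
                      erna_length = c(500, 1999))
  iv <- generate_ernas(cfg)
  expect_equal(nrow(iv), 100L)
  expect_equal(region_size(iv), sum(iv$end - iv$start))   # disjoint
  expect_true(all(diff(iv$start) > 0))
  expect_equal(nrow(filter_by_size(iv, 2000)), 100L)
  expect_true(all(iv$start >= cfg$margin))
  expect_true(all(iv$end <= cfg$chrom_length - cfg$margin))
  expect_equal(generate_ernas(cfg), iv)

  too_dense <- synth_config(seed = 54, n_ernas = 200, chrom_length = 3e5,
                            margin = 1000, erna_length = c(1500, 1999))
  expect_error(generate_ernas(too_dense), "infeasible")
})

test_that("generated catalogs recover the configured category mixture", {
  cfg <- synth_config(seed = 55, n_ernas = 10, chrom_length = 1e6,
                      margin = 20000, n_donors = 10, donor_total_median = 1500)
  coh <- simulate_cohort(cfg)
  expect_gt(nrow(coh$mutations), 10000)
  tal <- tally_spectrum(coh$mutations)
  by_cat <- tapply(tal$n, tal$category, sum)[sbs_categories()]
  n <- sum(by_cat)
  for (k in seq_len(6)) {
    w <- cfg$category_weights[k]
    se <- sqrt(w * (1 - w) / n)
    expect_lt(abs(by_cat[k] / n - w), 3.5 * se)
  }
  # forms are balanced genome-wide when strand_beta = 0
  pyr_frac <- sum(tal$n[tal$pyrimidine_form]) / n
  expect_lt(abs(pyr_frac - 0.5), 3.5 * sqrt(0.25 / n))
})

test_that("the injected strand asymmetry gives the expected downstream form split", {
  cfg <- synth_config(seed = 56, n_ernas = 60, chrom_length = 4e6,
                      margin = 20000, n_donors = 10, donor_total_median = 8000,
                      strand_beta = 0.3)
  coh <- simulate_cohort(cfg)
  mids <- focal_points(coh$ernas, "midpoint")
  occ <- focal_offsets(coh$mutations, mids, flank = 2000)
  cl <- classify_sbs(coh$mutations$ref[occ$mut_idx],
                     coh$mutations$alt[occ$mut_idx])
  down <- occ$offset >= 0
  se_d <- sqrt(0.65 * 0.35 / sum(down))
  se_u <- sqrt(0.65 * 0.35 / sum(!down))
  expect_lt(abs(mean(cl$pyrimidine_form[down]) - 0.65), 3.5 * se_d)
  expect_lt(abs(mean(cl$pyrimidine_form[!down]) - 0.35), 3.5 * se_u)
})

test_that("the injected midpoint dip halves the intensity at the focal base", {
  cfg <- synth_config(seed = 57, n_ernas = 60, chrom_length = 4e6,
                      margin = 20000, n_donors = 10, donor_total_median = 12000,
                      dip_depth = 0.5, dip_halfwidth = 200)
  coh <- simulate_cohort(cfg)
  pts <- focal_points(coh$ernas, "midpoint")
  # narrow bins so the central bin sits inside the kernel's deepest part
  prof <- bin_counts(coh$mutations, pts, bin_grid(2000, 20))
  cnt <- category_bin_counts(prof, "all")
  central <- mean(cnt[c(100, 101)])       # offsets [-20, 20)
  baseline <- mean(cnt[c(1:40, 161:200)]) # outside the kernel support
  expect_lt(abs(central / baseline - 0.525), 0.12)  # triangular-kernel mean
})

test_that("null configurations are spatially flat and pipelines run on empty catalogs", {
  cfg <- synth_config(seed = 58, n_ernas = 40, chrom_length = 3e6,
                      n_donors = 10, donor_total_median = 4000)
  coh <- simulate_cohort(cfg)
  prof <- bin_counts(coh$mutations, focal_points(coh$ernas, "midpoint"))
  cnt <- category_bin_counts(prof, "all")
  # flat within Poisson noise: chi-square goodness of fit, generous threshold
  expect_gt(chisq.test(cnt)$p.value, 1e-4)

  empty_cfg <- synth_config(seed = 59, n_donors = 3, donor_total_median = 0)
  coh0 <- simulate_cohort(empty_cfg)
  expect_equal(nrow(coh0$mutations), 0L)
  dir <- withr::local_tempdir()
  write_cohort(coh0, dir)
  suppressMessages(back <- read_mutations(file.path(dir, "mutations.tsv")))
  expect_equal(nrow(back), 0L)
})

test_that("null batches derive distinct reproducible seeds with zeroed effects", {
  cfg <- synth_config(seed = 60, dip_depth = 0.5, peak_height = 1,
                      strand_beta = 0.3)
  batch <- generate_null_batch(cfg, 10)
  seeds <- vapply(batch, `[[`, 1L, "seed")
  expect_equal(length(unique(seeds)), 10L)
  expect_equal(vapply(generate_null_batch(cfg, 10), `[[`, 1L, "seed"), seeds)
  expect_true(all(vapply(batch, function(b)
    b$dip_depth == 0 && b$peak_height == 0 && b$strand_beta == 0, TRUE)))
})

test_that("written cohorts round-trip through the package readers with zero drops", {
  cfg <- synth_config(seed = 61, n_ernas = 10, chrom_length = 5e5,
                      margin = 10000, n_donors = 4, donor_total_median = 300,
                      strand_beta = 0.2)
  coh <- simulate_cohort(cfg, with_reference = TRUE)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  suppressMessages(m <- read_mutations(file.path(dir, "mutations.tsv")))
  expect_equal(attr(m, "n_dropped"), 0L)
  expect_equal(nrow(m), nrow(coh$mutations))
  expect_equal(m$pos, coh$mutations$pos)
  iv <- read_bed(file.path(dir, "ernas.bed"))
  expect_equal(iv$start, coh$ernas$start)
  expect_equal(iv$end, coh$ernas$end)

  # harmonized reference carries the catalog's ref base at every mutated site
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  names(ref) <- normalize_chrom(names(ref))
  idx <- sample.int(nrow(m), 50)
  for (i in idx) {
    base <- as.character(Biostrings::subseq(ref[[m$chrom[i]]], m$pos[i], m$pos[i]))
    expect_equal(base, m$ref[i])
  }
})
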