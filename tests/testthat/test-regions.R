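test_that("focal points use the last-covered-base conventions", {
  iv <- interval_set("1", 100, 300)
  expect_equal(focal_points(iv, "start")$position, 100)
  expect_equal(focal_points(iv, "end")$position, 299)
  expect_equal(focal_points(iv, "midpoint")$position, 199)  # floor((100+299)/2)

  single <- interval_set("1", 100, 101)
  for (a in c("start", "midpoint", "end"))
    expect_equal(focal_points(single, a)$position, 100)
  expect_error(focal_points(iv[0, ], "start"), "empty")
})

test_that("region_size merges before summing and is subadditive", {
  expect_equal(region_size(interval_set("1", c(0, 50), c(100, 150))), 150)
  expect_equal(region_size(interval_set(c("1", "2"), c(0, 0), c(100, 100))), 200)
  expect_equal(region_size(interval_set("1", 5, 6)[0, ]), 0)

  set.seed(42)
  for (i in 1:20) {
    a <- random_interval_set(sample(1:20, 1))
    b <- random_interval_set(sample(1:20, 1))
    u <- interval_set(c(a$chrom, b$chrom), c(a$start, b$start), c(a$end, b$end))
    expect_gte(region_size(a) + region_size(b), region_size(u))
  }
})

test_that("filter_by_size uses a strict cutoff", {
  iv <- interval_set("1", c(0, 3000, 7000), c(1999, 5000, 9001))
  kept <- filter_by_size(iv, 2000)
  expect_equal(kept$end - kept$start, 1999)
  expect_equal(nrow(filter_by_size(iv, 10000)), 3L)
  expect_equal(nrow(filter_by_size(iv[0, ], 2000)), 0L)
})

test_that("pairwise overlap proportions are row-normalized and match per-base counting", {
  a <- interval_set("1", 0, 100, label = "a")
  b <- interval_set("1", 50, 150, label = "b")
  m <- pairwise_overlap(list(a = a, b = b))
  expect_equal(m["a", "b"], 0.5)
  expect_equal(m["a", "a"], 1)
  expect_equal(pairwise_overlap(list(x = a, y = a))["x", "y"], 1)
  disj <- interval_set("1", 500, 600)
  expect_equal(pairwise_overlap(list(a = a, d = disj))["a", "d"], 0)

  # empty set rows/columns are missing, not zero
  m2 <- pairwise_overlap(list(a = a, e = a[0, ]))
  expect_true(is.na(m2["a", "e"]) && is.na(m2["e", "e"]))

  # asymmetric proportion vs brute-force membership on random sets
  set.seed(7)
  for (i in 1:25) {
    x <- random_interval_set(sample(1:50, 1))
    y <- random_interval_set(sample(1:50, 1))
    m3 <- pairwise_overlap(list(x = x, y = y))
    expect_equal(m3["x", "y"], brute_overlap_prop(x, y))
    expect_equal(m3["y", "x"], brute_overlap_prop(y, x))
  }

  # jaccard mode is symmetric
  mj <- pairwise_overlap(list(a = a, b = b), mode = "jaccard")
  expect_equal(mj["a", "b"], mj["b", "a"])
  expect_equal(mj["a", "b"], 50 / 150)
})

test_that("nucleotide_profile reports per-offset base fractions around focal points", {
  ref <- Biostrings::DNAStringSet(c("1" = strrep("G", 200),
                                    "2" = strrep("A", 200),
                                    "3" = strrep("T", 200)))
  pts <- tibble::tibble(chrom = "1", position = 100, anchor = "midpoint",
                        strand = NA_character_)
  prof <- nucleotide_profile(pts, ref, flank = 10)
  expect_true(all(prof$G == 1))
  expect_true(all(prof$GC + prof$AT == 1))

  # complementary homopolymers average to 0.5/0.5
  pts2 <- tibble::tibble(chrom = c("2", "3"), position = 100,
                         anchor = "midpoint", strand = NA_character_)
  prof2 <- nucleotide_profile(pts2, ref, flank = 10)
  expect_true(all(prof2$A == 0.5 & prof2$T == 0.5))
  expect_true(all(prof2$n == 2))

  # window truncated at the chromosome edge drops out of the denominator
  pts3 <- tibble::tibble(chrom = "1", position = 3, anchor = "start",
                         strand = NA_character_)
  prof3 <- nucleotide_profile(pts3, ref, flank = 10)
  expect_equal(prof3$n[prof3$offset < -3], rep(0L, 7))
  expect_true(all(is.na(prof3$G[prof3$offset < -3])))
  expect_true(all(prof3$G[prof3$offset >= -3] == 1))

  # unknown chromosome skipped with a warning
  pts4 <- tibble::tibble(chrom = c("1", "99"), position = 100,
                         anchor = "midpoint", strand = NA_character_)
  expect_warning(nucleotide_profile(pts4, ref, flank = 5), "skipped")
})

test_that("strand-aware profiling flips minus-strand windows", {
  # chromosome: A at offset +1 from position 100 on the plus strand
  seqs <- rep("C", 200); seqs[102] <- "A"   # 1-based 102 = 0-based 101
  ref <- Biostrings::DNAStringSet(c("1" = paste(seqs, collapse = "")))
  plus <- tibble::tibble(chrom = "1", position = 100, anchor = "start",
                         strand = "+")
  minus <- tibble::tibble(chrom = "1", position = 100, anchor = "start",
                          strand = "-")
  p_plus <- nucleotide_profile(plus, ref, flank = 5, strand_aware = TRUE)
  p_minus <- nucleotide_profile(minus, ref, flank = 5, strand_aware = TRUE)
  expect_equal(p_plus$A[p_plus$offset == 1], 1)
  # flipped: base complemented (A -> T) and offset negated
  expect_equal(p_minus$T[p_minus$offset == -1], 1)
})
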