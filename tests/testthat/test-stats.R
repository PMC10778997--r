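test_that("poisson_background recovers the rate of a homogeneous process", {
  set.seed(21)
  r <- 0.01                      # mutations per bp
  chrom_len <- 400000
  n_mut <- rpois(1, r * chrom_len)
  m <- make_catalog("1", sample.int(chrom_len, n_mut, replace = TRUE))
  # points placed so both annuli (even the enlarged one) fit the chromosome
  pts <- tibble::tibble(chrom = "1", position = c(110000, 290000),
                        anchor = "midpoint", strand = NA_character_)
  grid <- bin_grid()
  bg <- poisson_background(m, pts, "all", grid, bg_window = c(5000, 50000))
  lambda_expect <- r * grid$bin_width * nrow(pts)
  se <- sqrt(bg$n_background) * grid$bin_width / (2 * 45000)
  expect_lt(abs(bg$lambda_bg - lambda_expect), 3 * se)
  expect_false(bg$pseudo_count)

  # enlarging the annulus leaves the rate unchanged within sampling error
  bg2 <- poisson_background(m, pts, "all", grid, bg_window = c(5000, 90000))
  expect_lt(abs(bg2$lambda_bg - lambda_expect),
            3 * sqrt(bg2$n_background) * grid$bin_width / (2 * 85000))

  # empty annulus falls back to the flagged pseudo-count
  far <- make_catalog("1", 399999)
  bg3 <- poisson_background(far, pts[1, ], "all", grid,
                            bg_window = c(5000, 20000))
  expect_true(bg3$pseudo_count)
  expect_equal(bg3$lambda_bg, 0.5 * 100 / (2 * 15000))

  expect_error(poisson_background(m, pts, "all", grid, c(1000, 50000)),
               "min_dist")
})

test_that("detect_peak_dip tests the extreme bins against the Poisson tails", {
  grid <- bin_grid()
  forms <- sbs_forms()
  mk_prof <- function(cnt) {
    counts <- matrix(0L, 12, grid$n_bins, dimnames = list(forms$form, NULL))
    counts["C>A", ] <- as.integer(cnt)
    structure(list(grid = grid, anchor = "midpoint", n_focal = 10L,
                   counts = counts, mpkm = NULL, counting = "per_occurrence"),
              class = "density_profile")
  }
  # flat at round(lambda): no calls
  flat <- detect_peak_dip(mk_prof(rep(10, 40)), lambda_bg = 10, "C>A")
  expect_true(all(flat$direction == "none"))

  # one bin at 30 against lambda 10: upper tail below 1e-5
  cnt <- rep(10, 40); cnt[31] <- 30
  res <- detect_peak_dip(mk_prof(cnt), lambda_bg = 10, "C>A")
  peak <- res[res$candidate == "peak", ]
  # independent tail sum: P(X >= 30 | 10) via direct term summation
  p_oracle <- sum(exp(-10 + (30:200) * log(10) - lgamma((30:200) + 1)))
  expect_equal(peak$p_nominal, p_oracle, tolerance = 1e-12)
  expect_lt(peak$p_nominal, 1e-5)
  expect_equal(peak$direction, "peak")
  expect_equal(peak$bin, 30L)

  # one empty bin against lambda 20: lower tail is exp(-20)
  cnt2 <- rep(20, 40); cnt2[1] <- 0
  res2 <- detect_peak_dip(mk_prof(cnt2), lambda_bg = 20, "C>A")
  dip <- res2[res2$candidate == "dip", ]
  expect_equal(dip$p_nominal, exp(-20), tolerance = 1e-12)
  expect_equal(dip$direction, "dip")
})

test_that("the strand-bias Wilcoxon matches full sign enumeration", {
  # identical form vectors: vacuous test
  same <- profile_from_forms(rep(1:5, 4), rep(1:5, 4))
  res <- strand_bias_test(same, "C>T", "whole")
  expect_equal(res$p, 1)
  expect_equal(res$n_informative, 0L)

  # 20 bins, all differences positive and distinct: p = 2 * 2^-20
  set.seed(31)
  x <- 10 + runif(20); y <- x - runif(20, 0.1, 1)
  prof <- profile_from_forms(x, y)
  res20 <- strand_bias_test(prof, "C>T", "whole")
  expect_equal(res20$p, 2 * 2^-20, tolerance = 1e-12)
  expect_equal(res20$p, enum_signrank_p(x - y), tolerance = 1e-12)

  # textbook 3-difference case {+3, +2, -1}: 8-case enumeration
  p3 <- enum_signrank_p(c(3, 2, -1))
  prof3 <- profile_from_forms(c(4, 3, 1, 0, 0, 0), c(1, 1, 2, 0, 0, 0))
  res3 <- strand_bias_test(prof3, "C>T", "left")
  expect_equal(res3$n_informative, 3L)
  expect_equal(res3$p, p3, tolerance = 1e-12)

  # random tie-free cases, n <= 10, exact path vs enumeration
  for (i in 1:20) {
    n <- sample(2:10, 1)
    d <- runif(n, -1, 1)
    x <- abs(d) + 1; y <- x - d
    prof_i <- profile_from_forms(c(x, rep(0, n)), c(y, rep(0, n)))
    res_i <- strand_bias_test(prof_i, "C>T", "left")
    expect_equal(res_i$p, enum_signrank_p(d), tolerance = 1e-12)
  }
})

test_that("large-sample strand tests use the corrected normal approximation", {
  set.seed(32)
  n <- 30                                   # informative n > 25
  d <- runif(n, -1, 1)
  x <- abs(d) + 1; y <- x - d
  prof <- profile_from_forms(c(x, rep(0, n)), c(y, rep(0, n)))
  res <- strand_bias_test(prof, "C>T", "left")
  ref <- wilcox.test(x[1:n], y[1:n], paired = TRUE, exact = FALSE,
                     correct = TRUE)
  expect_equal(res$p, ref$p.value)
  expect_equal(res$n_informative, n)
})

test_that("bh_adjust implements the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(33)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))   # monotone in raw p
  }
})

test_that("strand_bias_scan pools BH across categories and regions", {
  set.seed(34)
  cfg <- synth_config(seed = 99, n_ernas = 15, chrom_length = 8e5,
                      margin = 20000, n_donors = 5, donor_total_median = 1500)
  coh <- simulate_cohort(cfg)
  pts <- focal_points(coh$ernas, "midpoint")
  prof <- normalize_mpkm(bin_counts(coh$mutations, pts), nrow(coh$mutations))
  sb <- strand_bias_scan(prof)
  expect_equal(nrow(sb), 18L)
  expect_equal(sb$p_adjusted, bh_adjust(sb$p))
  expect_true(all(sb$p_adjusted >= sb$p))
})
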