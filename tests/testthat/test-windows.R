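test_that("W&C variance components match an independent implementation", {
  # fixed difference, equal sizes: all variance among populations
  v <- site_variance_components(c(4, 0, 0), c(4, 8, 0))
  expect_equal(v[["a"]] / sum(v), 1)
  # identical frequencies and het rates: no among-population variance
  v2 <- site_variance_components(c(6, 6, 2), c(6, 6, 2))
  expect_lte(v2[["a"]], 0)
  # a small-counts case against the textbook oracle
  v3 <- site_variance_components(c(4, 2, 2), c(4, 6, 2))
  o3 <- wc_oracle(4, 0.25, 0.5, 4, 0.75, 0.5)
  expect_equal(unname(v3), unname(o3), tolerance = 1e-12)
  # random instances
  set.seed(14)
  for (i in 1:100) {
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    d1 <- sample(0:(2 * n1), 1); d2 <- sample(0:(2 * n2), 1)
    h1 <- sample(0:min(n1, d1, 2 * n1 - d1), 1)
    h2 <- sample(0:min(n2, d2, 2 * n2 - d2), 1)
    got <- site_variance_components(c(n1, d1, h1), c(n2, d2, h2))
    want <- wc_oracle(n1, d1 / (2 * n1), h1 / n1, n2, d2 / (2 * n2), h2 / n2)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("window FST is the ratio of summed components", {
  # all fixed differences -> 1
  comp <- lapply(1:3, function(i) site_variance_components(c(4, 0, 0),
                                                           c(4, 8, 0)))
  a <- vapply(comp, `[`, 0, 1); b <- vapply(comp, `[`, 0, 2)
  cc <- vapply(comp, `[`, 0, 3)
  expect_equal(window_fst(a, b, cc), 1)
  # single site equals the per-site ratio; 3 hand-built sites equal the
  # hand-computed ratio of sums
  s1 <- site_variance_components(c(5, 3, 1), c(5, 7, 3))
  s2 <- site_variance_components(c(5, 1, 1), c(5, 2, 2))
  s3 <- site_variance_components(c(5, 5, 3), c(5, 5, 1))
  expect_equal(window_fst(s1[1], s1[2], s1[3]), unname(s1[1] / sum(s1)))
  expect_equal(window_fst(c(s1[1], s2[1], s3[1]), c(s1[2], s2[2], s3[2]),
                          c(s1[3], s2[3], s3[3])),
               unname((s1[1] + s2[1] + s3[1]) /
                        (sum(s1) + sum(s2) + sum(s3))))
  expect_true(is.nan(window_fst(numeric(), numeric(), numeric())))
})

test_that("windowed pi matches arithmetic and the pairwise oracle", {
  # x = 2 alt among 4 chromosomes in a 100 kb window
  expect_equal(window_pi(2, 4, 1e5), (2 * 2 * 2) / (4 * 3) / 1e5)
  expect_equal(window_pi(c(0, 0), c(8, 8), 1e4), 0)
  set.seed(31)
  gt <- matrix(sample(c(0:2, NA), 30, replace = TRUE), 10, 3)
  alt <- rowSums(gt, na.rm = TRUE)
  chroms <- 2 * rowSums(!is.na(gt))
  expect_equal(window_pi(alt, chroms, 500), pi_oracle(gt, 500),
               tolerance = 1e-12)
})

test_that("dxy matches the brute-force pair-counting oracle", {
  # 10 sites, one fixed difference, 2 diploids per deme: 4/40
  gt <- matrix(0L, 10, 4)
  gt[1, 3:4] <- 2L
  expect_equal(window_dxy(c(0, rep(0, 9)), rep(4, 10),
                          c(2 * 2, rep(0, 9)), rep(4, 10)), 0.1)
  expect_equal(dxy_oracle(gt, 2), 0.1)
  # identical demes -> 0
  expect_equal(window_dxy(c(1, 2), c(4, 4), c(1, 2), c(4, 4)) == 0, FALSE)
  expect_equal(window_dxy(rep(0, 5), rep(4, 5), rep(0, 5), rep(4, 5)), 0)
  # random windows with missing data
  set.seed(17)
  for (i in 1:40) {
    gt <- matrix(sample(c(0:2, NA), 6 * 5, replace = TRUE), 6, 5)
    n_a <- 3
    a1 <- rowSums(gt[, 1:n_a, drop = FALSE], na.rm = TRUE)
    c1 <- 2 * rowSums(!is.na(gt[, 1:n_a, drop = FALSE]))
    a2 <- rowSums(gt[, -(1:n_a), drop = FALSE], na.rm = TRUE)
    c2 <- 2 * rowSums(!is.na(gt[, -(1:n_a), drop = FALSE]))
    got <- window_dxy(a1, c1, a2, c2)
    want <- dxy_oracle(gt, n_a)
    if (is.nan(want)) expect_true(is.nan(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("dxy responds to invariant sites exactly as documented", {
  a1 <- c(2, 0); c1 <- c(4, 4); a2 <- c(4, 0); c2 <- c(4, 4)
  base <- window_dxy(a1, c1, a2, c2)
  # an invariant site with no genotyped individuals changes nothing
  expect_equal(window_dxy(c(a1, 0), c(c1, 0), c(a2, 0), c(c2, 0)), base)
  # a genotyped invariant site grows the denominator and lowers dxy
  expect_lt(window_dxy(c(a1, 0), c(c1, 4), c(a2, 0), c(c2, 4)), base)
})

test_that("windows tile chromosomes and respect min_snps", {
  ds <- small_sim()
  gm <- apply_maf_filter(
    filter_sites_and_samples(mask_low_confidence_genotypes(ds$gm_all) |>
                               (\(m) gm_subset(m, sites = which(!is.na(m$sites$alt))))()),
    0.05)
  w <- scan_windows(gm, NULL, window_size = 1e5, min_snps = 5,
                    chrom_lengths = c(chr01 = 250000, chr02 = 250000,
                                      chr03 = 250000))
  w1 <- w[w$chrom == "chr01", ]
  expect_equal(w1$start, c(1L, 100001L, 200001L))
  expect_equal(w1$end, c(100000L, 200000L, 250000L))
  expect_true(all(w$usable == (w$n_snps >= 5 & is.finite(w$fst))))
})

test_that("outlier windows use the type-7 95th percentile with >= ties", {
  w <- tibble::tibble(chrom = "c", start = 1:100, end = 1:100,
                      n_snps = 10L, fst = as.numeric(1:100),
                      pi_a = 0, pi_b = 0, dxy = 0, usable = TRUE)
  class(w) <- c("window_scan", class(w))
  out <- outlier_windows(w)
  expect_equal(attr(out, "fst_threshold"), 95.05)
  expect_equal(sum(out$outlier), 5)
  # all-equal FST: the threshold equals the common value, all flagged
  w$fst <- rep(0.5, 100)
  out2 <- outlier_windows(w)
  expect_equal(sum(out2$outlier), 100)
  expect_error(outlier_windows(w[1:10, ]), "too few")
})

test_that("spearman test uses average ranks and the t approximation", {
  expect_equal(spearman_test(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_test(1:10, -(1:10))$rho, -1)
  # 6-point case with a tie, against hand-computed average ranks
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 2, 1, 5, 4, 6) # ranks: 2.5, 2.5, 1, 5, 4, 6
  got <- spearman_test(x, y)
  want <- cor(rank(x), rank(y))
  expect_equal(got$rho, want, tolerance = 1e-12)
  expect_warning(res <- spearman_test(rep(1, 6), 1:6), "constant")
  expect_true(is.nan(res$rho))
  expect_error(spearman_test(1:3, 1:3), "at least 4")
})
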