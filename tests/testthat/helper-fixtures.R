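# Shared fixture builders. Everything is generated in code at test time.

# hand-built two-species genotype matrix; rows are sites, columns samples
toy_gm <- function(gt, gq = NULL, dp = NULL, n_a = NULL) {
  gt <- as.matrix(gt)
  n <- ncol(gt)
  if (is.null(n_a)) n_a <- ceiling(n / 2)
  samples <- tibble::tibble(
    sample = sprintf("S%02d", seq_len(n)),
    species = rep(c("A", "B"), c(n_a, n - n_a)),
    population = rep(c("A1", "B1"), c(n_a, n - n_a))
  )
  sites <- tibble::tibble(chrom = "chr1", pos = seq_len(nrow(gt)) * 10L,
                          ref = "A", alt = "T")
  geno_matrix(gt, sites, samples, gq = gq, dp = dp)
}

# small simulated study used across files (built once per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lay <- rad_layout(n_chrom = 3, chrom_length = 1.5e5, loci_per_chrom = 15,
                        locus_length = 300, divergent_chroms = 1L)
      truth <- demographic_params(500, 500, 500, 3000, 300, 10,
                                  mmj = 0.005, mjm = 0.05)
      cfg <- sim_config(lay, model_spec("SCS"), truth,
                        samples_per_deme = c(12, 8), theta_per_locus = 5,
                        n_pops = c(3, 2), seed = 421L)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})

# fold a site's joint allele counts into an SFS by brute force (oracle-side)
scaled_truth <- function() {
  demographic_params(500, 500, 500, 3000, 300, 10, mmj = 0.005, mjm = 0.05)
}

# observed joint SFS from freshly simulated loci (no missingness, full
# projection); mirrors how a variants-only matrix feeds the SFS
sim_obs_sfs <- function(truth, model, n_loci = 2000, n_hap = c(20, 10),
                        theta = 5) {
  trees <- lapply(seq_len(n_loci), function(i)
    sample_locus_genealogy(truth, model, n_hap))
  mL <- mean(vapply(trees, total_branch_length, 0))
  u <- matrix(0, n_hap[1] + 1, n_hap[2] + 1)
  for (tr in trees) {
    m <- genotypes_from_genealogy(tr, theta, 300, mean_L = mL)
    for (cs in m$carriers) {
      d1 <- sum(cs <= n_hap[1]); d2 <- length(cs) - d1
      u[d1 + 1, d2 + 1] <- u[d1 + 1, d2 + 1] + 1
    }
  }
  joint_sfs(divergescan:::fold_joint_sfs(u), n_hap)
}

# independent Weir & Cockerham (1984) two-population oracle, written from the
# textbook formulas with explicit scalars (no code shared with the package)
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# brute-force HWE exact test by direct enumeration of genotype configurations
hwe_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  if (min(nA, 2 * n - nA) == 0) return(1)
  hets <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- sapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) - (lchoose(2 * n, nA)))
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAB, hets)] + 1e-12])
}

# brute-force dxy: count differing allele pairs across demes site by site
dxy_oracle <- function(gt, n_a) {
  tot_d <- 0; tot_p <- 0
  for (i in seq_len(nrow(gt))) {
    a <- gt[i, seq_len(n_a)]; b <- gt[i, -seq_len(n_a)]
    ca <- unlist(lapply(a[!is.na(a)], function(g) c(g >= 1, g >= 2)))
    cb <- unlist(lapply(b[!is.na(b)], function(g) c(g >= 1, g >= 2)))
    for (x in ca) for (y in cb) {
      tot_p <- tot_p + 1
      if (x != y) tot_d <- tot_d + 1
    }
  }
  if (tot_p == 0) NaN else tot_d / tot_p
}

# brute-force pi: mean pairwise difference over all chromosome pairs in one
# deme, per bp
pi_oracle <- function(gt, window_len) {
  tot <- 0
  for (i in seq_len(nrow(gt))) {
    g <- gt[i, ]
    al <- unlist(lapply(g[!is.na(g)], function(x) c(x >= 1, x >= 2)))
    n <- length(al)
    if (n < 2) next
    d <- 0
    for (j in seq_len(n - 1)) for (k in (j + 1):n)
      if (al[j] != al[k]) d <- d + 1
    tot <- tot + d / choose(n, 2)
  }
  tot / window_len
}

# exhaustive per-deme projection vector from genotypes (NULL if too few
# genotyped chromosomes)
project_or_null <- function(g, n) {
  g <- g[!is.na(g)]
  chroms <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
  D <- length(chroms)
  if (D < n) return(NULL)
  subs <- utils::combn(D, n)
  out <- numeric(n + 1)
  for (j in seq_len(ncol(subs))) {
    k <- sum(chroms[subs[, j]])
    out[k + 1] <- out[k + 1] + 1
  }
  out / ncol(subs)
}

# exhaustive projection oracle: average the subsampled SFS over every
# chromosome subset of size n (site level)
project_oracle <- function(d, D, n) {
  chroms <- c(rep(1, d), rep(0, D - d))
  subs <- utils::combn(D, n)
  out <- numeric(n + 1)
  for (j in seq_len(ncol(subs))) {
    k <- sum(chroms[subs[, j]])
    out[k + 1] <- out[k + 1] + 1
  }
  out / ncol(subs)
}
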