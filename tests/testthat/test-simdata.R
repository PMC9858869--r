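test_that("layout validation enforces the documented invariants", {
  chroms <- tibble::tibble(chrom = "c1", length = 1000L)
  loci <- tibble::tibble(chrom = "c1", start = c(1L, 200L), length = 100L)
  expect_s3_class(genome_layout(chroms, loci), "genome_layout")
  # overlapping loci rejected
  bad <- tibble::tibble(chrom = "c1", start = c(1L, 50L), length = 100L)
  expect_error(genome_layout(chroms, bad), "overlap")
  # divergent region outside the chromosome rejected
  reg <- tibble::tibble(chrom = "c1", start = 900L, end = 1200L,
                        mode = "barrier")
  expect_error(genome_layout(chroms, loci, reg), "inside")
})

test_that("pairwise TMRCA matches the 2N coalescent expectation", {
  set.seed(101)
  p <- demographic_params(1000, 1000, 1000, 1e9)
  m <- model_spec("SI")
  tm <- replicate(4000, max(sample_locus_genealogy(p, m, c(2, 0))$time))
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2000), 3 * se)
})

test_that("IM with zero migration reproduces SI TMRCA behaviour", {
  p_si <- demographic_params(300, 300, 300, 800)
  p_im <- demographic_params(300, 300, 300, 800, mmj = 0, mjm = 0)
  set.seed(55)
  t_si <- replicate(400, max(sample_locus_genealogy(p_si, model_spec("SI"),
                                                    c(4, 4))$time))
  set.seed(55)
  t_im <- replicate(400, max(sample_locus_genealogy(p_im, model_spec("IM"),
                                                    c(4, 4))$time))
  # same RNG stream and identical dynamics: identical trees
  expect_identical(t_si, t_im)
})

test_that("mutation dropping respects topology and locus bounds", {
  set.seed(7)
  p <- demographic_params(500, 500, 500, 2000)
  tr <- sample_locus_genealogy(p, model_spec("SI"), c(4, 4))
  # theta -> 0: no variant sites
  m0 <- genotypes_from_genealogy(tr, 1e-9, 100)
  expect_equal(length(m0$position), 0)
  # dosage rows sum to the carrier count and positions are distinct
  set.seed(8)
  m <- genotypes_from_genealogy(tr, 20, 500)
  expect_equal(rowSums(m$dosage), lengths(m$carriers))
  expect_equal(anyDuplicated(m$position), 0)
  # a mutation on a terminal branch yields exactly one heterozygote
  n_leaf_mut <- vapply(m$carriers, length, 0L) == 1
  if (any(n_leaf_mut)) {
    row <- m$dosage[which(n_leaf_mut)[1], ]
    expect_equal(sum(row == 1), 1)
    expect_equal(sum(row), 1)
  }
  # more mutations than positions errors
  set.seed(9)
  expect_error(genotypes_from_genealogy(tr, 1e5, 3), "more mutations")
})

test_that("simulated datasets are internally consistent", {
  ds <- small_sim()
  gm <- ds$gm_all
  # REF at every site equals the FASTA base
  idx <- seq(1, n_sites(gm), by = 37)
  fa <- vapply(idx, function(k)
    as.character(Biostrings::subseq(ds$reference[[gm$sites$chrom[k]]],
                                    gm$sites$pos[k], gm$sites$pos[k])), "")
  expect_identical(fa, gm$sites$ref[idx])
  # positions strictly increasing within chromosomes
  for (ch in unique(gm$sites$chrom))
    expect_true(all(diff(gm$sites$pos[gm$sites$chrom == ch]) > 0))
  # every variant site maps to exactly one locus and one region label
  tt <- ds$truth
  expect_equal(nrow(tt$sites), n_sites(ds$gm))
  expect_true(all(!is.na(tt$sites$locus)))
  expect_true(all(tt$sites$region %in% c("none", "barrier", "barrier+linked")))
  # ALT differs from REF at variant sites
  expect_true(all(ds$gm$sites$alt != ds$gm$sites$ref))
})

test_that("write_dataset is byte-identical under a fixed seed", {
  lay <- rad_layout(n_chrom = 2, chrom_length = 4e4, loci_per_chrom = 6,
                    locus_length = 200, divergent_chroms = 1L)
  cfg <- sim_config(lay, model_spec("SCS"), scaled_truth(),
                    samples_per_deme = c(6, 4), n_pops = c(2, 2), seed = 33L)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  write_dataset(cfg, d1)
  write_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("deep isolation produces more diagnostic sites than migration", {
  # paired comparison under identical seeds: an SI history with a deep split
  # versus an IM history with strong gene flow
  p_si <- demographic_params(400, 400, 400, 8000)
  p_im <- demographic_params(400, 400, 400, 8000, mmj = 0.01, mjm = 0.01)
  frac_diag <- function(p, model, seed) {
    set.seed(seed)
    n_diag <- 0; n_tot <- 0
    for (i in 1:150) {
      tr <- sample_locus_genealogy(p, model, c(8, 6))
      m <- genotypes_from_genealogy(tr, 4, 300)
      for (cs in m$carriers) {
        n_tot <- n_tot + 1
        d1 <- sum(cs <= 8); d2 <- length(cs) - d1
        if ((d1 == 8 && d2 == 0) || (d1 == 0 && d2 == 6))
          n_diag <- n_diag + 1
      }
    }
    n_diag / max(n_tot, 1)
  }
  expect_gt(frac_diag(p_si, model_spec("SI"), 71),
            frac_diag(p_im, model_spec("IM"), 71))
})

test_that("dxy/pi grows with split time under SI", {
  # simulation means over a T_S grid: between-deme divergence accumulates
  # while within-deme diversity stays at its 4N-mu scale
  ratio_at <- function(TS, seed) {
    p <- demographic_params(300, 300, 300, TS)
    set.seed(seed)
    btw <- 0; wth <- 0
    for (i in 1:200) {
      tr <- sample_locus_genealogy(p, model_spec("SI"), c(4, 4))
      m <- genotypes_from_genealogy(tr, 5, 300)
      for (cs in m$carriers) {
        d1 <- sum(cs <= 4); d2 <- length(cs) - d1
        btw <- btw + d1 * (4 - d2) + (4 - d1) * d2
        wth <- wth + d1 * (4 - d1) + d2 * (4 - d2)
      }
    }
    btw / max(wth, 1)
  }
  r <- vapply(c(500, 2000, 8000), ratio_at, 0, seed = 91)
  expect_true(all(diff(r) > 0))
})
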