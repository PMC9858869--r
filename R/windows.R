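#' Weir-Cockerham variance components at one site
#'
#' The among-population (a), among-individual-within-population (b) and
#' within-individual (c) components of allele-frequency variance for r = 2
#' populations, from sample sizes, ALT allele counts and heterozygote
#' counts. Sites need at least two genotyped individuals per deme.
#'
#' @param deme_a,deme_b length-3 numeric vectors
#'   `(n_ind, alt_allele_count, het_count)` for the two demes.
#' @return named numeric vector `c(a, b, c)`.
#' @export
site_variance_components <- function(deme_a, deme_b) {
  comp <- wc_components(matrix(deme_a[1]), matrix(deme_a[2]), matrix(deme_a[3]),
                        matrix(deme_b[1]), matrix(deme_b[2]), matrix(deme_b[3]))
  c(a = comp$a[1], b = comp$b[1], c = comp$c[1])
}

# vectorized W&C (1984) components for r = 2; inputs are per-site vectors of
# genotyped individual counts, ALT allele counts and het counts per deme
wc_components <- function(n1, d1, h1, n2, d2, h2) {
  r <- 2
  p1 <- d1 / (2 * n1); p2 <- d2 / (2 * n2)
  hb1 <- h1 / n1; hb2 <- h2 / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * hb1 + n2 * hb2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# per-site W&C components for a two-species geno_matrix; sites with < 2
# genotyped individuals in either deme get NA
site_wc_components <- function(gm) {
  idx <- species_index(gm)
  stats_for <- function(cols) {
    g <- gm$gt[, cols, drop = FALSE]
    list(n = rowSums(!is.na(g)), d = rowSums(g, na.rm = TRUE),
         h = rowSums(g == 1L, na.rm = TRUE))
  }
  s1 <- stats_for(idx[[1]]); s2 <- stats_for(idx[[2]])
  comp <- wc_components(s1$n, s1$d, s1$h, s2$n, s2$d, s2$h)
  bad <- s1$n < 2 | s2$n < 2
  comp$a[bad] <- NA_real_; comp$b[bad] <- NA_real_; comp$c[bad] <- NA_real_
  comp
}

#' Windowed Weir-Cockerham FST (ratio of sums)
#'
#' `sum(a) / sum(a + b + c)` over the usable sites of a window; negative
#' values are preserved. `NaN` when the denominator is zero.
#'
#' @param a,b,c per-site variance components (NAs skipped).
#' @return numeric scalar.
#' @export
window_fst <- function(a, b, c) {
  ok <- is.finite(a) & is.finite(b) & is.finite(c)
  if (!any(ok)) return(NaN)
  den <- sum(a[ok] + b[ok] + c[ok])
  if (den == 0) return(NaN)
  sum(a[ok]) / den
}

#' Windowed nucleotide diversity (per bp)
#'
#' `sum(2 x (n - x) / (n (n - 1))) / window_len` over variant sites, where
#' `x` is the ALT chromosome count among `n` genotyped chromosomes in the
#' deme — i.e. the unbiased per-site heterozygosity averaged over the window
#' length, with only variant sites contributing to the numerator.
#'
#' @param alt,chroms per-site ALT and genotyped chromosome counts.
#' @param window_len window length in bp (> 0).
#' @return numeric scalar (0 for an empty window).
#' @export
window_pi <- function(alt, chroms, window_len) {
  stopifnot(window_len > 0)
  ok <- chroms >= 2
  if (!any(ok)) return(0)
  x <- alt[ok]; n <- chroms[ok]
  sum(2 * x * (n - x) / (n * (n - 1))) / window_len
}

#' Windowed absolute divergence dxy
#'
#' Missing-data-aware estimator: the number of differing between-deme allele
#' pairs summed over sites, divided by the number of compared pairs summed
#' over sites. Pairs are formed only among genotyped chromosomes, so missing
#' data is excluded rather than imputed, and invariant sites contribute to
#' the denominator — which is why this needs all-sites input.
#'
#' @param alt1,chroms1,alt2,chroms2 per-site ALT and genotyped chromosome
#'   counts in the two demes (all sites of the window, invariant included).
#' @return numeric scalar in `[0, 1]`; `NaN` when no pairs are comparable.
#' @export
window_dxy <- function(alt1, chroms1, alt2, chroms2) {
  diffs <- alt1 * (chroms2 - alt2) + (chroms1 - alt1) * alt2
  pairs <- chroms1 * chroms2
  tp <- sum(pairs)
  if (tp == 0) return(NaN)
  sum(diffs) / tp
}

window_bounds <- function(chrom_len, window_size) {
  starts <- seq(1L, chrom_len, by = window_size)
  tibble::tibble(start = as.integer(starts),
                 end = as.integer(pmin(starts + window_size - 1L, chrom_len)))
}

#' Sliding-window divergence landscape scan
#'
#' Tiles each chromosome with non-overlapping fixed-width windows and
#' computes, per window: SNP count, Weir-Cockerham FST (ratio of sums),
#' per-species nucleotide diversity from the variant matrix, and dxy from
#' the all-sites matrix. Windows with fewer than `min_snps` SNPs are kept
#' but flagged unusable for FST-based outlier calling.
#'
#' @param gm filtered variant [geno_matrix()] (two species).
#' @param gm_all all-sites [geno_matrix()] on the same reference; `NULL`
#'   skips dxy.
#' @param window_size window width in bp (default 100 kb).
#' @param min_snps minimum SNPs for a usable window (default 5).
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   largest observed position per chromosome.
#' @return a `window_scan` tibble: chrom, start, end, n_snps, fst, pi_a,
#'   pi_b, dxy, usable.
#' @export
scan_windows <- function(gm, gm_all = NULL, window_size = 1e5, min_snps = 5,
                         chrom_lengths = NULL) {
  idx <- species_index(gm)
  if (length(idx) != 2) stop("exactly two species required", call. = FALSE)
  if (is.unsorted(order(gm$sites$chrom, gm$sites$pos)))
    stop("unsorted variant input", call. = FALSE)
  comp <- site_wc_components(gm)
  ca <- site_allele_counts(gm, idx[[1]])
  cb <- site_allele_counts(gm, idx[[2]])
  if (!is.null(gm_all)) {
    idx2 <- species_index(gm_all)
    aa <- site_allele_counts(gm_all, idx2[[1]])
    ab <- site_allele_counts(gm_all, idx2[[2]])
  }
  chroms <- unique(gm$sites$chrom)
  if (is.null(chrom_lengths)) {
    pos_src <- if (!is.null(gm_all)) gm_all$sites else gm$sites
    chrom_lengths <- tapply(pos_src$pos, pos_src$chrom, max)
    chrom_lengths <- chrom_lengths[chroms]
    names(chrom_lengths) <- chroms
  }
  out <- list()
  for (ch in chroms) {
    wb <- window_bounds(chrom_lengths[[ch]], window_size)
    v_idx <- which(gm$sites$chrom == ch)
    vw <- findInterval(gm$sites$pos[v_idx], wb$start)
    if (!is.null(gm_all)) {
      a_idx <- which(gm_all$sites$chrom == ch)
      aw <- findInterval(gm_all$sites$pos[a_idx], wb$start)
    }
    res <- purrr::map_dfr(seq_len(nrow(wb)), function(w) {
      vi <- v_idx[vw == w]
      fst <- window_fst(comp$a[vi], comp$b[vi], comp$c[vi])
      wl <- wb$end[w] - wb$start[w] + 1L
      pi_a <- window_pi(ca$alt[vi], ca$chroms[vi], wl)
      pi_b <- window_pi(cb$alt[vi], cb$chroms[vi], wl)
      dxy <- NA_real_
      if (!is.null(gm_all)) {
        ai <- a_idx[aw == w]
        dxy <- window_dxy(aa$alt[ai], aa$chroms[ai], ab$alt[ai], ab$chroms[ai])
      }
      tibble::tibble(chrom = ch, start = wb$start[w], end = wb$end[w],
                     n_snps = length(vi), fst = fst, pi_a = pi_a,
                     pi_b = pi_b, dxy = dxy)
    })
    out[[ch]] <- res
  }
  res <- dplyr::bind_rows(out)
  res$usable <- res$n_snps >= min_snps & is.finite(res$fst)
  class(res) <- c("window_scan", class(res))
  res
}

#' Flag outlier (highly divergent) windows
#'
#' The FST threshold is the empirical `q`-quantile (type 7, linear
#' interpolation) over usable windows; windows with `fst >= threshold` are
#' flagged, so under ties all tied windows are flagged.
#'
#' @param stats a `window_scan` tibble.
#' @param q quantile (default 0.95, the 95th percentile).
#' @param min_windows minimum number of usable windows required.
#' @return the tibble with an added `outlier` column and the threshold in
#'   `attr(, "fst_threshold")`.
#' @export
outlier_windows <- function(stats, q = 0.95, min_windows = 20) {
  usable <- stats$usable & is.finite(stats$fst)
  if (sum(usable) < min_windows)
    stop("too few usable windows (", sum(usable), ") for outlier calling",
         call. = FALSE)
  thr <- quantile(stats$fst[usable], q, type = 7, names = FALSE)
  stats$outlier <- usable & stats$fst >= thr
  attr(stats, "fst_threshold") <- thr
  stats
}

#' Spearman rank correlation test
#'
#' Average ranks for ties and the large-sample t approximation for the
#' p-value (via [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped
#'   (n >= 4 required).
#' @return tibble (rho, p_value, n).
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: rho undefined")
    return(tibble::tibble(rho = NaN, p_value = NaN, n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
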