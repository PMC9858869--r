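#' Pairwise r-squared within chromosomes
#'
#' r2 is the squared Pearson correlation of diploid dosages over
#' pairwise-complete individuals (the standard genotype-correlation LD
#' estimator for unphased data). Pairs where either site is monomorphic
#' among the shared genotyped individuals, or with fewer than 3 shared
#' individuals, get `NA`.
#'
#' @param gm a [geno_matrix()]; use `species` to restrict to one deme.
#' @param species optional species label to subset samples.
#' @param max_dist only report pairs at or below this distance (bp).
#' @return tibble (chrom, pos_i, pos_j, dist, r2).
#' @export
pairwise_r2 <- function(gm, species = NULL, max_dist = NULL) {
  if (!is.null(species))
    gm <- gm_subset(gm, samples = which(gm$samples$species == species))
  out <- list()
  for (ch in unique(gm$sites$chrom)) {
    si <- which(gm$sites$chrom == ch)
    if (length(si) < 2) next
    g <- t(gm$gt[si, , drop = FALSE]) # individuals x sites
    cc <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))
    r2 <- cc^2
    called <- !is.na(g)
    shared <- crossprod(called) # shared individuals per pair
    r2[shared < 3] <- NA_real_
    pos <- gm$sites$pos[si]
    pr <- which(upper.tri(r2), arr.ind = TRUE)
    tb <- tibble::tibble(chrom = ch,
                         pos_i = pos[pr[, 1]], pos_j = pos[pr[, 2]],
                         dist = abs(pos[pr[, 2]] - pos[pr[, 1]]),
                         r2 = r2[pr])
    if (!is.null(max_dist)) tb <- tb[tb$dist <= max_dist, ]
    out[[ch]] <- tb
  }
  dplyr::bind_rows(out)
}

#' Hill-Weir expectation of r-squared under drift and recombination
#'
#' `E[r2] = (10 + C) / ((2 + C)(11 + C)) *
#'   (1 + ((3 + C)(12 + 12C + C^2)) / (n (2 + C)(11 + C)))`
#' where `C` is the population recombination parameter (rho times distance)
#' and `n` the sample size (chromosome count). Decreases from about 0.45 at
#' `C = 0` (large n) toward the sampling floor `1/n`.
#'
#' @param C non-negative numeric (vectorized).
#' @param n sample size (>= 2).
#' @return numeric vector.
#' @export
hill_weir_expectation <- function(C, n) {
  stopifnot(all(C >= 0), n >= 2)
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir LD decay curve
#'
#' Bins pair distances (mean r2 per bin, taming heteroskedasticity), then
#' least-squares fits `hill_weir_expectation(rho * dist, n)` over
#' `rho >= 0`. The background r2 level is the mean among pairs beyond the
#' `far_quantile` distance quantile, and the decay distance is the smallest
#' distance where the fitted curve comes within `epsilon` of background.
#'
#' @param pairs tibble from [pairwise_r2()] (needs `dist` and `r2`).
#' @param n sample size (chromosome count) for the Hill-Weir formula.
#' @param bin_width distance bin width in bp.
#' @param far_quantile distance quantile defining "background" pairs.
#' @param epsilon convergence band around the background level.
#' @param min_pairs minimum number of finite pairs required.
#' @return an `ld_decay_fit`: rho_per_bp, n, background_r2,
#'   decay_distance_bp, epsilon, sse, no_decay flag and the binned data.
#' @export
fit_ld_decay <- function(pairs, n, bin_width = 100, far_quantile = 0.9,
                         epsilon = 0.005, min_pairs = 50) {
  d <- pairs[is.finite(pairs$r2) & is.finite(pairs$dist), ]
  if (nrow(d) < min_pairs)
    stop("need at least ", min_pairs, " finite pairs", call. = FALSE)
  d$bin <- (d$dist %/% bin_width) * bin_width + bin_width / 2
  binned <- dplyr::summarise(dplyr::group_by(d, .data$bin),
                             r2 = mean(.data$r2), n_pairs = dplyr::n(),
                             .groups = "drop")
  far_cut <- quantile(d$dist, far_quantile, names = FALSE)
  background <- mean(d$r2[d$dist >= far_cut])
  rho0 <- 2 / stats::median(d$dist)
  fit <- tryCatch(
    minpack.lm::nlsLM(r2 ~ hill_weir_expectation(rho * bin, n),
                      data = data.frame(binned, n = n),
                      start = list(rho = rho0), lower = 0,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("LD decay fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  rho <- unname(stats::coef(fit)[["rho"]])
  sse <- sum(stats::residuals(fit)^2)
  no_decay <- rho <= 1e-12
  decay_d <- if (no_decay) Inf else {
    grid <- exp(seq(log(1), log(max(d$dist) * 10), length.out = 4000))
    diffs <- abs(hill_weir_expectation(rho * grid, n) - background)
    hit <- which(diffs <= epsilon)
    if (length(hit)) grid[hit[1]] else Inf
  }
  structure(list(rho_per_bp = rho, n = n, background_r2 = background,
                 decay_distance_bp = decay_d, epsilon = epsilon, sse = sse,
                 no_decay = no_decay, binned = binned,
                 far_cutoff = far_cut),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<ld_decay_fit> rho = %.3g /bp, n = %d, background r2 = %.4f, decay at %.0f bp\n",
    x$rho_per_bp, x$n, x$background_r2, x$decay_distance_bp))
  invisible(x)
}

#' @rdname fit_ld_decay
#' @param x an `ld_decay_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.ld_decay_fit <- function(x, ...) {
  tibble::tibble(term = c("rho_per_bp", "background_r2", "decay_distance_bp"),
                 estimate = c(x$rho_per_bp, x$background_r2,
                              x$decay_distance_bp))
}

#' @rdname fit_ld_decay
#' @exportS3Method generics::glance
#' @export
glance.ld_decay_fit <- function(x, ...) {
  tibble::tibble(rho_per_bp = x$rho_per_bp, n = x$n,
                 background_r2 = x$background_r2,
                 decay_distance_bp = x$decay_distance_bp, sse = x$sse,
                 no_decay = x$no_decay)
}

#' Full LD matrix for one chromosome and one species
#'
#' Symmetric r2 matrix over the chromosome's sites, ordered by position.
#' Sites monomorphic within the species get entirely-NA rows and columns
#' (the "white lines" convention of LD heatmaps); polymorphic sites have 1
#' on the diagonal.
#'
#' @param gm a [geno_matrix()].
#' @param chrom chromosome name.
#' @param species species label.
#' @return numeric matrix with positions as dimnames.
#' @export
ld_matrix <- function(gm, chrom, species) {
  gm <- gm_subset(gm, sites = which(gm$sites$chrom == chrom),
                  samples = which(gm$samples$species == species))
  ord <- order(gm$sites$pos)
  gm <- gm_subset(gm, sites = ord)
  g <- t(gm$gt)
  mono <- apply(g, 2, function(v) length(unique(v[!is.na(v)])) < 2)
  cc <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))
  m <- cc^2
  diag(m) <- 1
  m[mono, ] <- NA_real_
  m[, mono] <- NA_real_
  dimnames(m) <- list(gm$sites$pos, gm$sites$pos)
  m
}

#' Write an LD matrix as TSV with a positions header
#' @param m matrix from [ld_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(m, path) {
  df <- data.frame(pos = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}
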