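#' Filtering configuration
#'
#' Defaults mirror a standard RADseq cascade: genotypes kept only with GQ and
#' DP strictly greater than 5; sites kept when genotyped in at least 80% of
#' individuals; samples dropped when more than 80% missing; the main SNP set
#' additionally requires MAF > 0.05, with no HWE filter.
#'
#' @param min_gq,min_dp strict lower thresholds: genotypes with GQ <= min_gq
#'   or DP <= min_dp are set to missing.
#' @param site_call_rate minimum fraction of genotyped individuals per site.
#' @param max_sample_missing samples with a missing fraction strictly above
#'   this are dropped.
#' @param maf minor-allele-frequency threshold (strict >); ignored when
#'   `maf_mode = "none"`.
#' @param maf_mode `"0.05"`, `"0.01"` or `"none"`.
#' @param hwe_mode `"off"`, `"all_pops"` (drop sites violating HWE in every
#'   sampled population) or `"half_pops"` (in at least half of them).
#' @param hwe_alpha HWE exact-test significance level.
#' @param call_rate_scope `"global"` (call rate over all individuals) or
#'   `"per_species"` (drop only sites below the threshold in *both* species).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_gq = 5, min_dp = 5, site_call_rate = 0.8,
                          max_sample_missing = 0.8, maf = 0.05,
                          maf_mode = c("0.05", "0.01", "none"),
                          hwe_mode = c("off", "all_pops", "half_pops"),
                          hwe_alpha = 0.05,
                          call_rate_scope = c("global", "per_species")) {
  maf_mode <- match.arg(maf_mode)
  maf <- switch(maf_mode, "0.05" = 0.05, "0.01" = 0.01, "none" = NA_real_)
  stopifnot(min_gq >= 0, min_dp >= 0,
            site_call_rate >= 0, site_call_rate <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1,
            hwe_alpha >= 0, hwe_alpha <= 1)
  structure(list(min_gq = min_gq, min_dp = min_dp,
                 site_call_rate = site_call_rate,
                 max_sample_missing = max_sample_missing,
                 maf = maf, maf_mode = maf_mode,
                 hwe_mode = match.arg(hwe_mode), hwe_alpha = hwe_alpha,
                 call_rate_scope = match.arg(call_rate_scope)),
            class = "filter_config")
}

#' Mask low-confidence genotype calls
#'
#' Sets genotypes with `GQ <= min_gq` or `DP <= min_dp` to missing. The
#' thresholds are strict: a genotype exactly at the threshold fails.
#'
#' @param gm a [geno_matrix()] carrying GQ and DP matrices.
#' @param min_gq,min_dp thresholds (default 5).
#' @return the masked `geno_matrix`.
#' @export
mask_low_confidence_genotypes <- function(gm, min_gq = 5, min_dp = 5) {
  if (is.null(gm$gq)) stop("geno_matrix has no GQ annotation", call. = FALSE)
  if (is.null(gm$dp)) stop("geno_matrix has no DP annotation", call. = FALSE)
  bad <- (!is.na(gm$gq) & gm$gq <= min_gq) | (!is.na(gm$dp) & gm$dp <= min_dp)
  gm$gt[bad] <- NA_integer_
  gm
}

#' Site and sample missingness filters
#'
#' Drops sites below the call-rate threshold, then samples with too much
#' missing data (in that order; a single pass). With
#' `call_rate_scope = "per_species"` a site is dropped only when its call
#' rate is below threshold in both species. Sites that are monomorphic after
#' masking are retained (the SFS/dxy path needs them); the MAF step removes
#' them from the SNP path.
#'
#' @param gm a (typically masked) [geno_matrix()].
#' @param config a [filter_config()].
#' @return a filtered `geno_matrix`.
#' @export
filter_sites_and_samples <- function(gm, config = filter_config()) {
  called <- !is.na(gm$gt)
  if (config$call_rate_scope == "global") {
    keep_site <- rowMeans(called) >= config$site_call_rate
  } else {
    idx <- species_index(gm)
    rates <- vapply(idx, function(j) rowMeans(called[, j, drop = FALSE]),
                    numeric(nrow(gm$gt)))
    keep_site <- apply(rates >= config$site_call_rate, 1, any)
  }
  if (!any(keep_site)) stop("all data filtered: no site passes the call-rate filter",
                            call. = FALSE)
  gm <- gm_subset(gm, sites = which(keep_site))
  miss <- colMeans(is.na(gm$gt))
  keep_sample <- miss <= config$max_sample_missing
  if (!any(keep_sample)) stop("all data filtered: no sample passes", call. = FALSE)
  gm_subset(gm, samples = which(keep_sample))
}

#' Pooled minor-allele-frequency filter
#'
#' MAF is computed on the pooled sample over genotyped individuals only;
#' sites with MAF strictly greater than `maf` are retained (monomorphic
#' sites therefore drop out). Marks the result as MAF-filtered.
#'
#' @param gm a [geno_matrix()].
#' @param maf threshold; `NA` keeps all polymorphic sites.
#' @return a `geno_matrix` with `maf_filtered = TRUE`.
#' @export
apply_maf_filter <- function(gm, maf = 0.05) {
  ac <- site_allele_counts(gm, seq_len(n_samples(gm)))
  p <- ifelse(ac$chroms > 0, ac$alt / ac$chroms, 0)
  m <- pmin(p, 1 - p)
  keep <- if (is.na(maf)) m > 0 else m > maf
  out <- gm_subset(gm, sites = which(keep))
  out$maf_filtered <- TRUE
  out
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: conditional on the minor-allele count, the
#' probability of each compatible heterozygote count is
#' `n! 2^nAB / (nAA! nAB! nBB!) / choose(2n, nA)`, and the p-value sums the
#' probabilities of all outcomes no more likely than the observed one.
#' Degenerate inputs (monomorphic) return 1.
#'
#' @param n_homref,n_het,n_homalt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  n <- n_homref + n_het + n_homalt
  if (n < 1) stop("at least one genotype required", call. = FALSE)
  nA <- 2 * n_homref + n_het
  nB <- 2 * n_homalt + n_het
  n_minor <- min(nA, nB)
  if (n_minor == 0) return(1)
  het_vals <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(het_vals, function(h) {
    lgamma(n + 1) + h * log(2) - lgamma((nA - h) / 2 + 1) -
      lgamma(h + 1) - lgamma((nB - h) / 2 + 1) - lchoose(2 * n, nA)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, het_vals)]
  sum(p[p <= obs + 1e-12])
}

# per-population HWE violation matrix: TRUE where p < alpha
hwe_violations <- function(gm, alpha) {
  pops <- split(seq_len(n_samples(gm)), gm$samples$population)
  viol <- matrix(FALSE, n_sites(gm), length(pops),
                 dimnames = list(NULL, names(pops)))
  for (j in seq_along(pops)) {
    g <- gm$gt[, pops[[j]], drop = FALSE]
    n0 <- rowSums(g == 0L, na.rm = TRUE)
    n1 <- rowSums(g == 1L, na.rm = TRUE)
    n2 <- rowSums(g == 2L, na.rm = TRUE)
    for (i in seq_len(nrow(g))) {
      if (n0[i] + n1[i] + n2[i] >= 1) {
        pv <- hwe_exact_test(n0[i], n1[i], n2[i])
        viol[i, j] <- pv < alpha
      }
    }
  }
  viol
}

#' The six alternative SNP dataset variants
#'
#' From a genotype-masked (but not yet site/sample-filtered) matrix,
#' produces the main dataset and the five alternatives used to probe the
#' sensitivity of the divergence landscape to filtering choices:
#' \describe{
#'   \item{main}{global 80% call rate, MAF > 0.05, no HWE filter}
#'   \item{per_species_call_rate}{call rate applied per species}
#'   \item{maf01}{MAF > 0.01}
#'   \item{no_maf}{no MAF filter (polymorphic sites only)}
#'   \item{hwe_all_pops}{main minus sites violating HWE in every population}
#'   \item{hwe_half_pops}{main minus sites violating HWE in at least half
#'     of the populations}
#' }
#'
#' @param gm masked [geno_matrix()] whose samples carry population labels.
#' @param hwe_alpha significance level for the HWE exact test.
#' @return named list of six `geno_matrix` objects.
#' @export
make_dataset_variants <- function(gm, hwe_alpha = 0.05) {
  if (length(unique(gm$samples$population)) < 2)
    stop("population labels (beyond species) required for the HWE variants",
         call. = FALSE)
  base_g <- filter_sites_and_samples(gm, filter_config())
  base_s <- filter_sites_and_samples(
    gm, filter_config(call_rate_scope = "per_species"))
  main <- apply_maf_filter(base_g, 0.05)
  viol <- hwe_violations(main, hwe_alpha)
  n_pops <- ncol(viol)
  all_bad <- rowSums(viol) == n_pops
  half_bad <- rowSums(viol) >= ceiling(n_pops / 2)
  list(
    main = main,
    per_species_call_rate = apply_maf_filter(base_s, 0.05),
    maf01 = apply_maf_filter(base_g, 0.01),
    no_maf = apply_maf_filter(base_g, NA),
    hwe_all_pops = gm_subset(main, sites = which(!all_bad)),
    hwe_half_pops = gm_subset(main, sites = which(!half_bad))
  )
}
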