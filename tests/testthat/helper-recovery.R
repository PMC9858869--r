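# The demographic recovery study shared by the acceptance tests: 20
# datasets simulated under the scaled secondary-contact-with-stop truth
# (N = 500, T_S = 3000, T_1 = 300, T_2 = 10, strong asymmetric migration),
# 2000 loci at projection (20, 10); all five models fitted to each with the
# scale anchored at N_pma (the composite likelihood on polymorphic-site
# proportions is invariant to joint rescaling, see the methods vignette).
recovery_search <- function() {
  search_config(n_restarts = 1, n_loci = 400, polish_n_loci = 3000,
                final_n_loci = 1e4, maxit = 70, polish_maxit = 25,
                n_polish = 2, refine_maxit = 20,
                size_bounds = c(10, 1e5), time_bounds = c(1, 1e5),
                mig_bounds = c(1e-8, 0.5))
}

recovery_study <- local({
  cache <- NULL
  function(n_reps = 20) {
    if (!is.null(cache)) return(cache)
    truth <- scaled_truth()
    search <- recovery_search()
    best <- character(n_reps)
    ests <- vector("list", n_reps)
    scs_fits <- vector("list", n_reps)
    for (rep in seq_len(n_reps)) {
      set.seed(1000 + rep)
      obs <- sim_obs_sfs(truth, model_spec("SCS"))
      fits <- fit_all_models(obs, search = search, eval_seed = 1000 + rep,
                             fixed = list(N_pma = truth$N_pma))
      cmp <- compare_models(fits)
      best[rep] <- attr(cmp, "best")
      ests[[rep]] <- tidy(fits$SCS)
      scs_fits[[rep]] <- fits$SCS
    }
    cache <<- list(truth = truth, best = best, ests = ests,
                   scs_fits = scs_fits)
    cache
  }
})

# one simulated landscape replicate: a small genome with one planted
# barrier+linked region, filtered and scanned
landscape_replicate <- function(seed, n_chrom = 4, loci_per_chrom = 20) {
  lay <- rad_layout(n_chrom = n_chrom, chrom_length = 1.5e5,
                    loci_per_chrom = loci_per_chrom, locus_length = 300,
                    divergent_chroms = 1L, region_frac = 0.3,
                    region_mode = "barrier+linked")
  cfg <- sim_config(lay, model_spec("SCS"), scaled_truth(),
                    samples_per_deme = c(15, 10), theta_per_locus = 5,
                    n_pops = c(3, 2), seed = seed)
  ds <- simulate_dataset(cfg)
  masked <- mask_low_confidence_genotypes(ds$gm_all)
  var_gm <- gm_subset(masked, sites = which(!is.na(masked$sites$alt)))
  base <- filter_sites_and_samples(var_gm)
  main <- apply_maf_filter(base, 0.05)
  all_f <- gm_subset(masked, samples = match(base$samples$sample,
                                             masked$samples$sample))
  w <- scan_windows(main, all_f, window_size = 3e4, min_snps = 3,
                    chrom_lengths = setNames(lay$chromosomes$length,
                                             lay$chromosomes$chrom))
  w <- outlier_windows(w, min_windows = 10)
  region <- lay$divergent_regions
  w$planted <- w$chrom == region$chrom[1] & w$end >= region$start[1] &
    w$start <= region$end[1]
  list(ds = ds, main = main, windows = w, region = region)
}
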