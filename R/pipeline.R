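build_sim_config <- function(sim, seed) {
  layout <- rad_layout(
    n_chrom = sim$n_chrom %||% 6, chrom_length = sim$chrom_length %||% 3e5,
    loci_per_chrom = sim$loci_per_chrom %||% 20,
    locus_length = sim$locus_length %||% 300,
    divergent_chroms = sim$divergent_chroms %||% integer(),
    region_frac = sim$region_frac %||% 0.25,
    region_mode = sim$region_mode %||% "barrier+linked")
  truth <- do.call(demographic_params, sim$truth)
  sim_config(layout, model_spec(sim$model %||% "SCS"), truth,
             samples_per_deme = sim$samples_per_deme %||% c(20, 10),
             theta_per_locus = sim$theta_per_locus %||% 5,
             gene_fraction = sim$gene_fraction %||% 0.4,
             sweep_ne_scale = sim$sweep_ne_scale %||% 0.3,
             miss_rate = sim$miss_rate %||% 0.05,
             n_pops = sim$n_pops %||% c(4, 2), seed = seed)
}

#' Demo pipeline configuration
#'
#' A small self-contained configuration (simulated inputs, light search
#' settings) that runs end to end in a couple of minutes on one CPU.
#'
#' @param seed integer seed.
#' @return a nested configuration list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = seed,
    simulate = list(
      n_chrom = 4, chrom_length = 3e5, loci_per_chrom = 25,
      locus_length = 300, divergent_chroms = 1L,
      samples_per_deme = c(20, 10),
      model = "SCS",
      truth = list(N_anc = 500, N_pma = 500, N_pja = 500,
                   T_S = 3000, T_1 = 300, T_2 = 10,
                   mmj = 1e-4, mjm = 1e-3)
    ),
    filter = list(min_gq = 5, min_dp = 5),
    demography = list(models = c("SI", "SCS"),
                      n_restarts = 2, n_loci = 300, maxit = 80,
                      final_n_loci = 2000, n_boot = 0),
    scan = list(window_size = 5e4, min_snps = 5),
    ld = list(max_dist = NULL),
    annotate = list(updown_dist = 5000)
  )
}

#' Run the whole analysis pipeline
#'
#' Orchestrates simulate (or load) -> filter -> SFS -> demographic model
#' comparison -> window scan -> diagnostic SNPs -> LD -> annotation, and
#' writes per-stage TSV/JSON outputs plus a combined `report.json` (with
#' seeds and versions) into `outdir`. Re-running with an identical
#' configuration reproduces identical outputs. A stage failure raises an
#' error naming the stage; outputs of earlier stages are preserved.
#'
#' @param config nested list (see [demo_config()]) or path to a YAML file.
#' @param outdir output directory.
#' @return a list of the in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config needs a `seed`", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  set.seed(config$seed)
  res <- list()

  if (!is.null(config$simulate)) {
    ds <- stage("simulate", {
      cfg <- build_sim_config(config$simulate, config$seed)
      write_dataset(cfg, file.path(outdir, "simulated"))
    })
    gm_all <- ds$gm_all; fasta <- ds$reference
    genes <- ds$genes; go_map <- ds$go_map; go_parents <- ds$go_parents
    res$simulated <- ds
  } else {
    inp <- config$inputs
    if (is.null(inp$vcf) || is.null(inp$popmap))
      stop("stage 'load' failed: config$inputs needs at least vcf and popmap",
           call. = FALSE)
    gm_all <- stage("load", read_geno_vcf(inp$vcf, inp$popmap))
    fasta <- if (!is.null(inp$fasta)) Biostrings::readDNAStringSet(inp$fasta)
    genes <- if (!is.null(inp$gff)) read_gene_models(inp$gff)
    go_map <- if (!is.null(inp$go_map)) read_go_map(inp$go_map)
    go_parents <- if (!is.null(inp$go_parents))
      readr::read_tsv(inp$go_parents, show_col_types = FALSE)
  }

  flt <- config$filter %||% list()
  masked <- stage("filter",
                  mask_low_confidence_genotypes(gm_all, flt$min_gq %||% 5,
                                                flt$min_dp %||% 5))
  is_var <- !is.na(masked$sites$alt)
  var_gm <- gm_subset(masked, sites = which(is_var))
  base <- stage("filter", filter_sites_and_samples(var_gm, filter_config()))
  main <- stage("filter", apply_maf_filter(base, 0.05))
  all_f <- gm_subset(masked,
                     samples = match(base$samples$sample,
                                     masked$samples$sample))
  res$n_snps <- n_sites(main)

  dm <- config$demography %||% list()
  if (length(dm$models %||% character())) {
    obs <- stage("sfs", build_joint_folded_sfs(base))
    res$sfs <- obs
    search <- search_config(n_restarts = dm$n_restarts %||% 10,
                            n_loci = dm$n_loci %||% 10000,
                            final_n_loci = dm$final_n_loci %||% 50000,
                            maxit = dm$maxit %||% 320)
    eval_seed <- sample.int(.Machine$integer.max, 1)
    fits <- stage("demography", lapply(dm$models, function(m)
      fit_model(obs, model_spec(m), search, eval_seed = eval_seed)))
    names(fits) <- dm$models
    cmp <- compare_models(fits)
    res$fits <- fits; res$comparison <- cmp
    jsonlite::write_json(
      list(comparison = cmp,
           params = lapply(fits, function(f) unclass(f$params))),
      file.path(outdir, "model_fits.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    if ((dm$n_boot %||% 0) >= 2) {
      best_fit <- fits[[attr(cmp, "best")]]
      ci <- stage("demography",
                  bootstrap_ci(best_fit, n_boot = dm$n_boot,
                               search = search_config(
                                 n_restarts = 1, n_loci = search$n_loci,
                                 final_n_loci = search$n_loci,
                                 maxit = search$maxit)))
      res$bootstrap <- ci
      jsonlite::write_json(ci, file.path(outdir, "bootstrap_ci.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  sc <- config$scan %||% list()
  wins <- stage("scan", {
    w <- scan_windows(main, all_f, window_size = sc$window_size %||% 1e5,
                      min_snps = sc$min_snps %||% 5)
    outlier_windows(w, q = sc$outlier_quantile %||% 0.95,
                    min_windows = sc$min_windows %||% 20)
  })
  res$windows <- wins
  readr::write_tsv(tibble::as_tibble(wins), file.path(outdir, "windows.tsv"))

  diags <- stage("diagnostics", find_diagnostic_snps(main))
  res$diagnostics <- diags
  readr::write_tsv(diags, file.path(outdir, "diagnostics.tsv"))
  if (!is.null(fasta) && nrow(diags)) {
    fl <- stage("diagnostics",
                extract_flanks(fasta, diags$chrom, diags$pos, flank = 100,
                               ref = diags$ref))
    write_flanks_fasta(fl, file.path(outdir, "flanks.fasta"))
  }

  ldc <- config$ld %||% list()
  species <- unique(main$samples$species)
  ld_fits <- list()
  prs_all <- list()
  for (sp in species) {
    prs <- stage("ld", pairwise_r2(main, species = sp,
                                   max_dist = ldc$max_dist))
    prs$species <- sp
    prs_all[[sp]] <- prs
    n_chr <- 2 * sum(main$samples$species == sp)
    ld_fits[[sp]] <- tryCatch(fit_ld_decay(prs, n = n_chr),
                              error = function(e) NULL)
  }
  res$ld <- ld_fits
  readr::write_tsv(dplyr::bind_rows(prs_all), file.path(outdir, "ld_pairs.tsv"))
  out_chroms <- unique(wins$chrom[wins$outlier])
  if (length(out_chroms)) {
    for (sp in species) {
      m <- stage("ld", ld_matrix(main, out_chroms[1], sp))
      write_ld_matrix(m, file.path(
        outdir, sprintf("ld_matrix_%s_%s.tsv", out_chroms[1], sp)))
    }
  }

  if (!is.null(genes) && nrow(genes)) {
    ann <- stage("annotate", {
      hd_idx <- which(purrr::map_lgl(seq_len(n_sites(main)), function(k) {
        w <- wins[wins$chrom == main$sites$chrom[k] &
                    wins$start <= main$sites$pos[k] &
                    wins$end >= main$sites$pos[k], ]
        nrow(w) > 0 && any(w$outlier)
      }))
      dia_key <- paste(diags$chrom, diags$pos)
      hd_key <- paste(main$sites$chrom[hd_idx], main$sites$pos[hd_idx])
      hd_idx <- union(hd_idx, which(paste(main$sites$chrom, main$sites$pos)
                                    %in% dia_key))
      sites_hd <- main$sites[hd_idx, ]
      eff <- classify_variants(sites_hd, genes, fasta,
                               updown_dist = config$annotate$updown_dist %||% 5000)
      near <- assign_gene(sites_hd, genes)
      eff$nearest_gene <- near$gene_id
      list(effects = eff,
           table = tabulate_effects(
             eff, paste(eff$chrom, eff$pos) %in% dia_key))
    })
    res$effects <- ann$effects
    readr::write_tsv(ann$effects, file.path(outdir, "effects.tsv"))
    readr::write_tsv(ann$table, file.path(outdir, "effects_table.tsv"))
    if (!is.null(go_map) && nrow(go_map)) {
      enr <- stage("annotate", {
        study <- unique(stats::na.omit(ann$effects$nearest_gene))
        bg <- unique(go_map$gene)
        study <- intersect(study, bg)
        if (length(study))
          go_enrichment(study, bg, go_map, algorithm = "classic")
        else tibble::tibble()
      })
      res$enrichment <- enr
      readr::write_tsv(enr, file.path(outdir, "enrichment.tsv"))
    }
  }

  report <- list(
    seed = config$seed,
    package = as.character(utils::packageVersion("divergescan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_snps = res$n_snps,
    n_windows = nrow(wins),
    n_outlier_windows = sum(wins$outlier),
    fst_threshold = attr(wins, "fst_threshold"),
    n_diagnostic_snps = nrow(diags),
    best_model = if (!is.null(res$comparison)) attr(res$comparison, "best"),
    ld_decay_bp = lapply(ld_fits, function(f) if (is.null(f)) NA
                         else f$decay_distance_bp)
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(res)
}
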