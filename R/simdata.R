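#' Genome layout for the synthetic-study generator
#'
#' Describes chromosomes, RAD-like loci scattered along them, and optional
#' divergent regions. A divergent region models a barrier to gene flow:
#' loci inside it are simulated without migration (mode `"barrier"`), and in
#' mode `"barrier+linked"` all loci of the region additionally share a single
#' genealogy, mimicking a recombination-suppressed block such as an
#' inversion.
#'
#' @param chromosomes tibble with columns `chrom`, `length`.
#' @param loci tibble with columns `chrom`, `start`, `length` (1-based).
#' @param divergent_regions tibble with columns `chrom`, `start`, `end`,
#'   `mode` (`"barrier"` or `"barrier+linked"`), or `NULL`.
#' @return a `genome_layout`.
#' @export
genome_layout <- function(chromosomes, loci, divergent_regions = NULL) {
  chromosomes <- tibble::as_tibble(chromosomes)
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)),
            all(c("chrom", "start", "length") %in% names(loci)),
            all(loci$length >= 1))
  if (!is.null(divergent_regions)) {
    divergent_regions <- tibble::as_tibble(divergent_regions)
    stopifnot(all(c("chrom", "start", "end", "mode") %in% names(divergent_regions)),
              all(divergent_regions$mode %in% c("barrier", "barrier+linked")))
    cl <- setNames(chromosomes$length, chromosomes$chrom)
    if (any(divergent_regions$end > cl[divergent_regions$chrom]) ||
        any(divergent_regions$start < 1))
      stop("divergent regions must lie inside a chromosome", call. = FALSE)
  }
  # loci must not overlap within a chromosome
  by_chr <- split(loci, loci$chrom)
  for (d in by_chr) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] <= (d$start + d$length - 1)[-nrow(d)]))
      stop("loci overlap on chromosome ", d$chrom[1], call. = FALSE)
  }
  loci$end <- loci$start + loci$length - 1L
  loci$locus <- sprintf("locus_%04d", seq_len(nrow(loci)))
  structure(list(chromosomes = chromosomes, loci = loci,
                 divergent_regions = divergent_regions),
            class = "genome_layout")
}

#' RAD-like random layout
#'
#' Scatters fixed-length loci uniformly along equal-length chromosomes and
#' optionally plants one divergent region per requested chromosome, covering
#' a contiguous block in its middle. Uses the current RNG state.
#'
#' @param n_chrom,chrom_length,loci_per_chrom,locus_length layout scale.
#' @param divergent_chroms integer vector of chromosome indices carrying one
#'   planted divergent region each.
#' @param region_frac fraction of the chromosome covered by a planted region.
#' @param region_mode `"barrier"` or `"barrier+linked"`.
#' @return a [genome_layout()].
#' @export
rad_layout <- function(n_chrom = 19, chrom_length = 5e5,
                       loci_per_chrom = 25, locus_length = 300,
                       divergent_chroms = integer(), region_frac = 0.25,
                       region_mode = "barrier+linked") {
  chroms <- tibble::tibble(chrom = sprintf("chr%02d", seq_len(n_chrom)),
                           length = as.integer(chrom_length))
  loci <- purrr::map_dfr(seq_len(n_chrom), function(i) {
    # non-overlapping starts on a grid, then jittered within slots
    slot <- chrom_length %/% loci_per_chrom
    if (slot <= locus_length) stop("loci do not fit on the chromosome")
    off <- sample.int(slot - locus_length, loci_per_chrom, replace = TRUE)
    tibble::tibble(chrom = chroms$chrom[i],
                   start = as.integer((seq_len(loci_per_chrom) - 1L) * slot + off),
                   length = as.integer(locus_length))
  })
  regions <- NULL
  if (length(divergent_chroms)) {
    half <- region_frac / 2
    regions <- tibble::tibble(
      chrom = chroms$chrom[divergent_chroms],
      start = as.integer(chrom_length * (0.5 - half)) + 1L,
      end = as.integer(chrom_length * (0.5 + half)),
      mode = region_mode
    )
  }
  genome_layout(chroms, loci, regions)
}

#' Simulate one locus genealogy under a divergence model
#'
#' Structured coalescent for two demes with epoch-limited migration (see
#' [model_spec()] for when each model allows migration). With `barrier =
#' TRUE` migration is switched off for this locus regardless of the model,
#' emulating a barrier locus.
#'
#' @param params a [demographic_params()].
#' @param model a [model_spec()].
#' @param n_hap haploid sample sizes per deme, length-2 integer (>= 1 each,
#'   total >= 2).
#' @param barrier suppress migration at this locus.
#' @param ne_scale multiplier applied to both deme sizes (sweep-like
#'   diversity reduction inside divergent regions).
#' @return a `genealogy`: `parent` (1-based, `NA` at the root), `time`
#'   (node times in generations; leaves first, deme A leaves 1..n1), `n1`,
#'   `n2`.
#' @export
sample_locus_genealogy <- function(params, model, n_hap, barrier = FALSE,
                                   ne_scale = 1) {
  stopifnot(inherits(params, "demographic_params"), inherits(model, "model_spec"),
            length(n_hap) == 2, all(n_hap >= 0), sum(n_hap) >= 2)
  ep <- migration_epoch(params, model)
  m1 <- params$mjm # backward: deme A lineage into deme B
  m2 <- params$mmj # backward: deme B lineage into deme A
  if (barrier || model$name == "SI") { m1 <- 0; m2 <- 0 }
  tr <- .sim_genealogy_cpp(as.integer(n_hap[1]), as.integer(n_hap[2]),
                           params$N_pma * ne_scale, params$N_pja * ne_scale,
                           params$N_anc, params$T_S, ep[1], ep[2], m1, m2)
  structure(list(parent = ifelse(is.na(tr$parent), NA_integer_, tr$parent + 1L),
                 time = tr$time, n1 = tr$n1, n2 = tr$n2),
            class = "genealogy")
}

#' Total branch length of a genealogy, in generations
#' @param tree a genealogy from [sample_locus_genealogy()].
#' @return numeric scalar.
#' @export
total_branch_length <- function(tree) {
  ok <- !is.na(tree$parent)
  sum(tree$time[tree$parent[ok]] - tree$time[ok])
}

tree_tmrca <- function(tree) max(tree$time)

# list of leaf index vectors per node (leaves are nodes 1..n)
leaves_under <- function(tree) {
  n_nodes <- length(tree$parent)
  n <- tree$n1 + tree$n2
  sets <- vector("list", n_nodes)
  for (i in seq_len(n)) sets[[i]] <- i
  # internal nodes are created in time order, so ascending index works
  for (i in seq_len(n_nodes)) {
    p <- tree$parent[i]
    if (!is.na(p)) sets[[p]] <- c(sets[[p]], sets[[i]])
  }
  sets
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Mutation count is Poisson with mean `theta * L / mean_L`, where `L` is
#' this genealogy's total branch length and `mean_L` a normalizing branch
#' length (typically the dataset mean), so that `theta` is the expected
#' number of mutations per average locus. Each mutation lands on a branch
#' with probability proportional to its length and gets a distinct position
#' in `1..locus_length`.
#'
#' @param tree genealogy.
#' @param theta expected mutations per average-length locus (> 0).
#' @param locus_length locus length in bp.
#' @param mean_L normalizing total branch length; defaults to this tree's own.
#' @return list with `position` (sorted, within-locus), `dosage` (site x
#'   diploid-individual matrix; individuals pair consecutive leaves within
#'   each deme) and `carriers` (list of carrier leaf sets).
#' @export
genotypes_from_genealogy <- function(tree, theta, locus_length,
                                     mean_L = NULL) {
  stopifnot(theta > 0, locus_length >= 1)
  L <- total_branch_length(tree)
  lambda <- theta * L / (mean_L %||% L)
  n_mut <- rpois(1, lambda)
  if (n_mut > locus_length)
    stop("more mutations (", n_mut, ") than positions (", locus_length, ")",
         call. = FALSE)
  n <- tree$n1 + tree$n2
  n_ind <- n %/% 2
  if (n_mut == 0)
    return(list(position = integer(), carriers = list(),
                dosage = matrix(0L, 0, n_ind)))
  pos <- sort(sample.int(locus_length, n_mut))
  ok <- which(!is.na(tree$parent))
  blen <- tree$time[tree$parent[ok]] - tree$time[ok]
  branch <- ok[sample.int(length(ok), n_mut, replace = TRUE, prob = blen)]
  sets <- leaves_under(tree)
  carriers <- sets[branch]
  dosage <- matrix(0L, n_mut, n_ind)
  for (s in seq_len(n_mut)) {
    ind <- (carriers[[s]] + 1L) %/% 2L
    tab <- tabulate(ind, nbins = n_ind)
    dosage[s, ] <- as.integer(tab)
  }
  list(position = pos, carriers = carriers, dosage = dosage)
}

#' Configuration of a synthetic study
#'
#' @param layout a [genome_layout()].
#' @param model a [model_spec()] giving the true demographic scenario.
#' @param truth a [demographic_params()] with the true parameter values.
#' @param samples_per_deme diploid sample sizes, length 2 (>= 2 each;
#'   defaults mirror the 235 + 27 scallops of the motivating study).
#' @param theta_per_locus expected mutations per average locus (> 0).
#' @param gene_fraction fraction of loci carrying a gene model.
#' @param sweep_ne_scale Ne multiplier inside divergent regions (sweep-like
#'   diversity reduction).
#' @param miss_rate random genotype missingness added on top of the DP/GQ
#'   noise model.
#' @param n_pops number of sampled population labels per deme (used by the
#'   HWE filter variants).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @return a `sim_config`.
#' @export
sim_config <- function(layout, model, truth,
                       samples_per_deme = c(235, 27),
                       theta_per_locus = 5, gene_fraction = 0.4,
                       sweep_ne_scale = 0.3, miss_rate = 0.05,
                       n_pops = c(12, 2), seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"), inherits(model, "model_spec"),
            inherits(truth, "demographic_params"),
            length(samples_per_deme) == 2, all(samples_per_deme >= 2),
            theta_per_locus > 0)
  structure(list(layout = layout, model = model, truth = truth,
                 samples_per_deme = as.integer(samples_per_deme),
                 theta_per_locus = theta_per_locus,
                 gene_fraction = gene_fraction,
                 sweep_ne_scale = sweep_ne_scale, miss_rate = miss_rate,
                 n_pops = as.integer(n_pops), seed = as.integer(seed)),
            class = "sim_config")
}

# label loci with the divergent region (if any) overlapping them
label_loci <- function(layout) {
  loci <- layout$loci
  loci$region <- NA_integer_
  loci$mode <- "none"
  dr <- layout$divergent_regions
  if (!is.null(dr) && nrow(dr)) {
    for (r in seq_len(nrow(dr))) {
      hit <- loci$chrom == dr$chrom[r] & loci$end >= dr$start[r] &
        loci$start <= dr$end[r]
      loci$region[hit] <- r
      loci$mode[hit] <- dr$mode[r]
    }
  }
  loci
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# a gene occupying the first part of a locus of length L: two exons with
# 5'/3' UTRs and an intron; CDS starts ATG, ends TAA, no internal stops
make_gene <- function(L) {
  u5 <- max(9L, round(0.05 * L)); u3 <- max(9L, round(0.05 * L))
  intron <- max(30L, round(0.3 * L))
  cds_total <- L - u5 - u3 - intron
  cds_total <- (cds_total %/% 3L) * 3L
  if (cds_total < 9L) stop("locus too short for a gene model")
  codons <- setdiff(apply(expand.grid(BASES, BASES, BASES), 1, paste,
                          collapse = ""), STOPS)
  cds_seq <- paste0("ATG", paste(sample(codons, cds_total / 3L - 2L,
                                        replace = TRUE), collapse = ""), "TAA")
  cds1 <- (round(cds_total * 0.45) %/% 1L)
  cds2 <- cds_total - cds1
  seq <- paste0(random_dna(u5), substr(cds_seq, 1, cds1), random_dna(intron),
                substr(cds_seq, cds1 + 1, cds_total), random_dna(u3))
  gene_len <- nchar(seq)
  # sense-strand feature coordinates (1-based within the gene)
  feats <- tibble::tibble(
    type = c("five_prime_UTR", "CDS", "CDS", "three_prime_UTR", "exon", "exon"),
    start = c(1L, u5 + 1L, u5 + cds1 + intron + 1L,
              u5 + cds1 + intron + cds2 + 1L, 1L, u5 + cds1 + intron + 1L),
    end = c(u5, u5 + cds1, u5 + cds1 + intron + cds2,
            gene_len, u5 + cds1, gene_len),
    phase = c(NA, 0L, (3L - cds1 %% 3L) %% 3L, NA, NA, NA)
  )
  list(seq = seq, len = gene_len, feats = feats)
}

#' Simulate a complete synthetic study in memory
#'
#' Generates genealogies per locus under the configured demographic truth
#' (loci in divergent regions lose migration and have their Ne scaled down;
#' `barrier+linked` regions share one genealogy across loci), drops
#' infinite-sites mutations, builds reference sequences with gene models on
#' a fraction of loci, assigns GO terms, and adds a DP/GQ noise model.
#'
#' @param config a [sim_config()].
#' @return a `sim_dataset` list: `gm_all` (all-sites [geno_matrix()] with
#'   GQ/DP), `gm` (variant sites only), `reference`
#'   ([Biostrings::DNAStringSet]), `genes` (GFF3-shaped tibble), `go_map`,
#'   `go_parents`, `popmap`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- config$layout
  loci <- label_loci(layout)
  n_ind <- config$samples_per_deme
  n_hap <- 2L * n_ind
  truth <- config$truth
  model <- config$model

  # genealogies: one shared tree per barrier+linked region
  shared <- list()
  for (r in unique(loci$region[loci$mode == "barrier+linked"])) {
    if (is.na(r)) next
    shared[[as.character(r)]] <- sample_locus_genealogy(
      truth, model, n_hap, barrier = TRUE, ne_scale = config$sweep_ne_scale)
  }
  trees <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (loci$mode[i] == "barrier+linked") {
      trees[[i]] <- shared[[as.character(loci$region[i])]]
    } else if (loci$mode[i] == "barrier") {
      trees[[i]] <- sample_locus_genealogy(truth, model, n_hap, barrier = TRUE,
                                           ne_scale = config$sweep_ne_scale)
    } else {
      trees[[i]] <- sample_locus_genealogy(truth, model, n_hap)
    }
  }
  Ls <- vapply(trees, total_branch_length, 0)
  mean_L <- mean(Ls)

  muts <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci)))
    muts[[i]] <- genotypes_from_genealogy(trees[[i]], config$theta_per_locus,
                                          loci$length[i], mean_L)
  loci$tmrca <- vapply(trees, tree_tmrca, 0)
  loci$n_snps <- vapply(muts, function(m) length(m$position), 0L)

  # samples / popmap
  pops <- c(sprintf("pma_%02d", 1 + (seq_len(n_ind[1]) - 1L) %% config$n_pops[1]),
            sprintf("pja_%02d", 1 + (seq_len(n_ind[2]) - 1L) %% config$n_pops[2]))
  popmap <- tibble::tibble(
    sample = c(sprintf("PMA_%03d", seq_len(n_ind[1])),
               sprintf("PJA_%03d", seq_len(n_ind[2]))),
    species = rep(c("pma", "pja"), n_ind),
    population = pops
  )

  # reference genome, genes written over a fraction of loci
  ref_chr <- lapply(setNames(layout$chromosomes$length,
                             layout$chromosomes$chrom), random_dna)
  gene_loci <- which(runif(nrow(loci)) < config$gene_fraction &
                       loci$length >= 120L)
  gff <- list(); go_rows <- list()
  go_terms <- sprintf("GO:%07d", 1:12)
  go_parents <- tibble::tibble(child = go_terms,
                               parent = sprintf("GO:%07d", 100 + (0:11) %/% 3))
  for (gi in seq_along(gene_loci)) {
    i <- gene_loci[gi]
    g <- make_gene(loci$length[i])
    strand <- sample(c("+", "-"), 1)
    gstart <- loci$start[i]
    gseq <- if (strand == "+") g$seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$seq)))
    chrom <- loci$chrom[i]
    substr(ref_chr[[chrom]], gstart, gstart + g$len - 1L) <- gseq
    gid <- sprintf("gene_%03d", gi)
    to_genomic <- function(s, e) {
      if (strand == "+") c(gstart + s - 1L, gstart + e - 1L)
      else c(gstart + g$len - e, gstart + g$len - s)
    }
    span <- c(gstart, gstart + g$len - 1L)
    rows <- list(
      tibble::tibble(chrom = chrom, source = "divergescan", type = "gene",
                     start = span[1], end = span[2], strand = strand,
                     phase = NA_integer_, id = gid, parent = NA_character_),
      tibble::tibble(chrom = chrom, source = "divergescan", type = "mRNA",
                     start = span[1], end = span[2], strand = strand,
                     phase = NA_integer_, id = paste0(gid, ".t1"), parent = gid)
    )
    for (f in seq_len(nrow(g$feats))) {
      gc <- to_genomic(g$feats$start[f], g$feats$end[f])
      rows <- c(rows, list(tibble::tibble(
        chrom = chrom, source = "divergescan", type = g$feats$type[f],
        start = gc[1], end = gc[2], strand = strand,
        phase = g$feats$phase[f],
        id = sprintf("%s.t1.%s%d", gid, tolower(g$feats$type[f]), f),
        parent = paste0(gid, ".t1"))))
    }
    gff[[gi]] <- dplyr::bind_rows(rows)
    go_rows[[gi]] <- tibble::tibble(
      gene = gid, go = sample(go_terms, sample(1:3, 1)))
  }
  genes <- if (length(gff)) dplyr::bind_rows(gff) else
    tibble::tibble(chrom = character(), source = character(), type = character(),
                   start = integer(), end = integer(), strand = character(),
                   phase = integer(), id = character(), parent = character())
  go_map <- if (length(go_rows)) dplyr::bind_rows(go_rows) else
    tibble::tibble(gene = character(), go = character())

  # assemble the all-sites table, locus by locus
  n_tot <- sum(n_ind)
  all_rows <- vector("list", nrow(loci))
  var_flag <- vector("list", nrow(loci))
  gt_blocks <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    len <- loci$length[i]
    pos <- loci$start[i] + seq_len(len) - 1L
    gt <- matrix(0L, len, n_tot)
    isvar <- rep(FALSE, len)
    m <- muts[[i]]
    if (length(m$position)) {
      gt[m$position, ] <- m$dosage
      isvar[m$position] <- TRUE
    }
    all_rows[[i]] <- tibble::tibble(chrom = loci$chrom[i], pos = pos,
                                    locus = loci$locus[i],
                                    region = loci$mode[i])
    var_flag[[i]] <- isvar
    gt_blocks[[i]] <- gt
  }
  sites_all <- dplyr::bind_rows(all_rows)
  gt_all <- do.call(rbind, gt_blocks)
  isvar <- unlist(var_flag)
  sites_all$ref <- vapply(seq_len(nrow(sites_all)), function(k)
    substr(ref_chr[[sites_all$chrom[k]]], sites_all$pos[k], sites_all$pos[k]),
    "")
  sites_all$alt <- NA_character_
  if (any(isvar))
    sites_all$alt[isvar] <- vapply(which(isvar), function(k)
      sample(setdiff(BASES, sites_all$ref[k]), 1), "")

  # DP/GQ noise + random missingness; DP = 0 also means no call
  nc <- length(gt_all)
  dp <- matrix(rnbinom(nc, mu = 20, size = 5), nrow = nrow(gt_all))
  gq <- matrix(pmin(99L, rpois(nc, 40)), nrow = nrow(gt_all))
  gt_all[dp == 0L] <- NA_integer_
  if (config$miss_rate > 0)
    gt_all[runif(nc) < config$miss_rate] <- NA_integer_

  gm_all <- geno_matrix(gt_all,
                        sites_all[, c("chrom", "pos", "ref", "alt")],
                        popmap, gq = gq, dp = dp)
  gm <- gm_subset(gm_all, sites = which(isvar))

  truth_out <- list(
    model = model$name,
    params = unclass(truth)[!is.na(unclass(truth))],
    seed = config$seed,
    mean_total_branch_length = mean_L,
    loci = loci[, c("locus", "chrom", "start", "end", "length", "mode",
                    "region", "tmrca", "n_snps")],
    sites = sites_all[isvar, c("chrom", "pos", "locus", "region")]
  )
  structure(list(gm_all = gm_all, gm = gm,
                 reference = Biostrings::DNAStringSet(unlist(ref_chr)),
                 genes = genes, go_map = go_map, go_parents = go_parents,
                 popmap = popmap, truth = truth_out, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> model %s, %d loci, %d variant sites, %d samples\n",
              x$truth$model, nrow(x$truth$loci), n_sites(x$gm),
              n_samples(x$gm)))
  invisible(x)
}

gff3_attr <- function(id, parent) {
  a <- paste0("ID=", id)
  ifelse(is.na(parent), a, paste0(a, ";Parent=", parent))
}

#' Write a synthetic study to disk
#'
#' Emits `sites.vcf` (all-sites, GT:GQ:DP), `reference.fa`, `genes.gff3`,
#' `go_map.tsv`, `go_parents.tsv`, `popmap.tsv` and `truth.json` into
#' `outdir`. Regeneration with the same config is byte-identical.
#'
#' @param config a [sim_config()] (or an already simulated `sim_dataset`).
#' @param outdir output directory, created if needed.
#' @return the `sim_dataset`, invisibly.
#' @export
write_dataset <- function(config, outdir) {
  ds <- if (inherits(config, "sim_dataset")) config else simulate_dataset(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  contigs <- setNames(ds$config$layout$chromosomes$length,
                      ds$config$layout$chromosomes$chrom)
  write_geno_vcf(ds$gm_all, file.path(outdir, "sites.vcf"), contigs = contigs)
  # REF in the VCF equals the FASTA base by construction; assert anyway
  idx <- seq_len(min(200L, n_sites(ds$gm_all)))
  fa_base <- vapply(idx, function(k)
    as.character(Biostrings::subseq(
      ds$reference[[ds$gm_all$sites$chrom[k]]],
      ds$gm_all$sites$pos[k], ds$gm_all$sites$pos[k])), "")
  stopifnot(identical(fa_base, ds$gm_all$sites$ref[idx]))
  Biostrings::writeXStringSet(ds$reference, file.path(outdir, "reference.fa"))
  g <- ds$genes
  gff_lines <- c("##gff-version 3",
                 if (nrow(g)) paste(g$chrom, g$source, g$type, g$start, g$end,
                                    ".", g$strand,
                                    ifelse(is.na(g$phase), ".", g$phase),
                                    gff3_attr(g$id, g$parent), sep = "\t"))
  writeLines(gff_lines, file.path(outdir, "genes.gff3"))
  go_wide <- dplyr::summarise(dplyr::group_by(ds$go_map, .data$gene),
                              go = paste(sort(.data$go), collapse = ","),
                              .groups = "drop")
  readr::write_tsv(go_wide, file.path(outdir, "go_map.tsv"), col_names = FALSE)
  readr::write_tsv(ds$go_parents, file.path(outdir, "go_parents.tsv"))
  readr::write_tsv(ds$popmap, file.path(outdir, "popmap.tsv"),
                   col_names = FALSE)
  jsonlite::write_json(ds$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(ds)
}
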