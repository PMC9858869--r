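#' Genotype matrix container
#'
#' A `geno_matrix` bundles a sites-by-samples diploid dosage matrix (0, 1, 2
#' copies of the ALT allele, `NA` = missing) with per-site metadata, sample
#' metadata (species and population labels), and optional per-genotype
#' quality (GQ) and depth (DP) matrices.
#'
#' @param gt integer matrix, sites x samples; values in {0, 1, 2, NA}.
#' @param sites tibble with columns `chrom`, `pos`, `ref`, `alt` (one row per
#'   row of `gt`). `alt` may be `NA` for invariant (all-sites) records.
#' @param samples tibble with columns `sample`, `species`, and optionally
#'   `population` (one row per column of `gt`).
#' @param gq,dp optional numeric matrices with the same dimensions as `gt`.
#' @param maf_filtered logical provenance flag: `TRUE` once a minor-allele
#'   frequency filter has been applied. SFS construction refuses such input.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(gt, sites, samples, gq = NULL, dp = NULL,
                        maf_filtered = FALSE) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  sites <- tibble::as_tibble(sites)
  samples <- tibble::as_tibble(samples)
  stopifnot(nrow(sites) == nrow(gt), nrow(samples) == ncol(gt))
  if (!all(c("chrom", "pos") %in% names(sites)))
    stop("`sites` needs columns chrom and pos", call. = FALSE)
  if (!all(c("sample", "species") %in% names(samples)))
    stop("`samples` needs columns sample and species", call. = FALSE)
  if (!"population" %in% names(samples)) samples$population <- samples$species
  bad <- gt[!is.na(gt)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  for (m in list(gq, dp)) if (!is.null(m)) stopifnot(all(dim(m) == dim(gt)))
  colnames(gt) <- samples$sample
  structure(
    list(gt = gt, sites = sites, samples = samples, gq = gq, dp = dp,
         maf_filtered = isTRUE(maf_filtered)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d sites x %d samples (%s)\n",
              nrow(x$gt), ncol(x$gt),
              paste(sprintf("%s: %d", names(table(x$samples$species)),
                            table(x$samples$species)), collapse = ", ")))
  cat(sprintf("  missing genotypes: %.1f%%; MAF-filtered: %s\n",
              100 * mean(is.na(x$gt)), x$maf_filtered))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$gt)

#' Numbers of sites and samples in a geno_matrix
#' @param gm a [geno_matrix()].
#' @return integer scalar.
#' @export
n_sites <- function(gm) nrow(gm$gt)

#' @rdname n_sites
#' @export
n_samples <- function(gm) ncol(gm$gt)

#' Subset a geno_matrix by site or sample index
#' @param gm a [geno_matrix()].
#' @param sites,samples integer or logical index vectors.
#' @return a `geno_matrix`.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(gm)) else sites
  sa <- if (is.null(samples)) seq_len(n_samples(gm)) else samples
  sub <- function(m) if (is.null(m)) NULL else m[si, sa, drop = FALSE]
  geno_matrix(gm$gt[si, sa, drop = FALSE], gm$sites[si, , drop = FALSE],
              gm$samples[sa, , drop = FALSE], sub(gm$gq), sub(gm$dp),
              gm$maf_filtered)
}

# species-wise column index list, in order of first appearance
species_index <- function(gm) {
  sp <- gm$samples$species
  split(seq_along(sp), factor(sp, levels = unique(sp)))
}

# per-site alt allele count and genotyped chromosome count for given columns
site_allele_counts <- function(gm, cols) {
  g <- gm$gt[, cols, drop = FALSE]
  d <- rowSums(g, na.rm = TRUE)
  n <- 2L * rowSums(!is.na(g))
  list(alt = d, chroms = n)
}

#' Read a population map
#'
#' Two- or three-column TSV: sample, species, and optionally population.
#'
#' @param path file path.
#' @return tibble with columns `sample`, `species`, `population`.
#' @export
read_popmap <- function(path) {
  pm <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(pm) < 2) stop("popmap needs at least two columns", call. = FALSE)
  names(pm)[1:2] <- c("sample", "species")
  if (ncol(pm) >= 3) names(pm)[3] <- "population" else pm$population <- pm$species
  pm[, c("sample", "species", "population")]
}

#' Read a VCF into a geno_matrix
#'
#' Uses `vcfR` for parsing. Multiallelic records are dropped with a message.
#' Records with `ALT = "."` are kept as invariant sites (dosage 0 where
#' genotyped), which is what the all-sites dxy path needs.
#'
#' @param path VCF path (plain or bgzipped).
#' @param popmap tibble as returned by [read_popmap()], or a path to one.
#'   Samples absent from the popmap are dropped; popmap samples absent from
#'   the VCF raise an error naming them.
#' @return a [geno_matrix()].
#' @export
read_geno_vcf <- function(path, popmap) {
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::tibble(
    chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
    ref = vcfR::getREF(v), alt = vcfR::getALT(v)
  )
  fix$alt[fix$alt %in% c(".", "")] <- NA_character_
  multi <- !is.na(fix$alt) & grepl(",", fix$alt, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multiallelic records dropped")
  }
  keep <- !multi
  gt_chr <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dose <- function(s) {
    out <- rep(NA_integer_, length(s))
    out[s %in% c("0/0", "0|0")] <- 0L
    out[s %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[s %in% c("1/1", "1|1")] <- 2L
    out
  }
  gt <- matrix(dose(gt_chr), nrow = nrow(gt_chr),
               dimnames = list(NULL, colnames(gt_chr)))
  get_num <- function(el) {
    if (!grepl(el, v@gt[1, 1])) return(NULL)
    m <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    m[keep, , drop = FALSE]
  }
  strip <- function(m) { if (!is.null(m)) rownames(m) <- NULL; m }
  gq <- strip(get_num("GQ"))
  dp <- strip(get_num("DP"))
  missing_sm <- setdiff(popmap$sample, colnames(gt))
  if (length(missing_sm))
    stop("popmap samples absent from VCF: ",
         paste(missing_sm, collapse = ", "), call. = FALSE)
  ord <- match(popmap$sample, colnames(gt))
  sub <- function(m) if (is.null(m)) NULL else m[, ord, drop = FALSE]
  geno_matrix(gt[, ord, drop = FALSE], fix[keep, ], popmap,
              gq = sub(gq), dp = sub(dp))
}

#' Write a geno_matrix as a VCF text file
#'
#' Emits a minimal VCFv4.2 file with GT (and GQ/DP when present) FORMAT
#' fields. Invariant sites (`alt` `NA`) are written with `ALT = .`.
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @param contigs optional named vector of chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_geno_vcf <- function(gm, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=divergescan")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  fmt <- "GT"
  if (!is.null(gm$gq)) {
    hdr <- c(hdr, '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
    fmt <- paste0(fmt, ":GQ")
  }
  if (!is.null(gm$dp)) {
    hdr <- c(hdr, '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
    fmt <- paste0(fmt, ":DP")
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", gm$samples$sample), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L], nrow = nrow(gm$gt))
  gt_str[is.na(gm$gt)] <- "./."
  cell <- gt_str
  if (!is.null(gm$gq)) cell <- matrix(paste(cell, as.integer(gm$gq), sep = ":"),
                                      nrow = nrow(cell))
  if (!is.null(gm$dp)) cell <- matrix(paste(cell, as.integer(gm$dp), sep = ":"),
                                      nrow = nrow(cell))
  body <- paste(
    gm$sites$chrom, gm$sites$pos, ".",
    gm$sites$ref, ifelse(is.na(gm$sites$alt), ".", gm$sites$alt),
    ".", "PASS", ".", fmt,
    apply(cell, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
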