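#' Find fully diagnostic SNPs
#'
#' Sites where every genotyped individual of the first species is homozygous
#' REF and every genotyped individual of the second species is homozygous
#' ALT, with a per-species call-rate guard (fixedness is judged among
#' genotyped calls unless `strict = TRUE`, which rejects any missing call).
#' `both_orientations = TRUE` also reports the mirror (species A fixed ALT,
#' species B fixed REF).
#'
#' @param gm a two-species [geno_matrix()].
#' @param min_species_call_rate minimum genotyped fraction per species.
#' @param both_orientations also report the mirrored fixed difference.
#' @param strict disallow any missing genotype at the site.
#' @return tibble of diagnostic sites (chrom, pos, ref, alt, orientation,
#'   call_rate_a, call_rate_b).
#' @export
find_diagnostic_snps <- function(gm, min_species_call_rate = 0.8,
                                 both_orientations = FALSE, strict = FALSE) {
  idx <- species_index(gm)
  if (length(idx) != 2) stop("exactly two species required", call. = FALSE)
  ga <- gm$gt[, idx[[1]], drop = FALSE]
  gb <- gm$gt[, idx[[2]], drop = FALSE]
  cr_a <- rowMeans(!is.na(ga)); cr_b <- rowMeans(!is.na(gb))
  n_a <- rowSums(!is.na(ga)); n_b <- rowSums(!is.na(gb))
  guard <- cr_a >= min_species_call_rate & cr_b >= min_species_call_rate &
    n_a > 0 & n_b > 0
  if (strict) guard <- guard & cr_a == 1 & cr_b == 1
  a_ref <- rowSums(ga != 0L, na.rm = TRUE) == 0L
  a_alt <- rowSums(ga != 2L, na.rm = TRUE) == 0L
  b_ref <- rowSums(gb != 0L, na.rm = TRUE) == 0L
  b_alt <- rowSums(gb != 2L, na.rm = TRUE) == 0L
  fwd <- guard & a_ref & b_alt
  hit <- if (both_orientations) fwd | (guard & a_alt & b_ref) else fwd
  out <- gm$sites[hit, , drop = FALSE]
  out$orientation <- ifelse(fwd[hit], "A_ref_B_alt", "A_alt_B_ref")
  out$call_rate_a <- cr_a[hit]
  out$call_rate_b <- cr_b[hit]
  tibble::as_tibble(out)
}

#' Extract flanking sequence around a site
#'
#' Returns `flank` bases on either side of `pos` (so `2 * flank + 1` bp when
#' not truncated by a chromosome end; truncation is reported). When `ref` is
#' supplied the center base is checked against it.
#'
#' @param fasta a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param chrom,pos site coordinates (1-based).
#' @param flank flank length in bp.
#' @param ref expected reference base at `pos`, or `NULL` to skip the check.
#' @return tibble (chrom, pos, start, end, length, truncated, seq).
#' @export
extract_flanks <- function(fasta, chrom, pos, flank = 100, ref = NULL) {
  if (is.character(fasta)) fasta <- Biostrings::readDNAStringSet(fasta)
  names(fasta) <- sub("\\s.*", "", names(fasta))
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  purrr::map_dfr(seq_len(n), function(i) {
    if (!chrom[i] %in% names(fasta))
      stop("chromosome ", chrom[i], " not in FASTA", call. = FALSE)
    L <- Biostrings::width(fasta[chrom[i]])
    if (pos[i] < 1 || pos[i] > L)
      stop("position ", pos[i], " outside ", chrom[i], call. = FALSE)
    s <- max(1L, pos[i] - flank); e <- min(L, pos[i] + flank)
    sq <- as.character(Biostrings::subseq(fasta[[chrom[i]]], s, e))
    if (!is.null(ref)) {
      center <- substr(sq, pos[i] - s + 1L, pos[i] - s + 1L)
      if (center != rep_len(ref, n)[i])
        stop("reference mismatch at ", chrom[i], ":", pos[i],
             " (FASTA ", center, ", VCF ", rep_len(ref, n)[i], ")",
             call. = FALSE)
    }
    tibble::tibble(chrom = chrom[i], pos = pos[i], start = s, end = e,
                   length = e - s + 1L,
                   truncated = (e - s + 1L) < (2L * flank + 1L), seq = sq)
  })
}

#' Write flank sequences as FASTA
#' @param flanks tibble from [extract_flanks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flanks_fasta <- function(flanks, path) {
  seqs <- Biostrings::DNAStringSet(flanks$seq)
  names(seqs) <- sprintf("%s_%d", flanks$chrom, flanks$pos)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
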