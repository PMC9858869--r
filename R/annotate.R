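EFFECT_LEVELS <- c("loss_of_function", "missense_variant",
                   "synonymous_variant", "splice_region_intron_variant",
                   "three_prime_UTR_variant", "five_prime_UTR_variant",
                   "intron_variant", "upstream_gene_variant",
                   "downstream_gene_variant", "intergenic_region")

EFFECT_FLAGS <- tibble::tibble(
  category = EFFECT_LEVELS,
  within_gene = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  transcribed = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
)

#' Read gene models from a GFF3 file
#'
#' Normalizes to the tibble layout used by [classify_variants()]:
#' chrom, type, start, end, strand, phase, id, parent.
#'
#' @param path GFF3 path.
#' @return tibble of features.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(g)
  parent <- as.character(S4Vectors::sapply(md$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_))
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(g)),
    source = as.character(md$source),
    type = as.character(md$type),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    phase = if ("phase" %in% names(md)) as.integer(as.character(md$phase))
            else NA_integer_,
    id = as.character(md$ID), parent = parent
  )
}

comp_base <- function(b) chartr("ACGTacgt", "TGCAtgca", b)

# spliced CDS info for one mRNA: ordered segments, sequence, validity
mrna_cds <- function(feats, fasta) {
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(NULL)
  strand <- cds$strand[1]
  cds <- cds[order(cds$start, decreasing = (strand == "-")), ]
  segs <- lapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(fasta[[cds$chrom[i]]], cds$start[i],
                                    cds$end[i])))
  if (strand == "-")
    segs <- lapply(segs, function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  seq <- paste(unlist(segs), collapse = "")
  list(cds = cds, seq = seq, strand = strand,
       valid = nchar(seq) %% 3 == 0)
}

# CDS (1-based, sense-strand) coordinate of a genomic position, or NA
cds_coord <- function(cinfo, pos) {
  off <- 0L
  for (i in seq_len(nrow(cinfo$cds))) {
    s <- cinfo$cds$start[i]; e <- cinfo$cds$end[i]
    if (pos >= s && pos <= e) {
      within <- if (cinfo$strand == "+") pos - s + 1L else e - pos + 1L
      return(off + within)
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

coding_effect <- function(cinfo, pos, ref, alt) {
  cp <- cds_coord(cinfo, pos)
  if (is.na(cp)) return(NULL)
  codon_i <- (cp - 1L) %/% 3L + 1L
  codon_pos <- (cp - 1L) %% 3L + 1L
  codon <- substr(cinfo$seq, 3L * (codon_i - 1L) + 1L, 3L * codon_i)
  ref_s <- if (cinfo$strand == "+") ref else comp_base(ref)
  alt_s <- if (cinfo$strand == "+") alt else comp_base(alt)
  if (substr(codon, codon_pos, codon_pos) != toupper(ref_s))
    stop("reference mismatch inside CDS at position ", pos, call. = FALSE)
  alt_codon <- codon
  substr(alt_codon, codon_pos, codon_pos) <- toupper(alt_s)
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                               no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(alt_codon),
                                               no.init.codon = TRUE))
  if (aa_alt == "*" && aa_ref != "*") return("loss_of_function") # stop gained
  if (codon_i == 1L && aa_ref == "M" && aa_alt != "M")
    return("loss_of_function")                                   # start lost
  if (aa_ref == aa_alt) return("synonymous_variant")
  "missense_variant"
}

# effect of a site within one mRNA; NULL when outside the mRNA span
mrna_effect <- function(feats, fasta, pos, ref, alt, splice_region) {
  span <- range(c(feats$start, feats$end))
  if (pos < span[1] || pos > span[2]) return(NULL)
  strand <- feats$strand[1]
  exons <- feats[feats$type == "exon", , drop = FALSE]
  in_exon <- any(pos >= exons$start & pos <= exons$end)
  if (in_exon) {
    cinfo <- mrna_cds(feats, fasta)
    in_cds <- !is.null(cinfo) &&
      any(pos >= cinfo$cds$start & pos <= cinfo$cds$end)
    if (in_cds) {
      if (!cinfo$valid) return("intron_variant") # CDS length not /3: flagged upstream
      if (is.na(alt)) return("synonymous_variant")
      return(coding_effect(cinfo, pos, ref, alt))
    }
    utr <- feats[grepl("UTR", feats$type), , drop = FALSE]
    hit <- utr[pos >= utr$start & pos <= utr$end, , drop = FALSE]
    if (nrow(hit))
      return(if (grepl("three", hit$type[1])) "three_prime_UTR_variant"
             else "five_prime_UTR_variant")
    # exonic, no UTR feature: infer the UTR side from the CDS span
    if (!is.null(cinfo)) {
      cds_span <- range(c(cinfo$cds$start, cinfo$cds$end))
      before <- pos < cds_span[1]
      five <- (strand == "+") == before
      return(if (five) "five_prime_UTR_variant" else "three_prime_UTR_variant")
    }
    return("intron_variant")
  }
  # intronic: distance to the nearest exon boundary
  dists <- c(pos - exons$end, exons$start - pos)
  d <- min(dists[dists > 0])
  if (d <= 2) return("loss_of_function") # splice donor/acceptor
  if (d >= splice_region[1] && d <= splice_region[2])
    return("splice_region_intron_variant")
  "intron_variant"
}

#' Classify variant effects against gene models
#'
#' Assigns each site its most severe applicable category with precedence
#' loss-of-function > missense > synonymous > splice region > UTR > intron >
#' up/downstream > intergenic. Coding effects use codon substitution under
#' the standard genetic code, strand-aware. Loss of function covers stop
#' gained, start lost, and splice donor/acceptor (intronic 1-2 bp) changes.
#' Genes whose CDS length is not a multiple of 3 are flagged and their
#' coding effects skipped.
#'
#' @param sites tibble with chrom, pos, ref, alt.
#' @param genes gene-model tibble ([read_gene_models()] or the generator's).
#' @param fasta [Biostrings::DNAStringSet] or FASTA path.
#' @param updown_dist up/downstream distance from the gene span (bp).
#' @param splice_region intronic distance range counted as splice region.
#' @return tibble: chrom, pos, category, gene_id, within_gene, transcribed.
#' @export
classify_variants <- function(sites, genes, fasta, updown_dist = 5000,
                              splice_region = c(3, 8)) {
  if (is.character(fasta)) fasta <- Biostrings::readDNAStringSet(fasta)
  names(fasta) <- sub("\\s.*", "", names(fasta))
  gene_rows <- genes[genes$type == "gene", , drop = FALSE]
  mrna_rows <- genes[genes$type == "mRNA", , drop = FALSE]
  feat_rows <- genes[!genes$type %in% c("gene", "mRNA"), , drop = FALSE]
  feats_by_mrna <- split(feat_rows, feat_rows$parent)
  mrnas_by_gene <- split(mrna_rows$id, mrna_rows$parent)
  bad_cds <- character()
  for (m in mrna_rows$id) {
    ci <- mrna_cds(feats_by_mrna[[m]], fasta)
    if (!is.null(ci) && !ci$valid) bad_cds <- c(bad_cds, m)
  }
  if (length(bad_cds))
    warning("CDS length not a multiple of 3; coding effects skipped for: ",
            paste(bad_cds, collapse = ", "))
  res <- purrr::map_dfr(seq_len(nrow(sites)), function(k) {
    ch <- sites$chrom[k]; pos <- sites$pos[k]
    g_ch <- gene_rows[gene_rows$chrom == ch, , drop = FALSE]
    containing <- g_ch[pos >= g_ch$start & pos <= g_ch$end, , drop = FALSE]
    if (nrow(containing)) {
      best_cat <- "intron_variant"; best_gene <- containing$id[1]
      for (gi in seq_len(nrow(containing))) {
        for (m in mrnas_by_gene[[containing$id[gi]]] %||% character()) {
          eff <- mrna_effect(feats_by_mrna[[m]], fasta, pos,
                             sites$ref[k], sites$alt[k], splice_region)
          if (!is.null(eff) &&
              match(eff, EFFECT_LEVELS) < match(best_cat, EFFECT_LEVELS)) {
            best_cat <- eff; best_gene <- containing$id[gi]
          }
        }
      }
      return(tibble::tibble(chrom = ch, pos = pos, category = best_cat,
                            gene_id = best_gene))
    }
    if (!nrow(g_ch))
      return(tibble::tibble(chrom = ch, pos = pos,
                            category = "intergenic_region",
                            gene_id = NA_character_))
    dist_lo <- g_ch$start - pos # positive when gene is to the right
    dist_hi <- pos - g_ch$end   # positive when gene is to the left
    dist <- pmax(dist_lo, dist_hi)
    nearest <- order(dist, g_ch$start)[1]
    if (dist[nearest] > updown_dist)
      return(tibble::tibble(chrom = ch, pos = pos,
                            category = "intergenic_region",
                            gene_id = NA_character_))
    before <- pos < g_ch$start[nearest]
    upstream <- (g_ch$strand[nearest] == "+") == before
    tibble::tibble(chrom = ch, pos = pos,
                   category = if (upstream) "upstream_gene_variant"
                              else "downstream_gene_variant",
                   gene_id = g_ch$id[nearest])
  })
  dplyr::left_join(res, EFFECT_FLAGS, by = "category")
}

#' Assign each site to its containing or closest gene
#'
#' Containing gene wins; otherwise the gene minimizing the distance from the
#' site to the gene span, ties broken by lower start coordinate. A
#' chromosome with no genes yields `NA`.
#'
#' @param sites tibble with chrom, pos.
#' @param genes gene-model tibble.
#' @return tibble: chrom, pos, gene_id, distance (0 when inside).
#' @export
assign_gene <- function(sites, genes) {
  gene_rows <- genes[genes$type == "gene", , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(sites)), function(k) {
    ch <- sites$chrom[k]; pos <- sites$pos[k]
    g_ch <- gene_rows[gene_rows$chrom == ch, , drop = FALSE]
    if (!nrow(g_ch))
      return(tibble::tibble(chrom = ch, pos = pos, gene_id = NA_character_,
                            distance = NA_real_))
    dist <- pmax(g_ch$start - pos, pos - g_ch$end, 0)
    best <- order(dist, g_ch$start)[1]
    tibble::tibble(chrom = ch, pos = pos, gene_id = g_ch$id[best],
                   distance = dist[best])
  })
}

propagate_go <- function(go_map, parents) {
  if (is.null(parents)) return(go_map)
  anc <- function(term) {
    out <- character(); cur <- term
    while (length(cur)) {
      nxt <- unique(parents$parent[parents$child %in% cur])
      nxt <- setdiff(nxt, out)
      out <- c(out, nxt); cur <- nxt
    }
    out
  }
  extra <- purrr::map_dfr(unique(go_map$go), function(t)
    tibble::tibble(go = t, anc = anc(t)))
  added <- dplyr::inner_join(go_map, extra, by = "go",
                             relationship = "many-to-many")
  dplyr::distinct(dplyr::bind_rows(
    go_map, tibble::tibble(gene = added$gene, go = added$anc)))
}

#' GO term enrichment by one-sided Fisher exact test
#'
#' Hypergeometric upper-tail p-value per term. `algorithm = "classic"` tests
#' terms independently; `"elim"` processes terms most-specific-first
#' (requires `parents`) and removes the genes of significant child terms
#' from their ancestors before testing, decorrelating the hierarchy. No
#' multiple-testing correction is applied.
#'
#' @param study_genes character vector (subset of `background_genes`).
#' @param background_genes character vector.
#' @param go_map long tibble (gene, go).
#' @param algorithm `"classic"` or `"elim"`.
#' @param alpha significance level used by `"elim"` for child elimination.
#' @param parents optional tibble (child, parent) of the GO hierarchy; when
#'   supplied, gene annotations are propagated to ancestor terms first.
#' @param term_names optional tibble (go, term) of descriptions.
#' @return tibble (go_id, term, n_study_with, n_study, n_bg_with, n_bg,
#'   p_value), ascending in p.
#' @export
go_enrichment <- function(study_genes, background_genes, go_map,
                          algorithm = c("classic", "elim"), alpha = 0.05,
                          parents = NULL, term_names = NULL) {
  algorithm <- match.arg(algorithm)
  if (!length(study_genes)) {
    warning("empty study set")
    return(tibble::tibble(go_id = character(), term = character(),
                          n_study_with = integer(), n_study = integer(),
                          n_bg_with = integer(), n_bg = integer(),
                          p_value = numeric()))
  }
  if (!all(study_genes %in% background_genes))
    stop("study genes must be a subset of the background", call. = FALSE)
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  go_map <- propagate_go(dplyr::distinct(go_map[, c("gene", "go")]), parents)
  go_map <- go_map[go_map$gene %in% background_genes, ]
  ann <- split(go_map$gene, go_map$go)
  N <- length(background_genes); n_st <- length(study_genes)
  terms <- names(ann)
  if (algorithm == "elim") {
    if (is.null(parents))
      stop("algorithm = \"elim\" needs a `parents` hierarchy", call. = FALSE)
    depth <- vapply(terms, function(t) {
      d <- 0L; cur <- t
      repeat {
        nxt <- parents$parent[parents$child %in% cur]
        if (!length(nxt)) return(d)
        d <- d + 1L; cur <- unique(nxt)
        if (d > 50L) return(d)
      }
    }, 0L)
    ord <- order(-depth, lengths(ann)[terms])
  } else {
    ord <- seq_along(terms)
  }
  removed <- setNames(vector("list", length(terms)), terms)
  rows <- vector("list", length(terms))
  anc_of <- function(t) {
    out <- character(); cur <- t
    while (!is.null(parents) && length(cur)) {
      nxt <- setdiff(unique(parents$parent[parents$child %in% cur]), out)
      out <- c(out, nxt); cur <- nxt
    }
    out
  }
  for (i in ord) {
    t <- terms[i]
    genes_t <- setdiff(ann[[t]], removed[[t]])
    K <- sum(background_genes %in% genes_t)
    k <- sum(study_genes %in% genes_t)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n_st, lower.tail = FALSE)
    rows[[i]] <- tibble::tibble(go_id = t, n_study_with = k, n_study = n_st,
                                n_bg_with = K, n_bg = N, p_value = p)
    if (algorithm == "elim" && p < alpha) {
      for (a in intersect(anc_of(t), terms))
        removed[[a]] <- union(removed[[a]], ann[[t]])
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$p_value)
  out$term <- if (!is.null(term_names))
    term_names$term[match(out$go_id, term_names$go)] else NA_character_
  out[, c("go_id", "term", "n_study_with", "n_study", "n_bg_with", "n_bg",
          "p_value")]
}

#' Tabulate effect categories for divergent and diagnostic SNP sets
#'
#' @param effects tibble from [classify_variants()] for the highly divergent
#'   SNPs.
#' @param diagnostic logical vector marking which rows are also fully
#'   diagnostic.
#' @return tibble with counts and proportions per category for both sets.
#' @export
tabulate_effects <- function(effects, diagnostic) {
  stopifnot(length(diagnostic) == nrow(effects))
  cat_f <- factor(effects$category, levels = EFFECT_LEVELS)
  n_div <- as.integer(table(cat_f))
  n_dia <- as.integer(table(cat_f[diagnostic]))
  tb <- tibble::tibble(
    category = EFFECT_LEVELS,
    n_divergent = n_div,
    prop_divergent = if (sum(n_div)) n_div / sum(n_div) else 0,
    n_diagnostic = n_dia,
    prop_diagnostic = if (sum(n_dia)) n_dia / sum(n_dia) else 0
  )
  dplyr::left_join(tb, EFFECT_FLAGS, by = "category")
}

#' Read a gene-to-GO map
#'
#' Two-column TSV (gene, comma-separated GO ids), returned long.
#'
#' @param path TSV path.
#' @return tibble (gene, go).
#' @export
read_go_map <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("gene", "go"),
                         show_col_types = FALSE, progress = FALSE)
  tidyr::separate_rows(raw, "go", sep = ",")
}
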