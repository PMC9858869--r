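# a hand-built single-gene landscape: plus-strand gene on a 2 kb chromosome
# with CDS "ATG GCA TAA" split over two exons
toy_annotation <- function(strand = "+") {
  u5 <- 6L; cds1 <- 6L; intron <- 20L; cds2 <- 3L; u3 <- 6L
  cds_seq <- "ATGGCATAA"
  gene_seq <- paste0("TTTTTT", substr(cds_seq, 1, 6),
                     paste(rep("C", intron), collapse = ""),
                     substr(cds_seq, 7, 9), "GGGGGG")
  gene_len <- nchar(gene_seq)
  gstart <- 501L
  chrom_seq <- paste0(paste(rep("A", gstart - 1L), collapse = ""),
                      if (strand == "+") gene_seq else
                        as.character(Biostrings::reverseComplement(
                          Biostrings::DNAString(gene_seq))),
                      paste(rep("A", 2000L - gstart + 1L - gene_len),
                            collapse = ""))
  fa <- Biostrings::DNAStringSet(c(chr1 = chrom_seq))
  gpos <- function(s, e) {
    if (strand == "+") c(gstart + s - 1L, gstart + e - 1L)
    else c(gstart + gene_len - e, gstart + gene_len - s)
  }
  row <- function(type, s, e, phase = NA_integer_, id, parent = NA) {
    gc <- gpos(s, e)
    tibble::tibble(chrom = "chr1", source = "t", type = type,
                   start = gc[1], end = gc[2], strand = strand,
                   phase = phase, id = id, parent = parent)
  }
  genes <- dplyr::bind_rows(
    row("gene", 1L, gene_len, id = "g1"),
    row("mRNA", 1L, gene_len, id = "g1.t1", parent = "g1"),
    row("five_prime_UTR", 1L, u5, id = "u5", parent = "g1.t1"),
    row("exon", 1L, u5 + cds1, id = "e1", parent = "g1.t1"),
    row("CDS", u5 + 1L, u5 + cds1, phase = 0L, id = "c1", parent = "g1.t1"),
    row("exon", u5 + cds1 + intron + 1L, gene_len, id = "e2",
        parent = "g1.t1"),
    row("CDS", u5 + cds1 + intron + 1L, u5 + cds1 + intron + cds2,
        phase = 0L, id = "c2", parent = "g1.t1"),
    row("three_prime_UTR", u5 + cds1 + intron + cds2 + 1L, gene_len,
        id = "u3", parent = "g1.t1")
  )
  # sense-coordinate -> genomic position of a single base
  base_at <- function(s) gpos(s, s)[1]
  list(fa = fa, genes = genes, base_at = base_at, u5 = u5, cds1 = cds1,
       intron = intron, gstart = gstart, gene_len = gene_len,
       strand = strand)
}

site_row <- function(pos, ref, alt) {
  tibble::tibble(chrom = "chr1", pos = pos, ref = ref, alt = alt)
}

test_that("coding effects follow the codon table on both strands", {
  for (strand in c("+", "-")) {
    tt <- toy_annotation(strand)
    flip <- function(b) if (strand == "+") b else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    # codon 3 position 3: TAA -> TAG, a synonymous stop
    p_syn <- tt$base_at(tt$u5 + tt$cds1 + tt$intron + 3L)
    eff <- classify_variants(site_row(p_syn, flip("A"), flip("G")),
                             tt$genes, tt$fa)
    expect_equal(eff$category, "synonymous_variant")
    expect_true(eff$within_gene); expect_true(eff$transcribed)
    # codon 2 position 1: GCA -> ACA, Ala -> Thr
    p_mis <- tt$base_at(tt$u5 + 4L)
    eff2 <- classify_variants(site_row(p_mis, flip("G"), flip("A")),
                              tt$genes, tt$fa)
    expect_equal(eff2$category, "missense_variant")
    # codon 1 position 1: ATG -> TTG, start lost
    p_lof <- tt$base_at(tt$u5 + 1L)
    eff3 <- classify_variants(site_row(p_lof, flip("A"), flip("T")),
                              tt$genes, tt$fa)
    expect_equal(eff3$category, "loss_of_function")
    # codon 2 position 2: GCA -> GTA on the coding strand... use stop gain:
    # codon 2 GCA -> TGA via position 1 G->T? that is ACA no; make stop:
    # codon 3 position 2: TAA -> TGA stays stop (synonymous)
    p_syn2 <- tt$base_at(tt$u5 + tt$cds1 + tt$intron + 2L)
    eff4 <- classify_variants(site_row(p_syn2, flip("A"), flip("G")),
                              tt$genes, tt$fa)
    expect_equal(eff4$category, "synonymous_variant")
  }
})

test_that("non-coding categories follow position and strand", {
  tt <- toy_annotation("+")
  # intronic positions: 1-2 bp from the exon boundary are splice LoF,
  # 3-8 bp are splice region, deeper is intron
  exon1_end <- tt$base_at(tt$u5 + tt$cds1)
  for (d in 1:2)
    expect_equal(classify_variants(site_row(exon1_end + d, "C", "G"),
                                   tt$genes, tt$fa)$category,
                 "loss_of_function")
  for (d in 3:8)
    expect_equal(classify_variants(site_row(exon1_end + d, "C", "G"),
                                   tt$genes, tt$fa)$category,
                 "splice_region_intron_variant")
  expect_equal(classify_variants(site_row(exon1_end + 10L, "C", "G"),
                                 tt$genes, tt$fa)$category,
               "intron_variant")
  # UTRs
  expect_equal(classify_variants(site_row(tt$base_at(2L), "T", "A"),
                                 tt$genes, tt$fa)$category,
               "five_prime_UTR_variant")
  expect_equal(classify_variants(site_row(tt$base_at(tt$gene_len - 1L),
                                          "G", "A"),
                                 tt$genes, tt$fa)$category,
               "three_prime_UTR_variant")
  # upstream within 5 kb (plus strand: before the gene start)
  expect_equal(classify_variants(site_row(tt$gstart - 100L, "A", "T"),
                                 tt$genes, tt$fa)$category,
               "upstream_gene_variant")
  expect_equal(classify_variants(site_row(tt$gstart + tt$gene_len + 50L,
                                          "A", "T"),
                                 tt$genes, tt$fa)$category,
               "downstream_gene_variant")
  # a SNP ~7.5 kb from the gene with updown_dist = 5000 is intergenic
  fa2 <- Biostrings::DNAStringSet(c(chr1 = paste(rep("A", 9000),
                                                 collapse = "")))
  expect_equal(classify_variants(site_row(8000L, "A", "T"), tt$genes, fa2,
                                 updown_dist = 5000)$category,
               "intergenic_region")
  expect_equal(classify_variants(site_row(3000L, "A", "T"), tt$genes, fa2,
                                 updown_dist = 5000)$category,
               "downstream_gene_variant")
  expect_equal(classify_variants(site_row(150L, "A", "T"), tt$genes, fa2,
                                 updown_dist = 300)$category,
               "intergenic_region")
})

test_that("every site gets exactly one category with the Y/N flag mapping", {
  ds <- small_sim()
  sites <- ds$gm$sites[seq_len(min(80, n_sites(ds$gm))), ]
  eff <- classify_variants(sites, ds$genes, ds$reference)
  expect_equal(nrow(eff), nrow(sites))
  expect_true(all(!is.na(eff$category)))
  flags <- divergescan:::EFFECT_FLAGS
  merged <- dplyr::left_join(eff[, c("category", "within_gene", "transcribed")],
                             flags, by = "category",
                             suffix = c("", "_want"))
  expect_equal(merged$within_gene, merged$within_gene_want)
  expect_equal(merged$transcribed, merged$transcribed_want)
  # transcribed implies within gene
  expect_true(all(!eff$transcribed | eff$within_gene))
})

test_that("gene assignment prefers containment, then distance, then start", {
  genes <- tibble::tibble(
    chrom = "chr1", source = "t", type = "gene",
    start = c(100L, 900L), end = c(300L, 1100L), strand = "+",
    phase = NA_integer_, id = c("A", "B"), parent = NA_character_
  )
  expect_equal(assign_gene(site_row(150L, "A", "T"), genes)$gene_id, "A")
  # equidistant between A (ends 300) and B (starts 900): tie -> lower start
  expect_equal(assign_gene(site_row(600L, "A", "T"), genes)$gene_id, "A")
  expect_equal(assign_gene(site_row(601L, "A", "T"), genes)$gene_id, "B")
  # no genes on the chromosome
  g2 <- genes; g2$chrom <- "chr2"
  expect_true(is.na(assign_gene(site_row(1L, "A", "T"), g2)$gene_id))
  # brute-force scan on random sites
  set.seed(47)
  for (pos in sample(1:1500, 10)) {
    d <- pmax(genes$start - pos, pos - genes$end, 0)
    want <- genes$id[order(d, genes$start)][1]
    expect_equal(assign_gene(site_row(pos, "A", "T"), genes)$gene_id, want)
  }
})

test_that("GO enrichment matches the hypergeometric tail exactly", {
  bg <- sprintf("g%02d", 1:20)
  study <- bg[1:5]
  go_map <- tibble::tibble(gene = bg[c(1, 2, 3, 6, 7)], go = "GO:X")
  res <- go_enrichment(study, bg, go_map)
  expect_equal(res$p_value, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$n_study_with, 3)
  # study = background: p = 1 for every term
  res2 <- go_enrichment(bg, bg, go_map)
  expect_true(all(res2$p_value == 1))
  expect_warning(go_enrichment(character(), bg, go_map), "empty")
  expect_error(go_enrichment("not_in_bg", bg, go_map), "subset")
  # random tables against fisher.test and phyper
  set.seed(53)
  for (i in 1:100) {
    N <- sample(10:40, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    bgg <- sprintf("x%03d", 1:N)
    gom <- tibble::tibble(gene = bgg[1:K], go = "GO:Y")
    st <- sample(bgg, n)
    k <- sum(st %in% bgg[1:K])
    res <- go_enrichment(st, bgg, gom)
    want <- stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                               alternative = "greater")$p.value
    expect_equal(res$p_value, want, tolerance = 1e-10)
  }
})

test_that("elim removes significant children from ancestors", {
  parents <- tibble::tibble(child = c("GO:child"), parent = c("GO:parent"))
  bg <- sprintf("g%02d", 1:30)
  # child term: genes 1-5, all in the study; parent: child genes + 6-10
  go_map <- tibble::tibble(
    gene = c(bg[1:5], bg[1:10]),
    go = c(rep("GO:child", 5), rep("GO:parent", 10))
  )
  study <- bg[1:6]
  classic <- go_enrichment(study, bg, go_map, algorithm = "classic",
                           parents = parents)
  elim <- go_enrichment(study, bg, go_map, algorithm = "elim",
                        parents = parents, alpha = 0.05)
  pc <- function(r, t) r$p_value[r$go_id == t]
  expect_equal(pc(classic, "GO:child"), pc(elim, "GO:child"))
  # the child is significant, so its genes leave the parent's set
  expect_gt(pc(elim, "GO:parent"), pc(classic, "GO:parent"))
  expect_error(go_enrichment(study, bg, go_map, algorithm = "elim"),
               "parents")
})

test_that("planted enrichment is recovered as the top term", {
  set.seed(59)
  hits <- 0
  for (rep in 1:20) {
    bg <- sprintf("g%03d", 1:60)
    terms <- sprintf("GO:%03d", 1:6)
    go_map <- tibble::tibble(
      gene = rep(bg, each = 2),
      go = unlist(lapply(seq_along(bg), function(i) sample(terms, 2)))
    )
    target_genes <- unique(go_map$gene[go_map$go == "GO:001"])
    study <- unique(c(sample(target_genes, min(8, length(target_genes))),
                      sample(bg, 4)))
    res <- go_enrichment(study, bg, go_map)
    if (res$go_id[1] == "GO:001") hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("effect tabulation produces proportions that sum to one", {
  eff <- tibble::tibble(
    category = c("intergenic_region", "intron_variant", "intron_variant",
                 "synonymous_variant"),
    chrom = "c", pos = 1:4
  )
  tab <- tabulate_effects(eff, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(tab$n_divergent), 4)
  expect_equal(sum(tab$prop_divergent), 1)
  expect_equal(sum(tab$n_diagnostic), 1)
  expect_equal(sum(tab$prop_diagnostic), 1)
  # empty diagnostic set: zero column
  tab0 <- tabulate_effects(eff, rep(FALSE, 4))
  expect_equal(sum(tab0$n_diagnostic), 0)
  expect_true(all(tab$category %in% divergescan:::EFFECT_LEVELS))
})
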