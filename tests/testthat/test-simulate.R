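# synthetic-data generator: determinism, planted structure, count model

small_params <- function(...) {
  simParams(seed = 7, n_coding_genes = 24, n_known_lncrnas = 8,
            n_novel_lncrnas = 14, n_bait_transcripts = 3,
            n_cis_pairs = 2, n_trans_pairs = 3, n_duplex_pairs = 3,
            n_protein_partners = 2, chromosome_length = 1500000, ...)
}

test_that("the generator is a pure function of (config, seed)", {
  d1 <- file.path(tempdir(), "sim_det_1")
  d2 <- file.path(tempdir(), "sim_det_2")
  s1 <- simulateDataset(small_params(), outdir = d1)
  s2 <- simulateDataset(small_params(), outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  s3 <- simulateDataset(simParams(seed = 8, n_coding_genes = 24,
                                  n_known_lncrnas = 8, n_novel_lncrnas = 14,
                                  n_bait_transcripts = 3, n_cis_pairs = 2,
                                  n_trans_pairs = 3, n_duplex_pairs = 3,
                                  n_protein_partners = 2,
                                  chromosome_length = 1500000))
  expect_false(identical(as.character(s3$genome), as.character(s1$genome)))
})

test_that("invalid parameters are rejected", {
  expect_error(simParams(nb_dispersion = 0), "dispersion")
  expect_error(simParams(duplex_length = 5), "duplex_length")
  expect_error(simParams(n_novel_lncrnas = 3, n_cis_pairs = 2,
                         n_trans_pairs = 2, n_duplex_pairs = 2,
                         n_protein_partners = 2), "planted pairs")
  expect_error(simParams(n_coding_genes = 400, n_novel_lncrnas = 400,
                         chromosome_length = 100000) |>
                 simulateAnnotation(), "capacity")
})

test_that("each bait violates exactly its designated structural rule", {
  ds <- simulateDataset(small_params())
  tr <- ds$manifest$transcripts
  baits <- tr[tr$class == "bait", ]
  expect_identical(sort(unique(baits$bait_reason)),
                   c("low_expression", "mono_exonic", "too_short"))
  rep <- applyStructuralFilters(ds$annotation, ds$counts)
  for (i in seq_len(nrow(baits))) {
    row <- rep[rep$transcript_id == baits$transcript_id[i], ]
    expect_identical(row$status, "removed")
    expect_identical(row$reason, baits$bait_reason[i])
  }
  # exactly one rule violated: flipping the failing attribute retains them
  lens <- spliceLengths(ds$annotation)[baits$transcript_id]
  nex <- exonCounts(ds$annotation)[baits$transcript_id]
  tot <- rowSums(ds$counts)[baits$gene_id]
  for (i in seq_len(nrow(baits))) {
    r <- baits$bait_reason[i]
    expect_identical(unname(nex[i] < 2), r == "mono_exonic")
    expect_identical(unname(lens[i] <= 200), r == "too_short")
    expect_identical(unname(tot[i] <= 10), r == "low_expression")
  }
})

test_that("planted CIS pairs sit at the configured genomic gap in the GTF", {
  ds <- default_dataset()
  gtf <- readAnnotationGTF(file.path(default_dataset_dir(),
                                     "annotation.gtf"))
  spans <- geneSpans(gtf)
  cis <- ds$manifest$cis_pairs
  expect_gt(nrow(cis), 0)
  for (i in seq_len(nrow(cis))) {
    d <- genomicDistance(spans[cis$del_gene[i]], spans[cis$deg_gene[i]])
    expect_identical(as.integer(d), as.integer(cis$gap[i]))
  }
})

test_that("coding and noncoding classes separate by longest-ORF length", {
  ds <- default_dataset()
  tr <- ds$manifest$transcripts
  seqs <- as.character(txSequences(ds$annotation))
  orf_len <- vapply(seqs, function(s) longestOrf(s)$length, numeric(1))
  med_cod <- median(orf_len[tr$transcript_id[tr$class == "coding"]])
  med_nc <- median(orf_len[tr$transcript_id[
    tr$class %in% c("known_lncRNA", "novel_lncRNA")]])
  expect_gte(med_cod - med_nc, 200)
  # lncRNAs never carry an ORF of 100 nt or more
  expect_lt(max(orf_len[tr$transcript_id[
    tr$class %in% c("known_lncRNA", "novel_lncRNA")]]), 100)
  # coding ORFs are always >= 300 nt
  expect_gte(min(orf_len[tr$transcript_id[tr$class == "coding"]]), 300)
})

test_that("planted duplex windows are exact reverse complements", {
  ds <- default_dataset()
  dp <- ds$manifest$duplex_pairs
  seqs <- as.character(txSequences(ds$annotation))
  expect_gt(nrow(dp), 0)
  for (i in seq_len(nrow(dp))) {
    w_l <- substr(seqs[[dp$del_tx[i]]], dp$lnc_start[i], dp$lnc_end[i])
    w_m <- substr(seqs[[dp$deg_tx[i]]], dp$mrna_start[i], dp$mrna_end[i])
    expect_identical(w_l, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(w_m))))
  }
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  p <- simParams(seed = 5, n_coding_genes = 150, n_known_lncrnas = 25,
                 n_novel_lncrnas = 25, n_bait_transcripts = 0,
                 n_cis_pairs = 0, n_trans_pairs = 0, n_duplex_pairs = 0,
                 n_protein_partners = 0, de_fraction = 0,
                 nb_dispersion = 1e-6, chromosome_length = 3000000)
  ann <- simulateAnnotation(p)
  cnt <- simulateCounts(ann$annotation, ann$manifest, p)
  base <- cnt$base_means
  m <- rowMeans(cnt$counts)
  se <- sqrt(base / ncol(cnt$counts))
  within3 <- abs(m - base) <= 3 * se
  expect_gte(mean(within3), 0.95)   # ~99.7% expected, allow sampling noise
})

test_that("planted fold changes are recovered in the FPKM tissue ratio", {
  p <- simParams(seed = 42, planted_log2fc = 2)
  ds <- simulateDataset(p)
  lens <- spliceLengths(ds$annotation)
  g_of <- setNames(geneIds(ds$annotation), transcriptIds(ds$annotation))
  glen <- setNames(lens, g_of[names(lens)])[rownames(ds$counts)]
  fpkm <- computeFPKM(ds$counts, glen)
  de <- ds$manifest$de
  up_t <- de$gene_id[de$tissue == "T" & de$log2fc == 2]
  tis <- ds$samples$tissue
  ratio <- rowMeans(fpkm[up_t, tis == "T", drop = FALSE]) /
    rowMeans(fpkm[up_t, tis == "E", drop = FALSE])
  expect_gte(mean(ratio >= 2.5 & ratio <= 6.5), 0.95)
})

test_that("a base mean of zero yields an all-zero count row", {
  p <- small_params()
  ann <- simulateAnnotation(p)
  g0 <- ann$manifest$transcripts$gene_id[1]
  cnt <- simulateCounts(ann$annotation, ann$manifest, p,
                        base_means = setNames(0, g0))
  expect_true(all(cnt$counts[g0, ] == 0))
})

test_that("proteins are ORF translations; positives are interface-tilted", {
  ds <- default_dataset()
  expect_identical(lncLink:::translate_orf("ATGAAATAG", 1, 9), "MK")
  prot2 <- simulateProteins(ds$annotation, ds$manifest)
  expect_identical(as.character(ds$proteins), as.character(prot2))
  pos <- ds$manifest$protein_pairs$deg_gene
  neg <- setdiff(names(ds$proteins), pos)
  frac_iface <- function(p) {
    a <- strsplit(as.character(p), "")[[1]]
    mean(a %in% lncLink:::INTERFACE_AA)
  }
  f_pos <- vapply(ds$proteins[pos], frac_iface, numeric(1))
  f_neg <- vapply(ds$proteins[neg], frac_iface, numeric(1))
  expect_gt(mean(f_pos), mean(f_neg) + 0.1)
  expect_error(simulateProteins(ds$annotation, ds$manifest,
                                genes = "G_NLNC001"), "ORF")
})
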