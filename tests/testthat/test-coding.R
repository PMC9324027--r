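# ORF finding, the seven scorers, consensus vote, domain filter

test_that("ORF conventions: ATG..stop inclusive, run-to-end incomplete", {
  fr <- findOrfs("ATGAAATAG")
  expect_equal(fr$length[fr$frame == 0], 9)
  expect_true(fr$complete[fr$frame == 0])
  fr2 <- findOrfs("ATGAAACCC")
  expect_equal(fr2$length[fr2$frame == 0], 9)
  expect_false(fr2$complete[fr2$frame == 0])
  expect_equal(longestOrf("CCCCCC")$length, 0)
  # frame-1 ORF: C + ATG AAA TAG
  lo <- longestOrf("CATGAAATAG")
  expect_equal(lo$frame, 1)
  expect_equal(lo$start, 2)
  expect_equal(lo$end, 10)
  # first ATG of a stop-delimited segment opens the ORF
  lo2 <- longestOrf("ATGATGAAATAG")
  expect_equal(lo2$start, 1)
  expect_equal(lo2$length, 12)
})

test_that("Fickett score equals an independent lookup-procedure oracle", {
  expect_equal(fickettScore(strrep("A", 300)),
               fickett_oracle(strrep("A", 300)))
  set.seed(7)
  for (k in 1:20) {
    s <- rand_seq(sample(200:800, 1), gc = runif(1, 0.3, 0.7))
    expect_equal(fickettScore(s), fickett_oracle(s))
  }
  s <- rand_seq(300)
  expect_identical(fickettScore(s), fickettScore(s))  # deterministic
})

test_that("random-composition Fickett scores sit between the class means", {
  th <- codingScorerTables()$thresholds
  mc <- th$mean_coding[th$scorer == "fickett"]
  mn <- th$mean_noncoding[th$scorer == "fickett"]
  set.seed(7)
  sc <- vapply(1:100, function(i) fickettScore(rand_seq(400, gc = 0.5)),
               numeric(1))
  expect_gt(mean(sc), mn)
  expect_lt(mean(sc), mc)
})

test_that("hexamer score has its closed forms", {
  u <- setNames(rep(1 / 4096, 4096), lncLink:::mkAllStrings_acgt(6))
  s <- rand_seq(300)
  expect_equal(hexamerScore(s, u, u), 0)
  # one boosted period-3 hexamer, sequence = that hexamer repeated
  cod <- u; cod["ACGACG"] <- 2 * u[["ACGACG"]]
  expect_equal(hexamerScore(strrep("ACG", 40), cod, u), log(2))
  bad <- u; bad[1] <- 0
  expect_error(hexamerScore(s, bad, u), "> 0")
})

test_that("orf coverage and stop density behave as documented", {
  cseq <- lncLink:::sample_coding_seq
  set.seed(5)
  sc <- cseq()
  expect_equal(orfCoverage(sc$seq),
               (sc$orf_end - sc$orf_start + 1) / nchar(sc$seq))
  # coding: one nearly stop-free frame -> low min stop rate
  expect_lt(stopDensityScore(sc$seq), stopDensityScore(rand_seq(600)))
})

test_that("kmer and triplet scorers are deterministic and bounded", {
  s <- rand_seq(400)
  k1 <- kmerSpectrumScore(s)
  expect_gt(k1, 0); expect_lt(k1, 1)
  expect_identical(k1, kmerSpectrumScore(s))
  expect_identical(tripletFrameScore(s), tripletFrameScore(s))
})

test_that("consensus requires at least 5 of 7 noncoding votes", {
  v <- rep("noncoding", 7)
  expect_identical(codingConsensus(v), "noncoding")
  v[1:3] <- "coding"
  expect_identical(codingConsensus(v), "coding")   # only 4 noncoding
  v <- c(rep("noncoding", 5), rep("coding", 2))
  expect_identical(codingConsensus(v), "noncoding")
})

test_that("flipping a vote towards noncoding never flips the consensus back", {
  pats <- expand.grid(rep(list(c("coding", "noncoding")), 7),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pats))) {
    v <- unlist(pats[i, ])
    c0 <- codingConsensus(v)
    for (j in which(v == "coding")) {
      v2 <- v; v2[j] <- "noncoding"
      if (c0 == "noncoding")
        expect_identical(codingConsensus(v2), "noncoding")
    }
  }
})

test_that("scorers separate generator-style coding from noncoding", {
  set.seed(123)
  cod <- vapply(1:30, function(i) lncLink:::sample_coding_seq()$seq,
                character(1))
  nc <- vapply(1:30, function(i) lncLink:::sample_noncoding_seq(),
               character(1))
  names(cod) <- paste0("c", 1:30); names(nc) <- paste0("n", 1:30)
  a <- scoreCodingPotential(c(cod, nc))
  expect_gte(mean(a$consensus[1:30] == "coding"), 0.8)
  expect_gte(mean(a$consensus[31:60] == "noncoding"), 0.8)
  expect_true(all(a$noncoding_votes >= 0 & a$noncoding_votes <= 7))
  expect_identical(a$consensus,
                   ifelse(a$noncoding_votes >= 5, "noncoding", "coding"))
})

test_that("the domain filter gates final classification", {
  lib <- defaultMotifLibrary()
  expect_gt(length(lib), 5)
  # consensus-noncoding transcript with no ORF >= 90 nt -> novel_lncRNA
  set.seed(9)
  s_free <- lncLink:::sample_noncoding_seq(400)
  fake <- data.frame(transcript_id = "t1", consensus = "noncoding")
  out <- domainFilter(fake, c(t1 = s_free), lib)
  expect_identical(out$final_class, "novel_lncRNA")
  expect_identical(out$domain_hit, "")
  # transcript carrying the bundled TESTDOM consensus peptide -> coding
  aa_to_codon <- setNames(names(Biostrings::GENETIC_CODE),
                          Biostrings::GENETIC_CODE)
  pep <- "WRHWKNDEQSTW"
  codons <- vapply(strsplit(pep, "")[[1]],
                   function(a) aa_to_codon[[a]], character(1))
  orf <- paste0("ATG", paste(codons, collapse = ""),
                strrep("GCA", 17), "TAA")   # 93 nt, ORF >= 90
  s_dom <- paste0(substr(s_free, 1, 100), orf, substr(s_free, 101, 300))
  out2 <- domainFilter(data.frame(transcript_id = "t2",
                                  consensus = "noncoding"),
                       c(t2 = s_dom), lib)
  expect_identical(out2$final_class, "coding")
  expect_identical(out2$domain_hit, "TESTDOM")
  # consensus-coding transcripts stay coding regardless of motifs
  out3 <- domainFilter(data.frame(transcript_id = "t3",
                                  consensus = "coding"),
                       c(t3 = s_free), lib)
  expect_identical(out3$final_class, "coding")
  expect_error(domainFilter(fake, c(t1 = s_free), list()), "empty")
})
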