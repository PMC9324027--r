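# formats: GTF round-trip, sequence extraction, FPKM

test_that("GTF round-trips a two-exon transcript identically", {
  ann <- tiny_annotation(list(
    list(id = "tx1", gene = "g1", chr = "chr1", strand = "+",
         exons = list(c(100, 200), c(300, 450)), bt = "other",
         seq = rand_seq(252))))
  f <- tempfile(fileext = ".gtf")
  writeAnnotationGTF(ann, f)
  back <- readAnnotationGTF(f)
  expect_identical(transcriptIds(back), "tx1")
  expect_identical(geneIds(back), "g1")
  expect_identical(unname(biotypes(back)), "other")
  expect_equal(GenomicRanges::start(back@exons[["tx1"]]), c(100, 300))
  expect_equal(GenomicRanges::end(back@exons[["tx1"]]), c(200, 450))
  expect_equal(as.character(GenomicRanges::strand(back@exons[["tx1"]])),
               c("+", "+"))
  # second round trip is byte-identical
  f2 <- tempfile(fileext = ".gtf")
  writeAnnotationGTF(back, f2)
  ann2 <- tiny_annotation(list(
    list(id = "tx1", gene = "g1", chr = "chr1", strand = "+",
         exons = list(c(100, 200), c(300, 450)), bt = "other")))
  writeAnnotationGTF(ann2, f)
  expect_identical(readLines(f), readLines(f2))
})

test_that("spliced length follows 1-based inclusive interval arithmetic", {
  ann <- tiny_annotation(list(
    list(id = "tx1", gene = "g1", chr = "chr1", strand = "+",
         exons = list(c(100, 200), c(300, 450)), bt = "other")))
  expect_identical(unname(spliceLengths(ann)), 252L)  # 101 + 151
  expect_identical(unname(exonCounts(ann)), 2L)
})

test_that("malformed or 0-based GTF lines are rejected with line numbers", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
    "chr1\tsrc\texon\t0\t10\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";"),
    f)
  expect_error(readAnnotationGTF(f), "line 2.*start < 1")
  writeLines(c(
    "chr1\tsrc\texon\t20\t10\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";"),
    f)
  expect_error(readAnnotationGTF(f), "line 1.*end < start")
  writeLines("chr1\tonly\tthree", f)
  expect_error(readAnnotationGTF(f), "line 1")
})

test_that("transcript sequences are exon concatenations, revcomp on minus", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTT"))
  plus <- tiny_annotation(list(
    list(id = "t1", gene = "g1", chr = "chr1", strand = "+",
         exons = list(c(1, 4)), bt = "other")))
  expect_equal(as.character(txSequences(
    fillTranscriptSequences(plus, genome))[["t1"]]), "ACGT")
  minus <- tiny_annotation(list(
    list(id = "t1", gene = "g1", chr = "chr1", strand = "-",
         exons = list(c(1, 4)), bt = "other")))
  # ACGT is its own reverse complement
  expect_equal(as.character(txSequences(
    fillTranscriptSequences(minus, genome))[["t1"]]), "ACGT")
  twoex <- tiny_annotation(list(
    list(id = "t1", gene = "g1", chr = "chr1", strand = "+",
         exons = list(c(1, 3), c(5, 5)), bt = "other")))
  expect_equal(as.character(txSequences(
    fillTranscriptSequences(twoex, genome))[["t1"]]), "ACGT")
  # errors: unknown chromosome, exon beyond chromosome end
  badchr <- tiny_annotation(list(
    list(id = "t1", gene = "g1", chr = "chrX", strand = "+",
         exons = list(c(1, 3)), bt = "other")))
  expect_error(fillTranscriptSequences(badchr, genome), "chromosome")
  toolong <- tiny_annotation(list(
    list(id = "t1", gene = "g1", chr = "chr1", strand = "+",
         exons = list(c(2, 9)), bt = "other")))
  expect_error(fillTranscriptSequences(toolong, genome), "beyond")
})

test_that("FPKM matches its closed form and scales linearly in counts", {
  counts <- rbind(a = c(100L, 0L), b = c(999900L, 1000000L))
  lens <- c(a = 1000, b = 2000)
  f <- computeFPKM(counts, lens)
  expect_equal(unname(f["a", 1]), 100)   # count 100, 1 kb, 1e6 library
  expect_equal(unname(f["a", 2]), 0)     # zero count -> zero FPKM
  counts2 <- rbind(a = 50L, b = 1999950L)
  expect_equal(unname(computeFPKM(counts2, c(a = 500, b = 1))["a", 1]), 50)
  # oracle: elementwise formula on a random matrix
  set.seed(3)
  m <- matrix(rpois(40, 200), 8, 5,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
  L <- setNames(sample(200:2000, 8), rownames(m))
  f2 <- computeFPKM(m, L)
  lib <- colSums(m)
  for (i in 1:8) for (j in 1:5)
    expect_equal(f2[i, j], m[i, j] / ((L[[i]] / 1e3) * (lib[[j]] / 1e6)))
  # linearity at fixed library size: move counts between two features
  m2 <- m
  m2[1, ] <- m[1, ] * 2L
  m2[2, ] <- m[2, ] - m[1, ]    # column sums preserved
  f3 <- computeFPKM(m2, L)
  expect_equal(f3[1, ], 2 * f2[1, ])
  expect_equal(f3[3, ], f2[3, ])
})

test_that("FPKM rejects degenerate input", {
  counts <- rbind(a = c(1L, 1L))
  expect_error(computeFPKM(counts, c(a = 0)), "length")
  counts0 <- rbind(a = c(1L, 0L))
  expect_error(computeFPKM(counts0, c(a = 100)), "library")
})

test_that("interval lengths agree with position enumeration", {
  set.seed(11)
  for (k in 1:50) {
    s <- sample(1:10000, 1); e <- s + sample(0:500, 1)
    gr <- GenomicRanges::GRanges("c", IRanges::IRanges(s, e))
    expect_identical(GenomicRanges::width(gr), length(seq(s, e)))
  }
})

test_that("count matrix and sample sheet readers validate input", {
  d <- default_dataset_dir()
  cnt <- readCountMatrix(file.path(d, "counts.tsv"))
  smp <- readSampleSheet(file.path(d, "samples.tsv"))
  expect_true(all(cnt >= 0))
  expect_identical(colnames(cnt), smp$sample_id)
  se <- makeCountsSE(cnt, smp)
  expect_s4_class(se, "SummarizedExperiment")
  expect_identical(SummarizedExperiment::assay(se, "counts"), cnt)
  bad <- smp; bad$tissue[1] <- "XX"
  f <- tempfile(); write.table(bad, f, sep = "\t", row.names = FALSE,
                               quote = FALSE)
  expect_error(readSampleSheet(f), "tissue")
})
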