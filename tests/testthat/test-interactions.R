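# CIS distance, TRANS correlation, duplex ndG, RNA-protein, assembly, export

test_that("genomic distance: overlap 0, gap arithmetic, cross-chromosome NA", {
  gr <- function(chr, s, e) GenomicRanges::GRanges(chr,
                                                   IRanges::IRanges(s, e))
  expect_equal(genomicDistance(gr("c1", 100, 500), gr("c1", 300, 700)), 0)
  expect_equal(genomicDistance(gr("c1", 1, 1000), gr("c1", 51001, 52000)),
               50000)
  expect_equal(genomicDistance(gr("c1", 51001, 52000), gr("c1", 1, 1000)),
               50000)   # symmetric
  expect_true(is.na(genomicDistance(gr("c1", 1, 10), gr("c2", 1, 10))))
})

test_that("CIS finder is strict at the threshold and matches brute force", {
  spans <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(1, 101001, 100999, 300000),
                           c(1000, 102000, 101500, 301000)))
  names(spans) <- c("del1", "degA", "degB", "degC")
  # gaps from del1: degA = 100000 (excluded), degB = 99998 (kept)
  cis <- findCis("del1", c("degA", "degB", "degC"), spans)
  expect_identical(cis$deg_id, "degB")
  expect_equal(cis$distance, 99998)
  expect_identical(nrow(findCis("del1", "degB", spans, max_distance = 0)),
                   0L)
  expect_error(findCis("del1", "nope", spans), "not located")
})

test_that("TRANS finder applies |r| > 0.9 with the t-test p-value", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1, dimnames = list("d1", NULL))
  keep <- findTrans(x, x + 1)$relations          # y = x: r = 1
  expect_identical(keep$sign, "positive")
  neg <- findTrans(x, -x)$relations              # y = -x: r = -1
  expect_identical(neg$sign, "negative")
  # hand-computed example: r ~ 0.9897, p from t with df = 4
  y <- matrix(c(1, 2, 3, 4, 5, 7), 1, dimnames = list("g1", NULL))
  res <- findTrans(x, y)$relations
  sx <- c(1, 2, 3, 4, 5, 6); sy <- c(1, 2, 3, 4, 5, 7)
  r_hand <- sum((sx - mean(sx)) * (sy - mean(sy))) /
    sqrt(sum((sx - mean(sx))^2) * sum((sy - mean(sy))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(round(r_hand, 4), 0.9897)
  expect_equal(res$p, 2 * pt(-abs(r_hand * 2 / sqrt(1 - r_hand^2)), 4),
               tolerance = 1e-12)
  # r = 0.85 fails the threshold even if p is small
  set.seed(16)
  z <- rnorm(18)
  w <- 0.85 * scale(z)[, 1] + sqrt(1 - 0.72) * rnorm(18)
  mats <- findTrans(matrix(z, 1, dimnames = list("a", NULL)),
                    matrix(w, 1, dimnames = list("b", NULL)))
  expect_true(nrow(mats$relations) == 0 ||
                abs(cor(z, w)) > 0.9)
  # zero-variance profiles are skipped with a warning
  expect_warning(
    sk <- findTrans(matrix(5, 1, 6, dimnames = list("cst", NULL)),
                    matrix(1:6, 1, dimnames = list("ok", NULL))),
    "zero-variance")
  expect_identical(sk$skipped$feature_id, "cst")
  # permutation symmetry: permuting samples of both profiles leaves r fixed
  set.seed(17)
  a <- matrix(rnorm(18), 1, dimnames = list("a", NULL))
  b <- matrix(rnorm(18), 1, dimnames = list("b", NULL))
  pm <- sample(18)
  expect_equal(cor(a[1, ], b[1, ]), cor(a[1, pm], b[1, pm]))
})

test_that("duplex dG equals the exhaustive contiguous-pairing oracle", {
  set.seed(18)
  for (k in 1:30) {
    x <- rand_seq(sample(15:30, 1)); y <- rand_seq(sample(15:30, 1))
    mine <- duplexNdG(x, y)
    expect_equal(mine$dG, duplex_oracle_dG(x, y), info = paste(x, y))
  }
})

test_that("duplex scoring: no pairing, perfect complements, N handling", {
  r <- duplexNdG(strrep("A", 20), strrep("A", 20))
  expect_identical(r$dG, 0); expect_identical(r$ndG, 0)
  s <- rand_seq(20)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  perf <- duplexNdG(s, rc)
  expect_equal(perf$paired_length, 20)
  expect_lt(perf$ndG, -0.1)
  # extending a perfect complement only strengthens the duplex
  s2 <- rand_seq(30)
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s2)))
  expect_lte(duplexNdG(s2, rc2)$dG,
             duplexNdG(substr(s2, 1, 20),
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(substr(s2, 1, 20)))))$dG)
  # all-N sequences never pair
  rn <- duplexNdG(strrep("N", 15), rand_seq(15))
  expect_identical(rn$dG, 0)
  expect_error(duplexNdG("ACGT", rand_seq(20)), ">= 10")
})

test_that("RNA-protein scores are deterministic probabilities", {
  set.seed(19)
  lnc <- rand_seq(400)
  prot <- paste(sample(lncLink:::AA20, 150, replace = TRUE), collapse = "")
  s <- rnaProteinScore(lnc, prot)
  expect_gt(s, 0); expect_lt(s, 1)
  expect_identical(s, rnaProteinScore(lnc, prot))
  # X is imputed at mean propensity; unknown letters are an error
  expect_no_error(rnaProteinScore(lnc, paste0(prot, "XXX")))
  expect_error(rnaProteinScore(lnc, paste0(prot, "B")), "unknown residue")
})

test_that("relation assembly merges tiers, counts and gene classes", {
  empty <- assembleRelations()
  expect_identical(nrow(empty$relations), 0L)
  expect_true(all(empty$counts$n_all == 0))
  trans <- data.frame(del_id = "L1", deg_id = "G1", r = 0.95,
                      p = 1e-4, sign = "positive", tag = "E_vs_T")
  rr <- data.frame(del_id = "L1", deg_id = "G1", ndG = -0.5, tag = "E_vs_T")
  rp <- data.frame(del_id = "L2", deg_id = "G2", probability = 0.99,
                   tag = "E_vs_T")
  asm <- assembleRelations(trans = trans, rna_rna = rr, rna_protein = rp,
                           subset = "G1")
  expect_identical(nrow(asm$relations), 3L)
  gc <- setNames(asm$gene_classes$kinds, asm$gene_classes$deg_id)
  expect_identical(gc[["G1"]], "RNA_RNA+TRANS")
  expect_identical(gc[["G2"]], "RNA_PROTEIN")
  expect_true(all(asm$counts$n_subset <= asm$counts$n_all))
  # duplicates collapse with a warning
  expect_warning(dup <- assembleRelations(trans = rbind(trans, trans)),
                 "duplicate")
  expect_identical(nrow(dup$relations), 1L)
  expect_identical(dup$n_duplicates, 1L)
})

test_that("network exports round-trip through standard readers", {
  rel <- assembleRelations(
    trans = data.frame(del_id = c("L1", "L2"), deg_id = c("G1", "G1"),
                       r = c(0.95, -0.93), sign = c("positive", "negative"),
                       tag = "all"),
    rna_rna = data.frame(del_id = "L1", deg_id = "G2", ndG = -0.4,
                         tag = "all"))$relations
  sif <- tempfile(fileext = ".sif")
  exportNetworkSIF(rel, sif)
  ln <- readLines(sif)
  expect_identical(length(ln), nrow(rel))
  expect_true("L1 RNA_RNA G2" %in% ln)
  gml <- tempfile(fileext = ".graphml")
  exportNetworkGraphML(rel, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 4)             # L1, L2, G1, G2
  expect_equal(igraph::gsize(g), nrow(rel))      # n relations = n edges
  el <- igraph::as_data_frame(g)
  expect_setequal(paste(el$from, el$to, el$kind),
                  paste(rel$del_id, rel$deg_id, rel$kind))
  expect_error(exportNetworkSIF(rel[0, ], tempfile()), "empty")
})
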