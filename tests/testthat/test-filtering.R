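# known-lncRNA annotation by similarity + structural filter cascade

test_that("similarity classification honours identity and E-value rules", {
  set.seed(21)
  ref <- rand_seq(500)
  ann <- tiny_annotation(list(
    list(id = "exact", gene = "g1", chr = "c", strand = "+",
         exons = list(c(1, 500)), bt = "other", seq = ref),
    list(id = "diverged", gene = "g2", chr = "c", strand = "+",
         exons = list(c(1000, 1499)), bt = "other",
         seq = lncLink:::mutate_seq(ref, 0.15)),
    list(id = "tiny", gene = "g3", chr = "c", strand = "+",
         exons = list(c(2000, 2019)), bt = "other",
         seq = substr(ref, 101, 120))))
  res <- annotateKnownLncRNAs(ann, c(REF1 = ref))
  expect_identical(res$known, "exact")
  expect_setequal(res$candidates, c("diverged", "tiny"))
  expect_setequal(c(res$known, res$candidates), transcriptIds(ann))
  h <- res$hits
  exact <- h[h$query_id == "exact", ][1, ]
  expect_equal(exact$percent_identity, 100)
  expect_lt(exact$e_value, 1e-10)
  div <- h[h$query_id == "diverged", ][1, ]
  expect_lt(div$percent_identity, 90)   # ~85% planted identity
  expect_gt(div$percent_identity, 75)
  tiny <- h[h$query_id == "tiny", ][1, ]
  # a perfect 20-nt match cannot reach E < 1e-10 at this database size
  expect_equal(tiny$percent_identity, 100)
  expect_gt(tiny$e_value, 1e-10)
})

test_that("the Karlin-Altschul E-value follows its closed form", {
  lam <- lncLink:::ka_lambda()
  # lambda solves 0.25 e^(2L) + 0.75 e^(-3L) = 1
  expect_equal(0.25 * exp(2 * lam) + 0.75 * exp(-3 * lam), 1,
               tolerance = 1e-9)
  expect_equal(karlinAltschulE(40, 20, 500),
               0.41 * 20 * 500 * exp(-lam * 40))
})

test_that("internal aligner agrees with the Smith-Waterman oracle", {
  set.seed(31)
  for (k in 1:15) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    a <- rand_seq(n1)
    b <- if (k %% 3 == 0) rand_seq(n2)
         else lncLink:::mutate_seq(substr(a, 1, min(n1, n2)),
                                   runif(1, 0, 0.2))
    mine <- lncLink:::.sw_align(a, b, 2, -3, 5, 2)
    orac <- sw_oracle(a, b)
    expect_equal(mine$score, orac$score)
    expect_lt(abs(mine$identity - orac$identity), 1)
  }
})

test_that("empty inputs are rejected", {
  ann <- tiny_annotation(list(
    list(id = "t", gene = "g", chr = "c", strand = "+",
         exons = list(c(1, 10)), bt = "other", seq = rand_seq(10))))
  expect_error(annotateKnownLncRNAs(ann, character(0)), "empty")
  ann2 <- tiny_annotation(list(
    list(id = "t", gene = "g", chr = "c", strand = "+",
         exons = list(c(1, 10)), bt = "other")))
  expect_error(annotateKnownLncRNAs(ann2, c(R = rand_seq(100))),
               "sequences")
})

filter_fixture <- function() {
  specs <- list(
    list(id = "pc", gene = "g_pc", chr = "c", strand = "+",
         exons = list(c(1, 250), c(400, 649)), bt = "protein_coding"),
    list(id = "short3", gene = "g_s", chr = "c", strand = "+",
         exons = list(c(1000, 1049), c(1200, 1249), c(1400, 1449)),
         bt = "other"),                                   # 150 nt, 3 exons
    list(id = "mono", gene = "g_m", chr = "c", strand = "+",
         exons = list(c(2000, 2499)), bt = "other"),      # 500 nt, 1 exon
    list(id = "lowx", gene = "g_l", chr = "c", strand = "+",
         exons = list(c(3000, 3249), c(3400, 3649)), bt = "other"),
    list(id = "keep", gene = "g_k", chr = "c", strand = "+",
         exons = list(c(4000, 4100), c(4200, 4299)), bt = "other"))
  ann <- tiny_annotation(specs)
  counts <- matrix(c(50L, 50L, 50L, 5L, 11L), ncol = 1,
                   dimnames = list(c("pc", "short3", "mono", "lowx",
                                     "keep"), "s1"))
  list(ann = ann, counts = counts)
}

test_that("the cascade removes each violation with its recorded reason", {
  fx <- filter_fixture()
  rep <- applyStructuralFilters(fx$ann, fx$counts)
  got <- setNames(rep$reason, rep$transcript_id)
  expect_identical(got[["pc"]], "annotated_protein_coding")
  expect_identical(got[["short3"]], "too_short")
  expect_identical(got[["mono"]], "mono_exonic")
  expect_identical(got[["lowx"]], "low_expression")
  expect_identical(got[["keep"]], "")
  expect_identical(retainedIds(rep), "keep")   # 201 nt, 2 exons, 11 counts
  sc <- attr(rep, "stage_counts")
  expect_identical(unname(sc), c(5L, 4L, 3L, 2L, 1L))
  expect_true(all(diff(sc) <= 0))
})

test_that("boundary values (exactly 200 nt, exactly 10 counts) are removed", {
  ann <- tiny_annotation(list(
    list(id = "len200", gene = "g1", chr = "c", strand = "+",
         exons = list(c(1, 100), c(200, 299)), bt = "other"),
    list(id = "cnt10", gene = "g2", chr = "c", strand = "+",
         exons = list(c(1000, 1150), c(1300, 1449)), bt = "other")))
  counts <- matrix(c(50L, 10L), ncol = 1,
                   dimnames = list(c("len200", "cnt10"), "s1"))
  rep <- applyStructuralFilters(ann, counts)
  expect_identical(rep$reason[rep$transcript_id == "len200"], "too_short")
  expect_identical(rep$reason[rep$transcript_id == "cnt10"],
                   "low_expression")
})

test_that("a transcript with no count row counts as zero expression", {
  fx <- filter_fixture()
  cnt <- fx$counts[c("pc", "short3", "mono", "keep"), , drop = FALSE]
  rep <- applyStructuralFilters(fx$ann, cnt)
  expect_identical(rep$reason[rep$transcript_id == "lowx"],
                   "low_expression")
})

test_that("filtering is idempotent and order-independent in the retained set", {
  ds <- default_dataset()
  rep1 <- applyStructuralFilters(ds$annotation, ds$counts)
  kept <- retainedIds(rep1)
  rep2 <- applyStructuralFilters(ds$annotation, ds$counts, ids = kept)
  expect_identical(retainedIds(rep2), kept)
  expect_true(all(rep2$status == "retained"))
  # retained set = intersection of the single-filter survivor sets,
  # regardless of cascade order
  bt <- biotypes(ds$annotation); len <- spliceLengths(ds$annotation)
  nex <- exonCounts(ds$annotation)
  ids <- transcriptIds(ds$annotation)
  gid <- setNames(geneIds(ds$annotation), ids)
  tot <- rowSums(ds$counts)[gid[ids]]
  manual <- ids[bt[ids] != "protein_coding" & tot > 10 &
                  len[ids] > 200 & nex[ids] >= 2]
  expect_setequal(kept, manual)
})
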