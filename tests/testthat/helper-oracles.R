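# Independent oracles and shared fixtures for the test suite.

# ---- shared expensive fixtures (built once per test run) -------------------

.fixture_cache <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixture_cache$ds)) {
    dir <- file.path(tempdir(), "lnclink_ds42")
    .fixture_cache$ds <- simulateDataset(simParams(seed = 42), outdir = dir)
    .fixture_cache$ds_dir <- dir
  }
  .fixture_cache$ds
}

default_dataset_dir <- function() {
  default_dataset()
  .fixture_cache$ds_dir
}

default_config <- function(dir = default_dataset_dir(), ...) {
  pipelineConfig(gtf = file.path(dir, "annotation.gtf"),
                 transcripts = file.path(dir, "transcripts.fa"),
                 counts = file.path(dir, "counts.tsv"),
                 samples = file.path(dir, "samples.tsv"),
                 reference_lncrnas = file.path(dir, "reference_lncrna.fa"),
                 proteins = file.path(dir, "proteins.fa"), seed = 42L, ...)
}

pipeline_run <- function(which = c("a", "b")) {
  which <- match.arg(which)
  key <- paste0("run_", which)
  if (is.null(.fixture_cache[[key]])) {
    out <- file.path(tempdir(), paste0("lnclink_run_", which))
    .fixture_cache[[paste0(key, "_dir")]] <- out
    .fixture_cache[[key]] <- suppressMessages(
      runPipeline(default_config(), out))
  }
  .fixture_cache[[key]]
}

pipeline_run_dir <- function(which = "a") {
  pipeline_run(which)
  .fixture_cache[[paste0("run_", which, "_dir")]]
}

# ---- small builders --------------------------------------------------------

rand_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# minimal TranscriptAnnotation from a list of transcripts:
# list(id, gene, chr, strand, exons = matrix/ list of c(start, end), bt, seq)
tiny_annotation <- function(specs) {
  exl <- lapply(specs, function(s) {
    ex <- do.call(rbind, s$exons)
    GenomicRanges::GRanges(s$chr, IRanges::IRanges(ex[, 1], ex[, 2]),
                           strand = s$strand)
  })
  names(exl) <- vapply(specs, `[[`, character(1), "id")
  txd <- data.frame(
    transcript_id = names(exl),
    gene_id = vapply(specs, `[[`, character(1), "gene"),
    biotype = vapply(specs, `[[`, character(1), "bt"))
  seqs <- vapply(specs, function(s) s$seq %||% "", character(1))
  sset <- if (all(nzchar(seqs))) {
    x <- Biostrings::DNAStringSet(seqs); names(x) <- names(exl); x
  } else Biostrings::DNAStringSet()
  TranscriptAnnotation(GenomicRanges::GRangesList(exl), txd, sset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles ---------------------------------------------------

# BH step-up by the definition q_(i) = min_{j>=i}(p_(j) * m / j), capped.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# local alignment oracle via Biostrings::pairwiseAlignment
sw_oracle <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  list(score = Biostrings::score(al),
       identity = Biostrings::pid(al, type = "PID1"))
}

# exhaustive contiguous-duplex oracle (sequences <= ~30 nt): enumerates
# every antiparallel contiguous pairing and sums the same stack table.
duplex_oracle_dG <- function(x, y) {
  dt <- lncLink:::duplex_tables()
  code <- function(ch) match(ch, c("A", "C", "G", "T")) - 1L
  xs <- code(strsplit(toupper(x), "")[[1]])
  ys <- code(strsplit(toupper(y), "")[[1]])
  n <- length(xs); m <- length(ys)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    # pair x[i + t] with y[j - t], t = 0, 1, ...
    tmax <- min(n - i, j - 1)
    if (tmax < 1) next
    pair <- integer(0)
    for (t in 0:tmax) {
      cx <- xs[i + t]; cy <- ys[j - t]
      p <- if (is.na(cx) || is.na(cy)) 0L else cx * 4L + cy + 1L
      ok <- p > 0L && dt$pair_ok[p] == 1L
      pair <- c(pair, if (ok) p else NA_integer_)
    }
    for (t0 in seq_along(pair)) {
      if (is.na(pair[t0])) next
      e <- 0
      t1 <- t0
      while (t1 < length(pair) && !is.na(pair[t1 + 1])) {
        e <- e + dt$E[pair[t1], pair[t1 + 1]]
        t1 <- t1 + 1
        if (e < best) best <- e
      }
    }
  }
  best
}

# independent re-implementation of the Fickett lookup procedure
fickett_oracle <- function(seq) {
  tb <- lncLink:::.fickett
  s <- strsplit(toupper(seq), "")[[1]]
  s <- s[s %in% c("A", "C", "G", "T")]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    n1 <- sum(s[seq(1, length(s), 3)] == b)
    n2 <- sum(s[seq(2, length(s), 3)] == b)
    n3 <- sum(s[seq(3, length(s), 3)] == b)
    posv <- max(n1, n2, n3) / (min(n1, n2, n3) + 1)
    cont <- mean(s == b)
    ppos <- tb$position_prob[[b]][
      which(posv >= tb$position_para)[1] %||% 10]
    pcon <- tb$content_prob[[b]][
      which(cont >= tb$content_para)[1] %||% 10]
    total <- total + ppos * tb$position_weight[[b]] +
      pcon * tb$content_weight[[b]]
  }
  total
}

# brute-force all-pairs CIS oracle on plain coordinates
cis_oracle <- function(dels, degs, spans, max_distance = 1e5) {
  out <- list()
  for (i in dels) for (j in degs) {
    if (i == j) next
    a <- spans[i]; b <- spans[j]
    if (as.character(GenomicRanges::seqnames(a)) !=
        as.character(GenomicRanges::seqnames(b))) next
    d <- max(0, max(GenomicRanges::start(a), GenomicRanges::start(b)) -
                min(GenomicRanges::end(a), GenomicRanges::end(b)) - 1)
    if (d < max_distance)
      out[[length(out) + 1L]] <- data.frame(del_id = i, deg_id = j,
                                            distance = d)
  }
  if (!length(out))
    return(data.frame(del_id = character(0), deg_id = character(0),
                      distance = numeric(0)))
  d <- do.call(rbind, out)
  d <- d[order(d$del_id, d$deg_id), ]
  rownames(d) <- NULL
  d
}
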