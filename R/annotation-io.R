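#' Read transcript models from a GTF file
#'
#' Reads `exon` features (1-based inclusive coordinates) carrying `gene_id`
#' and `transcript_id` attributes and assembles them into a
#' [TranscriptAnnotation-class]. An optional `gene_biotype` (or
#' `transcript_biotype`) attribute populates the biotype column; unannotated
#' transcripts get biotype `other`.
#'
#' @param path path to a GTF file.
#' @return A [TranscriptAnnotation-class] (sequences absent).
#' @details Exons are sorted by start within each transcript. Lines that are
#'   not valid GTF raise a parse error naming the offending line; an exon
#'   with `end < start` or `start < 1` raises a validation error.
#' @seealso [writeAnnotationGTF()]
#' @export
readAnnotationGTF <- function(path) {
  stopifnot(file.exists(path))
  # Pre-scan for structural validity so errors can name the line.
  ln <- readLines(path)
  body <- which(!grepl("^#", ln) & nzchar(ln))
  for (i in body) {
    f <- strsplit(ln[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("GTF parse error at line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop("GTF parse error at line ", i, ": non-numeric coordinates")
    if (s < 1L)
      stop("GTF validation error at line ", i,
           ": start < 1 (coordinates are 1-based)")
    if (e < s)
      stop("GTF validation error at line ", i, ": end < start")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  if (is.null(gr$transcript_id) || is.null(gr$gene_id))
    stop("exon features must carry gene_id and transcript_id attributes")
  o <- order(gr$transcript_id, GenomicRanges::start(gr))
  gr <- gr[o]
  exl <- S4Vectors::split(gr, gr$transcript_id)
  exl <- GenomicRanges::GRangesList(lapply(exl, function(g) {
    GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                           IRanges::IRanges(GenomicRanges::start(g),
                                            GenomicRanges::end(g)),
                           strand = GenomicRanges::strand(g))
  }))
  first <- !duplicated(gr$transcript_id)
  bt <- if (!is.null(gr$gene_biotype)) gr$gene_biotype[first]
        else if (!is.null(gr$transcript_biotype)) gr$transcript_biotype[first]
        else rep("other", sum(first))
  bt[is.na(bt)] <- "other"
  bt[!bt %in% c("protein_coding", "known_lncRNA", "novel", "other")] <- "other"
  txd <- S4Vectors::DataFrame(transcript_id = gr$transcript_id[first],
                              gene_id = gr$gene_id[first],
                              biotype = bt)
  txd <- txd[match(names(exl), txd$transcript_id), , drop = FALSE]
  TranscriptAnnotation(exl, txd)
}

#' Write a TranscriptAnnotation to GTF
#'
#' Emits one `exon` feature per exon with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes. Round-trips with [readAnnotationGTF()] up to
#' attribute ordering.
#'
#' @param x a [TranscriptAnnotation-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationGTF <- function(x, path) {
  ids <- transcriptIds(x)
  n_ex <- S4Vectors::elementNROWS(x@exons)
  ex <- unlist(x@exons, use.names = FALSE)
  tx_id <- rep(ids, n_ex)
  g_id <- rep(geneIds(x), n_ex)
  bt <- rep(unname(biotypes(x)), n_ex)
  lines <- paste0(
    as.character(GenomicRanges::seqnames(ex)), "\tlncLink\texon\t",
    GenomicRanges::start(ex), "\t", GenomicRanges::end(ex), "\t.\t",
    as.character(GenomicRanges::strand(ex)), "\t.\t",
    "gene_id \"", g_id, "\"; transcript_id \"", tx_id,
    "\"; gene_biotype \"", bt, "\";")
  writeLines(lines, path)
  invisible(path)
}

#' Fill spliced transcript sequences from a genome
#'
#' Extracts each transcript's sequence as the concatenation of its exon
#' sequences in genomic order, reverse-complemented for `-`-strand
#' transcripts.
#'
#' @param x a [TranscriptAnnotation-class]
#' @param genome a named [Biostrings::DNAStringSet] (one entry per
#'   chromosome).
#' @return `x` with the `sequences` slot filled.
#' @export
fillTranscriptSequences <- function(x, genome) {
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  seqs <- vapply(seq_along(x@exons), function(i) {
    ex <- x@exons[[i]]
    chr <- as.character(GenomicRanges::seqnames(ex))[1]
    if (!chr %in% names(genome))
      stop("chromosome not in genome: ", chr)
    chrlen <- Biostrings::width(genome[chr])
    if (max(GenomicRanges::end(ex)) > chrlen)
      stop("exon beyond chromosome end on ", chr, " (transcript ",
           names(x@exons)[i], ")")
    parts <- as.character(Biostrings::subseq(
      rep(genome[chr], length(ex)),
      start = GenomicRanges::start(ex), end = GenomicRanges::end(ex)))
    s <- paste(parts, collapse = "")
    if (as.character(GenomicRanges::strand(ex))[1] == "-") revcomp_chr(s)
    else s
  }, character(1))
  sset <- Biostrings::DNAStringSet(seqs)
  names(sset) <- names(x@exons)
  initialize(x, sequences = sset)
}

#' Read a count matrix from TSV
#'
#' First column = feature ids, header row = sample ids, integer counts.
#'
#' @param path TSV path.
#' @return Integer matrix, features x samples.
#' @export
readCountMatrix <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  if (any(m < 0, na.rm = TRUE)) stop("negative counts in ", path)
  if (anyDuplicated(rownames(m))) stop("duplicated feature ids in ", path)
  m
}

#' Read a sample sheet from TSV
#'
#' Columns: `sample_id`, `tissue` (one of T, E, DD), `replicate`.
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
readSampleSheet <- function(path) {
  d <- read_tsv(path)
  stopifnot(all(c("sample_id", "tissue", "replicate") %in% colnames(d)))
  d$tissue <- as.character(d$tissue)
  bad <- setdiff(unique(d$tissue), c("T", "E", "DD"))
  if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ","))
  d
}

#' Bundle counts and sample metadata into a SummarizedExperiment
#'
#' @param counts integer matrix, features x samples.
#' @param samples data.frame with `sample_id`, `tissue`, `replicate`;
#'   `sample_id` must match `colnames(counts)`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`.
#' @export
makeCountsSE <- function(counts, samples) {
  stopifnot(identical(colnames(counts), samples$sample_id))
  if (any(counts < 0)) stop("negative counts")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
}

#' Compute FPKM from counts and feature lengths
#'
#' `fpkm[i, j] = counts[i, j] / ((length_i / 1e3) * (libsize_j / 1e6))`,
#' where the library size of a sample is its total counts over all features
#' in the matrix.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param lengths per-feature spliced lengths (nt), named or in row order.
#' @return Numeric matrix of FPKM values, same shape as `counts`.
#' @export
computeFPKM <- function(counts, lengths) {
  if (!is.null(names(lengths))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss)) stop("lengths missing for: ",
                           paste(head(miss, 3), collapse = ","))
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stop("zero- or negative-length feature")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("all-zero sample column: library size must be > 0")
  sweep(sweep(counts, 1, lengths / 1e3, "/"), 2, lib / 1e6, "/")
}
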