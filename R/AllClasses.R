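#' TranscriptAnnotation: transcript models with optional spliced sequences
#'
#' Container for a set of transcript models: per-transcript exon structure
#' (a [GenomicRanges::GRangesList] named by transcript id, all exons of a
#' transcript on one chromosome and strand, sorted by start and
#' non-overlapping), a per-transcript metadata table (transcript id, gene id,
#' biotype) and, optionally, the spliced transcript sequences.
#'
#' Coordinates are 1-based inclusive throughout (GTF convention).
#' Biotypes are one of `protein_coding`, `known_lncRNA`, `novel`, `other`.
#'
#' @slot exons [GenomicRanges::GRangesList] of exons, one element per
#'   transcript, named by transcript id.
#' @slot txData [S4Vectors::DataFrame] with columns `transcript_id`,
#'   `gene_id`, `biotype`, in the same order as `exons`.
#' @slot sequences [Biostrings::DNAStringSet] of spliced sequences named by
#'   transcript id, or an empty set when sequences have not been filled in.
#'
#' @seealso [readAnnotationGTF()], [fillTranscriptSequences()],
#'   [spliceLengths()], [geneSpans()]
#' @export
setClass("TranscriptAnnotation",
  slots = c(
    exons = "GRangesList",
    txData = "DataFrame",
    sequences = "DNAStringSet"
  )
)

setValidity("TranscriptAnnotation", function(object) {
  msg <- character()
  tx <- object@txData
  need <- c("transcript_id", "gene_id", "biotype")
  if (!all(need %in% colnames(tx)))
    return(paste("txData must have columns", paste(need, collapse = ", ")))
  if (length(object@exons) != nrow(tx))
    msg <- c(msg, "exons and txData disagree in length")
  if (anyDuplicated(tx$transcript_id))
    msg <- c(msg, "duplicated transcript_id")
  if (length(object@exons) &&
      !identical(names(object@exons), as.character(tx$transcript_id)))
    msg <- c(msg, "names(exons) must equal txData$transcript_id")
  bad_bt <- setdiff(unique(tx$biotype),
                    c("protein_coding", "known_lncRNA", "novel", "other"))
  if (length(bad_bt))
    msg <- c(msg, paste("unknown biotype:", paste(bad_bt, collapse = ",")))
  if (length(object@exons)) {
    st <- GenomicRanges::start(object@exons)
    if (min(min(st)) < 1)
      msg <- c(msg, "exon start < 1 (coordinates are 1-based)")
    ok <- vapply(seq_along(object@exons), function(i) {
      ex <- object@exons[[i]]
      if (length(unique(as.character(GenomicRanges::seqnames(ex)))) != 1L)
        return(FALSE)
      if (length(unique(as.character(GenomicRanges::strand(ex)))) != 1L)
        return(FALSE)
      s <- GenomicRanges::start(ex)
      e <- GenomicRanges::end(ex)
      if (is.unsorted(s)) return(FALSE)
      if (length(ex) > 1L && any(s[-1L] <= e[-length(ex)])) return(FALSE)
      TRUE
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, paste("transcript(s) with unsorted/overlapping or",
                          "multi-chromosome exons:",
                          paste(head(names(object@exons)[!ok], 3),
                                collapse = ",")))
  }
  if (length(object@sequences)) {
    if (!all(names(object@sequences) %in% tx$transcript_id))
      msg <- c(msg, "sequence names not in txData")
    common <- intersect(names(object@sequences), names(object@exons))
    sl <- sum(GenomicRanges::width(object@exons[common]))
    if (!identical(unname(as.integer(sl)),
                   unname(Biostrings::width(object@sequences[common]))))
      msg <- c(msg, "sequence length != summed exon length")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a TranscriptAnnotation
#'
#' @param exons [GenomicRanges::GRangesList] of exons named by transcript id.
#' @param txData data.frame or DataFrame with `transcript_id`, `gene_id`,
#'   `biotype`.
#' @param sequences optional named [Biostrings::DNAStringSet] of spliced
#'   sequences.
#' @return A [TranscriptAnnotation-class] object.
#' @export
TranscriptAnnotation <- function(exons, txData,
                                 sequences = Biostrings::DNAStringSet()) {
  txData <- S4Vectors::DataFrame(txData)
  txData$transcript_id <- as.character(txData$transcript_id)
  txData$gene_id <- as.character(txData$gene_id)
  txData$biotype <- as.character(txData$biotype)
  new("TranscriptAnnotation", exons = exons, txData = txData,
      sequences = sequences)
}

#' @describeIn TranscriptAnnotation number of transcripts
#' @param x,object a `TranscriptAnnotation`
#' @export
setMethod("length", "TranscriptAnnotation", function(x) length(x@exons))

setMethod("show", "TranscriptAnnotation", function(object) {
  bt <- table(object@txData$biotype)
  cat("TranscriptAnnotation with", length(object), "transcripts,",
      length(unique(object@txData$gene_id)), "genes\n")
  cat("  biotypes:", paste(names(bt), bt, sep = ":", collapse = " "), "\n")
  cat("  sequences:",
      if (length(object@sequences)) "filled" else "absent", "\n")
})

#' Accessors for TranscriptAnnotation
#'
#' `transcriptIds()`, `geneIds()` and `biotypes()` return per-transcript
#' vectors; `txSequences()` the spliced sequences; `exonsByTranscript()` the
#' exon `GRangesList`; `txTable()` the metadata table.
#'
#' @param x a [TranscriptAnnotation-class]
#' @return character vectors / `DNAStringSet` / `GRangesList` / `DataFrame`.
#' @export
transcriptIds <- function(x) as.character(x@txData$transcript_id)

#' @rdname transcriptIds
#' @export
geneIds <- function(x) as.character(x@txData$gene_id)

#' @rdname transcriptIds
#' @export
biotypes <- function(x) setNames(as.character(x@txData$biotype),
                                 transcriptIds(x))

#' @rdname transcriptIds
#' @export
txSequences <- function(x) x@sequences

#' @rdname transcriptIds
#' @export
exonsByTranscript <- function(x) x@exons

#' @rdname transcriptIds
#' @export
txTable <- function(x) x@txData

#' Subset a TranscriptAnnotation by transcript ids
#'
#' @param x a [TranscriptAnnotation-class]
#' @param ids character vector of transcript ids to keep (order preserved).
#' @return A `TranscriptAnnotation` restricted to `ids`.
#' @export
subsetTranscripts <- function(x, ids) {
  stopifnot(all(ids %in% transcriptIds(x)))
  idx <- match(ids, transcriptIds(x))
  seqs <- x@sequences
  if (length(seqs)) seqs <- seqs[intersect(ids, names(seqs))]
  TranscriptAnnotation(x@exons[idx], x@txData[idx, , drop = FALSE], seqs)
}

#' Spliced transcript lengths
#'
#' Sum of exon widths per transcript (equals the spliced sequence length).
#'
#' @param x a [TranscriptAnnotation-class]
#' @return Named integer vector of lengths in nucleotides.
#' @export
spliceLengths <- function(x) {
  setNames(as.integer(sum(GenomicRanges::width(x@exons))),
           names(x@exons))
}

#' Exon counts per transcript
#' @param x a [TranscriptAnnotation-class]
#' @return Named integer vector.
#' @export
exonCounts <- function(x) {
  setNames(S4Vectors::elementNROWS(x@exons), names(x@exons))
}

#' Genomic span of each gene
#'
#' The span covers every exon of every member transcript of the gene.
#'
#' @param x a [TranscriptAnnotation-class]
#' @return A [GenomicRanges::GRanges] named by gene id, strand `*`.
#' @export
geneSpans <- function(x) {
  ex <- unlist(x@exons, use.names = FALSE)
  gid <- rep(geneIds(x), S4Vectors::elementNROWS(x@exons))
  chr <- as.character(GenomicRanges::seqnames(ex))
  d <- data.frame(gid = gid, chr = chr,
                  start = GenomicRanges::start(ex),
                  end = GenomicRanges::end(ex))
  agg <- do.call(rbind, lapply(split(d, d$gid), function(z) {
    if (length(unique(z$chr)) != 1L)
      stop("gene ", z$gid[1], " spans multiple chromosomes")
    data.frame(gid = z$gid[1], chr = z$chr[1],
               start = min(z$start), end = max(z$end))
  }))
  gr <- GenomicRanges::GRanges(agg$chr,
                               IRanges::IRanges(agg$start, agg$end))
  names(gr) <- agg$gid
  gr
}
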