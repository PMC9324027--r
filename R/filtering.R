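#' Structural filtering cascade for lncRNA candidates
#'
#' Applies, in cascade order, the four structural filters that precede the
#' coding-potential screen: (1) remove transcripts annotated as
#' protein-coding, (2) remove transcripts whose summed raw count over all
#' samples is not greater than 10, (3) remove transcripts of spliced length
#' not greater than 200 nt, (4) remove mono-exonic transcripts. A transcript
#' is retained iff it passes all four; a removed transcript records the
#' first failing filter as its reason.
#'
#' Boundary behaviour is strict: exactly 200 nt or exactly 10 counts is
#' removed (retention requires length > 200 and counts > 10).
#' "Summed expression" is the sum of raw counts over all samples; a
#' transcript with no count row is treated as zero-count.
#'
#' @param annotation a [TranscriptAnnotation-class].
#' @param counts integer matrix (features x samples) of raw counts, rownames
#'   = transcript/gene ids matching the annotation's transcript or gene
#'   ids.
#' @param ids optional subset of transcript ids to filter (default: all).
#' @param min_length,min_counts,min_exons retention thresholds; retention
#'   requires length > `min_length`, total counts > `min_counts`,
#'   exon count >= `min_exons`.
#' @return A `FilterReport`: data.frame with `transcript_id`, `status`
#'   (`retained`/`removed`), `reason` (`annotated_protein_coding`,
#'   `low_expression`, `too_short`, `mono_exonic`, or `""`), plus attribute
#'   `stage_counts` (named vector: input and survivors after each filter).
#' @export
applyStructuralFilters <- function(annotation, counts, ids = NULL,
                                   min_length = 200L, min_counts = 10L,
                                   min_exons = 2L) {
  all_ids <- transcriptIds(annotation)
  if (is.null(ids)) ids <- all_ids
  stopifnot(all(ids %in% all_ids))
  bt <- biotypes(annotation)[ids]
  len <- spliceLengths(annotation)[ids]
  nex <- exonCounts(annotation)[ids]
  # count rows may be keyed by transcript or by gene id
  gid <- setNames(geneIds(annotation), all_ids)[ids]
  key <- ifelse(ids %in% rownames(counts), ids,
                ifelse(gid %in% rownames(counts), gid, NA))
  tot <- ifelse(is.na(key), 0, rowSums(counts)[key])
  tot[is.na(tot)] <- 0

  reason <- character(length(ids))
  reason[bt == "protein_coding"] <- "annotated_protein_coding"
  open <- reason == ""
  reason[open & tot <= min_counts] <- "low_expression"
  open <- reason == ""
  reason[open & len <= min_length] <- "too_short"
  open <- reason == ""
  reason[open & nex < min_exons] <- "mono_exonic"

  status <- ifelse(reason == "", "retained", "removed")
  rep <- data.frame(transcript_id = ids, status = status, reason = reason,
                    row.names = NULL)
  stage <- c(
    input = length(ids),
    after_protein_coding = sum(bt != "protein_coding"),
    after_expression = sum(bt != "protein_coding" & tot > min_counts),
    after_length = sum(bt != "protein_coding" & tot > min_counts &
                         len > min_length),
    after_exons = sum(status == "retained"))
  attr(rep, "stage_counts") <- stage
  class(rep) <- c("FilterReport", "data.frame")
  rep
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:", nrow(x), "transcripts,",
      sum(x$status == "retained"), "retained\n")
  sc <- attr(x, "stage_counts")
  cat("  cascade:", paste(names(sc), sc, sep = "=", collapse = " "), "\n")
  if (any(x$status == "removed")) {
    t <- table(x$reason[x$status == "removed"])
    cat("  removal reasons:",
        paste(names(t), t, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Retained transcript ids of a FilterReport
#' @param report a `FilterReport` from [applyStructuralFilters()].
#' @return character vector of retained transcript ids.
#' @export
retainedIds <- function(report) {
  report$transcript_id[report$status == "retained"]
}
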