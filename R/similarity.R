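# Local sequence-similarity search: exact k-mer seeding to select candidate
# query/reference pairs, affine-gap Smith-Waterman scoring (match +2,
# mismatch -3, gap open 5, extend 2) of the selected pairs, Karlin-Altschul
# E-values. This honours the usual BLAST-style thresholds (identity, E-value)
# without an external aligner.

SW_MATCH <- 2; SW_MISMATCH <- -3; SW_GAP_OPEN <- 5; SW_GAP_EXT <- 2

# Ungapped Karlin-Altschul lambda for the score scheme at uniform base
# composition: solves sum_ij p_i p_j exp(lambda * s_ij) = 1.
ka_lambda <- function(match = SW_MATCH, mismatch = SW_MISMATCH) {
  key <- paste0("ka_", match, "_", mismatch)
  if (!is.null(.lnclink_cache[[key]])) return(.lnclink_cache[[key]])
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  l <- uniroot(f, c(1e-6, 5), tol = 1e-12)$root
  .lnclink_cache[[key]] <- l
  l
}

KA_K <- 0.41  # documented constant for the +2/-3 scheme

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw local-alignment score `S`,
#' query length `m` and database length `n`.
#'
#' @param score raw Smith-Waterman score.
#' @param m query length (nt).
#' @param n total database length (nt).
#' @return Expected number of chance alignments with score >= `score`.
#' @export
karlinAltschulE <- function(score, m, n) {
  KA_K * m * n * exp(-ka_lambda() * score)
}

seed_kmers <- function(seq, k = 11L) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  unique(substring(seq, 1:(L - k + 1L), k:L))
}

#' Local similarity search of queries against a reference set
#'
#' For every query, exact 11-mer seeding selects candidate references; each
#' seeded pair is scored by affine-gap Smith-Waterman and reported with its
#' percent identity (over the best local alignment's length), raw score and
#' Karlin-Altschul E-value (database size = total reference length).
#'
#' @param queries named character vector or `DNAStringSet`.
#' @param references named character vector or `DNAStringSet`.
#' @param k seed word size (default 11).
#' @return data.frame of hits: `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `bit_score` (raw SW score) and `e_value`, sorted by
#'   query then ascending E-value.
#' @export
similaritySearch <- function(queries, references, k = 11L) {
  qs <- if (is(queries, "DNAStringSet")) setNames(as.character(queries),
                                                  names(queries))
        else queries
  rs <- if (is(references, "DNAStringSet")) setNames(as.character(references),
                                                      names(references))
        else references
  if (!length(rs)) stop("reference set is empty")
  if (any(!nzchar(qs))) stop("empty query sequence")
  qs <- toupper(qs); rs <- toupper(rs)
  db_n <- sum(nchar(rs))
  # index reference k-mers
  ref_kmers <- lapply(rs, seed_kmers, k = k)
  kmer_to_ref <- split(rep(seq_along(rs),
                           lengths(ref_kmers)), unlist(ref_kmers))
  hits <- list()
  for (qi in seq_along(qs)) {
    qk <- seed_kmers(qs[[qi]], k)
    cand <- unique(unlist(kmer_to_ref[intersect(qk, names(kmer_to_ref))]))
    for (ri in cand) {
      al <- .sw_align(qs[[qi]], rs[[ri]], SW_MATCH, SW_MISMATCH,
                      SW_GAP_OPEN, SW_GAP_EXT)
      ev <- karlinAltschulE(al$score, nchar(qs[[qi]]), db_n)
      hits[[length(hits) + 1L]] <- data.frame(
        query_id = names(qs)[qi] %||% as.character(qi),
        subject_id = names(rs)[ri] %||% as.character(ri),
        percent_identity = al$identity,
        alignment_length = al$align_length,
        bit_score = al$score,
        e_value = ev)
    }
  }
  if (!length(hits))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0),
                      alignment_length = integer(0),
                      bit_score = numeric(0), e_value = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$query_id, out$e_value), , drop = FALSE]
}

#' Annotate known lncRNAs by sequence similarity
#'
#' A transcript is classified as a known lncRNA when its best hit against
#' the reference lncRNA set has percent identity > 90 and E-value < 1e-10;
#' all other transcripts remain candidates. Known and candidates partition
#' the input.
#'
#' @param annotation a [TranscriptAnnotation-class] with sequences filled.
#' @param reference_lncrnas named character vector or `DNAStringSet` of
#'   reference lncRNA sequences.
#' @param min_identity,max_evalue classification thresholds (defaults: the
#'   conventional 90 % / 1e-10).
#' @return list with `known` and `candidates` (character vectors of
#'   transcript ids) and `hits` (the full similarity table).
#' @export
annotateKnownLncRNAs <- function(annotation, reference_lncrnas,
                                 min_identity = 90, max_evalue = 1e-10) {
  seqs <- txSequences(annotation)
  if (!length(seqs)) stop("annotation has no sequences; run ",
                          "fillTranscriptSequences() first")
  if (any(Biostrings::width(seqs) == 0)) stop("empty transcript sequence")
  hits <- similaritySearch(seqs, reference_lncrnas)
  known <- character(0)
  if (nrow(hits)) {
    best <- hits[!duplicated(hits$query_id), , drop = FALSE]  # lowest E first
    known <- best$query_id[best$percent_identity > min_identity &
                           best$e_value < max_evalue]
  }
  all_ids <- transcriptIds(annotation)
  list(known = all_ids[all_ids %in% known],
       candidates = all_ids[!all_ids %in% known],
       hits = hits)
}
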