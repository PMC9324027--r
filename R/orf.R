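STOP_CODONS <- c("TAA", "TAG", "TGA")

# Split a sequence into codon strings for a given forward frame (0,1,2).
frame_codons <- function(seq, frame) {
  L <- nchar(seq)
  if (L < frame + 3L) return(character(0))
  st <- seq.int(1L + frame, L - 2L, by = 3L)
  substring(seq, st, st + 2L)
}

# Lean ORF scan of one frame: first in-frame ATG per stop-delimited
# segment. Returns NULL or a list of parallel vectors (start, end, length
# in nt, complete) — kept free of data.frame overhead because this sits in
# the generator's and the scorers' hot path.
orf_scan <- function(seq, frame) {
  cod <- frame_codons(seq, frame)
  n <- length(cod)
  if (!n) return(NULL)
  stops <- which(cod %in% STOP_CODONS)
  atgs <- which(cod == "ATG")
  if (!length(atgs)) return(NULL)
  seg <- findInterval(atgs, stops) + 1L
  first <- !duplicated(seg)
  a <- atgs[first]
  sid <- seg[first]
  seg_end <- c(stops, n)[pmin(sid, length(stops) + 1L)]
  list(start = (a - 1L) * 3L + frame + 1L,
       end = seg_end * 3L + frame,
       length = (seg_end - a + 1L) * 3L,
       complete = sid <= length(stops))
}

# data.frame view of one frame's ORFs
orfs_in_frame <- function(seq, frame) {
  o <- orf_scan(seq, frame)
  if (is.null(o))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), complete = logical(0)))
  data.frame(start = o$start, end = o$end, length = o$length,
             complete = o$complete)
}

#' Find open reading frames in the three forward frames
#'
#' An ORF starts at an in-frame ATG and runs through the next in-frame stop
#' codon (length counted start through stop inclusive). An ORF with no
#' downstream stop runs to the last complete codon of the frame and is
#' flagged incomplete. Forward frames only: spliced transcripts are already
#' stranded.
#'
#' @param sequence a single nucleotide string over A,C,G,T,N.
#' @return data.frame with one row per frame (frames with no ATG get length
#'   0): `frame` (0,1,2), `start`, `end`, `length` (nt), `complete`.
#'   Attribute `longest` holds the row index of the overall longest ORF (0
#'   if none).
#' @examples
#' findOrfs("ATGAAATAG")   # one complete 9-nt ORF in frame 0
#' @export
findOrfs <- function(sequence) {
  sequence <- toupper(sequence)
  rows <- lapply(0:2, function(f) {
    o <- orf_scan(sequence, f)
    if (is.null(o))
      data.frame(frame = f, start = NA_integer_, end = NA_integer_,
                 length = 0L, complete = FALSE)
    else {
      i <- which.max(o$length)
      data.frame(frame = f, start = o$start[i], end = o$end[i],
                 length = o$length[i], complete = o$complete[i])
    }
  })
  res <- do.call(rbind, rows)
  attr(res, "longest") <- if (all(res$length == 0L)) 0L
                          else which.max(res$length)
  res
}

#' Longest ORF of a sequence
#'
#' @param sequence nucleotide string.
#' @return list(length, frame, start, end, complete); length 0 when the
#'   sequence has no ATG in any frame.
#' @export
longestOrf <- function(sequence) {
  sequence <- toupper(sequence)
  best <- list(length = 0L, frame = NA_integer_, start = NA_integer_,
               end = NA_integer_, complete = FALSE)
  for (f in 0:2) {
    o <- orf_scan(sequence, f)
    if (is.null(o)) next
    i <- which.max(o$length)
    if (o$length[i] > best$length)
      best <- list(length = o$length[i], frame = f, start = o$start[i],
                   end = o$end[i], complete = o$complete[i])
  }
  best
}

# Every ORF of length >= min_len across the three forward frames.
all_orfs <- function(sequence, min_len = 90L) {
  sequence <- toupper(sequence)
  out <- NULL
  for (f in 0:2) {
    o <- orf_scan(sequence, f)
    if (is.null(o)) next
    keep <- o$length >= min_len
    if (!any(keep)) next
    out <- rbind(out, data.frame(frame = f, start = o$start[keep],
                                 end = o$end[keep],
                                 length = o$length[keep],
                                 complete = o$complete[keep]))
  }
  out
}

# total ORF length at or above min_len (termination potential for the
# generator's ORF-breaking loop)
orf_length_total <- function(sequence, min_len) {
  tot <- 0L
  for (f in 0:2) {
    o <- orf_scan(toupper(sequence), f)
    if (is.null(o)) next
    tot <- tot + sum(o$length[o$length >= min_len])
  }
  tot
}
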