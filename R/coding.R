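# Seven coding-potential scorers and the >=5-of-7 non-coding consensus.
#
# Each scorer is a documented stand-in for the dominant feature family of one
# of the widely used coding-potential classifiers (ORF length, ORF coverage,
# Fickett TESTCODE, hexamer usage, k-mer spectrum, codon-pair frame bias,
# stop-codon density). Thresholds are calibrated once on a fixed-seed
# synthetic training set at the equal-error-rate point per scorer and
# shipped as data files.

SCORER_NAMES <- c("orf_length", "orf_coverage", "fickett", "hexamer",
                  "kmer_spectrum", "triplet_frame", "stop_density")

# ---- Fickett TESTCODE (published lookup tables) -----------------------------

.fickett <- list(
  position_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
  position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  position_para = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
  content_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
  content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
  content_para = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0))

fickett_lookup <- function(value, para, prob) {
  i <- which(value >= para)[1]
  if (is.na(i)) i <- length(para)
  prob[i]
}

#' Fickett TESTCODE score
#'
#' Computes the classical TESTCODE statistic: for each base, a position
#' parameter (max/min+1 asymmetry of base counts across the three codon
#' positions) and a content parameter (base frequency), each converted to a
#' probability through the published lookup tables and combined by the
#' published weights. Higher values are more coding-like.
#'
#' @param sequence nucleotide string (length >= 2 recommended; structural
#'   filtering upstream guarantees >= 200 nt in the pipeline).
#' @return Numeric TESTCODE score.
#' @export
fickettScore <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  keep <- s %in% c("A", "C", "G", "T")
  pos <- (seq_along(s) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(s == b & pos == p & keep), numeric(1))
    posval <- max(cnt) / (min(cnt) + 1)
    content <- if (sum(keep)) sum(s == b & keep) / sum(keep) else 0
    score <- score +
      fickett_lookup(posval, .fickett$position_para,
                     .fickett$position_prob[[b]]) *
        .fickett$position_weight[[b]] +
      fickett_lookup(content, .fickett$content_para,
                     .fickett$content_prob[[b]]) *
        .fickett$content_weight[[b]]
  }
  unname(score)
}

# ---- hexamer usage ----------------------------------------------------------

# In-frame hexamer counts of a sequence starting at `from` (step 3).
inframe_hexamer_counts <- function(sequence, from = 1L) {
  s <- substring(sequence, from)
  if (nchar(s) < 6L) return(NULL)
  x <- Biostrings::DNAStringSet(s)
  drop(Biostrings::oligonucleotideFrequency(x, width = 6L, step = 3L))
}

#' Hexamer usage log-likelihood-ratio score
#'
#' Mean natural-log likelihood ratio `ln(coding[h]/noncoding[h])` over the
#' in-frame hexamers of the longest-ORF frame (frame 0 when the sequence has
#' no ORF). Positive values indicate coding-like hexamer usage.
#'
#' @param sequence nucleotide string (must yield at least one hexamer).
#' @param coding_table,noncoding_table 4096-entry probability vectors named
#'   by hexamer, all entries > 0. Defaults to the bundled tables.
#' @return Mean log-likelihood ratio per hexamer.
#' @export
hexamerScore <- function(sequence,
                         coding_table = codingScorerTables()$hex_coding,
                         noncoding_table = codingScorerTables()$hex_noncoding) {
  stopifnot(length(coding_table) == 4096L, length(noncoding_table) == 4096L)
  if (any(coding_table <= 0) || any(noncoding_table <= 0))
    stop("hexamer tables must have all entries > 0")
  lo <- longestOrf(sequence)
  from <- if (lo$length > 0L) ((lo$frame) %% 3L) + 1L else 1L
  cnt <- inframe_hexamer_counts(toupper(sequence), from)
  if (is.null(cnt) || sum(cnt) == 0)
    stop("sequence too short for hexamer scoring (< 6 usable nt)")
  llr <- log(coding_table / noncoding_table)
  sum(cnt * llr[names(cnt)]) / sum(cnt)
}

# ---- ORF-derived scorers ----------------------------------------------------

#' Longest-ORF coverage
#'
#' Longest ORF length divided by transcript length.
#'
#' @param sequence nucleotide string.
#' @return Fraction in \[0, 1\].
#' @export
orfCoverage <- function(sequence) {
  longestOrf(sequence)$length / nchar(sequence)
}

# ---- k-mer spectrum logistic ------------------------------------------------

kmer_feature_vector <- function(seqs) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  do.call(cbind, lapply(1:5, function(k)
    Biostrings::oligonucleotideFrequency(x, width = k, as.prob = TRUE)))
}

#' k-mer spectrum logistic score
#'
#' Logistic score over the concatenated relative frequencies of all k-mers,
#' k = 1..5 (1364 features), with bundled weights trained on a fixed-seed
#' synthetic set. Returns the modelled probability that the sequence is
#' coding.
#'
#' @param sequence nucleotide string (or character vector of sequences).
#' @param weights named numeric vector: `(Intercept)` plus 1364 k-mer
#'   weights. Defaults to the bundled weights.
#' @return Probability/ies in (0, 1).
#' @export
kmerSpectrumScore <- function(sequence,
                              weights = codingScorerTables()$kmer_weights) {
  X <- kmer_feature_vector(sequence)
  b0 <- weights[["(Intercept)"]]
  w <- weights[colnames(X)]
  as.numeric(plogis(b0 + X %*% w))
}

# ---- codon-pair (triplet) frame bias ---------------------------------------

codon_index <- function(cod) {
  b <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  ok <- grepl("^[ACGT]{3}$", cod)
  idx <- rep(NA_integer_, length(cod))
  if (any(ok)) {
    m <- matrix(b[unlist(strsplit(cod[ok], ""))], ncol = 3, byrow = TRUE)
    idx[ok] <- m[, 1] * 16L + m[, 2] * 4L + m[, 3] + 1L
  }
  idx
}

#' Codon-pair frame-bias score
#'
#' Mean log-odds (coding vs noncoding) of adjacent in-frame codon pairs,
#' maximised over the three forward frames, using the bundled 64x64
#' log-odds matrix. Positive values are coding-like.
#'
#' @param sequence nucleotide string.
#' @param matrix 64x64 codon-pair log-odds matrix (bundled default).
#' @return Numeric score.
#' @export
tripletFrameScore <- function(sequence,
                              matrix = codingScorerTables()$codon_pair) {
  sequence <- toupper(sequence)
  best <- -Inf
  for (f in 0:2) {
    cod <- frame_codons(sequence, f)
    if (length(cod) < 2L) next
    idx <- codon_index(cod)
    a <- idx[-length(idx)]; b <- idx[-1]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    best <- max(best, mean(matrix[cbind(a[ok], b[ok])]))
  }
  if (!is.finite(best)) 0 else best
}

# ---- stop-codon density -----------------------------------------------------

#' Stop-codon density score
#'
#' Minimum over the three forward frames of the stop-codon rate per codon,
#' combined with GC content (`min stop rate - 0.2 * GC`). Coding sequences
#' keep one nearly stop-free frame, so lower values are coding-like.
#'
#' @param sequence nucleotide string.
#' @return Numeric score (lower = more coding-like).
#' @export
stopDensityScore <- function(sequence) {
  sequence <- toupper(sequence)
  rates <- vapply(0:2, function(f) {
    cod <- frame_codons(sequence, f)
    if (!length(cod)) return(1)
    mean(cod %in% STOP_CODONS)
  }, numeric(1))
  s <- strsplit(sequence, "")[[1]]
  gc <- mean(s %in% c("G", "C"))
  min(rates) - 0.2 * gc
}

# ---- bundled tables and consensus ------------------------------------------

.lnclink_cache <- new.env(parent = emptyenv())

#' Bundled coding-potential scorer tables
#'
#' Loads (and caches) the bundled hexamer probability tables, k-mer logistic
#' weights, codon-pair log-odds matrix and per-scorer decision thresholds.
#'
#' @return list with elements `hex_coding`, `hex_noncoding`, `kmer_weights`,
#'   `codon_pair`, `thresholds`.
#' @export
codingScorerTables <- function() {
  if (!is.null(.lnclink_cache$scorer_tables))
    return(.lnclink_cache$scorer_tables)
  hexnames <- mkAllStrings_acgt(6L)
  hc <- scan(extdata("hexamer_coding.txt"), quiet = TRUE)
  hn <- scan(extdata("hexamer_noncoding.txt"), quiet = TRUE)
  names(hc) <- hexnames; names(hn) <- hexnames
  kw <- read_tsv(extdata("kmer_weights.tsv"))
  kwv <- setNames(kw$weight, kw$feature)
  cp <- matrix(scan(extdata("codon_pair_logodds.txt"), quiet = TRUE),
               nrow = 64, byrow = TRUE)
  th <- read_tsv(extdata("scorer_thresholds.tsv"))
  tables <- list(hex_coding = hc, hex_noncoding = hn, kmer_weights = kwv,
                 codon_pair = cp, thresholds = th)
  .lnclink_cache$scorer_tables <- tables
  tables
}

# canonical k-mer ordering (the oligonucleotideFrequency column order)
mkAllStrings_acgt <- function(k) {
  colnames(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(strrep("A", k)), width = k))
}

#' Raw scores from the seven coding-potential scorers
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet].
#' @param tables bundled tables from [codingScorerTables()].
#' @return data.frame with one row per sequence and one column per scorer.
#' @export
codingRawScores <- function(sequences, tables = codingScorerTables()) {
  if (is(sequences, "DNAStringSet")) {
    nm <- names(sequences); sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  seqs <- toupper(sequences)
  kmer <- kmerSpectrumScore(seqs, tables$kmer_weights)
  out <- data.frame(
    transcript_id = names(seqs) %||% as.character(seq_along(seqs)),
    orf_length = vapply(seqs, function(s) longestOrf(s)$length, numeric(1)),
    orf_coverage = vapply(seqs, orfCoverage, numeric(1)),
    fickett = vapply(seqs, fickettScore, numeric(1)),
    hexamer = vapply(seqs, function(s)
      hexamerScore(s, tables$hex_coding, tables$hex_noncoding), numeric(1)),
    kmer_spectrum = kmer,
    triplet_frame = vapply(seqs, function(s)
      tripletFrameScore(s, tables$codon_pair), numeric(1)),
    stop_density = vapply(seqs, stopDensityScore, numeric(1)),
    row.names = NULL)
  out
}

#' Score transcripts with all seven scorers and take the consensus vote
#'
#' Each scorer votes `coding` or `noncoding` by comparing its raw score to
#' its bundled equal-error-rate threshold; a transcript's consensus is
#' `noncoding` if and only if at least 5 of the 7 scorers vote noncoding.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet] of
#'   transcript sequences (already past the structural filters).
#' @param tables bundled tables from [codingScorerTables()].
#' @return data.frame with the seven raw scores, the seven votes
#'   (`vote_<scorer>`, values `coding`/`noncoding`), `noncoding_votes`
#'   (0-7) and `consensus`.
#' @export
scoreCodingPotential <- function(sequences, tables = codingScorerTables()) {
  raw <- codingRawScores(sequences, tables)
  th <- tables$thresholds
  votes <- matrix("", nrow(raw), length(SCORER_NAMES),
                  dimnames = list(NULL, paste0("vote_", SCORER_NAMES)))
  for (sc in SCORER_NAMES) {
    r <- th[th$scorer == sc, ]
    stopifnot(nrow(r) == 1L)
    coding <- if (isTRUE(as.logical(r$coding_if_greater)))
      raw[[sc]] > r$threshold else raw[[sc]] < r$threshold
    votes[, paste0("vote_", sc)] <- ifelse(coding, "coding", "noncoding")
  }
  nv <- rowSums(votes == "noncoding")
  cbind(raw, as.data.frame(votes),
        data.frame(noncoding_votes = as.integer(nv),
                   consensus = ifelse(nv >= 5L, "noncoding", "coding")))
}

#' Consensus rule on a vote vector
#'
#' @param votes character vector (or matrix, rows = transcripts) of
#'   `coding`/`noncoding` votes from the seven scorers.
#' @return `"noncoding"` when at least 5 of 7 votes are noncoding, else
#'   `"coding"`.
#' @export
codingConsensus <- function(votes) {
  if (is.matrix(votes)) {
    nv <- rowSums(votes == "noncoding")
  } else {
    stopifnot(length(votes) == 7L)
    nv <- sum(votes == "noncoding")
  }
  ifelse(nv >= 5L, "noncoding", "coding")
}
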