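# Protein-domain final filter: position-specific scoring matrices over the
# 20-letter amino-acid alphabet, scanned against every translated ORF of a
# consensus-noncoding transcript. Any motif scoring above its per-motif
# threshold reclassifies the transcript as coding.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a PSSM motif library
#'
#' Plain-text format: for each motif a header line `> name threshold`
#' followed by one line per motif position holding 20 scores in the fixed
#' alphabet order `A R N D C Q E G H I L K M F P S T W Y V`.
#'
#' @param path path to a motif library file.
#' @return Named list of motifs; each motif is a list with `pssm` (positions
#'   x 20 matrix) and `threshold`.
#' @export
readMotifLibrary <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !grepl("^#", ln)]
  heads <- grep("^>", ln)
  if (!length(heads)) stop("no motifs in ", path)
  bounds <- c(heads, length(ln) + 1L)
  motifs <- list()
  for (i in seq_along(heads)) {
    hd <- strsplit(sub("^>\\s*", "", ln[heads[i]]), "\\s+")[[1]]
    name <- hd[1]; thr <- as.numeric(hd[2])
    rows <- ln[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    if (ncol(m) != 20L) stop("motif ", name, ": expected 20 columns")
    colnames(m) <- AA20
    motifs[[name]] <- list(pssm = m, threshold = thr)
  }
  motifs
}

#' Bundled motif library
#'
#' A small library of hand-built PSSMs patterned after widely conserved
#' protein-domain signatures (Walker A, zinc finger, homeobox helix, ...),
#' plus a `TESTDOM` motif whose consensus peptide is used by the test
#' suite. It is a desk-scale stand-in for a full domain-database scan; any
#' library in the same format can be substituted.
#'
#' @return Named list of motifs (see [readMotifLibrary()]).
#' @export
defaultMotifLibrary <- function() {
  if (is.null(.lnclink_cache$motifs))
    .lnclink_cache$motifs <- readMotifLibrary(extdata("motif_pssms.txt"))
  .lnclink_cache$motifs
}

# Best PSSM score of a peptide (max over windows); -Inf if peptide shorter
# than the motif.
pssm_best_score <- function(peptide, pssm) {
  aa <- strsplit(peptide, "")[[1]]
  W <- nrow(pssm)
  n <- length(aa)
  if (n < W) return(-Inf)
  col <- match(aa, AA20)
  best <- -Inf
  for (s in 1:(n - W + 1L)) {
    idx <- cbind(seq_len(W), col[s:(s + W - 1L)])
    v <- pssm[idx]
    v[is.na(v)] <- min(pssm)  # unknown residues get the worst score
    best <- max(best, sum(v))
  }
  best
}

translate_orf <- function(sequence, start, end) {
  orf <- substr(sequence, start, end)
  # drop a trailing stop codon if present, then any incomplete tail codon
  ncod <- nchar(orf) %/% 3L
  orf <- substr(orf, 1L, ncod * 3L)
  p <- as.character(Biostrings::translate(
    Biostrings::DNAString(orf), if.fuzzy.codon = "solve"))
  sub("\\*$", "", p)
}

#' Protein-domain filter for consensus-noncoding transcripts
#'
#' Translates every ORF of at least `min_orf_nt` nucleotides in the three
#' forward frames and scans each peptide against the motif library. A motif
#' scoring above its threshold sets `domain_hit` and reclassifies the
#' transcript as `coding`; consensus-coding transcripts are `coding`
#' regardless of motifs. Only consensus-noncoding transcripts with no
#' motif hit become `novel_lncRNA`.
#'
#' @param assessment data.frame from [scoreCodingPotential()] (needs
#'   `transcript_id` and `consensus`).
#' @param sequences named character vector or `DNAStringSet` covering the
#'   assessed transcripts.
#' @param motif_library motif list from [readMotifLibrary()] /
#'   [defaultMotifLibrary()]. An empty library is a configuration error.
#' @param min_orf_nt minimum ORF length to translate (default 90 nt).
#' @return `assessment` with added columns `domain_hit` (motif name or `""`)
#'   and `final_class` (`novel_lncRNA` / `coding`).
#' @export
domainFilter <- function(assessment, sequences,
                         motif_library = defaultMotifLibrary(),
                         min_orf_nt = 90L) {
  if (!length(motif_library))
    stop("empty motif library: the domain filter cannot run")
  if (is(sequences, "DNAStringSet")) {
    nm <- names(sequences); sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  hit <- character(nrow(assessment))
  for (i in seq_len(nrow(assessment))) {
    if (assessment$consensus[i] != "noncoding") next
    s <- sequences[[assessment$transcript_id[i]]]
    orfs <- all_orfs(s, min_len = min_orf_nt)
    if (is.null(orfs) || !nrow(orfs)) next
    for (r in seq_len(nrow(orfs))) {
      pep <- translate_orf(s, orfs$start[r], orfs$end[r])
      for (mn in names(motif_library)) {
        m <- motif_library[[mn]]
        if (pssm_best_score(pep, m$pssm) > m$threshold) {
          hit[i] <- mn
          break
        }
      }
      if (nzchar(hit[i])) break
    }
  }
  assessment$domain_hit <- hit
  assessment$final_class <- ifelse(
    assessment$consensus == "noncoding" & hit == "",
    "novel_lncRNA", "coding")
  assessment
}
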