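# Four-tier DEL-DEG relation engine: CIS genomic proximity, TRANS
# co-expression, direct RNA-RNA duplex free energy (ndG) and RNA-protein
# interaction probability, plus relation assembly and network export.

#' Genomic distance between two intervals
#'
#' Strand-agnostic gap in bp between two genomic intervals: `NA` on
#' different chromosomes, 0 when the intervals overlap or touch, otherwise
#' the number of positions strictly between them. Symmetric.
#'
#' @param a,b [GenomicRanges::GRanges] of length 1 (or equal lengths for a
#'   vectorised elementwise distance).
#' @return Integer distance(s) in bp, `NA` across chromosomes.
#' @export
genomicDistance <- function(a, b) {
  suppressWarnings(GenomicRanges::distance(a, b, ignore.strand = TRUE))
}

#' Find CIS relations between DELs and DEGs
#'
#' A DEL-DEG pair is CIS when both genes lie on the same chromosome with a
#' genomic span gap strictly below `max_distance` bp (overlap counts as
#' distance 0).
#'
#' @param dels,degs character vectors of gene ids.
#' @param spans named [GenomicRanges::GRanges] of gene spans covering all
#'   ids (from [geneSpans()]).
#' @param max_distance strict upper bound in bp (default 100000).
#' @return data.frame: `del_id`, `deg_id`, `distance`.
#' @export
findCis <- function(dels, degs, spans, max_distance = 1e5) {
  miss <- setdiff(c(dels, degs), names(spans))
  if (length(miss)) stop("feature(s) not located in annotation: ",
                         paste(head(miss, 3), collapse = ","))
  empty <- data.frame(del_id = character(0), deg_id = character(0),
                      distance = numeric(0))
  if (!length(dels) || !length(degs) || max_distance <= 0) return(empty)
  a <- spans[dels]; b <- spans[degs]
  ov <- GenomicRanges::findOverlaps(a, b,
                                    maxgap = as.integer(max_distance) - 1L,
                                    ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  d <- genomicDistance(a[qi], b[si])
  keep <- !is.na(d) & d < max_distance & dels[qi] != degs[si]
  out <- data.frame(del_id = dels[qi][keep], deg_id = degs[si][keep],
                    distance = as.numeric(d[keep]))
  out <- out[order(out$del_id, out$deg_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find TRANS (co-expression) relations between DELs and DEGs
#'
#' Pearson correlation of the two expression profiles across all samples;
#' the two-sided p-value comes from `t = r sqrt(n-2) / sqrt(1-r^2)` with
#' n-2 degrees of freedom. Pairs with `|r| > min_abs_r` and `p < max_p` are
#' kept, with the correlation sign recorded. Zero-variance profiles are
#' skipped with a warning record.
#'
#' @param del_fpkm,deg_fpkm numeric matrices (features x samples) of FPKM
#'   profiles over the same samples (>= 4).
#' @param min_abs_r,max_p thresholds (defaults 0.9 and 0.05).
#' @return list: `relations` (data.frame `del_id`, `deg_id`, `r`, `p`,
#'   `sign`) and `skipped` (data.frame of zero-variance pairs).
#' @export
findTrans <- function(del_fpkm, deg_fpkm, min_abs_r = 0.9, max_p = 0.05) {
  stopifnot(ncol(del_fpkm) == ncol(deg_fpkm), ncol(del_fpkm) >= 4L)
  n <- ncol(del_fpkm)
  sd_del <- apply(del_fpkm, 1, sd)
  sd_deg <- apply(deg_fpkm, 1, sd)
  skipped <- data.frame(feature_id = c(rownames(del_fpkm)[sd_del == 0],
                                       rownames(deg_fpkm)[sd_deg == 0]))
  if (nrow(skipped))
    warning("skipping ", nrow(skipped), " zero-variance profile(s)")
  dl <- del_fpkm[sd_del > 0, , drop = FALSE]
  dg <- deg_fpkm[sd_deg > 0, , drop = FALSE]
  rel <- data.frame(del_id = character(0), deg_id = character(0),
                    r = numeric(0), p = numeric(0), sign = character(0))
  if (nrow(dl) && nrow(dg)) {
    R <- cor(t(dl), t(dg))
    tt <- R * sqrt(n - 2) / sqrt(pmax(1 - R^2, 1e-300))
    P <- 2 * pt(-abs(tt), df = n - 2)
    keep <- which(abs(R) > min_abs_r & P < max_p, arr.ind = TRUE)
    if (nrow(keep)) {
      rel <- data.frame(
        del_id = rownames(dl)[keep[, 1]],
        deg_id = rownames(dg)[keep[, 2]],
        r = R[keep], p = P[keep],
        sign = ifelse(R[keep] > 0, "positive", "negative"))
      rel <- rel[order(rel$del_id, rel$deg_id), , drop = FALSE]
      rownames(rel) <- NULL
    }
  }
  list(relations = rel, skipped = skipped)
}

# ---- RNA-RNA duplex ---------------------------------------------------------

# 16x16 stack-energy matrix and pairability vector, built from the bundled
# nearest-neighbor table (10 Watson-Crick stacks + G.U terms, kcal/mol,
# 37 C). Indexing: pair code = 4*x + y over A,C,G,T codes 0..3.
duplex_tables <- function() {
  if (!is.null(.lnclink_cache$duplex)) return(.lnclink_cache$duplex)
  tab <- read_tsv(extdata("stack_energies.tsv"))
  wc <- setNames(tab$dG[tab$type == "WC"], tab$stack[tab$type == "WC"])
  gu1 <- tab$dG[tab$stack == "GU_one"]
  gu2 <- tab$dG[tab$stack == "GU_two"]
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pair_ok <- integer(16)
  is_wc <- logical(16); is_gu <- logical(16)
  for (x in 0:3) for (y in 0:3) {
    bx <- bases[x + 1]; by <- bases[y + 1]
    code <- x * 4 + y + 1
    if (comp[[bx]] == by) { pair_ok[code] <- 1L; is_wc[code] <- TRUE }
    if ((bx == "G" && by == "T") || (bx == "T" && by == "G")) {
      pair_ok[code] <- 1L; is_gu[code] <- TRUE
    }
  }
  E <- matrix(0, 16, 16)
  for (p1 in 1:16) for (p2 in 1:16) {
    if (!pair_ok[p1] || !pair_ok[p2]) next
    if (is_wc[p1] && is_wc[p2]) {
      x1 <- bases[(p1 - 1) %/% 4 + 1]; x2 <- bases[(p2 - 1) %/% 4 + 1]
      E[p1, p2] <- wc[[paste0(x1, x2)]]
    } else if (is_gu[p1] && is_gu[p2]) {
      E[p1, p2] <- gu2
    } else {
      E[p1, p2] <- gu1
    }
  }
  .lnclink_cache$duplex <- list(pair_ok = pair_ok, E = E)
  .lnclink_cache$duplex
}

#' Normalized free energy of the best lncRNA-mRNA duplex
#'
#' Slides one sequence over the reverse of the other at every offset and,
#' within each offset, finds the most stable contiguous run of stacked base
#' pairs (Watson-Crick and G-U) under the bundled nearest-neighbor stack
#' table (kcal/mol, 37 C; no loop or bulge penalties). `dG` is the most
#' negative total over all offsets; the normalised energy follows the
#' target-prediction convention `ndG = dG / min(length(lnc), length(mrna))`
#' (kcal/mol/nt), which makes the conventional -0.1 threshold
#' discriminative: an incidental short complementary run in long RNAs stays
#' above it, while a planted long duplex falls below. With no stackable
#' duplex anywhere, `dG = ndG = 0`. `U` is accepted as a synonym of `T`;
#' `N` never pairs. For an exact complementary pair of equal length the
#' normalisation equals the paired length.
#'
#' @param lnc_seq,mrna_seq nucleotide strings (>= 10 nt each).
#' @return list: `dG`, `paired_length`, `ndG`, and the paired windows
#'   `lnc_window` / `mrna_window` (1-based `c(start, end)`, `NA` when no
#'   duplex).
#' @export
duplexNdG <- function(lnc_seq, mrna_seq) {
  stopifnot(nchar(lnc_seq) >= 10L, nchar(mrna_seq) >= 10L)
  dt <- duplex_tables()
  r <- .duplex_scan(toupper(lnc_seq), toupper(mrna_seq), dt$pair_ok, dt$E)
  ndg <- if (r$paired_length > 0)
    r$dG / min(nchar(lnc_seq), nchar(mrna_seq)) else 0
  list(dG = r$dG, paired_length = r$paired_length, ndG = ndg,
       lnc_window = c(r$x_start, r$x_end),
       mrna_window = c(r$y_start, r$y_end))
}

#' Find direct RNA-RNA relations by duplex free energy
#'
#' Scores every DEL-DEG sequence pair with [duplexNdG()] and keeps pairs
#' with `ndG` below the threshold.
#'
#' @param del_seqs,deg_seqs named character vectors or `DNAStringSet`.
#' @param max_ndg strict threshold (default -0.1 kcal/mol/nt).
#' @return data.frame: `del_id`, `deg_id`, `dG`, `paired_length`, `ndG`.
#' @export
findRnaRna <- function(del_seqs, deg_seqs, max_ndg = -0.1) {
  dl <- if (is(del_seqs, "DNAStringSet"))
    setNames(as.character(del_seqs), names(del_seqs)) else del_seqs
  dg <- if (is(deg_seqs, "DNAStringSet"))
    setNames(as.character(deg_seqs), names(deg_seqs)) else deg_seqs
  out <- list()
  for (i in names(dl)) for (j in names(dg)) {
    r <- duplexNdG(dl[[i]], dg[[j]])
    if (r$ndG < max_ndg)
      out[[length(out) + 1L]] <- data.frame(
        del_id = i, deg_id = j, dG = r$dG,
        paired_length = r$paired_length, ndG = r$ndG)
  }
  if (!length(out))
    return(data.frame(del_id = character(0), deg_id = character(0),
                      dG = numeric(0), paired_length = integer(0),
                      ndG = numeric(0)))
  d <- do.call(rbind, out)
  d[order(d$del_id, d$deg_id), , drop = FALSE]
}

# ---- RNA-protein scoring ----------------------------------------------------

rnaprotein_model <- function() {
  if (!is.null(.lnclink_cache$rnaprotein)) return(.lnclink_cache$rnaprotein)
  sc <- read_tsv(extdata("protein_scales.tsv"))
  stopifnot(all(AA20 %in% sc$aa))
  scales <- list(
    hbond = setNames(sc$hbond, sc$aa),
    vdw = setNames(sc$vdw, sc$aa),
    helix = setNames(sc$helix, sc$aa))
  w <- read_tsv(extdata("rnaprotein_weights.tsv"))
  nr <- 16L; np <- 24L
  W <- matrix(w$weight[seq_len(nr * np)], nr, np)
  a <- w$weight[w$param == "logit_a"][1]
  b <- w$weight[w$param == "logit_b"][1]
  .lnclink_cache$rnaprotein <- list(scales = scales, W = W, a = a, b = b)
  .lnclink_cache$rnaprotein
}

# sliding-window profile of a numeric per-position track
window_profile <- function(v, w = 20L) {
  n <- length(v)
  if (n <= w) return(mean(v))
  cs <- cumsum(c(0, v))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

# first n_coef cosine coefficients of a profile (truncated Fourier series)
fourier_reduce <- function(p, n_coef = 8L) {
  L <- length(p)
  t <- (seq_len(L) - 0.5) / L
  vapply(0:(n_coef - 1L), function(k) mean(p * cos(pi * k * t)), numeric(1))
}

rna_feature_vector <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  gc <- as.numeric(s %in% c("G", "C"))
  a <- as.numeric(s == "A")
  c(fourier_reduce(window_profile(gc)), fourier_reduce(window_profile(a)))
}

protein_feature_vector <- function(seq, scales) {
  aa <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(aa), c(AA20, "X"))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ","))
  tracks <- lapply(scales, function(sc) {
    v <- unname(sc[aa])
    v[is.na(v)] <- mean(sc)  # X: mean-propensity imputation
    v
  })
  unlist(lapply(tracks, function(v)
    fourier_reduce(window_profile(v, 10L))), use.names = FALSE)
}

#' RNA-protein interaction probability
#'
#' Encodes the lncRNA as sliding-window composition profiles (GC content as
#' a base-pairing propensity proxy, plus A content), and the protein as
#' hydrogen-bonding, Van der Waals and helix-propensity profiles from the
#' bundled residue scales; both profile sets are reduced to fixed length by
#' truncated Fourier (cosine) series, and the score is a logistic of the
#' bilinear form `r' W p` with the bundled calibrated weights.
#'
#' @param lnc_seq nucleotide string.
#' @param protein_seq amino-acid string over the 20-letter alphabet (`X`
#'   allowed, mean-propensity imputed; other letters are an error).
#' @param model bundled model parameters (propensity scales, weight matrix
#'   `W`, logistic calibration).
#' @return Probability in (0, 1); deterministic.
#' @export
rnaProteinScore <- function(lnc_seq, protein_seq,
                            model = rnaprotein_model()) {
  r <- rna_feature_vector(lnc_seq)
  p <- protein_feature_vector(protein_seq, model$scales)
  s <- as.numeric(t(r) %*% model$W %*% p)
  # clamp the linear predictor so scores stay strictly inside (0, 1)
  unname(plogis(pmin(pmax(model$a + model$b * s, -30), 30)))
}

#' Find RNA-protein relations above a probability threshold
#'
#' @param del_seqs named character vector or `DNAStringSet` of lncRNA
#'   sequences.
#' @param protein_seqs named character vector or `AAStringSet` of protein
#'   sequences (names = partner gene ids).
#' @param min_prob strict threshold (default 0.90).
#' @return data.frame: `del_id`, `deg_id`, `probability`.
#' @export
findRnaProtein <- function(del_seqs, protein_seqs, min_prob = 0.90) {
  dl <- if (is(del_seqs, "DNAStringSet"))
    setNames(as.character(del_seqs), names(del_seqs)) else del_seqs
  pr <- if (is(protein_seqs, "AAStringSet"))
    setNames(as.character(protein_seqs), names(protein_seqs))
    else protein_seqs
  model <- rnaprotein_model()
  rf <- lapply(dl, rna_feature_vector)
  pf <- lapply(pr, protein_feature_vector, scales = model$scales)
  out <- list()
  for (i in names(dl)) for (j in names(pr)) {
    s <- unname(plogis(pmin(pmax(
      model$a + model$b * as.numeric(t(rf[[i]]) %*% model$W %*% pf[[j]]),
      -30), 30)))
    if (s > min_prob)
      out[[length(out) + 1L]] <- data.frame(del_id = i, deg_id = j,
                                            probability = s)
  }
  if (!length(out))
    return(data.frame(del_id = character(0), deg_id = character(0),
                      probability = numeric(0)))
  d <- do.call(rbind, out)
  d[order(d$del_id, d$deg_id), , drop = FALSE]
}

# ---- relation assembly and export ------------------------------------------

#' Assemble the unified relation table and cumulative counts
#'
#' Merges the four relation finders' outputs into one table, collapses
#' duplicate records (with a warning count), tabulates per-tag x per-kind
#' cumulative counts both for all DEGs and restricted to an optional gene
#' subset (e.g. a curated sperm-motility list), and classifies genes by the
#' set of relation kinds they appear in.
#'
#' @param cis,trans,rna_rna,rna_protein data.frames from the four finders
#'   (each needs `del_id`, `deg_id`; missing/NULL inputs are treated as
#'   empty). Each may carry a `tag` column (comparison or group label).
#' @param subset optional character vector of DEG gene ids defining the
#'   "subset" counts.
#' @return list: `relations` (unified table with `kind` and `score`
#'   columns), `counts` (data.frame tag x kind with `n_all`, `n_subset`),
#'   `gene_classes` (data.frame `deg_id`, `kinds` — "+"-joined sorted kind
#'   set), `n_duplicates` (collapsed duplicate records).
#' @export
assembleRelations <- function(cis = NULL, trans = NULL, rna_rna = NULL,
                              rna_protein = NULL, subset = NULL) {
  std <- function(d, kind, score_col) {
    if (is.null(d) || !nrow(d))
      return(data.frame(del_id = character(0), deg_id = character(0),
                        kind = character(0), tag = character(0),
                        score = numeric(0), sign = character(0)))
    data.frame(del_id = d$del_id, deg_id = d$deg_id, kind = kind,
               tag = if ("tag" %in% colnames(d)) d$tag else "all",
               score = d[[score_col]],
               sign = if ("sign" %in% colnames(d)) d$sign else "n/a")
  }
  rel <- rbind(std(cis, "CIS", "distance"),
               std(trans, "TRANS", "r"),
               std(rna_rna, "RNA_RNA", "ndG"),
               std(rna_protein, "RNA_PROTEIN", "probability"))
  key <- paste(rel$del_id, rel$deg_id, rel$kind, rel$tag, sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup) {
    warning(ndup, " duplicate relation record(s) collapsed")
    rel <- rel[!duplicated(key), , drop = FALSE]
  }
  kinds <- c("CIS", "TRANS", "RNA_RNA", "RNA_PROTEIN")
  tags <- sort(unique(rel$tag))
  counts <- do.call(rbind, lapply(tags, function(tg) {
    do.call(rbind, lapply(kinds, function(k) {
      sub <- rel[rel$tag == tg & rel$kind == k, ]
      data.frame(tag = tg, kind = k, n_all = nrow(sub),
                 n_subset = if (is.null(subset)) NA_integer_
                            else sum(sub$deg_id %in% subset))
    }))
  }))
  if (is.null(counts))
    counts <- data.frame(tag = character(0), kind = character(0),
                         n_all = integer(0), n_subset = integer(0))
  gene_classes <- if (nrow(rel)) {
    cl <- vapply(split(rel$kind, rel$deg_id), function(k)
      paste(sort(unique(k)), collapse = "+"), character(1))
    data.frame(deg_id = names(cl), kinds = unname(cl))
  } else data.frame(deg_id = character(0), kinds = character(0))
  rel <- rel[order(rel$kind, rel$tag, rel$del_id, rel$deg_id), ]
  rownames(rel) <- NULL
  list(relations = rel, counts = counts, gene_classes = gene_classes,
       n_duplicates = ndup)
}

#' Export a relation table as a SIF network file
#'
#' One line per relation: `del_id <kind> deg_id`.
#'
#' @param relations unified relation table (from
#'   [assembleRelations()]`$relations`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportNetworkSIF <- function(relations, path) {
  if (!nrow(relations)) stop("empty relation table")
  writeLines(paste(relations$del_id, relations$kind, relations$deg_id),
             path)
  invisible(path)
}

#' Export a relation table as GraphML
#'
#' Nodes are typed `lncRNA`/`gene`; edges carry `kind` and `score`
#' attributes. The file parses with standard graph readers.
#'
#' @param relations unified relation table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportNetworkGraphML <- function(relations, path) {
  if (!nrow(relations)) stop("empty relation table")
  nodes <- unique(c(relations$del_id, relations$deg_id))
  g <- igraph::graph_from_data_frame(
    relations[, c("del_id", "deg_id", "kind", "score")],
    directed = FALSE,
    vertices = data.frame(
      name = nodes,
      type = ifelse(nodes %in% relations$del_id, "lncRNA", "gene")))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
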