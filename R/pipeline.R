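# End-to-end orchestration: filtering -> coding potential -> differential
# expression -> profile groups -> relation inference -> reporting exports.

#' Pipeline configuration
#'
#' Collects all input paths and every stage threshold. The defaults are the
#' conventional values used throughout the package: similarity > 90 % at
#' E < 1e-10 for known-lncRNA annotation; retention requires > 10 summed
#' counts, > 200 nt and >= 2 exons; non-coding consensus needs >= 5 of 7
#' votes; DE requires adjusted p < 0.01 in both methods and |log2FC| > 1;
#' CIS means a gap < 100,000 bp; TRANS requires |r| > 0.9 and p < 0.05;
#' direct RNA-RNA requires ndG < -0.1; RNA-protein requires probability
#' > 0.90. Every stage reads its threshold from this object only.
#'
#' @param gtf,transcripts,counts,samples,reference_lncrnas,proteins input
#'   file paths (see [simulateDataset()] for the expected formats).
#' @param min_identity,max_evalue known-lncRNA annotation thresholds.
#' @param min_length,min_counts,min_exons structural-filter thresholds
#'   (strict: retention needs length > `min_length`, counts >
#'   `min_counts`).
#' @param min_noncoding_votes consensus vote threshold (of 7 scorers).
#' @param de_alpha,de_lfc DE thresholds (adjusted p, |log2FC|).
#' @param cis_max_distance,trans_min_r,trans_max_p,rna_max_ndg,protein_min_prob
#'   relation-tier thresholds.
#' @param seed master seed for any stage randomness.
#' @return A `PipelineConfig` list (class `"PipelineConfig"`).
#' @export
pipelineConfig <- function(gtf, transcripts, counts, samples,
                           reference_lncrnas, proteins = NULL,
                           min_identity = 90, max_evalue = 1e-10,
                           min_length = 200L, min_counts = 10L,
                           min_exons = 2L, min_noncoding_votes = 5L,
                           de_alpha = 0.01, de_lfc = 1,
                           cis_max_distance = 1e5, trans_min_r = 0.9,
                           trans_max_p = 0.05, rna_max_ndg = -0.1,
                           protein_min_prob = 0.90, seed = 1L) {
  cfg <- list(gtf = gtf, transcripts = transcripts, counts = counts,
              samples = samples, reference_lncrnas = reference_lncrnas,
              proteins = proteins, min_identity = min_identity,
              max_evalue = max_evalue, min_length = min_length,
              min_counts = min_counts, min_exons = min_exons,
              min_noncoding_votes = min_noncoding_votes,
              de_alpha = de_alpha, de_lfc = de_lfc,
              cis_max_distance = cis_max_distance,
              trans_min_r = trans_min_r, trans_max_p = trans_max_p,
              rna_max_ndg = rna_max_ndg,
              protein_min_prob = protein_min_prob, seed = as.integer(seed))
  stopifnot(cfg$min_identity >= 0, cfg$min_identity <= 100,
            cfg$max_evalue >= 0, cfg$de_alpha > 0, cfg$de_alpha <= 1,
            cfg$min_noncoding_votes >= 0, cfg$min_noncoding_votes <= 7,
            cfg$trans_min_r >= 0, cfg$trans_min_r <= 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

stage_msg <- function(log, stage, text) {
  line <- paste0("[", stage, "] ", text)
  message(format(Sys.time(), "%H:%M:%S "), line)
  c(log, line)
}

#' Run the full pipeline
#'
#' Executes filtering, coding-potential consensus, differential expression,
#' profile grouping, relation inference and reporting, writing every stage
#' output to `outdir`. Outputs are deterministic for a fixed configuration:
#' re-running with the same inputs and seed reproduces every file
#' byte-identically (`run.log` carries no timestamps).
#'
#' Stage outputs: `filter_report.tsv`, `similarity_hits.tsv`,
#' `known_lncrna.fasta`, `candidates.fasta`, `coding_assessment.tsv`,
#' `novel_lncrnas.fasta`, `de_results.tsv`, `dels.tsv`, `degs.tsv`,
#' `groups.tsv`, `zscores.tsv`, `ma.tsv`, `volcano.tsv`, `relations.tsv`,
#' `cumulative_counts.tsv`, `network.sif`, `network.graphml`,
#' `protein_list.txt`, `run_summary.tsv`, `run.log`.
#'
#' @param config a [pipelineConfig()] object.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results: `filter`
#'   (FilterReport), `known`, `assessment`, `novel`, `de`, `dels`, `degs`,
#'   `groups`, `relations`, `summary`.
#' @export
runPipeline <- function(config, outdir) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (f in c("gtf", "transcripts", "counts", "samples",
              "reference_lncrnas")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("pipeline aborted at stage [input]: missing input file '", f,
           "' (", config[[f]] %||% "NULL", ")")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline aborted at stage [", stage, "]: ",
           conditionMessage(e), call. = FALSE))
  }

  # ---- input
  log <- stage_msg(log, "input", "reading annotation, sequences and counts")
  ann <- run_stage("input", {
    a <- readAnnotationGTF(config$gtf)
    seqs <- Biostrings::readDNAStringSet(config$transcripts)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    a@sequences <- seqs[transcriptIds(a)]
    validObject(a)
    a
  })
  counts <- run_stage("input", readCountMatrix(config$counts))
  samples <- run_stage("input", readSampleSheet(config$samples))
  counts <- counts[, samples$sample_id, drop = FALSE]
  refs <- run_stage("input",
                    Biostrings::readDNAStringSet(config$reference_lncrnas))
  n_tx <- length(ann)

  # ---- known-lncRNA annotation
  log <- stage_msg(log, "known", "annotating known lncRNAs by similarity")
  kn <- run_stage("known", annotateKnownLncRNAs(
    ann, refs, min_identity = config$min_identity,
    max_evalue = config$max_evalue))
  write_tsv(kn$hits, file.path(outdir, "similarity_hits.tsv"))
  Biostrings::writeXStringSet(txSequences(ann)[kn$known],
                              file.path(outdir, "known_lncrna.fasta"))
  log <- stage_msg(log, "known", paste(length(kn$known), "known lncRNAs,",
                                       length(kn$candidates), "candidates"))

  # ---- structural filters on the candidates
  log <- stage_msg(log, "filter", "applying structural filter cascade")
  filt <- run_stage("filter", applyStructuralFilters(
    ann, counts, ids = kn$candidates, min_length = config$min_length,
    min_counts = config$min_counts, min_exons = config$min_exons))
  write_tsv(as.data.frame(filt), file.path(outdir, "filter_report.tsv"))
  surv <- retainedIds(filt)
  Biostrings::writeXStringSet(txSequences(ann)[surv],
                              file.path(outdir, "candidates.fasta"))
  log <- stage_msg(log, "filter",
                   paste(length(surv), "of", length(kn$candidates),
                         "candidates retained"))

  # ---- coding potential + domain filter
  log <- stage_msg(log, "classify", "seven-scorer consensus vote")
  assess <- run_stage("classify", {
    a <- scoreCodingPotential(txSequences(ann)[surv])
    nv <- a$noncoding_votes
    a$consensus <- ifelse(nv >= config$min_noncoding_votes,
                          "noncoding", "coding")
    domainFilter(a, txSequences(ann))
  })
  write_tsv(assess, file.path(outdir, "coding_assessment.tsv"))
  novel <- assess$transcript_id[assess$final_class == "novel_lncRNA"]
  Biostrings::writeXStringSet(txSequences(ann)[novel],
                              file.path(outdir, "novel_lncrnas.fasta"))
  log <- stage_msg(log, "classify", paste(length(novel), "novel lncRNAs"))

  # ---- differential expression (gene level)
  log <- stage_msg(log, "de", "dual-method differential expression")
  lens <- spliceLengths(ann)
  g_of <- setNames(geneIds(ann), transcriptIds(ann))
  gene_len <- tapply(lens[transcriptIds(ann)], g_of[transcriptIds(ann)],
                     max)
  gene_len <- setNames(as.numeric(gene_len), names(gene_len))
  de <- run_stage("de", callDE(counts, samples, gene_len,
                               alpha = config$de_alpha,
                               lfc_min = config$de_lfc))
  write_tsv(de, file.path(outdir, "de_results.tsv"))

  lnc_genes <- unique(g_of[c(kn$known, novel)])
  cod_genes <- unique(g_of[biotypes(ann) == "protein_coding"])
  de_feats <- unique(de$feature_id[de$is_de])
  dels <- intersect(de_feats, lnc_genes)
  degs <- intersect(de_feats, cod_genes)
  write_tsv(data.frame(gene_id = dels), file.path(outdir, "dels.tsv"))
  write_tsv(data.frame(gene_id = degs), file.path(outdir, "degs.tsv"))
  de_split <- table(factor(de$comparison[de$is_de],
                           levels = names(COMPARISONS)),
                    factor(de$direction[de$is_de], levels = c("up", "down")))
  log <- stage_msg(log, "de", paste(length(dels), "DELs,", length(degs),
                                    "DEGs"))

  # ---- profile groups and Z-scores
  groups <- run_stage("group", groupProfiles(de))
  write_tsv(groups, file.path(outdir, "groups.tsv"))
  fpkm <- computeFPKM(counts, gene_len[rownames(counts)])
  zf <- intersect(c(dels, degs), rownames(fpkm))
  z <- zscoreMatrix(fpkm, zf)
  write_tsv(data.frame(feature_id = rownames(z), z, check.names = FALSE),
            file.path(outdir, "zscores.tsv"))
  ma <- de[, c("feature_id", "comparison", "base_mean", "log2fc")]
  write_tsv(ma, file.path(outdir, "ma.tsv"))
  volc <- data.frame(de[, c("feature_id", "comparison", "log2fc")],
                     neg_log10_q = -log10(pmax(de$q_primary, 1e-300)))
  write_tsv(volc, file.path(outdir, "volcano.tsv"))

  # ---- relation inference, per comparison
  log <- stage_msg(log, "interactions", "four-tier relation inference")
  spans <- geneSpans(ann)
  tx_of_gene <- setNames(transcriptIds(ann), geneIds(ann))
  seqs_chr <- as.character(txSequences(ann))
  proteins <- NULL
  if (!is.null(config$proteins) && file.exists(config$proteins)) {
    proteins <- Biostrings::readAAStringSet(config$proteins)
    names(proteins) <- sub("\\s.*$", "", names(proteins))
  }
  cis_l <- trans_l <- rr_l <- rp_l <- list()
  duplex_cache <- new.env(parent = emptyenv())
  for (cmp in names(COMPARISONS)) {
    de_cmp <- de$feature_id[de$is_de & de$comparison == cmp]
    dl <- intersect(dels, de_cmp); dg <- intersect(degs, de_cmp)
    if (!length(dl) || !length(dg)) next
    cis <- findCis(dl, dg, spans, max_distance = config$cis_max_distance)
    if (nrow(cis)) cis_l[[cmp]] <- cbind(cis, tag = cmp)
    tr <- findTrans(fpkm[dl, , drop = FALSE], fpkm[dg, , drop = FALSE],
                    min_abs_r = config$trans_min_r,
                    max_p = config$trans_max_p)$relations
    if (nrow(tr)) trans_l[[cmp]] <- cbind(tr, tag = cmp)
    rr <- run_stage("interactions", {
      out <- list()
      for (i in dl) for (j in dg) {
        key <- paste(i, j)
        if (is.null(duplex_cache[[key]]))
          duplex_cache[[key]] <- duplexNdG(seqs_chr[[tx_of_gene[[i]]]],
                                           seqs_chr[[tx_of_gene[[j]]]])
        r <- duplex_cache[[key]]
        if (r$ndG < config$rna_max_ndg)
          out[[length(out) + 1L]] <- data.frame(
            del_id = i, deg_id = j, dG = r$dG,
            paired_length = r$paired_length, ndG = r$ndG)
      }
      if (length(out)) do.call(rbind, out) else NULL
    })
    if (!is.null(rr)) rr_l[[cmp]] <- cbind(rr, tag = cmp)
    if (!is.null(proteins)) {
      pg <- intersect(dg, names(proteins))
      if (length(pg)) {
        rp <- findRnaProtein(
          setNames(seqs_chr[tx_of_gene[dl]], dl), proteins[pg],
          min_prob = config$protein_min_prob)
        if (nrow(rp)) rp_l[[cmp]] <- cbind(rp, tag = cmp)
      }
    }
  }
  rbind_all <- function(l) if (length(l)) do.call(rbind, l) else NULL
  asm <- assembleRelations(cis = rbind_all(cis_l),
                           trans = rbind_all(trans_l),
                           rna_rna = rbind_all(rr_l),
                           rna_protein = rbind_all(rp_l))
  write_tsv(asm$relations, file.path(outdir, "relations.tsv"))
  write_tsv(asm$counts, file.path(outdir, "cumulative_counts.tsv"))
  if (nrow(asm$relations)) {
    exportNetworkSIF(asm$relations, file.path(outdir, "network.sif"))
    exportNetworkGraphML(asm$relations, file.path(outdir, "network.graphml"))
  }
  prot_ids <- unique(asm$relations$deg_id[
    asm$relations$kind == "RNA_PROTEIN"])
  writeLines(sort(prot_ids), file.path(outdir, "protein_list.txt"))
  log <- stage_msg(log, "interactions",
                   paste(nrow(asm$relations), "relations"))

  # ---- run summary
  sc <- attr(filt, "stage_counts")
  summary <- data.frame(
    metric = c("transcripts_input", "known_lncrnas", "candidates_input",
               names(sc)[-1], "novel_lncrnas", "lncrnas_total",
               paste0("dels_", rep(names(COMPARISONS), each = 2), "_",
                      rep(c("up", "down"), 3)),
               "dels_total", "degs_total",
               paste0("relations_", c("CIS", "TRANS", "RNA_RNA",
                                      "RNA_PROTEIN"))),
    value = c(n_tx, length(kn$known), sc[["input"]],
              unname(sc[-1]), length(novel), length(kn$known) + length(novel),
              as.vector(t(as.matrix(de_split))),
              length(dels), length(degs),
              vapply(c("CIS", "TRANS", "RNA_RNA", "RNA_PROTEIN"),
                     function(k) sum(asm$relations$kind == k), numeric(1))))
  write_tsv(summary, file.path(outdir, "run_summary.tsv"))
  writeLines(log, file.path(outdir, "run.log"))
  log <- stage_msg(log, "done", paste("outputs in", outdir))

  invisible(list(filter = filt, known = kn$known, assessment = assess,
                 novel = novel, de = de, dels = dels, degs = degs,
                 groups = groups, relations = asm$relations,
                 counts_table = asm$counts, summary = summary))
}
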