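# Relative quantification of qPCR validation assays (ddCt) and concordance
# with the sequencing-based expression estimates.

#' Relative quantification by the ddCt method
#'
#' For each sample, the target Ct is normalised against the reference
#' assay(s): the combined reference Ct is the arithmetic mean of the
#' reference Cts, which corresponds to the geometric mean of the reference
#' expression levels on the linear scale. `dCt = Ct_target - Ct_ref`;
#' `ddCt = dCt - mean(dCt of the calibrator tissue)`; relative quantity
#' `RQ = 2^(-ddCt)`.
#'
#' @param records data.frame with columns `sample_id`, `tissue`,
#'   `ct_target`, and one or more reference columns matching `ct_ref*`.
#' @param calibrator_tissue tissue whose mean dCt anchors RQ = 1.
#' @return `records` with added columns `ct_ref_combined`, `dct`, `ddct`,
#'   `rq`.
#' @export
ddctQuantify <- function(records, calibrator_tissue) {
  stopifnot(all(c("sample_id", "tissue", "ct_target") %in%
                  colnames(records)))
  refcols <- grep("^ct_ref", colnames(records), value = TRUE)
  if (!length(refcols)) stop("no reference Ct columns (ct_ref*)")
  refs <- as.matrix(records[, refcols, drop = FALSE])
  if (any(!is.finite(refs)) || any(refs <= 0) ||
      any(!is.finite(records$ct_target)) || any(records$ct_target <= 0))
    stop("Ct values must be positive and present for every sample")
  if (!calibrator_tissue %in% records$tissue)
    stop("calibrator tissue not present: ", calibrator_tissue)
  ref_comb <- rowMeans(refs)
  dct <- records$ct_target - ref_comb
  cal <- mean(dct[records$tissue == calibrator_tissue])
  ddct <- dct - cal
  records$ct_ref_combined <- ref_comb
  records$dct <- dct
  records$ddct <- ddct
  records$rq <- 2^(-ddct)
  records
}

#' Concordance of qPCR relative quantities with sequencing FPKM
#'
#' Compares per-tissue mean qPCR RQ with per-tissue mean FPKM for the same
#' features: reports, per feature, the fraction of tissue pairs whose
#' contrast sign agrees, and the Pearson correlation between log2 RQ and
#' log2 FPKM across tissues.
#'
#' @param rq_by_tissue numeric matrix: features x tissues of mean RQ.
#' @param fpkm_by_tissue numeric matrix: features x tissues of mean FPKM
#'   (same dimnames).
#' @return data.frame: `feature_id`, `direction_agreement` (fraction of
#'   tissue pairs, in \[0, 1\]), `log_pearson_r`.
#' @export
validateAgainstNGS <- function(rq_by_tissue, fpkm_by_tissue) {
  feats <- intersect(rownames(rq_by_tissue), rownames(fpkm_by_tissue))
  if (!length(feats)) stop("no overlapping features between qPCR and NGS")
  tis <- intersect(colnames(rq_by_tissue), colnames(fpkm_by_tissue))
  stopifnot(length(tis) >= 2L)
  out <- lapply(feats, function(f) {
    a <- log2(pmax(rq_by_tissue[f, tis], 1e-12))
    b <- log2(pmax(fpkm_by_tissue[f, tis], 1e-12))
    prs <- combn(length(tis), 2)
    sa <- sign(a[prs[1, ]] - a[prs[2, ]])
    sb <- sign(b[prs[1, ]] - b[prs[2, ]])
    r <- if (sd(a) > 0 && sd(b) > 0) cor(a, b) else NA_real_
    data.frame(feature_id = f, direction_agreement = mean(sa == sb),
               log_pearson_r = r)
  })
  do.call(rbind, out)
}
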