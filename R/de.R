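# Dual-method differential expression: a negative-binomial Wald test on
# counts (method 1) and an exact midrank permutation rank-sum test on FPKM
# (method 2). A feature is called DE only when BOTH methods pass the
# adjusted-p threshold and the fold change clears the cutoff.

#' Median-of-ratios size factors
#'
#' @param counts integer matrix, features x samples.
#' @return Named numeric vector of per-sample size factors (geometric-mean
#'   reference; falls back to relative library size when no feature is
#'   positive in all samples).
#' @export
sizeFactors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(pos) >= 1L) {
    logref <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(cj)
      exp(median(log(cj) - logref)))
  } else {
    lib <- colSums(counts)
    sf <- lib / exp(mean(log(lib)))
  }
  sf / exp(mean(log(sf)))
}

# Method-of-moments dispersion with a fitted mean-dispersion trend
# alpha(mu) = a0 + a1/mu, estimated across features.
trended_dispersion <- function(q1, q2) {
  mu1 <- rowMeans(q1); mu2 <- rowMeans(q2)
  v1 <- apply(q1, 1, var); v2 <- apply(q2, 1, var)
  n1 <- ncol(q1); n2 <- ncol(q2)
  mu <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
  v <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  raw <- (v - mu) / mu^2
  use <- is.finite(raw) & raw > 0 & mu > 0
  if (sum(use) >= 10L) {
    fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
    a0 <- max(coef(fit)[1], 1e-8)
    a1 <- max(coef(fit)[2], 0)
  } else {
    a0 <- max(median(raw[use], na.rm = TRUE), 1e-8)
    if (!is.finite(a0)) a0 <- 0.1
    a1 <- 0
  }
  alpha <- a0 + a1 / pmax(mu, 0.5)
  pmin(pmax(alpha, 1e-8), 10)
}

#' Negative-binomial Wald test (primary DE method)
#'
#' Library sizes are normalised by median-of-ratios across the two groups
#' jointly; per-feature dispersion is a method-of-moments estimate shrunk to
#' a fitted mean-dispersion trend; the Wald statistic compares group means
#' on the log scale with variance `(1/n_g)(1/mu_g + alpha)` per group.
#' Fold change uses pseudo-count 0.5 on normalised means, so zero groups
#' stay finite.
#'
#' @param counts_g1,counts_g2 integer matrices (features x replicates),
#'   same features in the same order; >= 2 replicates per group.
#' @return data.frame: `log2fc` (group1 over group2), `p` (two-sided).
#'   All-zero features in both groups get `log2fc = 0`, `p = 1`.
#' @export
deTestPrimary <- function(counts_g1, counts_g2) {
  stopifnot(nrow(counts_g1) == nrow(counts_g2),
            ncol(counts_g1) >= 2L, ncol(counts_g2) >= 2L)
  all0 <- rowSums(counts_g1) + rowSums(counts_g2) == 0
  sf <- sizeFactors(cbind(counts_g1, counts_g2))
  q1 <- sweep(counts_g1, 2, sf[seq_len(ncol(counts_g1))], "/")
  q2 <- sweep(counts_g2, 2, sf[ncol(counts_g1) + seq_len(ncol(counts_g2))],
              "/")
  alpha <- trended_dispersion(q1, q2)
  m1 <- rowMeans(q1); m2 <- rowMeans(q2)
  lfc <- log2((m1 + 0.5) / (m2 + 0.5))
  se2 <- (1 / ncol(q1)) * (1 / (m1 + 0.5) + alpha) +
         (1 / ncol(q2)) * (1 / (m2 + 0.5) + alpha)
  z <- (log(m1 + 0.5) - log(m2 + 0.5)) / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  p[all0] <- 1; lfc[all0] <- 0
  data.frame(log2fc = unname(lfc), p = unname(p),
             base_mean = unname((m1 + m2) / 2),
             row.names = rownames(counts_g1))
}

# cached index matrix of all n1-subsets of n1+n2 labels
perm_splits <- function(n1, n2) {
  key <- paste0("splits_", n1, "_", n2)
  if (is.null(.lnclink_cache[[key]]))
    .lnclink_cache[[key]] <- combn(n1 + n2, n1)
  .lnclink_cache[[key]]
}

#' Exact rank-sum test (secondary DE method)
#'
#' Two-sided rank-sum test on expression values with midranks for ties. For
#' up to 10 replicates per group the p-value is exact over all
#' `choose(n1+n2, n1)` group relabellings; larger groups use the normal
#' approximation with tie correction.
#'
#' @param x_g1,x_g2 numeric matrices (features x replicates) or vectors (one
#'   feature).
#' @return Numeric vector of two-sided p-values.
#' @export
deTestSecondary <- function(x_g1, x_g2) {
  if (is.null(dim(x_g1))) x_g1 <- matrix(x_g1, nrow = 1)
  if (is.null(dim(x_g2))) x_g2 <- matrix(x_g2, nrow = 1)
  stopifnot(nrow(x_g1) == nrow(x_g2),
            ncol(x_g1) >= 2L, ncol(x_g2) >= 2L)
  n1 <- ncol(x_g1); n2 <- ncol(x_g2)
  if (max(n1, n2) <= 10L) {
    cmb <- perm_splits(n1, n2)
    vapply(seq_len(nrow(x_g1)), function(i) {
      r <- rank(c(x_g1[i, ], x_g2[i, ]))
      W <- colSums(matrix(r[cmb], nrow = n1))
      w0 <- sum(r[seq_len(n1)])
      mu <- mean(W)
      mean(abs(W - mu) >= abs(w0 - mu) - 1e-9)
    }, numeric(1))
  } else {
    vapply(seq_len(nrow(x_g1)), function(i) {
      v <- c(x_g1[i, ], x_g2[i, ]); r <- rank(v)
      w0 <- sum(r[seq_len(n1)])
      mu <- n1 * (n1 + n2 + 1) / 2
      ties <- table(r)
      sig2 <- n1 * n2 / 12 *
        ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
      if (sig2 <= 0) return(1)
      2 * pnorm(-abs(w0 - mu) / sqrt(sig2))
    }, numeric(1))
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i}(p_(j) * m / j)`, capped at
#' 1, original order restored.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
adjustBH <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be finite and within [0, 1]")
  p.adjust(pvalues, method = "BH")
}

COMPARISONS <- list(E_vs_T = c("E", "T"), DD_vs_T = c("DD", "T"),
                    E_vs_DD = c("E", "DD"))

#' Call differential expression across the three tissue comparisons
#'
#' For each comparison (E vs T, DD vs T, E vs DD) both DE methods are run;
#' p-values are BH-adjusted within the comparison across tested features
#' (non-zero total count); a feature is DE iff `q_primary < alpha`,
#' `q_secondary < alpha` and `|log2fc| > lfc_min` — i.e. the call must be
#' confirmed by both methods.
#'
#' @param counts integer matrix, features x samples.
#' @param samples data.frame with `sample_id`, `tissue` (T/E/DD),
#'   `replicate`; `sample_id` matches `colnames(counts)`.
#' @param lengths named per-feature spliced lengths (for the FPKM values
#'   used by the rank-sum method).
#' @param alpha adjusted-p threshold (default 0.01).
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @return data.frame with one row per tested feature x comparison:
#'   `feature_id`, `comparison`, `log2fc`, `base_mean`, `p_primary`,
#'   `p_secondary`, `q_primary`, `q_secondary`, `confirmed_both`,
#'   `direction` (`up`/`down`), `is_de`.
#' @export
callDE <- function(counts, samples, lengths, alpha = 0.01, lfc_min = 1) {
  stopifnot(identical(colnames(counts), samples$sample_id))
  if (!all(c("T", "E", "DD") %in% samples$tissue))
    stop("all three tissues (T, E, DD) must be present")
  tested <- rownames(counts)[rowSums(counts) > 0]
  cts <- counts[tested, , drop = FALSE]
  fpkm <- computeFPKM(cts, lengths[tested])
  out <- lapply(names(COMPARISONS), function(cmp) {
    gg <- COMPARISONS[[cmp]]
    i1 <- samples$tissue == gg[1]; i2 <- samples$tissue == gg[2]
    prim <- deTestPrimary(cts[, i1, drop = FALSE], cts[, i2, drop = FALSE])
    psec <- deTestSecondary(fpkm[, i1, drop = FALSE],
                            fpkm[, i2, drop = FALSE])
    q1 <- adjustBH(prim$p); q2 <- adjustBH(psec)
    de <- q1 < alpha & q2 < alpha & abs(prim$log2fc) > lfc_min
    data.frame(feature_id = tested, comparison = cmp,
               log2fc = prim$log2fc, base_mean = prim$base_mean,
               p_primary = prim$p, p_secondary = psec,
               q_primary = q1, q_secondary = q2,
               confirmed_both = q1 < alpha & q2 < alpha,
               direction = ifelse(prim$log2fc > 0, "up", "down"),
               is_de = de, row.names = NULL)
  })
  do.call(rbind, out)
}

# sign of a feature's change relative to tissue X in a comparison
.sign_vs_tissue <- function(comparison, tissue, log2fc) {
  gg <- COMPARISONS[[comparison]]
  if (gg[1] == tissue) sign(log2fc) else -sign(log2fc)
}

#' Group DE features by tissue-specific expression profile
#'
#' A feature joins group `X_vs_rest` when it is DE in both comparisons that
#' involve tissue X, with a consistent direction relative to X (up in X in
#' both, or down in X in both). A feature qualifying for more than one group
#' (a fully monotone profile) is assigned to the group with the larger
#' minimum |log2fc| across its two comparisons.
#'
#' @param de_results data.frame from [callDE()].
#' @return data.frame: `feature_id`, `group` (`T_vs_rest` / `E_vs_rest` /
#'   `DD_vs_rest`), `direction` (relative to the group tissue).
#' @export
groupProfiles <- function(de_results) {
  involving <- list(T = c("E_vs_T", "DD_vs_T"),
                    E = c("E_vs_T", "E_vs_DD"),
                    DD = c("DD_vs_T", "E_vs_DD"))
  cand <- list()
  for (tis in names(involving)) {
    cmps <- involving[[tis]]
    d <- de_results[de_results$comparison %in% cmps & de_results$is_de, ]
    if (!nrow(d)) next
    both <- names(which(table(d$feature_id) == 2L))
    for (f in both) {
      rows <- d[d$feature_id == f, ]
      sgn <- vapply(seq_len(2), function(k)
        .sign_vs_tissue(rows$comparison[k], tis, rows$log2fc[k]), numeric(1))
      if (sgn[1] == sgn[2] && sgn[1] != 0) {
        cand[[length(cand) + 1L]] <- data.frame(
          feature_id = f, group = paste0(tis, "_vs_rest"),
          direction = if (sgn[1] > 0) "up" else "down",
          strength = min(abs(rows$log2fc)))
      }
    }
  }
  if (!length(cand))
    return(data.frame(feature_id = character(0), group = character(0),
                      direction = character(0)))
  d <- do.call(rbind, cand)
  d <- d[order(d$feature_id, -d$strength, d$group), ]
  d <- d[!duplicated(d$feature_id), c("feature_id", "group", "direction")]
  rownames(d) <- NULL
  d[order(d$group, d$feature_id), ]
}

#' Per-feature Z-score matrix
#'
#' `z[i, j] = (x[i, j] - mean_i) / sd_i` with the n-1 denominator; constant
#' rows get all-zero Z-scores.
#'
#' @param fpkm numeric matrix (features x samples).
#' @param features optional subset of row names.
#' @return Z-score matrix of the same shape (or the subset).
#' @export
zscoreMatrix <- function(fpkm, features = NULL) {
  m <- if (is.null(features)) fpkm else fpkm[features, , drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}
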