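# Univariate discriminative screening: balanced-subsample ROC-AUC per m/z
# feature, rank-sum testing with multiplicity correction, dual-threshold
# selection (AUC > 0.7 or AUC < 0.3, adjusted p < 0.001).

#' Balance group sizes by random subsampling
#'
#' Subsamples the larger outcome group's spectra (uniformly, without
#' replacement) down to the smaller group's spectrum count, so ROC analysis
#' is not biased by differing tissue sizes. Only tumor-ROI spectra are kept.
#'
#' @param fm an \code{\link{msi_features}} matrix with patient outcomes.
#' @param seed integer seed; the same seed reproduces the same subsample.
#' @return an \code{msi_features} matrix with equal spectra per group, rows in
#'   original order.
#' @export
balanced_subsample <- function(fm, seed = 1L) {
  stopifnot(inherits(fm, "msi_features"))
  outc <- .feature_outcome(fm)
  keep_roi <- fm$meta$roi_flag & !is.na(outc)
  n1 <- sum(outc[keep_roi] == "RecPro"); n2 <- sum(outc[keep_roi] == "NED")
  if (n1 == 0L || n2 == 0L) stopf("both outcome groups must have spectra")
  m <- min(n1, n2)
  keep <- rep(FALSE, nrow(fm$values))
  with_seed(seed, {
    for (g in c("RecPro", "NED")) {
      rows <- which(keep_roi & outc == g)
      keep[if (length(rows) > m) sample(rows, m) else rows] <- TRUE
    }
  })
  fm$values <- fm$values[keep, , drop = FALSE]
  fm$meta <- fm$meta[keep, , drop = FALSE]
  rownames(fm$meta) <- NULL
  fm
}

.feature_outcome <- function(fm) {
  idx <- match(fm$meta$patient_id, fm$patients$patient_id)
  factor(fm$patients$outcome[idx], levels = c("RecPro", "NED"))
}

#' ROC-AUC of one feature, RecPro vs NED orientation
#'
#' Probability that a randomly drawn RecPro spectrum has higher intensity than
#' a randomly drawn NED spectrum, ties counted one half; equals the
#' Mann-Whitney U statistic divided by \code{n1 * n2}. Values below 0.5 mean
#' lower intensity in the RecPro group.
#'
#' @param values_recpro,values_ned intensity vectors of the two groups.
#' @return the AUC in [0, 1].
#' @export
roc_auc <- function(values_recpro, values_ned) {
  if (!length(values_recpro) || !length(values_ned))
    stopf("both groups must be non-empty")
  .pair_auc(values_recpro, values_ned)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact null distribution (via \code{stats::pwilcox}) when the pooled sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param values_a,values_b observation vectors (each non-empty).
#' @return the two-sided p-value.
#' @export
ranksum_test <- function(values_a, values_b) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (!n1 || !n2) stopf("both groups must be non-empty")
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (n1 + n2 <= 12L && !ties) {
    p <- if (U > n1 * n2 / 2)
      stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE) + stats::pwilcox(n1 * n2 - U, n1, n2)
    else
      stats::pwilcox(U, n1, n2) + stats::pwilcox(n1 * n2 - U - 1, n1, n2, lower.tail = FALSE)
    return(min(1, p))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- if (!ties) {
    n1 * n2 * (n + 1) / 12
  } else {
    tt <- rle(sort(pooled))$lengths
    n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
  }
  if (sigma2 <= 0) return(1)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Adjust p-values for multiple testing
#'
#' @param p_list p-values in [0, 1].
#' @param method \code{"BH"} (Benjamini-Hochberg, default) or
#'   \code{"bonferroni"}.
#' @return adjusted p-values, bounded by 1.
#' @export
adjust_pvalues <- function(p_list, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.na(p_list) & (p_list < 0 | p_list > 1)))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_list, method = method)
}

#' Select discriminatory features
#'
#' A feature is selected when its AUC is strictly above \code{auc_hi} or
#' strictly below \code{auc_lo} (the latter capturing inverse association,
#' i.e. lower intensity in the RecPro group) and its adjusted p-value is
#' strictly below \code{alpha}.
#'
#' @param stats a feature-statistics data.frame (from
#'   \code{\link{screen_features}}) with columns \code{auc} and \code{p_adj}.
#' @param auc_lo,auc_hi AUC selection thresholds.
#' @param alpha significance threshold on the adjusted p-value.
#' @return sorted integer indices of the selected features.
#' @export
select_discriminatory <- function(stats, auc_lo = 0.3, auc_hi = 0.7, alpha = 0.001) {
  sel <- (stats$auc < auc_lo | stats$auc > auc_hi) & stats$p_adj < alpha
  sort(which(!is.na(sel) & sel))
}

#' Per-feature univariate screening
#'
#' Runs the full screening chain on tumor-ROI spectra: balanced subsampling of
#' the larger outcome group, per-feature RecPro-vs-NED ROC-AUC, two-sided
#' rank-sum test, multiplicity correction, and dual-threshold selection.
#'
#' @param fm an \code{\link{msi_features}} matrix (TIC-normalized intensities,
#'   not per-patient standardized).
#' @param seed seed for the balanced subsample.
#' @param auc_lo,auc_hi,alpha selection thresholds
#'   (see \code{\link{select_discriminatory}}).
#' @param method multiplicity correction, \code{"BH"} or \code{"bonferroni"}.
#' @param n_draws number of independent balanced-subsample draws; with
#'   \code{n_draws > 1} the reported AUC/p per feature come from the first
#'   draw and a \code{stable} column reports the fraction of draws in which
#'   the feature was selected.
#' @return a data.frame of class \code{msi_feature_stats} with columns
#'   \code{feature_mz}, \code{auc}, \code{p_raw}, \code{p_adj},
#'   \code{selected} (and \code{stability} when \code{n_draws > 1}).
#' @export
screen_features <- function(fm, seed = 1L, auc_lo = 0.3, auc_hi = 0.7,
                            alpha = 0.001, method = c("BH", "bonferroni"),
                            n_draws = 1L) {
  stopifnot(inherits(fm, "msi_features"))
  method <- match.arg(method)
  one_draw <- function(s) {
    bal <- balanced_subsample(fm, seed = s)
    outc <- .feature_outcome(bal)
    g1 <- outc == "RecPro"
    auc <- numeric(ncol(bal$values)); p <- numeric(ncol(bal$values))
    for (j in seq_len(ncol(bal$values))) {
      v <- bal$values[, j]
      auc[j] <- .pair_auc(v[g1], v[!g1])
      p[j] <- ranksum_test(v[g1], v[!g1])
    }
    padj <- adjust_pvalues(p, method)
    sel <- logical(length(auc))
    sel[select_discriminatory(data.frame(auc = auc, p_adj = padj),
                              auc_lo, auc_hi, alpha)] <- TRUE
    list(auc = auc, p = p, padj = padj, sel = sel)
  }
  first <- one_draw(seed)
  out <- data.frame(feature_mz = fm$feature_mz, auc = first$auc,
                    p_raw = first$p, p_adj = first$padj, selected = first$sel)
  if (n_draws > 1L) {
    hits <- first$sel
    for (d in seq_len(n_draws - 1L))
      hits <- hits + one_draw(seed + d)$sel
    out$stability <- hits / n_draws
  }
  class(out) <- c("msi_feature_stats", "data.frame")
  attr(out, "params") <- list(seed = seed, auc_lo = auc_lo, auc_hi = auc_hi,
                              alpha = alpha, method = method, n_draws = n_draws)
  out
}

#' @export
print.msi_feature_stats <- function(x, ...) {
  cat(sprintf("Univariate screening: %d features, %d selected (AUC outside [%.2f, %.2f], adj. p < %g)\n",
              nrow(x), sum(x$selected),
              attr(x, "params")$auc_lo, attr(x, "params")$auc_hi,
              attr(x, "params")$alpha))
  NextMethod()
}
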