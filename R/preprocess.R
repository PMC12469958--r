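# Preprocessing chain: top-hat baseline removal -> TIC normalization ->
# peak detection/alignment into an aligned feature matrix.

# --- sliding-window extrema (van Herk / Gil-Werman), vectorized over rows ---
#
# Rolling min/max with a centered flat window of `w` points over the columns
# of a matrix, using two block passes (prefix/suffix extrema) so the cost is
# independent of the window width. Edges use partial windows, equivalent to
# padding with +Inf (min) / -Inf (max).
.roll_extreme <- function(M, w, op, pad) {
  n <- ncol(M); h <- (w - 1L) %/% 2L
  np <- as.integer(ceiling((n + 2L * h) / w) * w)
  P <- matrix(pad, nrow(M), np)
  P[, h + seq_len(n)] <- M
  F <- P
  for (j in seq_len(np)[-1L])
    if ((j - 1L) %% w != 0L) F[, j] <- op(F[, j - 1L], P[, j])
  G <- P
  for (j in rev(seq_len(np - 1L)))
    if (j %% w != 0L) G[, j] <- op(G[, j + 1L], P[, j])
  idx <- h + seq_len(n)
  op(G[, idx - h, drop = FALSE], F[, idx + h, drop = FALSE])
}

.opening <- function(M, w) {
  ero <- .roll_extreme(M, w, pmin, Inf)
  .roll_extreme(ero, w, pmax, -Inf)
}

#' Morphological top-hat baseline removal
#'
#' Subtracts the morphological opening of each spectrum (erosion then dilation
#' with a flat structuring element of \code{structure_width} points), removing
#' slowly varying baseline while preserving peaks narrower than the element.
#' The result is non-negative and pointwise no larger than the input, and is
#' invariant to adding a constant offset.
#'
#' @param x a numeric vector (one spectrum), a spectra matrix (rows =
#'   spectra), or an \code{\link{msi_dataset}}.
#' @param structure_width odd integer width of the flat structuring element in
#'   axis points; must be smaller than the signal length. The default of 201
#'   points corresponds to the conventional "peak width 200" setting.
#' @return object of the same type as \code{x} with the baseline removed.
#' @export
tophat_baseline <- function(x, structure_width = 201L) UseMethod("tophat_baseline")

.check_tophat_width <- function(w, n) {
  assert_count(w, "structure_width", min = 1L)
  if (w %% 2L == 0L) stopf("`structure_width` must be odd")
  if (w >= n) stopf("`structure_width` (%d) must be smaller than the signal length (%d)", w, n)
}

#' @export
tophat_baseline.default <- function(x, structure_width = 201L) {
  x <- as.numeric(x)
  .check_tophat_width(structure_width, length(x))
  drop(tophat_baseline(matrix(x, nrow = 1L), structure_width))
}

#' @export
tophat_baseline.matrix <- function(x, structure_width = 201L) {
  .check_tophat_width(structure_width, ncol(x))
  x - .opening(x, as.integer(structure_width))
}

#' @export
tophat_baseline.msi_dataset <- function(x, structure_width = 201L) {
  x$intensities <- tophat_baseline(x$intensities, structure_width)
  x
}

#' Total ion count normalization
#'
#' Divides each spectrum by its intensity sum, so every spectrum sums to one.
#' This removes per-pixel multiplicative acquisition variation (matrix
#' coverage, laser coupling, per-slide gain).
#'
#' @param x a numeric vector, a spectra matrix, or an \code{\link{msi_dataset}}.
#' @param drop_empty for matrix/dataset input: if TRUE (default for datasets),
#'   spectra with non-positive total ion count are flagged and excluded with a
#'   warning; for a single vector a non-positive sum is an error.
#' @return normalized object of the same type as \code{x}.
#' @export
tic_normalize <- function(x, drop_empty = TRUE) UseMethod("tic_normalize")

#' @export
tic_normalize.default <- function(x, drop_empty = TRUE) {
  x <- as.numeric(x)
  s <- sum(x)
  if (!is.finite(s) || s <= 0) stopf("cannot TIC-normalize a spectrum with non-positive total ion count")
  x / s
}

#' @export
tic_normalize.matrix <- function(x, drop_empty = TRUE) {
  s <- rowSums(x)
  bad <- !is.finite(s) | s <= 0
  if (any(bad)) {
    if (!drop_empty) stopf("%d spectra have non-positive total ion count", sum(bad))
    warning(sprintf("excluding %d spectra with non-positive total ion count", sum(bad)))
    x <- x[!bad, , drop = FALSE]; s <- s[!bad]
  }
  x / s
}

#' @export
tic_normalize.msi_dataset <- function(x, drop_empty = TRUE) {
  s <- rowSums(x$intensities)
  bad <- !is.finite(s) | s <= 0
  if (any(bad)) {
    if (!drop_empty) stopf("%d spectra have non-positive total ion count", sum(bad))
    warning(sprintf("excluding %d spectra with non-positive total ion count", sum(bad)))
    x$intensities <- x$intensities[!bad, , drop = FALSE]
    x$meta <- x$meta[!bad, , drop = FALSE]
    rownames(x$meta) <- NULL
    s <- s[!bad]
  }
  x$intensities <- x$intensities / s
  x
}

#' Aligned feature matrix
#'
#' @param values numeric matrix, spectra x features.
#' @param feature_mz strictly increasing centroid m/z per feature column.
#' @param tolerance Da half-width of the alignment interval.
#' @param meta per-spectrum metadata (as in \code{\link{msi_dataset}}).
#' @param patients patient table (as in \code{\link{msi_dataset}}).
#' @param standardized has per-patient standardization been applied?
#' @return an object of class \code{msi_features}.
#' @export
msi_features <- function(values, feature_mz, tolerance, meta, patients,
                         standardized = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) != length(feature_mz))
    stopf("ncol(values) != length(feature_mz)")
  if (length(feature_mz) > 1L && any(diff(feature_mz) <= 0))
    stopf("feature centroids must be strictly increasing")
  if (nrow(values) != nrow(meta)) stopf("nrow(values) != nrow(meta)")
  structure(list(values = values, feature_mz = as.numeric(feature_mz),
                 tolerance = tolerance, meta = meta, patients = patients,
                 standardized = isTRUE(standardized)),
            class = "msi_features")
}

#' @export
print.msi_features <- function(x, ...) {
  cat(sprintf("Aligned feature matrix: %d spectra x %d features (+/- %.3f Da)%s\n",
              nrow(x$values), ncol(x$values), x$tolerance,
              if (x$standardized) ", per-patient standardized" else ""))
  invisible(x)
}

#' @export
dim.msi_features <- function(x) dim(x$values)

#' Detect and align peaks into a feature matrix
#'
#' Feature centroids are the local maxima of the mean spectrum over tumor-ROI
#' spectra that exceed \code{min_prominence}; maxima closer than
#' \code{2 * tolerance} are merged into the more intense one. Each spectrum's
#' feature value is the maximum (or sum) of its intensities within
#' centroid \code{+/- tolerance}. All spectra (including non-ROI pixels) are
#' quantified; modelling stages subset to ROI rows.
#'
#' @param dataset a preprocessed (baseline-removed, TIC-normalized)
#'   \code{\link{msi_dataset}}.
#' @param tolerance alignment half-width in Da.
#' @param min_prominence minimum mean-spectrum intensity for a local maximum
#'   to become a feature.
#' @param agg per-spectrum aggregation within the alignment window,
#'   \code{"max"} (default) or \code{"sum"}.
#' @return an \code{\link{msi_features}} matrix.
#' @export
detect_and_align_peaks <- function(dataset, tolerance = 0.2, min_prominence = 0,
                                   agg = c("max", "sum")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  agg <- match.arg(agg)
  if (tolerance <= 0) stopf("`tolerance` must be > 0")
  roi <- dataset$meta$roi_flag
  if (!any(roi)) stopf("no tumor-ROI spectra in dataset")
  m <- colMeans(dataset$intensities[roi, , drop = FALSE])
  n <- length(m)
  if (n < 3L) stopf("m/z axis too short for peak detection")
  is_max <- c(FALSE, m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n], FALSE) &
    m > min_prominence
  cand <- which(is_max)
  if (!length(cand)) {
    warning("no peaks found; returning an empty feature matrix")
    return(msi_features(matrix(0, nrow(dataset$intensities), 0L), numeric(0),
                        tolerance, dataset$meta, dataset$patients))
  }
  # merge: keep the more intense of any pair of maxima closer than 2*tolerance
  ord <- cand[order(-m[cand], dataset$mz[cand])]
  kept <- numeric(0)
  kept_idx <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(dataset$mz[i] - kept) >= 2 * tolerance)) {
      kept <- c(kept, dataset$mz[i]); kept_idx <- c(kept_idx, i)
    }
  }
  o <- order(kept)
  centroids <- kept[o]
  vals <- matrix(0, nrow(dataset$intensities), length(centroids))
  lo <- findInterval(centroids - tolerance, dataset$mz, left.open = TRUE) + 1L
  hi <- findInterval(centroids + tolerance, dataset$mz)
  for (k in seq_along(centroids)) {
    cols <- lo[k]:hi[k]
    sub <- dataset$intensities[, cols, drop = FALSE]
    vals[, k] <- if (agg == "max") do.call(pmax, as.data.frame(sub)) else rowSums(sub)
  }
  msi_features(vals, centroids, tolerance, dataset$meta, dataset$patients)
}

#' Down-sample a feature matrix by pairwise averaging
#'
#' Averages consecutive non-overlapping feature pairs (columns 1+2, 3+4, ...),
#' halving the feature count; the new centroid is the midpoint of each pair.
#' An unpaired trailing column is kept unchanged.
#'
#' @param fm an \code{\link{msi_features}} matrix.
#' @return the down-sampled \code{msi_features} matrix.
#' @export
downsample_features <- function(fm) {
  stopifnot(inherits(fm, "msi_features"))
  p <- ncol(fm$values)
  if (p < 2L) return(fm)
  npair <- p %/% 2L
  i1 <- 2L * seq_len(npair) - 1L
  i2 <- i1 + 1L
  vals <- (fm$values[, i1, drop = FALSE] + fm$values[, i2, drop = FALSE]) / 2
  mz <- (fm$feature_mz[i1] + fm$feature_mz[i2]) / 2
  if (p %% 2L == 1L) {
    vals <- cbind(vals, fm$values[, p])
    mz <- c(mz, fm$feature_mz[p])
  }
  msi_features(vals, mz, fm$tolerance, fm$meta, fm$patients,
               standardized = fm$standardized)
}

#' Per-patient feature standardization
#'
#' For every patient and feature, subtracts that patient's mean and divides by
#' that patient's standard deviation. Statistics are computed over all of the
#' patient's spectra (tumor ROI and adjacent tissue alike), so the patient's
#' non-tumor pixels act as an internal reference; downstream modelling uses
#' only ROI rows. Features with zero within-patient SD are set to 0 for that
#' patient. Each patient is standardized independently, so train- and
#' test-patient statistics never mix.
#'
#' @param fm an \code{\link{msi_features}} matrix.
#' @return the standardized \code{msi_features} matrix.
#' @export
per_patient_standardize <- function(fm) {
  stopifnot(inherits(fm, "msi_features"))
  vals <- fm$values
  for (pid in unique(fm$meta$patient_id)) {
    rows <- which(fm$meta$patient_id == pid)
    if (length(rows) < 2L)
      stopf("patient %s has a single spectrum; cannot standardize", pid)
    sub <- vals[rows, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- sqrt(colSums(sweep(sub, 2L, mu)^2) / (length(rows) - 1L))
    z <- sweep(sweep(sub, 2L, mu), 2L, ifelse(sdv > 0, sdv, 1), "/")
    z[, sdv == 0] <- 0
    vals[rows, ] <- z
  }
  fm$values <- vals
  fm$standardized <- TRUE
  fm
}

#' Quantify a dataset at fixed feature centroids
#'
#' Applies previously detected feature centroids (e.g. from a training cohort)
#' to another preprocessed dataset, so both cohorts share one feature space.
#'
#' @param dataset a preprocessed \code{\link{msi_dataset}}.
#' @param feature_mz centroid m/z values to quantify at.
#' @param tolerance alignment half-width in Da.
#' @param agg aggregation within the window, \code{"max"} or \code{"sum"}.
#' @return an \code{\link{msi_features}} matrix.
#' @export
apply_feature_centroids <- function(dataset, feature_mz, tolerance = 0.2,
                                    agg = c("max", "sum")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  agg <- match.arg(agg)
  vals <- matrix(0, nrow(dataset$intensities), length(feature_mz))
  lo <- findInterval(feature_mz - tolerance, dataset$mz, left.open = TRUE) + 1L
  hi <- findInterval(feature_mz + tolerance, dataset$mz)
  for (k in seq_along(feature_mz)) {
    if (lo[k] > hi[k]) next
    sub <- dataset$intensities[, lo[k]:hi[k], drop = FALSE]
    vals[, k] <- if (agg == "max") do.call(pmax, as.data.frame(sub)) else rowSums(sub)
  }
  msi_features(vals, feature_mz, tolerance, dataset$meta, dataset$patients)
}

#' Run the standard preprocessing chain
#'
#' Fixed order: top-hat baseline removal, then TIC normalization, then peak
#' detection and alignment. The applied steps and parameters are recorded in
#' the \code{provenance} attribute of the result.
#'
#' @param dataset a raw \code{\link{msi_dataset}}.
#' @param structure_width top-hat structuring element width (points).
#' @param tolerance peak alignment half-width (Da).
#' @param min_prominence peak detection threshold on the mean spectrum.
#' @param smooth if TRUE, a 5-point moving-average smoothing of each spectrum
#'   is applied before peak detection (off by default).
#' @return an \code{\link{msi_features}} matrix with a \code{provenance}
#'   attribute listing the steps in order.
#' @export
preprocess_dataset <- function(dataset, structure_width = 201L, tolerance = 0.2,
                               min_prominence = 0, smooth = FALSE) {
  steps <- character(0)
  # cap the structuring element below the axis length (short demo axes)
  w <- min(as.integer(structure_width), ncol(dataset$intensities) - 1L)
  if (w %% 2L == 0L) w <- w - 1L
  if (w >= 1L) {
    dataset <- tophat_baseline(dataset, w)
    steps <- c(steps, sprintf("tophat_baseline(structure_width=%d)", w))
  }
  dataset <- tic_normalize(dataset)
  steps <- c(steps, "tic_normalize")
  if (isTRUE(smooth)) {
    k <- rep(1 / 5, 5)
    sm <- t(apply(dataset$intensities, 1L, function(r) {
      f <- stats::filter(r, k, sides = 2)
      ifelse(is.na(f), r, as.numeric(f))
    }))
    dataset$intensities <- sm
    steps <- c(steps, "moving_average(window=5)")
  }
  fm <- detect_and_align_peaks(dataset, tolerance = tolerance,
                               min_prominence = min_prominence)
  steps <- c(steps, sprintf("detect_and_align_peaks(tolerance=%.3f)", tolerance))
  attr(fm, "provenance") <- steps
  fm
}
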