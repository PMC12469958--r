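# Peptide/protein annotation of discriminative m/z features against a
# bottom-up LC-MS/MS peptide library, with the two-peptide
# spatial-correlation validation rule.

#' Load a peptide library CSV
#'
#' Expects columns \code{sequence}, \code{monoisotopic_mass},
#' \code{protein_id}, \code{protein_name}, \code{score} (-logP). Duplicate
#' (sequence, protein) rows are deduplicated keeping the highest score.
#'
#' @param path path to the library CSV.
#' @return a data.frame of class \code{msi_peptide_library}.
#' @export
load_peptide_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "monoisotopic_mass", "protein_id", "protein_name", "score")
  miss <- setdiff(need, names(lib))
  if (length(miss)) stopf("peptide library is missing columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(lib)) {
    if (any(lib$monoisotopic_mass <= 0)) stopf("peptide masses must be positive")
    if (any(lib$score < 0)) stopf("-logP scores must be non-negative")
    lib <- lib[order(lib$sequence, lib$protein_id, -lib$score), ]
    lib <- lib[!duplicated(lib[, c("sequence", "protein_id")]), ]
    lib <- lib[order(lib$monoisotopic_mass), ]
    rownames(lib) <- NULL
  }
  class(lib) <- c("msi_peptide_library", "data.frame")
  lib
}

#' Write a peptide library CSV
#'
#' @param library an \code{msi_peptide_library} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_peptide_library <- function(library, path) {
  df <- as.data.frame(library)[, c("sequence", "monoisotopic_mass",
                                   "protein_id", "protein_name", "score")]
  df$monoisotopic_mass <- formatC(df$monoisotopic_mass, digits = 17, format = "g")
  df$score <- formatC(df$score, digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match m/z features to library peptides
#'
#' For each feature, library peptides whose expected ion mass lies within
#' \code{tolerance_da} are ranked by smallest absolute mass deviation, then
#' highest -logP score (then sequence, for a deterministic, library-order-free
#' result); the best candidate is reported. Observed MALDI m/z values are
#' treated as singly protonated ions, so library neutral monoisotopic masses
#' are offset by +1.00728 Da before comparison (disable with
#' \code{adduct = FALSE}).
#'
#' @param feature_mzs observed feature m/z values (Da).
#' @param library an \code{msi_peptide_library}.
#' @param tolerance_da matching half-window (Da).
#' @param adduct treat observed m/z as [M+H]+ (default TRUE).
#' @return data.frame with one row per feature: \code{feature_mz},
#'   \code{matched}, \code{sequence}, \code{protein_id}, \code{protein_name},
#'   \code{score}, \code{mass_deviation}.
#' @export
match_mz_features <- function(feature_mzs, library, tolerance_da = 0.2,
                              adduct = TRUE) {
  if (tolerance_da <= 0) stopf("`tolerance_da` must be positive")
  ion_mass <- library$monoisotopic_mass + if (isTRUE(adduct)) 1.00728 else 0
  out <- data.frame(feature_mz = feature_mzs, matched = FALSE,
                    sequence = NA_character_, protein_id = NA_character_,
                    protein_name = NA_character_, score = NA_real_,
                    mass_deviation = NA_real_, stringsAsFactors = FALSE)
  if (!nrow(library)) return(out)
  for (i in seq_along(feature_mzs)) {
    dev <- abs(feature_mzs[i] - ion_mass)
    cand <- which(dev <= tolerance_da)
    if (!length(cand)) next
    cand <- cand[order(dev[cand], -library$score[cand], library$sequence[cand])]
    b <- cand[1L]
    out$matched[i] <- TRUE
    out$sequence[i] <- library$sequence[b]
    out$protein_id[i] <- library$protein_id[b]
    out$protein_name[i] <- library$protein_name[b]
    out$score[i] <- library$score[b]
    out$mass_deviation[i] <- dev[b]
  }
  out
}

#' Validate protein identifications by co-localized peptides
#'
#' A protein is validated when at least \code{min_peptides} of its matched
#' peptide features have similar tissue distributions: all pairwise
#' correlations of their ROI-pixel intensity vectors reach
#' \code{min_correlation}.
#'
#' @param matches output of \code{\link{match_mz_features}}.
#' @param fm the \code{\link{msi_features}} matrix the features came from
#'   (TIC-normalized intensities; only tumor-ROI rows are used).
#' @param min_peptides minimum supporting peptides (default 2).
#' @param min_correlation minimum pairwise correlation (default 0.4).
#' @param method correlation type, \code{"pearson"} or \code{"spearman"}.
#' @return data.frame with one row per matched protein: \code{protein_id},
#'   \code{protein_name}, \code{n_peptides}, \code{min_pairwise_correlation},
#'   \code{validated}.
#' @export
validate_proteins <- function(matches, fm, min_peptides = 2L,
                              min_correlation = 0.4,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(fm, "msi_features"))
  hit <- matches[matches$matched, , drop = FALSE]
  feat_idx <- match(hit$feature_mz, fm$feature_mz)
  drop <- is.na(feat_idx)
  if (any(drop)) {
    warning(sprintf("dropping %d matched features without intensity images", sum(drop)))
    hit <- hit[!drop, , drop = FALSE]
    feat_idx <- feat_idx[!drop]
  }
  roi <- fm$meta$roi_flag
  prots <- sort(unique(hit$protein_id))
  res <- lapply(prots, function(p) {
    rows <- which(hit$protein_id == p)
    idx <- feat_idx[rows]
    mincor <- if (length(idx) >= 2L) {
      cm <- stats::cor(fm$values[roi, idx, drop = FALSE], method = method)
      min(cm[upper.tri(cm)])
    } else NA_real_
    data.frame(protein_id = p,
               protein_name = hit$protein_name[rows[1L]],
               n_peptides = length(idx),
               min_pairwise_correlation = mincor,
               validated = length(idx) >= min_peptides &&
                 !is.na(mincor) && mincor >= min_correlation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res) %||%
    data.frame(protein_id = character(0), protein_name = character(0),
               n_peptides = integer(0), min_pairwise_correlation = numeric(0),
               validated = logical(0))
  rownames(out) <- NULL
  out
}

#' Annotation report for screened features
#'
#' Joins peptide matches with screening statistics and protein validation
#' into one report over the selected (discriminatory) features.
#'
#' @param stats feature statistics from \code{\link{screen_features}}.
#' @param fm the \code{\link{msi_features}} matrix.
#' @param library an \code{msi_peptide_library}.
#' @param tolerance_da matching half-window (Da).
#' @param min_peptides,min_correlation validation rule parameters.
#' @return list with \code{matches} (per selected feature: m/z, AUC,
#'   peptide/protein, deviation, validated flag) and \code{proteins} (the
#'   \code{\link{validate_proteins}} table).
#' @export
annotate_features <- function(stats, fm, library, tolerance_da = 0.2,
                              min_peptides = 2L, min_correlation = 0.4) {
  sel <- which(stats$selected)
  matches <- match_mz_features(stats$feature_mz[sel], library, tolerance_da)
  prots <- validate_proteins(matches, fm, min_peptides, min_correlation)
  matches$auc <- stats$auc[sel]
  matches$validated <- prots$validated[match(matches$protein_id, prots$protein_id)]
  matches$validated[is.na(matches$validated)] <- FALSE
  list(matches = matches, proteins = prots)
}
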