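#' MSI dataset container
#'
#' Bundles a spectra intensity matrix (one row per pixel spectrum, one column
#' per m/z axis point), per-spectrum pixel metadata, and a patient table into
#' a single object used by all downstream stages.
#'
#' @param intensities numeric matrix, spectra x m/z axis points; non-negative.
#' @param mz numeric vector of m/z values (Da), strictly increasing, one per
#'   column of \code{intensities}.
#' @param meta data.frame with one row per spectrum and columns
#'   \code{patient_id}, \code{cohort}, \code{slide}, \code{x}, \code{y},
#'   \code{roi_flag} (TRUE for pixels inside the annotated tumor region).
#' @param patients data.frame with one row per patient and columns
#'   \code{patient_id}, \code{outcome} ("RecPro" or "NED"), \code{cohort},
#'   \code{slide}.
#' @return an object of class \code{msi_dataset}.
#' @export
msi_dataset <- function(intensities, mz, meta, patients) {
  intensities <- as.matrix(intensities)
  mz <- as.numeric(mz)
  if (ncol(intensities) != length(mz))
    stopf("ncol(intensities) (%d) != length(mz) (%d)", ncol(intensities), length(mz))
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stopf("m/z axis must be strictly increasing")
  need <- c("patient_id", "cohort", "slide", "x", "y", "roi_flag")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("meta is missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(meta) != nrow(intensities))
    stopf("nrow(meta) (%d) != nrow(intensities) (%d)", nrow(meta), nrow(intensities))
  needp <- c("patient_id", "outcome", "cohort", "slide")
  missp <- setdiff(needp, names(patients))
  if (length(missp)) stopf("patient table is missing columns: %s", paste(missp, collapse = ", "))
  unknown <- setdiff(unique(meta$patient_id), patients$patient_id)
  if (length(unknown))
    stopf("spectra reference patient ids absent from the patient table: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  if (anyDuplicated(patients$patient_id))
    stopf("duplicate patient ids in patient table")
  key <- paste(meta$patient_id, meta$x, meta$y)
  if (anyDuplicated(key))
    stopf("duplicate (patient, x, y) pixel keys in spectra table")
  bad <- !is.na(patients$outcome) & !patients$outcome %in% c("RecPro", "NED")
  if (any(bad)) stopf("patient outcomes must be 'RecPro' or 'NED'")
  meta$roi_flag <- as.logical(meta$roi_flag)
  rownames(meta) <- NULL
  rownames(patients) <- NULL
  structure(list(intensities = intensities, mz = mz,
                 meta = meta, patients = patients),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("MSI dataset: %d spectra (%d in tumor ROI), %d m/z points [%.3f..%.3f Da]\n",
              nrow(x$intensities), sum(x$meta$roi_flag), length(x$mz),
              min(x$mz), max(x$mz)))
  tab <- table(x$patients$outcome)
  cat(sprintf("  %d patients (%s), cohort(s): %s\n",
              nrow(x$patients),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              paste(unique(x$patients$cohort), collapse = ", ")))
  invisible(x)
}

#' @export
dim.msi_dataset <- function(x) dim(x$intensities)

# outcome per spectrum, as a factor with RecPro first (negative class)
spectrum_outcome <- function(dataset) {
  idx <- match(dataset$meta$patient_id, dataset$patients$patient_id)
  factor(dataset$patients$outcome[idx], levels = c("RecPro", "NED"))
}

#' Read a spectra table exported as CSV
#'
#' Reads the flat per-spectrum export format: columns \code{patient_id},
#' \code{cohort}, \code{slide}, \code{x}, \code{y}, \code{roi_flag}, then one
#' \code{mz_<value>} column per m/z axis point. A patient metadata table
#' (columns \code{patient_id}, \code{outcome}, \code{cohort}, \code{slide})
#' is read from \code{patients_path} when given, otherwise reconstructed from
#' the spectra table with outcome \code{NA}.
#'
#' @param path path to the spectra CSV.
#' @param patients_path optional path to the patient metadata CSV.
#' @return an \code{\link{msi_dataset}}.
#' @export
read_spectra_table <- function(path, patients_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("patient_id", "cohort", "slide", "x", "y", "roi_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("spectra table is missing columns: %s", paste(miss, collapse = ", "))
  mzcols <- grep("^mz_", names(df), value = TRUE)
  mz <- as.numeric(sub("^mz_", "", mzcols))
  if (length(mzcols) && anyNA(mz)) stopf("malformed mz_ column headers")
  intens <- as.matrix(df[, mzcols, drop = FALSE])
  storage.mode(intens) <- "double"
  dimnames(intens) <- NULL
  meta <- df[, need, drop = FALSE]
  if (!is.null(patients_path)) {
    patients <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  } else {
    patients <- unique(meta[, c("patient_id", "cohort", "slide")])
    patients$outcome <- rep(NA_character_, nrow(patients))
    patients <- patients[, c("patient_id", "outcome", "cohort", "slide")]
  }
  msi_dataset(intens, mz, meta, patients)
}

#' Write a dataset to the flat spectra-table CSV format
#'
#' Numeric values are written with 17 significant digits so that a
#' write-then-read round trip reproduces the dataset exactly.
#'
#' @param dataset an \code{\link{msi_dataset}}.
#' @param path output path for the spectra CSV.
#' @param patients_path optional output path for the patient metadata CSV.
#' @return \code{path}, invisibly.
#' @export
write_spectra_table <- function(dataset, path, patients_path = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"))
  vals <- dataset$intensities
  chr <- matrix(trimws(formatC(vals, digits = 17, format = "g")),
                nrow = nrow(vals), ncol = ncol(vals))
  df <- cbind(dataset$meta,
              stats::setNames(as.data.frame(chr, stringsAsFactors = FALSE),
                              sprintf("mz_%.17g", dataset$mz)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(patients_path))
    utils::write.csv(dataset$patients, patients_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
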