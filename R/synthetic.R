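# Synthetic two-cohort MALDI-MSI generator with known ground truth: planted
# outcome-associated m/z features (lower in the RecPro group), spatially
# correlated intratumoral subclones, per-slide batch effects, additive
# baseline, and adjacent non-tumor reference tissue per patient.

#' Specification of a synthetic MSI cohort
#'
#' Collects all generator parameters. Defaults emulate the training-cohort
#' shape: 31 patients (20 RecPro / 11 NED), 200 tumor spectra per patient at
#' 50 um pitch, 700 aligned peptide features in m/z 600-3200, 30 planted
#' outcome-associated features whose intensity is lower in RecPro tumors, and
#' contiguous subclone patches covering 20 percent of each tumor in which the
#' opposite class profile is expressed.
#'
#' @param cohort_id cohort label, e.g. \code{"CDDP"} or \code{"MMC"}.
#' @param n_patients_per_class named counts \code{c(RecPro=, NED=)}.
#' @param spectra_per_patient tumor-ROI pixels per patient.
#' @param n_features number of peptide peaks on the m/z axis.
#' @param mz_range \code{c(min, max)} m/z in Da.
#' @param n_signal_features number of planted outcome-associated features.
#' @param effect_size standardized class shift of planted features, in units
#'   of the within-group SD of log-intensity.
#' @param spatial_correlation_length smoothing length (pixels) of the spatial
#'   random fields.
#' @param subclone_fraction fraction of each tumor's pixels belonging to a
#'   discordant subclone expressing the opposite class profile.
#' @param slide_count number of slides patients are distributed over.
#' @param batch_sd SD of per-slide, per-feature log-intensity offsets.
#' @param normal_fraction non-tumor reference pixels per patient, as a
#'   fraction of \code{spectra_per_patient}.
#' @param sigma_pixel SD of white per-pixel, per-feature log-intensity noise.
#' @param sigma_spatial SD of the smooth per-pixel common field (matrix and
#'   sampling-efficiency variation shared by all features of a pixel; this is
#'   what TIC normalization removes).
#' @param sigma_patient SD of per-patient, per-feature offsets.
#' @param sigma_program SD of a latent spatial program shared by the planted
#'   features (co-expression of peptides from the same proteins).
#' @param feature_abundance_sd SD of per-feature log median abundance.
#' @param baseline_amplitude amplitude of the additive, slowly varying raw
#'   baseline along the m/z axis (relative to a median peak intensity of 1).
#' @param full_scale if TRUE, use 3500 tumor spectra per patient instead of
#'   the desk-scale 200.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(cohort_id = "CDDP",
                        n_patients_per_class = c(RecPro = 20L, NED = 11L),
                        spectra_per_patient = 200L,
                        n_features = 700L,
                        mz_range = c(600, 3200),
                        n_signal_features = 30L,
                        effect_size = 1.0,
                        spatial_correlation_length = 5L,
                        subclone_fraction = 0.2,
                        slide_count = 9L,
                        batch_sd = 0.1,
                        normal_fraction = 0.5,
                        sigma_pixel = 0.35,
                        sigma_spatial = 0.6,
                        sigma_patient = 0.2,
                        sigma_program = 0.35,
                        feature_abundance_sd = 0.4,
                        baseline_amplitude = 0.2,
                        full_scale = FALSE,
                        seed = 1L) {
  if (isTRUE(full_scale)) spectra_per_patient <- 3500L
  n_patients_per_class <- unlist(n_patients_per_class)   # accept YAML lists
  if (!all(c("RecPro", "NED") %in% names(n_patients_per_class)))
    stopf("`n_patients_per_class` must be named c(RecPro=, NED=)")
  assert_count(n_patients_per_class[["RecPro"]], "n_patients_per_class[RecPro]")
  assert_count(n_patients_per_class[["NED"]], "n_patients_per_class[NED]")
  assert_count(spectra_per_patient, "spectra_per_patient", min = 2L)
  assert_count(n_features, "n_features")
  assert_count(n_signal_features, "n_signal_features", min = 0L)
  assert_count(slide_count, "slide_count")
  if (n_signal_features > n_features)
    stopf("n_signal_features must not exceed n_features")
  if (length(mz_range) != 2L || mz_range[1] >= mz_range[2])
    stopf("mz_range must be (min, max) with min < max")
  assert_fraction(subclone_fraction, "subclone_fraction")
  assert_fraction(normal_fraction, "normal_fraction")
  if (effect_size < 0) stopf("effect_size must be non-negative")
  spec <- list(cohort_id = cohort_id,
               n_patients_per_class = n_patients_per_class,
               spectra_per_patient = as.integer(spectra_per_patient),
               n_features = as.integer(n_features),
               mz_range = as.numeric(mz_range),
               n_signal_features = as.integer(n_signal_features),
               effect_size = effect_size,
               spatial_correlation_length = as.integer(spatial_correlation_length),
               subclone_fraction = subclone_fraction,
               slide_count = as.integer(slide_count),
               batch_sd = batch_sd,
               normal_fraction = normal_fraction,
               sigma_pixel = sigma_pixel, sigma_spatial = sigma_spatial,
               sigma_patient = sigma_patient, sigma_program = sigma_program,
               feature_abundance_sd = feature_abundance_sd,
               baseline_amplitude = baseline_amplitude,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

# smooth Gaussian random field on an nr x nc grid: white noise smoothed by a
# moving-average kernel of width ~len in both directions, rescaled to unit SD
.smooth_field <- function(nr, nc, len) {
  if (len <= 1L) return(matrix(stats::rnorm(nr * nc), nr, nc))
  pad <- len
  z <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)), nr + 2 * pad, nc + 2 * pad)
  k <- rep(1, len)
  z <- apply(z, 2L, function(col) as.numeric(stats::filter(col, k, sides = 2)))
  z <- t(apply(z, 1L, function(row) as.numeric(stats::filter(row, k, sides = 2))))
  z <- z[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE]
  z <- z[seq_len(nr), seq_len(nc), drop = FALSE]
  (z - mean(z, na.rm = TRUE)) / stats::sd(as.numeric(z), na.rm = TRUE)
}

#' Generate a synthetic MSI cohort with ground truth
#'
#' Each patient receives a rectangular-ish pixel grid: tumor-ROI pixels plus
#' a band of adjacent non-tumor reference pixels (flagged
#' \code{roi_flag = FALSE}) expressing the class-neutral profile. On the log
#' scale, pixel intensities sum a per-feature abundance, per-patient and
#' per-slide offsets, a smooth spatial common field, a latent spatial program
#' over the planted features, the planted class shift, and white noise; the
#' planted shift lowers RecPro tumor intensity by
#' \code{effect_size * sd(log-intensity)} except inside subclone patches,
#' which express the opposite class profile. A slowly varying additive
#' baseline is laid along the raw m/z axis.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param signal_features optional integer indices of the planted features
#'   (default: a seeded random draw); pass another cohort's indices to build
#'   a shared-signal transfer cohort.
#' @param signal_direction per-feature sign of the planted shift; default -1
#'   (lower in RecPro).
#' @return a list with elements \code{dataset} (\code{\link{msi_dataset}})
#'   and \code{truth} (class \code{msi_ground_truth}: planted feature indices
#'   and m/z, shift directions, per-spectrum subclone mask, patient outcomes,
#'   and the noise SD used to scale the shift).
#' @export
generate_cohort <- function(spec, signal_features = NULL, signal_direction = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    nf <- spec$n_features
    n_axis <- 2L * nf + 1L
    mz <- seq(spec$mz_range[1], spec$mz_range[2], length.out = n_axis)
    peak_cols <- 2L * seq_len(nf)              # peaks interleaved with gaps
    n_pat <- sum(spec$n_patients_per_class)
    outcomes <- rep(c("RecPro", "NED"), spec$n_patients_per_class[c("RecPro", "NED")])
    pids <- sprintf("%s_P%02d", spec$cohort_id, seq_len(n_pat))
    slides <- sprintf("S%02d", sample(rep_len(seq_len(spec$slide_count), n_pat)))
    patients <- data.frame(patient_id = pids, outcome = outcomes,
                           cohort = spec$cohort_id, slide = slides,
                           stringsAsFactors = FALSE)

    if (is.null(signal_features)) {
      signal_features <- sort(sample(nf, spec$n_signal_features))
    } else {
      signal_features <- sort(as.integer(signal_features))
      if (any(signal_features < 1L | signal_features > nf))
        stopf("signal_features out of range")
    }
    direction <- signal_direction %||% rep(-1, length(signal_features))

    # total log-scale noise SD of a planted feature; the planted shift is
    # effect_size times this, so the standardized group difference equals
    # effect_size when there are no subclones
    sigma_total <- sqrt(spec$sigma_pixel^2 + spec$sigma_spatial^2 +
                        spec$sigma_patient^2 + spec$batch_sd^2 +
                        spec$sigma_program^2)
    shift <- numeric(nf)
    shift[signal_features] <- direction * spec$effect_size * sigma_total

    mu_f <- stats::rnorm(nf, 0, spec$feature_abundance_sd)
    slide_eff <- matrix(stats::rnorm(spec$slide_count * nf, 0, spec$batch_sd),
                        spec$slide_count, nf,
                        dimnames = list(sprintf("S%02d", seq_len(spec$slide_count)), NULL))
    baseline <- spec$baseline_amplitude *
      (0.6 * exp(-(mz - spec$mz_range[1]) / 800) +
       0.4 * (1 + cos(2 * pi * (mz - spec$mz_range[1]) / 1300)) / 2)

    n_tum <- spec$spectra_per_patient
    n_nor <- as.integer(round(spec$normal_fraction * n_tum))
    n_pix <- n_tum + n_nor
    total <- n_pat * n_pix
    intens <- matrix(0, total, n_axis)
    meta <- data.frame(patient_id = rep(pids, each = n_pix),
                       cohort = spec$cohort_id,
                       slide = rep(slides, each = n_pix),
                       x = 0L, y = 0L, roi_flag = FALSE,
                       stringsAsFactors = FALSE)
    subclone <- logical(total)

    ncol_grid <- ceiling(sqrt(n_pix))
    nrow_grid <- ceiling(n_pix / ncol_grid)
    gx <- rep(seq_len(ncol_grid) - 1L, times = nrow_grid)[seq_len(n_pix)]
    gy <- rep(seq_len(nrow_grid) - 1L, each = ncol_grid)[seq_len(n_pix)]
    # tumor ROI = first n_tum pixels in row-major order (a contiguous block);
    # the trailing band is adjacent non-tumor reference tissue
    roi <- c(rep(TRUE, n_tum), rep(FALSE, n_nor))

    for (p in seq_len(n_pat)) {
      rows <- (p - 1L) * n_pix + seq_len(n_pix)
      meta$x[rows] <- gx
      meta$y[rows] <- gy
      meta$roi_flag[rows] <- roi

      sf <- .smooth_field(nrow_grid, ncol_grid, spec$spatial_correlation_length)
      common <- spec$sigma_spatial * sf[cbind(gy + 1L, gx + 1L)]
      pf <- .smooth_field(nrow_grid, ncol_grid, spec$spatial_correlation_length)
      program <- spec$sigma_program * pf[cbind(gy + 1L, gx + 1L)]

      sub_field <- .smooth_field(nrow_grid, ncol_grid, spec$spatial_correlation_length)
      sub_vals <- sub_field[cbind(gy + 1L, gx + 1L)]
      sub_tum <- rep(FALSE, n_pix)
      if (spec$subclone_fraction > 0 && n_tum > 0L) {
        thr <- stats::quantile(sub_vals[roi], 1 - spec$subclone_fraction,
                               names = FALSE, type = 1)
        sub_tum[roi] <- sub_vals[roi] > thr
      }
      subclone[rows] <- sub_tum

      # planted profile: tumor pixels express their class profile except in
      # subclone patches (opposite class); non-tumor tissue is class-neutral
      is_rec <- outcomes[p] == "RecPro"
      expressed <- roi & (if (is_rec) !sub_tum else sub_tum)

      a_pf <- stats::rnorm(nf, 0, spec$sigma_patient)
      b_sf <- slide_eff[slides[p], ]
      eps <- matrix(stats::rnorm(n_pix * nf, 0, spec$sigma_pixel), n_pix, nf)
      logI <- eps +
        rep(mu_f + a_pf + b_sf, each = n_pix) +
        common +
        outer(as.numeric(expressed), shift) +
        outer(program, as.numeric(seq_len(nf) %in% signal_features))
      peaks <- exp(logI)
      spect <- matrix(rep(baseline, each = n_pix), n_pix, n_axis)
      spect <- spect + matrix(abs(stats::rnorm(n_pix * n_axis, 0, 0.004)), n_pix, n_axis)
      spect[, peak_cols] <- spect[, peak_cols] + peaks
      intens[rows, ] <- spect
    }

    dataset <- msi_dataset(intens, mz, meta, patients)
    truth <- structure(list(signal_features = signal_features,
                            direction = direction,
                            signal_mz = mz[peak_cols][signal_features],
                            feature_mz = mz[peak_cols],
                            subclone = subclone,
                            outcomes = stats::setNames(outcomes, pids),
                            sigma_total = sigma_total,
                            effect_size = spec$effect_size),
                       class = "msi_ground_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Generate a synthetic bottom-up peptide library
#'
#' Builds an LC-MS/MS-style peptide library aligned with a generated cohort's
#' feature m/z grid. "Validating" proteins receive
#' \code{peptides_per_protein} peptides mapped to planted (hence spatially
#' co-expressed) features; once planted features are exhausted, additional
#' proteins draw their peptides from non-planted features (co-localization is
#' then not guaranteed); \code{n_singletons} further proteins receive a
#' single peptide each and can never pass the two-peptide validation rule.
#' Library masses are stored as neutral monoisotopic masses, i.e. the feature
#' m/z (treated as the [M+H]+ ion) minus one proton mass, plus measurement
#' jitter.
#'
#' @param truth an \code{msi_ground_truth} from \code{\link{generate_cohort}}.
#' @param feature_mzs centroid m/z values of the aligned feature matrix.
#' @param n_proteins number of multi-peptide proteins.
#' @param peptides_per_protein peptides per multi-peptide protein (>= 1).
#' @param mass_jitter_sd SD (Da) of the library mass error.
#' @param n_singletons number of single-peptide proteins appended.
#' @param seed integer seed.
#' @return a data.frame of class \code{msi_peptide_library} with columns
#'   \code{sequence}, \code{monoisotopic_mass}, \code{protein_id},
#'   \code{protein_name}, \code{score}; the planted feature-to-protein map is
#'   attached as attribute \code{"planted"}.
#' @export
generate_peptide_library <- function(truth, feature_mzs, n_proteins = 10L,
                                     peptides_per_protein = 2L,
                                     mass_jitter_sd = 0, n_singletons = 3L,
                                     seed = 1L) {
  assert_count(peptides_per_protein, "peptides_per_protein")
  assert_count(n_proteins, "n_proteins", min = 0L)
  assert_count(n_singletons, "n_singletons", min = 0L)
  with_seed(seed, {
    nf <- length(feature_mzs)
    sig <- intersect(truth$signal_features, seq_len(nf))
    null_feats <- setdiff(seq_len(nf), sig)
    rand_pep <- function(n) {
      aa <- c("A", "D", "E", "F", "G", "H", "I", "L", "N", "P", "Q", "S", "T", "V", "W", "Y")
      vapply(seq_len(n), function(i)
        paste0(paste(sample(aa, sample(7:14, 1), replace = TRUE), collapse = ""),
               sample(c("K", "R"), 1)), character(1))
    }
    rows <- list()
    planted <- list()
    pool_sig <- sig
    pool_null <- sample(null_feats)
    for (k in seq_len(n_proteins)) {
      if (length(pool_sig) >= peptides_per_protein) {
        feats <- pool_sig[seq_len(peptides_per_protein)]
        pool_sig <- pool_sig[-seq_len(peptides_per_protein)]
      } else {
        if (length(pool_null) < peptides_per_protein) break
        feats <- pool_null[seq_len(peptides_per_protein)]
        pool_null <- pool_null[-seq_len(peptides_per_protein)]
      }
      pid <- sprintf("PROT%03d", k)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = rand_pep(length(feats)),
        monoisotopic_mass = feature_mzs[feats] - 1.00728 +
          stats::rnorm(length(feats), 0, mass_jitter_sd),
        protein_id = pid,
        protein_name = sprintf("Synthetic protein %d", k),
        stringsAsFactors = FALSE)
      planted[[pid]] <- feats
    }
    for (k in seq_len(n_singletons)) {
      if (!length(pool_null)) break
      f <- pool_null[1L]; pool_null <- pool_null[-1L]
      pid <- sprintf("SING%03d", k)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = rand_pep(1L),
        monoisotopic_mass = feature_mzs[f] - 1.00728 +
          stats::rnorm(1L, 0, mass_jitter_sd),
        protein_id = pid,
        protein_name = sprintf("Synthetic singleton %d", k),
        stringsAsFactors = FALSE)
      planted[[pid]] <- f
    }
    lib <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sequence = character(0), monoisotopic_mass = numeric(0),
                 protein_id = character(0), protein_name = character(0),
                 stringsAsFactors = FALSE)
    lib$score <- if (nrow(lib)) stats::runif(nrow(lib), 20, 60) else numeric(0)
    rownames(lib) <- NULL
    class(lib) <- c("msi_peptide_library", "data.frame")
    attr(lib, "planted") <- planted
    lib
  })
}

#' Write a generated cohort to disk
#'
#' Writes the spectra table CSV, the patient metadata CSV, and the ground
#' truth as JSON into \code{dir}.
#'
#' @param cohort a list with \code{dataset} and \code{truth} as returned by
#'   \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra_table(cohort$dataset, file.path(dir, "spectra.csv"),
                      patients_path = file.path(dir, "patients.csv"))
  gt <- cohort$truth
  jsonlite::write_json(list(signal_features = gt$signal_features,
                            direction = gt$direction,
                            signal_mz = gt$signal_mz,
                            subclone = gt$subclone,
                            outcomes = as.list(gt$outcomes),
                            sigma_total = gt$sigma_total,
                            effect_size = gt$effect_size),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
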