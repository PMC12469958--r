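# End-to-end orchestration: simulate -> preprocess -> screen -> fit ->
# transfer -> annotate -> report, with YAML config, provenance logging, and
# deterministic outputs.

#' Default pipeline configuration
#'
#' Returns the demo configuration as a nested list; every field can be
#' overridden via a YAML file or by modifying the list. Cohort blocks accept
#' any \code{\link{cohort_spec}} argument.
#'
#' @param seed master seed; cohort and stage seeds are derived from it.
#' @return a named list.
#' @export
default_config <- function(seed = 1L) {
  list(seed = seed,
       cohorts = list(
         train = list(cohort_id = "CDDP", seed = seed),
         transfer = list(cohort_id = "MMC",
                         n_patients_per_class = c(RecPro = 15L, NED = 14L),
                         seed = seed + 1000L)),
       shared_signal = FALSE,
       preprocessing = list(structure_width = 201L, tolerance = 0.2,
                            min_prominence = 0, smooth = FALSE),
       screening = list(auc_lo = 0.3, auc_hi = 0.7, alpha = 0.001,
                        method = "BH", n_draws = 1L),
       models = list(all_mz = list(lambda = 0.02),
                     restricted = list(lambda = 0.05)),
       cv = list(n_folds = 5L),
       annotation = list(tolerance_da = 0.2, min_peptides = 2L,
                         min_correlation = 0.4, n_proteins = 10L,
                         peptides_per_protein = 2L, mass_jitter_sd = 0.05,
                         n_singletons = 3L))
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config(config$seed %||% 1L)
  utils::modifyList(base, config)
}

.log_stage <- function(con, msg, t0 = NULL) {
  line <- sprintf("[%s] %s%s", format(Sys.time(), "%H:%M:%S"), msg,
                  if (!is.null(t0)) sprintf(" (%.1fs)",
                                            as.numeric(Sys.time()) - t0) else "")
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Executes all stages on synthetic cohorts and writes every report into
#' \code{out_dir}: feature statistics, within-cohort and transfer metric
#' tables (wide, split columns plus mean), per-patient classification tables,
#' per-pixel class-probability maps, the annotation report, the ground truth,
#' and a provenance log with package version, seeds, and parameters.
#' Re-running with the same config reproduces identical output values.
#'
#' @param config a config list (see \code{\link{default_config}}) or the path
#'   to a YAML file with the same structure.
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("msirun")) {
  cfg <- .load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "provenance.log"), open = "wt")
  on.exit(close(logf))
  .log_stage(logf, sprintf("msiclass %s; master seed %d",
                           as.character(utils::packageVersion("msiclass")),
                           cfg$seed))
  .log_stage(logf, paste("config:", jsonlite::toJSON(cfg, auto_unbox = TRUE)))

  t0 <- as.numeric(Sys.time())
  spec_a <- do.call(cohort_spec, cfg$cohorts$train)
  coh_a <- generate_cohort(spec_a)
  spec_b <- do.call(cohort_spec, cfg$cohorts$transfer)
  coh_b <- if (isTRUE(cfg$shared_signal))
    generate_cohort(spec_b, signal_features = coh_a$truth$signal_features,
                    signal_direction = coh_a$truth$direction)
  else generate_cohort(spec_b)
  .log_stage(logf, sprintf("simulate: %d + %d spectra", nrow(coh_a$dataset$intensities),
                           nrow(coh_b$dataset$intensities)), t0)

  t0 <- as.numeric(Sys.time())
  pp <- cfg$preprocessing
  fm_a <- preprocess_dataset(coh_a$dataset, pp$structure_width, pp$tolerance,
                             pp$min_prominence, pp$smooth)
  ds_b <- tic_normalize(tophat_baseline(coh_b$dataset, pp$structure_width))
  fm_b <- apply_feature_centroids(ds_b, fm_a$feature_mz, pp$tolerance)
  .log_stage(logf, sprintf("preprocess: %d aligned features [%s]",
                           ncol(fm_a$values),
                           paste(attr(fm_a, "provenance"), collapse = " -> ")), t0)

  t0 <- as.numeric(Sys.time())
  sc <- cfg$screening
  stats <- screen_features(fm_a, seed = cfg$seed, auc_lo = sc$auc_lo,
                           auc_hi = sc$auc_hi, alpha = sc$alpha,
                           method = sc$method, n_draws = sc$n_draws)
  utils::write.csv(as.data.frame(stats), file.path(out_dir, "feature_stats.csv"),
                   row.names = FALSE)
  .log_stage(logf, sprintf("screen: %d/%d features selected",
                           sum(stats$selected), nrow(stats)), t0)

  t0 <- as.numeric(Sys.time())
  fits <- list()
  transfers <- list()
  plan <- make_grouped_stratified_folds(coh_a$dataset$patients,
                                        cfg$cv$n_folds, seed = cfg$seed)
  fits$all_mz <- outcome_cv(fm_a, lambda = cfg$models$all_mz$lambda,
                            feature_mode = "all_mz", plan = plan)
  sel <- which(stats$selected)
  if (length(sel)) {
    fits$restricted <- outcome_cv(fm_a, lambda = cfg$models$restricted$lambda,
                                  feature_mode = "restricted",
                                  restrict_to = sel, plan = plan)
  } else .log_stage(logf, "fit: no features selected; skipping restricted model")
  for (nm in names(fits)) transfers[[nm]] <- cross_cohort_evaluate(fits[[nm]], fm_b)
  .log_stage(logf, sprintf("fit+transfer: models [%s]",
                           paste(names(fits), collapse = ", ")), t0)

  metrics_out <- list()
  for (nm in names(fits)) {
    metrics_out[[nm]] <- list(within = .metrics_table(fits[[nm]]$metrics),
                              transfer = .metrics_table(transfers[[nm]]$metrics))
    utils::write.csv(metrics_out[[nm]]$within,
                     file.path(out_dir, sprintf("metrics_within_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(metrics_out[[nm]]$transfer,
                     file.path(out_dir, sprintf("metrics_transfer_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(fits[[nm]]$patient_predictions,
                     file.path(out_dir, sprintf("patient_predictions_%s.csv", nm)),
                     row.names = FALSE)
    roi <- fits[[nm]]$meta$roi_flag
    maps <- data.frame(patient_id = fits[[nm]]$meta$patient_id[roi],
                       x = fits[[nm]]$meta$x[roi], y = fits[[nm]]$meta$y[roi],
                       p_ned = fits[[nm]]$prob_ned[roi])
    utils::write.csv(maps, file.path(out_dir, sprintf("probability_maps_%s.csv", nm)),
                     row.names = FALSE)
  }
  jsonlite::write_json(metrics_out, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  t0 <- as.numeric(Sys.time())
  an <- cfg$annotation
  lib <- generate_peptide_library(coh_a$truth, fm_a$feature_mz,
                                  n_proteins = an$n_proteins,
                                  peptides_per_protein = an$peptides_per_protein,
                                  mass_jitter_sd = an$mass_jitter_sd,
                                  n_singletons = an$n_singletons,
                                  seed = cfg$seed)
  write_peptide_library(lib, file.path(out_dir, "peptide_library.csv"))
  annot <- annotate_features(stats, fm_a, lib, tolerance_da = an$tolerance_da,
                             min_peptides = an$min_peptides,
                             min_correlation = an$min_correlation)
  utils::write.csv(annot$matches, file.path(out_dir, "annotation_matches.csv"),
                   row.names = FALSE)
  utils::write.csv(annot$proteins, file.path(out_dir, "annotation_proteins.csv"),
                   row.names = FALSE)
  .log_stage(logf, sprintf("annotate: %d/%d selected features matched, %d/%d proteins validated",
                           sum(annot$matches$matched), nrow(annot$matches),
                           sum(annot$proteins$validated), nrow(annot$proteins)), t0)

  jsonlite::write_json(list(signal_features = coh_a$truth$signal_features,
                            signal_mz = coh_a$truth$signal_mz,
                            direction = coh_a$truth$direction),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage(logf, sprintf("done: outputs in %s", out_dir))
  invisible(list(config = cfg, cohort = coh_a, transfer_cohort = coh_b,
                 features = fm_a, transfer_features = fm_b, stats = stats,
                 fits = fits, transfers = transfers, annotation = annot,
                 out_dir = out_dir))
}

#' Render human-readable reports from a pipeline run directory
#'
#' Reads the artifacts written by \code{\link{run_pipeline}} (no quantity is
#' re-computed) and renders a plain-text summary, a per-patient
#' correct-fraction bar chart, and per-patient class-probability maps as PNG
#' files. Idempotent: re-rendering overwrites the same files.
#'
#' @param run_dir a \code{\link{run_pipeline}} output directory.
#' @param models which fitted models to render (default: all found).
#' @return invisibly, the paths of the rendered files.
#' @export
render_reports <- function(run_dir, models = c("all_mz", "restricted")) {
  stopifnot(dir.exists(run_dir))
  rendered <- character(0)
  summary_path <- file.path(run_dir, "summary.txt")
  con <- file(summary_path, open = "wt")
  on.exit(close(con))
  for (nm in models) {
    mfile <- file.path(run_dir, sprintf("metrics_within_%s.csv", nm))
    pfile <- file.path(run_dir, sprintf("patient_predictions_%s.csv", nm))
    mapfile <- file.path(run_dir, sprintf("probability_maps_%s.csv", nm))
    if (!file.exists(mfile)) {
      if (nm %in% c("all_mz")) stopf("missing pipeline artifact: %s", mfile)
      next
    }
    if (!file.exists(pfile)) stopf("missing pipeline artifact: %s", pfile)
    writeLines(sprintf("== %s features: within-cohort cross-validation ==", nm), con)
    tab <- utils::read.csv(mfile)
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], round, digits = 3)
    utils::capture.output(print(tab, row.names = FALSE), file = con)
    tfile <- file.path(run_dir, sprintf("metrics_transfer_%s.csv", nm))
    if (file.exists(tfile)) {
      writeLines(sprintf("== %s features: cross-cohort transfer ==", nm), con)
      tt <- utils::read.csv(tfile)
      num <- vapply(tt, is.numeric, logical(1))
      tt[num] <- lapply(tt[num], round, digits = 3)
      utils::capture.output(print(tt, row.names = FALSE), file = con)
    }
    pp <- utils::read.csv(pfile, stringsAsFactors = FALSE)
    png_path <- file.path(run_dir, sprintf("patient_fraction_%s.png", nm))
    grDevices::png(png_path, width = 1000, height = 500)
    if (nrow(pp)) {
      pp <- pp[order(pp$true, -pp$fraction_correct), ]
      graphics::barplot(pp$fraction_correct, names.arg = pp$patient_id,
                        col = ifelse(pp$true == "NED", "#2166ac", "#b2182b"),
                        las = 2, cex.names = 0.6,
                        ylab = "fraction of spectra correctly classified",
                        main = sprintf("%s features", nm))
      graphics::abline(h = 0.5, lty = 2)
    } else graphics::plot.new()
    grDevices::dev.off()
    rendered <- c(rendered, png_path)
    if (file.exists(mapfile)) {
      maps <- utils::read.csv(mapfile, stringsAsFactors = FALSE)
      map_png <- file.path(run_dir, sprintf("probability_maps_%s.png", nm))
      pats <- unique(maps$patient_id)
      nc <- ceiling(sqrt(length(pats)))
      grDevices::png(map_png, width = 220 * nc, height = 220 * ceiling(length(pats) / nc))
      op <- graphics::par(mfrow = c(ceiling(length(pats) / nc), nc),
                          mar = c(1, 1, 2, 1))
      pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(101)
      for (p in pats) {
        sub <- maps[maps$patient_id == p, ]
        img <- matrix(NA_real_, max(sub$y) + 1L, max(sub$x) + 1L)
        img[cbind(sub$y + 1L, sub$x + 1L)] <- sub$p_ned
        graphics::image(t(img), col = pal, zlim = c(0, 1), axes = FALSE, main = p)
      }
      graphics::par(op)
      grDevices::dev.off()
      rendered <- c(rendered, map_png)
    }
  }
  rendered <- c(summary_path, rendered)
  invisible(rendered)
}
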