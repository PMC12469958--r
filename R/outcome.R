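# Outcome classification: L1-penalized logistic regression on per-patient
# standardized feature intensities, patient-grouped stratified 5-fold
# cross-validation, spectra- and patient-level evaluation, majority voting,
# coefficient stability, and cross-cohort transfer.
#
# NED is the positive class throughout (sensitivity = NED recall).

#' Patient-grouped, class-stratified cross-validation folds
#'
#' Assigns whole patients to folds by seeded round-robin over class-shuffled
#' patients, so every spectrum of a patient falls in exactly one fold and the
#' per-fold class mix is balanced to within one patient per class.
#'
#' @param patients patient table with columns \code{patient_id} and
#'   \code{outcome}.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return a data.frame of class \code{msi_cv_plan} with columns
#'   \code{patient_id}, \code{outcome}, \code{fold}.
#' @export
make_grouped_stratified_folds <- function(patients, n_folds = 5L, seed = 1L) {
  assert_count(n_folds, "n_folds", min = 2L)
  if (nrow(patients) < n_folds)
    stopf("fewer patients (%d) than folds (%d)", nrow(patients), n_folds)
  plan <- patients[, c("patient_id", "outcome")]
  plan$fold <- NA_integer_
  with_seed(seed, {
    for (cls in sort(unique(plan$outcome))) {
      idx <- which(plan$outcome == cls)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(n_folds, 1L)
      plan$fold[idx] <- ((start - 1L + seq_along(idx) - 1L) %% n_folds) + 1L
    }
  })
  class(plan) <- c("msi_cv_plan", "data.frame")
  attr(plan, "n_folds") <- as.integer(n_folds)
  plan
}

#' Fit a class-weighted L1-penalized logistic regression
#'
#' Minimizes the weighted mean negative log-likelihood plus
#' \code{lambda * sum(abs(coefficients))} (intercept unpenalized), with
#' observation weights inversely proportional to class frequency by default.
#' The solver is the coordinate-descent path of \pkg{glmnet}, whose binomial
#' objective with weights normalized by their sum equals this contract.
#'
#' @param x numeric feature matrix (rows = spectra), already standardized.
#' @param y labels: factor/character with values "NED" (positive) and
#'   "RecPro", or a 0/1 vector (1 = NED).
#' @param lambda non-negative L1 penalty weight.
#' @param weights optional observation weights; default inverse class
#'   frequency.
#' @param maxit maximum coordinate-descent passes.
#' @return a list of class \code{msi_l1fit}: \code{coefficients},
#'   \code{intercept}, \code{lambda}, \code{converged}.
#' @export
fit_l1_logistic <- function(x, y, lambda, weights = NULL, maxit = 1e5) {
  if (lambda < 0) stopf("lambda must be non-negative")
  y01 <- if (is.numeric(y)) as.integer(y) else as.integer(as.character(y) == "NED")
  if (!all(y01 %in% c(0L, 1L))) stopf("labels must be NED/RecPro or 0/1")
  if (length(unique(y01)) < 2L) stopf("both classes must be present in training data")
  if (is.null(weights)) {
    n <- length(y01)
    weights <- ifelse(y01 == 1L, n / (2 * sum(y01 == 1L)), n / (2 * sum(y01 == 0L)))
  }
  x <- as.matrix(x)
  # glmnet needs a decreasing path ending at the requested lambda for a
  # stable solution; warm starts make the path cheap
  lam_path <- sort(unique(c(lambda * exp(seq(log(50), 0, length.out = 15)), lambda)),
                   decreasing = TRUE)
  if (lambda == 0) lam_path <- c(exp(seq(log(1), log(1e-4), length.out = 15)), 0)
  fit <- glmnet::glmnet(x, y01, family = "binomial", weights = weights,
                        lambda = lam_path, standardize = FALSE,
                        thresh = 1e-10, maxit = maxit)
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))
  structure(list(coefficients = cf[-1L], intercept = cf[1L], lambda = lambda,
                 converged = fit$jerr == 0), class = "msi_l1fit")
}

#' Per-spectrum class probabilities from a fitted model
#'
#' @param model an \code{msi_l1fit} (or any list with \code{coefficients} and
#'   \code{intercept}).
#' @param x feature matrix with the same columns the model was fitted on.
#' @return vector of P(NED) per spectrum, in [0, 1].
#' @export
predict_spectra <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$coefficients))
    stopf("feature dimension mismatch: model has %d coefficients, data has %d columns",
          length(model$coefficients), ncol(x))
  stats::plogis(drop(x %*% model$coefficients) + model$intercept)
}

#' Aggregate spectrum probabilities to patient calls
#'
#' Sums P(NED) and P(RecPro) = 1 - P(NED) over each patient's spectra; the
#' patient is called for the class with the larger aggregated probability
#' (ties go to RecPro, the conservative call). Also reports the fraction of
#' spectra whose individual call matches the true label and the
#' majority-voting flag (correct iff strictly more than half the spectra are
#' correct).
#'
#' @param prob_ned per-spectrum P(NED).
#' @param patient_ids patient id per spectrum.
#' @param true_labels optional named vector or per-spectrum vector of true
#'   outcomes ("NED"/"RecPro").
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{sum_p_ned}, \code{sum_p_recpro}, \code{predicted},
#'   \code{true} / \code{fraction_correct} / \code{majority_correct} when
#'   true labels are supplied.
#' @export
aggregate_patient <- function(prob_ned, patient_ids, true_labels = NULL) {
  stopifnot(length(prob_ned) == length(patient_ids))
  ids <- unique(patient_ids)
  sum_ned <- vapply(ids, function(p) sum(prob_ned[patient_ids == p]), numeric(1))
  sum_rec <- vapply(ids, function(p) sum(1 - prob_ned[patient_ids == p]), numeric(1))
  out <- data.frame(patient_id = ids, sum_p_ned = sum_ned, sum_p_recpro = sum_rec,
                    predicted = ifelse(sum_ned > sum_rec, "NED", "RecPro"),
                    stringsAsFactors = FALSE)
  if (!is.null(true_labels)) {
    tl <- if (!is.null(names(true_labels))) unname(true_labels[ids])
          else vapply(ids, function(p) as.character(true_labels[patient_ids == p][1L]), character(1))
    spec_call <- ifelse(prob_ned > 0.5, "NED", "RecPro")
    frac <- vapply(ids, function(p) {
      truth <- tl[match(p, ids)]
      mean(spec_call[patient_ids == p] == truth)
    }, numeric(1))
    out$true <- tl
    out$fraction_correct <- frac
    out$majority_correct <- frac > 0.5
  }
  rownames(out) <- NULL
  out
}

#' Classification metrics with NED as the positive class
#'
#' Sensitivity is the NED recall, specificity the RecPro recall, balanced
#' accuracy their arithmetic mean, and the ROC-AUC is computed from the
#' scores with NED as positive. A class absent from the truth yields NA for
#' its recall (flagged via the \code{"undefined"} attribute).
#'
#' @param true_labels true outcomes ("NED"/"RecPro").
#' @param predicted_labels predicted outcomes.
#' @param probabilities optional scores (e.g. P(NED)) for the ROC-AUC.
#' @return named list: \code{sensitivity}, \code{specificity},
#'   \code{balanced_accuracy}, \code{auc}.
#' @export
compute_metrics <- function(true_labels, predicted_labels, probabilities = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  pos <- true_labels == "NED"
  sens <- if (any(pos)) mean(predicted_labels[pos] == "NED") else NA_real_
  spec <- if (any(!pos)) mean(predicted_labels[!pos] == "RecPro") else NA_real_
  auc <- if (!is.null(probabilities) && any(pos) && any(!pos))
    .pair_auc(probabilities[pos], probabilities[!pos]) else NA_real_
  out <- list(sensitivity = sens, specificity = spec,
              balanced_accuracy = balanced_accuracy(sens, spec), auc = auc)
  if (anyNA(c(sens, spec))) attr(out, "undefined") <- TRUE
  out
}

#' Balanced accuracy
#'
#' The arithmetic mean of sensitivity and specificity.
#'
#' @param sensitivity,specificity recalls of the positive (NED) and negative
#'   (RecPro) classes.
#' @return \code{(sensitivity + specificity) / 2}.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

# evaluate one prediction set at spectra and patient level
.eval_both_levels <- function(prob, pids, truth_per_spectrum) {
  spec_call <- ifelse(prob > 0.5, "NED", "RecPro")
  sp <- compute_metrics(truth_per_spectrum, spec_call, prob)
  agg <- aggregate_patient(prob, pids,
                           true_labels = stats::setNames(
                             vapply(unique(pids), function(p)
                               as.character(truth_per_spectrum[pids == p][1L]), character(1)),
                             unique(pids)))
  pt <- compute_metrics(agg$true, agg$predicted, agg$sum_p_ned)
  list(spectra = sp, patient = pt, patient_table = agg)
}

#' Cross-validated L1-logistic outcome model
#'
#' The central fitting routine: builds the requested feature representation,
#' standardizes per patient, assigns patient-grouped stratified folds, fits a
#' class-weighted L1-logistic model per training split, and evaluates held-out
#' spectra and patients. Returns an object with \code{print}, \code{summary},
#' \code{coef}, \code{predict}, and \code{plot} methods.
#'
#' @param fm an \code{\link{msi_features}} matrix (TIC-normalized; not yet
#'   standardized).
#' @param lambda L1 penalty weight (see \code{\link{fit_l1_logistic}}).
#' @param feature_mode \code{"all_mz"} (2x down-sampled full feature set) or
#'   \code{"restricted"} (the subset in \code{restrict_to}).
#' @param restrict_to integer feature indices (columns of \code{fm}) for
#'   \code{feature_mode = "restricted"}, typically from
#'   \code{\link{select_discriminatory}}.
#' @param n_folds number of cross-validation folds.
#' @param seed seed for fold assignment.
#' @param plan optional pre-built \code{\link{make_grouped_stratified_folds}}
#'   plan (overrides \code{n_folds}/\code{seed}).
#' @return an object of class \code{msi_cv}.
#' @export
outcome_cv <- function(fm, lambda = 0.02, feature_mode = c("all_mz", "restricted"),
                       restrict_to = NULL, n_folds = 5L, seed = 1L, plan = NULL) {
  stopifnot(inherits(fm, "msi_features"))
  feature_mode <- match.arg(feature_mode)
  fm_model <- .build_model_features(fm, feature_mode, restrict_to)
  fm_model <- per_patient_standardize(fm_model)
  patients <- fm_model$patients[!is.na(fm_model$patients$outcome), , drop = FALSE]
  if (is.null(plan)) plan <- make_grouped_stratified_folds(patients, n_folds, seed)
  n_folds <- attr(plan, "n_folds")

  roi <- fm_model$meta$roi_flag
  pids <- fm_model$meta$patient_id
  outc <- as.character(.feature_outcome(fm_model))
  fold_of <- plan$fold[match(pids, plan$patient_id)]
  fold_of[is.na(fold_of)] <- 0L   # spectra of patients without outcome: never used

  models <- vector("list", n_folds)
  split_rows <- list()
  patient_tables <- list()
  prob_all <- rep(NA_real_, nrow(fm_model$values))
  for (k in seq_len(n_folds)) {
    tr <- roi & fold_of != k
    te <- roi & fold_of == k
    stopifnot(!any(unique(pids[tr]) %in% unique(pids[te])))  # leakage guard
    models[[k]] <- fit_l1_logistic(fm_model$values[tr, , drop = FALSE],
                                   outc[tr], lambda = lambda)
    prob <- predict_spectra(models[[k]], fm_model$values[te, , drop = FALSE])
    prob_all[which(te)] <- prob
    ev <- .eval_both_levels(prob, pids[te], outc[te])
    patient_tables[[k]] <- cbind(ev$patient_table, split = k)
    split_rows[[k]] <- data.frame(
      split = k,
      level = rep(c("spectra", "patient"), each = 4L),
      metric = rep(c("balanced_accuracy", "auc", "sensitivity", "specificity"), 2L),
      value = c(ev$spectra$balanced_accuracy, ev$spectra$auc,
                ev$spectra$sensitivity, ev$spectra$specificity,
                ev$patient$balanced_accuracy, ev$patient$auc,
                ev$patient$sensitivity, ev$patient$specificity))
  }
  metrics <- do.call(rbind, split_rows)
  coefs <- vapply(models, function(m) m$coefficients, numeric(ncol(fm_model$values)))
  if (is.null(dim(coefs))) coefs <- matrix(coefs, nrow = 1L)
  structure(list(models = models, coefficients = coefs,
                 intercepts = vapply(models, function(m) m$intercept, numeric(1)),
                 metrics = metrics,
                 mean_metrics = stats::aggregate(value ~ level + metric,
                                                 metrics, mean),
                 patient_predictions = do.call(rbind, patient_tables),
                 prob_ned = prob_all,
                 plan = plan, lambda = lambda, feature_mode = feature_mode,
                 feature_mz = fm_model$feature_mz,
                 restrict_to = restrict_to,
                 tolerance = fm_model$tolerance,
                 meta = fm_model$meta,
                 call = match.call()),
            class = "msi_cv")
}

.build_model_features <- function(fm, feature_mode, restrict_to) {
  if (feature_mode == "all_mz") return(downsample_features(fm))
  if (is.null(restrict_to)) stopf("feature_mode='restricted' needs `restrict_to` indices")
  restrict_to <- sort(unique(as.integer(restrict_to)))
  if (!length(restrict_to)) stopf("`restrict_to` selects no features")
  if (any(restrict_to < 1L | restrict_to > ncol(fm$values)))
    stopf("`restrict_to` indices out of range")
  msi_features(fm$values[, restrict_to, drop = FALSE], fm$feature_mz[restrict_to],
               fm$tolerance, fm$meta, fm$patients, standardized = fm$standardized)
}

# Table-2-shaped wide metrics: rows level x metric, columns split1..k, mean
.metrics_table <- function(metrics) {
  k <- max(metrics$split)
  wide <- stats::reshape(metrics, idvar = c("level", "metric"),
                         timevar = "split", direction = "wide")
  names(wide) <- sub("^value\\.", "split", names(wide))
  wide$mean <- rowMeans(wide[, grep("^split", names(wide)), drop = FALSE])
  ord <- c("balanced_accuracy", "auc", "sensitivity", "specificity")
  wide <- wide[order(match(wide$level, c("spectra", "patient")),
                     match(wide$metric, ord)), ]
  rownames(wide) <- NULL
  wide
}

#' @export
print.msi_cv <- function(x, ...) {
  cat(sprintf("Cross-validated L1-logistic outcome model (%s features, %d folds, lambda=%g)\n",
              x$feature_mode, attr(x$plan, "n_folds"), x$lambda))
  nz <- colSums(x$coefficients != 0)
  cat(sprintf("  %d features; nonzero coefficients per split: %s\n",
              nrow(x$coefficients), paste(colSums(x$coefficients != 0), collapse = ", ")))
  mm <- x$mean_metrics
  for (lv in c("spectra", "patient")) {
    row <- function(m) mm$value[mm$level == lv & mm$metric == m]
    cat(sprintf("  %s level: b.acc %.3f, AUC %.3f, sens %.3f, spec %.3f\n",
                lv, row("balanced_accuracy"), row("auc"),
                row("sensitivity"), row("specificity")))
  }
  invisible(x)
}

#' @export
summary.msi_cv <- function(object, ...) {
  out <- list(table = .metrics_table(object$metrics),
              stability = coefficient_stability(object),
              patient_predictions = object$patient_predictions,
              feature_mode = object$feature_mode, lambda = object$lambda)
  class(out) <- "summary.msi_cv"
  out
}

#' @export
print.summary.msi_cv <- function(x, ...) {
  cat(sprintf("Outcome model (%s features, lambda=%g)\n\n", x$feature_mode, x$lambda))
  tab <- x$table
  tab[, -(1:2)] <- round(tab[, -(1:2)], 3)
  print(tab, row.names = FALSE)
  cat(sprintf("\n%d stable features (nonzero in >= 2 splits), %d sign-consistent\n",
              nrow(x$stability), sum(x$stability$sign_consistent)))
  invisible(x)
}

#' Coefficient stability across cross-validation splits
#'
#' Reports features whose coefficient is nonzero in at least
#' \code{min_splits} splits, with the number of splits, the mean coefficient,
#' and whether all nonzero coefficients share one sign.
#'
#' @param object an \code{msi_cv} fit.
#' @param min_splits minimum number of splits with a nonzero coefficient.
#' @param ... unused.
#' @return data.frame: \code{feature_mz}, \code{n_splits}, \code{mean_coef},
#'   \code{sign_consistent}, ordered by decreasing |mean_coef|.
#' @export
coefficient_stability <- function(object, min_splits = 2L, ...) {
  stopifnot(inherits(object, "msi_cv"))
  B <- object$coefficients
  nz <- B != 0
  keep <- which(rowSums(nz) >= min_splits)
  out <- data.frame(
    feature_mz = object$feature_mz[keep],
    n_splits = rowSums(nz)[keep],
    mean_coef = rowMeans(B)[keep],
    sign_consistent = vapply(keep, function(i) {
      s <- sign(B[i, nz[i, ]]); all(s == s[1L])
    }, logical(1)))
  out <- out[order(-abs(out$mean_coef)), ]
  rownames(out) <- NULL
  out
}

#' @rdname coefficient_stability
#' @export
coef.msi_cv <- function(object, min_splits = 2L, ...) {
  coefficient_stability(object, min_splits = min_splits)
}

#' Apply a cross-validated model to another cohort
#'
#' Quantifies the new cohort at the training feature centroids (if given a
#' dataset), rebuilds the training feature representation, standardizes the
#' new cohort's patients on their own spectra, and evaluates every split's
#' model on all new-cohort tumor spectra — the transfer analogue of the
#' within-cohort summary table.
#'
#' @param object an \code{msi_cv} fit.
#' @param newdata an \code{\link{msi_features}} matrix built on the same
#'   feature centroids as the training cohort (same columns as the matrix
#'   passed to \code{\link{outcome_cv}}).
#' @return a list of class \code{msi_transfer}: per-split and mean metrics at
#'   both levels, plus per-patient predictions per split.
#' @export
cross_cohort_evaluate <- function(object, newdata) {
  stopifnot(inherits(object, "msi_cv"), inherits(newdata, "msi_features"))
  fm_model <- .build_model_features(newdata, object$feature_mode, object$restrict_to)
  if (ncol(fm_model$values) != nrow(object$coefficients))
    stopf("feature mismatch: model has %d features, new cohort has %d",
          nrow(object$coefficients), ncol(fm_model$values))
  fm_model <- per_patient_standardize(fm_model)
  roi <- fm_model$meta$roi_flag
  pids <- fm_model$meta$patient_id[roi]
  outc <- as.character(.feature_outcome(fm_model))[roi]
  x <- fm_model$values[roi, , drop = FALSE]
  split_rows <- list(); patient_tables <- list()
  for (k in seq_along(object$models)) {
    prob <- predict_spectra(object$models[[k]], x)
    ev <- .eval_both_levels(prob, pids, outc)
    patient_tables[[k]] <- cbind(ev$patient_table, split = k)
    split_rows[[k]] <- data.frame(
      split = k,
      level = rep(c("spectra", "patient"), each = 4L),
      metric = rep(c("balanced_accuracy", "auc", "sensitivity", "specificity"), 2L),
      value = c(ev$spectra$balanced_accuracy, ev$spectra$auc,
                ev$spectra$sensitivity, ev$spectra$specificity,
                ev$patient$balanced_accuracy, ev$patient$auc,
                ev$patient$sensitivity, ev$patient$specificity))
  }
  metrics <- do.call(rbind, split_rows)
  structure(list(metrics = metrics,
                 mean_metrics = stats::aggregate(value ~ level + metric, metrics, mean),
                 patient_predictions = do.call(rbind, patient_tables),
                 feature_mode = object$feature_mode),
            class = "msi_transfer")
}

#' @export
print.msi_transfer <- function(x, ...) {
  cat(sprintf("Cross-cohort transfer (%s features)\n", x$feature_mode))
  tab <- .metrics_table(x$metrics)
  tab[, -(1:2)] <- round(tab[, -(1:2)], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @describeIn outcome_cv predict P(NED) for new spectra; \code{type =
#'   "spectra"} returns per-split probability columns, \code{type =
#'   "patient"} per-split patient calls.
#' @param object an \code{msi_cv} fit.
#' @param newdata an \code{\link{msi_features}} matrix on the training
#'   centroids.
#' @param type \code{"spectra"} or \code{"patient"}.
#' @param ... unused.
#' @export
predict.msi_cv <- function(object, newdata, type = c("spectra", "patient"), ...) {
  type <- match.arg(type)
  fm_model <- .build_model_features(newdata, object$feature_mode, object$restrict_to)
  fm_model <- per_patient_standardize(fm_model)
  roi <- fm_model$meta$roi_flag
  x <- fm_model$values[roi, , drop = FALSE]
  probs <- vapply(object$models, function(m) predict_spectra(m, x),
                  numeric(nrow(x)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  colnames(probs) <- sprintf("split%d", seq_along(object$models))
  if (type == "spectra") return(probs)
  pids <- fm_model$meta$patient_id[roi]
  do.call(rbind, lapply(seq_len(ncol(probs)), function(k)
    cbind(aggregate_patient(probs[, k], pids), split = k)))
}

#' @describeIn outcome_cv bar chart of per-patient fraction of correctly
#'   classified spectra (majority-voting view).
#' @param x an \code{msi_cv} fit.
#' @export
plot.msi_cv <- function(x, ...) {
  pp <- x$patient_predictions
  pp <- pp[order(pp$true, -pp$fraction_correct), ]
  cols <- ifelse(pp$true == "NED", "#2166ac", "#b2182b")
  graphics::barplot(pp$fraction_correct, names.arg = pp$patient_id,
                    col = cols, las = 2, cex.names = 0.6,
                    ylab = "fraction of spectra correctly classified",
                    main = sprintf("Per-patient classification (%s features)",
                                   x$feature_mode), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}
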