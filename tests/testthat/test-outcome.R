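fake_patients <- function(n_rec = 20L, n_ned = 11L) {
  data.frame(patient_id = sprintf("P%02d", seq_len(n_rec + n_ned)),
             outcome = rep(c("RecPro", "NED"), c(n_rec, n_ned)),
             cohort = "CDDP", slide = "S01")
}

test_that("grouped stratified folds partition patients evenly", {
  plan <- make_grouped_stratified_folds(fake_patients(), n_folds = 5L, seed = 1L)
  sizes <- sort(as.integer(table(plan$fold)), decreasing = TRUE)
  expect_identical(sizes, c(7L, 6L, 6L, 6L, 6L))
  expect_identical(anyDuplicated(plan$patient_id), 0L)
  for (s in 1:10) {
    p <- make_grouped_stratified_folds(fake_patients(), seed = s)
    ned_per_fold <- table(p$fold[p$outcome == "NED"])
    expect_true(all(ned_per_fold >= 2L))                # 11 NED over 5 folds
    rec_per_fold <- table(p$fold[p$outcome == "RecPro"])
    expect_true(max(rec_per_fold) - min(rec_per_fold) <= 1L)
  }
  expect_identical(make_grouped_stratified_folds(fake_patients(), seed = 3L),
                   make_grouped_stratified_folds(fake_patients(), seed = 3L))
  expect_error(make_grouped_stratified_folds(fake_patients(2L, 1L), n_folds = 5L),
               "fewer patients")
})

test_that("L1 logistic shrinkage and sign behaviour", {
  withr::with_seed(20, {
    x <- matrix(rnorm(200), 100, 2)
    y <- as.integer(x[, 1] + rnorm(100, sd = 0.5) > 0)
  })
  big <- fit_l1_logistic(x, y, lambda = 100)
  expect_identical(unname(big$coefficients), c(0, 0))
  small <- fit_l1_logistic(x, y, lambda = 0.01)
  expect_gt(small$coefficients[1], 0)      # separation direction
  expect_error(fit_l1_logistic(x, rep(1L, 100), lambda = 1), "both classes")
})

test_that("L1 logistic minimizes the stated objective (grid-search oracle)", {
  withr::with_seed(21, {
    x1 <- rnorm(60)
    y <- rbinom(60, 1, plogis(1.5 * x1))
  })
  x <- cbind(x1, 0)
  lam <- 0.5
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  objective <- function(b0, b1) {
    eta <- b0 + b1 * x1
    sum(w * -(y * eta - log1p(exp(eta)))) / sum(w) + lam * abs(b1)
  }
  fit <- fit_l1_logistic(x, y, lambda = lam)
  grid <- expand.grid(b0 = seq(-2, 2, 0.01), b1 = seq(-2, 2, 0.01))
  vals <- mapply(objective, grid$b0, grid$b1)
  expect_lt(objective(fit$intercept, fit$coefficients[1]) - min(vals), 1e-3)
})

test_that("nonzero-coefficient count is non-increasing in lambda", {
  withr::with_seed(22, {
    x <- matrix(rnorm(100 * 20), 100, 20)
    y <- as.integer(x[, 1] - x[, 2] + rnorm(100) > 0)
  })
  nz <- vapply(c(0.001, 0.01, 0.05, 0.1, 0.5),
               function(l) sum(fit_l1_logistic(x, y, l)$coefficients != 0),
               numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("spectrum probabilities follow the logistic link", {
  null_model <- list(coefficients = c(0, 0), intercept = 0)
  expect_equal(predict_spectra(null_model, matrix(rnorm(10), 5, 2)), rep(0.5, 5))
  m <- list(coefficients = c(0.5, -1), intercept = 0.25)
  x <- rbind(c(1, 2), c(-0.5, 0.5))
  expect_equal(predict_spectra(m, x),
               1 / (1 + exp(-c(1 * 0.5 - 2 * 1 + 0.25, -0.25 - 0.5 + 0.25))))
  expect_equal(predict_spectra(m, rbind(c(1.5, 1))), 0.5)  # on the boundary
  expect_error(predict_spectra(m, matrix(1, 2, 3)), "dimension mismatch")
})

test_that("patient aggregation sums probabilities and applies majority voting", {
  one <- aggregate_patient(0.9, "A", c(A = "NED"))
  expect_identical(one$predicted, "NED")
  expect_true(one$majority_correct)
  agg <- aggregate_patient(c(0.6, 0.6, 0.1), rep("B", 3), c(B = "NED"))
  expect_equal(agg$sum_p_ned, 1.3)
  expect_equal(agg$sum_p_recpro, 1.7)
  expect_identical(agg$predicted, "RecPro")              # summed call
  expect_equal(agg$fraction_correct, 2 / 3)              # per-spectrum votes
  tie <- aggregate_patient(c(0.2, 0.8), rep("C", 2), c(C = "NED"))
  expect_identical(tie$predicted, "RecPro")              # tied sums -> RecPro
  expect_false(tie$majority_correct)                     # exactly 50% is not enough
})

test_that("metrics use NED as positive class and satisfy the b.acc identity", {
  truth <- c("NED", "NED", "RecPro", "RecPro", "RecPro")
  pred <- c("NED", "RecPro", "RecPro", "RecPro", "NED")
  m <- compute_metrics(truth, pred, c(0.9, 0.3, 0.2, 0.1, 0.8))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$balanced_accuracy, (0.5 + 2 / 3) / 2)
  perfect <- compute_metrics(truth, truth, c(1, 1, 0, 0, 0))
  expect_true(all(unlist(perfect) == 1))
  onecls <- compute_metrics(rep("NED", 3), rep("NED", 3), c(1, 1, 1))
  expect_true(is.na(onecls$specificity))
  expect_true(attr(onecls, "undefined"))
})

test_that("cross-validation keeps train and test patients disjoint and averages splits", {
  coh <- tiny_cohort()
  fm <- preprocess_dataset(coh$dataset)
  fit <- outcome_cv(fm, lambda = 0.02, feature_mode = "all_mz", seed = 1L)
  # every patient is predicted exactly once across splits
  expect_identical(sort(unique(fit$patient_predictions$patient_id)),
                   sort(fm$patients$patient_id))
  expect_identical(anyDuplicated(fit$patient_predictions$patient_id), 0L)
  # mean row is the arithmetic mean of split rows, for every level and metric
  for (i in seq_len(nrow(fit$mean_metrics))) {
    r <- fit$mean_metrics[i, ]
    splits <- fit$metrics$value[fit$metrics$level == r$level &
                                fit$metrics$metric == r$metric]
    expect_equal(r$value, mean(splits))
  }
  # balanced-accuracy identity on every emitted split row
  for (s in 1:5) for (lv in c("spectra", "patient")) {
    g <- function(m) fit$metrics$value[fit$metrics$split == s &
                                       fit$metrics$level == lv &
                                       fit$metrics$metric == m]
    expect_equal(g("balanced_accuracy"),
                 balanced_accuracy(g("sensitivity"), g("specificity")))
  }
})

test_that("patient ids are pure metadata for prediction", {
  coh <- tiny_cohort()
  fm <- preprocess_dataset(coh$dataset)
  plan <- make_grouped_stratified_folds(fm$patients, seed = 2L)
  fit1 <- outcome_cv(fm, lambda = 0.05, feature_mode = "all_mz", plan = plan)
  ren <- fm
  map <- setNames(sprintf("Q%02d", seq_len(nrow(fm$patients))), fm$patients$patient_id)
  ren$meta$patient_id <- unname(map[ren$meta$patient_id])
  ren$patients$patient_id <- unname(map[ren$patients$patient_id])
  plan2 <- plan
  plan2$patient_id <- unname(map[plan2$patient_id])
  fit2 <- outcome_cv(ren, lambda = 0.05, feature_mode = "all_mz", plan = plan2)
  expect_equal(fit1$prob_ned, fit2$prob_ned)
  expect_equal(fit1$metrics, fit2$metrics)
})

test_that("coefficient stability reports splits, means, and sign consistency", {
  obj <- structure(list(coefficients = rbind(c(1, 2, 1.5, 0, 0),
                                             c(0, 0, 0, 0, 0),
                                             c(1, -1, 0, 0, 0)),
                        feature_mz = c(100, 200, 300)),
                   class = "msi_cv")
  st <- coefficient_stability(obj)
  expect_identical(st$feature_mz, c(100, 300))   # nonzero in >= 2 splits only
  expect_identical(st$n_splits[st$feature_mz == 100], 3)
  expect_true(st$sign_consistent[st$feature_mz == 100])
  expect_false(st$sign_consistent[st$feature_mz == 300])  # {+1, -1} flagged
  expect_equal(st$mean_coef[st$feature_mz == 100], 0.9)
})

test_that("a model applied to its own cohort is self-consistent", {
  coh <- tiny_cohort()
  fm <- preprocess_dataset(coh$dataset)
  fit <- outcome_cv(fm, lambda = 0.02, feature_mode = "all_mz", seed = 1L)
  self <- cross_cohort_evaluate(fit, fm)
  expect_identical(sort(unique(self$metrics$metric)),
                   sort(unique(fit$metrics$metric)))
  pb_cv <- fit$mean_metrics$value[fit$mean_metrics$level == "patient" &
                                  fit$mean_metrics$metric == "balanced_accuracy"]
  pb_self <- self$mean_metrics$value[self$mean_metrics$level == "patient" &
                                     self$mean_metrics$metric == "balanced_accuracy"]
  expect_gte(pb_self, pb_cv - 0.1)   # in-sample evaluation cannot be much worse
  expect_error(cross_cohort_evaluate(fit,
    msi_features(fm$values[, 1:10], fm$feature_mz[1:10], fm$tolerance,
                 fm$meta, fm$patients)), "feature mismatch")
})

test_that("recovered coefficient signs agree with the planted direction", {
  # planted features are lower in RecPro, so on standardized intensities the
  # NED-probability coefficients of recovered features should be positive
  coh <- cached("mid_cohort", generate_cohort(
    cohort_spec(n_patients_per_class = c(RecPro = 8L, NED = 8L),
                spectra_per_patient = 100L, n_features = 200L,
                n_signal_features = 20L, slide_count = 4L, seed = 1L)))
  fm <- preprocess_dataset(coh$dataset)
  fit <- outcome_cv(fm, lambda = 0.02, feature_mode = "restricted",
                    restrict_to = coh$truth$signal_features, seed = 1L)
  st <- coefficient_stability(fit)
  expect_gt(nrow(st), 3L)
  expect_gte(mean(st$mean_coef > 0), 0.8)
  expect_gte(mean(st$sign_consistent), 0.8)
})

test_that("restricted feature mode uses exactly the requested subset", {
  coh <- tiny_cohort()
  fm <- preprocess_dataset(coh$dataset)
  sel <- c(3L, 10L, 41L)
  fit <- outcome_cv(fm, lambda = 0.05, feature_mode = "restricted",
                    restrict_to = sel, seed = 1L)
  expect_identical(nrow(fit$coefficients), length(sel))
  expect_identical(fit$feature_mz, fm$feature_mz[sel])
  expect_error(outcome_cv(fm, feature_mode = "restricted"), "restrict_to")
  expect_error(outcome_cv(fm, feature_mode = "restricted", restrict_to = 10000L),
               "out of range")
})
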