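toy_dataset <- function() {
  meta <- data.frame(patient_id = c("P1", "P1", "P2"), cohort = "CDDP",
                     slide = "S01", x = c(0L, 1L, 0L), y = 0L,
                     roi_flag = c(TRUE, TRUE, FALSE))
  patients <- data.frame(patient_id = c("P1", "P2"),
                         outcome = c("RecPro", "NED"),
                         cohort = "CDDP", slide = "S01")
  msi_dataset(matrix(c(0.1, 1.5, 2, 3.25, 0.5, 7), 3, 2),
              c(600.125, 1200.5), meta, patients)
}

test_that("spectra table CSV round-trips exactly", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_spectra_table(ds, file.path(dir, "s.csv"), file.path(dir, "p.csv"))
  back <- read_spectra_table(file.path(dir, "s.csv"), file.path(dir, "p.csv"))
  expect_identical(back$intensities, ds$intensities)
  expect_identical(back$mz, ds$mz)
  expect_identical(back$meta, ds$meta)
  expect_identical(back$patients, ds$patients)
})

test_that("a header-only spectra table loads as an empty dataset", {
  ds <- toy_dataset()
  ds$intensities <- ds$intensities[0, , drop = FALSE]
  ds$meta <- ds$meta[0, , drop = FALSE]
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(ds, path)
  back <- read_spectra_table(path)
  expect_identical(nrow(back$intensities), 0L)
  expect_identical(back$mz, ds$mz)
})

test_that("malformed spectra tables are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,x,y", "P1,0,0"), path)
  expect_error(read_spectra_table(path), "missing columns")
  writeLines(c("patient_id,cohort,slide,x,y,roi_flag,mz_600",
               "P1,C,S,0,0,TRUE,1", "P1,C,S,0,0,TRUE,2"), path)
  expect_error(read_spectra_table(path), "duplicate")
  meta <- data.frame(patient_id = "P9", cohort = "C", slide = "S",
                     x = 0L, y = 0L, roi_flag = TRUE)
  pats <- data.frame(patient_id = "P1", outcome = "NED", cohort = "C", slide = "S")
  expect_error(msi_dataset(matrix(1), 600, meta, pats), "absent from the patient table")
})

test_that("TIC normalization scales spectra to unit sum", {
  expect_equal(tic_normalize(c(1, 3)), c(0.25, 0.75))
  expect_equal(tic_normalize(c(0.25, 0.75)), c(0.25, 0.75))  # idempotent
  x <- withr::with_seed(1, runif(711))
  expect_lt(abs(sum(tic_normalize(x)) - 1), 1e-12)
  expect_error(tic_normalize(numeric(3)), "non-positive total ion count")
  M <- rbind(c(1, 3), c(0, 0))
  expect_warning(out <- tic_normalize(M), "excluding 1 spectra")
  expect_equal(out, matrix(c(0.25, 0.75), 1))
})

test_that("top-hat removes flat baselines and is offset-invariant", {
  expect_equal(tophat_baseline(rep(3.2, 20), 5), rep(0, 20))
  x <- withr::with_seed(2, runif(30))
  expect_equal(tophat_baseline(x + 17.3, 7), tophat_baseline(x, 7))
  th <- tophat_baseline(x, 7)
  expect_true(all(th >= 0))
  expect_true(all(th <= x + 1e-12))
})

test_that("top-hat equals brute-force erosion-then-dilation", {
  x15 <- withr::with_seed(3, rnorm(15))
  expect_equal(tophat_baseline(x15, 5), brute_tophat(x15, 5))
  for (i in 1:25) {
    n <- sample(10:60, 1)
    w <- sample(seq(1, min(n - 1, 15), by = 2), 1)
    x <- rnorm(n) + seq(0, 3, length.out = n)
    expect_equal(tophat_baseline(x, w), brute_tophat(x, w))
  }
})

test_that("top-hat validates the structuring element", {
  expect_error(tophat_baseline(1:10, 4), "odd")
  expect_error(tophat_baseline(1:10, 11), "smaller than the signal length")
  expect_error(tophat_baseline(1:10, 0), "structure_width")
})

test_that("peak detection finds, merges, and aligns peaks", {
  mk <- function(vals) {
    n <- length(vals[[1]])
    meta <- data.frame(patient_id = rep("P1", length(vals)), cohort = "C",
                       slide = "S", x = seq_along(vals) - 1L, y = 0L, roi_flag = TRUE)
    pats <- data.frame(patient_id = "P1", outcome = "NED", cohort = "C", slide = "S")
    msi_dataset(do.call(rbind, vals), seq(100, by = 0.1, length.out = n), meta, pats)
  }
  # one shared bell-shaped peak -> one feature at the apex m/z
  shape <- exp(-(seq(-5, 5, length.out = 21))^2)
  ds <- mk(list(shape, 2 * shape, 0.5 * shape))
  fm <- detect_and_align_peaks(ds, tolerance = 0.2)
  expect_identical(ncol(fm$values), 1L)
  expect_equal(fm$feature_mz, ds$mz[which.max(shape)])
  # two peaks separated by > 2*tolerance stay separate; < tolerance merge
  two <- numeric(41); two[11] <- 1; two[31] <- 0.8      # 2.0 Da apart
  fm2 <- detect_and_align_peaks(mk(list(two, two)), tolerance = 0.2)
  expect_identical(ncol(fm2$values), 2L)
  close2 <- numeric(41); close2[20] <- 1; close2[22] <- 0.8  # 0.2 Da apart
  fm3 <- detect_and_align_peaks(mk(list(close2, close2)), tolerance = 0.3)
  expect_identical(ncol(fm3$values), 1L)
  expect_equal(fm3$feature_mz, 101.9)   # kept the more intense maximum
})

test_that("feature values equal an exhaustive windowed-max scan", {
  withr::with_seed(4, {
    vals <- replicate(5, abs(rnorm(50)) + 0.01, simplify = FALSE)
  })
  meta <- data.frame(patient_id = paste0("P", 1:5), cohort = "C", slide = "S",
                     x = 0:4, y = 0L, roi_flag = TRUE)
  pats <- data.frame(patient_id = paste0("P", 1:5),
                     outcome = rep(c("NED", "RecPro"), c(3, 2)),
                     cohort = "C", slide = "S")
  ds <- msi_dataset(do.call(rbind, vals), seq(200, by = 0.05, length.out = 50),
                    meta, pats)
  fm <- detect_and_align_peaks(ds, tolerance = 0.12)
  for (k in seq_along(fm$feature_mz)) {
    inwin <- abs(ds$mz - fm$feature_mz[k]) <= fm$tolerance
    for (i in 1:5)
      expect_equal(fm$values[i, k], max(ds$intensities[i, inwin]))
  }
})

test_that("down-sampling averages non-overlapping pairs", {
  meta <- data.frame(patient_id = "P1", cohort = "C", slide = "S",
                     x = 0L, y = 0L, roi_flag = TRUE)
  pats <- data.frame(patient_id = "P1", outcome = "NED", cohort = "C", slide = "S")
  fm <- msi_features(matrix(c(1, 2, 3, 4), 1), c(10, 20, 30, 40), 0.2, meta, pats)
  dn <- downsample_features(fm)
  expect_equal(unname(dn$values), matrix(c(1.5, 3.5), 1))
  expect_equal(dn$feature_mz, c(15, 35))
  one <- msi_features(matrix(5, 1), 10, 0.2, meta, pats)
  expect_identical(downsample_features(one)$values, one$values)
  wide <- msi_features(matrix(seq_len(711), 1), seq(600, by = 1, length.out = 711),
                       0.2, meta, pats)
  dw <- downsample_features(wide)
  expect_identical(ncol(dw$values), 356L)
  expect_equal(dw$values[1, 356], 711)   # unpaired trailing column kept as-is
})

test_that("per-patient standardization gives zero mean and unit SD per patient", {
  coh <- tiny_cohort()
  fm <- preprocess_dataset(coh$dataset)
  z <- per_patient_standardize(fm)
  for (pid in unique(z$meta$patient_id)[1:3]) {
    rows <- z$meta$patient_id == pid
    expect_true(all(abs(colMeans(z$values[rows, ])) < 1e-9))
    expect_true(all(abs(apply(z$values[rows, ], 2, sd) - 1) < 1e-9))
  }
})

test_that("standardization handles constants and rejects singleton patients", {
  meta <- data.frame(patient_id = c("A", "A", "B", "B"), cohort = "C",
                     slide = "S", x = c(0L, 1L, 0L, 1L), y = 0L, roi_flag = TRUE)
  pats <- data.frame(patient_id = c("A", "B"), outcome = c("NED", "RecPro"),
                     cohort = "C", slide = "S")
  vals <- rbind(c(1, 5), c(3, 5), c(2, 1), c(6, 3))
  fm <- msi_features(vals, c(10, 20), 0.2, meta, pats)
  z <- per_patient_standardize(fm)
  # hand-worked: A col1 mean 2 sd sqrt(2); B col1 mean 4 sd 2*sqrt(2)
  expect_equal(z$values[, 1],
               c(-1 / sqrt(2), 1 / sqrt(2), -2 / (2 * sqrt(2)), 2 / (2 * sqrt(2))))
  expect_equal(z$values[1:2, 2], c(0, 0))   # zero-SD feature -> 0
  expect_equal(z$values[3:4, 2], c(-1, 1) / sqrt(2))
  single <- msi_features(vals[c(1, 3, 4), ], c(10, 20), 0.2,
                         meta[c(1, 3, 4), ], pats)
  expect_error(per_patient_standardize(single), "single spectrum")
})

test_that("the preprocessing chain records its stage order", {
  coh <- tiny_cohort()
  fm <- preprocess_dataset(coh$dataset)
  prov <- attr(fm, "provenance")
  expect_match(prov[1], "tophat_baseline")
  expect_match(prov[2], "tic_normalize")
  expect_match(prov[length(prov)], "detect_and_align_peaks")
  expect_true(all(is.finite(fm$values)) && all(fm$values >= 0))
  expect_identical(ncol(fm$values), 80L)  # one feature per planted peak
})
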