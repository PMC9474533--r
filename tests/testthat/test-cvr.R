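test_that("noiseless GLM recovers the generating coefficient exactly", {
  acq <- acq_params()
  reg <- build_regressor(make_capno_trace(noise_sd = 0), acq)
  x <- reg$values - mean(reg$values)
  Y <- rbind(0.1 * x, -0.05 * x, 0 * x)   # voxels x time
  b <- bold_series(array(Y, c(1, 1, 3, 92)), tr_s = 3, units = "percent")
  m <- fit_cvr_map(b, reg)
  expect_equal(as.vector(m$beta), c(0.1, -0.05, 0), tolerance = 1e-9)
  expect_lt(max(m$residual_sd), 1e-9)
  expect_equal(m$dof, 90)
})

test_that("null t-statistics are centred and orthogonal confounds are inert", {
  acq <- acq_params()
  reg <- build_regressor(make_capno_trace(noise_sd = 0), acq)
  set.seed(11)
  Y <- matrix(rnorm(1000 * 92), 1000, 92)   # voxels x time
  b <- bold_series(array(Y, c(10, 10, 10, 92)), tr_s = 3, units = "percent")
  m <- fit_cvr_map(b, reg)
  expect_lt(abs(mean(m$tstat)), 0.1)
  # empirical t quantiles follow Student-t(90)
  expect_equal(unname(quantile(abs(m$tstat), 0.95)), qt(0.975, 90),
               tolerance = 0.15)

  # confound orthogonal to the regressor leaves beta untouched
  x <- reg$values - mean(reg$values)
  conf <- rnorm(92); conf <- conf - mean(conf)
  conf <- conf - x * sum(conf * x) / sum(x^2)
  m2 <- fit_cvr_map(b, reg, confounds = conf)
  expect_equal(m2$beta, m$beta, tolerance = 1e-9)

  # collinear design is rejected by name
  expect_error(fit_cvr_map(b, reg, confounds = cbind(reg$values)),
               "collinear.*confound")
})

test_that("ROI medians honour the exclusion contract and midpoint convention", {
  beta <- array(0.09, c(6, 6, 6))
  masks <- list(gm = array(FALSE, c(6, 6, 6)), wm = array(FALSE, c(6, 6, 6)),
                csf = array(FALSE, c(6, 6, 6)))
  masks$gm[1:3, , ] <- TRUE; masks$wm[4:6, , ] <- TRUE
  map <- structure(list(beta = beta), class = "cvr_map")
  s <- summarize_cvr(map, masks)
  expect_equal(s$cvr_gm, 0.09)
  expect_true(is.na(s$cvr_lesion))

  # lesion voxels poisoned with -1 do not move the WM median
  lesion <- array(FALSE, c(6, 6, 6)); lesion[5, 1:2, 1] <- TRUE
  beta2 <- beta; beta2[lesion] <- -1
  map2 <- structure(list(beta = beta2), class = "cvr_map")
  s2 <- summarize_cvr(map2, masks, lesion)
  expect_equal(s2$cvr_wm, 0.09)
  expect_equal(s2$cvr_lesion, -1)

  # median is robust to outliers and uses the midpoint for even counts
  b3 <- beta
  gm_idx <- which(masks$gm)
  b3[gm_idx] <- 0.1
  b3[gm_idx[1]] <- 0.9; b3[gm_idx[2]] <- 0.2
  map3 <- structure(list(beta = b3), class = "cvr_map")
  expect_equal(median(c(0.1, 0.2, 0.9)), 0.2)   # outlier-insensitive
  s3 <- summarize_cvr(map3, masks)
  expect_equal(s3$cvr_gm, 0.1)
  expect_error(summarize_cvr(map, masks, lesion_mask = masks$gm | masks$wm),
               "empty")
})

test_that("full subject pipeline is exact on noiseless data and scales in mmHg", {
  s <- noiseless_subject(cvr_gm = 0.105, cvr_wm = 0.068)
  res <- run_subject(s$bold, trace = s$trace, prob_maps = s$prob_maps,
                     acq = s$acq)
  expect_lt(abs(res$summary$cvr_gm - 0.105), 1e-6)
  expect_lt(abs(res$summary$cvr_wm - 0.068), 1e-6)

  # unit contract: doubling the regressor halves every beta
  pct <- highpass_gaussian(fractional_bold(s$bold), 60)
  reg <- highpass_gaussian(s$regressor, 60)
  reg2 <- reg; reg2$values <- 2 * reg$values
  m1 <- fit_cvr_map(pct, reg); m2 <- fit_cvr_map(pct, reg2)
  expect_equal(m2$beta, m1$beta / 2, tolerance = 1e-9)

  # determinism: identical rerun gives identical summaries
  res2 <- run_subject(s$bold, trace = s$trace, prob_maps = s$prob_maps,
                      acq = s$acq)
  expect_identical(res$summary, res2$summary)
})

test_that("tissue medians concentrate near truth under noise", {
  s <- noiseless_subject(cvr_gm = 0.105, cvr_wm = 0.068, grid = c(16, 16, 16),
                         noise_sd = 0.005, seed = 8)
  res <- run_subject(s$bold, trace = s$trace, prob_maps = s$prob_maps,
                     acq = s$acq)
  expect_lt(abs(res$summary$cvr_gm - 0.105), 0.01)
  expect_lt(abs(res$summary$cvr_wm - 0.068), 0.01)
})

test_that("file-based subject pipeline writes maps, summary and provenance", {
  dir <- withr_local_tempdir()
  s <- noiseless_subject(grid = c(12, 12, 12))
  write_volume(s$bold$data, file.path(dir, "bold.nii.gz"), c(3, 3, 3), tr_s = 3)
  for (nm in c("gm", "wm", "csf"))
    write_volume(s$prob_maps[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  write_capno(s$trace, file.path(dir, "capno.tsv"))
  res <- run_subject_files(file.path(dir, "bold.nii.gz"),
                           file.path(dir, "capno.tsv"),
                           file.path(dir, "gm.nii.gz"),
                           file.path(dir, "wm.nii.gz"),
                           file.path(dir, "csf.nii.gz"),
                           out_dir = file.path(dir, "out"), acq = s$acq)
  expect_true(file.exists(file.path(dir, "out", "cvr_beta.nii.gz")))
  summ <- read_cohort_table(file.path(dir, "out", "summary.tsv"))
  expect_equal(summ$cvr_gm, 0.105, tolerance = 1e-5)
})
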