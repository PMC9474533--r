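test_that("phantom without lesions partitions the brain cleanly", {
  ph <- make_phantom(c(16, 16, 16), lesion_count = 0, seed = 1)
  expect_false(any(ph$lesion_mask))
  expect_true(all(ph$prob_gm + ph$prob_wm + ph$prob_csf <= 1 + 1e-9))
  masks <- classify_tissue(ph$prob_gm, ph$prob_wm, ph$prob_csf)
  expect_true(all(ph$s0[masks$brain] > 0))
  # every brain voxel lands in exactly one compartment
  expect_equal(masks$gm + masks$wm + masks$csf, masks$brain * 1L,
               ignore_attr = TRUE)
})

test_that("lesions form the requested number of disjoint WM components", {
  ph <- make_phantom(c(32, 32, 32), lesion_count = 2, seed = 7)
  labs <- flood_label(ph$lesion_mask, connectivity = 26)
  expect_identical(max(labs), 2L)
  wm_argmax <- with(ph, prob_wm >= prob_gm & prob_wm >= prob_csf &
                      pmax(prob_gm, prob_wm, prob_csf) >= 0.05)
  expect_true(all(wm_argmax[ph$lesion_mask]))
})

test_that("generators are bit-identical under a fixed seed", {
  expect_identical(make_phantom(c(16, 16, 16), 2, seed = 3),
                   make_phantom(c(16, 16, 16), 2, seed = 3))
  expect_identical(make_capno_trace(seed = 5), make_capno_trace(seed = 5))
  s <- noiseless_subject(noise_sd = 0.005, seed = 2)
  s2 <- noiseless_subject(noise_sd = 0.005, seed = 2)
  expect_identical(s$bold$data, s2$bold$data)
  co <- make_cohort(cohort_spec(seed = 9))
  co2 <- make_cohort(cohort_spec(seed = 9))
  expect_identical(co$truth, co2$truth)
})

test_that("impossible lesion placement fails with a clear message", {
  expect_error(make_phantom(c(8, 8, 8), lesion_count = 4, seed = 1),
               "lesion")
})

test_that("capno trace follows the breath-hold schedule", {
  p <- bh_paradigm()
  tr <- make_capno_trace(p, bh_rise = 8, noise_sd = 0)
  # duration covers lead-in plus five hold/recovery cycles
  expect_equal(max(tr$t), p$lead_in_s + 5 * (16 + 34))
  # local-maximum census on the noiseless trace: one post-hold peak per
  # block, amplitude baseline + rise, within one breath of the hold end
  x <- tr$co2
  locmax <- which(diff(sign(diff(x))) < 0) + 1L
  high <- locmax[x[locmax] > 40 + 4]
  expect_length(high, p$n_blocks)
  expect_equal(x[high], rep(48, 5), tolerance = 1e-12)
  for (i in seq_len(p$n_blocks))
    expect_lt(tr$t[high[i]] - hold_ends(p)[i], p$breath_period_s)
  # no modulation: every end-tidal peak at baseline
  tr0 <- make_capno_trace(p, bh_rise = 0, noise_sd = 0)
  pk <- detect_end_tidal(tr0)
  expect_equal(pk$peak_values, rep(40, length(pk$peak_values)),
               tolerance = 1e-9)
  expect_error(make_capno_trace(p, noise_sd = -1), "noise_sd")
})

test_that("BOLD generative model matches its definition", {
  s <- noiseless_subject(cvr_gm = 0, cvr_wm = 0, grid = c(12, 12, 12))
  # null response: constant in time at s0
  tm0 <- make_truth_maps(s$phantom, 0, 0)
  b0 <- make_bold(s$phantom, tm0, s$regressor, s$acq)
  expect_equal(apply(b0$data, 1:3, sd), array(0, c(12, 12, 12)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # single-voxel fractional signal equals cvr/100 * demeaned regressor
  x <- s$regressor$values - mean(s$regressor$values)
  tm <- make_truth_maps(s$phantom, 0.1, 0.1, cvr_csf = 0.1)
  b <- make_bold(s$phantom, tm, s$regressor, s$acq)
  v <- which(classify_tissue(s$phantom$prob_gm, s$phantom$prob_wm,
                             s$phantom$prob_csf)$gm, arr.ind = TRUE)[1, ]
  ts <- b$data[v[1], v[2], v[3], ]
  expect_equal(ts / mean(ts) - 1, 0.001 * x, tolerance = 1e-9)
  # shape mismatch rejected
  ph2 <- make_phantom(c(14, 14, 14), 0, seed = 1)
  expect_error(make_bold(ph2, tm, s$regressor, s$acq), "grid")
})

test_that("cohort truth has the specified lesion structure and change model", {
  spec <- cohort_spec(seed = 4)
  co <- make_cohort(spec)
  tr <- co$truth
  # per-session lesion-positive counts
  pos <- sapply(1:3, function(s)
    sum(tr$gd_count[tr$group == "MS" & tr$session == s] > 0))
  expect_equal(pos, c(12, 8, 3))
  # nested persistence of positivity
  pos_ids <- lapply(1:3, function(s)
    tr$subject[tr$group == "MS" & tr$session == s & tr$gd_count > 0])
  expect_true(all(pos_ids[[3]] %in% pos_ids[[2]]))
  expect_true(all(pos_ids[[2]] %in% pos_ids[[1]]))
  # declared missing sessions are absent
  expect_equal(sum(tr$subject == "MS01" & tr$session == 2), 0)
  # HC have exactly one session
  expect_true(all(table(tr$subject[tr$group == "HC"]) == 1))

  # restoration effect: true change negatively correlated with true pre
  ms <- tr[tr$group == "MS", ]
  wide <- reshape(ms[, c("subject", "session", "cvr_gm_true")],
                  idvar = "subject", timevar = "session", direction = "wide")
  cc <- wide[complete.cases(wide), ]
  pre <- (cc$cvr_gm_true.1 + cc$cvr_gm_true.2) / 2
  delta <- cc$cvr_gm_true.3 - pre
  expect_lt(cor(pre, delta), 0)

  # no-change cohort: session 3 equals pre-treatment truth
  spec0 <- cohort_spec(delta_mean = c(gm = 0, wm = 0),
                       delta_sd = c(gm = 0, wm = 0), delta_slope = 0,
                       session_sd = 0, missing_sessions = NULL, seed = 2)
  tr0 <- make_cohort(spec0)$truth
  ms0 <- tr0[tr0$group == "MS", ]
  s1 <- ms0[ms0$session == 1, ]; s3 <- ms0[ms0$session == 3, ]
  expect_equal(s3$cvr_gm_true[match(s1$subject, s3$subject)], s1$cvr_gm_true,
               tolerance = 1e-12)
})

test_that("cohort file set round-trips through disk", {
  dir <- withr_local_tempdir()
  spec <- cohort_spec(n_hc = 2, n_ms = 3, gd_positive_counts = c(1, 1, 1),
                      missing_sessions = NULL, seed = 6)
  co <- make_cohort(spec, acq = acq_params(grid_shape = c(12, 12, 12)))
  manifest <- write_cohort(co, dir)
  expect_equal(nrow(manifest), nrow(co$truth))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  tr <- read_capno(file.path(dir, manifest$capno[1]))
  expect_s3_class(tr, "capno_trace")
  b <- read_volume(file.path(dir, manifest$bold[1]))
  expect_equal(length(dim(b)), 4)
})
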