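#' Specification of a synthetic longitudinal cohort
#'
#' Defaults encode the study conditions the pipeline is designed for: 18
#' healthy controls (HC, one session) and 23 multiple-sclerosis patients
#' (MS, two pre-treatment sessions and one on-treatment session), with
#' group-level tissue CVR distributions (%BOLD/mmHg) of
#' GM 0.105 +/- 0.026 and WM 0.068 +/- 0.020 for HC, and pre-treatment
#' GM 0.091 +/- 0.026 and WM 0.055 +/- 0.020 for MS. The on-treatment
#' change of MS subject i is built as
#' `delta_i = delta_mean + delta_slope * (pre_i - mean_pre) + eta_i`, with
#' a negative `delta_slope` emulating a restoration effect (greater
#' recovery for greater initial impairment); `eta_sd` is set so the
#' marginal SD of the change matches `delta_sd` (GM 0.016 +/- 0.030,
#' WM 0.011 +/- 0.022). Gd+ lesion positivity is assigned to 12/8/3
#' subjects at sessions 1/2/3 with nested persistence (later positives are
#' a subset of earlier ones). One subject misses session 2 and two miss
#' session 3 by default.
#'
#' @param n_hc,n_ms group sizes.
#' @param sessions number of MS sessions.
#' @param means,sds named lists with `hc` and `ms` entries, each a vector
#'   `c(gm = , wm = )` of between-subject means/SDs.
#' @param session_sd within-subject session-to-session SD of the true CVR.
#' @param delta_mean,delta_sd mean and marginal SD of the true on-minus-pre
#'   change per tissue.
#' @param delta_slope regression slope of the change on the pre-treatment
#'   level (restoration effect; negative).
#' @param gd_positive_counts lesion-positive MS subjects per session.
#' @param gd_lesions_range ranges (min, max) of lesion counts for positive
#'   subjects per session.
#' @param lesion_factor lesion true CVR as a fraction of the subject's WM
#'   CVR (0.5 halves it, matching a depressed lesion CVR of about half the
#'   surrounding WM).
#' @param missing_sessions data.frame(subject_index, session) of
#'   MS sessions to drop, or `"default"` for one missing session 2 and two
#'   missing session 3, or `NULL` for none.
#' @param vol_mean,vol_sd normalised tissue volume distributions, cm^3.
#' @param vol_cvr_r correlation of GM volume with the subject's (pre) GM
#'   CVR, per group.
#' @param noise_sd fractional BOLD noise SD for simulated series.
#' @param capno_noise_sd capnograph noise SD, mmHg.
#' @param bh_rise breath-hold PetCO2 excursion, mmHg.
#' @param seed master seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(
    n_hc = 18, n_ms = 23, sessions = 3,
    means = list(hc = c(gm = 0.105, wm = 0.068),
                 ms = c(gm = 0.091, wm = 0.055)),
    sds = list(hc = c(gm = 0.026, wm = 0.020),
               ms = c(gm = 0.026, wm = 0.020)),
    session_sd = 0.005,
    delta_mean = c(gm = 0.016, wm = 0.011),
    delta_sd = c(gm = 0.030, wm = 0.022),
    delta_slope = -0.6,
    gd_positive_counts = c(12, 8, 3),
    gd_lesions_range = list(c(1, 5), c(1, 5), c(1, 2)),
    lesion_factor = 0.5,
    missing_sessions = "default",
    vol_mean = c(gm = 750, wm = 700), vol_sd = c(gm = 60, wm = 55),
    vol_cvr_r = c(hc = 0.12, ms = 0.6),
    noise_sd = 0.002, capno_noise_sd = 0.3, bh_rise = 8,
    seed = 1) {
  if (n_hc < 2 || n_ms < 2) stop_cvr("cohort", "need n >= 2 per group")
  if (any(unlist(sds) <= 0) || any(delta_sd < 0))
    stop_cvr("cohort", "SDs must be positive (delta_sd may be 0)")
  if (any(gd_positive_counts > n_ms))
    stop_cvr("cohort", "gd_positive_counts cannot exceed n_ms")
  if (identical(missing_sessions, "default"))
    missing_sessions <- data.frame(subject_index = c(1, 2, 3),
                                   session = c(2, 3, 3))
  for (tis in c("gm", "wm"))
    if (delta_slope^2 * sds$ms[tis]^2 > delta_sd[tis]^2)
      stop_cvr("cohort",
               "delta_slope and pre-treatment SD imply more change variance than delta_sd[%s]",
               tis)
  structure(list(n_hc = n_hc, n_ms = n_ms, sessions = sessions,
                 means = means, sds = sds, session_sd = session_sd,
                 delta_mean = delta_mean, delta_sd = delta_sd,
                 delta_slope = delta_slope,
                 gd_positive_counts = gd_positive_counts,
                 gd_lesions_range = gd_lesions_range,
                 lesion_factor = lesion_factor,
                 missing_sessions = missing_sessions,
                 vol_mean = vol_mean, vol_sd = vol_sd, vol_cvr_r = vol_cvr_r,
                 noise_sd = noise_sd, capno_noise_sd = capno_noise_sd,
                 bh_rise = bh_rise, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws subject-level true tissue CVRs from the per-(group, session,
#' tissue) distributions of a [cohort_spec()], assigns nested Gd+ lesion
#' positivity, generates correlated normalised tissue volumes, and returns
#' a truth table recording every generated parameter. Image and trace data
#' are not materialised here; [simulate_session()] generates them lazily
#' per subject-session, and [run_cohort()] runs the full estimation
#' pipeline over the cohort.
#'
#' @param spec a [cohort_spec()].
#' @param paradigm a [bh_paradigm()].
#' @param acq an [acq_params()].
#' @return a `cvr_cohort`: `truth` data.frame (one row per present
#'   subject-session: subject, group, session, true tissue CVRs, lesion
#'   CVR, gd_count, volumes, per-session seed), plus the spec, paradigm,
#'   acq, and the shared `phantom`.
#' @export
make_cohort <- function(spec = cohort_spec(), paradigm = bh_paradigm(),
                        acq = acq_params()) {
  # shared grid and phantom; placed lesion components cap the number of
  # spheres actually drawn in a mask (counts in the table are not capped).
  # The grid's WM core bounds how many disjoint lesions fit.
  phantom <- NULL
  for (n_les in 2:0) {
    phantom <- tryCatch(
      make_phantom(acq$grid_shape, lesion_count = n_les, seed = spec$seed,
                   voxel_mm = acq$voxel_mm),
      error = function(e) NULL)
    if (!is.null(phantom)) break
  }
  if (is.null(phantom)) stop_cvr("cohort", "could not build the shared phantom")

  truth <- with_seed(spec$seed, {
    rows <- list()
    z_vol <- function(r, z_cvr) r * z_cvr + sqrt(1 - r^2) * rnorm(length(z_cvr))
    # healthy controls: one session
    z_hc <- matrix(rnorm(spec$n_hc * 2), ncol = 2)
    hc_gm <- spec$means$hc["gm"] + spec$sds$hc["gm"] * z_hc[, 1]
    hc_wm <- spec$means$hc["wm"] + spec$sds$hc["wm"] * z_hc[, 2]
    hc_vol_gm <- spec$vol_mean["gm"] +
      spec$vol_sd["gm"] * z_vol(spec$vol_cvr_r["hc"], z_hc[, 1])
    hc_vol_wm <- spec$vol_mean["wm"] + spec$vol_sd["wm"] * rnorm(spec$n_hc)
    for (i in seq_len(spec$n_hc)) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("HC%02d", i), group = "HC", session = 1,
        cvr_gm_true = hc_gm[i], cvr_wm_true = hc_wm[i],
        lesion_cvr_true = NA_real_, gd_count = 0L,
        vol_gm = hc_vol_gm[i], vol_wm = hc_vol_wm[i])
    }

    # MS: latent pre-treatment level, session wobble, structured change
    z_ms <- matrix(rnorm(spec$n_ms * 2), ncol = 2)
    pre <- cbind(gm = spec$means$ms["gm"] + spec$sds$ms["gm"] * z_ms[, 1],
                 wm = spec$means$ms["wm"] + spec$sds$ms["wm"] * z_ms[, 2])
    eta_sd <- sqrt(spec$delta_sd^2 - spec$delta_slope^2 * spec$sds$ms^2)
    delta <- sapply(c("gm", "wm"), function(tis)
      spec$delta_mean[tis] +
        spec$delta_slope * (pre[, tis] - spec$means$ms[tis]) +
        rnorm(spec$n_ms, 0, eta_sd[tis]))

    # nested Gd+ positivity and per-session lesion counts
    pos <- vector("list", spec$sessions)
    pos[[1]] <- sample(seq_len(spec$n_ms), spec$gd_positive_counts[1])
    for (s in seq_len(spec$sessions)[-1])
      pos[[s]] <- sample(pos[[s - 1]], spec$gd_positive_counts[s])
    gd <- matrix(0L, spec$n_ms, spec$sessions)
    for (s in seq_len(spec$sessions)) {
      rng <- spec$gd_lesions_range[[s]]
      gd[pos[[s]], s] <- sample(seq(rng[1], rng[2]), length(pos[[s]]),
                                replace = TRUE)
    }

    ms_vol_gm <- spec$vol_mean["gm"] +
      spec$vol_sd["gm"] * z_vol(spec$vol_cvr_r["ms"], z_ms[, 1])
    ms_vol_wm <- spec$vol_mean["wm"] + spec$vol_sd["wm"] * rnorm(spec$n_ms)

    miss <- spec$missing_sessions
    for (i in seq_len(spec$n_ms)) {
      for (s in seq_len(spec$sessions)) {
        if (!is.null(miss) && nrow(miss) > 0 &&
            any(miss$subject_index == i & miss$session == s)) next
        wob <- rnorm(2, 0, spec$session_sd)
        cvr_gm <- pre[i, "gm"] + wob[1] + if (s == 3) delta[i, "gm"] else 0
        cvr_wm <- pre[i, "wm"] + wob[2] + if (s == 3) delta[i, "wm"] else 0
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("MS%02d", i), group = "MS", session = s,
          cvr_gm_true = cvr_gm, cvr_wm_true = cvr_wm,
          lesion_cvr_true = if (gd[i, s] > 0) spec$lesion_factor * cvr_wm
                            else NA_real_,
          gd_count = gd[i, s],
          vol_gm = ms_vol_gm[i], vol_wm = ms_vol_wm[i])
      }
    }
    do.call(rbind, rows)
  })
  truth$sim_seed <- spec$seed + 97L * seq_len(nrow(truth))
  rownames(truth) <- NULL
  structure(list(truth = truth, spec = spec, paradigm = paradigm, acq = acq,
                 phantom = phantom),
            class = "cvr_cohort")
}

#' Simulate the raw data of one cohort subject-session
#'
#' Generates the capnograph trace, truth maps (uniform tissue CVRs from
#' the cohort truth table, depressed lesion CVR where the session is
#' lesion-positive) and the raw BOLD series for a single row of the
#' cohort's truth table.
#'
#' @param cohort a `cvr_cohort`.
#' @param row row index into `cohort$truth`.
#' @return list with `trace`, `truth_maps`, `bold`, `lesion_mask`, `row`.
#' @export
simulate_session <- function(cohort, row) {
  tr <- cohort$truth[row, ]
  sd_seed <- tr$sim_seed
  trace <- make_capno_trace(cohort$paradigm,
                            bh_rise = cohort$spec$bh_rise,
                            noise_sd = cohort$spec$capno_noise_sd,
                            seed = sd_seed)
  n_components <- min(tr$gd_count, cohort$phantom$lesion_count)
  lesion_mask <- lesion_subset(cohort$phantom$lesion_mask, n_components)
  ph <- cohort$phantom
  ph$lesion_mask <- lesion_mask
  truth <- make_truth_maps(ph, cvr_gm = tr$cvr_gm_true,
                           cvr_wm = tr$cvr_wm_true,
                           lesion_cvr = if (n_components > 0)
                             tr$lesion_cvr_true else NULL,
                           noise_sd = cohort$spec$noise_sd)
  reg <- build_regressor(trace, cohort$acq)
  bold <- make_bold(ph, truth, reg, cohort$acq, seed = sd_seed + 1L)
  list(trace = trace, truth_maps = truth, bold = bold,
       lesion_mask = lesion_mask, row = tr)
}

# First k connected components (6-connectivity order of discovery) of a
# lesion mask.
lesion_subset <- function(mask, k) {
  if (k <= 0) return(array(FALSE, dim(mask)))
  labs <- label_components(mask, connectivity = 6)
  labs > 0 & labs <= k
}

#' Run the estimation pipeline over a whole synthetic cohort
#'
#' For every present subject-session, simulates the raw data and runs
#' [run_subject()], returning the estimated cohort table in the layout
#' [analyze_cohort()] consumes (plus the generating truth columns for
#' recovery checks).
#'
#' @param cohort a `cvr_cohort`.
#' @param ... passed to [run_subject()].
#' @return data.frame: subject, group, session, estimated `cvr_gm`,
#'   `cvr_wm`, `cvr_lesion`, `gd_count`, `vol_gm`, `vol_wm`, and the
#'   `*_true` columns.
#' @export
run_cohort <- function(cohort, ...) {
  prob_maps <- list(gm = cohort$phantom$prob_gm, wm = cohort$phantom$prob_wm,
                    csf = cohort$phantom$prob_csf)
  res <- lapply(seq_len(nrow(cohort$truth)), function(i) {
    sim <- simulate_session(cohort, i)
    fit <- run_subject(sim$bold, trace = sim$trace, prob_maps = prob_maps,
                       acq = cohort$acq, lesion_mask = sim$lesion_mask, ...)
    data.frame(subject = sim$row$subject, group = sim$row$group,
               session = sim$row$session,
               cvr_gm = fit$summary$cvr_gm, cvr_wm = fit$summary$cvr_wm,
               cvr_lesion = fit$summary$cvr_lesion,
               gd_count = sim$row$gd_count,
               vol_gm = sim$row$vol_gm, vol_wm = sim$row$vol_wm,
               cvr_gm_true = sim$row$cvr_gm_true,
               cvr_wm_true = sim$row$cvr_wm_true,
               lesion_cvr_true = sim$row$lesion_cvr_true)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a cohort's file set to disk
#'
#' Materialises per-subject-session NIfTI volumes (BOLD, probability maps,
#' lesion masks) and capnograph traces, a manifest, the truth table and
#' the generation config (JSON) under `dir`.
#'
#' @param cohort a `cvr_cohort`.
#' @param dir output directory.
#' @return invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- cohort$acq$voxel_mm
  for (nm in c("prob_gm", "prob_wm", "prob_csf"))
    write_volume(cohort$phantom[[nm]], file.path(dir, paste0(nm, ".nii.gz")), vox)
  manifest <- lapply(seq_len(nrow(cohort$truth)), function(i) {
    tr <- cohort$truth[i, ]
    base <- sprintf("%s_s%d", tr$subject, tr$session)
    sim <- simulate_session(cohort, i)
    write_capno(sim$trace, file.path(dir, paste0(base, "_capno.tsv")))
    write_volume(sim$bold$data, file.path(dir, paste0(base, "_bold.nii.gz")),
                 vox, tr_s = cohort$acq$tr_s)
    if (any(sim$lesion_mask))
      write_volume(sim$lesion_mask * 1L,
                   file.path(dir, paste0(base, "_lesions.nii.gz")), vox)
    data.frame(subject = tr$subject, group = tr$group, session = tr$session,
               bold = paste0(base, "_bold.nii.gz"),
               capno = paste0(base, "_capno.tsv"),
               lesions = if (any(sim$lesion_mask))
                 paste0(base, "_lesions.nii.gz") else NA_character_)
  })
  manifest <- do.call(rbind, manifest)
  write_cohort_table(manifest, file.path(dir, "manifest.tsv"))
  write_cohort_table(cohort$truth, file.path(dir, "truth.tsv"))
  cfg <- cohort$spec
  cfg$missing_sessions <- as.list(cfg$missing_sessions)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
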