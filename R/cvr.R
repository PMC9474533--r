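#' Voxel-wise GLM estimation of CVR
#'
#' Ordinary least squares of each voxel's percent-BOLD time series on the
#' demeaned PetCO2 regressor plus an intercept (and optional confound
#' columns). The regressor coefficient is the CVR estimate in %BOLD/mmHg;
#' its t-statistic, the residual SD and the residual degrees of freedom are
#' returned alongside.
#'
#' @param bold_pct a `bold_series` in percent units (typically filtered).
#' @param regressor a `petco2_regressor` (filter it identically to the BOLD
#'   data if a temporal filter was applied; see [run_subject()]).
#' @param confounds optional numeric matrix of confound series (columns).
#' @param mask optional 3D logical array restricting the fit.
#' @return a `cvr_map`: 3D arrays `beta`, `tstat`, `residual_sd`, scalar
#'   `dof`, and `provenance`.
#' @export
fit_cvr_map <- function(bold_pct, regressor, confounds = NULL, mask = NULL) {
  if (bold_pct$units != "percent")
    stop_cvr("glm", "BOLD input must be in percent units")
  d <- dim(bold_pct$data); nt <- d[4]
  x <- regressor$values
  if (length(x) != nt)
    stop_cvr("glm", "regressor length %d != time dimension %d", length(x), nt)
  X <- cbind(intercept = 1, petco2 = x - mean(x))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop_cvr("glm", "rank-deficient design; collinear columns: %s",
             paste(bad, collapse = ", "))
  }
  dof <- nt - ncol(X)
  nv <- prod(d[1:3])
  Y <- t(matrix(bold_pct$data, nv, nt))     # time x voxels
  coefs <- qr.coef(qrX, Y)
  resid <- Y - X %*% coefs
  sigma2 <- colSums(resid^2) / dof
  xtxinv <- solve(crossprod(X))
  se <- sqrt(sigma2 * xtxinv[2, 2])
  beta <- coefs[2, ]
  tstat <- ifelse(se > 0, beta / se, 0)
  out <- list(beta = array(beta, d[1:3]),
              tstat = array(tstat, d[1:3]),
              residual_sd = array(sqrt(sigma2), d[1:3]),
              dof = dof,
              provenance = list(regressor = regressor$provenance,
                                n_confounds = ncol(X) - 2L))
  if (!is.null(mask)) {
    out$beta[!mask] <- 0; out$tstat[!mask] <- 0
  }
  structure(out, class = "cvr_map")
}

#' Tissue-median CVR with lesion exclusion
#'
#' Medians of the GLM beta-weights within the GM and WM masks, excluding
#' lesion voxels, plus the median within the lesion mask itself. The median
#' of an even count is the midpoint of the central pair.
#'
#' @param map a `cvr_map`.
#' @param masks a `tissue_masks` object on the same grid.
#' @param lesion_mask optional 3D logical lesion array.
#' @return a `roi_summary`: `cvr_gm`, `cvr_wm`, `cvr_lesion` (NA when the
#'   lesion mask is empty) and `voxel_counts`.
#' @export
summarize_cvr <- function(map, masks, lesion_mask = NULL) {
  if (!identical(dim(map$beta), dim(masks$gm)))
    stop_cvr("summary", "masks not on the map grid")
  if (is.null(lesion_mask)) lesion_mask <- array(FALSE, dim(map$beta))
  gm_in <- masks$gm & !lesion_mask
  wm_in <- masks$wm & !lesion_mask
  if (!any(gm_in) || !any(wm_in))
    stop_cvr("summary", "empty GM or WM mask after lesion exclusion")
  les_n <- sum(lesion_mask)
  structure(list(
    cvr_gm = median(map$beta[gm_in]),
    cvr_wm = median(map$beta[wm_in]),
    cvr_lesion = if (les_n > 0) median(map$beta[lesion_mask]) else NA_real_,
    voxel_counts = c(gm = sum(gm_in), wm = sum(wm_in), lesion = les_n)
  ), class = "roi_summary")
}

#' Run the full single-subject CVR pipeline
#'
#' Composition of the per-subject stages: PetCO2 regressor construction
#' from the raw capnograph trace, fractional BOLD conversion, Gaussian
#' high-pass temporal filtering, tissue classification, voxel-wise GLM and
#' ROI summarisation with lesion exclusion. By default the same temporal
#' high-pass filter applied to the BOLD data is also applied to the
#' regressor, mirroring the usual FSL convention of filtering data and
#' model identically; this makes noiseless recovery exact.
#'
#' @param bold a raw `bold_series`.
#' @param trace a `capno_trace` (ignored when `regressor` is supplied).
#' @param prob_maps list with `gm`, `wm`, `csf` probability arrays.
#' @param acq an [acq_params()].
#' @param lesion_mask optional lesion array.
#' @param regressor optional precomputed `petco2_regressor`.
#' @param hrf an [hrf_params()].
#' @param highpass_sigma_s temporal filter SD, s (`NA` disables filtering).
#' @param filter_design apply the same temporal filter to the regressor.
#' @param confounds optional confound matrix passed to [fit_cvr_map()].
#' @return list with `map` (`cvr_map`), `summary` (`roi_summary`),
#'   `regressor`, `masks`, and `volumes` (normalised GM/WM volumes, cm^3).
#' @export
run_subject <- function(bold, trace = NULL, prob_maps, acq = acq_params(),
                        lesion_mask = NULL, regressor = NULL,
                        hrf = hrf_params(), highpass_sigma_s = 60,
                        filter_design = TRUE, confounds = NULL) {
  if (is.null(regressor)) {
    if (is.null(trace)) stop_cvr("subject", "need a capno trace or a regressor")
    regressor <- build_regressor(trace, acq, hrf)
  }
  pct <- fractional_bold(bold)
  reg <- regressor
  if (!is.na(highpass_sigma_s)) {
    pct <- highpass_gaussian(pct, highpass_sigma_s)
    if (filter_design) reg <- highpass_gaussian(reg, highpass_sigma_s)
  }
  masks <- classify_tissue(prob_maps$gm, prob_maps$wm, prob_maps$csf)
  map <- fit_cvr_map(pct, reg, confounds = confounds)
  summ <- summarize_cvr(map, masks, lesion_mask)
  vols <- c(gm = normalized_volume(prob_maps$gm, bold$voxel_mm),
            wm = normalized_volume(prob_maps$wm, bold$voxel_mm))
  list(map = map, summary = summ, regressor = regressor, masks = masks,
       volumes = vols)
}

#' File-based single-subject pipeline
#'
#' Reads NIfTI volumes and a delimited capnograph trace, runs
#' [run_subject()], and writes the beta and t-statistic maps, a one-row
#' summary table and a provenance JSON into `out_dir`.
#'
#' @param bold_path 4D BOLD NIfTI path.
#' @param trace_path two-column capnograph text file.
#' @param gm_path,wm_path,csf_path tissue probability NIfTI paths.
#' @param lesion_path optional lesion mask NIfTI path.
#' @param out_dir output directory (created if missing).
#' @param subject,session identifiers recorded in the summary row.
#' @param ... passed to [run_subject()].
#' @return invisibly, the [run_subject()] result.
#' @export
run_subject_files <- function(bold_path, trace_path, gm_path, wm_path,
                              csf_path, lesion_path = NULL, out_dir,
                              subject = "subj", session = 1,
                              acq = acq_params(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  raw <- read_volume(bold_path)
  vox <- attr(raw, "voxel_mm"); if (is.null(vox)) vox <- c(3, 3, 3)
  bold <- bold_series(unclass(raw), vox, acq$tr_s, "raw")
  prob_maps <- list(gm = read_volume(gm_path), wm = read_volume(wm_path),
                    csf = read_volume(csf_path))
  lesion <- if (!is.null(lesion_path)) read_volume(lesion_path) > 0.5 else NULL
  res <- run_subject(bold, trace = read_capno(trace_path),
                     prob_maps = prob_maps, acq = acq,
                     lesion_mask = lesion, ...)
  write_volume(res$map$beta, file.path(out_dir, "cvr_beta.nii.gz"), vox)
  write_volume(res$map$tstat, file.path(out_dir, "cvr_tstat.nii.gz"), vox)
  row <- data.frame(subject = subject, session = session,
                    cvr_gm = res$summary$cvr_gm, cvr_wm = res$summary$cvr_wm,
                    cvr_lesion = res$summary$cvr_lesion,
                    n_gm = res$summary$voxel_counts["gm"],
                    n_wm = res$summary$voxel_counts["wm"],
                    n_lesion = res$summary$voxel_counts["lesion"])
  write_cohort_table(row, file.path(out_dir, "summary.tsv"))
  jsonlite::write_json(res$map$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
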