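#' Construct a BOLD series object
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxel_mm voxel size, mm.
#' @param tr_s repetition time, s.
#' @param units `"raw"` or `"percent"`.
#' @return a `bold_series`.
#' @export
bold_series <- function(data, voxel_mm = c(3, 3, 3), tr_s = 3,
                        units = c("raw", "percent")) {
  if (length(dim(data)) != 4) stop_cvr("bold", "data must be 4D (x, y, z, t)")
  if (tr_s <= 0) stop_cvr("bold", "tr_s must be > 0")
  structure(list(data = data, voxel_mm = rep_len(voxel_mm, 3), tr_s = tr_s,
                 units = match.arg(units)),
            class = "bold_series")
}

#' Fractional (percent) BOLD signal change
#'
#' Expresses each voxel's time series as percent change with respect to its
#' temporal mean: `100 * (y - mean_t y) / mean_t y`. Voxels with
#' non-positive temporal mean are flagged invalid (set to zero and excluded
#' via the returned validity mask).
#'
#' @param bold a `bold_series` with raw units.
#' @return a `bold_series` in percent units; attribute `valid` is a 3D
#'   logical array of voxels with positive temporal mean.
#' @export
fractional_bold <- function(bold) {
  if (bold$units != "raw") stop_cvr("fractional", "input must be in raw units")
  d <- dim(bold$data); nv <- prod(d[1:3]); nt <- d[4]
  Y <- matrix(bold$data, nv, nt)
  mu <- rowMeans(Y)
  valid <- mu > 0
  out <- matrix(0, nv, nt)
  out[valid, ] <- 100 * (Y[valid, , drop = FALSE] / mu[valid] - 1)
  res <- bold_series(array(out, d), bold$voxel_mm, bold$tr_s, "percent")
  attr(res, "valid") <- array(valid, d[1:3])
  res
}

# Dense 1D Gaussian smoothing operator with reflective boundaries
# (mirror including the edge sample); rows sum to 1 so constants are fixed
# points.
gaussian_smooth_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + (-r:r)
    # reflect: ... 3 2 1 | 1 2 3 ... n | n n-1 ...
    j <- ifelse(j < 1, 1 - j, j)
    j <- ifelse(j > n, 2 * n + 1 - j, j)
    j <- pmin(pmax(j, 1), n)
    for (k in seq_along(j)) S[i, j[k]] <- S[i, j[k]] + w[k]
  }
  S
}

#' Gaussian high-pass temporal filter
#'
#' Subtracts a Gaussian-weighted running mean of standard deviation
#' `sigma_s` (converted to volumes via the TR; reflective boundaries) from
#' each voxel time series — the subtract-smoothed-signal realisation of a
#' high-pass filter. Accepts a `bold_series`, a numeric vector (e.g. a
#' regressor), or a matrix with time along columns.
#'
#' @param x input series.
#' @param sigma_s filter standard deviation, s.
#' @param tr_s sampling interval, s (taken from the object when available).
#' @return filtered object of the same type.
#' @export
highpass_gaussian <- function(x, sigma_s = 60, tr_s = NULL) {
  if (sigma_s <= 0) stop_cvr("highpass", "sigma_s must be > 0")
  if (inherits(x, "bold_series")) {
    d <- dim(x$data)
    S <- hp_matrix(d[4], sigma_s, x$tr_s)
    Y <- matrix(x$data, prod(d[1:3]), d[4])
    out <- x
    out$data <- array(Y %*% t(S), d)
    attr(out, "valid") <- attr(x, "valid")
    return(out)
  }
  if (inherits(x, "petco2_regressor")) {
    x$values <- as.numeric(hp_matrix(length(x$values), sigma_s, x$tr_s) %*% x$values)
    x$provenance$highpass_sigma_s <- sigma_s
    return(x)
  }
  if (is.matrix(x)) {
    if (is.null(tr_s)) stop_cvr("highpass", "tr_s required for matrix input")
    return(x %*% t(hp_matrix(ncol(x), sigma_s, tr_s)))
  }
  if (is.null(tr_s)) stop_cvr("highpass", "tr_s required for vector input")
  as.numeric(hp_matrix(length(x), sigma_s, tr_s) %*% x)
}

hp_matrix <- function(nt, sigma_s, tr_s) {
  if (sigma_s <= tr_s)
    warning("highpass sigma <= TR: filter removes almost everything")
  diag(nt) - gaussian_smooth_matrix(nt, sigma_s / tr_s)
}

#' Classify voxels by most probable tissue compartment
#'
#' Per-voxel argmax over GM/WM/CSF probability maps, ties broken in the
#' fixed order GM > WM > CSF; background voxels (all probabilities below
#' `background_thresh`) are excluded from every mask.
#'
#' @param prob_gm,prob_wm,prob_csf probability arrays on one grid.
#' @param background_thresh background exclusion threshold.
#' @return a `tissue_masks` list of logical arrays `gm`, `wm`, `csf` that
#'   partition the brain.
#' @export
classify_tissue <- function(prob_gm, prob_wm, prob_csf,
                            background_thresh = 0.05) {
  if (!identical(dim(prob_gm), dim(prob_wm)) ||
      !identical(dim(prob_gm), dim(prob_csf)))
    stop_cvr("classify", "probability maps must share one grid")
  brain <- pmax(prob_gm, prob_wm, prob_csf) >= background_thresh
  gm <- brain & prob_gm >= prob_wm & prob_gm >= prob_csf
  wm <- brain & !gm & prob_wm >= prob_csf
  csf <- brain & !gm & !wm
  structure(list(gm = gm, wm = wm, csf = csf, brain = brain),
            class = "tissue_masks")
}

#' Normalised tissue volume
#'
#' Volume = `scaling * voxel_volume * sum(probabilities)`, in cm^3. The
#' scaling factor stands in for normalisation to a standard intracranial
#' volume; it is 1 for synthetic subjects that share one grid.
#'
#' @param prob_map probability array in `[0, 1]`.
#' @param voxel_mm voxel size, mm.
#' @param scaling normalisation factor.
#' @return volume in cm^3.
#' @export
normalized_volume <- function(prob_map, voxel_mm = c(3, 3, 3), scaling = 1) {
  if (any(prob_map < 0 | prob_map > 1))
    stop_cvr("volume", "probabilities must lie in [0, 1]")
  scaling * prod(rep_len(voxel_mm, 3)) * sum(prob_map) / 1000
}

#' Isotropic spatial Gaussian smoothing of a 3D map
#'
#' Separable Gaussian smoothing with standard deviation `sigma_mm`,
#' converted per axis to voxels, with reflective boundaries (so a uniform
#' field is unchanged). `sigma_mm = 0` is the identity.
#'
#' @param map3d 3D numeric array.
#' @param sigma_mm smoothing SD, mm.
#' @param voxel_mm voxel size, mm.
#' @return smoothed array.
#' @export
smooth_spatial <- function(map3d, sigma_mm = 4, voxel_mm = c(3, 3, 3)) {
  if (sigma_mm < 0) stop_cvr("smooth", "sigma_mm must be >= 0")
  if (sigma_mm == 0) return(map3d)
  d <- dim(map3d)
  voxel_mm <- rep_len(voxel_mm, 3)
  out <- map3d
  for (ax in 1:3) {
    S <- gaussian_smooth_matrix(d[ax], sigma_mm / voxel_mm[ax])
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(out, perm), d[ax])
    m <- S %*% m
    out <- aperm(array(m, d[perm]), order(perm))
  }
  out
}
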