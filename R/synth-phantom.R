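#' Generate a concentric-shell digital head phantom
#'
#' Builds smooth GM/WM/CSF probability maps on a 3D grid: a WM core, a GM
#' shell and a CSF rim, with logistic transitions between compartments, plus
#' an optional set of disjoint spherical white-matter lesions and a baseline
#' signal field `s0`. The phantom stands in for a probabilistic tissue
#' segmentation and manually drawn lesion masks so that the downstream
#' pipeline can be exercised with known ground truth.
#'
#' @param grid_shape 3D grid dimensions (each >= 8).
#' @param lesion_count number of spherical lesions to place in the
#'   WM-dominant region (0 for none).
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @param lesion_radius_vox lesion radius in voxels.
#' @param voxel_mm voxel size in mm.
#' @return a `phantom` object: probability arrays `prob_gm`, `prob_wm`,
#'   `prob_csf` in `[0, 1]` summing to at most 1, a logical `lesion_mask`
#'   with `lesion_count` disjoint connected components, a positive baseline
#'   field `s0`, and `voxel_mm`.
#' @examples
#' ph <- make_phantom(c(16, 16, 16), lesion_count = 0, seed = 1)
#' range(ph$prob_gm + ph$prob_wm + ph$prob_csf)
#' @export
make_phantom <- function(grid_shape, lesion_count = 0, seed = 1,
                         lesion_radius_vox = 1.0, voxel_mm = c(3, 3, 3)) {
  grid_shape <- as.integer(rep_len(grid_shape, 3))
  if (any(grid_shape < 8)) stop_cvr("phantom", "grid_shape must be >= 8 on each axis")
  if (lesion_count < 0) stop_cvr("phantom", "lesion_count must be >= 0")

  ctr <- (grid_shape + 1) / 2
  half <- (grid_shape - 1) / 2
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - ctr[a]) / half[a])
  # normalised radius: 1 at the face-centre of the grid boundary
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))

  sigm <- function(x, w = 0.04) 1 / (1 + exp(-x / w))
  inside <- sigm(0.90 - r)             # brain support
  p_wm   <- sigm(0.55 - r)             # core
  p_csf  <- sigm(r - 0.70)             # rim
  p_gm   <- pmax(0, 1 - p_wm - p_csf)  # shell
  prob_gm  <- p_gm  * inside
  prob_wm  <- p_wm  * inside
  prob_csf <- p_csf * inside

  s0 <- inside * (500 + 500 * prob_gm + 400 * prob_wm + 600 * prob_csf)

  wm_argmax <- inside > 0.5 & prob_wm >= prob_gm & prob_wm >= prob_csf
  lesion_mask <- array(FALSE, grid_shape)
  if (lesion_count > 0) {
    lesion_mask <- with_seed(seed, place_lesions(wm_argmax, lesion_count,
                                                 lesion_radius_vox, grid_shape))
  }

  structure(list(prob_gm = prob_gm, prob_wm = prob_wm, prob_csf = prob_csf,
                 lesion_mask = lesion_mask, s0 = s0,
                 voxel_mm = rep_len(voxel_mm, 3), grid_shape = grid_shape,
                 lesion_count = as.integer(lesion_count)),
            class = "phantom")
}

# Place `n` disjoint spheres fully inside the WM-argmax mask; centres are
# kept >= 2*(radius+1) voxels apart so components stay separate even under
# 26-connectivity. Errors if the WM region cannot host them.
place_lesions <- function(wm_mask, n, radius, dims) {
  offs <- sphere_offsets(radius)
  idx_wm <- which(wm_mask)
  coords <- arrayInd(idx_wm, dims)
  fits <- vapply(seq_len(nrow(coords)), function(i) {
    pts <- sweep(offs, 2, coords[i, ], "+")
    if (any(pts < 1) || any(sweep(pts, 2, dims, ">") > 0)) return(FALSE)
    all(wm_mask[pts])
  }, logical(1))
  eligible <- coords[fits, , drop = FALSE]
  if (nrow(eligible) == 0)
    stop_cvr("phantom", "WM region too small to host a lesion of radius %.1f voxels", radius)
  min_sep <- 2 * (radius + 1)
  chosen <- matrix(numeric(0), 0, 3)
  for (attempt in seq_len(100)) {   # greedy passes with randomised order
    chosen <- matrix(numeric(0), 0, 3)
    ord <- sample.int(nrow(eligible))
    for (i in ord) {
      cand <- eligible[i, ]
      if (nrow(chosen) == 0 ||
          all(sqrt(rowSums(sweep(chosen, 2, cand)^2)) >= min_sep)) {
        chosen <- rbind(chosen, cand)
        if (nrow(chosen) == n) break
      }
    }
    if (nrow(chosen) == n) break
  }
  if (nrow(chosen) < n)
    stop_cvr("phantom",
             "could only place %d of %d disjoint lesions in the WM region (radius %.1f voxels)",
             nrow(chosen), n, radius)
  mask <- array(FALSE, dims)
  for (i in seq_len(nrow(chosen))) {
    pts <- sweep(offs, 2, chosen[i, ], "+")
    mask[pts] <- TRUE
  }
  mask
}

sphere_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[sqrt(g$x^2 + g$y^2 + g$z^2) <= radius, ]
  as.matrix(g)
}

#' Ground-truth maps for a phantom
#'
#' Assigns a uniform true CVR (in %BOLD/mmHg) to each tissue compartment
#' (by argmax classification of the phantom probabilities), an optionally
#' depressed CVR inside the lesion mask, per-voxel polynomial drift
#' coefficients and a fractional-signal noise SD.
#'
#' @param phantom a [make_phantom()] object.
#' @param cvr_gm,cvr_wm,cvr_csf true CVR per compartment, %BOLD/mmHg.
#' @param lesion_cvr true CVR inside lesions; if `NULL`, lesions get
#'   `lesion_factor * cvr_wm`.
#' @param lesion_factor depression factor applied to the WM CVR inside
#'   lesions when `lesion_cvr` is `NULL`; the default halves it.
#' @param drift_coeffs numeric vector of polynomial drift coefficients
#'   (linear, quadratic, ... in normalised time on `[0, 1]`), applied
#'   uniformly, or `NULL` for no drift.
#' @param noise_sd fractional-signal noise SD (e.g. `0.002` = 0.2%).
#' @return a `truth_maps` object with fields `cvr_true`, `drift_coeffs`,
#'   `noise_sd`.
#' @export
make_truth_maps <- function(phantom, cvr_gm, cvr_wm, cvr_csf = 0,
                            lesion_cvr = NULL, lesion_factor = 0.5,
                            drift_coeffs = NULL, noise_sd = 0) {
  masks <- classify_tissue(phantom$prob_gm, phantom$prob_wm, phantom$prob_csf)
  cvr <- array(0, phantom$grid_shape)
  cvr[masks$gm] <- cvr_gm
  cvr[masks$wm] <- cvr_wm
  cvr[masks$csf] <- cvr_csf
  if (any(phantom$lesion_mask)) {
    les_val <- if (is.null(lesion_cvr)) lesion_factor * cvr_wm else lesion_cvr
    cvr[phantom$lesion_mask] <- les_val
  }
  if (!all(is.finite(cvr))) stop_cvr("truth", "cvr_true must be finite")
  if (any(noise_sd < 0)) stop_cvr("truth", "noise_sd must be >= 0")
  structure(list(cvr_true = cvr, drift_coeffs = drift_coeffs,
                 noise_sd = noise_sd),
            class = "truth_maps")
}
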