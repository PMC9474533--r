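#' Connected-component labelling of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background), numbered in
#'   discovery order.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  d <- dim(mask)
  array(label_components_cpp(as.logical(mask), as.integer(d),
                             as.integer(connectivity)), d)
}

#' Threshold-free cluster enhancement
#'
#' For each voxel v, `TFCE(v) = sum_h e(h, v)^E * h^H * dh` over thresholds
#' `h = dh, 2 dh, ...` up to the map maximum, where `e(h, v)` is the voxel
#' count of the connected component containing v in the superthreshold set
#' `map >= h`. Negative values are handled by enhancing the negated map
#' separately and negating the result. Defaults are the standard settings
#' of the method: `E = 0.5`, `H = 2`, `dh` = 1/100 of the absolute maximum,
#' 26-connectivity.
#'
#' @param stat_map 3D statistic map.
#' @param mask optional logical array restricting the enhancement.
#' @param E,H extent and height exponents.
#' @param dh threshold step (in statistic units); `NULL` for max/100.
#' @param connectivity 6, 18 or 26.
#' @return enhanced 3D map (signed).
#' @export
tfce_enhance <- function(stat_map, mask = NULL, E = 0.5, H = 2, dh = NULL,
                         connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  d <- dim(stat_map)
  m <- stat_map
  if (!is.null(mask)) m[!mask] <- 0
  if (!all(is.finite(m))) stop_cvr("tfce", "non-finite values in stat map")
  if (all(m == 0)) return(array(0, d))
  if (is.null(dh)) dh <- max(abs(m)) / 100
  if (dh <= 0) stop_cvr("tfce", "dh must be > 0")
  enh <- function(v) tfce_cpp(as.numeric(v), as.integer(d), E, H, dh,
                              as.integer(connectivity))
  array(enh(pmax(m, 0)) - enh(pmax(-m, 0)), d)
}

#' Permutation-based TFCE-corrected p-maps
#'
#' Group-level voxel-wise inference by permutation of the maximum TFCE
#' statistic. Each subject map is optionally smoothed (Gaussian,
#' `sigma_mm`); the observed group t-map is TFCE-enhanced; for every
#' permutation (sign flips of subject maps for the one-sample/paired
#' design, group-label exchanges for the two-sample design) the maximum
#' TFCE value is recorded, and the corrected p-value of voxel v is
#' `(1 + #\{max_perm >= TFCE_obs(v)\}) / (n_perm + 1)`. Inference is
#' one-sided in the direction of the contrast (enhancement of the positive
#' statistic); permutations are enumerated exhaustively when there are no
#' more than `n_perm` of them.
#'
#' @param subject_maps 4D array (x, y, z, subject) of per-subject maps;
#'   paired differences (on minus pre) for the one-sample design.
#' @param scheme `"onesample"` (sign flips) or `"twosample"` (label
#'   exchange).
#' @param labels for the two-sample scheme, a vector of two group labels,
#'   one per subject; the contrast is first level minus second.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param E,H,dh,connectivity TFCE parameters, see [tfce_enhance()].
#' @param sigma_mm per-subject smoothing SD, mm (0 = none).
#' @param voxel_mm voxel size for smoothing.
#' @param mask optional brain mask.
#' @return list: `p` (corrected p-map), `tstat` (observed t-map), `tfce`
#'   (observed enhanced map), `max_null` (permutation maxima), `n_perm`,
#'   `exhaustive`.
#' @export
permutation_pmap <- function(subject_maps, scheme = c("onesample", "twosample"),
                             labels = NULL, n_perm = 1000, seed = 1,
                             E = 0.5, H = 2, dh = NULL, connectivity = 26,
                             sigma_mm = 0, voxel_mm = c(3, 3, 3),
                             mask = NULL) {
  scheme <- match.arg(scheme)
  d <- dim(subject_maps)
  if (length(d) != 4) stop_cvr("perm", "subject_maps must be 4D (x, y, z, subject)")
  n <- d[4]
  if (n < 5) stop_cvr("perm", "need at least 5 subjects, got %d", n)
  if (n_perm < 100) stop_cvr("perm", "n_perm must be >= 100")
  if (n_perm < 19)
    warning("n_perm too small for p < 0.05")

  if (sigma_mm > 0)
    for (i in seq_len(n))
      subject_maps[, , , i] <- smooth_spatial(subject_maps[, , , i],
                                              sigma_mm, voxel_mm)
  nv <- prod(d[1:3])
  M <- t(matrix(subject_maps, nv, n))   # subjects x voxels
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mvec <- as.vector(mask)

  if (scheme == "onesample") {
    tfun <- function(s) {
      mu <- colMeans(s * M)
      v <- (colSums(M^2) - n * mu^2) / (n - 1)
      ifelse(v > 0, mu / sqrt(v / n), 0)
    }
    all_perms <- 2^n
    exhaustive <- all_perms <= n_perm
    signs <- if (exhaustive) {
      sm <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      n_perm <- nrow(sm); sm
    } else {
      with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                             n_perm, n))
    }
    obs_stat <- tfun(rep(1, n))
    perm_stats <- function(i) tfun(signs[i, ])
  } else {
    if (is.null(labels) || length(labels) != n)
      stop_cvr("perm", "two-sample scheme needs one label per subject")
    labels <- as.factor(labels)
    if (nlevels(labels) != 2) stop_cvr("perm", "need exactly two groups")
    g1 <- labels == levels(labels)[1]
    n1 <- sum(g1); n2 <- n - n1
    ss_all <- colSums(M^2)
    tfun <- function(sel1) {
      m1 <- colMeans(M[sel1, , drop = FALSE])
      m2 <- colMeans(M[!sel1, , drop = FALSE])
      sp2 <- (ss_all - n1 * m1^2 - n2 * m2^2) / (n - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      ifelse(se > 0, (m1 - m2) / se, 0)
    }
    all_perms <- choose(n, n1)
    exhaustive <- all_perms <= n_perm
    sel_list <- if (exhaustive) {
      cmb <- utils::combn(n, n1)
      n_perm <- ncol(cmb)
      lapply(seq_len(n_perm), function(i) seq_len(n) %in% cmb[, i])
    } else {
      with_seed(seed, lapply(seq_len(n_perm), function(i)
        seq_len(n) %in% sample(n, n1)))
    }
    obs_stat <- tfun(g1)
    perm_stats <- function(i) tfun(sel_list[[i]])
  }

  tfce_of <- function(stat) {
    s <- stat; s[!mvec] <- 0
    tfce_enhance(array(s, d[1:3]), E = E, H = H, dh = dh,
                 connectivity = connectivity)
  }
  dh_use <- dh
  if (is.null(dh_use)) dh_use <- max(abs(obs_stat[mvec]), 0) / 100
  obs_enh <- tfce_of(obs_stat)
  max_null <- vapply(seq_len(n_perm), function(i) {
    e <- tfce_cpp(pmax(`[<-`(perm_stats(i), !mvec, 0), 0),
                  as.integer(d[1:3]), E, H, dh_use, as.integer(connectivity))
    max(e, 0)
  }, numeric(1))
  pvals <- vapply(as.vector(obs_enh), function(v)
    (1 + sum(max_null >= v)) / (n_perm + 1), numeric(1))
  p <- array(pvals, d[1:3])
  p[!mask] <- 1
  list(p = p, tstat = array(obs_stat, d[1:3]), tfce = obs_enh,
       max_null = max_null, n_perm = n_perm, exhaustive = exhaustive)
}

#' Group difference maps: mean change, t-score, corrected significance
#'
#' Produces the three standard outputs of a group-level CVR contrast: the
#' mean difference map in absolute units, the voxel-wise t-score map, and
#' the TFCE permutation-corrected p-map thresholded at `alpha`. For the
#' paired (longitudinal) contrast, supply the on-treatment and
#' pre-treatment stacks; for the two-sample contrast, the two group
#' stacks.
#'
#' @param maps_a 4D stack: on-treatment maps (paired) or group A.
#' @param maps_b 4D stack: pre-treatment maps (paired) or group B.
#' @param contrast `"paired"` (a minus b within subject) or `"twosample"`.
#' @param alpha significance threshold for the thresholded map.
#' @param sigma_mm per-subject smoothing, mm.
#' @param ... further arguments to [permutation_pmap()].
#' @return list: `delta` (mean difference), `tstat`, `p`, `sig`
#'   (logical `p < alpha`), `perm` (full [permutation_pmap()] result).
#' @export
group_difference_maps <- function(maps_a, maps_b,
                                  contrast = c("paired", "twosample"),
                                  alpha = 0.05, sigma_mm = 4,
                                  voxel_mm = c(3, 3, 3), ...) {
  contrast <- match.arg(contrast)
  if (contrast == "paired") {
    if (!identical(dim(maps_a), dim(maps_b)))
      stop_cvr("groupmaps", "paired stacks must share dimensions")
    diffs <- maps_a - maps_b
    perm <- permutation_pmap(diffs, "onesample", sigma_mm = sigma_mm,
                             voxel_mm = voxel_mm, ...)
    delta <- apply(diffs, 1:3, mean)
  } else {
    if (!identical(dim(maps_a)[1:3], dim(maps_b)[1:3]))
      stop_cvr("groupmaps", "group stacks must share the 3D grid")
    stack <- array(c(maps_a, maps_b), c(dim(maps_a)[1:3],
                                        dim(maps_a)[4] + dim(maps_b)[4]))
    labels <- rep(c("A", "B"), c(dim(maps_a)[4], dim(maps_b)[4]))
    perm <- permutation_pmap(stack, "twosample", labels = labels,
                             sigma_mm = sigma_mm, voxel_mm = voxel_mm, ...)
    delta <- apply(maps_a, 1:3, mean) - apply(maps_b, 1:3, mean)
  }
  list(delta = delta, tstat = perm$tstat, p = perm$p, sig = perm$p < alpha,
       perm = perm)
}
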