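#' Simulate a BOLD series from a phantom, truth maps and a regressor
#'
#' Generative model, the inverse of the analysis GLM: for voxel v with
#' baseline `s0(v)` and true CVR `c(v)` (%BOLD/mmHg),
#' `y(v, t) = s0(v) * (1 + c(v)/100 * x(t) + d(v, t) + e(v, t))`, where
#' `x` is the PetCO2 regressor minus its temporal mean (mmHg), `d` the
#' polynomial drift from the truth maps (in normalised time on `[0, 1]`)
#' and `e` i.i.d. Gaussian noise with the truth maps' fractional SD. A
#' noiseless, drift-free series therefore yields fractional BOLD exactly
#' equal to `c(v)/100 * x(t) * 100`%, and the downstream GLM recovers
#' `c(v)` to numerical precision.
#'
#' @param phantom a [make_phantom()] object.
#' @param truth a [make_truth_maps()] object.
#' @param regressor a `petco2_regressor` of length `acq$n_volumes`.
#' @param acq an [acq_params()].
#' @param seed integer seed for the noise.
#' @return a `bold_series` (raw units).
#' @export
make_bold <- function(phantom, truth, regressor, acq = acq_params(), seed = 1) {
  if (length(regressor$values) != acq$n_volumes)
    stop_cvr("bold-sim", "regressor length %d != n_volumes %d",
             length(regressor$values), acq$n_volumes)
  if (!identical(dim(truth$cvr_true), phantom$grid_shape))
    stop_cvr("bold-sim", "truth and phantom grids differ")
  d <- phantom$grid_shape; nt <- acq$n_volumes; nv <- prod(d)
  x <- regressor$values - mean(regressor$values)
  M <- 1 + outer(as.vector(truth$cvr_true) / 100, x)
  if (!is.null(truth$drift_coeffs) && length(truth$drift_coeffs) > 0) {
    tn <- (seq_len(nt) - 1) / (nt - 1)
    dr <- numeric(nt)
    for (k in seq_along(truth$drift_coeffs))
      dr <- dr + truth$drift_coeffs[k] * tn^k
    M <- M + rep(dr, each = nv)
  }
  if (any(truth$noise_sd > 0)) {
    eps <- with_seed(seed, rnorm(nv * nt, 0, 1)) * truth$noise_sd
    M <- M + matrix(eps, nv, nt)
  }
  Y <- as.vector(phantom$s0) * M
  bold_series(array(Y, c(d, nt)), phantom$voxel_mm, acq$tr_s, "raw")
}
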