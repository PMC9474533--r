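#' Detect end-tidal CO2 peaks in a capnograph trace
#'
#' Finds per-breath expiratory maxima: local maxima with topographic
#' prominence of at least `prominence_mmHg`, separated by at least
#' `min_breath_interval_s` (when two candidates fall closer, the higher one
#' is kept). Breath holds produce no peaks, so the deliberate post-hold
#' expiration supplies the end-of-hold PetCO2 sample.
#'
#' @param trace a `capno_trace`.
#' @param min_breath_interval_s refractory interval between breaths, s.
#' @param prominence_mmHg minimum peak prominence, mmHg.
#' @return a `petco2_series`: list with `peak_times` (s) and `peak_values`
#'   (mmHg).
#' @export
detect_end_tidal <- function(trace, min_breath_interval_s = 2,
                             prominence_mmHg = 5) {
  if (min_breath_interval_s <= 0)
    stop_cvr("petco2", "min_breath_interval_s must be > 0")
  x <- trace$co2; tt <- trace$t; n <- length(x)
  if (max(diff(tt)) >= 2)
    stop_cvr("petco2", "sampling gaps >= 2 s in trace")
  cand <- which(diff(sign(diff(x))) < 0) + 1L  # strict rise then fall/plateau
  cand <- cand[x[cand] > 0]
  keep <- vapply(cand, function(i) {
    peak_prominence(x, i) >= prominence_mmHg
  }, logical(1))
  cand <- cand[keep]
  # refractory interval: greedy scan keeping the higher of clashing peaks
  if (length(cand) > 1) {
    sel <- cand[1]
    for (i in cand[-1]) {
      last <- sel[length(sel)]
      if (tt[i] - tt[last] >= min_breath_interval_s) sel <- c(sel, i)
      else if (x[i] > x[last]) sel[length(sel)] <- i
    }
    cand <- sel
  }
  if (length(cand) < 3)
    stop_cvr("petco2", "insufficient breaths: only %d prominent peaks detected",
             length(cand))
  vals <- x[cand]
  if (any(vals < 0 | vals > 150))
    stop_cvr("petco2", "end-tidal values outside physiological bounds [0, 150] mmHg")
  structure(list(peak_times = tt[cand], peak_values = vals),
            class = "petco2_series")
}

# Topographic prominence of a local maximum: height above the higher of the
# two minima separating it from taller terrain (or from the record edge).
peak_prominence <- function(x, i) {
  v <- x[i]
  left <- x[seq_len(i - 1)]
  right <- x[seq(i + 1, length(x))]
  higher_l <- which(left > v)
  lmin <- if (length(higher_l)) min(left[seq(max(higher_l), length(left))]) else min(left)
  higher_r <- which(right > v)
  rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
  v - max(lmin, rmin)
}

#' Resample an end-tidal series onto the acquisition grid
#'
#' Linear interpolation between end-tidal samples, evaluated at the
#' volume-acquisition midpoints, with constant extrapolation beyond the
#' first/last peak.
#'
#' @param pet a `petco2_series`.
#' @param acq an [acq_params()].
#' @return numeric vector of length `acq$n_volumes`, mmHg.
#' @export
interpolate_to_grid <- function(pet, acq) {
  if (length(pet$peak_times) == 0) stop_cvr("petco2", "empty end-tidal series")
  span <- diff(range(pet$peak_times))
  if (span < 0.5 * acq$n_volumes * acq$tr_s)
    stop_cvr("petco2", "end-tidal series spans %.0f s, less than half the scan", span)
  approx(pet$peak_times, pet$peak_values, xout = volume_times(acq),
         rule = 2, ties = "ordered")$y
}

#' Quadratic detrending
#'
#' Residuals of an ordinary least-squares fit of a degree-2 polynomial in
#' time; the output is orthogonal to the span of `{1, t, t^2}`.
#'
#' @param series numeric vector (length >= 4).
#' @param t optional time vector (defaults to sample index).
#' @return residual vector of the same length.
#' @export
detrend_quadratic <- function(series, t = seq_along(series)) {
  n <- length(series)
  if (n < 4) stop_cvr("detrend", "need at least 4 samples, got %d", n)
  tc <- (t - mean(t)) / max(abs(t - mean(t)))  # centred/scaled for conditioning
  X <- cbind(1, tc, tc^2)
  qr.resid(qr(X), series)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Positive gamma lobe minus a scaled undershoot lobe, sampled on the
#' `dt_s` grid, truncated at `length_s` and normalised to unit sum so that
#' convolution preserves the amplitude (and units) of a sustained step.
#'
#' @param params an [hrf_params()].
#' @return numeric kernel; attribute `t_s` holds its time axis.
#' @export
canonical_hrf <- function(params = hrf_params()) {
  t <- seq(0, params$length_s, by = params$dt_s)
  k <- dgamma(t, shape = params$peak_delay_s / params$peak_disp,
              scale = params$peak_disp) -
    dgamma(t, shape = params$undershoot_delay_s / params$under_disp,
           scale = params$under_disp) / params$p_u_ratio
  s <- sum(k)
  if (s <= 0) stop_cvr("hrf", "kernel must integrate to a positive value")
  k <- k / s
  attr(k, "t_s") <- t
  k
}

#' Causal convolution with an HRF kernel
#'
#' 'Same'-length causal convolution: output sample k reflects the input
#' history up to sample k. The input is constant-extrapolated before its
#' first sample so a unit-sum kernel maps a constant series to itself.
#'
#' @param x input series.
#' @param kernel convolution kernel (e.g. from [canonical_hrf()]).
#' @return convolved series, same length as `x`.
#' @export
convolve_hrf <- function(x, kernel) {
  L <- length(kernel)
  xp <- c(rep(x[1], L - 1), x)
  y <- stats::filter(xp, kernel, method = "convolution", sides = 1)
  as.numeric(y[seq(L, length(xp))])
}

#' Build the PetCO2 GLM regressor from a raw capnograph trace
#'
#' Full processing chain: end-tidal peak detection, linear resampling,
#' quadratic detrending, and convolution with the canonical HRF. Detrending
#' and convolution run on the HRF kernel's fine `dt_s` grid and the result
#' is then sampled at the volume-acquisition midpoints, so the post-hold
#' response peaks are not distorted by TR-level quantisation of the kernel.
#' The result is on the mmHg scale (the HRF kernel has unit sum), so GLM
#' beta-weights against percent BOLD are in %BOLD/mmHg.
#'
#' @param trace a `capno_trace`.
#' @param acq an [acq_params()].
#' @param hrf an [hrf_params()]; `dt_s` sets the internal model resolution.
#' @param min_breath_interval_s,prominence_mmHg peak-detection settings.
#' @param lag_s optional global shift (s) applied to end-tidal times before
#'   resampling; 0 (no lag optimisation) by default.
#' @return a `petco2_regressor`: list with `values` (length
#'   `acq$n_volumes`), `tr_s` and a `provenance` list of all parameters.
#' @export
build_regressor <- function(trace, acq = acq_params(), hrf = hrf_params(),
                            min_breath_interval_s = 2, prominence_mmHg = 5,
                            lag_s = 0) {
  pet <- detect_end_tidal(trace, min_breath_interval_s, prominence_mmHg)
  if (lag_s != 0) pet$peak_times <- pet$peak_times + lag_s
  span <- diff(range(pet$peak_times))
  if (span < 0.5 * acq$n_volumes * acq$tr_s)
    stop_cvr("petco2", "end-tidal series spans %.0f s, less than half the scan", span)
  tf <- seq(0, acq$n_volumes * acq$tr_s, by = hrf$dt_s)
  fine <- approx(pet$peak_times, pet$peak_values, xout = tf, rule = 2,
                 ties = "ordered")$y
  detr <- detrend_quadratic(fine, t = tf)
  kern <- canonical_hrf(hrf)
  conv <- convolve_hrf(detr, kern)
  vals <- approx(tf, conv, xout = volume_times(acq), rule = 2)$y
  if (!all(is.finite(vals))) stop_cvr("regressor", "non-finite regressor values")
  structure(list(
    values = vals, tr_s = acq$tr_s,
    provenance = list(n_peaks = length(pet$peak_times),
                      min_breath_interval_s = min_breath_interval_s,
                      prominence_mmHg = prominence_mmHg, lag_s = lag_s,
                      hrf = unclass(hrf), n_volumes = acq$n_volumes,
                      detrend = "quadratic", interpolation = "linear",
                      convolution = "causal-same")),
    class = "petco2_regressor")
}
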