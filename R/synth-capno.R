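#' Simulate a capnograph trace for a breath-hold task
#'
#' Synthesises the expired-CO2 partial pressure recorded at the nostril
#' during a paced-breathing task with end-expiration breath holds. During
#' paced breathing the trace alternates inspiratory troughs (near 0 mmHg)
#' and end-tidal expiratory peaks (at `baseline_petco2`); during each hold
#' the trace stays near zero (no airflow); the deliberate forced expiration
#' right after each hold produces a single peak at
#' `baseline_petco2 + bh_rise`, the end-of-hold PetCO2 sample. Breath
#' upstrokes/downstrokes are triangular, so every noiseless local maximum
#' equals its scheduled end-tidal value exactly.
#'
#' @param paradigm a [bh_paradigm()].
#' @param sample_hz sampling rate, Hz (>= 5).
#' @param baseline_petco2 end-tidal plateau during paced breathing, mmHg.
#' @param bh_rise PetCO2 excursion produced by one hold, mmHg.
#' @param noise_sd additive Gaussian noise SD, mmHg (trace clamped at 0).
#' @param seed integer seed.
#' @param exhale_delay_s delay of the post-hold expiration peak after the
#'   hold ends, s (within one breath); the end-tidal value registers at the
#'   end of the deliberate full expiration.
#' @return a `capno_trace`; attribute `peak_schedule` holds the noiseless
#'   end-tidal peak times/values used to build it.
#' @examples
#' tr <- make_capno_trace(bh_paradigm(), noise_sd = 0)
#' max(tr$co2)   # baseline + bh_rise
#' @export
make_capno_trace <- function(paradigm = bh_paradigm(), sample_hz = 20,
                             baseline_petco2 = 40, bh_rise = 8,
                             noise_sd = 0.5, seed = 1, exhale_delay_s = 2) {
  if (sample_hz < 5) stop_cvr("capno-sim", "sample_hz must be >= 5")
  if (baseline_petco2 <= 0) stop_cvr("capno-sim", "baseline_petco2 must be > 0")
  if (bh_rise < 0) stop_cvr("capno-sim", "bh_rise must be >= 0")
  if (noise_sd < 0) stop_cvr("capno-sim", "noise_sd must be >= 0")

  per <- paradigm$breath_period_s
  snap <- function(x) round(x * sample_hz) / sample_hz

  peak_t <- numeric(0); peak_v <- numeric(0)
  add_paced <- function(from, to) {
    if (to - from < per) return(invisible())
    tt <- seq(from + per, to - per / 2, by = per)
    peak_t <<- c(peak_t, tt); peak_v <<- c(peak_v, rep(baseline_petco2, length(tt)))
  }
  add_paced(0, paradigm$lead_in_s)
  ends <- hold_ends(paradigm)
  for (m in seq_len(paradigm$n_blocks)) {
    post <- ends[m] + exhale_delay_s
    peak_t <- c(peak_t, post)
    peak_v <- c(peak_v, baseline_petco2 + bh_rise)
    add_paced(post, ends[m] + paradigm$recovery_s)
  }
  peak_t <- snap(peak_t)
  ord <- order(peak_t); peak_t <- peak_t[ord]; peak_v <- peak_v[ord]

  t <- seq(0, paradigm$total_s, by = 1 / sample_hz)
  co2 <- numeric(length(t))
  w <- 0.45 * per   # tent half-width; tents of adjacent breaths never overlap
  for (i in seq_along(peak_t)) {
    contrib <- peak_v[i] * pmax(0, 1 - abs(t - peak_t[i]) / w)
    co2 <- pmax(co2, contrib)
  }
  if (noise_sd > 0)
    co2 <- pmax(0, co2 + with_seed(seed, rnorm(length(t), 0, noise_sd)))

  out <- capno_trace(t, co2)
  attr(out, "peak_schedule") <- data.frame(time_s = peak_t, petco2 = peak_v)
  attr(out, "paradigm") <- paradigm
  out
}
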