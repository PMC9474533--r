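#' Breath-hold task paradigm
#'
#' Describes a paced-breathing task with repeated end-expiration breath
#' holds: a paced-breathing lead-in followed by `n_blocks` cycles of a
#' `hold_s` apnea and a `recovery_s` paced-breathing recovery. The default
#' is five 16 s holds each followed by 34 s of recovery, preceded by a 26 s
#' lead-in so that the task exactly fills a 92-volume acquisition at
#' TR = 3 s.
#'
#' @param n_blocks number of breath-hold blocks.
#' @param hold_s hold (apnea) duration in seconds.
#' @param recovery_s paced-breathing recovery duration after each hold, s.
#' @param lead_in_s paced breathing before the first hold, s.
#' @param breath_period_s paced breathing period, s.
#' @return an object of class `bh_paradigm` with the above fields plus
#'   `total_s`, the total task duration
#'   `lead_in_s + n_blocks * (hold_s + recovery_s)`.
#' @examples
#' p <- bh_paradigm()
#' p$total_s   # 276 s
#' @export
bh_paradigm <- function(n_blocks = 5, hold_s = 16, recovery_s = 34,
                        lead_in_s = 26, breath_period_s = 4) {
  if (n_blocks < 1) stop_cvr("paradigm", "n_blocks must be >= 1")
  durs <- c(hold_s = hold_s, recovery_s = recovery_s,
            lead_in_s = lead_in_s, breath_period_s = breath_period_s)
  if (any(durs[c("hold_s", "recovery_s", "breath_period_s")] <= 0) ||
      lead_in_s < 0)
    stop_cvr("paradigm", "durations must be positive")
  structure(list(
    n_blocks = as.integer(n_blocks), hold_s = hold_s,
    recovery_s = recovery_s, lead_in_s = lead_in_s,
    breath_period_s = breath_period_s,
    total_s = lead_in_s + n_blocks * (hold_s + recovery_s)
  ), class = "bh_paradigm")
}

#' Hold end times of a paradigm
#'
#' @param paradigm a [bh_paradigm()].
#' @return numeric vector of the times (s) at which each hold ends.
#' @export
hold_ends <- function(paradigm) {
  paradigm$lead_in_s +
    (seq_len(paradigm$n_blocks) - 1) * (paradigm$hold_s + paradigm$recovery_s) +
    paradigm$hold_s
}

hold_starts <- function(paradigm) {
  paradigm$lead_in_s +
    (seq_len(paradigm$n_blocks) - 1) * (paradigm$hold_s + paradigm$recovery_s)
}

#' BOLD acquisition parameters
#'
#' @param tr_s repetition time, s.
#' @param n_volumes number of volumes in the 4D series.
#' @param voxel_mm voxel size, mm (length-3).
#' @param grid_shape 3D grid dimensions.
#' @return an `acq_params` object.
#' @examples
#' acq_params()          # 92 volumes at TR = 3 s
#' @export
acq_params <- function(tr_s = 3, n_volumes = 92, voxel_mm = c(3, 3, 3),
                       grid_shape = c(16, 16, 16)) {
  if (tr_s <= 0) stop_cvr("acq", "tr_s must be > 0")
  if (n_volumes < 2) stop_cvr("acq", "n_volumes must be >= 2")
  structure(list(tr_s = tr_s, n_volumes = as.integer(n_volumes),
                 voxel_mm = rep_len(voxel_mm, 3),
                 grid_shape = as.integer(rep_len(grid_shape, 3))),
            class = "acq_params")
}

#' Times (s) of volume-acquisition midpoints
#' @param acq an [acq_params()].
#' @return numeric vector of length `n_volumes`.
#' @export
volume_times <- function(acq) {
  (seq_len(acq$n_volumes) - 0.5) * acq$tr_s
}

#' Canonical HRF parameters
#'
#' Parameters of the double-gamma canonical hemodynamic response function:
#' a positive gamma lobe peaking at `peak_delay_s` minus an undershoot lobe
#' peaking at `undershoot_delay_s`, scaled down by `p_u_ratio`. The kernel
#' is truncated at `length_s` and normalised to unit sum so convolving a
#' sustained step leaves its plateau amplitude (and hence the mmHg scale of
#' a PetCO2 regressor) unchanged.
#'
#' @param peak_delay_s delay of the response peak, s.
#' @param undershoot_delay_s delay of the undershoot, s.
#' @param peak_disp,under_disp dispersions (gamma scale parameters), s.
#' @param p_u_ratio peak-to-undershoot amplitude ratio.
#' @param dt_s sampling interval of the kernel, s.
#' @param length_s truncation length, s.
#' @return an `hrf_params` object.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_disp = 1, under_disp = 1, p_u_ratio = 6,
                       dt_s = 0.1, length_s = 32) {
  vals <- c(peak_delay_s, undershoot_delay_s, peak_disp, under_disp,
            p_u_ratio, dt_s, length_s)
  if (any(vals <= 0)) stop_cvr("hrf", "all HRF parameters must be positive")
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_disp = peak_disp, under_disp = under_disp,
                 p_u_ratio = p_u_ratio, dt_s = dt_s, length_s = length_s),
            class = "hrf_params")
}
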