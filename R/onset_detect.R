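#' Onset-detection configuration
#'
#' Parameters of the slope-sum-function (SSF) onset detector: traces are
#' Savitzky-Golay smoothed (27 frames, order 2), the SSF is the windowed sum
#' of positive slopes over 375 ms, and the onset is the earliest point where
#' the SSF exceeds 10% of its peak, walked back to the preceding local SSF
#' minimum, minus a calibration `correction` (see [calibrate_correction()]).
#'
#' @param ssf_window SSF window, seconds
#' @param sg_frames Savitzky-Golay window, frames (odd, > `sg_order`)
#' @param sg_order Savitzky-Golay polynomial order
#' @param peak_threshold_fraction threshold as a fraction of the SSF peak
#' @param n_boot bootstrap samples for [neuron_median_onset()]
#' @param correction calibration correction, seconds (subtracted from
#'   detected onsets)
#' @param noise_mult peak must exceed `noise_mult` times the median SSF,
#'   otherwise the trace is reported as having no detectable onset
#' @return object of class `onset_config`
#' @export
onset_config <- function(ssf_window = 0.375, sg_frames = 27, sg_order = 2,
                         peak_threshold_fraction = 0.10, n_boot = 10000,
                         correction = 0, noise_mult = 3) {
  stopifnot(ssf_window > 0, sg_order >= 0, n_boot >= 1, noise_mult > 0)
  if (sg_frames %% 2 != 1 || sg_frames <= sg_order)
    stop("sg_frames must be odd and greater than sg_order")
  if (peak_threshold_fraction <= 0 || peak_threshold_fraction >= 1)
    stop("peak_threshold_fraction must be in (0, 1)")
  structure(list(ssf_window = ssf_window, sg_frames = as.integer(sg_frames),
                 sg_order = as.integer(sg_order),
                 peak_threshold_fraction = peak_threshold_fraction,
                 n_boot = as.integer(n_boot), correction = correction,
                 noise_mult = noise_mult),
            class = "onset_config")
}

# vectorized SSF onset detection on a matrix of already-smoothed traces
# (rows = traces); returns one onset time (or NA) per row
ssf_onsets_smoothed <- function(S, time, config, check_noise = TRUE) {
  fr <- 1 / stats::median(diff(time))
  w <- max(1L, round(config$ssf_window * fr))
  nT <- ncol(S)
  if (w >= nT) stop("SSF window is longer than the trace")
  D <- pmax(S[, -1, drop = FALSE] - S[, -nT, drop = FALSE], 0)
  # trailing rolling sum via banded matrix
  m <- ncol(D)
  W <- matrix(0, m, m)
  for (j in seq_len(m)) W[max(1L, j - w + 1L):j, j] <- 1
  ssf <- D %*% W
  peak <- do.call(pmax, as.data.frame(ssf))
  # floor at filter roundoff: constant traces give zero SSF up to eps * |S|
  absmax <- do.call(pmax, as.data.frame(abs(S)))
  ok <- peak > 1e-9 * absmax & peak > 0
  if (check_noise) {
    med <- apply(ssf, 1L, stats::median)
    ok <- ok & !(med > 0 & peak < config$noise_mult * med)
  }
  thr <- config$peak_threshold_fraction * peak
  above <- ssf > thr
  i <- max.col(above, ties.method = "first")   # first crossing per row
  i[!above[cbind(seq_len(nrow(S)), i)]] <- NA_integer_
  # walk back to the preceding local SSF minimum (vectorized)
  act <- which(ok & !is.na(i) & i > 1L)
  repeat {
    if (!length(act)) break
    can <- ssf[cbind(act, i[act] - 1L)] < ssf[cbind(act, i[act])]
    i[act[can]] <- i[act[can]] - 1L
    act <- act[can]
    act <- act[i[act] > 1L]
  }
  out <- rep(NA_real_, nrow(S))
  det <- ok & !is.na(i)
  out[det] <- time[i[det]] - config$correction
  out
}

sg_smooth_rows <- function(M, config) {
  t(apply(M, 1L, function(tr)
    signal::sgolayfilt(tr, p = config$sg_order, n = config$sg_frames)))
}

#' Slope-sum-function onset of a single trace
#'
#' Detects the response onset of one dF/F0 trace (a single trial or a
#' trial-averaged trace): Savitzky-Golay smoothing, SSF (windowed sum of
#' positive slopes), earliest crossing of 10% of the SSF peak walked back to
#' the local SSF minimum, minus the calibration correction.
#'
#' @param trace numeric dF/F0 series
#' @param time time axis, seconds (uniform spacing)
#' @param config an [onset_config()]
#' @return onset time in seconds (same coordinates as `time`), or NA when no
#'   SSF peak exceeds the noise level
#' @export
ssf_onset_single_trial <- function(trace, time, config = onset_config()) {
  stopifnot(length(trace) == length(time))
  if (length(trace) <= config$sg_frames)
    stop("trace is shorter than the Savitzky-Golay window")
  s <- signal::sgolayfilt(trace, p = config$sg_order, n = config$sg_frames)
  ssf_onsets_smoothed(matrix(s, 1), time, config)[1]
}

#' Bootstrap median response onset of a neuron
#'
#' Resamples trials with replacement `config$n_boot` times; for each
#' resample the SSF onset is detected on the resampled trial-averaged
#' (Savitzky-Golay-smoothed) trace, and the neuron onset is the median of
#' the resample onsets. Averaging within resamples suppresses the influence
#' of noisy individual trials, which would otherwise dominate single-trial
#' threshold crossings. Resamples with no detectable onset are excluded; NA
#' is returned when fewer than `min_frac` of the resamples yield an onset.
#'
#' @param trials numeric matrix, trials x time (>= 5 trials)
#' @param time time axis, seconds
#' @param config an [onset_config()]
#' @param min_frac minimum fraction of resamples with a detected onset
#' @return onset time in seconds, or NA
#' @export
neuron_median_onset <- function(trials, time, config = onset_config(),
                                min_frac = 0.5) {
  if (nrow(trials) < 5) return(NA_real_)
  S <- sg_smooth_rows(trials, config)
  # detectability (SSF peak vs noise floor) is judged once on the average
  # trace; resample onsets are then detected without the per-resample check
  if (is.na(ssf_onsets_smoothed(matrix(colMeans(S), 1), time, config)[1]))
    return(NA_real_)
  n <- nrow(S)
  C <- boot_count_matrix(n, config$n_boot) / n
  onsets <- ssf_onsets_smoothed(C %*% S, time, config, check_noise = FALSE)
  det <- onsets[!is.na(onsets)]
  if (length(det) < min_frac * config$n_boot) return(NA_real_)
  stats::median(det)
}

#' Calibrate the onset-detector correction factor
#'
#' Runs the detector on a simulated ramp dataset with known onsets (see
#' [generate_ramp_calibration_set()]) and returns the median signed
#' detection error over cells; storing it as `correction` in the
#' [onset_config()] removes the deterministic bias introduced by filtering
#' and the decision rule.
#'
#' @param calibration_set list with `tensor` (cells x trials x time
#'   [aligned_tensor()]) and `truth` (data.frame with `true_onset`)
#' @param config an [onset_config()] whose `correction` is ignored
#' @param seed optional seed for the bootstrap
#' @return correction in seconds, with attributes `bias_before` (identical:
#'   the raw median signed error), `n_detected`, and `per_cell` errors
#' @export
calibrate_correction <- function(calibration_set, config = onset_config(),
                                 seed = NULL) {
  tens <- calibration_set$tensor
  truth <- calibration_set$truth
  cfg0 <- config
  cfg0$correction <- 0
  n_cells <- dim(tens$data)[1]
  with_seed(seed, {
    err <- rep(NA_real_, n_cells)
    n_det <- 0L
    for (i in seq_len(n_cells)) {
      m <- array(tens$data[i, , , drop = FALSE], dim = dim(tens$data)[2:3])
      on_i <- neuron_median_onset(m, tens$time, cfg0)
      if (!is.na(on_i)) {
        n_det <- n_det + 1L
        err[i] <- on_i - truth$true_onset[i]
      }
    }
    if (n_det < 10) stop("fewer than 10 cells yielded onsets; cannot calibrate")
    corr <- stats::median(err, na.rm = TRUE)
    structure(corr, bias_before = corr, n_detected = n_det, per_cell = err)
  })
}
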