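#' Aligned trial tensor
#'
#' Container for trial-aligned signals: a neurons x trials x time array with a
#' uniform time axis (seconds, zero at the alignment event) and per-trial
#' movement labels.
#'
#' @param data numeric array neurons x trials x time
#' @param time numeric time axis, strictly increasing, uniform spacing
#' @param trial_labels character/factor of length `n_trials` ("push"/"pull"),
#'   or NULL
#' @param alignment one of "motion_onset", "cue", "movement_completion"
#' @return object of class `aligned_tensor`
#' @export
aligned_tensor <- function(data, time,
                           trial_labels = NULL,
                           alignment = c("motion_onset", "cue", "movement_completion")) {
  alignment <- match.arg(alignment)
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(time) != dim(data)[3])
    stop("time axis length must equal the time dimension")
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6)
    stop("time axis must be strictly increasing with uniform spacing")
  if (!is.null(trial_labels) && length(trial_labels) != dim(data)[2])
    stop("trial_labels length must equal the trial dimension")
  structure(list(data = data, time = time,
                 trial_labels = if (is.null(trial_labels)) NULL else as.character(trial_labels),
                 alignment = alignment,
                 frame_rate = 1 / stats::median(dt)),
            class = "aligned_tensor")
}

#' @export
print.aligned_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<aligned_tensor> %d neurons x %d trials x %d frames, %.5g Hz, aligned to %s\n",
              d[1], d[2], d[3], x$frame_rate, x$alignment))
  cat(sprintf("  time: [%.3f, %.3f] s\n", x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' Motion index from a grayscale frame stack
#'
#' The motion index at frame f is the sum over (masked) pixels of the squared
#' intensity difference between consecutive frames:
#' `MI_f = sum_i (c_{f+1,i} - c_{f,i})^2`. One value is produced per
#' consecutive frame pair; smoothing is left to the caller (see
#' [loess_smooth()]).
#'
#' @param frames numeric array height x width x n_frames (grayscale levels)
#' @param roi_mask logical matrix matching the frame shape, or NULL for the
#'   whole frame
#' @param frame_rate acquisition rate, Hz
#' @return object of class `motion_index_series` with fields `values`
#'   (length n_frames - 1) and `frame_rate`
#' @export
compute_motion_index <- function(frames, roi_mask = NULL, frame_rate) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  d <- dim(frames)
  if (d[3] < 2) stop("at least 2 frames are required")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(roi_mask), d[1:2])) stop("roi_mask must match the frame shape")
  if (!any(roi_mask)) stop("roi_mask is empty")
  m <- matrix(frames, d[1] * d[2], d[3])[as.vector(roi_mask), , drop = FALSE]
  dm <- m[, -1, drop = FALSE] - m[, -d[3], drop = FALSE]
  motion_index_series(colSums(dm^2), frame_rate)
}

#' Motion index series container
#' @param values nonnegative motion index values, one per frame pair
#' @param frame_rate Hz
#' @param onset_times optional per-trial onset times, seconds
#' @return object of class `motion_index_series`
#' @export
motion_index_series <- function(values, frame_rate, onset_times = NULL) {
  if (any(values < 0)) stop("motion index values must be nonnegative")
  structure(list(values = as.numeric(values), frame_rate = frame_rate,
                 onset_times = onset_times),
            class = "motion_index_series")
}

# precompute the linear smoother matrix for locally-weighted linear
# regression (tricube weights, fixed window in samples, truncated at the
# boundaries) on a uniform grid of length n
loess_smoother_matrix <- function(n, half_width) {
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - floor(half_width)):min(n, i + floor(half_width))
    d <- (j - i)
    u <- abs(d) / half_width
    w <- (1 - u^3)^3
    w[u >= 1] <- 0
    if (sum(w > 0) < 2) { S[i, i] <- 1; next }
    s0 <- sum(w); s1 <- sum(w * d); s2 <- sum(w * d^2)
    den <- s0 * s2 - s1^2
    if (abs(den) < 1e-12) { S[i, j] <- w / s0 } else {
      S[i, j] <- w * (s2 - s1 * d) / den
    }
  }
  S
}

#' LOESS smoothing with a fixed time window
#'
#' Locally weighted linear regression with tricube weights over a window of
#' `span` seconds centered on each sample; boundary windows are truncated,
#' not padded. Constant and exactly linear series are reproduced.
#'
#' @param x numeric series, or a matrix smoothed row-wise
#' @param span window width, seconds (must cover at least 3 samples)
#' @param frame_rate sampling rate, Hz
#' @return smoothed series (same shape as `x`)
#' @export
loess_smooth <- function(x, span, frame_rate) {
  w_samples <- span * frame_rate
  if (w_samples < 3) stop("span must cover at least 3 samples")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  S <- loess_smoother_matrix(n, w_samples / 2)
  if (is.matrix(x)) x %*% t(S) else as.numeric(S %*% x)
}

#' Normalized fluorescence (dF/F0)
#'
#' Per neuron, the baseline F0 is the 5th percentile of the 1 Hz low-pass
#' filtered raw signal (zero-phase second-order Butterworth), and
#' dF/F0 = (F - F0) / F0.
#'
#' @param raw positive numeric matrix, neurons x frames (a vector is treated
#'   as one neuron)
#' @param frame_rate acquisition rate, Hz (> 2)
#' @return object of class `dff_traces` with fields `dff`, `f0`, `frame_rate`
#' @export
compute_dff <- function(raw, frame_rate) {
  if (is.vector(raw)) raw <- matrix(raw, nrow = 1)
  if (any(raw <= 0)) stop("raw fluorescence must be positive")
  if (frame_rate <= 2) stop("frame_rate must exceed 2 Hz (1 Hz low-pass)")
  if (ncol(raw) / frame_rate < 10) stop("recording must be at least 10 s long")
  bf <- signal::butter(2, 1 / (frame_rate / 2), type = "low")
  # reflection padding suppresses filtfilt edge transients
  pad <- min(ncol(raw) - 1, ceiling(5 * frame_rate))
  f0 <- apply(raw, 1L, function(v) {
    vp <- c(rev(v[seq_len(pad)]), v, rev(v[(length(v) - pad + 1):length(v)]))
    f <- signal::filtfilt(bf, vp)[(pad + 1):(pad + length(v))]
    stats::quantile(f, 0.05, names = FALSE)
  })
  dff <- sweep(sweep(raw, 1L, f0, "-"), 1L, f0, "/")
  structure(list(dff = dff, f0 = f0, frame_rate = frame_rate),
            class = "dff_traces")
}

#' Detect the motion-index onset of one trial
#'
#' Imaging mode: the baseline is the inter-trial segment before the cue
#' (`baseline_s` seconds); the threshold is the upper bound of a percentile
#' bootstrap 95% CI of the baseline mean of the 1 s LOESS-smoothed motion
#' index, and the onset is the start of the suprathreshold run that leads
#' into the lever movement.
#'
#' Ephys mode: the threshold is the baseline mean + 2 SD (baseline = 1.5 s
#' before cue, unsmoothed) and the onset is the first suprathreshold point
#' after the cue; if the motion index is already above threshold at the cue
#' the trial is flagged for exclusion (attribute `excluded`).
#'
#' @param mi a [motion_index_series()]
#' @param trial list or one-row data.frame with `cue_s` and the lever
#'   movement time (`move_s`, falling back to `completion_s`)
#' @param mode "imaging" or "ephys"
#' @param baseline_s baseline window length before the cue, seconds
#' @param n_boot bootstrap samples for the imaging-mode CI
#' @param span smoothing window for imaging mode, seconds
#' @return onset time in seconds, or NA if the threshold is never crossed;
#'   ephys-mode onsets carry an `excluded` attribute
#' @export
detect_motion_onset <- function(mi, trial, mode = c("imaging", "ephys"),
                                baseline_s = 1.5, n_boot = 10000, span = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(mi, "motion_index_series"))
  fr <- mi$frame_rate
  v <- mi$values
  cue <- as.numeric(trial$cue_s)
  move <- as.numeric(trial$move_s %||% trial$completion_s)
  if (is.na(cue) || is.na(move) || cue >= move)
    stop("trial must have cue before lever movement")
  fidx <- function(t) round(t * fr) + 1L
  b0 <- fidx(cue - baseline_s); b1 <- fidx(cue) - 1L
  if (b0 < 1 || b1 > length(v)) stop("baseline window out of range")
  mf <- min(fidx(move), length(v))

  if (mode == "imaging") {
    seg0 <- max(1L, b0 - round(span * fr))
    seg1 <- min(length(v), mf + round(span * fr))
    sm <- loess_smooth(v[seg0:seg1], span, fr)
    at <- function(f) sm[f - seg0 + 1L]
    base <- sm[(b0:b1) - seg0 + 1L]
    thr <- percentile_ci(boot_means(base, n_boot), 95)[2]
    eps <- 1e-9 * (abs(thr) + 1)   # guard against smoother roundoff
    search <- fidx(cue):mf
    above <- vapply(search, at, numeric(1)) > thr + eps
    if (!any(above)) return(NA_real_)
    last <- max(which(above))
    i <- last
    while (i > 1 && above[i - 1]) i <- i - 1
    # the smoothing window backdates the CI crossing; refine within the
    # suprathreshold run to the raw motion index's sustained (75 ms)
    # departure from baseline, so isolated noise excursions cannot backdate
    # the onset
    base_raw <- v[b0:b1]
    thr_raw <- max(thr, mean(base_raw) + 2 * stats::sd(base_raw))
    run <- search[i]:search[last]
    above_raw <- v[run] > thr_raw + eps
    sus <- min(max(1L, round(0.075 * fr)), length(run))
    streak <- as.numeric(stats::filter(as.numeric(above_raw), rep(1, sus),
                                       sides = 1))
    hit <- which(streak == sus)
    f_on <- if (length(hit)) run[hit[1] - sus + 1L] else search[i]
    (f_on - 1L) / fr
  } else {
    base <- v[b0:b1]
    thr <- mean(base) + 2 * stats::sd(base)
    cf <- fidx(cue)
    excluded <- v[cf] > thr
    search <- cf:mf
    hit <- which(v[search] > thr)
    if (!length(hit)) return(structure(NA_real_, excluded = excluded))
    structure((search[hit[1]] - 1L) / fr, excluded = excluded)
  }
}

#' Align traces to per-trial events
#'
#' Slices the signal around each event without interpolation; the time axis
#' is zero at the event. Trials whose window falls outside the recording are
#' kept, filled with NA and reported in the `flagged_trials` attribute.
#'
#' @param x a [compute_dff()] result, or a numeric matrix neurons x frames
#' @param events event times, seconds (one per trial; frame 0 is time 0)
#' @param window c(pre, post) seconds
#' @param frame_rate required when `x` is a plain matrix
#' @param trial_labels optional "push"/"pull" labels per trial
#' @param alignment alignment event name stored in the tensor
#' @return an [aligned_tensor()]
#' @export
align_trials <- function(x, events, window, frame_rate = NULL,
                         trial_labels = NULL, alignment = "motion_onset") {
  if (inherits(x, "dff_traces")) { frame_rate <- x$frame_rate; x <- x$dff }
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.null(frame_rate)) stop("frame_rate is required for matrix input")
  n_pre <- round(window[1] * frame_rate); n_post <- round(window[2] * frame_rate)
  tt <- (-n_pre:n_post) / frame_rate
  out <- array(NA_real_, dim = c(nrow(x), length(events), length(tt)))
  flagged <- integer(0)
  for (k in seq_along(events)) {
    f <- round(events[k] * frame_rate) + 1L
    lo <- f - n_pre; hi <- f + n_post
    if (is.na(f) || lo < 1 || hi > ncol(x)) { flagged <- c(flagged, k); next }
    out[, k, ] <- x[, lo:hi, drop = FALSE]
  }
  at <- aligned_tensor(out, tt, trial_labels = trial_labels, alignment = alignment)
  attr(at, "flagged_trials") <- flagged
  at
}

#' Resample variable-length trials to a fixed length
#'
#' Linear interpolation of each trial onto `n_out` equally spaced points
#' spanning the trial (endpoints preserved).
#'
#' @param trials list of numeric series (each with >= 2 samples)
#' @param n_out output length (>= 2)
#' @return matrix n_trials x n_out
#' @export
resample_trials_fixed_length <- function(trials, n_out) {
  if (n_out < 2) stop("n_out must be >= 2")
  do.call(rbind, lapply(trials, function(tr) {
    if (length(tr) < 2) stop("each trial must have at least 2 samples")
    stats::approx(seq_along(tr), tr, xout = seq(1, length(tr), length.out = n_out))$y
  }))
}
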