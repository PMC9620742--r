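#' Synthetic session configuration
#'
#' Defines the generative model for a synthetic push/pull imaging session:
#' trial structure (alternating cued push and pull movements separated by
#' randomized 4-6 s inter-trial intervals), GCaMP6s-like calcium transients
#' (difference-of-exponentials kernel with a 0.5 s rise), planted neuron
#' classes with known response amplitudes, per-trial onset jitter, ROI
#' centroid positions in a field of view, and a forelimb motion index locked
#' to movement initiation.
#'
#' Neuron classes and their planted push/pull transient amplitudes (in units
#' of `effect_amplitude` A; suppressed amplitudes are clamped at -0.35 dF/F0
#' so fluorescence stays positive):
#' \itemize{
#'   \item `invariant_up` (A, A), `invariant_down` (-A, -A)
#'   \item `push_type1` (A, A/2): increased in both, larger for push
#'   \item `push_type2` (A, 0): selective increase for push
#'   \item `push_type3` (-A, 0): selective decrease for push
#'   \item `push_type4` (-A, -A/2): decreased in both, deeper for push
#'   \item `pull_type1..4`: mirror images
#'   \item `reward_phase`: transient starting 1.1 s after movement completion
#'   \item `non_responsive`: baseline only
#' }
#'
#' @param n_neurons number of neurons
#' @param class_proportions named numeric vector over the class enumeration
#'   above, summing to 1
#' @param n_push_trials,n_pull_trials trial counts per movement (>= 2 each)
#' @param frame_rate imaging rate, Hz
#' @param trial_window c(pre, post) seconds around movement initiation used by
#'   downstream alignment defaults
#' @param kernel_rise,kernel_decay transient kernel time constants, seconds
#' @param effect_amplitude planted transient amplitude, dF/F0 units
#' @param noise_sd i.i.d. Gaussian noise SD, dF/F0 units
#' @param onset_jitter_sd per-neuron-per-trial onset jitter SD, seconds
#' @param fov_size field of view c(width, height), micrometers
#' @param spatial_clustering logical; when TRUE neurons of the same class are
#'   placed around per-class cluster centers
#' @param cluster_radius cluster SD scale, micrometers (used when clustering on)
#' @param baseline_f baseline fluorescence, arbitrary units
#' @param reward_offset seconds after movement completion at which
#'   reward-phase transients start
#' @param seed integer RNG seed recorded in session metadata
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_neurons = 100,
                         class_proportions = c(
                           invariant_up = 0.45, invariant_down = 0.08,
                           push_type1 = 0.08, push_type2 = 0.03,
                           push_type3 = 0.015, push_type4 = 0.005,
                           pull_type1 = 0.08, pull_type2 = 0.03,
                           pull_type3 = 0.015, pull_type4 = 0.005,
                           reward_phase = 0.10, non_responsive = 0.11),
                         n_push_trials = 40, n_pull_trials = 40,
                         frame_rate = 40,
                         trial_window = c(2.5, 5),
                         kernel_rise = 0.5, kernel_decay = 1.5,
                         effect_amplitude = 1.0, noise_sd = 0.2,
                         onset_jitter_sd = 0.05,
                         fov_size = c(250, 250),
                         spatial_clustering = FALSE, cluster_radius = 50,
                         baseline_f = 100, reward_offset = 1.1,
                         seed = 1L) {
  cls <- neuron_classes()
  if (!all(names(class_proportions) %in% cls) || anyNA(class_proportions))
    stop("class_proportions must be named by the neuron class enumeration")
  p <- stats::setNames(numeric(length(cls)), cls)
  p[names(class_proportions)] <- class_proportions
  if (abs(sum(p) - 1) > 1e-9) stop("class_proportions must sum to 1 (within 1e-9)")
  if (any(p < 0)) stop("class_proportions must be nonnegative")
  stopifnot(kernel_rise > 0, kernel_decay > 0, noise_sd >= 0, frame_rate > 0,
            kernel_decay > kernel_rise, effect_amplitude >= 0, baseline_f > 0,
            n_neurons >= 1, length(trial_window) == 2, all(trial_window > 0))
  if (n_push_trials < 2 || n_pull_trials < 2)
    stop("at least 2 trials per movement type are required")
  structure(list(
    n_neurons = as.integer(n_neurons), class_proportions = p,
    n_push_trials = as.integer(n_push_trials),
    n_pull_trials = as.integer(n_pull_trials),
    frame_rate = frame_rate, trial_window = trial_window,
    kernel_rise = kernel_rise, kernel_decay = kernel_decay,
    effect_amplitude = effect_amplitude, noise_sd = noise_sd,
    onset_jitter_sd = onset_jitter_sd, fov_size = fov_size,
    spatial_clustering = isTRUE(spatial_clustering),
    cluster_radius = cluster_radius, baseline_f = baseline_f,
    reward_offset = reward_offset, seed = as.integer(seed)),
    class = "synth_config")
}

neuron_classes <- function() {
  c("invariant_up", "invariant_down",
    "push_type1", "push_type2", "push_type3", "push_type4",
    "pull_type1", "pull_type2", "pull_type3", "pull_type4",
    "reward_phase", "non_responsive")
}

# deterministic largest-remainder allocation of n items to proportions
allocate_classes <- function(n, props) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(frac, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# planted (push, pull) dF/F0 amplitudes for a class
class_amplitudes <- function(class, A) {
  Ad <- -min(A, 0.35)
  switch(class,
    invariant_up   = c(A, A),
    invariant_down = c(Ad, Ad),
    push_type1 = c(A, A / 2),  push_type2 = c(A, 0),
    push_type3 = c(Ad, 0),     push_type4 = c(Ad, Ad / 2),
    pull_type1 = c(A / 2, A),  pull_type2 = c(0, A),
    pull_type3 = c(0, Ad),     pull_type4 = c(Ad / 2, Ad),
    reward_phase = c(A, A),
    non_responsive = c(0, 0),
    stop("unknown class: ", class))
}

# difference-of-exponentials transient kernel sampled at the frame rate,
# normalized to unit peak
calcium_kernel <- function(rise, decay, frame_rate) {
  tt <- seq(0, rise + 5 * decay, by = 1 / frame_rate)
  k <- exp(-tt / decay) - exp(-tt / rise)
  k / max(k)
}

#' Generate a synthetic push/pull imaging session with ground truth
#'
#' Builds a continuous recording: per-neuron fluorescence is
#' `baseline_f * (1 + planted dF/F0 signal) + Gaussian noise`, where the
#' planted signal is a calcium-transient kernel scaled by the neuron's
#' class-dependent push/pull amplitude at each (jittered) movement
#' initiation (or 1.1 s after completion for reward-phase neurons). The
#' trial table alternates push and pull with ITIs drawn uniformly from
#' [4, 6] s, and the emitted motion index rises at each movement initiation.
#' Identical seeds give bit-identical output.
#'
#' @param config a [synth_config()]
#' @return list with elements `session` (class `session_data`) and
#'   `truth` (class `ground_truth`, one row per neuron with true class,
#'   onset, push/pull amplitudes and centroid)
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_session_impl(config))
}

generate_session_impl <- function(cfg) {
  fr <- cfg$frame_rate
  counts <- allocate_classes(cfg$n_neurons, cfg$class_proportions)
  classes <- rep(names(cfg$class_proportions), counts)
  classes <- sample(classes)   # seeded shuffle; counts unchanged

  # trial schedule: alternate push/pull until one type is exhausted
  n_tot <- cfg$n_push_trials + cfg$n_pull_trials
  type <- character(n_tot)
  np <- nl <- 0L
  for (k in seq_len(n_tot)) {
    want_push <- (k %% 2L == 1L)
    if ((want_push && np < cfg$n_push_trials) || nl >= cfg$n_pull_trials) {
      type[k] <- "push"; np <- np + 1L
    } else {
      type[k] <- "pull"; nl <- nl + 1L
    }
  }
  t_end <- 10
  cue <- init <- comp <- numeric(n_tot)
  for (k in seq_len(n_tot)) {
    iti <- stats::runif(1, 4, 6)
    cue[k] <- t_end + iti
    init[k] <- cue[k] + stats::runif(1, 0.2, 0.5)
    comp[k] <- init[k] + stats::runif(1, 0.3, 0.6)
    t_end <- comp[k] + cfg$reward_offset + 1.4
  }
  n_frames <- as.integer(ceiling((t_end + 10) * fr))
  trials <- data.frame(trial_id = seq_len(n_tot), type = type,
                       cue_s = cue, motion_onset_s = init,
                       completion_s = comp, outcome = "success",
                       stringsAsFactors = FALSE)

  kern <- calcium_kernel(cfg$kernel_rise, cfg$kernel_decay, fr)
  lk <- length(kern)
  amps <- t(vapply(classes, class_amplitudes, numeric(2), A = cfg$effect_amplitude))
  colnames(amps) <- c("push", "pull")

  jitter <- if (cfg$onset_jitter_sd > 0)
    matrix(stats::rnorm(cfg$n_neurons * n_tot, 0, cfg$onset_jitter_sd),
           cfg$n_neurons, n_tot) else matrix(0, cfg$n_neurons, n_tot)

  dff_sig <- matrix(0, cfg$n_neurons, n_frames)
  for (i in seq_len(cfg$n_neurons)) {
    cl <- classes[i]
    for (k in seq_len(n_tot)) {
      a <- amps[i, type[k]]
      ev <- if (cl == "reward_phase") comp[k] + cfg$reward_offset else init[k]
      if (a == 0) next
      f0 <- round((ev + jitter[i, k]) * fr) + 1L
      idx <- f0:min(f0 + lk - 1L, n_frames)
      if (f0 < 1L) next
      dff_sig[i, idx] <- dff_sig[i, idx] + a * kern[seq_along(idx)]
    }
  }
  raw <- cfg$baseline_f * (1 + dff_sig)
  if (cfg$noise_sd > 0)
    raw <- raw + matrix(stats::rnorm(length(raw), 0, cfg$noise_sd * cfg$baseline_f),
                        nrow(raw), ncol(raw))
  raw <- pmax(raw, 1)

  # motion index: near-baseline except a pulse rising at movement initiation
  mi <- numeric(n_frames)
  for (k in seq_len(n_tot)) {
    a <- round(init[k] * fr) + 1L
    b <- min(round((comp[k] + 0.2) * fr) + 1L, n_frames)
    mi[a:b] <- 1
    dec <- b + seq_len(round(0.3 * fr))
    dec <- dec[dec <= n_frames]
    mi[dec] <- pmax(mi[dec], rev(seq_along(dec)) / (length(dec) + 1))
  }
  if (cfg$noise_sd > 0) mi <- pmax(mi + stats::rnorm(n_frames, 0, 0.02), 0)

  centroids <- synth_centroids(classes, cfg)

  session <- session_data(
    raw_f = raw, frame_rate = fr, trials = trials, centroids = centroids,
    cell_class = NULL, motion_index = mi,
    meta = list(seed = cfg$seed, animal_id = "synthetic", fov_id = "synthetic-1",
                schema_version = "1.0",
                provenance = "lever2p::generate_session"))

  true_onset <- ifelse(classes == "reward_phase",
                       stats::median(comp - init) + cfg$reward_offset,
                       ifelse(classes == "non_responsive", NA_real_, 0))
  truth <- data.frame(neuron = seq_len(cfg$n_neurons), true_class = classes,
                      true_onset = true_onset,
                      true_amplitude_push = amps[, "push"],
                      true_amplitude_pull = amps[, "pull"],
                      x_um = centroids[, 1], y_um = centroids[, 2],
                      stringsAsFactors = FALSE)
  class(truth) <- c("ground_truth", "data.frame")
  list(session = session, truth = truth)
}

synth_centroids <- function(classes, cfg) {
  n <- length(classes)
  if (!cfg$spatial_clustering) {
    cbind(x_um = stats::runif(n, 0, cfg$fov_size[1]),
          y_um = stats::runif(n, 0, cfg$fov_size[2]))
  } else {
    ucls <- unique(classes)
    cx <- stats::runif(length(ucls), 0, cfg$fov_size[1])
    cy <- stats::runif(length(ucls), 0, cfg$fov_size[2])
    names(cx) <- names(cy) <- ucls
    x <- pmin(pmax(cx[classes] + stats::rnorm(n, 0, cfg$cluster_radius / 2), 0),
              cfg$fov_size[1])
    y <- pmin(pmax(cy[classes] + stats::rnorm(n, 0, cfg$cluster_radius / 2), 0),
              cfg$fov_size[2])
    cbind(x_um = unname(x), y_um = unname(y))
  }
}

#' Generate the linear-ramp onset-calibration dataset
#'
#' Each trial is a flat zero baseline followed by a linear ramp of duration
#' `rise` starting at a known per-cell onset time, holding at unit amplitude
#' afterwards, plus i.i.d. Gaussian noise. Used to calibrate the slope-sum
#' onset detector (see [calibrate_correction()]).
#'
#' @param n_cells,n_trials design size (the reference design is 100 cells
#'   with 30 trials each)
#' @param rise ramp duration, seconds (> 0)
#' @param noise_sd trace noise SD, dF/F0 units
#' @param frame_rate sampling rate, Hz
#' @param seed integer seed
#' @param window c(pre, post) seconds covered by each trial around time zero
#' @return list with `tensor` (an [aligned_tensor()], cells x trials x time)
#'   and `truth` (data.frame with per-cell `true_onset` seconds)
#' @export
generate_ramp_calibration_set <- function(n_cells = 100, n_trials = 30,
                                          rise = 0.5, noise_sd = 0.2,
                                          frame_rate = 30, seed = 1L,
                                          window = c(2, 3)) {
  stopifnot(n_cells >= 1, n_trials >= 1)
  if (rise <= 0) stop("rise must be > 0")
  with_seed(seed, {
    tt <- seq(-window[1], window[2], by = 1 / frame_rate)
    onsets <- stats::runif(n_cells, -0.5, 0.5)
    dat <- array(0, dim = c(n_cells, n_trials, length(tt)))
    for (i in seq_len(n_cells)) {
      ramp <- pmin(pmax((tt - onsets[i]) / rise, 0), 1)
      for (j in seq_len(n_trials)) {
        tr <- ramp
        if (noise_sd > 0) tr <- tr + stats::rnorm(length(tt), 0, noise_sd)
        dat[i, j, ] <- tr
      }
    }
    list(tensor = aligned_tensor(dat, tt,
                                 trial_labels = rep("push", n_trials),
                                 alignment = "motion_onset"),
         truth = data.frame(cell = seq_len(n_cells), true_onset = onsets))
  })
}
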