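#' Epoch specification for response classification
#'
#' Baseline and peri-movement epochs relative to motion-index onset. The
#' defaults are a (-0.500, -0.150) s baseline and a peri-movement window from
#' -0.150 s to 40 ms after the median movement completion, analysed in
#' 250 ms bins (only full bins are used). Windows are half-open
#' `[start, end)`.
#'
#' @param peri_end end of the peri-movement window, seconds (median movement
#'   completion + 0.040 s)
#' @param baseline c(start, end) seconds
#' @param peri_start start of the peri-movement window, seconds
#' @param bin_width bin width, seconds
#' @return object of class `epoch_spec`
#' @export
epoch_spec <- function(peri_end, baseline = c(-0.500, -0.150),
                       peri_start = -0.150, bin_width = 0.250) {
  stopifnot(baseline[1] < baseline[2], bin_width > 0)
  if (baseline[2] > peri_start) stop("baseline must precede the peri-movement epoch")
  if (floor((peri_end - peri_start) / bin_width + 1e-9) < 1)
    stop("peri-movement epoch must contain at least one full bin")
  structure(list(baseline = baseline, peri = c(peri_start, peri_end),
                 bin_width = bin_width),
            class = "epoch_spec")
}

epoch_bin_starts <- function(epochs) {
  k <- floor((epochs$peri[2] - epochs$peri[1]) / epochs$bin_width + 1e-9)
  epochs$peri[1] + (seq_len(k) - 1) * epochs$bin_width
}

#' Percentile bootstrap confidence interval
#'
#' @param values numeric sample (>= 2 values)
#' @param n_boot bootstrap resamples
#' @param level confidence level, percent
#' @param statistic statistic function (default mean, computed by a fast
#'   vectorized path)
#' @return c(lo, hi)
#' @export
bootstrap_ci <- function(values, n_boot = 10000, level = 95, statistic = mean) {
  if (length(values) < 2) stop("at least 2 values are required")
  stats_b <- if (identical(statistic, mean)) boot_means(values, n_boot)
  else {
    n <- length(values)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    apply(idx, 1L, function(j) statistic(values[j]))
  }
  percentile_ci(stats_b, level)
}

# --- internal machinery for the two bootstrap classification methods ------

# bootstrap baseline-to-peak statistics for one movement:
# resample trials, average, find the largest |deviation from baseline| in the
# peri window, return the mean of the 100 ms centered on it minus the
# baseline mean; one value per bootstrap resample plus the point estimate
btp_bootstrap <- function(mat, time, epochs, n_boot) {
  fr <- 1 / stats::median(diff(time))
  bl <- time >= epochs$baseline[1] & time < epochs$baseline[2]
  pr <- time >= epochs$peri[1] & time < epochs$peri[2]
  w100 <- max(1L, round(0.1 * fr))
  n <- nrow(mat)
  C <- boot_count_matrix(n, n_boot) / n
  Mb <- C %*% mat[, bl, drop = FALSE]
  Mp <- C %*% mat[, pr, drop = FALSE]
  b <- rowMeans(Mb)
  dev <- Mp - b
  # centered 100 ms rolling mean across peri columns (truncated at edges)
  Tp <- ncol(Mp)
  B <- matrix(0, Tp, Tp)
  h <- (w100 - 1) %/% 2
  for (j in seq_len(Tp)) {
    jj <- max(1L, j - h):min(Tp, j + h + (w100 - 1) %% 2)
    B[jj, j] <- 1 / length(jj)
  }
  RM <- dev %*% B
  pk <- max.col(abs(dev), ties.method = "first")
  stat_b <- RM[cbind(seq_len(n_boot), pk)]

  # point estimate on the un-resampled data
  m0 <- colMeans(mat[, pr, drop = FALSE]) - mean(mat[, bl, drop = FALSE])
  pk0 <- which.max(abs(m0))
  est <- as.numeric(m0 %*% B[, pk0])
  list(boot = stat_b, estimate = est)
}

# per-trial bin means within the peri window (one column per full bin) and
# per-trial baseline means
trial_bin_means <- function(mat, time, epochs) {
  starts <- epoch_bin_starts(epochs)
  X <- vapply(starts, function(s) {
    idx <- time >= s & time < s + epochs$bin_width
    rowMeans(mat[, idx, drop = FALSE])
  }, numeric(nrow(mat)))
  if (is.null(dim(X))) X <- matrix(X, nrow = nrow(mat))
  bl <- time >= epochs$baseline[1] & time < epochs$baseline[2]
  list(bins = X, baseline = rowMeans(mat[, bl, drop = FALSE]), starts = starts)
}

ci_excludes_zero <- function(ci) !is.na(ci[1]) && (ci[1] > 0 || ci[2] < 0)

#' Bootstrap response classification of one neuron for one movement
#'
#' Two independent tests against the baseline epoch, each with `n_boot`
#' trial resamples: (1) the 95% CI of the bootstrapped baseline-to-peak
#' value (mean of the 100 ms centered on the largest absolute deviation from
#' baseline within the peri-movement window, minus the baseline mean) must
#' exclude 0; (2) for each 250 ms peri-movement bin, the bootstrapped
#' distribution of the bin mean is compared with the bootstrapped
#' distribution of the baseline mean, a bin being significant when the two
#' 95% percentile CIs are disjoint.
#' The neuron is significant if either method fires; the sign is the sign of
#' the firing contrast. No multiple-testing correction is applied across
#' bins.
#'
#' @param mat numeric matrix, trials x time (one neuron, one movement)
#' @param time time axis, seconds, zero at motion-index onset
#' @param epochs an [epoch_spec()]
#' @param n_boot bootstrap resamples per method
#' @return list with `significant`, `sign` (+1/-1/0), and `detail` (per
#'   method estimates and CIs). With fewer than 5 trials the neuron is
#'   unclassifiable: `significant` is NA.
#' @export
classify_response <- function(mat, time, epochs, n_boot = 10000) {
  if (epochs$baseline[1] < time[1] || epochs$peri[2] > time[length(time)] + 1e-9)
    stop("epochs outside the aligned window")
  if (nrow(mat) < 5)
    return(list(significant = NA, sign = NA_real_,
                detail = list(reason = "fewer than 5 trials")))
  m1 <- btp_bootstrap(mat, time, epochs, n_boot)
  ci1 <- percentile_ci(m1$boot, 95)
  sig1 <- ci_excludes_zero(ci1)

  tb <- trial_bin_means(mat, time, epochs)
  n <- nrow(mat)
  Cx <- boot_count_matrix(n, n_boot) / n
  Cb <- boot_count_matrix(n, n_boot) / n
  bci <- percentile_ci(Cb %*% tb$baseline, 95)
  ci2 <- apply(Cx %*% tb$bins, 2L, percentile_ci, level = 95)
  sig2 <- ci2[1, ] > bci[2] | ci2[2, ] < bci[1]   # disjoint 95% CIs
  est2 <- colMeans(tb$bins) - mean(tb$baseline)

  significant <- sig1 || any(sig2)
  sgn <- 0
  if (sig1) sgn <- sign(m1$estimate)
  else if (any(sig2)) sgn <- sign(est2[which.max(abs(est2) * sig2)])
  list(significant = significant, sign = sgn,
       detail = list(
         method1 = list(estimate = m1$estimate, ci = ci1, significant = sig1),
         method2 = list(bin_starts = tb$starts, estimates = est2,
                        ci = ci2, significant = sig2),
         n_trials = n))
}

#' Assign responsiveness from significance and onset
#'
#' Non-responsive when neither movement shows a significant response;
#' reward-phase when significant but the median response onset falls after
#' the median movement completion plus 40 ms; movement-related otherwise
#' (including when no onset could be detected).
#'
#' @param sig_push,sig_pull logical significance per movement (NA treated as
#'   FALSE)
#' @param median_onset neuron median onset, seconds (NA allowed)
#' @param median_completion median movement completion, seconds
#' @param rise_correction GCaMP rise allowance, seconds
#' @return one of "non_responsive", "reward_phase", "movement_related"
#' @export
assign_responsiveness <- function(sig_push, sig_pull, median_onset,
                                  median_completion, rise_correction = 0.040) {
  sig <- isTRUE(sig_push) || isTRUE(sig_pull)
  if (!sig) return("non_responsive")
  if (!is.na(median_onset) && median_onset > median_completion + rise_correction)
    return("reward_phase")
  "movement_related"
}

#' Classify movement bias of a movement-related neuron
#'
#' Applies the same two bootstrap methods to the push-vs-pull contrast:
#' (1) the difference of the two movements' bootstrapped baseline-to-peak
#' values (independent trial resamples per movement; 95% CI excluding 0);
#' (2) per 250 ms bin, the movements' bootstrapped baseline-corrected bin
#' means compared via disjoint 95% CIs (baseline subtraction keeps
#' resting-level differences between trial types out of the bias test).
#' If either contrast is significant the neuron is biased toward the
#' movement with the larger absolute baseline-to-peak response; otherwise it
#' is movement-invariant.
#'
#' @param push_mat,pull_mat trials x time matrices per movement (>= 5 trials
#'   each)
#' @param time time axis, seconds
#' @param epochs an [epoch_spec()]
#' @param n_boot bootstrap resamples
#' @return list with `bias` ("invariant", "push", "pull") and `detail`
#' @export
classify_bias <- function(push_mat, pull_mat, time, epochs, n_boot = 10000) {
  if (nrow(push_mat) < 5 || nrow(pull_mat) < 5)
    stop("at least 5 trials of each movement are required")
  bp <- btp_bootstrap(push_mat, time, epochs, n_boot)
  bl <- btp_bootstrap(pull_mat, time, epochs, n_boot)
  ci1 <- percentile_ci(bp$boot - bl$boot, 95)
  sig1 <- ci_excludes_zero(ci1)

  tp <- trial_bin_means(push_mat, time, epochs)
  tq <- trial_bin_means(pull_mat, time, epochs)
  Xp <- tp$bins - tp$baseline   # baseline-corrected per-trial bin responses
  Xq <- tq$bins - tq$baseline
  Cp <- boot_count_matrix(nrow(Xp), n_boot) / nrow(Xp)
  Cq <- boot_count_matrix(nrow(Xq), n_boot) / nrow(Xq)
  cip <- apply(Cp %*% Xp, 2L, percentile_ci, level = 95)
  ciq <- apply(Cq %*% Xq, 2L, percentile_ci, level = 95)
  sig2 <- cip[1, ] > ciq[2, ] | ciq[1, ] > cip[2, ]   # disjoint 95% CIs
  ci2 <- rbind(cip[1, ] - ciq[2, ], cip[2, ] - ciq[1, ])

  significant <- sig1 || any(sig2)
  bias <- if (!significant) "invariant"
  else if (abs(bp$estimate) >= abs(bl$estimate)) "push" else "pull"
  list(bias = bias,
       detail = list(
         method1 = list(estimate = bp$estimate - bl$estimate, ci = ci1,
                        significant = sig1),
         method2 = list(bin_starts = tp$starts,
                        estimates = colMeans(Xp) - colMeans(Xq),
                        ci = ci2, significant = sig2)))
}

#' Assign the movement-bias type (1-4)
#'
#' Type 1: significant increase during both movements. Type 2: significant
#' increase during exactly one movement, no response during the other.
#' Type 3: significant decrease during exactly one movement, no response
#' during the other. Type 4: significant decrease during both movements.
#' A mixed increase/decrease pair is mapped to type 2 (a selective increase
#' exists); this convention is recorded here because the taxonomy does not
#' name that case.
#'
#' @param sig_push,sig_pull per-movement significance flags
#' @param sign_push,sign_pull per-movement response signs (+1/-1)
#' @return integer 1-4, or NA when neither movement is significant
#' @export
assign_bias_type <- function(sig_push, sign_push, sig_pull, sign_pull) {
  sig_push <- isTRUE(sig_push); sig_pull <- isTRUE(sig_pull)
  if (sig_push && (is.na(sign_push) || sign_push == 0) ||
      sig_pull && (is.na(sign_pull) || sign_pull == 0))
    stop("significant response without a sign")
  if (!sig_push && !sig_pull) return(NA_integer_)
  if (sig_push && sig_pull) {
    if (sign_push > 0 && sign_pull > 0) return(1L)
    if (sign_push < 0 && sign_pull < 0) return(4L)
    return(2L)   # mixed increase/decrease: documented convention
  }
  s <- if (sig_push) sign_push else sign_pull
  if (s > 0) 2L else 3L
}

#' Putative pyramidal unit by spike width
#'
#' @param median_spike_width_ms trough-to-peak width, milliseconds (> 0)
#' @return TRUE iff the width is strictly greater than 0.4 ms
#' @export
is_putative_pyramidal <- function(median_spike_width_ms) {
  if (any(median_spike_width_ms <= 0)) stop("spike width must be positive")
  median_spike_width_ms > 0.4
}

#' Classify a spiking unit as movement-responsive and push/pull-biased
#'
#' Firing rates are computed by convolving motion-index-onset-aligned spike
#' times with a 50 ms Gaussian kernel. Per 250 ms bin tiling the response
#' period (extending back from the latest median movement completion to
#' include the motion-index onset), the mean rate change versus a 1 s
#' pre-cue baseline is bootstrapped; the unit is responsive if at least one
#' bin's 95% CI excludes 0 for either movement, and biased when the push and
#' pull CIs are disjoint in a responsive bin (toward the larger change).
#'
#' @param spike_times list of numeric spike-time vectors (seconds, session
#'   clock), one per trial
#' @param trials data.frame with `type`, `cue_s`, `completion_s`
#' @param mi_onsets motion-index onset per trial, seconds (NA = undetected;
#'   onsets before the cue are excluded)
#' @param n_boot bootstrap resamples
#' @param kernel_sd Gaussian kernel SD, seconds
#' @param dt rate sampling step, seconds
#' @return list with `responsive`, `bias` ("push"/"pull"/"none") and
#'   `detail`; an empty spike train gives `responsive = FALSE`
#' @export
classify_unit_firing <- function(spike_times, trials, mi_onsets,
                                 n_boot = 10000, kernel_sd = 0.050, dt = 0.010) {
  stopifnot(length(spike_times) == nrow(trials),
            length(mi_onsets) == nrow(trials))
  ok <- !is.na(mi_onsets) & mi_onsets >= trials$cue_s
  if (sum(ok & trials$type == "push") < 5 || sum(ok & trials$type == "pull") < 5)
    stop("at least 5 valid trials per movement are required")
  tr <- trials[ok, ]; st <- spike_times[ok]; on <- mi_onsets[ok]

  comp_rel <- tr$completion_s - on
  resp_end <- max(stats::median(comp_rel[tr$type == "push"]),
                  stats::median(comp_rel[tr$type == "pull"]))
  k_bins <- ceiling(resp_end / 0.250)
  bin_starts <- resp_end - (k_bins:1) * 0.250   # tile back to include onset

  # per-trial rate change per bin (vs 1 s pre-cue baseline)
  kt <- seq(-4 * kernel_sd, 4 * kernel_sd, by = dt)
  kern <- stats::dnorm(kt, sd = kernel_sd)
  kern <- kern / sum(kern)
  grid0 <- min(bin_starts) - 0.5
  changes <- matrix(NA_real_, nrow(tr), k_bins)
  for (i in seq_len(nrow(tr))) {
    # absolute grid spanning baseline and response period
    g_lo <- tr$cue_s[i] - 1.5
    g_hi <- on[i] + resp_end + 0.5
    grid <- seq(g_lo, g_hi, by = dt)
    counts <- tabulate(findInterval(st[[i]], grid), nbins = length(grid))
    rate <- as.numeric(stats::filter(counts / dt, kern, sides = 2))
    rate[is.na(rate)] <- 0
    base_idx <- grid >= tr$cue_s[i] - 1 & grid < tr$cue_s[i]
    base <- mean(rate[base_idx])
    for (b in seq_len(k_bins)) {
      idx <- grid >= on[i] + bin_starts[b] & grid < on[i] + bin_starts[b] + 0.250
      changes[i, b] <- mean(rate[idx]) - base
    }
  }

  ci_for <- function(rows) {
    if (sum(rows) < 2) return(matrix(NA_real_, 2, k_bins))
    C <- boot_count_matrix(sum(rows), n_boot) / sum(rows)
    apply(C %*% changes[rows, , drop = FALSE], 2L, percentile_ci, level = 95)
  }
  is_push <- tr$type == "push"
  ci_p <- ci_for(is_push); ci_q <- ci_for(!is_push)
  sig_p <- apply(ci_p, 2L, ci_excludes_zero)
  sig_q <- apply(ci_q, 2L, ci_excludes_zero)
  responsive <- any(sig_p) || any(sig_q)

  bias <- "none"
  if (responsive) {
    resp_bins <- which(sig_p | sig_q)
    disjoint <- vapply(resp_bins, function(b)
      ci_p[1, b] > ci_q[2, b] || ci_q[1, b] > ci_p[2, b], logical(1))
    if (any(disjoint)) {
      bb <- resp_bins[disjoint]
      mp <- colMeans(changes[is_push, bb, drop = FALSE])
      mq <- colMeans(changes[!is_push, bb, drop = FALSE])
      best <- which.max(abs(mp - mq))
      bias <- if (mp[best] > mq[best]) "push" else "pull"
    }
  }
  list(responsive = responsive, bias = bias,
       detail = list(bin_starts = bin_starts, changes = changes,
                     ci_push = ci_p, ci_pull = ci_q,
                     n_excluded = sum(!ok)))
}

#' Classify all neurons of an aligned session
#'
#' Session-level driver: for each neuron, runs the two-method bootstrap
#' response test per movement ([classify_response()]); neurons silent in the
#' movement epochs are additionally screened with the baseline-to-peak test
#' over a post-movement reward window so that reward-phase activity (which
#' starts after the movement epoch ends) can reach the onset rule. Median
#' onsets come from the SSF detector over all trials; responsiveness,
#' movement bias and bias type are then assigned.
#'
#' @param aligned an [aligned_tensor()] aligned to motion-index onset, with
#'   push/pull `trial_labels`
#' @param completion_rel movement completion per trial, seconds relative to
#'   motion-index onset
#' @param epochs an [epoch_spec()]; defaults to the standard epochs with
#'   `peri_end = median(completion_rel) + 0.040`
#' @param onset_cfg an [onset_config()]
#' @param n_boot bootstrap resamples
#' @param reward_window length of the post-movement reward screening
#'   window, seconds (0 disables the screen)
#' @param onset_search c(start, end) seconds of the onset search region
#' @return data.frame of class `neuron_classification`: one row per neuron
#'   with responsiveness, bias, bias_type, per-movement significance flags
#'   and signs, and median onset
#' @export
classify_neurons <- function(aligned, completion_rel,
                             epochs = NULL, onset_cfg = onset_config(),
                             n_boot = 10000, reward_window = 2.5,
                             onset_search = c(-0.15, 5)) {
  stopifnot(inherits(aligned, "aligned_tensor"), !is.null(aligned$trial_labels))
  time <- aligned$time
  med_comp <- stats::median(completion_rel)
  if (is.null(epochs)) epochs <- epoch_spec(peri_end = med_comp + 0.040)
  is_push <- aligned$trial_labels == "push"
  n_neurons <- dim(aligned$data)[1]

  reward_epochs <- NULL
  if (reward_window > 0) {
    r_start <- epochs$peri[2]
    r_end <- min(r_start + reward_window, time[length(time)])
    if (r_end - r_start >= epochs$bin_width)
      reward_epochs <- epoch_spec(peri_end = r_end, baseline = epochs$baseline,
                                  peri_start = r_start,
                                  bin_width = epochs$bin_width)
  }
  s_idx <- time >= onset_search[1] & time <= onset_search[2]

  rows <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    m <- array(aligned$data[i, , , drop = FALSE], dim = dim(aligned$data)[2:3])
    rp <- classify_response(m[is_push, , drop = FALSE], time, epochs, n_boot)
    rq <- classify_response(m[!is_push, , drop = FALSE], time, epochs, n_boot)
    sig_p <- isTRUE(rp$significant); sig_q <- isTRUE(rq$significant)

    reward_hit <- FALSE
    if (!sig_p && !sig_q && !is.null(reward_epochs)) {
      # method-1-only screen on the reward window (a multi-bin screen over a
      # long window would inflate the false-positive rate)
      bp <- btp_bootstrap(m[is_push, , drop = FALSE], time, reward_epochs, n_boot)
      bq <- btp_bootstrap(m[!is_push, , drop = FALSE], time, reward_epochs, n_boot)
      reward_hit <- ci_excludes_zero(percentile_ci(bp$boot, 95)) ||
                    ci_excludes_zero(percentile_ci(bq$boot, 95))
    }

    med_onset <- NA_real_
    if (sig_p || sig_q || reward_hit)
      med_onset <- neuron_median_onset(m[, s_idx, drop = FALSE], time[s_idx],
                                       onset_cfg)
    resp <- assign_responsiveness(sig_p || reward_hit, sig_q || reward_hit,
                                  med_onset, med_comp)

    bias <- NA_character_; btype <- NA_integer_
    if (resp == "movement_related") {
      cb <- classify_bias(m[is_push, , drop = FALSE], m[!is_push, , drop = FALSE],
                          time, epochs, n_boot)
      bias <- cb$bias
      if (bias != "invariant")
        btype <- assign_bias_type(sig_p, rp$sign, sig_q, rq$sign)
    }
    rows[[i]] <- data.frame(
      neuron = i, responsiveness = resp, bias = bias, bias_type = btype,
      sig_push = sig_p, sign_push = rp$sign %||% NA_real_,
      sig_pull = sig_q, sign_pull = rq$sign %||% NA_real_,
      median_onset = med_onset, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "epochs") <- epochs
  attr(out, "median_completion") <- med_comp
  class(out) <- c("neuron_classification", "data.frame")
  out
}

#' @export
summary.neuron_classification <- function(object, ...) {
  resp <- table(factor(object$responsiveness,
                       levels = c("movement_related", "reward_phase", "non_responsive")))
  mr <- object[object$responsiveness == "movement_related", ]
  bias <- table(factor(mr$bias, levels = c("invariant", "push", "pull")))
  types <- table(factor(mr$bias_type, levels = 1:4))
  out <- list(n = nrow(object), responsiveness = resp, bias = bias,
              bias_types = types)
  class(out) <- "summary.neuron_classification"
  out
}

#' @export
print.summary.neuron_classification <- function(x, ...) {
  cat(sprintf("Neuron classification (%d neurons)\n", x$n))
  cat("responsiveness:\n"); print(x$responsiveness)
  cat(sprintf("bias (of %d movement-related):\n", sum(x$bias)))
  print(x$bias)
  cat("bias types (1-4):\n"); print(x$bias_types)
  invisible(x)
}

#' @export
print.neuron_classification <- function(x, ...) {
  cat(sprintf("<neuron_classification> %d neurons\n", nrow(x)))
  print(summary(x))
  invisible(x)
}
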