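#' PCA trajectories of peri-movement population activity
#'
#' Trials are concatenated in time, smoothed with a 3-frame boxcar, whitened
#' per neuron (z-scoring across the concatenated samples), and projected
#' onto the leading principal components. Per-movement mean trajectories
#' with percentile bootstrap CIs (resampling trials) are computed for each
#' retained PC.
#'
#' @param aligned an [aligned_tensor()] over the peri-movement window (the
#'   reference design uses a 7.5 s window) with push/pull `trial_labels`
#' @param n_pcs retained components (default 16; must not exceed
#'   min(neurons, samples))
#' @param boxcar boxcar width, frames
#' @param n_boot trajectory bootstrap resamples
#' @param seed optional seed
#' @return list of class `pca_trajectories`: `proj` (trials x time x PC),
#'   `time`, `labels`, `mean_push`/`mean_pull` (time x PC), `ci_push`/
#'   `ci_pull` (2 x time x PC), `explained_variance` (fraction per PC),
#'   `rotation`, and the whitening parameters
#' @export
pca_trajectories <- function(aligned, n_pcs = 16, boxcar = 3, n_boot = 100,
                             seed = NULL) {
  stopifnot(inherits(aligned, "aligned_tensor"))
  dat <- aligned$data
  n_neurons <- dim(dat)[1]; n_trials <- dim(dat)[2]; n_t <- dim(dat)[3]
  if (n_pcs > min(n_neurons, n_trials * n_t))
    stop("n_pcs exceeds min(neurons, samples)")
  labels <- aligned$trial_labels

  # boxcar per neuron x trial, then concatenate trials: (trials*T) x neurons
  M <- matrix(NA_real_, n_trials * n_t, n_neurons)
  for (i in seq_len(n_neurons))
    for (j in seq_len(n_trials))
      M[((j - 1) * n_t + 1):(j * n_t), i] <- boxcar_smooth(dat[i, j, ], boxcar)

  mu <- colMeans(M); sd <- apply(M, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  W <- sweep(sweep(M, 2L, mu, "-"), 2L, sd, "/")
  pc <- stats::prcomp(W, center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ev <- pc$sdev^2 / sum(pc$sdev^2)

  proj <- array(NA_real_, dim = c(n_trials, n_t, k))
  for (j in seq_len(n_trials))
    proj[j, , ] <- scores[((j - 1) * n_t + 1):(j * n_t), , drop = FALSE]

  traj <- function(rows) {
    sub <- proj[rows, , , drop = FALSE]
    m <- apply(sub, c(2, 3), mean)
    ci <- with_seed(seed, {
      nr <- sum(rows)
      boots <- array(NA_real_, dim = c(n_boot, n_t, k))
      for (b in seq_len(n_boot)) {
        jj <- sample.int(nr, nr, replace = TRUE)
        boots[b, , ] <- apply(sub[jj, , , drop = FALSE], c(2, 3), mean)
      }
      apply(boots, c(2, 3), stats::quantile, probs = c(0.025, 0.975))
    })
    list(mean = m, ci = ci)
  }
  tp <- traj(labels == "push"); tq <- traj(labels == "pull")

  structure(list(proj = proj, time = aligned$time, labels = labels,
                 mean_push = tp$mean, mean_pull = tq$mean,
                 ci_push = tp$ci, ci_pull = tq$ci,
                 explained_variance = ev[seq_len(k)],
                 explained_variance_all = ev,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 whitening = list(mean = mu, sd = sd)),
            class = "pca_trajectories")
}

dprime_stat <- function(x_push, x_pull) {
  mp <- colMeans(x_push); mq <- colMeans(x_pull)
  vp <- apply(x_push, 2L, stats::var); vq <- apply(x_pull, 2L, stats::var)
  pool <- 0.5 * (vp + vq)
  out <- abs(mp - mq) / sqrt(pool)
  out[pool <= 0] <- NA_real_
  out
}

#' Trajectory separability d'(t) with trial-shuffle significance
#'
#' Per PC, the time-resolved separability is
#' `d'(t) = |m_push(t) - m_pull(t)| / sqrt(0.5 (v_push(t) + v_pull(t)))`
#' with trial means and variances; its variability is estimated from 400
#' within-class bootstrap resamples. A shuffled counterpart is computed
#' with trial labels permuted. A PC is declared separable when the
#' difference between the window-maximum d' and the window-maximum shuffled
#' d' exceeds zero by 1.96 times the summed bootstrap SD (one-sided 97.5%
#' lower bound above 0); frames with zero pooled variance are flagged NA.
#'
#' @param proj trials x time x PC projection array (see
#'   [pca_trajectories()])
#' @param labels "push"/"pull" per trial (>= 3 per class)
#' @param time time axis, seconds
#' @param window c(start, end) seconds of the movement window over which
#'   separability is assessed (onset to the longest movement duration)
#' @param n_boot bootstrap resamples
#' @param seed optional seed
#' @return list of class `dprime_series`: `per_pc` data.frame (max d',
#'   shuffled max, z, separable), `dprime_ts` / `shuffle_ts` (PC x time),
#'   `max_significant_dprime`
#' @export
dprime_timeseries <- function(proj, labels, time, window = NULL,
                              n_boot = 400, seed = NULL) {
  if (length(dim(proj)) == 2) proj <- array(proj, dim = c(dim(proj), 1))
  labels <- as.character(labels)
  if (min(table(labels)) < 3) stop("at least 3 trials per class are required")
  k <- dim(proj)[3]
  window <- window %||% range(time)
  widx <- which(time >= window[1] & time <= window[2])
  if (!length(widx)) stop("empty d-prime window")
  is_push <- labels == "push"

  with_seed(seed, {
    dts <- sts <- matrix(NA_real_, k, length(time))
    per <- vector("list", k)
    shuffle <- sample(is_push)   # one trial-shuffled dataset per call
    for (p in seq_len(k)) {
      Xp <- matrix(proj[is_push, , p], nrow = sum(is_push))
      Xq <- matrix(proj[!is_push, , p], nrow = sum(!is_push))
      Sp <- matrix(proj[shuffle, , p], nrow = sum(shuffle))
      Sq <- matrix(proj[!shuffle, , p], nrow = sum(!shuffle))
      dts[p, ] <- dprime_stat(Xp, Xq)
      sts[p, ] <- dprime_stat(Sp, Sq)
      # vectorized within-class bootstrap of the window-max d'
      boot_max <- function(A, B) {
        nA <- nrow(A); nB <- nrow(B)
        CA <- boot_count_matrix(nA, n_boot) / nA
        CB <- boot_count_matrix(nB, n_boot) / nB
        Aw <- A[, widx, drop = FALSE]; Bw <- B[, widx, drop = FALSE]
        mA <- CA %*% Aw; mB <- CB %*% Bw
        vA <- (CA %*% Aw^2 - mA^2) * nA / (nA - 1)
        vB <- (CB %*% Bw^2 - mB^2) * nB / (nB - 1)
        pool <- 0.5 * (vA + vB)
        d <- abs(mA - mB) / sqrt(pool)
        d[pool <= 0] <- NA_real_
        do.call(pmax, c(as.data.frame(d), na.rm = TRUE))
      }
      bm <- boot_max(Xp, Xq); bs <- boot_max(Sp, Sq)
      d_max <- max(dts[p, widx], na.rm = TRUE)
      s_max <- max(sts[p, widx], na.rm = TRUE)
      se <- sqrt(stats::var(bm) + stats::var(bs))
      z <- (d_max - s_max) / se
      per[[p]] <- data.frame(pc = p, max_dprime = d_max, shuffle_max = s_max,
                             se = se, z = z,
                             separable = is.finite(z) && (d_max - s_max - 1.96 * se > 0))
    }
    per <- do.call(rbind, per)
    msd <- if (any(per$separable)) max(per$max_dprime[per$separable]) else NA_real_
    structure(list(per_pc = per, dprime_ts = dts, shuffle_ts = sts,
                   time = time, window = window,
                   max_significant_dprime = msd),
              class = "dprime_series")
  })
}
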