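# ---- Gaussian naive Bayes, leave-one-out over trials ----------------------

# LOO-correctness of a single feature vector (one frame): for each held-out
# trial, per-class Gaussians (mean, floored variance) are fit on the
# remaining trials and the trial is classified by maximum posterior.
nb_loo_frame <- function(v, y1, var_floor = 1e-6, priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  n <- length(v)
  n1 <- sum(y1); n2 <- n - n1
  S1 <- sum(v[y1]); S2 <- sum(v[!y1])
  Q1 <- sum(v[y1]^2); Q2 <- sum(v[!y1]^2)
  mu1 <- (S1 - ifelse(y1, v, 0)) / (n1 - y1)
  mu2 <- (S2 - ifelse(!y1, v, 0)) / (n2 - !y1)
  ss1 <- Q1 - ifelse(y1, v^2, 0) - (n1 - y1) * mu1^2
  ss2 <- Q2 - ifelse(!y1, v^2, 0) - (n2 - !y1) * mu2^2
  v1 <- pmax(ss1 / pmax(n1 - y1 - 1, 1), var_floor)
  v2 <- pmax(ss2 / pmax(n2 - !y1 - 1, 1), var_floor)
  if (priors == "empirical") {
    p1 <- (n1 - y1) / (n - 1); p2 <- 1 - p1
  } else { p1 <- p2 <- 0.5 }
  ll1 <- -0.5 * log(v1) - (v - mu1)^2 / (2 * v1) + log(p1)
  ll2 <- -0.5 * log(v2) - (v - mu2)^2 / (2 * v2) + log(p2)
  pred1 <- ll1 > ll2
  pred1 == y1
}

#' Single-neuron naive-Bayes decoding accuracy time series
#'
#' At each frame, trials are decoded leave-one-out: per-class Gaussians
#' (mean, variance with a small floor) are fit at that frame on the training
#' trials and the held-out trial is classified by maximum posterior with
#' empirical class priors. The accuracy time series is the mean leave-one-out
#' correctness per frame.
#'
#' @param mat trials x time dF/F0 matrix for one neuron
#' @param labels "push"/"pull" per trial (>= 3 trials per class)
#' @param var_floor variance floor, (dF/F0)^2
#' @return list of class `nb_decoding` with `accuracy_ts` (per frame) and
#'   `correct` (trials x frames logical)
#' @export
nb_accuracy_timeseries <- function(mat, labels, var_floor = 1e-6) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("labels must contain both classes")
  if (min(table(labels)) < 2) stop("at least 2 trials per class are required")
  y1 <- labels == "push"
  correct <- vapply(seq_len(ncol(mat)), function(t)
    nb_loo_frame(mat[, t], y1, var_floor), logical(nrow(mat)))
  structure(list(accuracy_ts = colMeans(correct), correct = correct),
            class = "nb_decoding")
}

#' Simulated-null session decoding threshold
#'
#' Simulates `n_reps` label-free sessions: features are i.i.d. standard
#' Gaussian draws with the session's trial counts, decoded with the same
#' leave-one-out Gaussian naive-Bayes rule under a 50:50 prior. The
#' threshold is the mean + 2 SD of the null accuracies.
#'
#' @param n_trials_per_class integer vector c(n_push, n_pull) (each >= 4)
#' @param n_reps simulated datasets
#' @param seed optional seed (NULL uses the current RNG stream)
#' @return threshold accuracy (fraction)
#' @export
session_null_threshold <- function(n_trials_per_class, n_reps = 1000, seed = NULL) {
  stopifnot(length(n_trials_per_class) == 2, all(n_trials_per_class >= 4))
  with_seed(seed, {
    n <- sum(n_trials_per_class)
    y1 <- rep(c(TRUE, FALSE), n_trials_per_class)
    X <- matrix(stats::rnorm(n * n_reps), n, n_reps)
    acc <- colMeans(vapply(seq_len(n_reps), function(r)
      nb_loo_frame(X[, r], y1, priors = "equal"), logical(n)))
    mean(acc) + 2 * stats::sd(acc)
  })
}

#' Per-neuron peri-movement decoding epoch
#'
#' The epoch starts at -0.15 s relative to motion-index onset; its end is
#' the later of the two per-movement median dF/F0 peak times (median over
#' trials of each trial's peak position).
#'
#' @param mat trials x time matrix
#' @param labels "push"/"pull" per trial
#' @param time time axis, seconds
#' @param start epoch start, seconds
#' @return list with `start`, `end`, `flagged` (TRUE when the peak-derived
#'   end does not lie after the start, in which case the epoch is collapsed)
#' @export
neuron_epoch <- function(mat, labels, time, start = -0.15) {
  peak_med <- function(rows) {
    pk <- time[max.col(mat[rows, , drop = FALSE], ties.method = "first")]
    stats::median(pk)
  }
  end <- max(peak_med(labels == "push"), peak_med(labels == "pull"))
  flagged <- end <= start
  list(start = start, end = if (flagged) NA_real_ else end, flagged = flagged)
}

#' Flag a high-decoding-accuracy (HDA) neuron
#'
#' Per non-overlapping 250 ms bin (left-aligned to the epoch start), the
#' trials' leave-one-out correctness is bootstrapped; the neuron is HDA when
#' at least one bin's 95% CI lower bound exceeds the session threshold.
#'
#' @param nb an `nb_decoding` result (see [nb_accuracy_timeseries()])
#' @param time time axis matching its frames
#' @param epoch list with `start`, `end` (see [neuron_epoch()])
#' @param threshold session null threshold (see [session_null_threshold()])
#' @param bin_width bin width, seconds
#' @param n_boot bootstrap resamples
#' @return list with `hda`, per-bin `ci` and `bin_starts`
#' @export
flag_hda <- function(nb, time, epoch, threshold, bin_width = 0.25,
                     n_boot = 10000) {
  if (is.na(epoch$end) || epoch$end <= epoch$start)
    return(list(hda = FALSE, ci = NULL, bin_starts = numeric(0)))
  k <- floor((epoch$end - epoch$start) / bin_width + 1e-9)
  if (k < 1) k <- 1L
  starts <- epoch$start + (seq_len(k) - 1) * bin_width
  n <- nrow(nb$correct)
  C <- boot_count_matrix(n, n_boot) / n
  ci <- vapply(starts, function(s) {
    idx <- time >= s & time < s + bin_width
    if (!any(idx)) return(c(NA_real_, NA_real_))
    p <- rowMeans(nb$correct[, idx, drop = FALSE])
    percentile_ci(C %*% p, 95)
  }, numeric(2))
  hda <- any(ci[1, ] > threshold, na.rm = TRUE)
  list(hda = hda, ci = ci, bin_starts = starts)
}

# ---- population decoding: weakly regularized logistic regression ----------

# IRLS ridge logistic (intercept unpenalized); returns c(b0, beta)
irls_ridge <- function(X, y, lambda, beta0 = NULL, max_iter = 50, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  b <- beta0 %||% numeric(p + 1)
  Xa <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xa * w, Xa) + pen
    bn <- tryCatch(solve(H, crossprod(Xa * w, z)), error = function(e) b)
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  drop(b)
}

# exact LOO correctness for ridge logistic on (possibly wide) X; features are
# standardized on the full data and the fit is solved in the right-singular
# basis of X (equivalent to the primal ridge problem, n << p safe)
loo_logistic_correct <- function(X, y1, lambda = 1) {
  n <- nrow(X)
  mu <- colMeans(X); sd <- apply(X, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
  sv <- svd(Xs)
  keep <- sv$d > max(sv$d[1], 1e-8) * 1e-10
  Z <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  y <- as.numeric(y1)
  warm <- irls_ridge(Z, y, lambda)
  correct <- logical(n)
  for (i in seq_len(n)) {
    b <- irls_ridge(Z[-i, , drop = FALSE], y[-i], lambda, beta0 = warm,
                    max_iter = 25)
    eta <- b[1] + sum(Z[i, ] * b[-1])
    correct[i] <- (eta > 0) == y1[i]
  }
  correct
}

#' Population decoding accuracy
#'
#' Leave-one-out logistic regression (weak L2 penalty, per-feature
#' standardization) on the population vector: per frame for the accuracy
#' time series, and on 250 ms bin-averaged features within the
#' peri-movement epoch for the summary, which is the maximum bin accuracy.
#'
#' @param pop an [aligned_tensor()] (or neurons x trials x time array)
#' @param labels "push"/"pull" per trial
#' @param epoch list with `start`, `end` seconds for the binned summary
#' @param lambda ridge penalty
#' @param bin_width bin width, seconds
#' @param compute_ts compute the per-frame time series (set FALSE for speed
#'   in repeated retraining analyses)
#' @return list of class `population_decoding` with `population_ts`,
#'   `bin_accuracy`, `bin_correct` (trials x bins), `bin_starts`,
#'   `max_in_bin`
#' @export
population_accuracy <- function(pop, labels, epoch, lambda = 1,
                                bin_width = 0.25, compute_ts = TRUE) {
  if (inherits(pop, "aligned_tensor")) { time <- pop$time; pop <- pop$data }
  else stop("pop must be an aligned_tensor")
  labels <- as.character(labels)
  if (dim(pop)[1] < 1) stop("at least 1 neuron is required")
  if (min(table(labels)) < 3) stop("at least 3 trials per class are required")
  y1 <- labels == "push"

  ts <- NULL
  if (compute_ts)
    ts <- vapply(seq_along(time), function(t)
      mean(loo_logistic_correct(t(matrix(pop[, , t], nrow = dim(pop)[1])),
                                y1, lambda)), numeric(1))

  k <- max(1L, floor((epoch$end - epoch$start) / bin_width + 1e-9))
  starts <- epoch$start + (seq_len(k) - 1) * bin_width
  bin_correct <- vapply(starts, function(s) {
    idx <- time >= s & time < s + bin_width
    Xb <- t(apply(pop[, , idx, drop = FALSE], c(1, 2), mean))
    loo_logistic_correct(Xb, y1, lambda)
  }, logical(dim(pop)[2]))
  bin_acc <- colMeans(bin_correct)
  structure(list(population_ts = ts, time = time,
                 bin_accuracy = bin_acc, bin_correct = bin_correct,
                 bin_starts = starts, max_in_bin = max(bin_acc)),
            class = "population_decoding")
}

#' Shuffled-label chance reference for population decoding
#'
#' Accuracy distribution of the population decoder on label-shuffled data:
#' each of `n_samples` draws picks one random time point and a random
#' permutation of the trial labels, and evaluates the leave-one-out
#' logistic-regression accuracy there.
#'
#' @param pop an [aligned_tensor()]
#' @param labels trial labels
#' @param n_samples shuffle draws
#' @param lambda ridge penalty
#' @param seed optional seed
#' @return list with `ci` (95% percentile interval) and `accuracies`
#' @export
population_shuffle_reference <- function(pop, labels, n_samples = 1000,
                                         lambda = 1, seed = NULL) {
  stopifnot(inherits(pop, "aligned_tensor"))
  dat <- pop$data
  with_seed(seed, {
    acc <- vapply(seq_len(n_samples), function(s) {
      t <- sample.int(dim(dat)[3], 1)
      y1 <- sample(labels == "push")
      mean(loo_logistic_correct(t(matrix(dat[, , t], nrow = dim(dat)[1])),
                                y1, lambda))
    }, numeric(1))
    list(ci = percentile_ci(acc, 95), accuracies = acc)
  })
}

#' Neuron-removal curves for population decoding
#'
#' Neurons are removed one at a time, either in descending order of their
#' single-neuron decoding accuracy (ties broken by neuron index) or in
#' random order (`n_random_reps` repetitions, median curve reported), and
#' the population decoder is retrained from scratch after each removal. The
#' reported accuracy at each step is the maximum 250 ms bin accuracy within
#' the epoch. `proportion_to_chance` is the fraction of neurons removed when
#' the accuracy's bootstrap 95% CI first overlaps the shuffled-data 95% CI.
#'
#' @param pop an [aligned_tensor()]
#' @param labels trial labels
#' @param single_acc per-neuron maximum decoding accuracy (for ordering)
#' @param epoch list with `start`, `end`
#' @param shuffle_ci c(lo, hi) from [population_shuffle_reference()]
#' @param order "by_accuracy" or "random"
#' @param n_random_reps random-order repetitions
#' @param lambda ridge penalty
#' @param bin_width bin width, seconds
#' @param n_boot_ci bootstrap resamples for the per-step accuracy CI
#' @param seed optional seed
#' @return list with `n_removed`, `accuracy`, `ci_lo`, `proportion_to_chance`
#' @export
removal_curve <- function(pop, labels, single_acc, epoch, shuffle_ci,
                          order = c("by_accuracy", "random"),
                          n_random_reps = 25, lambda = 1, bin_width = 0.25,
                          n_boot_ci = 1000, seed = NULL) {
  order <- match.arg(order)
  stopifnot(inherits(pop, "aligned_tensor"))
  dat <- pop$data
  n_neurons <- dim(dat)[1]
  y1 <- labels == "push"

  step_eval <- function(keep) {
    sub <- aligned_tensor(dat[keep, , , drop = FALSE], pop$time,
                          trial_labels = labels, alignment = pop$alignment)
    pa <- population_accuracy(sub, labels, epoch, lambda = lambda,
                              bin_width = bin_width, compute_ts = FALSE)
    best <- which.max(pa$bin_accuracy)
    p <- pa$bin_correct[, best]
    ci <- percentile_ci(boot_means(as.numeric(p), n_boot_ci), 95)
    c(acc = pa$max_in_bin, lo = ci[1], hi = ci[2])
  }
  run_order <- function(ord) {
    out <- matrix(NA_real_, n_neurons, 3)
    for (r in 0:(n_neurons - 1)) {
      keep <- if (r == 0) seq_len(n_neurons) else setdiff(seq_len(n_neurons), ord[seq_len(r)])
      out[r + 1, ] <- step_eval(keep)
    }
    out
  }
  with_seed(seed, {
    if (order == "by_accuracy") {
      ord <- order(single_acc, decreasing = TRUE)   # ties: lower index first
      curve <- run_order(ord)
    } else {
      reps <- lapply(seq_len(n_random_reps), function(r)
        run_order(sample.int(n_neurons)))
      curve <- apply(simplify2array(reps), c(1, 2), stats::median)
    }
    overlap <- curve[, 2] <= shuffle_ci[2]
    first <- if (any(overlap)) which(overlap)[1] - 1L else NA_integer_
    list(n_removed = 0:(n_neurons - 1), accuracy = curve[, 1],
         ci_lo = curve[, 2], ci_hi = curve[, 3],
         proportion_to_chance = if (is.na(first)) NA_real_ else first / n_neurons)
  })
}

#' Session-level single-neuron decoding driver
#'
#' Computes each neuron's leave-one-out naive-Bayes accuracy time series,
#' peri-movement epoch, maximum accuracy within the epoch, and HDA flag
#' against the simulated-null session threshold.
#'
#' @param aligned an [aligned_tensor()] over the 5 s peri-movement window,
#'   with push/pull `trial_labels`
#' @param n_null_reps simulated null datasets for the session threshold
#' @param n_boot bootstrap resamples for the HDA bin test
#' @param var_floor naive-Bayes variance floor
#' @param seed optional seed
#' @return list of class `decoding_result`: per-neuron data.frame `neurons`
#'   (max_accuracy, epoch bounds, hda), `threshold`, `accuracy_ts`
#'   (neurons x frames), `correct` (list of trials x frames matrices),
#'   `hda_detail`
#' @export
decode_session <- function(aligned, n_null_reps = 1000, n_boot = 10000,
                           var_floor = 1e-6, seed = NULL) {
  stopifnot(inherits(aligned, "aligned_tensor"), !is.null(aligned$trial_labels))
  labels <- aligned$trial_labels
  time <- aligned$time
  n_neurons <- dim(aligned$data)[1]
  with_seed(seed, {
    threshold <- session_null_threshold(as.integer(table(labels)[c("push", "pull")]),
                                        n_reps = n_null_reps)
    acc_ts <- matrix(NA_real_, n_neurons, length(time))
    correct <- vector("list", n_neurons)
    rows <- vector("list", n_neurons)
    hda_detail <- vector("list", n_neurons)
    for (i in seq_len(n_neurons)) {
      m <- array(aligned$data[i, , , drop = FALSE], dim = dim(aligned$data)[2:3])
      nb <- nb_accuracy_timeseries(m, labels, var_floor)
      acc_ts[i, ] <- nb$accuracy_ts
      correct[[i]] <- nb$correct
      ep <- neuron_epoch(m, labels, time)
      hd <- flag_hda(nb, time, ep, threshold, n_boot = n_boot)
      hda_detail[[i]] <- hd
      in_ep <- !is.na(ep$end) & time >= ep$start & time <= ep$end
      rows[[i]] <- data.frame(
        neuron = i,
        max_accuracy = if (any(in_ep)) max(nb$accuracy_ts[in_ep]) else NA_real_,
        epoch_start = ep$start, epoch_end = ep$end, epoch_flagged = ep$flagged,
        hda = hd$hda)
    }
    structure(list(neurons = do.call(rbind, rows), threshold = threshold,
                   accuracy_ts = acc_ts, time = time, correct = correct,
                   hda_detail = hda_detail, labels = labels),
              class = "decoding_result")
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d neurons, %d trials; session threshold %.3f\n",
              nrow(x$neurons), length(x$labels), x$threshold))
  cat(sprintf("  HDA neurons: %d (%.1f%%); median max accuracy %.3f\n",
              sum(x$neurons$hda), 100 * mean(x$neurons$hda),
              stats::median(x$neurons$max_accuracy, na.rm = TRUE)))
  invisible(x)
}
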