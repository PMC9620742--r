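test_that("config validation rejects bad proportions and trial counts", {
  expect_error(synth_config(class_proportions = c(invariant_up = 0.5)),
               "sum to 1")
  expect_error(synth_config(n_push_trials = 1), "2 trials")
  expect_error(synth_config(kernel_rise = -1))
})

test_that("class allocation by proportion is deterministic", {
  cfg <- synth_config(n_neurons = 100,
                      class_proportions = c(invariant_up = 0.6,
                                            push_type1 = 0.2,
                                            non_responsive = 0.2),
                      n_push_trials = 2, n_pull_trials = 2, seed = 1)
  g <- generate_session(cfg)
  counts <- table(g$truth$true_class)
  expect_equal(unname(counts[c("invariant_up", "push_type1", "non_responsive")]),
               c(60, 20, 20), ignore_attr = TRUE)
})

test_that("same seed gives bit-identical sessions", {
  cfg <- synth_config(n_neurons = 5, n_push_trials = 3, n_pull_trials = 3, seed = 99)
  g1 <- generate_session(cfg)
  g2 <- generate_session(cfg)
  expect_identical(g1$session$raw_f, g2$session$raw_f)
  expect_identical(g1$session$trials, g2$session$trials)
  expect_identical(g1$truth, g2$truth)
})

test_that("noise-free invariant neuron has identical push and pull mean responses", {
  # short decay so transients die out within the inter-trial interval
  cfg <- synth_config(n_neurons = 1,
                      class_proportions = c(invariant_up = 1),
                      n_push_trials = 8, n_pull_trials = 8,
                      noise_sd = 0, onset_jitter_sd = 0,
                      kernel_decay = 0.6, seed = 3)
  g <- generate_session(cfg)
  al <- align_trials(g$session$raw_f, g$session$trials$motion_onset_s,
                     c(0.5, 3), frame_rate = cfg$frame_rate,
                     trial_labels = g$session$trials$type)
  m <- matrix(al$data[1, , ], nrow = dim(al$data)[2])
  push_mean <- colMeans(m[al$trial_labels == "push", ])
  pull_mean <- colMeans(m[al$trial_labels == "pull", ])
  expect_lt(max(abs(push_mean - pull_mean)), 1e-9)
})

test_that("trial-averaged amplitudes match the planted ground truth", {
  cfg <- synth_config(
    n_neurons = 12, n_push_trials = 15, n_pull_trials = 15,
    class_proportions = c(invariant_up = 0.25, invariant_down = 0.25,
                          push_type1 = 0.25, pull_type2 = 0.25),
    onset_jitter_sd = 0, noise_sd = 0.1, seed = 23)
  g <- generate_session(cfg)
  al <- align_trials(g$session$raw_f, g$session$trials$motion_onset_s,
                     c(0.5, 3), frame_rate = cfg$frame_rate,
                     trial_labels = g$session$trials$type)
  pk <- al$time >= 0.3 & al$time <= 1.0
  kern <- exp(-al$time[pk] / cfg$kernel_decay) - exp(-al$time[pk] / cfg$kernel_rise)
  kern <- kern / max(exp(-seq(0, 9, 1 / 40) / cfg$kernel_decay) -
                     exp(-seq(0, 9, 1 / 40) / cfg$kernel_rise))
  for (mv in c("push", "pull")) {
    rows <- al$trial_labels == mv
    amp_true <- g$truth[[paste0("true_amplitude_", mv)]]
    tol <- 3 * cfg$noise_sd / sqrt(sum(rows) * sum(pk))
    for (i in seq_len(nrow(g$truth))) {
      m <- matrix(al$data[i, rows, ], nrow = sum(rows))
      est <- mean((colMeans(m)[pk] - cfg$baseline_f) / cfg$baseline_f) / mean(kern)
      expect_lt(abs(est - amp_true[i]), tol / mean(kern))
    }
  }
})

test_that("centroids are uniform over the FOV when clustering is off", {
  cfg <- synth_config(n_neurons = 1000, n_push_trials = 2, n_pull_trials = 2,
                      seed = 12)
  g <- generate_session(cfg)
  ks_x <- ks.test(g$truth$x_um / cfg$fov_size[1], "punif")
  ks_y <- ks.test(g$truth$y_um / cfg$fov_size[2], "punif")
  expect_gt(ks_x$p.value, 0.01)
  expect_gt(ks_y$p.value, 0.01)
})

test_that("ramp calibration set is built as specified", {
  r <- generate_ramp_calibration_set(n_cells = 100, n_trials = 30, seed = 2)
  expect_equal(dim(r$tensor$data)[1:2], c(100, 30))
  expect_equal(nrow(r$truth), 100)

  r0 <- generate_ramp_calibration_set(n_cells = 1, n_trials = 1, rise = 0.5,
                                      noise_sd = 0, frame_rate = 40, seed = 4)
  tr <- r0$tensor$data[1, 1, ]
  tt <- r0$tensor$time
  on <- r0$truth$true_onset[1]
  expect_true(all(tr[tt < on] == 0))
  ramp_idx <- tt >= on & tt <= on + 0.5
  expect_lt(max(abs(tr[ramp_idx] - (tt[ramp_idx] - on) / 0.5)), 1e-9)
  expect_true(all(tr[tt > on + 0.5] == 1))
  expect_error(generate_ramp_calibration_set(rise = 0), "rise")
})

test_that("noise-free ramps with different onsets are pure time shifts", {
  r <- generate_ramp_calibration_set(n_cells = 2, n_trials = 1, noise_sd = 0,
                                     frame_rate = 40, seed = 8)
  tt <- r$tensor$time
  shift <- r$truth$true_onset[2] - r$truth$true_onset[1]
  k <- round(shift * 40)
  a <- r$tensor$data[1, 1, ]
  b <- r$tensor$data[2, 1, ]
  idx <- seq_len(length(tt) - abs(k))
  if (k >= 0) expect_lt(max(abs(b[idx + k] - a[idx])), 0.06)
  else expect_lt(max(abs(a[idx - k] - b[idx])), 0.06)
})

test_that("noise-free sessions yield motion onsets within one frame", {
  cfg <- synth_config(n_neurons = 2, class_proportions = c(invariant_up = 1),
                      n_push_trials = 5, n_pull_trials = 5, noise_sd = 0,
                      seed = 5)
  g <- generate_session(cfg)
  mi <- motion_index_series(g$session$motion_index, cfg$frame_rate)
  set.seed(50)
  ons <- vapply(seq_len(nrow(g$session$trials)), function(k)
    detect_motion_onset(mi, g$session$trials[k, ], n_boot = 500), numeric(1))
  expect_true(all(abs(ons - g$session$trials$motion_onset_s) <= 1 / cfg$frame_rate + 1e-9))
})
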