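test_that("motion index matches the brute-force pixel-loop oracle", {
  mi_oracle <- function(frames, mask) {
    d <- dim(frames)
    out <- numeric(d[3] - 1)
    for (f in seq_len(d[3] - 1))
      for (i in seq_len(d[1]))
        for (j in seq_len(d[2]))
          if (mask[i, j])
            out[f] <- out[f] + (frames[i, j, f + 1] - frames[i, j, f])^2
    out
  }
  set.seed(1)
  for (rep in 1:3) {
    h <- sample(4:32, 1); w <- sample(4:32, 1); n <- sample(3:50, 1)
    frames <- array(sample(0:255, h * w * n, replace = TRUE), dim = c(h, w, n))
    mask <- matrix(runif(h * w) > 0.3, h, w)
    if (!any(mask)) mask[1, 1] <- TRUE
    mi <- compute_motion_index(frames, mask, frame_rate = 60)
    expect_equal(mi$values, mi_oracle(frames, mask))
  }
})

test_that("motion index handles trivial and degenerate inputs", {
  fr <- array(5, dim = c(4, 4, 3))
  expect_equal(compute_motion_index(fr, frame_rate = 60)$values, c(0, 0))

  fr2 <- array(0, dim = c(2, 2, 2))
  fr2[1, 1, 2] <- 3
  mask <- matrix(TRUE, 2, 2)
  expect_equal(compute_motion_index(fr2, mask, 60)$values, 9)

  expect_error(compute_motion_index(array(0, c(2, 2, 1)), frame_rate = 60),
               "2 frames")
  expect_error(compute_motion_index(fr2, matrix(FALSE, 2, 2), 60), "empty")
})

test_that("LOESS smoothing preserves constants and lines, attenuates noise", {
  expect_equal(loess_smooth(rep(4.2, 50), span = 0.25, frame_rate = 40),
               rep(4.2, 50))
  x <- seq(0, 5, length.out = 100)
  lin <- 2 + 3 * x
  expect_lt(max(abs(loess_smooth(lin, 0.5, 20) - lin)), 1e-9)
  expect_error(loess_smooth(1:10, span = 0.01, frame_rate = 40), "3 samples")

  set.seed(2)
  tt <- seq(0, 10, by = 1 / 40)
  sine <- sin(2 * pi * 0.3 * tt)
  worse <- 0
  for (r in 1:20) {
    noisy <- sine + rnorm(length(tt), 0, 0.3)
    sm <- loess_smooth(noisy, span = 0.5, frame_rate = 40)
    if (var(sm - sine) >= var(noisy - sine)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("dF/F0 baseline and normalization behave as specified", {
  fr <- 40
  n <- 20 * fr
  const <- matrix(100, 1, n)
  d <- compute_dff(const, fr)
  expect_equal(d$f0, 100, ignore_attr = TRUE)
  expect_equal(max(abs(d$dff)), 0)

  # brief transients leave the 5th percentile of the filtered trace at baseline
  tr <- rep(100, n)
  for (s in seq(2 * fr, n - fr, by = 5 * fr)) tr[s:(s + 2)] <- 200
  d2 <- compute_dff(matrix(tr, 1), fr)
  expect_lt(abs(d2$f0 - 100) / 100, 0.01)

  # scale invariance
  set.seed(4)
  raw <- matrix(100 + abs(rnorm(2 * n, 0, 5)), 2)
  a <- compute_dff(raw, fr)$dff
  b <- compute_dff(3.7 * raw, fr)$dff
  expect_lt(max(abs(a - b)), 1e-9)

  # f0 is monotone under pointwise increases of the raw trace
  bump <- raw; bump[, 10:200] <- bump[, 10:200] + 2
  expect_true(all(compute_dff(bump, fr)$f0 >= compute_dff(raw, fr)$f0 - 1e-9))

  expect_error(compute_dff(matrix(-1, 1, n), fr), "positive")
})

test_that("motion onset detection finds steps, misses sub-threshold series, and is translation-equivariant", {
  fr <- 40
  n <- 30 * fr
  v <- numeric(n)
  t0 <- 10
  v[(t0 * fr + 1):n] <- 1
  mi <- motion_index_series(v, fr)
  trial <- list(cue_s = 9.5, move_s = 10.5)
  set.seed(5)
  on <- detect_motion_onset(mi, trial, n_boot = 500)
  expect_equal(on, t0, tolerance = 1.5 / fr)

  # never strictly above the baseline-derived threshold
  mi_flat <- motion_index_series(rep(0.5, n), fr)
  set.seed(6)
  expect_true(is.na(detect_motion_onset(mi_flat, trial, n_boot = 500)))

  # translation equivariance
  shift <- 2
  v2 <- c(numeric(shift * fr), v)[1:n]
  set.seed(5)
  on2 <- detect_motion_onset(motion_index_series(v2, fr),
                             list(cue_s = 9.5 + shift, move_s = 10.5 + shift),
                             n_boot = 500)
  expect_equal(on2 - on, shift, tolerance = 1e-9)
})

test_that("ephys-mode onset uses mean + 2 SD after the cue and flags pre-cue movement", {
  fr <- 100
  n <- 20 * fr
  set.seed(7)
  v <- abs(rnorm(n, 0.1, 0.01))
  v[(10 * fr + 1):(11 * fr)] <- 1
  mi <- motion_index_series(v, fr)
  on <- detect_motion_onset(mi, list(cue_s = 9.8, move_s = 10.8), mode = "ephys")
  expect_false(attr(on, "excluded"))
  expect_equal(as.numeric(on), 10, tolerance = 2 / fr)

  v2 <- v; v2[(9.75 * fr):(11 * fr)] <- 1   # moving already at cue
  on2 <- detect_motion_onset(motion_index_series(v2, fr),
                             list(cue_s = 9.8, move_s = 10.8), mode = "ephys")
  expect_true(attr(on2, "excluded"))
})

test_that("trial alignment slices without interpolation and flags out-of-range events", {
  fr <- 40
  x <- matrix(seq_len(2 * 400), nrow = 2)   # distinct values per frame
  ev <- 100 / fr                            # event at 0-based frame 100
  al <- align_trials(x, c(ev, ev), c(1, 1), frame_rate = fr,
                     trial_labels = c("push", "pull"))
  expect_equal(dim(al$data)[3], 81)
  expect_equal(al$data[1, 1, 41], x[1, 101])  # sample 40 (0-based) = frame 100
  expect_identical(al$data[, 1, ], al$data[, 2, ])

  al2 <- align_trials(x, c(ev, 0.1), c(1, 1), frame_rate = fr)
  expect_equal(attr(al2, "flagged_trials"), 2L)
  expect_true(all(is.na(al2$data[, 2, ])))

  # round trip: aligned slice equals the raw segment
  expect_equal(al$data[2, 1, ], x[2, 61:141])
})

test_that("fixed-length resampling preserves identity grids, lines, and smooth trials", {
  tr <- sin(seq(0, 1, length.out = 50))
  expect_equal(resample_trials_fixed_length(list(tr), 50)[1, ], tr)

  lin <- seq(2, 8, length.out = 31)
  out <- resample_trials_fixed_length(list(lin), 11)[1, ]
  expect_equal(out, seq(2, 8, length.out = 11))

  dense <- sin(seq(0, 2 * pi, length.out = 400))
  down <- resample_trials_fixed_length(list(dense), 50)[1, ]
  up <- resample_trials_fixed_length(list(down), 400)[1, ]
  h <- 2 * pi / 49
  bound <- max(abs(diff(dense, differences = 2))) + h^2 / 8  # linear-interp error bound
  expect_lt(max(abs(up - dense)), bound)
  expect_error(resample_trials_fixed_length(list(dense), 1), "n_out")
})
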