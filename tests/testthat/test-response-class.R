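time_ax <- seq(-1, 4, by = 1 / 40)
epochs <- epoch_spec(peri_end = 0.54)

test_that("bootstrap CI brackets the statistic and matches the normal width on Bernoulli data", {
  expect_equal(bootstrap_ci(rep(3.3, 10), n_boot = 200), c(3.3, 3.3))

  set.seed(1)
  x <- rnorm(40)
  ci <- bootstrap_ci(x, n_boot = 5000)
  expect_lte(ci[1], mean(x))
  expect_gte(ci[2], mean(x))

  set.seed(2)
  b <- rbinom(200, 1, 0.5)
  ci_b <- bootstrap_ci(b, n_boot = 10000)
  analytic <- 2 * 1.96 * sqrt(0.5 * 0.5 / 200)
  expect_lt(abs(diff(ci_b) - analytic) / analytic, 0.2)
  expect_error(bootstrap_ci(1), "2 values")
})

test_that("planted responses are detected with the right sign; flat neurons rarely fire", {
  set.seed(3)
  up <- planted_trials(30, time_ax, amp = 1, noise_sd = 0.2)
  r_up <- classify_response(up, time_ax, epochs, n_boot = 2000)
  expect_true(r_up$significant)
  expect_equal(r_up$sign, 1)

  down <- planted_trials(30, time_ax, amp = -1, noise_sd = 0.2)
  r_dn <- classify_response(down, time_ax, epochs, n_boot = 2000)
  expect_true(r_dn$significant)
  expect_equal(r_dn$sign, -1)

  # null calibration of the combined two-method rule
  set.seed(4)
  fp <- mean(vapply(1:80, function(i) {
    m <- matrix(rnorm(30 * length(time_ax), 0, 0.2), 30)
    isTRUE(classify_response(m, time_ax, epochs, n_boot = 2000)$significant)
  }, logical(1)))
  expect_lte(fp, 0.25)   # empirical type-I error of the uncorrected rule

  expect_true(is.na(classify_response(up[1:3, ], time_ax, epochs, 500)$significant))
  expect_error(classify_response(up, time_ax, epoch_spec(peri_end = 10), 500),
               "outside")
})

test_that("responsiveness assignment follows significance and onset timing", {
  expect_equal(assign_responsiveness(FALSE, FALSE, NA, 0.5), "non_responsive")
  expect_equal(assign_responsiveness(TRUE, FALSE, 1.7, 0.5), "reward_phase")
  expect_equal(assign_responsiveness(TRUE, TRUE, -0.1, 0.5), "movement_related")
  expect_equal(assign_responsiveness(TRUE, TRUE, NA, 0.5), "movement_related")
})

test_that("bias classification is invariant under the null and detects planted contrasts symmetrically", {
  set.seed(5)
  inv <- mean(vapply(1:25, function(i) {
    a <- planted_trials(30, time_ax, amp = 1, noise_sd = 0.2)
    b <- planted_trials(30, time_ax, amp = 1, noise_sd = 0.2)
    classify_bias(a, b, time_ax, epochs, n_boot = 2000)$bias == "invariant"
  }, logical(1)))
  expect_gte(inv, 0.8)

  set.seed(6)
  strong <- planted_trials(30, time_ax, amp = 2, noise_sd = 0.2)
  weak <- planted_trials(30, time_ax, amp = 1, noise_sd = 0.2)
  expect_equal(classify_bias(strong, weak, time_ax, epochs, 2000)$bias, "push")
  expect_equal(classify_bias(weak, strong, time_ax, epochs, 2000)$bias, "pull")
  expect_error(classify_bias(strong[1:4, ], weak, time_ax, epochs, 500),
               "5 trials")
})

test_that("bias types follow the sign taxonomy", {
  expect_equal(assign_bias_type(TRUE, 1, TRUE, 1), 1L)
  expect_equal(assign_bias_type(TRUE, 1, FALSE, NA), 2L)
  expect_equal(assign_bias_type(FALSE, NA, TRUE, -1), 3L)
  expect_equal(assign_bias_type(TRUE, -1, TRUE, -1), 4L)
  expect_true(is.na(assign_bias_type(FALSE, NA, FALSE, NA)))
  expect_error(assign_bias_type(TRUE, 0, FALSE, NA), "sign")
})

test_that("spike width rule is strict at 0.4 ms", {
  expect_true(is_putative_pyramidal(0.6))
  expect_false(is_putative_pyramidal(0.3))
  expect_false(is_putative_pyramidal(0.4))
  expect_error(is_putative_pyramidal(0))
})

test_that("unit firing classification calibrates on Poisson nulls and detects rate steps", {
  gen_trials <- function(n_per, rate_fun) {
    # one trial every 12 s; cue at +10, onset +10.4, completion +10.9
    trials <- data.frame(
      type = rep(c("push", "pull"), n_per),
      cue_s = 10 + 12 * (seq_len(2 * n_per) - 1))
    trials$completion_s <- trials$cue_s + 0.9
    mi_onsets <- trials$cue_s + 0.4
    spikes <- lapply(seq_len(nrow(trials)), function(k) {
      t0 <- trials$cue_s[k] - 3; t1 <- trials$cue_s[k] + 3
      tt <- seq(t0, t1, by = 0.001)
      lam <- rate_fun(tt - mi_onsets[k], trials$type[k])
      tt[runif(length(tt)) < lam * 0.001]
    })
    list(trials = trials, mi_onsets = mi_onsets, spikes = spikes)
  }

  set.seed(7)
  fp <- mean(vapply(1:20, function(i) {
    g <- gen_trials(8, function(t, ty) rep(5, length(t)))
    classify_unit_firing(g$spikes, g$trials, g$mi_onsets, n_boot = 1000)$responsive
  }, logical(1)))
  expect_lte(fp, 0.25)

  set.seed(8)
  g <- gen_trials(10, function(t, ty) ifelse(t > 0 & t < 0.5, 15, 5))
  r <- classify_unit_firing(g$spikes, g$trials, g$mi_onsets, n_boot = 2000)
  expect_true(r$responsive)
  expect_equal(r$bias, "none")   # equal modulation in both movements

  set.seed(9)
  g2 <- gen_trials(10, function(t, ty)
    if (ty == "push") ifelse(t > 0 & t < 0.5, 25, 5) else rep(5, length(t)))
  r2 <- classify_unit_firing(g2$spikes, g2$trials, g2$mi_onsets, n_boot = 2000)
  expect_true(r2$responsive)
  expect_equal(r2$bias, "push")

  # empty spike train: unresponsive, not an error
  g3 <- gen_trials(5, function(t, ty) rep(5, length(t)))
  g3$spikes <- lapply(g3$spikes, function(s) numeric(0))
  r3 <- classify_unit_firing(g3$spikes, g3$trials, g3$mi_onsets, n_boot = 500)
  expect_false(r3$responsive)
})

test_that("session classification recovers planted classes and respects label exchange", {
  s <- small_session()
  set.seed(10)
  cl <- classify_neurons(s$aligned, s$completion_rel, n_boot = 3000,
                         onset_cfg = onset_config(n_boot = 3000))
  exp <- expected_labels(s$truth$true_class)
  ok <- cl$responsiveness == exp$responsiveness &
    (is.na(exp$bias) | (!is.na(cl$bias) & cl$bias == exp$bias))
  expect_gte(mean(ok), 0.85)

  # label-exchange symmetry: swapping push and pull labels swaps the bias
  swapped <- s$aligned
  swapped$trial_labels <- ifelse(s$aligned$trial_labels == "push", "pull", "push")
  set.seed(10)
  cl_sw <- classify_neurons(swapped, s$completion_rel, n_boot = 3000,
                            onset_cfg = onset_config(n_boot = 3000))
  mr <- which(cl$responsiveness == "movement_related" &
              cl_sw$responsiveness == "movement_related")
  map <- c(push = "pull", pull = "push", invariant = "invariant")
  agree <- mean(cl_sw$bias[mr] == map[cl$bias[mr]], na.rm = TRUE)
  expect_gte(agree, 0.9)
})
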