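make_aligned <- function(dat, fr = 40, labels = NULL) {
  n_tr <- dim(dat)[2]
  aligned_tensor(dat, seq(-0.5, by = 1 / fr, length.out = dim(dat)[3]),
                 trial_labels = labels %||% rep(c("push", "pull"),
                                                length.out = n_tr))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pairwise correlations hit the exact limits and stay near zero for noise", {
  n_t <- 120
  tt_sig <- sin(seq(0, 4 * pi, length.out = n_t))
  dat <- array(NA_real_, dim = c(3, 4, n_t))
  for (j in 1:4) {
    dat[1, j, ] <- tt_sig
    dat[2, j, ] <- tt_sig          # identical to neuron 1
    dat[3, j, ] <- -tt_sig         # negation
  }
  al <- make_aligned(dat)
  cent <- cbind(c(0, 30, 60), c(0, 40, 0))
  pt <- pairwise_activity_correlations(al, cent, epoch = c(-0.2, 2))
  r12 <- pt$pearson_r[pt$neuron_i == 1 & pt$neuron_j == 2]
  r13 <- pt$pearson_r[pt$neuron_i == 1 & pt$neuron_j == 3]
  expect_equal(unique(round(r12, 9)), 1)
  expect_equal(unique(round(r13, 9)), -1)
  expect_equal(unique(pt$distance_um[pt$neuron_i == 1 & pt$neuron_j == 2]), 50)

  # distances obey the triangle inequality
  d <- with(unique(pt[, c("neuron_i", "neuron_j", "distance_um")]), {
    dm <- matrix(0, 3, 3); dm[cbind(neuron_i, neuron_j)] <- distance_um
    dm + t(dm)
  })
  expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-9)

  set.seed(1)
  dat2 <- array(rnorm(10 * 6 * 200), dim = c(10, 6, 200))
  al2 <- make_aligned(dat2)
  cent2 <- cbind(runif(10, 0, 200), runif(10, 0, 200))
  # minimal smoothing: the machinery itself must not induce correlation
  pt2 <- pairwise_activity_correlations(al2, cent2, epoch = c(-0.2, 4),
                                        span = 0.075)
  expect_lt(median(abs(pt2$pearson_r), na.rm = TRUE), 0.15)
  # the default 1 s smoothing leaves few effective samples; correlations
  # broaden but stay centered
  pt2b <- pairwise_activity_correlations(al2, cent2, epoch = c(-0.2, 4))
  expect_lt(abs(median(pt2b$pearson_r, na.rm = TRUE)), 0.35)

  # constant trace flagged
  dat3 <- dat2; dat3[1, , ] <- 5
  pt3 <- pairwise_activity_correlations(make_aligned(dat3),
                                        cbind(runif(10), runif(10)),
                                        epoch = c(-0.2, 4))
  expect_true(all(is.na(pt3$pearson_r[pt3$neuron_i == 1])))
})

test_that("group median differences are centered, track shifts, and are deterministic", {
  set.seed(2)
  n <- 60
  pt <- data.frame(neuron_i = rep(1:6, 10), neuron_j = rep(7:12, 10),
                   pearson_r = rnorm(n, 0.3, 0.1),
                   distance_um = runif(n, 10, 200),
                   group_i = "HDA", group_j = "HDA",
                   movement = "push", animal_id = "A1", flagged = FALSE)
  g0 <- group_median_difference(pt, "r", n_boot = 2000, seed = 3)
  expect_equal(g0$estimate, 0)
  expect_true(g0$ci[1] <= 0 && g0$ci[2] >= 0)
  expect_identical(g0$ci,
                   group_median_difference(pt, "r", n_boot = 2000, seed = 3)$ci)

  pt2 <- pt
  lda <- pt2$neuron_i > 3
  pt2$group_i[lda] <- pt2$group_j[lda] <- "LDA"
  delta <- 0.25
  pt2$pearson_r[!lda] <- pt2$pearson_r[!lda] + delta
  g1 <- group_median_difference(pt2, "r", reference = "LDA",
                                n_boot = 2000, seed = 4)
  expect_equal(g1$boot_median, delta, tolerance = 0.08)
  expect_error(group_median_difference(pt2[1:4, ], "r"), "5 pairs")
})

test_that("trial-to-trial correlations separate reproducible from independent trials", {
  n_t <- 100
  base <- sin(seq(0, 3 * pi, length.out = n_t))
  dat <- array(NA_real_, dim = c(2, 8, n_t))
  set.seed(5)
  for (j in 1:8) {
    dat[1, j, ] <- base                      # perfectly reproducible
    dat[2, j, ] <- rnorm(n_t)                # independent across trials
  }
  al <- make_aligned(dat)
  tc <- trial_correlation_analyses(al, epoch = c(-0.2, 1.5), n_boot = 200,
                                   seed = 6)
  v1 <- tc$per_neuron$mean_trial_r[tc$per_neuron$neuron == 1]
  v2 <- tc$per_neuron$mean_trial_r[tc$per_neuron$neuron == 2]
  expect_true(all(v1 > 0.999))
  expect_lt(max(abs(v2)), 0.5)
})

test_that("population trial-pair correlations rise with motion-index correlations by construction", {
  # population dF/F0 is a deterministic function of the motion index
  set.seed(7)
  n_tr <- 16; n_t <- 80
  mi <- matrix(NA_real_, n_tr, n_t)
  shapes <- rbind(sin(seq(0, 2 * pi, length.out = n_t)),
                  cos(seq(0, 2 * pi, length.out = n_t)))
  for (j in seq_len(n_tr))
    mi[j, ] <- shapes[1 + (j %% 2), ] + rnorm(n_t, 0, 0.1)
  dat <- array(NA_real_, dim = c(3, n_tr, n_t))
  for (i in 1:3) dat[i, , ] <- mi
  al <- make_aligned(dat)
  tc <- trial_correlation_analyses(al, mi_aligned = mi, epoch = c(-0.2, 1),
                                   n_boot = 500, seed = 8)
  pp <- tc$population$pairs
  # same-shape pairs have high MI correlation and high population correlation
  expect_gt(cor(pp$r_mi, pp$r_pop), 0.9)
})

test_that("HDA time course counts bins above threshold", {
  ci_lower <- rbind(c(0.8, 0.4), c(0.9, 0.4), c(0.2, 0.4))
  expect_equal(hda_timecourse(ci_lower, 0.7), c(2 / 3, 0))
  expect_equal(hda_timecourse(matrix(0.1, 4, 3), 0.7), c(0, 0, 0))
})

test_that("clustering model recovers null and injected distance effects", {
  set.seed(9)
  n <- 2000
  pairs <- data.frame(
    neuron_i = sample(50, n, TRUE), neuron_j = sample(50, n, TRUE),
    pearson_r = rnorm(n, 0.3, 0.2), distance_um = runif(n, 5, 300),
    group_i = "HDA", group_j = "HDA",
    movement = sample(c("push", "pull"), n, TRUE),
    animal_id = sample(paste0("A", 1:4), n, TRUE), flagged = FALSE)
  class(pairs) <- c("pair_table", "data.frame")
  acc <- runif(50, 0.5, 1)

  fit0 <- fit_clustering_model(pairs, accuracies = acc)
  co <- fit0$coefficients
  expect_setequal(co$term,
                  c("(Intercept)", "distance", "accuracy", "distance:accuracy"))
  slope <- co[co$term == "distance", ]
  expect_lt(abs(slope$estimate), 2 * slope$se)

  beta <- -5e-4
  pairs2 <- pairs
  pairs2$pearson_r <- pairs2$pearson_r + beta * pairs2$distance_um
  fit1 <- fit_clustering_model(pairs2, accuracies = acc)
  s1 <- fit1$coefficients[fit1$coefficients$term == "distance", ]
  expect_lt(abs(s1$estimate - beta), 2 * s1$se)
  expect_lt(s1$estimate, 0)
})
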