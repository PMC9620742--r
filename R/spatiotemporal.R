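#' Pairwise activity correlations and ROI distances
#'
#' Pearson correlations between neurons' trial-averaged, 1 s LOESS-smoothed
#' peri-movement dF/F0 traces, per movement, together with the Euclidean
#' distance between ROI centroids. One row per unordered neuron pair
#' (i < j) per movement. Pairs involving a constant trace get `r = NA` and
#' are flagged.
#'
#' @param aligned an [aligned_tensor()] with push/pull `trial_labels`
#' @param centroids neurons x 2 matrix of ROI centroids, micrometers
#' @param epoch c(start, end) seconds of the peri-movement window
#' @param groups optional per-neuron "HDA"/"LDA" labels
#' @param animal_id animal identifier attached to all rows
#' @param span LOESS window, seconds
#' @return data.frame of class `pair_table` with columns neuron_i, neuron_j,
#'   pearson_r, distance_um, group_i, group_j, movement, animal_id, flagged
#' @export
pairwise_activity_correlations <- function(aligned, centroids, epoch,
                                           groups = NULL, animal_id = "A1",
                                           span = 1) {
  stopifnot(inherits(aligned, "aligned_tensor"), !is.null(aligned$trial_labels))
  n <- dim(aligned$data)[1]
  if (n < 2) stop("at least 2 neurons are required")
  stopifnot(nrow(centroids) == n)
  time <- aligned$time
  eidx <- time >= epoch[1] & time <= epoch[2]
  dmat <- as.matrix(stats::dist(centroids))

  out <- list()
  for (mv in c("push", "pull")) {
    rows <- aligned$trial_labels == mv
    if (!any(rows)) next
    # trial-averaged trace per neuron, smoothed, cropped to the epoch
    avg <- t(vapply(seq_len(n), function(i)
      colMeans(matrix(aligned$data[i, rows, ], nrow = sum(rows))),
      numeric(length(time))))
    sm <- loess_smooth(avg, span, aligned$frame_rate)[, eidx, drop = FALSE]
    sds <- apply(sm, 1L, stats::sd)
    cc <- suppressWarnings(stats::cor(t(sm)))
    ij <- which(upper.tri(cc), arr.ind = TRUE)
    r <- cc[ij]
    flagged <- sds[ij[, 1]] < 1e-12 | sds[ij[, 2]] < 1e-12
    r[flagged] <- NA_real_
    out[[mv]] <- data.frame(
      neuron_i = ij[, 1], neuron_j = ij[, 2], pearson_r = r,
      distance_um = dmat[ij],
      group_i = if (is.null(groups)) NA_character_ else groups[ij[, 1]],
      group_j = if (is.null(groups)) NA_character_ else groups[ij[, 2]],
      movement = mv, animal_id = animal_id, flagged = flagged,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pair_table", "data.frame")
  res
}

#' Bootstrapped median difference between a pair group and a reference
#'
#' Resamples pairs with replacement within the group (both members in
#' `group`) and within the reference ("all" pairs or both-LDA pairs) and
#' reports the bootstrap distribution of median(group) - median(reference).
#'
#' @param pairs a `pair_table` (see [pairwise_activity_correlations()])
#' @param value "r" or "distance"
#' @param group group label (default "HDA")
#' @param reference "all" or "LDA"
#' @param n_boot bootstrap resamples
#' @param seed optional seed
#' @return list with `estimate` (point median difference), `boot_median`,
#'   and `ci`
#' @export
group_median_difference <- function(pairs, value = c("r", "distance"),
                                    group = "HDA", reference = c("all", "LDA"),
                                    n_boot = 10000, seed = NULL) {
  value <- match.arg(value)
  reference <- match.arg(reference)
  v <- if (value == "r") pairs$pearson_r else pairs$distance_um
  in_group <- pairs$group_i == group & pairs$group_j == group
  in_group[is.na(in_group)] <- FALSE
  in_ref <- if (reference == "all") rep(TRUE, nrow(pairs))
  else pairs$group_i == "LDA" & pairs$group_j == "LDA"
  in_ref[is.na(in_ref)] <- FALSE
  g <- v[in_group & !is.na(v)]
  rf <- v[in_ref & !is.na(v)]
  if (length(g) < 5 || length(rf) < 5) stop("at least 5 pairs per group are required")
  with_seed(seed, {
    bg <- boot_medians(g, n_boot)
    br <- boot_medians(rf, n_boot)
    d <- bg - br
    list(estimate = stats::median(g) - stats::median(rf),
         boot_median = stats::median(d), ci = percentile_ci(d, 95))
  })
}

#' Trial-to-trial correlation analyses
#'
#' Per neuron and movement, the mean Pearson correlation over all pairs of
#' 1 s LOESS-smoothed peri-movement single-trial traces; summarized as
#' bootstrapped medians per movement-bias class (10,000 repetitions of 50
#' samples). For the population analysis, the summed dF/F0 of all
#' movement-related neurons is correlated between trial pairs and compared
#' with the corresponding motion-index trial-pair correlations, binned by
#' the motion-index correlation with a bootstrapped median per bin.
#'
#' @param aligned an [aligned_tensor()] with push/pull `trial_labels`
#' @param mi_aligned trials x time matrix of the motion index aligned the
#'   same way (or NULL to skip the population analysis)
#' @param classification a [classify_neurons()] result (or NULL: per-neuron
#'   values only, no class medians, population uses all neurons)
#' @param epoch c(start, end) seconds
#' @param span LOESS window, seconds
#' @param n_boot bootstrap repetitions
#' @param n_sample samples per bootstrap repetition
#' @param mi_bins bin edges for the motion-index correlation axis
#' @param seed optional seed
#' @return list with `per_neuron` (neuron, movement, mean_trial_r),
#'   `class_medians` (bias class bootstrap medians), and `population`
#'   (per trial pair: r_mi, r_pop, bin; plus per-bin bootstrap medians)
#' @export
trial_correlation_analyses <- function(aligned, mi_aligned = NULL,
                                       classification = NULL,
                                       epoch = c(-0.15, 1), span = 1,
                                       n_boot = 10000, n_sample = 50,
                                       mi_bins = seq(-1, 1, by = 0.25),
                                       seed = NULL) {
  stopifnot(inherits(aligned, "aligned_tensor"), !is.null(aligned$trial_labels))
  time <- aligned$time
  eidx <- which(time >= epoch[1] & time <= epoch[2])
  if (length(eidx) < 3) stop("epoch must contain at least 3 frames")
  n <- dim(aligned$data)[1]
  labels <- aligned$trial_labels
  S <- loess_smoother_matrix(length(eidx), span * aligned$frame_rate / 2)

  mean_offdiag <- function(cm) mean(cm[upper.tri(cm)])
  per <- list()
  for (mv in c("push", "pull")) {
    rows <- which(labels == mv)
    if (length(rows) < 2) stop("at least 2 trials per movement are required")
    vals <- vapply(seq_len(n), function(i) {
      m <- matrix(aligned$data[i, rows, eidx], nrow = length(rows))
      sm <- m %*% t(S)
      cm <- suppressWarnings(stats::cor(t(sm)))
      mean_offdiag(cm)
    }, numeric(1))
    per[[mv]] <- data.frame(neuron = seq_len(n), movement = mv,
                            mean_trial_r = vals, stringsAsFactors = FALSE)
  }
  per_neuron <- do.call(rbind, per)
  rownames(per_neuron) <- NULL

  class_medians <- NULL
  if (!is.null(classification)) {
    cls <- ifelse(classification$responsiveness != "movement_related", NA,
                  classification$bias)
    class_medians <- with_seed(seed, {
      do.call(rbind, lapply(stats::na.omit(unique(cls)), function(cl) {
        v <- per_neuron$mean_trial_r[cls[per_neuron$neuron] %in% cl]
        v <- v[!is.na(v)]
        if (length(v) < 2) return(NULL)
        bm <- boot_medians(v, n_boot, sample_size = min(n_sample, length(v)))
        data.frame(bias = cl, n = length(v), median = stats::median(v),
                   boot_median = stats::median(bm),
                   ci_lo = percentile_ci(bm)[1], ci_hi = percentile_ci(bm)[2])
      }))
    })
  }

  population <- NULL
  if (!is.null(mi_aligned)) {
    keep <- if (is.null(classification)) seq_len(n)
    else which(classification$responsiveness == "movement_related")
    if (length(keep) >= 1) {
      pop <- apply(aligned$data[keep, , eidx, drop = FALSE], c(2, 3), sum)
      mi <- mi_aligned[, eidx, drop = FALSE]
      pr <- list()
      for (mv in c("push", "pull")) {
        rows <- which(labels == mv)
        cp <- suppressWarnings(stats::cor(t(pop[rows, , drop = FALSE])))
        cm <- suppressWarnings(stats::cor(t(mi[rows, , drop = FALSE])))
        ut <- upper.tri(cp)
        pr[[mv]] <- data.frame(movement = mv, r_pop = cp[ut], r_mi = cm[ut])
      }
      pp <- do.call(rbind, pr)
      pp$bin <- cut(pp$r_mi, mi_bins, include.lowest = TRUE)
      bin_medians <- with_seed(seed, {
        do.call(rbind, lapply(levels(droplevels(pp$bin)), function(b) {
          v <- pp$r_pop[pp$bin == b & !is.na(pp$r_pop)]
          if (length(v) < 2) return(NULL)
          bm <- boot_medians(v, n_boot, sample_size = min(n_sample, length(v)))
          data.frame(bin = b, n = length(v), boot_median = stats::median(bm),
                     ci_lo = percentile_ci(bm)[1], ci_hi = percentile_ci(bm)[2])
        }))
      })
      population <- list(pairs = pp, bin_medians = bin_medians)
    }
  }
  list(per_neuron = per_neuron, class_medians = class_medians,
       population = population)
}

#' Time course of the proportion of neurons decoding above chance
#'
#' At each decoding bin, the fraction of neurons whose accuracy bootstrap
#' CI lower bound exceeds the session threshold.
#'
#' @param ci_lower neurons x bins matrix of bin-accuracy CI lower bounds
#'   (see [flag_hda()])
#' @param threshold session null threshold
#' @return numeric fraction per bin
#' @export
hda_timecourse <- function(ci_lower, threshold) {
  colMeans(ci_lower > threshold, na.rm = TRUE)
}

#' Mixed-model test of spatial clustering
#'
#' Fits `r ~ distance * accuracy + (1 | movement) + (1 | animal)` by REML:
#' the pairwise correlation as a function of pairwise ROI distance
#' (continuous) interacting with decoding accuracy (standardized), with
#' random intercepts for movement type and animal. A singular random-effects
#' structure triggers a refit without the offending term (flagged in the
#' result); with no random terms left an ordinary linear model is used.
#'
#' @param pairs a `pair_table`
#' @param accuracies per-neuron decoding accuracies; a pair's accuracy is
#'   the mean of its two members'. Alternatively supply `pair_accuracy`.
#' @param pair_accuracy optional per-row accuracy overriding `accuracies`
#' @return list of class `cluster_model`: `coefficients` (estimate, SE, df,
#'   t, p per fixed term), `model`, `dropped` (random terms removed),
#'   `singular`
#' @export
fit_clustering_model <- function(pairs, accuracies = NULL, pair_accuracy = NULL) {
  d <- as.data.frame(pairs)
  d <- d[!is.na(d$pearson_r), ]
  if (is.null(pair_accuracy)) {
    if (is.null(accuracies)) stop("supply accuracies or pair_accuracy")
    pair_accuracy <- (accuracies[d$neuron_i] + accuracies[d$neuron_j]) / 2
  }
  d$accuracy <- as.numeric(scale(pair_accuracy))
  d$distance <- d$distance_um
  dropped <- character(0)

  forms <- list(
    r1 = pearson_r ~ distance * accuracy + (1 | movement) + (1 | animal_id),
    r2 = pearson_r ~ distance * accuracy + (1 | animal_id),
    r3 = pearson_r ~ distance * accuracy + (1 | movement))
  try_fit <- function(f) suppressMessages(suppressWarnings(
    lmerTest::lmer(f, data = d, REML = TRUE)))
  # random terms need > 1 level to be estimable
  n_mv <- length(unique(d$movement)); n_an <- length(unique(d$animal_id))
  if (n_mv < 2 && n_an < 2) {
    dropped <- c("movement", "animal_id")
    fit <- stats::lm(pearson_r ~ distance * accuracy, data = d)
  } else if (n_mv < 2) { dropped <- "movement"; fit <- try_fit(forms$r2)
  } else if (n_an < 2) { dropped <- "animal_id"; fit <- try_fit(forms$r3)
  } else fit <- try_fit(forms$r1)
  singular <- inherits(fit, "lmerMod") && lme4::isSingular(fit)
  if (singular) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    bad <- vc$grp[vc$vcov < 1e-10 & vc$grp != "Residual"]
    remaining <- setdiff(c("movement", "animal_id"), dropped)
    bad <- intersect(bad, remaining)
    keep <- setdiff(remaining, bad)
    dropped <- union(dropped, bad)
    fit <- if (identical(keep, "animal_id")) try_fit(forms$r2)
    else if (identical(keep, "movement")) try_fit(forms$r3)
    else stats::lm(pearson_r ~ distance * accuracy, data = d)
    if (inherits(fit, "lmerMod") && lme4::isSingular(fit)) {
      dropped <- c("movement", "animal_id")
      fit <- stats::lm(pearson_r ~ distance * accuracy, data = d)
    }
  }
  co <- if (inherits(fit, "lmerModLmerTest")) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, "Estimate"],
               se = s[, "Std. Error"], df = s[, "df"],
               t = s[, "t value"], p = s[, "Pr(>|t|)"], row.names = NULL)
  } else {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               df = stats::df.residual(fit), t = s[, 3], p = s[, 4],
               row.names = NULL)
  }
  structure(list(coefficients = co, model = fit, dropped = dropped,
                 singular = singular),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> pairwise correlation ~ distance * accuracy",
      "+ (1|movement) + (1|animal)\n")
  if (length(x$dropped))
    cat("  singular random effects dropped:", paste(x$dropped, collapse = ", "), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
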