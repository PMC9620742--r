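# shared small fixtures, built once per test run

small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(
        n_neurons = 24, n_push_trials = 12, n_pull_trials = 12,
        class_proportions = c(invariant_up = 0.375, invariant_down = 0.125,
                              push_type1 = 0.125, pull_type2 = 0.125,
                              reward_phase = 0.125, non_responsive = 0.125),
        seed = 7)
      g <- generate_session(cfg)
      dff <- compute_dff(g$session$raw_f, g$session$frame_rate)
      mi <- motion_index_series(g$session$motion_index, g$session$frame_rate)
      set.seed(70)
      ons <- vapply(seq_len(nrow(g$session$trials)), function(k)
        detect_motion_onset(mi, g$session$trials[k, ], n_boot = 1000),
        numeric(1))
      al <- align_trials(dff, ons, c(1, 4),
                         trial_labels = g$session$trials$type)
      cache <<- list(cfg = cfg, session = g$session, truth = g$truth,
                     dff = dff, mi = mi, onsets = ons, aligned = al,
                     completion_rel = g$session$trials$completion_s - ons)
    }
    cache
  }
})

# trials x time matrix with a planted difference-of-exponentials transient
planted_trials <- function(n_trials, time, amp, onset = 0, noise_sd = 0.2,
                           rise = 0.5, decay = 1.5) {
  fr <- 1 / median(diff(time))
  kern_t <- pmax(time - onset, 0)
  kern <- ifelse(time >= onset, exp(-kern_t / decay) - exp(-kern_t / rise), 0)
  kern <- kern / max(kern)
  m <- matrix(rep(amp * kern, each = n_trials), n_trials)
  m + matrix(rnorm(n_trials * length(time), 0, noise_sd), n_trials)
}

expected_labels <- function(true_class) {
  bias <- rep(NA_character_, length(true_class))
  bias[grepl("^invariant", true_class)] <- "invariant"
  bias[grepl("^push", true_class)] <- "push"
  bias[grepl("^pull", true_class)] <- "pull"
  resp <- ifelse(true_class == "non_responsive", "non_responsive",
                 ifelse(true_class == "reward_phase", "reward_phase",
                        "movement_related"))
  data.frame(responsiveness = resp, bias = bias, stringsAsFactors = FALSE)
}
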