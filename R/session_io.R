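SCHEMA_VERSION <- "1.0"

#' Session data container
#'
#' In-memory representation of one recording: raw fluorescence (neurons x
#' frames), frame rate, trial table, ROI centroids, optional cell-class
#' labels and motion index, plus provenance metadata.
#'
#' @param raw_f numeric matrix neurons x frames
#' @param frame_rate Hz
#' @param trials data.frame with trial_id, type, cue_s, motion_onset_s,
#'   completion_s, outcome
#' @param centroids neurons x 2 matrix (x_um, y_um)
#' @param cell_class optional per-neuron projection-class labels
#' @param motion_index optional per-frame motion index
#' @param meta list (seed, animal_id, fov_id, schema_version, provenance)
#' @return object of class `session_data`
#' @export
session_data <- function(raw_f, frame_rate, trials, centroids,
                         cell_class = NULL, motion_index = NULL,
                         meta = list()) {
  meta$schema_version <- meta$schema_version %||% SCHEMA_VERSION
  s <- structure(list(raw_f = raw_f, frame_rate = frame_rate, trials = trials,
                      centroids = centroids, cell_class = cell_class,
                      motion_index = motion_index, meta = meta),
                 class = "session_data")
  validate_session(s)
  s
}

validate_session <- function(s) {
  need <- c("trial_id", "type", "cue_s", "motion_onset_s", "completion_s", "outcome")
  miss <- setdiff(need, names(s$trials))
  if (length(miss))
    stop_lever2p("lever2p_missing_dataset", "trial table lacks columns: %s",
                 paste(miss, collapse = ", "))
  if (nrow(s$centroids) != nrow(s$raw_f))
    stop_lever2p("lever2p_shape_mismatch",
                 "centroids (%d) do not match neurons (%d)",
                 nrow(s$centroids), nrow(s$raw_f))
  if (!is.null(s$motion_index) && length(s$motion_index) != ncol(s$raw_f))
    stop_lever2p("lever2p_shape_mismatch",
                 "motion index length (%d) does not match frames (%d)",
                 length(s$motion_index), ncol(s$raw_f))
  if (!is.null(s$cell_class) && length(s$cell_class) != nrow(s$raw_f))
    stop_lever2p("lever2p_shape_mismatch",
                 "cell_class length does not match neurons")
  span <- ncol(s$raw_f) / s$frame_rate
  tt <- s$trials
  if (any(!(tt$cue_s < tt$motion_onset_s & tt$motion_onset_s < tt$completion_s)) ||
      is.unsorted(tt$cue_s) || any(tt$cue_s < 0) || any(tt$completion_s > span))
    stop_lever2p("lever2p_unordered_trials",
                 "trial times must be ordered (cue < onset < completion) and inside the recording")
  invisible(s)
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data> %d neurons x %d frames at %g Hz; %d trials (%s)\n",
              nrow(x$raw_f), ncol(x$raw_f), x$frame_rate, nrow(x$trials),
              paste(names(table(x$trials$type)), table(x$trials$type),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Write a session container to disk
#'
#' The container is a directory of plain-text files: `raw_f.csv` (neurons x
#' frames), `motion_index.csv`, `roi.csv` (centroids + optional class),
#' `trials.csv` and `meta.json` — inspectable by any toolchain.
#'
#' @param session a [session_data()]
#' @param path directory to create/overwrite
#' @return `path`, invisibly
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(session$raw_f),
                     file.path(path, "raw_f.csv"), col.names = FALSE)
  if (!is.null(session$motion_index))
    data.table::fwrite(data.table::data.table(mi = session$motion_index),
                       file.path(path, "motion_index.csv"))
  roi <- data.frame(x_um = session$centroids[, 1], y_um = session$centroids[, 2])
  if (!is.null(session$cell_class)) roi$cell_class <- session$cell_class
  data.table::fwrite(roi, file.path(path, "roi.csv"))
  data.table::fwrite(session$trials, file.path(path, "trials.csv"))
  meta <- session$meta
  meta$frame_rate <- session$frame_rate
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session container
#'
#' @param path container directory written by [write_session()]
#' @return a validated [session_data()]
#' @export
read_session <- function(path) {
  need <- c("raw_f.csv", "roi.csv", "trials.csv", "meta.json")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop_lever2p("lever2p_missing_dataset", "missing dataset: %s", f)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), SCHEMA_VERSION))
    stop_lever2p("lever2p_schema_version", "unsupported schema version: %s",
                 meta$schema_version %||% "<none>")
  raw <- as.matrix(data.table::fread(file.path(path, "raw_f.csv"), header = FALSE))
  dimnames(raw) <- NULL
  roi <- data.table::fread(file.path(path, "roi.csv"), data.table = FALSE)
  trials <- data.table::fread(file.path(path, "trials.csv"), data.table = FALSE)
  mi_path <- file.path(path, "motion_index.csv")
  mi <- if (file.exists(mi_path))
    data.table::fread(mi_path, data.table = FALSE)$mi else NULL
  fr <- meta$frame_rate
  meta$frame_rate <- NULL
  session_data(raw_f = raw, frame_rate = fr, trials = trials,
               centroids = as.matrix(roi[, c("x_um", "y_um")]),
               cell_class = roi$cell_class, motion_index = mi, meta = meta)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a synthetic or stored session
#'
#' Orchestrates the stages in order: `simulate` (or load a stored session),
#' `preprocess` (dF/F0, motion-index onsets, alignment), `classify`
#' (+ onsets), `decode`, `pca`, `spatial`, `report`. Later stages refuse to
#' run when a stage they depend on was not requested. Deterministic given
#' the seed; every output table carries the seed and a hash of the
#' configuration.
#'
#' @param config list (or path to a JSON file) with optional elements:
#'   `seed` (integer), `stages` (character vector), `session_path` (load
#'   instead of simulating), `synth` (overrides for [synth_config()]),
#'   `n_boot`, `n_null_reps`, `decode_window`, `pca_window` (c(pre, post)
#'   seconds)
#' @param out_dir output directory
#' @return (invisibly) list with the stage results and output paths
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("simulate", "preprocess", "classify",
                                 "decode", "pca", "spatial", "report")
  n_boot <- config$n_boot %||% 10000
  n_null_reps <- config$n_null_reps %||% 1000
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  stamp <- function(df) { df$seed <- seed; df$config_hash <- hash; df }
  write_out <- function(df, name) data.table::fwrite(stamp(as.data.frame(df)),
                                                     file.path(out_dir, name))
  need <- function(dep, stage)
    if (!dep %in% stages)
      stop_lever2p("lever2p_stage_dependency",
                   "stage '%s' requires stage '%s'", stage, dep)
  res <- list()

  if ("simulate" %in% stages && is.null(config$session_path)) {
    sc_args <- config$synth %||% list()
    sc_args$seed <- sc_args$seed %||% seed
    sc <- do.call(synth_config, sc_args)
    gen <- generate_session(sc)
    res$session <- gen$session; res$truth <- gen$truth
    write_session(gen$session, file.path(out_dir, "session"))
    data.table::fwrite(as.data.frame(gen$truth),
                       file.path(out_dir, "ground_truth.csv"))
  } else if (!is.null(config$session_path)) {
    res$session <- read_session(config$session_path)
  }

  if ("preprocess" %in% stages) {
    if (is.null(res$session)) need("simulate", "preprocess")
    s <- res$session
    set.seed(seed + 1L)
    dff <- compute_dff(s$raw_f, s$frame_rate)
    mi <- motion_index_series(s$motion_index, s$frame_rate)
    onsets <- vapply(seq_len(nrow(s$trials)), function(k)
      detect_motion_onset(mi, s$trials[k, ], mode = "imaging",
                          n_boot = min(n_boot, 2000)), numeric(1))
    dw <- config$decode_window %||% c(1, 4)
    pw <- config$pca_window %||% c(2.5, 5)
    res$dff <- dff
    res$mi_onsets <- onsets
    ok <- !is.na(onsets)
    res$aligned <- align_trials(dff, onsets[ok], dw,
                                trial_labels = s$trials$type[ok])
    res$aligned_pca <- align_trials(dff, onsets[ok], pw,
                                    trial_labels = s$trials$type[ok])
    res$completion_rel <- (s$trials$completion_s - onsets)[ok]
    res$mi_aligned <- align_trials(matrix(s$motion_index, 1), onsets[ok], dw,
                                   frame_rate = s$frame_rate)
  }

  if ("classify" %in% stages) {
    need("preprocess", "classify")
    set.seed(seed + 2L)
    res$classification <- classify_neurons(res$aligned, res$completion_rel,
                                           n_boot = n_boot)
    write_out(res$classification, "classification.csv")
    sm <- summary(res$classification)
    res$summary_counts <- list(
      responsiveness = as.list(sm$responsiveness),
      bias = as.list(sm$bias), bias_types = as.list(sm$bias_types))
  }

  if ("decode" %in% stages) {
    need("preprocess", "decode")
    res$decoding <- decode_session(res$aligned, n_null_reps = n_null_reps,
                                   n_boot = n_boot, seed = seed + 3L)
    write_out(res$decoding$neurons, "decoding_neurons.csv")
  }

  if ("pca" %in% stages) {
    need("preprocess", "pca")
    res$pca <- pca_trajectories(res$aligned_pca,
                                n_pcs = min(16, dim(res$aligned_pca$data)[1]),
                                seed = seed + 4L)
    mv_end <- stats::median(res$completion_rel)
    res$dprime <- dprime_timeseries(res$pca$proj, res$aligned_pca$trial_labels,
                                    res$aligned_pca$time,
                                    window = c(0, max(res$completion_rel)),
                                    seed = seed + 5L)
    write_out(res$dprime$per_pc, "dprime.csv")
  }

  if ("spatial" %in% stages) {
    need("classify", "spatial"); need("decode", "spatial")
    groups <- ifelse(res$decoding$neurons$hda, "HDA", "LDA")
    ep <- attr(res$classification, "epochs")
    res$pairs <- pairwise_activity_correlations(
      res$aligned, res$session$centroids, epoch = ep$peri, groups = groups)
    write_out(res$pairs, "pairs.csv")
    res$cluster_model <- fit_clustering_model(
      res$pairs, accuracies = res$decoding$neurons$max_accuracy)
    write_out(res$cluster_model$coefficients, "model_coefficients.csv")
  }

  if ("report" %in% stages) {
    report <- list(seed = seed, config_hash = hash,
                   schema_version = SCHEMA_VERSION,
                   counts = res$summary_counts,
                   decoding = if (!is.null(res$decoding)) list(
                     threshold = res$decoding$threshold,
                     n_hda = sum(res$decoding$neurons$hda),
                     median_max_accuracy = stats::median(
                       res$decoding$neurons$max_accuracy, na.rm = TRUE)),
                   dprime = if (!is.null(res$dprime))
                     res$dprime$max_significant_dprime)
    jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(res)
}
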