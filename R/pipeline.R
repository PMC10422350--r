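#' Pipeline configuration
#'
#' Layered defaults for the whole chain. Unknown keys are rejected so typos
#' fail loudly.
#'
#' @param window_samples Moving-variance window (default 1000 samples =
#'   250 ms at 4 kHz).
#' @param hop_samples Moving-variance hop (default 1).
#' @param order Polynomial order for cycle fits (default 7).
#' @param windows_per_matrix Cumulative-AUC samples per signature frame
#'   (default 40; at 4 kHz that is 100 frames per second of signal).
#' @param alpha Significance level for group comparisons (default 0.05).
#' @param seed Integer seed for simulation commands.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_samples = 1000L, hop_samples = 1L,
                            order = 7L, windows_per_matrix = 40L,
                            alpha = 0.05, seed = 1L) {
  cfg <- list(window_samples = as.integer(window_samples),
              hop_samples = as.integer(hop_samples),
              order = as.integer(order),
              windows_per_matrix = as.integer(windows_per_matrix),
              alpha = alpha, seed = as.integer(seed))
  if (cfg$window_samples <= 1L || cfg$hop_samples < 1L || cfg$order < 1L ||
      cfg$windows_per_matrix < 2L || alpha <= 0 || alpha >= 1) {
    stop("invalid pipeline configuration", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Merge a config list into pipeline defaults, rejecting unknown keys
#' @param overrides Named list of configuration overrides.
#' @return A [pipeline_config()].
#' @export
as_pipeline_config <- function(overrides = list()) {
  if (inherits(overrides, "pipeline_config")) return(overrides)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(pipeline_config, overrides)
}

#' Pipeline commands
#'
#' Thin, deterministic wrappers tying the stages together; each is a pure
#' function of its inputs, the configuration and the seed, and each report
#' echoes the configuration it was produced with.
#'
#' * `run_simulate()` generates a recording and writes CSV + JSON sidecar.
#' * `run_features()` reads a recording and writes the per-cycle AUC table
#'   for both channels.
#' * `run_fuse()` builds per-cycle target signature matrices from a
#'   recording (zoned by the template library's stored boundaries) and
#'   classifies each against the library.
#' * `run_stats()` compares per-cycle cumulative AUCs between two conditions
#'   with the two-group F test for each channel.
#'
#' @param sim A [sim_config()].
#' @param csv_path Recording CSV path.
#' @param config A [pipeline_config()] or named list of overrides.
#' @return Each command returns its primary artifact invisibly (path or
#'   report list).
#' @export
run_simulate <- function(sim, csv_path) {
  rec <- simulate_recording(sim)
  write_recording(rec, csv_path)
}

#' @rdname run_simulate
#' @param out_path Output path for the command's artifact.
#' @export
run_features <- function(csv_path, out_path, config = list()) {
  config <- as_pipeline_config(config)
  rec <- read_recording(csv_path)
  feats <- do.call(rbind, lapply(c("sound", "ecg"), function(ch)
    as.data.frame(extract_cycle_features(
      rec, ch, window_samples = config$window_samples,
      hop_samples = config$hop_samples, order = config$order))))
  write_features(feats, out_path)
  invisible(feats)
}

#' @rdname run_simulate
#' @param templates_path JSON template library (with stored zone
#'   boundaries) used to zone and classify the targets.
#' @export
run_fuse <- function(csv_path, templates_path, out_path, config = list()) {
  config <- as_pipeline_config(config)
  rec <- read_recording(csv_path)
  lib <- read_template_library(templates_path)
  if (is.null(lib$boundaries)) {
    stop(sprintf("template library %s carries no zone boundaries",
                 templates_path), call. = FALSE)
  }
  sig <- signature_series(rec, boundaries = lib$boundaries,
                          windows_per_matrix = config$windows_per_matrix,
                          window_samples = config$window_samples,
                          hop_samples = config$hop_samples)
  results <- lapply(sig$matrices, classify_signature, library = lib)
  report <- list(
    config = unclass(config),
    templates = basename(templates_path),
    cycles = lapply(seq_along(results), function(k) {
      r <- results[[k]]
      list(cycle = k,
           true_condition = attr(sig$matrices[[k]], "condition"),
           label = r$label, margin = r$margin, tie = r$tie,
           sse = as.list(r$sse),
           matrix = as.vector(t(unclass(sig$matrices[[k]]))))
    })
  )
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @rdname run_simulate
#' @param features_path Features CSV produced by `run_features()`.
#' @param group_a,group_b Condition names: a tidal volume in mL (`"1000"`,
#'   `"500"`, ...) or `"cough"`.
#' @export
run_stats <- function(features_path, group_a = "1000", group_b = "500",
                      out_path = NULL, config = list()) {
  config <- as_pipeline_config(config)
  feats <- read_features(features_path)
  pick <- function(df, cond) {
    if (identical(cond, "cough")) df[df$is_cough, ]
    else df[!df$is_cough & df$tidal_volume_ml == as.numeric(cond), ]
  }
  per_channel <- lapply(c(sound = "sound", ecg = "ecg"), function(ch) {
    d <- feats[feats$channel == ch, ]
    a <- pick(d, group_a)$cum_auc_final
    b <- pick(d, group_b)$cum_auc_final
    if (length(a) < 2L || length(b) < 2L) {
      stop(sprintf("condition groups too small for channel %s (%d vs %d cycles)",
                   ch, length(a), length(b)), call. = FALSE)
    }
    one_way_f_test(a, b, alpha = config$alpha,
                   labels = c(group_a, group_b))
  })
  report <- list(
    config = unclass(config),
    comparison = paste(group_a, "vs", group_b),
    f_sound = per_channel$sound$f_value,
    p_sound = per_channel$sound$p_value,
    f_ecg = per_channel$ecg$f_value,
    p_ecg = per_channel$ecg$p_value,
    f_critical = per_channel$sound$f_critical,
    df = as.list(per_channel$sound$df),
    alpha = config$alpha
  )
  if (!is.null(out_path)) {
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Build a template library from labelled recordings
#'
#' Pools the within-cycle cumulative-AUC values of all recordings to derive
#' tertile zone boundaries, builds per-cycle signature matrices per
#' condition, and averages them into one template per condition. The
#' boundaries are stored in the library so later targets are zoned
#' identically.
#'
#' @param recordings Named list of `multimodal_recording` objects (names =
#'   condition labels).
#' @param config A [pipeline_config()] or overrides list.
#' @return A [template_library()] with boundaries.
#' @export
build_templates <- function(recordings, config = list()) {
  config <- as_pipeline_config(config)
  if (!length(recordings) || is.null(names(recordings))) {
    stop("`recordings` must be a named list of recordings", call. = FALSE)
  }
  curves <- lapply(recordings, cycle_cumulative_curves,
                   windows_per_matrix = config$windows_per_matrix,
                   window_samples = config$window_samples,
                   hop_samples = config$hop_samples)
  bounds <- auto_zone_boundaries(
    unlist(lapply(curves, function(cv) unlist(cv$sound))),
    unlist(lapply(curves, function(cv) unlist(cv$ecg)))
  )
  entries <- lapply(names(recordings), function(cond) {
    cv <- curves[[cond]]
    mats <- lapply(seq_along(cv$sound), function(k)
      build_signature_matrix(cv$sound[[k]], cv$ecg[[k]], bounds,
                             sample_point = k, condition = cond))
    mean_signature(mats, condition = cond)
  })
  names(entries) <- names(recordings)
  template_library(entries, boundaries = bounds)
}

# Within-cycle cumulative-AUC curves for both channels of one recording.
cycle_cumulative_curves <- function(recording, windows_per_matrix = 40L,
                                    window_samples = 1000L,
                                    hop_samples = 1L) {
  feats <- lapply(c(sound = "sound", ecg = "ecg"), function(ch)
    extract_cycle_features(recording, ch, window_samples = window_samples,
                           hop_samples = hop_samples))
  curves <- lapply(feats, function(f)
    lapply(attr(f, "fits"), function(fit)
      cumulative_auc_series(fit, n_points = windows_per_matrix)$values))
  list(sound = curves$sound, ecg = curves$ecg,
       sound_features = feats$sound, ecg_features = feats$ecg)
}
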