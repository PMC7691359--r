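#' @title End-to-end pipeline
#'
#' @description Orchestrates simulate -> background-subtract -> calibrate ->
#' accept -> downsample -> nested validation as one deterministic run.
#' Sessions are materialised one at a time: the full perturbation sequence
#' is kept for calibration but only the strongest difference images (the
#' only candidates for acceptance at practical particle ratios) are
#' retained, so a whole campaign never sits in memory.
#'
#' @name pipeline_cli
#' @keywords internal
NULL

# simulate one planned session and reduce it to (P sequence, retained images)
collect_session_samples <- function(plan, index, keep_top_frac = 0.25) {
  stream <- materialize_session(plan, index)
  diffs <- background_subtract(stream)
  P <- diffs$meta$P
  n_keep <- max(1L, ceiling(keep_top_frac * length(P)))
  keep_idx <- sort(order(P, decreasing = TRUE)[seq_len(n_keep)])
  kept <- subset_samples(diffs, keep_idx)
  kept$meta$true_label <- stream$label
  list(P = P, kept = kept, kept_index = keep_idx, label = stream$label,
       session_id = stream$session_id,
       n_particle_frames = length(unique(stream$annotations$frame)))
}

#' Simulate, calibrate and preprocess a planned campaign
#'
#' Builds the acceptance curve from the pooled perturbation sequences,
#' selects the common threshold achieving \code{target_R} (unless a
#' \code{theta} is given), applies the acceptance rule per session, and
#' downsamples the accepted samples.
#'
#' @param plan a \code{session_plan} from
#'   \code{\link{make_intertwined_dataset}}.
#' @param target_R target particle ratio (ignored when \code{theta} given).
#' @param theta optional fixed acceptance threshold.
#' @param factor downsampling factor applied to accepted samples.
#' @param keep_top_frac fraction of highest-P difference images retained per
#'   session while streaming; must comfortably exceed \code{target_R}.
#' @param threshold_grid optional explicit theta grid for the curve.
#' @return list with \code{dataset} (a \code{session_dataset}),
#'   \code{curve}, \code{theta}, \code{achieved_R} and per-session counts.
#' @export
preprocess_plan <- function(plan, target_R = 0.04, theta = NULL, factor = 1,
                            keep_top_frac = 0.25, threshold_grid = NULL) {
  n_sessions <- length(plan$entries)
  collected <- lapply(seq_len(n_sessions), collect_session_samples,
                      plan = plan, keep_top_frac = keep_top_frac)
  curve <- build_curve(lapply(collected, `[[`, "P"), threshold_grid,
                       tag = if (plan$optical$grating_enabled) "DG" else "NDG")
  if (is.null(theta)) {
    sel <- threshold_for_ratio(curve, target_R)
    theta <- sel$theta
    achieved <- sel$achieved_R
  } else {
    achieved <- NA_real_
  }
  sessions <- lapply(collected, function(cs) {
    acc <- which(acceptance_flags(cs$P, theta))
    if (!all(acc %in% cs$kept_index)) {
      stop("keep_top_frac too small: accepted frames were not retained")
    }
    s <- subset_samples(cs$kept, match(acc, cs$kept_index))
    if (factor > 1) s <- downsample_samples(s, factor)
    s
  })
  pairs <- lapply(seq_len(plan$N_s), function(n) {
    list(A = sessions[[2 * n - 1]], B = sessions[[2 * n]])
  })
  counts <- data.frame(
    session_id = vapply(collected, `[[`, "", "session_id"),
    label = vapply(collected, `[[`, "", "label"),
    particle_frames = vapply(collected, `[[`, 0L, "n_particle_frames"),
    accepted = vapply(sessions, function(s) nrow(s$images), 0L))
  list(dataset = session_dataset(pairs, theta), curve = curve, theta = theta,
       achieved_R = achieved, counts = counts)
}

resolve_run_config <- function(config = list()) {
  defaults <- list(
    seed = 1, N_s = 5, target_R = 0.04, factor = 2, keep_fraction = 1,
    grating = FALSE, bias = 0, audit = FALSE, keep_top_frac = 0.25,
    n_frames_per_session = 400, hyper_grid = default_C_grid(),
    # desk-scale bead concentrations: boosted (same A:B ratio as the bench
    # mixtures) so a few-hundred-frame session reaches the R ~ 0.04 working
    # point with a clean margin between background and particle P
    bead_a = bead_class_A(concentration_per_ml = 2.8e4),
    bead_b = bead_class_B(concentration_per_ml = 1.6e4),
    optical = list(), flow = list(), acquisition = list(), drift = list())
  cfg <- utils::modifyList(defaults, config)
  cfg$optical <- do.call(desk_optical_config,
                         utils::modifyList(list(grating_enabled = cfg$grating),
                                           cfg$optical))
  cfg$flow <- do.call(flow_config, cfg$flow)
  acq_args <- utils::modifyList(
    list(session_duration = cfg$n_frames_per_session / 138), cfg$acquisition)
  cfg$acquisition <- do.call(acquisition_config, acq_args)
  cfg$drift <- do.call(session_drift_model,
                       utils::modifyList(list(drift_class_correlation = cfg$bias),
                                         cfg$drift))
  cfg
}

#' Run the full classification experiment
#'
#' Executes the whole pipeline deterministically from a single
#' configuration: plan the intertwined sessions, simulate and preprocess
#' them, calibrate the acceptance threshold, run the nested session-wise
#' validation (and optionally the bias audit), and write all artifacts to
#' \code{out_dir}.
#'
#' @param config named list of overrides; see
#'   \code{holocyto:::resolve_run_config} for fields and defaults (notably
#'   \code{seed}, \code{N_s}, \code{target_R}, \code{factor},
#'   \code{grating}, \code{bias}, \code{n_frames_per_session}).
#' @param out_dir optional output directory for the resolved config,
#'   acceptance curve CSV, CV report JSON/CSV and manifest.
#' @return list with the \code{cv_report}, preprocessing results, resolved
#'   config and (if requested) the audit.
#' @export
run_experiment <- function(config = list(), out_dir = NULL) {
  cfg <- resolve_run_config(config)
  plan <- make_intertwined_dataset(
    cfg$N_s, cfg$bead_a, cfg$bead_b, cfg$optical, cfg$flow,
    cfg$acquisition, cfg$drift, seed = cfg$seed)
  prep <- preprocess_plan(plan, target_R = cfg$target_R, factor = cfg$factor,
                          keep_top_frac = cfg$keep_top_frac)
  report <- nested_session_cv(prep$dataset, cfg$hyper_grid, cfg$keep_fraction)
  audit <- if (isTRUE(cfg$audit)) bias_audit(prep$dataset) else NULL
  result <- list(report = report, prep = prep, config = cfg, audit = audit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_out <- cfg
    for (f in c("optical", "flow", "acquisition", "drift", "bead_a", "bead_b")) {
      cfg_out[[f]] <- unclass(cfg[[f]])
    }
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    write_curve(prep$curve, file.path(out_dir, "acceptance_curve.csv"))
    write_cv_report(report, file.path(out_dir, "cv_report.json"))
    utils::write.csv(prep$counts, file.path(out_dir, "session_counts.csv"),
                     row.names = FALSE)
    if (!is.null(audit)) {
      jsonlite::write_json(audit, file.path(out_dir, "bias_audit.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  result
}

#' Per-particle inference latency of the deployed pipeline
#'
#' Times the online classification path (float conversion + background
#' subtraction + perturbation threshold + weighted sum) on raw frames.
#' Reported for information only; wall-clock values are hardware-dependent.
#'
#' @param readout a trained \code{linear_readout}.
#' @param frames list of raw integer frames (consecutive; frame 1 is the
#'   background reference).
#' @param theta acceptance threshold applied to P.
#' @param repeats number of timed iterations (median reported).
#' @param factor downsampling factor matching the readout's resolution.
#' @return list with \code{median_us}, \code{iqr_us}, \code{resolution},
#'   \code{repeats}.
#' @export
benchmark_inference <- function(readout, frames, theta = 0, repeats = 100,
                                factor = 1) {
  stopifnot(length(frames) >= 2, repeats >= 1)
  bg <- frames[[1]]
  times <- vapply(seq_len(repeats), function(r) {
    f <- frames[[2 + (r - 1) %% (length(frames) - 1)]]
    t0 <- proc.time()[["elapsed"]]
    d <- matrix(as.numeric(f), nrow(f)) - matrix(as.numeric(bg), nrow(bg))
    if (overall_perturbation(d) > theta) {
      img <- if (factor > 1) downsample(d, factor) else d
      x <- matrix(as.numeric(img), nrow = 1)
      if (!is.null(readout$feature_mask)) {
        x <- x[, as.logical(readout$feature_mask$mask), drop = FALSE]
      }
      xs <- (x - readout$feature_means) / readout$feature_scales
      invisible(sum(xs * readout$weights) + readout$intercept)
    }
    (proc.time()[["elapsed"]] - t0) * 1e6
  }, 0)
  list(median_us = stats::median(times),
       iqr_us = unname(diff(stats::quantile(times, c(0.25, 0.75)))),
       resolution = if (!is.null(readout$input_shape))
         readout$input_shape else dim(bg),
       repeats = repeats)
}
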