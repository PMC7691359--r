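#' @title Frame-stream and report I/O
#'
#' @description Sessions are persisted as 8-bit grayscale PNG sequences with
#' a JSON sidecar carrying the ground-truth annotations, drift state and
#' seed; directories follow the layout \code{session_<idx>_<class>/}.
#'
#' @name holocyto_io
#' @keywords internal
NULL

#' Write a session as a PNG sequence plus JSON sidecar
#'
#' @param stream a \code{frame_stream}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_session_png <- function(stream, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(stream$frames)) {
    png::writePNG(stream$frames[[t]] / 255,
                  file.path(dir, sprintf("frame_%05d.png", t)))
  }
  sidecar <- list(session_id = stream$session_id, label = stream$label,
                  seed = stream$seed,
                  drift_state = unclass(stream$drift_state),
                  n_frames = stream$n_frames,
                  sensor_shape = stream$optical$sensor_shape,
                  annotations = stream$annotations)
  jsonlite::write_json(sidecar, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a session written by \code{\link{write_session_png}}
#'
#' @param dir session directory.
#' @return a \code{frame_stream} (configs are not round-tripped; the frames,
#'   annotations, drift state and identity are).
#' @export
read_session_png <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
  ann <- as.data.frame(meta$annotations)
  structure(list(frames = frames, session_id = meta$session_id,
                 label = meta$label, seed = meta$seed,
                 drift_state = structure(meta$drift_state, class = "drift_state"),
                 annotations = ann,
                 optical = list(sensor_shape = meta$sensor_shape),
                 n_frames = length(frames)),
            class = "frame_stream")
}

#' Write a nested-CV report as JSON (+ per-fold CSV)
#'
#' @param report a \code{cv_report}.
#' @param path JSON output path; a sibling \code{*_folds.csv} is written too.
#' @export
write_cv_report <- function(report, path) {
  obj <- list(p_final = report$p_final, folds = report$folds,
              hyper_grid = report$hyper_grid,
              keep_fraction = report$keep_fraction)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  utils::write.csv(report$folds,
                   sub("\\.json$", "_folds.csv", path), row.names = FALSE)
  invisible(path)
}
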