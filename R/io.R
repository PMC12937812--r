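#' NIfTI and tabular I/O
#'
#' Volumes, masks and weight maps are written as NIfTI-1 (via \pkg{RNifti});
#' schedules, tap events, scores and traces as CSV; ground truth and model
#' metadata as JSON sidecars.
#'
#' @param x object to write (see details per function).
#' @param path output file path.
#' @name nfsim-io
NULL

#' @rdname nfsim-io
#' @export
write_volume_nifti <- function(x, path) {
  stopifnot(inherits(x, "volume_series"))
  arr <- array(x$data, dim = c(x$grid_shape, ncol(x$data)))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, x$tr_s))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nfsim-io
#' @param tr_s repetition time to attach when reading.
#' @export
read_volume_nifti <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4)
  tr_s <- tr_s %||% RNifti::pixdim(img)[4]
  volume_series(matrix(img, prod(d[1:3]), d[4]), d[1:3], tr_s)
}

#' @rdname nfsim-io
#' @export
write_mask_nifti <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(x), dim = dim(x))), path,
                     datatype = "uint8")
  invisible(path)
}

#' @rdname nfsim-io
#' @export
write_schedule_csv <- function(x, path) {
  stopifnot(inherits(x, "block_schedule"))
  utils::write.csv(x$blocks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname nfsim-io
#' @export
read_schedule_csv <- function(path, run_kind, tr_s = 2, total_duration_s = NULL) {
  block_schedule(utils::read.csv(path), run_kind = run_kind, tr_s = tr_s,
                 total_duration_s = total_duration_s)
}

#' @rdname nfsim-io
#' @param streams list of `tap_stream`s.
#' @export
write_taps_csv <- function(streams, path) {
  streams <- as_stream_list(streams)
  rows <- do.call(rbind, lapply(streams, function(s)
    if (length(s$tap_times_s))
      data.frame(block_id = s$block_id, instructed_rate_hz = s$instructed_rate_hz,
                 onset_s = s$onset_s, duration_s = s$duration_s,
                 tap_time_s = s$tap_times_s)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname nfsim-io
#' @export
read_taps_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$block_id), function(b)
    structure(list(block_id = b$block_id[1],
                   instructed_rate_hz = b$instructed_rate_hz[1],
                   onset_s = b$onset_s[1], duration_s = b$duration_s[1],
                   tap_times_s = sort(b$tap_time_s)),
              class = "tap_stream"))
}

#' @rdname nfsim-io
#' @param model a `classifier_model`.
#' @param prefix path prefix; writes `<prefix>_weights.nii.gz` and
#'   `<prefix>_model.json`.
#' @export
write_model <- function(model, prefix) {
  w <- volume_series(matrix(model$weights, ncol = 1), model$grid_shape, 1)
  write_volume_nifti(w, paste0(prefix, "_weights.nii.gz"))
  jsonlite::write_json(list(bias = model$bias, grid_shape = model$grid_shape,
                            training_meta = model$training_meta),
                       paste0(prefix, "_model.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname nfsim-io
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$tap_scores, file.path(dir, "tap_scores.csv"), row.names = FALSE)
  utils::write.csv(report$improvements, file.path(dir, "improvements.csv"), row.names = FALSE)
  utils::write.csv(report$imagery_accuracy, file.path(dir, "imagery_accuracy.csv"), row.names = FALSE)
  utils::write.csv(report$held_out, file.path(dir, "held_out_accuracy.csv"), row.names = FALSE)
  for (nm in names(report$group)) {
    utils::write.csv(as.data.frame(report$group[[nm]]$clusters),
                     file.path(dir, paste0("clusters_", nm, ".csv")), row.names = FALSE)
    sm <- report$group[[nm]]$map
    write_volume_nifti(volume_series(matrix(ifelse(is.na(sm$t), 0, sm$t), ncol = 1),
                                     sm$grid_shape, 1),
                       file.path(dir, paste0("tmap_", nm, ".nii.gz")))
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
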