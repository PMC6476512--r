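#' Write and read glottal area waveforms as CSV
#'
#' The CSV carries one row per frame with columns `frame` (0-based),
#' `gaw_total`, `gaw_left`, `gaw_right`; frame rate and glottal length go
#' into a JSON sidecar written next to the CSV when `sidecar = TRUE`.
#'
#' @param triple A [gaw_triple()].
#' @param path Output CSV path.
#' @param sidecar Also write `<path>.json` with `fps` and `glottal_length`.
#' @export
write_gaw_csv <- function(triple, path, sidecar = TRUE) {
  stopifnot(inherits(triple, "gaw_triple"))
  df <- data.frame(frame = seq_along(triple$total) - 1L,
                   gaw_total = triple$total,
                   gaw_left = triple$left,
                   gaw_right = triple$right)
  write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(list(fps = triple$fps,
                              glottal_length = triple$glottal_length),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_gaw_csv
#' @param fps,glottal_length Used when no JSON sidecar is found.
#' @export
read_gaw_csv <- function(path, fps = NULL, glottal_length = NA_real_) {
  df <- read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(fps)) fps <- meta$fps
    if (is.na(glottal_length) && !is.null(meta$glottal_length)) {
      glottal_length <- meta$glottal_length
    }
  }
  if (is.null(fps)) stop("`fps` must be given when no sidecar exists", call. = FALSE)
  gaw_triple(df$gaw_total, df$gaw_left, df$gaw_right, fps, glottal_length)
}

#' Write and read video stacks as multi-page TIFF
#'
#' Frames are stored as 8-bit grayscale pages. [write_video_tiff()] can add
#' a JSON sidecar with the generating configuration and ground truth of a
#' synthetic recording.
#'
#' @param video A [video_stack()].
#' @param path Output TIFF path.
#' @param config,truth Optional [subject_config()] and ground truth to store
#'   in `<path>.json`.
#' @export
write_video_tiff <- function(video, path, config = NULL, truth = NULL) {
  stopifnot(inherits(video, "video_stack"))
  pages <- lapply(seq_len(dim(video$px)[3]), function(f) video$px[, , f] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(fps = video$fps)
  if (!is.null(config)) meta$config <- unclass(config)
  if (!is.null(truth)) meta$truth <- unclass(truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_video_tiff
#' @param fps Frame rate; read from the JSON sidecar when present.
#' @export
read_video_tiff <- function(path, fps = NULL) {
  side <- paste0(path, ".json")
  if (file.exists(side) && is.null(fps)) {
    fps <- jsonlite::read_json(side, simplifyVector = TRUE)$fps
  }
  if (is.null(fps)) stop("`fps` must be given when no sidecar exists", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  px <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) px[, , f] <- round(pages[[f]] * 255)
  video_stack(px, fps)
}
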