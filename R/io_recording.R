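#' Write / read a recording as CSV plus JSON annotation sidecar
#'
#' The CSV has header `time_s,sound,ecg`; samples are printed with 17
#' significant digits so that `read_recording(write_recording(x))` round-trips
#' every double exactly. Annotations go to a JSON sidecar
#' (`{sampling_rate_hz, cycles: [{start, inhale_end, end, tidal_volume_ml,
#' is_cough}, ...]}`) whose default path is the CSV path with extension
#' `.json`.
#'
#' @param recording A `multimodal_recording`.
#' @param csv_path Path of the sample CSV to write/read.
#' @param json_path Path of the annotation sidecar; defaults to `csv_path`
#'   with a `.json` extension.
#' @return `write_recording()` returns `csv_path` invisibly;
#'   `read_recording()` returns a `multimodal_recording`.
#' @export
write_recording <- function(recording, csv_path,
                            json_path = sidecar_path(csv_path)) {
  validate_recording(recording)
  n <- length(recording$sound)
  time_s <- (seq_len(n) - 1) / recording$sampling_rate_hz
  lines <- c(
    "time_s,sound,ecg",
    sprintf("%.17g,%.17g,%.17g", time_s, recording$sound, recording$ecg)
  )
  writeLines(lines, csv_path)
  ann <- recording$annotations
  jsonlite::write_json(
    list(
      sampling_rate_hz = recording$sampling_rate_hz,
      cycles = ann[, c("start", "inhale_end", "end", "tidal_volume_ml",
                       "is_cough")]
    ),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(csv_path)
}

sidecar_path <- function(csv_path) {
  sub("\\.[A-Za-z0-9]+$", ".json", csv_path)
}

#' @rdname write_recording
#' @export
read_recording <- function(csv_path, json_path = sidecar_path(csv_path)) {
  if (!file.exists(csv_path)) {
    stop(sprintf("recording file not found: %s", csv_path), call. = FALSE)
  }
  lines <- readLines(csv_path)
  if (length(lines) == 0L || all(!nzchar(lines))) {
    stop(sprintf("empty recording file: %s", csv_path), call. = FALSE)
  }
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  required <- c("time_s", "sound", "ecg")
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop(sprintf("recording CSV %s is missing column(s): %s",
                 csv_path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) {
    stop(sprintf("recording CSV %s has a header but no samples", csv_path),
         call. = FALSE)
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad)) {
    stop(sprintf("parse error in %s at line %d: expected %d fields, found %d",
                 csv_path, bad[1] + 1L, length(header), nf[bad[1]]),
         call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = length(header), byrow = TRUE)
  if (anyNA(mat)) {
    bad_row <- which(apply(mat, 1, anyNA))[1]
    stop(sprintf("parse error in %s at line %d: non-numeric value",
                 csv_path, bad_row + 1L), call. = FALSE)
  }
  colnames(mat) <- header

  if (!file.exists(json_path)) {
    stop(sprintf("annotation sidecar not found: %s", json_path),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz) || is.null(meta$cycles)) {
    stop(sprintf("annotation sidecar %s must contain sampling_rate_hz and cycles",
                 json_path), call. = FALSE)
  }
  cyc <- as.data.frame(meta$cycles)
  ann <- data.frame(
    cycle = seq_len(nrow(cyc)),
    start = as.integer(cyc$start),
    inhale_end = as.integer(cyc$inhale_end),
    end = as.integer(cyc$end),
    tidal_volume_ml = as.numeric(cyc$tidal_volume_ml),
    is_cough = as.logical(cyc$is_cough)
  )
  rec <- structure(list(
    sampling_rate_hz = as.numeric(meta$sampling_rate_hz),
    sound = unname(mat[, "sound"]),
    ecg = unname(mat[, "ecg"]),
    annotations = ann
  ), class = "multimodal_recording")
  validate_recording(rec)
}
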