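# Readers and writers for the package's plain-text exchange formats:
# gaze streams as CSV (header t,x,y,valid, '.' decimal separator, UTF-8),
# boards and reports as versioned JSON, heat maps as dense matrix CSV.

# format doubles so that a write -> read round trip is exact
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- "NA"
  out
}

#' Read a gaze recording from CSV
#'
#' Expects delimited text with a header line `t,x,y,valid`. Timestamps are
#' seconds since test start (device millisecond ticks must be converted at
#' ingest; every dwell threshold in the package is in seconds). `valid` is
#' 0/1; invalid samples may carry `NaN` coordinates.
#'
#' @param path file path.
#' @param sample_rate_hz,meta passed to [gaze_recording()].
#' @return An `etnt_gaze` object with samples sorted by time.
#' @export
read_gaze <- function(path, sample_rate_hz = NA_real_, meta = list()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("t", "x", "y", "valid")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("gaze file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("t", "x", "y")) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !(toupper(trimws(v)) %in% c("NAN", "NA", "")))
      if (length(bad)) {
        stop(sprintf("malformed value in column '%s' at data row %d of %s",
                     col, bad[1L], path), call. = FALSE)
      }
      raw[[col]] <- num
    }
  }
  if (nrow(raw)) {
    bad <- which(diff(raw$t) <= 0)
    if (length(bad)) {
      stop(sprintf("non-monotone timestamps in %s at data row %d",
                   path, bad[1L] + 1L), call. = FALSE)
    }
  }
  gaze_recording(raw, sample_rate_hz = sample_rate_hz, meta = meta)
}

#' Write a gaze recording to CSV
#'
#' @param recording an `etnt_gaze` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(recording, path) {
  stopifnot(inherits(recording, "etnt_gaze"))
  s <- recording$samples
  out <- data.frame(t = fmt_num(s$t), x = fmt_num(s$x), y = fmt_num(s$y),
                    valid = as.integer(s$valid), stringsAsFactors = FALSE)
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write gaze file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Write a stimulus board to JSON
#'
#' The document carries an explicit `schema_version` field alongside the
#' geometry, detection parameters and stimulus list.
#'
#' @param board an `etnt_board` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_board <- function(board, path) {
  stopifnot(inherits(board, "etnt_board"))
  doc <- list(
    schema_version = ETNT_SCHEMA_VERSION,
    geometry = list(width_px = board$geometry$width_px,
                    height_px = board$geometry$height_px),
    detection = list(dwell_s = board$detection$dwell_s,
                     zone_diameter = board$detection$zone_diameter),
    stimuli = board$stimuli[, c("id", "x", "y", "kind")]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stimulus board from JSON
#'
#' @param path file written by [write_board()].
#' @return An `etnt_board` object.
#' @export
read_board <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("schema_version", "geometry", "detection", "stimuli")
  missing_keys <- setdiff(required, names(doc))
  if (length(missing_keys)) {
    stop("board file ", path, " is missing keys: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  stimulus_board(
    doc$stimuli,
    geometry = screen_geometry(doc$geometry$width_px, doc$geometry$height_px),
    detection = detection_params(doc$detection$dwell_s,
                                 doc$detection$zone_diameter)
  )
}

# indexes a report JSON must carry to be loadable
report_required_keys <- function() {
  c("located_total", "located_left", "located_right",
    "missed_left", "missed_right", "test_duration_s",
    "mean_latency_s", "mean_proximity", "laterality_index",
    "start_sector", "strategy")
}

#' Write a neglect report to JSON
#'
#' Serializes every index of the report plus provenance (board fingerprint
#' and the detection parameters in force when it was scored). Undefined
#' indexes are written as JSON null.
#'
#' @param report an `etnt_report` object from [score_test()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "etnt_report"))
  doc <- unclass(report)
  doc$schema_version <- ETNT_SCHEMA_VERSION
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a neglect report from JSON
#'
#' @param path file written by [write_report()].
#' @return An `etnt_report` object.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing_keys <- setdiff(report_required_keys(), names(doc))
  if (length(missing_keys)) {
    stop("report file ", path, " is missing required indexes: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  doc$schema_version <- NULL
  for (k in c("mean_latency_s", "mean_proximity", "laterality_index")) {
    if (is.null(doc[[k]])) doc[[k]] <- NA_real_
  }
  if (is.null(doc$start_sector)) doc$start_sector <- NA_character_
  if (!is.null(doc$located_ids)) doc$located_ids <- as.character(doc$located_ids)
  structure(doc, class = "etnt_report")
}

#' Write a heat map as a dense matrix CSV
#'
#' One row per y bin (top row first), one column per x bin; cells hold
#' cumulative valid-gaze seconds.
#'
#' @param hm an `etnt_heatmap` object from [heat_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_heat_map <- function(hm, path) {
  stopifnot(inherits(hm, "etnt_heatmap"))
  utils::write.table(
    matrix(fmt_num(hm$grid), nrow = nrow(hm$grid)),
    path, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a heat map matrix CSV
#'
#' @param path file written by [write_heat_map()].
#' @return An `etnt_heatmap` object.
#' @export
read_heat_map <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  structure(list(grid = m, bins_x = ncol(m), bins_y = nrow(m)),
            class = "etnt_heatmap")
}
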