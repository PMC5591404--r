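#' etnt: gaze-based cancellation testing for visuospatial neglect
#'
#' Core toolkit for the eye-tracker variant of the cancellation test:
#' stimulus boards of targets and distractors, dwell-based detection of
#' "found" stimuli from gaze recordings, neglect indexes, search-strategy
#' classification, gaze heat maps, clinical summary scores, and a
#' synthetic-patient gaze simulator.
#'
#' All screen coordinates in the package are normalized to the unit square
#' with the origin at the top-left corner: x grows rightward in units of
#' screen width, y grows downward in units of screen height. The left
#' hemifield is x < 0.5. Times are in seconds since test start.
#'
#' @name etnt-package
#' @import stats
#' @importFrom utils read.csv write.csv head tail
#' @importFrom ggplot2 .data
"_PACKAGE"

ETNT_SCHEMA_VERSION <- 1L

# ---- ScreenGeometry ---------------------------------------------------------

#' Screen geometry
#'
#' Pixel dimensions of the display. Coordinates everywhere else are
#' normalized to \[0,1\] x \[0,1\]; the pixel geometry is kept only to fix the
#' aspect ratio (circular detection zones are circular on the physical
#' screen, so vertical distances are rescaled by width/height) and for
#' rendering.
#'
#' @param width_px,height_px positive integer pixel dimensions.
#' @return An object of class `etnt_geometry`.
#' @export
#' @examples
#' screen_geometry(1920, 1080)
screen_geometry <- function(width_px = 1920L, height_px = 1080L) {
  if (!is.numeric(width_px) || length(width_px) != 1L || width_px <= 0 ||
      !is.numeric(height_px) || length(height_px) != 1L || height_px <= 0) {
    stop("width_px and height_px must be positive scalars", call. = FALSE)
  }
  structure(
    list(width_px = as.integer(round(width_px)),
         height_px = as.integer(round(height_px))),
    class = "etnt_geometry"
  )
}

#' @export
print.etnt_geometry <- function(x, ...) {
  cat(sprintf("<screen %d x %d px, aspect %.3f>\n",
              x$width_px, x$height_px, x$width_px / x$height_px))
  invisible(x)
}

# aspect factor that converts normalized y distances into width units
aspect_ratio <- function(geometry) geometry$height_px / geometry$width_px

# ---- DetectionParams --------------------------------------------------------

#' Dwell-based detection parameters
#'
#' A stimulus counts as found when the point of gaze is held for at least
#' `dwell_s` seconds within a circular zone centred on the stimulus whose
#' diameter is `zone_diameter` of the total screen width.
#'
#' @param dwell_s minimum uninterrupted in-zone dwell, seconds (default 0.4).
#' @param zone_diameter zone diameter as a fraction of screen width
#'   (default 0.07).
#' @return An object of class `etnt_detection`.
#' @export
detection_params <- function(dwell_s = 0.4, zone_diameter = 0.07) {
  if (!is.numeric(dwell_s) || length(dwell_s) != 1L || dwell_s <= 0) {
    stop("dwell_s must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(zone_diameter) || length(zone_diameter) != 1L ||
      zone_diameter <= 0 || zone_diameter >= 1) {
    stop("zone_diameter must lie in (0, 1)", call. = FALSE)
  }
  structure(list(dwell_s = dwell_s, zone_diameter = zone_diameter),
            class = "etnt_detection")
}

# ---- StimulusBoard ----------------------------------------------------------

#' Construct a stimulus board
#'
#' A board is an ordered set of stimuli (targets and distractors) with
#' normalized positions, a screen geometry, and the detection parameters
#' used when scoring gaze against it. The hemifield (`side`) of each
#' stimulus is derived from its x coordinate: left iff x < 0.5.
#'
#' @param stimuli a data frame with columns `id` (unique labels), `x`, `y`
#'   (normalized coordinates in \[0,1\]) and `kind` (`"target"` or
#'   `"distractor"`).
#' @param geometry a [screen_geometry()].
#' @param detection a [detection_params()].
#' @param check if `TRUE` (default) enforce the zone-disjointness invariant:
#'   the minimum pairwise centre distance (in width units, aspect-corrected)
#'   must be at least the zone diameter.
#' @return An object of class `etnt_board`.
#' @seealso [generate_board()] to sample boards satisfying the standard
#'   composition, [board_summary()] for counts.
#' @export
stimulus_board <- function(stimuli,
                           geometry = screen_geometry(),
                           detection = detection_params(),
                           check = TRUE) {
  stimuli <- as.data.frame(stimuli, stringsAsFactors = FALSE)
  required <- c("id", "x", "y", "kind")
  missing_cols <- setdiff(required, names(stimuli))
  if (length(missing_cols)) {
    stop("stimuli is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  stimuli$id <- as.character(stimuli$id)
  if (anyDuplicated(stimuli$id)) {
    stop("stimulus ids must be unique", call. = FALSE)
  }
  if (!all(stimuli$kind %in% c("target", "distractor"))) {
    stop("kind must be 'target' or 'distractor'", call. = FALSE)
  }
  if (nrow(stimuli) &&
      (any(stimuli$x < 0 | stimuli$x > 1) || any(stimuli$y < 0 | stimuli$y > 1))) {
    stop("stimulus coordinates must lie in [0, 1]", call. = FALSE)
  }
  stimuli$side <- ifelse(stimuli$x < 0.5, "left", "right")
  rownames(stimuli) <- NULL
  board <- structure(
    list(stimuli = stimuli[, c("id", "x", "y", "kind", "side")],
         geometry = geometry, detection = detection),
    class = "etnt_board"
  )
  if (check && nrow(stimuli) > 1L) {
    dmin <- min_pairwise_distance(board)
    if (dmin < detection$zone_diameter - 1e-12) {
      stop(sprintf(
        "detection zones overlap: minimum centre distance %.4f < zone diameter %.4f",
        dmin, detection$zone_diameter), call. = FALSE)
    }
  }
  board
}

# minimum pairwise centre distance in width units (aspect-corrected),
# brute force over all pairs; NA for boards with < 2 stimuli
min_pairwise_distance <- function(board) {
  s <- board$stimuli
  if (nrow(s) < 2L) return(NA_real_)
  a <- aspect_ratio(board$geometry)
  d <- as.matrix(stats::dist(cbind(s$x, s$y * a)))
  min(d[upper.tri(d)])
}

#' @export
print.etnt_board <- function(x, ...) {
  s <- x$stimuli
  cat(sprintf(
    "<stimulus board: %d stimuli (%d targets, %d distractors); %d left / %d right>\n",
    nrow(s), sum(s$kind == "target"), sum(s$kind == "distractor"),
    sum(s$side == "left"), sum(s$side == "right")))
  cat(sprintf("  dwell %.2f s, zone diameter %.3f of screen width\n",
              x$detection$dwell_s, x$detection$zone_diameter))
  invisible(x)
}

# ---- GazeRecording ----------------------------------------------------------

#' Construct a gaze recording
#'
#' A timestamped gaze-sample stream from one test administration. Samples
#' must be strictly increasing in time. Invalid samples (blinks, tracking
#' loss) carry `valid = FALSE`; their coordinates may be `NaN`. Coordinates
#' may fall outside \[0,1\] under calibration distortion.
#'
#' @param samples data frame with columns `t` (seconds since test start),
#'   `x`, `y` (normalized coordinates) and `valid` (logical or 0/1).
#' @param sample_rate_hz nominal sampling rate, metadata only; the scoring
#'   code always uses the recorded timestamps, never the nominal rate.
#' @param meta named list of free-form metadata (patient label, session,
#'   timepoint).
#' @return An object of class `etnt_gaze`.
#' @export
gaze_recording <- function(samples, sample_rate_hz = NA_real_, meta = list()) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("t", "x", "y", "valid")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("samples is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  samples$valid <- as.logical(samples$valid)
  if (anyNA(samples$valid)) {
    stop("valid column must be coercible to logical with no NA", call. = FALSE)
  }
  if (nrow(samples)) {
    if (anyNA(samples$t) || any(samples$t < 0)) {
      stop("timestamps must be non-negative and non-missing", call. = FALSE)
    }
    bad <- which(diff(samples$t) <= 0)
    if (length(bad)) {
      stop(sprintf("timestamps must be strictly increasing: violation at row %d",
                   bad[1L] + 1L), call. = FALSE)
    }
  }
  rownames(samples) <- NULL
  structure(
    list(samples = samples[, required],
         sample_rate_hz = sample_rate_hz,
         meta = meta),
    class = "etnt_gaze"
  )
}

#' Duration of a gaze recording
#'
#' Time span from first to last sample, in seconds; 0 for recordings with
#' fewer than 2 samples.
#'
#' @param recording an `etnt_gaze` object.
#' @return Duration in seconds.
#' @export
gaze_duration <- function(recording) {
  t <- recording$samples$t
  if (length(t) < 2L) return(0)
  t[length(t)] - t[1L]
}

#' @export
print.etnt_gaze <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<gaze recording: %d samples, %.2f s, %.0f%% valid>\n",
              n, gaze_duration(x),
              if (n) 100 * mean(x$samples$valid) else 100))
  invisible(x)
}

# Fingerprint used to stamp reports with the board they were scored against.
# Not cryptographic; collision-resistant enough for provenance checks.
board_fingerprint <- function(board) {
  s <- board$stimuli
  if (!nrow(s)) return("empty-board")
  w <- seq_len(nrow(s))
  sprintf("n%d-t%d-%08x-%08x",
          nrow(s), sum(s$kind == "target"),
          as.integer(round(sum(s$x * w) * 1e4)) %% .Machine$integer.max,
          as.integer(round(sum(s$y * w) * 1e4)) %% .Machine$integer.max)
}
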