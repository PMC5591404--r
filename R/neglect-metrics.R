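# Neglect indexes derived from tag events: per-side located/missed target
# counts, latency, inter-tag proximity, a bounded laterality index, search
# start sector and scan-strategy classification, plus gaze heat maps.
#
# The original touch-screen software's proprietary "neglect score" formula
# is not published; this package instead exposes laterality_index =
# (located_right - located_left) / (located_right + located_left), a
# bounded substitute in [-1, 1] that is 0 for side-symmetric performance
# and +1 when only right-hemifield targets are found (left neglect).
# Latency is the mean time-to-tag from test start over located targets;
# proximity is the mean aspect-corrected distance between consecutively
# tagged targets. Both are documented interpretations of the cancellation
# literature, not claimed equivalent to the unpublished originals.

#' Score one test administration
#'
#' Combines tag events, the board and the recording into the index set of
#' a single cancellation-test administration.
#'
#' @param tags tag-event data frame from [detect_tags()] run on this
#'   board/recording pair.
#' @param board the `etnt_board` the recording was made against.
#' @param recording the `etnt_gaze` recording.
#' @param fixations optional precomputed fixation data frame from
#'   [extract_fixations()]; extracted from the recording when `NULL`.
#' @return An object of class `etnt_report` with fields `located_total`,
#'   `located_left`, `located_right`, `missed_left`, `missed_right`,
#'   `test_duration_s`, `mean_latency_s` (NA when no target located),
#'   `mean_proximity` (NA when fewer than 2 targets located),
#'   `laterality_index` (0 when no target located), `start_sector`,
#'   `strategy`, `located_ids` (tagged target ids in tag order), and
#'   provenance (`board_fingerprint`, `dwell_s`, `zone_diameter`).
#' @export
score_test <- function(tags, board, recording, fixations = NULL) {
  stopifnot(inherits(board, "etnt_board"), inherits(recording, "etnt_gaze"))
  st <- board$stimuli
  unknown <- setdiff(tags$stimulus_id, st$id)
  if (length(unknown)) {
    stop("tags reference stimuli absent from the board: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tags <- tags[order(tags$t_tag), , drop = FALSE]
  idx <- match(tags$stimulus_id, st$id)
  is_target <- st$kind[idx] == "target"
  tagged_targets <- tags[is_target, , drop = FALSE]
  tidx <- idx[is_target]

  targets_left <- sum(st$kind == "target" & st$side == "left")
  targets_right <- sum(st$kind == "target" & st$side == "right")
  located_left <- sum(st$side[tidx] == "left")
  located_right <- sum(st$side[tidx] == "right")
  located_total <- located_left + located_right

  lat <- if (located_total >= 1L) mean(tagged_targets$t_tag) else NA_real_
  prox <- if (located_total >= 2L) {
    a <- aspect_ratio(board$geometry)
    xs <- st$x[tidx]; ys <- st$y[tidx] * a
    mean(sqrt(diff(xs)^2 + diff(ys)^2))
  } else NA_real_
  li <- if (located_total > 0L) {
    (located_right - located_left) / located_total
  } else 0

  fix <- if (is.null(fixations)) {
    extract_fixations(recording, dispersion = board$detection$zone_diameter)
  } else fixations

  structure(
    list(
      located_total = located_total,
      located_left = located_left, located_right = located_right,
      missed_left = targets_left - located_left,
      missed_right = targets_right - located_right,
      test_duration_s = gaze_duration(recording),
      mean_latency_s = lat, mean_proximity = prox,
      laterality_index = li,
      start_sector = classify_start_sector(tags, fix, board),
      strategy = classify_scan_strategy(tags, board),
      located_ids = tagged_targets$stimulus_id,
      board_fingerprint = board_fingerprint(board),
      dwell_s = board$detection$dwell_s,
      zone_diameter = board$detection$zone_diameter
    ),
    class = "etnt_report"
  )
}

#' @export
print.etnt_report <- function(x, ...) {
  cat(sprintf("<neglect report: %d targets located (L %d/%d missed, R %d/%d missed)>\n",
              x$located_total, x$missed_left, x$missed_left + x$located_left,
              x$missed_right, x$missed_right + x$located_right))
  cat(sprintf("  laterality %.3f; start %s; strategy %s; duration %.1f s\n",
              x$laterality_index, x$start_sector, x$strategy,
              x$test_duration_s))
  invisible(x)
}

#' Classify the search start sector
#'
#' The start sector is the screen quadrant (split at x = 0.5, y = 0.5) of
#' the first fixation whose centroid lies within any stimulus zone; if no
#' fixation hits a zone, the first fixation overall is used. Points exactly
#' on a split line resolve rightward / upward, so the screen centre is
#' classified upper-right.
#'
#' @param tags tag events (unused in the current rule; kept in the
#'   signature so richer rules can combine fixations with tag order).
#' @param fixations fixation data frame from [extract_fixations()].
#' @param board the `etnt_board` (supplies zones and aspect ratio).
#' @return One of `"upper-left"`, `"upper-right"`, `"lower-left"`,
#'   `"lower-right"`, or `NA` if there are no fixations.
#' @export
classify_start_sector <- function(tags, fixations, board) {
  if (is.null(fixations) || !nrow(fixations)) return(NA_character_)
  st <- board$stimuli
  pick <- 1L
  if (nrow(st)) {
    a <- aspect_ratio(board$geometry)
    r <- board$detection$zone_diameter / 2
    for (i in seq_len(nrow(fixations))) {
      d2 <- (st$x - fixations$x[i])^2 + ((st$y - fixations$y[i]) * a)^2
      if (any(d2 <= r * r)) { pick <- i; break }
    }
  }
  x <- fixations$x[pick]; y <- fixations$y[pick]
  paste0(if (y > 0.5) "lower" else "upper",
         "-",
         if (x >= 0.5) "right" else "left")
}

#' Classify the scan strategy from the tag sequence
#'
#' Left-neglect patients typically start at the right edge and scan
#' leftward in vertical columns; unaffected searchers read the board
#' left-to-right, top-down. The classifier compares the median absolute
#' step between consecutively tagged stimuli along x and y and the
#' Spearman rank trend of tag order against x (resp. y):
#' `"vertical-leftward"` when vertical steps dominate and x decreases with
#' tag order (rank correlation <= -0.5); `"horizontal-top-down"` when
#' horizontal steps dominate and y increases with tag order (rank
#' correlation >= 0.5); otherwise (or with fewer than 4 tags) `"other"`.
#'
#' @param tags ordered tag-event data frame.
#' @param board the `etnt_board`.
#' @return One of `"vertical-leftward"`, `"horizontal-top-down"`,
#'   `"other"`.
#' @export
classify_scan_strategy <- function(tags, board) {
  if (is.null(tags) || nrow(tags) < 4L) return("other")
  st <- board$stimuli
  idx <- match(tags$stimulus_id, st$id)
  x <- st$x[idx]; y <- st$y[idx]
  ord <- seq_along(x)
  dx <- stats::median(abs(diff(x)))
  dy <- stats::median(abs(diff(y)))
  rx <- suppressWarnings(stats::cor(ord, x, method = "spearman"))
  ry <- suppressWarnings(stats::cor(ord, y, method = "spearman"))
  if (!is.na(rx) && dy > dx && rx <= -0.5) return("vertical-leftward")
  if (!is.na(ry) && dx > dy && ry >= 0.5) return("horizontal-top-down")
  "other"
}

#' Cumulative gaze heat map
#'
#' Accumulates valid gaze time on a `bins_y` x `bins_x` grid over the unit
#' square: each inter-sample interval is credited to the cell of its
#' leading sample when that sample is valid, so the grid total equals the
#' recording's total valid-sample time exactly. Samples outside \[0,1\]
#' (calibration distortion) are clipped to the edge cells.
#'
#' @param recording an `etnt_gaze` object.
#' @param bins_x,bins_y grid resolution (defaults 32 x 18).
#' @return An object of class `etnt_heatmap`: `grid` (matrix, row = y bin,
#'   top row first; column = x bin), `bins_x`, `bins_y`.
#' @export
heat_map <- function(recording, bins_x = 32L, bins_y = 18L) {
  stopifnot(inherits(recording, "etnt_gaze"))
  if (bins_x < 1L || bins_y < 1L) {
    stop("bins_x and bins_y must be positive", call. = FALSE)
  }
  grid <- matrix(0, nrow = bins_y, ncol = bins_x)
  s <- recording$samples
  n <- nrow(s)
  if (n >= 2L) {
    dt <- diff(s$t)
    lead <- seq_len(n - 1L)
    keep <- s$valid[lead] & is.finite(s$x[lead]) & is.finite(s$y[lead])
    if (any(keep)) {
      ix <- pmin(pmax(floor(s$x[lead][keep] * bins_x) + 1L, 1L), bins_x)
      iy <- pmin(pmax(floor(s$y[lead][keep] * bins_y) + 1L, 1L), bins_y)
      cell <- (ix - 1L) * bins_y + iy
      acc <- tapply(dt[keep], cell, sum)
      grid[as.integer(names(acc))] <- as.numeric(acc)
    }
  }
  structure(list(grid = grid, bins_x = as.integer(bins_x),
                 bins_y = as.integer(bins_y)),
            class = "etnt_heatmap")
}

#' @export
print.etnt_heatmap <- function(x, ...) {
  cat(sprintf("<heat map %d x %d, %.2f s total gaze>\n",
              x$bins_y, x$bins_x, sum(x$grid)))
  invisible(x)
}

#' Post-minus-pre difference heat map
#'
#' Cellwise subtraction of two heat maps on identical grids; the result's
#' cell sum equals the difference in total gaze time. Positive cells mark
#' screen regions explored more after the intervention.
#'
#' @param post,pre `etnt_heatmap` objects with identical grid shapes.
#' @return An `etnt_heatmap`-shaped object with a signed `grid`.
#' @export
diff_heat_map <- function(post, pre) {
  stopifnot(inherits(post, "etnt_heatmap"), inherits(pre, "etnt_heatmap"))
  if (post$bins_x != pre$bins_x || post$bins_y != pre$bins_y) {
    stop(sprintf("heat map shapes differ: %dx%d vs %dx%d",
                 post$bins_y, post$bins_x, pre$bins_y, pre$bins_x),
         call. = FALSE)
  }
  structure(list(grid = post$grid - pre$grid,
                 bins_x = post$bins_x, bins_y = post$bins_y),
            class = "etnt_heatmap")
}

#' Export a search path to CSV (and optionally PNG)
#'
#' Writes one row per fixation (`order`, `t_start`, `t_end`, `x`, `y`,
#' `duration_s`); read back in order, the rows form the search-path
#' polyline. With `png = TRUE` a rendering of the path over the tagged
#' targets is additionally written next to the CSV.
#'
#' @param tags tag events from [detect_tags()].
#' @param fixations fixation data frame from [extract_fixations()].
#' @param path output CSV path.
#' @param board optional `etnt_board`, required when `png = TRUE`.
#' @param png also write `<path>.png` via [plot_search_path()].
#' @return The CSV path, invisibly.
#' @export
export_search_path <- function(tags, fixations, path, board = NULL,
                               png = FALSE) {
  fix <- as.data.frame(fixations)
  out <- data.frame(order = seq_len(nrow(fix)),
                    t_start = fmt_num(fix$t_start),
                    t_end = fmt_num(fix$t_end),
                    x = fmt_num(fix$x), y = fmt_num(fix$y),
                    duration_s = fmt_num(fix$duration_s),
                    stringsAsFactors = FALSE)
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write search path ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (png) {
    if (is.null(board)) stop("board is required for png rendering", call. = FALSE)
    ggplot2::ggsave(paste0(path, ".png"),
                    plot_search_path(tags, fixations, board),
                    width = 8, height = 4.5, dpi = 120)
  }
  invisible(path)
}
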