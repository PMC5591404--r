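# Stimulus-board generation. The standard display is 60 stimuli (20 target
# squares, 40 distractors) split equally into 30 per hemifield (10 targets,
# 20 distractors each side), uniformly distributed. "Uniform" is realized as
# per-side uniform rejection sampling under a hard minimum-distance
# constraint equal to the zone diameter, which guarantees disjoint detection
# zones and hence at most one zone per gaze sample.

# run expr with a fixed RNG stream without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Board generation configuration
#'
#' Defaults reproduce the standard test display: 10 targets and 20
#' distractors per hemifield. The practice display uses
#' `targets_per_side = 2, distractors_per_side = 4` (4 targets, 8
#' distractors in total).
#'
#' @param targets_per_side,distractors_per_side stimulus counts per
#'   hemifield (defaults 10 and 20).
#' @param zone_diameter detection-zone diameter, fraction of screen width
#'   (default 0.07); also the minimum allowed distance between stimulus
#'   centres.
#' @param margin stimulus-free band at each screen edge, fraction of the
#'   relevant dimension (default 0.05).
#' @param center_guard half-width of the exclusion band around the vertical
#'   midline x = 0.5, so no stimulus is ambiguous between hemifields
#'   (default `zone_diameter / 2`).
#' @param dwell_s dwell threshold stored with the board (default 0.4 s).
#' @param geometry a [screen_geometry()].
#' @param seed integer seed; the same configuration and seed always yield
#'   the identical board. `NULL` uses the current RNG stream.
#' @return An object of class `etnt_board_config`.
#' @export
board_config <- function(targets_per_side = 10L,
                         distractors_per_side = 20L,
                         zone_diameter = 0.07,
                         margin = 0.05,
                         center_guard = zone_diameter / 2,
                         dwell_s = 0.4,
                         geometry = screen_geometry(),
                         seed = NULL) {
  if (targets_per_side < 0 || distractors_per_side < 0) {
    stop("stimulus counts must be non-negative", call. = FALSE)
  }
  if (margin < 0 || center_guard < 0 ||
      margin + center_guard >= 0.5 || 2 * margin >= 1) {
    stop("margin and center_guard leave no placeable area", call. = FALSE)
  }
  structure(
    list(targets_per_side = as.integer(targets_per_side),
         distractors_per_side = as.integer(distractors_per_side),
         zone_diameter = zone_diameter, margin = margin,
         center_guard = center_guard, dwell_s = dwell_s,
         geometry = geometry, seed = seed),
    class = "etnt_board_config"
  )
}

#' Generate a stimulus board
#'
#' Samples stimulus positions uniformly within each hemifield, rejecting
#' candidates closer than the zone diameter (aspect-corrected Euclidean
#' distance in screen-width units) to an already placed stimulus, until the
#' configured per-side counts of targets and distractors are reached.
#' Before sampling, feasibility is checked with an area heuristic: the
#' total zone area per side must not exceed 60% of that side's placeable
#' area.
#'
#' @param config an [board_config()]; the default yields the standard
#'   60-stimulus display.
#' @param max_attempts rejection budget per hemifield.
#' @return An `etnt_board`.
#' @export
#' @examples
#' b <- generate_board(board_config(seed = 1))
#' board_summary(b)
generate_board <- function(config = board_config(), max_attempts = 50000L) {
  stopifnot(inherits(config, "etnt_board_config"))
  n_side <- config$targets_per_side + config$distractors_per_side
  aspect <- aspect_ratio(config$geometry)
  # placeable centre region per side, in width-normalized units
  side_w <- 0.5 - config$center_guard - config$margin
  side_h <- (1 - 2 * config$margin) * aspect
  zone_area <- pi * (config$zone_diameter / 2)^2
  if (n_side > 0 && n_side * zone_area > 0.6 * side_w * side_h) {
    stop(sprintf(
      "infeasible packing: %d zones of area %.4f exceed 60%% of placeable side area %.4f",
      n_side, zone_area, side_w * side_h), call. = FALSE)
  }

  sample_side <- function(xlo, xhi) {
    pts <- matrix(numeric(0), ncol = 2L)
    attempts <- 0L
    while (nrow(pts) < n_side) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf("rejection budget of %d attempts exhausted after placing %d of %d stimuli",
                     max_attempts, nrow(pts), n_side), call. = FALSE)
      }
      cand <- c(stats::runif(1L, xlo, xhi),
                stats::runif(1L, config$margin, 1 - config$margin))
      if (nrow(pts)) {
        d2 <- (pts[, 1L] - cand[1L])^2 + ((pts[, 2L] - cand[2L]) * aspect)^2
        if (min(d2) < config$zone_diameter^2) next
      }
      pts <- rbind(pts, cand)
    }
    pts
  }

  with_local_seed(config$seed, {
    left <- sample_side(config$margin, 0.5 - config$center_guard)
    right <- sample_side(0.5 + config$center_guard, 1 - config$margin)
  })

  label <- function(side_letter, pts) {
    nt <- config$targets_per_side
    nd <- config$distractors_per_side
    if (!n_side) {
      return(data.frame(id = character(0), x = numeric(0), y = numeric(0),
                        kind = character(0), stringsAsFactors = FALSE))
    }
    data.frame(
      id = c(if (nt) sprintf("T%s%02d", side_letter, seq_len(nt)),
             if (nd) sprintf("D%s%02d", side_letter, seq_len(nd))),
      x = pts[, 1L], y = pts[, 2L],
      kind = rep(c("target", "distractor"), c(nt, nd)),
      stringsAsFactors = FALSE
    )
  }

  stimulus_board(
    rbind(label("L", left), label("R", right)),
    geometry = config$geometry,
    detection = detection_params(config$dwell_s, config$zone_diameter)
  )
}

#' Summarize a stimulus board
#'
#' Counts by kind and hemifield plus the brute-force minimum pairwise
#' centre distance (aspect-corrected, width units). The distance is `NA`
#' for boards with fewer than 2 stimuli.
#'
#' @param board an `etnt_board`.
#' @return A list with counts and `min_distance`.
#' @export
board_summary <- function(board) {
  stopifnot(inherits(board, "etnt_board"))
  s <- board$stimuli
  list(
    total = nrow(s),
    targets_left = sum(s$kind == "target" & s$side == "left"),
    targets_right = sum(s$kind == "target" & s$side == "right"),
    distractors_left = sum(s$kind == "distractor" & s$side == "left"),
    distractors_right = sum(s$kind == "distractor" & s$side == "right"),
    min_distance = min_pairwise_distance(board)
  )
}
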