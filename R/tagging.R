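# Dwell-based detection: a stimulus counts as found ("circled") when the
# point of gaze is held, uninterrupted, for at least dwell_s seconds inside
# the circular zone centred on it (diameter = zone_diameter of screen
# width). Dwell must be contiguous: a blink or an excursion out of the zone
# resets the clock. Re-entries after a stimulus has been tagged add to its
# total dwell but never create a second tag event.

# in-zone membership matrix: samples x stimuli, boundary counts as inside.
# Zones are disjoint by board invariant; defensively, a sample that would
# fall in several zones is assigned to the nearest centre only.
zone_membership <- function(recording, board) {
  s <- recording$samples
  st <- board$stimuli
  a <- aspect_ratio(board$geometry)
  r <- board$detection$zone_diameter / 2
  dx <- outer(s$x, st$x, "-")
  dy <- outer(s$y, st$y, "-") * a
  d2 <- dx * dx + dy * dy
  inside <- d2 <= r * r
  inside[is.na(inside)] <- FALSE
  multi <- which(rowSums(inside) > 1L)
  for (i in multi) {
    keep <- which.min(ifelse(inside[i, ], d2[i, ], Inf))
    inside[i, ] <- FALSE
    inside[i, keep] <- TRUE
  }
  inside
}

#' Detect tagged stimuli in a gaze recording
#'
#' Applies the dwell-based detection rule to every stimulus on the board:
#' a stimulus is tagged iff there is a run of consecutive valid samples,
#' all inside its zone, whose time span (last minus first timestamp, so
#' irregular sampling is handled) reaches the dwell threshold. The tag time
#' `t_tag` is the timestamp at which the first qualifying run first attains
#' the threshold. Invalid samples (blinks) and samples outside the zone
#' break a run.
#'
#' @param recording an `etnt_gaze` object.
#' @param board an `etnt_board`; its `detection` parameters are used unless
#'   overridden.
#' @param dwell_s,zone_diameter optional overrides of the board's detection
#'   parameters (used e.g. for sensitivity analyses).
#' @return A data frame of tag events ordered by `t_tag`, one row per
#'   tagged stimulus: `stimulus_id`, `t_tag`, `dwell_total_s` (total
#'   in-zone gaze time over the whole recording, summed over runs).
#' @export
#' @examples
#' board <- generate_board(board_config(seed = 1))
#' prof <- neglect_profile(beta0 = -10, beta = 0, noise_sd = 0,
#'                         blink_rate_hz = 0, seed = 1)
#' sim <- simulate_patient(board, prof)
#' nrow(detect_tags(sim$recording, board))  # all 20 targets found
detect_tags <- function(recording, board,
                        dwell_s = board$detection$dwell_s,
                        zone_diameter = board$detection$zone_diameter) {
  stopifnot(inherits(recording, "etnt_gaze"), inherits(board, "etnt_board"))
  empty <- data.frame(stimulus_id = character(0), t_tag = numeric(0),
                      dwell_total_s = numeric(0), stringsAsFactors = FALSE)
  samples <- recording$samples
  if (!nrow(samples) || !nrow(board$stimuli)) return(empty)

  det <- board
  det$detection <- detection_params(dwell_s, zone_diameter)
  inside <- zone_membership(recording, det)
  t <- samples$t
  ok <- samples$valid

  events <- lapply(seq_len(ncol(inside)), function(j) {
    inz <- inside[, j] & ok
    if (!any(inz)) return(NULL)
    r <- rle(inz)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    spans <- t[ends[runs]] - t[starts[runs]]
    total <- sum(spans)
    qual <- which(spans >= dwell_s)
    if (!length(qual)) return(NULL)
    first <- runs[qual[1L]]
    i0 <- starts[first]
    # first timestamp within the run at which the span reaches the threshold
    within <- t[i0:ends[first]]
    t_tag <- within[which(within - t[i0] >= dwell_s)[1L]]
    data.frame(stimulus_id = board$stimuli$id[j], t_tag = t_tag,
               dwell_total_s = total, stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, events)
  if (is.null(events) || !nrow(events)) return(empty)
  events <- events[order(events$t_tag), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Extract fixations with a dispersion-threshold (I-DT) algorithm
#'
#' Scans each maximal run of valid samples with a growing window: a
#' fixation is a maximal window whose dispersion (x range plus y range, in
#' normalized units) stays within `dispersion` and whose time span is at
#' least `min_fix_duration`. Used for search-path drawing and start-sector
#' classification, not for tag detection.
#'
#' @param recording an `etnt_gaze` object.
#' @param dispersion dispersion threshold in normalized units (default:
#'   the standard zone diameter, 0.07).
#' @param min_fix_duration minimum fixation duration in seconds
#'   (default 0.1).
#' @return A data frame, one row per fixation, ordered and non-overlapping
#'   in time: `t_start`, `t_end`, `x`, `y` (centroid), `duration_s`.
#' @export
extract_fixations <- function(recording, dispersion = 0.07,
                              min_fix_duration = 0.1) {
  stopifnot(inherits(recording, "etnt_gaze"))
  s <- recording$samples
  out <- list()
  if (nrow(s)) {
    r <- rle(s$valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out <- c(out, idt_run(s$t[starts[k]:ends[k]],
                            s$x[starts[k]:ends[k]],
                            s$y[starts[k]:ends[k]],
                            dispersion, min_fix_duration))
    }
  }
  if (!length(out)) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      x = numeric(0), y = numeric(0),
                      duration_s = numeric(0)))
  }
  fix <- do.call(rbind, out)
  fix <- fix[order(fix$t_start), , drop = FALSE]
  rownames(fix) <- NULL
  fix
}

# I-DT over one uninterrupted run of valid samples
idt_run <- function(t, x, y, dispersion, min_dur) {
  n <- length(t)
  fixes <- list()
  i <- 1L
  while (i <= n) {
    # smallest window starting at i that covers the minimum duration
    j <- i
    while (j < n && t[j] - t[i] < min_dur) j <- j + 1L
    if (t[j] - t[i] < min_dur) break
    win_x <- x[i:j]; win_y <- y[i:j]
    if (diff(range(win_x)) + diff(range(win_y)) > dispersion) {
      i <- i + 1L
      next
    }
    # grow while dispersion stays within threshold
    while (j < n) {
      nx <- c(win_x, x[j + 1L]); ny <- c(win_y, y[j + 1L])
      if (diff(range(nx)) + diff(range(ny)) > dispersion) break
      win_x <- nx; win_y <- ny; j <- j + 1L
    }
    fixes[[length(fixes) + 1L]] <- data.frame(
      t_start = t[i], t_end = t[j],
      x = mean(win_x), y = mean(win_y),
      duration_s = t[j] - t[i])
    i <- j + 1L
  }
  fixes
}
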