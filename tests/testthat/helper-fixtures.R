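# Shared fixtures and independent oracles. Boards built here use a square
# screen (aspect 1) unless stated, so hand-computed distances need no
# aspect correction.

make_board <- function(x, y, kind = rep("target", length(x)),
                       id = sprintf("S%02d", seq_along(x)),
                       dwell_s = 0.4, zone_diameter = 0.07,
                       geometry = screen_geometry(1000, 1000),
                       check = TRUE) {
  stimulus_board(data.frame(id = id, x = x, y = y, kind = kind),
                 geometry = geometry,
                 detection = detection_params(dwell_s, zone_diameter),
                 check = check)
}

make_gaze <- function(t, x, y, valid = rep(TRUE, length(t)), rate = NA) {
  gaze_recording(data.frame(t = t, x = x, y = y, valid = valid),
                 sample_rate_hz = rate)
}

# gaze that sits at (x, y) from t0 for dur seconds at the given rate;
# times built as t0 + k/rate so sample spans compare exactly with
# thresholds like 24/60 = 0.4
hold_samples <- function(x, y, t0, dur, rate = 60) {
  t <- t0 + (0:round(dur * rate)) / rate
  data.frame(t = t, x = rep(x, length(t)), y = rep(y, length(t)),
             valid = TRUE)
}

# Independent dwell-rule oracle: per stimulus, scan every window start and
# extend through consecutive valid in-zone samples; tagged iff some window
# spans >= dwell_s, t_tag = earliest qualifying end time. Deliberately
# avoids the rle-based route of the implementation.
oracle_tags <- function(recording, board,
                        dwell_s = board$detection$dwell_s,
                        zone_diameter = board$detection$zone_diameter) {
  s <- recording$samples
  st <- board$stimuli
  a <- board$geometry$height_px / board$geometry$width_px
  r <- zone_diameter / 2
  n <- nrow(s)
  out <- list()
  for (k in seq_len(nrow(st))) {
    inz <- logical(n)
    for (i in seq_len(n)) {
      inz[i] <- s$valid[i] && is.finite(s$x[i]) && is.finite(s$y[i]) &&
        sqrt((s$x[i] - st$x[k])^2 + ((s$y[i] - st$y[k]) * a)^2) <= r
    }
    t_tag <- Inf
    total <- 0
    i <- 1L
    while (i <= n) {
      if (!inz[i]) { i <- i + 1L; next }
      j <- i
      while (j < n && inz[j + 1L]) j <- j + 1L
      total <- total + (s$t[j] - s$t[i])
      if (s$t[j] - s$t[i] >= dwell_s) {
        hits <- which(s$t[i:j] - s$t[i] >= dwell_s)
        t_tag <- min(t_tag, s$t[i:j][hits[1L]])
      }
      i <- j + 1L
    }
    if (is.finite(t_tag)) {
      out[[length(out) + 1L]] <- data.frame(
        stimulus_id = st$id[k], t_tag = t_tag, dwell_total_s = total,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(stimulus_id = character(0), t_tag = numeric(0),
                      dwell_total_s = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$t_tag), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random-walk recording over a board: wanders between stimuli with holds
# of random length around the dwell threshold, occasional invalid bursts
random_recording <- function(board, n_samples, rate = 60,
                             p_invalid = 0.05) {
  st <- board$stimuli
  t <- seq(0, by = 1 / rate, length.out = n_samples)
  n_anchor <- max(2L, ceiling(n_samples / 25))
  at <- sort(c(0, runif(n_anchor - 2L, 0, t[n_samples]), t[n_samples]))
  pick <- sample(nrow(st), n_anchor, replace = TRUE)
  jitter_a <- runif(n_anchor, 0, 0.06)
  ax <- st$x[pick] + rnorm(n_anchor, 0, jitter_a)
  ay <- st$y[pick] + rnorm(n_anchor, 0, jitter_a)
  x <- approx(at, ax, t)$y
  y <- approx(at, ay, t)$y
  valid <- runif(n_samples) > p_invalid
  x[!valid] <- NaN
  y[!valid] <- NaN
  make_gaze(t, x, y, valid, rate)
}

# small well-spread board for oracle comparisons
oracle_board <- function(dwell_s = 0.4, zone_diameter = 0.07) {
  make_board(x = c(0.2, 0.45, 0.7, 0.25, 0.75),
             y = c(0.2, 0.55, 0.25, 0.8, 0.75),
             kind = c("target", "target", "distractor", "target",
                      "distractor"),
             dwell_s = dwell_s, zone_diameter = zone_diameter)
}

# clean simulation profile: detection recovers ground truth exactly
clean_profile <- function(...) {
  neglect_profile(noise_sd = 0, calib_bias = c(0, 0),
                  calib_scale = c(1, 1), blink_rate_hz = 0, ...)
}
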