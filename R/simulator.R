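# Synthetic neglect-patient gaze. A virtual patient scans the board
# following a search strategy (left-neglect patients typically start at
# the right edge and scan leftward in vertical columns), omits left-field
# stimuli according to a logistic gradient in signed distance from the
# midline, holds gaze on each found target for a dwell drawn near the
# detection threshold, and reports gaze corrupted by jitter, an affine
# calibration distortion and blink bursts. Defaults are plausible but not
# empirical: no quantitative scan kinematics of the original patient
# cohort are published.

#' Generative profile of a synthetic neglect patient
#'
#' Omission follows a logistic gradient:
#' P(omit | x) = plogis(beta0 + beta * (0.5 - x)), so beta > 0
#' concentrates omissions in the left hemifield (x < 0.5) and beta0 sets
#' the overall severity; beta = 0 with strongly negative beta0 gives an
#' unimpaired searcher.
#'
#' @param beta0 omission-gradient intercept (default -2).
#' @param beta omission-gradient slope, >= 0 (default 4).
#' @param start_side `"right"` (typical for left neglect) or `"left"`.
#' @param strategy `"vertical-leftward"` (columns from the start side) or
#'   `"horizontal-top-down"` (rows from the top).
#' @param dwell_mean_s,dwell_sd_s dwell duration on found targets,
#'   seconds; draws are clamped from below so each found target's hold
#'   exceeds the detection threshold (defaults 0.6 and 0.1 s, i.e. dwells
#'   around the 0.4 s threshold).
#' @param saccade_speed gaze travel speed between stimuli, screen widths
#'   per second (default 1.5).
#' @param noise_sd gaze jitter standard deviation, normalized units
#'   (default 0.01; the detection zone radius is 0.035).
#' @param calib_bias length-2 offset (dx, dy) of reported gaze.
#' @param calib_scale length-2 gain (sx, sy) applied about the screen
#'   centre; both must be positive.
#' @param blink_rate_hz rate of invalid-sample bursts (default 0.1 Hz).
#' @param seed integer seed for reproducible simulation; `NULL` uses the
#'   current RNG stream.
#' @return An object of class `etnt_profile`.
#' @export
neglect_profile <- function(beta0 = -2, beta = 4,
                            start_side = c("right", "left"),
                            strategy = c("vertical-leftward",
                                         "horizontal-top-down"),
                            dwell_mean_s = 0.6, dwell_sd_s = 0.1,
                            saccade_speed = 1.5, noise_sd = 0.01,
                            calib_bias = c(0, 0), calib_scale = c(1, 1),
                            blink_rate_hz = 0.1, seed = NULL) {
  start_side <- match.arg(start_side)
  strategy <- match.arg(strategy)
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  if (dwell_mean_s <= 0 || dwell_sd_s < 0) {
    stop("dwell_mean_s must be positive and dwell_sd_s non-negative",
         call. = FALSE)
  }
  if (saccade_speed <= 0) stop("saccade_speed must be positive", call. = FALSE)
  if (noise_sd < 0 || blink_rate_hz < 0) {
    stop("noise_sd and blink_rate_hz must be non-negative", call. = FALSE)
  }
  if (length(calib_bias) != 2L || length(calib_scale) != 2L ||
      any(calib_scale <= 0)) {
    stop("calib_bias and calib_scale must be length 2, scales positive",
         call. = FALSE)
  }
  structure(list(beta0 = beta0, beta = beta, start_side = start_side,
                 strategy = strategy, dwell_mean_s = dwell_mean_s,
                 dwell_sd_s = dwell_sd_s, saccade_speed = saccade_speed,
                 noise_sd = noise_sd, calib_bias = calib_bias,
                 calib_scale = calib_scale, blink_rate_hz = blink_rate_hz,
                 seed = seed),
            class = "etnt_profile")
}

# scan order over a stimulus subset under a search strategy; columns (or
# rows) are spatial bins, traversed from the start side (or the top)
scan_order <- function(stimuli, strategy, start_side, n_bins = 8L) {
  if (!nrow(stimuli)) return(integer(0))
  if (strategy == "vertical-leftward") {
    col <- pmin(pmax(ceiling(stimuli$x * n_bins), 1L), n_bins)
    major <- if (start_side == "right") -col else col
    order(major, stimuli$y)
  } else {
    row <- pmin(pmax(ceiling(stimuli$y * n_bins), 1L), n_bins)
    minor <- if (start_side == "right") -stimuli$x else stimuli$x
    order(row, minor)
  }
}

#' Simulate one test administration of a synthetic patient
#'
#' Draws per-stimulus omissions from the profile's logistic gradient,
#' builds a piecewise-linear scan path through the non-omitted stimuli in
#' strategy order (found targets get a supra-threshold hold, distractors a
#' short glance), samples it at the given rate, and then applies jitter,
#' the affine calibration distortion and blink bursts. With zero noise,
#' identity calibration and no blinks, [detect_tags()] recovers exactly
#' the ground-truth found-target set.
#'
#' @param board an `etnt_board`.
#' @param profile an [neglect_profile()].
#' @param sample_rate_hz sampling rate; must give at least 3 samples per
#'   dwell threshold.
#' @return A list with `recording` (`etnt_gaze`) and `truth` (class
#'   `etnt_truth`: `visited` stimulus ids in scan order, `found_targets`,
#'   `omitted_targets`, `dwell` — named per-visit hold durations).
#' @export
simulate_patient <- function(board, profile, sample_rate_hz = 60) {
  stopifnot(inherits(board, "etnt_board"), inherits(profile, "etnt_profile"))
  dwell_s <- board$detection$dwell_s
  if (sample_rate_hz * dwell_s < 3) {
    stop(sprintf(
      "sample_rate_hz = %g gives fewer than 3 samples per %g s dwell threshold",
      sample_rate_hz, dwell_s), call. = FALSE)
  }
  # a slow saccade could linger in a crossed zone long enough to tag it
  if (2 * board$detection$zone_diameter / profile$saccade_speed >
      0.5 * dwell_s) {
    stop("saccade_speed too low: zone crossings would approach the dwell threshold",
         call. = FALSE)
  }
  st <- board$stimuli
  aspect <- aspect_ratio(board$geometry)

  with_local_seed(profile$seed, {
    p_omit <- stats::plogis(profile$beta0 + profile$beta * (0.5 - st$x))
    omitted <- stats::runif(nrow(st)) < p_omit
    is_target <- st$kind == "target"
    visit_idx <- which(!omitted)
    visit_idx <- visit_idx[scan_order(st[visit_idx, , drop = FALSE],
                                      profile$strategy, profile$start_side)]

    # per-visit hold durations: found targets dwell past the threshold,
    # everything else gets a sub-threshold glance
    n_visit <- length(visit_idx)
    hold <- stats::runif(n_visit, 0.2 * dwell_s, 0.5 * dwell_s)
    tgt <- is_target[visit_idx]
    if (any(tgt)) {
      floor_dwell <- dwell_s + 2 / sample_rate_hz
      hold[tgt] <- pmax(floor_dwell,
                        stats::rnorm(sum(tgt), profile$dwell_mean_s,
                                     profile$dwell_sd_s))
    }

    # waypoints of the true gaze path: saccade to each stimulus, hold
    start_xy <- c(if (profile$start_side == "right") 0.92 else 0.08, 0.15)
    wt <- 0; wx <- start_xy[1L]; wy <- start_xy[2L]
    pos <- start_xy
    for (i in seq_len(n_visit)) {
      s_xy <- c(st$x[visit_idx[i]], st$y[visit_idx[i]])
      dist <- sqrt((s_xy[1L] - pos[1L])^2 + ((s_xy[2L] - pos[2L]) * aspect)^2)
      t_arrive <- wt[length(wt)] + max(dist / profile$saccade_speed,
                                       1 / sample_rate_hz)
      t_leave <- t_arrive + hold[i]
      wt <- c(wt, t_arrive, t_leave)
      wx <- c(wx, s_xy[1L], s_xy[1L])
      wy <- c(wy, s_xy[2L], s_xy[2L])
      pos <- s_xy
    }
    wt <- c(wt, wt[length(wt)] + 0.2)          # brief terminal hold
    wx <- c(wx, wx[length(wx)]); wy <- c(wy, wy[length(wy)])

    t <- seq(0, wt[length(wt)], by = 1 / sample_rate_hz)
    x <- stats::approx(wt, wx, t)$y
    y <- stats::approx(wt, wy, t)$y

    # jitter, then calibration distortion (gain about screen centre + bias)
    if (profile$noise_sd > 0) {
      x <- x + stats::rnorm(length(t), 0, profile$noise_sd)
      y <- y + stats::rnorm(length(t), 0, profile$noise_sd)
    }
    x <- 0.5 + profile$calib_scale[1L] * (x - 0.5) + profile$calib_bias[1L]
    y <- 0.5 + profile$calib_scale[2L] * (y - 0.5) + profile$calib_bias[2L]

    valid <- rep(TRUE, length(t))
    if (profile$blink_rate_hz > 0) {
      n_blinks <- stats::rpois(1L, profile$blink_rate_hz * t[length(t)])
      if (n_blinks > 0) {
        starts <- sample.int(length(t), min(n_blinks, length(t)))
        lens <- 1L + stats::rgeom(length(starts),
                                  1 / max(1, 0.1 * sample_rate_hz))
        for (b in seq_along(starts)) {
          idx <- starts[b]:min(length(t), starts[b] + lens[b] - 1L)
          valid[idx] <- FALSE
        }
        x[!valid] <- NaN
        y[!valid] <- NaN
      }
    }

    recording <- gaze_recording(
      data.frame(t = t, x = x, y = y, valid = valid),
      sample_rate_hz = sample_rate_hz,
      meta = list(source = "simulated", strategy = profile$strategy,
                  start_side = profile$start_side)
    )
    truth <- structure(
      list(visited = st$id[visit_idx],
           found_targets = st$id[visit_idx][tgt],
           omitted_targets = st$id[is_target & omitted],
           dwell = stats::setNames(hold, st$id[visit_idx])),
      class = "etnt_truth")
    list(recording = recording, truth = truth)
  })
}

#' Recover the omission gradient from scored reports
#'
#' Maximum-likelihood logistic regression of per-target omission outcomes
#' on signed distance from the midline (0.5 - x), pooling all reports
#' scored against the same board. Recovers the generative (beta0, beta) of
#' [neglect_profile()] from simulated cohorts.
#'
#' @param reports list of `etnt_report` objects carrying `located_ids`.
#' @param board the common `etnt_board`.
#' @return A list: `beta0`, `beta`, `se_beta0`, `se_beta`, `degenerate`
#'   (TRUE when every target was found in every test, none ever was, or
#'   the fit separated), `n_tests`, `n_obs`.
#' @export
recover_gradient <- function(reports, board) {
  stopifnot(inherits(board, "etnt_board"))
  if (length(reports) < 2L) {
    stop("at least 2 scored reports are required", call. = FALSE)
  }
  targets <- board$stimuli[board$stimuli$kind == "target", , drop = FALSE]
  if (!nrow(targets)) stop("board has no targets", call. = FALSE)
  omit <- unlist(lapply(reports, function(rep) {
    !(targets$id %in% rep$located_ids)
  }))
  xs <- rep(0.5 - targets$x, times = length(reports))
  degenerate_out <- function() {
    list(beta0 = NA_real_, beta = NA_real_, se_beta0 = NA_real_,
         se_beta = NA_real_, degenerate = TRUE,
         n_tests = length(reports), n_obs = length(omit))
  }
  if (all(omit) || !any(omit)) return(degenerate_out())
  fit <- suppressWarnings(stats::glm(omit ~ xs, family = stats::binomial()))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (!fit$converged || any(abs(cf) > 15)) return(degenerate_out())
  list(beta0 = unname(cf[1L]), beta = unname(cf[2L]),
       se_beta0 = unname(se[1L]), se_beta = unname(se[2L]),
       degenerate = FALSE, n_tests = length(reports), n_obs = length(omit))
}

#' Simulate a pre/post cohort with a training effect
#'
#' Each virtual patient gets an individual omission intercept (population
#' intercept plus normal heterogeneity) and is simulated and scored twice:
#' pre, and post with the intercept reduced by `effect_shift` (less
#' omission after training). A training diary with configurable attendance
#' accompanies the cohort so the feasibility summaries can be exercised on
#' the same fixture.
#'
#' @param n_patients number of virtual patients, >= 1.
#' @param board an `etnt_board`.
#' @param profile population-level [neglect_profile()].
#' @param effect_shift reduction of `beta0` at post (0 = null effect).
#' @param beta0_sd between-patient standard deviation of `beta0`
#'   (default 0.5).
#' @param attendance integer vector of attended sessions per patient;
#'   default draws from 12..15.
#' @param max_sessions diary maximum (default 15).
#' @param sample_rate_hz passed to [simulate_patient()].
#' @param keep_recordings retain the raw recordings (large) in the result.
#' @param seed integer seed.
#' @return A list of class `etnt_cohort`: `patients` (per patient:
#'   `report_pre`, `report_post`, `truth_pre`, `truth_post`, `beta0`, and
#'   optionally the recordings), `diary` (an `etnt_diary`), `board`.
#' @export
simulate_cohort <- function(n_patients, board, profile = neglect_profile(),
                            effect_shift = 1, beta0_sd = 0.5,
                            attendance = NULL, max_sessions = 15L,
                            sample_rate_hz = 60,
                            keep_recordings = FALSE, seed = NULL) {
  stopifnot(n_patients >= 1L, inherits(board, "etnt_board"),
            inherits(profile, "etnt_profile"))
  with_local_seed(seed, {
    if (is.null(attendance)) {
      attendance <- sample(12:15, n_patients, replace = TRUE)
    }
    if (length(attendance) != n_patients) {
      stop("attendance must have one entry per patient", call. = FALSE)
    }
    patients <- lapply(seq_len(n_patients), function(i) {
      b0 <- profile$beta0 + stats::rnorm(1L, 0, beta0_sd)
      run <- function(b0_i) {
        p <- profile
        p$beta0 <- b0_i
        p$seed <- NULL                     # inherit the cohort stream
        sim <- simulate_patient(board, p, sample_rate_hz)
        tags <- detect_tags(sim$recording, board)
        list(report = score_test(tags, board, sim$recording),
             truth = sim$truth,
             recording = if (keep_recordings) sim$recording)
      }
      pre <- run(b0)
      post <- run(b0 - effect_shift)
      out <- list(patient = sprintf("P%d", i), beta0 = b0,
                  report_pre = pre$report, report_post = post$report,
                  truth_pre = pre$truth, truth_post = post$truth)
      if (keep_recordings) {
        out$recording_pre <- pre$recording
        out$recording_post <- post$recording
      }
      out
    })
    sessions <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
      n <- attendance[i]
      if (!n) return(NULL)
      data.frame(
        patient = sprintf("P%d", i),
        date = sprintf("2026-01-%02d", seq_len(n)),
        minutes = round(stats::runif(n, 20, 40)),
        games = sample(2:4, n, replace = TRUE),
        difficulty = sample(1:5, n, replace = TRUE),
        state = sample(c("fit", "tired"), n, replace = TRUE,
                       prob = c(0.8, 0.2)),
        stringsAsFactors = FALSE)
    }))
    diary <- feasibility_diary(sessions, max_sessions = max_sessions)
    structure(list(patients = patients, diary = diary, board = board),
              class = "etnt_cohort")
  })
}
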