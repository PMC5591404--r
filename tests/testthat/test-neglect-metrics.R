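# A hand-built administration on a small square-screen board: three
# targets tagged at known times and positions, so latency and proximity
# have closed-form values.
scored_fixture <- function() {
  board <- make_board(x = c(0.2, 0.4, 0.7, 0.8),
                      y = c(0.3, 0.6, 0.4, 0.8),
                      kind = c("target", "target", "target", "target"))
  s <- rbind(hold_samples(0.7, 0.4, 0, 0.5),
             hold_samples(0.4, 0.6, 1, 0.5),
             hold_samples(0.2, 0.3, 2, 0.5))
  rec <- make_gaze(s$t, s$x, s$y)
  list(board = board, rec = rec, tags = detect_tags(rec, board))
}

test_that("report counts, latency and proximity match hand computation", {
  f <- scored_fixture()
  rep <- score_test(f$tags, f$board, f$rec)
  expect_equal(rep$located_total, 3)
  expect_equal(rep$located_left, 2)   # targets at x = 0.2, 0.4
  expect_equal(rep$located_right, 1)  # x = 0.7; x = 0.8 missed
  expect_equal(rep$missed_left, 0)
  expect_equal(rep$missed_right, 1)
  # tag order S03, S02, S01 at ~0.4 s into each hold (exact tag times are
  # quantized to the 60 Hz sample grid); the report's latency must equal
  # the plain mean of the event times
  expect_equal(f$tags$stimulus_id, c("S03", "S02", "S01"))
  expect_true(all(abs(f$tags$t_tag - c(0.4, 1.4, 2.4)) <= 1 / 60 + 1e-9))
  expect_equal(rep$mean_latency_s, mean(f$tags$t_tag), tolerance = 1e-12)
  d1 <- sqrt((0.7 - 0.4)^2 + (0.4 - 0.6)^2)
  d2 <- sqrt((0.4 - 0.2)^2 + (0.6 - 0.3)^2)
  expect_equal(rep$mean_proximity, mean(c(d1, d2)), tolerance = 1e-9)
  expect_equal(rep$laterality_index, (1 - 2) / 3, tolerance = 1e-12)
  expect_equal(rep$test_duration_s, gaze_duration(f$rec))
  # count conservation per side
  expect_equal(rep$located_left + rep$missed_left, 2)
  expect_equal(rep$located_right + rep$missed_right, 2)
})

test_that("perfect and fully lateralized performances hit the index bounds", {
  board <- generate_board(board_config(seed = 5))
  sim <- simulate_patient(board, clean_profile(beta0 = -30, beta = 0, seed = 5))
  tags <- detect_tags(sim$recording, board)
  rep <- score_test(tags, board, sim$recording)
  expect_equal(rep$located_total, 20)
  expect_equal(rep$missed_left, 0)
  expect_equal(rep$missed_right, 0)
  expect_equal(rep$laterality_index, 0)

  right_only <- tags[grepl("^TR", tags$stimulus_id), ]
  rep_r <- score_test(right_only, board, sim$recording)
  expect_equal(rep_r$laterality_index, 1)
  expect_equal(rep_r$missed_left, 10)
  expect_equal(rep_r$located_right, 10)
})

test_that("degenerate reports flag undefined latency and proximity", {
  f <- scored_fixture()
  none <- f$tags[0, ]
  rep0 <- score_test(none, f$board, f$rec)
  expect_equal(rep0$located_total, 0)
  expect_equal(rep0$laterality_index, 0)
  expect_true(is.na(rep0$mean_latency_s))
  expect_true(is.na(rep0$mean_proximity))
  one <- f$tags[1, ]
  rep1 <- score_test(one, f$board, f$rec)
  expect_false(is.na(rep1$mean_latency_s))
  expect_true(is.na(rep1$mean_proximity))
})

test_that("tags referencing unknown stimuli are rejected", {
  f <- scored_fixture()
  bad <- f$tags
  bad$stimulus_id[1] <- "GHOST"
  expect_error(score_test(bad, f$board, f$rec), "GHOST")
})

test_that("mirroring a test about the midline negates the laterality index", {
  board <- generate_board(board_config(seed = 21))
  sim <- simulate_patient(board, clean_profile(seed = 21))
  rep <- score_test(detect_tags(sim$recording, board), board, sim$recording)

  ms <- board$stimuli
  ms$x <- 1 - ms$x
  mirror_board <- stimulus_board(ms[, c("id", "x", "y", "kind")],
                                 geometry = board$geometry,
                                 detection = board$detection)
  mrec <- sim$recording
  mrec$samples$x <- 1 - mrec$samples$x
  mrep <- score_test(detect_tags(mrec, mirror_board), mirror_board, mrec)

  expect_equal(mrep$laterality_index, -rep$laterality_index,
               tolerance = 1e-12)
  expect_equal(mrep$located_left, rep$located_right)
  expect_equal(mrep$missed_left, rep$missed_right)
})

test_that("start sector picks the first fixation inside a stimulus zone", {
  board <- oracle_board()
  fix <- data.frame(t_start = c(0, 1), t_end = c(0.5, 1.5),
                    x = c(0.8, 0.2), y = c(0.2, 0.2),
                    duration_s = c(0.5, 0.5))
  expect_equal(classify_start_sector(NULL, fix[1, ], board), "upper-right")
  expect_equal(classify_start_sector(NULL, fix[2, ], board), "upper-left")
  expect_equal(classify_start_sector(NULL, fix[0, ], board), NA_character_)
  # centre of screen resolves to upper-right by the tie rule
  centre <- data.frame(t_start = 0, t_end = 1, x = 0.5, y = 0.5,
                       duration_s = 1)
  expect_equal(classify_start_sector(NULL, centre, board), "upper-right")
  # first fixation misses every zone; second one (in S01's zone) decides
  two <- data.frame(t_start = c(0, 1), t_end = c(0.5, 1.5),
                    x = c(0.55, 0.21), y = c(0.95, 0.21),
                    duration_s = c(0.5, 0.5))
  expect_equal(classify_start_sector(NULL, two, board), "upper-left")
})

test_that("scan strategies are classified from the tag sequence", {
  # column sweep right -> left, top-down within columns
  grid <- expand.grid(y = c(0.2, 0.5, 0.8), x = c(0.15, 0.4, 0.65, 0.9))
  board <- make_board(grid$x, grid$y)
  cols <- board$stimuli[order(-board$stimuli$x, board$stimuli$y), ]
  vert <- data.frame(stimulus_id = cols$id, t_tag = seq_len(nrow(cols)),
                     dwell_total_s = 0.5)
  expect_equal(classify_scan_strategy(vert, board), "vertical-leftward")
  # row sweep top -> bottom, left-to-right within rows
  rows <- board$stimuli[order(board$stimuli$y, board$stimuli$x), ]
  horiz <- data.frame(stimulus_id = rows$id, t_tag = seq_len(nrow(rows)),
                      dwell_total_s = 0.5)
  expect_equal(classify_scan_strategy(horiz, board), "horizontal-top-down")
  expect_equal(classify_scan_strategy(vert[1:3, ], board), "other")
})

test_that("heat maps conserve valid gaze time exactly", {
  set.seed(77)
  board <- oracle_board()
  for (i in 1:10) {
    rec <- random_recording(board, 1000)
    hm <- heat_map(rec)
    s <- rec$samples
    expected <- sum(diff(s$t)[s$valid[-nrow(s)]])
    expect_equal(sum(hm$grid), expected, tolerance = 1e-9)
  }
})

test_that("stationary, empty and out-of-screen gaze bin as specified", {
  rec <- make_gaze(c(0, 1, 2), rep(0.31, 3), rep(0.62, 3))
  hm <- heat_map(rec)
  expect_equal(sum(hm$grid > 0), 1)
  expect_equal(max(hm$grid), 2)
  empty <- heat_map(make_gaze(numeric(0), numeric(0), numeric(0)))
  expect_true(all(empty$grid == 0))
  # calibration drift beyond the screen clips to edge cells
  off <- make_gaze(c(0, 1, 2), c(1.4, 1.4, 1.4), c(-0.2, -0.2, -0.2))
  hoff <- heat_map(off)
  expect_equal(hoff$grid[1, 32], 2)
  expect_error(heat_map(rec, bins_x = 0), "positive")
})

test_that("difference maps subtract cellwise and track duration change", {
  set.seed(88)
  board <- oracle_board()
  pre <- heat_map(random_recording(board, 400))
  post <- heat_map(random_recording(board, 700))
  d <- diff_heat_map(post, pre)
  expect_equal(d$grid, post$grid - pre$grid)
  expect_equal(sum(d$grid), sum(post$grid) - sum(pre$grid),
               tolerance = 1e-9)
  expect_true(all(diff_heat_map(pre, pre)$grid == 0))
  zero <- heat_map(make_gaze(numeric(0), numeric(0), numeric(0)))
  expect_equal(diff_heat_map(post, zero)$grid, post$grid)
  small <- heat_map(random_recording(board, 100), bins_x = 8, bins_y = 8)
  expect_error(diff_heat_map(post, small), "shapes differ")
})

test_that("heat map CSV round trips", {
  set.seed(99)
  hm <- heat_map(random_recording(oracle_board(), 500))
  path <- withr::local_tempfile(fileext = ".csv")
  write_heat_map(hm, path)
  back <- read_heat_map(path)
  expect_equal(back$grid, hm$grid, tolerance = 1e-12)
  expect_equal(back$bins_x, hm$bins_x)
})

test_that("search-path CSV export round trips the fixation list", {
  board <- oracle_board()
  sim <- simulate_patient(board, clean_profile(seed = 31))
  fix <- extract_fixations(sim$recording)
  tags <- detect_tags(sim$recording, board)
  path <- withr::local_tempfile(fileext = ".csv")
  export_search_path(tags, fix, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(fix))
  expect_equal(back$order, seq_len(nrow(fix)))
  expect_equal(back$x, fix$x, tolerance = 1e-12)
  expect_equal(back$t_start, fix$t_start, tolerance = 1e-12)
  # zero fixations still writes a parseable header-only file
  empty_path <- withr::local_tempfile(fileext = ".csv")
  export_search_path(tags[0, ], fix[0, ], empty_path)
  expect_equal(nrow(utils::read.csv(empty_path)), 0)
})
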