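test_that("anosognosia index reproduces worked examples", {
  expect_equal(anosognosia_index(anosognosia_ratings(rep(3, 6), rep(3, 6))), 0)
  expect_equal(anosognosia_index(anosognosia_ratings(rep(5, 6), rep(1, 6))), -1)
  expect_equal(anosognosia_index(anosognosia_ratings(rep(1, 6), rep(5, 6))), 1)
  expect_equal(
    anosognosia_index(anosognosia_ratings(c(3, 3, 3, 3, 3, 2), rep(3, 6))),
    1 / 24)
  # raw-mean variant divides by K only
  expect_equal(
    anosognosia_index(anosognosia_ratings(c(3, 3, 3, 3, 3, 2), rep(3, 6)),
                      normalization = "mean"),
    1 / 6)
})

test_that("anosognosia index obeys the sign law and bounds", {
  set.seed(14)
  for (i in 1:300) {
    k <- sample(1:8, 1)
    self <- sample(1:5, k, replace = TRUE)
    ext <- sample(1:5, k, replace = TRUE)
    ai <- anosognosia_index(anosognosia_ratings(self, ext))
    expect_gte(ai, -1)
    expect_lte(ai, 1)
    expect_equal(ai < 0, sum(self) > sum(ext))
    expect_equal(ai == 0, sum(self) == sum(ext))
  }
})

test_that("invalid ratings are rejected", {
  expect_error(anosognosia_ratings(1:5, 1:4), "equal length")
  expect_error(anosognosia_ratings(c(1, 6), c(1, 2)), "1..5")
  expect_error(anosognosia_ratings(integer(0), integer(0)), "at least one")
})

test_that("adherence percentage rounds to the nearest integer", {
  expect_identical(adherence_percent(14, 15), 93L)
  expect_identical(adherence_percent(15, 15), 100L)
  expect_identical(adherence_percent(0, 15), 0L)
  expect_identical(adherence_percent(7, 18), 39L)
  expect_error(adherence_percent(16, 15), "0..max_sessions")
  expect_error(adherence_percent(-1, 15), "0..max_sessions")
  # monotone in attended sessions
  vals <- vapply(0:15, adherence_percent, integer(1), max_sessions = 15)
  expect_true(all(diff(vals) >= 0))
})

make_diary <- function(attendance, dropouts = character(0),
                       adverse = character(0), minutes = 30) {
  sessions <- do.call(rbind, lapply(seq_along(attendance), function(i) {
    n <- attendance[i]
    if (!n) return(NULL)
    data.frame(patient = sprintf("P%d", i),
               date = sprintf("2026-02-%02d", seq_len(n)),
               minutes = minutes, games = 3, difficulty = 2,
               state = rep(c("fit", "tired"), length.out = n),
               stringsAsFactors = FALSE)
  }))
  feasibility_diary(sessions, dropouts = dropouts, adverse_events = adverse)
}

test_that("feasibility summary matches the study-style no-dropout cohort", {
  d <- make_diary(c(15, 15, 14, 14, 13, 12, 10))
  s <- feasibility_summary(d)
  expect_equal(s$enrolled, 7)
  expect_equal(s$attrition_count, 0)
  expect_equal(s$attrition_pct, 0)
  expect_equal(s$adverse_event_count, 0)
  expect_equal(s$sessions_median, 14)
  expect_equal(s$adherence_median_pct, adherence_percent(14, 15))
})

test_that("feasibility summary handles medians, dropouts and edge cases", {
  d <- make_diary(c(10, 12, 14, 15, 15))
  s <- feasibility_summary(d)
  expect_equal(s$sessions_median, 14)
  expect_equal(s$adherence_iqr,
               c(adherence_percent(12, 15), adherence_percent(15, 15)))

  one <- make_diary(15)
  expect_equal(feasibility_summary(one)$adherence_median_pct, 100)

  dd <- make_diary(c(15, 8), dropouts = "P3", adverse = "fall during session")
  sd <- feasibility_summary(dd)
  expect_equal(sd$enrolled, 3)
  expect_equal(sd$attrition_count, 1)
  expect_equal(sd$attrition_pct, 100 / 3)
  expect_equal(sd$adverse_event_count, 1)
  expect_equal(sd$fit_session_fraction,
               mean(rep(c("fit", "tired"), length.out = 15) == "fit") * 15 / 23 +
                 mean(rep(c("fit", "tired"), length.out = 8) == "fit") * 8 / 23)

  expect_error(feasibility_diary(make_diary(3)$sessions, max_sessions = 2),
               "more sessions")
})

test_that("effect size r follows z / sqrt(n) with the 0.1/0.3/0.5 bands", {
  expect_equal(effect_size_r(0, 10)$r, 0)
  expect_equal(effect_size_r(0, 10)$band, "negligible")
  e <- effect_size_r(2, 16)
  expect_equal(e$r, 0.5)
  expect_equal(e$band, "large")
  expect_equal(effect_size_r(-1.2, 9)$r, -0.4)
  expect_equal(effect_size_r(-1.2, 9)$band, "medium")
  expect_equal(effect_size_r(0.4, 16)$band, "small")
  expect_error(effect_size_r(1, 0), "positive")
  # quadrupling n halves |r|
  set.seed(5)
  for (i in 1:20) {
    z <- rnorm(1); n <- sample(1:50, 1)
    expect_equal(effect_size_r(z, 4 * n)$r, effect_size_r(z, n)$r / 2,
                 tolerance = 1e-12)
  }
})

test_that("paired comparison reproduces the all-improve worked example", {
  res <- paired_compare(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$statistic, 15)
  expect_equal(res$p, 2 / 32)
  expect_equal(res$m, 5)
  expect_equal(res$effect$n, 10)
})

test_that("identical vectors give an undefined statistic and p = 1", {
  res <- paired_compare(c(3, 1, 4), c(3, 1, 4))
  expect_true(is.na(res$statistic))
  expect_equal(res$p, 1)
  expect_error(paired_compare(1:3, 1:4), "equal length")
})

test_that("exact paired p matches the enumeration oracle on random data", {
  set.seed(61)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    pre <- sample(0:8, n, replace = TRUE)
    post <- sample(0:8, n, replace = TRUE)
    res <- paired_compare(pre, post)
    expect_equal(res$p, oracle_signed_rank_p(pre, post),
                 tolerance = 1e-12,
                 info = paste("case", i))
  }
})

test_that("exact paired p agrees with wilcox.test on tie-free data", {
  set.seed(62)
  for (i in 1:20) {
    n <- sample(5:11, 1)
    pre <- rnorm(n)
    post <- rnorm(n)
    res <- paired_compare(pre, post)
    ref <- wilcox.test(post, pre, paired = TRUE, exact = TRUE,
                       correct = FALSE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("normal approximation is close to the exact p at m = 25", {
  set.seed(63)
  for (i in 1:10) {
    # tie-free data so the exact reference distribution is psignrank
    pre <- rnorm(25)
    post <- pre + rnorm(25, 0.3)
    approx <- paired_compare(pre, post)   # m = 25 > exact_max
    expect_false(approx$exact)
    ref <- wilcox.test(post, pre, paired = TRUE, exact = TRUE)$p.value
    expect_lt(abs(ref - approx$p), 0.02)
  }
})

test_that("repeated comparison handles degenerate and maximal patterns", {
  same <- cbind(c(2, 5, 1), c(2, 5, 1), c(2, 5, 1))
  res <- repeated_compare(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # strictly increasing rows maximize the statistic: value 8 for s=4, k=3
  inc <- cbind(1:4, 2:5, 3:6)
  res2 <- repeated_compare(inc)
  expect_equal(res2$statistic, 8)
  expect_equal(res2$p, (1 / 6)^4 * 6, tolerance = 1e-12)
  expect_error(repeated_compare(list(1:3, 1:3, 1:2)), "same number")
})

test_that("exact Friedman p matches the enumeration oracle", {
  set.seed(71)
  for (i in 1:8) {
    s <- sample(3:5, 1)
    y <- matrix(sample(0:4, s * 3, replace = TRUE), nrow = s)
    res <- repeated_compare(y)
    expect_true(res$exact)
    expect_equal(res$p, oracle_friedman_p(y), tolerance = 1e-12,
                 info = paste("case", i))
  }
})

test_that("Friedman statistic agrees with stats::friedman.test", {
  set.seed(72)
  for (i in 1:10) {
    s <- sample(4:9, 1)
    y <- matrix(rnorm(s * 3), nrow = s)
    res <- repeated_compare(y, exact_max = 0)
    ref <- friedman.test(y)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  }
})
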