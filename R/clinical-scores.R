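# Clinical-layer computations: the anosognosia index contrasting a
# patient's self-ratings with an examiner's external ratings, feasibility
# summaries of a training diary (adherence, attrition, safety), and
# nonparametric effect sizes with exact small-sample paired and repeated
# comparisons.

#' Self/external rating pairs for the anosognosia index
#'
#' Ratings are integers on a 5-point Likert scale (1 = severe difficulties,
#' 5 = no difficulties), one pair per subtest; the study design used 6
#' subtests.
#'
#' @param self_ratings,external_ratings integer vectors of equal length,
#'   every value in 1..5.
#' @return An object of class `etnt_ratings`.
#' @export
anosognosia_ratings <- function(self_ratings, external_ratings) {
  if (length(self_ratings) != length(external_ratings)) {
    stop("self and external ratings must have equal length", call. = FALSE)
  }
  if (!length(self_ratings)) {
    stop("at least one subtest rating is required", call. = FALSE)
  }
  ok <- function(v) is.numeric(v) && all(v %in% 1:5)
  if (!ok(self_ratings) || !ok(external_ratings)) {
    stop("all ratings must be integers in 1..5", call. = FALSE)
  }
  structure(list(self_ratings = as.integer(self_ratings),
                 external_ratings = as.integer(external_ratings)),
            class = "etnt_ratings")
}

#' Anosognosia index
#'
#' Mean signed discrepancy between external and self ratings, scaled to
#' \[-1, 1\]: AI = sum(external - self) / (4K) with K subtests (4 is the
#' maximal per-item discrepancy on the 1..5 scale). AI < 0 indicates
#' anosognosia: the patient rates their own performance better than the
#' examiner does (net self-overestimation). AI >= 0 indicates realistic or
#' pessimistic self-rating. `normalization = "mean"` divides by K only,
#' giving the raw mean discrepancy in rating points (range \[-4, 4\]).
#'
#' @param ratings an [anosognosia_ratings()] object.
#' @param normalization `"unit"` (default, AI in \[-1,1\]) or `"mean"`.
#' @return The index value.
#' @export
#' @examples
#' anosognosia_index(anosognosia_ratings(c(3, 3, 3, 3, 3, 2), rep(3, 6)))
anosognosia_index <- function(ratings, normalization = c("unit", "mean")) {
  stopifnot(inherits(ratings, "etnt_ratings"))
  normalization <- match.arg(normalization)
  k <- length(ratings$self_ratings)
  total <- sum(ratings$external_ratings - ratings$self_ratings)
  total / (k * if (normalization == "unit") 4 else 1)
}

#' Training adherence percentage
#'
#' Completed sessions as a percentage of the maximum possible sessions,
#' rounded to the nearest integer (halves away from zero, so 14 of 15 is
#' 93%).
#'
#' @param attended completed session count.
#' @param max_sessions maximum possible sessions (study protocol: 15).
#' @return Integer percentage.
#' @export
adherence_percent <- function(attended, max_sessions = 15L) {
  if (max_sessions <= 0) stop("max_sessions must be positive", call. = FALSE)
  if (attended < 0 || attended > max_sessions) {
    stop(sprintf("attended (%s) must lie in 0..max_sessions (%s)",
                 attended, max_sessions), call. = FALSE)
  }
  as.integer(floor(100 * attended / max_sessions + 0.5))
}

#' Training diary
#'
#' Session-level protocol of a training program: one row per completed
#' session with the patient label, date, effective minutes, games played,
#' difficulty level and perceived state after training (`"fit"` or
#' `"tired"`), plus the dropout and adverse-event logs.
#'
#' @param sessions data frame with columns `patient`, `date`, `minutes`,
#'   `games`, `difficulty`, `state`.
#' @param max_sessions maximum possible sessions per patient (default 15).
#' @param adverse_events character vector describing adverse events.
#' @param dropouts character vector of patients lost during the
#'   intervention.
#' @param enrolled number enrolled; defaults to patients appearing in the
#'   diary plus dropouts without sessions.
#' @return An object of class `etnt_diary`.
#' @export
feasibility_diary <- function(sessions, max_sessions = 15L,
                              adverse_events = character(0),
                              dropouts = character(0),
                              enrolled = NULL) {
  sessions <- as.data.frame(sessions, stringsAsFactors = FALSE)
  required <- c("patient", "date", "minutes", "games", "difficulty", "state")
  missing_cols <- setdiff(required, names(sessions))
  if (length(missing_cols)) {
    stop("sessions is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(sessions) && any(sessions$minutes < 0)) {
    stop("minutes must be non-negative", call. = FALSE)
  }
  counts <- table(sessions$patient)
  if (any(counts > max_sessions)) {
    stop("a patient has more sessions than max_sessions", call. = FALSE)
  }
  if (nrow(sessions) && !all(sessions$state %in% c("fit", "tired"))) {
    stop("state must be 'fit' or 'tired'", call. = FALSE)
  }
  patients <- union(unique(sessions$patient), dropouts)
  if (is.null(enrolled)) enrolled <- length(patients)
  if (enrolled < length(patients)) {
    stop("enrolled cannot be below the number of patients observed",
         call. = FALSE)
  }
  structure(list(sessions = sessions, max_sessions = as.integer(max_sessions),
                 adverse_events = adverse_events, dropouts = dropouts,
                 enrolled = as.integer(enrolled)),
            class = "etnt_diary")
}

# median / quartiles with midpoint interpolation at discontinuities
# (quantile type 2), the convention used for the diary summaries
mid_quantile <- function(x, p) unname(stats::quantile(x, p, type = 2))

#' Feasibility summary of a training diary
#'
#' Implementation-level outcomes of the training program: attrition
#' (dropouts / enrolled), per-patient adherence (median and IQR, midpoint
#' interpolation), adverse-event count, and medians of sessions and
#' training minutes, plus the fraction of sessions after which the patient
#' reported feeling fit.
#'
#' @param diary an [feasibility_diary()] object with at least one enrolled
#'   patient.
#' @return A list: `enrolled`, `attrition_count`, `attrition_pct`,
#'   `adherence_median_pct`, `adherence_iqr` (length-2, 25th and 75th
#'   percentile), `adverse_event_count`, `sessions_median`,
#'   `minutes_median` (median per-session minutes), `fit_session_fraction`.
#' @export
feasibility_summary <- function(diary) {
  stopifnot(inherits(diary, "etnt_diary"))
  if (diary$enrolled < 1L) stop("diary has no enrolled patients", call. = FALSE)
  patients <- union(unique(diary$sessions$patient), diary$dropouts)
  if (!length(patients)) stop("diary is empty", call. = FALSE)
  attended <- vapply(patients,
                     function(p) sum(diary$sessions$patient == p),
                     integer(1))
  adherence <- vapply(attended, adherence_percent, integer(1),
                      max_sessions = diary$max_sessions)
  list(
    enrolled = diary$enrolled,
    attrition_count = length(diary$dropouts),
    attrition_pct = 100 * length(diary$dropouts) / diary$enrolled,
    adherence_median_pct = mid_quantile(adherence, 0.5),
    adherence_iqr = mid_quantile(adherence, c(0.25, 0.75)),
    adverse_event_count = length(diary$adverse_events),
    sessions_median = mid_quantile(attended, 0.5),
    minutes_median = if (nrow(diary$sessions))
      mid_quantile(diary$sessions$minutes, 0.5) else NA_real_,
    fit_session_fraction = if (nrow(diary$sessions))
      mean(diary$sessions$state == "fit") else NA_real_
  )
}

#' Nonparametric effect size r
#'
#' r = z / sqrt(n): the standardized test statistic divided by the square
#' root of the number of observations entering the test. Interpretation
#' bands follow the 0.1 / 0.3 / 0.5 convention for small, medium and large
#' effects, boundaries inclusive upward.
#'
#' @param z standardized statistic of a nonparametric test.
#' @param n observation count entering the test (for a paired test, twice
#'   the number of non-zero pairs).
#' @return A list of class `etnt_effect`: `z`, `n`, `r`, `band`
#'   (`"negligible"`, `"small"`, `"medium"`, `"large"`).
#' @export
effect_size_r <- function(z, n) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("n must be a positive count", call. = FALSE)
  }
  r <- z / sqrt(n)
  band <- if (is.na(r)) NA_character_
  else if (abs(r) >= 0.5) "large"
  else if (abs(r) >= 0.3) "medium"
  else if (abs(r) >= 0.1) "small"
  else "negligible"
  structure(list(z = z, n = n, r = r, band = band), class = "etnt_effect")
}

#' @export
print.etnt_effect <- function(x, ...) {
  cat(sprintf("<effect size r = %.3f (%s); z = %.3f, n = %d>\n",
              x$r, x$band, x$z, as.integer(x$n)))
  invisible(x)
}

# signed-rank preliminaries shared by statistic and enumeration: drop
# zero differences, midranks on tied absolute differences
signed_ranks <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  list(d = d, ranks = if (length(d)) rank(abs(d)) else numeric(0))
}

#' Paired comparison by the Wilcoxon signed-rank test
#'
#' Compares post- with pre-intervention scores. Zero differences are
#' dropped and tied absolute differences receive midranks. For m <= 12
#' non-zero pairs the two-sided p-value is exact, computed by enumerating
#' all 2^m sign assignments of the rank sum (twice the smaller tail
#' probability, capped at 1); for larger m the normal approximation
#' without continuity correction is used. The effect size divides z by
#' sqrt(2 m), m the number of non-zero pairs, i.e. the total observations
#' entering the test.
#'
#' @param pre,post numeric vectors of equal length.
#' @param exact_max largest m for which the exact enumeration is used.
#' @return A list of class `etnt_comparison`: `statistic` (rank sum of
#'   positive differences; NA when every difference is zero), `z`, `p`
#'   (convention p = 1 when every difference is zero), `m` (non-zero
#'   pairs), `exact`, and `effect` (an `etnt_effect`).
#' @export
#' @examples
#' paired_compare(1:5, 2:6)  # every patient improves by 1: exact p = 0.0625
paired_compare <- function(pre, post, exact_max = 12L) {
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length", call. = FALSE)
  }
  if (!length(pre)) stop("at least one pair is required", call. = FALSE)
  sr <- signed_ranks(pre, post)
  m <- length(sr$d)
  if (m == 0L) {
    eff <- effect_size_r(NA_real_, 2L * length(pre))
    return(structure(list(statistic = NA_real_, z = NA_real_, p = 1,
                          m = 0L, exact = TRUE, effect = eff),
                     class = "etnt_comparison"))
  }
  w <- sum(sr$ranks[sr$d > 0])
  ew <- sum(sr$ranks) / 2
  vw <- sum(sr$ranks^2) / 4
  z <- (w - ew) / sqrt(vw)
  if (m <= exact_max) {
    dist <- signed_rank_distribution(sr$ranks)
    eps <- 1e-9
    p_lo <- sum(dist$prob[dist$w <= w + eps])
    p_hi <- sum(dist$prob[dist$w >= w - eps])
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  structure(list(statistic = w, z = z, p = p, m = m, exact = exact,
                 effect = effect_size_r(z, 2L * m)),
            class = "etnt_comparison")
}

# null distribution of the positive-rank sum over all 2^m sign patterns
signed_rank_distribution <- function(ranks) {
  m <- length(ranks)
  combos <- expand.grid(rep(list(c(0, 1)), m))
  w <- as.numeric(as.matrix(combos) %*% ranks)
  list(w = w, prob = rep(1 / 2^m, length(w)))
}

#' @export
print.etnt_comparison <- function(x, ...) {
  cat(sprintf("<paired comparison: W = %s, z = %s, p = %.4g (%s), r = %.3f>\n",
              format(x$statistic), format(round(x$z, 3)), x$p,
              if (x$exact) "exact" else "normal approx.", x$effect$r))
  invisible(x)
}

#' Repeated-measures comparison by the Friedman test
#'
#' Tests for differences across k = 3 (or more) measurement time points in
#' s subjects using within-subject midranks and the tie-corrected Friedman
#' chi-square. For s <= `exact_max` subjects the p-value is exact, by
#' enumerating all (k!)^s within-subject orderings; otherwise the
#' chi-square approximation with k - 1 degrees of freedom is used.
#'
#' @param scores a list of equal-length numeric vectors, one per time
#'   point (e.g. pre, post, follow-up), or a subjects x timepoints matrix.
#' @param exact_max largest subject count for which the exact enumeration
#'   is used (default 8).
#' @return A list of class `etnt_friedman`: `statistic`, `df`, `p`,
#'   `exact`, `s`, `k`. Identical scores across all time points give
#'   statistic 0 and p = 1.
#' @export
repeated_compare <- function(scores, exact_max = 8L) {
  y <- if (is.matrix(scores)) scores else {
    if (length(unique(lengths(scores))) != 1L) {
      stop("all time points must have the same number of subjects",
           call. = FALSE)
    }
    do.call(cbind, scores)
  }
  s <- nrow(y); k <- ncol(y)
  if (k < 2L) stop("at least two time points are required", call. = FALSE)
  if (s < 1L) stop("at least one subject is required", call. = FALSE)
  r <- t(apply(y, 1L, rank))
  stat <- friedman_statistic(r, s, k)
  if (s <= exact_max) {
    stats_null <- friedman_null_statistics(r, s, k)
    p <- mean(stats_null >= stat - 1e-9)
    exact <- TRUE
  } else {
    p <- if (is.na(stat)) 1 else stats::pchisq(stat, k - 1L, lower.tail = FALSE)
    exact <- FALSE
  }
  if (is.na(stat)) { stat <- 0; p <- 1 }
  structure(list(statistic = stat, df = k - 1L, p = p, exact = exact,
                 s = s, k = k),
            class = "etnt_friedman")
}

# tie-corrected Friedman chi-square from a matrix of within-subject ranks;
# NA when every subject is fully tied (correction factor 0)
friedman_statistic <- function(r, s, k) {
  ties <- apply(r, 1L, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  })
  C <- 1 - sum(ties) / (s * (k^3 - k))
  num <- 12 * sum((colSums(r) - s * (k + 1) / 2)^2)
  if (C <= 0) {
    if (num == 0) return(NA_real_)
    stop("degenerate tie structure", call. = FALSE)
  }
  num / (s * k * (k + 1) * C)
}

# exact null: statistic under every assignment of each subject's observed
# ranks to the k conditions, accumulated as column-sum vectors
friedman_null_statistics <- function(r, s, k) {
  perms <- permutations_of(k)
  ties <- apply(r, 1L, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  })
  C <- 1 - sum(ties) / (s * (k^3 - k))
  colsums <- matrix(0, nrow = 1L, ncol = k)
  for (i in seq_len(s)) {
    rows <- matrix(r[i, ][perms], nrow = nrow(perms))
    n_old <- nrow(colsums); n_new <- nrow(rows)
    colsums <- colsums[rep(seq_len(n_old), each = n_new), , drop = FALSE] +
      rows[rep(seq_len(n_new), times = n_old), , drop = FALSE]
  }
  num <- 12 * rowSums((colsums - s * (k + 1) / 2)^2)
  if (C <= 0) return(ifelse(num == 0, 0, NA_real_))
  num / (s * k * (k + 1) * C)
}

# all k! permutations of 1..k, one per row
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow = nrow(sub)))
  }))
}

#' @export
print.etnt_friedman <- function(x, ...) {
  cat(sprintf("<Friedman: chi^2(%d) = %.3f, p = %.4g (%s), %d subjects x %d time points>\n",
              x$df, x$statistic, x$p,
              if (x$exact) "exact" else "chi-square approx.", x$s, x$k))
  invisible(x)
}
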