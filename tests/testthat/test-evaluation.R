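mk_trials <- function(err, case = "C1", user = 1L, dist = NULL) {
  data.frame(case = rep(case, length(err)), user = rep(user, length(err)),
             rep = rep(1L, length(err)), kind = rep("tracking", length(err)),
             target = if (length(err)) paste0("T", seq_along(err)) else character(0),
             error_mm = err,
             distance_to_marker_mm = if (is.null(dist)) seq_along(err) else dist,
             stringsAsFactors = FALSE)
}

test_that("error summaries match a brute-force sorting oracle", {
  expect_error(summarize_errors(mk_trials(numeric(0))), "no trials")
  const <- summarize_errors(mk_trials(rep(2.5, 8)), group_by = character())
  expect_equal(const$sd_mm, 0)
  expect_equal(const$mean_mm, 2.5)

  set.seed(71)
  e <- round(runif(10, 0, 5), 3)
  s <- summarize_errors(mk_trials(e), group_by = character())
  # sorted-interpolation quartile oracle (type-7): q = x[1 + (n-1)p] interp
  srt <- sort(e)
  qor <- function(p) { h <- 1 + (length(srt) - 1) * p
    lo <- floor(h); srt[lo] + (h - lo) * (srt[min(lo + 1, length(srt))] - srt[lo]) }
  expect_equal(s$q1_mm, qor(0.25)); expect_equal(s$median_mm, qor(0.5))
  expect_equal(s$q3_mm, qor(0.75))
  expect_equal(s$mean_mm, mean(e)); expect_equal(s$sd_mm, sd(e))
  expect_equal(s$whisker_low, mean(e) - 1.5 * sd(e))
  expect_equal(s$whisker_high, mean(e) + 1.5 * sd(e))
  # permutation invariance
  perm <- mk_trials(sample(e))
  expect_equal(summarize_errors(perm, character())[-1],
               s[-1])
  # Tukey whisker option
  st <- summarize_errors(mk_trials(e), character(), whiskers = "iqr")
  expect_equal(st$whisker_low, qor(0.25) - 1.5 * (qor(0.75) - qor(0.25)))
})

test_that("grouping by case yields one row per phantom", {
  tr <- rbind(mk_trials(1:4, "A"), mk_trials(2:9, "B"), mk_trials(1:3, "C"))
  s <- summarize_errors(tr, "case")
  expect_equal(nrow(s), 3L)
  expect_equal(s$n, c(4L, 8L, 3L))
  expect_equal(s$mean_mm[2], mean(2:9))
})

test_that("the paired user test matches the t formula and handles ties", {
  idt <- paired_user_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idt$t, 0); expect_equal(idt$p, 1)
  u1 <- c(2.1, 1.8, 2.5, 3.0, 2.2); u2 <- c(1.9, 2.0, 2.3, 2.8, 2.6)
  r <- paired_user_test(u1, u2)
  d <- u1 - u2
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(r$t, t_hand, tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-10)
  expect_error(paired_user_test(1:3, 1:4), "equal length")
})

test_that("null p-values are uniform (Kolmogorov-Smirnov sanity)", {
  set.seed(72)
  p <- replicate(1000, {
    a <- rnorm(8); b <- rnorm(8)
    paired_user_test(a, b)$p
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("distance-error correlation detects the lever arm and flags constants", {
  flat <- distance_error_correlation(mk_trials(rep(1, 10), dist = 1:10))
  expect_false(flat$defined)
  lin <- distance_error_correlation(mk_trials(0.02 * (1:20), dist = 1:20))
  expect_equal(lin$rho, 1)
  expect_error(distance_error_correlation(mk_trials(1:3, dist = c(1, 1, 1))),
               "distinct")
})

test_that("survey summaries reproduce the printed averages exactly", {
  surg <- read_survey(system.file("extdata", "surgeon_survey.csv",
                                  package = "arguide"))
  s <- survey_summary(surg)
  expect_equal(unname(s$question_means[1]), 4.5)   # AR in surgeries (general)
  expect_equal(unname(s$question_means),
               c(4.5, 4.0, 4.7, 4.8, 5.0, 4.5, 4.5, 4.3, 4.7, 4.7, 4.8,
                 4.7, 5.0, 4.5, 4.5))
  expect_equal(unname(s$respondent_means), c(4.9, 4.1, 4.5, 4.9, 4.3, 5.0))
  # grand mean over every cell (the printed condensed average covers an
  # unenumerated question subset, so only the cell-wise mean is asserted)
  expect_equal(s$overall_mean, 4.6)
  pat <- read_survey(system.file("extdata", "patient_survey.csv",
                                 package = "arguide"))
  sp <- survey_summary(pat)
  expect_equal(unname(sp$question_means), c(3, 5, 5))
})

test_that("survey validation and bounds hold", {
  all5 <- survey_summary(matrix(5L, 4, 3))
  expect_true(all(all5$question_means == 5.0))
  expect_error(survey_table(matrix(c(1, 2, 6, 3), 2)), "1..5")
  set.seed(73)
  m <- matrix(sample(1:5, 30, TRUE), 6, 5)
  s <- survey_summary(m)
  expect_true(all(s$raw$question_means >= apply(m, 1, min) &
                  s$raw$question_means <= apply(m, 1, max)))
  # printed tables round half-up: 4.45 -> 4.5 (not banker's 4.4)
  expect_equal(arguide:::round_half_up(4.45, 1), 4.5)
  expect_equal(arguide:::round_half_up(2.25, 1), 2.3)
})

test_that("trial CSVs round-trip and empty tables are rejected", {
  tr <- mk_trials(c(1.2, 3.4), "A")
  f <- tempfile(fileext = ".csv")
  write_trials(tr, f)
  tr2 <- read_trials(f)
  expect_equal(tr2$error_mm, tr$error_mm)
  empty <- tempfile(fileext = ".csv")
  write.csv(tr[0, ], empty, row.names = FALSE)
  expect_error(read_trials(empty), "empty")
})
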