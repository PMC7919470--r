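#' Summary statistics of trial errors
#'
#' Groups per-target errors (by case, user, or any column combination) and
#' reports n, mean, sample standard deviation (n - 1 convention), median,
#' first/third quartiles and whisker bounds. Whiskers follow the mean plus or
#' minus 1.5 standard deviations convention used in the validation figures;
#' `whiskers = "iqr"` switches to Tukey's 1.5 IQR fences.
#'
#' @param trials `trial_result` data.frame (needs an `error_mm` column).
#' @param group_by character vector of grouping columns (may be empty for an
#'   overall row).
#' @param whiskers "sd" (mean +/- 1.5 sd) or "iqr" (Tukey fences).
#' @return data.frame with one row per group.
#' @export
summarize_errors <- function(trials, group_by = "case",
                             whiskers = c("sd", "iqr")) {
  whiskers <- match.arg(whiskers)
  if (!nrow(trials)) stop("no trials to summarize")
  stopifnot("error_mm" %in% names(trials), all(group_by %in% names(trials)))
  key <- if (length(group_by))
    interaction(trials[group_by], drop = TRUE, lex.order = TRUE)
  else factor(rep("all", nrow(trials)))
  rows <- lapply(levels(key), function(lv) {
    e <- trials$error_mm[key == lv]
    q <- stats::quantile(e, c(0.25, 0.5, 0.75), names = FALSE)
    m <- mean(e); s <- stats::sd(e)
    w <- if (whiskers == "sd") c(m - 1.5 * s, m + 1.5 * s)
         else c(q[1] - 1.5 * (q[3] - q[1]), q[3] + 1.5 * (q[3] - q[1]))
    g <- if (length(group_by))
      trials[which(key == lv)[1], group_by, drop = FALSE]
    else data.frame(group = "all")
    cbind(g, data.frame(n = length(e), mean_mm = m, sd_mm = s,
                        median_mm = q[2], q1_mm = q[1], q3_mm = q[3],
                        whisker_low = w[1], whisker_high = w[2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired user comparison (two-sided paired t-test)
#'
#' Tests whether two users differ systematically, pairing their per-trial (or
#' per-phantom) mean errors. Identical vectors are reported as t = 0, p = 1
#' (no evidence of a difference, rather than an undefined statistic).
#'
#' @param u1,u2 numeric vectors of equal length (>= 2), paired.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_user_test <- function(u1, u2) {
  if (length(u1) != length(u2)) stop("paired vectors must have equal length")
  if (length(u1) < 2) stop("need at least 2 pairs")
  d <- u1 - u2
  if (all(abs(d - d[1]) < .Machine$double.eps * 100) && abs(d[1]) < 1e-300)
    return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0))
  ht <- stats::t.test(u1, u2, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}

#' Rank correlation between target distance and error
#'
#' Spearman correlation between each target's distance to the marker and its
#' error, quantifying the lever-arm effect (rotational tracking noise grows
#' linearly with distance from the marker, so errors increase away from it).
#'
#' @param trials `trial_result` data.frame with `error_mm` and
#'   `distance_to_marker_mm` columns (>= 3 distinct distances).
#' @return list with `rho`, `p`, `n` and `defined` (FALSE when the inputs are
#'   constant and the correlation is undefined).
#' @export
distance_error_correlation <- function(trials) {
  stopifnot(all(c("error_mm", "distance_to_marker_mm") %in% names(trials)))
  x <- trials$distance_to_marker_mm; y <- trials$error_mm
  if (length(unique(x)) < 3) stop("need >= 3 targets with distinct distances")
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x), defined = TRUE)
}

# round half up to `digits` decimals (printed Likert tables use half-up, while
# base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Likert survey table
#'
#' Respondent-by-question integer scores on a 1-5 scale.
#' @param scores matrix or data.frame, one row per question, one column per
#'   respondent (this is the printed orientation of the survey tables).
#' @param questions,respondents optional labels.
#' @export
survey_table <- function(scores, questions = NULL, respondents = NULL) {
  m <- as.matrix(scores)
  if (!all(m %in% 1:5)) stop("survey scores must be integers in 1..5")
  storage.mode(m) <- "integer"
  rownames(m) <- if (is.null(questions)) rownames(scores) else questions
  colnames(m) <- if (is.null(respondents)) colnames(scores) else respondents
  structure(list(scores = m), class = "survey_table")
}

#' Summarize a Likert survey
#'
#' Arithmetic means per question and per respondent, plus the grand mean,
#' rounded half-up to one decimal as printed in the survey tables.
#'
#' @param table a `survey_table` (or a question x respondent matrix).
#' @param digits decimals for the rounded display values.
#' @return list with `question_means`, `respondent_means`, `overall_mean`
#'   (all rounded) and the unrounded `raw` counterparts.
#' @export
survey_summary <- function(table, digits = 1) {
  if (!inherits(table, "survey_table")) table <- survey_table(table)
  m <- table$scores
  qm <- rowMeans(m); rm_ <- colMeans(m); om <- mean(m)
  list(question_means = round_half_up(qm, digits),
       respondent_means = round_half_up(rm_, digits),
       overall_mean = round_half_up(om, digits),
       raw = list(question_means = qm, respondent_means = rm_,
                  overall_mean = om))
}

#' Read a survey CSV
#'
#' Expected layout: first column question labels, remaining columns integer
#' scores with a header row of respondent ids.
#' @param path CSV path.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  survey_table(as.matrix(df[, -1, drop = FALSE]), questions = df[[1]])
}

#' Write / read trial results as CSV
#' @param trials a `trial_result` data.frame.
#' @param path CSV path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty trial table: ", path)
  class(df) <- c("trial_result", "data.frame")
  df
}

#' Box plot of per-case errors
#'
#' One box per group with the validation-figure conventions: box edges at the
#' quartiles, centre line at the median, whiskers at mean +/- 1.5 sd.
#'
#' @param trials `trial_result` data.frame.
#' @param group_by grouping column.
#' @param main,ylab plot labels.
#' @export
plot_error_boxes <- function(trials, group_by = "case",
                             main = "Error by case", ylab = "Error [mm]") {
  s <- summarize_errors(trials, group_by)
  ng <- nrow(s)
  graphics::plot(NULL, xlim = c(0.5, ng + 0.5),
                 ylim = range(c(s$whisker_low, s$whisker_high, 0)),
                 xaxt = "n", xlab = "", ylab = ylab, main = main)
  graphics::axis(1, at = seq_len(ng), labels = s[[group_by]], las = 2)
  for (i in seq_len(ng)) {
    graphics::rect(i - 0.3, s$q1_mm[i], i + 0.3, s$q3_mm[i], col = "grey85")
    graphics::segments(i - 0.3, s$median_mm[i], i + 0.3, s$median_mm[i], lwd = 2)
    graphics::segments(i, s$whisker_low[i], i, s$q1_mm[i], lty = 2)
    graphics::segments(i, s$q3_mm[i], i, s$whisker_high[i], lty = 2)
  }
  invisible(s)
}
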