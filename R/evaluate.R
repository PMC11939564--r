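#' Error metrics for blood-pressure predictions
#'
#' Mean error `ME = mean(y - yhat)`, mean absolute error, root mean square
#' error, sample standard deviation of the error (n - 1 denominator) and
#' mean relative error `MRE = mean(|y - yhat| / y) * 100`.
#'
#' @param y_true,y_pred mmHg vectors of equal nonzero length; `y_true` must
#'   be strictly positive for the relative error.
#' @return list of class `metrics_report`: `me`, `mae`, `rmse`, `sd_error`
#'   (all mmHg), `mre` (percent), `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty input")
  if (any(y_true <= 0)) stop("true values must be positive for MRE")
  e <- y_true - y_pred
  structure(list(
    me = mean(e),
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    sd_error = if (length(e) > 1L) stats::sd(e) else 0,
    mre = mean(abs(e) / y_true) * 100,
    n = length(e)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "ME %.2f  MAE %.2f  RMSE %.2f  SD %.2f mmHg  MRE %.2f%%  (n = %d)\n",
    x$me, x$mae, x$rmse, x$sd_error, x$mre, x$n))
  invisible(x)
}

BHS_THRESHOLDS <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))

#' British Hypertension Society error grading
#'
#' Cumulative percentages of absolute errors under 5, 10 and 15 mmHg
#' (strict inequality), graded against the protocol thresholds: grade A
#' requires 60/85/95%, B 50/75/90%, C 40/65/85%, each comparison inclusive
#' (`>=`). The best grade whose three thresholds are all met is returned;
#' `"ungraded"` otherwise.
#'
#' @param errors mmHg error vector (prediction minus reference or reverse;
#'   only magnitudes matter).
#' @return list of class `bhs_result`: `cum5`, `cum10`, `cum15` (percent),
#'   `grade` ("A", "B", "C" or "ungraded").
#' @export
bhs_grade <- function(errors) {
  errors <- as.numeric(errors)
  if (!length(errors)) stop("empty error vector")
  cums <- vapply(c(5, 10, 15),
                 function(th) 100 * mean(abs(errors) < th), numeric(1))
  structure(list(cum5 = cums[1], cum10 = cums[2], cum15 = cums[3],
                 grade = bhs_grade_from_cums(cums)),
            class = "bhs_result")
}

#' Grade a cumulative-frequency triple against the BHS thresholds
#'
#' @param cums numeric length 3: percent of absolute errors under 5, 10 and
#'   15 mmHg.
#' @return "A", "B", "C" or "ungraded".
#' @export
bhs_grade_from_cums <- function(cums) {
  stopifnot(length(cums) == 3L)
  for (g in names(BHS_THRESHOLDS)) {
    if (all(cums >= BHS_THRESHOLDS[[g]])) return(g)
  }
  "ungraded"
}

#' AAMI compliance check
#'
#' A device passes when the mean error lies within +/-5 mmHg (inclusive)
#' and the error standard deviation is below 8 mmHg (exclusive).
#'
#' @param me mean error in mmHg.
#' @param sd error standard deviation in mmHg (>= 0).
#' @return list of class `aami_result`: `me`, `sd`, `pass`.
#' @export
aami_check <- function(me, sd) {
  if (sd < 0) stop("sd must be non-negative")
  structure(list(me = me, sd = sd, pass = (abs(me) <= 5) && (sd < 8)),
            class = "aami_result")
}

#' Bland-Altman agreement analysis
#'
#' Differences are prediction minus reference; limits of agreement are the
#' mean difference +/- 1.96 times the sample SD (n - 1) of the differences.
#'
#' @param y_true,y_pred mmHg vectors of equal length >= 2.
#' @return list of class `bland_altman`: `mean_diff`, `loa_low`,
#'   `loa_high` (mmHg) and `pairs` (data.frame of `average`, `difference`).
#' @export
bland_altman <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least 2 pairs")
  d <- y_pred - y_true
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, loa_low = m - 1.96 * s,
                 loa_high = m + 1.96 * s,
                 pairs = data.frame(average = (y_true + y_pred) / 2,
                                    difference = d)),
            class = "bland_altman")
}

#' Regression statistics between predictions and reference
#'
#' Pearson r, the OLS best-fit line of prediction on reference, and the R^2
#' of that fit.
#'
#' @param y_true,y_pred mmHg vectors with nonzero variance.
#' @return list with `r`, `r2`, `slope`, `intercept`.
#' @export
regression_stats <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    stop("zero-variance input")
  }
  fit <- stats::lm(y_pred ~ y_true)
  r <- stats::cor(y_true, y_pred)
  # simple regression: the fit's R^2 equals the squared correlation
  list(r = r,
       r2 = r^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Full validation report for one pressure component
#'
#' @param y_true,y_pred mmHg vectors.
#' @return list with `metrics` ([compute_metrics()]), `bhs`
#'   ([bhs_grade()]), `aami` ([aami_check()]), `bland_altman`
#'   ([bland_altman()]) and `regression` ([regression_stats()]).
#' @export
validation_report <- function(y_true, y_pred) {
  m <- compute_metrics(y_true, y_pred)
  list(metrics = m,
       bhs = bhs_grade(y_true - y_pred),
       aami = aami_check(m$me, m$sd_error),
       bland_altman = bland_altman(y_true, y_pred),
       regression = if (stats::sd(y_true) > 0 && stats::sd(y_pred) > 0) {
         regression_stats(y_true, y_pred)
       } else NULL)
}

#' Write a validation report to CSV and plain text
#'
#' @param report_s,report_d reports from [validation_report()] for the
#'   systolic and diastolic components.
#' @param dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_reports <- function(report_s, report_d, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  row <- function(lbl, r) {
    data.frame(component = lbl, me = r$metrics$me, mae = r$metrics$mae,
               rmse = r$metrics$rmse, sd = r$metrics$sd_error,
               mre = r$metrics$mre, n = r$metrics$n,
               bhs_cum5 = r$bhs$cum5, bhs_cum10 = r$bhs$cum10,
               bhs_cum15 = r$bhs$cum15, bhs_grade = r$bhs$grade,
               aami_pass = r$aami$pass,
               loa_low = r$bland_altman$loa_low,
               loa_high = r$bland_altman$loa_high)
  }
  tab <- rbind(row("SBP", report_s), row("DBP", report_d))
  csv <- file.path(dir, "validation.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  txt <- file.path(dir, "validation.txt")
  lines <- c(
    "Blood-pressure validation report",
    "================================",
    vapply(seq_len(nrow(tab)), function(i) {
      with(tab[i, ], sprintf(
        paste0("%s: ME %.2f, MAE %.2f, RMSE %.2f, SD %.2f mmHg, MRE %.2f%% | ",
               "BHS %.1f/%.1f/%.1f%% grade %s | AAMI %s | LOA [%.2f, %.2f]"),
        component, me, mae, rmse, sd, mre, bhs_cum5, bhs_cum10, bhs_cum15,
        bhs_grade, ifelse(aami_pass, "pass", "fail"), loa_low, loa_high))
    }, character(1)))
  writeLines(lines, txt)
  invisible(c(csv = csv, txt = txt))
}
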