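# Evaluation metrics for predicted versus measured angular velocity
# (RMSE, Pearson correlation, NRMSE, R squared) and the cohort comparison
# report contrasting performance with and without quick training.

#' Pair predicted and measured velocity series
#'
#' @param predicted Numeric vector of predicted joint velocities (deg/s).
#' @param measured Numeric vector of measured joint velocities (deg/s).
#' @return An object of class `velocity_prediction`.
#' @export
prediction <- function(predicted, measured) {
  predicted <- as.numeric(predicted)
  measured <- as.numeric(measured)
  if (length(predicted) != length(measured))
    wv_stop("prediction: lengths differ (", length(predicted), " vs ",
            length(measured), ")")
  if (length(predicted) == 0L) wv_stop("prediction: empty series")
  if (any(!is.finite(predicted)) || any(!is.finite(measured)))
    wv_stop("prediction: non-finite values")
  structure(list(predicted = predicted, measured = measured,
                 n = length(predicted)),
            class = "velocity_prediction")
}

#' Root-mean-square error
#'
#' `sqrt(mean((predicted - measured)^2))`, in deg/s.
#'
#' @param p A [prediction()].
#' @return Non-negative RMSE.
#' @export
rmse <- function(p) {
  stopifnot(inherits(p, "velocity_prediction"))
  sqrt(mean((p$predicted - p$measured)^2))
}

#' Pearson correlation between predicted and measured velocity
#'
#' The covariance of the two series normalised by the product of their
#' standard deviations; always in [-1, 1], and undefined (an error) when
#' either series has zero variance.
#'
#' @param p A [prediction()].
#' @return Correlation in [-1, 1].
#' @export
pearson <- function(p) {
  stopifnot(inherits(p, "velocity_prediction"))
  if (p$n < 2L) wv_stop("pearson: need at least 2 frames")
  a <- p$predicted - mean(p$predicted)
  b <- p$measured - mean(p$measured)
  sa <- sqrt(sum(a * a)); sb <- sqrt(sum(b * b))
  if (sa == 0 || sb == 0)
    wv_stop("pearson: zero variance in ",
            if (sa == 0) "predicted" else "measured", " series")
  max(-1, min(1, sum(a * b) / (sa * sb)))
}

#' Normalised root-mean-square error
#'
#' RMSE divided by a scale of the measured series.  The normaliser is
#' configurable because published values depend on the convention; the
#' default is the measured range (max - min).
#'
#' @param p A [prediction()].
#' @param normalizer `"range"`, `"mean"` or `"sd"` of the measured
#'   series.
#' @return The normalised RMSE.
#' @export
nrmse <- function(p, normalizer = c("range", "mean", "sd")) {
  stopifnot(inherits(p, "velocity_prediction"))
  normalizer <- match.arg(normalizer)
  denom <- switch(normalizer,
                  range = diff(range(p$measured)),
                  mean = abs(mean(p$measured)),
                  sd = stats::sd(p$measured))
  if (!is.finite(denom) || denom <= 0)
    wv_stop("nrmse: measured ", normalizer, " is zero; NRMSE undefined")
  rmse(p) / denom
}

#' Coefficient of determination
#'
#' `1 - RSS/TSS` about the measured mean; negative when predictions are
#' worse than predicting the mean.
#'
#' @param p A [prediction()].
#' @return R squared (at most 1, possibly negative).
#' @export
r_squared <- function(p) {
  stopifnot(inherits(p, "velocity_prediction"))
  if (p$n < 2L) wv_stop("r_squared: need at least 2 frames")
  tss <- sum((p$measured - mean(p$measured))^2)
  if (tss == 0) wv_stop("r_squared: zero variance in measured series")
  1 - sum((p$predicted - p$measured)^2) / tss
}

#' Evaluate one subject under one condition
#'
#' @param p A [prediction()].
#' @param subject Subject identifier.
#' @param condition `"without_quick"` or `"with_quick"`.
#' @param task Task name.
#' @return A one-row data frame with RMSE, PC, NRMSE and R squared.
#' @export
evaluate_prediction <- function(p, subject, condition =
                                  c("without_quick", "with_quick"),
                                task = NA_character_) {
  condition <- match.arg(condition)
  data.frame(task = task, subject = as.character(subject),
             condition = condition,
             rmse = rmse(p),
             pc = tryCatch(pearson(p), error = function(e) NA_real_),
             nrmse = tryCatch(nrmse(p), error = function(e) NA_real_),
             r2 = tryCatch(r_squared(p), error = function(e) NA_real_),
             stringsAsFactors = FALSE)
}

#' Build a with/without quick-training comparison report
#'
#' Produces the per-subject grid, per-task condition averages, per-task
#' percent change of average RMSE (decrease) and average PC (increase),
#' and the cross-task mean of those percent changes.  Averages are
#' unweighted means over the subjects present for that condition; a
#' subject missing under a condition is recorded as absent and excluded.
#'
#' @param results A data frame with columns `task`, `subject`,
#'   `condition` (`without_quick` / `with_quick`), `rmse`, `pc`.
#' @return An object of class `comparison_report` with fields `grid`,
#'   `task_summary`, `rmse_decrease_pct_mean`, `pc_increase_pct_mean`.
#' @export
build_report <- function(results) {
  results <- as.data.frame(results, stringsAsFactors = FALSE)
  need <- c("task", "subject", "condition", "rmse", "pc")
  if (!all(need %in% names(results)) || nrow(results) == 0L)
    wv_stop("build_report: need a non-empty data frame with columns ",
            paste(need, collapse = ", "))
  if (!all(results$condition %in% c("without_quick", "with_quick")))
    wv_stop("build_report: condition must be without_quick or with_quick")
  tasks <- unique(results$task)
  summ <- lapply(tasks, function(tk) {
    sub <- results[results$task == tk, ]
    avg <- function(cond, col) {
      v <- sub[sub$condition == cond, col]
      v <- v[is.finite(v)]
      if (!length(v)) NA_real_ else mean(v)
    }
    rw <- avg("without_quick", "rmse"); rq <- avg("with_quick", "rmse")
    pw <- avg("without_quick", "pc"); pq <- avg("with_quick", "pc")
    data.frame(task = tk,
               rmse_without = rw, rmse_with = rq,
               rmse_decrease_pct = 100 * (rw - rq) / rw,
               pc_without = pw, pc_with = pq,
               pc_increase_pct = 100 * (pq - pw) / abs(pw),
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  structure(list(grid = results,
                 task_summary = summ,
                 rmse_decrease_pct_mean = mean(summ$rmse_decrease_pct,
                                               na.rm = TRUE),
                 pc_increase_pct_mean = mean(summ$pc_increase_pct,
                                             na.rm = TRUE)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  g <- x$grid
  subjects <- unique(g$subject)
  cat("Per-subject RMSE (deg/s) and PC, before/after quick training\n")
  for (tk in unique(g$task)) {
    for (cond in c("without_quick", "with_quick")) {
      for (met in c("rmse", "pc")) {
        vals <- vapply(subjects, function(s) {
          v <- g[g$task == tk & g$condition == cond & g$subject == s, met]
          if (length(v) && is.finite(v[1L]))
            sprintf("%7.2f", v[1L]) else "      -"
        }, character(1))
        row <- x$task_summary[x$task_summary$task == tk, ]
        ave <- if (met == "rmse") {
          if (cond == "without_quick") row$rmse_without else row$rmse_with
        } else {
          if (cond == "without_quick") row$pc_without else row$pc_with
        }
        cat(sprintf("%-8s %-8s %-5s %s %7.2f\n", tk,
                    if (cond == "without_quick") "WO-Quick" else "W-Quick",
                    toupper(met), paste(vals, collapse = " "), ave))
      }
    }
  }
  cat(sprintf("\nCross-task mean RMSE decrease: %.1f%%; mean PC increase: %.1f%%\n",
              x$rmse_decrease_pct_mean, x$pc_increase_pct_mean))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits the per-subject grid as CSV and the averages / percent changes
#' as JSON.
#'
#' @param report A [build_report()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid_path <- file.path(dir, "report_grid.csv")
  json_path <- file.path(dir, "report_summary.json")
  data.table::fwrite(report$grid, grid_path)
  jsonlite::write_json(
    list(task_summary = report$task_summary,
         rmse_decrease_pct_mean = report$rmse_decrease_pct_mean,
         pc_increase_pct_mean = report$pc_increase_pct_mean),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt_path <- file.path(dir, "report_table.txt")
  sink(txt_path); print(report); sink()
  invisible(c(grid = grid_path, summary = json_path, table = txt_path))
}
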