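#' Exposure grouping by recurrent activity
#'
#' Splits the population in two for one activity: patients whose row-i sum
#' over the frequent-history windows `1..w-1` reaches the population mean of
#' that sum (exposed, `>=` includes equality) versus the rest. The
#' relative-risk validation is run on the entire population (train and
#' test together) in the pipeline.
#'
#' @param dataset a `matrix_dataset` (values on the stored, rescaled scale;
#'   the mean threshold is on the same scale, so grouping is identical on
#'   raw counts).
#' @param activity an activity label in `dataset$row_labels`.
#' @return Object of class `exposure_grouping`: list with `label`, `scope`,
#'   `exposure` (0/1 named by patient id), `threshold` (the population
#'   mean).
#' @export
exposure_frequent <- function(dataset, activity) {
  exposure_build(dataset, activity, scope = "frequent")
}

#' @rdname exposure_frequent
#' @description `exposure_last_window()` applies the same mean-threshold
#'   rule to the single last time window `x[i, w]` before the index date.
#' @export
exposure_last_window <- function(dataset, activity) {
  exposure_build(dataset, activity, scope = "last-window")
}

exposure_build <- function(dataset, activity, scope) {
  i <- match(activity, dataset$row_labels)
  if (is.na(i)) stop("activity not in row_labels: ", activity)
  l <- length(dataset$row_labels); w <- dataset$window$n_windows
  cols <- if (scope == "frequent") i + (seq_len(w - 1L) - 1L) * l
          else i + (w - 1L) * l
  stat <- rowSums(dataset$values[, cols, drop = FALSE])
  thr <- mean(stat)
  structure(list(label = activity, scope = scope,
                 exposure = stats::setNames(as.integer(stat >= thr),
                                            dataset$patient_ids),
                 threshold = thr),
            class = "exposure_grouping")
}

# rr + Katz log-normal 95% CI from 2x2 counts; +0.5 continuity on zero cells
rr_from_counts <- function(a, b, c, d) {
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  rr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  ci <- exp(log(rr) + c(-1, 1) * 1.96 * se)
  list(rr = rr, ci_low = ci[1], ci_high = ci[2], corrected = corrected)
}

#' Relative risk of the outcome given an exposure grouping
#'
#' Builds the 2x2 table (a = exposed positive, b = exposed negative, c =
#' unexposed positive, d = unexposed negative), computes `RR =
#' (a/(a+b)) / (c/(c+d))` and the 95% Katz log-normal confidence interval
#' `exp(log RR +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. When any
#' cell is zero, 0.5 is added to all four cells (flagged `corrected`).
#'
#' @param grouping an `exposure_grouping`, or a 0/1 exposure vector.
#' @param outcomes 0/1 outcome vector aligned with the exposure (for an
#'   `exposure_grouping`, aligned with its patient order).
#' @return One-row data.frame of class `risk_record`: `label, scope, a, b,
#'   c, d, rr, ci_low, ci_high, significant, corrected`.
#' @export
relative_risk <- function(grouping, outcomes) {
  if (inherits(grouping, "exposure_grouping")) {
    expo <- grouping$exposure
    label <- grouping$label; scope <- grouping$scope
  } else {
    expo <- grouping; label <- NA_character_; scope <- NA_character_
  }
  if (length(expo) != length(outcomes)) stop("exposure/outcomes length mismatch")
  if (all(expo == 1L) || all(expo == 0L))
    stop("undefined relative risk: an exposure group is empty")
  a <- sum(expo == 1L & outcomes == 1L); b <- sum(expo == 1L & outcomes == 0L)
  c <- sum(expo == 0L & outcomes == 1L); d <- sum(expo == 0L & outcomes == 0L)
  kz <- rr_from_counts(a, b, c, d)
  out <- data.frame(label = label, scope = scope, a = a, b = b, c = c, d = d,
                    rr = kz$rr, ci_low = kz$ci_low, ci_high = kz$ci_high,
                    significant = kz$ci_low > 1 | kz$ci_high < 1,
                    corrected = kz$corrected, stringsAsFactors = FALSE)
  class(out) <- c("risk_record", class(out))
  out
}

#' Relative risks for a table of ranked activities
#'
#' For each ranked activity, groups the population by the scope-matched
#' exposure rule and computes the relative risk of the outcome.
#'
#' @param ranking data.frame from [rank_frequent()] / [rank_last_window()].
#' @param dataset a `matrix_dataset` (the whole population).
#' @return data.frame of stacked risk records (one row per activity).
#' @export
risk_table <- function(ranking, dataset) {
  rows <- lapply(seq_len(nrow(ranking)), function(r) {
    g <- if (ranking$scope[r] == "frequent")
      exposure_frequent(dataset, ranking$label[r])
    else exposure_last_window(dataset, ranking$label[r])
    tryCatch(relative_risk(g, dataset$classes),
             error = function(e) NULL)       # degenerate exposure -> skip
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- relative_risk(structure(list(label = NA, scope = NA,
                                        exposure = c(0L, 1L)),
                                   class = "exposure_grouping"),
                         c(0L, 1L))[0, ]
  rownames(out) <- NULL
  out
}

#' Select the final explaining risk factors
#'
#' Keeps records whose 95% CI excludes 1 with RR > 1, orders them by RR
#' descending and returns the top `k_final` (15 in the case study). May
#' return fewer when few records are significant.
#'
#' @param records data.frame of risk records (e.g. from [risk_table()]).
#' @param k_final maximum number of factors returned.
#' @return The selected rows, RR-descending.
#' @export
select_risk_factors <- function(records, k_final = 15L) {
  keep <- records$significant & records$rr > 1
  out <- records[keep, , drop = FALSE]
  out <- out[order(-out$rr, out$label), , drop = FALSE]
  out <- utils::head(out, k_final)
  rownames(out) <- NULL
  out
}

#' Forest plot of relative risks
#'
#' One row per factor, point at RR with the 95% CI as a horizontal segment,
#' on a log-scale axis with the null line at RR = 1.
#'
#' @param records data.frame of risk records.
#' @param ... passed to [graphics::plot()].
#' @export
plot_forest <- function(records, ...) {
  n <- nrow(records)
  if (n == 0L) stop("no risk records to plot")
  y <- rev(seq_len(n))
  xlim <- range(c(records$ci_low, records$ci_high, 1))
  graphics::plot(records$rr, y, log = "x", xlim = xlim, pch = 16,
                 yaxt = "n", xlab = "relative risk (log scale)", ylab = "",
                 ylim = c(0.5, n + 0.5), ...)
  graphics::segments(records$ci_low, y, records$ci_high, y)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = y, labels = paste0(records$label, " (", records$scope, ")"),
                 las = 2, cex.axis = 0.7)
  invisible(records)
}

#' Write a relative-risk report to CSV
#'
#' Columns `label,system,scope,a,b,c,d,rr,ci_low,ci_high,significant,corrected`.
#'
#' @param records risk records data.frame.
#' @param systems optional label -> system named vector.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_risk_report <- function(records, path, systems = NULL) {
  out <- records
  out$system <- if (is.null(systems)) NA_character_ else
    unname(systems[records$label])
  out <- out[, c("label", "system", "scope", "a", "b", "c", "d", "rr",
                 "ci_low", "ci_high", "significant", "corrected")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
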