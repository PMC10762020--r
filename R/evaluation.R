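# Accuracy metrics and statistical comparisons for estimated-vs-
# reference respiratory rate.

#' Align estimates with a reference series
#'
#' The reference is linearly interpolated onto the estimate timestamps
#' (cycle-to-cycle comparison). Estimates outside the reference time
#' support are dropped, and the drop count is reported via
#' [message()].
#'
#' @param est An `rr_series` from [estimate_rr()], or a data frame with
#'   columns `time_s` and `rr_bpm`.
#' @param ref A reference: a data frame with columns `time_s` and
#'   `rr_bpm` (e.g. from [read_rr_csv()]), or a function of time
#'   returning bpm (e.g. a `synthetic_truth$true_rr`).
#' @param smoothed Use the smoothed estimates (default) or the raw
#'   ones.
#' @return An `aligned_rr` data frame with columns `times`, `estimated`
#'   and `reference`.
#' @export
align_rr <- function(est, ref, smoothed = TRUE) {
  if (inherits(est, "rr_series")) {
    times <- est$times
    values <- if (smoothed) est$rr_smoothed else est$rr_raw
  } else {
    if (!all(c("time_s", "rr_bpm") %in% names(est)))
      stop_input("`est` needs columns time_s and rr_bpm")
    times <- est$time_s; values <- est$rr_bpm
  }
  if (is.function(ref)) {
    refv <- ref(times)
    keep <- is.finite(refv)
  } else {
    if (!all(c("time_s", "rr_bpm") %in% names(ref)))
      stop_input("`ref` needs columns time_s and rr_bpm")
    refv <- stats::approx(ref$time_s, ref$rr_bpm, xout = times,
                          rule = 1, ties = "ordered")$y
    keep <- !is.na(refv)
  }
  if (sum(keep) == 0L)
    stop_input("estimate and reference series have no overlapping time support")
  if (any(!keep))
    message(sprintf("dropped %d estimate(s) outside the reference support",
                    sum(!keep)))
  structure(data.frame(times = times[keep], estimated = values[keep],
                       reference = refv[keep]),
            class = c("aligned_rr", "data.frame"))
}

#' Error metrics for aligned RR series
#'
#' Absolute error `|est - ref|` (bpm), relative error
#' `100 * |est - ref| / ref` (%), RMSE, and the R-squared of an
#' ordinary least-squares fit of the estimates on the reference (with
#' intercept). The identity-line R-squared
#' (`1 - SS(est - ref) / SS(ref - mean(ref))`) is reported alongside.
#' Pairs with a zero reference are excluded from the relative error
#' and the exclusion reported.
#'
#' @param a An [align_rr()] result (or any data frame with `estimated`
#'   and `reference` columns).
#' @return An `eval_report` list: `n`, `abs_err` and `rel_err` (each
#'   with `mean`, `median`, `sd`), `rmse`, `bias`, `r2` (fit), and
#'   `r2_identity`, `slope`, `intercept`.
#' @export
error_metrics <- function(a) {
  if (!all(c("estimated", "reference") %in% names(a)))
    stop_input("`a` needs estimated and reference columns")
  est <- a$estimated; ref <- a$reference
  if (length(est) < 2L) stop_input("need at least 2 aligned pairs")
  abs_err <- abs(est - ref)
  nz <- ref != 0
  if (any(!nz))
    message(sprintf(
      "relative error undefined for %d pair(s) with zero reference; excluded",
      sum(!nz)))
  rel_err <- 100 * abs_err[nz] / abs(ref[nz])
  fit <- stats::lm(est ~ ref)
  sstot <- sum((est - mean(est))^2)
  r2_fit <- if (sstot > 0) 1 - sum(stats::residuals(fit)^2) / sstot else 1
  r2_id <- if (sstot > 0) 1 - sum((est - ref)^2) / sstot else NA_real_
  structure(list(
    n = length(est),
    abs_err = list(mean = mean(abs_err), median = stats::median(abs_err),
                   sd = stats::sd(abs_err)),
    rel_err = list(mean = mean(rel_err), median = stats::median(rel_err),
                   sd = stats::sd(rel_err)),
    rmse = sqrt(mean((est - ref)^2)),
    bias = mean(est - ref),
    r2 = r2_fit,
    r2_identity = r2_id,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L])),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d pairs\n", x$n))
  cat(sprintf("  absolute error (bpm): mean %.3f, median %.3f, sd %.3f\n",
              x$abs_err$mean, x$abs_err$median, x$abs_err$sd))
  cat(sprintf("  relative error (%%):   mean %.3f, median %.3f, sd %.3f\n",
              x$rel_err$mean, x$rel_err$median, x$rel_err$sd))
  cat(sprintf("  RMSE %.3f bpm, bias %+.3f bpm\n", x$rmse, x$bias))
  cat(sprintf("  linear fit R^2 %.4f (slope %.3f, intercept %.3f); identity R^2 %.4f\n",
              x$r2, x$slope, x$intercept, x$r2_identity))
  invisible(x)
}

#' TOST equivalence test on paired RR differences
#'
#' Two one-sided t tests on the paired differences `est - ref`:
#' equivalence at margin `delta` is concluded when the
#' `conf`-level confidence interval of the mean difference lies
#' entirely inside `(-delta, +delta)` (equivalently, both one-sided
#' p-values fall below `(1 - conf) / 2`). With zero variance the
#' interval degenerates to the point estimate.
#'
#' @param a An [align_rr()] result, or a numeric vector of paired
#'   differences.
#' @param delta Equivalence margin in bpm (default 2).
#' @param conf Confidence level of the interval (default 0.90).
#' @return A `tost_result` list: `bias`, `ci` (two-sided `conf`
#'   interval), `p_lower`, `p_upper`, `equivalent`, `n`, `delta`,
#'   `conf`.
#' @export
tost_equivalence <- function(a, delta = 2, conf = 0.90) {
  d <- if (is.numeric(a)) a else {
    if (!all(c("estimated", "reference") %in% names(a)))
      stop_input("`a` needs estimated and reference columns")
    a$estimated - a$reference
  }
  n <- length(d)
  if (n < 3L) stop_input("need at least 3 paired differences")
  if (delta <= 0) stop_config("delta must be > 0")
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    ci <- c(m, m)
    p_lower <- as.numeric(m <= -delta)
    p_upper <- as.numeric(m >= delta)
  } else {
    se <- s / sqrt(n)
    tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1L)
    ci <- c(m - tcrit * se, m + tcrit * se)
    p_lower <- stats::pt((m + delta) / se, df = n - 1L, lower.tail = FALSE)
    p_upper <- stats::pt((m - delta) / se, df = n - 1L)
  }
  structure(list(bias = m, ci = ci, p_lower = p_lower, p_upper = p_upper,
                 equivalent = ci[1] > -delta && ci[2] < delta,
                 n = n, delta = delta, conf = conf),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf(
    "<tost_result> bias %+.3f bpm, %d%% CI [%.3f, %.3f], margin +/-%g bpm\n",
    x$bias, round(100 * x$conf), x$ci[1], x$ci[2], x$delta))
  cat(sprintf("  one-sided p: lower %.3g, upper %.3g -> %s\n",
              x$p_lower, x$p_upper,
              if (x$equivalent) "EQUIVALENT" else "not equivalent"))
  invisible(x)
}

#' Pairwise Wilcoxon rank-sum comparison of RR distributions
#'
#' Two-sided rank-sum test for every pair of groups (e.g. the RR
#' estimates collected at different ventilator settings). The exact
#' null distribution is enumerated for small tie-free samples (both
#' groups <= 10); larger or tied samples use the continuity-corrected
#' normal approximation with tie correction. A pair whose values are
#' all identical gets p = 1.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return A symmetric matrix of two-sided p-values with `NA` on the
#'   diagonal.
#' @export
ranksum_compare <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_input("`groups` must be a list of >= 2 numeric vectors")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop_input("every group needs >= 2 values")
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- groups[[i]]; y <- groups[[j]]
    if (length(unique(c(x, y))) == 1L) {
      pv <- 1
    } else {
      exact <- length(x) <= 10L && length(y) <= 10L &&
        !any(duplicated(c(x, y)))
      pv <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
      if (!is.finite(pv)) pv <- 1
    }
    p[i, j] <- p[j, i] <- pv
  }
  p
}
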