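# Group-level comparison of band powers, PAC summaries and LTP windows.

#' Two-sample t-test with mean difference and 95% CI
#'
#' Pooled-variance (equal-variance) two-sided test by default, matching
#' the convention used for band-power and PAC summaries; Welch's
#' correction is available by flag. Degenerate zero-variance input with
#' equal means returns `t = 0, p = 1` rather than an error.
#'
#' @param a,b numeric vectors (one value per subject), each of length >= 2.
#' @param var_equal pooled variance if `TRUE` (default), Welch otherwise.
#' @return A `group_comparison` with `statistic`, `p_value`, `mean_diff`
#'   (`mean(a) - mean(b)`), `ci95`, `df`, `n1`, `n2`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 values", call. = FALSE)
  if (!all(is.finite(c(a, b)))) stop("non-finite values", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    d <- mean(a) - mean(b)
    res <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p_value = if (d == 0) 1 else 0,
                mean_diff = d, ci95 = c(d, d), df = n1 + n2 - 2,
                n1 = n1, n2 = n2)
    return(structure(res, class = "group_comparison"))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 mean_diff = unname(diff(rev(tt$estimate))),
                 ci95 = as.numeric(tt$conf.int), df = unname(tt$parameter),
                 n1 = n1, n2 = n2),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t(%0.1f) = %.3f, p = %.4g; diff = %.3g [%.3g, %.3g] (n = %d, %d)\n",
              x$df, x$statistic, x$p_value, x$mean_diff, x$ci95[1], x$ci95[2],
              x$n1, x$n2))
  invisible(x)
}

#' Per-timepoint comparison of two groups of LTP time courses
#'
#' Runs [two_sample_t] across subjects at every shared time point,
#' adjusts p-values for multiplicity (Holm by default), and reports
#' maximal runs of consecutive significant points as time spans.
#'
#' @param group_a,group_b lists of [ltp_timecourse] objects on identical
#'   time grids, >= 2 subjects each.
#' @param correction method for [stats::p.adjust] (default `"holm"`).
#' @param alpha significance level for the spans (default 0.05).
#' @param var_equal passed to [two_sample_t].
#' @return A `timecourse_comparison` with `times_min`, `comparisons`
#'   (list of `group_comparison`), `p`, `adjusted_p`, `significant`
#'   (logical) and `significant_spans` (data frame `start_min, end_min`).
#' @export
compare_timecourses <- function(group_a, group_b, correction = "holm",
                                alpha = 0.05, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need >= 2 subjects per group", call. = FALSE)
  t0 <- group_a[[1]]$times_min
  ok <- vapply(c(group_a, group_b), function(tc)
    length(tc$times_min) == length(t0) && all(abs(tc$times_min - t0) < 1e-9),
    TRUE)
  if (!all(ok)) stop("time grids differ between subjects", call. = FALSE)
  ma <- do.call(rbind, lapply(group_a, `[[`, "pct_baseline"))
  mb <- do.call(rbind, lapply(group_b, `[[`, "pct_baseline"))
  comps <- lapply(seq_along(t0), function(j)
    two_sample_t(ma[, j], mb[, j], var_equal = var_equal))
  p <- vapply(comps, `[[`, numeric(1), "p_value")
  adj <- stats::p.adjust(p, method = correction)
  sig <- adj < alpha
  spans <- if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start_min = t0[starts[r$values]], end_min = t0[ends[r$values]])
  } else data.frame(start_min = numeric(0), end_min = numeric(0))
  structure(list(times_min = t0, comparisons = comps, p = p,
                 adjusted_p = adj, significant = sig,
                 significant_spans = spans, correction = correction,
                 alpha = alpha),
            class = "timecourse_comparison")
}

#' @export
print.timecourse_comparison <- function(x, ...) {
  cat(sprintf("<timecourse_comparison> %d time points, %s-adjusted; %d significant at alpha = %g\n",
              length(x$times_min), x$correction, sum(x$significant), x$alpha))
  if (nrow(x$significant_spans))
    for (i in seq_len(nrow(x$significant_spans)))
      cat(sprintf("  significant span: %g to %g min\n",
                  x$significant_spans$start_min[i], x$significant_spans$end_min[i]))
  invisible(x)
}
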