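#' Asterisk significance tier of a p-value
#'
#' The reporting convention used throughout: `ns` for `p >= 0.05`, `*` for
#' `0.01 <= p < 0.05`, `**` for `0.001 <= p < 0.01`, `***` for `p < 0.001`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of tiers.
#' @examples
#' significance_tier(c(0.2, 0.049, 0.0099, 5e-4)) # ns * ** ***
#' @export
significance_tier <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must be p-values in [0, 1]", call. = FALSE)
  }
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Two-sample comparison under the cohort protocol
#'
#' The testing protocol for animal-level read-outs: normality of each group
#' is assessed by a Shapiro-Wilk test (recorded, and warned about when
#' rejected, but non-blocking — the t-test is reported regardless), then a
#' two-sided Student's t-test assuming equal variances compares the group
#' means, and the p-value is mapped to an asterisk tier by
#' [significance_tier()]. Group means and SEMs are reported alongside.
#'
#' When both groups have zero variance the t statistic is undefined; by
#' convention equal constant groups give `statistic 0, p = 1` and unequal
#' constant groups give an infinite statistic with `p = 0`.
#'
#' @param a,b numeric samples, at least 3 values each (one per animal).
#' @param var_equal assume equal variances (classical Student's t); set
#'   `FALSE` for the Welch variant.
#' @param labels length-2 character vector naming the groups.
#' @return an object of class `"xci_comparison"`: list with `statistic`,
#'   `df`, `p_value`, `tier`, `normality_ok` (named logical pair, `NA` when
#'   not assessable), `group_means`, `group_sems`, `n`, `method`, `labels`.
#' @examples
#' two_sample_compare(c(108, 111, 105, 108.5), c(97, 99, 95, 97.2))
#' @export
two_sample_compare <- function(a, b, var_equal = TRUE,
                               labels = c("group1", "group2")) {
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b)) {
    stop("`a` and `b` must be numeric samples without missing values",
         call. = FALSE)
  }
  if (length(a) < 3L || length(b) < 3L) {
    stop("insufficient sample: both groups need n >= 3", call. = FALSE)
  }
  normality <- vapply(list(a, b), function(x) {
    if (length(unique(x)) < 3L || length(x) > 5000L) return(NA)
    stats::shapiro.test(x)$p.value >= 0.05
  }, NA)
  names(normality) <- labels
  if (any(!normality, na.rm = TRUE)) {
    warning("Shapiro-Wilk normality rejected for group(s) ",
            paste(labels[which(!normality)], collapse = ", "),
            "; proceeding with the t-test per protocol", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      statistic <- 0; p <- 1; df <- length(a) + length(b) - 2
    } else {
      statistic <- sign(mean(a) - mean(b)) * Inf; p <- 0
      df <- length(a) + length(b) - 2
    }
    method <- "Two Sample t-test (degenerate zero-variance convention)"
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    statistic <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
    method <- tt$method
  }
  structure(list(
    statistic = statistic,
    df = df,
    p_value = p,
    tier = significance_tier(p),
    normality_ok = normality,
    group_means = stats::setNames(c(mean(a), mean(b)), labels),
    group_sems = stats::setNames(c(sem(a), sem(b)), labels),
    n = stats::setNames(c(length(a), length(b)), labels),
    method = method,
    labels = labels
  ), class = "xci_comparison")
}

#' @export
print.xci_comparison <- function(x, ...) {
  cat(x$method, "\n")
  for (i in 1:2) {
    cat(sprintf("  %s: %.4g +/- %.3g (mean +/- SEM, n = %d)%s\n",
                x$labels[i], x$group_means[i], x$group_sems[i], x$n[i],
                if (isFALSE(x$normality_ok[i])) "  [normality rejected]" else ""))
  }
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g  %s\n",
              x$statistic, x$df, x$p_value,
              if (x$tier == "ns") "(ns)" else x$tier))
  invisible(x)
}
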