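#' Survival probability of reporter-negative cells from a GFP-positive fraction
#'
#' Under random X-inactivation, reporter-positive (normal-X-active) and
#' reporter-negative (mutant-X-active) cells are produced in equal numbers,
#' and reporter-positive cells are assumed to survive throughout development.
#' The observed GFP-positive fraction `p_gfp` then determines the survival
#' probability of the reporter-negative lineage as
#' `P_survival = 1 / p_gfp - 1`, the inverse of
#' [forward_gfp_fraction()].
#'
#' Fractions below 0.5 give estimates above 1, which the generative model
#' cannot produce; `estimate_survival()` returns them as computed, and
#' aggregating callers such as [survival_by_group()] cap them at 1 while
#' flagging the group as clipped.
#'
#' @param p_gfp numeric vector of GFP-positive fractions in `(0, 1]`.
#' @return numeric vector of survival probabilities (`>= 0`).
#' @seealso [forward_gfp_fraction()], [survival_by_group()]
#' @examples
#' estimate_survival(0.9766) # ~0.024: near-complete elimination
#' estimate_survival(0.5)    # 1: no elimination
#' @export
estimate_survival <- function(p_gfp) {
  if (!is.numeric(p_gfp) || length(p_gfp) == 0L) {
    stop("`p_gfp` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p_gfp)) || any(p_gfp <= 0) || any(p_gfp > 1)) {
    if (any(p_gfp == 0, na.rm = TRUE)) {
      stop("undefined estimate: GFP-positive fraction of 0 (no surviving ",
           "reporter-positive cells violates the model assumptions)",
           call. = FALSE)
    }
    stop("`p_gfp` must lie in (0, 1]", call. = FALSE)
  }
  1 / p_gfp - 1
}

#' Expected GFP-positive fraction for a given survival probability
#'
#' The forward model: with symmetric X-inactivation (both lineages produced
#' in equal numbers), full survival of reporter-positive cells, and survival
#' probability `p_survival` for reporter-negative cells, the expected
#' GFP-positive fraction is `1 / (1 + p_survival)`. Exact inverse of
#' [estimate_survival()] on `(0, 1]`.
#'
#' @param p_survival numeric vector of survival probabilities in `[0, 1]`.
#' @return numeric vector of expected GFP-positive fractions in `[0.5, 1]`.
#' @examples
#' forward_gfp_fraction(1)    # 0.5
#' forward_gfp_fraction(0.25) # 0.8
#' @export
forward_gfp_fraction <- function(p_survival) {
  if (!is.numeric(p_survival) || length(p_survival) == 0L) {
    stop("`p_survival` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p_survival)) || any(p_survival < 0) || any(p_survival > 1)) {
    stop("`p_survival` must lie in [0, 1]", call. = FALSE)
  }
  1 / (1 + p_survival)
}

#' Correct a GFP-positive fraction for one-way miscounting
#'
#' GFP signals resemble tissue autofluorescence, so truly GFP-negative cells
#' can be recorded as positive; over-counting inflates the positive fraction
#' and biases survival estimates towards elimination. Under one-way
#' misclassification at rate `alpha` (negatives flip to positive, positives
#' never flip), the observed fraction is
#' `p_obs = p_true + alpha * (1 - p_true)`, inverted here as
#' `p_true = (p_obs - alpha) / (1 - alpha)`.
#'
#' @param p_obs observed GFP-positive fraction(s) in `[0, 1]`.
#' @param alpha false-positive rate in `[0, 1)`.
#' @return corrected fraction(s).
#' @examples
#' correct_miscount(0.6, 0.2) # 0.5
#' @export
correct_miscount <- function(p_obs, alpha) {
  if (!is.numeric(p_obs) || any(!is.finite(p_obs)) || any(p_obs < 0) || any(p_obs > 1)) {
    stop("`p_obs` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha >= 1) {
    stop("`alpha` must be a single value in [0, 1)", call. = FALSE)
  }
  if (any(p_obs < alpha)) {
    stop("infeasible correction: observed fraction below the false-positive ",
         "rate alpha", call. = FALSE)
  }
  (p_obs - alpha) / (1 - alpha)
}

#' Per-animal survival estimates aggregated by group
#'
#' The unit of replication is the animal: within each group (by default a
#' cohort/region/stage combination) each animal's counts are pooled into one
#' GFP-positive fraction, optionally corrected for miscounting, and
#' transformed to a survival estimate via [estimate_survival()]. The group
#' summary is the mean of the per-animal estimates with its standard error —
#' the average of independent experiments, not the transform of the pooled
#' fraction (the two differ by Jensen's inequality because `1/p - 1` is
#' convex). Per-animal estimates above 1 are capped at 1 and counted in
#' `clipped_n`. Uncertainty is a seeded bootstrap that resamples animals; the
#' default interval is studentized (bootstrap-t), which holds close to
#' nominal coverage at the 4-8 animals typical of these cohorts, where the
#' plain percentile interval undercovers; `ci_method = "percentile"` selects
#' the simpler interval.
#'
#' @param records data.frame of count records with columns `animal_id`,
#'   `region`, `stage`, `n_gfp_pos`, `n_gfp_neg` and optionally `cohort`
#'   (see [read_count_table()] or [simulate_cohort()]).
#' @param by character vector of grouping columns; entries absent from
#'   `records` are ignored.
#' @param miscount_alpha false-positive rate passed to [correct_miscount()]
#'   before the survival transform; 0 disables correction.
#' @param boot number of bootstrap resamples (0 disables the CI).
#' @param conf confidence level of the interval.
#' @param ci_method `"studentized"` (default) or `"percentile"`.
#' @param seed optional integer seed for the bootstrap; the caller's RNG
#'   state is preserved.
#' @return a data.frame of class `"xci_survival"` with one row per group and
#'   columns the grouping keys, `n_animals`, `mean_gfp_pct`, `sem_gfp_pct`,
#'   `p_survival_mean`, `p_survival_sem`, `ci_low`, `ci_high`, `clipped_n`.
#'   Per-animal estimates are attached as `attr(, "per_animal")`, a named
#'   list of data.frames.
#' @examples
#' cfg <- sim_config(n_animals = 6, stages = "adult",
#'                   survival = survival_spec(0.714), seed = 11)
#' est <- survival_by_group(simulate_cohort(cfg), seed = 1)
#' est
#' @export
survival_by_group <- function(records,
                              by = c("cohort", "region", "stage"),
                              miscount_alpha = 0,
                              boot = 2000,
                              conf = 0.95,
                              ci_method = c("studentized", "percentile"),
                              seed = NULL) {
  ci_method <- match.arg(ci_method)
  records <- validate_count_records(records, context = "estimation")
  by <- intersect(by, names(records))
  if (length(by) == 0L) {
    groups <- factor(rep("all", nrow(records)))
  } else {
    groups <- interaction(records[by], drop = TRUE, sep = "/", lex.order = TRUE)
  }
  if (nrow(records) == 0L) {
    stop("empty group: no records to aggregate", call. = FALSE)
  }
  method <- if (miscount_alpha > 0) "bias_corrected" else "raw"
  with_seed(seed, {
    pieces <- lapply(split(records, groups), function(g) {
      aggregate_one_group(g, by, miscount_alpha, boot, conf, ci_method)
    })
    out <- do.call(rbind, lapply(pieces, `[[`, "row"))
    rownames(out) <- NULL
    attr(out, "per_animal") <- lapply(pieces, `[[`, "per_animal")
    attr(out, "conf") <- conf
    attr(out, "boot") <- boot
    attr(out, "ci_method") <- ci_method
    attr(out, "method") <- method
    class(out) <- c("xci_survival", class(out))
    out
  })
}

# One group: per-animal fractions -> survival transform -> mean +/- SEM and
# a bootstrap CI over animals (studentized by default; percentile optional).
aggregate_one_group <- function(g, by, miscount_alpha, boot, conf, ci_method) {
  pos <- tapply(g$n_gfp_pos, g$animal_id, sum)
  tot <- tapply(g$n_gfp_pos + g$n_gfp_neg, g$animal_id, sum)
  frac <- as.numeric(pos / tot)
  animals <- names(pos)
  label <- paste(vapply(g[1, by, drop = FALSE], as.character, ""), collapse = "/")
  if (any(frac == 0)) {
    stop("undefined estimate: animal(s) ",
         paste(animals[frac == 0], collapse = ", "),
         " in group '", label, "' have GFP-positive fraction 0", call. = FALSE)
  }
  if (miscount_alpha > 0) {
    frac_true <- correct_miscount(frac, miscount_alpha)
    if (any(frac_true == 0)) {
      stop("undefined estimate after miscount correction for animal(s) ",
           paste(animals[frac_true == 0], collapse = ", "),
           " in group '", label, "'", call. = FALSE)
    }
  } else {
    frac_true <- frac
  }
  raw <- estimate_survival(frac_true)
  clipped <- raw > 1
  est <- pmin(raw, 1)
  n <- length(est)
  ci <- c(NA_real_, NA_real_)
  if (boot > 0 && n >= 2L) {
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    X <- matrix(est[matrix(sample.int(n, n * boot, replace = TRUE), nrow = n)],
                nrow = n)
    bmeans <- colMeans(X)
    if (ci_method == "studentized") {
      m <- mean(est)
      se0 <- stats::sd(est) / sqrt(n)
      bse <- sqrt(pmax(0, (colSums(X^2) - n * bmeans^2) / (n - 1))) / sqrt(n)
      tb <- ifelse(bse > 0, (bmeans - m) / bse, 0)
      q <- unname(stats::quantile(tb, probs))
      ci <- c(m - q[2] * se0, m - q[1] * se0)
    } else {
      ci <- unname(stats::quantile(bmeans, probs))
    }
  }
  keys <- g[1, by, drop = FALSE]
  rownames(keys) <- NULL
  row <- cbind(keys, data.frame(
    n_animals = n,
    mean_gfp_pct = 100 * mean(frac),
    sem_gfp_pct = 100 * sem(frac),
    p_survival_mean = mean(est),
    p_survival_sem = sem(est),
    ci_low = ci[1],
    ci_high = ci[2],
    clipped_n = sum(clipped),
    stringsAsFactors = FALSE
  ))
  per_animal <- data.frame(
    animal_id = animals,
    gfp_fraction = frac,
    p_survival_raw = raw,
    p_survival = est,
    clipped = clipped,
    stringsAsFactors = FALSE
  )
  rownames(per_animal) <- NULL
  list(row = row, per_animal = per_animal)
}

#' @export
print.xci_survival <- function(x, digits = 4, ...) {
  cat("Per-animal survival estimates (P_survival = 1/P_GFP+ - 1,",
      "mean over animals)\n")
  cat(sprintf("method: %s; bootstrap: %s resamples, %.0f%% %s CI\n",
              attr(x, "method") %||% "raw",
              format(attr(x, "boot") %||% 0),
              100 * (attr(x, "conf") %||% 0.95),
              attr(x, "ci_method") %||% "studentized"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) signif(col, digits))
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.xci_survival <- function(object, ...) {
  print(object, ...)
  pa <- attr(object, "per_animal")
  cat("\nPer-animal estimates:\n")
  for (nm in names(pa)) {
    cat("--", nm, "\n")
    print(pa[[nm]], row.names = FALSE, digits = 4)
  }
  invisible(object)
}
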