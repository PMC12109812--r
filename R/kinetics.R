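#' Predicted GFP-positive trajectory under staged survival
#'
#' Staged form of the mosaic survival model: if a fraction `p` of cells
#' starts reporter-positive and the reporter-negative lineage survives each
#' stage interval `k` with probability `s_k` (interval 1 being everything
#' before the first observed stage), the expected positive fraction at stage
#' `t` is `p / (p + (1 - p) * prod(s[1:t]))`. With `p = 0.5` the final stage
#' reduces to [forward_gfp_fraction()] of the cumulative survival.
#'
#' @param per_stage_survival numeric vector of per-stage survivals in
#'   `[0, 1]`, one per stage.
#' @param p initial reporter-positive fraction in `(0, 1)`.
#' @return numeric vector of expected GFP-positive fractions, one per stage.
#' @examples
#' predict_trajectory(c(1, 0.5, 0.5, 0.5)) # 0.5, 0.667, 0.8, 0.889
#' @export
predict_trajectory <- function(per_stage_survival, p = 0.5) {
  if (length(per_stage_survival) == 0L) {
    stop("`per_stage_survival` must be non-empty", call. = FALSE)
  }
  if (!is_prob(per_stage_survival)) {
    stop("`per_stage_survival` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("`p` must be a single value in (0, 1)", call. = FALSE)
  }
  cum <- cumprod(per_stage_survival)
  p / (p + (1 - p) * cum)
}

#' Summarise a count table into a stage trajectory
#'
#' Per-stage mean and SEM of the per-animal GFP-positive fractions (pooling
#' regions within an animal), in the stage order given or the order of first
#' appearance.
#'
#' @param records count records (see [read_count_table()]).
#' @param stages optional ordered character vector of stage labels to keep.
#' @return data.frame of class `"xci_trajectory"` with columns `stage`,
#'   `gfp_fraction_mean`, `gfp_fraction_sem`, `n_animals`.
#' @export
stage_trajectory <- function(records, stages = NULL) {
  records <- validate_count_records(records, context = "estimation")
  if (is.null(stages)) stages <- unique(records$stage)
  records <- records[records$stage %in% stages, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records for the requested stages", call. = FALSE)
  rows <- lapply(stages, function(st) {
    g <- records[records$stage == st, , drop = FALSE]
    pos <- tapply(g$n_gfp_pos, g$animal_id, sum)
    tot <- tapply(g$n_gfp_pos + g$n_gfp_neg, g$animal_id, sum)
    frac <- as.numeric(pos / tot)
    data.frame(stage = st,
               gfp_fraction_mean = mean(frac),
               gfp_fraction_sem = sem(frac),
               n_animals = length(frac),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("xci_trajectory", class(out))
  out
}

#' Fit per-stage survival to an observed GFP-positivity trajectory
#'
#' Recovers the staged survival probabilities of the reporter-negative
#' lineage from an observed trajectory of GFP-positive fractions by
#' box-constrained weighted least squares: minimise
#' `sum(w_t * (predicted_t - observed_t)^2)` over `s` in `[0, 1]^T`, with
#' weights `1/sem^2` where a positive SEM is available and 1 otherwise.
#' Optimisation uses `L-BFGS-B` from a deterministic multi-start set — a
#' closed-form inversion of the noiseless model plus fixed constant starts —
#' so the fit is reproducible and does not depend on the RNG. Elimination
#' already complete at the first observed stage is reported in the first
#' entry (survival before the first stage), not attributed to the observed
#' intervals.
#'
#' @param traj a data.frame with columns `stage`, `gfp_fraction_mean` and
#'   optionally `gfp_fraction_sem` (see [stage_trajectory()]), or a bare
#'   numeric vector of per-stage fractions.
#' @param p initial reporter-positive fraction (random XCI: 0.5).
#' @return an object of class `"xci_trajectory_fit"` with components
#'   `per_stage_survival` (named by stage), `cumulative_survival`, `sse`,
#'   `fitted`, `observed`, `weights`, `p` and `convergence`. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' f <- predict_trajectory(c(1, 0.5, 0.5, 0.5))
#' fit <- fit_trajectory(data.frame(stage = c("P6", "P13", "P20", "adult"),
#'                                  gfp_fraction_mean = f))
#' coef(fit)
#' @export
fit_trajectory <- function(traj, p = 0.5) {
  if (is.numeric(traj)) {
    traj <- data.frame(stage = paste0("t", seq_along(traj)),
                       gfp_fraction_mean = traj, stringsAsFactors = FALSE)
  }
  if (!all(c("stage", "gfp_fraction_mean") %in% names(traj))) {
    stop("`traj` needs columns `stage` and `gfp_fraction_mean`", call. = FALSE)
  }
  obs <- traj$gfp_fraction_mean
  T <- length(obs)
  if (T < 2L) {
    stop("underdetermined fit: at least 2 stages are required", call. = FALSE)
  }
  if (any(!is.finite(obs)) || any(obs <= 0) || any(obs > 1)) {
    stop("observed fractions must lie in (0, 1]", call. = FALSE)
  }
  sem_col <- traj$gfp_fraction_sem
  w <- rep(1, T)
  if (!is.null(sem_col)) {
    ok <- is.finite(sem_col) & sem_col > 0
    w[ok] <- 1 / sem_col[ok]^2
  }
  objective <- function(s) {
    pred <- p / (p + (1 - p) * cumprod(s))
    sum(w * (pred - obs)^2)
  }
  # closed-form start: invert f_t for the cumulative odds, take stagewise
  # ratios; exact on noiseless monotone data, clipped into the box otherwise.
  cum_odds <- p * (1 - obs) / ((1 - p) * obs)
  s0 <- cum_odds / c(1, cum_odds[-T])
  s0[!is.finite(s0)] <- 1
  starts <- list(clip01(s0), rep(1, T), rep(0.9, T), rep(0.5, T), rep(0.1, T))
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, objective, method = "L-BFGS-B",
                        lower = rep(0, T), upper = rep(1, T),
                        control = list(factr = 10, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  s_hat <- clip01(best$par)
  pred <- p / (p + (1 - p) * cumprod(s_hat))
  structure(list(
    per_stage_survival = stats::setNames(s_hat, traj$stage),
    cumulative_survival = prod(s_hat),
    sse = best$value,
    fitted = stats::setNames(pred, traj$stage),
    observed = traj,
    weights = w,
    p = p,
    convergence = best$convergence
  ), class = "xci_trajectory_fit")
}

#' @export
print.xci_trajectory_fit <- function(x, digits = 4, ...) {
  cat("Staged survival fit of a GFP-positivity trajectory\n")
  cat(sprintf("  initial reporter-positive fraction p = %g\n", x$p))
  cat("  per-stage survival of the reporter-negative lineage:\n")
  print(signif(x$per_stage_survival, digits))
  cat(sprintf("  cumulative survival: %.4g   weighted SSE: %.3g\n",
              x$cumulative_survival, x$sse))
  invisible(x)
}

#' @export
summary.xci_trajectory_fit <- function(object, ...) {
  print(object, ...)
  tab <- data.frame(stage = names(object$fitted),
                    observed = object$observed$gfp_fraction_mean,
                    fitted = unname(object$fitted),
                    residual = unname(residuals(object)),
                    weight = object$weights)
  cat("\n")
  print(tab, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.xci_trajectory_fit <- function(object, ...) object$per_stage_survival

#' @export
fitted.xci_trajectory_fit <- function(object, ...) object$fitted

#' @export
residuals.xci_trajectory_fit <- function(object, ...) {
  stats::setNames(object$observed$gfp_fraction_mean - unname(object$fitted),
                  names(object$fitted))
}

#' Predicted fractions from a fitted staged survival model
#'
#' @param object an `"xci_trajectory_fit"`.
#' @param per_stage_survival optional replacement survival vector to predict
#'   from (defaults to the fitted coefficients).
#' @param ... unused.
#' @return named numeric vector of predicted GFP-positive fractions.
#' @export
predict.xci_trajectory_fit <- function(object, per_stage_survival = NULL, ...) {
  s <- per_stage_survival %||% unname(object$per_stage_survival)
  stats::setNames(predict_trajectory(s, object$p),
                  names(object$per_stage_survival))
}

#' @export
plot.xci_trajectory_fit <- function(x, ...) {
  T <- length(x$fitted)
  obs <- x$observed$gfp_fraction_mean
  sems <- x$observed$gfp_fraction_sem
  plot(seq_len(T), obs, ylim = c(0, 1), xaxt = "n",
       xlab = "stage", ylab = "GFP-positive fraction",
       pch = 19, ...)
  graphics::axis(1, at = seq_len(T), labels = names(x$fitted))
  if (!is.null(sems)) {
    ok <- is.finite(sems)
    graphics::segments(seq_len(T)[ok], obs[ok] - sems[ok],
                       seq_len(T)[ok], obs[ok] + sems[ok])
  }
  graphics::lines(seq_len(T), unname(x$fitted), col = 2, lwd = 2)
  graphics::legend("bottomright", legend = c("observed", "fitted"),
                   pch = c(19, NA), lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}
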