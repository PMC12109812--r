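#' Survival specification for a simulated cohort
#'
#' Per-stage survival probabilities of the two XCI lineages. Entry `k` is the
#' survival of the lineage over the interval ending at the `k`-th listed
#' stage; entry 1 covers everything before the first observed stage, so a
#' lineage already eliminated at the first stage (Purkinje-like) is expressed
#' as `s_base[1] < 1`, while granule-like kinetics start from `s_base[1] = 1`
#' (the first stage reflects X-inactivation and clonal expansion only). The
#' product over stages is the cumulative survival probability. Scalars are
#' interpreted as the cumulative survival reached at the final stage and
#' spread over the post-first-stage intervals by [survival_from_cumulative()]
#' when the spec is attached to a config.
#'
#' @param s_base survival of the reporter-negative (mutant-X-active) lineage:
#'   either a vector with one entry per stage or a single cumulative value.
#' @param s_positive survival of the reporter-positive lineage; defaults to 1
#'   at every stage (reporter-positive cells remain present throughout
#'   development).
#' @param competition optional [competition_model()]; `NULL` means purely
#'   cell-autonomous elimination.
#' @return an object of class `"xci_survival_spec"`.
#' @export
survival_spec <- function(s_base = 1, s_positive = NULL, competition = NULL) {
  if (!is_prob(s_base) || length(s_base) < 1L) {
    stop("`s_base` must be probabilities in [0, 1]", call. = FALSE)
  }
  if (!is.null(s_positive) && !is_prob(s_positive)) {
    stop("`s_positive` must be probabilities in [0, 1]", call. = FALSE)
  }
  if (!is.null(competition) && !inherits(competition, "xci_competition_model")) {
    stop("`competition` must be built with competition_model()", call. = FALSE)
  }
  structure(list(s_base = s_base, s_positive = s_positive,
                 competition = competition),
            class = "xci_survival_spec")
}

#' Spread a cumulative survival over the observed-stage intervals
#'
#' Returns a per-stage survival vector whose product is `s_cum`, with no
#' elimination before the first observed stage (`s[1] = 1`) and the remainder
#' split evenly on the probability scale across the later intervals. With a
#' single stage the whole cumulative survival is assigned to the
#' pre-first-stage epoch.
#'
#' @param s_cum cumulative survival in `[0, 1]`.
#' @param n_stages number of observed stages.
#' @return numeric vector of length `n_stages` with product `s_cum`.
#' @examples
#' survival_from_cumulative(0.714, 4)
#' @export
survival_from_cumulative <- function(s_cum, n_stages) {
  stopifnot(is_prob(s_cum), length(s_cum) == 1L, n_stages >= 1)
  if (n_stages == 1L) return(s_cum)
  c(1, rep(s_cum^(1 / (n_stages - 1)), n_stages - 1L))
}

#' Linear cell-competition penalty
#'
#' Mosaic tissue can eliminate low-fitness cells beyond their cell-autonomous
#' death rate when they are intermixed with fitter neighbours. The penalty is
#' phenomenological: over each inter-stage interval the effective survival of
#' the reporter-negative (low-fitness) lineage is
#' `s_eff = s_base * (1 - kappa * phi_high)`, where `phi_high` is the tissue
#' fraction of normal (reporter-positive) cells at the start of the interval,
#' recomputed after every stage. In a uniform low-fitness tissue
#' (`phi_high = 0`) the penalty is inert, which is what makes the
#' hemizygote-versus-heterozygote contrast informative. The penalty acts on
#' the intervals between observed stages (not on the pre-first-stage epoch,
#' where the tissue is still proliferating progenitors).
#'
#' @param kappa competition coefficient in `[0, 1]`; 0 disables competition.
#' @param form penalty functional form; only `"linear"` is defined.
#' @return an object of class `"xci_competition_model"`.
#' @export
competition_model <- function(kappa, form = "linear") {
  if (!is_prob(kappa) || length(kappa) != 1L) {
    stop("`kappa` must be a single value in [0, 1]", call. = FALSE)
  }
  form <- match.arg(form)
  structure(list(kappa = kappa, form = form), class = "xci_competition_model")
}

#' Configuration of a simulated XCI-mosaic cohort
#'
#' Full parameterisation of one simulated cohort of animals. Each animal
#' starts as `n_founders` progenitors that commit their X-inactivation
#' independently (`p_reporter_active` chance of keeping the reporter-bearing,
#' normal-allele X active; random XCI is 0.5) and expand into clones whose
#' relative sizes are symmetric-Dirichlet with concentration
#' `1/clone_dispersion` (`clone_dispersion = 0` gives equal clones). The
#' reporter-negative lineage is then thinned at each stage interval according
#' to the `survival` spec (with the competition penalty if configured), and
#' `n_cells_per_region` cells are counted per region at every stage, with a
#' truly negative cell recorded positive with probability `miscount_alpha`.
#'
#' Defaults emulate the study conditions the estimator is meant for: 8
#' animals, random XCI (`p = 0.5`), 500 cells counted per region, and a
#' founder pool of 150, which reproduces a between-animal SEM of the
#' GFP-positive percentage of roughly 1-2 percentage points at n = 8.
#'
#' @param n_animals number of animals in the cohort.
#' @param n_founders progenitor-pool size at XCI commitment, per animal.
#' @param p_reporter_active probability a founder keeps the reporter-bearing
#'   X active (equivalently, inactivates the mutant X).
#' @param n_cells_per_region cells counted per region, per animal and stage.
#' @param clone_dispersion non-negative overdispersion of clone sizes
#'   (0 = equal clones; larger values give fewer effective founders).
#' @param survival a [survival_spec()]; scalar `s_base`/`s_positive` entries
#'   are expanded with [survival_from_cumulative()] to match `stages`.
#' @param miscount_alpha probability a truly GFP-negative cell is recorded
#'   GFP-positive.
#' @param stages ordered character vector of stage labels.
#' @param regions character vector of region labels counted for each animal.
#' @param seed integer root seed of the cohort; per-animal streams are
#'   derived deterministically from `(seed, animal_index)`.
#' @param cohort cohort label written into the output table.
#' @return an object of class `"xci_sim_config"`.
#' @examples
#' cfg <- sim_config(n_animals = 8, survival = survival_spec(0.714),
#'                   stages = "adult", seed = 1)
#' head(simulate_cohort(cfg))
#' @export
sim_config <- function(n_animals = 8,
                       n_founders = 150,
                       p_reporter_active = 0.5,
                       n_cells_per_region = 500,
                       clone_dispersion = 0,
                       survival = survival_spec(1),
                       miscount_alpha = 0,
                       stages = c("P6", "P13", "P20", "adult"),
                       regions = "cgc",
                       seed = 1L,
                       cohort = "cohort1") {
  if (!is.numeric(n_animals) || length(n_animals) != 1L || n_animals < 0 ||
      n_animals != round(n_animals)) {
    stop("configuration error: `n_animals` must be a non-negative integer",
         call. = FALSE)
  }
  if (!is.numeric(n_founders) || length(n_founders) != 1L || n_founders < 1 ||
      n_founders != round(n_founders)) {
    stop("configuration error: `n_founders` must be a positive integer",
         call. = FALSE)
  }
  if (!is_prob(p_reporter_active) || length(p_reporter_active) != 1L) {
    stop("configuration error: `p_reporter_active` must be in [0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(n_cells_per_region) || n_cells_per_region < 1) {
    stop("configuration error: `n_cells_per_region` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(clone_dispersion) || clone_dispersion < 0) {
    stop("configuration error: `clone_dispersion` must be >= 0", call. = FALSE)
  }
  if (!is_prob(miscount_alpha) || length(miscount_alpha) != 1L) {
    stop("configuration error: `miscount_alpha` must be in [0, 1]", call. = FALSE)
  }
  stages <- as.character(stages)
  if (length(stages) == 0L || anyDuplicated(stages)) {
    stop("configuration error: `stages` must be a non-empty list of distinct, ",
         "ordered labels", call. = FALSE)
  }
  if (length(regions) == 0L) {
    stop("configuration error: `regions` must be non-empty", call. = FALSE)
  }
  if (!inherits(survival, "xci_survival_spec")) {
    survival <- survival_spec(survival)
  }
  T <- length(stages)
  s_base <- survival$s_base
  if (length(s_base) == 1L && T > 1L) {
    s_base <- survival_from_cumulative(s_base, T)
  }
  if (length(s_base) != T) {
    stop("configuration error: `s_base` must have one entry per stage ",
         "(or be a single cumulative value)", call. = FALSE)
  }
  s_positive <- survival$s_positive %||% rep(1, T)
  if (length(s_positive) == 1L) s_positive <- rep(s_positive, T)
  if (length(s_positive) != T) {
    stop("configuration error: `s_positive` must have one entry per stage",
         call. = FALSE)
  }
  structure(list(
    n_animals = as.integer(n_animals),
    n_founders = as.integer(n_founders),
    p_reporter_active = p_reporter_active,
    n_cells_per_region = as.integer(n_cells_per_region),
    clone_dispersion = clone_dispersion,
    s_base = s_base,
    s_positive = s_positive,
    competition = survival$competition,
    miscount_alpha = miscount_alpha,
    stages = stages,
    regions = as.character(regions),
    seed = as.integer(seed),
    cohort = as.character(cohort)
  ), class = "xci_sim_config")
}

#' @export
print.xci_sim_config <- function(x, ...) {
  cat("XCI mosaic cohort configuration\n")
  cat(sprintf("  cohort: %s  (seed %d)\n", x$cohort, x$seed))
  cat(sprintf("  %d animals; %d founders; p(reporter X active) = %g\n",
              x$n_animals, x$n_founders, x$p_reporter_active))
  cat(sprintf("  %d cells per region; regions: %s; clone dispersion %g\n",
              x$n_cells_per_region, paste(x$regions, collapse = ", "),
              x$clone_dispersion))
  cat(sprintf("  stages: %s\n", paste(x$stages, collapse = " -> ")))
  cat(sprintf("  s_base: %s (cumulative %.4g); s_positive: %s\n",
              paste(signif(x$s_base, 4), collapse = ", "), prod(x$s_base),
              paste(signif(x$s_positive, 4), collapse = ", ")))
  if (!is.null(x$competition)) {
    cat(sprintf("  competition: %s penalty, kappa = %g\n",
                x$competition$form, x$competition$kappa))
  }
  if (x$miscount_alpha > 0) {
    cat(sprintf("  miscount alpha = %g (one-way false positives)\n",
                x$miscount_alpha))
  }
  invisible(x)
}

#' Read a cohort configuration from JSON or YAML
#'
#' The document mirrors the [sim_config()] fields; the survival model is a
#' nested object with `s_base`, optional `s_positive` and optional
#' `competition` (`kappa`, `form`). The alternative key spellings
#' `p_inactivate_mutant_x`, `miscount_rate_alpha` and `survival_model` are
#' accepted.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return an `"xci_sim_config"` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format '", ext, "' (use json or yaml)",
         call. = FALSE)
  )
  sv <- doc$survival %||% doc$survival_model
  surv <- if (is.null(sv)) survival_spec(1) else {
    comp <- if (!is.null(sv$competition)) {
      competition_model(sv$competition$kappa, sv$competition$form %||% "linear")
    }
    survival_spec(unlist(sv$s_base), if (!is.null(sv$s_positive)) unlist(sv$s_positive), comp)
  }
  args <- list(
    survival = surv,
    p_reporter_active = doc$p_reporter_active %||% doc$p_inactivate_mutant_x,
    miscount_alpha = doc$miscount_alpha %||% doc$miscount_rate_alpha
  )
  for (nm in c("n_animals", "n_founders", "n_cells_per_region",
               "clone_dispersion", "stages", "regions", "seed", "cohort")) {
    if (!is.null(doc[[nm]])) args[[nm]] <- doc[[nm]]
  }
  args <- args[!vapply(args, is.null, TRUE)]
  do.call(sim_config, args)
}
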