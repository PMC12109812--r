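# Stochastic simulator of XCI-mosaic cell-count tables.
#
# Generative chain per animal: founder XCI commitment (Bernoulli per founder)
# -> clonal expansion (Dirichlet clone weights) -> staged thinning of the
# reporter-negative lineage (cell-autonomous survival times an optional
# competition penalty, applied to the tissue-level lineage mass) -> binomial
# counting of n cells per region at every stage, with one-way false-positive
# miscounting.

# Deterministic lineage-mass recursion shared by the sampler and by
# expected_trajectory(): returns per-stage reporter-positive fraction and
# total surviving mass, given the starting positive fraction phi0.
lineage_recursion <- function(phi0, s_base, s_positive, kappa) {
  T <- length(s_base)
  a_pos <- phi0
  a_neg <- 1 - phi0
  frac <- mass <- numeric(T)
  for (t in seq_len(T)) {
    s_eff <- s_base[t]
    if (t > 1L && kappa > 0) {
      tot <- a_pos + a_neg
      phi <- if (tot > 0) a_pos / tot else 0
      s_eff <- clip01(s_base[t] * (1 - kappa * phi))
    }
    a_neg <- a_neg * s_eff
    a_pos <- a_pos * s_positive[t]
    tot <- a_pos + a_neg
    if (tot <= 0) {
      stop("simulation error: entire tissue eliminated at stage ", t,
           call. = FALSE)
    }
    frac[t] <- a_pos / tot
    mass[t] <- tot
  }
  list(gfp_fraction = frac, tissue_mass = mass)
}

#' Simulate the count records of one animal
#'
#' Draws one animal's founder pool, expands it into clones, applies the
#' staged survival model of the configuration, and returns one count record
#' per (region, stage). The animal's random stream is derived
#' deterministically from `(config$seed, animal_index)`, so a single animal
#' is reproducible on its own and [simulate_cohort()] is the concatenation
#' over animals. The caller's RNG state is left untouched.
#'
#' @param config an [sim_config()] object.
#' @param animal_index animal number in `1:config$n_animals`.
#' @return data.frame with columns `cohort`, `animal_id`, `region`, `stage`,
#'   `n_gfp_pos`, `n_gfp_neg`.
#' @export
simulate_animal <- function(config, animal_index) {
  stopifnot(inherits(config, "xci_sim_config"))
  if (!is.numeric(animal_index) || length(animal_index) != 1L ||
      animal_index < 1 || animal_index > config$n_animals) {
    stop("`animal_index` must be in 1:n_animals", call. = FALSE)
  }
  with_seed(stream_seed(config$seed, animal_index), {
    K <- config$n_founders
    g <- stats::rbinom(K, 1L, config$p_reporter_active)
    w <- if (config$clone_dispersion == 0) {
      rep(1 / K, K)
    } else {
      conc <- 1 / config$clone_dispersion
      raw <- stats::rgamma(K, shape = conc, rate = 1)
      if (sum(raw) == 0) rep(1 / K, K) else raw / sum(raw)
    }
    phi0 <- sum(w * g)
    kappa <- if (is.null(config$competition)) 0 else config$competition$kappa
    # degenerate mosaics: an all-negative (or all-positive) animal is valid
    # tissue; the recursion handles phi0 = 0 or 1.
    traj <- lineage_recursion(phi0, config$s_base, config$s_positive, kappa)
    T <- length(config$stages)
    R <- length(config$regions)
    n <- config$n_cells_per_region
    frac <- rep(traj$gfp_fraction, each = R)
    k_true <- stats::rbinom(T * R, n, frac)
    flips <- stats::rbinom(T * R, n - k_true, config$miscount_alpha)
    n_pos <- k_true + flips
    data.frame(
      cohort = config$cohort,
      animal_id = sprintf("a%02d", animal_index),
      region = rep(config$regions, times = T),
      stage = rep(config$stages, each = R),
      n_gfp_pos = n_pos,
      n_gfp_neg = n - n_pos,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a full cohort of animals
#'
#' Concatenation of [simulate_animal()] over all animals of the
#' configuration; deterministic per seed (the same seed gives an identical
#' table).
#'
#' @param config an [sim_config()] object.
#' @return data.frame of count records (possibly zero rows if
#'   `n_animals = 0`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "xci_sim_config"))
  if (config$n_animals == 0L) {
    return(data.frame(cohort = character(), animal_id = character(),
                      region = character(), stage = character(),
                      n_gfp_pos = integer(), n_gfp_neg = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(config$n_animals), function(i) {
    simulate_animal(config, i)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a uniform-genotype versus mosaic paired design
#'
#' The hemizygote/heterozygote contrast: a uniform cohort in which every cell
#' carries the same (low-fitness) genotype, and a mosaic cohort in which the
#' two XCI lineages coexist. The uniform cohort must have
#' `p_reporter_active` of exactly 0 or 1 — with 0 the whole tissue is the
#' reporter-negative genotype and the competition penalty is inert
#' (`phi_high = 0`); the mosaic cohort must have `0 < p < 1`. Both
#' configurations must share the same stage list.
#'
#' @param uniform_config,mosaic_config [sim_config()] objects.
#' @return named list with elements `uniform` and `mosaic`, each a count
#'   table from [simulate_cohort()].
#' @export
simulate_paired_design <- function(uniform_config, mosaic_config) {
  stopifnot(inherits(uniform_config, "xci_sim_config"),
            inherits(mosaic_config, "xci_sim_config"))
  if (!uniform_config$p_reporter_active %in% c(0, 1)) {
    stop("configuration error: the uniform cohort must have ",
         "p_reporter_active of exactly 0 or 1", call. = FALSE)
  }
  p <- mosaic_config$p_reporter_active
  if (p <= 0 || p >= 1) {
    stop("configuration error: the mosaic cohort must have 0 < ",
         "p_reporter_active < 1", call. = FALSE)
  }
  if (!identical(uniform_config$stages, mosaic_config$stages)) {
    stop("configuration error: uniform and mosaic cohorts must share the ",
         "same stage list", call. = FALSE)
  }
  list(uniform = simulate_cohort(uniform_config),
       mosaic = simulate_cohort(mosaic_config))
}

#' Deterministic expected trajectory of a configuration
#'
#' Infinite-founder-pool expectation of the simulator: starting from a
#' reporter-positive fraction equal to `p_reporter_active`, applies the
#' staged survival model (including the competition penalty, with `phi_high`
#' recomputed after every stage) and returns the expected GFP-positive
#' fraction and the surviving fraction of the initial tissue mass at every
#' stage. The tissue-mass column is the quantity layer thickness is
#' proportional to when thickness scales with surviving cell number.
#'
#' @param config an [sim_config()] object.
#' @return data.frame with columns `stage`, `gfp_fraction`, `tissue_mass`.
#' @examples
#' cfg <- sim_config(survival = survival_spec(c(1, 0.5, 0.5, 0.5)))
#' expected_trajectory(cfg)
#' @export
expected_trajectory <- function(config) {
  stopifnot(inherits(config, "xci_sim_config"))
  kappa <- if (is.null(config$competition)) 0 else config$competition$kappa
  traj <- lineage_recursion(config$p_reporter_active, config$s_base,
                            config$s_positive, kappa)
  data.frame(stage = config$stages,
             gfp_fraction = traj$gfp_fraction,
             tissue_mass = traj$tissue_mass,
             stringsAsFactors = FALSE)
}
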