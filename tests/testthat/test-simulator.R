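test_that("configuration invariants are enforced", {
  expect_error(sim_config(p_reporter_active = 1.2), "configuration error")
  expect_error(sim_config(n_founders = 0), "configuration error")
  expect_error(sim_config(stages = character()), "configuration error")
  expect_error(sim_config(stages = c("P6", "P6")), "configuration error")
  expect_error(sim_config(miscount_alpha = -0.1), "configuration error")
  expect_error(sim_config(survival = survival_spec(c(1, 0.5)),
                          stages = c("P6", "P13", "adult")),
               "one entry per stage")
  expect_error(survival_spec(1.4), "\\[0, 1\\]")
  expect_error(competition_model(2), "\\[0, 1\\]")
})

test_that("cohorts are deterministic per seed and animals are streamed", {
  cfg <- sim_config(n_animals = 4, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  # per-animal streams: an animal simulated alone matches its cohort rows
  co <- simulate_cohort(cfg)
  a3 <- simulate_animal(cfg, 3)
  expect_identical(`rownames<-`(co[co$animal_id == "a03", ], NULL), a3)
  # different seeds differ
  cfg2 <- sim_config(n_animals = 4, seed = 100)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
  # and the caller's RNG state is untouched
  set.seed(1); before <- .Random.seed
  invisible(simulate_cohort(cfg))
  expect_identical(before, .Random.seed)
})

test_that("an empty cohort gives an empty, well-formed table", {
  co <- simulate_cohort(sim_config(n_animals = 0))
  expect_equal(nrow(co), 0L)
  expect_true(all(c("cohort", "animal_id", "region", "stage",
                    "n_gfp_pos", "n_gfp_neg") %in% names(co)))
})

test_that("counts are conserved at the requested cells per region", {
  cfg <- sim_config(n_animals = 3, n_cells_per_region = 137,
                    regions = c("purkinje", "cgc"), seed = 5,
                    survival = survival_spec(c(1, 0.5, 0.5, 0.5)))
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 3 * 2 * 4) # animals x regions x stages
  expect_true(all(co$n_gfp_pos + co$n_gfp_neg == 137L))
})

test_that("trivial survival limits give the analytic fractions", {
  # full survival, symmetric XCI: expected fraction 0.5
  co <- simulate_cohort(wt_config(seed = 21))
  fr <- co$n_gfp_pos / (co$n_gfp_pos + co$n_gfp_neg)
  expect_lt(abs(mean(fr) - 0.5), 3 * sd(fr) / sqrt(length(fr)))
  # total elimination: fraction exactly 1 in post-elimination stages
  cfg0 <- sim_config(n_animals = 4, stages = c("P6", "adult"),
                     survival = survival_spec(c(1, 0)), seed = 3)
  co0 <- simulate_cohort(cfg0)
  expect_true(all(co0$n_gfp_neg[co0$stage == "adult"] == 0L))
  expect_true(any(co0$n_gfp_neg[co0$stage == "P6"] > 0L))
  # closed form: cumulative s = 0.25 -> expected fraction 0.8
  co25 <- simulate_cohort(wt_config(seed = 8, s = 0.25))
  fr25 <- co25$n_gfp_pos / 500
  expect_lt(abs(mean(fr25) - 0.8), 3 * sd(fr25) / sqrt(length(fr25)))
})

test_that("the WT-regime expectation matches the independent analytic value", {
  # frozen from the brute-force per-cell oracle: E[P_GFP+] = 1/(1+0.714)
  co <- simulate_cohort(wt_config(seed = 13, s = 0.714))
  fr <- co$n_gfp_pos / 500
  expect_lt(abs(mean(fr) - 0.5834), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("two cohorts differing only in seed agree within sampling error", {
  m <- vapply(1:12, function(sd_) {
    co <- simulate_cohort(wt_config(seed = sd_, s = 0.714))
    mean(co$n_gfp_pos / 500)
  }, 0)
  # cohort means scatter around a common expectation
  expect_lt(abs(mean(m) - 1 / 1.714), 3 * sd(m) / sqrt(length(m)))
  expect_gt(sd(m), 0)
})

test_that("miscounting shifts the observed fraction by alpha * (1 - p_true)", {
  cfg <- wt_config(seed = 17, n_animals = 60, miscount_alpha = 0.3)
  co <- simulate_cohort(cfg)
  fr <- co$n_gfp_pos / 500
  expected <- 0.5 + 0.3 * 0.5
  expect_lt(abs(mean(fr) - expected), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("lowering a stage survival never decreases the expected fraction", {
  base <- c(1, 0.9, 0.8, 0.7)
  for (k in 2:4) {
    lower <- base; lower[k] <- lower[k] - 0.3
    f_base <- expected_trajectory(sim_config(survival = survival_spec(base)))
    f_low <- expected_trajectory(sim_config(survival = survival_spec(lower)))
    expect_true(all(f_low$gfp_fraction[k:4] >= f_base$gfp_fraction[k:4]))
    expect_true(all(f_low$gfp_fraction[seq_len(k - 1)] ==
                    f_base$gfp_fraction[seq_len(k - 1)]))
  }
})

test_that("between-animal variance rises with clone dispersion, falls with founders", {
  var_at <- function(founders, dispersion) {
    cfg <- sim_config(n_animals = 150, n_founders = founders,
                      clone_dispersion = dispersion, stages = "adult",
                      n_cells_per_region = 300, seed = 31)
    co <- simulate_cohort(cfg)
    var(co$n_gfp_pos / 300)
  }
  v_grid <- c(var_at(40, 0), var_at(40, 1), var_at(40, 5))
  expect_true(all(diff(v_grid) > 0))
  expect_gt(var_at(10, 0), var_at(200, 0))
})

test_that("with no elimination the counting chain is binomial in p", {
  # near-infinite founder pool isolates the counting layer; the positive
  # counts across animals should be Binomial(n, p)-consistent
  cfg <- sim_config(n_animals = 200, n_founders = 20000, stages = "adult",
                    n_cells_per_region = 200, seed = 77)
  k <- simulate_cohort(cfg)$n_gfp_pos
  qs <- qbinom(seq(0.1, 0.9, by = 0.1), 200, 0.5)
  breaks <- c(-1, unique(qs), 201)
  obs <- table(cut(k, breaks))
  pr <- diff(pbinom(breaks, 200, 0.5))
  expect_gt(suppressWarnings(chisq.test(as.vector(obs), p = pr)$p.value), 0.01)
})

test_that("paired designs validate genotype structure and stage lists", {
  u <- sim_config(p_reporter_active = 0, stages = c("P6", "adult"),
                  survival = survival_spec(c(1, 0.8)), cohort = "uniform",
                  n_animals = 2, seed = 1)
  m <- sim_config(stages = c("P6", "adult"), n_animals = 2, seed = 1,
                  survival = survival_spec(c(1, 0.8)), cohort = "mosaic")
  pair <- simulate_paired_design(u, m)
  expect_true(all(pair$uniform$n_gfp_pos == 0L)) # all-mutant tissue: no GFP
  expect_true(all(pair$mosaic$n_gfp_pos > 0L))
  expect_error(simulate_paired_design(m, m), "exactly 0 or 1")
  expect_error(simulate_paired_design(u, u), "0 < p_reporter_active < 1")
  m2 <- sim_config(stages = c("P6", "P13"), n_animals = 2, seed = 1)
  expect_error(simulate_paired_design(u, m2), "same stage list")
})

test_that("the linear competition penalty follows its algebra in expectation", {
  mk <- function(kappa) {
    sim_config(stages = c("P6", "adult"),
               survival = survival_spec(c(1, 0.8),
                                        competition = competition_model(kappa)))
  }
  # kappa = 0: low-fitness cumulative survival is s_base
  tr0 <- expected_trajectory(mk(0))
  expect_equal(tr0$gfp_fraction[2], 1 / 1.8, tolerance = 1e-12)
  # kappa = 0.5, phi = 0.5 at the interval opening: s_eff = 0.8 * 0.75 = 0.6
  tr <- expected_trajectory(mk(0.5))
  expect_equal(tr$gfp_fraction[2], 0.5 / (0.5 + 0.5 * 0.6), tolerance = 1e-12)
  expect_equal(tr$tissue_mass[2], 0.5 + 0.5 * 0.6, tolerance = 1e-12)
  # full penalty at phi -> 1 eliminates the low-fitness lineage
  cfg1 <- sim_config(stages = c("P6", "adult"), p_reporter_active = 0.999,
                     survival = survival_spec(c(1, 1),
                                              competition = competition_model(1)))
  tr1 <- expected_trajectory(cfg1)
  expect_equal(tr1$gfp_fraction[2], 0.999 / (0.999 + 0.001 * (1 - 0.999)),
               tolerance = 1e-9)
  # uniform all-mutant tissue: penalty inert (phi_high = 0)
  cfgu <- sim_config(p_reporter_active = 0, stages = c("P6", "adult"),
                     survival = survival_spec(c(1, 0.8),
                                              competition = competition_model(0.9)))
  expect_equal(expected_trajectory(cfgu)$tissue_mass[2], 0.8, tolerance = 1e-12)
})

test_that("config round-trips through JSON and YAML documents", {
  doc <- list(n_animals = 3, n_founders = 50, p_inactivate_mutant_x = 0.5,
              n_cells_per_region = 100, clone_dispersion = 0.5,
              miscount_rate_alpha = 0.02, stages = c("P6", "adult"),
              seed = 9, cohort = "demo",
              survival_model = list(s_base = c(1, 0.7),
                                    competition = list(kappa = 0.3)))
  jf <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, jf, auto_unbox = TRUE)
  cfg <- read_sim_config(jf)
  expect_s3_class(cfg, "xci_sim_config")
  expect_equal(cfg$n_animals, 3L)
  expect_equal(cfg$s_base, c(1, 0.7))
  expect_equal(cfg$competition$kappa, 0.3)
  expect_equal(cfg$miscount_alpha, 0.02)
  yf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, yf)
  cfg_y <- read_sim_config(yf)
  expect_equal(cfg_y$s_base, cfg$s_base)
  expect_identical(simulate_cohort(cfg_y), simulate_cohort(cfg))
})
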