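test_that("kappa inversion reproduces the linear-form algebra exactly", {
  # s_uniform = 0.8, s_mosaic = 0.6, phi at the interval opening = 0.5:
  # kappa = (1 - 0.6/0.8) / 0.5 = 0.5
  rec <- records_with_stage_fractions(c(P6 = 0.5, adult = 1 / 1.6))
  fit <- estimate_competition(0.8, rec, boot = 0)
  expect_equal(fit$kappa_hat, 0.5, tolerance = 1e-10)
  expect_equal(fit$delta, 0.8 - 0.6, tolerance = 1e-10)
  expect_equal(unname(fit$phi_by_stage["P6"]), 0.5)
  # no competition: identical survivals give kappa 0 (n chosen so the
  # fraction 1/1.8 is exactly representable as counts)
  rec0 <- records_with_stage_fractions(c(P6 = 0.5, adult = 1 / 1.8), n = 900)
  expect_equal(estimate_competition(0.8, rec0, boot = 0)$kappa_hat, 0)
  # full elimination beyond what kappa = 1 explains clips at 1
  rec1 <- records_with_stage_fractions(c(P6 = 0.5, adult = 0.99))
  expect_equal(estimate_competition(0.8, rec1, boot = 0)$kappa_hat, 1)
})

test_that("multi-interval inversion uses the stagewise penalty product", {
  # two elimination intervals with known phis: survival ratio
  # R = (1 - k*phi1)(1 - k*phi2); check the root-solve inverts it
  k_true <- 0.3; phi <- c(0.5, 0.6)
  R <- prod(1 - k_true * phi)
  f3 <- 1 / (1 + 0.8 * R) # final fraction when s_base cumulative is 0.8
  rec <- records_with_stage_fractions(c(P6 = phi[1], P13 = phi[2], adult = f3),
                                      n = 10000)
  fit <- estimate_competition(0.8, rec, boot = 0)
  expect_equal(fit$kappa_hat, k_true, tolerance = 1e-3)
  # the single-factor variants are different (and documented as approximate)
  fit_m <- estimate_competition(0.8, rec, boot = 0, phi = "mean")
  expect_false(isTRUE(all.equal(fit_m$kappa_hat, fit$kappa_hat)))
})

test_that("degenerate inputs raise the documented errors", {
  rec <- records_with_stage_fractions(c(P6 = 0.5, adult = 0.625))
  expect_error(estimate_competition(0, rec), "\\(0, 1\\]")
  expect_error(estimate_competition(rec, rec), "s_base_reference")
  one_stage <- records_with_stage_fractions(c(adult = 0.625))
  expect_error(estimate_competition(0.8, one_stage), "single stage")
  # a mosaic with phi = 0 at every interval opening is unidentifiable
  # (final fraction kept below the no-competition value so the ratio is
  # informative and the phi check is actually reached)
  rec0 <- records_with_stage_fractions(c(P6 = 0.5, adult = 0.625))
  rec0$n_gfp_pos[rec0$stage == "P6"] <- 0L
  rec0$n_gfp_neg[rec0$stage == "P6"] <- 1000L
  expect_error(estimate_competition(0.8, rec0, boot = 0), "unidentifiable")
})

test_that("kappa is recovered from paired simulations without gross bias", {
  k_hat <- vapply(1:30, function(s) {
    mcfg <- sim_config(stages = c("P6", "adult"),
                       survival = survival_spec(c(1, 0.8),
                                                competition = competition_model(0.4)),
                       cohort = "mosaic", seed = 1000 + s)
    estimate_competition(0.8, simulate_cohort(mcfg), boot = 0)$kappa_hat
  }, 0)
  expect_lt(abs(mean(k_hat) - 0.4), 0.1)
})

test_that("the kappa bootstrap is seeded and ordered", {
  mcfg <- sim_config(stages = c("P6", "adult"),
                     survival = survival_spec(c(1, 0.8),
                                              competition = competition_model(0.4)),
                     cohort = "mosaic", seed = 4)
  rec <- simulate_cohort(mcfg)
  f1 <- estimate_competition(0.8, rec, boot = 300, seed = 5)
  f2 <- estimate_competition(0.8, rec, boot = 300, seed = 5)
  expect_identical(f1$ci_low, f2$ci_low)
  expect_lte(f1$ci_low, f1$ci_high)
})

test_that("layer-thickness comparison matches a hand-computed t statistic", {
  a <- c(108, 111, 105, 108.4) # uniform-analog animals
  b <- c(97, 99, 95, 97.1)     # mosaic animals
  cmp <- compare_layer_thickness(a, b)
  # pooled-variance Student's t by hand
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)
  expect_identical(cmp$labels, c("uniform", "mosaic"))
})

test_that("competition thins the mosaic tissue below the uniform tissue", {
  # thickness proportional to surviving cell mass; kappa above the
  # (1 - s)/(s * phi) threshold reverses the naive mosaic advantage
  ucfg <- sim_config(p_reporter_active = 0, stages = c("P6", "adult"),
                     survival = survival_spec(c(1, 0.8)))
  mcfg <- sim_config(stages = c("P6", "adult"),
                     survival = survival_spec(c(1, 0.8),
                                              competition = competition_model(0.8)))
  mass_u <- expected_trajectory(ucfg)$tissue_mass[2]
  mass_m <- expected_trajectory(mcfg)$tissue_mass[2]
  expect_equal(mass_u, 0.8, tolerance = 1e-12)
  expect_lt(mass_m, mass_u)
  set.seed(19)
  hits <- replicate(60, {
    th_u <- rnorm(8, 120 * mass_u, 4)
    th_m <- rnorm(8, 120 * mass_m, 4)
    mean(th_m) < mean(th_u)
  })
  expect_gte(mean(hits), 0.95)
})
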