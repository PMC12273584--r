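test_that("Hill saturation has the defining fixed points", {
  m <- hill_model(15, 2)
  expect_equal(hill_saturation(15, m), 0.5)
  expect_equal(hill_saturation(0, m), 0)
  expect_gt(hill_saturation(1e9, m), 1 - 1e-6)
  expect_equal(hill_saturation(10, m), 100 / 325)
  expect_error(hill_saturation(-1, m), "nonneg")
  # strictly increasing
  cc <- seq(0.01, 200, length.out = 500)
  expect_true(all(diff(hill_saturation(cc, m)) > 0))
})

test_that("the Hill fit recovers generating parameters exactly from clean data", {
  concs <- titration_concs()
  fit <- fit_hill(concs, hill_saturation(concs, hill_model(15, 2)))
  expect_true(fit$converged)
  expect_lt(rel_err(fit$model$K_d, 15), 1e-6)
  expect_lt(rel_err(fit$model$n, 2), 1e-6)

  # self-consistency across a parameter sweep
  for (K in c(0.5, 5, 40)) {
    for (n in c(0.8, 1.5, 3)) {
      f <- fit_hill(concs, hill_saturation(concs, hill_model(K, n)))
      expect_lt(rel_err(f$model$K_d, K), 1e-6)
      expect_lt(rel_err(f$model$n, n), 1e-6)
    }
  }
  expect_error(fit_hill(c(1, 2, 3), c(0.1, 0.2, 0.3)), "4 points")
})

test_that("Hill fits tolerate multiplicative noise", {
  concs <- titration_concs()
  truth <- hill_model(15, 2)
  errs <- vapply(1:100, function(s) {
    d <- gen_titration(truth, mapping = NULL, noise_sd = 0.05, seed = s)
    f <- fit_hill(d$bulk_nM, d$response, free_amplitude = TRUE)
    rel_err(f$model$K_d, 15)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("the power mapping and its log-log fit are mutually consistent", {
  id <- power_mapping(1, 1)
  expect_equal(power_map(c(0.5, 10, 80), id), c(0.5, 10, 80))

  # two-point calibration: (10 -> 30) and (100 -> 100) nM
  mp <- fit_power_map(c(10, 100), c(30, 100))
  expect_equal(mp$b, 1 - log10(3), tolerance = 1e-12)
  expect_equal(mp$A, 9, tolerance = 1e-12)

  # exact recovery from dense power-law samples
  truth <- power_mapping(4.2, 0.63)
  cb <- titration_concs()
  rec <- fit_power_map(cb, power_map(cb, truth))
  expect_lt(rel_err(rec$A, 4.2), 1e-9)
  expect_lt(rel_err(rec$b, 0.63), 1e-9)

  expect_error(power_map(-1, id), "positive")
  expect_error(fit_power_map(c(1, 2), c(0, 3)), "positive")
})

test_that("apparent Hill parameters obey the Hill-compose-power closed form", {
  # identity mapping: the true parameters are reproduced faithfully
  ap <- apparent_experiment(mapping = power_mapping(1, 1),
                            truth = hill_model(15, 2))
  expect_lt(rel_err(ap$apparent$K_d, 15), 1e-6)
  expect_lt(rel_err(ap$apparent$n, 2), 1e-6)

  # algebraic identity n_app = n b, K_app = (K/A)^(1/b) across mappings
  cases <- expand.grid(A = c(2, 9), b = c(0.4, 1 - log10(3), 0.9),
                       K = c(5, 15), n = c(1, 2))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    ap <- apparent_experiment(mapping = power_mapping(cs$A, cs$b),
                              truth = hill_model(cs$K, cs$n))
    expect_lt(rel_err(ap$apparent$n, cs$n * cs$b), 1e-6)
    expect_lt(rel_err(ap$apparent$K_d, (cs$K / cs$A)^(1 / cs$b)), 1e-6)
  }

  # reconstructed two-point mapping: higher apparent affinity, lower
  # apparent cooperativity
  ap <- apparent_experiment(mapping = power_mapping(),
                            truth = hill_model(15, 2))
  expect_equal(ap$apparent$K_d, (15 / 9)^(1 / (1 - log10(3))), tolerance = 1e-6)
  expect_equal(ap$apparent$n, 2 * (1 - log10(3)), tolerance = 1e-6)
  expect_lt(ap$apparent$K_d, 15)
  expect_lt(ap$apparent$n, 2)
})

test_that("concave enrichment always lowers apparent K_d and n", {
  truth <- hill_model(15, 2)
  for (b in c(0.3, 0.6, 0.9)) {
    A <- 2 * 15^(1 - b)  # 2-fold enrichment at K_d
    ap <- apparent_experiment(mapping = power_mapping(A, b), truth = truth)
    expect_lt(ap$apparent$K_d, truth$K_d)
    expect_lt(ap$apparent$n, truth$n)
  }
  # pure scaling (b = 1, A > 1) shifts K_d only
  ap1 <- apparent_experiment(mapping = power_mapping(3, 1), truth = truth)
  expect_equal(ap1$apparent$K_d, 15 / 3, tolerance = 1e-6)
  expect_equal(ap1$apparent$n, 2, tolerance = 1e-6)
})

test_that("release budget arithmetic converts flux to molecules, moles and nM", {
  b <- release_budget(600, 1000, 600, 1e5, 100e-6)
  expect_equal(b$molecules, 3.6e13)
  expect_equal(b$moles, 6e-11, tolerance = 0.005)
  expect_equal(b$conc_nM, 600, tolerance = 0.005)

  z <- release_budget(600, 1000, 0, 1e5, 100e-6)
  expect_equal(z$molecules, 0)
  expect_equal(z$conc_nM, 0)
  expect_error(release_budget(600, 1000, 600, 1e5, 0), "positive")
})

test_that("vesicle content and turnover rate match the flux bookkeeping", {
  expect_equal(vesicle_content(0.1, 10), 0.0252, tolerance = 1e-2)
  expect_equal(vesicle_content(0.2, 10), 0.202, tolerance = 1e-2)
  expect_equal(vesicle_content(0.2, 0), 0)
  expect_equal(vesicle_rate(600, 10), 60)
  expect_equal(vesicle_rate(0, 10), 0)
  expect_equal(vesicle_rate(600, 0.2), 3000)
  expect_error(vesicle_rate(600, 0), "positive")
})
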