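# Shared small-grid configuration keeps the stiff integrations quick while
# staying well inside the discretization error targets checked below.
test_grid <- function(n = 150) radial_grid(10, 100, n)

test_that("the radial grid is uniform and conserves volume", {
  g <- radial_grid(10, 100, 18)
  expect_equal(g$edges, seq(10, 100, by = 5))
  expect_equal(sum(g$volumes), 4 * pi / 3 * (100^3 - 10^3))
  expect_true(all(g$volumes > 0))
  expect_error(radial_grid(10, 100, 5), "10 cells")
  expect_error(radial_grid(100, 10, 50), "below")
})

test_that("receptor introduction (S1) equilibrates to a uniform ligand field", {
  g <- test_grid()
  k <- rd_kinetics()
  sc <- rd_scenario("S1", grid = g, kinetics = k)
  sim <- simulate_rd(sc, t_eval = c(0, 1, 10, 100, 500, 1500, 3000))

  # transient negative peak at the membrane
  expect_lt(sim$L[2, 1], sc$L0)

  # equilibrium: no ligand concentration gradient
  expect_lt(gradient_metric(sim), 1e-3)

  # detailed balance k_on L R = k_off LR within 0.1% in the receptor shell
  i <- nrow(sim$L); j <- sc$shell_idx
  lhs <- k$k_on * sim$L[i, j] * sim$R[i, j]
  rhs <- k$k_off * sim$LR[i, j]
  expect_lt(max(abs(lhs - rhs) / rhs), 1e-3)

  # mass conservation under zero-flux boundaries
  drift <- rel_err(total_mass(sim)[["total_ligand"]],
                   total_mass(sim, 1)[["total_ligand"]])
  expect_lt(drift, 1e-3)

  # receptor conservation per cell across all times
  tot0 <- sim$LR[1, ] + sim$R[1, ]
  dev <- apply(sim$LR + sim$R, 1, function(x) max(abs(x - tot0)))
  expect_lt(max(dev) / max(tot0), 1e-6)
})

test_that("a distant ligand bolus (S2) ends spatially homogeneous", {
  sc <- rd_scenario("S2", grid = test_grid(), kinetics = rd_kinetics())
  sim <- simulate_rd(sc, t_eval = c(0, 1, 10, 100, 1000, 3000))
  # early: ligand confined distally, membrane depleted relative to the mean
  expect_lt(sim$L[2, 1], mean(sim$L[2, ]))
  expect_lt(gradient_metric(sim), 1e-3)
})

test_that("an exocytosis pulse (S3) gives a transient positive membrane peak", {
  sc <- rd_scenario("S3", grid = test_grid(), kinetics = rd_kinetics())
  sim <- simulate_rd(sc, t_eval = c(0, 0.5, 2, 10, 1000, 3000))
  L_eq0 <- sim$L[1, ncol(sim$L)]
  peak <- sim$L[2:4, 1] - L_eq0
  expect_true(all(peak > 0))
  # transient: the final field is uniform again
  expect_lt(gradient_metric(sim), 1e-3)
  n_t <- length(sim$times)
  expect_lt(sim$L[n_t, 1] - sim$L[n_t, ncol(sim$L)], max(peak))
})

test_that("a continuous membrane source (S4) reaches the analytic steady profile", {
  g <- test_grid()
  k <- rd_kinetics()
  sc <- rd_scenario("S4", grid = g, kinetics = k)
  sim <- simulate_rd(sc, t_eval = c(0, 10, 100, 500, 2000, 5000))
  c0 <- sc$outer_bc$value
  J <- sc$inner_bc$J
  analytic <- c0 + (J * g$a^2 / k$D) * (1 / g$centers - 1 / g$R_out)
  final <- sim$L[nrow(sim$L), ]
  expect_lt(max(rel_err(final, analytic)), 0.01)
  # permanent positive peak at the membrane
  expect_gt(final[1] - c0, 0)
})

test_that("equilibrium depletion matches the zero-dimensional conservation law", {
  g <- test_grid()
  k <- rd_kinetics()
  expect_equal(equilibrium_depletion(0, L0 = 10, kinetics = k, grid = g), 0)

  # inverse problem: receptor pool for 10% depletion, verified through the PDE
  R_T <- receptor_for_depletion(0.10, L0 = 10, kinetics = k, grid = g)
  sc <- rd_scenario("S1", grid = g, kinetics = k, receptor_nM = R_T)
  sim <- simulate_rd(sc, t_eval = c(0, 100, 1000, 3000))
  expect_lt(abs(equilibrium_depletion(sim) - 0.10), 0.005)

  # PDE equilibrium agrees with the 0-D oracle for an arbitrary pool
  sc2 <- rd_scenario("S1", grid = g, kinetics = k, receptor_nM = 3000)
  sim2 <- simulate_rd(sc2, t_eval = c(0, 100, 1000, 3000))
  expect_lt(abs(equilibrium_depletion(sim2) - equilibrium_depletion(sc2)), 0.005)

  expect_error(receptor_for_depletion(1.2), "\\[0, 1\\)")
})

test_that("molecular totals follow shell-volume-weighted arithmetic", {
  g <- test_grid()
  sc <- rd_scenario("S1", grid = g, kinetics = rd_kinetics(), receptor_nM = 0)
  sim <- simulate_rd(sc, t_eval = c(0, 1))
  m <- total_mass(sim, 1)
  expect_equal(m[["free"]], 0.6022 * 10 * 4 * pi / 3 * (100^3 - 10^3),
               tolerance = 1e-10)
  expect_equal(m[["bound"]], 0)
  expect_equal(m[["receptor"]], 0)

  sc0 <- rd_scenario("S1", grid = g, kinetics = rd_kinetics(),
                     L0 = 0, receptor_nM = 0)
  sim0 <- simulate_rd(sc0, t_eval = c(0, 1))
  expect_equal(unname(total_mass(sim0)), rep(0, 4))
})

test_that("the gradient metric measures relative spatial nonuniformity", {
  expect_equal(gradient_metric(rep(4, 10)), 0)
  expect_equal(gradient_metric(c(1, 3)), 0.5)
  expect_equal(gradient_metric(rep(0, 5)), 0)
  expect_error(gradient_metric(numeric(0)), "empty")
})

test_that("reported equilibria are grid-converged", {
  k <- rd_kinetics()
  # fixed 0.9-um receptor shell so both grids carry the same receptor pool
  dep <- vapply(c(100, 200), function(n) {
    g <- radial_grid(10, 100, n)
    sc <- rd_scenario("S1", grid = g, kinetics = k, receptor_nM = 5000,
                      shell_um = 0.9)
    equilibrium_depletion(simulate_rd(sc, t_eval = c(0, 500, 3000)))
  }, numeric(1))
  expect_lt(abs(dep[2] - dep[1]) / dep[1], 0.002)
})
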