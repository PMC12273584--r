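test_that("Fick steady profile satisfies its boundary and far-field conditions", {
  sol <- fick_steady_profile(10, 3, 1, c(10, 20, 1e7))
  expect_equal(sol$profile$value[1], 3)                   # c(a) = c_m
  expect_equal(sol$profile$value[2], 2)                   # 10*2/20 + 1
  expect_lt(rel_err(sol$profile$value[3], 1), 1e-5)       # far field -> c_0
  expect_equal(sol$K1, 10 * (1 - 3))
  expect_equal(sol$K2, 1)
  expect_error(fick_steady_profile(10, 3, 1, c(5, 20)), ">= a")
})

test_that("Fick profile has r^2 dc/dr constant everywhere", {
  sol <- fick_steady_profile(10, 3, 1, c(10, 50))
  # exact invariant: (c(r) - c_0) * r is constant
  r <- seq(10.001, 200, length.out = 2000)
  cr <- predict(sol, r)
  expect_equal(diff(range((cr - sol$c_0) * r)), 0, tolerance = 1e-12)
  # dense finite differences on r^2 dc/dr
  h <- 1e-4
  deriv <- (predict(sol, r + h) - predict(sol, r - h)) / (2 * h)
  k1 <- r^2 * deriv
  expect_lt(max(abs(k1 - sol$K1)) / abs(sol$K1), 1e-6)
})

test_that("membrane flux is D (c_m - c_0)/a with the documented worked values", {
  expect_equal(membrane_flux(10, 5, 5, 150), 0)
  expect_equal(membrane_flux(10, 18.75, 6.25, 150), 187.5)
  expect_equal(membrane_flux(3, 18.75, 6.25, 150), 625)
  expect_error(membrane_flux(0, 1, 1, 150), "positive")
  # linear in the concentration difference and D, inverse in a
  expect_equal(membrane_flux(10, 10, 4, 150), 2 * membrane_flux(10, 7, 4, 150))
  expect_equal(membrane_flux(10, 10, 4, 300), 2 * membrane_flux(10, 10, 4, 150))
  expect_equal(membrane_flux(20, 10, 4, 150), membrane_flux(10, 10, 4, 150) / 2)
  expect_gt(membrane_flux(10, 5, 1, 150), 0)
  expect_lt(membrane_flux(10, 1, 5, 150), 0)
})

test_that("diffusivity model fit recovers exact and degenerate inputs", {
  r <- seq(11, 45, by = 1)
  truth <- dip_model()
  fit <- fit_diffusivity(r, predict(truth, r))
  expect_lt(max(rel_err(coef(fit), coef(truth))), 1e-6)
  expect_true(attr(fit, "identifiable"))

  flat <- fit_diffusivity(r[1:6], rep(100, 6))
  expect_equal(flat$p1, 0)
  expect_equal(flat$p3, 100)
  expect_false(attr(flat, "identifiable"))

  expect_error(fit_diffusivity(rep(20, 6), rep(100, 6)), "degenerate")
  expect_error(fit_diffusivity(r[1:3], c(1, 2, 3)), "4 samples")
})

test_that("diffusivity fit tolerates measurement noise", {
  r <- seq(11, 45, by = 1)
  truth <- dip_model()
  D0 <- predict(truth, r)
  set.seed(7)
  errs <- replicate(50, {
    fit <- fit_diffusivity(r, D0 * stats::rlnorm(length(r), 0, 0.02))
    rel_err(fit$p3, truth$p3)
  })
  expect_lt(stats::median(errs), 0.03)
})

test_that("Fokker-Planck constants come from the boundary system", {
  sol <- fokker_planck_steady(dip_model(), rbind(c(13, 2), c(35, 2)))
  # independent 2x2 linear solve as oracle
  m <- dip_model()
  Dv <- m$p1 * (c(13, 35) - m$p2)^2 + m$p3
  K <- solve(cbind(-1, c(13, 35)), Dv * 2 * c(13, 35))
  expect_equal(unname(coef(sol)), unname(K), tolerance = 1e-12)
  expect_equal(sol$K3, 308.672, tolerance = 1e-4)
  expect_equal(sol$K4, 276.5414, tolerance = 1e-4)

  # both boundary concentrations reproduced
  expect_lt(max(rel_err(predict(sol, c(13, 35)), 2)), 1e-9)
  # interior maximum near the diffusivity minimum
  r <- seq(13, 35, by = 0.01)
  cr <- predict(sol, r)
  expect_lt(abs(r[which.max(cr)] - 23.47), 0.5)
  expect_equal(max(cr), 2.884, tolerance = 1e-3)

  expect_error(fokker_planck_steady(dip_model(), rbind(c(13, 2), c(13, 3))),
               "singular")
})

test_that("the defining invariant r^2 d(Dc)/dr = K3 holds on a dense grid", {
  sol <- fokker_planck_steady(dip_model(), rbind(c(13, 2), c(35, 2)))
  r <- seq(13, 35, length.out = 3000)
  h <- 1e-5
  Dc <- function(r) predict(sol$model, r) * predict(sol, r)
  k3 <- r^2 * (Dc(r + h) - Dc(r - h)) / (2 * h)
  expect_lt(max(abs(k3 - sol$K3)) / abs(sol$K3), 1e-6)
})

test_that("closed form matches an independent boundary-value integration", {
  radii <- seq(13, 35, length.out = 101)
  sol <- fokker_planck_steady(dip_model(), rbind(c(13, 2), c(35, 2)))
  oracle <- fp_shooting_oracle(dip_model(), 13, 2, 35, 2, radii)
  expect_lt(max(rel_err(predict(sol, radii), oracle)), 1e-8)
})

test_that("concentration peaks mirror diffusivity troughs", {
  # constant diffusivity, equal boundary concentrations: uniform profile
  flat <- diffusivity_model(0, 20, 100)
  sol0 <- fokker_planck_steady(flat, rbind(c(13, 2), c(35, 2)))
  expect_equal(sol0$K3, 0, tolerance = 1e-10)
  r <- seq(13, 35, by = 0.1)
  expect_equal(predict(sol0, r), rep(2, length(r)), tolerance = 1e-12)

  # an interior diffusivity minimum forces an interior concentration maximum
  sol1 <- fokker_planck_steady(diffusivity_model(0.5, 24, 80),
                               rbind(c(13, 2), c(35, 2)))
  cr <- predict(sol1, r)
  expect_gt(max(cr), 2)
  expect_true(which.max(cr) > 1 && which.max(cr) < length(r))
})

test_that("per-confocal-volume densities convert as N / V_C", {
  expect_equal(per_confocal_to_per_um3(3, 0.16), 18.75)
  expect_equal(per_confocal_to_per_um3(1, 0.16), 6.25)
  expect_equal(per_confocal_to_per_um3(0, 0.3), 0)
  expect_error(per_confocal_to_per_um3(1, 0), "positive")
})

test_that("radial profiles carry both coordinates and a unit tag", {
  p <- radial_profile(c(11, 15, 30), c(3, 2, 1), unit = "per_confocal", a = 10)
  expect_equal(p$distance_um, c(1, 5, 20))
  expect_equal(attr(p, "unit"), "per_confocal")
  expect_error(radial_profile(c(5, 15), c(1, 2), unit = "nM", a = 10), ">=")
})
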