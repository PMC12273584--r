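#' Radial profile container
#'
#' A quantity sampled along the radial coordinate outside a spherical cell.
#' Radii `r` are measured from the cell centre; the distance from the
#' membrane `d = r - a` is carried alongside because both coordinates are in
#' common use. Every profile carries an explicit unit tag.
#'
#' @param r radii in um (>= a).
#' @param value sampled values.
#' @param unit one of `"per_confocal"`, `"per_um3"`, `"nM"` (concentration)
#'   or `"um2_per_s"` (diffusivity).
#' @param a cell radius in um (default 10).
#' @return object of class `radial_profile` (a data.frame with columns
#'   `r_um`, `distance_um`, `value` and attributes `unit`, `a`).
#' @export
radial_profile <- function(r, value, unit = c("per_confocal", "per_um3", "nM", "um2_per_s"),
                           a = 10) {
  unit <- match.arg(unit)
  stop_if(length(r) != length(value), "r and value must have equal length")
  check_finite_positive(a, "a")
  stop_if(any(!is.finite(r)) || any(r < a), "radii must be finite and >= cell radius a")
  out <- data.frame(r_um = as.numeric(r), distance_um = as.numeric(r) - a,
                    value = as.numeric(value))
  attr(out, "unit") <- unit
  attr(out, "a") <- a
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Steady-state Fick profile outside a spherical cell
#'
#' At steady state with a constant diffusion coefficient, the spherically
#' symmetric diffusion equation reduces to r^2 dc/dr = K1, whose solution
#' under the boundary conditions c(a) = c_m and c(infinity) = c_0 is
#' \deqn{c(r) = \frac{a(c_m - c_0)}{r} + c_0,}
#' with integration constants K1 = a (c_0 - c_m) and K2 = c_0.
#'
#' @param a cell radius in um (> 0).
#' @param c_m concentration at the membrane.
#' @param c_0 bulk concentration (same unit as c_m).
#' @param radii evaluation radii in um, all >= a.
#' @param unit unit tag passed to [radial_profile()].
#' @return object of class `fick_solution`: the profile plus constants
#'   `K1`, `K2` and the inputs.
#' @examples
#' sol <- fick_steady_profile(10, 3, 1, c(10, 20, 1e7))
#' sol$profile$value  # 3, 2, ~1
#' @export
fick_steady_profile <- function(a, c_m, c_0, radii, unit = "per_confocal") {
  check_finite_positive(a, "a")
  check_finite_nonneg(c(c_m, c_0), "concentrations")
  stop_if(any(!is.finite(radii)) || any(radii < a), "all radii must be >= a")
  prof <- radial_profile(radii, a * (c_m - c_0) / radii + c_0, unit = unit, a = a)
  structure(list(a = a, c_m = c_m, c_0 = c_0,
                 K1 = a * (c_0 - c_m), K2 = c_0,
                 profile = prof, unit = unit),
            class = "fick_solution")
}

#' @export
print.fick_solution <- function(x, ...) {
  cat(sprintf("Fick steady state: a = %g um, c_m = %g, c_0 = %g [%s]\n",
              x$a, x$c_m, x$c_0, x$unit))
  cat(sprintf("  c(r) = a(c_m - c_0)/r + c_0;  K1 = %g, K2 = %g\n", x$K1, x$K2))
  invisible(x)
}

#' @export
predict.fick_solution <- function(object, r, ...) {
  stop_if(any(r < object$a), "all radii must be >= a")
  object$a * (object$c_m - object$c_0) / r + object$c_0
}

#' Diffusive membrane flux sustaining a steady Fick gradient
#'
#' From Fick's first law evaluated at the membrane,
#' J(a) = -D dc/dr |_a = D (c_m - c_0) / a. Positive J means ligand must be
#' delivered outward at the membrane to sustain the gradient. J is linear in
#' (c_m - c_0) and D and inverse in the length scale a.
#'
#' @param a length scale (cell radius) in um (> 0).
#' @param c_m membrane concentration in particles/um^3.
#' @param c_0 bulk concentration in particles/um^3.
#' @param D diffusion coefficient in um^2/s.
#' @return flux in particles/(um^2 s).
#' @examples
#' membrane_flux(a = 3, c_m = 18.75, c_0 = 6.25, D = 150)   # 625
#' membrane_flux(a = 10, c_m = 18.75, c_0 = 6.25, D = 150)  # 187.5
#' @export
membrane_flux <- function(a, c_m, c_0, D) {
  check_finite_positive(a, "a")
  check_finite_positive(D, "D")
  check_finite_nonneg(c(c_m, c_0), "concentrations")
  D * (c_m - c_0) / a
}

#' Parabolic-with-offset diffusivity model
#'
#' D(r) = p1 (r - p2)^2 + p3: a local diffusivity minimum of depth p3 at
#' radius p2 with curvature p1. With p1 >= 0 and p3 > 0, D is positive
#' everywhere.
#'
#' @param p1 curvature in (um^2/s)/um^2 (>= 0).
#' @param p2 radius of the minimum in um.
#' @param p3 minimum diffusivity in um^2/s (> 0).
#' @return object of class `diffusivity_model`; callable via [predict()].
#' @export
diffusivity_model <- function(p1, p2, p3) {
  stop_if(!is.finite(p1) || p1 < 0, "'p1' must be finite and >= 0")
  stop_if(!is.finite(p2), "'p2' must be finite")
  check_finite_positive(p3, "p3")
  structure(list(p1 = p1, p2 = p2, p3 = p3), class = "diffusivity_model")
}

#' @export
print.diffusivity_model <- function(x, ...) {
  cat(sprintf("D(r) = %.4g (r - %.4g)^2 + %.4g um^2/s\n", x$p1, x$p2, x$p3))
  invisible(x)
}

#' @export
predict.diffusivity_model <- function(object, r, ...) {
  object$p1 * (r - object$p2)^2 + object$p3
}

#' @export
coef.diffusivity_model <- function(object, ...) {
  c(p1 = object$p1, p2 = object$p2, p3 = object$p3)
}

#' Fit the parabolic diffusivity model to measured D(r) samples
#'
#' Least-squares fit of D(r) = p1 (r - p2)^2 + p3 in original (not log)
#' space, with p3 constrained positive and p1 nonnegative. A constant sample
#' set is detected up front and returned as p1 = 0, p3 = mean(D), with p2
#' flagged unidentifiable.
#'
#' @param radii sampling radii in um (at least 4, not all equal).
#' @param D_samples diffusion coefficients in um^2/s.
#' @return a [diffusivity_model()] with attributes `identifiable` (logical)
#'   and `residual_norm`.
#' @export
fit_diffusivity <- function(radii, D_samples) {
  stop_if(length(radii) != length(D_samples), "radii and D_samples must match in length")
  stop_if(length(radii) < 4, "at least 4 samples required")
  stop_if(length(unique(radii)) == 1, "degenerate design: all radii equal")
  check_finite_positive(D_samples, "D_samples")

  if (stats::sd(D_samples) < 1e-10 * mean(D_samples)) {
    out <- diffusivity_model(0, mean(radii), mean(D_samples))
    attr(out, "identifiable") <- FALSE
    attr(out, "residual_norm") <- 0
    return(out)
  }

  i_min <- which.min(D_samples)
  start <- list(p1 = max((max(D_samples) - min(D_samples)) /
                           max((max(radii) - min(radii))^2 / 4, 1e-8), 1e-6),
                p2 = radii[i_min], p3 = max(min(D_samples), 1e-6))
  dat <- data.frame(r = radii, D = D_samples)
  fit <- minpack.lm::nlsLM(D ~ p1 * (r - p2)^2 + p3, data = dat, start = start,
                           lower = c(p1 = 0, p2 = -Inf, p3 = 1e-12),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  cf <- stats::coef(fit)
  out <- diffusivity_model(cf[["p1"]], cf[["p2"]], cf[["p3"]])
  attr(out, "identifiable") <- TRUE
  attr(out, "residual_norm") <- sqrt(sum(stats::resid(fit)^2))
  out
}

#' Fokker-Planck steady state with spatially varying diffusivity
#'
#' When the diffusion coefficient varies in space, the steady state of the
#' Fokker-Planck (Smoluchowski) equation is Laplacian(D c) = 0, i.e. in
#' spherical symmetry r^2 d(Dc)/dr = K3. The closed-form solution is
#' \deqn{c(r) = \frac{K_4 r - K_3}{D(r)\, r},}
#' with K3, K4 determined by two Dirichlet boundary conditions via the 2x2
#' linear system D(r_i) c_i r_i = K4 r_i - K3. Concentration peaks coincide
#' with diffusivity troughs: with equal boundary concentrations the profile
#' has an interior maximum iff D has an interior minimum, and is uniform for
#' constant D.
#'
#' @param model a [diffusivity_model()].
#' @param bc two boundary conditions as a 2x2 matrix or data.frame with
#'   columns (radius, concentration), or a list of two `c(r, conc)` pairs.
#' @param radii optional evaluation radii for the returned profile.
#' @param unit unit tag of the boundary concentrations (default
#'   `"per_confocal"`).
#' @param a cell radius used for distance-from-membrane reporting.
#' @return object of class `fp_solution`: `model`, constants `K3`, `K4`,
#'   `bc`, and (when `radii` given) a [radial_profile()] in `profile`.
#' @examples
#' m <- diffusivity_model(0.32, 23.47, 91.32)
#' sol <- fokker_planck_steady(m, rbind(c(13, 2), c(35, 2)))
#' predict(sol, 23.47)  # interior maximum ~2.88
#' @export
fokker_planck_steady <- function(model, bc, radii = NULL,
                                 unit = "per_confocal", a = 10) {
  stopifnot(inherits(model, "diffusivity_model"))
  if (is.list(bc) && !is.data.frame(bc)) bc <- do.call(rbind, bc)
  bc <- as.matrix(bc)
  stop_if(nrow(bc) != 2 || ncol(bc) != 2, "bc must supply exactly two (radius, concentration) pairs")
  r_bc <- bc[, 1]; c_bc <- bc[, 2]
  check_finite_positive(r_bc, "boundary radii")
  check_finite_nonneg(c_bc, "boundary concentrations")
  stop_if(r_bc[1] == r_bc[2], "singular system: boundary radii coincide")

  # D(r_i) c_i r_i = K4 r_i - K3  =>  [-1  r_i] [K3 K4]' = D c r
  A <- cbind(-1, r_bc)
  rhs <- predict(model, r_bc) * c_bc * r_bc
  K <- unname(solve(A, rhs))
  sol <- structure(list(model = model, K3 = K[1], K4 = K[2],
                        bc = bc, unit = unit, a = a),
                   class = "fp_solution")
  if (!is.null(radii)) {
    sol$profile <- radial_profile(radii, predict(sol, radii), unit = unit, a = a)
  }
  sol
}

#' @export
predict.fp_solution <- function(object, r, ...) {
  check_finite_positive(r, "r")
  (object$K4 * r - object$K3) / (predict(object$model, r) * r)
}

#' @export
print.fp_solution <- function(x, ...) {
  cat("Fokker-Planck steady state, c(r) = (K4 r - K3) / (D(r) r)\n  ")
  print(x$model)
  cat(sprintf("  K3 = %.6g, K4 = %.6g  [bc: c(%g) = %g, c(%g) = %g, %s]\n",
              x$K3, x$K4, x$bc[1, 1], x$bc[1, 2], x$bc[2, 1], x$bc[2, 2], x$unit))
  invisible(x)
}

#' @export
coef.fp_solution <- function(object, ...) c(K3 = object$K3, K4 = object$K4)

#' @export
plot.fp_solution <- function(x, r = NULL, ...) {
  if (is.null(r)) r <- seq(min(x$bc[, 1]), max(x$bc[, 1]), length.out = 200)
  graphics::plot(r, predict(x, r), type = "l", lwd = 2,
                 xlab = "r (um)", ylab = paste0("c (", x$unit, ")"), ...)
  invisible(x)
}
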