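#' Hill binding model
#'
#' Fractional receptor saturation as a function of free-ligand concentration:
#' theta(c) = c^n / (K_d^n + c^n). By construction theta(K_d) = 0.5 and theta
#' is strictly increasing; n > 1 indicates positive cooperativity.
#'
#' @param K_d dissociation constant in nM (> 0).
#' @param n Hill coefficient (> 0).
#' @return object of class `hill_model`.
#' @export
hill_model <- function(K_d, n = 1) {
  check_finite_positive(K_d, "K_d")
  check_finite_positive(n, "n")
  structure(list(K_d = K_d, n = n), class = "hill_model")
}

#' @export
print.hill_model <- function(x, ...) {
  cat(sprintf("Hill model: K_d = %.4g nM, n = %.4g\n", x$K_d, x$n))
  invisible(x)
}

#' @export
coef.hill_model <- function(object, ...) c(K_d = object$K_d, n = object$n)

#' Fractional saturation under the Hill equation
#'
#' @param c ligand concentration in nM (nonnegative).
#' @param model a [hill_model()].
#' @return saturation fraction in \[0, 1\].
#' @examples
#' hill_saturation(10, hill_model(15, 2))  # 100/325
#' @export
hill_saturation <- function(c, model) {
  stopifnot(inherits(model, "hill_model"))
  check_finite_nonneg(c, "c")
  cn <- c^model$n
  cn / (model$K_d^model$n + cn)
}

#' Fit the Hill equation to a titration
#'
#' Nonlinear least squares of theta(c) = A_max c^n / (K_d^n + c^n), with K_d
#' parameterized on the log scale for stable optimization. For normalized
#' experimental data a free maximal amplitude `A_max` can be included (the
#' common case when responses are scaled to the highest-concentration point);
#' for ideal fractional-saturation data it is fixed at 1.
#'
#' @param concs concentrations in nM (> 0 where response is informative).
#' @param responses measured saturations/responses.
#' @param free_amplitude also fit the maximal response A_max (default FALSE).
#' @return object of class `hill_fit`: `model` ([hill_model()]), `A_max`,
#'   `converged`, `residual_norm`, `stderr`, data and fitted values.
#' @export
fit_hill <- function(concs, responses, free_amplitude = FALSE) {
  stop_if(length(concs) != length(responses), "concs and responses must match in length")
  stop_if(length(concs) < 4, "at least 4 points required")
  check_finite_nonneg(concs, "concs")
  stop_if(any(!is.finite(responses)), "responses must be finite")

  pos <- concs > 0
  # initial K_d: concentration closest to half the top response
  top0 <- max(responses)
  stop_if(top0 <= 0, "no positive response to fit")
  i_half <- which.min(abs(responses - top0 / 2))
  K0 <- max(concs[i_half], min(concs[pos]))
  dat <- data.frame(c = concs, y = responses)
  start <- list(lK = log(K0), n = 1)
  if (free_amplitude) start$A <- top0
  form <- if (free_amplitude) {
    y ~ A * c^n / (exp(lK)^n + c^n)
  } else {
    y ~ c^n / (exp(lK)^n + c^n)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      lower = if (free_amplitude) c(lK = -50, n = 1e-3, A = 1e-9)
                              else c(lK = -50, n = 1e-3),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(model = NULL, A_max = NA_real_, converged = FALSE,
                          residual_norm = NA_real_, stderr = NULL,
                          concs = concs, responses = responses, fitted = NULL,
                          message = conditionMessage(fit)),
                     class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  model <- hill_model(exp(cf[["lK"]]), cf[["n"]])
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(model = model,
                 A_max = if (free_amplitude) cf[["A"]] else 1,
                 converged = TRUE,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 stderr = se,
                 concs = concs, responses = responses,
                 fitted = stats::fitted(fit),
                 message = "converged"),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill equation fit\n")
  if (!x$converged) {
    cat("  FAILED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  K_d = %.4g nM, n = %.4g, A_max = %.4g (residual norm %.3g)\n",
              x$model$K_d, x$model$n, x$A_max, x$residual_norm))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  if (!object$converged) return(NULL)
  c(K_d = object$model$K_d, n = object$model$n, A_max = object$A_max)
}

#' @export
predict.hill_fit <- function(object, concs = object$concs, ...) {
  stop_if(!object$converged, "cannot predict from a failed fit")
  object$A_max * hill_saturation(concs, object$model)
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$concs, x$responses, log = "x", pch = 16,
                 xlab = "concentration (nM)", ylab = "response", ...)
  if (x$converged) {
    cc <- exp(seq(log(min(x$concs[x$concs > 0])), log(max(x$concs)), length.out = 200))
    graphics::lines(cc, predict(x, cc), col = 2, lwd = 2)
  }
  invisible(x)
}

#' Bulk-to-membrane power-law concentration mapping
#'
#' Membrane-proximal enrichment is modelled as c_mem = A c_bulk^b. The
#' identity mapping is (A = 1, b = 1); a concave mapping (b < 1 with
#' enrichment at low concentrations) captures a membrane-proximal peak that
#' fades at high bulk concentrations.
#'
#' The default, labelled *reconstructed*, is calibrated from two observed
#' anchor points — roughly 3-fold enrichment at 10 nM and none at 100 nM —
#' giving b = 1 - log10(3) and A = 9.
#'
#' @param A prefactor (nM^(1-b), > 0).
#' @param b exponent (> 0).
#' @return object of class `power_mapping`.
#' @export
power_mapping <- function(A = 9, b = 1 - log10(3)) {
  check_finite_positive(A, "A")
  check_finite_positive(b, "b")
  structure(list(A = A, b = b), class = "power_mapping")
}

#' @export
print.power_mapping <- function(x, ...) {
  cat(sprintf("Power mapping: c_mem = %.4g * c_bulk^%.4g\n", x$A, x$b))
  invisible(x)
}

#' @export
coef.power_mapping <- function(object, ...) c(A = object$A, b = object$b)

#' Apply or fit the bulk-to-membrane power mapping
#'
#' `power_map` evaluates c_mem = A c_bulk^b; `fit_power_map` recovers (A, b)
#' by linear regression of log(c_mem) on log(c_bulk), exact for noiseless
#' power-law data.
#'
#' @param c_bulk bulk concentrations in nM (positive).
#' @param mapping a [power_mapping()].
#' @return `power_map`: membrane concentrations in nM.
#' @export
power_map <- function(c_bulk, mapping) {
  stopifnot(inherits(mapping, "power_mapping"))
  check_finite_positive(c_bulk, "c_bulk")
  mapping$A * c_bulk^mapping$b
}

#' @param c_mem membrane concentrations in nM (positive).
#' @rdname power_map
#' @return `fit_power_map`: a [power_mapping()].
#' @export
fit_power_map <- function(c_bulk, c_mem) {
  check_finite_positive(c_bulk, "c_bulk")
  check_finite_positive(c_mem, "c_mem")
  stop_if(length(c_bulk) != length(c_mem), "lengths must match")
  stop_if(length(c_bulk) < 2, "at least 2 points required")
  fit <- stats::lm(log(c_mem) ~ log(c_bulk))
  power_mapping(A = exp(stats::coef(fit)[[1]]), b = stats::coef(fit)[[2]])
}

#' Default in-silico titration concentration grid
#'
#' 12 log-spaced concentrations from 0.01 to 100 nM.
#' @param n number of concentrations.
#' @param from,to range in nM.
#' @return concentrations in nM.
#' @export
titration_concs <- function(n = 12, from = 0.01, to = 100) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Apparent affinity and cooperativity under membrane enrichment
#'
#' Simulates the equilibrium binding experiment in which the receptor sees
#' the membrane-proximal ligand concentration (via a [power_mapping()]) while
#' the experimenter plots saturation against the *bulk* concentration:
#' saturation is computed with the true [hill_model()] at the mapped
#' concentrations, and the Hill equation is then fitted against the bulk
#' axis. Because a Hill curve composed with a power law is exactly a Hill
#' curve, the apparent parameters obey the closed form
#' n_app = n b and K_app = (K_d / A)^{1/b}, which is returned alongside the
#' fit as a cross-check. A concave enrichment mapping therefore raises the
#' apparent affinity (lower K_d) and lowers the apparent cooperativity.
#'
#' @param bulk_concs bulk concentrations in nM (default: 12 log-spaced
#'   points, 0.01 to 100 nM).
#' @param mapping a [power_mapping()]; identity reproduces the true model.
#' @param truth the true [hill_model()].
#' @return object of class `apparent_fit`: `truth`, `mapping`, `fit` (the
#'   [fit_hill()] result against bulk), `apparent` ([hill_model()] of fitted
#'   K_d_app, n_app), `closed_form` (the algebraic prediction), and the
#'   titration table.
#' @examples
#' ap <- apparent_experiment(truth = hill_model(15, 2), mapping = power_mapping())
#' coef(ap$apparent)
#' @export
apparent_experiment <- function(bulk_concs = titration_concs(),
                                mapping = power_mapping(),
                                truth = hill_model(15, 2)) {
  stopifnot(inherits(mapping, "power_mapping"), inherits(truth, "hill_model"))
  check_finite_positive(bulk_concs, "bulk_concs")
  mem <- power_map(bulk_concs, mapping)
  sat <- hill_saturation(mem, truth)
  fit <- fit_hill(bulk_concs, sat)
  stop_if(!fit$converged, paste("apparent Hill fit failed:", fit$message))
  closed <- hill_model((truth$K_d / mapping$A)^(1 / mapping$b),
                       truth$n * mapping$b)
  structure(list(truth = truth, mapping = mapping, fit = fit,
                 apparent = fit$model, closed_form = closed,
                 table = data.frame(bulk_nM = bulk_concs, mem_nM = mem,
                                    saturation = sat)),
            class = "apparent_fit")
}

#' @export
print.apparent_fit <- function(x, ...) {
  cat("Apparent binding parameters under membrane enrichment\n  true:     ")
  print(x$truth)
  cat("  mapping:  "); print(x$mapping)
  cat(sprintf("  apparent: K_d = %.4g nM, n = %.4g (closed form %.4g nM, %.4g)\n",
              x$apparent$K_d, x$apparent$n, x$closed_form$K_d, x$closed_form$n))
  invisible(x)
}

#' @export
coef.apparent_fit <- function(object, ...) {
  c(K_d_app = object$apparent$K_d, n_app = object$apparent$n)
}

#' Molecular budget of continuous ligand release
#'
#' Number of ligand molecules that a sustained membrane flux would release:
#' molecules = flux x area x duration x n_cells, converted to moles and to
#' the concentration those molecules would reach in the incubation volume.
#'
#' @param flux molecules/(um^2 s).
#' @param area_per_cell membrane area per cell in um^2.
#' @param duration seconds.
#' @param n_cells number of cells.
#' @param volume_L incubation volume in litres.
#' @return named list: `molecules`, `moles`, `conc_nM`.
#' @examples
#' release_budget(600, 1000, 600, 1e5, 100e-6)  # 3.6e13 molecules, ~600 nM
#' @export
release_budget <- function(flux, area_per_cell, duration, n_cells, volume_L) {
  check_finite_nonneg(c(flux, duration), "flux/duration")
  check_finite_positive(c(area_per_cell, n_cells, volume_L), "area/n_cells/volume")
  molecules <- flux * area_per_cell * duration * n_cells
  moles <- molecules / AVOGADRO
  list(molecules = molecules, moles = moles,
       conc_nM = moles / volume_L * 1e9)
}

#' Expected free ligand molecules inside a vesicle
#'
#' (4 pi / 3) r^3 times the bulk concentration, converted with
#' 0.6022 molecules/(um^3 nM). At 10 nM a 0.1-0.2 um vesicle holds only
#' 0.02-0.2 free molecules, so bound ligand must dominate vesicular cargo.
#'
#' @param radius vesicle radius in um (> 0).
#' @param conc_nM ligand concentration in nM (>= 0).
#' @return expected molecules per vesicle.
#' @export
vesicle_content <- function(radius, conc_nM) {
  check_finite_positive(radius, "radius")
  check_finite_nonneg(conc_nM, "conc_nM")
  4 * pi / 3 * radius^3 * conc_nM * PARTICLES_PER_UM3_PER_NM
}

#' Vesicle turnover rate implied by a molecular flux
#'
#' flux / per_vesicle: how many vesicles per um^2 per second must be cycled
#' to deliver the given molecular flux.
#'
#' @param flux molecules/(um^2 s).
#' @param per_vesicle molecules delivered per vesicle (> 0).
#' @return vesicles/(um^2 s).
#' @examples
#' vesicle_rate(600, 10)  # 60
#' @export
vesicle_rate <- function(flux, per_vesicle) {
  check_finite_nonneg(flux, "flux")
  check_finite_positive(per_vesicle, "per_vesicle")
  flux / per_vesicle
}
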