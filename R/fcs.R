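#' Construct an autocorrelation curve
#'
#' Container for a fluorescence correlation spectroscopy (FCS) autocorrelation
#' measurement: lag times in seconds against the dimensionless correlation
#' amplitude G(t). Lags must be strictly increasing and positive; for a
#' well-formed single-component curve G decays towards 1 at long lags.
#'
#' @param lags lag times in seconds, strictly increasing, positive.
#' @param values G(t) values, finite.
#' @param n_runs number of averaged acquisition runs (metadata).
#' @return an object of class `acf_curve` (a data.frame with columns
#'   `lag_s`, `G` and attribute `n_runs`).
#' @export
acf_curve <- function(lags, values, n_runs = 1L) {
  stop_if(length(lags) != length(values), "lags and values must have equal length")
  check_finite_positive(lags, "lags")
  stop_if(any(diff(lags) <= 0), "lags must be strictly increasing")
  stop_if(!is.numeric(values) || any(!is.finite(values)), "values must be finite")
  out <- data.frame(lag_s = as.numeric(lags), G = as.numeric(values))
  attr(out, "n_runs") <- as.integer(n_runs)
  class(out) <- c("acf_curve", "data.frame")
  out
}

#' Autocorrelation model parameters
#'
#' Parameters of the single-component 3-D diffusion model with a triplet term:
#' mean particle number `N` in the confocal volume, triplet fraction `T`
#' (bounded to be less than 1), triplet correlation time `tau_triplet` (s),
#' diffusion correlation time `tau_D` (s) and the beam shape parameter `kappa`
#' (axial-to-lateral extent ratio, > 1). A triplet time exceeding the
#' diffusion time is physically suspect and triggers a warning.
#'
#' @param N mean particles per confocal volume (> 0).
#' @param T_trip triplet fraction in \[0, 1).
#' @param tau_triplet triplet correlation time in seconds (> 0).
#' @param tau_D diffusion correlation time in seconds (> 0).
#' @param kappa beam shape parameter (> 1).
#' @return an object of class `acf_params` (named list).
#' @export
acf_params <- function(N, T_trip = 0, tau_triplet = 5e-6, tau_D, kappa = 5) {
  check_finite_positive(N, "N")
  stop_if(!is.finite(T_trip) || T_trip < 0 || T_trip >= 1, "'T_trip' must be in [0, 1)")
  check_finite_positive(tau_triplet, "tau_triplet")
  check_finite_positive(tau_D, "tau_D")
  stop_if(!is.finite(kappa) || kappa <= 1, "'kappa' must be > 1")
  if (tau_triplet >= tau_D)
    warning("tau_triplet >= tau_D: triplet and diffusion terms exchange roles", call. = FALSE)
  structure(list(N = N, T_trip = T_trip, tau_triplet = tau_triplet,
                 tau_D = tau_D, kappa = kappa),
            class = "acf_params")
}

#' Single-component autocorrelation model with triplet blinking
#'
#' Evaluates
#' \deqn{G(t) = 1 + \frac{1}{N}\,\frac{1 - T(1 - e^{-t/\tau_{tr}})}{1 - T}\,
#'   \frac{1}{1 + t/\tau_D}\,\frac{1}{\sqrt{1 + t/(\kappa^2\tau_D)}}}
#' elementwise: free 3-D diffusion of one species through a 3-D Gaussian
#' detection volume, with a fast exponential triplet-blinking term.
#'
#' @param lags lag times in seconds (nonnegative).
#' @param params an [acf_params()] object.
#' @return numeric vector of G values.
#' @examples
#' p <- acf_params(N = 2, T_trip = 0, tau_D = 1e-4)
#' acf_model(0, p)  # 1 + 1/N = 1.5
#' @export
acf_model <- function(lags, params) {
  stopifnot(inherits(params, "acf_params"))
  check_finite_nonneg(lags, "lags")
  with(params, {
    triplet <- (1 - T_trip * (1 - exp(-lags / tau_triplet))) / (1 - T_trip)
    1 + (1 / N) * triplet / (1 + lags / tau_D) / sqrt(1 + lags / (kappa^2 * tau_D))
  })
}

acf_model_raw <- function(lags, N, T_trip, tau_triplet, tau_D, kappa) {
  triplet <- (1 - T_trip * (1 - exp(-lags / tau_triplet))) / (1 - T_trip)
  1 + (1 / N) * triplet / (1 + lags / tau_D) / sqrt(1 + lags / (kappa^2 * tau_D))
}

#' Fit the autocorrelation model to a measured curve
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of the
#' single-component triplet model against an [acf_curve()]. The beam shape
#' parameter kappa is held fixed by default because kappa and tau_D are weakly
#' identifiable jointly from a single curve. The triplet fraction is bounded
#' to \[0, 0.5\] during fitting to prevent exchange with the diffusion
#' amplitude (a fitting constraint, not physics).
#'
#' Starting values, when `init` is absent, come from the curve itself:
#' N from the amplitude at the first lag, tau_D from the lag at which G - 1
#' falls to half its initial value, triplet fraction 0.1.
#'
#' A curve with no decaying amplitude (e.g. G identically 1) yields a result
#' with `converged = FALSE` rather than arbitrary parameter values.
#'
#' @param curve an [acf_curve()].
#' @param init optional [acf_params()] with starting values.
#' @param fix_kappa keep kappa fixed at its initial value (default TRUE).
#' @param kappa beam shape parameter used when `init` is absent.
#' @return object of class `acf_fit`: elements `params` ([acf_params()]),
#'   `converged`, `residual_norm`, `stderr` (per-parameter standard errors),
#'   `curve`, `fitted`, `message`.
#' @export
fit_acf <- function(curve, init = NULL, fix_kappa = TRUE, kappa = 5) {
  stopifnot(inherits(curve, "acf_curve"))
  lags <- curve$lag_s
  G <- curve$G
  if (length(lags) < 10 || (max(lags) / min(lags)) < 1e3)
    warning("fewer than 10 lags or span under 3 decades; fit may be unstable", call. = FALSE)

  amp0 <- G[1] - 1
  if (is.null(init)) {
    if (!is.finite(amp0) || amp0 <= 10 * .Machine$double.eps) {
      return(acf_fit_failure(curve, "no correlation amplitude above 1; nothing to fit"))
    }
    half_idx <- which(G - 1 <= amp0 / 2)
    tau_D0 <- if (length(half_idx)) lags[half_idx[1]] else stats::median(lags)
    init <- acf_params(N = 1 / amp0, T_trip = 0.1, tau_triplet = 5e-6,
                       tau_D = tau_D0, kappa = kappa)
  }
  stopifnot(inherits(init, "acf_params"))

  start <- list(N = init$N, T_trip = max(init$T_trip, 1e-4),
                tau_triplet = init$tau_triplet, tau_D = init$tau_D)
  lower <- c(N = 1e-12, T_trip = 0, tau_triplet = 1e-9, tau_D = 1e-9)
  upper <- c(N = Inf, T_trip = 0.5, tau_triplet = Inf, tau_D = Inf)
  if (!fix_kappa) {
    start$kappa <- init$kappa
    lower <- c(lower, kappa = 1 + 1e-6)
    upper <- c(upper, kappa = Inf)
  }
  kap_fixed <- init$kappa

  dat <- data.frame(t = lags, G = G)
  form <- if (fix_kappa) {
    G ~ acf_model_raw(t, N, T_trip, tau_triplet, tau_D, kap_fixed)
  } else {
    G ~ acf_model_raw(t, N, T_trip, tau_triplet, tau_D, kappa)
  }
  env <- list2env(list(acf_model_raw = acf_model_raw, kap_fixed = kap_fixed))
  environment(form) <- env

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(acf_fit_failure(curve, conditionMessage(fit)))
  }

  cf <- stats::coef(fit)
  params <- suppressWarnings(acf_params(
    N = cf[["N"]], T_trip = min(cf[["T_trip"]], 1 - 1e-12),
    tau_triplet = cf[["tau_triplet"]], tau_D = cf[["tau_D"]],
    kappa = if (fix_kappa) kap_fixed else cf[["kappa"]]))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  res <- stats::resid(fit)
  structure(list(params = params,
                 converged = TRUE,
                 residual_norm = sqrt(sum(res^2)),
                 stderr = se,
                 curve = curve,
                 fitted = stats::fitted(fit),
                 fix_kappa = fix_kappa,
                 message = "converged"),
            class = "acf_fit")
}

acf_fit_failure <- function(curve, msg) {
  structure(list(params = NULL, converged = FALSE, residual_norm = NA_real_,
                 stderr = NULL, curve = curve, fitted = NULL,
                 fix_kappa = NA, message = msg),
            class = "acf_fit")
}

#' @export
print.acf_fit <- function(x, ...) {
  cat("FCS autocorrelation fit (triplet + single 3-D diffusion component)\n")
  if (!x$converged) {
    cat("  FAILED:", x$message, "\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf("  N           = %.4g particles/confocal volume\n", p$N))
  cat(sprintf("  T (triplet) = %.4g\n", p$T_trip))
  cat(sprintf("  tau_triplet = %.4g s\n", p$tau_triplet))
  cat(sprintf("  tau_D       = %.4g s\n", p$tau_D))
  cat(sprintf("  kappa       = %.4g%s\n", p$kappa,
              if (isTRUE(x$fix_kappa)) " (fixed)" else ""))
  cat(sprintf("  residual norm = %.3g over %d lags\n",
              x$residual_norm, nrow(x$curve)))
  invisible(x)
}

#' @export
coef.acf_fit <- function(object, ...) {
  if (!object$converged) return(NULL)
  p <- object$params
  c(N = p$N, T_trip = p$T_trip, tau_triplet = p$tau_triplet,
    tau_D = p$tau_D, kappa = p$kappa)
}

#' @export
predict.acf_fit <- function(object, lags = object$curve$lag_s, ...) {
  stop_if(!object$converged, "cannot predict from a failed fit")
  acf_model(lags, object$params)
}

#' @export
residuals.acf_fit <- function(object, ...) {
  stop_if(!object$converged, "no residuals for a failed fit")
  object$curve$G - object$fitted
}

#' @export
plot.acf_fit <- function(x, ...) {
  graphics::plot(x$curve$lag_s, x$curve$G, log = "x", pch = 16, cex = 0.5,
                 xlab = "lag time (s)", ylab = "G(t)", ...)
  if (x$converged) {
    graphics::lines(x$curve$lag_s, x$fitted, col = 2, lwd = 2)
  }
  invisible(x)
}

#' Beam geometry of the confocal detection volume
#'
#' Lateral e^-2 beam radius `omega` (um), shape parameter `kappa` and the
#' derived 3-D Gaussian confocal volume V_C = pi^{3/2} kappa omega^3.
#'
#' @param omega lateral beam radius in um (> 0).
#' @param kappa beam shape parameter (> 1).
#' @return object of class `beam_geometry`.
#' @export
beam_geometry <- function(omega, kappa = 5) {
  check_finite_positive(omega, "omega")
  stop_if(!is.finite(kappa) || kappa <= 1, "'kappa' must be > 1")
  structure(list(omega = omega, kappa = kappa,
                 confocal_volume = pi^(3 / 2) * kappa * omega^3),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("Beam geometry: omega = %.4g um, kappa = %.3g, V_C = %.4g um^3\n",
              x$omega, x$kappa, x$confocal_volume))
  invisible(x)
}

#' Calibrate the beam waist against a reference dye
#'
#' Fits the autocorrelation model to a curve measured on a dye of known
#' diffusion coefficient (e.g. Alexa Fluor 546, 341 um^2/s at 25 C) and
#' inverts D = omega^2 / (4 tau_D) for the lateral beam radius.
#'
#' @param curve_ref [acf_curve()] of the reference dye.
#' @param D_ref known diffusion coefficient in um^2/s (> 0).
#' @param kappa beam shape parameter held fixed during the fit.
#' @return a [beam_geometry()], with the underlying `acf_fit` attached as
#'   attribute `fit`.
#' @export
calibrate_beam <- function(curve_ref, D_ref = 341, kappa = 5) {
  check_finite_positive(D_ref, "D_ref")
  fit <- fit_acf(curve_ref, fix_kappa = TRUE, kappa = kappa)
  stop_if(!fit$converged, paste("reference fit failed:", fit$message))
  omega <- sqrt(4 * D_ref * fit$params$tau_D)
  geom <- beam_geometry(omega, kappa)
  attr(geom, "fit") <- fit
  geom
}

#' Diffusion coefficient from the diffusion correlation time
#'
#' D = omega^2 / (4 tau_D).
#'
#' @param tau_D diffusion correlation time in seconds (> 0).
#' @param omega lateral beam radius in um (> 0), or a [beam_geometry()].
#' @return D in um^2/s.
#' @export
diffusion_from_tau <- function(tau_D, omega) {
  if (inherits(omega, "beam_geometry")) omega <- omega$omega
  check_finite_positive(tau_D, "tau_D")
  check_finite_positive(omega, "omega")
  omega^2 / (4 * tau_D)
}

#' Intensity-weighted mean fluorescence lifetime
#'
#' For a multi-exponential decay with amplitudes A_i and lifetimes tau_i,
#' tau_eff = sum(A_i tau_i^2) / sum(A_i tau_i). Invariant under common
#' rescaling of the amplitudes; equals the common lifetime when all
#' components share one.
#'
#' @param amplitudes nonnegative amplitudes, at least one positive.
#' @param lifetimes lifetimes in ns (> 0), same length.
#' @return tau_eff in ns.
#' @examples
#' intensity_weighted_lifetime(c(1, 1), c(1, 3))  # 2.5
#' @export
intensity_weighted_lifetime <- function(amplitudes, lifetimes) {
  stop_if(length(amplitudes) != length(lifetimes), "amplitudes and lifetimes must match in length")
  stop_if(length(amplitudes) < 1, "at least one component required")
  check_finite_nonneg(amplitudes, "amplitudes")
  check_finite_positive(lifetimes, "lifetimes")
  stop_if(all(amplitudes == 0), "all amplitudes are zero")
  sum(amplitudes * lifetimes^2) / sum(amplitudes * lifetimes)
}

#' Quasi-logarithmic correlator lag grid
#'
#' 200 points from 300 ns to 1 s, log-spaced, mirroring typical hardware
#' correlator output.
#'
#' @param n number of lags.
#' @param t_min,t_max first and last lag in seconds.
#' @return numeric vector of lag times (s).
#' @export
correlator_lags <- function(n = 200, t_min = 3e-7, t_max = 1) {
  check_finite_positive(c(t_min, t_max), "lag range")
  stop_if(t_min >= t_max, "t_min must be below t_max")
  exp(seq(log(t_min), log(t_max), length.out = n))
}
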