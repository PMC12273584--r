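#' Seeded synthetic FCS autocorrelation curves
#'
#' Evaluates the forward model [acf_model()] on a correlator-style lag grid
#' and adds seeded Gaussian noise to G. With `noise_sd = 0` the output equals
#' the noiseless model exactly; identical seeds give identical curves.
#'
#' @param truth generating [acf_params()].
#' @param lags lag grid in seconds (default [correlator_lags()]: 200
#'   quasi-logarithmic points, 300 ns to 1 s).
#' @param noise_sd additive Gaussian noise s.d. on G (default 0.005).
#' @param n_curves number of curves.
#' @param seed integer seed.
#' @return a list of [acf_curve()] objects (length `n_curves`).
#' @export
gen_acf_curves <- function(truth, lags = correlator_lags(), noise_sd = 0.005,
                           n_curves = 1, seed = 1) {
  stopifnot(inherits(truth, "acf_params"))
  check_finite_nonneg(noise_sd, "noise_sd")
  stop_if(n_curves < 1, "n_curves must be >= 1")
  G0 <- acf_model(lags, truth)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_curves), function(i) {
    acf_curve(lags, G0 + stats::rnorm(length(lags), 0, noise_sd))
  })
}

#' Synthetic radial concentration and diffusivity profiles
#'
#' Emulates FCS depth scans above a cell: particle counts per confocal
#' volume and diffusion coefficients sampled every micrometre up to 20 um
#' from the membrane and every 10 um beyond, out to 100 um.
#'
#' The concentration is built from two structurally distinct components:
#' a membrane-proximal peak, modelled as an exponential enrichment
#' `bulk * (1 + (fold - 1) exp(-d / decay))` that is by construction
#' uncorrelated with diffusivity, and (when a diffusivity dip is supplied)
#' a membrane-distal excess derived from the Fokker-Planck steady state of
#' that dip, anchored at `anchor_fold * bulk` (default 2, the particle count
#' measured at those depths) at 3 and 25 um from the membrane and floored at
#' zero excess elsewhere — so the concentration/diffusivity anticorrelation
#' of the distal peak is structural, not drawn independently. Multiplicative
#' lognormal noise is applied last.
#'
#' @param bulk bulk concentration in particles/confocal volume.
#' @param fold proximal peak amplitude as a multiple of bulk (default 3).
#' @param decay proximal decay length in um (default 5).
#' @param dip optional [diffusivity_model()] describing the distal
#'   diffusivity minimum (default: the measured dip, p1 = 0.32,
#'   p2 = 23.47 um, p3 = 91.32 um^2/s). `NULL` gives flat diffusivity and no
#'   distal peak.
#' @param anchor_fold concentration at the distal anchor depths (3 and
#'   25 um) as a multiple of bulk, used as the Fokker-Planck boundary value.
#' @param D_flat diffusivity in um^2/s when `dip` is NULL.
#' @param a cell radius in um.
#' @param distances sampling distances from the membrane in um.
#' @param noise_sd relative (lognormal) noise per point (default 0.05).
#' @param seed integer seed.
#' @return list with elements `concentration` and `diffusivity`, both
#'   [radial_profile()] objects.
#' @export
gen_radial_profiles <- function(bulk = 1, fold = 3, decay = 5,
                                dip = diffusivity_model(0.32, 23.47, 91.32),
                                anchor_fold = 2, D_flat = 150, a = 10,
                                distances = c(0:20, seq(30, 100, by = 10)),
                                noise_sd = 0.05, seed = 1) {
  check_finite_nonneg(c(bulk, noise_sd), "bulk/noise_sd")
  stop_if(fold < 0, "fold must be nonnegative")
  check_finite_positive(decay, "decay")
  r <- a + distances
  conc <- bulk * (1 + (fold - 1) * exp(-distances / decay))
  if (!is.null(dip)) {
    stopifnot(inherits(dip, "diffusivity_model"))
    anchor <- anchor_fold * bulk
    fp <- fokker_planck_steady(dip, rbind(c(a + 3, anchor), c(a + 25, anchor)), a = a)
    conc <- conc + pmax(predict(fp, r) - anchor, 0)
    D <- predict(dip, r)
  } else {
    D <- rep(D_flat, length(r))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (noise_sd > 0) {
    conc <- conc * stats::rlnorm(length(conc), -noise_sd^2 / 2, noise_sd)
    D <- D * stats::rlnorm(length(D), -noise_sd^2 / 2, noise_sd)
  }
  list(concentration = radial_profile(r, conc, unit = "per_confocal", a = a),
       diffusivity = radial_profile(r, D, unit = "um2_per_s", a = a))
}

#' Synthetic equilibrium titration data
#'
#' Responses are fractional saturations of the true [hill_model()] evaluated
#' at membrane concentrations obtained through a [power_mapping()]
#' (cell-like data) or at the bulk concentrations themselves
#' (`mapping = NULL`, GPMV-like data where bulk and membrane-proximal
#' concentrations coincide), with multiplicative lognormal noise.
#'
#' @param truth the true [hill_model()].
#' @param mapping a [power_mapping()], or NULL for the identity.
#' @param concs bulk concentrations in nM (default [titration_concs()]).
#' @param noise_sd relative noise (default 0.05).
#' @param seed integer seed.
#' @return data.frame with columns `bulk_nM`, `response`.
#' @export
gen_titration <- function(truth = hill_model(15, 2), mapping = power_mapping(),
                          concs = titration_concs(), noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(truth, "hill_model"))
  check_finite_positive(concs, "concs")
  check_finite_nonneg(noise_sd, "noise_sd")
  mem <- if (is.null(mapping)) concs else power_map(concs, mapping)
  resp <- hill_saturation(mem, truth)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (noise_sd > 0) resp <- resp * stats::rlnorm(length(resp), -noise_sd^2 / 2, noise_sd)
  data.frame(bulk_nM = concs, response = resp)
}

#' Synthetic time-correlated single-photon-counting decay histogram
#'
#' Draws `total_counts` photons from the multi-exponential decay density
#' I(t) = sum_i A_i exp(-t / tau_i) integrated over time bins (one
#' multinomial draw), emulating a TCSPC histogram without instrument
#' response.
#'
#' @param amplitudes component amplitudes (nonnegative, one positive).
#' @param lifetimes component lifetimes in ns (> 0).
#' @param total_counts total photons (>= 1000).
#' @param bin_ns bin width in ns.
#' @param t_max_ns histogram extent in ns.
#' @param seed integer seed.
#' @return data.frame with columns `t_ns` (bin midpoints), `counts`.
#' @export
gen_decay_histogram <- function(amplitudes, lifetimes, total_counts = 1e5,
                                bin_ns = 0.05, t_max_ns = 50, seed = 1) {
  stop_if(length(amplitudes) != length(lifetimes), "amplitudes and lifetimes must match")
  check_finite_nonneg(amplitudes, "amplitudes")
  check_finite_positive(lifetimes, "lifetimes")
  stop_if(all(amplitudes == 0), "all amplitudes zero")
  stop_if(total_counts < 1e3, "at least 1000 counts required")
  edges <- seq(0, t_max_ns, by = bin_ns)
  # integral of sum A_i exp(-t/tau_i) over each bin
  mass <- Reduce(`+`, lapply(seq_along(amplitudes), function(i) {
    amplitudes[i] * lifetimes[i] *
      (exp(-edges[-length(edges)] / lifetimes[i]) - exp(-edges[-1] / lifetimes[i]))
  }))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, total_counts, mass / sum(mass)))
  data.frame(t_ns = (edges[-1] + edges[-length(edges)]) / 2, counts = counts)
}

#' Fit a multi-exponential decay to a photon-count histogram
#'
#' Simple unweighted least-squares companion fitter for
#' [gen_decay_histogram()] recovery studies: counts ~ sum of 1 or 2
#' exponential components. Lifetimes are reported in ns along with the
#' intensity-weighted mean lifetime of the fitted components.
#'
#' @param hist data.frame with columns `t_ns`, `counts`.
#' @param n_components 1 or 2.
#' @return list: `amplitudes`, `lifetimes` (ns, slow to fast ordering not
#'   guaranteed), `tau_eff` (ns), `converged`.
#' @export
fit_decay <- function(hist, n_components = 1) {
  stopifnot(is.data.frame(hist), all(c("t_ns", "counts") %in% names(hist)))
  stop_if(!n_components %in% 1:2, "n_components must be 1 or 2")
  t <- hist$t_ns; y <- hist$counts
  pos <- y > 0
  # crude lifetime guesses from early and late log-slopes
  sl <- function(sel) {
    f <- stats::lm(log(y[sel & pos]) ~ t[sel & pos])
    -1 / stats::coef(f)[[2]]
  }
  tau_late <- abs(sl(t > stats::quantile(t[pos], 0.4)))
  if (n_components == 1) {
    starts <- list(list(A1 = max(y), tau1 = tau_late))
    form <- y ~ A1 * exp(-t / tau1)
    lower <- c(A1 = 0, tau1 = 1e-6)
  } else {
    # the two lifetimes must start well separated or the Jacobian is singular
    starts <- lapply(c(4, 8, 2.5), function(k)
      list(A1 = max(y) / 2, tau1 = tau_late / k, A2 = max(y) / 2, tau2 = tau_late))
    form <- y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
    lower <- c(A1 = 0, tau1 = 1e-6, A2 = 0, tau2 = 1e-6)
  }
  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(t = t, y = y), start = start,
                        lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    return(list(amplitudes = NULL, lifetimes = NULL, tau_eff = NA_real_,
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  amps <- cf[grep("^A", names(cf))]
  taus <- cf[grep("^tau", names(cf))]
  list(amplitudes = unname(amps), lifetimes = unname(taus),
       tau_eff = intensity_weighted_lifetime(pmax(amps, 0), taus),
       converged = TRUE)
}
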