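#' Uniform radial finite-volume grid
#'
#' Discretizes the extracellular space between the cell surface (r = a) and
#' an outer radius into concentric spherical shells of equal radial width.
#' Shell volumes 4 pi/3 (r_{i+1}^3 - r_i^3) are exposed for mass accounting
#' and sum exactly to the domain volume.
#'
#' @param a inner (cell) radius in um.
#' @param R_out outer radius in um (> a).
#' @param n_cells number of shells (>= 10).
#' @return object of class `radial_grid`: `edges`, `centers`, `volumes`
#'   (um^3), `areas` (face areas, um^2), `dr`, `a`, `R_out`, `n_cells`.
#' @export
radial_grid <- function(a = 10, R_out = 100, n_cells = 400) {
  check_finite_positive(c(a, R_out), "radii")
  stop_if(a >= R_out, "'a' must be below 'R_out'")
  stop_if(n_cells < 10, "at least 10 cells required")
  edges <- seq(a, R_out, length.out = n_cells + 1)
  structure(list(a = a, R_out = R_out, n_cells = as.integer(n_cells),
                 edges = edges,
                 centers = (edges[-1] + edges[-(n_cells + 1)]) / 2,
                 volumes = 4 * pi / 3 * diff(edges^3),
                 areas = 4 * pi * edges^2,
                 dr = edges[2] - edges[1]),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("Radial grid: [%g, %g] um, %d shells of width %.4g um\n",
              x$a, x$R_out, x$n_cells, x$dr))
  invisible(x)
}

#' Ligand-receptor kinetic parameters
#'
#' Association rate k_on, dissociation rate k_off and the free-ligand
#' diffusion coefficient D. The equilibrium dissociation constant
#' K_d = k_off / k_on is derived. Defaults are the EGF/EGFR literature
#' values used throughout: D = 150 um^2/s, k_on = 0.0023 /(nM s),
#' k_off = 0.003 /s (K_d ~ 1.3 nM).
#'
#' @param D diffusion coefficient in um^2/s.
#' @param k_on association rate constant in 1/(nM s).
#' @param k_off dissociation rate constant in 1/s.
#' @return object of class `rd_kinetics`.
#' @export
rd_kinetics <- function(D = 150, k_on = 0.0023, k_off = 0.003) {
  check_finite_positive(c(D, k_on, k_off), "kinetic parameters")
  structure(list(D = D, k_on = k_on, k_off = k_off, K_d = k_off / k_on),
            class = "rd_kinetics")
}

#' @export
print.rd_kinetics <- function(x, ...) {
  cat(sprintf("Kinetics: D = %g um^2/s, k_on = %g /(nM s), k_off = %g /s, K_d = %.4g nM\n",
              x$D, x$k_on, x$k_off, x$K_d))
  invisible(x)
}

shell_cells <- function(grid, shell_um) {
  if (is.null(shell_um)) shell_um <- grid$dr
  idx <- which(grid$centers - grid$a < shell_um + 1e-12)
  if (!length(idx)) idx <- 1L
  idx
}

#' Membrane-source simulation scenarios
#'
#' Builds the initial fields, boundary conditions and sources for the four
#' canonical in-silico experiments on a spherical cell of radius `a`:
#'
#' * `"S1"` (receptor introduction): free ligand uniform at `L0`; unliganded
#'   receptor appears in a thin membrane shell at t = 0; zero-flux at both
#'   boundaries. Binding transiently depletes ligand near the membrane (a
#'   negative concentration peak) before a uniform equilibrium is reached.
#' * `"S2"` (distant bolus): receptor at the membrane; free ligand at
#'   `bolus_nM` confined to a distal band `bolus_band` (distances from the
#'   membrane, um); zero everywhere else; zero-flux boundaries.
#' * `"S3"` (exocytosis pulse): the system is pre-equilibrated with `L0`
#'   and the membrane receptor pool, then liganded receptor `pulse_LR` (nM
#'   within the shell) is added at t = 0, producing a transient positive
#'   free-ligand peak at the membrane.
#' * `"S4"` (continuous source): pre-equilibrated as in S3; a constant
#'   ligand influx at the inner boundary (default the flux equivalent of
#'   625 molecules/(um^2 s)) with the outer concentration clamped (Dirichlet),
#'   producing a permanent positive membrane-proximal peak.
#'
#' Receptor amounts default to the surface density that gives `depletion`
#' (10 %) ligand depletion at equilibrium, computed from the zero-dimensional
#' conservation law ([receptor_for_depletion()]).
#'
#' @param scenario `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param grid a [radial_grid()].
#' @param kinetics an [rd_kinetics()].
#' @param L0 initial/bulk free-ligand concentration in nM.
#' @param receptor_nM receptor concentration within the membrane shell (nM);
#'   default from `depletion`.
#' @param depletion target equilibrium ligand depletion used to size the
#'   receptor pool when `receptor_nM` is absent.
#' @param shell_um thickness of the membrane receptor shell (default: one
#'   grid cell).
#' @param bolus_nM,bolus_band S2 bolus concentration and band (distance from
#'   the membrane, um).
#' @param pulse_LR S3 liganded-receptor addition (nM within the shell);
#'   default equals the pre-existing receptor pool.
#' @param influx S4 inner-boundary ligand influx in molecules/(um^2 s).
#' @return object of class `rd_scenario`.
#' @export
rd_scenario <- function(scenario = c("S1", "S2", "S3", "S4"),
                        grid = radial_grid(), kinetics = rd_kinetics(),
                        L0 = 10, receptor_nM = NULL, depletion = 0.1,
                        shell_um = NULL,
                        bolus_nM = 40, bolus_band = c(80, 90),
                        pulse_LR = NULL, influx = 625) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(grid, "radial_grid"), inherits(kinetics, "rd_kinetics"))
  check_finite_nonneg(L0, "L0")
  idx <- shell_cells(grid, shell_um)
  if (is.null(receptor_nM)) {
    receptor_nM <- receptor_for_depletion(depletion, L0 = if (scenario == "S2")
      total_over_domain(bolus_nM, bolus_band, grid) else L0,
      kinetics = kinetics, grid = grid, shell_um = shell_um)
  }
  check_finite_nonneg(receptor_nM, "receptor_nM")

  n <- grid$n_cells
  L <- LR <- R <- numeric(n)
  inner_bc <- list(type = "zero_flux")
  outer_bc <- list(type = "zero_flux")

  if (scenario == "S1") {
    L[] <- L0
    R[idx] <- receptor_nM
  } else if (scenario == "S2") {
    d <- grid$centers - grid$a
    L[d >= bolus_band[1] & d <= bolus_band[2]] <- bolus_nM
    R[idx] <- receptor_nM
  } else {
    eq <- equilibrium_0d(receptor_nM, L0, kinetics, grid, idx)
    L[] <- eq$L_eq
    R[idx] <- eq$R_eq
    LR[idx] <- eq$LR_eq
    if (scenario == "S3") {
      if (is.null(pulse_LR)) pulse_LR <- receptor_nM
      check_finite_nonneg(pulse_LR, "pulse_LR")
      LR[idx] <- LR[idx] + pulse_LR
    } else {
      check_finite_nonneg(influx, "influx")
      # molecules/(um^2 s) -> nM um / s
      inner_bc <- list(type = "influx", J = influx / PARTICLES_PER_UM3_PER_NM)
      outer_bc <- list(type = "dirichlet", value = eq$L_eq)
    }
  }
  structure(list(scenario = scenario, grid = grid, kinetics = kinetics,
                 L = L, LR = LR, R = R, shell_idx = idx,
                 receptor_nM = receptor_nM, L0 = L0,
                 inner_bc = inner_bc, outer_bc = outer_bc),
            class = "rd_scenario")
}

# total amount of a banded bolus expressed as a uniform domain concentration
total_over_domain <- function(conc, band, grid) {
  d <- grid$centers - grid$a
  sel <- d >= band[1] & d <= band[2]
  sum(conc * grid$volumes[sel]) / sum(grid$volumes)
}

#' @export
print.rd_scenario <- function(x, ...) {
  cat(sprintf("Scenario %s on [%g, %g] um (%d cells), L0 = %g nM, receptor %g nM in %d shell cell(s)\n",
              x$scenario, x$grid$a, x$grid$R_out, x$grid$n_cells,
              x$L0, x$receptor_nM, length(x$shell_idx)))
  cat(sprintf("  inner bc: %s, outer bc: %s\n", x$inner_bc$type, x$outer_bc$type))
  invisible(x)
}

rd_rhs <- function(t, y, parms) {
  n <- parms$n
  L <- y[seq_len(n)]
  LR <- y[n + seq_len(n)]
  R <- y[2 * n + seq_len(n)]
  D <- parms$D; dr <- parms$dr
  # diffusive face fluxes of free ligand (outward-positive gradient flux)
  f_int <- D * diff(L) / dr                      # faces 2..n
  flux <- numeric(n + 1)
  flux[2:n] <- f_int
  if (parms$inner$type == "influx") flux[1] <- -parms$inner$J  # into the domain
  if (parms$outer$type == "dirichlet")
    flux[n + 1] <- D * (parms$outer$value - L[n]) / (dr / 2)
  # conservative divergence (A_out F_out - A_in F_in)/V with F = D dc/dr
  dL_diff <- (parms$areas[-1] * flux[-1] - parms$areas[-(n + 1)] * flux[-(n + 1)]) / parms$volumes
  react <- parms$k_on * L * R - parms$k_off * LR
  list(c(dL_diff - react, react, -react))
}

#' Simulate a membrane-source scenario
#'
#' Method-of-lines solution of the coupled free-ligand / liganded-receptor /
#' free-receptor system
#' \deqn{\partial_t L = \frac{D}{r^2}\partial_r(r^2 \partial_r L) + k_{off} LR - k_{on} L R}
#' with LR and R immobile, using a conservative finite-volume discretization
#' in spherical shells and adaptive implicit stiff integration
#' (`deSolve::ode`, `lsodes`).
#'
#' @param scenario an [rd_scenario()].
#' @param t_eval output times in seconds, increasing from 0.
#' @param rtol,atol relative and absolute solver tolerances (atol in nM).
#' @return object of class `rd_sim`: `times`, matrices `L`, `LR`, `R`
#'   (time x cell, nM), the `scenario`, and solver diagnostics.
#' @export
simulate_rd <- function(scenario, t_eval, rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(scenario, "rd_scenario"))
  stop_if(any(diff(t_eval) <= 0) || t_eval[1] < 0, "t_eval must increase from 0")
  if (t_eval[1] > 0) t_eval <- c(0, t_eval)
  g <- scenario$grid
  parms <- list(n = g$n_cells, dr = g$dr, areas = g$areas, volumes = g$volumes,
                D = scenario$kinetics$D, k_on = scenario$kinetics$k_on,
                k_off = scenario$kinetics$k_off,
                inner = scenario$inner_bc, outer = scenario$outer_bc)
  y0 <- c(scenario$L, scenario$LR, scenario$R)
  out <- deSolve::ode(y = y0, times = t_eval, func = rd_rhs, parms = parms,
                      method = "lsodes", rtol = rtol, atol = atol)
  stop_if(attr(out, "istate")[1] < 0,
          sprintf("solver failed; last valid time %g s", max(out[, 1])))
  n <- g$n_cells
  L <- out[, 1 + seq_len(n), drop = FALSE]
  LR <- out[, 1 + n + seq_len(n), drop = FALSE]
  R <- out[, 1 + 2 * n + seq_len(n), drop = FALSE]
  neg <- min(L, LR, R)
  stop_if(neg < -1e3 * atol - 1e-8 * max(abs(scenario$L), 1),
          sprintf("negative concentrations beyond tolerance (min %.3g nM)", neg))
  structure(list(times = out[, 1], L = L, LR = LR, R = R,
                 scenario = scenario, rtol = rtol, atol = atol),
            class = "rd_sim")
}

#' @export
print.rd_sim <- function(x, ...) {
  cat(sprintf("Reaction-diffusion run, scenario %s: %d times to %g s, %d cells\n",
              x$scenario$scenario, length(x$times), max(x$times),
              x$scenario$grid$n_cells))
  gm <- gradient_metric(x$L[nrow(x$L), ])
  cat(sprintf("  final free-ligand gradient metric: %.3g\n", gm))
  invisible(x)
}

#' @export
plot.rd_sim <- function(x, times = NULL, ...) {
  g <- x$scenario$grid
  if (is.null(times)) times <- x$times[unique(round(seq(1, length(x$times), length.out = 5)))]
  idx <- vapply(times, function(t) which.min(abs(x$times - t)), integer(1))
  graphics::matplot(g$centers - g$a, t(x$L[idx, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "distance from membrane (um)",
                    ylab = "free ligand (nM)", ...)
  graphics::legend("topright", legend = sprintf("t = %.3g s", x$times[idx]),
                   col = seq_along(idx), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Shell-volume-weighted molecular totals of a field state
#'
#' Converts the nM fields of one time point into molecule counts using
#' 0.6022 molecules/(um^3 nM) and the shell volumes.
#'
#' @param sim an [rd_sim()].
#' @param i time index (default: last).
#' @return named vector: `free`, `bound`, `receptor` (LR + R),
#'   `total_ligand` (free + bound), in molecules.
#' @export
total_mass <- function(sim, i = nrow(sim$L)) {
  stopifnot(inherits(sim, "rd_sim"))
  V <- sim$scenario$grid$volumes
  stop_if(ncol(sim$L) != length(V), "field/grid shape mismatch")
  f <- PARTICLES_PER_UM3_PER_NM
  free <- sum(sim$L[i, ] * V) * f
  bound <- sum(sim$LR[i, ] * V) * f
  receptor <- sum((sim$LR[i, ] + sim$R[i, ]) * V) * f
  c(free = free, bound = bound, receptor = receptor, total_ligand = free + bound)
}

#' Spatial nonuniformity of the free-ligand field
#'
#' max_i |L_i - mean(L)| / mean(L); zero for a uniform field, and defined as
#' zero for an identically zero field.
#'
#' @param L free-ligand concentrations per cell (nM), or an [rd_sim()]
#'   (last time point is used).
#' @return dimensionless nonuniformity.
#' @export
gradient_metric <- function(L) {
  if (inherits(L, "rd_sim")) L <- L$L[nrow(L$L), ]
  stop_if(length(L) == 0, "empty field")
  m <- mean(L)
  if (m == 0) {
    stop_if(any(L != 0), "field has zero mean but nonzero entries")
    return(0)
  }
  max(abs(L - m)) / m
}

# 0-D equilibrium of the conservation law:
# L0 V_dom = L_eq V_dom + R_T L_eq/(K_d + L_eq) V_shell
equilibrium_0d <- function(R_T, L0, kinetics, grid, shell_idx) {
  V_dom <- sum(grid$volumes)
  V_shell <- sum(grid$volumes[shell_idx])
  K_d <- kinetics$K_d
  if (R_T == 0 || L0 == 0) {
    return(list(L_eq = L0, LR_eq = 0, R_eq = R_T))
  }
  f <- function(L) L0 * V_dom - L * V_dom - R_T * L / (K_d + L) * V_shell
  L_eq <- stats::uniroot(f, c(0, L0), tol = 1e-14 * max(L0, 1))$root
  LR_eq <- R_T * L_eq / (K_d + L_eq)
  list(L_eq = L_eq, LR_eq = LR_eq, R_eq = R_T - LR_eq)
}

#' Equilibrium ligand depletion
#'
#' Fraction of the initially free ligand bound by the membrane receptor pool
#' once dissociation equilibrium is reached: (L0 - L_eq)/L0. Given a
#' simulation, L_eq is taken from the final (uniform) free-ligand field;
#' given a receptor concentration, L_eq comes from scalar root-finding on
#' the zero-dimensional conservation law
#' L0 V_dom = L_eq V_dom + R_T L_eq/(K_d + L_eq) V_shell.
#'
#' @param x an [rd_sim()] or an [rd_scenario()] (uses its receptor pool), or
#'   a receptor concentration in nM.
#' @param L0 initial ligand concentration in nM (scenario/sim: taken from it).
#' @param kinetics an [rd_kinetics()].
#' @param grid a [radial_grid()].
#' @param shell_um membrane shell thickness (default one grid cell).
#' @return depletion fraction in \[0, 1).
#' @export
equilibrium_depletion <- function(x, L0 = 10, kinetics = rd_kinetics(),
                                  grid = radial_grid(), shell_um = NULL) {
  if (inherits(x, "rd_sim")) {
    L0 <- x$scenario$L0
    L_eq <- mean(x$L[nrow(x$L), ])
    return((L0 - L_eq) / L0)
  }
  if (inherits(x, "rd_scenario")) {
    idx <- x$shell_idx
    eq <- equilibrium_0d(x$receptor_nM, x$L0, x$kinetics, x$grid, idx)
    return((x$L0 - eq$L_eq) / x$L0)
  }
  check_finite_nonneg(x, "receptor concentration")
  idx <- shell_cells(grid, shell_um)
  eq <- equilibrium_0d(x, L0, kinetics, grid, idx)
  (L0 - eq$L_eq) / L0
}

#' Receptor pool required for a target equilibrium depletion
#'
#' Inverts the zero-dimensional conservation law by scalar root-finding:
#' returns the receptor concentration (nM within the membrane shell) at
#' which the equilibrium free-ligand loss is `depletion`.
#'
#' @param depletion requested depletion fraction in (0, 1); 0 returns 0.
#' @inheritParams equilibrium_depletion
#' @return receptor concentration in nM within the shell.
#' @export
receptor_for_depletion <- function(depletion, L0 = 10, kinetics = rd_kinetics(),
                                   grid = radial_grid(), shell_um = NULL) {
  stop_if(!is.finite(depletion) || depletion < 0 || depletion >= 1,
          "depletion must be in [0, 1)")
  if (depletion == 0) return(0)
  idx <- shell_cells(grid, shell_um)
  # closed-form bracket endpoint, then uniroot for robustness
  V_dom <- sum(grid$volumes)
  V_shell <- sum(grid$volumes[idx])
  L_eq <- L0 * (1 - depletion)
  R_hi <- 2 * L0 * depletion * V_dom / V_shell * (kinetics$K_d + L_eq) / L_eq
  f <- function(R_T) equilibrium_depletion(R_T, L0, kinetics, grid, shell_um) - depletion
  stats::uniroot(f, c(0, R_hi), tol = 1e-12 * R_hi)$root
}
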