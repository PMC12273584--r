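rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# the measured diffusivity dip used throughout
dip_model <- function() diffusivity_model(0.32, 23.47, 91.32)

# Independent numerical oracle for the steady-state Fokker-Planck profile:
# integrate u'' = -(2/r) u' for u = D c (the spherically symmetric Laplace
# equation) as two IVPs from r1 and combine them linearly to satisfy the
# boundary value at r2 (exact for a linear ODE), at tight solver tolerance.
fp_shooting_oracle <- function(model, r1, c1, r2, c2, radii) {
  u1 <- predict(model, r1) * c1 * 1  # u at r1
  u2 <- predict(model, r2) * c2
  rhs <- function(r, y, p) list(c(y[2], -2 / r * y[2]))
  times <- sort(unique(c(r1, radii, r2)))
  base <- deSolve::ode(c(u1, 0), times, rhs, NULL, method = "lsoda",
                       rtol = 1e-12, atol = 1e-12)
  slope <- deSolve::ode(c(0, 1), times, rhs, NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-12)
  s <- (u2 - base[nrow(base), 2]) / slope[nrow(slope), 2]
  u <- base[, 2] + s * slope[, 2]
  u_at <- stats::approx(times, u, xout = radii)$y  # times == radii nodes
  u_at / predict(model, radii)
}
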