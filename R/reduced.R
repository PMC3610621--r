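# Radially symmetric reduced model: 1D quasi-steady substrate solve feeding a
# radius ODE (uniform-density spherical mass balance), used for the
# terminal-size analysis in terms of A = lambda_A / lambda_M and as the
# oracle for the 3D solver on spherically symmetric configurations.

#' Solve the radial quasi-steady substrate profile
#'
#' Finite-volume solve of
#' `0 = D_n (1/r^(d-1)) (r^(d-1) n')' + delivery*(level - n) - uptake * n`
#' with symmetry at `r = 0` and zero flux at `R_max`.  Supply modes:
#' `"core"` delivers from the pre-existing vascular ball
#' (`r < root_radius`); `"distributed"` spreads the angiogenic vasculature
#' over the tumor with total capacity that of the fully perfused node,
#' `nu_eff = nu_ang * min(1, (R_node/R)^d)`.
#'
#' @param R tumor radius (mm), `R > 0`.
#' @param params a `lympho_params`.
#' @param supply `"distributed"` or `"core"`.
#' @param level delivery level of the vasculature (the maturation state
#'   `n_v`; 1 = fully functional).
#' @param dr radial mesh width (mm).
#' @param pad domain padding beyond the tumor radius (mm).
#' @param dim spherical (3) or polar (2) symmetry.
#' @return a `radial_profile`: mesh `r`, substrate `n`, tumor indicator
#'   `in_tumor`, and the inputs.
#' @export
radial_substrate <- function(R, params = model_parameters(),
                             supply = c("distributed", "core"), level = 1,
                             dr = 0.01, pad = 1.0, dim = 3) {
  supply <- match.arg(supply)
  if (R <= 0) stop("tumor radius must be positive")
  u <- sim_units(params)
  r <- seq(dr / 2, R + pad, by = dr)
  m <- length(r)
  in_t <- r < R
  upt <- ifelse(in_t, u$upt_V, u$upt_H)
  deliv <- if (supply == "distributed") {
    phi <- min(1, (params$node_radius / R)^dim)
    ifelse(in_t, u$nu_ang * phi, 0)
  } else {
    ifelse(r < params$root_radius, u$nu_ang, 0)
  }
  rf_lo <- (r - dr / 2)^(dim - 1)
  rf_hi <- (r + dr / 2)^(dim - 1)
  rc <- r^(dim - 1)
  aW <- u$D_n * rf_lo / dr^2 / rc
  aE <- u$D_n * rf_hi / dr^2 / rc
  aW[1] <- 0; aE[m] <- 0
  n <- thomas_solve(-aW, aW + aE + upt + deliv, -aE, deliv * level)
  structure(list(r = r, n = pmax(pmin(n, 1), 0), in_tumor = in_t,
                 R = R, dr = dr, dim = dim, supply = supply, level = level),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial substrate profile: R = %.3g mm (%s supply), n(0) = %.3f, n(R) = %.3f\n",
              x$R, x$supply, x$n[1], x$n[max(which(x$in_tumor))]))
  invisible(x)
}

#' Radius growth rate from the radial mass balance
#'
#' Uniform-density spherical mass balance:
#' `dR/dt = (1/R^(d-1)) * integral_0^R [lambda_M n H(n - n_N) - lambda_A -
#' lambda_N H(n_N - n)] r^(d-1) dr` (trapezoidal quadrature on the profile
#' mesh).  Proliferation acts where substrate exceeds the threshold,
#' quiescent tissue below the threshold necroses.
#'
#' @param profile a `radial_profile` from [radial_substrate()].
#' @param params a `lympho_params`.
#' @return `dR/dt` in mm/day.
#' @export
radius_rhs <- function(profile, params = model_parameters()) {
  u <- sim_units(params)
  r <- profile$r; n <- profile$n
  sel <- profile$in_tumor
  if (!any(sel)) return(0)
  integrand <- (u$lam_M * n * (n > u$n_N) - u$lam_A - u$lam_N * (n <= u$n_N)) *
    r^(profile$dim - 1)
  ri <- r[sel]; fi <- integrand[sel]
  if (sum(sel) < 2) return(fi[1] * profile$dr / profile$R^(profile$dim - 1))
  int <- sum((fi[-1] + fi[-length(fi)]) / 2 * diff(ri)) +
    fi[1] * (ri[1] - 0) + fi[length(fi)] * (profile$R - ri[length(fi)])
  int / profile$R^(profile$dim - 1)
}

# One RHS evaluation of the reduced system y = (R, n_v, f_D).
reduced_rhs <- function(t, y, params, supply, dim, dr) {
  R <- max(y[1], 0.05); n_v <- min(1, y[2]); f_D <- min(1, max(0, y[3]))
  u <- sim_units(params)
  prof <- radial_substrate(R, params, supply = supply, level = n_v,
                           dr = dr, dim = dim)
  dR <- radius_rhs(prof, params)
  sel <- prof$in_tumor
  w <- prof$r[sel]^(dim - 1)
  fh <- sum((prof$n[sel] <= u$n_N) * w) / sum(w)
  # vascular functional maturation while hypoxia persists
  dnv <- params$k_remodel * (1 - n_v) * min(1, fh / params$remodel_gate)
  # companion dead-fraction diagnostic: death feeds the dead pool, clearance
  # drains it, growth dilutes it
  death <- u$lam_A + u$lam_N * fh
  dil <- if (dR > 0) dim * dR / R else 0
  dfD <- death * (1 - f_D) - u$lam_D * f_D - dil * f_D
  list(c(dR = dR, dnv = dnv, dfD = dfD), fh = fh)
}

#' Integrate the reduced spherical growth model
#'
#' Fixed-step integration (classical Runge--Kutta via \pkg{deSolve}) of the
#' tumor radius from the Day-9 seed, coupled to the vascular maturation level
#' `n_v(t)` (starting at `n_init`) and a diagnostic dead-tissue fraction.
#'
#' @param params a `lympho_params`.
#' @param t_end final day of integration.
#' @param dt time step (day).
#' @param supply supply mode, see [radial_substrate()].
#' @param dim symmetry dimension (3 = sphere).
#' @param dr radial mesh width (mm).
#' @param record_every trajectory output interval (day).
#' @return a data.frame trajectory: `time`, `radius_mm`, `diameter_mm`,
#'   `delivery_level`, `dead_fraction`, `hypoxic_fraction`, `dRdt`.
#' @export
grow_radius <- function(params = model_parameters(), t_end = 21, dt = 0.02,
                        supply = "distributed", dim = 3, dr = 0.01,
                        record_every = 0.5) {
  times <- seq(params$t_seed_day, t_end, by = record_every)
  fn <- function(t, y, p) reduced_rhs(t, y, params, supply, dim, dr)
  sol <- deSolve::ode(y = c(R = params$seed_radius, n_v = params$n_init, f_D = 0),
                      times = times, func = fn, parms = NULL,
                      method = "rk4", hini = dt)
  rr <- vapply(seq_len(nrow(sol)), function(i) {
    out <- reduced_rhs(sol[i, 1], sol[i, -1], params, supply, dim, dr)
    c(out[[1]][1], out$fh)
  }, numeric(2))
  data.frame(time = sol[, "time"],
             radius_mm = pmax(sol[, "R"], 0.05),
             diameter_mm = 2 * pmax(sol[, "R"], 0.05),
             delivery_level = pmin(1, sol[, "n_v"]),
             dead_fraction = sol[, "f_D"],
             hypoxic_fraction = rr[2, ],
             dRdt = rr[1, ])
}

#' Terminal tumor diameter of the reduced model
#'
#' Integrates the reduced spherical model at apoptosis-to-proliferation
#' ratio `A` until the radius plateaus (change over one day below `tol`),
#' and returns the terminal diameter `2 R`.  Unbounded growth (radius
#' exceeding `R_unbounded`) is reported as `Inf`.
#'
#' @param A apoptosis-to-proliferation ratio `lambda_A / lambda_M`.
#' @param params baseline parameters; `lambda_A` is overridden by
#'   `A * lambda_M`.
#' @param supply supply mode (the terminal-size analysis uses
#'   `"distributed"`).
#' @param tol plateau tolerance: radius change per day (mm).
#' @param t_max give up after this many days (reported as non-converged).
#' @param dt,dr discretization controls.
#' @return terminal diameter in mm (with attribute `t_terminal`), or `Inf`
#'   for unbounded growth.
#' @export
terminal_diameter <- function(A = 0.4, params = model_parameters(),
                              supply = "distributed", tol = 2e-3,
                              t_max = 400, dt = 0.02, dr = 0.01,
                              R_unbounded = 5) {
  if (A < 0) stop("A must be non-negative")
  params <- model_parameters_replace(params, lambda_A = A * params$lambda_M)
  pl <- reduced_plateau(params, supply, tol, t_max, dt, dr, R_unbounded)
  out <- if (pl$unbounded) Inf else as.numeric(2 * pl$R)
  attr(out, "t_terminal") <- pl$t
  out
}

# Integrate the reduced model until the radius plateaus; returns the final
# state and diagnostics.
reduced_plateau <- function(params, supply = "distributed", tol = 2e-3,
                            t_max = 400, dt = 0.02, dr = 0.01,
                            R_unbounded = 5) {
  y <- c(R = params$seed_radius, n_v = params$n_init, f_D = 0)
  t <- params$t_seed_day
  fn <- function(t, y, p) reduced_rhs(t, y, params, supply, 3, dr)
  span <- 1
  converged <- FALSE
  repeat {
    sol <- deSolve::ode(y = y, times = c(t, t + span), func = fn,
                        parms = NULL, method = "rk4", hini = dt)
    Rold <- y[[1]]
    y <- setNames(as.numeric(sol[nrow(sol), 1 + seq_along(y)]), names(y))
    y[1] <- max(y[1], 0.05)
    t <- t + span
    if (y[[1]] > R_unbounded)
      return(list(R = y[[1]], n_v = y[[2]], f_D = y[[3]], t = t,
                  fh = NA_real_, unbounded = TRUE, converged = FALSE))
    if (t > params$t_seed_day + 2 && abs(y[[1]] - Rold) < tol * span) {
      converged <- TRUE
      break
    }
    if (t >= t_max) {
      warning("no plateau within ", t_max, " days; returning current state")
      break
    }
  }
  final <- reduced_rhs(t, y, params, supply, 3, dr)
  list(R = y[[1]], n_v = y[[2]], f_D = y[[3]], t = t, fh = final$fh,
       unbounded = FALSE, converged = converged)
}

# Rebuild a params object with selected fields replaced (keeps validation).
model_parameters_replace <- function(p, ...) {
  vals <- unclass(p)
  over <- list(...)
  vals[names(over)] <- over
  out <- structure(vals, class = "lympho_params")
  validate_parameters(out)
  out
}
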