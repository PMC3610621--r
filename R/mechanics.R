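# Tissue mechanics: oncotic pressure, generalized Darcy velocities,
# conservative transport of the volume fractions, and the main time loop.
#
# Mixture closure: the tissue is solid-saturated (viable + dead + host fill
# each cell; interstitial water moves freely on a faster time scale), so the
# net tissue production S_total must be accommodated by bulk motion:
# div(k grad p) = -S_total.  On a closed box this Poisson problem is solvable
# only for zero-mean sources; the mean of S_total is projected out, which
# models uniform interstitial drainage (lymphatic return), and p is gauged to
# zero mean.

#' Solve the oncotic pressure field
#'
#' @param grid a `lympho_grid`.
#' @param S_total net tissue source field (1/day).
#' @param mobility cell mobility field `k(x)` (strictly positive).
#' @param tol relative residual tolerance.
#' @return pressure field (zero-mean gauge).
#' @export
solve_pressure <- function(grid, S_total, mobility, tol = 1e-8, x0 = NULL) {
  if (length(mobility) == 1) mobility <- array(mobility, dim = grid$n)
  if (any(mobility <= 0)) stop("mobility must be strictly positive everywhere")
  zero <- array(0, dim = grid$n)
  # multigrid-preconditioned CG: the pure-Neumann Poisson problem is the
  # stiffest solve in the loop
  solve_helmholtz(grid, mobility, zero, S_total, tol = tol, deflate = TRUE,
                  what = "pressure", x0 = x0, mg = TRUE)
}

# helpers for axis-generic slicing
slice_get <- function(x, a, idx) {
  d <- dim(x); args <- lapply(d, seq_len); args[[a]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}
slice_assign <- function(x, a, idx, value) {
  d <- dim(x); args <- lapply(d, seq_len); args[[a]] <- idx
  do.call(`[<-`, c(list(x), args, list(value)))
}

# Harmonic mean of a cell field at faces along axis a (matches the flux
# discretization of the elliptic solver).
face_harmonic <- function(k, a) {
  d <- dim(k)
  lo <- slice_get(k, a, 1:(d[a] - 1)); hi <- slice_get(k, a, 2:d[a])
  out <- array(0, dim = d)
  slice_assign(out, a, 1:(d[a] - 1), 2 * lo * hi / pmax(lo + hi, .Machine$double.xmin))
}

# Arithmetic mean at faces (for transported coefficients like chi terms).
face_mean <- function(x, a) {
  d <- dim(x)
  lo <- slice_get(x, a, 1:(d[a] - 1)); hi <- slice_get(x, a, 2:d[a])
  out <- array(0, dim = d)
  slice_assign(out, a, 1:(d[a] - 1), (lo + hi) / 2)
}

# Variational derivative of the cell-cell adhesion energy
# E = int psi(rho_T) + (eps^2/2)|grad rho_T|^2, psi = 18 rho^2 (1-rho)^2
# (double-well with minima at 0 and 1).
adhesion_potential <- function(grid, rho_T, eps_int) {
  psi_p <- 36 * rho_T * (1 - rho_T) * (1 - 2 * rho_T)
  lap <- array(0, dim = dim(rho_T))
  for (a in seq_len(grid$dim)) {
    d <- dim(rho_T)
    interior <- 2:(d[a] - 1)
    lo <- slice_get(rho_T, a, 1:(d[a] - 2))
    mid <- slice_get(rho_T, a, interior)
    hi <- slice_get(rho_T, a, 3:d[a])
    contrib <- array(0, dim = d)
    contrib <- slice_assign(contrib, a, interior, (lo - 2 * mid + hi) / grid$h^2)
    # zero-flux ends: mirror ghost
    first <- (slice_get(rho_T, a, 2) - slice_get(rho_T, a, 1)) / grid$h^2
    last  <- (slice_get(rho_T, a, d[a] - 1) - slice_get(rho_T, a, d[a])) / grid$h^2
    contrib <- slice_assign(contrib, a, 1, first)
    contrib <- slice_assign(contrib, a, d[a], last)
    lap <- lap + contrib
  }
  psi_p - eps_int^2 * lap
}

#' Generalized Darcy cell velocities
#'
#' Face-centered velocities per species:
#' tumor species `u_i = -k_i k(x) (grad p - gamma grad mu) + chi_n grad n +
#' chi_h grad f`; host `u_H = -k_H k(x) grad p` (no chemotaxis or haptotaxis
#' for host cells).  `mu` is the variational derivative of the adhesion
#' energy of the total tumor fraction.
#'
#' @param grid a `lympho_grid`.
#' @param state a `tissue_state` with current `p`, `n`, `f`.
#' @param mobility node mobility field `k(x)`.
#' @param params a `lympho_params`.
#' @return a `velocity_field`: per species (`V`, `D`, `H`) a list of
#'   face-velocity arrays, one per axis (mm/day).
#' @export
cell_velocity <- function(grid, state, mobility, params = model_parameters()) {
  if (length(mobility) == 1) mobility <- array(mobility, dim = grid$n)
  mu <- if (params$gamma > 0)
    adhesion_potential(grid, state$rho_V + state$rho_D, params$eps_int)
  else NULL
  vel <- list(V = vector("list", grid$dim), D = vector("list", grid$dim),
              H = vector("list", grid$dim))
  for (a in seq_len(grid$dim)) {
    kf <- face_harmonic(mobility, a)
    gp <- face_diff_fast(state$p, a, grid$h)
    drive <- gp
    # adhesion flux runs down the chemical-potential gradient (energy
    # decreases along trajectories)
    if (!is.null(mu)) drive <- drive + params$gamma * face_diff_fast(mu, a, grid$h)
    adv <- 0
    if (params$chi_n > 0) adv <- adv + params$chi_n * face_diff_fast(state$n, a, grid$h)
    if (params$chi_h > 0) adv <- adv + params$chi_h * face_diff_fast(state$f, a, grid$h)
    vel$V[[a]] <- -params$k_V * kf * drive + adv
    vel$D[[a]] <- -params$k_D * kf * drive
    vel$H[[a]] <- -params$k_H * kf * gp
  }
  structure(vel, class = "velocity_field")
}

# Compact face difference used in hot paths.
face_diff_fast <- function(x, a, h) {
  d <- dim(x)
  lo <- slice_get(x, a, 1:(d[a] - 1)); hi <- slice_get(x, a, 2:d[a])
  out <- array(0, dim = d)
  slice_assign(out, a, 1:(d[a] - 1), (hi - lo) / h)
}

# One conservative transport step for a single species.  scheme "upwind" is
# first-order donor-cell; "muscl" adds minmod-limited linear reconstruction
# (second order in smooth regions, positivity-preserving under the CFL
# bound), which keeps the tumor interface markedly sharper.  The kernel is
# compiled (face-by-face flux differencing, zero-flux walls).
advect_upwind <- function(grid, rho, ufaces, dt, scheme = "upwind") {
  dims <- as.integer(c(grid$n, rep(1L, 3 - grid$dim)))
  uf <- lapply(seq_len(3), function(a)
    if (a <= grid$dim) as.numeric(ufaces[[a]]) else numeric(prod(dims)))
  out <- advect_cpp(as.numeric(rho), uf, dims, dt, grid$h,
                    muscl = identical(scheme, "muscl"))
  array(out, dim = grid$n)
}

max_face_speed <- function(grid, vel) {
  m <- 0
  for (sp in c("V", "D", "H"))
    for (a in seq_len(grid$dim)) m <- max(m, max(abs(vel[[sp]][[a]])))
  m
}

#' Advance the volume fractions by one time step
#'
#' Conservative first-order upwind transport of each species with its own
#' face velocity, followed by explicit kinetic sources.  Fractions are
#' clipped to `[0, 1]` (and the solid sum to 1) with the clipped mass
#' recorded in the result attributes.
#'
#' @param state a `tissue_state`.
#' @param vel a `velocity_field` from [cell_velocity()].
#' @param sources a `source_terms` object.
#' @param dt time step (day); must satisfy the advective CFL bound.
#' @param cfl_max maximum admissible CFL number (default 0.9).
#' @param scheme `"upwind"` (default) or `"muscl"` (minmod-limited second
#'   order; sharper interfaces).
#' @return the updated `tissue_state`, with attributes `mass_change`
#'   (per-species mass change from transport+sources, pre-clip) and
#'   `clipped_mass`.
#' @export
advance_fractions <- function(state, vel, sources, dt, cfl_max = 0.9,
                              scheme = "upwind") {
  grid <- state$grid
  umax <- max_face_speed(grid, vel)
  cfl <- grid$dim * umax * dt / grid$h
  if (cfl > cfl_max)
    stop(sprintf("CFL violation: dt = %.4g day gives CFL %.3g > %.3g; use dt <= %.4g",
                 dt, cfl, cfl_max, cfl_max * grid$h / (grid$dim * umax)))
  dims <- as.integer(c(grid$n, rep(1L, 3 - grid$dim)))
  pad <- function(v) lapply(seq_len(3), function(a)
    if (a <= grid$dim) as.numeric(v[[a]]) else numeric(prod(dims)))
  res <- advance_cpp(as.numeric(state$rho_V), as.numeric(state$rho_D),
                     as.numeric(state$rho_H),
                     pad(vel$V), pad(vel$D), pad(vel$H),
                     as.numeric(sources$S_V), as.numeric(sources$S_D),
                     as.numeric(sources$S_H),
                     dims, dt, grid$h, identical(scheme, "muscl"))
  meas <- cell_measure(grid)
  st <- state
  st$rho_V <- array(res$rho_V, dim = grid$n)
  st$rho_D <- array(res$rho_D, dim = grid$n)
  st$rho_H <- array(res$rho_H, dim = grid$n)
  st$time <- state$time + dt
  attr(st, "mass_change") <- c(V = res$mass[1], D = res$mass[2],
                               H = res$mass[3]) * meas
  attr(st, "clipped_mass") <- c(negative = res$clip[1] * meas,
                                excess = res$clip[2] * meas)
  st
}
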