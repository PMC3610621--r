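# Cartesian grids, scalar fields, lymph-node geometry and tumor measurement.
#
# Conventions: cell-centered fields, 0-based physical origin at the box
# corner, coordinates of cell (i,j,k) are ((i-1/2) h, ...) in mm.  Fields are
# plain R arrays with dim = grid$n.

#' Create a Cartesian simulation grid
#'
#' @param extent physical box size per axis in mm (recycled to `dim` axes).
#'   The baseline domain is a 6.4 mm box.
#' @param spacing grid spacing in um (isotropic); baseline 100 um.
#' @param dim dimensionality, 2 or 3.
#' @return a `lympho_grid` object with cell counts `n`, spacing `h` (mm),
#'   extents (mm) and cell-center coordinate vectors.
#' @examples
#' g <- make_grid(6.4, 100, dim = 3)   # 64 x 64 x 64
#' @export
make_grid <- function(extent = 6.4, spacing = 100, dim = 3) {
  if (!dim %in% c(2, 3)) stop("dim must be 2 or 3")
  extent <- rep_len(extent, dim)
  h <- spacing / 1000  # mm
  ncell <- extent / h
  if (any(abs(ncell - round(ncell)) > 1e-8))
    stop("extent (", paste(extent, collapse = " x "),
         " mm) is not divisible by spacing (", spacing, " um)")
  ncell <- as.integer(round(ncell))
  coords <- lapply(seq_len(dim), function(a) (seq_len(ncell[a]) - 0.5) * h)
  structure(list(n = ncell, h = h, extent = extent, dim = dim, coords = coords),
            class = "lympho_grid")
}

#' @export
print.lympho_grid <- function(x, ...) {
  cat(sprintf("%dD grid: %s cells, h = %g um, box %s mm\n", x$dim,
              paste(x$n, collapse = " x "), x$h * 1000,
              paste(x$extent, collapse = " x ")))
  invisible(x)
}

# Array of squared distance (mm^2) from a point (defaults to box center).
grid_dist2 <- function(grid, center = grid$extent / 2) {
  d2 <- 0
  for (a in seq_len(grid$dim)) {
    da <- grid$coords[[a]] - center[a]
    shape <- rep(1L, grid$dim); shape[a] <- grid$n[a]
    d2 <- d2 + array(rep(da^2, each = prod(grid$n[seq_len(a - 1)])), dim = grid$n)
  }
  d2
}

# Volume fraction of each cell covered by a ball (smooth partial-volume ramp
# over one cell width at the surface).
ball_fraction <- function(grid, radius, center = grid$extent / 2) {
  r <- sqrt(grid_dist2(grid, center))
  pmax(pmin((radius - r) / grid$h + 0.5, 1), 0)
}

#' Lymph-node geometry with mobility-modulated boundary
#'
#' The healthy node is approximated as a sphere centered in the domain; the
#' tumor boundary is delineated by reducing cell mobility beyond the sphere.
#'
#' @param grid a `lympho_grid`.
#' @param radius node radius in mm (default 1.5).
#' @param mobility_reduction factor by which mobility is reduced outside the
#'   node sphere (default 10; 1 disables the confinement).
#' @param k_inside mobility value inside the node.
#' @param center node center in mm (defaults to the box center).
#' @return a `lympho_node` object holding the mobility field `k` and geometry.
#' @export
make_node <- function(grid, radius = 1.5, mobility_reduction = 10,
                      k_inside = 1, center = grid$extent / 2) {
  stopifnot(inherits(grid, "lympho_grid"))
  if (mobility_reduction <= 0) stop("mobility_reduction must be positive")
  if (radius >= min(grid$extent) / 2)
    stop("node radius (", radius, " mm) must be smaller than the half-extent (",
         min(grid$extent) / 2, " mm)")
  inside <- ball_fraction(grid, radius, center)
  k <- k_inside * (inside + (1 - inside) / mobility_reduction)
  structure(list(grid = grid, radius = radius, center = center,
                 mobility_reduction = mobility_reduction,
                 k = k, inside = inside),
            class = "lympho_node")
}

#' @export
print.lympho_node <- function(x, ...) {
  cat(sprintf("lymph node: radius %g mm, mobility reduced %gx outside\n",
              x$radius, x$mobility_reduction))
  invisible(x)
}

#' Create an initial tissue state
#'
#' Host tissue fills the domain at unit solid fraction; a viable tumor seed
#' of radius `seed_radius` (partial-volume rasterized) is placed at `center`.
#' Substrate starts at the delivery level `n_init`, VEGF and pressure at zero,
#' ECM at 1 inside the node.
#'
#' @param grid a `lympho_grid`.
#' @param node a `lympho_node` (or `NULL` for uniform ECM/mobility).
#' @param params a `lympho_params`.
#' @param center seed center (mm), default node/box center.
#' @return a `tissue_state` object: fields `rho_V`, `rho_D`, `rho_H`, `f`,
#'   `n`, `n_V`, `p` and the simulation `time` in days.
#' @export
initial_state <- function(grid, node = NULL, params = model_parameters(),
                          center = grid$extent / 2) {
  seed <- ball_fraction(grid, params$seed_radius, center)
  zero <- array(0, dim = grid$n)
  f <- if (is.null(node)) zero + 1 else node$inside
  st <- list(grid = grid,
             rho_V = seed, rho_D = zero, rho_H = 1 - seed,
             f = f, n = zero + params$n_init, n_V = zero, p = zero,
             time = params$t_seed_day)
  structure(st, class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("tissue state at day %.2f: tumor volume %.3g mm^3, equivalent diameter %.3g mm\n",
              x$time, tumor_volume(x), equivalent_diameter(x)))
  invisible(x)
}

validate_state <- function(st, tol = 1e-9) {
  for (fld in c("rho_V", "rho_D", "rho_H", "n", "n_V")) {
    v <- st[[fld]]
    if (any(v < -tol) || any(v > 1 + tol))
      stop("field '", fld, "' leaves [0,1]: range ",
           paste(signif(range(v), 6), collapse = " .. "))
  }
  tot <- st$rho_V + st$rho_D + st$rho_H
  if (any(tot > 1 + 1e-6))
    stop("total tissue fraction exceeds 1 (max ", signif(max(tot), 6), ")")
  invisible(st)
}

# Per-cell volume (mm^3 in 3D, mm^2 in 2D).
cell_measure <- function(grid) grid$h^grid$dim

#' Total tumor (viable + dead) volume in mm^3 (mm^2 in 2D)
#' @param state a `tissue_state`.
#' @export
tumor_volume <- function(state) {
  sum(state$rho_V + state$rho_D) * cell_measure(state$grid)
}

# Radius of the sphere (circle) with the given measure.
measure_to_radius <- function(V, dim) {
  if (V <= 0) return(0)
  if (dim == 3) (3 * V / (4 * pi))^(1 / 3) else sqrt(V / pi)
}

#' Equivalent spherical diameter of the simulated tumor
#'
#' The tumor region is the set where the total tumor fraction
#' `rho_V + rho_D` reaches `threshold` (default 0.5, the interface level set
#' used for all diameter reporting).  Returns the diameter of the sphere
#' (circle in 2D) whose volume (area) equals the measure of that region.
#'
#' @param state a `tissue_state`.
#' @param threshold interface level in (0,1).
#' @return diameter in mm (0 for an empty region).
#' @export
equivalent_diameter <- function(state, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  V <- sum(state$rho_V + state$rho_D >= threshold) * cell_measure(state$grid)
  2 * measure_to_radius(V, state$grid$dim)
}

# Volume-based tumor radius (smooth in time; used for solver cross-checks).
volume_radius <- function(state) {
  measure_to_radius(tumor_volume(state), state$grid$dim)
}
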