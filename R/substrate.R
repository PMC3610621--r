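# Quasi-steady reaction-diffusion solves for the nutrient substrate n and
# VEGF n_V.  Both are non-dimensionalized by their maximum level inside
# vessels, so 0 <= n, n_V <= 1; both are treated as stationary and re-solved
# whenever sources change.

# Shared linear solve: (-D lap + c) u = f, zero-flux walls.
solve_helmholtz <- function(grid, D, cfield, rhs, tol = 1e-8, maxit = 5000,
                            deflate = FALSE, what = "field", x0 = NULL,
                            mg = FALSE) {
  res <- elliptic_cg(as.numeric(rhs), as.numeric(cfield), as.numeric(D),
                     as.integer(c(grid$n, rep(1L, 3 - grid$dim))),
                     grid$h, tol, as.integer(maxit), deflate,
                     if (is.null(x0)) NULL else as.numeric(x0), mg)
  if (!res$converged)
    stop(what, " solve did not converge within ", maxit,
         " iterations (relative residual ", signif(res$relres, 3),
         "); residual history: ",
         paste(signif(utils::tail(res$reshist, 5), 3), collapse = ", "))
  array(res$x, dim = grid$n)
}

#' Solve the quasi-steady substrate (oxygen/nutrient) field
#'
#' Solves `0 = D_n lap(n) + delivery*(level - n) - (upt_V rho_V + upt_H rho_H) n
#' - dec_n n` with zero-flux boundaries.  The delivery term releases substrate
#' from vessel-occupied cells and saturates toward the intravascular level, so
#' `0 <= n <= 1` holds unconditionally (maximum principle).
#'
#' @param grid a `lympho_grid`.
#' @param delivery vessel delivery coefficient field (1/day per cell): for a
#'   binary vessel indicator this is `nu * delta_vessel` (with the Dirac
#'   scaling applied by [rasterize_network()]); a homogenized vessel-density
#'   field is equally valid.
#' @param rho_V,rho_H viable tumor and host volume-fraction fields.
#' @param params a `lympho_params`.
#' @param level intravascular substrate level the vessels deliver toward
#'   (a scalar or field; default 1).  The functional maturation model feeds
#'   the current delivery level `n_v(t)` through this argument.
#' @param tol relative residual tolerance of the iterative solve.
#' @return the substrate field `n`.
#' @export
solve_substrate <- function(grid, delivery, rho_V, rho_H,
                            params = model_parameters(), level = 1,
                            tol = 1e-8, x0 = NULL) {
  if (any(delivery < 0)) stop("delivery coefficients must be non-negative")
  u <- sim_units(params)
  cfield <- delivery + u$upt_V * rho_V + u$upt_H * rho_H + u$dec_n
  rhs <- delivery * level
  n <- solve_helmholtz(grid, u$D_n, cfield, rhs, tol = tol, what = "substrate",
                       x0 = x0)
  pmax(pmin(n, 1), 0)
}

#' Solve the quasi-steady VEGF field
#'
#' Hypoxic viable tumor cells secrete VEGF (saturating toward the normalized
#' level 1); vessels take it up; diffusion spreads it with `D_nV << D_n`.
#'
#' @param grid a `lympho_grid`.
#' @param delivery vessel delivery coefficient field (used, rescaled to the
#'   VEGF uptake rate, as the vessel sink).
#' @param hypoxic_mask logical/0-1 field of hypoxic viable tissue
#'   (`n < n_N` and `rho_V > 0`).
#' @param rho_V viable tumor fraction field.
#' @param params a `lympho_params`.
#' @param tol relative residual tolerance.
#' @return the VEGF field `n_V`.
#' @export
solve_vegf <- function(grid, delivery, hypoxic_mask, rho_V,
                       params = model_parameters(), tol = 1e-8, x0 = NULL) {
  u <- sim_units(params)
  src <- u$sec_V * rho_V * (hypoxic_mask != 0)
  if (all(src == 0)) return(array(0, dim = grid$n))
  # vessel sink with the VEGF uptake rate; delivery > 0 marks vessel presence
  sink <- u$vegf_upt * (delivery > 0)
  cfield <- src + sink + u$dec_nV
  nv <- solve_helmholtz(grid, u$D_nV, cfield, src, tol = tol, what = "VEGF",
                        x0 = x0)
  pmax(pmin(nv, 1), 0)
}

#' Hypoxic fraction of the tumor
#'
#' Fraction of the viable-tumor region experiencing substrate below the
#' quiescence/necrosis threshold `n_N`.
#'
#' @param state a `tissue_state` with a current substrate field.
#' @param params a `lympho_params`.
#' @param floor viable fraction below which a cell is not counted as tumor
#'   (numerical floor for "rho_V > 0").
#' @return the hypoxic fraction in `[0, 1]`.
#' @export
hypoxic_fraction_of_tumor <- function(state, params = model_parameters(),
                                      floor = 1e-3) {
  tum <- state$rho_V > floor
  denom <- sum(tum)
  if (denom == 0) stop("empty tumor: hypoxic fraction is undefined")
  sum(tum & state$n < params$n_N) / denom
}
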