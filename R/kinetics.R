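# Source terms of the tissue conservation laws: mitosis above the substrate
# threshold, quiescence below it, apoptosis, necrosis (both transferring mass
# from the living species to the dead compartment) and dead-cell degradation.
#
# The Heaviside switch is implemented exactly (H(0) = 0); an optional smoothed
# variant of width `eps` in n is available for stiffness control.

heaviside <- function(x, eps = 0) {
  if (eps <= 0) as.numeric(x > 0) else pmax(pmin(x / eps + 0.5, 1), 0)
}

#' Kinetic source terms for the tissue species
#'
#' Computes, per unit time (1/day):
#' \deqn{S_V = \lambda_M n H(n-n_N)\rho_V - \lambda_A \rho_V - \lambda_N H(n_N-n)\rho_V}
#' \deqn{S_H = -\lambda_{A,H}\rho_H - \lambda_{N,H} H(n_N-n)\rho_H}
#' \deqn{S_D = \sum_i [\lambda_{A,i}\rho_i + \lambda_{N,i} H(n_N-n)\rho_i] - \lambda_D \rho_D}
#' Death transfers mass between species; only mitosis creates tissue and only
#' degradation removes it.  Host cells do not proliferate.
#'
#' @param rho_V,rho_D,rho_H volume-fraction fields (each in `[0,1]`).
#' @param n substrate field in `[0,1]`.
#' @param params a `lympho_params`.
#' @param eps_H optional smoothing width for the Heaviside switch (0 = exact).
#' @return a `source_terms` list: fields `S_V`, `S_D`, `S_H` plus diagnostic
#'   masks `proliferating` and `quiescent` partitioning the viable tumor.
#' @export
source_terms <- function(rho_V, rho_D, rho_H, n, params = model_parameters(),
                         eps_H = 0) {
  if (any(rho_V < 0) || any(rho_D < 0) || any(rho_H < 0))
    stop("volume fractions must be non-negative")
  u <- sim_units(params)
  Hup <- heaviside(n - u$n_N, eps_H)     # proliferation switch
  Hdn <- heaviside(u$n_N - n, eps_H)     # quiescence/necrosis switch
  mit   <- u$lam_M * n * Hup * rho_V
  apo_V <- u$lam_A * rho_V
  nec_V <- u$lam_N * Hdn * rho_V
  apo_H <- u$lam_A_H * rho_H
  nec_H <- u$lam_N_H * Hdn * rho_H
  S_V <- mit - apo_V - nec_V
  S_H <- -apo_H - nec_H
  S_D <- apo_V + nec_V + apo_H + nec_H - u$lam_D * rho_D
  structure(list(S_V = S_V, S_D = S_D, S_H = S_H,
                 proliferating = (Hup > 0) & (rho_V > 0),
                 quiescent = (Hdn > 0) & (rho_V > 0)),
            class = "source_terms")
}

#' Tumor-averaged apoptosis rate
#'
#' Viable-volume-weighted mean of the apoptotic loss rate per unit viable
#' fraction, in 1/day.  With a uniform apoptosis rate this returns
#' `lambda_A` exactly; the weighting matters when per-region rate fields are
#' supplied.
#'
#' @param state a `tissue_state`.
#' @param params a `lympho_params`.
#' @param rate_field optional spatial apoptosis-rate field (1/day); defaults
#'   to the uniform `lambda_A`.
#' @return mean apoptosis rate (1/day).
#' @export
average_apoptosis_rate <- function(state, params = model_parameters(),
                                   rate_field = NULL) {
  w <- sum(state$rho_V)
  if (w == 0) stop("empty tumor: average apoptosis rate is undefined")
  if (is.null(rate_field)) return(params$lambda_A)
  sum(rate_field * state$rho_V) / w
}
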