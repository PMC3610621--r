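# Model parameters, baseline values and non-dimensionalization.
#
# Unit conventions (documented, not enforced by a units library):
#   diffusivities D_n, D_nV        cm^2/s
#   vessel delivery nu, uptake/decay/secretion rates   1/s
#   kinetic rates lambda_M, lambda_A, lambda_D         1/day
#   lambda_N                       non-dimensional (units of lambda_M)
#   lengths (node_radius, seed_radius, ...)            mm, except L_hypoxia in um
#   times t_seed_day, t_end_day    day
# Internally the simulators work in mm and day (see `sim_units()`).

.param_defaults <- function() {
  list(
    # cell kinetics
    lambda_M       = NA_real_,  # 1/day; default derived: 24 h / prolif_cycle_h
    lambda_A       = NA_real_,  # 1/day; default derived: A_ratio * lambda_M
    A_ratio        = 0.4,       # apoptosis-to-proliferation ratio lambda_A/lambda_M
    lambda_N       = 6,         # non-dim necrosis rate (units of lambda_M)
    lambda_D       = NA_real_,  # 1/day; default derived: 24 h / apop_window_h
    lambda_A_host  = 0,         # 1/day (homeostatic host: turnover balanced)
    lambda_N_host  = 0,         # non-dim
    n_N            = exp(-1),   # quiescence/necrosis substrate threshold
    n_init         = 1,         # initial functional delivery level of vasculature
    # transport
    D_n            = 1e-5,      # cm^2/s oxygen/nutrient
    D_nV           = 1e-7,      # cm^2/s VEGF
    nu             = 20,        # 1/s per-vessel-voxel delivery (100 um reference voxel)
    lambda_upt_V   = NA_real_,  # 1/s; default derived from L_hypoxia anchor
    lambda_upt_H   = NA_real_,  # 1/s; default lambda_upt_V / 2
    lambda_dec_n   = 0,         # 1/s
    lambda_dec_nV  = 1e-4,      # 1/s VEGF tissue clearance (~2 h half-life)
    lambda_sec_V   = 0.01,      # 1/s VEGF secretion by hypoxic tumor
    nu_vegf_upt    = 0.01,      # 1/s VEGF uptake at vessels
    # mechanics
    k_V            = 1,         # non-dim mobilities
    k_D            = 1,
    k_H            = 1,
    gamma          = 0,         # adhesion force coefficient (off at baseline)
    eps_int        = 0.1,       # mm, adhesion interface width
    chi_n          = 0,         # chemotaxis (tumor); host is always 0
    chi_h          = 0,         # haptotaxis (tumor); host is always 0
    # cellular-scale anchors
    L_hypoxia      = 80,        # um oxygen diffusion distance (range 60-100)
    prolif_cycle_h = 20,        # h
    apop_window_h  = 5,         # h
    # geometry and schedule
    node_radius    = 1.5,       # mm
    seed_radius    = 0.45,      # mm initial nodal colonization at Day 9
    root_radius    = 0.3,       # mm pre-existing vascular core ball
    mobility_reduction = 10,    # factor outside the node sphere
    t_seed_day     = 9,
    t_end_day      = 21,
    # angiogenic supply (distributed mode) and vascular maturation
    f_CD31_ref     = 0.08,      # reference CD31 stained fraction (sets n_perf)
    k_remodel      = 1.5,       # 1/day functional maturation of vasculature
    remodel_gate   = 0.01,      # hypoxic fraction saturating the maturation drive
    # sprouting network
    theta_sprout   = 0.017,     # VEGF threshold for tip initiation
    p_sprout       = 35,        # 1/day tip initiation rate per eligible vessel voxel
    beta_sprout    = 30,        # softmax gradient bias (per unit VEGF difference)
    branch_rate    = 32,        # 1/day branching rate scale (times local VEGF)
    tip_speed      = 0.5        # mm/day sprout extension (~20 um/h)
  )
}

.derived_keys <- c("lambda_M", "lambda_A", "lambda_D", "lambda_upt_V", "lambda_upt_H")

.nonneg_keys <- c("lambda_M", "lambda_A", "A_ratio", "lambda_N", "lambda_D",
                  "lambda_A_host", "lambda_N_host", "nu", "lambda_upt_V",
                  "lambda_upt_H", "lambda_dec_n", "lambda_dec_nV", "lambda_sec_V",
                  "nu_vegf_upt", "k_V", "k_D", "k_H", "gamma", "chi_n", "chi_h",
                  "L_hypoxia", "prolif_cycle_h", "apop_window_h", "node_radius",
                  "seed_radius", "root_radius", "mobility_reduction",
                  "k_remodel", "remodel_gate", "theta_sprout", "p_sprout",
                  "beta_sprout", "branch_rate", "tip_speed", "D_n", "D_nV",
                  "eps_int")

#' Construct the model parameter set
#'
#' Returns the full parameter list at documented baseline values, with any
#' number of overrides.  Derived defaults are resolved here: `lambda_M` from
#' the proliferation cycle (24 h / `prolif_cycle_h`), `lambda_A` from
#' `A_ratio * lambda_M`, `lambda_D` from the apoptosis detectability window
#' (24 h / `apop_window_h`), and the viable-tissue uptake `lambda_upt_V` from
#' the oxygen diffusion distance anchor `L_hypoxia` via
#' `lambda_upt_V = D_n / L_hypoxia^2`.
#'
#' @param ... named parameter overrides (see `.param_defaults` keys).
#' @return an object of class `lympho_params`: a named list of parameters.
#' @examples
#' p <- model_parameters()
#' p$D_n                     # 1e-5 cm^2/s
#' model_parameters(n_init = 0.5)$n_init
#' @export
model_parameters <- function(...) {
  over <- list(...)
  defs <- .param_defaults()
  unknown <- setdiff(names(over), names(defs))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  p <- modifyList(defs, over)
  # resolve derived defaults (only where not explicitly supplied)
  if (is.na(p$lambda_M)) p$lambda_M <- 24 / p$prolif_cycle_h
  if (is.na(p$lambda_A)) p$lambda_A <- p$A_ratio * p$lambda_M
  if (is.na(p$lambda_D)) p$lambda_D <- 24 / p$apop_window_h
  if (is.na(p$lambda_upt_V)) {
    # L_hypoxia [um] = sqrt(D_n/lambda_upt_V); D_n in cm^2/s = 1e8 um^2/s
    p$lambda_upt_V <- (p$D_n * 1e8) / p$L_hypoxia^2
  }
  if (is.na(p$lambda_upt_H)) p$lambda_upt_H <- p$lambda_upt_V / 2
  validate_parameters(p)
  structure(p, class = "lympho_params")
}

validate_parameters <- function(p) {
  for (key in .nonneg_keys) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("parameter '", key, "' must be a single non-negative number, got: ",
           deparse(v))
  }
  if (p$n_N <= 0 || p$n_N >= 1)
    stop("parameter 'n_N' must lie strictly inside (0, 1), got: ", p$n_N)
  if (p$n_init <= 0 || p$n_init > 1)
    stop("parameter 'n_init' must lie in (0, 1], got: ", p$n_init)
  if (p$D_nV >= p$D_n)
    stop("parameter 'D_nV' must be smaller than 'D_n' (VEGF diffuses slower)")
  invisible(p)
}

#' @export
print.lympho_params <- function(x, ...) {
  cat("lymphoma growth model parameters\n")
  cat(sprintf("  kinetics : lambda_M %.3g/day, lambda_A %.3g/day (A = %.3g), ",
              x$lambda_M, x$lambda_A, x$lambda_A / x$lambda_M))
  cat(sprintf("lambda_N %.3g (non-dim), lambda_D %.3g/day\n", x$lambda_N, x$lambda_D))
  cat(sprintf("  transport: D_n %.3g cm2/s, D_nV %.3g cm2/s, uptake %.3g/s, nu %.3g/s\n",
              x$D_n, x$D_nV, x$lambda_upt_V, x$nu))
  cat(sprintf("  substrate: n_N %.3g, n_init %.3g, L_hypoxia %g um\n",
              x$n_N, x$n_init, x$L_hypoxia))
  cat(sprintf("  geometry : node %g mm, seed %g mm, Day %g -> Day %g\n",
              x$node_radius, x$seed_radius, x$t_seed_day, x$t_end_day))
  invisible(x)
}

#' Load a run configuration from key=value text
#'
#' The configuration format is flat `key = value` text; `#` starts a comment;
#' blank lines are ignored.  Unknown keys and out-of-range values are
#' rejected with a message naming the key.  Keys not present take the
#' documented baseline values.
#'
#' @param text a character vector of configuration lines, or a single string
#'   with embedded newlines.
#' @param file alternatively, path to a configuration file.
#' @return a `lympho_params` object.
#' @examples
#' load_config("n_init = 0.5")$n_init
#' load_config(character(0))$D_n     # baseline 1e-5
#' @export
load_config <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- readLines(file)
  if (is.null(text)) text <- character(0)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("cannot parse configuration line (expected key=value): '", ln, "'")
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("cannot parse configuration line: '", ln, "'")
    key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val))
      stop("value for key '", key, "' is not numeric")
    over[[key]] <- val
  }
  do.call(model_parameters, over)
}

#' Write a configuration file for a parameter set
#'
#' Writes every parameter as `key = value` with full precision, so that
#' `load_config(file = path)` restores the parameters exactly.
#'
#' @param p a `lympho_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  stopifnot(inherits(p, "lympho_params"))
  lines <- c("# lymphosim run configuration",
             vapply(names(p), function(k)
               sprintf("%s = %s", k, format(p[[k]], digits = 17)), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Export resolved parameters as JSON (provenance record)
#'
#' @param p a `lympho_params` object.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
params_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "lympho_params"))
  js <- jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Non-dimensionalize a parameter set
#'
#' Length is scaled by the substrate diffusion length
#' `L = sqrt(D_n / lambda_upt_V)` (the 80 um hypoxia anchor at baseline) and
#' time by `1 / lambda_M` (the proliferation time scale).  Rates printed "in
#' non-dimensional units" elsewhere in the package (e.g. the necrosis rate
#' 5--7) are interpreted on this scale.
#'
#' @param p a `lympho_params` object with `lambda_upt_V > 0`, `lambda_M > 0`.
#' @return an object of class `lympho_nondim` with fields `length_scale_um`,
#'   `time_scale_day`, and `values` (the rescaled parameters).
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "lympho_params"))
  if (p$lambda_upt_V <= 0) stop("lambda_upt_V must be positive to set the length scale")
  if (p$lambda_M <= 0) stop("lambda_M must be positive to set the time scale")
  Lum <- sqrt(p$D_n * 1e8 / p$lambda_upt_V)  # um
  Tday <- 1 / p$lambda_M                     # day
  Tsec <- Tday * 86400
  v <- list(
    # rates 1/day -> multiply by Tday; rates 1/s -> by Tsec;
    # diffusivities cm^2/s -> um^2/s * Tsec / Lum^2; lengths mm -> /Lum*1000
    lambda_M = p$lambda_M * Tday, lambda_A = p$lambda_A * Tday,
    lambda_N = p$lambda_N,  # already non-dim
    lambda_D = p$lambda_D * Tday,
    lambda_A_host = p$lambda_A_host * Tday, lambda_N_host = p$lambda_N_host,
    D_n = p$D_n * 1e8 * Tsec / Lum^2, D_nV = p$D_nV * 1e8 * Tsec / Lum^2,
    nu = p$nu * Tsec, lambda_upt_V = p$lambda_upt_V * Tsec,
    lambda_upt_H = p$lambda_upt_H * Tsec,
    lambda_dec_n = p$lambda_dec_n * Tsec, lambda_dec_nV = p$lambda_dec_nV * Tsec,
    lambda_sec_V = p$lambda_sec_V * Tsec, nu_vegf_upt = p$nu_vegf_upt * Tsec,
    node_radius = p$node_radius * 1000 / Lum,
    seed_radius = p$seed_radius * 1000 / Lum,
    root_radius = p$root_radius * 1000 / Lum,
    L_hypoxia = p$L_hypoxia / Lum,
    n_N = p$n_N, n_init = p$n_init
  )
  structure(list(length_scale_um = Lum, time_scale_day = Tday, values = v,
                 dimensional = p),
            class = "lympho_nondim")
}

#' Recover dimensional parameters from a non-dimensional set
#'
#' Inverse of [nondimensionalize()]; round-trips to within 1e-12 relative
#' error.
#'
#' @param nd a `lympho_nondim` object.
#' @return the dimensional `lympho_params`.
#' @export
redimensionalize <- function(nd) {
  stopifnot(inherits(nd, "lympho_nondim"))
  Lum <- nd$length_scale_um; Tday <- nd$time_scale_day; Tsec <- Tday * 86400
  v <- nd$values
  p <- nd$dimensional
  out <- unclass(p)
  out$lambda_M <- v$lambda_M / Tday
  out$lambda_A <- v$lambda_A / Tday
  out$lambda_D <- v$lambda_D / Tday
  out$lambda_A_host <- v$lambda_A_host / Tday
  out$D_n  <- v$D_n * Lum^2 / Tsec / 1e8
  out$D_nV <- v$D_nV * Lum^2 / Tsec / 1e8
  out$nu <- v$nu / Tsec
  out$lambda_upt_V <- v$lambda_upt_V / Tsec
  out$lambda_upt_H <- v$lambda_upt_H / Tsec
  out$lambda_dec_n <- v$lambda_dec_n / Tsec
  out$lambda_dec_nV <- v$lambda_dec_nV / Tsec
  out$lambda_sec_V <- v$lambda_sec_V / Tsec
  out$nu_vegf_upt <- v$nu_vegf_upt / Tsec
  out$node_radius <- v$node_radius * Lum / 1000
  out$seed_radius <- v$seed_radius * Lum / 1000
  out$root_radius <- v$root_radius * Lum / 1000
  out$L_hypoxia <- v$L_hypoxia * Lum
  structure(out, class = "lympho_params")
}

#' @export
print.lympho_nondim <- function(x, ...) {
  cat(sprintf("non-dimensional parameter set: length scale %.4g um, time scale %.4g day\n",
              x$length_scale_um, x$time_scale_day))
  invisible(x)
}

# Convert parameters to the internal simulation units (mm, day).
# 1 cm^2/s = 8.64e6 mm^2/day; 1/s = 86400/day.
sim_units <- function(p) {
  n_perf <- (1 - p$f_CD31_ref)^1.5
  uptV <- p$lambda_upt_V * 86400
  list(
    D_n   = p$D_n * 8.64e6,
    D_nV  = p$D_nV * 8.64e6,
    nu    = p$nu * 86400,
    upt_V = uptV,
    upt_H = p$lambda_upt_H * 86400,
    dec_n = p$lambda_dec_n * 86400,
    dec_nV = p$lambda_dec_nV * 86400,
    sec_V = p$lambda_sec_V * 86400,
    vegf_upt = p$nu_vegf_upt * 86400,
    lam_M = p$lambda_M,
    lam_A = p$lambda_A,
    lam_N = p$lambda_N * p$lambda_M,       # dimensionalized necrosis rate
    lam_D = p$lambda_D,
    lam_A_H = p$lambda_A_host,
    lam_N_H = p$lambda_N_host * p$lambda_M,
    n_N   = p$n_N,
    n_init = p$n_init,
    n_perf = n_perf,
    # homogenized delivery of a fully developed angiogenic vasculature:
    # equilibrium nu_ang*(1-n) = upt_V*n at n = n_perf
    nu_ang = uptV * n_perf / (1 - n_perf),
    L_mm  = p$L_hypoxia / 1000
  )
}
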