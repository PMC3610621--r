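# Virtual histology: emulates the experimental sectioning scheme on
# simulation output.  Five section planes (S1..S5) span the tumor extent
# along one axis; S1/S5 sit at the tumor poles and S3 at the center.  Each
# section reports area-fraction statistics split into the core and a
# periphery defined as the tumor region within 200 um of the boundary.

# k-fold erosion of a logical mask (face neighbours), zero outside.
erode_mask <- function(mask, k) {
  d <- dim(mask); nd <- length(d)
  m <- mask
  for (rep in seq_len(k)) {
    out <- m
    for (a in seq_len(nd)) {
      lo <- slice_get(m, a, c(1, 1:(d[a] - 1)))      # shifted +1 (edge repeats)
      hi <- slice_get(m, a, c(2:d[a], d[a]))
      # boundary cells treated as adjacent to outside
      lo <- slice_assign(lo, a, 1, slice_get(array(FALSE, d), a, 1))
      hi <- slice_assign(hi, a, d[a], slice_get(array(FALSE, d), a, d[a]))
      out <- out & lo & hi
    }
    m <- out
  }
  m
}

#' Tumor periphery mask
#'
#' Voxels inside the tumor (total tumor fraction at or above the 0.5
#' interface level) lying within `width` of the tumor boundary, computed by
#' iterated erosion of the tumor mask.
#'
#' @param state a `tissue_state`.
#' @param width shell width in mm (default 0.2 = 200 um).
#' @param threshold tumor interface level.
#' @return logical array.
#' @export
periphery_mask <- function(state, width = 0.2, threshold = 0.5) {
  tum <- (state$rho_V + state$rho_D) >= threshold
  k <- floor(width / state$grid$h + 1e-9)
  if (k < 1) return(tum & FALSE)
  core <- erode_mask(tum, k)
  tum & !core
}

#' Extract virtual histology sections
#'
#' Five planes at equal spacing across the tumor extent along `axis`;
#' statistics are computed on each plane restricted to the tumor region and
#' split into core and periphery.  The proliferating and apoptotic "stain"
#' proxies invert the calibration formulas (rate times detectability
#' window), so virtual IHC and rate calibration are mutually consistent.
#'
#' @param state a `tissue_state`.
#' @param params a `lympho_params`.
#' @param vessels optional vessel indicator field (for endothelial density).
#' @param axis sectioning axis (default the last grid axis).
#' @param n_sections number of section planes (default 5).
#' @param threshold tumor interface level.
#' @return a `section_stats` data.frame: one row per (section, region) with
#'   `viable_fraction`, `hypoxic_fraction`, `vessel_density`,
#'   `proliferating_fraction`, `apoptotic_fraction`, `tumor_voxels`.
#' @export
extract_sections <- function(state, params = model_parameters(),
                             vessels = NULL, axis = state$grid$dim,
                             n_sections = 5, threshold = 0.5) {
  grid <- state$grid
  u <- sim_units(params)
  tum <- (state$rho_V + state$rho_D) >= threshold
  if (!any(tum)) stop("empty tumor: no sections to extract")
  prof <- apply(tum, axis, any)
  lo <- min(which(prof)); hi <- max(which(prof))
  if (hi - lo + 1 < n_sections)
    stop("tumor spans fewer than ", n_sections, " voxels along axis ", axis)
  planes <- round(seq(lo, hi, length.out = n_sections))
  peri <- periphery_mask(state, 0.2, threshold)
  rho_T <- pmax(state$rho_V + state$rho_D, .Machine$double.eps)
  viab <- state$rho_V / rho_T
  prolif <- u$lam_M * state$n * (state$n > u$n_N) * viab *
    (params$prolif_cycle_h / 24)
  apof <- u$lam_A * viab * (params$apop_window_h / 24)
  hyp <- state$n < u$n_N
  ves <- if (is.null(vessels)) array(0, grid$n) else (vessels > 0) * 1
  rows <- list()
  for (s in seq_along(planes)) {
    pl_tum <- slice_get(tum, axis, planes[s])
    for (reg in c("core", "periphery")) {
      rm <- if (reg == "core") !slice_get(peri, axis, planes[s])
            else slice_get(peri, axis, planes[s])
      sel <- pl_tum & rm
      nsel <- sum(sel)
      stat <- function(x) if (nsel) mean(slice_get(x, axis, planes[s])[sel]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        section = paste0("S", s), region = reg, plane_index = planes[s],
        tumor_voxels = nsel,
        viable_fraction = stat(viab),
        hypoxic_fraction = stat(hyp * 1),
        vessel_density = stat(ves),
        proliferating_fraction = stat(prolif),
        apoptotic_fraction = stat(apof))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("section_stats", "data.frame")
  out
}
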