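# Mathematical-pathology calibration: IHC stain-count tables to model rates,
# the necrosis-rate acceptance sweep, and the synthetic IHC fixture
# generator.
#
# Conversion rules (per section/region stained fractions f):
#   proliferation  lambda_M * <n> = (f_Ki67 / 20 h) * 24 h/day
#   apoptosis      lambda_A       = (f_Casp3 / 5 h) * 24 h/day
#   vascular support fraction     = (1 - f_CD31)^(3/2)
#   hypoxic cell fraction         = (f_HIF1a)^(3/2)

.ihc_markers <- c("Ki67", "Casp3", "CD31", "HIF1a", "HE")
.ihc_sections <- paste0("S", 1:5)

#' Convert a Ki-67 stained fraction to the mitosis rate
#'
#' `lambda_M = (f / prolif_cycle_h) * 24 / mean_n`, i.e. the per-day
#' proliferation rate implied by the fraction of cells inside the
#' proliferation cycle, corrected by the average substrate the model says
#' those cells experienced.
#'
#' @param f_stained Ki-67 stained fraction in `[0, 1]`.
#' @param mean_n average substrate level `<n>` in `(0, 1]`.
#' @param prolif_cycle_h proliferation cycle duration (h), default 20.
#' @return `lambda_M` in 1/day.
#' @examples
#' proliferation_rate(0.5, 1)    # 0.6 / day
#' proliferation_rate(0.5, 0.5)  # 1.2 / day
#' @export
proliferation_rate <- function(f_stained, mean_n, prolif_cycle_h = 20) {
  stopifnot(all(f_stained >= 0 & f_stained <= 1))
  if (any(mean_n <= 0)) stop("mean_n must be positive (rate undefined at 0)")
  (f_stained / prolif_cycle_h) * 24 / mean_n
}

#' Convert a Caspase-3 stained fraction to the apoptosis rate
#'
#' `lambda_A = (f / apop_window_h) * 24`: the apoptotic state is detectable
#' for about 5 hours, so the stained fraction divided by the window length
#' is the event rate.
#'
#' @param f_stained Caspase-3 stained fraction in `[0, 1]`.
#' @param apop_window_h apoptosis detectability window (h), default 5.
#' @return `lambda_A` in 1/day.
#' @examples
#' apoptosis_rate(0.1)  # 0.48 / day
#' apoptosis_rate(1)    # 4.8 / day, the upper bound
#' @export
apoptosis_rate <- function(f_stained, apop_window_h = 5) {
  stopifnot(all(f_stained >= 0 & f_stained <= 1))
  (f_stained / apop_window_h) * 24
}

#' Vascular support fraction from a CD31 stained fraction
#'
#' Fraction of cells supported per endothelial cell in a unit volume:
#' `(1 - f)^(3/2)` (an areal density of endothelium converted to a
#' volumetric support fraction).
#'
#' @param f_stained CD31 stained fraction in `[0, 1]`.
#' @return support fraction in `[0, 1]`.
#' @examples
#' vascular_support_fraction(0.75)  # 0.125
#' @export
vascular_support_fraction <- function(f_stained) {
  stopifnot(all(f_stained >= 0 & f_stained <= 1))
  (1 - f_stained)^1.5
}

#' Hypoxic cell fraction from a HIF-1alpha stained fraction
#'
#' `f^(3/2)`: areal stained density converted to a volumetric fraction.
#'
#' @param f_stained HIF-1alpha stained fraction in `[0, 1]`.
#' @return hypoxic cell fraction in `[0, 1]`.
#' @examples
#' hypoxic_cell_fraction(0.25)  # 0.125
#' @export
hypoxic_cell_fraction <- function(f_stained) {
  stopifnot(all(f_stained >= 0 & f_stained <= 1))
  f_stained^1.5
}

#' Validate and construct an IHC stain-count table
#'
#' @param df a data.frame with columns `section` (S1..S5), `marker`
#'   (Ki67, Casp3, CD31, HIF1a, HE), `region` (core/periphery), `stained`,
#'   `unstained` (non-negative integer counts, positive row totals).
#' @return the table with class `ihc_table`.
#' @export
ihc_table <- function(df) {
  need <- c("section", "marker", "region", "stained", "unstained")
  if (!all(need %in% names(df)))
    stop("IHC table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$section %in% .ihc_sections)) stop("section must be one of S1..S5")
  if (!all(df$marker %in% .ihc_markers))
    stop("marker must be one of ", paste(.ihc_markers, collapse = ", "))
  if (!all(df$region %in% c("core", "periphery")))
    stop("region must be 'core' or 'periphery'")
  cnt <- c(df$stained, df$unstained)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  if (any(df$stained + df$unstained <= 0))
    stop("each row needs a positive total count")
  structure(df, class = c("ihc_table", "data.frame"))
}

#' Read / write IHC tables as CSV
#'
#' CSV schema: header `section,marker,region,stained,unstained`.
#' @param path file path.
#' @return `read_ihc` returns an `ihc_table`.
#' @export
read_ihc <- function(path) ihc_table(read.csv(path, stringsAsFactors = FALSE))

#' @rdname read_ihc
#' @param tab an `ihc_table`.
#' @export
write_ihc <- function(tab, path) {
  stopifnot(inherits(tab, "ihc_table"))
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Baseline stained-fraction presets.  The "sensitive" phenotype carries the
# periphery-enriched viability and higher apoptosis; "resistant" the
# center-enriched viability and 4-fold central endothelial enrichment.
ihc_presets <- function(phenotype = c("baseline", "resistant", "sensitive")) {
  phenotype <- match.arg(phenotype)
  base <- list(
    Ki67  = c(core = 0.88, periphery = 0.82),
    Casp3 = c(core = 0.08, periphery = 0.12),
    CD31  = c(core = 0.12, periphery = 0.04),
    HIF1a = c(core = 0.02, periphery = 0.10),
    HE    = c(core = 0.92, periphery = 0.88))
  if (phenotype == "resistant") {
    base$CD31 <- c(core = 0.16, periphery = 0.04)   # 4x central enrichment
    base$HE   <- c(core = 0.94, periphery = 0.86)
  } else if (phenotype == "sensitive") {
    base$Casp3 <- c(core = 0.10, periphery = 0.16)
    base$HE    <- c(core = 0.88, periphery = 0.92)  # denser periphery
    base$HIF1a <- c(core = 0.03, periphery = 0.14)
  }
  base
}

#' Generate a synthetic IHC table
#'
#' Emulates the five-section staining scheme: for every section, marker and
#' region, stained counts are drawn binomially around target fractions.
#' Targets default to the phenotype presets; a small section-to-section
#' gradient moves core-like values toward periphery-like values in the
#' extreme sections S1/S5.  Synthetic stand-in for slide-derived count
#' tables; no measured data enter here.
#'
#' @param phenotype preset name (`"baseline"`, `"resistant"`,
#'   `"sensitive"`), or pass explicit `targets`.
#' @param targets optional named list `marker -> c(core=, periphery=)` of
#'   stained fractions, overriding the preset.
#' @param total counts per row (cells scored per region of a section).
#' @param noise if `FALSE`, counts are deterministic roundings of the target
#'   fractions.
#' @param rng_seed integer seed.
#' @return an `ihc_table`.
#' @export
synth_ihc <- function(phenotype = "baseline", targets = NULL, total = 1000,
                      noise = TRUE, rng_seed = 1L) {
  tg <- if (is.null(targets)) ihc_presets(phenotype) else targets
  set.seed(substream_seed(rng_seed, "ihc-fixture"))
  rows <- list()
  for (s in seq_along(.ihc_sections)) {
    # S1/S5 are the tumor poles: even their cores resemble periphery
    polew <- c(0.8, 0.3, 0, 0.3, 0.8)[s]
    for (mk in names(tg)) {
      fc <- tg[[mk]]["core"] * (1 - polew) + tg[[mk]]["periphery"] * polew
      fp <- tg[[mk]]["periphery"]
      for (reg in c("core", "periphery")) {
        f <- if (reg == "core") fc else fp
        st <- if (noise) rbinom(1, total, f) else round(total * f)
        rows[[length(rows) + 1]] <- data.frame(
          section = .ihc_sections[s], marker = mk, region = reg,
          stained = as.integer(st), unstained = as.integer(total - st))
      }
    }
  }
  ihc_table(do.call(rbind, rows))
}

stained_fraction <- function(tab, marker, region = NULL) {
  sel <- tab$marker == marker
  if (!is.null(region)) sel <- sel & tab$region == region
  if (!any(sel)) return(NA_real_)
  sum(tab$stained[sel]) / sum(tab$stained[sel] + tab$unstained[sel])
}

#' Calibrate model rates from an IHC table
#'
#' Applies the four conversion rules to the pooled stained fractions.  The
#' average substrate `<n>` entering the proliferation conversion is
#' initialized from the CD31-derived vascular support fraction (nutrient
#' follows vessel density) and, when `refine = TRUE`, refined by a fixed
#' point: calibrate, run the reduced model, recompute the tumor-averaged
#' substrate, repeat until `lambda_M` moves by less than `tol_rel`
#' (at most `max_iter` rounds).
#'
#' @param tab an `ihc_table`.
#' @param params baseline parameters used by the refinement simulation.
#' @param refine run the simulation fixed point for `<n>`.
#' @param max_iter,tol_rel fixed-point controls.
#' @return a `calibration_result`: `lambda_M`, `lambda_A`, `A`,
#'   `vascular_support`, `hypoxic_fraction`, `mean_n`, `iterations`.
#' @export
calibrate_ihc <- function(tab, params = model_parameters(), refine = FALSE,
                          max_iter = 10, tol_rel = 0.01) {
  stopifnot(inherits(tab, "ihc_table"))
  f_ki <- stained_fraction(tab, "Ki67")
  f_ca <- stained_fraction(tab, "Casp3")
  f_cd <- stained_fraction(tab, "CD31")
  f_hf <- stained_fraction(tab, "HIF1a")
  support <- vascular_support_fraction(f_cd)
  hyp <- hypoxic_cell_fraction(f_hf)
  lam_A <- apoptosis_rate(f_ca, params$apop_window_h)
  mean_n <- support   # vessel-density estimate of <n>
  lam_M <- proliferation_rate(f_ki, mean_n, params$prolif_cycle_h)
  iters <- 0L
  if (refine) {
    for (it in seq_len(max_iter)) {
      iters <- it
      p2 <- model_parameters_replace(params, lambda_M = lam_M,
                                     lambda_A = lam_A)
      tr <- grow_radius(p2, t_end = p2$t_end_day, record_every = 1)
      prof <- radial_substrate(tr$radius_mm[nrow(tr)], p2,
                               level = tr$delivery_level[nrow(tr)])
      sel <- prof$in_tumor
      w <- prof$r[sel]^2
      new_mean <- sum(prof$n[sel] * w) / sum(w)
      new_lam <- proliferation_rate(f_ki, new_mean, params$prolif_cycle_h)
      done <- abs(new_lam - lam_M) <= tol_rel * lam_M
      lam_M <- new_lam; mean_n <- new_mean
      if (done) break
    }
  }
  structure(list(lambda_M = lam_M, lambda_A = lam_A, A = lam_A / lam_M,
                 vascular_support = support, hypoxic_fraction = hyp,
                 mean_n = mean_n, iterations = iters,
                 stained = c(Ki67 = f_ki, Casp3 = f_ca, CD31 = f_cd,
                             HIF1a = f_hf)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("IHC calibration result\n")
  cat(sprintf("  lambda_M = %.3f /day  (<n> = %.3f)\n", x$lambda_M, x$mean_n))
  cat(sprintf("  lambda_A = %.3f /day   A = lambda_A/lambda_M = %.3f\n",
              x$lambda_A, x$A))
  cat(sprintf("  vascular support %.3f, hypoxic cell fraction %.4f\n",
              x$vascular_support, x$hypoxic_fraction))
  invisible(x)
}

#' Acceptance bands for the necrosis sweep derived from an IHC table
#'
#' Synthetic-fixture defaults (not measured ranges): the hypoxic-fraction
#' band spans the HIF-derived
#' hypoxic cell fractions of the core and periphery presets; the
#' apoptosis-rate band spans the Caspase-3-derived rates.
#'
#' @param tab an `ihc_table` (default: the baseline synthetic fixture,
#'   noise-free).
#' @return list with `hypoxic` and `apoptosis` range vectors.
#' @export
sweep_bands <- function(tab = synth_ihc(noise = FALSE)) {
  hb <- range(hypoxic_cell_fraction(
    c(stained_fraction(tab, "HIF1a", "core"),
      stained_fraction(tab, "HIF1a", "periphery"))))
  ab <- range(apoptosis_rate(
    c(stained_fraction(tab, "Casp3", "core"),
      stained_fraction(tab, "Casp3", "periphery"))))
  list(hypoxic = hb, apoptosis = ab)
}

#' Necrosis-rate calibration sweep
#'
#' For each candidate non-dimensional necrosis rate, runs the reduced model
#' at `n_init = 0.5` to its plateau, records the tumor hypoxic fraction and
#' the average apoptosis rate, and returns the contiguous set of rates whose
#' outputs fall inside both acceptance bands.  The accepted rates are then
#' re-run across an `n_init` grid to confirm the outputs stay in band.
#'
#' @param params baseline parameters.
#' @param lambda_N_grid candidate non-dimensional necrosis rates.
#' @param bands acceptance bands (`list(hypoxic=, apoptosis=)`), default
#'   derived from the synthetic IHC fixture via [sweep_bands()].
#' @param n_init_grid confirmation grid of initial nutrient levels (the
#'   sweep's base condition 0.5 is already measured, so the default re-checks
#'   the flanking levels).
#' @param t_max plateau search horizon per run (day).
#' @return a `necrosis_sweep` list: per-rate `results` data.frame, the
#'   `accepted` rates (possibly empty), `confirm` data.frame across the
#'   `n_init` grid, and the `bands`.
#' @export
necrosis_sweep <- function(params = model_parameters(),
                           lambda_N_grid = 1:10,
                           bands = sweep_bands(),
                           n_init_grid = c(0.3, 1.0),
                           t_max = 150) {
  run_one <- function(lamN, n_init) {
    p <- model_parameters_replace(params, lambda_N = lamN, n_init = n_init)
    pl <- reduced_plateau(p, t_max = t_max)
    data.frame(lambda_N = lamN, n_init = n_init,
               diameter_mm = 2 * pl$R,
               hypoxic_fraction = pl$fh,
               apoptosis_rate = params$lambda_A,
               viability = 1 - pl$f_D)
  }
  res <- do.call(rbind, lapply(lambda_N_grid, run_one, n_init = 0.5))
  inb <- res$hypoxic_fraction >= bands$hypoxic[1] &
    res$hypoxic_fraction <= bands$hypoxic[2] &
    res$apoptosis_rate >= bands$apoptosis[1] &
    res$apoptosis_rate <= bands$apoptosis[2]
  accepted <- lambda_N_grid[inb]
  # keep the contiguous run containing the interval (largest run if split)
  if (length(accepted)) {
    runs <- split(accepted, cumsum(c(1, diff(match(accepted, lambda_N_grid)) != 1)))
    accepted <- runs[[which.max(lengths(runs))]]
  }
  confirm <- NULL
  if (length(accepted)) {
    confirm <- do.call(rbind, lapply(accepted, function(lamN)
      do.call(rbind, lapply(n_init_grid, function(ni) run_one(lamN, ni)))))
  }
  structure(list(results = res, accepted = accepted, confirm = confirm,
                 bands = bands), class = "necrosis_sweep")
}

#' @export
print.necrosis_sweep <- function(x, ...) {
  cat("necrosis-rate sweep\n")
  print(x$results, row.names = FALSE)
  if (length(x$accepted))
    cat("accepted lambda_N interval: [", min(x$accepted), ",",
        max(x$accepted), "]\n")
  else cat("no lambda_N accepted by the bands\n")
  invisible(x)
}
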