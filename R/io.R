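# Trajectory CSV and VTK structured-points field output.

#' Write / read a growth trajectory as CSV
#'
#' Fixed column order, full float precision; round-trips exactly.
#' @param traj a `growth_trajectory` data.frame (or any data.frame).
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 17, trim = TRUE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("growth_trajectory", "data.frame")
  out
}

#' Write tissue-state fields as a legacy VTK structured-points file
#'
#' ASCII legacy VTK (`DATASET STRUCTURED_POINTS`), cell-centered values
#' written as point data with origin at the first cell center.  Values are
#' written with 17 significant digits so that [read_fields()] restores them
#' bit-exactly.
#'
#' @param state a `tissue_state`.
#' @param path output path (conventionally `.vtk`).
#' @param fields which state fields to write.
#' @export
write_fields <- function(state, path,
                         fields = c("rho_V", "rho_D", "rho_H", "f", "n",
                                    "n_V", "p")) {
  grid <- state$grid
  n3 <- c(grid$n, rep(1L, 3 - grid$dim))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("lymphosim fields day=%.6f", state$time),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n3[1], n3[2], n3[3]),
               sprintf("ORIGIN %.17g %.17g %.17g", grid$h / 2, grid$h / 2,
                       if (grid$dim == 3) grid$h / 2 else 0),
               sprintf("SPACING %.17g %.17g %.17g", grid$h, grid$h, grid$h),
               sprintf("POINT_DATA %d", prod(n3))), con)
  for (fld in fields) {
    writeLines(c(sprintf("SCALARS %s double 1", fld), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.17g", as.numeric(state[[fld]])), con)
  }
  invisible(path)
}

#' Read a legacy VTK structured-points file written by [write_fields()]
#'
#' @param path input path.
#' @return a list with `dims`, `spacing`, `time` (if recorded) and one array
#'   per scalar field.
#' @export
read_fields <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "",
                  lines[grep("^DIMENSIONS", lines)])), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "",
                  lines[grep("^SPACING", lines)])), "\\s+")[[1]])
  np <- prod(dims)
  tm <- NA_real_
  tline <- grep("day=", lines, value = TRUE)
  if (length(tline)) tm <- as.numeric(sub(".*day=", "", tline[1]))
  out <- list(dims = dims, spacing = spacing[1], time = tm)
  heads <- grep("^SCALARS", lines)
  for (hi in heads) {
    name <- strsplit(lines[hi], "\\s+")[[1]][2]
    vals <- as.numeric(lines[(hi + 2):(hi + 1 + np)])
    out[[name]] <- array(vals, dim = dims[dims > 1 | seq_along(dims) <= 2])
  }
  out
}
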