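# CSV interchange and visualization writers. CSV is the interchange format
# for this domain (no bioinformatics standard applies); legacy VTK is offered
# only for optional field visualization.

#' Write / read wall-shear profiles
#'
#' Columns: `z_m`, `tau_axial_Pa`, `tau_azimuthal_Pa`,
#' `tau_azimuthal_traction_Pa`, `tau_mag_Pa`.
#'
#' @param wss A `wall_shear_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a data.frame (reader).
#' @export
write_wss_csv <- function(wss, path) {
  stopifnot(inherits(wss, "wall_shear_profile"))
  utils::write.csv(wss$profile, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wss_csv
#' @export
read_wss_csv <- function(path) utils::read.csv(path)

#' Write / read deposition records
#'
#' Columns: `particle_id`, `fate`, `z_m`, `theta_deg`, `time_s`,
#' `path_length_m`. The reader restores the fate factor levels.
#'
#' @param run A `seeding_run` (or its records data.frame).
#' @param path CSV path.
#' @return `path`, invisibly (writer); a records data.frame (reader).
#' @export
write_records_csv <- function(run, path) {
  rec <- if (inherits(run, "seeding_run")) run$records else run
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  rec <- utils::read.csv(path)
  need <- c("particle_id", "fate", "z_m", "theta_deg", "time_s", "path_length_m")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop("records CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rec$fate <- factor(rec$fate, levels = c("trapped", "escaped", "incomplete"))
  rec
}

#' Write a deposition map as a dense matrix CSV
#'
#' One row per axial bin; first column `z_m`, remaining columns named
#' `theta_<mid>` carrying the deposition density fraction (or counts when the
#' map has no fraction).
#'
#' @param map A `deposition_map`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "deposition_map"))
  m <- if (!is.null(map$fraction_density)) map$fraction_density else map$counts
  df <- data.frame(z_m = map$z_mid, m)
  names(df) <- c("z_m", sprintf("theta_%g", map$theta_mid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write paired axial/circumferential profiles
#'
#' @param profiles A `deposition_profiles`.
#' @param path CSV path (long format: direction, position, fraction_density).
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  stopifnot(inherits(profiles, "deposition_profiles"))
  df <- rbind(
    data.frame(direction = "axial", position = profiles$axial$z_m,
               fraction_density = profiles$axial$fraction_density),
    data.frame(direction = "circumferential",
               position = profiles$circumferential$theta_deg,
               fraction_density = profiles$circumferential$fraction_density)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read punch sample sets
#'
#' Columns: `punch_id`, `z_m`, `theta_deg`, `count`, `replicate`, `seed`.
#' Real experimental counts in the same schema are accepted by the reader and
#' by [compare_punch_profiles()].
#'
#' @param samples A `punch_samples`.
#' @param path CSV path.
#' @param geometry Geometry used to rebuild the layout on read.
#' @return `path`, invisibly (writer); a `punch_samples` (reader).
#' @export
write_punches_csv <- function(samples, path) {
  stopifnot(inherits(samples, "punch_samples"))
  df <- samples$samples
  df$seed <- samples$seed
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_punches_csv
#' @export
read_punches_csv <- function(path, geometry = bioreactor_geometry()) {
  df <- utils::read.csv(path)
  need <- c("punch_id", "z_m", "theta_deg", "count", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("punch CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  zs <- sort(unique(df$z_m)); ts <- sort(unique(df$theta_deg))
  layout <- make_punch_layout(geometry, n_axial = length(zs), n_circ = length(ts))
  structure(list(samples = df[need], expected = NULL, layout = layout,
                 cells_per_particle = NA, dispersion = NA,
                 seed = if ("seed" %in% names(df)) df$seed[1] else NA,
                 noise = "external"),
            class = "punch_samples")
}

#' Export the flow field as a legacy-VTK structured grid
#'
#' ASCII legacy VTK (STRUCTURED_GRID) of the (r, z) plane swept over theta,
#' with point vectors (u_r = 0, azimuthal w, axial u_z) for visualization in
#' ParaView and friends.
#'
#' @param field A `flow_field`.
#' @param path Output `.vtk` path.
#' @param n_theta Number of azimuthal stations for the sweep.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(field, path, n_theta = 24) {
  stopifnot(inherits(field, "flow_field"))
  r <- field$r; z <- field$z
  th <- seq(0, 2 * pi, length.out = n_theta)
  nr <- length(r); nz <- length(z); nt <- length(th)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tracheoseed composite lumen flow field", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d %d", nr, nt, nz),
               sprintf("POINTS %d float", nr * nt * nz)), con)
  pts <- vel <- matrix(0, nr * nt * nz, 3)
  i <- 1L
  for (kz in seq_len(nz)) for (kt in seq_len(nt)) for (kr in seq_len(nr)) {
    x <- r[kr] * sin(th[kt]); y <- r[kr] * cos(th[kt])
    pts[i, ] <- c(x, y, z[kz])
    w <- field$w[kr, kz]
    vel[i, ] <- c(-w * cos(th[kt]), w * sin(th[kt]), field$uz[kr])
    # theta-hat at angle-from-top th is (cos th, -sin th); swirl w along it
    i <- i + 1L
  }
  utils::write.table(format(pts, scientific = TRUE, digits = 6), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("POINT_DATA %d", nr * nt * nz),
               "VECTORS velocity float"), con)
  utils::write.table(format(vel, scientific = TRUE, digits = 6), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
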