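#' Bin deposition records onto the unrolled lumen surface
#'
#' Bins trapped-particle wall contacts into an `n_z x n_theta` grid of
#' equal-area bins over `[0, L] x [0, 360)` degrees (uniform dz and dtheta on
#' a cylinder) and computes the surface density (count per m^2) and the
#' deposition density fraction: density divided by the total number trapped,
#' so that the surface integral of `fraction_density` is exactly 1.
#'
#' @param records A `seeding_run`, or its `records` data.frame.
#' @param geometry The lumen geometry (taken from the run when omitted).
#' @param n_z,n_theta Bin counts (defaults 50 x 36).
#' @param fraction Compute `fraction_density`? With zero trapped particles
#'   this errors ("no deposition"); set `fraction = FALSE` to still obtain
#'   the (all-zero) count/density map.
#' @return Object of class `deposition_map`: bin edges/mids, `counts`,
#'   `density`, `fraction_density` (all `n_z x n_theta`), `n_trapped`, and
#'   the run metadata.
#' @export
bin_deposition <- function(records, geometry = NULL, n_z = 50, n_theta = 36,
                           fraction = TRUE) {
  meta <- NULL
  if (inherits(records, "seeding_run")) {
    meta <- records[c("operating", "seed", "mode")]
    if (is.null(geometry)) geometry <- records$geometry
    records <- records$records
  }
  if (is.null(geometry)) stop("geometry required when passing bare records", call. = FALSE)
  L <- geometry$lumen_length
  R <- geometry$lumen_radius
  tr <- records[records$fate == "trapped", , drop = FALSE]
  n_trapped <- nrow(tr)
  if (fraction && n_trapped == 0) {
    stop("no deposition: zero trapped particles, fraction_density undefined; call with fraction = FALSE for the density map", call. = FALSE)
  }
  z_edges <- seq(0, L, length.out = n_z + 1)
  t_edges <- seq(0, 360, length.out = n_theta + 1)
  counts <- matrix(0L, n_z, n_theta)
  if (n_trapped > 0) {
    iz <- pmin(pmax(findInterval(tr$z_m, z_edges, rightmost.closed = TRUE), 1L), n_z)
    it <- pmin(pmax(findInterval(tr$theta_deg %% 360, t_edges,
                                 rightmost.closed = TRUE), 1L), n_theta)
    tab <- table(factor(iz, levels = seq_len(n_z)),
                 factor(it, levels = seq_len(n_theta)))
    counts <- matrix(as.integer(tab), n_z, n_theta)
  }
  bin_area <- (L / n_z) * (2 * pi * R / n_theta)
  density <- counts / bin_area
  structure(list(
    z_edges = z_edges, theta_edges = t_edges,
    z_mid = (z_edges[-1] + z_edges[-(n_z + 1)]) / 2,
    theta_mid = (t_edges[-1] + t_edges[-(n_theta + 1)]) / 2,
    counts = counts, density = density,
    fraction_density = if (n_trapped > 0) density / n_trapped else NULL,
    bin_area = bin_area, n_trapped = n_trapped,
    geometry = geometry, meta = meta
  ), class = "deposition_map")
}

#' @export
print.deposition_map <- function(x, ...) {
  cat(sprintf("<deposition_map> %d x %d bins, %d trapped particles\n",
              nrow(x$counts), ncol(x$counts), x$n_trapped))
  invisible(x)
}

#' Axial and circumferential deposition profiles
#'
#' Averages the deposition density fraction over the circumference at each
#' axial position (axial profile) and over the length at each circumferential
#' position (circumferential profile). Bins are equal-area, so unweighted bin
#' means reproduce per-position averaging.
#'
#' @param map A `deposition_map` with `fraction_density`.
#' @return Object of class `deposition_profiles`: data.frames `axial`
#'   (`z_m`, `fraction_density`) and `circumferential` (`theta_deg`,
#'   `fraction_density`).
#' @export
deposition_profiles <- function(map) {
  stopifnot(inherits(map, "deposition_map"))
  if (is.null(map$fraction_density)) {
    stop("map has no fraction_density (no deposition)", call. = FALSE)
  }
  structure(list(
    axial = data.frame(z_m = map$z_mid,
                       fraction_density = rowMeans(map$fraction_density)),
    circumferential = data.frame(theta_deg = map$theta_mid,
                                 fraction_density = colMeans(map$fraction_density))
  ), class = "deposition_profiles")
}

#' Deposition uniformity metrics
#'
#' Quantifies the qualitative uniformity language used for seeding outcomes:
#' coefficients of variation (sd/mean) of the circumferential and axial
#' profiles, the axial centroid as a fraction of scaffold length
#' (0.5 = uniform), and the fraction of trapped particles in the proximal
#' half (z < L/2).
#'
#' @param map A `deposition_map`.
#' @return Named list: `cv_circumferential`, `cv_axial`,
#'   `axial_centroid_fraction`, `proximal_half_fraction`.
#' @export
uniformity_metrics <- function(map) {
  stopifnot(inherits(map, "deposition_map"))
  pr <- deposition_profiles(map)
  ax <- pr$axial$fraction_density
  ci <- pr$circumferential$fraction_density
  if (mean(ax) == 0 || mean(ci) == 0) {
    stop("zero-mean profile: uniformity metrics undefined", call. = FALSE)
  }
  L <- map$geometry$lumen_length
  prox <- sum(map$counts[map$z_mid < L / 2, ]) / map$n_trapped
  list(
    cv_circumferential = stats::sd(ci) / mean(ci),
    cv_axial = stats::sd(ax) / mean(ax),
    axial_centroid_fraction = sum(map$z_mid * ax) / (L * sum(ax)),
    proximal_half_fraction = prox
  )
}

#' Compare deposition between the two inlet designs
#'
#' Pairs maps from identical operating conditions (rpm and flow rate must
#' match) and reports profile deltas and metric differences, flagging which
#' design is more axially uniform.
#'
#' @param map_single,map_double `deposition_map`s from the single-rotating and
#'   double-static designs at the same operating point.
#' @return Object of class `design_comparison`: `metrics` data.frame (one row
#'   per design plus a delta row), paired `axial` profiles, and
#'   `more_axially_uniform` (design name).
#' @export
design_compare <- function(map_single, map_double) {
  stopifnot(inherits(map_single, "deposition_map"),
            inherits(map_double, "deposition_map"))
  o1 <- map_single$meta$operating; o2 <- map_double$meta$operating
  if (is.null(o1) || is.null(o2)) {
    stop("maps must carry run metadata (build them from seeding_run objects)",
         call. = FALSE)
  }
  if (abs(o1$rpm - o2$rpm) > 1e-12 ||
      abs(o1$flow_rate - o2$flow_rate) > 1e-18) {
    stop("maps come from mismatched operating conditions", call. = FALSE)
  }
  m1 <- uniformity_metrics(map_single)
  m2 <- uniformity_metrics(map_double)
  metrics <- rbind(
    data.frame(design = "single_rotating", as.data.frame(m1)),
    data.frame(design = "double_static", as.data.frame(m2)),
    data.frame(design = "delta (double - single)",
               as.data.frame(Map(function(a, b) b - a, m1, m2)))
  )
  p1 <- deposition_profiles(map_single)$axial
  p2 <- deposition_profiles(map_double)$axial
  structure(list(
    metrics = metrics,
    axial = data.frame(z_m = p1$z_m, single = p1$fraction_density,
                       double = p2$fraction_density),
    more_axially_uniform = if (m1$cv_axial <= m2$cv_axial) "single_rotating" else "double_static"
  ), class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  print(x$metrics)
  cat("more axially uniform design:", x$more_axially_uniform, "\n")
  invisible(x)
}
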