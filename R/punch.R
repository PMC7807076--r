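#' Bio-punch sampling layout on the unrolled lumen surface
#'
#' Places an `n_axial x n_circ` grid of equally spaced punch centres over the
#' unrolled surface `[0, L] x [0, 360)`, emulating the validation protocol of
#' 25 equally spaced 6-mm bio-punches over a 5-cm scaffold. Punches must be
#' pairwise disjoint and lie fully inside the surface in z.
#'
#' @param geometry Lumen geometry.
#' @param n_axial,n_circ Grid dimensions (defaults 5 x 5).
#' @param diameter Punch diameter in m (default 6e-3).
#' @param shape `"disk"` (a circular bio-punch) or `"rect"` (rectangular
#'   cells; with `diameter` ignored the cells tile the whole surface exactly,
#'   used for conservation checks).
#' @return Object of class `punch_layout`: data.frame `punches` (punch_id,
#'   z_m, theta_deg) plus layout parameters.
#' @export
make_punch_layout <- function(geometry = bioreactor_geometry(),
                              n_axial = 5, n_circ = 5, diameter = 6e-3,
                              shape = c("disk", "rect")) {
  shape <- match.arg(shape)
  L <- geometry$lumen_length
  R <- geometry$lumen_radius
  dz <- L / n_axial
  arc <- 2 * pi * R / n_circ
  if (shape == "disk") {
    if (diameter > dz) {
      stop(sprintf("punches overlap axially: diameter %.3g m > axial spacing %.3g m",
                   diameter, dz), call. = FALSE)
    }
    if (diameter > arc) {
      stop(sprintf("punches overlap circumferentially: diameter %.3g m > arc spacing %.3g m",
                   diameter, arc), call. = FALSE)
    }
    if (diameter / 2 > dz / 2) {
      stop("punches exceed the scaffold length", call. = FALSE)
    }
  }
  centres <- expand.grid(
    z_m = (seq_len(n_axial) - 0.5) * dz,
    theta_deg = (seq_len(n_circ) - 0.5) * 360 / n_circ
  )
  punches <- data.frame(punch_id = seq_len(nrow(centres)), centres)
  structure(list(punches = punches, n_axial = n_axial, n_circ = n_circ,
                 diameter = diameter, shape = shape, geometry = geometry),
            class = "punch_layout")
}

#' @export
print.punch_layout <- function(x, ...) {
  cat(sprintf("<punch_layout> %d x %d %s punches, diameter %.1f mm\n",
              x$n_axial, x$n_circ, x$shape, x$diameter * 1e3))
  invisible(x)
}

# Integral of fraction_density over one punch footprint (m^-2 * m^2 -> pure
# fraction). Disks use a fixed tensor quadrature; rects use exact bin-overlap.
punch_fraction_integral <- function(map, z0, theta0, layout) {
  R <- map$geometry$lumen_radius
  L <- map$geometry$lumen_length
  fd <- map$fraction_density
  nz <- nrow(fd); nt <- ncol(fd)
  dzb <- L / nz; dtb <- 360 / nt
  lookup <- function(z, th) {
    iz <- pmin(pmax(ceiling(z / dzb), 1L), nz)
    it <- pmin(pmax(ceiling((th %% 360) / dtb), 1L), nt)
    fd[cbind(iz, it)]
  }
  if (layout$shape == "rect") {
    # exact integral of the piecewise-constant map over an axis-aligned cell
    zlo <- z0 - L / layout$n_axial / 2; zhi <- z0 + L / layout$n_axial / 2
    tlo <- theta0 - 180 / layout$n_circ; thi <- theta0 + 180 / layout$n_circ
    ze <- map$z_edges; te <- map$theta_edges
    ov <- function(alo, ahi, blo, bhi) pmax(0, pmin(ahi, bhi) - pmax(alo, blo))
    wz <- ov(ze[-length(ze)], ze[-1], zlo, zhi)
    wt <- ov(te[-length(te)], te[-1], tlo %% 360, thi %% 360)
    # handle a cell wrapping past 360
    if (thi > 360) wt <- wt + ov(te[-length(te)], te[-1], 0, thi - 360)
    if (tlo < 0) wt <- wt + ov(te[-length(te)], te[-1], 360 + tlo, 360)
    sum((wz %o% (wt * pi * R / 180)) * fd)
  } else {
    # equal-area polar quadrature over the punch disk (z along the axis,
    # arc length around it): cells tile the disk exactly, so a uniform map
    # integrates exactly to fraction * area
    a <- layout$diameter / 2
    ns <- 16L; na <- 32L
    rq <- a * sqrt((rep(seq_len(ns), each = na) - 0.5) / ns)
    aq <- 2 * pi * (rep(seq_len(na), times = ns) - 0.5) / na
    zq <- z0 + rq * cos(aq)
    tq <- theta0 + (rq * sin(aq) / R) * 180 / pi
    cell <- pi * a^2 / (ns * na)
    sum(lookup(pmin(pmax(zq, 0), L), tq)) * cell
  }
}

#' Synthesize bio-punch cell counts from a deposition map
#'
#' Emulates the validation measurement: the expected cell count in each punch
#' is the deposition density fraction integrated over the punch footprint,
#' times the total deposited cell count (`n_trapped * cells_per_particle`).
#' Observed counts are drawn negative-binomially around that expectation with
#' dispersion `k` (variance `mu + mu^2/k`), modelling cell clumping --- the
#' dominant unmodelled experimental effect; `k = Inf` gives Poisson counting
#' noise, and `noise = "none"` returns the (unrounded) expectations.
#'
#' @param map A `deposition_map` with `fraction_density`.
#' @param layout A `punch_layout`.
#' @param cells_per_particle Cells represented by one simulated particle.
#' @param dispersion Negative-binomial dispersion k (> 0, or `Inf`).
#' @param n_replicates Number of replicate sample sets.
#' @param seed Integer seed; identical seeds give identical sample sets.
#' @param noise `"nb"` (default) or `"none"`.
#' @return Object of class `punch_samples`: data.frame `samples` (punch_id,
#'   z_m, theta_deg, count, replicate) plus generator parameters.
#' @export
synthesize_punch_counts <- function(map, layout = make_punch_layout(map$geometry),
                                    cells_per_particle = 100,
                                    dispersion = 5, n_replicates = 1, seed = 1,
                                    noise = c("nb", "none")) {
  noise <- match.arg(noise)
  stopifnot(inherits(map, "deposition_map"), inherits(layout, "punch_layout"))
  if (is.null(map$fraction_density) || map$n_trapped == 0) {
    stop("empty map: cannot synthesize punch counts", call. = FALSE)
  }
  if (!is.infinite(dispersion) && dispersion <= 0) {
    stop("dispersion k must be > 0", call. = FALSE)
  }
  p <- layout$punches
  total <- map$n_trapped * cells_per_particle
  expected <- vapply(seq_len(nrow(p)), function(i) {
    total * punch_fraction_integral(map, p$z_m[i], p$theta_deg[i], layout)
  }, numeric(1))
  draw <- function() {
    if (noise == "none") return(expected)
    if (is.infinite(dispersion)) return(stats::rpois(length(expected), expected))
    stats::rnbinom(length(expected), size = dispersion, mu = expected)
  }
  samples <- with_seed(seed, do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
    data.frame(punch_id = p$punch_id, z_m = p$z_m, theta_deg = p$theta_deg,
               count = draw(), replicate = rep)
  })))
  structure(list(samples = samples, expected = expected, layout = layout,
                 cells_per_particle = cells_per_particle,
                 dispersion = dispersion, seed = seed, noise = noise),
            class = "punch_samples")
}

#' @export
print.punch_samples <- function(x, ...) {
  cat(sprintf("<punch_samples> %d punches x %d replicate(s), k = %g, seed %d\n",
              nrow(x$layout$punches), max(x$samples$replicate), x$dispersion,
              x$seed))
  invisible(x)
}

#' Compare a simulated deposition map against punch samples
#'
#' Converts punch counts to punch-level density fractions (count per punch
#' area divided by the total count over all punches) and builds the paired
#' axial (mean over punch columns at each z) and circumferential (mean over
#' punch rows at each theta) profiles for both the samples and the map (the
#' map is integrated over the same punch footprints and renormalized over the
#' layout). Reports, per direction, the mean absolute fraction-density
#' difference and the Spearman rank correlation.
#'
#' Punch samples may come from [synthesize_punch_counts()] or from a real
#' experiment read with [read_punches_csv()]; the comparison is
#' source-agnostic.
#'
#' @param map A `deposition_map`.
#' @param samples A `punch_samples` (replicates are averaged).
#' @return Object of class `punch_comparison`: `axial` and `circumferential`
#'   data.frames (position, sim, obs), and `stats` with `mean_abs_diff` and
#'   `rank_correlation` per direction.
#' @export
compare_punch_profiles <- function(map, samples) {
  stopifnot(inherits(map, "deposition_map"), inherits(samples, "punch_samples"))
  layout <- samples$layout
  p <- layout$punches
  area <- if (layout$shape == "disk") pi * (layout$diameter / 2)^2 else {
    (map$geometry$lumen_length / layout$n_axial) *
      (2 * pi * map$geometry$lumen_radius / layout$n_circ)
  }
  obs_counts <- stats::aggregate(count ~ punch_id, data = samples$samples, FUN = mean)
  obs <- obs_counts$count[order(obs_counts$punch_id)]
  if (all(obs == 0)) stop("all punch counts are zero: nothing to compare", call. = FALSE)
  obs_f <- obs / area / sum(obs)
  sim_int <- vapply(seq_len(nrow(p)), function(i) {
    punch_fraction_integral(map, p$z_m[i], p$theta_deg[i], layout)
  }, numeric(1))
  sim_f <- sim_int / area / sum(sim_int)
  prof <- function(pos, v) {
    agg <- stats::aggregate(v, list(pos = pos), FUN = mean)
    agg[order(agg$pos), ]
  }
  ax_obs <- prof(p$z_m, obs_f); ax_sim <- prof(p$z_m, sim_f)
  ci_obs <- prof(p$theta_deg, obs_f); ci_sim <- prof(p$theta_deg, sim_f)
  rk <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    suppressWarnings(stats::cor(a, b, method = "spearman"))
  }
  structure(list(
    axial = data.frame(z_m = ax_sim$pos, sim = ax_sim$x, obs = ax_obs$x),
    circumferential = data.frame(theta_deg = ci_sim$pos, sim = ci_sim$x,
                                 obs = ci_obs$x),
    stats = data.frame(
      direction = c("axial", "circumferential"),
      mean_abs_diff = c(mean(abs(ax_sim$x - ax_obs$x)),
                        mean(abs(ci_sim$x - ci_obs$x))),
      rank_correlation = c(rk(ax_sim$x, ax_obs$x), rk(ci_sim$x, ci_obs$x))
    )
  ), class = "punch_comparison")
}

#' @export
print.punch_comparison <- function(x, ...) {
  print(x$stats)
  invisible(x)
}
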