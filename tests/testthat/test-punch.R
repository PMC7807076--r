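test_that("punch layout geometry: 25 equally spaced punches fit the scaffold", {
  lay <- make_punch_layout()
  expect_equal(nrow(lay$punches), 25)
  expect_equal(sort(unique(lay$punches$z_m)), (1:5 - 0.5) * 0.01)
  expect_equal(sort(unique(lay$punches$theta_deg)), (1:5 - 0.5) * 72)
  # fully inside the surface in z
  expect_true(all(lay$punches$z_m - 3e-3 >= 0))
  expect_true(all(lay$punches$z_m + 3e-3 <= 0.05))

  one <- make_punch_layout(n_axial = 1, n_circ = 1)
  expect_equal(one$punches$z_m, 0.025)

  # 2*pi*R/5 = 7.98 mm arc spacing: an 8.5 mm punch overlaps
  expect_error(make_punch_layout(diameter = 8.5e-3), "overlap")
  expect_error(make_punch_layout(n_axial = 10, diameter = 6e-3), "overlap")
})

test_that("expected punch counts: uniform map gives the area-ratio formula", {
  m <- bin_deposition(ts_uniform_records(), bioreactor_geometry())
  s <- synthesize_punch_counts(m, cells_per_particle = 100, noise = "none")
  expected <- m$n_trapped * 100 * pi * (3e-3)^2 / (2 * pi * 6.35e-3 * 0.05)
  expect_equal(unname(s$samples$count), rep(expected, 25), tolerance = 5e-3)
})

test_that("exhaustive rectangular layout conserves the deposited cell total", {
  map <- ts_map("single_rotating", 0, 1)
  lay <- make_punch_layout(n_axial = 10, n_circ = 12, shape = "rect")
  s <- synthesize_punch_counts(map, lay, cells_per_particle = 100, noise = "none")
  expect_equal(sum(s$samples$count), map$n_trapped * 100, tolerance = 1e-9)
})

test_that("counting noise: determinism, Poisson limit, and clumping overdispersion", {
  m <- bin_deposition(ts_uniform_records(), bioreactor_geometry())
  s1 <- synthesize_punch_counts(m, dispersion = 5, seed = 3)
  s2 <- synthesize_punch_counts(m, dispersion = 5, seed = 3)
  expect_identical(s1$samples, s2$samples)
  expect_true(all(s1$samples$count >= 0))
  expect_true(all(s1$samples$count == round(s1$samples$count)))

  # k -> Inf: Poisson, relative deviation ~ 1/sqrt(expected)
  sp <- synthesize_punch_counts(m, dispersion = Inf, seed = 4, n_replicates = 40)
  ratio <- mean(sp$samples$count) / mean(sp$expected)
  expect_lt(abs(ratio - 1), 4 / sqrt(sum(sp$expected) * 40 / 25))

  # strong clumping (k = 0.5) inflates the variance over k = 50 (NB law
  # var = mu + mu^2/k), checked empirically over 1000 draws per punch
  s_lo <- synthesize_punch_counts(m, dispersion = 0.5, seed = 5, n_replicates = 1000)
  s_hi <- synthesize_punch_counts(m, dispersion = 50, seed = 5, n_replicates = 1000)
  v_lo <- stats::var(s_lo$samples$count[s_lo$samples$punch_id == 1])
  v_hi <- stats::var(s_hi$samples$count[s_hi$samples$punch_id == 1])
  expect_gt(v_lo, v_hi)
  mu <- s_lo$expected[1]
  expect_equal(v_lo, mu + mu^2 / 0.5, tolerance = 0.15)

  expect_error(synthesize_punch_counts(m, dispersion = 0), "k must be")
})

test_that("comparison stage: noise-free identity and reversed-profile detection", {
  map <- ts_map("single_rotating", 0, 1)
  s0 <- synthesize_punch_counts(map, noise = "none")
  cmp <- compare_punch_profiles(map, s0)
  expect_equal(cmp$stats$mean_abs_diff, c(0, 0), tolerance = 1e-9)

  # reversing a monotone profile in z flips the axial rank correlation
  rec <- ts_uniform_records()
  rec <- rec[rep(seq_len(nrow(rec)), times = ceiling(rec$z_m / (0.05 / 50))), ]
  rec$particle_id <- seq_len(nrow(rec))
  mono <- bin_deposition(rec, bioreactor_geometry())
  sm <- synthesize_punch_counts(mono, noise = "none")
  expect_equal(compare_punch_profiles(mono, sm)$stats$rank_correlation[1], 1)
  p <- sm$layout$punches
  mirror <- match(paste(0.05 - p$z_m, p$theta_deg), paste(p$z_m, p$theta_deg))
  srev <- sm
  srev$samples$count <- sm$samples$count[mirror]
  cmp_rev <- compare_punch_profiles(mono, srev)
  expect_lte(cmp_rev$stats$rank_correlation[1], 0)

  zeros <- s0
  zeros$samples$count <- 0
  expect_error(compare_punch_profiles(map, zeros), "zero")
})

test_that("profiles estimated from synthetic punches converge with replicates", {
  map <- ts_map("single_rotating", 0, 1)
  mad_of <- function(reps, seed) {
    s <- synthesize_punch_counts(map, dispersion = 5, n_replicates = reps,
                                 seed = seed)
    compare_punch_profiles(map, s)$stats$mean_abs_diff[1]
  }
  m1 <- mean(sapply(1:3, function(s) mad_of(1, s)))
  m100 <- mean(sapply(1:3, function(s) mad_of(100, s)))
  expect_lt(m100, m1)
})

test_that("punch CSVs round-trip and external counts are accepted", {
  map <- ts_map("single_rotating", 0, 1)
  s <- synthesize_punch_counts(map, dispersion = 5, seed = 9, n_replicates = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_punches_csv(s, path)
  s2 <- read_punches_csv(path)
  expect_equal(s2$samples$count, s$samples$count)
  cmp <- compare_punch_profiles(map, s2)
  expect_equal(nrow(cmp$axial), 5)
})
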