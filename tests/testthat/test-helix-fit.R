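test_that("radius estimation is exact on noise-free shells and robust to decoys", {
  ax <- straight_axis_df(2000)
  set.seed(3)
  p <- cyl_particles(s = runif(1000, 0, 2000), phi_deg = runif(1000, -180, 180),
                     r = 140)
  est <- estimate_radius(p, ax)
  expect_equal(est$radius_A, 140, tolerance = 1e-9)
  expect_gte(est$radius_sd_A, 0)

  # 10% decoys at r = 210 barely move the median
  pd <- cyl_particles(s = runif(100, 0, 2000), phi_deg = runif(100, -180, 180),
                      r = 210)
  pd$particle_id <- sprintf("d%05d", 1:100)
  est2 <- estimate_radius(dplyr::bind_rows(p, pd), ax)
  expect_lt(abs(est2$radius_A - 140), 2)

  # noisy shell: within 1 A of truth
  pn <- p
  pn$x_A <- pn$x_A + rnorm(1000, 0, 5)
  pn$y_A <- pn$y_A + rnorm(1000, 0, 5)
  pn$z_A <- pn$z_A + rnorm(1000, 0, 5)
  expect_lt(abs(estimate_radius(pn, ax)$radius_A - 140), 1)

  expect_error(estimate_radius(p[1:5, ], ax), class = "coat_insufficient_data")
})

test_that("noise-free lattices are recovered exactly for 1 to 5 starts", {
  cfg <- short_noiseless()
  for (n in 1:5) {
    cfg_n <- short_noiseless(starts_distribution = stats::setNames(
      as.numeric(1:5 == n), 1:5))
    ds <- simulate_dataset(cfg_n, n_tubes = 10, seed = 100 + n)
    fit <- fit_helix(ds$particles, ds$axes)
    expect_true(all(fit$n_starts == n), label = sprintf("n = %d", n))
    expect_recovers_helix(fit, ds$helices)
  }
})

test_that("noisy lattices are recovered within tolerance", {
  # sigma_pos 5 A, sigma_ang 5 deg, full-length tubes (generator defaults)
  cfg <- generator_config()
  ds <- simulate_dataset(cfg, n_tubes = 60, seed = 77)
  fit <- fit_helix(ds$particles, ds$axes)
  m <- match(fit$tube_id, ds$helices$tube_id)
  expect_gte(mean(fit$n_starts == ds$helices$n_starts[m]), 0.98)
  ok <- fit$n_starts == ds$helices$n_starts[m]
  expect_lt(max(abs(fit$radius_A - ds$helices$radius_A[m])), 1)
  expect_lt(max(abs(fit$pitch_A[ok] / ds$helices$pitch_A[m][ok] - 1)), 0.02)
  expect_true(all(fit$handedness[ok] == ds$helices$handedness[m][ok]))
})

test_that("handedness flips under mirror reflection and with left-handed lattices", {
  cfg <- short_noiseless()
  ds <- simulate_dataset(cfg, n_tubes = 2, seed = 55)
  fit <- fit_helix(ds$particles, ds$axes)
  expect_true(all(fit$handedness == 1))
  # mirror everything through the xy plane
  pm <- dplyr::mutate(ds$particles, z_A = -z_A)
  am <- dplyr::mutate(ds$axes, z_A = -z_A)
  fm <- fit_helix(pm, am)
  expect_true(all(fm$handedness == -1))
  expect_equal(fm$n_starts, fit$n_starts)
  expect_equal(fm$pitch_A, fit$pitch_A, tolerance = 1e-3)
  # generator with handedness -1
  dsl <- simulate_dataset(short_noiseless(handedness = -1), 2, seed = 56)
  expect_true(all(fit_helix(dsl$particles, dsl$axes)$handedness == -1))
})

test_that("detection is invariant under rigid motion of the whole tube", {
  cfg <- short_noiseless()
  ds <- simulate_dataset(cfg, n_tubes = 1, seed = 60)
  f1 <- detect_starts(ds$particles, ds$axes)
  Rm <- euler_to_matrix(35, 55, 10)
  tr <- c(1000, -500, 300)
  rot <- function(df) {
    P <- as.matrix(df[, c("x_A", "y_A", "z_A")]) %*% t(Rm)
    df$x_A <- P[, 1] + tr[1]; df$y_A <- P[, 2] + tr[2]; df$z_A <- P[, 3] + tr[3]
    df
  }
  f2 <- detect_starts(rot(ds$particles), rot(ds$axes))
  expect_equal(f2$n_starts, f1$n_starts)
  expect_equal(f2$handedness, f1$handedness)
  expect_equal(f2$pitch_A, f1$pitch_A, tolerance = 1e-4)
})

test_that("derived lead angle and per-particle twist follow the closed forms", {
  cfg <- short_noiseless()
  ds <- simulate_dataset(cfg, n_tubes = 3, seed = 65)
  fit <- fit_helix(ds$particles, ds$axes)
  # lead angle = atan(P / (2 pi R))
  expect_equal(fit$lead_angle_deg,
               atan(fit$pitch_A / (2 * pi * fit$radius_A)) * 180 / pi,
               tolerance = 1e-9)
  # twist per particle = a cos(theta) / R, in degrees; against the direct
  # angle between successive noise-free particles about the axis
  m <- match(fit$tube_id, ds$helices$tube_id)
  tr <- ds$helices[m, ]
  expected_twist <- tr$handedness *
    (tr$a_A * cos(tr$lead_angle_deg * pi / 180) / tr$radius_A) * 180 / pi
  expect_equal(fit$twist_per_particle_deg, expected_twist, tolerance = 0.02)
})

test_that("an isotropic point cloud raises no-lattice-detected", {
  ax <- straight_axis_df(2000)
  set.seed(4)
  p <- cyl_particles(s = runif(400, 0, 2000), phi_deg = runif(400, -180, 180),
                     r = 140 + rnorm(400, 0, 20))
  expect_error(detect_starts(p, ax), class = "coat_no_lattice")
})

test_that("tidy and glance summarize helix fits broom-style", {
  cfg <- short_noiseless()
  ds <- simulate_dataset(cfg, n_tubes = 2, seed = 70)
  fit <- fit_helix(ds$particles, ds$axes)
  td <- tidy(fit)
  expect_true(all(c("tube_id", "term", "estimate", "std.error") %in% names(td)))
  expect_setequal(unique(td$tube_id), fit$tube_id)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_tubes, 2)
})
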