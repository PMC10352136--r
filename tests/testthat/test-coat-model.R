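test_that("expand_helix replicates the asymmetric unit with helical operators", {
  hel <- list(n_starts = 3, twist_per_particle_deg = 20.3,
              rise_per_particle_A = 10.5)
  unit <- tibble::tibble(chain = "A", x_A = 158.5, y_A = 0, z_A = 0)
  # identity expansion
  e1 <- expand_helix(unit, list(n_starts = 1, twist_per_particle_deg = 20,
                                rise_per_particle_A = 10), n_steps = 1)
  expect_equal(nrow(e1$atoms), 1)
  expect_equal(e1$atoms$x_A, unit$x_A)
  # 3 starts x 10 steps = 30 copies, uniquified chains
  e30 <- expand_helix(unit, hel, n_steps = 10)
  expect_equal(nrow(e30$atoms), 30)
  expect_equal(length(unique(e30$atoms$chain)), 30)
  expect_error(expand_helix(unit, hel, n_steps = 1000, max_copies = 100),
               class = "coat_size_error")
})

test_that("expand_helix then fit_helix is the identity on the helix model", {
  cfg <- short_noiseless()
  h <- coatlattice:::helix_from_lattice(cfg, 3)
  hel <- list(n_starts = 3,
              twist_per_particle_deg = (h$a_A * cos(h$lead_angle_deg * pi / 180) /
                                          h$radius_A) * 180 / pi,
              rise_per_particle_A = h$a_A * sin(h$lead_angle_deg * pi / 180))
  ex <- expand_helix(tibble::tibble(x_A = h$radius_A, y_A = 0, z_A = 0),
                     hel, n_steps = 40)
  p <- tibble::tibble(tube_id = "t", particle_id = sprintf("p%03d", 1:nrow(ex$atoms)),
                      x_A = ex$atoms$x_A, y_A = ex$atoms$y_A, z_A = ex$atoms$z_A)
  ax <- tibble::tibble(tube_id = "t", point_index = 1:2, x_A = 0, y_A = 0,
                       z_A = c(-50, max(p$z_A) + 50))
  fit <- fit_helix(p, ax)
  expect_equal(fit$n_starts, 3L)
  expect_lt(abs(fit$radius_A - h$radius_A), 0.1)
  expect_lt(abs(fit$pitch_A / h$pitch_A - 1), 0.001)
  expect_equal(fit$handedness, 1)
})

test_that("circle fit is exact on circles, noise-tolerant, and rigid-motion invariant", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  pts <- cbind(x_A = 160 * cos(th) + 7, y_A = 160 * sin(th) - 4, z_A = 3)
  f <- fit_curvature_circle(pts)
  expect_equal(f$radius_A, 160, tolerance = 1e-9)
  expect_equal(f$diameter_nm, 32, tolerance = 1e-9)
  expect_lt(f$rms_residual_A, 1e-9)

  set.seed(2)
  noisy <- pts + matrix(rnorm(length(pts), 0, 2), nrow(pts), 3)
  fn <- fit_curvature_circle(noisy)
  expect_lt(abs(fn$radius_A - 160), 2)

  Rm <- euler_to_matrix(25, 65, 110)
  moved <- t(Rm %*% t(pts)) + matrix(c(100, -50, 80), nrow(pts), 3, byrow = TRUE)
  expect_equal(fit_curvature_circle(moved)$radius_A, 160, tolerance = 1e-9)

  # a partial arc (BAR-dimer-like, ~1/6 of a turn) still yields the radius
  arc <- cbind(x_A = 160 * cos(th[th < pi / 3]), y_A = 160 * sin(th[th < pi / 3]),
               z_A = 0)
  expect_equal(fit_curvature_circle(arc)$radius_A, 160, tolerance = 1e-6)

  expect_error(fit_curvature_circle(cbind(x_A = 1:5, y_A = 2 * (1:5),
                                          z_A = 3 * (1:5))),
               class = "coat_degenerate_input")
})

test_that("Shrake-Rupley SASA matches closed forms", {
  # isolated atom: 4 pi (r + probe)^2
  a1 <- tibble::tibble(element = "C", chain = "A", x_A = 0, y_A = 0, z_A = 0,
                       radius_A = 1.7)
  s1 <- sasa_atoms(a1, probe_A = 1.4, n_points = 960)
  expect_equal(s1$sasa_A2, 4 * pi * 3.1^2, tolerance = 1e-9)

  # two identical atoms 3.0 A apart: analytic spherical-cap occlusion
  re <- 1.7 + 1.4
  d <- 3.0
  cap <- 2 * pi * re * (re - d / 2)
  a2 <- tibble::tibble(element = "C", chain = c("A", "B"), x_A = c(0, d),
                       y_A = 0, z_A = 0, radius_A = 1.7)
  s2 <- sasa_atoms(a2, 1.4, 960)
  expect_lt(abs(s2$sasa_A2[1] / (4 * pi * re^2 - cap) - 1), 0.01)

  # quadrature convergence on a random 100-atom toy
  set.seed(6)
  toy <- tibble::tibble(element = sample(c("C", "N", "O"), 100, TRUE),
                        chain = "A",
                        x_A = runif(100, 0, 20), y_A = runif(100, 0, 20),
                        z_A = runif(100, 0, 20))
  toy$radius_A <- vdw_radii()[toy$element]
  lo <- sasa_atoms(toy, 1.4, 960)$sasa_A2
  hi <- sasa_atoms(toy, 1.4, 3840)$sasa_A2
  expect_lt(max(abs(lo - hi)), 0.01 * 4 * pi * 3.2^2)

  expect_error(sasa_atoms(dplyr::mutate(a1, radius_A = 0), 1.4, 960),
               class = "coat_invalid_input")
})

test_that("interface metrics: burial is symmetric, non-negative, zero when apart", {
  re <- 1.7 + 1.4
  d <- 3.0
  cap <- 2 * pi * re * (re - d / 2)
  two <- tibble::tibble(element = c("C", "N"), chain = c("A", "B"),
                        x_A = c(0, d), y_A = 0, z_A = 0, radius_A = 1.7)
  im <- interface_metrics(two, "A", "B")
  expect_lt(abs(im$buried_area_A2 / (2 * cap) - 1), 0.01)
  im_swap <- interface_metrics(two, "B", "A")
  expect_equal(im_swap$buried_area_A2, im$buried_area_A2, tolerance = 1e-9)
  # polar fraction: the N atom contributes half the buried area here
  expect_equal(im$polar_fraction, 0.5, tolerance = 0.02)

  apart <- dplyr::mutate(two, x_A = c(0, 100))
  expect_equal(interface_metrics(apart, "A", "B")$buried_area_A2, 0)

  expect_error(interface_metrics(two, "A", "A"), class = "coat_invalid_input")
})
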