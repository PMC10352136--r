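qc_fixture <- function(n_tubes = 4, seed = 23, outlier_rate = 0.05,
                       dropout_rate = 0, ...) {
  cfg <- short_noisy(outlier_rate = outlier_rate, dropout_rate = dropout_rate, ...)
  ds <- simulate_dataset(cfg, n_tubes = n_tubes, seed = seed)
  ds$fit <- fit_helix(ds$particles, ds$axes)
  ds
}

test_that("a clean noise-free lattice has no flags on interior particles", {
  cfg <- short_noiseless(cc_model = list(mean_true = 0.5, mean_outlier = 0.1,
                                         sd = 0))  # constant cc
  ds <- simulate_dataset(cfg, n_tubes = 2, seed = 41)
  fit <- fit_helix(ds$particles, ds$axes)
  qc <- apply_qc(ds$particles, ds$axes, fit)
  # interior = particles with both along-strand neighbors inside the tube
  expect_equal(qc$summary$extreme_radius, 0L)
  expect_equal(qc$summary$extreme_angle, 0L)
  expect_equal(qc$summary$low_cc, 0L)
  expect_equal(qc$summary$missing_neighbor, 0L)
})

test_that("a particle displaced to 1.5 radius is flagged extreme_radius", {
  cfg <- short_noiseless(cc_model = list(mean_true = 0.5, mean_outlier = 0.1, sd = 0))
  ds <- simulate_dataset(cfg, n_tubes = 1, seed = 42)
  fit <- fit_helix(ds$particles, ds$axes)
  p <- ds$particles
  u <- unroll_particles(p, ds$axes)
  k <- which.min(abs(u$s_A - median(u$s_A)))[1]
  u$r_A[k] <- 1.5 * fit$radius_A
  p2 <- roll_particles(u, ds$axes)
  qc <- apply_qc(p2, ds$axes, fit)
  expect_true(qc$flags$extreme_radius[k])
  expect_false(p2$particle_id[k] %in% qc$particles$particle_id)
})

test_that("injected outliers are flagged and clean particles spared", {
  ds <- qc_fixture(n_tubes = 6, outlier_rate = 0.05, dropout_rate = 0)
  qc <- apply_qc(ds$particles, ds$axes, ds$fit)
  lab <- ds$truth$label[match(ds$particles$particle_id, ds$truth$particle_id)]
  any_flag <- !(ds$particles$particle_id %in% qc$particles$particle_id)
  expect_gte(mean(any_flag[lab == "outlier"]), 0.95)
  # with zero dropout every clean particle has its along-strand neighbors
  # (strand-terminal sides are exempt), so false flags should be rare
  expect_lte(mean(any_flag[lab == "lattice"]), 0.01 + 1e-9)
})

test_that("QC monotonicity: loosening thresholds never shrinks the retained set", {
  ds <- qc_fixture(n_tubes = 2, seed = 29)
  base <- qc_thresholds()
  n_base <- nrow(apply_qc(ds$particles, ds$axes, ds$fit, base)$particles)
  looser <- list(qc_thresholds(radius_frac_tol = 0.4),
                 qc_thresholds(angle_tol_deg = 60),
                 qc_thresholds(neighbor_tol_frac = 0.9),
                 qc_thresholds(cc_percentile_min = 1))
  tighter <- list(qc_thresholds(radius_frac_tol = 0.1),
                  qc_thresholds(angle_tol_deg = 15),
                  qc_thresholds(neighbor_tol_frac = 0.2),
                  qc_thresholds(cc_percentile_min = 20))
  for (th in looser) {
    expect_gte(nrow(apply_qc(ds$particles, ds$axes, ds$fit, th)$particles), n_base)
  }
  for (th in tighter) {
    expect_lte(nrow(apply_qc(ds$particles, ds$axes, ds$fit, th)$particles), n_base)
  }
})

test_that("missing-neighbor criterion: a pair at spacing a passes, a singleton fails", {
  cfg <- short_noiseless()
  hel <- tibble::tibble(tube_id = "t1",
                        !!!coatlattice:::helix_from_lattice(cfg, 1))
  a <- hel$a_A
  theta <- hel$lead_angle_deg * pi / 180
  ax <- straight_axis_df(3000)
  # two particles along one strand at spacing a, mid-tube, plus a far
  # isolated one; orientations x along strand at phi = 0
  xhat <- c(0, cos(theta), sin(theta))
  zhat <- c(1, 0, 0)
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  e <- matrix_to_euler(cbind(xhat, yhat, zhat))
  mk <- function(pos, id) tibble::tibble(
    tube_id = "t1", particle_id = id, x_A = pos[1], y_A = pos[2], z_A = pos[3],
    rot_deg = e[1], tilt_deg = e[2], psi_deg = e[3], cc = 0.5, flags = "")
  p0 <- c(hel$radius_A, 0, 1500)
  p <- dplyr::bind_rows(mk(p0, "pa"), mk(p0 + a * xhat, "pb"),
                        mk(c(hel$radius_A, 0, 300), "iso"))
  qc <- apply_qc(p, ax, hel,
                 qc_thresholds(cc_percentile_min = 0.0001))
  fl <- qc$flags[match(c("pa", "pb", "iso"), qc$flags$particle_id), ]
  expect_false(fl$missing_neighbor[1])
  expect_false(fl$missing_neighbor[2])
  expect_true(fl$missing_neighbor[3])
})

test_that("QC report counts are consistent and order-invariant", {
  ds <- qc_fixture(n_tubes = 2, seed = 53)
  qc <- apply_qc(ds$particles, ds$axes, ds$fit)
  expect_equal(qc$summary$retained, qc$summary$total - qc$summary$flagged)
  expect_equal(qc$summary$flagged,
               sum(qc$flags$extreme_radius | qc$flags$extreme_angle |
                     qc$flags$missing_neighbor | qc$flags$low_cc))
  set.seed(1)
  shuf <- ds$particles[sample(nrow(ds$particles)), ]
  qc2 <- apply_qc(shuf, ds$axes, ds$fit)
  expect_equal(qc2$summary, qc$summary)
  expect_setequal(qc2$particles$particle_id, qc$particles$particle_id)
})
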