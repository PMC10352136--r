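# shared fixtures: small, fast generator configurations and simple axes

noiseless_config <- function(...) {
  args <- utils::modifyList(list(sigma_pos_A = 0, sigma_ang_deg = 0,
                                 dropout_rate = 0, outlier_rate = 0),
                            list(...))
  do.call(generator_config, args)
}

# short tubes keep per-test particle counts low
short_args <- list(tube_length_min_A = 1600, tube_length_mean_A = 2200,
                   tube_length_max_A = 3200)

short_noiseless <- function(...) {
  do.call(noiseless_config, utils::modifyList(short_args, list(...)))
}

short_noisy <- function(...) {
  do.call(generator_config, utils::modifyList(short_args, list(...)))
}

straight_axis <- function(length_A = 1000, tube_id = "t1") {
  tube_axis(cbind(x_A = 0, y_A = 0, z_A = c(0, length_A)), tube_id = tube_id)
}

straight_axis_df <- function(length_A = 1000, tube_id = "t1") {
  tibble::tibble(tube_id = tube_id, point_index = 1:2,
                 x_A = 0, y_A = 0, z_A = c(0, length_A))
}

# particles on a straight z axis from cylinder coordinates
cyl_particles <- function(s, phi_deg, r, tube_id = "t1", cc = 0.5) {
  tibble::tibble(
    tube_id = tube_id,
    particle_id = sprintf("p%05d", seq_along(s)),
    x_A = r * cos(phi_deg * pi / 180),
    y_A = r * sin(phi_deg * pi / 180),
    z_A = s,
    rot_deg = 0, tilt_deg = 0, psi_deg = 0,
    cc = cc, flags = "")
}

expect_recovers_helix <- function(fit, truth, radius_tol = 1e-3,
                                  pitch_rel_tol = 1e-3) {
  m <- match(fit$tube_id, truth$tube_id)
  expect_equal(fit$n_starts, truth$n_starts[m])
  expect_equal(fit$handedness, truth$handedness[m])
  expect_lt(max(abs(fit$radius_A - truth$radius_A[m])), radius_tol * 160)
  expect_lt(max(abs(fit$pitch_A / truth$pitch_A[m] - 1)), pitch_rel_tol)
}
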