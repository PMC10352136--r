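ident_particles <- function(pos, tube_id = "t1", cc = 0.5) {
  tibble::tibble(tube_id = tube_id,
                 particle_id = sprintf("p%03d", seq_len(nrow(pos))),
                 x_A = pos[, 1], y_A = pos[, 2], z_A = pos[, 3],
                 rot_deg = 0, tilt_deg = 0, psi_deg = 0, cc = cc, flags = "")
}

test_that("relative poses are expressed in the reference particle frame", {
  p <- ident_particles(rbind(c(0, 0, 0), c(30, 0, 0)))
  cl <- relative_poses(p, cutoff_A = 50)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$dx_A, c(30, -30))
  expect_equal(cl$dy_A, c(0, 0))

  # rotating particle 1 by 90 deg about z turns its neighbor offset into -dy
  p2 <- p
  p2$rot_deg[1] <- 90
  cl2 <- relative_poses(p2, 50)
  row1 <- cl2[cl2$id_i == "p001", ]
  expect_equal(c(row1$dx_A, row1$dy_A), c(0, -30), tolerance = 1e-9)

  expect_error(relative_poses(p, -1), class = "coat_invalid_parameter")
})

test_that("cloud size is n(n-1) for mutually close particles and the cloud is centro-symmetric", {
  set.seed(5)
  pos <- matrix(runif(21, 0, 20), ncol = 3)
  p <- ident_particles(pos)
  cl <- relative_poses(p, cutoff_A = 100)
  expect_equal(nrow(cl), nrow(pos) * (nrow(pos) - 1))
  # identity-oriented set: exact centro-symmetry
  key <- paste(round(cl$dx_A, 9), round(cl$dy_A, 9), round(cl$dz_A, 9))
  neg <- paste(round(-cl$dx_A, 9), round(-cl$dy_A, 9), round(-cl$dz_A, 9))
  expect_setequal(key, neg)
})

test_that("rigidly moving the whole set leaves the cloud unchanged", {
  cfg <- short_noiseless()
  ds <- simulate_dataset(cfg, n_tubes = 1, seed = 8)
  p <- ds$particles[1:80, ]
  cl <- relative_poses(p, 70)
  Rm <- euler_to_matrix(15, 40, 75)
  P <- as.matrix(p[, c("x_A", "y_A", "z_A")]) %*% t(Rm)
  p2 <- p
  p2$x_A <- P[, 1] + 5; p2$y_A <- P[, 2] - 8; p2$z_A <- P[, 3] + 11
  for (i in seq_len(nrow(p2))) {
    e <- matrix_to_euler(Rm %*% euler_to_matrix(p$rot_deg[i], p$tilt_deg[i],
                                                p$psi_deg[i]))
    p2$rot_deg[i] <- e[1]; p2$tilt_deg[i] <- e[2]; p2$psi_deg[i] <- e[3]
  }
  cl2 <- relative_poses(p2, 70)
  ord <- function(x) x[order(x$id_i, x$id_j), ]
  expect_equal(ord(cl2)$dx_A, ord(cl)$dx_A, tolerance = 1e-6)
  expect_equal(ord(cl2)$dz_A, ord(cl)$dz_A, tolerance = 1e-6)
})

test_that("find_peaks recovers known cluster centers, deterministically", {
  centers <- rbind(c(55, 0, 0), c(-55, 0, 0), c(20, 58, 0),
                   c(-20, -58, 0), c(-35, 58, 0), c(35, -58, 0))
  set.seed(12)
  X <- centers[rep(1:6, each = 150), ] + matrix(rnorm(2700, 0, 1), 900, 3)
  cl <- tibble::tibble(tube_id = "t1", id_i = "a", id_j = "b",
                       dx_A = X[, 1], dy_A = X[, 2], dz_A = X[, 3],
                       dist_A = sqrt(rowSums(X^2)))
  class(cl) <- c("coat_cloud", class(cl))
  pk <- find_peaks(cl, k = 6, seed = 4)
  for (i in 1:6) {
    d <- sqrt(rowSums((as.matrix(pk[, c("dx_A", "dy_A", "dz_A")]) -
                         matrix(centers[i, ], 6, 3, byrow = TRUE))^2))
    expect_lt(min(d), 0.5)
  }
  pk2 <- find_peaks(cl, k = 6, seed = 4)
  expect_identical(pk, pk2)
  # k = 1 is the cloud mean
  pk1 <- find_peaks(cl, k = 1, seed = 1)
  expect_equal(c(pk1$dx_A, pk1$dy_A, pk1$dz_A), colMeans(X), tolerance = 1e-9)
  expect_error(find_peaks(cl[1:3, ], k = 6), class = "coat_insufficient_data")
})

test_that("lattice extraction is exact on noise-free tubes and tolerant to noise", {
  for (noisy in c(FALSE, TRUE)) {
    cfg <- if (noisy) short_noisy() else short_noiseless()
    ds <- simulate_dataset(cfg, n_tubes = 3, seed = 14)
    fit <- fit_helix(ds$particles, ds$axes)
    for (id in fit$tube_id) {
      p <- dplyr::filter(ds$particles, tube_id == id)
      h <- fit[fit$tube_id == id, ]
      cl <- relative_poses(p, 1.3 * max(h$a_A, h$d_perp_A), axes = ds$axes)
      lat <- lattice_from_peaks(find_peaks(cl, 6, seed = 2), h, cloud = cl)
      tr <- ds$helices[ds$helices$tube_id == id, ]
      tol_len <- if (noisy) 2 else 0.1
      tol_ang <- if (noisy) 1.5 else 0.1
      expect_lt(abs(lat$a_A - tr$a_A), tol_len)
      expect_lt(abs(lat$b_A - tr$b_A), tol_len)
      expect_lt(abs(lat$alpha_deg - tr$alpha_deg), tol_ang)
      # relative angle between consecutive particles: a cos(theta) / R
      delta_true <- (tr$a_A * cos(tr$lead_angle_deg * pi / 180) / tr$radius_A) *
        180 / pi
      expect_lt(abs(lat$delta_angle_deg - delta_true), if (noisy) 0.6 else 0.05)
    }
  }
})

test_that("fewer than two symmetric pairs raises lattice-undetermined", {
  pk <- tibble::tibble(peak = 1:3, dx_A = c(55, -55, 40), dy_A = c(0, 0, 40),
                       dz_A = 0, occupancy = c(10, 10, 5))
  expect_error(lattice_from_peaks(pk, list(radius_A = 158.5, n_starts = 3)),
               class = "coat_lattice_undetermined")
})

test_that("neighborhood histogram conserves counts and symmetry", {
  set.seed(30)
  X <- rbind(matrix(rnorm(600, 0, 2), 200, 3) +
               matrix(c(20, 6, 0), 200, 3, byrow = TRUE),
             matrix(rnorm(600, 0, 2), 200, 3) +
               matrix(c(-20, -6, 0), 200, 3, byrow = TRUE))
  cl <- tibble::tibble(tube_id = "t", id_i = "a", id_j = "b",
                       dx_A = X[, 1], dy_A = X[, 2], dz_A = X[, 3],
                       dist_A = sqrt(rowSums(X^2)))
  class(cl) <- c("coat_cloud", class(cl))
  hg <- neighborhood_histogram(cl, bin_A = 2)
  expect_equal(sum(hg$count), nrow(cl))
  # argmax bins sit at the generating offsets to within one bin
  top <- hg[order(-hg$count), ][1:2, ]
  expect_lt(min(abs(top$x_A - 20) + abs(top$y_A - 6)), 4.1)
  expect_lt(min(abs(top$x_A + 20) + abs(top$y_A + 6)), 4.1)
  # a centro-symmetric cloud gives a 180-degree symmetric histogram
  Xs <- rbind(X, -X)
  cls <- cl[rep(1, nrow(Xs)), ]
  cls$dx_A <- Xs[, 1]; cls$dy_A <- Xs[, 2]; cls$dz_A <- Xs[, 3]
  hgs <- neighborhood_histogram(cls, bin_A = 2, limits = c(-40, 40))
  flip <- hgs
  flip$x_A <- -flip$x_A; flip$y_A <- -flip$y_A
  flip <- flip[order(flip$x_A, flip$y_A), ]
  hgs2 <- hgs[order(hgs$x_A, hgs$y_A), ]
  expect_equal(hgs2$count, flip$count)
})

test_that("along-strand peaks are tighter than lateral peaks under anisotropic noise", {
  # emulate rounded along-strand density peaks vs broader lateral ones
  set.seed(44)
  along <- cbind(rnorm(300, 55, 1.5), rnorm(300, 0, 1.5), 0)
  lateral <- cbind(rnorm(300, 20, 4), rnorm(300, 58, 4), 0)
  X <- rbind(along, -along, lateral, -lateral)
  cl <- tibble::tibble(tube_id = "t", id_i = "a", id_j = "b",
                       dx_A = X[, 1], dy_A = X[, 2], dz_A = X[, 3],
                       dist_A = sqrt(rowSums(X^2)))
  class(cl) <- c("coat_cloud", class(cl))
  pk <- find_peaks(cl, k = 4, seed = 7)
  asg <- attr(pk, "assignment")
  vr <- purrr::map_dbl(1:4, function(k) {
    sum(diag(stats::cov(X[asg == k, , drop = FALSE])))
  })
  is_along <- abs(pk$dy_A) < 20
  expect_lt(max(vr[is_along]), min(vr[!is_along]))
})
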