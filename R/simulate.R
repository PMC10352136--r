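#' Configuration for the synthetic tubule-lattice generator
#'
#' The generator emulates the statistical structure of membrane tubules
#' coated by a helical protein lattice, as seen in cryo-ET of SNX-BAR
#' tubulation reactions: tubes lying in the xy plane with no preferred
#' in-plane orientation, lengths following a truncated log-normal
#' (mean 466 nm, s.d. 224 nm, range 157-1,552 nm), right-handed lattices
#' with 1-4 starts at the observed frequencies (5.6 / 31.7 / 27.2 / 36.1 %),
#' a particle shell at membrane radius + coat offset (140 + 18.5 Angstrom,
#' i.e. 28 nm outer-leaflet diameter under a 3.7 nm coat), Gaussian
#' positional/angular noise, dropout, decoy outliers, and simulated
#' cross-correlation scores.
#'
#' The coat lattice is specified by its in-surface lattice vectors: `a_A`
#' (along-strand spacing), `b_A` (inter-row vector length) and `alpha_deg`
#' (angle between them). For a given number of starts `n` the lattice is
#' wrapped onto the cylinder through the integer closure condition
#' `C = k*A + n*B` (the circumference vector must be a lattice vector); a
#' small isotropic strain (typically < 4%) is applied so every start class
#' reaches the same target radius. This reproduces the observation that
#' lattice parameters vary only minimally between start classes while the
#' relative angle between consecutive particles adapts to the lead angle.
#'
#' @param membrane_radius_A Outer-leaflet membrane radius (Angstrom).
#' @param coat_offset_A Radial offset from the outer leaflet to the particle
#'   center (half the coat thickness).
#' @param starts_distribution Named probability vector over starts 1..4
#'   (normalized internally).
#' @param a_A,b_A,alpha_deg Generating 2D lattice: along-strand spacing,
#'   inter-row vector length (Angstrom) and their angle (degrees).
#' @param handedness +1 (right-handed) or -1.
#' @param tube_length_min_A,tube_length_mean_A,tube_length_max_A,tube_length_sd_A
#'   Truncated log-normal tube length model (Angstrom).
#' @param sigma_pos_A Positional noise s.d. per coordinate (Angstrom).
#' @param sigma_ang_deg Angular noise s.d. (degrees, rotation angle about a
#'   uniformly random axis).
#' @param dropout_rate Fraction of lattice sites left empty.
#' @param outlier_rate Fraction of emitted particles that are injected
#'   decoys (radius perturbed by 20-60%, normal tilted by 40-90 degrees,
#'   low cross-correlation).
#' @param cc_model List with `mean_true`, `mean_outlier`, `sd`: Gaussian
#'   cross-correlation scores, clipped to (0, 1].
#' @param axis_point_spacing_A Spacing of axis control points.
#' @param axis_curvature_max Maximum in-plane axis curvature (1/Angstrom).
#' @param z_undulation_A Amplitude of the gentle out-of-plane undulation.
#' @param seed Default seed for [simulate_dataset()].
#' @return A validated list of class `coat_config`.
#' @export
#' @examples
#' cfg <- generator_config()
#' cfg$a_A
generator_config <- function(membrane_radius_A = 140,
                             coat_offset_A = 18.5,
                             starts_distribution = c(`1` = 5.6, `2` = 31.7,
                                                     `3` = 27.2, `4` = 36.1),
                             a_A = 57,
                             b_A = 65,
                             alpha_deg = 70,
                             handedness = 1,
                             tube_length_min_A = 1570,
                             tube_length_mean_A = 4660,
                             tube_length_max_A = 15520,
                             tube_length_sd_A = 2240,
                             sigma_pos_A = 5,
                             sigma_ang_deg = 5,
                             dropout_rate = 0.05,
                             outlier_rate = 0.05,
                             cc_model = list(mean_true = 0.3,
                                             mean_outlier = 0.1,
                                             sd = 0.05),
                             axis_point_spacing_A = 500,
                             axis_curvature_max = 2e-5,
                             z_undulation_A = 20,
                             seed = 1L) {
  if (any(starts_distribution < 0) || sum(starts_distribution) <= 0) {
    abort("`starts_distribution` must be non-negative with positive sum",
          class = "coat_invalid_config")
  }
  if (is.null(names(starts_distribution))) {
    names(starts_distribution) <- seq_along(starts_distribution)
  }
  starts_distribution <- starts_distribution / sum(starts_distribution)
  stopifnot(membrane_radius_A > 0, coat_offset_A >= 0, a_A > 0, b_A > 0,
            alpha_deg > 0, alpha_deg < 180, handedness %in% c(-1, 1),
            tube_length_min_A > 0,
            tube_length_min_A <= tube_length_mean_A,
            tube_length_mean_A <= tube_length_max_A,
            sigma_pos_A >= 0, sigma_ang_deg >= 0,
            dropout_rate >= 0, dropout_rate < 1,
            outlier_rate >= 0, outlier_rate < 1)
  structure(list(
    membrane_radius_A = membrane_radius_A, coat_offset_A = coat_offset_A,
    starts_distribution = starts_distribution,
    a_A = a_A, b_A = b_A, alpha_deg = alpha_deg, handedness = handedness,
    tube_length_min_A = tube_length_min_A,
    tube_length_mean_A = tube_length_mean_A,
    tube_length_max_A = tube_length_max_A,
    tube_length_sd_A = tube_length_sd_A,
    sigma_pos_A = sigma_pos_A, sigma_ang_deg = sigma_ang_deg,
    dropout_rate = dropout_rate, outlier_rate = outlier_rate,
    cc_model = cc_model,
    axis_point_spacing_A = axis_point_spacing_A,
    axis_curvature_max = axis_curvature_max,
    z_undulation_A = z_undulation_A,
    seed = as.integer(seed)
  ), class = "coat_config")
}

#' @export
print.coat_config <- function(x, ...) {
  cat(sprintf(paste0("<coat_config: shell radius %.1f A, lattice a=%.1f b=%.1f ",
                     "alpha=%.1f deg, starts %s>\n"),
              x$membrane_radius_A + x$coat_offset_A, x$a_A, x$b_A, x$alpha_deg,
              paste(sprintf("%d:%.1f%%", as.integer(names(x$starts_distribution)),
                            100 * x$starts_distribution), collapse = " ")))
  invisible(x)
}

# Solve the cylinder-closure condition C = k*A + n*B for a given number of
# starts: pick the integer k whose circumference best matches the target
# shell radius, then strain the lattice isotropically to hit it exactly.
helix_from_lattice <- function(config, n_starts) {
  r_t <- config$membrane_radius_A + config$coat_offset_A
  al <- deg2rad(config$alpha_deg)
  b_along <- config$b_A * cos(al)
  b_perp <- config$b_A * sin(al)
  k <- round((2 * pi * r_t - n_starts * b_along) / config$a_A)
  cx <- k * config$a_A + n_starts * b_along
  cy <- n_starts * b_perp
  if (cx <= 0) {
    abort("lattice cannot close around a cylinder of this radius",
          class = "coat_invalid_config")
  }
  clen <- sqrt(cx^2 + cy^2)
  strain <- 2 * pi * r_t / clen
  theta <- atan2(cy, cx)
  list(
    n_starts = n_starts,
    radius_A = r_t,
    lead_angle_deg = rad2deg(theta),
    pitch_A = 2 * pi * r_t * tan(theta),
    handedness = config$handedness,
    a_A = strain * config$a_A,
    b_A = strain * config$b_A,
    alpha_deg = config$alpha_deg,
    k_wrap = k,
    strain = strain
  )
}

#' Sample tube axes and ground-truth helix models
#'
#' Draws `n_tubes` tubes: length from the truncated log-normal, start number
#' from the configured distribution, an in-plane axis with uniform random
#' orientation, gentle curvature and out-of-plane undulation, and the
#' closure-consistent helix model for the tube's start class.
#'
#' @param config A [generator_config()].
#' @param n_tubes Number of tubes (>= 1).
#' @param seed Integer seed (all randomness flows from it).
#' @return A list with `axes` (control-point tibble: `tube_id`,
#'   `point_index`, `x_A`, `y_A`, `z_A`) and `helices` (per-tube truth:
#'   radius, pitch, starts, handedness, lead angle, strained lattice
#'   parameters, length).
#' @export
sample_tubes <- function(config, n_tubes, seed = config$seed) {
  stopifnot(inherits(config, "coat_config"), n_tubes >= 1)
  with_seed(seed, function() {
    mu <- config$tube_length_mean_A
    sdv <- config$tube_length_sd_A
    sdlog <- sqrt(log(1 + (sdv / mu)^2))
    meanlog <- log(mu) - sdlog^2 / 2
    draw_len <- function(n) {
      out <- numeric(0)
      while (length(out) < n) {
        x <- rlnorm(2 * n, meanlog, sdlog)
        out <- c(out, x[x >= config$tube_length_min_A & x <= config$tube_length_max_A])
      }
      out[seq_len(n)]
    }
    lens <- draw_len(n_tubes)
    nopts <- as.integer(names(config$starts_distribution))
    nstarts <- sample(nopts, n_tubes, replace = TRUE, prob = config$starts_distribution)
    axes <- vector("list", n_tubes)
    hel <- vector("list", n_tubes)
    for (i in seq_len(n_tubes)) {
      id <- sprintf("tube_%04d", i)
      L <- lens[i]
      p0 <- c(runif(2, 0, 1e5), runif(1, 500, 2500))
      psi <- runif(1, 0, 2 * pi)
      kap <- runif(1, -config$axis_curvature_max, config$axis_curvature_max)
      sgrid <- seq(0, L, by = config$axis_point_spacing_A)
      if (sgrid[length(sgrid)] < L) sgrid <- c(sgrid, L)
      d <- c(cos(psi), sin(psi))
      if (abs(kap) < 1e-9) {
        xy <- cbind(p0[1] + d[1] * sgrid, p0[2] + d[2] * sgrid)
      } else {
        pp <- c(-sin(psi), cos(psi))
        ctr <- p0[1:2] + pp / kap
        xy <- cbind(ctr[1] - pp[1] / kap * cos(kap * sgrid) + d[1] / kap * sin(kap * sgrid),
                    ctr[2] - pp[2] / kap * cos(kap * sgrid) + d[2] / kap * sin(kap * sgrid))
      }
      zph <- runif(1, 0, 2 * pi)
      z <- p0[3] + config$z_undulation_A * sin(2 * pi * sgrid / L + zph)
      axes[[i]] <- tibble(tube_id = id, point_index = seq_along(sgrid),
                          x_A = xy[, 1], y_A = xy[, 2], z_A = z)
      h <- helix_from_lattice(config, nstarts[i])
      hel[[i]] <- tibble(tube_id = id, length_A = L, !!!h)
    }
    list(axes = bind_rows(axes), helices = bind_rows(hel))
  })
}

# vectorised axes -> intrinsic ZXZ euler angles (degrees); columns of the
# orientation matrix are the rows of xhat, yhat, zhat
vec_axes_to_euler <- function(xhat, yhat, zhat) {
  c2 <- pmax(-1, pmin(1, zhat[, 3]))
  tilt <- acos(c2)
  s2 <- sin(tilt)
  rot <- atan2(zhat[, 1], -zhat[, 2])
  psi <- atan2(xhat[, 3], yhat[, 3])
  deg <- abs(s2) < 1e-9
  if (any(deg)) {
    psi[deg] <- 0
    rot[deg] <- atan2(xhat[deg, 2], xhat[deg, 1]) * sign(c2[deg])
  }
  cbind(rot_deg = rad2deg(rot), tilt_deg = rad2deg(tilt), psi_deg = rad2deg(psi))
}

# rotate rows of v about unit-axis rows w by angles g (Rodrigues, vectorised)
rotate_rows <- function(v, w, g) {
  cg <- cos(g); sg <- sin(g)
  wv <- rowSums(w * v)
  cr <- cbind(w[, 2] * v[, 3] - w[, 3] * v[, 2],
              w[, 3] * v[, 1] - w[, 1] * v[, 3],
              w[, 1] * v[, 2] - w[, 2] * v[, 1])
  v * cg + cr * sg + w * (wv * (1 - cg))
}

#' Decorate one tube with helical lattice particles
#'
#' Places noise-free particles on the `n_starts` strands of the tube's helix
#' model (strands offset by 2 pi / n in azimuth, along-strand registration
#' given by the lattice vector b), orients each particle with its x axis
#' along the local strand direction and its z axis radially outward, then
#' applies positional/angular noise, dropout and injected outliers per the
#' configuration.
#'
#' @param axis A [tube_axis()] object.
#' @param helix One row of the `helices` tibble from [sample_tubes()] (or a
#'   list with the same fields).
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A list with `particles` (canonical particle tibble: `tube_id`,
#'   `particle_id`, `x_A`..`z_A`, `rot_deg`, `tilt_deg`, `psi_deg`, `cc`,
#'   `flags`) and `truth` (per emitted or dropped lattice site: label
#'   `lattice` / `dropout` / `outlier`, noise-free pose, strand index and
#'   cylinder coordinates).
#' @export
decorate_tube <- function(axis, helix, config, seed = config$seed) {
  stopifnot(inherits(axis, "tube_axis"), inherits(config, "coat_config"))
  h <- as.list(helix)
  if (h$a_A <= 0 || h$radius_A <= 0) {
    abort("helix spacing and radius must be positive", class = "coat_invalid_config")
  }
  with_seed(seed, function() {
    a <- h$a_A; b <- h$b_A; al <- deg2rad(h$alpha_deg)
    n <- h$n_starts; R <- h$radius_A; hand <- h$handedness
    theta <- deg2rad(h$lead_angle_deg)
    L <- axis$length_A
    sA <- a * sin(theta);              uA <- a * cos(theta)
    sB <- b * sin(theta - al);         uB <- b * cos(al - theta)
    s_off <- runif(1, 0, sA)
    phi0 <- runif(1, 0, 2 * pi)
    grids <- purrr::map(seq_len(n) - 1L, function(j) {
      lo <- ceiling((0 - j * sB - s_off) / sA)
      hi <- floor((L - j * sB - s_off) / sA)
      if (hi < lo) return(NULL)
      i <- lo:hi
      tibble(strand = j, i = i,
             s = i * sA + j * sB + s_off,
             u = i * uA + j * uB)
    })
    g <- bind_rows(grids)
    if (nrow(g) == 0) {
      abort("tube too short for any lattice site", class = "coat_invalid_config")
    }
    phi <- hand * g$u / R + phi0
    fr <- local_frames(axis, g$s)
    tn <- as.matrix(fr[, c("tx", "ty", "tz")])
    nm <- as.matrix(fr[, c("nx", "ny", "nz")])
    bn <- as.matrix(fr[, c("bx", "by", "bz")])
    radial <- nm * cos(phi) + bn * sin(phi)
    phihat <- -nm * sin(phi) + bn * cos(phi)
    pos0 <- as.matrix(fr[, c("x_A", "y_A", "z_A")]) + R * radial
    xhat0 <- sin(theta) * tn + hand * cos(theta) * phihat
    zhat0 <- radial
    yhat0 <- cbind(zhat0[, 2] * xhat0[, 3] - zhat0[, 3] * xhat0[, 2],
                   zhat0[, 3] * xhat0[, 1] - zhat0[, 1] * xhat0[, 3],
                   zhat0[, 1] * xhat0[, 2] - zhat0[, 2] * xhat0[, 1])
    eul0 <- vec_axes_to_euler(xhat0, yhat0, zhat0)
    m <- nrow(g)
    keep <- runif(m) >= config$dropout_rate
    label <- ifelse(keep, "lattice", "dropout")

    truth <- tibble(tube_id = axis$tube_id,
                    site = seq_len(m), strand = g$strand, i = g$i,
                    label = label, s_A = g$s, u_A = g$u, phi_deg = rad2deg(phi %% (2 * pi)),
                    x_A = pos0[, 1], y_A = pos0[, 2], z_A = pos0[, 3],
                    rot_deg = eul0[, 1], tilt_deg = eul0[, 2], psi_deg = eul0[, 3])

    ik <- which(keep)
    nk <- length(ik)
    pos <- pos0[ik, , drop = FALSE]
    xh <- xhat0[ik, , drop = FALSE]; yh <- yhat0[ik, , drop = FALSE]
    zh <- zhat0[ik, , drop = FALSE]
    if (config$sigma_pos_A > 0) {
      pos <- pos + matrix(rnorm(3 * nk, 0, config$sigma_pos_A), nk, 3)
    }
    if (config$sigma_ang_deg > 0) {
      w <- matrix(rnorm(3 * nk), nk, 3)
      w <- w / sqrt(rowSums(w^2))
      gang <- deg2rad(rnorm(nk, 0, config$sigma_ang_deg))
      xh <- rotate_rows(xh, w, gang)
      yh <- rotate_rows(yh, w, gang)
      zh <- rotate_rows(zh, w, gang)
    }
    cc <- pmin(pmax(rnorm(nk, config$cc_model$mean_true, config$cc_model$sd), 1e-6), 1)
    labels_out <- rep("lattice", nk)
    site_out <- ik

    n_out <- if (config$outlier_rate > 0 && nk > 0) {
      round(config$outlier_rate / (1 - config$outlier_rate) * nk)
    } else 0L
    if (n_out > 0) {
      ob <- sample(seq_len(m), n_out, replace = TRUE)
      f <- 1 + sample(c(-1, 1), n_out, TRUE) * runif(n_out, 0.2, 0.6)
      opos <- as.matrix(fr[ob, c("x_A", "y_A", "z_A")]) +
        (f * R) * radial[ob, , drop = FALSE] +
        matrix(rnorm(3 * n_out, 0, max(config$sigma_pos_A, 1)), n_out, 3)
      # tilt about a random axis in the local tangent plane
      mix <- runif(n_out, 0, 2 * pi)
      wax <- cos(mix) * xhat0[ob, , drop = FALSE] + sin(mix) * yhat0[ob, , drop = FALSE]
      gt <- deg2rad(runif(n_out, 40, 90)) * sample(c(-1, 1), n_out, TRUE)
      oxh <- rotate_rows(xhat0[ob, , drop = FALSE], wax, gt)
      oyh <- rotate_rows(yhat0[ob, , drop = FALSE], wax, gt)
      ozh <- rotate_rows(zhat0[ob, , drop = FALSE], wax, gt)
      occ <- pmin(pmax(rnorm(n_out, config$cc_model$mean_outlier, config$cc_model$sd), 1e-6), 1)
      pos <- rbind(pos, opos)
      xh <- rbind(xh, oxh); yh <- rbind(yh, oyh); zh <- rbind(zh, ozh)
      cc <- c(cc, occ)
      labels_out <- c(labels_out, rep("outlier", n_out))
      site_out <- c(site_out, rep(NA_integer_, n_out))
      otruth <- tibble(tube_id = axis$tube_id, site = NA_integer_,
                       strand = NA_integer_, i = NA_integer_,
                       label = "outlier",
                       s_A = fr$s_A[ob], u_A = NA_real_, phi_deg = NA_real_,
                       x_A = opos[, 1], y_A = opos[, 2], z_A = opos[, 3],
                       rot_deg = NA_real_, tilt_deg = NA_real_, psi_deg = NA_real_)
      truth <- bind_rows(truth, otruth)
    }
    eul <- vec_axes_to_euler(xh, yh, zh)
    particles <- tibble(
      tube_id = axis$tube_id,
      particle_id = sprintf("%s_p%05d", axis$tube_id, seq_len(nrow(pos))),
      x_A = pos[, 1], y_A = pos[, 2], z_A = pos[, 3],
      rot_deg = eul[, 1], tilt_deg = eul[, 2], psi_deg = eul[, 3],
      cc = cc, flags = "")
    truth$particle_id <- NA_character_
    emitted <- which(truth$label != "dropout")
    truth$particle_id[emitted] <- particles$particle_id
    truth$emitted_label <- NULL
    list(particles = particles, truth = truth)
  })
}

#' Simulate a complete multi-tube coat dataset
#'
#' Samples tubes with [sample_tubes()] and decorates each with
#' [decorate_tube()]; all randomness flows from the single `seed`, so equal
#' seeds give identical output tables.
#'
#' @param config A [generator_config()].
#' @param n_tubes Number of tubes.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with `particles` (all tubes, globally unique particle
#'   ids), `axes` (control-point tibble), `helices` (per-tube ground-truth
#'   helix models) and `truth` (per-site labels and noise-free poses).
#' @export
#' @examples
#' cfg <- generator_config(tube_length_min_A = 1600, tube_length_mean_A = 1800,
#'                         tube_length_max_A = 2200)
#' ds <- simulate_dataset(cfg, n_tubes = 1, seed = 7)
#' nrow(ds$particles)
simulate_dataset <- function(config, n_tubes, seed = config$seed) {
  tubes <- sample_tubes(config, n_tubes, seed = seed)
  axlist <- build_axes(tubes$axes)
  subseeds <- with_seed(seed + 1L, function() sample.int(.Machine$integer.max - 1L, n_tubes))
  parts <- vector("list", n_tubes)
  truths <- vector("list", n_tubes)
  for (i in seq_len(n_tubes)) {
    hrow <- tubes$helices[i, ]
    ax <- axlist[[hrow$tube_id]]
    dec <- decorate_tube(ax, hrow, config, seed = subseeds[i])
    parts[[i]] <- dec$particles
    truths[[i]] <- dec$truth
  }
  list(particles = bind_rows(parts), axes = tubes$axes,
       helices = tubes$helices, truth = bind_rows(truths),
       config = config)
}
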