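#' Generate helix-guided subbox poses along a tube
#'
#' Places poses on each of the `n_starts` strands of a fitted helix at fixed
#' arc steps measured along the strand (the subboxing step of lattice-guided
#' subtomogram extraction, e.g. every 16 pixels at 2.73 Angstrom/pixel =
#' 43.68 Angstrom). Each pose's x axis points along the local strand
#' direction (the azimuth-corrected subvolume frame) and its z axis points
#' radially outward. Cross-correlation is unset (`NA`).
#'
#' @param axes Axis table or list of [tube_axis()] objects.
#' @param helix Per-tube helix tibble (e.g. from [fit_helix()] or the
#'   generator truth) with columns `tube_id`, `radius_A`, `lead_angle_deg`,
#'   `n_starts`, `handedness`.
#' @param step_A Arc step along the strand (> 0), default 16 px * 2.73 A/px.
#' @param phi0_deg Azimuth of strand 0 at s = 0 (degrees); a per-tube
#'   `phi0_deg` column in `helix` (e.g. from [estimate_strand_phase()])
#'   takes precedence.
#' @return Particle tibble of poses (`cc = NA`, `flags = "subbox"`).
#' @export
helix_subbox <- function(axes, helix, step_A = 16 * 2.73, phi0_deg = 0) {
  if (step_A <= 0) abort("`step_A` must be positive", class = "coat_invalid_parameter")
  axes <- build_axes(axes)
  helix <- as_tibble(helix)
  rows <- purrr::map(seq_len(nrow(helix)), function(i) {
    h <- helix[i, ]
    if (h$radius_A <= 0) {
      abort("degenerate helix (radius <= 0)", class = "coat_invalid_input")
    }
    ax <- axis_for_tube(axes, h$tube_id)
    theta <- deg2rad(h$lead_angle_deg)
    phi00 <- if ("phi0_deg" %in% names(h) && is.finite(h$phi0_deg)) h$phi0_deg
             else phi0_deg
    l_strand <- ax$length_A / sin(theta)
    ell <- seq(0, l_strand, by = step_A)
    out <- purrr::map(seq_len(h$n_starts) - 1L, function(m) {
      s <- ell * sin(theta)
      phi <- deg2rad(phi00) + 2 * pi * m / h$n_starts +
        h$handedness * ell * cos(theta) / h$radius_A
      fr <- local_frames(ax, s)
      tn <- as.matrix(fr[, c("tx", "ty", "tz")])
      nm <- as.matrix(fr[, c("nx", "ny", "nz")])
      bn <- as.matrix(fr[, c("bx", "by", "bz")])
      radial <- nm * cos(phi) + bn * sin(phi)
      phihat <- -nm * sin(phi) + bn * cos(phi)
      pos <- as.matrix(fr[, c("x_A", "y_A", "z_A")]) + h$radius_A * radial
      xh <- sin(theta) * tn + h$handedness * cos(theta) * phihat
      zh <- radial
      yh <- cbind(zh[, 2] * xh[, 3] - zh[, 3] * xh[, 2],
                  zh[, 3] * xh[, 1] - zh[, 1] * xh[, 3],
                  zh[, 1] * xh[, 2] - zh[, 2] * xh[, 1])
      eul <- vec_axes_to_euler(xh, yh, zh)
      tibble(tube_id = h$tube_id, strand = m, ell_A = ell, s_A = s,
             x_A = pos[, 1], y_A = pos[, 2], z_A = pos[, 3],
             rot_deg = eul[, 1], tilt_deg = eul[, 2], psi_deg = eul[, 3])
    }) |> bind_rows()
    out$particle_id <- sprintf("%s_sb%05d", h$tube_id, seq_len(nrow(out)))
    out
  })
  bind_rows(rows) |>
    mutate(cc = NA_real_, flags = "subbox") |>
    select("tube_id", "particle_id", "x_A", "y_A", "z_A",
           "rot_deg", "tilt_deg", "psi_deg", "cc", "flags",
           "strand", "ell_A", "s_A")
}

#' Deduplicate particles by cross-correlation (greedy suppression)
#'
#' Coordinates with similar positions (within `range_A`) are reduced to the
#' coordinate with the highest cross-correlation value, by greedy best-first
#' (non-maximum-suppression style) selection: particles are visited in
#' decreasing `cc` order (ties broken by ascending `particle_id`) and
#' accepted iff no previously accepted particle of the same tube lies within
#' `range_A` (full 3D Euclidean distance). The operation is idempotent, its
#' output contains no pair closer than `range_A`, and it is independent of
#' the input row order when `cc` values are distinct.
#'
#' @param particles Particle tibble with finite `cc` for every row.
#' @param range_A Suppression radius in Angstrom. The pixel ranges of
#'   Dynamo-style workflows convert via the pixel size (8 px and 17 px at
#'   2.73 Angstrom/px are 21.84 and 46.41 Angstrom).
#' @return The retained particles, ordered by acceptance (cc descending
#'   within tube).
#' @export
dedup_particles <- function(particles, range_A) {
  if (range_A <= 0) abort("`range_A` must be positive", class = "coat_invalid_parameter")
  particles <- as_tibble(particles)
  if (!"cc" %in% names(particles) || any(!is.finite(particles$cc))) {
    bad <- if ("cc" %in% names(particles))
      particles$particle_id[!is.finite(particles$cc)] else "all"
    abort(paste0("dedup requires finite cc for every particle; offending: ",
                 paste(utils::head(bad, 5), collapse = ", ")),
          class = "coat_invalid_input")
  }
  split(particles, particles$tube_id) |>
    purrr::map(function(df) {
      df <- df[order(-df$cc, df$particle_id), ]
      keep <- .greedy_suppress(as.matrix(df[, c("x_A", "y_A", "z_A")]), range_A)
      df[keep, ]
    }) |>
    bind_rows()
}

#' Apply a rigid transform to a particle set
#'
#' Recentring step of multi-tube alignment: positions and orientations are
#' composed with a rotation + translation (applied per tube or globally).
#' Pairwise distances are preserved to numerical precision.
#'
#' @param particles Particle tibble.
#' @param rotation A 3x3 orthonormal rotation matrix (determinant +1), or a
#'   named list of such matrices keyed by `tube_id`.
#' @param translation Numeric length-3 vector (Angstrom), or a named list
#'   keyed by `tube_id`.
#' @return The transformed particle tibble.
#' @export
recenter_particles <- function(particles, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  particles <- as_tibble(particles)
  get_for <- function(x, id, default) {
    if (is.list(x) && !is.matrix(x)) {
      if (is.null(x[[id]])) default else x[[id]]
    } else x
  }
  out <- split(particles, particles$tube_id) |>
    purrr::map(function(df) {
      Rm <- get_for(rotation, df$tube_id[1], diag(3))
      tr <- get_for(translation, df$tube_id[1], c(0, 0, 0))
      if (!is_rotation_matrix(Rm)) {
        abort("`rotation` must be orthonormal with determinant +1 (rigid transform)",
              class = "coat_invalid_input")
      }
      P <- as.matrix(df[, c("x_A", "y_A", "z_A")])
      Pn <- P %*% t(Rm)
      df$x_A <- Pn[, 1] + tr[1]; df$y_A <- Pn[, 2] + tr[2]; df$z_A <- Pn[, 3] + tr[3]
      if (all(c("rot_deg", "tilt_deg", "psi_deg") %in% names(df)) &&
          max(abs(Rm - diag(3))) > 0) {
        for (i in seq_len(nrow(df))) {
          Ri <- Rm %*% euler_to_matrix(df$rot_deg[i], df$tilt_deg[i], df$psi_deg[i])
          e <- matrix_to_euler(Ri)
          df$rot_deg[i] <- e[1]; df$tilt_deg[i] <- e[2]; df$psi_deg[i] <- e[3]
        }
      }
      df
    }) |>
    bind_rows()
  out[match(particles$particle_id, out$particle_id), ]
}
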