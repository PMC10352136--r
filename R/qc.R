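#' Thresholds for the four-criterion outlier exclusion
#'
#' The four exclusion criteria of coordinate-level subtomogram cleaning:
#' (a) extreme radius, (b) extreme angle between the particle's outward
#' normal and the local tube-surface normal, (c) missing along-strand
#' neighbors on both tips, (d) low cross-correlation. Numeric thresholds
#' are declared package defaults validated by recovery on synthetic data.
#'
#' @param radius_frac_tol Fractional radial tolerance (flag when
#'   `|r - R|/R` exceeds it). Default 0.2.
#' @param angle_tol_deg Maximum angle (degrees) between the particle z axis
#'   and the local surface normal. Default 30.
#' @param neighbor_tol_frac Search radius around each expected along-strand
#'   neighbor position, as a fraction of the along-strand spacing `a`.
#'   Default 0.5.
#' @param cc_percentile_min Particles below this per-tube cc percentile are
#'   flagged. Default 5.
#' @return A validated list of class `coat_qc_thresholds`.
#' @export
qc_thresholds <- function(radius_frac_tol = 0.2, angle_tol_deg = 30,
                          neighbor_tol_frac = 0.5, cc_percentile_min = 5) {
  stopifnot(radius_frac_tol > 0, angle_tol_deg > 0, neighbor_tol_frac > 0,
            cc_percentile_min >= 0, cc_percentile_min < 100)
  structure(list(radius_frac_tol = radius_frac_tol,
                 angle_tol_deg = angle_tol_deg,
                 neighbor_tol_frac = neighbor_tol_frac,
                 cc_percentile_min = cc_percentile_min),
            class = "coat_qc_thresholds")
}

#' Four-criterion outlier exclusion
#'
#' Flags each particle with any of `extreme_radius`, `extreme_angle`,
#' `missing_neighbor`, `low_cc` and excludes particles carrying at least one
#' flag:
#' \itemize{
#'   \item \strong{extreme_radius}: `|r_i - R| / R > radius_frac_tol`,
#'     with `R` the tube's fitted shell radius;
#'   \item \strong{extreme_angle}: angle between the particle z axis and
#'     the local surface normal (radial direction) exceeds `angle_tol_deg`;
#'   \item \strong{missing_neighbor}: no other particle lies within
#'     `neighbor_tol_frac * a` of either expected along-strand neighbor
#'     position (`+/- a` along the particle's x axis). An expected position
#'     beyond the tube end is treated as satisfied, so strand-terminal
#'     particles are only judged on their open, in-bounds tip;
#'   \item \strong{low_cc}: `cc` below the tube's `cc_percentile_min`
#'     percentile.
#' }
#'
#' @param particles Particle tibble (orientations and `cc` required).
#' @param axes Axis table or list of [tube_axis()] objects.
#' @param helix Per-tube helix tibble (from [fit_helix()] or generator
#'   truth) with `radius_A`, `a_A`, `lead_angle_deg`.
#' @param thresholds A [qc_thresholds()].
#' @return A list with `particles` (retained set), `flags` (per-particle
#'   logical flag columns) and `summary` (per-criterion counts and the
#'   retained count; `retained = total - flagged`).
#' @export
apply_qc <- function(particles, axes, helix, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "coat_qc_thresholds"))
  helix <- as_tibble(helix)
  need <- c("radius_A", "a_A", "lead_angle_deg")
  if (!all(need %in% names(helix))) {
    abort("`helix` must provide radius_A, a_A and lead_angle_deg (fit the helix first)",
          class = "coat_invalid_input")
  }
  if (!"cc" %in% names(particles) || any(!is.finite(particles$cc))) {
    abort("QC requires finite cc values", class = "coat_invalid_input")
  }
  axes <- build_axes(axes)
  unr <- unroll_particles(particles, axes)
  flags <- split(unr, unr$tube_id) |>
    purrr::map(function(df) {
      h <- helix[match(df$tube_id[1], helix$tube_id), ]
      ax <- axis_for_tube(axes, df$tube_id[1])
      R <- h$radius_A; a <- h$a_A
      f_rad <- abs(df$r_A - R) / R > thresholds$radius_frac_tol
      # particle outward normal vs surface normal
      fr <- local_frames(ax, df$s_A)
      phi <- deg2rad(df$phi_deg)
      radial <- as.matrix(fr[, c("nx", "ny", "nz")]) * cos(phi) +
        as.matrix(fr[, c("bx", "by", "bz")]) * sin(phi)
      # particle z axis from the euler triplet (third rotation-matrix column)
      zax <- cbind(sin(deg2rad(df$rot_deg)) * sin(deg2rad(df$tilt_deg)),
                   -cos(deg2rad(df$rot_deg)) * sin(deg2rad(df$tilt_deg)),
                   cos(deg2rad(df$tilt_deg)))
      cosang <- pmax(-1, pmin(1, rowSums(zax * radial)))
      f_ang <- rad2deg(acos(cosang)) > thresholds$angle_tol_deg
      # expected along-strand neighbors: one along-strand step on the fitted
      # helix surface (the strand is curved, so stepping along the straight
      # particle tangent would miss the true site by the curvature sag)
      theta <- deg2rad(h$lead_angle_deg)
      hd <- if ("handedness" %in% names(h)) h$handedness else 1
      P <- as.matrix(df[, c("x_A", "y_A", "z_A")])
      tol <- thresholds$neighbor_tol_frac * a
      found <- matrix(FALSE, nrow(df), 2)
      for (side in 1:2) {
        sgn <- c(1, -1)[side]
        s_exp <- df$s_A + sgn * a * sin(theta)
        phi_exp <- deg2rad(df$phi_deg) + sgn * hd * a * cos(theta) / R
        oob <- s_exp < 0 | s_exp > ax$length_A
        fr2 <- local_frames(ax, pmin(pmax(s_exp, 0), ax$length_A))
        expect <- as.matrix(fr2[, c("x_A", "y_A", "z_A")]) +
          R * (as.matrix(fr2[, c("nx", "ny", "nz")]) * cos(phi_exp) +
                 as.matrix(fr2[, c("bx", "by", "bz")]) * sin(phi_exp))
        found[, side] <- oob | has_point_within(P, df$s_A, expect, s_exp, tol)
      }
      f_nb <- !(found[, 1] | found[, 2])
      f_cc <- df$cc < quantile(df$cc, thresholds$cc_percentile_min / 100, type = 7)
      tibble(tube_id = df$tube_id, particle_id = df$particle_id,
             extreme_radius = f_rad, extreme_angle = f_ang,
             missing_neighbor = f_nb, low_cc = f_cc)
    }) |>
    bind_rows()
  flags <- flags[match(particles$particle_id, flags$particle_id), ]
  any_flag <- flags$extreme_radius | flags$extreme_angle |
    flags$missing_neighbor | flags$low_cc
  summary <- tibble(
    total = nrow(particles),
    extreme_radius = sum(flags$extreme_radius),
    extreme_angle = sum(flags$extreme_angle),
    missing_neighbor = sum(flags$missing_neighbor),
    low_cc = sum(flags$low_cc),
    flagged = sum(any_flag),
    retained = nrow(particles) - sum(any_flag))
  list(particles = as_tibble(particles)[!any_flag, ], flags = flags, summary = summary)
}

# is there a particle (other than the owner, implicitly: any particle at
# distance > 0) within tol of each expected position? s-window accelerated.
has_point_within <- function(P, s, expect, s_exp, tol) {
  ord <- order(s)
  s_sorted <- s[ord]
  lo <- findInterval(s_exp - tol - 1e-9, s_sorted) + 1L
  hi <- findInterval(s_exp + tol + 1e-9, s_sorted)
  out <- logical(nrow(P))
  for (i in seq_len(nrow(P))) {
    if (hi[i] < lo[i]) next
    j <- ord[lo[i]:hi[i]]
    j <- j[j != i]  # a particle is not its own neighbor
    if (!length(j)) next
    d2 <- (P[j, 1] - expect[i, 1])^2 + (P[j, 2] - expect[i, 2])^2 +
      (P[j, 3] - expect[i, 3])^2
    out[i] <- any(d2 <= tol^2)
  }
  out
}
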