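#' Estimate tube radius from particle positions
#'
#' The particle-shell radius of each tube is the median radial distance of
#' its particles to the tube axis (robust to decoys), with a seeded
#' bootstrap standard deviation.
#'
#' @param particles Particle tibble (`tube_id`, `x_A`, `y_A`, `z_A`, ...).
#' @param axes Axis table or list of [tube_axis()] objects.
#' @param n_boot Bootstrap resamples for the uncertainty (default 200).
#' @param seed Seed for the bootstrap.
#' @return A tibble with one row per tube: `tube_id`, `radius_A`,
#'   `radius_sd_A`, `n_particles`, `residual_mad_A`.
#' @export
estimate_radius <- function(particles, axes, n_boot = 200, seed = 1L) {
  unr <- if ("r_A" %in% names(particles)) particles else unroll_particles(particles, axes)
  res <- unr |>
    group_by(.data$tube_id) |>
    summarise(radius_A = median(.data$r_A),
              n_particles = dplyr::n(),
              residual_mad_A = stats::mad(.data$r_A),
              .groups = "drop")
  if (any(res$n_particles < 10)) {
    abort(sprintf("tube(s) with fewer than 10 particles: %s",
                  paste(res$tube_id[res$n_particles < 10], collapse = ", ")),
          class = "coat_insufficient_data")
  }
  boot <- with_seed(seed, function() {
    unr |>
      group_by(.data$tube_id) |>
      summarise(radius_sd_A = sd(purrr::map_dbl(seq_len(n_boot), function(b) {
        median(sample(.data$r_A, length(.data$r_A), replace = TRUE))
      })), .groups = "drop")
  })
  left_join(res, boot, by = "tube_id") |>
    select("tube_id", "radius_A", "radius_sd_A", "n_particles", "residual_mad_A")
}

# nearest-neighbour vectors in the unrolled (s, u) plane, using an s-window
# search; du is the wrapped azimuth difference scaled by the shell radius
unrolled_nn_vectors <- function(s, phi_deg, radius, window_A = 150) {
  ord <- order(s)
  s <- s[ord]; phi <- phi_deg[ord]
  n <- length(s)
  ds <- du <- rep(NA_real_, n)
  lo <- findInterval(s - window_A, s) + 1L
  hi <- findInterval(s + window_A, s)
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    j <- j[j != i]
    if (!length(j)) next
    dsi <- s[j] - s[i]
    dui <- radius * deg2rad(wrap180(phi[j] - phi[i]))
    d2 <- dsi^2 + dui^2
    k <- which.min(d2)
    ds[i] <- dsi[k]; du[i] <- dui[k]
  }
  ok <- !is.na(ds)
  cbind(du = du[ok], ds = ds[ok])
}

#' Detect the number of helical starts, pitch and handedness
#'
#' Deterministic lattice analysis in the unrolled plane:
#' \enumerate{
#'   \item find the dominant along-strand direction as the modal orientation
#'     (2-degree circular histogram, half-turn period) of nearest-neighbor
#'     vectors, refined by a principal-axis fit of the modal cluster;
#'   \item read the lead angle \eqn{\theta} (strand vs. circumferential
#'     axis) and handedness (sign of the strand slope du/ds) off that
#'     direction;
#'   \item refine \eqn{\theta} and count the starts by maximizing, over
#'     \eqn{\theta} and candidate start numbers n, the circular
#'     concentration of the perpendicular row coordinate wrapped at the
#'     full-turn row period \eqn{V = 2\pi R \sin\theta}: rows of an n-start
#'     lattice are evenly spaced at \eqn{V/n};
#'   \item pitch \eqn{P = 2\pi R \tan\theta}, row spacing
#'     \eqn{d_\perp = V/n}.
#' }
#'
#' @param particles Particle tibble for one or more tubes.
#' @param axes Axis table or list of [tube_axis()] objects.
#' @param radius Optional per-tube radius tibble from [estimate_radius()];
#'   computed if `NULL`.
#' @param max_starts Largest start number considered (default 8).
#' @param nn_window_A Half-width of the s-window used for neighbor search.
#' @param min_concentration Below this circular concentration the point
#'   cloud is declared lattice-free (error `coat_no_lattice`).
#' @return A tibble with one row per tube: `n_starts`, `pitch_A`,
#'   `handedness`, `lead_angle_deg`, `d_perp_A`, `a_A` (modal along-strand
#'   spacing), `concentration`, `n_vectors`.
#' @export
detect_starts <- function(particles, axes, radius = NULL, max_starts = 8,
                          nn_window_A = 150, min_concentration = 0.25) {
  unr <- if (all(c("s_A", "phi_deg", "r_A") %in% names(particles))) particles
         else unroll_particles(particles, axes)
  if (is.null(radius)) {
    # median radius only: the bootstrap uncertainty of estimate_radius is
    # not needed for start detection
    radius <- unr |>
      group_by(.data$tube_id) |>
      summarise(radius_A = median(.data$r_A), .groups = "drop")
  }
  rows <- purrr::map(split(unr, unr$tube_id), function(df) {
    R <- radius$radius_A[match(df$tube_id[1], radius$tube_id)]
    fit <- detect_starts_one(df$s_A, df$phi_deg, R, max_starts, nn_window_A,
                             min_concentration)
    tibble(tube_id = df$tube_id[1], !!!fit)
  })
  bind_rows(rows)
}

detect_starts_one <- function(s, phi_deg, R, max_starts = 6, nn_window_A = 150,
                              min_concentration = 0.25) {
  nn <- unrolled_nn_vectors(s, phi_deg, R, window_A = nn_window_A)
  if (nrow(nn) < 4) {
    abort("too few neighbor vectors for lattice analysis",
          class = "coat_insufficient_data")
  }
  # orientation of each NN vector measured from the circumferential (u) axis,
  # folded to the half-turn [0, 180)
  ang <- rad2deg(atan2(nn[, "ds"], nn[, "du"])) %% 180
  br <- seq(0, 180, by = 2)
  hc <- graphics::hist(ang, breaks = br, plot = FALSE)$counts
  center <- br[which.max(hc)] + 1
  # iterated half-turn circular mean of the modal cluster: the histogram
  # mode alone is only 2-degree coarse and noise can displace it
  for (it in 1:3) {
    dev <- abs(wrap180(2 * (ang - center))) / 2
    sel <- dev <= 12
    if (sum(sel) < 3) sel <- dev <= 25
    center <- center + rad2deg(atan2(mean(sin(deg2rad(2 * (ang[sel] - center)))),
                                     mean(cos(deg2rad(2 * (ang[sel] - center)))))) / 2
  }
  # principal axis of the selected cluster (flip vectors to a half-plane)
  v <- nn[sel, , drop = FALSE]
  flip <- abs(wrap180(rad2deg(atan2(v[, "ds"], v[, "du"])) - center)) > 90
  v[flip, ] <- -v[flip, ]
  pc <- prcomp(v, center = FALSE)$rotation[, 1]
  if (sum(pc * colMeans(v)) < 0) pc <- -pc
  theta0 <- atan2(abs(pc["ds"]), abs(pc["du"]))
  handed <- if (sign(pc["du"]) * sign(pc["ds"]) >= 0) 1 else -1
  a_est <- median(sqrt(rowSums(v^2)))
  # refine theta and count rows by circular concentration of the wrapped
  # perpendicular row coordinate; the grid step must resolve the phase
  # coherence of the longest tubes (the wrap count v/V times cot(theta)
  # dominates the dephasing rate)
  u <- R * deg2rad(phi_deg)
  conc_all_on <- function(theta, uu, ss) {
    V <- 2 * pi * R * sin(theta)
    w <- exp(2i * pi * (-uu * sin(theta) + handed * ss * cos(theta)) / V)
    e <- w
    out <- numeric(max_starts)
    for (n in seq_len(max_starts)) {
      out[n] <- Mod(mean(e))
      if (n < max_starts) e <- e * w
    }
    out
  }
  conc_all <- function(theta) conc_all_on(theta, u, s)
  # the grid search only needs enough particles for a clear peak; use a
  # deterministic thinning, then score the final angle on the full tube
  sub <- if (length(s) > 600) round(seq(1, length(s), length.out = 600)) else seq_along(s)
  score <- function(theta) max(conc_all_on(theta, u[sub], s[sub]))
  theta0 <- max(theta0, deg2rad(0.2))
  V0 <- 2 * pi * R * sin(theta0)
  vv0 <- -u * sin(theta0) + handed * s * cos(theta0)
  g0 <- u * cos(theta0) + handed * s * sin(theta0)
  dpsi <- 2 * pi * max_starts *
    (sd(vv0 / V0) / tan(theta0) + sd(g0) / V0)  # phase-spread rate (rad/rad)
  step <- max(deg2rad(2e-4), min(deg2rad(0.05), 0.3 / max(dpsi, 1)))
  search <- function(half_window) {
    lo <- max(theta0 - half_window, deg2rad(0.05))
    hi <- min(theta0 + half_window, deg2rad(89.9))
    grid <- seq(lo, hi, by = step)
    gs <- purrr::map_dbl(grid, score)
    gbest <- grid[which.max(gs)]
    opt <- optimize(score, c(max(lo, gbest - step), min(hi, gbest + step)),
                    maximum = TRUE, tol = 1e-9)
    if (opt$objective >= max(gs)) opt$maximum else gbest
  }
  theta <- search(deg2rad(1))
  cs <- conc_all(theta)
  if (max(cs) < min_concentration) {  # wider fallback window
    theta <- search(deg2rad(4))
    cs <- conc_all(theta)
  }
  n_starts <- which.max(cs)
  if (cs[n_starts] < min_concentration) {
    abort("no helical lattice detected (isotropic neighbor cloud)",
          class = "coat_no_lattice")
  }
  V <- 2 * pi * R * sin(theta)
  list(n_starts = as.integer(n_starts),
       pitch_A = 2 * pi * R * tan(theta),
       handedness = handed,
       lead_angle_deg = rad2deg(theta),
       d_perp_A = V / n_starts,
       a_A = a_est,
       concentration = cs[n_starts],
       n_vectors = nrow(nn))
}

#' Estimate the azimuthal phase of the helical strands
#'
#' Given a fitted helix, locates the strand lines of each tube in the
#' unrolled plane from the circular mean phase of the wrapped perpendicular
#' row coordinate, and converts it to the azimuth of strand 0 at s = 0.
#' [helix_subbox()] poses generated with this phase fall onto the observed
#' strands rather than at an arbitrary azimuth offset.
#'
#' @param particles Particle tibble.
#' @param axes Axis table or list of [tube_axis()] objects.
#' @param helix Helix tibble from [fit_helix()].
#' @return `helix` with a `phi0_deg` column added.
#' @export
estimate_strand_phase <- function(particles, axes, helix) {
  unr <- if (all(c("s_A", "phi_deg", "r_A") %in% names(particles))) particles
         else unroll_particles(particles, axes)
  helix <- as_tibble(helix)
  phi0 <- purrr::map_dbl(seq_len(nrow(helix)), function(i) {
    h <- helix[i, ]
    df <- unr[unr$tube_id == h$tube_id, ]
    R <- h$radius_A
    theta <- deg2rad(h$lead_angle_deg)
    u <- R * deg2rad(df$phi_deg)
    vv <- -u * sin(theta) + h$handedness * df$s_A * cos(theta)
    dperp <- h$d_perp_A
    v0 <- dperp * Arg(mean(exp(2i * pi * vv / dperp))) / (2 * pi)
    # strand 0 passes (s = 0, phi = phi0): its v is -R * phi0 * sin(theta)
    rad2deg(-v0 / (R * sin(theta)))
  })
  helix$phi0_deg <- phi0
  helix
}

#' Fit the full helix model of each tube
#'
#' Composes [estimate_radius()] and [detect_starts()] and fills in the
#' derived per-particle rise and twist from the measured along-strand
#' spacing: `rise = a sin(theta)`, `twist = handedness * a cos(theta) / R`.
#'
#' @inheritParams detect_starts
#' @param ... Passed to [detect_starts()].
#' @return A tibble of class `coat_helix_fit`, one row per tube with
#'   `radius_A`, `radius_sd_A`, `pitch_A`, `n_starts`, `handedness`,
#'   `lead_angle_deg`, `a_A`, `d_perp_A`, `rise_per_particle_A`,
#'   `twist_per_particle_deg`, plus fit diagnostics.
#' @export
#' @examples
#' cfg <- generator_config(sigma_pos_A = 0, sigma_ang_deg = 0,
#'                         dropout_rate = 0, outlier_rate = 0,
#'                         tube_length_min_A = 1600, tube_length_mean_A = 1800,
#'                         tube_length_max_A = 2200)
#' ds <- simulate_dataset(cfg, n_tubes = 1, seed = 3)
#' fit_helix(ds$particles, ds$axes)
fit_helix <- function(particles, axes, ...) {
  unr <- unroll_particles(particles, axes)
  rad <- estimate_radius(unr, axes)
  det <- detect_starts(unr, axes, radius = rad, ...)
  out <- left_join(rad, det, by = "tube_id") |>
    mutate(rise_per_particle_A = .data$a_A * sin(deg2rad(.data$lead_angle_deg)),
           twist_per_particle_deg = .data$handedness *
             rad2deg(.data$a_A * cos(deg2rad(.data$lead_angle_deg)) / .data$radius_A))
  class(out) <- c("coat_helix_fit", class(out))
  out
}

#' @export
tidy.coat_helix_fit <- function(x, ...) {
  x |>
    as_tibble() |>
    tidyr::pivot_longer(cols = c("radius_A", "pitch_A", "n_starts",
                                 "handedness", "lead_angle_deg", "a_A",
                                 "d_perp_A", "rise_per_particle_A",
                                 "twist_per_particle_deg"),
                        names_to = "term", values_to = "estimate") |>
    mutate(std.error = ifelse(.data$term == "radius_A", .data$radius_sd_A, NA_real_)) |>
    select("tube_id", "term", "estimate", "std.error")
}

#' @export
glance.coat_helix_fit <- function(x, ...) {
  tibble(n_tubes = nrow(x),
         n_particles = sum(x$n_particles),
         mean_radius_A = mean(x$radius_A),
         mean_pitch_A = mean(x$pitch_A),
         mean_concentration = mean(x$concentration),
         starts_table = paste(sprintf("%d:%d", sort(unique(x$n_starts)),
                                      tabulate(x$n_starts)[sort(unique(x$n_starts))]),
                              collapse = " "))
}
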