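#' Unroll particles onto cylinder coordinates around their tube axis
#'
#' Realizes the helix parametrization: each particle is assigned the arc
#' length `s_A` of its closest axis point, its radial distance `r_A`, the
#' azimuth `phi_deg` measured in the transported local frame (zero at the
#' transported normal, positive right-handed about the tangent), and the
#' circumferential coordinate `u_A = r_ref * phi_rad`, where `r_ref` is the
#' tube's median radius (so the (s, u) plane is the unrolled tube surface).
#'
#' @param particles Particle tibble with at least `tube_id`, `x_A`, `y_A`,
#'   `z_A`.
#' @param axes Axis table or list of [tube_axis()] objects (see
#'   [build_axes()]).
#' @return The input tibble with columns `s_A`, `r_A`, `phi_deg`, `u_A`
#'   added (existing columns of those names are replaced).
#' @export
unroll_particles <- function(particles, axes) {
  particles <- as_tibble(particles)
  axes <- build_axes(axes)
  split_idx <- split(seq_len(nrow(particles)), particles$tube_id)
  out <- particles
  out$s_A <- out$r_A <- out$phi_deg <- out$u_A <- NA_real_
  for (id in names(split_idx)) {
    ix <- split_idx[[id]]
    ax <- axis_for_tube(axes, id)
    P <- as.matrix(particles[ix, c("x_A", "y_A", "z_A")])
    cp <- closest_axis_point(ax, P, particle_id = particles$particle_id[ix])
    fr <- local_frames(ax, cp$s)
    d <- P - as.matrix(fr[, c("x_A", "y_A", "z_A")])
    dn <- rowSums(d * as.matrix(fr[, c("nx", "ny", "nz")]))
    db <- rowSums(d * as.matrix(fr[, c("bx", "by", "bz")]))
    r <- sqrt(dn^2 + db^2)
    phi <- rad2deg(atan2(db, dn))
    rref <- median(r)
    out$s_A[ix] <- cp$s
    out$r_A[ix] <- r
    out$phi_deg[ix] <- phi
    out$u_A[ix] <- rref * deg2rad(phi)
  }
  out
}

# two-stage closest-point search on the dense axis polyline
closest_axis_point <- function(ax, P, particle_id = NULL) {
  m <- nrow(ax$pts)
  stride <- max(1L, min(25L, m %/% 4L))
  ic <- unique(c(seq(1L, m, by = stride), m))
  D <- ax$pts[ic, , drop = FALSE]
  n <- nrow(P)
  # coarse distances, chunked to bound memory
  best <- integer(n)
  bestd <- numeric(n)
  second_far <- logical(n)
  chunk <- max(1L, floor(2e6 / length(ic)))
  for (st in seq(1L, n, by = chunk)) {
    en <- min(n, st + chunk - 1L)
    idx <- st:en
    d2 <- outer(rowSums(P[idx, , drop = FALSE]^2), rowSums(D^2), "+") -
      2 * P[idx, , drop = FALSE] %*% t(D)
    jb <- max.col(-d2, ties.method = "first")
    best[idx] <- ic[jb]
    bestd[idx] <- sqrt(pmax(d2[cbind(seq_along(jb), jb)], 0))
    # a second, distant coarse point almost as close flags branch ambiguity
    near <- d2 <= (bestd[idx] + 1)^2
    faridx <- abs(outer(ic[jb], ic, "-")) > 4L * stride
    second_far[idx] <- rowSums(near & faridx) > 0
  }
  if (any(second_far)) {
    who <- if (is.null(particle_id)) which(second_far) else particle_id[second_far]
    abort(paste0("ambiguous axis assignment (particle equidistant from two ",
                 "axis branches): ", paste(utils::head(who, 5), collapse = ", ")),
          class = "coat_ambiguity_error")
  }
  # refine on the dense grid around the coarse minimum
  w <- stride + 1L
  off <- -w:w
  idxm <- pmin(pmax(outer(best, off, "+"), 1L), m)
  dd <- matrix(0, n, length(off))
  for (k in 1:3) {
    dd <- dd + (P[, k] - matrix(ax$pts[idxm, k], n))^2
  }
  jb <- max.col(-dd, ties.method = "first")
  ifin <- idxm[cbind(seq_len(n), jb)]
  # foot-point refinement below the dense grid: project the residual onto
  # the local tangent (exact on straight segments)
  step <- if (length(ax$s) > 1) ax$s[2] - ax$s[1] else 1
  tg <- ax$tangent[ifin, , drop = FALSE]
  delta <- rowSums((P - ax$pts[ifin, , drop = FALSE]) * tg)
  delta <- pmin(pmax(delta, -step), step)
  s_ref <- pmin(pmax(ax$s[ifin] + delta, 0), ax$length_A)
  list(s = s_ref, dist = sqrt(dd[cbind(seq_len(n), jb)]))
}

#' Roll cylinder coordinates back to 3D positions
#'
#' Inverse of [unroll_particles()]: reconstructs `x_A`, `y_A`, `z_A` from
#' `tube_id`, `s_A`, `phi_deg` and `r_A`.
#'
#' @param coords Tibble with `tube_id`, `s_A`, `phi_deg`, `r_A`.
#' @param axes Axis table or list of [tube_axis()] objects.
#' @return `coords` with `x_A`, `y_A`, `z_A` (re)computed.
#' @export
roll_particles <- function(coords, axes) {
  coords <- as_tibble(coords)
  axes <- build_axes(axes)
  split_idx <- split(seq_len(nrow(coords)), coords$tube_id)
  out <- coords
  out$x_A <- out$y_A <- out$z_A <- NA_real_
  for (id in names(split_idx)) {
    ix <- split_idx[[id]]
    ax <- axis_for_tube(axes, id)
    fr <- local_frames(ax, coords$s_A[ix])
    phi <- deg2rad(coords$phi_deg[ix])
    r <- coords$r_A[ix]
    radial <- as.matrix(fr[, c("nx", "ny", "nz")]) * cos(phi) +
      as.matrix(fr[, c("bx", "by", "bz")]) * sin(phi)
    p <- as.matrix(fr[, c("x_A", "y_A", "z_A")]) + radial * r
    out$x_A[ix] <- p[, 1]; out$y_A[ix] <- p[, 2]; out$z_A[ix] <- p[, 3]
  }
  out
}
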