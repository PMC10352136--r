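#' Relative poses of all neighboring particles (neighborhood cloud)
#'
#' For every ordered pair of particles of the same tube within `cutoff_A`,
#' the neighbor's position is expressed in the reference particle's own
#' orientation frame (dx along the particle x axis, dy lateral, dz radial).
#' Pooling these relative positions over all particles produces the
#' neighborhood plot whose density peaks define the lattice vectors.
#'
#' @param particles Particle tibble with orientations.
#' @param cutoff_A Neighbor cutoff distance (> 0).
#' @param axes Optional axis table/list; when given, the rotation angle
#'   about the tube axis between the two particles is attached as
#'   `axial_angle_deg`.
#' @return A tibble of class `coat_cloud`: `tube_id`, `id_i`, `id_j`,
#'   `dx_A`, `dy_A`, `dz_A`, `dist_A` and (optionally) `axial_angle_deg`,
#'   with attribute `cutoff_A`. Contains n*(n-1) rows for n mutually close
#'   particles.
#' @export
relative_poses <- function(particles, cutoff_A, axes = NULL) {
  if (!is.numeric(cutoff_A) || cutoff_A <= 0) {
    abort("`cutoff_A` must be positive", class = "coat_invalid_parameter")
  }
  particles <- as_tibble(particles)
  if (!is.null(axes) && !"phi_deg" %in% names(particles)) {
    particles <- unroll_particles(particles, axes)
  }
  out <- split(particles, particles$tube_id) |>
    purrr::map(function(df) {
      P <- as.matrix(df[, c("x_A", "y_A", "z_A")])
      n <- nrow(P)
      if (n < 2) return(NULL)
      # s-window prefilter when cylinder coordinates are available
      if ("s_A" %in% names(df)) {
        ord <- order(df$s_A)
        df <- df[ord, ]; P <- P[ord, , drop = FALSE]
        ssorted <- df$s_A
        lo <- findInterval(ssorted - cutoff_A - 1e-9, ssorted) + 1L
        hi <- findInterval(ssorted + cutoff_A + 1e-9, ssorted)
        cand <- purrr::map(seq_len(n), function(i) setdiff(lo[i]:hi[i], i))
      } else {
        cand <- purrr::map(seq_len(n), function(i) setdiff(seq_len(n), i))
      }
      Rm <- euler_rows_to_matrices(df$rot_deg, df$tilt_deg, df$psi_deg)
      pieces <- purrr::map(seq_len(n), function(i) {
        j <- cand[[i]]
        if (!length(j)) return(NULL)
        d <- P[j, , drop = FALSE] -
          matrix(P[i, ], length(j), 3, byrow = TRUE)
        dist <- sqrt(rowSums(d^2))
        sel <- dist <= cutoff_A
        if (!any(sel)) return(NULL)
        j <- j[sel]; d <- d[sel, , drop = FALSE]; dist <- dist[sel]
        dl <- d %*% Rm[[i]]  # = t(R_i) %*% d for each row
        res <- tibble(tube_id = df$tube_id[1],
                      id_i = df$particle_id[i], id_j = df$particle_id[j],
                      dx_A = dl[, 1], dy_A = dl[, 2], dz_A = dl[, 3],
                      dist_A = dist)
        if ("phi_deg" %in% names(df)) {
          res$axial_angle_deg <- wrap180(df$phi_deg[j] - df$phi_deg[i])
        }
        res
      })
      bind_rows(pieces)
    }) |>
    bind_rows()
  attr(out, "cutoff_A") <- cutoff_A
  class(out) <- c("coat_cloud", class(out))
  out
}

#' Find density peaks of a neighborhood cloud by k-means
#'
#' k-means on the relative positions `(dx, dy, dz)` with 50 restarts under a
#' fixed seed; the best-inertia solution is kept. Centroids are ordered by
#' occupancy (cluster size) descending, then by distance from the origin.
#'
#' @param cloud A `coat_cloud` from [relative_poses()].
#' @param k Number of peaks (default 6: two along-strand and four lateral
#'   first-shell neighbors).
#' @param seed Seed for the restarts.
#' @param nstart Number of random restarts (default 50).
#' @return A tibble `peak`, `dx_A`, `dy_A`, `dz_A`, `occupancy`, with the
#'   per-pose cluster assignment attached as attribute `assignment` (in
#'   cloud row order).
#' @export
find_peaks <- function(cloud, k = 6, seed = 1L, nstart = 50) {
  X <- as.matrix(cloud[, c("dx_A", "dy_A", "dz_A")])
  if (nrow(X) < k) {
    abort(sprintf("neighborhood cloud has %d poses but k = %d", nrow(X), k),
          class = "coat_insufficient_data")
  }
  km <- with_seed(seed, function() {
    # individual restarts can hit the Quick-TRANSfer cap on heavily
    # overlapping clusters; the best-inertia solution is still well defined
    suppressWarnings(kmeans(X, centers = k, nstart = nstart, iter.max = 100))
  })
  ord <- order(-km$size, sqrt(rowSums(km$centers^2)))
  out <- tibble(peak = seq_len(k),
                dx_A = km$centers[ord, 1],
                dy_A = km$centers[ord, 2],
                dz_A = km$centers[ord, 3],
                occupancy = km$size[ord])
  attr(out, "assignment") <- match(km$cluster, ord)
  out
}

#' Derive lattice parameters from neighborhood peaks
#'
#' Identifies centro-symmetric centroid pairs (two centroids whose sum-norm
#' is below a quarter of the shorter one), takes lattice vector `a` as the
#' pair most parallel to the strand direction (the particle x axis), `b` as
#' the next-nearest independent pair, and reads the lattice angle `alpha`
#' off the tangent-plane (dx, dy) components. The relative angle about the
#' tube axis between consecutive along-strand particles (`delta_angle_deg`)
#' is averaged over the cloud poses belonging to the `a` peaks, when the
#' cloud is supplied with axial angles.
#'
#' @param peaks Centroid tibble from [find_peaks()].
#' @param helix One-row helix tibble for the tube (supplies `radius_A`,
#'   `n_starts`).
#' @param cloud Optional `coat_cloud` with `axial_angle_deg` for
#'   `delta_angle_deg`.
#' @return One-row tibble: `a_A`, `b_A`, `alpha_deg`, `radius_A`,
#'   `delta_angle_deg`, `n_starts`.
#' @export
lattice_from_peaks <- function(peaks, helix, cloud = NULL) {
  C <- as.matrix(peaks[, c("dx_A", "dy_A", "dz_A")])
  nrm <- sqrt(rowSums(C^2))
  # centro-symmetry is assessed on the tangent-plane components: membrane
  # curvature makes both members of a pair sag radially (dz < 0), so the
  # full 3D sum-norm would never cancel
  pairs <- list()
  used <- logical(nrow(C))
  for (i in seq_len(nrow(C) - 1)) {
    if (used[i]) next
    for (j in seq((i + 1), nrow(C))) {
      if (used[j]) next
      if (sqrt(sum((C[i, 1:2] + C[j, 1:2])^2)) < 0.25 * min(nrm[i], nrm[j])) {
        pairs[[length(pairs) + 1]] <- c(i, j)
        used[i] <- used[j] <- TRUE
        break
      }
    }
  }
  if (length(pairs) < 2) {
    abort("fewer than two centro-symmetric peak pairs: lattice undetermined",
          class = "coat_lattice_undetermined")
  }
  h <- as.list(helix)
  # unbend each pair vector onto the cylinder surface: chord components in
  # the particle frame (x along strand, z radial) are mapped back to
  # in-surface (along-strand, lateral) arc coordinates using the fitted
  # radius, lead angle and handedness; without helix geometry the raw
  # tangent-plane components are used
  unbend <- function(vec) {
    if (is.null(h$radius_A) || is.null(h$lead_angle_deg) || !is.finite(h$radius_A)) {
      return(vec[1:2])
    }
    R <- h$radius_A
    th <- deg2rad(h$lead_angle_deg)
    hd <- if (is.null(h$handedness)) 1 else h$handedness
    dels <- vec[1] * sin(th) + vec[2] * hd * cos(th)          # axial
    q <- vec[1] * hd * cos(th) - vec[2] * sin(th)             # R sin(dbeta)
    du <- R * atan2(q / R, 1 + vec[3] / R)                    # circumferential arc
    c(along = dels * sin(th) + hd * du * cos(th),
      lateral = hd * dels * cos(th) - du * sin(th))
  }
  # unbend every centroid individually (the radial sag carries the arc
  # information and is equal, not opposite, across a symmetric pair), then
  # average each pair on the surface
  surf_cent <- t(vapply(seq_len(nrow(C)), function(i) unbend(C[i, ]), numeric(2)))
  surf <- t(vapply(pairs, function(p) (surf_cent[p[1], ] - surf_cent[p[2], ]) / 2,
                   numeric(2)))
  pair_vec <- t(vapply(pairs, function(p) (C[p[1], ] - C[p[2], ]) / 2, numeric(3)))
  plen <- sqrt(rowSums(surf^2))
  # a: most parallel to the strand direction (the along-strand axis)
  cosx <- abs(surf[, 1]) / plen
  ia <- which.max(cosx)
  av <- surf[ia, ]
  if (av[1] < 0) av <- -av
  av3 <- if (pair_vec[ia, 1] < 0) -pair_vec[ia, ] else pair_vec[ia, ]
  # b: shortest remaining pair not (anti)parallel to a
  rest <- setdiff(seq_len(nrow(surf)), ia)
  angs <- purrr::map_dbl(rest, function(i) {
    rad2deg(acos(pmin(1, abs(sum(surf[i, ] * av)) / (plen[i] * sqrt(sum(av^2))))))
  })
  rest <- rest[angs > 20]
  if (!length(rest)) {
    abort("no independent second lattice vector found", class = "coat_lattice_undetermined")
  }
  ib <- rest[which.min(plen[rest])]
  bv <- surf[ib, ]
  if (bv[2] < 0) bv <- -bv
  alpha <- rad2deg(acos(pmax(-1, pmin(1, sum(av * bv) /
                                        (sqrt(sum(av^2)) * sqrt(sum(bv^2)))))))
  # canonical branch: the same lattice is described by (alpha, b) and
  # (180 - alpha, -b); report alpha in (0, 90]
  if (alpha > 90) alpha <- 180 - alpha
  delta <- NA_real_
  if (!is.null(cloud) && "axial_angle_deg" %in% names(cloud)) {
    X <- as.matrix(cloud[, c("dx_A", "dy_A", "dz_A")])
    da <- sqrt(rowSums((X - matrix(av3, nrow(X), 3, byrow = TRUE))^2))
    db2 <- sqrt(rowSums((X + matrix(av3, nrow(X), 3, byrow = TRUE))^2))
    on_a <- pmin(da, db2) < 0.3 * sqrt(sum(av3^2))
    if (any(on_a)) delta <- mean(abs(cloud$axial_angle_deg[on_a]))
  }
  tibble(tube_id = if (!is.null(h$tube_id)) h$tube_id else NA_character_,
         a_A = plen[ia], b_A = plen[ib], alpha_deg = alpha,
         radius_A = h$radius_A,
         delta_angle_deg = delta,
         n_starts = h$n_starts)
}

#' Project a neighborhood cloud onto a 2D histogram grid
#'
#' @param cloud A `coat_cloud`.
#' @param plane `"tangent"` (dx vs dy: the in-surface projection) or
#'   `"axial"` (dx vs dz).
#' @param bin_A Bin width in Angstrom (> 0).
#' @param limits Optional `c(min, max)` applied to both axes; defaults to
#'   the data range expanded to whole bins.
#' @return A tibble `x_A`, `y_A` (bin centers), `count`, with attributes
#'   `origin`, `bin_A`, `plane`. Total count equals the number of poses
#'   inside the grid bounds.
#' @export
neighborhood_histogram <- function(cloud, plane = c("tangent", "axial"),
                                   bin_A = 2, limits = NULL) {
  plane <- match.arg(plane)
  if (bin_A <= 0) abort("`bin_A` must be positive", class = "coat_invalid_parameter")
  x <- cloud$dx_A
  y <- if (plane == "tangent") cloud$dy_A else cloud$dz_A
  if (is.null(limits)) {
    lim <- range(c(x, y))
    limits <- c(floor(lim[1] / bin_A) * bin_A, ceiling(lim[2] / bin_A) * bin_A)
  }
  brk <- seq(limits[1], limits[2], by = bin_A)
  if (brk[length(brk)] < limits[2]) brk <- c(brk, brk[length(brk)] + bin_A)
  inside <- x >= brk[1] & x <= brk[length(brk)] & y >= brk[1] & y <= brk[length(brk)]
  xi <- pmin(findInterval(x[inside], brk, rightmost.closed = TRUE), length(brk) - 1)
  yi <- pmin(findInterval(y[inside], brk, rightmost.closed = TRUE), length(brk) - 1)
  tab <- table(factor(xi, levels = seq_len(length(brk) - 1)),
               factor(yi, levels = seq_len(length(brk) - 1)))
  centers <- brk[-length(brk)] + bin_A / 2
  out <- tidyr::expand_grid(xi = seq_along(centers), yi = seq_along(centers)) |>
    mutate(x_A = centers[.data$xi], y_A = centers[.data$yi],
           count = as.integer(tab[cbind(.data$xi, .data$yi)])) |>
    select("x_A", "y_A", "count")
  attr(out, "origin") <- limits[1]
  attr(out, "bin_A") <- bin_A
  attr(out, "plane") <- plane
  out
}
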