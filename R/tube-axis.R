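#' Build a tube-axis spline from control points
#'
#' A tube axis is the traced centerline of a membrane tubule. The control
#' points are interpolated with a natural cubic spline (per coordinate,
#' against the chord-length parameter), then reparametrized by arc length on
#' a dense 1 Angstrom grid. Local orthonormal frames (tangent, normal,
#' binormal) are attached by rotation-minimizing (parallel) transport, seeded
#' with a fixed normal at s = 0, so that frames vary continuously along the
#' tube and azimuth angles measured against them are well defined.
#'
#' @param control_points A numeric matrix or data frame with columns
#'   `x_A`, `y_A`, `z_A` (or an unnamed 3-column matrix), in Angstrom,
#'   ordered along the tube. At least 2 distinct points.
#' @param tube_id Identifier attached to the axis (default `"tube"`).
#' @param step_A Arc-length step of the dense reparametrization (default 1).
#' @return An object of class `tube_axis`: a list with elements `tube_id`,
#'   `s` (dense arc-length grid), `pts`, `tangent`, `normal`, `binormal`
#'   (dense n x 3 matrices), `length_A` and `control_points`.
#' @export
#' @examples
#' ax <- tube_axis(cbind(x_A = 0, y_A = 0, z_A = seq(0, 1000, by = 250)))
#' ax$length_A
tube_axis <- function(control_points, tube_id = "tube", step_A = 1) {
  cp <- as.matrix(as.data.frame(control_points))
  if (!is.null(colnames(cp)) && all(c("x_A", "y_A", "z_A") %in% colnames(cp))) {
    cp <- cp[, c("x_A", "y_A", "z_A"), drop = FALSE]
  }
  storage.mode(cp) <- "double"
  if (nrow(cp) < 2) {
    abort("a tube axis needs at least 2 control points", class = "coat_invalid_input")
  }
  seg <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-nrow(cp), , drop = FALSE])^2))
  if (any(seg == 0)) {
    abort("consecutive axis control points must be distinct", class = "coat_invalid_input")
  }
  tcp <- c(0, cumsum(seg))
  if (nrow(cp) == 2) {
    fx <- function(t) cp[1, 1] + (cp[2, 1] - cp[1, 1]) * t / tcp[2]
    fy <- function(t) cp[1, 2] + (cp[2, 2] - cp[1, 2]) * t / tcp[2]
    fz <- function(t) cp[1, 3] + (cp[2, 3] - cp[1, 3]) * t / tcp[2]
  } else {
    fx <- splinefun(tcp, cp[, 1], method = "natural")
    fy <- splinefun(tcp, cp[, 2], method = "natural")
    fz <- splinefun(tcp, cp[, 3], method = "natural")
  }
  # dense chord sampling, then arc-length reparametrization at step_A
  tfine <- seq(0, tcp[length(tcp)], length.out = max(32L, ceiling(tcp[length(tcp)] / (step_A / 2))))
  pf <- cbind(fx(tfine), fy(tfine), fz(tfine))
  sf <- c(0, cumsum(sqrt(rowSums((pf[-1, , drop = FALSE] - pf[-nrow(pf), , drop = FALSE])^2))))
  total <- sf[length(sf)]
  sg <- seq(0, total, by = step_A)
  if (sg[length(sg)] < total) sg <- c(sg, total)
  tg <- approx(sf, tfine, xout = sg, ties = "ordered")$y
  pts <- cbind(fx(tg), fy(tg), fz(tg))
  # tangents by central differences on the dense grid
  nd <- nrow(pts)
  tanm <- rbind(pts[2, ] - pts[1, ],
                pts[3:nd, , drop = FALSE] - pts[1:(nd - 2), , drop = FALSE],
                pts[nd, ] - pts[nd - 1, ])
  tanm <- tanm / sqrt(rowSums(tanm^2))
  # seed normal: basis vector least aligned with the first tangent
  t0 <- tanm[1, ]
  e <- diag(3)[, which.min(abs(t0))]
  n0 <- e - sum(e * t0) * t0
  n0 <- n0 / sqrt(sum(n0^2))
  nrm <- .pt_frames(pts, tanm, n0)
  bin <- cbind(tanm[, 2] * nrm[, 3] - tanm[, 3] * nrm[, 2],
               tanm[, 3] * nrm[, 1] - tanm[, 1] * nrm[, 3],
               tanm[, 1] * nrm[, 2] - tanm[, 2] * nrm[, 1])
  structure(list(tube_id = tube_id, s = sg, pts = pts, tangent = tanm,
                 normal = nrm, binormal = bin, length_A = total,
                 control_points = cp),
            class = "tube_axis")
}

#' @export
print.tube_axis <- function(x, ...) {
  cat(sprintf("<tube_axis %s: length %.1f A (%.1f nm), %d control points>\n",
              x$tube_id, x$length_A, x$length_A / 10, nrow(x$control_points)))
  invisible(x)
}

#' Build tube-axis objects from an axis table
#'
#' @param axes A tibble with columns `tube_id`, `point_index`, `x_A`, `y_A`,
#'   `z_A` (one row per control point), or an already-built list of
#'   [tube_axis()] objects (returned unchanged).
#' @return A named list of `tube_axis` objects, one per tube.
#' @export
build_axes <- function(axes) {
  if (is.list(axes) && !is.data.frame(axes) &&
      all(purrr::map_lgl(axes, inherits, "tube_axis"))) {
    return(axes)
  }
  axes <- as_tibble(axes)
  need <- c("tube_id", "x_A", "y_A", "z_A")
  miss <- setdiff(need, names(axes))
  if (length(miss)) {
    abort(paste0("axis table is missing column(s): ", paste(miss, collapse = ", ")),
          class = "coat_schema_error")
  }
  if ("point_index" %in% names(axes)) axes <- arrange(axes, .data$tube_id, .data$point_index)
  split(axes, axes$tube_id) |>
    purrr::imap(function(df, id) tube_axis(df[, c("x_A", "y_A", "z_A")], tube_id = id))
}

axis_for_tube <- function(axes_list, tube_id) {
  ax <- axes_list[[as.character(tube_id)]]
  if (is.null(ax)) {
    abort(sprintf("no axis found for tube '%s'", tube_id), class = "coat_invalid_input")
  }
  ax
}

#' Resample a tube axis at regular arc-length spacing
#'
#' Mirrors the oversampling step of lattice-guided subtomogram workflows,
#' where subvolumes are extracted at a fixed pixel spacing along the traced
#' tube (e.g. every 36 pixels at 2.73 Angstrom per pixel = 98.28 Angstrom).
#'
#' @param axes An axis table, a list of [tube_axis()] objects, or a single
#'   `tube_axis`.
#' @param spacing_A Arc-length spacing in Angstrom (> 0).
#' @return A tibble with columns `tube_id`, `s_A`, `x_A`, `y_A`, `z_A`.
#'   The first point of every tube sits at `s_A = 0`; consecutive gaps equal
#'   `spacing_A` except possibly the last.
#' @export
#' @examples
#' ax <- tube_axis(cbind(x_A = 0, y_A = 0, z_A = c(0, 1000)))
#' resample_axis(ax, 100)
resample_axis <- function(axes, spacing_A) {
  if (!is.numeric(spacing_A) || length(spacing_A) != 1 || spacing_A <= 0) {
    abort("`spacing_A` must be a single positive number", class = "coat_invalid_parameter")
  }
  if (inherits(axes, "tube_axis")) axes <- stats::setNames(list(axes), axes$tube_id)
  axes <- build_axes(axes)
  purrr::map(axes, function(ax) {
    sq <- seq(0, ax$length_A, by = spacing_A)
    p <- axis_point_at(ax, sq)
    tibble(tube_id = ax$tube_id, s_A = sq,
           x_A = p[, 1], y_A = p[, 2], z_A = p[, 3])
  }) |> bind_rows()
}

# linear interpolation of the dense polyline at arc lengths s (vectorised)
axis_point_at <- function(ax, s) {
  interp_rows(ax$s, ax$pts, s)
}

interp_rows <- function(grid, mat, s) {
  i <- findInterval(s, grid, all.inside = TRUE)
  w <- (s - grid[i]) / (grid[i + 1] - grid[i])
  mat[i, , drop = FALSE] * (1 - w) + mat[i + 1, , drop = FALSE] * w
}

#' Local orthonormal frame(s) along a tube axis
#'
#' Returns the rotation-minimizing frame at the requested arc lengths:
#' tangent along the curve, and a transported normal/binormal pair fixing
#' the azimuth zero. The frame is right-handed (`tangent = normal x binormal`
#' cross products are consistent: `binormal = tangent x normal`).
#'
#' @param axis A single [tube_axis()] object.
#' @param s_A Arc lengths in `[0, length_A]` (vector allowed).
#' @return A tibble with the origin (`x_A`,`y_A`,`z_A`) and frame vectors
#'   (`t?`, `n?`, `b?` columns for tangent, normal, binormal).
#' @export
local_frames <- function(axis, s_A) {
  stopifnot(inherits(axis, "tube_axis"))
  if (any(s_A < -1e-9 | s_A > axis$length_A + 1e-9)) {
    abort("`s_A` out of range [0, length_A]", class = "coat_invalid_parameter")
  }
  s_A <- pmin(pmax(s_A, 0), axis$length_A)
  p <- interp_rows(axis$s, axis$pts, s_A)
  tn <- interp_rows(axis$s, axis$tangent, s_A)
  nm <- interp_rows(axis$s, axis$normal, s_A)
  # re-orthonormalise after interpolation
  tn <- tn / sqrt(rowSums(tn^2))
  nm <- nm - rowSums(nm * tn) * tn
  nm <- nm / sqrt(rowSums(nm^2))
  bn <- cbind(tn[, 2] * nm[, 3] - tn[, 3] * nm[, 2],
              tn[, 3] * nm[, 1] - tn[, 1] * nm[, 3],
              tn[, 1] * nm[, 2] - tn[, 2] * nm[, 1])
  tibble(tube_id = axis$tube_id, s_A = s_A,
         x_A = p[, 1], y_A = p[, 2], z_A = p[, 3],
         tx = tn[, 1], ty = tn[, 2], tz = tn[, 3],
         nx = nm[, 1], ny = nm[, 2], nz = nm[, 3],
         bx = bn[, 1], by = bn[, 2], bz = bn[, 3])
}

# maximum curvature (1/A) of the dense polyline, for axis QC filters
axis_max_curvature <- function(ax, window = 5L) {
  p <- ax$pts
  n <- nrow(p)
  if (n < 2L * window + 1L) return(0)
  i <- seq(window + 1L, n - window)
  d1 <- (p[i + window, , drop = FALSE] - p[i - window, , drop = FALSE]) / (2 * window)
  d2 <- (p[i + window, , drop = FALSE] - 2 * p[i, , drop = FALSE] +
           p[i - window, , drop = FALSE]) / (window^2)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  k <- sqrt(rowSums(cr^2)) / (sqrt(rowSums(d1^2))^3)
  max(k, na.rm = TRUE)
}
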