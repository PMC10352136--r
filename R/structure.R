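#' Default van der Waals radii used for surface-area calculations
#'
#' C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Angstrom; anything else 1.80.
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

#' Read an atomic structure into an atom tibble
#'
#' Thin wrapper over `bio3d` (PDB and mmCIF). Hydrogens are kept; waters
#' are dropped. Radii are assigned from [vdw_radii()] by element.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param keep_hetero Keep HETATM records (default FALSE).
#' @return Atom tibble: `element`, `name`, `chain`, `resno`, `resid`,
#'   `x_A`, `y_A`, `z_A`, `radius_A`.
#' @export
read_structure <- function(path, keep_hetero = FALSE) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading structures requires the 'bio3d' package")
  }
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  at <- as_tibble(pdb$atom)
  if (!keep_hetero) at <- filter(at, .data$type == "ATOM")
  at <- filter(at, !.data$resid %in% c("HOH", "WAT"))
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  }
  elem <- toupper(trimws(elem))
  rad <- vdw_radii()[elem]
  rad[is.na(rad)] <- 1.80
  tibble(element = elem, name = at$elety, chain = at$chain,
         resno = at$resno, resid = at$resid,
         x_A = at$x, y_A = at$y, z_A = at$z, radius_A = unname(rad))
}

#' Helical symmetry expansion of an asymmetric unit
#'
#' Replicates an atom tibble (or bare point set) according to a helix
#' model whose axis is the z axis: copy `j` on strand `m` is rotated about
#' z by `j * twist_per_particle + m * 360 / n_starts` degrees and
#' translated by `j * rise_per_particle` along z. Chain identifiers are
#' uniquified per copy.
#'
#' @param x Atom tibble (with `x_A`, `y_A`, `z_A` and optionally `chain`)
#'   or a matrix/tibble of 3D points.
#' @param helix Helix tibble/list with `n_starts`,
#'   `twist_per_particle_deg`, `rise_per_particle_A`.
#' @param n_steps Copies per strand (>= 1).
#' @param max_copies Refuse expansions beyond this copy count (default 1000).
#' @return A list with `atoms` (expanded tibble, added columns `copy`,
#'   `strand`, `step`) and `operators` (tibble of rotation angle and axial
#'   translation per copy).
#' @export
expand_helix <- function(x, helix, n_steps, max_copies = 1000) {
  h <- as.list(helix)
  stopifnot(n_steps >= 1)
  n_copies <- h$n_starts * n_steps
  if (n_copies > max_copies) {
    abort(sprintf("expansion would create %d copies (cap %d)", n_copies, max_copies),
          class = "coat_size_error")
  }
  df <- as_tibble(as.data.frame(x))
  if (!all(c("x_A", "y_A", "z_A") %in% names(df))) {
    names(df)[1:3] <- c("x_A", "y_A", "z_A")
  }
  P <- as.matrix(df[, c("x_A", "y_A", "z_A")])
  ops <- tidyr::expand_grid(strand = seq_len(h$n_starts) - 1L,
                            step = seq_len(n_steps) - 1L) |>
    mutate(copy = dplyr::row_number(),
           angle_deg = .data$step * h$twist_per_particle_deg +
             .data$strand * 360 / h$n_starts,
           dz_A = .data$step * h$rise_per_particle_A)
  out <- purrr::pmap(ops, function(strand, step, copy, angle_deg, dz_A) {
    th <- deg2rad(angle_deg)
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    Pn <- P %*% t(Rz)
    d <- df
    d$x_A <- Pn[, 1]; d$y_A <- Pn[, 2]; d$z_A <- Pn[, 3] + dz_A
    d$copy <- copy; d$strand <- strand; d$step <- step
    if ("chain" %in% names(d)) d$chain <- paste0(d$chain, "_", copy)
    d
  }) |> bind_rows()
  list(atoms = out, operators = ops)
}

#' Fit a circle to a curved point set (Taubin algebraic fit)
#'
#' Projects the points onto their best-fit plane (dropping the smallest
#' principal axis) and fits a circle with Taubin's algebraic method. Used
#' to measure the preferred membrane curvature of a BAR-domain dimer from
#' its backbone trace.
#'
#' @param points Matrix or tibble of 3D points (`x_A`, `y_A`, `z_A` or
#'   three unnamed columns); at least 3 non-collinear points.
#' @return A list: `radius_A`, `diameter_nm`, `center_A` (3D), `normal`
#'   (plane normal), `rms_residual_A`.
#' @export
fit_curvature_circle <- function(points) {
  P <- as.matrix(as.data.frame(points))
  if (!is.null(colnames(P)) && all(c("x_A", "y_A", "z_A") %in% colnames(P))) {
    P <- P[, c("x_A", "y_A", "z_A")]
  }
  storage.mode(P) <- "double"
  if (nrow(P) < 3) abort("need at least 3 points", class = "coat_degenerate_input")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-9 * sv$d[1]) {
    abort("points are collinear: no unique circle", class = "coat_degenerate_input")
  }
  basis <- sv$v[, 1:2]
  normal <- sv$v[, 3]
  XY <- Pc %*% basis
  fit <- taubin_circle(XY[, 1], XY[, 2])
  res <- sqrt((XY[, 1] - fit$cx)^2 + (XY[, 2] - fit$cy)^2) - fit$r
  list(radius_A = fit$r,
       diameter_nm = 2 * fit$r / 10,
       center_A = as.numeric(ctr + basis %*% c(fit$cx, fit$cy)),
       normal = as.numeric(normal),
       rms_residual_A = sqrt(mean(res^2)))
}

# Taubin (1991) algebraic circle fit in 2D
taubin_circle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  u <- x - mx; v <- y - my
  z <- u^2 + v^2
  zm <- mean(z)
  Z <- cbind((z - zm) / (2 * sqrt(zm)), u, v)
  sv <- svd(Z)
  A <- sv$v[, 3]
  a0 <- A[1] / (2 * sqrt(zm))
  b1 <- A[2]; b2 <- A[3]
  c0 <- -zm * a0
  cx <- -b1 / (2 * a0)
  cy <- -b2 / (2 * a0)
  r <- sqrt(cx^2 + cy^2 - c0 / a0)
  list(cx = cx + mx, cy = cy + my, r = r)
}

# deterministic, roughly even unit-sphere point template (Fibonacci spiral)
sphere_template <- function(n_points) {
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic Fibonacci point template on each
#' atom's probe-expanded sphere: a test point is accessible iff it lies
#' outside every neighboring atom's expanded sphere.
#'
#' @param atoms Atom tibble with `x_A`, `y_A`, `z_A`, `radius_A`.
#' @param probe_A Probe radius (default 1.4, water).
#' @param n_points Test points per atom (>= 100; default 960).
#' @return The input tibble with a per-atom `sasa_A2` column added.
#' @export
sasa_atoms <- function(atoms, probe_A = 1.4, n_points = 960) {
  stopifnot(probe_A > 0, n_points >= 100)
  atoms <- as_tibble(atoms)
  if (any(atoms$radius_A <= 0)) {
    abort("zero or negative atom radius", class = "coat_invalid_input")
  }
  P <- as.matrix(atoms[, c("x_A", "y_A", "z_A")])
  re <- atoms$radius_A + probe_A
  n <- nrow(P)
  tpl <- sphere_template(n_points)
  # neighbor prefilter via x-sorted window
  ord <- order(P[, 1])
  xs <- P[ord, 1]
  maxre <- max(re)
  sasa <- numeric(n)
  for (ii in seq_len(n)) {
    cut <- re[ii] + maxre
    lo <- findInterval(P[ii, 1] - cut, xs) + 1L
    hi <- findInterval(P[ii, 1] + cut, xs)
    nb <- ord[lo:hi]
    nb <- nb[nb != ii]
    if (length(nb)) {
      d2 <- (P[nb, 1] - P[ii, 1])^2 + (P[nb, 2] - P[ii, 2])^2 + (P[nb, 3] - P[ii, 3])^2
      nb <- nb[d2 < (re[ii] + re[nb])^2]
    }
    if (!length(nb)) {
      sasa[ii] <- 4 * pi * re[ii]^2
      next
    }
    pts <- tpl * re[ii] + matrix(P[ii, ], n_points, 3, byrow = TRUE)
    acc <- rep(TRUE, n_points)
    for (jj in nb) {
      if (!any(acc)) break
      w <- which(acc)
      d2 <- (pts[w, 1] - P[jj, 1])^2 + (pts[w, 2] - P[jj, 2])^2 +
        (pts[w, 3] - P[jj, 3])^2
      acc[w[d2 < re[jj]^2]] <- FALSE
    }
    sasa[ii] <- 4 * pi * re[ii]^2 * sum(acc) / n_points
  }
  atoms$sasa_A2 <- sasa
  atoms
}

#' Interface buried area and polar fraction between two chain groups
#'
#' `buried = SASA(A alone) + SASA(B alone) - SASA(complex)` (the two-sided
#' sum over both protomers). The polar fraction is the share of the buried
#' area contributed by nitrogen and oxygen atoms (a common, but
#' definition-dependent, convention; sulfur is counted apolar).
#'
#' @param atoms Atom tibble (see [read_structure()]).
#' @param chains_A,chains_B Disjoint, non-empty chain-id vectors.
#' @inheritParams sasa_atoms
#' @return A list: `buried_area_A2`, `polar_fraction`, `sasa_A_A2`,
#'   `sasa_B_A2`, `sasa_complex_A2`.
#' @export
interface_metrics <- function(atoms, chains_A, chains_B, probe_A = 1.4,
                              n_points = 960) {
  if (!length(chains_A) || !length(chains_B) ||
      length(intersect(chains_A, chains_B))) {
    abort("chain groups must be non-empty and disjoint", class = "coat_invalid_input")
  }
  a <- filter(atoms, .data$chain %in% chains_A)
  b <- filter(atoms, .data$chain %in% chains_B)
  sa <- sasa_atoms(a, probe_A, n_points)
  sb <- sasa_atoms(b, probe_A, n_points)
  sc <- sasa_atoms(bind_rows(a, b), probe_A, n_points)
  alone <- c(sa$sasa_A2, sb$sasa_A2)
  buried_atom <- alone - sc$sasa_A2
  buried <- sum(buried_atom)
  polar <- sum(buried_atom[c(a$element, b$element) %in% c("N", "O")])
  list(buried_area_A2 = buried,
       polar_fraction = if (buried > 0) polar / buried else NA_real_,
       sasa_A_A2 = sum(sa$sasa_A2),
       sasa_B_A2 = sum(sb$sasa_A2),
       sasa_complex_A2 = sum(sc$sasa_A2))
}
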