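#' Describe a particle-table dialect
#'
#' Maps the canonical semantic fields (tube id, coordinates, the three
#' intrinsic Z-X-Z Euler angles in degrees, cross-correlation) onto the
#' columns of a concrete table format.
#'
#' @param name `"csv"`, `"star"` or `"dynamo_tbl"`.
#' @param columns Named list mapping semantic fields (`tube_id`,
#'   `particle_id`, `x`, `y`, `z`, `rot`, `tilt`, `psi`, `cc`) to column
#'   names (csv/star) or 1-based column indices (dynamo_tbl). Defaults are
#'   provided for csv (canonical header) and star (RELION-style tags);
#'   dynamo tables have no reliable fixed layout across versions, so an
#'   explicit index map is required there.
#' @param coords_unit `"A"` or `"px"`; pixel-unit tables are converted to
#'   Angstrom on read using `pixel_size_A`.
#' @param pixel_size_A Pixel size in Angstrom (required when
#'   `coords_unit = "px"`, e.g. 2.73).
#' @return A list of class `coat_dialect`.
#' @export
particle_dialect <- function(name = c("csv", "star", "dynamo_tbl"),
                             columns = NULL, coords_unit = c("A", "px"),
                             pixel_size_A = NULL) {
  name <- match.arg(name)
  coords_unit <- match.arg(coords_unit)
  defaults <- switch(name,
    csv = list(tube_id = "tube_id", particle_id = "particle_id",
               x = "x_A", y = "y_A", z = "z_A", rot = "rot_deg",
               tilt = "tilt_deg", psi = "psi_deg", cc = "cc"),
    star = list(tube_id = "rlnMicrographName", particle_id = "rlnImageName",
                x = "rlnCoordinateX", y = "rlnCoordinateY",
                z = "rlnCoordinateZ", rot = "rlnAngleRot",
                tilt = "rlnAngleTilt", psi = "rlnAnglePsi",
                cc = "rlnMaxValueProbDistribution"),
    dynamo_tbl = NULL)
  if (is.null(columns)) columns <- defaults
  if (is.null(columns)) {
    abort("dynamo_tbl dialect needs an explicit `columns` index map",
          class = "coat_schema_error")
  }
  need <- c("tube_id", "x", "y", "z", "rot", "tilt", "psi", "cc")
  miss <- setdiff(need, names(columns))
  if (length(miss)) {
    abort(paste0("dialect is missing mapping(s) for: ", paste(miss, collapse = ", ")),
          class = "coat_schema_error")
  }
  if (coords_unit == "px" && is.null(pixel_size_A)) {
    abort("pixel-unit coordinates need `pixel_size_A`", class = "coat_schema_error")
  }
  structure(list(name = name, columns = columns, coords_unit = coords_unit,
                 pixel_size_A = pixel_size_A), class = "coat_dialect")
}

#' Read a particle table
#'
#' @param path File path.
#' @param dialect A [particle_dialect()] (default: canonical csv).
#' @return Canonical particle tibble (`tube_id`, `particle_id`, `x_A`,
#'   `y_A`, `z_A`, `rot_deg`, `tilt_deg`, `psi_deg`, `cc`, `flags`), with
#'   coordinates in Angstrom.
#' @export
read_particles <- function(path, dialect = particle_dialect("csv")) {
  stopifnot(inherits(dialect, "coat_dialect"))
  raw <- switch(dialect$name,
    csv = readr::read_csv(path, show_col_types = FALSE),
    star = read_star_block(path),
    dynamo_tbl = {
      tb <- utils::read.table(path, header = FALSE)
      cols <- dialect$columns
      maxc <- max(unlist(cols))
      if (ncol(tb) < maxc) {
        abort(sprintf("dynamo table has %d columns but the map needs %d",
                      ncol(tb), maxc), class = "coat_schema_error")
      }
      out <- purrr::map(cols, function(ci) tb[[ci]])
      as_tibble(out)
    })
  cols <- dialect$columns
  if (dialect$name != "dynamo_tbl") {
    miss <- setdiff(unlist(cols), names(raw))
    if (length(miss)) {
      abort(paste0("table is missing mapped column(s): ", paste(miss, collapse = ", ")),
            class = "coat_schema_error")
    }
    raw <- stats::setNames(raw[, unlist(cols)], names(cols))
  }
  out <- tibble(
    tube_id = as.character(raw$tube_id),
    particle_id = if ("particle_id" %in% names(raw)) as.character(raw$particle_id)
                  else sprintf("p%06d", seq_len(nrow(raw))),
    x_A = as.numeric(raw$x), y_A = as.numeric(raw$y), z_A = as.numeric(raw$z),
    rot_deg = as.numeric(raw$rot), tilt_deg = as.numeric(raw$tilt),
    psi_deg = as.numeric(raw$psi), cc = as.numeric(raw$cc), flags = "")
  num <- c("x_A", "y_A", "z_A", "rot_deg", "tilt_deg", "psi_deg", "cc")
  bad <- which(!stats::complete.cases(out[, num]) |
                 !apply(is.finite(as.matrix(out[, num])), 1, all))
  if (length(bad)) {
    abort(paste0("non-finite values in row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")),
          class = "coat_row_error")
  }
  if (dialect$coords_unit == "px") {
    out <- mutate(out, dplyr::across(c("x_A", "y_A", "z_A"),
                                     ~.x * dialect$pixel_size_A))
  }
  if (anyDuplicated(out$particle_id)) {
    abort("particle_id values are not unique", class = "coat_invalid_input")
  }
  out
}

#' Write a particle table
#'
#' @param particles Canonical particle tibble.
#' @param path Output path.
#' @param dialect A [particle_dialect()]; csv writes the canonical header,
#'   star writes a single `data_particles` loop block. Coordinates are
#'   written in the dialect's unit.
#' @export
write_particles <- function(particles, path, dialect = particle_dialect("csv")) {
  stopifnot(inherits(dialect, "coat_dialect"))
  df <- as_tibble(particles)
  if (dialect$coords_unit == "px") {
    df <- mutate(df, dplyr::across(c("x_A", "y_A", "z_A"),
                                   ~.x / dialect$pixel_size_A))
  }
  if (dialect$name == "csv") {
    readr::write_csv(df, path)
  } else if (dialect$name == "star") {
    cols <- dialect$columns
    sem <- c(tube_id = "tube_id", particle_id = "particle_id", x = "x_A",
             y = "y_A", z = "z_A", rot = "rot_deg", tilt = "tilt_deg",
             psi = "psi_deg", cc = "cc")
    sem <- sem[names(sem) %in% names(cols)]
    body <- df[, unname(sem)]
    hdr <- c("data_particles", "", "loop_",
             sprintf("_%s #%d", unlist(cols[names(sem)]), seq_along(sem)))
    cols_chr <- purrr::map(body, function(col) {
      if (is.numeric(col)) sprintf("%.15g", col) else as.character(col)
    })
    lines <- do.call(paste, c(cols_chr, sep = "\t"))
    writeLines(c(hdr, lines), path)
  } else {
    abort("writing dynamo tables is not supported", class = "coat_schema_error")
  }
  invisible(path)
}

# minimal STAR reader: first data_ block with a loop_
read_star_block <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  li <- which(lines == "loop_")
  if (!length(li)) abort("no loop_ block in STAR file", class = "coat_schema_error")
  i <- li[1] + 1
  tags <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("^_", "", sub("\\s+#\\d+$", "", lines[i])))
    i <- i + 1
  }
  body <- character(0)
  while (i <= length(lines) && nzchar(lines[i]) &&
         !startsWith(lines[i], "data_") && !startsWith(lines[i], "loop_")) {
    body <- c(body, lines[i])
    i <- i + 1
  }
  mat <- do.call(rbind, strsplit(body, "\\s+"))
  if (is.null(mat) || ncol(mat) != length(tags)) {
    abort("malformed STAR loop body", class = "coat_schema_error")
  }
  df <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  names(df) <- tags
  for (k in names(df)) {
    suppressWarnings(v <- as.numeric(df[[k]]))
    if (!anyNA(v)) df[[k]] <- v
  }
  df
}

#' Read / write tube-axis control-point tables
#'
#' CSV with columns `tube_id`, `point_index`, `x_A`, `y_A`, `z_A`.
#' @param path File path.
#' @return A tibble of control points.
#' @export
read_axes <- function(path) {
  ax <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("tube_id", "point_index", "x_A", "y_A", "z_A")
  miss <- setdiff(need, names(ax))
  if (length(miss)) {
    abort(paste0("axis table is missing column(s): ", paste(miss, collapse = ", ")),
          class = "coat_schema_error")
  }
  mutate(ax, tube_id = as.character(.data$tube_id))
}

#' @rdname read_axes
#' @param axes Axis control-point tibble.
#' @export
write_axes <- function(axes, path) {
  readr::write_csv(axes, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level sections: `generator` (arguments of
#' [generator_config()]), `qc` (arguments of [qc_thresholds()]), `subbox`
#' (`step_px`, `pixel_size_A`, `snap_max_frac`), `dedup` (`first_px`,
#' `second_px`), `filters` (`min_length_A`, `curvature_radius_factor`),
#' `neighborhood` (`k`, `cutoff_factor`, `bin_A`), `n_tubes`, `seed`.
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A list of class `coat_pipeline_config` (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Assemble a pipeline configuration
#'
#' @param generator List of [generator_config()] arguments (or a ready
#'   `coat_config`).
#' @param qc List of [qc_thresholds()] arguments.
#' @param subbox List: `step_px` (default 16), `pixel_size_A` (default
#'   2.73), `snap_max_frac` (snap radius as fraction of the along-strand
#'   spacing, default 0.5).
#' @param dedup List: `first_px` (default 8), `second_px` (default 17).
#' @param filters List: `min_length_A` (default 1600) and
#'   `curvature_radius_factor` (default 10: tubes whose axis curvature
#'   radius drops below factor * tube radius are excluded).
#' @param neighborhood List: `k` (default 6), `cutoff_factor` (default
#'   1.6), `bin_A` (default 2).
#' @param n_tubes Number of tubes to simulate when no particles are given.
#' @param seed Pipeline seed.
#' @return A list of class `coat_pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), qc = list(), subbox = list(),
                            dedup = list(), filters = list(),
                            neighborhood = list(), n_tubes = 10, seed = 1L) {
  gen <- if (inherits(generator, "coat_config")) generator
         else do.call(generator_config, generator)
  qct <- do.call(qc_thresholds, qc)
  sb <- utils::modifyList(list(step_px = 16, pixel_size_A = 2.73,
                               snap_max_frac = 0.5), subbox)
  dd <- utils::modifyList(list(first_px = 8, second_px = 17), dedup)
  fl <- utils::modifyList(list(min_length_A = 1600, curvature_radius_factor = 10),
                          filters)
  nb <- utils::modifyList(list(k = 6, cutoff_factor = 1.3, bin_A = 2), neighborhood)
  extra <- setdiff(names(sb), c("step_px", "pixel_size_A", "snap_max_frac"))
  if (length(extra)) abort(paste0("unknown subbox key(s): ", paste(extra, collapse = ", ")),
                           class = "coat_schema_error")
  extra <- setdiff(names(nb), c("k", "cutoff_factor", "bin_A"))
  if (length(extra)) abort(paste0("unknown neighborhood key(s): ", paste(extra, collapse = ", ")),
                           class = "coat_schema_error")
  extra <- setdiff(names(dd), c("first_px", "second_px"))
  if (length(extra)) abort(paste0("unknown dedup key(s): ", paste(extra, collapse = ", ")),
                           class = "coat_schema_error")
  extra <- setdiff(names(fl), c("min_length_A", "curvature_radius_factor"))
  if (length(extra)) abort(paste0("unknown filters key(s): ", paste(extra, collapse = ", ")),
                           class = "coat_schema_error")
  structure(list(generator = gen, qc = qct, subbox = sb, dedup = dd,
                 filters = fl, neighborhood = nb,
                 n_tubes = as.integer(n_tubes), seed = as.integer(seed)),
            class = "coat_pipeline_config")
}
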