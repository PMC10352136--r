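#' Run the full coordinate-analysis pipeline
#'
#' Sequences the coordinate-level stages of lattice-guided subtomogram
#' processing on a particle dataset (simulated by default):
#' \enumerate{
#'   \item simulate (or ingest) particles and tube axes;
#'   \item filter tubes by minimum length and maximum axis curvature;
#'   \item fit the helix model of every tube ([fit_helix()]);
#'   \item generate helix-guided subbox poses ([helix_subbox()]) and snap
#'     each pose to the nearest observed particle (the coordinate-level
#'     counterpart of local subvolume alignment, which locks oversampled
#'     poses onto real coat subunits);
#'   \item first deduplication at 8 px ([dedup_particles()]);
#'   \item four-criterion outlier exclusion ([apply_qc()]);
#'   \item second deduplication at 17 px;
#'   \item per-tube neighborhood analysis ([relative_poses()],
#'     [find_peaks()]) and lattice extraction ([lattice_from_peaks()]).
#' }
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param particles,axes Optional observed data; when `NULL`, a dataset is
#'   simulated from `config$generator` with `config$n_tubes` tubes.
#' @return A list of class `coat_pipeline_result`: `helices` (fits),
#'   `qc_summary`, `lattices` (one row per surviving tube), `particles`
#'   (final retained set), `log` (per-stage in/out counts) and `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(generator = list(tube_length_min_A = 1700,
#'                                         tube_length_mean_A = 2000,
#'                                         tube_length_max_A = 2500),
#'                        n_tubes = 2, seed = 42)
#' res <- run_pipeline(cfg)
#' res$lattices
#' }
run_pipeline <- function(config, particles = NULL, axes = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "coat_pipeline_config"))
  logs <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    logs[[length(logs) + 1]] <<- tibble(stage = stage, n_in = n_in,
                                        n_out = n_out, detail = detail)
  }
  px <- config$subbox$pixel_size_A

  if (is.null(particles)) {
    ds <- simulate_dataset(config$generator, config$n_tubes, seed = config$seed)
    particles <- ds$particles
    axes <- ds$axes
    note("simulate", config$n_tubes, nrow(particles),
         sprintf("%d tubes", config$n_tubes))
  }
  axlist <- build_axes(axes)

  # tube filters: minimum length, no extreme curvature
  keep_tube <- purrr::map_lgl(axlist, function(ax) {
    rad_guess <- config$generator$membrane_radius_A + config$generator$coat_offset_A
    ok_len <- ax$length_A >= config$filters$min_length_A
    ok_curv <- axis_max_curvature(ax) <=
      1 / (config$filters$curvature_radius_factor * rad_guess)
    ok_len && ok_curv
  })
  dropped <- names(axlist)[!keep_tube]
  axlist <- axlist[keep_tube]
  n0 <- nrow(particles)
  particles <- filter(particles, .data$tube_id %in% names(axlist))
  note("filter_tubes", n0, nrow(particles),
       if (length(dropped)) paste("dropped:", paste(dropped, collapse = ","))
       else "")
  if (!nrow(particles)) abort("no tubes left after filtering", class = "coat_invalid_input")

  helices <- fit_helix(particles, axlist)
  note("fit_helix", length(axlist), nrow(helices), "")

  helices <- estimate_strand_phase(particles, axlist, helices)
  poses <- helix_subbox(axlist, helices, step_A = config$subbox$step_px * px)
  note("subbox", nrow(particles), nrow(poses), "poses")

  snapped <- snap_poses(poses, particles, helices,
                        max_frac = config$subbox$snap_max_frac)
  note("snap", nrow(poses), nrow(snapped), "")

  d1 <- dedup_particles(snapped, config$dedup$first_px * px)
  note("dedup_8px", nrow(snapped), nrow(d1),
       sprintf("range %.2f A", config$dedup$first_px * px))

  qc <- apply_qc(d1, axlist, helices, config$qc)
  note("qc", nrow(d1), nrow(qc$particles), "")

  d2 <- dedup_particles(qc$particles, config$dedup$second_px * px)
  note("dedup_17px", nrow(qc$particles), nrow(d2),
       sprintf("range %.2f A", config$dedup$second_px * px))

  lat <- purrr::map(split(d2, d2$tube_id), function(df) {
    h <- helices[match(df$tube_id[1], helices$tube_id), ]
    cutoff <- config$neighborhood$cutoff_factor * max(h$a_A, h$d_perp_A)
    cl <- relative_poses(df, cutoff, axes = axlist)
    if (nrow(cl) < config$neighborhood$k) return(NULL)
    pk <- find_peaks(cl, k = config$neighborhood$k, seed = config$seed)
    tryCatch(lattice_from_peaks(pk, h, cloud = cl),
             coat_lattice_undetermined = function(e) NULL)
  }) |> bind_rows()
  note("lattice", nrow(helices), nrow(lat), "tubes with lattice solution")

  structure(list(helices = helices, qc_summary = qc$summary, lattices = lat,
                 particles = d2, log = bind_rows(logs), config = config),
            class = "coat_pipeline_result")
}

#' @export
print.coat_pipeline_result <- function(x, ...) {
  cat("<coat_pipeline_result>\n")
  print(x$log)
  invisible(x)
}

# snap each subbox pose to its nearest observed particle (inheriting the
# particle's pose and cc); poses farther than max_frac * a are dropped,
# duplicates are resolved by the subsequent dedup pass
snap_poses <- function(poses, particles, helices, max_frac = 0.5) {
  split(poses, poses$tube_id) |>
    purrr::map(function(ps) {
      id <- ps$tube_id[1]
      obs <- filter(particles, .data$tube_id == id)
      if (!nrow(obs)) return(NULL)
      h <- helices[match(id, helices$tube_id), ]
      maxd <- max_frac * h$a_A
      P <- as.matrix(ps[, c("x_A", "y_A", "z_A")])
      Q <- as.matrix(obs[, c("x_A", "y_A", "z_A")])
      ordq <- order(Q[, 1])
      qx <- Q[ordq, 1]
      hit <- integer(nrow(P))
      for (i in seq_len(nrow(P))) {
        lo <- findInterval(P[i, 1] - maxd, qx) + 1L
        hi <- findInterval(P[i, 1] + maxd, qx)
        if (hi < lo) { hit[i] <- NA_integer_; next }
        j <- ordq[lo:hi]
        d2 <- (Q[j, 1] - P[i, 1])^2 + (Q[j, 2] - P[i, 2])^2 + (Q[j, 3] - P[i, 3])^2
        k <- which.min(d2)
        hit[i] <- if (d2[k] <= maxd^2) j[k] else NA_integer_
      }
      # duplicates (several poses snapping onto one particle) are kept here;
      # the 8 px dedup pass reduces them by cross-correlation
      obs[hit[!is.na(hit)], ]
    }) |>
    bind_rows()
}
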