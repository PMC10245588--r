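#' Default pipeline configuration
#'
#' The full set of tunable parameters of [run_pipeline()], with their default
#' values. A user config may override any subset; unknown keys are rejected so
#' that typos cannot silently fall back to defaults. All parameters actually
#' used are logged verbatim into the run manifest.
#'
#' @return nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    replicate = 1L,
    scene = list(
      kinetics = unclass(kinetics_params()),
      input = NULL  # or list(fxm=, nuclei=, darkfield=, frames=) of TIFF paths
    ),
    optics = {
      o <- unclass(optics_params())
      o["pillar_centers_px"] <- list(NULL)  # filled in by optics_params()
      o
    },
    preprocess = list(n_per_axis = 24, n_min = 40, sample_smooth_sigma = 2,
                      provisional_fg_frac = 0.95, exclusion_dilate_px = 4),
    segment = list(denoise_sigma = 1, close_radius = 1, min_area_px = 20,
                   seed_sigma = 2, seed_d_min = 5, dilate_radius = 2),
    track = list(max_disp_um = 10, memory_frames = 2, min_length = 5),
    volumetry = list(window_s = 120, min_coverage = 0.5, roll_k = 5,
                     inner_px = 2, outer_px = 10),
    motility = list(tau = 3, spacing_um = 10),
    output_dir = NULL
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [default_run_config()].
#' @return config list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

# Merge a user config over the defaults, rejecting unknown keys.
merge_config <- function(user, defaults, path = "config") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      merge_config(user[[nm]], defaults[[nm]], paste(path, nm, sep = "$"))
    else user[[nm]]
  }
  defaults
}

# Segment + measure one corrected frame; returns a detections data.frame.
analyze_frame <- function(corrected, nuclei, pillars, seg, vol,
                          pixel_size_um, chamber_height_um) {
  den <- denoise_gaussian(corrected, sigma = seg$denoise_sigma)
  mag <- edge_magnitude(den)
  edges <- suppressWarnings(threshold_edges(mag))
  if (seg$close_radius > 0) {
    brush <- EBImage::makeBrush(2 * seg$close_radius + 1, shape = "disc")
    edges <- as_matrix_image(EBImage::closing(EBImage::Image(edges * 1),
                                              brush)) > 0
  }
  fg <- fill_foreground(edges)
  fg <- fg & !pillars
  fg <- prune_small_components(fg, seg$min_area_px)
  if (is.null(nuclei)) {
    seeds <- detect_seeds(max(corrected) - corrected,
                          sigma = seg$seed_sigma, d_min = seg$seed_d_min)
  } else {
    seeds <- detect_seeds(nuclei, sigma = seg$seed_sigma,
                          d_min = seg$seed_d_min)
  }
  labels <- suppressWarnings(label_cells(fg, seeds, pillars))
  labels <- dilate_labels(labels, seg$dilate_radius, pillars)
  measure_frame(corrected, labels, pillars, pixel_size_um, chamber_height_um,
                inner_px = vol$inner_px, outer_px = vol$outer_px)
}

#' Run the full FxM analysis pipeline
#'
#' Config-driven orchestration of simulate/load, flatfield correction,
#' segmentation, tracking, volumetry and motility: for every frame the FxM
#' channel is darkfield-subtracted and flatfield-normalised
#' ([fit_flatfield()], [correct_illumination()]), cells are segmented
#' (edge enhancement, log-space thresholding, flood fill, nuclei-seeded
#' watershed, constrained dilation), measured ([measure_frame()]), then
#' detections are linked in time ([link_tracks()]), volume traces normalised
#' to the pre-stimulus window ([normalize_trace()]) and motility statistics
#' computed ([velocity()], [angular_alignment()]). The run is deterministic
#' given `config$seed`.
#'
#' When `config$scene$input` is `NULL` a synthetic scene is simulated and
#' rendered on the fly from `config$scene$kinetics` and `config$optics`, and
#' the ground truth is returned alongside the measurements. Otherwise
#' multi-page TIFFs are read from the given paths; a missing darkfield is
#' replaced by zero with a prominent warning and a missing nuclei channel
#' falls back to seeding from FxM intensity deficits, also with a warning.
#'
#' @param config nested list (see [default_run_config()]) or path to a YAML
#'   file. Unknown keys are rejected.
#' @return list with elements `detections`, `tracks`, `volumes` (per
#'   cell-frame normalised traces), `motility`, `volume_summary`,
#'   `motility_summary`, `ground_truth` (synthetic runs only) and `manifest`
#'   (the fully-merged config actually used). If `config$output_dir` is set,
#'   tables are written there as CSV and the manifest as JSON.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(config, default_run_config())
  seed <- as.integer(cfg$seed)

  synthetic <- is.null(cfg$scene$input)
  ground_truth <- NULL
  if (synthetic) {
    kin <- do.call(kinetics_params,
                   c(cfg$scene$kinetics[setdiff(names(cfg$scene$kinetics), "seed")],
                     list(seed = seed)))
    opt <- do.call(optics_params, cfg$optics)
    arena <- opt$image_shape_px * opt$pixel_size_um
    ground_truth <- simulate_kinetics(kin, arena_um = arena)
    frames <- seq_len(length(seq(0, kin$duration_s, by = kin$frame_interval_s)))
    t_of_frame <- (frames - 1) * kin$frame_interval_s
    stim_time_s <- kin$stim_time_s
    frame_interval_s <- kin$frame_interval_s
    dark <- render_darkfield(opt)
    pillars <- pillar_mask(opt)
    get_frame <- function(f) {
      fr <- render_frame(ground_truth[ground_truth$frame == f, , drop = FALSE],
                         opt, seed = seed + 1000L + f)
      list(fxm = fr$fxm, nuclei = fr$nuclei)
    }
    pixel_size_um <- opt$pixel_size_um
    chamber_height_um <- opt$chamber_height_um
  } else {
    inp <- cfg$scene$input
    stim_time_s <- cfg$scene$kinetics$stim_time_s
    frame_interval_s <- cfg$scene$kinetics$frame_interval_s
    fxm_pages <- tiff::readTIFF(inp$fxm, all = TRUE)
    nuc_pages <- if (!is.null(inp$nuclei)) tiff::readTIFF(inp$nuclei, all = TRUE)
    else {
      warning("no nuclei channel supplied; seeding from FxM deficits",
              call. = FALSE)
      NULL
    }
    dark <- if (!is.null(inp$darkfield)) tiff::readTIFF(inp$darkfield)
    else {
      warning("no darkfield supplied; proceeding with zero darkfield",
              call. = FALSE)
      0
    }
    scale <- if (!is.null(inp$tiff_scale)) inp$tiff_scale else 1
    fxm_pages <- lapply(fxm_pages, function(m) as_matrix_image(m) * scale)
    if (!is.null(nuc_pages))
      nuc_pages <- lapply(nuc_pages, function(m) as_matrix_image(m) * scale)
    if (is.matrix(dark)) dark <- as_matrix_image(dark) * scale
    frames <- seq_along(fxm_pages)
    t_of_frame <- (frames - 1) * frame_interval_s
    cfg$optics$image_shape_px <- dim(fxm_pages[[1]])
    opt <- do.call(optics_params, cfg$optics)
    pixel_size_um <- opt$pixel_size_um
    chamber_height_um <- opt$chamber_height_um
    pillars <- pillar_mask(opt)
    get_frame <- function(f) list(fxm = fxm_pages[[f]],
                                  nuclei = if (is.null(nuc_pages)) NULL
                                  else nuc_pages[[f]])
  }

  pillars_wide <- as_matrix_image(
    EBImage::dilate(EBImage::Image(pillars * 1),
                    EBImage::makeBrush(7, "disc"))) > 0

  det_list <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    ch <- get_frame(f)
    raw <- ch$fxm
    net <- raw - dark
    # smooth before sampling: suppresses shot noise so that (a) even shallow
    # cell rims fall below the provisional-foreground threshold and (b) the
    # interpolated surface does not chase per-pixel noise
    net_sm <- denoise_gaussian(net, sigma = cfg$preprocess$sample_smooth_sigma)
    med <- stats::median(net_sm)
    excl <- net_sm < cfg$preprocess$provisional_fg_frac * med
    if (cfg$preprocess$exclusion_dilate_px > 0)
      excl <- as_matrix_image(EBImage::dilate(
        EBImage::Image(excl * 1),
        EBImage::makeBrush(2 * cfg$preprocess$exclusion_dilate_px + 1,
                           "disc"))) > 0
    excl <- excl | pillars_wide
    pts <- sample_background_points(dim(raw), excl,
                                    n_per_axis = cfg$preprocess$n_per_axis,
                                    n_min = cfg$preprocess$n_min)
    ff <- fit_flatfield(dark + net_sm, pts)
    corrected <- correct_illumination(raw, dark, ff)
    det <- analyze_frame(corrected, ch$nuclei, pillars, cfg$segment,
                         cfg$volumetry, pixel_size_um, chamber_height_um)
    if (nrow(det)) {
      det$frame <- f
      det$t_s <- t_of_frame[fi]
    } else {
      det$frame <- integer(0)
      det$t_s <- numeric(0)
    }
    det_list[[fi]] <- det
  }
  detections <- do.call(rbind, det_list)

  if (is.null(detections) || !nrow(detections)) {
    warning("no cells detected in any frame; returning empty tables",
            call. = FALSE)
    empty <- data.frame()
    res <- list(detections = data.frame(), tracks = data.frame(),
                volumes = data.frame(), motility = data.frame(),
                volume_summary = empty, motility_summary = empty,
                ground_truth = ground_truth, manifest = cfg)
    return(write_pipeline_outputs(res, cfg))
  }

  tracks <- link_tracks(detections[detections$measurable, , drop = FALSE],
                        max_disp_um = cfg$track$max_disp_um,
                        memory_frames = cfg$track$memory_frames)
  tracks <- filter_tracks(tracks, cfg$track$min_length)

  vol_list <- lapply(split(tracks, tracks$cell_id), function(tr) {
    out <- normalize_trace(tr, t_stim_s = stim_time_s,
                           window_s = cfg$volumetry$window_s,
                           min_coverage = cfg$volumetry$min_coverage,
                           roll_k = cfg$volumetry$roll_k)
    out
  })
  volumes <- do.call(rbind, vol_list)
  rownames(volumes) <- NULL
  volumes$replicate <- cfg$replicate

  mot_list <- lapply(split(tracks, tracks$cell_id), function(tr) {
    data.frame(cell_id = tr$cell_id, frame = tr$frame, t_s = tr$t_s,
               v_um_s = velocity(tr, tau = cfg$motility$tau),
               alignment = angular_alignment(tr,
                                             spacing_um = cfg$motility$spacing_um))
  })
  motility <- do.call(rbind, mot_list)
  rownames(motility) <- NULL
  motility$replicate <- cfg$replicate

  volume_summary <- if (any(is.finite(volumes$normalized))) {
    population_volume_summary(volumes)
  } else data.frame()
  vser <- data.frame(replicate = motility$replicate, t_s = motility$t_s,
                     value = motility$v_um_s)
  motility_summary <- if (any(is.finite(vser$value))) {
    population_motility_summary(vser[is.finite(vser$value), ])
  } else data.frame()

  res <- list(detections = detections, tracks = tracks, volumes = volumes,
              motility = motility, volume_summary = volume_summary,
              motility_summary = motility_summary,
              ground_truth = ground_truth, manifest = cfg)
  write_pipeline_outputs(res, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(res, cfg) {
  if (is.null(cfg$output_dir)) return(res)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(cfg$output_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wr(res$tracks, "tracks")
  wr(res$volumes, "volumes")
  wr(res$motility, "motility")
  wr(res$volume_summary, "volume_summary")
  wr(res$motility_summary, "motility_summary")
  if (!is.null(res$ground_truth)) wr(res$ground_truth, "ground_truth")
  manifest <- res$manifest
  manifest$package_version <- as.character(utils::packageVersion("fxmtools"))
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  res
}
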