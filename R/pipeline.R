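# End-to-end analysis of single fields of view and coverslips.

#' Pipeline configuration
#'
#' All tunable parameters of the analysis, with defaults chosen for
#' fluorescence micrographs at ~6 pixels/um. Every run records the resolved
#' values; [config_hash()] gives a stable fingerprint for provenance.
#'
#' @param resolution pixels per micrometre.
#' @param diffusion_time,diffusion_sigma,diffusion_rho,diffusion_alpha,diffusion_dt
#'   coherence-enhancing diffusion parameters (see [diffusion_params()]).
#' @param tophat_radius_px disc radius for top-hat contrast enhancement.
#' @param bg_grid_px,bg_percentile background-surface block size and
#'   quantile.
#' @param thresh_window_px,thresh_offset adaptive-threshold window (odd; the
#'   default 49 px is roughly four sarcomere spacings) and offset.
#' @param min_spur_px,min_object_px skeleton trimming floors.
#' @param orient_window_px,energy_floor orientation-estimation window and
#'   validity floor.
#' @param actin_blur_sigma Gaussian scale applied to the actin channel
#'   before normalization and orientation estimation.
#' @param grid_um actin director tile edge in micrometres.
#' @param gamma_threshold off-target classification threshold (gamma >=
#'   threshold is off-target), default 0.7.
#' @param link_min_cos optional angular floor for pixel linking.
#' @param czl_min_pixels minimum line size entering the median continuous
#'   z-line length.
#' @param spacing_min_lag_px,spacing_peak_frac sarcomere-spacing peak
#'   detection controls.
#' @param nuclei_blur_sigma,nuclei_min_area_px nuclei counting controls.
#' @param major_axis_deg cell major-axis angle for the stress estimate.
#' @return an object of class `zline_config` (a named list).
#' @export
zline_config <- function(resolution = 6,
                         diffusion_time = 3, diffusion_sigma = 0.5,
                         diffusion_rho = 4, diffusion_alpha = 0.05,
                         diffusion_dt = 0.2,
                         tophat_radius_px = 6,
                         bg_grid_px = 32, bg_percentile = 0.1,
                         thresh_window_px = 49, thresh_offset = 0.01,
                         min_spur_px = 4, min_object_px = 4,
                         orient_window_px = 9, energy_floor = 0.01,
                         actin_blur_sigma = 1.5,
                         grid_um = 5, gamma_threshold = 0.7,
                         link_min_cos = 0, czl_min_pixels = 2,
                         spacing_min_lag_px = 4, spacing_peak_frac = 0.3,
                         nuclei_blur_sigma = 2, nuclei_min_area_px = 30,
                         major_axis_deg = 0) {
  cfg <- as.list(environment())
  structure(cfg, class = "zline_config")
}

#' @export
print.zline_config <- function(x, ...) {
  cat("<zline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Stable fingerprint of a configuration
#'
#' MD5 of the canonical JSON serialization; identical configurations give
#' identical hashes, for provenance in output tables.
#'
#' @param config a [zline_config()].
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "zline_config"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))], digits = NA,
                              auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write / read a configuration as YAML
#'
#' @param config a [zline_config()].
#' @param path file path.
#' @return `write_config` returns the path invisibly; `read_config` returns
#'   a [zline_config()] (unknown keys are rejected, missing keys take
#'   defaults).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "zline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(zline_config)))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(zline_config, vals)
}

#' Alpha-actinin preprocessing chain
#'
#' Rescales to unit maximum, applies coherence-enhancing diffusion, top-hat
#' contrast enhancement, background-surface removal and adaptive
#' thresholding, then thins and trims to the alpha-actinin skeleton. The
#' per-pixel orientation field is estimated from the diffusion-filtered
#' image.
#'
#' @param image a [gray_image()], channel `"alpha_actinin"`.
#' @param config a [zline_config()].
#' @return list with `skeleton` ([binary_skeleton()]), `field`
#'   ([orientation_field()]) and `diffused` (the filtered image).
#' @export
preprocess_actinin <- function(image, config = zline_config()) {
  stopifnot(is_gray_image(image))
  px <- image$pixels
  if (max(px) > 0) px <- px / max(px)
  img <- gray_image(px, image$resolution, image$channel)
  dp <- diffusion_params(time = config$diffusion_time,
                         sigma = config$diffusion_sigma,
                         rho = config$diffusion_rho,
                         alpha = config$diffusion_alpha,
                         dt = config$diffusion_dt)
  diffused <- diffuse(img, dp)
  field <- estimate_orientation(diffused, config$orient_window_px,
                                config$energy_floor)
  enhanced <- tophat_enhance(diffused, config$tophat_radius_px)
  flat <- remove_background(enhanced, config$bg_grid_px, config$bg_percentile)
  mask <- binarize_adaptive(flat, config$thresh_window_px,
                            config$thresh_offset)
  skeleton <- skeletonize_and_trim(mask, config$min_spur_px,
                                   config$min_object_px, image$resolution)
  list(skeleton = skeleton, field = field, diffused = diffused)
}

#' Analyze one field of view
#'
#' Runs the full pipeline on an alpha-actinin micrograph: preprocessing to
#' skeleton and orientation field; actin-guided segmentation when an actin
#' channel is supplied (otherwise the degraded mode reports the plain
#' alpha-actinin orientational order and the z-line fraction is missing);
#' continuous z-line detection; and the scalar metrics. Reruns on identical
#' inputs produce identical outputs.
#'
#' @param actinin [gray_image()] of the alpha-actinin channel (required).
#' @param actin optional [gray_image()] of the actin channel.
#' @param nuclei optional [gray_image()] of the nuclei channel.
#' @param config a [zline_config()].
#' @param image_id identifier carried into the report.
#' @return an object of class `zline_analysis` with the report and all
#'   intermediate artifacts.
#' @export
run_image <- function(actinin, actin = NULL, nuclei = NULL,
                      config = zline_config(), image_id = "image") {
  stopifnot(is_gray_image(actinin))
  res <- actinin$resolution
  pre <- preprocess_actinin(actinin, config)
  skeleton <- pre$skeleton
  field <- pre$field
  n_total <- as.integer(prod(dim(actinin$pixels)))

  aact_angles <- field$theta[skeleton$mask & field$valid]
  aoop <- if (length(aact_angles) > 0) oop(aact_angles) else NA_real_

  seg <- NULL
  grid <- NULL
  spacing <- numeric(0)
  if (!is.null(actin)) {
    stopifnot(is_gray_image(actin))
    if (!identical(dim(actin$pixels), dim(actinin$pixels)))
      stop("actin and alpha-actinin images must have the same shape")
    actin_norm <- normalize_image(actin, config$actin_blur_sigma)
    actin_field <- estimate_orientation(actin_norm, config$orient_window_px,
                                        config$energy_floor)
    grid <- compute_director_grid(actin_field, config$grid_um, res)
    seg <- segment_offtarget(skeleton, field, grid, config$gamma_threshold)
    work_skel <- seg$zline_skeleton
    if (any(grid$populated & !grid$degenerate) && any(work_skel$mask))
      spacing <- sarcomere_spacing(work_skel, grid,
                                   config$spacing_min_lag_px,
                                   config$spacing_peak_frac)
  } else {
    # degraded mode: no actin co-stain, striations cannot be decoupled
    # from off-target staining
    work_skel <- skeleton
  }

  z_angles <- field$theta[work_skel$mask & field$valid]
  lines <- group_lines(link_neighbors(work_skel, field, config$link_min_cos),
                       res, image_id)
  med <- if (length(lines$lines) > 0) {
    suppressWarnings(median_czl(lines, config$czl_min_pixels))
  } else NA_real_
  lengths_tab <- line_lengths(lines)

  frac <- if (!is.null(seg) && seg$n_alpha > 0) seg$n_z / seg$n_alpha
          else NA_real_
  zoop <- if (!is.null(seg) && length(z_angles) > 0) oop(z_angles)
          else NA_real_
  sx <- if (!is.null(seg))
    estimate_stress(z_angles, n_total = n_total,
                    major_axis = config$major_axis_deg * pi / 180)
  else NA_real_

  nuc_count <- NA_integer_
  area_mm2 <- prod(dim(actinin$pixels)) / (res^2 * 1e6)
  if (!is.null(nuclei)) {
    stopifnot(is_gray_image(nuclei))
    nuc_count <- count_nuclei(nuclei, config$nuclei_blur_sigma,
                              config$nuclei_min_area_px)
  }

  report <- zline_report(
    image_id = image_id, resolution = res,
    zline_oop = zoop, aactinin_oop = aoop,
    zline_fraction = frac, median_czl_um = med,
    n_z = if (!is.null(seg)) seg$n_z else NA_integer_,
    n_alpha = if (!is.null(seg)) seg$n_alpha else sum(skeleton$mask),
    sigma_x = sx, n_total = n_total,
    sarcomere_spacing_um = spacing,
    nuclei_count = nuc_count,
    field_area_mm2 = area_mm2,
    nuclei_per_mm2 = if (!is.na(nuc_count)) nuc_count / area_mm2 else NA_real_,
    zline_angles = as.numeric(z_angles),
    aactinin_angles = as.numeric(aact_angles),
    czl_lengths_um = lengths_tab$length_um,
    czl_pixel_counts = as.integer(lengths_tab$pixel_count))

  structure(list(report = report, skeleton = skeleton, field = field,
                 segmentation = seg, grid = grid, lines = lines,
                 config = config, config_hash = config_hash(config)),
            class = "zline_analysis")
}

#' @export
print.zline_analysis <- function(x, ...) {
  cat("<zline_analysis>\n")
  print(x$report)
  invisible(x)
}

#' @export
summary.zline_analysis <- function(object, ...) {
  r <- object$report
  lens <- r$czl_lengths_um[r$czl_pixel_counts >= 2]
  cat("Z-line architecture summary --", r$image_id, "\n")
  print(r)
  if (length(lens) > 0) {
    cat(sprintf("  continuous lines  %d (>= 2 px); length quartiles %s um\n",
                length(lens),
                paste(signif(stats::quantile(lens, c(.25, .5, .75)), 3),
                      collapse = " / ")))
  }
  invisible(r)
}

#' @export
plot.zline_analysis <- function(x, ...) {
  m <- x$skeleton$mask
  cls <- matrix(0L, nrow(m), ncol(m))
  if (!is.null(x$segmentation)) {
    cls[x$segmentation$offtarget_mask] <- 1L
    cls[x$segmentation$zline_skeleton$mask] <- 2L
    cls[x$segmentation$unassigned_mask] <- 3L
  } else {
    cls[m] <- 2L
  }
  graphics::image(t(cls[nrow(cls):1, , drop = FALSE]),
                  col = c("black", "dodgerblue", "red", "grey50"),
                  axes = FALSE, asp = nrow(cls) / ncol(cls),
                  main = paste("z-lines (red) / off-target (blue):",
                               x$report$image_id), ...)
  invisible(x)
}

#' Analyze a coverslip (multiple fields of view)
#'
#' Runs [run_image()] per field and pools the per-field reports with
#' [aggregate_report()]. A failing field is skipped with a warning and the
#' batch continues; fields with mixed resolutions are rejected.
#'
#' @param entries list of fields; each a list with elements `actinin`
#'   (required), `actin`, `nuclei` ([gray_image()]s or NULL), `field_id`.
#' @param config a [zline_config()].
#' @param coverslip_id identifier for the pooled report.
#' @return list with `fields` (per-field `zline_analysis` objects) and
#'   `pooled` (the coverslip `zline_report`).
#' @export
run_coverslip <- function(entries, config = zline_config(),
                          coverslip_id = "coverslip") {
  if (length(entries) == 0L) stop("at least one field is required")
  res <- vapply(entries, function(e) {
    if (is_gray_image(e$actinin)) e$actinin$resolution else NA_real_
  }, numeric(1))
  if (length(unique(res[!is.na(res)])) > 1L)
    stop("fields have mixed resolutions")
  fields <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    fid <- if (!is.null(e$field_id)) e$field_id
           else paste0(coverslip_id, "_f", i)
    ana <- tryCatch(
      run_image(e$actinin, e$actin, e$nuclei, config, image_id = fid),
      error = function(err) {
        warning("field ", fid, " failed and was skipped: ",
                conditionMessage(err))
        NULL
      })
    if (!is.null(ana)) fields[[length(fields) + 1L]] <- ana
  }
  if (length(fields) == 0L) stop("all fields failed")
  pooled <- aggregate_report(lapply(fields, `[[`, "report"), coverslip_id)
  list(fields = fields, pooled = pooled)
}
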