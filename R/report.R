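# Per-field and per-coverslip metric reports.

#' Assemble a metrics report
#'
#' Container for the scalar architecture metrics of one field of view
#' (or a pooled coverslip). Raw angle lists, line lengths and counts are
#' retained so that pooling can recompute metrics from raw data rather
#' than averaging per-field scalars.
#'
#' @param image_id identifier.
#' @param resolution pixels per micrometre.
#' @param zline_oop,aactinin_oop orientational order parameters.
#' @param zline_fraction fraction of assigned skeleton pixels kept as
#'   z-lines (`NA` when segmentation was unavailable).
#' @param median_czl_um median continuous z-line length.
#' @param n_z,n_alpha z-line and assigned alpha-actinin pixel counts.
#' @param sigma_x normalized stress estimate.
#' @param n_total total pixels used as `N_T` in the stress estimate.
#' @param sarcomere_spacing_um pooled spacing distribution (vector, um).
#' @param nuclei_count,field_area_mm2 per-field nuclei data (`NA` if absent).
#' @param nuclei_per_mm2 nuclei density.
#' @param zline_angles,aactinin_angles raw nematic angle vectors.
#' @param czl_lengths_um,czl_pixel_counts raw per-line measurements.
#' @return an object of class `zline_report`.
#' @export
zline_report <- function(image_id = NA_character_, resolution = 6,
                         zline_oop = NA_real_, aactinin_oop = NA_real_,
                         zline_fraction = NA_real_, median_czl_um = NA_real_,
                         n_z = NA_integer_, n_alpha = NA_integer_,
                         sigma_x = NA_real_, n_total = NA_integer_,
                         sarcomere_spacing_um = numeric(0),
                         nuclei_count = NA_integer_,
                         field_area_mm2 = NA_real_,
                         nuclei_per_mm2 = NA_real_,
                         zline_angles = numeric(0),
                         aactinin_angles = numeric(0),
                         czl_lengths_um = numeric(0),
                         czl_pixel_counts = integer(0)) {
  structure(list(
    image_id = image_id, resolution = resolution,
    zline_oop = zline_oop, aactinin_oop = aactinin_oop,
    zline_fraction = zline_fraction, median_czl_um = median_czl_um,
    n_z = n_z, n_alpha = n_alpha, sigma_x = sigma_x, n_total = n_total,
    sarcomere_spacing_um = sarcomere_spacing_um,
    nuclei_count = nuclei_count, field_area_mm2 = field_area_mm2,
    nuclei_per_mm2 = nuclei_per_mm2,
    zline_angles = zline_angles, aactinin_angles = aactinin_angles,
    czl_lengths_um = czl_lengths_um, czl_pixel_counts = czl_pixel_counts),
    class = "zline_report")
}

#' @export
print.zline_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "--" else sprintf("%.4g", v)
  cat(sprintf("<zline_report> %s\n", x$image_id))
  cat(sprintf("  z-line OOP        %s\n", fmt(x$zline_oop)))
  cat(sprintf("  alpha-actinin OOP %s\n", fmt(x$aactinin_oop)))
  cat(sprintf("  z-line fraction   %s  (N_z = %s, N_alpha = %s)\n",
              fmt(x$zline_fraction), fmt(x$n_z), fmt(x$n_alpha)))
  cat(sprintf("  median CZL        %s um\n", fmt(x$median_czl_um)))
  cat(sprintf("  sigma_x           %s\n", fmt(x$sigma_x)))
  if (length(x$sarcomere_spacing_um) > 0)
    cat(sprintf("  sarcomere spacing %.3g um (median of %d tiles)\n",
                stats::median(x$sarcomere_spacing_um),
                length(x$sarcomere_spacing_um)))
  if (!is.na(x$nuclei_per_mm2))
    cat(sprintf("  nuclei density    %s / mm^2\n", fmt(x$nuclei_per_mm2)))
  invisible(x)
}

#' Pool per-field reports into a coverslip report
#'
#' Pooled metrics are recomputed from raw data, not averaged: OOPs from
#' concatenated angle lists, the z-line fraction from summed counts, the
#' median continuous z-line length from the pooled line lengths, the stress
#' estimate from concatenated angles and summed pixel totals, and the
#' nuclei density from summed counts over summed areas.
#'
#' @param per_field list of `zline_report` objects (at least one) sharing a
#'   resolution.
#' @param image_id identifier for the pooled report.
#' @return a `zline_report`.
#' @export
aggregate_report <- function(per_field, image_id = "pooled") {
  if (length(per_field) == 0L) stop("at least one field is required")
  stopifnot(all(vapply(per_field, inherits, logical(1), "zline_report")))
  res <- vapply(per_field, `[[`, numeric(1), "resolution")
  if (length(unique(res)) != 1L)
    stop("fields have inconsistent resolutions")
  if (length(per_field) == 1L) {
    out <- per_field[[1]]
    out$image_id <- image_id
    return(out)
  }
  za <- unlist(lapply(per_field, `[[`, "zline_angles"))
  aa <- unlist(lapply(per_field, `[[`, "aactinin_angles"))
  lens <- unlist(lapply(per_field, `[[`, "czl_lengths_um"))
  pxc <- unlist(lapply(per_field, `[[`, "czl_pixel_counts"))
  n_z <- sum(vapply(per_field, `[[`, numeric(1), "n_z"), na.rm = TRUE)
  n_alpha <- sum(vapply(per_field, `[[`, numeric(1), "n_alpha"), na.rm = TRUE)
  n_total <- sum(vapply(per_field, `[[`, numeric(1), "n_total"), na.rm = TRUE)
  spac <- unlist(lapply(per_field, `[[`, "sarcomere_spacing_um"))
  counts <- vapply(per_field, `[[`, numeric(1), "nuclei_count")
  areas <- vapply(per_field, `[[`, numeric(1), "field_area_mm2")
  have_nuc <- !is.na(counts) & !is.na(areas)

  frac <- if (n_alpha > 0) n_z / n_alpha else NA_real_
  med <- if (any(pxc >= 2)) stats::median(lens[pxc >= 2]) else NA_real_
  zoop <- if (length(za) > 0) oop(za) else NA_real_
  aoop <- if (length(aa) > 0) oop(aa) else NA_real_
  sx <- if (n_total > 0) estimate_stress(za, n_total = n_total) else NA_real_

  zline_report(
    image_id = image_id, resolution = res[1],
    zline_oop = zoop, aactinin_oop = aoop,
    zline_fraction = frac, median_czl_um = med,
    n_z = as.integer(n_z), n_alpha = as.integer(n_alpha),
    sigma_x = sx, n_total = as.integer(n_total),
    sarcomere_spacing_um = spac,
    nuclei_count = if (any(have_nuc)) sum(counts[have_nuc]) else NA_integer_,
    field_area_mm2 = if (any(have_nuc)) sum(areas[have_nuc]) else NA_real_,
    nuclei_per_mm2 = if (any(have_nuc))
      nuclei_density(counts[have_nuc], areas[have_nuc]) else NA_real_,
    zline_angles = za, aactinin_angles = aa,
    czl_lengths_um = lens, czl_pixel_counts = pxc)
}

#' Write reports as a CSV table
#'
#' One row per report with fixed column names; missing values are written
#' as empty cells, never as 0.
#'
#' @param reports a `zline_report` or list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  if (inherits(reports, "zline_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    data.frame(
      image_id = r$image_id,
      zline_oop = r$zline_oop,
      aactinin_oop = r$aactinin_oop,
      zline_fraction = r$zline_fraction,
      median_czl_um = r$median_czl_um,
      n_z = r$n_z,
      n_alpha = r$n_alpha,
      sigma_x = r$sigma_x,
      sarcomere_spacing_um = if (length(r$sarcomere_spacing_um) > 0)
        stats::median(r$sarcomere_spacing_um) else NA_real_,
      nuclei_per_mm2 = r$nuclei_per_mm2)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
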