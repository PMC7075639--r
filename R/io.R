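# Reading micrographs and writing masks / labels.

#' Read a grayscale micrograph
#'
#' Reads an 8- or 16-bit TIFF or PNG. Multi-channel images are averaged to
#' grayscale with a warning. Intensities are returned on the reader's
#' [0, 1] scale.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param resolution pixels per micrometre.
#' @param channel channel tag, see [gray_image()].
#' @return a [gray_image()].
#' @export
read_gray_image <- function(path, resolution = 6,
                            channel = c("alpha_actinin", "actin", "nuclei")) {
  channel <- match.arg(channel)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3L) {
    warning("multi-channel image: averaging channels to grayscale")
    arr <- apply(arr, c(1, 2), mean)
  }
  gray_image(arr, resolution, channel)
}

#' Write a binary mask as an 8-bit PNG (255 = TRUE)
#'
#' @param mask logical matrix or [binary_skeleton()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (is_binary_skeleton(mask)) mask$mask else mask
  stopifnot(is.matrix(m), is.logical(m))
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Read a reference trace mask from a PNG (nonzero = TRUE)
#'
#' @param path PNG path.
#' @param resolution pixels per micrometre.
#' @param provenance skeleton provenance tag.
#' @return a [binary_skeleton()].
#' @export
read_mask_png <- function(path, resolution = 6,
                          provenance = "raw_alpha_actinin") {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  binary_skeleton(arr > 0, resolution, provenance)
}

#' Write a line set as a labeled 16-bit PNG and a CSV table
#'
#' The PNG encodes one integer id per line (scaled to 16-bit range); the
#' CSV lists line id, pixel count, length and centroid.
#'
#' @param lines a `line_set`.
#' @param dims image dimensions `c(nrow, ncol)`.
#' @param png_path,csv_path output paths (either may be NULL to skip).
#' @return invisibly, the label matrix.
#' @export
write_line_labels <- function(lines, dims, png_path = NULL, csv_path = NULL) {
  stopifnot(inherits(lines, "line_set"))
  lab <- matrix(0L, dims[1], dims[2])
  rows <- list()
  for (i in seq_along(lines$lines)) {
    l <- lines$lines[[i]]
    lab[l$path] <- i
    rows[[i]] <- data.frame(
      line_id = i, pixel_count = l$pixel_count, length_um = l$length_um,
      centroid_row = mean(l$path[, 1]), centroid_col = mean(l$path[, 2]))
  }
  if (!is.null(png_path))
    png::writePNG(lab / 65535, png_path, dpi = NULL)
  if (!is.null(csv_path)) {
    tab <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(line_id = integer(0), pixel_count = integer(0),
                 length_um = numeric(0), centroid_row = numeric(0),
                 centroid_col = numeric(0))
    utils::write.csv(tab, csv_path, row.names = FALSE, na = "")
  }
  invisible(lab)
}
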