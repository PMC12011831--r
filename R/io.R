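# File-format plumbing: grayscale TIFF/PNG flow images with JSON sidecars,
# tidy metrics CSV, mask PNGs.

#' Read an en-face flow image with its metadata sidecar
#'
#' Reads an 8/16-bit grayscale TIFF or PNG (values arrive in \[0, 1\]) plus a
#' JSON sidecar `<image>.json` with fields `{ssi, eye, target, extent_mm}`.
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @param sidecar optional explicit sidecar path; default replaces the image
#'   extension with `.json`.
#' @return a [flow_image()].
#' @export
read_flow_image <- function(path, sidecar = NULL) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(x)) == 3) x <- x[, , 1]   # grayscale stored with channels
  if (is.null(sidecar))
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  extent <- if (!is.null(meta$extent_mm)) meta$extent_mm else 3.0
  flow_image(x,
             grid = image_grid(nrow(x), ncol(x), extent),
             signal_strength_index = if (!is.null(meta$ssi)) meta$ssi else NA,
             eye = meta$eye, target = meta$target)
}

#' Write a flow image and sidecar
#'
#' @param image a [flow_image()].
#' @param path output path ending in `.tif`/`.tiff`/`.png`.
#' @return `path`, invisibly.
#' @export
write_flow_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  x <- image$intensities
  switch(ext,
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 16),
    png = png::writePNG(x, path),
    stop("unsupported image format: ", ext))
  meta <- list(ssi = image$signal_strength_index, eye = image$eye,
               target = image$target, extent_mm = image$grid$extent_mm)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a binary mask as a PNG
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Write per-image vessel metrics as tidy CSV
#'
#' One row per region with identifying columns prepended.
#'
#' @param metrics data.frame from [quantify_image()].
#' @param path output CSV path.
#' @param subject,eye,target identifiers repeated on each row.
#' @param append append to an existing file without rewriting the header.
#' @return the rows written, invisibly.
#' @export
write_metrics_csv <- function(metrics, path, subject = NA, eye = NA,
                              target = NA, append = FALSE) {
  out <- cbind(data.frame(subject = subject, eye = eye, target = target,
                          stringsAsFactors = FALSE), metrics)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, qmethod = "double")
  invisible(out)
}

#' Render a matrix as a heat-map PNG
#'
#' Used for the local VAD/VCI maps; blue = low, red = high.
#'
#' @param values numeric matrix.
#' @param path output PNG path.
#' @param zlim optional fixed color range.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(values, path, zlim = range(values, finite = TRUE)) {
  grDevices::png(path, width = ncol(values), height = nrow(values))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
  # image() draws x along rows; transpose and flip so the PNG matches the
  # matrix orientation (row 1 at the top)
  graphics::image(t(values[nrow(values):1, ]), col = pal, zlim = zlim,
                  axes = FALSE, useRaster = TRUE)
  invisible(path)
}
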