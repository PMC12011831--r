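#' Image grid describing a square en-face scan
#'
#' An `image_grid` ties a pixel raster to physical coordinates. Standard
#' peripapillary and macular angiography scans cover a 3 x 3 mm square field
#' of view, so the default physical extent is 3 mm. The physical origin is at
#' the image centre, x increases to the right (columns), y increases upward
#' (row 1 is anatomically superior), and distances are measured from pixel
#' centres.
#'
#' @param height_px,width_px raster dimensions in pixels.
#' @param extent_mm physical side length of the square field of view (mm).
#' @return an object of class `image_grid` with fields `height_px`,
#'   `width_px`, `extent_mm` and the derived `pixel_size_mm`.
#' @examples
#' g <- image_grid(300, 300)
#' g$pixel_size_mm  # 0.01 mm / px
#' @export
image_grid <- function(height_px, width_px = height_px, extent_mm = 3.0) {
  stopifnot(height_px >= 1, width_px >= 1, extent_mm > 0)
  structure(list(
    height_px = as.integer(height_px),
    width_px = as.integer(width_px),
    extent_mm = extent_mm,
    pixel_size_mm = extent_mm / width_px
  ), class = "image_grid")
}

#' Annulus region of interest in physical coordinates
#'
#' The peripapillary disc ROI is an annulus of outer diameter 1.375 mm and
#' inner diameter 0.5 mm centred on the disc; the macular ROI uses inner
#' diameter 0.75 mm centred on the foveal avascular zone. Both are expressed
#' here in mm so they are resolution independent.
#'
#' @param inner_diameter_mm,outer_diameter_mm annulus diameters (mm);
#'   `inner_diameter_mm` may be 0 (filled disc).
#' @param center_mm numeric length-2 (x, y) centre in physical coordinates;
#'   `c(0, 0)` is the image centre.
#' @return an `annulus_roi` object.
#' @export
annulus_roi <- function(inner_diameter_mm, outer_diameter_mm,
                        center_mm = c(0, 0)) {
  stopifnot(inner_diameter_mm >= 0, outer_diameter_mm > 0,
            length(center_mm) == 2)
  if (inner_diameter_mm >= outer_diameter_mm)
    stop("inner_diameter_mm must be smaller than outer_diameter_mm")
  structure(list(
    inner_diameter_mm = inner_diameter_mm,
    outer_diameter_mm = outer_diameter_mm,
    center_mm = as.numeric(center_mm)
  ), class = "annulus_roi")
}

#' Standard disc and macula annulus definitions
#'
#' @param target `"disc"` (inner 0.5 mm) or `"macula"` (inner 0.75 mm);
#'   outer diameter 1.375 mm in both cases.
#' @param center_mm ROI centre, default image centre.
#' @return an [annulus_roi()].
#' @export
default_annulus <- function(target = c("disc", "macula"), center_mm = c(0, 0)) {
  target <- match.arg(target)
  inner <- if (target == "disc") 0.5 else 0.75
  annulus_roi(inner, 1.375, center_mm)
}

#' Convert a physical length to pixels
#'
#' @param grid an [image_grid()].
#' @param length_mm nonnegative length in mm.
#' @return length in pixels (possibly fractional).
#' @export
mm_to_px <- function(grid, length_mm) {
  stopifnot(inherits(grid, "image_grid"))
  if (any(length_mm < 0)) stop("length_mm must be nonnegative")
  length_mm / grid$pixel_size_mm
}

# Physical (x, y) coordinates in mm of every pixel centre, as two matrices.
# x: rightward from image centre; y: upward (row 1 superior).
pixel_centers_mm <- function(grid) {
  px <- grid$pixel_size_mm
  x <- (seq_len(grid$width_px) - 0.5) * px - grid$extent_mm / 2
  yext <- grid$height_px * px
  y <- yext / 2 - (seq_len(grid$height_px) - 0.5) * px
  list(x = matrix(x, grid$height_px, grid$width_px, byrow = TRUE),
       y = matrix(y, grid$height_px, grid$width_px, byrow = FALSE))
}

#' Boolean pixel mask of an annulus ROI
#'
#' A pixel is in-mask iff the Euclidean distance d from its centre to the ROI
#' centre satisfies `inner_radius <= d < outer_radius` (half-open, so
#' concentric rings are disjoint).
#'
#' @param grid an [image_grid()].
#' @param roi an [annulus_roi()].
#' @return logical matrix of dimension `height_px x width_px`, with attribute
#'   `clipped = TRUE` when part of the annulus falls outside the field of
#'   view. An annulus entirely outside the image is an error.
#' @export
make_annulus_mask <- function(grid, roi) {
  stopifnot(inherits(grid, "image_grid"), inherits(roi, "annulus_roi"))
  cc <- pixel_centers_mm(grid)
  d <- sqrt((cc$x - roi$center_mm[1])^2 + (cc$y - roi$center_mm[2])^2)
  r_in <- roi$inner_diameter_mm / 2
  r_out <- roi$outer_diameter_mm / 2
  mask <- d >= r_in & d < r_out
  if (!any(mask))
    stop("annulus lies entirely outside the image extent (empty mask)")
  # clipped if the outer circle extends past any image edge
  half_w <- grid$width_px * grid$pixel_size_mm / 2
  half_h <- grid$height_px * grid$pixel_size_mm / 2
  clipped <- (abs(roi$center_mm[1]) + r_out > half_w) ||
             (abs(roi$center_mm[2]) + r_out > half_h)
  attr(mask, "clipped") <- clipped
  mask
}

#' Sector partition scheme for an annulus
#'
#' Two schemes are supported. `quadrants_4` uses the standard RNFL quadrant
#' convention with boundaries on the 45 degree diagonals: superior (S) is
#' \[45, 135) with 90 degrees pointing to the image top, inferior (I) is
#' \[225, 315), and the lateral quadrants are nasal (N) and temporal (T).
#' `macula_6` splits each hemifield into three 60 degree sectors
#' (S, SN, ST / I, IN, IT). Nasal/temporal assignment depends on laterality:
#' for a right eye (OD) the nasal retina is on the image right, for a left
#' eye (OS) on the image left; superior and inferior labels are unaffected.
#'
#' @param scheme `"quadrants_4"` or `"macula_6"`.
#' @param laterality `"OD"` or `"OS"`.
#' @return a `sector_partition` with per-label half-open angular intervals
#'   (degrees, measured counterclockwise from the +x axis) that tile
#'   \[0, 360) exactly.
#' @export
sector_partition <- function(scheme = c("quadrants_4", "macula_6"),
                             laterality = c("OD", "OS")) {
  scheme <- match.arg(scheme)
  laterality <- match.arg(laterality)
  # intervals written for OD (nasal retina on the +x / image-right side);
  # OS mirrors left-right, which swaps every nasal label with its temporal
  # counterpart while leaving S and I fixed
  swap_nt <- function(nm) {
    chartr("NT", "TN", nm)
  }
  if (scheme == "quadrants_4") {
    b <- list(S = c(45, 135), T = c(135, 225), I = c(225, 315),
              N = c(315, 405))  # N wraps through 0 degrees
    labels <- c("S", "N", "I", "T")
  } else {
    b <- list(SN = c(0, 60), S = c(60, 120), ST = c(120, 180),
              IT = c(180, 240), I = c(240, 300), IN = c(300, 360))
    labels <- c("S", "SN", "ST", "I", "IN", "IT")
  }
  if (laterality == "OS") names(b) <- swap_nt(names(b))
  structure(list(scheme = scheme, laterality = laterality,
                 angular_bounds_deg = b, labels = labels),
            class = "sector_partition")
}

#' Flip the laterality of a sector partition
#'
#' Swaps nasal and temporal labels; an involution (flipping twice restores
#' the original partition).
#'
#' @param part a [sector_partition()].
#' @return the mirrored partition.
#' @export
flip_laterality <- function(part) {
  stopifnot(inherits(part, "sector_partition"))
  sector_partition(part$scheme,
                   if (part$laterality == "OD") "OS" else "OD")
}

#' Assign every in-annulus pixel to exactly one sector
#'
#' @param grid an [image_grid()].
#' @param roi an [annulus_roi()].
#' @param part a [sector_partition()].
#' @return character matrix with the sector label for in-annulus pixels and
#'   `NA` elsewhere; the union of sectors equals the annulus mask.
#' @export
partition_sectors <- function(grid, roi, part) {
  stopifnot(inherits(part, "sector_partition"))
  mask <- make_annulus_mask(grid, roi)
  cc <- pixel_centers_mm(grid)
  ang <- atan2(cc$y - roi$center_mm[2], cc$x - roi$center_mm[1]) * 180 / pi
  ang <- ang %% 360
  lab <- matrix(NA_character_, grid$height_px, grid$width_px)
  for (nm in names(part$angular_bounds_deg)) {
    iv <- part$angular_bounds_deg[[nm]]
    if (iv[2] <= 360) {
      sel <- ang >= iv[1] & ang < iv[2]
    } else {                       # interval wrapping through 0 degrees
      sel <- ang >= iv[1] | ang < (iv[2] - 360)
    }
    lab[mask & sel] <- nm
  }
  attr(lab, "mask") <- mask
  lab
}

#' Read an ROI definition from a JSON config
#'
#' Accepts `{scheme, center_mm, inner_diameter_mm, outer_diameter_mm,
#' laterality}` and returns the corresponding ROI and partition objects.
#'
#' @param path path to a JSON file.
#' @return list with elements `roi` and `partition`.
#' @export
read_roi_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  center <- if (!is.null(cfg$center_mm)) as.numeric(cfg$center_mm) else c(0, 0)
  list(
    roi = annulus_roi(cfg$inner_diameter_mm, cfg$outer_diameter_mm, center),
    partition = sector_partition(cfg$scheme, cfg$laterality)
  )
}

#' Export a sector label mask as an indexed PNG
#'
#' Writes the label matrix as a grayscale PNG with a fixed integer palette:
#' background 0 and sector i of the partition's label order mapped to i,
#' scaled into \[0,1\] by the number of labels.
#'
#' @param label_mask matrix from [partition_sectors()].
#' @param part the [sector_partition()] used.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(label_mask, part, path) {
  idx <- matrix(0L, nrow(label_mask), ncol(label_mask))
  for (i in seq_along(part$labels))
    idx[!is.na(label_mask) & label_mask == part$labels[i]] <- i
  png::writePNG(idx / length(part$labels), path)
  invisible(path)
}
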