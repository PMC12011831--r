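#' En-face OCTA flow image
#'
#' Wraps a 2D grid of flow intensities together with its physical grid and
#' acquisition metadata. Intensities are normalized to \[0, 1\] (values from
#' 8/16-bit files are divided by their nominal maximum on read; any input
#' with a maximum above 1 is rescaled here).
#'
#' @param intensities numeric matrix of flow values.
#' @param grid an [image_grid()] matching the matrix dimensions; defaults to
#'   a 3 mm square grid of the matrix size.
#' @param signal_strength_index device-reported scan quality score (0-10).
#' @param eye `"OD"` or `"OS"`.
#' @param target `"disc"` or `"macula"`.
#' @return a `flow_image` object.
#' @export
flow_image <- function(intensities, grid = NULL, signal_strength_index = NA,
                       eye = c("OD", "OS"), target = c("disc", "macula")) {
  eye <- match.arg(eye)
  target <- match.arg(target)
  stopifnot(is.matrix(intensities))
  if (is.null(grid))
    grid <- image_grid(nrow(intensities), ncol(intensities))
  stopifnot(grid$height_px == nrow(intensities),
            grid$width_px == ncol(intensities))
  mx <- max(intensities)
  if (mx > 1) intensities <- intensities / mx
  if (min(intensities) < 0) stop("flow intensities must be nonnegative")
  structure(list(intensities = intensities, grid = grid,
                 signal_strength_index = signal_strength_index,
                 eye = eye, target = target),
            class = "flow_image")
}

#' Quality-control filter on signal strength
#'
#' Scans are retained only when the device signal strength index strictly
#' exceeds the threshold (default 7); an image with SSI exactly 7 fails.
#'
#' @param image a [flow_image()].
#' @param threshold minimum acceptable SSI (exclusive).
#' @return `TRUE`/`FALSE`, with attribute `reason` when failing.
#' @export
qc_filter <- function(image, threshold = 7) {
  ssi <- image$signal_strength_index
  if (is.null(ssi) || is.na(ssi)) {
    out <- FALSE
    attr(out, "reason") <- "missing signal strength index"
    return(out)
  }
  out <- ssi > threshold
  if (!out) attr(out, "reason") <-
      sprintf("signal strength index %.2f <= %.2f", ssi, threshold)
  out
}

# Gaussian second-derivative kernels at scale s (px); odd-sized.
gauss_deriv_kernels <- function(s) {
  r <- max(2L, ceiling(3 * s))
  x <- -r:r
  g <- exp(-x^2 / (2 * s^2))
  g <- g / sum(g)
  gxx <- (x^2 / s^4 - 1 / s^2) * g       # d2/dx2 of the 1-D Gaussian
  gxx <- gxx - sum(gxx) * g              # zero-DC despite truncation
  gx <- (-x / s^2) * g
  list(
    kxx = outer(g, gxx),   # rows = y, cols = x
    kyy = outer(gxx, g),
    kxy = outer(gx, gx)
  )
}

#' Multiscale Hessian vesselness enhancement
#'
#' Frangi-style filter for bright curvilinear structures on a dark
#' background. At each scale the image is convolved with gamma-normalized
#' (factor s^2) Gaussian second-derivative kernels; the Hessian eigenvalues
#' give the vesselness response, and the per-pixel maximum over scales is
#' returned, rescaled to \[0, 1\]. A constant image yields an all-zero
#' response. Deterministic for fixed input and scales.
#'
#' @param image a [flow_image()] or numeric matrix in \[0, 1\].
#' @param scales_px vessel radii to probe, in pixels (default `c(1, 2, 3)`).
#' @param beta blob-discrimination parameter (default 0.5).
#' @return numeric matrix in \[0, 1\] of the same dimension.
#' @export
enhance_vessels <- function(image, scales_px = c(1, 2, 3), beta = 0.5) {
  x <- if (inherits(image, "flow_image")) image$intensities else image
  if (!length(scales_px)) stop("scales_px must be a nonempty list of scales")
  stopifnot(all(scales_px > 0))
  best <- matrix(0, nrow(x), ncol(x))
  for (s in scales_px) {
    k <- gauss_deriv_kernels(s)
    lxx <- s^2 * ebi_filter(x, k$kxx)
    lyy <- s^2 * ebi_filter(x, k$kyy)
    lxy <- s^2 * ebi_filter(x, k$kxy)
    # eigenvalues of [[lxx, lxy], [lxy, lyy]]
    tr <- lxx + lyy
    disc <- sqrt(pmax((lxx - lyy)^2 + 4 * lxy^2, 0))
    l1 <- (tr + disc) / 2
    l2 <- (tr - disc) / 2
    # order by |lambda|: la small, lb large
    swap <- abs(l1) > abs(l2)
    la <- ifelse(swap, l2, l1)
    lb <- ifelse(swap, l1, l2)
    S2 <- la^2 + lb^2
    c2 <- max(S2) / 4                 # c = half the max Frobenius norm
    if (c2 < 1e-10) next              # no structure beyond numerical noise
    rb2 <- ifelse(lb != 0, (la / lb)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * pmax(c2, 1e-12))))
    v[lb >= 0] <- 0                   # bright structures: lambda_2 < 0
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  best
}

# filter2 keeps matrix orientation; replicate boundary avoids wrap artefacts
ebi_filter <- function(x, kernel) {
  as.matrix(EBImage::filter2(EBImage::Image(x), kernel,
                             boundary = "replicate"))
}

#' Binarize an enhanced image into a vessel candidate mask
#'
#' @param enhanced numeric matrix in \[0, 1\].
#' @param method `"global_otsu"` (threshold chosen by Otsu's criterion on the
#'   image histogram) or `"fixed"`.
#' @param level required for `method = "fixed"`; a pixel is foreground iff
#'   its value is `>= level`.
#' @return logical matrix.
#' @export
binarize <- function(enhanced, method = c("global_otsu", "fixed"),
                     level = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(enhanced))
  if (method == "fixed") {
    if (is.null(level)) stop("method 'fixed' requires a 'level'")
    return(enhanced >= level)
  }
  if (max(enhanced) == min(enhanced)) {
    # degenerate histogram: no threshold separates anything
    return(matrix(FALSE, nrow(enhanced), ncol(enhanced)))
  }
  th <- EBImage::otsu(EBImage::Image(enhanced), range = c(0, 1))
  enhanced > th
}

#' Split a vessel mask into capillaries and large vessels
#'
#' Large vessels are connected structures wider than `diameter_cutoff_px`,
#' found by morphological opening with a disc of that diameter (rounded up
#' to the next odd size) followed by a short geodesic reconstruction inside
#' the mask to recover boundary pixels lost to the opening. The returned
#' masks are disjoint and union to the input.
#'
#' @param mask logical matrix.
#' @param diameter_cutoff_px cutoff diameter in pixels (default 6).
#' @param reconstruct_iter dilation steps of the constrained reconstruction
#'   (default 2; kept small so thin side-branches are not swallowed).
#' @return list with logical matrices `capillary` and `large`.
#' @export
remove_large_vessels <- function(mask, diameter_cutoff_px = 6,
                                 reconstruct_iter = 2) {
  if (diameter_cutoff_px < 1) stop("diameter_cutoff_px must be >= 1")
  mask <- mask > 0
  size <- as.integer(diameter_cutoff_px)
  if (size %% 2 == 0) size <- size + 1L
  if (size < 3L || !any(mask)) {
    return(list(capillary = mask,
                large = matrix(FALSE, nrow(mask), ncol(mask))))
  }
  brush <- EBImage::makeBrush(size, shape = "disc")
  seeds <- as.matrix(EBImage::opening(EBImage::Image(mask * 1), brush)) > 0
  large <- reconstruct_in_mask(seeds, mask, max_iter = reconstruct_iter)
  list(capillary = mask & !large, large = large)
}

#' Vessel maps for one image
#'
#' Bundles the binary capillary mask, the removed large-vessel mask, the
#' skeleton and the perimeter map; the skeleton and perimeter are computed
#' from the capillary mask.
#'
#' @param vessel_mask logical capillary mask (large vessels removed).
#' @param large_vessel_mask logical mask of removed large vessels.
#' @return a `vessel_maps` object with fields `vessel_mask`,
#'   `large_vessel_mask`, `skeleton`, `perimeter`.
#' @export
vessel_maps <- function(vessel_mask, large_vessel_mask = NULL) {
  vessel_mask <- vessel_mask > 0
  if (is.null(large_vessel_mask))
    large_vessel_mask <- matrix(FALSE, nrow(vessel_mask), ncol(vessel_mask))
  stopifnot(!any(vessel_mask & large_vessel_mask))
  structure(list(
    vessel_mask = vessel_mask,
    large_vessel_mask = large_vessel_mask > 0,
    skeleton = skeletonize_mask(vessel_mask),
    perimeter = perimeter_map(vessel_mask)
  ), class = "vessel_maps")
}

#' The six vessel parameters within one ROI
#'
#' Within the ROI mask: VAD = vessel px / ROI px; VSD = skeleton px / ROI px;
#' VDI = vessel px / skeleton px (mean vessel diameter, flagged undefined
#' when the skeleton is empty); VPI = perimeter px / ROI px;
#' VCI = perimeter^2 / (4 pi vessel px) (flagged undefined with no vessel
#' pixels); flux = mean normalized flow intensity over vessel-and-ROI pixels.
#' All metrics are capillary-bed metrics: large vessels are excluded
#' throughout, including from flux.
#'
#' @param maps a [vessel_maps()].
#' @param flow the source [flow_image()].
#' @param roi_mask logical ROI mask on the same grid.
#' @param region_label identifier stored in the output row.
#' @return one-row data.frame: `region, roi_px, vad, vsd, vdi, vpi, vci,
#'   flux, flags`.
#' @export
compute_metrics <- function(maps, flow, roi_mask, region_label = "whole") {
  stopifnot(inherits(maps, "vessel_maps"))
  roi_mask <- roi_mask > 0
  if (!any(roi_mask)) stop("empty ROI mask")
  n_roi <- sum(roi_mask)
  n_v <- sum(maps$vessel_mask & roi_mask)
  n_s <- sum(maps$skeleton & roi_mask)
  n_p <- sum(maps$perimeter & roi_mask)
  flags <- character()
  vad <- n_v / n_roi
  vsd <- n_s / n_roi
  vpi <- n_p / n_roi
  if (n_s > 0) vdi <- n_v / n_s else { vdi <- NA_real_; flags <- c(flags, "vdi_undefined") }
  if (n_v > 0) vci <- n_p^2 / (4 * pi * n_v) else { vci <- NA_real_; flags <- c(flags, "vci_undefined") }
  fx <- if (inherits(flow, "flow_image")) flow$intensities else flow
  sel <- maps$vessel_mask & roi_mask
  flux <- if (any(sel)) mean(fx[sel]) else { flags <- c(flags, "flux_undefined"); NA_real_ }
  data.frame(region = region_label, roi_px = n_roi, vad = vad, vsd = vsd,
             vdi = vdi, vpi = vpi, vci = vci, flux = flux,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Default settings for the quantification pipeline
#'
#' @param scales_px vesselness scales in pixels.
#' @param binarize_method `"global_otsu"` or `"fixed"`.
#' @param binarize_level level for the fixed method.
#' @param combine_raw also threshold the raw intensity image and take the
#'   union with the vesselness mask (hybrid segmentation; keeps wide bright
#'   vessels whose plateau interior has little tubular response).
#' @param large_vessel_cutoff_px diameter cutoff for large-vessel removal
#'   (default 6 px, about 60 um at 10 um/px).
#' @param qc_threshold minimum SSI (exclusive).
#' @param literal_vci if `TRUE`, report perimeter px / vessel px instead of
#'   the isoperimetric complexity index.
#' @return a list of class `quant_config`.
#' @export
quant_config <- function(scales_px = c(1, 2, 3),
                         binarize_method = "global_otsu",
                         binarize_level = NULL,
                         combine_raw = TRUE,
                         large_vessel_cutoff_px = 6,
                         qc_threshold = 7,
                         literal_vci = FALSE) {
  structure(list(scales_px = scales_px, binarize_method = binarize_method,
                 binarize_level = binarize_level, combine_raw = combine_raw,
                 large_vessel_cutoff_px = large_vessel_cutoff_px,
                 qc_threshold = qc_threshold, literal_vci = literal_vci),
            class = "quant_config")
}

#' Segment a flow image into vessel maps
#'
#' Runs enhancement, binarization and large-vessel removal with the given
#' configuration and returns the resulting [vessel_maps()].
#'
#' @param image a [flow_image()].
#' @param config a [quant_config()].
#' @return a `vessel_maps` object.
#' @export
segment_vessels <- function(image, config = quant_config()) {
  enh <- enhance_vessels(image, config$scales_px)
  mask <- binarize(enh, config$binarize_method, config$binarize_level)
  if (isTRUE(config$combine_raw))
    mask <- mask | binarize(image$intensities, config$binarize_method,
                            config$binarize_level)
  split <- remove_large_vessels(mask, config$large_vessel_cutoff_px)
  vessel_maps(split$capillary, split$large)
}

#' Quantify one image over an annulus ROI and its sectors
#'
#' Produces one metrics row for the whole annulus plus one per sector.
#'
#' @param image a [flow_image()] that passed QC.
#' @param roi an [annulus_roi()]; defaults to the standard annulus for the
#'   image's target.
#' @param part a [sector_partition()]; defaults to quadrants for disc and
#'   the 6-sector scheme for macula, using the image's laterality.
#' @param config a [quant_config()].
#' @param maps optional precomputed [vessel_maps()] (e.g. ground truth).
#' @return data.frame of [compute_metrics()] rows, regions
#'   `c("whole", sector labels)`.
#' @export
quantify_image <- function(image, roi = NULL, part = NULL,
                           config = quant_config(), maps = NULL) {
  stopifnot(inherits(image, "flow_image"))
  if (is.null(roi)) roi <- default_annulus(image$target)
  if (is.null(part)) {
    scheme <- if (image$target == "disc") "quadrants_4" else "macula_6"
    part <- sector_partition(scheme, image$eye)
  }
  if (is.null(maps)) maps <- segment_vessels(image, config)
  labels <- partition_sectors(image$grid, roi, part)
  ann <- attr(labels, "mask")
  rows <- list(compute_metrics(maps, image, ann, "whole"))
  for (nm in part$labels) {
    sect <- !is.na(labels) & labels == nm
    rows[[length(rows) + 1]] <- compute_metrics(maps, image, sect, nm)
  }
  out <- do.call(rbind, rows)
  if (isTRUE(config$literal_vci)) {
    nv <- out$vad * out$roi_px
    np <- out$vpi * out$roi_px
    out$vci <- ifelse(nv > 0, np / nv, NA_real_)
  }
  out
}

#' Sliding-window local metric map
#'
#' Local VAD (fraction of vessel pixels) or local VCI computed in a square
#' window around every pixel, for rendering density/complexity heat maps.
#'
#' @param maps a [vessel_maps()].
#' @param metric `"vad"` or `"vci"`.
#' @param window odd window side length in pixels (default 31).
#' @return numeric matrix of local metric values.
#' @export
local_metric_map <- function(maps, metric = c("vad", "vci"), window = 31) {
  metric <- match.arg(metric)
  stopifnot(window %% 2 == 1)
  box <- matrix(1, window, window)
  nv <- ebi_filter(maps$vessel_mask * 1, box)
  if (metric == "vad") return(pmax(pmin(nv / window^2, 1), 0))
  np <- ebi_filter(maps$perimeter * 1, box)
  ifelse(nv > 0.5, np^2 / (4 * pi * nv), 0)
}
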