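# Procedural vascular phantoms: branching vessel trees rendered on a grid
# with known ground-truth masks, standing in for acquired en-face scans.

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic vessel-network phantom
#'
#' @param grid an [image_grid()] (default 512 px over 3 mm).
#' @param n_trunks number of large vessels crossing the field.
#' @param trunk_width_px,branch_width_px stroke widths in pixels.
#' @param branching_probability per-step probability that a trunk spawns a
#'   side branch.
#' @param capillary_density target fraction of the field covered by the
#'   thin-vessel (capillary) ground truth, in \[0, 0.9\].
#' @param noise_sd Gaussian speckle standard deviation added to the
#'   rendered intensities.
#' @param seed integer RNG seed; the same spec renders identically.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid = image_grid(512), n_trunks = 3,
                         trunk_width_px = 12, branch_width_px = 3,
                         branching_probability = 0.02,
                         capillary_density = 0.2, noise_sd = 0.05,
                         seed = 1L) {
  stopifnot(trunk_width_px >= 1, branch_width_px >= 1,
            capillary_density >= 0, noise_sd >= 0)
  if (capillary_density > 0.9)
    stop("capillary_density above 0.9 is unsatisfiable")
  structure(list(grid = grid, n_trunks = n_trunks,
                 trunk_width_px = trunk_width_px,
                 branch_width_px = branch_width_px,
                 branching_probability = branching_probability,
                 capillary_density = capillary_density,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Stamp offsets for a disc of the given stroke width (precomputed patch).
stroke_offsets <- function(width) {
  r <- width / 2
  ri <- ceiling(r - 0.5)
  d <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  d <- d[d$dr^2 + d$dc^2 <= r^2 + 1e-9, ]
  as.matrix(d)
}

# Random-walk stroke with momentum; returns pixel indices covered.
# Direction jitter in radians per unit step controls tortuosity.
walk_stroke <- function(nr, nc, start, theta0, n_steps, width,
                        jitter = 0.15) {
  offs <- stroke_offsets(width)
  r <- start[1]; c <- start[2]; th <- theta0
  pts_r <- numeric(n_steps); pts_c <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    th <- th + stats::rnorm(1, 0, jitter)
    r <- r + sin(th); c <- c + cos(th)
    if (r < 1 || r > nr || c < 1 || c > nc) { n_steps <- i - 1; break }
    pts_r[i] <- r; pts_c[i] <- c
  }
  if (n_steps < 1) return(integer(0))
  rr <- rep(round(pts_r[1:n_steps]), each = nrow(offs)) + offs[, 1]
  cc <- rep(round(pts_c[1:n_steps]), each = nrow(offs)) + offs[, 2]
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  unique((cc[ok] - 1L) * nr + rr[ok])
}

#' Generate a synthetic vascular phantom
#'
#' Renders `n_trunks` large vessels as random-walk strokes across the field,
#' spawns thin side branches with the given per-step probability, then adds
#' further capillary strokes until the thin-vessel ground truth reaches the
#' requested density. Vessels are bright on a dark background; speckle noise
#' is added last and the image clipped to \[0, 1\]. Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [flow_image()]), `truth` (a [vessel_maps()]
#'   whose `vessel_mask` is the thin-vessel/capillary ground truth and
#'   `large_vessel_mask` the trunks), `strokes` (per-capillary-stroke pixel
#'   indices, used by [generate_grade_series()]), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$grid$height_px; nc <- spec$grid$width_px
  with_seed(spec$seed, {
    large <- matrix(FALSE, nr, nc)
    strokes <- list()
    for (k in seq_len(spec$n_trunks)) {
      # start on a random edge heading inward
      edge <- sample(4, 1)
      start <- switch(edge,
        c(1, stats::runif(1, 1, nc)), c(nr, stats::runif(1, 1, nc)),
        c(stats::runif(1, 1, nr), 1), c(stats::runif(1, 1, nr), nc))
      th0 <- switch(edge, pi / 2, -pi / 2, 0, pi) +
        stats::rnorm(1, 0, 0.3)
      n_steps <- round(1.5 * max(nr, nc))
      idx <- walk_stroke(nr, nc, start, th0, n_steps,
                         spec$trunk_width_px, jitter = 0.05)
      large[idx] <- TRUE
      # side branches off the trunk
      n_branch <- stats::rbinom(1, n_steps, spec$branching_probability)
      if (n_branch > 0 && length(idx)) {
        for (b in seq_len(n_branch)) {
          p <- idx[sample(length(idx), 1)]
          br <- c((p - 1L) %% nr + 1L, (p - 1L) %/% nr + 1L)
          bidx <- walk_stroke(nr, nc, br, stats::runif(1, 0, 2 * pi),
                              round(nr / 4), spec$branch_width_px,
                              jitter = 0.2)
          if (length(bidx)) strokes[[length(strokes) + 1]] <- bidx
        }
      }
    }
    # capillary strokes until the thin-vessel density target is met
    thin <- matrix(FALSE, nr, nc)
    for (s in strokes) thin[s] <- TRUE
    n_px <- nr * nc
    guard <- 0
    while (sum(thin & !large) / n_px < spec$capillary_density &&
           guard < 30000) {
      guard <- guard + 1
      start <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
      cidx <- walk_stroke(nr, nc, start, stats::runif(1, 0, 2 * pi),
                          round(nr / 3), spec$branch_width_px, jitter = 0.25)
      if (length(cidx) < 5) next
      strokes[[length(strokes) + 1]] <- cidx
      thin[cidx] <- TRUE
    }
    cap <- thin & !large
    # render: dark background, bright vessels with mild per-pixel variation
    img <- matrix(0.08, nr, nc)
    vessel_gain <- matrix(stats::runif(n_px, 0.85, 1.0), nr, nc)
    img[cap] <- 0.75 * vessel_gain[cap]
    img[large] <- 0.92 * vessel_gain[large]
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n_px, 0, spec$noise_sd), nr, nc)
    img <- pmin(pmax(img, 0), 1)
    fi <- flow_image(img, spec$grid, signal_strength_index = 10,
                     eye = "OD", target = "disc")
    list(image = fi, truth = vessel_maps(cap, large), strokes = strokes,
         spec = spec)
  })
}

#' Generate a DR-grade series of phantoms by capillary dropout
#'
#' Emulates progressive microvascular dropout: the same base phantom is
#' degraded grade by grade by deleting a nondecreasing fraction of its
#' capillary strokes (in one fixed random order, so later grades always
#' delete supersets of earlier ones and measured density is monotone).
#'
#' @param base a [phantom_spec()] or a [generate_phantom()] result.
#' @param dropout_per_grade nondecreasing dropout fractions in \[0, 1\],
#'   one per grade (default 5 grades, DR0-DR4).
#' @return list of per-grade lists `(image, truth, dropout, truth_vad)`.
#' @export
generate_grade_series <- function(base = phantom_spec(),
                                  dropout_per_grade = c(0, 0.1, 0.2, 0.3, 0.4)) {
  if (any(dropout_per_grade < 0 | dropout_per_grade > 1))
    stop("dropout fractions must lie in [0, 1]")
  if (is.unsorted(dropout_per_grade))
    stop("dropout fractions must be nondecreasing over grades")
  ph <- if (inherits(base, "phantom_spec")) generate_phantom(base) else base
  spec <- ph$spec
  nr <- spec$grid$height_px; nc <- spec$grid$width_px
  K <- length(ph$strokes)
  with_seed(spec$seed + 1L, {
    ord <- sample(K)
    noise <- matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    gain <- matrix(stats::runif(nr * nc, 0.85, 1.0), nr, nc)
    lapply(seq_along(dropout_per_grade), function(g) {
      drop_k <- ord[seq_len(round(dropout_per_grade[g] * K))]
      thin <- matrix(FALSE, nr, nc)
      for (s in ph$strokes[setdiff(seq_len(K), drop_k)]) thin[s] <- TRUE
      cap <- thin & !ph$truth$large_vessel_mask
      img <- matrix(0.08, nr, nc)
      img[cap] <- 0.75 * gain[cap]
      img[ph$truth$large_vessel_mask] <- 0.92 * gain[ph$truth$large_vessel_mask]
      img <- pmin(pmax(img + noise, 0), 1)
      list(image = flow_image(img, spec$grid, signal_strength_index = 10,
                              eye = "OD", target = "disc"),
           truth = vessel_maps(cap, ph$truth$large_vessel_mask),
           dropout = dropout_per_grade[g],
           truth_vad = sum(cap) / (nr * nc))
    })
  })
}

#' Write a phantom bundle to disk
#'
#' Image as 16-bit TIFF with JSON sidecar, ground-truth masks as PNG, and
#' the spec (including its seed) as JSON.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_flow_image(phantom$image, file.path(dir, paste0(name, ".tif")))
  write_mask_png(phantom$truth$vessel_mask,
                 file.path(dir, paste0(name, "_capillary_mask.png")))
  write_mask_png(phantom$truth$large_vessel_mask,
                 file.path(dir, paste0(name, "_large_vessel_mask.png")))
  sp <- phantom$spec
  jsonlite::write_json(
    list(height_px = sp$grid$height_px, width_px = sp$grid$width_px,
         extent_mm = sp$grid$extent_mm, n_trunks = sp$n_trunks,
         trunk_width_px = sp$trunk_width_px,
         branch_width_px = sp$branch_width_px,
         branching_probability = sp$branching_probability,
         capillary_density = sp$capillary_density,
         noise_sd = sp$noise_sd, seed = sp$seed),
    file.path(dir, paste0(name, "_spec.json")), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
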