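# Shared in-code fixtures: analytic phantoms with known geometry.

# Horizontal bright bar of given width/length centred in an n x n field.
bar_image <- function(n = 128, width = 3, lo = 0.05, hi = 0.9,
                      rows = NULL, cols = NULL) {
  img <- matrix(lo, n, n)
  if (is.null(rows)) {
    mid <- floor(n / 2)
    half <- floor(width / 2)
    rows <- (mid - half):(mid - half + width - 1)
  }
  if (is.null(cols)) cols <- 10:(n - 10)
  img[rows, cols] <- hi
  attr(img, "gt") <- {
    gt <- matrix(FALSE, n, n); gt[rows, cols] <- TRUE; gt
  }
  img
}

# Vertical parallel bars: width w, pitch p, over an n x n field.
bars_image <- function(n = 512, w = 4, p = 16, lo = 0.05, hi = 0.9) {
  img <- matrix(lo, n, n)
  gt <- matrix(FALSE, n, n)
  for (s in seq(ceiling(p / 2), n - w, by = p)) {
    img[, s:(s + w - 1)] <- hi
    gt[, s:(s + w - 1)] <- TRUE
  }
  attr(img, "gt") <- gt
  img
}

# Filled disc of radius r at the centre of an n x n field.
disc_mask <- function(n = 101, r = 20) {
  ctr <- (n + 1) / 2
  d2 <- outer((1:n - ctr)^2, (1:n - ctr)^2, "+")
  d2 < r^2
}

rot90 <- function(m) t(m)[ncol(m):1, ]

count_2x2_blocks <- function(m) {
  sum(m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] & m[-nrow(m), -1] & m[-1, -1])
}

# Cache the default clean phantom across test files (segmentation is the
# expensive step).
phantom_cache <- new.env(parent = emptyenv())
clean_phantom <- function() {
  if (is.null(phantom_cache$ph)) {
    phantom_cache$ph <- generate_phantom(phantom_spec(noise_sd = 0))
    phantom_cache$maps <- segment_vessels(phantom_cache$ph$image)
  }
  list(ph = phantom_cache$ph, maps = phantom_cache$maps)
}
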