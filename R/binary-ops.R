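# Low-level binary-mask operations shared by the quantification pipeline.
# Masks are logical matrices; out-of-image pixels count as background.

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = FALSE) {
  out <- matrix(fill, nrow(m), ncol(m))
  ri <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
  ci <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
  out[ri, ci] <- m[ri - dr, ci - dc]
  out
}

#' Label 8-connected components of a binary mask
#'
#' EBImage's `bwlabel` uses 4-connectivity; vessel skeletons are conventionally
#' analysed with 8-connectivity (diagonal skeleton steps keep a vessel in one
#' piece), so this labeller is provided alongside.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask)
  idx <- which(mask)
  nxt <- 0L
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      nb <- p + offs
      # drop neighbours that wrap across matrix columns or run off the ends
      keep <- nb >= 1L & nb <= length(mask)
      rr <- (nb - 1L) %% nr + 1L
      keep <- keep & abs(rr - r) <= 1L
      nb <- nb[keep]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Count 8-connected components
#' @param mask logical matrix.
#' @return integer component count.
#' @export
count_components8 <- function(mask) max(label_components8(mask))

#' Perimeter map of a binary mask
#'
#' A pixel is a perimeter pixel iff it is foreground and at least one of its
#' 4-neighbours (up/down/left/right; out-of-image counts as background) is
#' background.
#'
#' @param mask logical matrix.
#' @return logical matrix of perimeter pixels (subset of `mask`).
#' @export
perimeter_map <- function(mask) {
  mask <- mask > 0
  interior <- shift_mat(mask, 1, 0) & shift_mat(mask, -1, 0) &
              shift_mat(mask, 0, 1) & shift_mat(mask, 0, -1)
  mask & !interior
}

# Guo-Hall sub-iteration: returns the deletion mask for parity 0/1.
guo_hall_step <- function(m, parity) {
  p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
  p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
  p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
  p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
       (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  N <- pmin(N1, N2)
  cond <- if (parity == 0) (p2 | p3 | !p5) & p4 else (p6 | p7 | !p9) & p8
  m & C == 1 & N >= 2 & N <= 3 & !cond
}

#' Topology-preserving skeletonization (thinning)
#'
#' Guo-Hall parallel thinning: only simple points are removed, so the number
#' of 8-connected components is preserved and the result is one pixel wide.
#' A final sequential pass removes redundant pixels of any residual 2x2
#' block, again deleting only simple points.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix, a subset of `mask`.
#' @export
skeletonize_mask <- function(mask) {
  m <- mask > 0
  repeat {
    changed <- FALSE
    for (parity in c(0, 1)) {
      del <- guo_hall_step(m, parity)
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  prune_blocks(m)
}

# Remove redundant pixels so no 2x2 all-foreground block remains, deleting
# one simple point at a time.
prune_blocks <- function(m) {
  nr <- nrow(m)
  repeat {
    # anchor (r, c) at the top-left corner of each 2x2 all-foreground block
    blocks <- m & shift_mat(m, -1, 0) & shift_mat(m, 0, -1) &
      shift_mat(m, -1, -1)
    cand <- which(blocks)
    if (!length(cand)) break
    progress <- FALSE
    for (p in cand) {
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      # re-check: block may have been broken by an earlier deletion
      if (!(m[r, c] && r < nrow(m) && c < ncol(m) &&
            m[r + 1, c] && m[r, c + 1] && m[r + 1, c + 1])) next
      quad <- list(c(r, c), c(r, c + 1), c(r + 1, c), c(r + 1, c + 1))
      done <- FALSE
      for (q in quad) {
        if (is_simple_point(m, q[1], q[2])) {
          m[q[1], q[2]] <- FALSE
          progress <- TRUE
          done <- TRUE
          break
        }
      }
      if (!done) {
        # locked block: no pixel is locally simple, but deletion may still
        # be globally safe; fall back to an exact component-count check
        n0 <- count_components8(m)
        for (q in quad) {
          m2 <- m
          m2[q[1], q[2]] <- FALSE
          if (count_components8(m2) == n0) {
            m <- m2
            progress <- TRUE
            break
          }
        }
      }
    }
    if (!progress) break  # no deletable pixel; give up rather than loop
  }
  m
}

# A foreground pixel is simple iff deleting it does not change local
# topology: its 8-neighbourhood has exactly one 8-connected foreground
# component, at least 2 foreground neighbours (not an endpoint), and the
# crossing-number condition holds.
is_simple_point <- function(m, r, c) {
  nb <- matrix(FALSE, 3, 3)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m))
      nb[dr + 2, dc + 2] <- m[rr, cc]
  }
  nb[2, 2] <- FALSE
  if (sum(nb) < 2) return(FALSE)
  # Yokoi connectivity number (same C as the thinning step): deletable iff 1
  p2 <- nb[1, 2]; p3 <- nb[1, 3]; p4 <- nb[2, 3]; p5 <- nb[3, 3]
  p6 <- nb[3, 2]; p7 <- nb[3, 1]; p8 <- nb[2, 1]; p9 <- nb[1, 1]
  C <- (!p2 && (p3 || p4)) + (!p4 && (p5 || p6)) +
       (!p6 && (p7 || p8)) + (!p8 && (p9 || p2))
  C == 1
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|A & B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical matrices of equal dimension.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Morphological reconstruction of seeds within a mask
#'
#' Geodesic dilation of `seeds` inside `mask` with a 3x3 structuring element,
#' iterated `max_iter` times or to convergence.
#'
#' @param seeds,mask logical matrices, `seeds` a subset of `mask`.
#' @param max_iter maximum dilation steps; `Inf` runs to convergence.
#' @return logical matrix of reconstructed pixels.
#' @export
reconstruct_in_mask <- function(seeds, mask, max_iter = Inf) {
  cur <- seeds & mask
  it <- 0
  while (it < max_iter) {
    dil <- cur | shift_mat(cur, 1, 0) | shift_mat(cur, -1, 0) |
      shift_mat(cur, 0, 1) | shift_mat(cur, 0, -1) |
      shift_mat(cur, 1, 1) | shift_mat(cur, 1, -1) |
      shift_mat(cur, -1, 1) | shift_mat(cur, -1, -1)
    dil <- dil & mask
    if (identical(dil, cur)) break
    cur <- dil
    it <- it + 1
  }
  cur
}
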