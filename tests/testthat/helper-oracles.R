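# Independent oracles used across the suite. These deliberately avoid the
# package's own kernels: brute-force pixel enumeration and closed-form
# solutions only.

# squared Euclidean distance from every pixel to the nearest TRUE pixel,
# by exhaustive search
brute_edt2 <- function(mask) {
  f <- which(mask, arr.ind = TRUE)
  d <- matrix(Inf, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask)))
    for (c in seq_len(ncol(mask)))
      d[r, c] <- min((f[, 1] - r)^2 + (f[, 2] - c)^2)
  d
}

# per-pixel nearest-particle assignment by exhaustive search; particles are
# cells (point generators, in id order) then obstacle components (extended
# generators). Returns the cell index (1..n_cells) or 0 for obstacle-owned
# or solid/outside pixels. Ties: lowest particle index wins, cells first.
brute_voronoi <- function(scene) {
  cl <- scene$cells[order(scene$cells$id), , drop = FALSE]
  lab <- strucell:::.label4_cpp(scene$mask)
  r <- scene$roi
  roi_labs <- setdiff(unique(as.vector(lab[r[1]:r[2], r[3]:r[4]])), 0L)
  comp_px <- lapply(roi_labs, function(l) which(lab == l, arr.ind = TRUE))
  out <- matrix(0L, nrow(scene$mask), ncol(scene$mask))
  for (rr in r[1]:r[2]) for (cc in r[3]:r[4]) {
    if (scene$mask[rr, cc]) next
    best_d <- Inf; best <- 0L
    for (k in seq_len(nrow(cl))) {
      d <- (cl$row[k] - rr)^2 + (cl$col[k] - cc)^2
      if (d < best_d) { best_d <- d; best <- k }
    }
    for (px in comp_px) {
      d <- min((px[, 1] - rr)^2 + (px[, 2] - cc)^2)
      if (d < best_d) { best_d <- d; best <- 0L }  # strict: cell wins ties
    }
    out[rr, cc] <- best
  }
  out
}

# closed-form cross-channel profile of the interpolated thick/thin-limit
# channel flow, normalised to unit mean; x and w, h in pixels
brinkman_channel_profile <- function(x, w, h) {
  k <- sqrt(12) / h
  raw <- 1 - cosh(k * (x - w / 2)) / cosh(k * w / 2)
  raw / (1 - tanh(k * w / 2) / (k * w / 2))
}

# empty straight channel scene: ny rows (flow direction) by nx columns
channel_scene <- function(nx, ny, height_px, pixel_size = 0.5) {
  new_scene(matrix(FALSE, ny, nx), pixel_size = pixel_size,
            height_um = pixel_size * height_px)
}

# maximum relative-to-peak deviation from the closed form at mid-channel,
# excluding pixels within one boundary-layer width (h/sqrt(12), at least
# one pixel) of the side walls where the staircase discretisation cannot
# resolve the profile pointwise
profile_error <- function(field, height_px) {
  nx <- ncol(field$v_face)
  ny <- nrow(field$v_face)
  prof <- field$v_face[floor(ny / 2), ]
  x <- seq_len(nx) - 0.5
  exact <- brinkman_channel_profile(x, nx, height_px)
  keep <- x >= max(1, height_px / sqrt(12)) &
    x <= nx - max(1, height_px / sqrt(12))
  max(abs(prof[keep] - exact[keep])) / max(exact)
}
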