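#' Rendering configuration
#'
#' Controls how a simulated monolayer is rasterized into phase-contrast-like
#' frames. Each cell is painted as a frozen, per-cell pseudo-random speckle
#' texture (PIV needs intra-window texture, which plain Gaussian blobs lack),
#' windowed to the cell radius, plus Gaussian sensor noise. The rendered
#' window is an interior crop of the periodic box so that velocimetry never
#' sees a wrap seam.
#'
#' @param pixel_size Calibration, um/px. Default 0.75488.
#' @param image_shape Side of the square rendered window, px.
#' @param blob_sigma Correlation length of the intra-cell speckle, px.
#' @param texture_amplitude Peak-to-background amplitude of the texture, on a
#'   0-1 intensity scale.
#' @param noise_sigma Gaussian sensor noise standard deviation, 0-1 scale.
#' @param bit_depth 8 or 16; quantization applied to rendered intensities.
#' @return A list of class `render_config`.
#' @export
render_config <- function(pixel_size = 0.75488, image_shape = 384,
                          blob_sigma = 1.5, texture_amplitude = 0.6,
                          noise_sigma = 0.01, bit_depth = 16) {
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  structure(
    list(pixel_size = pixel_size, image_shape = as.integer(image_shape),
         blob_sigma = blob_sigma, texture_amplitude = texture_amplitude,
         noise_sigma = noise_sigma, bit_depth = as.integer(bit_depth)),
    class = "render_config"
  )
}

#' Calibrated image stack
#'
#' Container for a frame sequence with its physical calibration; the input
#' type of [multipass_piv()].
#'
#' @param frames List of numeric matrices (all the same shape, intensities on
#'   any common scale).
#' @param frame_interval Time between frames, min.
#' @param pixel_size Calibration, um/px.
#' @param source_id Free-text provenance tag.
#' @return A list of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval, pixel_size,
                        source_id = "unknown") {
  if (length(frames) < 2) abort("An image stack needs at least 2 frames.")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) abort("All frames must share one shape.")
  if (frame_interval <= 0 || pixel_size <= 0) {
    abort("`frame_interval` and `pixel_size` must be positive.")
  }
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size, source_id = source_id),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<image_stack> %d frames of %dx%d px, %g um/px, every %g min (%s)\n",
    length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval, x$source_id
  ))
  invisible(x)
}

# Separable Gaussian blur of a matrix (reflective edges), used for speckle.
gaussian_blur_ <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
  mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m))]
  out <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
  out <- t(apply(out, 1, function(row) stats::filter(row, k, sides = 2)))
  out[r + seq_len(nrow(m)), r + seq_len(ncol(m))]
}

# Frozen speckle texture for one cell, seeded from (stack seed, cell id).
cell_texture_ <- function(cell_id, base_seed, radius_px, blob_sigma,
                          amplitude) {
  m <- 2L * ceiling(radius_px) + 5L
  with_seed_((base_seed + 7919L * cell_id) %% .Machine$integer.max, {
    speck <- matrix(runif(m * m, -1, 1), m, m)
    speck <- gaussian_blur_(speck, blob_sigma)
    speck <- speck / max(abs(speck))
    ctr <- (m + 1) / 2
    rr <- sqrt(outer((seq_len(m) - ctr)^2, (seq_len(m) - ctr)^2, "+"))
    taper <- 0.5 * (1 + cos(pi * pmin(rr / radius_px, 1)))
    amplitude * (0.5 + 0.5 * speck) * taper
  })
}

# um -> px coordinate of the rendered window (1 = centre of first pixel).
window_origin_ <- function(box_size, rc) {
  (box_size - rc$image_shape * rc$pixel_size) / 2
}

#' Render a simulated trajectory as an image stack
#'
#' Paints each cell's frozen speckle texture at its wrapped position with
#' bilinear subpixel placement, adds Gaussian sensor noise, and quantizes to
#' the configured bit depth. Identical trajectory, configuration and seed
#' reproduce pixels exactly.
#'
#' @param traj A `monolayer_trajectory` from [simulate_monolayer()].
#' @param rc A [render_config()]. The rendered window (an interior, centred
#'   crop of the box) must fit: `image_shape * pixel_size <= box_size`.
#' @return An [image_stack()] with one frame per trajectory frame,
#'   intensities quantized to `0 .. 2^bit_depth - 1`.
#' @export
render_frames <- function(traj, rc) {
  stopifnot(inherits(traj, "monolayer_trajectory"),
            inherits(rc, "render_config"))
  box <- traj$config$box_size
  if (rc$image_shape * rc$pixel_size > box + 1e-9) {
    abort("Rendered window does not fit inside the box; shrink `image_shape`.")
  }
  n <- traj$config$n_cells
  nf <- traj$config$n_frames
  sz <- rc$image_shape
  r_px <- traj$config$cell_radius / rc$pixel_size
  base_seed <- traj$config$rng_seed
  textures <- lapply(seq_len(n), cell_texture_, base_seed = base_seed,
                     radius_px = r_px, blob_sigma = rc$blob_sigma,
                     amplitude = rc$texture_amplitude)
  m <- nrow(textures[[1]])
  half <- (m - 1L) %/% 2L
  k <- seq_len(m) - 1
  k[k > m / 2] <- k[k > m / 2] - m
  freqs <- k / m
  tex_fft <- lapply(textures, fft)
  origin <- window_origin_(box, rc)
  qmax <- 2^rc$bit_depth - 1

  frames <- vector("list", nf)
  for (fr in seq_len(nf)) {
    img <- matrix(0.1, sz, sz)  # background level
    cx <- (traj$positions[fr, , 1] - origin) / rc$pixel_size + 0.5
    cy <- (traj$positions[fr, , 2] - origin) / rc$pixel_size + 0.5
    for (i in seq_len(n)) {
      if (cx[i] < -half || cx[i] > sz + half ||
          cy[i] < -half || cy[i] > sz + half) next
      bx <- floor(cx[i]); fx <- cx[i] - bx
      by <- floor(cy[i]); fy <- cy[i] - by
      # band-limited (Fourier) subpixel shift: shift-invariant blur, so
      # fractional positions do not alias into displacement estimates
      shifted <- Re(fft(tex_fft[[i]] * outer(exp(-2i * pi * freqs * fy),
                                             exp(-2i * pi * freqs * fx)),
                        inverse = TRUE)) / (m * m)
      rows <- (by - half):(by + half)        # y = row
      cols <- (bx - half):(bx + half)        # x = column
      ok_r <- rows >= 1L & rows <= sz
      ok_c <- cols >= 1L & cols <= sz
      if (!any(ok_r) || !any(ok_c)) next
      img[rows[ok_r], cols[ok_c]] <- img[rows[ok_r], cols[ok_c]] +
        shifted[which(ok_r), which(ok_c)]
    }
    if (rc$noise_sigma > 0) {
      img <- img + with_seed_(
        (base_seed + 104729L * fr) %% .Machine$integer.max,
        matrix(rnorm(sz * sz, sd = rc$noise_sigma), sz, sz)
      )
    }
    frames[[fr]] <- round(pmin(pmax(img, 0), 1) * qmax)
  }
  image_stack(frames, traj$config$frame_interval, rc$pixel_size,
              source_id = sprintf("synthetic seed %d", base_seed))
}

#' Integer label mask
#'
#' @param labels Integer matrix; 0 marks background, positive values one
#'   connected cell each.
#' @param pixel_size Calibration, um/px.
#' @return A list of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size) {
  if (any(labels < 0)) abort("Labels must be non-negative.")
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "label_mask")
}

#' Rasterized periodic Voronoi tessellation of point centres
#'
#' Assigns every pixel of a square window (an interior, centred crop of the
#' periodic box) to its nearest centre under the minimum-image metric. Cells
#' are space filling: there are no background boundary pixels, so adjacent
#' labels touch directly. Labels are renumbered consecutively over the
#' centres actually present in the window.
#'
#' @param centers Two-column matrix of centre coordinates, um, inside the box.
#' @param box_size Periodic box side, um.
#' @param rc A [render_config()] giving window size and calibration.
#' @return A [label_mask()].
#' @export
voronoi_mask_from_centers <- function(centers, box_size, rc) {
  centers <- as.matrix(centers)
  if (anyDuplicated(round(centers / 1e-9))) {
    warn("Coincident centres perturbed by 1e-6 * box_size.")
    centers <- centers + matrix(
      runif(length(centers), -1e-6, 1e-6) * box_size, ncol = 2
    )
  }
  sz <- rc$image_shape
  origin <- window_origin_(box_size, rc)
  # pixel-centre coordinates in box frame; row = y, column = x
  coord <- origin + (seq_len(sz) - 0.5) * rc$pixel_size
  labels <- matrix(0L, sz, sz)
  chunk <- max(1L, floor(2e6 / (nrow(centers) * sz)))
  for (start in seq(1L, sz, by = chunk)) {
    rows <- start:min(start + chunk - 1L, sz)
    py <- rep(coord[rows], times = sz)
    px <- rep(coord, each = length(rows))
    dx <- abs(outer(px, centers[, 1], "-")); dx <- pmin(dx, box_size - dx)
    dy <- abs(outer(py, centers[, 2], "-")); dy <- pmin(dy, box_size - dy)
    labels[rows, ] <- matrix(max.col(-(dx * dx + dy * dy), "first"),
                             nrow = length(rows))
  }
  present <- sort(unique(as.vector(labels)))
  relabel <- integer(nrow(centers))
  relabel[present] <- seq_along(present)
  label_mask(matrix(relabel[labels], sz, sz), rc$pixel_size)
}

#' Voronoi label mask of one trajectory frame
#'
#' Stand-in for membrane-delineated cell borders: the wrapped cell centres of
#' `frame` are tessellated with [voronoi_mask_from_centers()].
#'
#' @param traj A `monolayer_trajectory`.
#' @param frame Frame index.
#' @param rc A [render_config()].
#' @return A [label_mask()].
#' @export
voronoi_masks <- function(traj, frame, rc) {
  stopifnot(inherits(traj, "monolayer_trajectory"))
  if (frame < 1 || frame > traj$config$n_frames) abort("Invalid frame index.")
  voronoi_mask_from_centers(traj$positions[frame, , , drop = TRUE],
                            traj$config$box_size, rc)
}
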