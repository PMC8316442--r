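# Fixtures built in code: textured images, spectral shifts, rasterized
# shapes, analytic velocity fields.

# Smooth random speckle image, reproducible for a given seed.
speckle_image <- function(n, seed, sigma = 2) {
  set.seed(seed)
  raw <- matrix(runif(n * n), n, n)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(m) m[c(rev(seq_len(r)), seq_len(nrow(m)),
                         nrow(m) + 1 - seq_len(r)),
                       c(rev(seq_len(r)), seq_len(ncol(m)),
                         ncol(m) + 1 - seq_len(r))]
  sm <- apply(pad(raw), 2, function(col) stats::filter(col, k, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, sides = 2)))
  sm[r + seq_len(n), r + seq_len(n)]
}

# Subpixel circular shift by (dx, dy) via Fourier phase ramp: the exact
# ground truth for subpixel displacement recovery.
fourier_shift <- function(img, dx, dy) {
  n <- nrow(img); m <- ncol(img)
  freq <- function(len) {
    k <- seq_len(len) - 1
    k[k > len / 2] <- k[k > len / 2] - len
    k / len
  }
  phase <- exp(-2i * pi * (outer(freq(n) * dy, freq(m) * dx, "+")))
  Re(fft(fft(img) * phase, inverse = TRUE)) / (n * m)
}

# Binary masks of reference shapes on a zero background.
raster_disk <- function(r, pad = 10L) {
  n <- 2L * r + 2L * pad
  ctr <- n / 2 + 0.5
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  (d2 <= r^2) + 0L
}

raster_square <- function(side, pad = 10L) {
  n <- side + 2L * pad
  m <- matrix(0L, n, n)
  m[pad + seq_len(side), pad + seq_len(side)] <- 1L
  m
}

# Regular hexagon (vertex on the x axis), circumradius r: intersection of
# three slabs with normals at 30, 90 and 150 degrees and apothem r*sqrt(3)/2.
raster_hexagon <- function(r, pad = 10L) {
  n <- 2L * r + 2L * pad
  ctr <- n / 2 + 0.5
  x <- matrix(rep(seq_len(n) - ctr, each = n), n)   # column coordinate
  y <- matrix(rep(seq_len(n) - ctr, times = n), n)  # row coordinate
  a <- r * sqrt(3) / 2
  inside <- matrix(TRUE, n, n)
  for (th in c(pi / 6, pi / 2, 5 * pi / 6)) {
    inside <- inside & abs(x * cos(th) + y * sin(th)) <= a
  }
  inside + 0L
}

# Analytic velocity-field sequence on a regular grid (units um/min).
analytic_fields <- function(u_fun, v_fun, times, gx_px, gy_px,
                            pixel_size = 1, frame_interval = 5) {
  rows <- lapply(times, function(t) {
    g <- expand.grid(grid_y_px = gy_px, grid_x_px = gx_px)
    x_um <- g$grid_x_px * pixel_size
    y_um <- g$grid_y_px * pixel_size
    tibble::tibble(
      t_min = t, grid_x_px = g$grid_x_px, grid_y_px = g$grid_y_px,
      u_um_min = u_fun(x_um, y_um, t), v_um_min = v_fun(x_um, y_um, t),
      valid = TRUE
    )
  })
  velocity_fields(dplyr::bind_rows(rows), pixel_size, frame_interval)
}

# Small rendered drift stack: every cell translates at `v_px_frame` px/frame.
drift_stack <- function(v_px_frame = c(1, 0), n_frames = 6, image_shape = 256,
                        n_cells = 150, seed = 11, noise_sigma = 0.01,
                        frame_interval = 5, pixel_size = 0.75488) {
  rc <- render_config(pixel_size = pixel_size, image_shape = image_shape,
                      noise_sigma = noise_sigma)
  cfg <- sim_config(n_cells = n_cells,
                    box_size = image_shape * pixel_size + 40,
                    v0 = 0, d_r = 0, repulsion_stiffness = 0,
                    n_frames = n_frames, frame_interval = frame_interval,
                    equil_time = 0, rng_seed = seed)
  v_um_min <- v_px_frame * pixel_size / frame_interval
  traj <- drift_trajectory(cfg, v_um_min)
  list(traj = traj, stack = render_frames(traj, rc), rc = rc, cfg = cfg,
       v_um_min = v_um_min)
}

# Direct trajectory_set constructor for closed-form dynamics fixtures.
make_trajectory_set <- function(r, frame_interval = 5) {
  nt <- dim(r)[1]; ntr <- dim(r)[2]
  structure(
    list(r = r, times = (seq_len(nt) - 1) * frame_interval,
         active = matrix(TRUE, nt, ntr),
         seed_spacing = NA_real_, frame_interval = frame_interval),
    class = "trajectory_set"
  )
}
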