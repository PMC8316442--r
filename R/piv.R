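#' PIV configuration
#'
#' Multi-pass FFT cross-correlation settings. The default two passes (64 then
#' 32 px interrogation windows at 50% overlap) reproduce the standard scheme
#' for epithelial monolayer movies; pass n+1 uses the validated, bilinearly
#' interpolated field of pass n as a window-offset predictor.
#'
#' @param window_sizes Interrogation window sides in px, strictly decreasing
#'   powers of two.
#' @param overlap_fraction Window overlap in `[0, 1)`; grid spacing is
#'   `window * (1 - overlap_fraction)`.
#' @param outlier_threshold Normalized-median-test statistic above which a
#'   vector is replaced by its neighbourhood median.
#' @param min_valid_fraction Below this valid-vector fraction a field is
#'   marked low quality and the pipeline warns.
#' @param eps Noise floor of the normalized median test, px.
#' @param highpass_sigma Gaussian high-pass applied to every frame before
#'   correlation (the frame minus its `highpass_sigma`-blurred version), px;
#'   0 disables. Removes cell-scale envelope structure whose static window
#'   crop otherwise biases fractional displacements toward integers.
#' @return A list of class `piv_config`.
#' @export
piv_config <- function(window_sizes = c(64L, 32L), overlap_fraction = 0.5,
                       outlier_threshold = 2.0, min_valid_fraction = 0.8,
                       eps = 0.1, highpass_sigma = 2) {
  window_sizes <- as.integer(window_sizes)
  if (any(diff(window_sizes) >= 0)) {
    abort("`window_sizes` must be strictly decreasing.")
  }
  if (any(bitwAnd(window_sizes, window_sizes - 1L) != 0L)) {
    abort("`window_sizes` must be powers of two.")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must be in [0, 1).")
  }
  structure(
    list(window_sizes = window_sizes, overlap_fraction = overlap_fraction,
         subpixel_method = "gaussian3", outlier_threshold = outlier_threshold,
         min_valid_fraction = min_valid_fraction, eps = eps,
         highpass_sigma = highpass_sigma),
    class = "piv_config"
  )
}

# 3-point fit around the correlation peak along one axis; Gaussian in log
# intensities, falling back to a parabola when a sample is non-positive.
subpixel_offset_ <- function(c_m, c_0, c_p) {
  if (c_m > 0 && c_0 > 0 && c_p > 0) {
    num <- log(c_m) - log(c_p)
    den <- 2 * (log(c_m) - 2 * log(c_0) + log(c_p))
  } else {
    num <- c_m - c_p
    den <- 2 * (c_m - 2 * c_0 + c_p)
  }
  if (den == 0 || !is.finite(den)) return(0)
  off <- num / den
  if (!is.finite(off) || abs(off) > 1) 0 else off
}

#' Displacement between two image patches by circular cross-correlation
#'
#' Computes the mean-subtracted circular cross-correlation of two equal,
#' square patches by FFT and returns the location of its peak refined by a
#' 3-point Gaussian subpixel fit per axis. Sign convention: the returned
#' `(dx, dy)` is the motion of `win_b`'s content relative to `win_a`, with
#' x along columns and y along rows (image coordinates, origin top left).
#'
#' @param win_a,win_b Numeric matrices of identical square shape.
#' @return A list with `dx`, `dy` (px) and `valid`; a constant (zero
#'   variance) patch yields `valid = FALSE` and zero displacement.
#' @export
cross_correlate_window <- function(win_a, win_b) {
  stopifnot(is.matrix(win_a), identical(dim(win_a), dim(win_b)),
            nrow(win_a) == ncol(win_a))
  a <- win_a - mean(win_a)
  b <- win_b - mean(win_b)
  if (sum(a * a) == 0 || sum(b * b) == 0) {
    return(list(dx = 0, dy = 0, valid = FALSE))
  }
  n <- nrow(a)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / (n * n)
  peak <- arrayInd(which.max(cc), dim(cc))
  iy <- peak[1]; ix <- peak[2]
  wrap <- function(i) ((i - 1L) %% n) + 1L
  dy <- (iy - 1L); dx <- (ix - 1L)
  sub_y <- subpixel_offset_(cc[wrap(iy - 1L), ix], cc[iy, ix],
                            cc[wrap(iy + 1L), ix])
  sub_x <- subpixel_offset_(cc[iy, wrap(ix - 1L)], cc[iy, ix],
                            cc[iy, wrap(ix + 1L)])
  if (dy > n / 2) dy <- dy - n
  if (dx > n / 2) dx <- dx - n
  list(dx = dx + sub_x, dy = dy + sub_y, valid = TRUE)
}

# Tile top-left corners for one pass; tiles that do not fit are dropped.
tile_starts_ <- function(extent, window, spacing) {
  s <- seq(1L, extent - window + 1L, by = spacing)
  s[s + window - 1L <= extent]
}

#' Single PIV pass over a frame pair
#'
#' Tiles the frames at spacing `window * (1 - overlap)` and correlates each
#' window pair with [cross_correlate_window()]. With a `predictor`, the
#' second frame's window is offset by the rounded predicted displacement
#' (clamped to the frame) before correlation and the applied offset added
#' back, so only the residual must fit in the window.
#'
#' @param frame_a,frame_b Numeric matrices of identical shape.
#' @param window Interrogation window side, px.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param predictor Optional list with matrices `u`, `v` (px) on this pass's
#'   grid.
#' @return A `piv_field_raw` list: grid centre coordinates `gx`, `gy` (px),
#'   displacement matrices `u`, `v` (px, rows = y, columns = x) and `valid`.
#' @export
piv_pass <- function(frame_a, frame_b, window, overlap, predictor = NULL) {
  if (window > min(dim(frame_a))) {
    abort("Interrogation window larger than the image.")
  }
  spacing <- max(1L, as.integer(round(window * (1 - overlap))))
  ys <- tile_starts_(nrow(frame_a), window, spacing)
  xs <- tile_starts_(ncol(frame_a), window, spacing)
  u <- v <- matrix(0, length(ys), length(xs))
  valid <- matrix(TRUE, length(ys), length(xs))
  nr <- nrow(frame_b); nc <- ncol(frame_b)
  for (j in seq_along(xs)) {
    for (i in seq_along(ys)) {
      y0 <- ys[i]; x0 <- xs[j]
      off_x <- off_y <- 0L
      if (!is.null(predictor)) {
        off_x <- as.integer(round(predictor$u[i, j]))
        off_y <- as.integer(round(predictor$v[i, j]))
        off_y <- min(max(off_y, 1L - y0), nr - window + 1L - y0)
        off_x <- min(max(off_x, 1L - x0), nc - window + 1L - x0)
      }
      wa <- frame_a[y0:(y0 + window - 1L), x0:(x0 + window - 1L)]
      wb <- frame_b[(y0 + off_y):(y0 + off_y + window - 1L),
                    (x0 + off_x):(x0 + off_x + window - 1L)]
      res <- cross_correlate_window(wa, wb)
      u[i, j] <- res$dx + off_x
      v[i, j] <- res$dy + off_y
      valid[i, j] <- res$valid
    }
  }
  structure(
    list(gx = xs + window / 2 - 0.5, gy = ys + window / 2 - 0.5,
         u = u, v = v, valid = valid, window = window, spacing = spacing),
    class = "piv_field_raw"
  )
}

# Median over the 8-neighbourhood of each entry, NA-tolerant.
neighbour_median_ <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      ii <- max(1, i - 1):min(nr, i + 1)
      jj <- max(1, j - 1):min(nc, j + 1)
      vals <- m[ii, jj]
      vals <- vals[!(ii[row(vals)] == i & jj[col(vals)] == j)]
      out[i, j] <- median(vals, na.rm = TRUE)
    }
  }
  out
}

#' Validate a raw PIV field by the normalized median test
#'
#' Each component is compared against its 8-neighbourhood median; the
#' residual, normalized by the median neighbour residual plus a noise floor
#' `eps`, flags a vector when it exceeds `threshold` on either axis. Flagged
#' and correlation-invalid vectors are replaced by the neighbourhood median
#' and keep `valid = FALSE`.
#'
#' @param field A `piv_field_raw` from [piv_pass()].
#' @param threshold Normalized-median-test statistic cutoff.
#' @param eps Noise floor, px.
#' @param min_valid_fraction Below this valid fraction the field is marked
#'   low quality (`attr(field, "low_quality")`) with a warning.
#' @return The field with outliers replaced; `valid` marks untouched vectors.
#' @export
validate_vectors <- function(field, threshold = 2.0, eps = 0.1,
                             min_valid_fraction = 0.8) {
  stopifnot(inherits(field, "piv_field_raw"))
  u <- field$u; v <- field$v
  u[!field$valid] <- NA; v[!field$valid] <- NA
  med_u <- neighbour_median_(u); med_v <- neighbour_median_(v)
  res_u <- abs(u - med_u); res_v <- abs(v - med_v)
  rm_u <- neighbour_median_(res_u); rm_v <- neighbour_median_(res_v)
  stat_u <- res_u / (rm_u + eps)
  stat_v <- res_v / (rm_v + eps)
  bad <- !field$valid | is.na(stat_u) | is.na(stat_v) |
    stat_u > threshold | stat_v > threshold
  u_fix <- field$u; v_fix <- field$v
  u_fix[bad] <- med_u[bad]
  v_fix[bad] <- med_v[bad]
  # no informative neighbours at all: fall back to the global median
  u_fix[is.na(u_fix)] <- median(field$u[field$valid], na.rm = TRUE)
  v_fix[is.na(v_fix)] <- median(field$v[field$valid], na.rm = TRUE)
  u_fix[is.na(u_fix)] <- 0
  v_fix[is.na(v_fix)] <- 0
  field$u <- u_fix
  field$v <- v_fix
  field$valid <- !bad
  frac_valid <- mean(field$valid)
  attr(field, "replaced_fraction") <- mean(bad)
  attr(field, "low_quality") <- frac_valid < min_valid_fraction
  if (attr(field, "low_quality")) {
    warn(sprintf("Low-quality PIV field: only %.0f%% of vectors valid.",
                 100 * frac_valid))
  }
  field
}

# Bilinear interpolation of a gridded matrix at arbitrary points, constant
# extrapolation beyond the grid hull.
interp_bilinear_ <- function(gx, gy, z, x, y) {
  if (length(gx) == 1L) { gx <- c(gx, gx + 1); z <- cbind(z, z) }
  if (length(gy) == 1L) { gy <- c(gy, gy + 1); z <- rbind(z, z) }
  fx <- findInterval(x, gx, all.inside = TRUE)
  fy <- findInterval(y, gy, all.inside = TRUE)
  x1 <- gx[fx]; x2 <- gx[fx + 1L]
  y1 <- gy[fy]; y2 <- gy[fy + 1L]
  tx <- pmin(pmax((x - x1) / (x2 - x1), 0), 1)
  ty <- pmin(pmax((y - y1) / (y2 - y1), 0), 1)
  z11 <- z[cbind(fy, fx)];     z12 <- z[cbind(fy, fx + 1L)]
  z21 <- z[cbind(fy + 1L, fx)]; z22 <- z[cbind(fy + 1L, fx + 1L)]
  (1 - ty) * ((1 - tx) * z11 + tx * z12) + ty * ((1 - tx) * z21 + tx * z22)
}

#' Construct a velocity-field sequence from a data frame
#'
#' Builds the tidy `velocity_fields` container used throughout the dynamics
#' module from per-vector rows, e.g. when importing fields produced by
#' another PIV tool. Rows must form a complete regular grid per time point.
#'
#' @param data Data frame with columns `t_min`, `grid_x_px`, `grid_y_px`,
#'   `u_um_min`, `v_um_min` and optionally `valid` (default all TRUE).
#' @param pixel_size Calibration, um/px.
#' @param frame_interval Time between frames, min.
#' @param window Interrogation window the grid derives from, px.
#' @param overlap Overlap fraction.
#' @param low_quality_pairs Indices of low-quality frame pairs, if known.
#' @return A `velocity_fields` tibble.
#' @export
velocity_fields <- function(data, pixel_size, frame_interval,
                            window = 32L, overlap = 0.5,
                            low_quality_pairs = integer(0)) {
  need <- c("t_min", "grid_x_px", "grid_y_px", "u_um_min", "v_um_min")
  if (!all(need %in% names(data))) {
    abort(paste("`data` needs columns:", paste(need, collapse = ", ")))
  }
  data <- as_tibble(data)
  if (!"valid" %in% names(data)) data$valid <- TRUE
  m <- sum(data$t_min == data$t_min[1])
  structure(
    data,
    class = c("velocity_fields", class(data)),
    pixel_size = pixel_size, frame_interval = frame_interval,
    window = as.integer(window), overlap = overlap,
    grid_spacing_px = window * (1 - overlap),
    M = m, low_quality_pairs = low_quality_pairs
  )
}

#' Multi-pass PIV over an image stack
#'
#' For every consecutive frame pair, runs the configured interrogation passes
#' (validated between passes, with the previous pass bilinearly interpolated
#' onto the next grid as predictor) and calibrates displacements from
#' px/frame to um/min with `pixel_size / frame_interval`.
#'
#' @param stack An [image_stack()].
#' @param cfg A [piv_config()].
#' @return A `velocity_fields` tibble with one row per grid vector per frame
#'   pair: `t_min` (time of the pair's first frame), `grid_x_px`,
#'   `grid_y_px`, `u_um_min`, `v_um_min`, `valid`. Attributes record the
#'   calibration, final grid geometry, the vector count `M` per field, and
#'   which pairs were low quality.
#' @export
multipass_piv <- function(stack, cfg = piv_config()) {
  stopifnot(inherits(stack, "image_stack"), inherits(cfg, "piv_config"))
  n_pairs <- length(stack$frames) - 1L
  out <- vector("list", n_pairs)
  low_quality <- logical(n_pairs)
  scale <- stack$pixel_size / stack$frame_interval
  frames <- stack$frames
  if (cfg$highpass_sigma > 0) {
    frames <- lapply(frames, function(f) {
      f - gaussian_blur_(f, cfg$highpass_sigma)
    })
  }
  for (p in seq_len(n_pairs)) {
    a <- frames[[p]]
    b <- frames[[p + 1L]]
    field <- NULL
    for (w in cfg$window_sizes) {
      predictor <- NULL
      if (!is.null(field)) {
        spacing <- max(1L, as.integer(round(w * (1 - cfg$overlap_fraction))))
        ys <- tile_starts_(nrow(a), w, spacing) + w / 2 - 0.5
        xs <- tile_starts_(ncol(a), w, spacing) + w / 2 - 0.5
        pts <- expand.grid(y = ys, x = xs)
        predictor <- list(
          u = matrix(interp_bilinear_(field$gx, field$gy, field$u,
                                      pts$x, pts$y), length(ys)),
          v = matrix(interp_bilinear_(field$gx, field$gy, field$v,
                                      pts$x, pts$y), length(ys))
        )
      }
      field <- piv_pass(a, b, w, cfg$overlap_fraction, predictor)
      field <- validate_vectors(field, cfg$outlier_threshold, cfg$eps,
                                cfg$min_valid_fraction)
    }
    low_quality[p] <- isTRUE(attr(field, "low_quality"))
    grid <- expand.grid(grid_y_px = field$gy, grid_x_px = field$gx)
    out[[p]] <- tibble(
      t_min = (p - 1) * stack$frame_interval,
      grid_x_px = grid$grid_x_px,
      grid_y_px = grid$grid_y_px,
      u_um_min = as.vector(field$u) * scale,
      v_um_min = as.vector(field$v) * scale,
      valid = as.vector(field$valid)
    )
  }
  velocity_fields(bind_rows(out), stack$pixel_size, stack$frame_interval,
                  window = cfg$window_sizes[length(cfg$window_sizes)],
                  overlap = cfg$overlap_fraction,
                  low_quality_pairs = which(low_quality))
}

#' Summarise a velocity-field sequence
#'
#' @param x A `velocity_fields` tibble from [multipass_piv()].
#' @param ... Unused.
#' @return One-row tibble: number of fields, vectors per field (`M`), grid
#'   spacing, mean speed, RMS speed, valid fraction.
#' @export
glance.velocity_fields <- function(x, ...) {
  sp <- sqrt(x$u_um_min^2 + x$v_um_min^2)
  tibble(
    n_fields = length(unique(x$t_min)),
    m_vectors = attr(x, "M"),
    grid_spacing_px = attr(x, "grid_spacing_px"),
    mean_speed_um_min = mean(sp[x$valid]),
    rms_speed_um_min = sqrt(mean(sp[x$valid]^2)),
    valid_fraction = mean(x$valid)
  )
}

#' Speed-map plot of one velocity field
#'
#' @param object A `velocity_fields` tibble.
#' @param t_min Which field (time of first frame of the pair); default first.
#' @param ... Unused.
#' @return A ggplot: speed raster with velocity glyphs.
#' @export
autoplot.velocity_fields <- function(object, t_min = NULL, ...) {
  t_min <- t_min %||% object$t_min[1]
  df <- dplyr::filter(as_tibble(object), .data$t_min == !!t_min)
  df$speed <- sqrt(df$u_um_min^2 + df$v_um_min^2)
  sc <- attr(object, "grid_spacing_px") / max(df$speed, 1e-12) * 0.8
  ggplot2::ggplot(df, ggplot2::aes(.data$grid_x_px, .data$grid_y_px)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$speed)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$grid_x_px + sc * .data$u_um_min,
                   yend = .data$grid_y_px + sc * .data$v_um_min),
      linewidth = 0.3, colour = "white"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "speed\n(um/min)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("Speed map, t = %g min", t_min))
}
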