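#' Read and write calibrated image stacks as multi-page TIFF
#'
#' Intensities are stored as 16-bit (or 8-bit) unsigned samples; calibration
#' is not carried by the TIFF and must be supplied on read.
#'
#' @param stack An [image_stack()]; intensities on the `0 .. 2^bit_depth - 1`
#'   scale.
#' @param path Output TIFF path.
#' @param bit_depth 8 or 16.
#' @return `write_stack_tiff()`: the path, invisibly.
#' @export
write_stack_tiff <- function(stack, path, bit_depth = 16) {
  stopifnot(inherits(stack, "image_stack"))
  qmax <- 2^bit_depth - 1
  frames01 <- lapply(stack$frames, function(f) pmin(pmax(f / qmax, 0), 1))
  tiff::writeTIFF(frames01, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' @param frame_interval,pixel_size Calibration for the stack being read.
#' @param source_id Provenance tag.
#' @rdname write_stack_tiff
#' @return `read_stack_tiff()`: an [image_stack()] with integer intensities.
#' @export
read_stack_tiff <- function(path, frame_interval, pixel_size,
                            source_id = basename(path)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    matrix(as.numeric(p), nrow(p))
  })
  image_stack(frames, frame_interval, pixel_size, source_id)
}

#' Read and write integer label masks as single-page 16-bit TIFF
#'
#' @param mask A [label_mask()] (labels must fit in 16 bits).
#' @param path TIFF path.
#' @return `write_mask_tiff()`: the path, invisibly;
#'   `read_mask_tiff()`: a [label_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535) abort("Labels exceed 16-bit range.")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @param pixel_size Calibration, um/px.
#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path, pixel_size) {
  p <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(p)) == 3) p <- p[, , 1]
  label_mask(matrix(as.integer(round(p)), nrow(p)), pixel_size)
}

#' Write simulator ground truth alongside its configuration
#'
#' Positions go to CSV (`frame, cell_id, x_um, y_um, x_unwrapped_um,
#' y_unwrapped_um`), the configuration to YAML, next to each other.
#'
#' @param traj A `monolayer_trajectory`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_ground_truth <- function(traj, dir, prefix = "ground_truth") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  yml <- file.path(dir, paste0(prefix, "_config.yaml"))
  utils::write.csv(tidy(traj), csv, row.names = FALSE)
  yaml::write_yaml(unclass(traj$config), yml)
  invisible(c(positions = csv, config = yml))
}

#' Write a velocity-field sequence as tidy CSV
#'
#' @param fields A `velocity_fields` tibble.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_fields_csv <- function(fields, path) {
  utils::write.csv(as_tibble(fields), path, row.names = FALSE)
  invisible(path)
}

#' Write an RGB array as PNG
#'
#' @param rgb `[h, w, 3]` array in `[0, 1]` (e.g. from
#'   [colorize_aspect_ratio()]).
#' @param path PNG path.
#' @return The path, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}
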