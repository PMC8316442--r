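test_that("perimeter estimators match closed forms where naive counting fails", {
  disk <- raster_disk(150)
  # naive boundary-pixel counting would give ~8r per quadrant-symmetric disk
  expect_equal(crofton_perimeter(disk), 2 * pi * 150, tolerance = 0.01)
  expect_equal(contour_perimeter(disk), 2 * pi * 150, tolerance = 0.01)
  sq <- raster_square(300)
  expect_equal(contour_perimeter(sq), 1200, tolerance = 0.01)
  hx <- raster_hexagon(150)
  expect_equal(contour_perimeter(hx), 900, tolerance = 0.01)
})

test_that("shape index hits the square, hexagon and disk closed forms", {
  ps <- 1
  tab_sq <- shape_metrics(label_mask(raster_square(300), ps),
                          exclude_border = FALSE)
  expect_equal(tab_sq$q, 4.0, tolerance = 0.01)
  expect_equal(tab_sq$area_um2, 300^2)

  q_hex <- 6 / sqrt(3 * sqrt(3) / 2)  # 3.7224
  tab_hex <- shape_metrics(label_mask(raster_hexagon(150), ps),
                           exclude_border = FALSE)
  expect_equal(tab_hex$q, q_hex, tolerance = 0.01)

  tab_disk <- shape_metrics(label_mask(raster_disk(150), ps),
                            exclude_border = FALSE)
  expect_equal(tab_disk$q, 2 * sqrt(pi), tolerance = 0.01)
  expect_equal(tab_disk$aspect_ratio, 1.0, tolerance = 0.02)
})

test_that("q is scale invariant under 2x upsampling", {
  for (shape in list(raster_disk(150), raster_hexagon(150))) {
    q1 <- shape_metrics(label_mask(shape, 1), exclude_border = FALSE)$q
    up <- shape[rep(seq_len(nrow(shape)), each = 2),
                rep(seq_len(ncol(shape)), each = 2)]
    q2 <- shape_metrics(label_mask(up, 1), exclude_border = FALSE)$q
    expect_equal(q2, q1, tolerance = 0.005)
  }
})

test_that("every reported q respects the isoperimetric bound", {
  cfg <- sim_config(n_cells = 120, v0 = 1.5, n_frames = 5, rng_seed = 8)
  traj <- simulate_monolayer(cfg)
  rc <- render_config(image_shape = 256, pixel_size = 0.9)
  tab <- shape_metrics(voronoi_masks(traj, 5, rc))
  expect_true(all(tab$q >= 2 * sqrt(pi) - 0.02))
  expect_true(all(tab$aspect_ratio >= 1))
  expect_true(all(tab$area_um2 > 0))
})

test_that("tiny labels are excluded with a warning; empty masks error", {
  lab <- matrix(0L, 40, 40)
  lab[2:25, 2:25] <- 1L
  lab[30:31, 30:32] <- 2L  # 6 px, below the 9 px floor
  expect_warning(tab <- shape_metrics(label_mask(lab, 1),
                                      exclude_border = FALSE), "9 px")
  expect_equal(tab$cell_id, 1L)
  expect_error(shape_metrics(label_mask(matrix(0L, 10, 10), 1)), "labels")
})

test_that("jamming calls follow the p0 threshold with ties unjammed", {
  sq <- tibble::tibble(q = rep(4.0, 20))
  expect_equal(classify_jamming(sq)$state, "unjammed")
  hex <- tibble::tibble(q = rep(3.722, 20))
  call <- classify_jamming(hex)
  expect_equal(call$state, "jammed")
  expect_equal(call$threshold, 3.813)
  tie <- tibble::tibble(q = rep(3.813, 5))
  expect_equal(classify_jamming(tie)$state, "unjammed")
  expect_error(classify_jamming(tibble::tibble(q = numeric(0))), "Empty")
})

test_that("pooled and per-field aggregations are both available", {
  tab <- tibble::tibble(q = c(3.5, 3.5, 3.5, 4.4),
                        field = c("a", "a", "a", "b"))
  pooled <- classify_jamming(tab)
  by_field <- classify_jamming(tab, by = "field")
  expect_equal(pooled$mean_q, mean(tab$q))
  expect_equal(by_field$mean_q, mean(c(3.5, 4.4)))
  expect_equal(pooled$state, "jammed")
  expect_equal(by_field$state, "unjammed")
})

test_that("watershed segmentation recovers the Voronoi partition", {
  # membrane rendered analytically as a bright ridge along the Voronoi
  # bisectors (intensity falls off with distance to the nearest cell-cell
  # interface), at typical high-magnification stain resolution
  cfg <- sim_config(n_cells = 50, v0 = 0.5, n_frames = 3, rng_seed = 14)
  rc <- render_config(image_shape = 320, pixel_size = 0.3)
  traj <- simulate_monolayer(cfg)
  truth <- voronoi_masks(traj, 3, rc)
  lab <- truth$labels
  centers <- traj$positions[3, , , drop = TRUE]
  origin <- (cfg$box_size - rc$image_shape * rc$pixel_size) / 2
  coord <- origin + (seq_len(320) - 0.5) * rc$pixel_size
  px <- rep(coord, each = 320); py <- rep(coord, times = 320)
  dx <- abs(outer(px, centers[, 1], "-"))
  dx <- pmin(dx, cfg$box_size - dx)
  dy <- abs(outer(py, centers[, 2], "-"))
  dy <- pmin(dy, cfg$box_size - dy)
  nearest2 <- apply(sqrt(dx^2 + dy^2), 1, function(r) sort(r)[1:2])
  bisector_dist <- (nearest2[2, ] - nearest2[1, ]) / 2  # um to interface
  membrane <- matrix(0.1 + 0.9 * exp(-(bisector_dist / 0.3)^2 / 2), 320)

  sx <- (centers[, 1] - origin) / rc$pixel_size + 0.5
  sy <- (centers[, 2] - origin) / rc$pixel_size + 0.5
  keep <- which(sx >= 2 & sx <= 319 & sy >= 2 & sy <= 319)
  got <- segment_membranes(membrane,
                           seeds = data.frame(x = sx[keep], y = sy[keep]),
                           pixel_size = 0.3, smooth_sigma = 1)
  # majority-overlap label matching, scored over the territory of seeded
  # cells (cells whose centre lies outside the window cannot be seeded)
  seeded_ids <- lab[cbind(round(sy[keep]), round(sx[keep]))]
  eval_px <- lab %in% seeded_ids
  agree <- 0
  for (id in setdiff(unique(as.vector(got$labels)), 0L)) {
    agree <- agree + max(tabulate(lab[got$labels == id & eval_px]))
  }
  expect_gt(agree / sum(eval_px), 0.95)
})

test_that("blank images and unseedable images raise clear errors", {
  expect_error(segment_membranes(matrix(0.5, 50, 50)), "[Bb]lank")
  expect_error(segment_membranes(matrix(runif(100), 10),
                                 seeds = data.frame(x = numeric(0),
                                                    y = numeric(0))),
               "seed")
})

test_that("a closed bright outline separates inside from outside", {
  img <- matrix(0.05, 120, 120)
  img[40:80, c(40, 80)] <- 1
  img[c(40, 80), 40:80] <- 1
  img <- img + matrix(runif(120 * 120, 0, 0.01), 120)
  mask <- segment_membranes(img, smooth_sigma = 1.5, h = 0.05)
  expect_equal(length(setdiff(unique(as.vector(mask$labels)), 0L)), 2L)
  inner_label <- mask$labels[60, 60]
  inner_area <- sum(mask$labels == inner_label)
  expect_equal(inner_area, 41^2, tolerance = 0.15)
})

test_that("aspect-ratio colouring is deterministic with clipped endpoints", {
  lab <- matrix(0L, 20, 40)
  lab[3:18, 3:18] <- 1L
  lab[3:18, 23:38] <- 2L
  mask <- label_mask(lab, 1)
  tab <- tibble::tibble(cell_id = c(1L, 2L), aspect_ratio = c(1, 4))
  rgb <- colorize_aspect_ratio(mask, tab)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255
  expect_equal(as.vector(rgb[10, 10, ]), unname(pal[, 1]))
  expect_equal(as.vector(rgb[10, 30, ]), unname(pal[, 256]))
  expect_equal(as.vector(rgb[1, 1, ]), c(0, 0, 0))
  expect_identical(rgb, colorize_aspect_ratio(mask, tab))
  # uniform AR -> one colour over all cells
  tab1 <- tibble::tibble(cell_id = c(1L, 2L), aspect_ratio = c(1, 1))
  rgb1 <- colorize_aspect_ratio(mask, tab1)
  expect_equal(rgb1[10, 10, ], rgb1[10, 30, ])
})

test_that("mean shape index rises with motility across a v0 sweep", {
  rc <- render_config(image_shape = 256)
  qs <- vapply(c(0.2, 1.0, 2.5), function(v0) {
    dt <- 5 / ceiling(5 / min(0.5, 11 / (10 * v0)))
    cfg <- sim_config(n_cells = 135, v0 = v0, dt = dt, n_frames = 9,
                      rng_seed = 17)
    traj <- simulate_monolayer(cfg)
    mean(shape_metrics(voronoi_masks(traj, 9, rc))$q)
  }, numeric(1))
  expect_true(all(diff(qs) >= 0))
})
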