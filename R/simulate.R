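#' Simulation configuration for the synthetic monolayer
#'
#' Parameters of the active-Brownian-particle (ABP) monolayer model: `n_cells`
#' self-propelled soft disks in a periodic square box. Each cell moves at
#' constant speed `v0` along a heading that diffuses rotationally at rate
#' `d_r`, and overlapping cells (centre distance below `2 * cell_radius`)
#' repel through a harmonic (linear-in-overlap) force of stiffness
#' `repulsion_stiffness`. Low `v0` produces caged, jammed-like dynamics;
#' high `v0` produces persistent collective flow.
#'
#' Defaults emulate a confluent 40x field of airway epithelium: 300 cells of
#' radius 11 um (about 380 um^2 each) at packing fraction ~0.9, imaged every
#' 5 min for 200 min (41 frames).
#'
#' @param n_cells Number of cells (>= 1).
#' @param box_size Side of the periodic square box in um. Default `NULL`
#'   chooses the box so that the disk packing fraction is 0.9.
#' @param v0 Self-propulsion speed, um/min.
#' @param d_r Rotational diffusion rate, 1/min.
#' @param cell_radius Cell radius, um.
#' @param repulsion_stiffness Harmonic repulsion stiffness; the repulsive
#'   drift speed of a pair overlapping by `delta` um is
#'   `repulsion_stiffness * delta` um/min.
#' @param dt Integration time step, min. Must divide `frame_interval` and
#'   satisfy the stability guard `dt <= cell_radius / (10 * v0)`.
#' @param n_frames Number of recorded frames (the first is the initial state).
#' @param frame_interval Time between recorded frames, min.
#' @param equil_time Equilibration run, min: the same dynamics are
#'   integrated for this long before the first recorded frame, so that the
#'   initial lattice's overlap-relaxation transient does not contaminate the
#'   recorded statistics.
#' @param rng_seed Integer seed; fixes trajectories bit-exactly.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 20, v0 = 0.2, n_frames = 5)
#' traj <- simulate_monolayer(cfg)
sim_config <- function(n_cells = 300, box_size = NULL, v0 = 0.3, d_r = 0.1,
                       cell_radius = 11, repulsion_stiffness = 0.05,
                       dt = 0.5, n_frames = 41, frame_interval = 5,
                       equil_time = 30, rng_seed = 1L) {
  if (is.null(box_size)) {
    box_size <- sqrt(n_cells * pi * cell_radius^2 / 0.9)
  }
  cfg <- list(
    n_cells = as.integer(n_cells), box_size = box_size, v0 = v0, d_r = d_r,
    cell_radius = cell_radius, repulsion_stiffness = repulsion_stiffness,
    dt = dt, n_frames = as.integer(n_frames),
    frame_interval = frame_interval, equil_time = equil_time,
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$n_cells < 1) abort("`n_cells` must be >= 1.")
  if (cfg$box_size <= 2 * cfg$cell_radius) {
    abort("`box_size` must exceed twice `cell_radius`.")
  }
  if (cfg$dt <= 0) abort("`dt` must be positive.")
  steps <- cfg$frame_interval / cfg$dt
  if (abs(steps - round(steps)) > 1e-9) {
    abort("`frame_interval` must be an integer multiple of `dt`.")
  }
  if (cfg$v0 < 0 || cfg$d_r < 0) abort("`v0` and `d_r` must be non-negative.")
  if (cfg$equil_time < 0) abort("`equil_time` must be non-negative.")
  if (cfg$v0 > 0 && cfg$dt > cfg$cell_radius / (10 * cfg$v0)) {
    abort(sprintf(
      "Unstable step: require dt <= cell_radius / (10 * v0) = %.3g min.",
      cfg$cell_radius / (10 * cfg$v0)
    ))
  }
  phi <- cfg$n_cells * pi * cfg$cell_radius^2 / cfg$box_size^2
  if (phi > 1.1) {
    abort(sprintf(
      "Packing fraction %.2f > 1.1: initial placement impossible at this density.",
      phi
    ))
  }
  structure(cfg, class = "sim_config")
}

# Run `code` under a fixed seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Jittered hexagonal lattice filling the periodic box with exactly n points.
hex_lattice_ <- function(n, box, jitter_frac = 0.15) {
  ncol <- ceiling(sqrt(n * 2 / sqrt(3)))
  nrow <- ceiling(n / ncol)
  a <- box / ncol          # horizontal spacing
  b <- box / nrow          # vertical spacing (compressed to fit the box)
  row <- rep(seq_len(nrow) - 1L, each = ncol)
  col <- rep(seq_len(ncol) - 1L, times = nrow)
  x <- (col + 0.25 + 0.5 * (row %% 2)) * a
  y <- (row + 0.5) * b
  keep <- sort(sample.int(length(x), n))
  x <- x[keep] + rnorm(n, sd = jitter_frac * a)
  y <- y[keep] + rnorm(n, sd = jitter_frac * a)
  cbind(x %% box, y %% box)
}

# Pairwise harmonic repulsion displacements (um/min), minimum-image convention.
repulsion_drift_ <- function(pos, box, radius, k) {
  n <- nrow(pos)
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dx <- dx - box * round(dx / box)
  dy <- dy - box * round(dy / box)
  d2 <- dx * dx + dy * dy
  cut2 <- (2 * radius)^2
  touch <- d2 < cut2 & d2 > 0
  if (!any(touch)) return(matrix(0, n, 2))
  d <- sqrt(d2)
  f <- matrix(0, n, n)
  f[touch] <- k * (2 * radius - d[touch]) / d[touch]
  cbind(rowSums(f * dx), rowSums(f * dy))
}

#' Simulate an active monolayer
#'
#' Integrates the ABP model of [sim_config()] by Euler-Maruyama stepping:
#' per step each cell advances `v0 * dt` along its heading plus the harmonic
#' repulsion drift, and headings pick up Gaussian increments of variance
#' `2 * d_r * dt`. Positions are tracked both periodic-wrapped (for rendering)
#' and unwrapped (for MSD ground truth). Identical seeds reproduce
#' trajectories bit-exactly.
#'
#' @param config A [sim_config()].
#' @return A `monolayer_trajectory`: list with `positions` and
#'   `unwrapped_positions` (arrays `[n_frames, n_cells, 2]`, um), `headings`
#'   (`[n_frames, n_cells]`, rad), `times` (min) and `config`. Use [tidy()]
#'   for a long tibble.
#' @export
simulate_monolayer <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cells
  box <- config$box_size
  steps_per_frame <- as.integer(round(config$frame_interval / config$dt))
  n_steps <- (config$n_frames - 1L) * steps_per_frame

  n_equil <- as.integer(round(config$equil_time / config$dt))

  with_seed_(config$rng_seed, {
    pos <- hex_lattice_(n, box)
    theta <- runif(n, 0, 2 * pi)
    sig0 <- sqrt(2 * config$d_r * config$dt)
    for (s in seq_len(n_equil)) {
      drift <- config$v0 * cbind(cos(theta), sin(theta))
      if (config$repulsion_stiffness > 0) {
        drift <- drift +
          repulsion_drift_(pos, box, config$cell_radius,
                           config$repulsion_stiffness)
      }
      pos <- (pos + drift * config$dt) %% box
      if (config$d_r > 0) theta <- theta + sig0 * rnorm(n)
    }
    unwrapped <- pos

    wrapped_out <- array(NA_real_, c(config$n_frames, n, 2))
    unwrapped_out <- array(NA_real_, c(config$n_frames, n, 2))
    headings_out <- matrix(NA_real_, config$n_frames, n)
    wrapped_out[1, , ] <- pos
    unwrapped_out[1, , ] <- unwrapped
    headings_out[1, ] <- theta

    sig <- sqrt(2 * config$d_r * config$dt)
    for (s in seq_len(n_steps)) {
      drift <- config$v0 * cbind(cos(theta), sin(theta))
      if (config$repulsion_stiffness > 0) {
        drift <- drift +
          repulsion_drift_(pos, box, config$cell_radius,
                           config$repulsion_stiffness)
      }
      step <- drift * config$dt
      unwrapped <- unwrapped + step
      pos <- (pos + step) %% box
      if (config$d_r > 0) theta <- theta + sig * rnorm(n)
      if (s %% steps_per_frame == 0L) {
        fr <- s %/% steps_per_frame + 1L
        wrapped_out[fr, , ] <- pos
        unwrapped_out[fr, , ] <- unwrapped
        headings_out[fr, ] <- theta
      }
    }

    structure(
      list(
        positions = wrapped_out,
        unwrapped_positions = unwrapped_out,
        headings = headings_out,
        times = (seq_len(config$n_frames) - 1) * config$frame_interval,
        config = config
      ),
      class = "monolayer_trajectory"
    )
  })
}

#' @export
print.monolayer_trajectory <- function(x, ...) {
  cat(sprintf(
    "<monolayer_trajectory> %d cells, %d frames every %g min, box %.1f um, v0 = %g um/min\n",
    x$config$n_cells, x$config$n_frames, x$config$frame_interval,
    x$config$box_size, x$config$v0
  ))
  invisible(x)
}

#' Tidy a simulated trajectory into a long tibble
#'
#' @param x A `monolayer_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per cell per frame: `frame`, `time_min`,
#'   `cell_id`, wrapped `x_um`/`y_um` and `x_unwrapped_um`/`y_unwrapped_um`.
#' @export
tidy.monolayer_trajectory <- function(x, ...) {
  nf <- x$config$n_frames
  nc <- x$config$n_cells
  tibble(
    frame = rep(seq_len(nf), times = nc),
    time_min = rep(x$times, times = nc),
    cell_id = rep(seq_len(nc), each = nf),
    x_um = as.vector(x$positions[, , 1]),
    y_um = as.vector(x$positions[, , 2]),
    x_unwrapped_um = as.vector(x$unwrapped_positions[, , 1]),
    y_unwrapped_um = as.vector(x$unwrapped_positions[, , 2])
  )
}

#' Uniform-drift trajectory fixture
#'
#' A degenerate monolayer "simulation" in which every cell translates with
#' one constant velocity; displacement, MSD and V_RMS are then known in
#' closed form, which makes this the fixture of record for end-to-end
#' pipeline recovery checks.
#'
#' @param config A [sim_config()] (its `v0`/`d_r` are ignored).
#' @param velocity Length-2 numeric, (vx, vy) in um/min.
#' @return A `monolayer_trajectory`.
#' @export
drift_trajectory <- function(config, velocity) {
  stopifnot(inherits(config, "sim_config"), length(velocity) == 2)
  n <- config$n_cells
  box <- config$box_size
  pos0 <- with_seed_(config$rng_seed, hex_lattice_(n, box))
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  unwrapped <- array(NA_real_, c(config$n_frames, n, 2))
  for (fr in seq_len(config$n_frames)) {
    unwrapped[fr, , 1] <- pos0[, 1] + velocity[1] * times[fr]
    unwrapped[fr, , 2] <- pos0[, 2] + velocity[2] * times[fr]
  }
  structure(
    list(positions = unwrapped %% box, unwrapped_positions = unwrapped,
         headings = matrix(atan2(velocity[2], velocity[1]),
                           config$n_frames, n),
         times = times, config = config),
    class = "monolayer_trajectory"
  )
}

#' Ensemble mean-squared displacement of simulator ground truth
#'
#' MSD over unwrapped positions, averaged over cells and sliding time
#' origins; the reference against which the image-based pipeline is checked.
#'
#' @param traj A `monolayer_trajectory`.
#' @param max_lag_frames Largest lag, in frames. Default: all available.
#' @return Tibble with `lag_min`, `msd_um2`, `n_pairs`.
#' @export
ground_truth_msd <- function(traj, max_lag_frames = NULL) {
  nf <- traj$config$n_frames
  max_lag_frames <- max_lag_frames %||% (nf - 1L)
  u <- traj$unwrapped_positions
  lags <- seq_len(min(max_lag_frames, nf - 1L))
  msd <- vapply(lags, function(l) {
    d <- u[(l + 1):nf, , , drop = FALSE] - u[1:(nf - l), , , drop = FALSE]
    mean(d[, , 1]^2 + d[, , 2]^2)
  }, numeric(1))
  tibble(
    lag_min = lags * traj$config$frame_interval,
    msd_um2 = msd,
    n_pairs = (nf - lags) * traj$config$n_cells
  )
}

#' Window-coherent ground-truth velocity fields
#'
#' Builds the velocity-field sequence an ideal correlation velocimeter would
#' measure: for every frame pair and every interrogation-window position,
#' the mean displacement of the cells inside that window, calibrated to
#' um/min. Windowed velocimetry estimates exactly this spatially coherent
#' component; motion that is incoherent below the window scale (e.g. caged
#' rattling of cells with independent headings) is invisible to it. Use this
#' as the oracle for PIV-chain recovery on fixtures with sub-window motion.
#'
#' @param traj A `monolayer_trajectory`.
#' @param rc The [render_config()] used for imaging (window geometry and
#'   calibration are taken from it).
#' @param window Interrogation window, px (default 32, the second PIV pass).
#' @param overlap Overlap fraction (default 0.5).
#' @return A `velocity_fields` tibble, as from [multipass_piv()]; windows
#'   containing no cell centre are marked invalid with zero velocity.
#' @export
ground_truth_fields <- function(traj, rc, window = 32L, overlap = 0.5) {
  stopifnot(inherits(traj, "monolayer_trajectory"),
            inherits(rc, "render_config"))
  cfg <- traj$config
  sz <- rc$image_shape
  spacing <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- tile_starts_(sz, window, spacing)
  centers <- starts + window / 2 - 0.5
  origin <- window_origin_(cfg$box_size, rc)
  half_um <- window / 2 * rc$pixel_size
  ctr_um <- origin + centers * rc$pixel_size

  out <- vector("list", cfg$n_frames - 1L)
  for (p in seq_len(cfg$n_frames - 1L)) {
    pos <- traj$positions[p, , , drop = FALSE]
    dim(pos) <- dim(traj$positions)[2:3]
    disp <- traj$unwrapped_positions[p + 1L, , ] -
      traj$unwrapped_positions[p, , ]
    dim(disp) <- dim(pos)
    grid <- expand.grid(cy = ctr_um, cx = ctr_um)
    u <- v <- numeric(nrow(grid))
    valid <- logical(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      inside <- abs(pos[, 1] - grid$cx[g]) <= half_um &
        abs(pos[, 2] - grid$cy[g]) <= half_um
      if (any(inside)) {
        u[g] <- mean(disp[inside, 1]) / cfg$frame_interval
        v[g] <- mean(disp[inside, 2]) / cfg$frame_interval
        valid[g] <- TRUE
      }
    }
    out[[p]] <- tibble(
      t_min = (p - 1) * cfg$frame_interval,
      grid_x_px = (grid$cx - origin) / rc$pixel_size,
      grid_y_px = (grid$cy - origin) / rc$pixel_size,
      u_um_min = u, v_um_min = v, valid = valid
    )
  }
  velocity_fields(bind_rows(out), rc$pixel_size, cfg$frame_interval,
                  window = window, overlap = overlap)
}

#' Closed-form MSD of a free active Brownian particle
#'
#' For a non-interacting ABP in two dimensions,
#' `MSD(t) = (2 v0^2 / d_r^2) (d_r t - 1 + exp(-d_r t))`; the independent
#' oracle for the simulator.
#'
#' @param t Lag times, min.
#' @param v0 Self-propulsion speed, um/min.
#' @param d_r Rotational diffusion rate, 1/min.
#' @return MSD values, um^2.
#' @export
abp_msd_theory <- function(t, v0, d_r) {
  if (d_r == 0) return((v0 * t)^2)
  (2 * v0^2 / d_r^2) * (d_r * t - 1 + exp(-d_r * t))
}
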