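#' Integrate grid-seeded trajectories through a velocity-field sequence
#'
#' Seeds virtual tracers on a regular grid at `t = 0` and advances each one
#' through the field sequence by explicit Euler steps: the velocity at the
#' tracer position is bilinearly interpolated from the current field and the
#' tracer moves by `v * frame_interval`. Tracers that leave the gridded
#' region are frozen in place, flagged inactive, and excluded from later
#' statistics.
#'
#' @param fields A `velocity_fields` tibble from [multipass_piv()].
#' @param seed_spacing Tracer seeding pitch in um; default one velocity grid
#'   spacing (one tracer per independent velocity estimate).
#' @return A `trajectory_set`: positions `r` (`[n_times, n_tracks, 2]`, um),
#'   `times` (min), logical `active` (`[n_times, n_tracks]`), and
#'   `seed_spacing`. Use [tidy()] for a long tibble.
#' @export
integrate_trajectories <- function(fields, seed_spacing = NULL) {
  stopifnot(inherits(fields, "velocity_fields"))
  ps <- attr(fields, "pixel_size")
  dt <- attr(fields, "frame_interval")
  times <- sort(unique(fields$t_min))
  gx_px <- sort(unique(fields$grid_x_px))
  gy_px <- sort(unique(fields$grid_y_px))
  gx <- gx_px * ps
  gy <- gy_px * ps
  seed_spacing <- seed_spacing %||% (attr(fields, "grid_spacing_px") * ps)

  sx <- seq(min(gx), max(gx), by = seed_spacing)
  sy <- seq(min(gy), max(gy), by = seed_spacing)
  seeds <- expand.grid(x = sx, y = sy)
  n_tracks <- nrow(seeds)
  n_times <- length(times) + 1L

  r <- array(NA_real_, c(n_times, n_tracks, 2))
  active <- matrix(TRUE, n_times, n_tracks)
  pos <- cbind(seeds$x, seeds$y)
  r[1, , ] <- pos

  df <- as_tibble(fields)
  for (k in seq_along(times)) {
    fk <- df[df$t_min == times[k], ]
    ord <- order(match(fk$grid_x_px, gx_px), match(fk$grid_y_px, gy_px))
    fk <- fk[ord, ]
    um <- matrix(fk$u_um_min, length(gy), length(gx))
    vm <- matrix(fk$v_um_min, length(gy), length(gx))
    alive <- active[k, ]
    ux <- interp_bilinear_(gx, gy, um, pos[alive, 1], pos[alive, 2])
    uy <- interp_bilinear_(gx, gy, vm, pos[alive, 1], pos[alive, 2])
    pos[alive, 1] <- pos[alive, 1] + ux * dt
    pos[alive, 2] <- pos[alive, 2] + uy * dt
    inside <- pos[, 1] >= min(gx) & pos[, 1] <= max(gx) &
      pos[, 2] >= min(gy) & pos[, 2] <= max(gy)
    active[k + 1L, ] <- alive & inside
    r[k + 1L, , ] <- pos
  }
  structure(
    list(r = r, times = c(times, times[length(times)] + dt),
         active = active, seed_spacing = seed_spacing,
         frame_interval = dt),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d tracks over %d time points (%.1f%% active at end)\n",
    dim(x$r)[2], dim(x$r)[1], 100 * mean(x$active[nrow(x$active), ])
  ))
  invisible(x)
}

#' @rdname tidy.monolayer_trajectory
#' @export
tidy.trajectory_set <- function(x, ...) {
  nt <- dim(x$r)[1]; ntr <- dim(x$r)[2]
  tibble(
    time_min = rep(x$times, times = ntr),
    track_id = rep(seq_len(ntr), each = nt),
    x_um = as.vector(x$r[, , 1]),
    y_um = as.vector(x$r[, , 2]),
    active = as.vector(x$active)
  )
}

# Lagged displacement statistic over tracks and (optionally) sliding origins.
lag_stat_ <- function(traj, fun, origin_policy) {
  nt <- dim(traj$r)[1]
  if (nt < 2) abort("Need at least 2 time points.")
  if (!any(traj$active[1, ])) abort("All tracks inactive at t = 0.")
  lags <- seq_len(nt - 1L)
  vals <- numeric(length(lags))
  ns <- integer(length(lags))
  for (l in lags) {
    if (origin_policy == "sliding") {
      d1 <- traj$r[(l + 1):nt, , 1, drop = FALSE] -
        traj$r[1:(nt - l), , 1, drop = FALSE]
      d2 <- traj$r[(l + 1):nt, , 2, drop = FALSE] -
        traj$r[1:(nt - l), , 2, drop = FALSE]
      ok <- traj$active[(l + 1):nt, , drop = FALSE]
    } else {
      d1 <- traj$r[l + 1, , 1, drop = FALSE] - traj$r[1, , 1, drop = FALSE]
      d2 <- traj$r[l + 1, , 2, drop = FALSE] - traj$r[1, , 2, drop = FALSE]
      ok <- traj$active[l + 1, , drop = FALSE]
      dim(d1) <- dim(d2) <- dim(ok)
    }
    disp2 <- d1^2 + d2^2
    vals[l] <- fun(disp2[ok])
    ns[l] <- sum(ok)
  }
  list(lag_min = lags * traj$frame_interval, value = vals, n = ns)
}

#' Mean-squared displacement of a trajectory set
#'
#' `MSD(dt) = <|r_i(t + dt) - r_i(t)|^2>`, averaged over tracks and, with the
#' default policy, over sliding time origins. Frozen tracks contribute only
#' while active. The zero lag (MSD = 0 by definition) is included.
#'
#' @param traj A `trajectory_set` (or `monolayer_trajectory` ground truth,
#'   via [ground_truth_msd()]).
#' @param origin_policy `"sliding"` (average over all time origins, default)
#'   or `"first"` (displacements from `t = 0` only).
#' @return Tibble with `lag_min`, `msd_um2`, `n_pairs`.
#' @export
compute_msd <- function(traj, origin_policy = c("sliding", "first")) {
  origin_policy <- match.arg(origin_policy)
  s <- lag_stat_(traj, mean, origin_policy)
  tibble(
    lag_min = c(0, s$lag_min),
    msd_um2 = c(0, s$value),
    n_pairs = c(sum(traj$active[1, ]), s$n)
  )
}

#' Self-overlap order parameter Q
#'
#' `Q(dt) = N^-1 sum_i w^i`, where the indicator `w^i` is 1 when track i's
#' displacement over the lag stays below the cutoff `d_c` and 0 otherwise,
#' averaged over tracks and (by default) sliding origins. Q runs from 1
#' (frozen, jammed) to 0 (fully rearranged); `Q(0) = 1` by construction.
#'
#' The indicator-below-cutoff form is the standard self-overlap definition;
#' `d_c` defaults in the pipeline to one velocity grid spacing in um.
#'
#' @param traj A `trajectory_set`.
#' @param d_c Overlap cutoff distance, um (> 0).
#' @inheritParams compute_msd
#' @return Tibble with `lag_min`, `q_overlap`, `n_pairs`.
#' @export
compute_overlap <- function(traj, d_c,
                            origin_policy = c("sliding", "first")) {
  origin_policy <- match.arg(origin_policy)
  if (d_c <= 0) abort("`d_c` must be positive.")
  s <- lag_stat_(traj, function(d2) mean(d2 < d_c^2), origin_policy)
  tibble(
    lag_min = c(0, s$lag_min),
    q_overlap = c(1, s$value),
    n_pairs = c(sum(traj$active[1, ]), s$n)
  )
}

#' Instantaneous RMS velocity of each field
#'
#' `V_RMS(t) = sqrt(M^-1 sum_j |v_j(t)|^2)` over the M valid grid vectors of
#' each velocity field.
#'
#' @param fields A `velocity_fields` tibble.
#' @return Tibble with `t_min`, `vrms_um_min` (NA, with a warning, for a
#'   field with no valid vectors) and `n_valid`.
#' @export
compute_vrms <- function(fields) {
  stopifnot(is.data.frame(fields),
            all(c("t_min", "u_um_min", "v_um_min", "valid") %in%
                  names(fields)))
  out <- as_tibble(fields) |>
    group_by(.data$t_min) |>
    summarise(
      vrms_um_min = if (any(.data$valid)) {
        sqrt(mean(.data$u_um_min[.data$valid]^2 +
                    .data$v_um_min[.data$valid]^2))
      } else NA_real_,
      n_valid = sum(.data$valid),
      .groups = "drop"
    )
  if (anyNA(out$vrms_um_min)) {
    warn("Some fields have no valid vectors; V_RMS reported as NA there.")
  }
  out
}

#' All three dynamics statistics of a velocity-field sequence
#'
#' Convenience wrapper: integrates grid-seeded trajectories, then computes
#' MSD, the overlap parameter Q, and V_RMS.
#'
#' @param fields A `velocity_fields` tibble from [multipass_piv()].
#' @param d_c Overlap cutoff, um; default one velocity grid spacing.
#' @param seed_spacing Tracer pitch, um; same default.
#' @inheritParams compute_msd
#' @return A `dynamics_summary` list with tibbles `msd`, `q`, `vrms` and the
#'   cutoff `d_c`; [tidy()] stacks them into one long tibble and
#'   [autoplot()] draws the three panels.
#' @export
monolayer_dynamics <- function(fields, d_c = NULL, seed_spacing = NULL,
                               origin_policy = c("sliding", "first")) {
  origin_policy <- match.arg(origin_policy)
  ps <- attr(fields, "pixel_size")
  d_c <- d_c %||% (attr(fields, "grid_spacing_px") * ps)
  traj <- integrate_trajectories(fields, seed_spacing)
  structure(
    list(
      msd = compute_msd(traj, origin_policy),
      q = compute_overlap(traj, d_c, origin_policy),
      vrms = compute_vrms(fields),
      d_c = d_c,
      trajectories = traj
    ),
    class = "dynamics_summary"
  )
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<dynamics_summary> %d lags, d_c = %.2f um\n",
           "  terminal MSD %.2f um2 | terminal Q %.3f | mean V_RMS %.3f um/min\n"),
    nrow(x$msd) - 1L, x$d_c,
    x$msd$msd_um2[nrow(x$msd)], x$q$q_overlap[nrow(x$q)],
    mean(x$vrms$vrms_um_min, na.rm = TRUE)
  ))
  invisible(x)
}

#' Tidy a dynamics summary
#'
#' @param x A `dynamics_summary`.
#' @param ... Unused.
#' @return Long tibble: `statistic` (msd / q_overlap / vrms),
#'   `lag_or_time_min`, `value`, `n_contributing`.
#' @export
tidy.dynamics_summary <- function(x, ...) {
  bind_rows(
    tibble(statistic = "msd", lag_or_time_min = x$msd$lag_min,
           value = x$msd$msd_um2, n_contributing = x$msd$n_pairs),
    tibble(statistic = "q_overlap", lag_or_time_min = x$q$lag_min,
           value = x$q$q_overlap, n_contributing = x$q$n_pairs),
    tibble(statistic = "vrms", lag_or_time_min = x$vrms$t_min,
           value = x$vrms$vrms_um_min, n_contributing = x$vrms$n_valid)
  )
}

#' @rdname tidy.dynamics_summary
#' @export
glance.dynamics_summary <- function(x, ...) {
  tibble(
    terminal_msd_um2 = x$msd$msd_um2[nrow(x$msd)],
    terminal_q = x$q$q_overlap[nrow(x$q)],
    mean_vrms_um_min = mean(x$vrms$vrms_um_min, na.rm = TRUE),
    d_c_um = x$d_c,
    n_tracks = dim(x$trajectories$r)[2]
  )
}

#' @param object A `dynamics_summary`.
#' @rdname tidy.dynamics_summary
#' @export
autoplot.dynamics_summary <- function(object, ...) {
  df <- tidy(object)
  labels <- c(msd = "MSD (um²)", q_overlap = "Q",
              vrms = "V_RMS (um/min)")
  df$statistic <- labels[df$statistic]
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_or_time_min, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "lag or time (min)", y = NULL)
}
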