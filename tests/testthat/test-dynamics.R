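grid_px <- seq(15.5, 239.5, by = 16)

test_that("all-zero fields leave tracers at their seeds", {
  f <- analytic_fields(function(x, y, t) 0, function(x, y, t) 0,
                       times = c(0, 5, 10), gx_px = grid_px,
                       gy_px = grid_px)
  tr <- integrate_trajectories(f)
  expect_equal(tr$r[4, , ], tr$r[1, , ], tolerance = 1e-12)
  expect_true(all(tr$active))
})

test_that("Euler integration of a constant field is exact", {
  f <- analytic_fields(function(x, y, t) 1, function(x, y, t) 0,
                       times = seq(0, 45, by = 5),
                       gx_px = seq(15.5, 1039.5, by = 16),
                       gy_px = seq(15.5, 1039.5, by = 16))
  tr <- integrate_trajectories(f)
  alive <- tr$active[11, ]
  expect_gt(sum(alive), 0)
  moved <- tr$r[11, alive, ] - tr$r[1, alive, ]
  expect_equal(moved[, 1], rep(50, nrow(moved)), tolerance = 1e-9)
  expect_equal(moved[, 2], rep(0, nrow(moved)), tolerance = 1e-9)
})

test_that("tracers leaving the field freeze and drop from statistics", {
  f <- analytic_fields(function(x, y, t) 10, function(x, y, t) 0,
                       times = seq(0, 20, by = 5), gx_px = grid_px,
                       gy_px = grid_px)
  tr <- integrate_trajectories(f)
  expect_true(any(!tr$active[4, ]))
  frozen <- which(!tr$active[4, ])  # inactive entering field step 4
  expect_equal(tr$r[5, frozen, ], tr$r[4, frozen, ], tolerance = 1e-12)
})

test_that("rotation-field radius drift shrinks with the Euler step", {
  omega <- 0.02  # rad/min
  u <- function(x, y, t) -omega * (y - 128)
  v <- function(x, y, t) omega * (x - 128)
  gx <- seq(8, 248, by = 8)
  run <- function(interval, n_steps) {
    f <- analytic_fields(u, v, times = seq(0, by = interval,
                                           length.out = n_steps),
                         gx_px = gx, gy_px = gx, pixel_size = 1,
                         frame_interval = interval)
    tr <- integrate_trajectories(f, seed_spacing = 60)
    r0 <- sqrt((tr$r[1, , 1] - 128)^2 + (tr$r[1, , 2] - 128)^2)
    r1 <- sqrt((tr$r[n_steps + 1, , 1] - 128)^2 +
                 (tr$r[n_steps + 1, , 2] - 128)^2)
    keep <- r0 > 1 & tr$active[n_steps + 1, ]
    mean(r1[keep] / r0[keep]) - 1
  }
  drift_full <- run(5, 20)
  drift_half <- run(2.5, 40)
  expect_gt(drift_full, 0)                     # Euler spirals outward
  expect_equal(drift_half / drift_full, 0.5, tolerance = 0.1)
})

test_that("MSD closed forms hold for static and drifting tracers", {
  n <- 50; nt <- 8
  r_static <- array(rep(matrix(runif(n * 2, 0, 100), n), each = nt),
                    c(nt, n, 2))
  expect_equal(compute_msd(make_trajectory_set(r_static))$msd_um2,
               rep(0, nt), tolerance = 1e-12)
  v <- 0.4
  r_drift <- r_static
  for (k in seq_len(nt)) r_drift[k, , 1] <- r_drift[k, , 1] + v * 5 * (k - 1)
  for (policy in c("sliding", "first")) {
    m <- compute_msd(make_trajectory_set(r_drift), origin_policy = policy)
    expect_equal(m$msd_um2, (v * m$lag_min)^2, tolerance = 1e-9)
  }
})

test_that("random-walk MSD is linear with the right diffusivity and slope", {
  set.seed(31)
  n <- 10000; nt <- 16; sigma <- 1.5
  steps <- array(rnorm(2 * n * (nt - 1), sd = sigma), c(nt - 1, n, 2))
  r <- array(0, c(nt, n, 2))
  for (k in 2:nt) r[k, , ] <- r[k - 1, , ] + steps[k - 1, , ]
  m <- compute_msd(make_trajectory_set(r, frame_interval = 1))
  lag_frames <- m$lag_min[-1]
  expect_lt(max(abs(m$msd_um2[-1] / (2 * sigma^2 * lag_frames) - 1)), 0.05)
  fit <- stats::lm(log(m$msd_um2[-1]) ~ log(lag_frames))
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.1)
})

test_that("overlap parameter follows its indicator definition exactly", {
  n <- 30; nt <- 6; v <- 1; interval <- 5
  r <- array(0, c(nt, n, 2))
  r[, , 1] <- matrix(v * interval * (seq_len(nt) - 1), nt, n)
  r[1, , 2] <- r[nt, , 2] <- 0
  tr <- make_trajectory_set(r, frame_interval = interval)
  # static: Q = 1 at every lag
  q_static <- compute_overlap(make_trajectory_set(array(1, c(nt, n, 2))),
                              d_c = 0.5)
  expect_equal(q_static$q_overlap, rep(1, nt))
  # cutoff below one frame's displacement: Q = 0 at all positive lags
  q0 <- compute_overlap(tr, d_c = 0.9 * v * interval)
  expect_equal(q0$q_overlap, c(1, rep(0, nt - 1)))
  # cutoff at 1.5 frame displacements: Q = 1 at lag 1, 0 beyond
  q1 <- compute_overlap(tr, d_c = 1.5 * v * interval)
  expect_equal(q1$q_overlap, c(1, 1, rep(0, nt - 2)))
  # bounds and monotone decay for drift
  expect_true(all(q1$q_overlap >= 0 & q1$q_overlap <= 1))
  expect_true(all(diff(q1$q_overlap) <= 1e-12))
  expect_error(compute_overlap(tr, d_c = 0), "d_c")
})

test_that("V_RMS matches closed forms and the brute-force definition", {
  f <- analytic_fields(function(x, y, t) 3, function(x, y, t) 0,
                       times = c(0, 5), gx_px = grid_px, gy_px = grid_px)
  expect_equal(compute_vrms(f)$vrms_um_min, c(3, 3), tolerance = 1e-12)
  # half the vectors 0, half magnitude a -> a / sqrt(2)
  a <- 2.4
  f2 <- analytic_fields(function(x, y, t) ifelse(x < 120, a, 0),
                        function(x, y, t) 0,
                        times = 0, gx_px = seq(7.5, 232.5, by = 15),
                        gy_px = grid_px)
  expect_equal(compute_vrms(f2)$vrms_um_min, a / sqrt(2), tolerance = 1e-12)
  # brute-force loop equality on an arbitrary field
  f3 <- analytic_fields(function(x, y, t) sin(x / 30) + 0.2 * y,
                        function(x, y, t) cos(y / 17),
                        times = c(0, 5), gx_px = grid_px, gy_px = grid_px)
  v <- compute_vrms(f3)
  for (t in c(0, 5)) {
    rows <- f3[f3$t_min == t, ]
    acc <- 0
    for (k in seq_len(nrow(rows))) {
      acc <- acc + rows$u_um_min[k]^2 + rows$v_um_min[k]^2
    }
    expect_equal(v$vrms_um_min[v$t_min == t], sqrt(acc / nrow(rows)),
                 tolerance = 1e-12)
  }
})

test_that("a field with no valid vectors reports a missing V_RMS", {
  f <- analytic_fields(function(x, y, t) 1, function(x, y, t) 0,
                       times = c(0, 5), gx_px = grid_px, gy_px = grid_px)
  f$valid[f$t_min == 5] <- FALSE
  expect_warning(v <- compute_vrms(f), "valid")
  expect_true(is.na(v$vrms_um_min[v$t_min == 5]))
})

test_that("PIV-chain MSD and V_RMS agree with uniform-drift ground truth", {
  d <- drift_stack(v_px_frame = c(1, 0.5), n_frames = 10)
  f <- multipass_piv(d$stack)
  dyn <- monolayer_dynamics(f)
  speed <- sqrt(sum(d$v_um_min^2))
  keep <- dyn$msd$lag_min > 0 & dyn$msd$lag_min <= 15
  expect_lt(max(abs(dyn$msd$msd_um2[keep] /
                      (speed * dyn$msd$lag_min[keep])^2 - 1)), 0.15)
  expect_lt(abs(mean(dyn$vrms$vrms_um_min) / speed - 1), 0.05)
  # MSD log-log slope on the ballistic fixture
  fit <- stats::lm(log(dyn$msd$msd_um2[keep]) ~ log(dyn$msd$lag_min[keep]))
  expect_equal(unname(stats::coef(fit)[2]), 2, tolerance = 0.05)
})

test_that("PIV tracks the window-coherent ground truth at moderate motility", {
  rc <- render_config(image_shape = 256)
  # appreciable stiffness so part of the motion is collective at window scale
  cfg <- sim_config(n_cells = 135, v0 = 0.5, repulsion_stiffness = 0.5,
                    n_frames = 9, rng_seed = 2)
  traj <- simulate_monolayer(cfg)
  f <- suppressWarnings(multipass_piv(render_frames(traj, rc)))
  gtf <- ground_truth_fields(traj, rc)
  # vector-wise agreement with what an ideal windowed velocimeter sees
  expect_gt(cor(f$u_um_min, gtf$u_um_min), 0.8)
  expect_gt(cor(f$v_um_min, gtf$v_um_min), 0.8)
  # amplitude attenuation of sub-window incoherent motion is bounded
  dyn_piv <- suppressWarnings(monolayer_dynamics(f))
  dyn_gt <- suppressWarnings(monolayer_dynamics(gtf))
  keep <- dyn_piv$msd$lag_min > 0
  ratio <- dyn_piv$msd$msd_um2[keep] / dyn_gt$msd$msd_um2[keep]
  expect_true(all(ratio > 0.4 & ratio < 1.1))
  # and PIV never reports more motion than the cells actually perform
  gt <- ground_truth_msd(traj)
  expect_true(all(dyn_piv$msd$msd_um2[keep] <=
                    gt$msd_um2[match(dyn_piv$msd$lag_min[keep],
                                     gt$lag_min)]))
})
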