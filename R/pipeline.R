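#' Run the full dynamics pipeline
#'
#' Chains the measurement stages — multi-pass PIV, grid-seeded trajectory
#' integration, MSD / overlap / V_RMS — on either a supplied image stack or
#' a freshly simulated and rendered monolayer, with provenance recorded for
#' every run. Re-running with an identical configuration reproduces outputs
#' exactly.
#'
#' @param stack An [image_stack()] to analyse, or NULL to simulate one.
#' @param sim A [sim_config()] used when `stack` is NULL.
#' @param render A [render_config()] used when simulating.
#' @param piv A [piv_config()].
#' @param d_c Overlap cutoff, um; default one velocity grid spacing.
#' @param origin_policy Time-origin policy for MSD / Q, see [compute_msd()].
#' @param output_dir If given, tidy CSVs (velocity fields, dynamics) and a
#'   JSON provenance record are written there.
#' @return A list of class `pipeline_run`: `dynamics` (a `dynamics_summary`),
#'   `fields`, the simulated `truth` (NULL for supplied stacks), `provenance`
#'   and `status` (0 = clean, 3 = completed with low-quality PIV warnings).
#' @export
run_dynamics_pipeline <- function(stack = NULL, sim = sim_config(),
                                  render = render_config(),
                                  piv = piv_config(), d_c = NULL,
                                  origin_policy = "sliding",
                                  output_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  truth <- NULL
  if (is.null(stack)) {
    truth <- simulate_monolayer(sim)
    stack <- render_frames(truth, render)
  }
  t_sim <- proc.time()[["elapsed"]]
  fields <- multipass_piv(stack, piv)
  t_piv <- proc.time()[["elapsed"]]
  dyn <- monolayer_dynamics(fields, d_c = d_c,
                            origin_policy = origin_policy)
  t_dyn <- proc.time()[["elapsed"]]

  low_q <- attr(fields, "low_quality_pairs")
  provenance <- list(
    config_hash = rlang::hash(list(
      sim = if (is.null(truth)) NULL else unclass(truth$config),
      render = if (is.null(truth)) NULL else unclass(render),
      piv = unclass(piv), d_c = dyn$d_c, origin_policy = origin_policy,
      source_id = stack$source_id
    )),
    software_version = as.character(utils::packageVersion("jamscope")),
    source_id = stack$source_id,
    rng_seed = if (is.null(truth)) NA_integer_ else truth$config$rng_seed,
    n_frames = length(stack$frames),
    pixel_size_um = stack$pixel_size,
    frame_interval_min = stack$frame_interval,
    d_c_um = dyn$d_c,
    timings_s = list(simulate_render = t_sim - t0, piv = t_piv - t_sim,
                     dynamics = t_dyn - t_piv),
    warnings = if (length(low_q)) {
      sprintf("low-quality PIV field(s) at pair(s): %s",
              paste(low_q, collapse = ", "))
    } else character(0)
  )
  status <- if (length(low_q)) 3L else 0L

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_fields_csv(fields, file.path(output_dir, "velocity_fields.csv"))
    utils::write.csv(tidy(dyn), file.path(output_dir, "dynamics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(provenance,
                         file.path(output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(dynamics = dyn, fields = fields, truth = truth,
                 provenance = provenance, status = status),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> status %d, %d frames from %s\n",
              x$status, x$provenance$n_frames, x$provenance$source_id))
  print(x$dynamics)
  invisible(x)
}

#' Low- versus high-motility jamming benchmark
#'
#' Runs the full pipeline on two simulated monolayers that differ only in
#' self-propulsion speed: a low-motility arm emulating a maturing control
#' epithelium approaching arrest, and a high-motility arm emulating the
#' persistently migratory state. For each arm it reports MSD, Q, V_RMS, the
#' Voronoi-derived mean shape index and the jamming call against `p0`, and
#' checks the expected contrast: the high-motility arm must be called
#' unjammed with strictly larger terminal MSD and smaller terminal Q than
#' the low-motility arm.
#'
#' @param seed Integer master seed; the two arms use seeds derived from it.
#' @param v0_low,v0_high Self-propulsion speeds of the two arms, um/min.
#' @param sim Base [sim_config()] shared by both arms (its `v0` and
#'   `rng_seed` are overridden per arm).
#' @param render A [render_config()].
#' @param threshold Jamming threshold `p0`.
#' @param check If TRUE (default), fail on a violated contrast instead of
#'   just recording it.
#' @return A `jamming_benchmark` list: per-arm `pipeline_run`s, shape
#'   tables, jamming calls, a one-row-per-arm summary tibble, and
#'   `contrast_ok`.
#' @export
run_jamming_benchmark <- function(seed = 1L, v0_low = 0.1, v0_high = 2.5,
                                  sim = sim_config(), render = render_config(),
                                  threshold = 3.813, check = TRUE) {
  arm <- function(v0, arm_seed) {
    cfg <- sim
    cfg$v0 <- v0
    cfg$rng_seed <- as.integer(arm_seed)
    # largest divisor of the frame interval satisfying the stability guard
    dt_max <- min(cfg$dt, cfg$cell_radius / (10 * max(v0, 1e-9)))
    cfg$dt <- cfg$frame_interval / ceiling(cfg$frame_interval / dt_max)
    cfg <- do.call(sim_config, unclass(cfg))
    run <- run_dynamics_pipeline(sim = cfg, render = render)
    mask <- voronoi_masks(run$truth, cfg$n_frames, render)
    shapes <- shape_metrics(mask)
    call <- classify_jamming(shapes, threshold = threshold)
    list(run = run, shapes = shapes, call = call)
  }
  low <- arm(v0_low, seed)
  high <- arm(v0_high, (seed + 500009L) %% .Machine$integer.max)

  gl <- function(a, name, v0) {
    g <- glance(a$run$dynamics)
    tibble(arm = name, v0_um_min = v0, mean_q = a$call$mean_q,
           state = a$call$state, n_cells = a$call$n_cells,
           terminal_msd_um2 = g$terminal_msd_um2, terminal_q = g$terminal_q,
           mean_vrms_um_min = g$mean_vrms_um_min)
  }
  summary <- bind_rows(gl(low, "low_motility", v0_low),
                       gl(high, "high_motility", v0_high))
  contrast_ok <- high$call$state == "unjammed" &&
    low$call$state == "jammed" &&
    summary$terminal_msd_um2[2] > summary$terminal_msd_um2[1] &&
    summary$terminal_q[2] < summary$terminal_q[1]
  if (check && !contrast_ok) {
    abort("Benchmark contrast violated: see the summary table.")
  }
  structure(
    list(low = low, high = high, summary = summary,
         contrast_ok = contrast_ok, seed = seed, threshold = threshold),
    class = "jamming_benchmark"
  )
}

#' @export
print.jamming_benchmark <- function(x, ...) {
  cat(sprintf("<jamming_benchmark> seed %d, p0 = %.3f, contrast %s\n",
              x$seed, x$threshold, if (x$contrast_ok) "OK" else "VIOLATED"))
  print(x$summary)
  invisible(x)
}

#' @rdname tidy.dynamics_summary
#' @export
tidy.jamming_benchmark <- function(x, ...) x$summary
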