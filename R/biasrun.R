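#' Run MD with the on-the-fly maximum-entropy RDF bias
#'
#' The full controller loop: integrate with the bias forces, sample the
#' kernel RDF every `schedule$sample_every` steps, average over
#' `schedule$window` steps, update the Lagrange multipliers by normalised
#' gradient descent, optionally pause sampling for `schedule$equilibrate`
#' steps, and repeat.  Deterministic for a fixed `seed`.
#'
#' At startup the expected ideal-gas pair count in the narrowest bin per
#' window is estimated; below ~10 counts the multiplier updates become
#' noisy (a warning is issued suggesting a coarser grid or longer window).
#'
#' @param frame starting [md_frame()].
#' @param config an [engine_config()] (its `temperature` supplies the
#'   `k_B T` scale of the updates).
#' @param target target [rdf_histogram()].
#' @param schedule a [bias_schedule()].
#' @param n_updates maximum number of update cycles.
#' @param weighting [species_weighting()] for measurement and bias.
#' @param velocities optional starting velocities.
#' @param state optional [bias_state()] to continue from (default: zero
#'   multipliers at the frame's volume).
#' @param stop_mae optional early-stop threshold on the windowed MAE.
#' @param extra_updates update cycles to keep running after `stop_mae` is
#'   first reached (lets the multipliers settle).
#' @param seed optional integer seed for the whole run.
#' @param traj_every forwards to [run_md()] snapshot cadence (per window).
#' @param verbose print per-update progress.
#' @return list of class `bias_run`: final `frame`, `velocities`, `state`
#'   (bias with learned multipliers), `mae_history`, `lambda_trace`
#'   (updates x bins matrix), `updates_to_stop` (first cycle at or below
#'   `stop_mae`, NA if never), `avg_rdf` of the last window, and the
#'   per-window trajectory snapshots.
#' @export
run_biased_md <- function(frame, config, target, schedule,
                          n_updates, weighting = species_weighting(),
                          velocities = NULL, state = NULL, stop_mae = NULL,
                          extra_updates = 0, seed = NULL, traj_every = 0,
                          verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state))
    state <- bias_state(target$grid, ref_volume = frame_volume(frame),
                        weighting = weighting)
  if (!grids_equal(state$grid, target$grid))
    stop("bias state and target must share one grid")
  if (is.null(velocities))
    velocities <- init_velocities(frame, config$temperature, config)

  check_bin_statistics(frame, target$grid, schedule)

  cstate <- controller_state(state, target)
  b <- target$grid$b
  lambda_trace <- matrix(NA_real_, n_updates, b)
  mae_hist <- numeric(0)
  updates_to_stop <- NA_integer_
  trajectory <- list()
  dropped_warned <- FALSE
  u_done <- 0L

  for (u in seq_len(n_updates)) {
    res <- run_md(frame, config, n_steps = schedule$window,
                  velocities = velocities, bias = cstate$bias,
                  sample_every = schedule$sample_every,
                  traj_every = traj_every)
    frame <- res$frame
    velocities <- res$velocities
    if (!dropped_warned && res$dropped_kernel_mass > 0) {
      warning("kernel mass truncated at the grid ends (total ",
              signif(res$dropped_kernel_mass, 3),
              "); widen the grid if unintended", call. = FALSE)
      dropped_warned <- TRUE
    }
    trajectory <- c(trajectory, res$trajectory)
    cstate <- controller_absorb(cstate, res$avg_rdf$values,
                                res$avg_virial_per_bin, res$n_samples)
    cstate <- update_multipliers(cstate, schedule, config$temperature)
    mae_hist <- cstate$mae_history
    lambda_trace[u, ] <- cstate$bias$lambda_hat
    u_done <- u
    if (verbose)
      message(sprintf("update %3d: MAE = %.4f", u, mae_hist[u]))
    if (schedule$equilibrate > 0) {
      res_eq <- run_md(frame, config, n_steps = schedule$equilibrate,
                       velocities = velocities, bias = cstate$bias)
      frame <- res_eq$frame
      velocities <- res_eq$velocities
    }
    if (!is.null(stop_mae) && is.na(updates_to_stop) &&
        mae_hist[u] <= stop_mae)
      updates_to_stop <- u
    if (!is.na(updates_to_stop) && u >= updates_to_stop + extra_updates)
      break
  }

  avg_last <- res$avg_rdf
  structure(list(frame = frame, velocities = velocities,
                 state = cstate$bias, target = target,
                 mae_history = mae_hist,
                 lambda_trace = lambda_trace[seq_len(u_done), , drop = FALSE],
                 updates_to_stop = updates_to_stop,
                 avg_rdf = avg_last, schedule = schedule,
                 trajectory = trajectory, config = config),
            class = "bias_run")
}

#' @export
print.bias_run <- function(x, ...) {
  cat(sprintf(
    "biased MD run: %d update cycles, final windowed MAE = %.4g\n",
    length(x$mae_history), tail(x$mae_history, 1)))
  invisible(x)
}

#' Multipliers averaged over the final update cycles
#'
#' The converged multipliers fluctuate around the fixed point with a
#' constant l1 step per update; averaging the trace over the last `k`
#' cycles gives a smoother profile for inspection or pair-potential
#' comparison.
#'
#' @param run a [run_biased_md()] result.
#' @param k number of final cycles to average (clipped to the trace).
#' @return numeric vector of `b` multipliers.
#' @export
lambda_converged <- function(run, k = 30) {
  u <- nrow(run$lambda_trace)
  k <- min(k, u)
  colMeans(run$lambda_trace[(u - k + 1):u, , drop = FALSE])
}

check_bin_statistics <- function(frame, grid, schedule) {
  n <- nrow(frame$positions)
  v <- frame_volume(frame)
  n_samples <- schedule$window %/% schedule$sample_every
  counts <- n * (n - 1) / 2 * bin_volumes(grid) / v * n_samples
  if (min(counts) < 10)
    warning(sprintf(
      paste0("expected pair count in the narrowest bin is %.2f per window ",
             "(< 10): multiplier updates may be noisy; consider a coarser ",
             "grid or a longer window"), min(counts)), call. = FALSE)
  invisible(counts)
}
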