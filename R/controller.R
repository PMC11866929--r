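#' Bias update schedule
#'
#' Cadence and step size of the on-the-fly gradient descent for the
#' Lagrange multipliers.  The RDF is sampled every `sample_every` steps,
#' averaged over `window` steps, the multipliers are updated once per
#' window, and sampling then pauses for `equilibrate` steps.  `gamma` is
#' the dimensionless step size (applied as `gamma * k_B T` of multiplier
#' change per update); step sizes around 10-5 suit RDF matching in liquids
#' and 5-1 suit liquid-to-solid transitions.  `kappa_mode` optionally damps
#' the update of bins whose average per-bin bias virial drives contraction
#' (`"anti_contraction"`, bins with negative virial) or expansion
#' (`"anti_expansion"`, positive virial) by `kappa_factor`.
#'
#' @param gamma dimensionless step size, `> 0`.
#' @param sample_every steps between RDF samples.
#' @param window steps averaged per update (multiple of `sample_every`).
#' @param equilibrate sampling pause after each update, in steps.
#' @param kappa_mode `"none"`, `"anti_contraction"` or `"anti_expansion"`.
#' @param kappa_factor damping factor in (0, 1].
#' @return object of class `bias_schedule`.
#' @export
bias_schedule <- function(gamma, sample_every = 10, window = 100,
                          equilibrate = 0,
                          kappa_mode = c("none", "anti_contraction",
                                         "anti_expansion"),
                          kappa_factor = 1) {
  kappa_mode <- match.arg(kappa_mode)
  stopifnot(gamma > 0, sample_every >= 1, window >= sample_every,
            window %% sample_every == 0, equilibrate >= 0,
            kappa_factor > 0, kappa_factor <= 1)
  structure(list(gamma = gamma, sample_every = as.integer(sample_every),
                 window = as.integer(window),
                 equilibrate = as.integer(equilibrate),
                 kappa_mode = kappa_mode, kappa_factor = kappa_factor),
            class = "bias_schedule")
}

#' Gradient of the maxent objective with respect to the multipliers
#'
#' Per bin, the target intensity minus the windowed average measured in the
#' biased simulation.  (The objective itself, a Legendre transform
#' involving the partition function, is never evaluated; only this gradient
#' is needed.)
#'
#' @param target target [rdf_histogram()].
#' @param avg windowed-average [rdf_histogram()] on the same grid.
#' @return numeric vector of per-bin differences.
#' @export
rdf_gradient <- function(target, avg) {
  if (!grids_equal(target$grid, avg$grid)) stop("grid mismatch")
  target$values - avg$values
}

#' Per-bin update damping from the bias virial
#'
#' @param avg_virial_per_bin windowed mean of the per-bin bias virial.
#' @param schedule a [bias_schedule()].
#' @return vector of per-bin factors in (0, 1].
#' @export
kappa_vector <- function(avg_virial_per_bin, schedule) {
  b <- length(avg_virial_per_bin)
  switch(schedule$kappa_mode,
         none = rep(1, b),
         anti_contraction = ifelse(avg_virial_per_bin < 0,
                                   schedule$kappa_factor, 1),
         anti_expansion = ifelse(avg_virial_per_bin > 0,
                                 schedule$kappa_factor, 1))
}

#' Controller state for the multiplier gradient descent
#'
#' @param bias a [bias_state()].
#' @param target target [rdf_histogram()] on the bias grid.
#' @return object of class `controller_state` carrying the bias, the
#'   target, the running averages of the window and the MAE history.
#' @export
controller_state <- function(bias, target) {
  if (!grids_equal(bias$grid, target$grid))
    stop("bias and target must share one grid")
  structure(list(bias = bias, target = target,
                 acc = rdf_accumulator(bias$grid),
                 vpb_sum = numeric(bias$grid$b), vpb_n = 0L,
                 update_count = 0L, mae_history = numeric(0)),
            class = "controller_state")
}

# feed one window's worth of pre-averaged samples into the state
controller_absorb <- function(cstate, avg_g, avg_vpb, n_samples) {
  cstate$acc$add(rdf_histogram(cstate$bias$grid, avg_g))
  cstate$vpb_sum <- cstate$vpb_sum + avg_vpb
  cstate$vpb_n <- cstate$vpb_n + 1L
  cstate
}

#' One gradient-descent update of the Lagrange multipliers
#'
#' Applies
#' \deqn{\hat\lambda_b \leftarrow \hat\lambda_b - \gamma k_B T \kappa_b
#'   \frac{\tilde g_b^{target} - \langle g_b \rangle}
#'        {\sum_{b'} |\tilde g_{b'}^{target} - \langle g_{b'} \rangle|}}
#' so the l1 norm of the change is exactly `gamma * k_B T` when all
#' `kappa_b = 1`, independent of how close the measured average already is
#' to the target.  Where the target exceeds the measured average the
#' multiplier decreases, rewarding configurations with more intensity
#' there.  A perfectly matched window (zero denominator) is a logged no-op.
#' The window averages are reset afterwards.
#'
#' @param cstate a [controller_state()] holding a full averaging window.
#' @param schedule a [bias_schedule()].
#' @param temperature k_B T in energy units (k_B = 1).
#' @return the updated `controller_state`.
#' @export
update_multipliers <- function(cstate, schedule, temperature = 1) {
  avg <- cstate$acc$mean()
  diff <- rdf_gradient(cstate$target, avg)
  mae_now <- mean(abs(diff))
  denom <- sum(abs(diff))
  if (denom > 0) {
    kap <- if (cstate$vpb_n > 0)
      kappa_vector(cstate$vpb_sum / cstate$vpb_n, schedule)
    else rep(1, length(diff))
    delta <- -schedule$gamma * temperature * kap * diff / denom
    lam <- cstate$bias$lambda_hat + delta
    if (!all(is.finite(lam))) stop("non-finite multiplier update")
    cstate$bias$lambda_hat <- lam
  } else {
    message("update_multipliers: measured average matches target exactly; ",
            "no-op update")
  }
  cstate$acc$reset()
  cstate$vpb_sum <- numeric(cstate$bias$grid$b)
  cstate$vpb_n <- 0L
  cstate$update_count <- cstate$update_count + 1L
  cstate$mae_history <- c(cstate$mae_history, mae_now)
  cstate
}
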