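#' Maximum-entropy bias state
#'
#' The linear bias \eqn{E_{bias} = \sum_b \hat\lambda_b g_b} acting on the
#' kernel RDF.  The Lagrange multipliers `lambda_hat` carry energy units
#' (\eqn{\hat\lambda_b = k_B T \lambda_b}).  The RDF prefactor inside the
#' bias uses a fixed reference volume (normally the volume at which the
#' bias was set up) rather than the instantaneous box volume, so the bias
#' energy has no explicit volume dependence and its pairwise force virial
#' equals the isotropic-scaling derivative \eqn{-(1/d)\,\partial E_{bias} /
#' \partial \ln s}; under a barostat the controller absorbs the residual
#' rescaling into the multipliers.
#'
#' @param grid an [rdf_grid()] (must match the target RDF's grid).
#' @param ref_volume reference volume for the RDF normalisation.
#' @param lambda_hat `b` finite multipliers, energy units (default all 0).
#' @param weighting a [species_weighting()].
#' @param enabled logical; a disabled bias cannot be evaluated.
#' @return object of class `bias_state`.
#' @export
bias_state <- function(grid, ref_volume, lambda_hat = NULL,
                       weighting = species_weighting(), enabled = TRUE) {
  if (is.null(lambda_hat)) lambda_hat <- numeric(grid$b)
  stopifnot(inherits(grid, "rdf_grid"), length(lambda_hat) == grid$b,
            all(is.finite(lambda_hat)), ref_volume > 0)
  structure(list(grid = grid, lambda_hat = as.numeric(lambda_hat),
                 weighting = weighting, ref_volume = as.numeric(ref_volume),
                 enabled = isTRUE(enabled)),
            class = "bias_state")
}

#' @export
print.bias_state <- function(x, ...) {
  cat(sprintf(
    "maxent bias: %d bins, |lambda|_1 = %.4g, ref. volume %.4g (%s)\n",
    x$grid$b, sum(abs(x$lambda_hat)), x$ref_volume,
    if (x$enabled) "enabled" else "disabled"))
  invisible(x)
}

bias_eval <- function(frame, state) {
  if (!state$enabled) stop("bias state is disabled")
  check_grid_box(state$grid, frame$box)
  res <- resolve_weighting(frame, state$weighting)
  pref <- pair_prefactor(res, state$ref_volume)
  cpp_bias_eval(frame$positions, frame$box, res$codes, state$lambda_hat,
                state$grid$r_lo, state$grid$delta, state$grid$b,
                pref, bin_volumes(state$grid))
}

#' Bias energy of a frame
#'
#' \eqn{\sum_b \hat\lambda_b g_b} with \eqn{g_b} the instantaneous kernel
#' RDF (including species weighting, at the bias reference volume).
#'
#' @param frame an [md_frame()].
#' @param state a [bias_state()].
#' @return scalar energy.
#' @export
bias_energy <- function(frame, state) bias_eval(frame, state)$energy

#' Bias forces on every atom
#'
#' Exact gradient forces \eqn{F_i = -\partial E_{bias} / \partial r_i}:
#' pairwise, central, and local to the two bins each pair's kernel touches
#' (the rectangular kernel crosses exactly one interior bin boundary, so
#' only the `1/delta` boundary terms of the containing and adjacent bin
#' contribute).
#'
#' @inheritParams bias_energy
#' @return N x 3 matrix of forces.
#' @export
bias_forces <- function(frame, state) bias_eval(frame, state)$forces

#' Bias virial and its per-bin decomposition
#'
#' Total bias virial \eqn{T_{ME} = (1/d) \sum_{pairs} r_{ij} \cdot F_{ij}}
#' (d = 3), decomposed over the bin whose multiplier generated each force
#' term; the per-bin values sum to the total identically.
#'
#' @inheritParams bias_energy
#' @return object of class `virial_report`: list with `total` and `per_bin`.
#' @export
bias_virial <- function(frame, state) {
  ev <- bias_eval(frame, state)
  virial_report(ev$virial_total, ev$virial_per_bin)
}

virial_report <- function(total, per_bin) {
  structure(list(total = total, per_bin = per_bin), class = "virial_report")
}

#' @export
print.virial_report <- function(x, ...) {
  cat(sprintf("bias virial T_ME = %.6g over %d bins\n",
              x$total, length(x$per_bin)))
  invisible(x)
}

#' Effective pair potential encoded by the bias
#'
#' For a single-species system a pair at distance r in bin b feels the bias
#' pair energy \eqn{u_{bias}(r_b) = \hat\lambda_b \, 2 V_{ref} /
#' (N (N - 1) V_b)}.  Comparing this profile with a known pair-potential
#' difference is the classic check that the maximum-entropy bias recovers
#' the interaction that generated the target RDF.
#'
#' @param state a [bias_state()].
#' @param n number of atoms of the (single-species) system.
#' @param lambda_hat optional multiplier vector to use instead of the
#'   state's own (e.g. an average over late update cycles).
#' @return data.frame with columns `r` and `u`.
#' @export
bias_pair_potential <- function(state, n, lambda_hat = NULL) {
  if (is.null(lambda_hat)) lambda_hat <- state$lambda_hat
  stopifnot(length(lambda_hat) == state$grid$b, n >= 2)
  u <- lambda_hat * 2 * state$ref_volume /
    (n * (n - 1) * bin_volumes(state$grid))
  data.frame(r = grid_centers(state$grid), u = u)
}
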