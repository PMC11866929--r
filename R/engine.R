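#' Engine configuration (reduced Lennard-Jones units, k_B = 1)
#'
#' Pair parameters may be scalars (single species) or S x S matrices
#' indexed by `species`.  `damp` is the Langevin thermostat time constant
#' (larger = weaker coupling; `NULL` disables the thermostat, giving NVE).
#' Setting `pressure` enables the isotropic Berendsen barostat with time
#' constant `ptau`, driven by the total virial (physical + bias).
#' `shift` selects the Lennard-Jones truncation: `"energy"` shifts the
#' energy to zero at the cutoff, `"force"` additionally makes the force
#' continuous (best energy conservation), `"none"` is the bare truncation.
#'
#' @param species character vector of species labels.
#' @param epsilon,sigma,cutoff LJ well depth, diameter and cutoff
#'   (scalar or S x S matrix).
#' @param mass per-species masses.
#' @param dt integration time step.
#' @param temperature thermostat set point (also used for `k_B T` in
#'   multiplier updates).
#' @param damp Langevin damping time; `NULL` = no thermostat.
#' @param pressure barostat set point; `NULL` = constant volume.
#' @param ptau Berendsen barostat time constant.
#' @param shift `"energy"`, `"force"` or `"none"`.
#' @return object of class `engine_config`.
#' @export
engine_config <- function(species = "A", epsilon = 1, sigma = 1,
                          cutoff = 2.5, mass = 1, dt = 0.005,
                          temperature = 1, damp = NULL,
                          pressure = NULL, ptau = 1, shift = "energy") {
  s <- length(species)
  as_mat <- function(x, what) {
    if (length(x) == 1) x <- matrix(x, s, s)
    x <- as.matrix(x)
    if (!all(dim(x) == c(s, s)) || !isTRUE(all.equal(x, t(x))))
      stop(what, " must be a scalar or a symmetric ", s, "x", s, " matrix")
    x
  }
  shift <- match.arg(shift, c("energy", "force", "none"))
  stopifnot(dt > 0, is.null(damp) || damp > 0, temperature >= 0)
  structure(list(species = species,
                 epsilon = as_mat(epsilon, "epsilon"),
                 sigma = as_mat(sigma, "sigma"),
                 cutoff = as_mat(cutoff, "cutoff"),
                 mass = rep_len(mass, s), dt = dt,
                 temperature = temperature, damp = damp,
                 pressure = pressure, ptau = ptau, shift = shift),
            class = "engine_config")
}

shift_code <- function(shift) match(shift, c("none", "energy", "force")) - 1L

config_codes <- function(frame, config) {
  idx <- match(frame$species, config$species)
  if (any(is.na(idx)))
    stop("frame species not covered by engine config: ",
         paste(unique(frame$species[is.na(idx)]), collapse = ", "))
  idx - 1L
}

#' Lennard-Jones energy, forces and virial of a frame
#'
#' Truncated (optionally shifted) 12-6 potential under the minimum-image
#' convention; forces are the exact gradient, the virial is the pairwise
#' sum \eqn{(1/3)\sum r_{ij} \cdot F_{ij}}.
#'
#' @param frame an [md_frame()].
#' @param config an [engine_config()].
#' @return list with `energy`, `forces` (N x 3) and `virial`.
#' @export
lj_forces <- function(frame, config) {
  if (max(config$cutoff) > min(frame$box) / 2 + 1e-12)
    stop("cutoff exceeds half the smallest box length")
  cpp_lj_eval(frame$positions, frame$box, config_codes(frame, config),
              config$epsilon, config$sigma, config$cutoff,
              shift_code(config$shift))
}

#' Crystalline starting configuration
#'
#' A periodic fcc, bcc or sc lattice at the requested number density.
#'
#' @param cells unit cells per box edge.
#' @param density number density N / V.
#' @param lattice `"fcc"` (4 atoms/cell), `"bcc"` (2) or `"sc"` (1).
#' @param species species label(s) for the atoms.
#' @return an [md_frame()].
#' @export
lattice_frame <- function(cells, density, lattice = "fcc", species = "A") {
  basis <- switch(match.arg(lattice, c("fcc", "bcc", "sc")),
                  fcc = rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                              c(0, 0.5, 0.5)),
                  bcc = rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)),
                  sc = rbind(c(0, 0, 0)))
  a <- (nrow(basis) / density)^(1 / 3)
  idx <- as.matrix(expand.grid(0:(cells - 1), 0:(cells - 1), 0:(cells - 1)))
  pos <- do.call(rbind, lapply(seq_len(nrow(basis)), function(k)
    sweep(idx, 2, basis[k, ], "+")))
  md_frame(pos * a, box = rep(cells * a, 3), species = species)
}

#' Maxwell-Boltzmann initial velocities
#'
#' Gaussian velocities at the requested temperature with the center-of-mass
#' drift removed and the kinetic energy rescaled to exactly `3 N k_B T / 2`.
#'
#' @param frame an [md_frame()].
#' @param temperature target temperature.
#' @param config an [engine_config()] (for the per-species masses).
#' @return N x 3 velocity matrix.
#' @export
init_velocities <- function(frame, temperature, config = engine_config()) {
  n <- nrow(frame$positions)
  m <- config$mass[config_codes(frame, config) + 1L]
  v <- matrix(rnorm(3 * n, sd = sqrt(temperature / rep(m, 3))), n, 3)
  v <- sweep(v, 2, colSums(v * m) / sum(m))  # remove COM drift
  ke <- 0.5 * sum(m * rowSums(v^2))
  if (ke > 0) v <- v * sqrt(1.5 * n * temperature / ke)
  v
}

#' Integrate the equations of motion
#'
#' Velocity-Verlet with optional Langevin thermostat, isotropic Berendsen
#' barostat and the maximum-entropy bias as an additional force provider.
#' With a fixed `seed` a run is bit-reproducible.  The total virial
#' reported in the trace is the physical pair virial plus the bias virial.
#'
#' @param frame starting [md_frame()].
#' @param config an [engine_config()].
#' @param n_steps number of time steps.
#' @param velocities N x 3 matrix; drawn fresh at `config$temperature`
#'   when NULL.
#' @param bias optional [bias_state()] force provider.
#' @param grid optional measurement [rdf_grid()] when sampling without a
#'   bias (a bias provides its own grid).
#' @param weighting measurement [species_weighting()]; defaults to the
#'   bias's weighting, else identical.
#' @param sample_every accumulate the kernel RDF (and per-bin bias virial)
#'   every this many steps; 0 = no sampling.
#' @param traj_every store an unwrapped-coordinate snapshot every this many
#'   steps; 0 = never.
#' @param trace_every record thermodynamic state every this many steps.
#' @param seed optional integer passed to [set.seed()].
#' @return list of class `md_run`: final `frame`, `velocities`,
#'   `positions_unwrapped`, windowed `avg_rdf` / `avg_virial_per_bin`,
#'   energies and virials of the final step, a `trace` data.frame and a
#'   `trajectory` list of snapshots.
#' @export
run_md <- function(frame, config, n_steps, velocities = NULL, bias = NULL,
                   grid = NULL, weighting = NULL, sample_every = 0,
                   traj_every = 0, trace_every = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(velocities))
    velocities <- init_velocities(frame, config$temperature, config)
  stopifnot(all(dim(velocities) == dim(frame$positions)))
  if (max(config$cutoff) > min(frame$box) / 2 + 1e-12)
    stop("cutoff exceeds half the smallest box length")

  bias_on <- !is.null(bias) && bias$enabled
  mgrid <- if (bias_on) bias$grid else grid
  sampling <- sample_every > 0
  if (sampling && is.null(mgrid))
    stop("sampling requested but no grid available")
  if (!is.null(mgrid)) check_grid_box(mgrid, frame$box)

  if (is.null(weighting))
    weighting <- if (bias_on) bias$weighting else species_weighting()

  # weighting prefactor matrices expressed on the engine's species set
  codes <- config_codes(frame, config)
  s_eng <- length(config$species)
  build_pref <- function(w, volume) {
    if (w$mode == "identical") {
      n <- nrow(frame$positions)
      return(matrix(2 * volume / (n * (n - 1)), s_eng, s_eng))
    }
    res <- resolve_weighting(frame, w)
    idx <- match(w$species, config$species)
    if (any(is.na(idx)))
      stop("weighting species not covered by engine config")
    m <- matrix(0, s_eng, s_eng)
    m[idx, idx] <- pair_prefactor(res, volume)
    m
  }
  if (!is.null(mgrid)) {
    meas_unit <- build_pref(weighting, 1)
    bias_pref <- if (bias_on) build_pref(bias$weighting, bias$ref_volume)
                 else meas_unit  # unused when lambda is empty
    lambda <- if (bias_on) bias$lambda_hat else numeric(0)
    gpar <- list(r_lo = mgrid$r_lo, delta = mgrid$delta, b = mgrid$b,
                 binvol = bin_volumes(mgrid))
  } else {
    meas_unit <- bias_pref <- matrix(1, s_eng, s_eng)
    lambda <- numeric(0)
    gpar <- list(r_lo = 0, delta = 1, b = 1, binvol = 1)
  }

  out <- cpp_md_run(frame$positions, velocities, frame$box, codes,
                    config$mass, config$epsilon, config$sigma, config$cutoff,
                    shift_code(config$shift),
                    config$dt, as.integer(n_steps),
                    config$temperature,
                    if (is.null(config$damp)) 0 else config$damp,
                    if (is.null(config$pressure)) 0 else config$pressure,
                    config$ptau, !is.null(config$pressure),
                    lambda, gpar$r_lo, gpar$delta, gpar$b,
                    bias_pref, meas_unit, gpar$binvol,
                    as.integer(sample_every), as.integer(traj_every),
                    as.integer(trace_every))

  avg_rdf <- if (sampling && out$n_samples > 0)
    rdf_histogram(mgrid, out$avg_g) else NULL
  structure(list(
    frame = md_frame(out$positions, out$box, frame$species,
                     time = frame$time + n_steps * config$dt, wrap = FALSE),
    velocities = out$velocities,
    positions_unwrapped = out$positions_unwrapped,
    avg_rdf = avg_rdf,
    avg_virial_per_bin = if (sampling) out$avg_virial_per_bin else NULL,
    n_samples = out$n_samples,
    e_pair = out$e_pair, e_bias = out$e_bias,
    virial_pair = out$virial_pair, virial_bias = out$virial_bias,
    virial_total = out$virial_pair + out$virial_bias,
    dropped_kernel_mass = out$dropped_kernel_mass,
    trace = as.data.frame(out$trace),
    trajectory = out$trajectory,
    config = config), class = "md_run")
}

#' @export
print.md_run <- function(x, ...) {
  cat(sprintf("MD run: %d atoms, t = %.4g, E_pair = %.6g, E_bias = %.6g\n",
              nrow(x$frame$positions), x$frame$time, x$e_pair, x$e_bias))
  invisible(x)
}
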