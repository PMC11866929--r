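#' Specification of an analytic crystalline target
#'
#' A broadened-shell model of a crystal's RDF: each coordination shell of
#' the given lattice contributes a Gaussian peak.  This is the same
#' mathematical object as a sharply peaked crystalline target RDF measured
#' from a cold reference simulation, but available in closed form.
#'
#' @param lattice `"fcc"`, `"bcc"`, `"sc"` or `"hcp"`.
#' @param spacing nearest-neighbour distance (length units).
#' @param sigma Gaussian broadening width of the shells.
#' @param n_shells number of coordination shells to include.
#' @return object of class `lattice_spec`.
#' @export
lattice_spec <- function(lattice = c("fcc", "bcc", "sc", "hcp"),
                         spacing, sigma, n_shells = 8) {
  lattice <- match.arg(lattice)
  stopifnot(spacing > 0, sigma > 0, n_shells >= 1)
  structure(list(lattice = lattice, spacing = spacing, sigma = sigma,
                 n_shells = as.integer(n_shells)),
            class = "lattice_spec")
}

#' Coordination shells of an ideal lattice
#'
#' Shell radii and coordination numbers, computed by enumerating lattice
#' points around an atom (no table lookup, so any supported lattice and
#' spacing works).
#'
#' @param spec a [lattice_spec()].
#' @return data.frame with columns `radius` and `z` (coordination number),
#'   sorted by radius, `n_shells` rows.
#' @export
lattice_shells <- function(spec) {
  nn <- spec$spacing
  m <- ceiling(spec$n_shells^(1 / 2)) + 3  # generous cell range
  if (spec$lattice == "hcp") {
    a <- nn
    c_ax <- sqrt(8 / 3) * a
    a1 <- c(a, 0, 0); a2 <- c(a / 2, a * sqrt(3) / 2, 0); a3 <- c(0, 0, c_ax)
    basis <- rbind(c(0, 0, 0),
                   (a1 + a2) / 3 + a3 / 2)
    cells <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
    pts <- do.call(rbind, lapply(1:2, function(k)
      cells %*% rbind(a1, a2, a3) +
        matrix(basis[k, ], nrow(cells), 3, byrow = TRUE)))
  } else {
    a <- switch(spec$lattice,
                fcc = nn * sqrt(2),
                bcc = nn * 2 / sqrt(3),
                sc = nn)
    basis <- switch(spec$lattice,
                    fcc = rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5),
                                c(0, .5, .5)),
                    bcc = rbind(c(0, 0, 0), c(.5, .5, .5)),
                    sc = rbind(c(0, 0, 0)))
    cells <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
    pts <- do.call(rbind, lapply(seq_len(nrow(basis)), function(k)
      (cells + matrix(basis[k, ], nrow(cells), 3, byrow = TRUE)) * a))
  }
  r <- sqrt(rowSums(pts^2))
  r <- r[r > 1e-9]
  r <- round(r, 8)
  shells <- sort(unique(r))
  # keep only shells safely inside the enumerated cluster
  shells <- shells[shells < 0.7 * max(r)]
  shells <- head(shells, spec$n_shells)
  z <- vapply(shells, function(s) sum(abs(r - s) < 1e-7), numeric(1))
  data.frame(radius = shells, z = z)
}

#' Analytic broadened-lattice target RDF
#'
#' \deqn{g(r) = \sum_k \frac{z_k}{4 \pi r^2 \rho}\,
#'   \mathcal{N}(r; r_k, \sigma)}
#' binned on the grid, so integrating \eqn{g \cdot 4 \pi r^2 \rho} over one
#' peak recovers that shell's coordination number exactly, independent of
#' \eqn{\sigma}.  Peaks much narrower than the bins (`sigma < delta / 3`)
#' trigger a warning: such targets produce large multiplier differences
#' between adjacent bins and violently varying bias forces.
#'
#' @param spec a [lattice_spec()].
#' @param density number density of the target crystal.
#' @param grid an [rdf_grid()].
#' @return an [rdf_histogram()].
#' @export
lattice_target <- function(spec, density, grid) {
  if (spec$sigma < grid$delta / 3)
    warning("shell width sigma < delta/3: target peaks are thinner than ",
            "the bins; expect noisy multiplier updates", call. = FALSE)
  shells <- lattice_shells(spec)
  keep <- shells$radius <= grid_upper(grid) + 4 * spec$sigma
  if (!any(keep)) stop("no lattice shell inside the grid range")
  shells <- shells[keep, ]
  r <- grid_centers(grid)
  g <- numeric(grid$b)
  for (k in seq_len(nrow(shells)))
    g <- g + shells$z[k] * dnorm(r, shells$radius[k], spec$sigma) /
      (4 * pi * r^2 * density)
  rdf_histogram(grid, g)
}

#' Target RDF from an unbiased reference simulation
#'
#' Runs the engine without bias and returns the time-averaged kernel RDF:
#' the standard way to create a target from a better (or differently
#' parametrised) model.  A drift check compares the mean pair energy of
#' the first and second half of the production run and warns when they
#' differ by more than three standard errors (possibly unequilibrated
#' input).
#'
#' @param frame equilibrated starting [md_frame()] (run [run_md()] first or
#'   pass `equil_steps`).
#' @param config an [engine_config()].
#' @param grid measurement [rdf_grid()].
#' @param weighting measurement [species_weighting()].
#' @param n_frames number of RDF samples to average.
#' @param sample_every steps between samples.
#' @param equil_steps unbiased steps to run before sampling starts.
#' @param seed optional seed.
#' @return an [rdf_histogram()]; attribute `run` holds the final `md_run`.
#' @export
reference_run_target <- function(frame, config, grid,
                                 weighting = species_weighting(),
                                 n_frames = 200, sample_every = 10,
                                 equil_steps = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vel <- init_velocities(frame, config$temperature, config)
  if (equil_steps > 0) {
    eq <- run_md(frame, config, equil_steps, velocities = vel)
    frame <- eq$frame
    vel <- eq$velocities
  }
  prod <- run_md(frame, config, n_frames * sample_every, velocities = vel,
                 grid = grid, weighting = weighting,
                 sample_every = sample_every,
                 trace_every = sample_every)
  e <- prod$trace$e_pair
  half <- seq_len(length(e) %/% 2)
  drift <- abs(mean(e[half]) - mean(e[-half]))
  se <- sd(e) / sqrt(length(e) / 2)
  if (is.finite(se) && se > 0 && drift > 3 * se)
    warning("pair-energy block averages drift (", signif(drift / se, 3),
            " SE): reference run may not be equilibrated", call. = FALSE)
  h <- prod$avg_rdf
  attr(h, "run") <- prod
  h
}
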