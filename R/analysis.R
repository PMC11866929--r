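#' Mean absolute error between two histograms
#'
#' Mean over bins of the absolute intensity difference; the headline
#' convergence diagnostic for RDF (and ADF) matching.
#'
#' @param a,b two [rdf_histogram()]s on one grid, or two `adf_histogram`s
#'   with identical binning.
#' @return non-negative scalar.
#' @export
mae <- function(a, b) {
  if (inherits(a, "rdf_histogram") && inherits(b, "rdf_histogram")) {
    if (!grids_equal(a$grid, b$grid)) stop("grid mismatch")
    return(mean(abs(a$values - b$values)))
  }
  if (inherits(a, "adf_histogram") && inherits(b, "adf_histogram")) {
    if (length(a$theta) != length(b$theta) ||
        max(abs(a$theta - b$theta)) > 1e-9)
      stop("ADF binning mismatch")
    return(mean(abs(a$density - b$density)))
  }
  stop("mae() expects two rdf_histogram or two adf_histogram objects")
}

#' Angular distribution function
#'
#' For every central atom (optionally restricted to one species), every
#' unordered pair of neighbours within `cutoff` contributes the angle it
#' subtends at the center.  The histogram covers (0, 180] degrees and is
#' normalised to unit integral (density per degree).
#'
#' @param frames an [md_frame()] or list of frames.
#' @param cutoff neighbour cutoff (length units, at most half the box).
#' @param species optional central/neighbour species label.
#' @param bin_width_deg angular bin width in degrees (default 2).
#' @return object of class `adf_histogram`: `theta` (bin centers, degrees),
#'   `density`, `cutoff`, `n_angles`.
#' @export
adf <- function(frames, cutoff, species = NULL, bin_width_deg = 2) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  breaks <- seq(0, 180, by = bin_width_deg)
  counts <- numeric(length(breaks) - 1)
  n_angles <- 0
  for (fr in frames) {
    stopifnot(inherits(fr, "md_frame"))
    if (cutoff > min(fr$box) / 2 + 1e-12)
      stop("cutoff exceeds half the smallest box length")
    sel <- if (is.null(species)) seq_len(nrow(fr$positions))
           else which(fr$species == species)
    if (length(sel) < 3) next
    d <- min_image_dist(fr$positions[sel, , drop = FALSE], fr$box)
    diag(d) <- Inf
    for (ii in seq_along(sel)) {
      nb <- which(d[ii, ] <= cutoff)
      if (length(nb) < 2) next
      v <- min_image_vec(fr$positions[sel, , drop = FALSE], ii, nb, fr$box)
      v <- v / sqrt(rowSums(v^2))
      cosang <- tcrossprod(v)
      ang <- acos(pmin(1, pmax(-1, cosang[upper.tri(cosang)]))) * 180 / pi
      h <- graphics::hist(ang, breaks = breaks, plot = FALSE,
                          right = TRUE, include.lowest = FALSE)
      counts <- counts + h$counts
      n_angles <- n_angles + length(ang)
    }
  }
  if (n_angles == 0 || sum(counts) == 0)
    stop("no atom has two neighbours within the cutoff; no angles defined")
  density <- counts / (sum(counts) * bin_width_deg)
  structure(list(theta = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 density = density, cutoff = cutoff,
                 bin_width_deg = bin_width_deg, n_angles = n_angles),
            class = "adf_histogram")
}

#' @export
print.adf_histogram <- function(x, ...) {
  cat(sprintf("ADF: %d angles, cutoff %g, peak at %g deg\n",
              x$n_angles, x$cutoff, x$theta[which.max(x$density)]))
  invisible(x)
}

# coerce supported trajectory containers to list(times, array T x N x 3,
# species)
as_traj_array <- function(traj, dt = NULL, species = NULL) {
  if (inherits(traj, c("md_run", "bias_run"))) {
    if (is.null(dt)) dt <- traj$config$dt
    species <- traj$frame$species
    traj <- traj$trajectory
  }
  stopifnot(is.list(traj), length(traj) >= 2)
  if (inherits(traj[[1]], "md_frame")) {
    if (!isTRUE(attr(traj[[1]], "unwrapped")))
      warning("trajectory frames are not marked unwrapped; MSD across ",
              "periodic boundaries will be wrong", call. = FALSE)
    pos <- lapply(traj, function(f) f$positions)
    times <- vapply(traj, function(f) f$time, numeric(1))
    species <- traj[[1]]$species
  } else {
    pos <- lapply(traj, function(s) s$positions)
    steps <- vapply(traj, function(s) s$step, numeric(1))
    if (is.null(dt)) dt <- 1
    times <- steps * dt
  }
  n <- nrow(pos[[1]])
  arr <- array(NA_real_, c(length(pos), n, 3))
  for (t in seq_along(pos)) arr[t, , ] <- pos[[t]]
  if (is.null(species)) species <- rep("A", n)
  list(times = times, arr = arr, species = species)
}

#' Mean squared displacement
#'
#' Time- and particle-averaged MSD over all lag times up to half the
#' trajectory length (every frame serves as an origin).  Coordinates must
#' be unwrapped.
#'
#' @param traj an `md_run`/`bias_run` object, a list of unwrapped
#'   [md_frame()]s, or a list of snapshots with `positions` and `step`.
#' @param dt time per step (taken from the run's config if available).
#' @param species optional species filter.
#' @param max_lag_frac largest lag as a fraction of the trajectory length.
#' @return data.frame with columns `time` (lag) and `msd`.
#' @export
msd <- function(traj, dt = NULL, species = NULL, max_lag_frac = 0.5) {
  ta <- as_traj_array(traj, dt)
  keep <- if (is.null(species)) seq_len(dim(ta$arr)[2])
          else which(ta$species == species)
  stopifnot(length(keep) >= 1)
  arr <- ta$arr[, keep, , drop = FALSE]
  nt <- dim(arr)[1]
  lags <- seq_len(max(1, floor(nt * max_lag_frac)))
  out <- vapply(lags, function(l) {
    d <- arr[(1 + l):nt, , , drop = FALSE] -
         arr[1:(nt - l), , , drop = FALSE]
    mean(apply(d^2, c(1, 2), sum))
  }, numeric(1))
  data.frame(time = (ta$times[1 + lags] - ta$times[1]), msd = out)
}

#' Diffusion coefficient from the Einstein relation
#'
#' Least-squares slope of MSD(t) over the fit window divided by `2 d`
#' (d = 3).  The result carries a `flagged` attribute set when the MSD is
#' not in the diffusive regime: linear fit R-squared below 0.9 or log-log
#' slope deviating from 1 by more than 0.25 (e.g. ballistic motion,
#' MSD proportional to t^2), with a warning.
#'
#' @inheritParams msd
#' @param fit_window fractions of the available lag range to fit over
#'   (default the second half).
#' @param d dimensionality (3).
#' @return scalar D with attributes `flagged`, `r_squared`,
#'   `loglog_slope`.
#' @export
diffusion_coefficient <- function(traj, dt = NULL, species = NULL,
                                  fit_window = c(0.5, 1), d = 3) {
  m <- msd(traj, dt = dt, species = species)
  tmax <- max(m$time)
  sel <- m$time >= fit_window[1] * tmax & m$time <= fit_window[2] * tmax
  stopifnot(sum(sel) >= 3)
  fit <- lm(msd ~ time, data = m[sel, ])
  slope <- coef(fit)[["time"]]
  dd <- max(0, slope) / (2 * d)
  if (max(m$msd) <= 1e-12) {
    # frozen configuration: no displacement at all
    out <- 0
    attr(out, "flagged") <- FALSE
    attr(out, "r_squared") <- NA_real_
    attr(out, "loglog_slope") <- NA_real_
    return(out)
  }
  r2 <- summary(fit)$r.squared
  pos <- m$msd > 0 & m$time > 0 & sel
  alpha <- if (sum(pos) >= 3)
    coef(lm(log(msd) ~ log(time), data = m[pos, ]))[[2]] else NA_real_
  flagged <- r2 < 0.9 || (is.finite(alpha) && abs(alpha - 1) > 0.25)
  if (flagged)
    warning(sprintf(
      "MSD not in the diffusive regime (R^2 = %.3f, log-log slope = %.2f)",
      r2, alpha), call. = FALSE)
  out <- dd
  attr(out, "flagged") <- flagged
  attr(out, "r_squared") <- r2
  attr(out, "loglog_slope") <- alpha
  out
}

#' Averaged local Steinhardt bond-order parameters
#'
#' Per-atom \eqn{\bar q_l}: the Steinhardt complex order parameters
#' \eqn{q_{lm}(i)} are averaged over the neighbourhood of `i` *including
#' `i` itself* before taking the rotation-invariant magnitude
#' \deqn{\bar q_l(i) = \sqrt{\tfrac{4\pi}{2l+1}
#'   \sum_{m=-l}^{l} |\bar q_{lm}(i)|^2}.}
#' This neighbourhood averaging sharpens the separation between liquid-
#' and solid-like environments compared with the bare \eqn{q_l}.
#'
#' @param frame an [md_frame()].
#' @param l even spherical-harmonic degree (6, 8, 10, ...).
#' @param neighbor_rule `list(cutoff = r)` for a distance cutoff or
#'   `list(knn = k)` for the k nearest neighbours.
#' @return object of class `boop_result` with per-atom `qbar` (NA for
#'   atoms without neighbours, which are reported via a warning), `l` and
#'   the rule used.
#' @export
qlbar <- function(frame, l, neighbor_rule = list(knn = 12)) {
  stopifnot(l >= 1, l == round(l))
  n <- nrow(frame$positions)
  d <- min_image_dist(frame$positions, frame$box)
  diag(d) <- Inf
  nb <- vector("list", n)
  if (!is.null(neighbor_rule$cutoff)) {
    rc <- neighbor_rule$cutoff
    if (rc > min(frame$box) / 2 + 1e-12)
      stop("cutoff exceeds half the smallest box length")
    for (i in seq_len(n)) nb[[i]] <- which(d[i, ] <= rc)
  } else if (!is.null(neighbor_rule$knn)) {
    k <- neighbor_rule$knn
    stopifnot(k >= 1, k <= n - 1)
    for (i in seq_len(n)) nb[[i]] <- order(d[i, ])[seq_len(k)]
  } else stop("neighbor_rule must give 'cutoff' or 'knn'")

  qlm <- matrix(NA_complex_, n, l + 1)  # columns m = 0..l
  for (i in seq_len(n)) {
    js <- nb[[i]]
    if (length(js) == 0) next
    v <- min_image_vec(frame$positions, i, js, frame$box)
    r <- sqrt(rowSums(v^2))
    qlm[i, ] <- colMeans(sph_harm_block(l, v[, 3] / r,
                                        atan2(v[, 2], v[, 1])))
  }
  qbar <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    js <- nb[[i]]
    if (length(js) == 0 || anyNA(qlm[i, ])) next
    group <- c(i, js[!vapply(js, function(j) anyNA(qlm[j, ]), logical(1))])
    qbar_lm <- colMeans(qlm[group, , drop = FALSE])
    s2 <- Mod(qbar_lm[1])^2 + 2 * sum(Mod(qbar_lm[-1])^2)
    qbar[i] <- sqrt(4 * pi / (2 * l + 1) * s2)
  }
  if (anyNA(qbar))
    warning(sum(is.na(qbar)), " isolated atom(s) excluded from qlbar",
            call. = FALSE)
  structure(list(qbar = qbar, l = as.integer(l),
                 neighbor_rule = neighbor_rule), class = "boop_result")
}

# Spherical harmonics Y_l^m for m = 0..l at (cos theta, phi), as a
# length(x) x (l+1) complex matrix.  Own upward recurrence for the
# associated Legendre functions (Condon-Shortley phase included); the
# m < 0 components follow from conjugation and are folded into the
# magnitude in qlbar().
sph_harm_block <- function(l, costh, phi) {
  x <- costh
  sx <- sqrt(pmax(0, 1 - x^2))
  nb <- length(x)
  p <- matrix(0, nb, l + 1)  # P_l^m for the target l, built by recurrence
  # diagonal terms P_m^m, then two-term upward recurrence in degree
  pmm <- rep(1, nb)
  for (m in 0:l) {
    if (m > 0) pmm <- -pmm * (2 * m - 1) * sx
    if (m == l) {
      p[, m + 1] <- pmm
    } else {
      pm1 <- x * (2 * m + 1) * pmm       # P_{m+1}^m
      if (m + 1 == l) {
        p[, m + 1] <- pm1
      } else {
        pa <- pmm; pb <- pm1
        for (ll in (m + 2):l) {
          pc <- ((2 * ll - 1) * x * pb - (ll + m - 1) * pa) / (ll - m)
          pa <- pb; pb <- pc
        }
        p[, m + 1] <- pb
      }
    }
  }
  m <- 0:l
  norm <- sqrt((2 * l + 1) / (4 * pi) *
                 exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
  y <- matrix(0i, nb, l + 1)
  for (mm in m)
    y[, mm + 1] <- norm[mm + 1] * p[, mm + 1] * exp(1i * mm * phi)
  y
}

#' @export
print.boop_result <- function(x, ...) {
  cat(sprintf("qbar_%d for %d atoms: median %.4f (range %.4f - %.4f)\n",
              x$l, length(x$qbar), stats::median(x$qbar, na.rm = TRUE),
              min(x$qbar, na.rm = TRUE), max(x$qbar, na.rm = TRUE)))
  invisible(x)
}

#' Classify atoms as liquid- or solid-like
#'
#' Label an atom solid when its \eqn{\bar q_l} exceeds the threshold.
#' Conventional presets: \eqn{\bar q_6 > 0.07} (water/ice, 3.5 A cutoff),
#' \eqn{\bar q_8 > 0.073} (rutile, 12 nearest neighbours) and
#' \eqn{\bar q_{10} > 0.085} (anatase, 12 nearest neighbours), available
#' as `boop_thresholds`.
#'
#' @param boop a [qlbar()] result.
#' @param threshold classification threshold in (0, 1).
#' @return factor of labels `liquid`/`solid` with attribute
#'   `solid_fraction` (NA atoms excluded).
#' @export
classify_phase <- function(boop, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  lab <- ifelse(boop$qbar > threshold, "solid", "liquid")
  out <- factor(lab, levels = c("liquid", "solid"))
  attr(out, "solid_fraction") <- mean(lab == "solid", na.rm = TRUE)
  out
}

#' Conventional bond-order classification presets
#'
#' Named thresholds for [classify_phase()]: `ice_q6` (0.07), `rutile_q8`
#' (0.073), `anatase_q10` (0.085).
#' @export
boop_thresholds <- c(ice_q6 = 0.07, rutile_q8 = 0.073, anatase_q10 = 0.085)
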