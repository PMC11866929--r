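#' RDF binning grid
#'
#' The common binning that every RDF histogram, target and Lagrange
#' multiplier vector lives on: `b` half-open bins `[r_lo + (k-1) delta,
#' r_lo + k delta)` with centers `r_k = r_lo + (k - 1/2) delta`.
#'
#' @param delta bin width (length units), `> 0`.
#' @param b number of bins, `>= 2`.
#' @param r_lo lower edge of the first bin (default 0).
#' @return an object of class `rdf_grid`.
#' @export
rdf_grid <- function(delta, b, r_lo = 0) {
  stopifnot(is.numeric(delta), length(delta) == 1, delta > 0,
            is.numeric(b), length(b) == 1, b >= 2, b == round(b),
            is.numeric(r_lo), length(r_lo) == 1, r_lo >= 0)
  structure(list(delta = as.numeric(delta), b = as.integer(b),
                 r_lo = as.numeric(r_lo)),
            class = "rdf_grid")
}

#' @export
print.rdf_grid <- function(x, ...) {
  cat(sprintf("RDF grid: %d bins of width %g on [%g, %g)\n",
              x$b, x$delta, x$r_lo, grid_upper(x)))
  invisible(x)
}

#' Bin centers of an RDF grid
#' @param grid an [rdf_grid()].
#' @return numeric vector of the `b` bin centers.
#' @export
grid_centers <- function(grid) {
  grid$r_lo + (seq_len(grid$b) - 0.5) * grid$delta
}

grid_upper <- function(grid) grid$r_lo + grid$b * grid$delta

grids_equal <- function(a, b, tol = 1e-9) {
  a$b == b$b && abs(a$delta - b$delta) <= tol * a$delta &&
    abs(a$r_lo - b$r_lo) <= tol * max(a$delta, 1)
}

#' Volume of a spherical RDF bin
#'
#' `(4 pi / 3) * ((r_b + delta/2)^3 - (r_b - delta/2)^3)` for the bin(s) `b`.
#'
#' @param grid an [rdf_grid()].
#' @param b bin index or vector of indices (1-based).
#' @return bin volume(s), strictly positive.
#' @export
bin_volume <- function(grid, b) {
  if (any(b < 1 | b > grid$b)) stop("bin index out of range [1, ", grid$b, "]")
  r <- grid_centers(grid)[b]
  (4 * pi / 3) * ((r + grid$delta / 2)^3 - (r - grid$delta / 2)^3)
}

bin_volumes <- function(grid) bin_volume(grid, seq_len(grid$b))

#' Split a pair distance over its two kernel bins
#'
#' The rectangular kernel of width `delta` centered at `r` overlaps the bin
#' containing `r` and one adjacent bin; the overlap areas are the fractions
#' with which the pair contributes to each bin.  A distance exactly on a bin
#' edge splits 0.5/0.5; exactly at a bin center contributes fully to that
#' bin.  Fraction spilling past either end of the grid is dropped and
#' reported in the `truncated` column.
#'
#' @param r pair distance; accepted while any part of the kernel overlaps
#'   the grid, i.e. within `[r_lo - delta/2, r_lo + b*delta + delta/2)`.
#' @param grid an [rdf_grid()].
#' @return data.frame with columns `bin`, `fraction`, and attribute
#'   `truncated` (dropped fraction, 0 unless the kernel leaves the grid).
#' @export
kernel_split <- function(r, grid) {
  stopifnot(length(r) == 1, is.finite(r))
  x <- (r - grid$r_lo) / grid$delta
  if (x < -0.5 || x >= grid$b + 0.5)
    stop("distance ", r, " outside the kernel-extended grid range [",
         grid$r_lo - grid$delta / 2, ", ",
         grid_upper(grid) + grid$delta / 2, ")")
  b <- floor(x)
  u <- x - b - 0.5
  b1 <- b + 1L                       # 1-based; 0 or b+1 at the grid ends
  b2 <- if (u >= 0) b1 + 1L else b1 - 1L
  bins <- c(b1, b2)
  fracs <- c(1 - abs(u), abs(u))
  valid <- bins >= 1L & bins <= grid$b
  out <- data.frame(bin = bins[valid], fraction = fracs[valid])
  attr(out, "truncated") <- sum(fracs[!valid])
  out
}

#' RDF histogram on a grid
#'
#' @param grid an [rdf_grid()].
#' @param values `b` non-negative finite intensities.
#' @return object of class `rdf_histogram` with fields `grid` and `values`.
#' @export
rdf_histogram <- function(grid, values) {
  stopifnot(inherits(grid, "rdf_grid"), length(values) == grid$b,
            all(is.finite(values)))
  if (any(values < -1e-12)) stop("RDF intensities must be non-negative")
  structure(list(grid = grid, values = as.numeric(values)),
            class = "rdf_histogram")
}

#' @export
print.rdf_histogram <- function(x, ...) {
  cat(sprintf("RDF histogram: %d bins on [%g, %g), max intensity %.4g\n",
              x$grid$b, x$grid$r_lo, grid_upper(x$grid), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.rdf_histogram <- function(x, ...) {
  data.frame(r = grid_centers(x$grid), g = x$values)
}

#' Mean of a set of RDF histograms on a shared grid
#' @param hists list of [rdf_histogram()] objects.
#' @return an [rdf_histogram()] with the unweighted per-bin mean.
#' @export
rdf_average <- function(hists) {
  stopifnot(length(hists) >= 1)
  g <- hists[[1]]$grid
  for (h in hists)
    if (!grids_equal(h$grid, g)) stop("histograms do not share one grid")
  vals <- rowMeans(vapply(hists, function(h) h$values, numeric(g$b)))
  rdf_histogram(g, vals)
}

#' Streaming accumulator for windowed RDF averages
#'
#' Collects instantaneous histograms sampled every `sample_every` steps and
#' returns their unweighted mean over the current window; `reset()` starts a
#' new window (the controller resets after every multiplier update).
#'
#' @param grid an [rdf_grid()].
#' @return a list of closures: `add(hist)`, `mean()`, `reset()`, `count()`.
#' @export
rdf_accumulator <- function(grid) {
  sum_v <- numeric(grid$b)
  n <- 0L
  list(
    add = function(hist) {
      if (!grids_equal(hist$grid, grid)) stop("histogram grid mismatch")
      sum_v <<- sum_v + hist$values
      n <<- n + 1L
      invisible(NULL)
    },
    mean = function() {
      if (n == 0L) stop("empty averaging window")
      rdf_histogram(grid, sum_v / n)
    },
    reset = function() {
      sum_v <<- numeric(grid$b)
      n <<- 0L
      invisible(NULL)
    },
    count = function() n
  )
}
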