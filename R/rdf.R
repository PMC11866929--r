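#' Instantaneous kernel RDF of a frame
#'
#' Each unordered pair within the grid range contributes the overlap
#' fractions of a rectangular kernel of width `delta` centered at its
#' minimum-image distance, scaled by the species-pair weight and the
#' single-species normalisation `2V / (N_eff^2 V_b)` (ordered-pair count
#' `N_eff^2 = N (N - 1)`, so an ideal gas averages to exactly 1 per bin).
#' Kernel mass spilling past either grid end is dropped and reported in the
#' `dropped` attribute of the result.
#'
#' @param frame an [md_frame()].
#' @param grid an [rdf_grid()]; its upper edge must not exceed half the
#'   smallest box length.
#' @param weighting a [species_weighting()] (default: identical species).
#' @return an [rdf_histogram()]; attribute `dropped` holds the truncated
#'   kernel mass.
#' @export
instantaneous_rdf <- function(frame, grid, weighting = species_weighting()) {
  check_grid_box(grid, frame$box)
  res <- resolve_weighting(frame, weighting)
  pref <- pair_prefactor(res, frame_volume(frame))
  out <- cpp_rdf_kernel(frame$positions, frame$box, res$codes,
                        grid$r_lo, grid$delta, grid$b,
                        pref, bin_volumes(grid))
  h <- rdf_histogram(grid, out$values)
  attr(h, "dropped") <- out$dropped
  h
}

#' Partial RDF restricted to one species pair
#'
#' `g_b^{alpha beta}` with the per-partial normalisation (ideal-gas
#' expectation 1), so that a weighted total RDF equals
#' `sum over alpha <= beta of w^{alpha beta} g^{alpha beta}`.
#'
#' @param frame an [md_frame()].
#' @param grid an [rdf_grid()].
#' @param pair character vector of the two species labels (may be equal).
#' @return an [rdf_histogram()].
#' @export
partial_rdf <- function(frame, grid, pair) {
  stopifnot(length(pair) == 2)
  lv <- sort(unique(frame$species))
  if (!all(pair %in% lv)) stop("unknown species label(s) in pair")
  w <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  w[pair[1], pair[2]] <- 1
  w[pair[2], pair[1]] <- 1
  weighting <- structure(list(mode = "frequency", species = lv,
                              pair_weights = w, scattering_factors = NULL),
                         class = "species_weighting")
  instantaneous_rdf(frame, grid, weighting)
}

check_grid_box <- function(grid, box) {
  # pairs up to half a kernel width beyond the grid still contribute
  if (grid_upper(grid) + grid$delta / 2 > min(box) / 2 + 1e-12)
    stop("grid range ", grid_upper(grid), " (+ half a kernel width)",
         " exceeds half the smallest box length (", min(box) / 2,
         "); minimum-image distances are not defined beyond that")
  invisible(TRUE)
}
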