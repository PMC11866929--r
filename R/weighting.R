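#' Species weighting for total RDFs
#'
#' How partial RDFs \eqn{g_b^{\alpha\beta}} are combined into the total RDF:
#' \describe{
#'   \item{identical}{all atoms treated as one species (single-species
#'     normalisation `2V / (N (N-1) V_b)`).}
#'   \item{frequency}{partials weighted by the relative pair frequency
#'     \eqn{w^{\alpha\beta} = (2 - \delta_{\alpha\beta})
#'     c_\alpha c_\beta}.}
#'   \item{xray}{X-ray weighting under the Warren-Krutter-Morningstar
#'     approximation with constant effective scattering factors, see
#'     [xray_pair_weights()].}
#' }
#' In the frequency and xray modes the unordered pair weights sum to 1, so
#' the ideal-gas expectation of the weighted total is 1 per bin.
#'
#' @param mode one of `"identical"`, `"frequency"`, `"xray"`.
#' @param species species labels (required unless mode is `"identical"`).
#' @param concentrations named number fractions, summing to 1 (frequency
#'   and xray modes; defaults to equal fractions).
#' @param scattering_factors named positive effective scattering factors
#'   (xray mode; defaults to [atomic_scattering_factors()]).
#' @return object of class `species_weighting` with a symmetric
#'   `pair_weights` matrix (NULL in identical mode).
#' @export
species_weighting <- function(mode = c("identical", "frequency", "xray"),
                              species = NULL, concentrations = NULL,
                              scattering_factors = NULL) {
  mode <- match.arg(mode)
  if (mode == "identical")
    return(structure(list(mode = "identical", species = NULL,
                          pair_weights = NULL, scattering_factors = NULL),
                     class = "species_weighting"))
  if (is.null(species)) {
    if (!is.null(concentrations)) species <- names(concentrations)
    else stop("species labels required for mode '", mode, "'")
  }
  if (is.null(concentrations))
    concentrations <- setNames(rep(1 / length(species), length(species)),
                               species)
  concentrations <- concentrations[species]
  if (any(is.na(concentrations)) || abs(sum(concentrations) - 1) > 1e-8)
    stop("concentrations must be named for every species and sum to 1")
  if (mode == "frequency") {
    w <- 2 * outer(concentrations, concentrations)
    diag(w) <- diag(w) / 2
    dimnames(w) <- list(species, species)
    return(structure(list(mode = "frequency", species = species,
                          pair_weights = w, scattering_factors = NULL),
                     class = "species_weighting"))
  }
  if (is.null(scattering_factors))
    scattering_factors <- atomic_scattering_factors(species)
  xray_pair_weights(concentrations, scattering_factors[species])
}

#' Packaged constant effective scattering factors
#'
#' Per-species effective X-ray scattering factors, constant in the
#' scattering vector (the Warren-Krutter-Morningstar approximation removes
#' the q dependence); the packaged defaults are the atomic numbers.
#' Arbitrary per-species values may be supplied instead wherever a
#' weighting is built.
#'
#' @param species character vector of species labels.
#' @return named numeric vector of scattering factors.
#' @export
atomic_scattering_factors <- function(species) {
  tab <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
           F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
           S = 16, Cl = 17, Ar = 18, K = 19, Ca = 20, Ti = 22, Fe = 26)
  f <- tab[species]
  if (any(is.na(f)))
    stop("no packaged scattering factor for species: ",
         paste(species[is.na(f)], collapse = ", "),
         " -- supply scattering_factors explicitly")
  setNames(as.numeric(f), species)
}

#' X-ray pair weights (Warren-Krutter-Morningstar)
#'
#' Weight of the unordered species pair \eqn{(\alpha, \beta)}:
#' \deqn{w^{\alpha\beta} = (2 - \delta_{\alpha\beta})
#'   \frac{c_\alpha c_\beta f_\alpha f_\beta}
#'        {(\sum_\gamma c_\gamma f_\gamma)^2}}
#' with concentrations \eqn{c} and constant effective scattering factors
#' \eqn{f}; the weights sum to 1.
#'
#' @param concentrations named number fractions summing to 1.
#' @param scattering_factors named positive factors for the same species.
#' @return a `species_weighting` in mode `"xray"`.
#' @export
xray_pair_weights <- function(concentrations, scattering_factors) {
  species <- names(concentrations)
  stopifnot(!is.null(species), length(scattering_factors) >= length(species))
  f <- scattering_factors[species]
  if (any(is.na(f)) || any(f <= 0))
    stop("scattering factors must be positive and named for every species")
  if (abs(sum(concentrations) - 1) > 1e-8)
    stop("concentrations must sum to 1")
  denom <- sum(concentrations * f)^2
  w <- 2 * outer(concentrations * f, concentrations * f) / denom
  diag(w) <- diag(w) / 2
  dimnames(w) <- list(species, species)
  structure(list(mode = "xray", species = species, pair_weights = w,
                 scattering_factors = setNames(as.numeric(f), species)),
            class = "species_weighting")
}

#' @export
print.species_weighting <- function(x, ...) {
  cat("Species weighting, mode:", x$mode, "\n")
  if (!is.null(x$pair_weights)) print(round(x$pair_weights, 4))
  invisible(x)
}

# Resolve frame species against a weighting; returns list(codes (0-based),
# weights matrix, counts, species levels).  In identical mode every atom is
# one species with weight 1.
resolve_weighting <- function(frame, weighting) {
  if (weighting$mode == "identical") {
    return(list(codes = integer(nrow(frame$positions)),
                w = matrix(1, 1, 1), counts = nrow(frame$positions),
                species = "X"))
  }
  lv <- weighting$species
  idx <- match(frame$species, lv)
  if (any(is.na(idx)))
    stop("unknown species label(s): ",
         paste(unique(frame$species[is.na(idx)]), collapse = ", "))
  counts <- vapply(seq_along(lv), function(k) sum(idx == k), integer(1))
  list(codes = idx - 1L, w = weighting$pair_weights, counts = counts,
       species = lv)
}

# S x S prefactor matrix: pair (i, j) of species (a, b) contributes
# pref[a, b] * fraction / V_bin to the histogram.  `volume` is the
# normalisation volume (frame volume for measurement, the stored reference
# volume for the bias).
pair_prefactor <- function(res, volume) {
  s <- length(res$counts)
  k <- matrix(0, s, s)
  for (a in seq_len(s)) for (b in seq_len(s)) {
    if (a == b) {
      k[a, b] <- if (res$counts[a] >= 2)
        2 / (res$counts[a] * (res$counts[a] - 1)) else 0
    } else {
      k[a, b] <- if (res$counts[a] >= 1 && res$counts[b] >= 1)
        1 / (res$counts[a] * res$counts[b]) else 0
    }
  }
  res$w * k * volume
}
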