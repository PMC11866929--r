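# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written against the definitions, not the
# package's code paths.

# uniform random frame in a cubic box
random_frame <- function(n, box_len, species = "A") {
  md_frame(matrix(runif(3 * n, 0, box_len), ncol = 3),
           box = rep(box_len, 3), species = species)
}

# minimum-image pair distances, straight from the definition
oracle_pair_distances <- function(frame) {
  pos <- frame$positions
  n <- nrow(pos)
  out <- numeric(0)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (k in seq_len(nrow(ij))) {
    d <- pos[ij[k, 1], ] - pos[ij[k, 2], ]
    d <- d - frame$box * round(d / frame$box)
    out <- c(out, sqrt(sum(d^2)))
  }
  out
}

# Brute-force kernel RDF for a single-species frame: for every pair, the
# exact overlap of the width-delta rectangle centred at r with every bin,
# by interval intersection (no reuse of the package's split logic).
oracle_rdf_identical <- function(frame, grid) {
  n <- nrow(frame$positions)
  v <- prod(frame$box)
  pref <- 2 * v / (n * (n - 1))
  edges <- grid$r_lo + (0:grid$b) * grid$delta
  centers <- grid$r_lo + ((1:grid$b) - 0.5) * grid$delta
  vb <- (4 * pi / 3) * ((centers + grid$delta / 2)^3 -
                          (centers - grid$delta / 2)^3)
  g <- numeric(grid$b)
  for (r in oracle_pair_distances(frame)) {
    # the kernel contributes while any part of it overlaps the grid
    if (r + grid$delta / 2 <= grid$r_lo ||
        r - grid$delta / 2 >= edges[grid$b + 1]) next
    lo <- r - grid$delta / 2
    hi <- r + grid$delta / 2
    for (b in seq_len(grid$b)) {
      ov <- max(0, min(hi, edges[b + 1]) - max(lo, edges[b]))
      if (ov > 0) g[b] <- g[b] + pref * (ov / grid$delta) / vb[b]
    }
  }
  g
}

# Averaged local bond-order parameter via pracma's associated Legendre
# functions (independent of the package's own recurrence).
oracle_qlbar <- function(frame, l, knn = NULL, cutoff = NULL) {
  pos <- frame$positions
  box <- frame$box
  n <- nrow(pos)
  dm <- matrix(0, n, n)
  for (d in 1:3) {
    dd <- outer(pos[, d], pos[, d], "-")
    dd <- dd - box[d] * round(dd / box[d])
    dm <- dm + dd^2
  }
  dm <- sqrt(dm)
  diag(dm) <- Inf
  nbrs <- lapply(seq_len(n), function(i) {
    if (!is.null(knn)) order(dm[i, ])[seq_len(knn)]
    else which(dm[i, ] <= cutoff)
  })
  mm <- 0:l
  nrm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - mm) /
                factorial(l + mm))
  qlm <- matrix(0i, n, l + 1)
  for (i in seq_len(n)) {
    js <- nbrs[[i]]
    dv <- pos[js, , drop = FALSE] -
      matrix(pos[i, ], length(js), 3, byrow = TRUE)
    for (d in 1:3) dv[, d] <- dv[, d] - box[d] * round(dv[, d] / box[d])
    r <- sqrt(rowSums(dv^2))
    ct <- dv[, 3] / r
    phi <- atan2(dv[, 2], dv[, 1])
    p <- pracma::legendre(l, ct)  # (l+1) x k, rows m = 0..l
    if (is.null(dim(p))) p <- matrix(p, ncol = 1)
    for (m in mm)
      qlm[i, m + 1] <- mean(nrm[m + 1] * p[m + 1, ] * exp(1i * m * phi))
  }
  vapply(seq_len(n), function(i) {
    grp <- c(i, nbrs[[i]])
    qb <- colMeans(qlm[grp, , drop = FALSE])
    sqrt(4 * pi / (2 * l + 1) * (Mod(qb[1])^2 + 2 * sum(Mod(qb[-1])^2)))
  }, numeric(1))
}

# energy-units LJ pair potential difference for well depths differing by
# d_eps (sigma = 1)
lj_du <- function(r, d_eps) 4 * d_eps * (r^-12 - r^-6)

# one shared long experiment for the acceptance tests (runs once per suite)
experiment_cache <- new.env(parent = emptyenv())
get_lj_experiment <- function() {
  if (is.null(experiment_cache$ex))
    experiment_cache$ex <- lj_matching_experiment(seed = 42)
  experiment_cache$ex
}
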