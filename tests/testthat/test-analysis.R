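test_that("mae is a symmetric metric on histograms", {
  g <- rdf_grid(0.1, 10)
  a <- rdf_histogram(g, rep(1, 10))
  b <- rdf_histogram(g, rep(1.1, 10))
  c3 <- rdf_histogram(g, runif(10))
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a, b), 0.1, tolerance = 1e-12)
  expect_equal(mae(a, b), mae(b, a))
  expect_lte(mae(a, c3), mae(a, b) + mae(b, c3) + 1e-12)
  expect_error(mae(a, rdf_histogram(rdf_grid(0.1, 12), rep(1, 12))),
               "mismatch")
})

test_that("the ADF localises simple coordination geometries", {
  box <- rep(30, 3)
  # three collinear atoms: a single 180-degree angle at the middle one
  fr <- md_frame(rbind(c(10, 10, 10), c(11, 10, 10), c(9, 10, 10)), box)
  a <- adf(fr, cutoff = 1.5)
  expect_equal(a$theta[which.max(a$density)], 179)
  # right-angle triad
  fr2 <- md_frame(rbind(c(10, 10, 10), c(11, 10, 10), c(10, 11, 10)), box)
  a2 <- adf(fr2, cutoff = 1.5)
  expect_gt(a2$density[a2$theta == 89], 0)
  # ideal tetrahedron: all angles at 109.47 degrees
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  fr3 <- md_frame(rbind(c(15, 15, 15), sweep(tet, 2, c(15, 15, 15), "+")),
                  box)
  a3 <- adf(fr3, cutoff = 1.5)
  peak <- a3$theta[which.max(a3$density)]
  expect_lt(abs(peak - 109.47), a3$bin_width_deg)
  # density integrates to one
  expect_equal(sum(a3$density) * a3$bin_width_deg, 1, tolerance = 1e-12)
  # no neighbours -> explicit error
  fr4 <- md_frame(rbind(c(1, 1, 1), c(20, 20, 20), c(8, 25, 3)), box)
  expect_error(adf(fr4, cutoff = 1.5), "no atom")
})

brownian_traj <- function(n, steps, d_true, dt = 0.05, every = 10) {
  pos <- matrix(50, n, 3)
  out <- list()
  for (t in seq_len(steps)) {
    pos <- pos + matrix(rnorm(3 * n, sd = sqrt(2 * d_true * dt)), n, 3)
    if (t %% every == 0)
      out[[length(out) + 1]] <- list(step = t, positions = pos,
                                     box = rep(100, 3))
  }
  out
}

test_that("diffusion coefficients recover the Einstein relation", {
  set.seed(81)
  # frozen particles diffuse with D = 0
  frozen <- lapply(1:20, function(t)
    list(step = t, positions = matrix(1:30, 10, 3), box = rep(50, 3)))
  d0 <- diffusion_coefficient(frozen, dt = 1)
  expect_equal(as.numeric(d0), 0)
  expect_false(attr(d0, "flagged"))
  # ballistic motion is flagged as non-diffusive
  v <- matrix(rnorm(30), 10, 3)
  ball <- lapply(1:40, function(t)
    list(step = t, positions = 50 + v * t, box = rep(1e4, 3)))
  expect_warning(db <- diffusion_coefficient(ball, dt = 1), "regime")
  expect_true(attr(db, "flagged"))
  expect_gt(attr(db, "loglog_slope"), 1.5)
  # overdamped free particles recover the input D within 10%
  tr <- brownian_traj(n = 400, steps = 3000, d_true = 0.7)
  dd <- diffusion_coefficient(tr, dt = 0.05)
  expect_false(attr(dd, "flagged"))
  expect_lt(abs(dd - 0.7) / 0.7, 0.1)
})

test_that("msd grows linearly for Brownian motion", {
  set.seed(82)
  tr <- brownian_traj(n = 200, steps = 1000, d_true = 0.5)
  m <- msd(tr, dt = 0.05)
  fit <- lm(msd ~ time, data = m)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(coef(fit)[["time"]], 6 * 0.5, tolerance = 0.1)
})

test_that("perfect-fcc qbar6 matches the independent oracle", {
  fr <- lattice_frame(3, density = 1.0)  # N = 108, periodic fcc
  b6 <- qlbar(fr, l = 6, neighbor_rule = list(knn = 12))
  # every atom shares one environment
  expect_lt(diff(range(b6$qbar)), 1e-10)
  o <- oracle_qlbar(fr, 6, knn = 12)
  expect_lt(max(abs(b6$qbar - o)), 1e-8)
  # the known fcc value
  expect_equal(b6$qbar[1], 0.5745, tolerance = 1e-3)
})

test_that("qlbar agrees with the oracle on disordered frames", {
  set.seed(83)
  for (k in 1:3) {
    fr <- random_frame(40, 10)
    for (l in c(4, 6)) {
      b <- qlbar(fr, l = l, neighbor_rule = list(knn = 8))
      o <- oracle_qlbar(fr, l, knn = 8)
      expect_lt(max(abs(b$qbar - o)), 1e-8)
    }
  }
  # and with a cutoff rule
  fr <- random_frame(60, 8)
  b <- qlbar(fr, l = 6, neighbor_rule = list(cutoff = 2))
  o <- oracle_qlbar(fr, 6, cutoff = 2)
  expect_lt(max(abs(b$qbar - o), na.rm = TRUE), 1e-8)
})

test_that("qlbar is invariant under global rotation", {
  set.seed(84)
  n <- 30
  pts <- matrix(runif(3 * n, 12, 18), n, 3)  # cluster far from the walls
  fr <- md_frame(pts, rep(30, 3))
  b1 <- qlbar(fr, 6, list(knn = 8))
  # random rotation about the cluster center
  ang <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
              c(sin(ang[2]), cos(ang[2]), 0), c(0, 0, 1))
  rot <- rx %*% rz
  ctr <- colMeans(pts)
  pts2 <- sweep(sweep(pts, 2, ctr) %*% t(rot), 2, ctr, "+")
  b2 <- qlbar(md_frame(pts2, rep(30, 3)), 6, list(knn = 8))
  expect_lt(max(abs(b1$qbar - b2$qbar)), 1e-10)
})

test_that("bond order separates lattice from gas and classifies phases", {
  set.seed(85)
  fcc <- lattice_frame(3, density = 1.0)
  gas <- random_frame(108, prod(fcc$box)^(1 / 3))
  q_fcc <- qlbar(fcc, 6, list(knn = 12))
  q_gas <- qlbar(gas, 6, list(knn = 12))
  expect_gt(stats::median(q_fcc$qbar), stats::median(q_gas$qbar))
  # zero overlap at the 0.35 threshold
  expect_gt(min(q_fcc$qbar), 0.35)
  expect_lt(max(q_gas$qbar), 0.35)
  cls_fcc <- classify_phase(q_fcc, 0.35)
  cls_gas <- classify_phase(q_gas, 0.35)
  expect_equal(attr(cls_fcc, "solid_fraction"), 1)
  expect_equal(attr(cls_gas, "solid_fraction"), 0)
  # all atoms below threshold -> 0% solid labelling survives NA handling
  expect_true(all(cls_gas == "liquid"))
  # conventional presets are exposed
  expect_equal(unname(boop_thresholds["ice_q6"]), 0.07)
  expect_equal(unname(boop_thresholds["rutile_q8"]), 0.073)
  expect_equal(unname(boop_thresholds["anatase_q10"]), 0.085)
})
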