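test_that("bin volumes follow the spherical-shell closed form", {
  g1 <- rdf_grid(delta = 1, b = 4)
  expect_equal(bin_volume(g1, 1), 4 * pi / 3, tolerance = 1e-12)
  g2 <- rdf_grid(delta = 0.2, b = 10)
  expect_equal(bin_volume(g2, 5), (4 * pi / 3) * (1.0^3 - 0.8^3),
               tolerance = 1e-12)
  # strictly increasing, strictly positive
  v <- bin_volume(g2, 1:10)
  expect_true(all(v > 0))
  expect_true(all(diff(v) > 0))
  # thin-shell limit: V_b -> 4 pi r_b^2 delta
  rb <- 2
  g3 <- rdf_grid(delta = 1e-3 * rb, b = 2500)
  b <- which.min(abs(grid_centers(g3) - rb))
  expect_equal(bin_volume(g3, b) / (4 * pi * grid_centers(g3)[b]^2 *
                                      g3$delta), 1, tolerance = 1e-3)
  expect_error(bin_volume(g1, 5), "out of range")
})

grid_upper_test <- function(g) g$r_lo + g$b * g$delta

test_that("kernel_split reproduces the rectangle-overlap geometry", {
  g <- rdf_grid(delta = 0.5, b = 10)
  # exactly at a bin center: full weight in that bin
  ks <- kernel_split(grid_centers(g)[4], g)
  expect_equal(ks$bin[1], 4)
  expect_equal(ks$fraction[1], 1)
  expect_equal(sum(ks$fraction), 1)
  # a quarter-width to the right: 0.75 / 0.25 with the upper neighbour
  ks <- kernel_split(grid_centers(g)[4] + g$delta / 4, g)
  expect_equal(ks$fraction[match(4, ks$bin)], 0.75)
  expect_equal(ks$fraction[match(5, ks$bin)], 0.25)
  # exactly on an edge: symmetric 0.5 / 0.5
  ks <- kernel_split(g$r_lo + 3 * g$delta, g)
  expect_setequal(ks$bin, c(3, 4))
  expect_equal(ks$fraction, c(0.5, 0.5))
  # fractions always sum to 1 unless truncated at the grid ends
  set.seed(7)
  for (r in runif(50, g$r_lo + g$delta, grid_upper_test(g) - g$delta)) {
    ks <- kernel_split(r, g)
    expect_equal(sum(ks$fraction) + attr(ks, "truncated"), 1)
  }
  # truncation at the last bin is flagged, not renormalised
  ks <- kernel_split(grid_upper_test(g) - g$delta / 8, g)
  expect_equal(attr(ks, "truncated"), 0.375)
  expect_equal(sum(ks$fraction), 0.625)
  # a pair just beyond the grid still feeds its in-grid kernel part back
  ks <- kernel_split(grid_upper_test(g) + g$delta / 4, g)
  expect_equal(ks$bin, 10)
  expect_equal(ks$fraction, 0.25)
  expect_equal(attr(ks, "truncated"), 0.75)
  expect_error(kernel_split(grid_upper_test(g) + g$delta, g), "outside")
})

test_that("a single pair at a bin center gives the closed-form intensity", {
  g <- rdf_grid(delta = 0.5, b = 10)
  box <- rep(11, 3)
  r <- grid_centers(g)[6]
  fr <- md_frame(rbind(c(1, 1, 1), c(1 + r, 1, 1)), box)
  h <- instantaneous_rdf(fr, g)
  expect_equal(h$values[6], 2 * prod(box) / (2 * 1 * bin_volume(g, 6)),
               tolerance = 1e-12)
  expect_equal(sum(h$values[-6]), 0)
})

test_that("kernel RDF equals the brute-force exact-overlap oracle", {
  set.seed(101)
  for (k in 1:5) {
    box_len <- runif(1, 6, 12)
    fr <- random_frame(sample(10:40, 1), box_len)
    g <- rdf_grid(delta = runif(1, 0.05, 0.3), b = sample(10:40, 1))
    if (g$r_lo + g$b * g$delta > box_len / 2) next
    h <- instantaneous_rdf(fr, g)
    o <- oracle_rdf_identical(fr, g)
    expect_lt(max(abs(h$values - o)) / max(o, 1e-300), 1e-12)
  }
})

test_that("ideal-gas frames normalise to 1 per bin", {
  set.seed(202)
  n <- 200
  box_len <- 8
  g <- rdf_grid(delta = 0.1, b = 35)
  hs <- lapply(1:40, function(i) instantaneous_rdf(
    random_frame(n, box_len), g))
  avg <- rdf_average(hs)
  # per-bin Poisson counting error of the mean of 40 frames
  sigma <- sqrt(2 * box_len^3 / (n * (n - 1) * bin_volume(g, 1:g$b))) /
    sqrt(40)
  expect_true(all(abs(avg$values - 1) < 4.5 * sigma))
  # away from the first bins (where the kernel's width-delta smearing
  # inflates the expectation by ~(delta^2/12)/r^2) the mean is 1
  expect_equal(mean(avg$values[4:35]), 1, tolerance = 0.01)
})

test_that("x-ray pair weights follow the WKM closed form", {
  # single species: everything in the only pair
  w1 <- xray_pair_weights(c(A = 1), c(A = 3.7))
  expect_equal(as.numeric(w1$pair_weights), 1)
  # two species, equal concentration and factor: (1/4, 1/2, 1/4)
  # (the matrix stores the unordered pair weight symmetrically)
  w2 <- xray_pair_weights(c(A = 0.5, B = 0.5), c(A = 2, B = 2))
  expect_equal(w2$pair_weights["A", "A"], 0.25)
  expect_equal(w2$pair_weights["A", "B"], 0.5)
  expect_equal(w2$pair_weights["B", "B"], 0.25)
  # water with atomic-number factors: OO weight (8/3)^2 / (10/3)^2 = 0.64
  ww <- xray_pair_weights(c(O = 1 / 3, H = 2 / 3), c(O = 8, H = 1))
  expect_equal(ww$pair_weights["O", "O"], 0.64, tolerance = 1e-12)
  expect_equal(sum(ww$pair_weights[upper.tri(ww$pair_weights, diag = TRUE)]),
               1, tolerance = 1e-12)
  expect_error(xray_pair_weights(c(A = 1), c(A = 0)), "positive")
  expect_error(xray_pair_weights(c(A = 0.7), c(A = 1)), "sum to 1")
})

test_that("weighted total RDF is the weighted sum of the partials", {
  set.seed(33)
  n <- 60
  fr <- random_frame(n, 9, species = sample(c("O", "H"), n, replace = TRUE,
                                            prob = c(1 / 3, 2 / 3)))
  g <- rdf_grid(delta = 0.15, b = 25)
  conc <- c(O = mean(fr$species == "O"), H = mean(fr$species == "H"))
  for (w in list(species_weighting("frequency", concentrations = conc),
                 xray_pair_weights(conc, c(O = 8, H = 1)))) {
    total <- instantaneous_rdf(fr, g, w)
    combo <- w$pair_weights["O", "O"] * partial_rdf(fr, g, c("O", "O"))$values +
      w$pair_weights["O", "H"] * partial_rdf(fr, g, c("O", "H"))$values +
      w$pair_weights["H", "H"] * partial_rdf(fr, g, c("H", "H"))$values
    expect_equal(total$values, combo, tolerance = 1e-12)
    wsum <- sum(w$pair_weights[upper.tri(w$pair_weights, diag = TRUE)])
    expect_equal(wsum, 1, tolerance = 1e-12)
  }
})

test_that("running averages behave like unweighted means", {
  g <- rdf_grid(delta = 0.2, b = 5)
  acc <- rdf_accumulator(g)
  h1 <- rdf_histogram(g, rep(2, 5))
  # constant stream reproduces itself
  acc$add(h1); acc$add(h1); acc$add(h1)
  expect_equal(acc$mean()$values, rep(2, 5))
  # (0, 2) averages to 1
  acc$reset()
  acc$add(rdf_histogram(g, rep(0, 5)))
  acc$add(rdf_histogram(g, rep(2, 5)))
  expect_equal(acc$mean()$values, rep(1, 5))
  acc$reset()
  expect_error(acc$mean(), "empty")
  # variance of a k-frame mean scales as 1/k (ideal-gas histograms)
  set.seed(404)
  one_mean <- function(k) {
    hs <- lapply(seq_len(k), function(i)
      instantaneous_rdf(random_frame(80, 7), rdf_grid(0.2, 15)))
    rdf_average(hs)$values[10]
  }
  v1 <- stats::var(replicate(40, one_mean(1)))
  v8 <- stats::var(replicate(40, one_mean(8)))
  expect_gt(v1 / v8, 4)   # expected ratio 8, generous band
  expect_lt(v1 / v8, 16)
})

test_that("configuration errors are rejected", {
  fr <- random_frame(20, 6)
  expect_error(instantaneous_rdf(fr, rdf_grid(0.1, 40)), "half")
  w <- species_weighting("frequency", concentrations = c(A = 0.5, B = 0.5))
  frB <- random_frame(20, 6, species = "C")
  expect_error(instantaneous_rdf(frB, rdf_grid(0.1, 25), w), "unknown species")
})
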