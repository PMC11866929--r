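make_bias_fixture <- function(seed = 5, n = 24, box_len = 9, b = 25,
                              delta = 0.15, lambda_sd = 1) {
  set.seed(seed)
  fr <- random_frame(n, box_len)
  g <- rdf_grid(delta = delta, b = b)
  st <- bias_state(g, ref_volume = prod(fr$box),
                   lambda_hat = rnorm(b, sd = lambda_sd))
  list(frame = fr, grid = g, state = st)
}

test_that("zero multipliers give zero energy, forces and virial", {
  fx <- make_bias_fixture()
  st0 <- bias_state(fx$grid, ref_volume = prod(fx$frame$box))
  expect_equal(bias_energy(fx$frame, st0), 0)
  expect_equal(max(abs(bias_forces(fx$frame, st0))), 0)
  vr <- bias_virial(fx$frame, st0)
  expect_equal(vr$total, 0)
  expect_equal(max(abs(vr$per_bin)), 0)
})

test_that("the bias is linear in the multipliers", {
  fx <- make_bias_fixture()
  e1 <- bias_energy(fx$frame, fx$state)
  st2 <- fx$state
  st2$lambda_hat <- 2 * st2$lambda_hat
  expect_equal(bias_energy(fx$frame, st2), 2 * e1, tolerance = 1e-12)
  expect_equal(bias_forces(fx$frame, st2),
               2 * bias_forces(fx$frame, fx$state), tolerance = 1e-12)
})

test_that("a single pair reproduces energy = lambda_b * g_b", {
  g <- rdf_grid(delta = 0.5, b = 10)
  box <- rep(11, 3)
  r <- grid_centers(g)[6]
  fr <- md_frame(rbind(c(1, 1, 1), c(1 + r, 1, 1)), box)
  lam <- numeric(10); lam[6] <- 1.7
  st <- bias_state(g, ref_volume = prod(box), lambda_hat = lam)
  g_b <- instantaneous_rdf(fr, g)$values[6]
  expect_equal(bias_energy(fr, st), 1.7 * g_b, tolerance = 1e-12)
})

test_that("bias forces are pairwise central and sum to zero", {
  for (seed in c(5, 6, 7)) {
    fx <- make_bias_fixture(seed)
    f <- bias_forces(fx$frame, fx$state)
    expect_lt(max(abs(colSums(f))), 1e-10 * max(abs(f), 1))
  }
})

test_that("forces match central finite differences of the energy", {
  fx <- make_bias_fixture(8)
  f <- bias_forces(fx$frame, fx$state)
  h <- 1e-6 * fx$grid$delta
  set.seed(9)
  for (k in 1:12) {
    i <- sample(nrow(fx$frame$positions), 1)
    d <- sample(3, 1)
    fp <- fx$frame; fp$positions[i, d] <- fp$positions[i, d] + h
    fm <- fx$frame; fm$positions[i, d] <- fm$positions[i, d] - h
    fd <- -(bias_energy(fp, fx$state) - bias_energy(fm, fx$state)) / (2 * h)
    expect_lt(abs(fd - f[i, d]), 1e-6 * max(abs(f)))
  }
})

test_that("virial equals the isotropic-scaling derivative; per-bin sums to total", {
  scale_frame <- function(fr, s)
    md_frame(fr$positions * s, fr$box * s, fr$species, wrap = FALSE)
  for (seed in c(5, 11)) {
    fx <- make_bias_fixture(seed)
    vr <- bias_virial(fx$frame, fx$state)
    expect_lt(abs(sum(vr$per_bin) - vr$total), 1e-10 * max(abs(vr$total), 1))
    h <- 1e-6
    dE <- (bias_energy(scale_frame(fx$frame, 1 + h), fx$state) -
             bias_energy(scale_frame(fx$frame, 1 - h), fx$state)) / (2 * h)
    expect_equal(vr$total, -dE / 3, tolerance = 1e-5)
  }
})

test_that("force terms are local to the two bins a pair's kernel touches", {
  g <- rdf_grid(delta = 0.5, b = 10)
  box <- rep(11, 3)
  fr <- md_frame(rbind(c(1, 1, 1), c(1 + 2.8, 1, 1)), box)  # bin 6 center
  # the pair sits at the center of bin 6 with u slightly + so kernel
  # touches bins 6 and 7; multipliers elsewhere must not matter
  fr$positions[2, 1] <- 1 + 2.85
  lam_far <- numeric(10); lam_far[c(1:4, 9:10)] <- rnorm(6)
  st_far <- bias_state(g, ref_volume = prod(box), lambda_hat = lam_far)
  expect_equal(max(abs(bias_forces(fr, st_far))), 0)
  lam_near <- numeric(10); lam_near[6:7] <- c(1, -1)
  st_near <- bias_state(g, ref_volume = prod(box), lambda_hat = lam_near)
  expect_gt(max(abs(bias_forces(fr, st_near))), 0)
})

test_that("NVE with a small fixed bias conserves total energy", {
  set.seed(21)
  frame <- lattice_frame(3, density = 0.8)  # N = 108
  g <- rdf_grid(delta = 0.1, b = 20)
  st <- bias_state(g, ref_volume = prod(frame$box),
                   lambda_hat = 0.05 * sin(seq(0, pi, length.out = 20)))
  cfg <- engine_config(temperature = 0.8, shift = "force", dt = 0.002)
  r <- run_md(frame, cfg, 2000, bias = st, trace_every = 50, seed = 31)
  n <- nrow(frame$positions)
  etot <- r$trace$e_pair + r$trace$e_bias +
    1.5 * n * r$trace$temperature
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 5e-3)
})

test_that("a disabled bias refuses evaluation", {
  fx <- make_bias_fixture()
  st <- fx$state; st$enabled <- FALSE
  expect_error(bias_energy(fx$frame, st), "disabled")
})
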