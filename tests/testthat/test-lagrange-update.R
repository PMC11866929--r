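grid5 <- rdf_grid(delta = 0.2, b = 5)
hist5 <- function(v) rdf_histogram(grid5, v)

test_that("the objective gradient is target minus measured average", {
  a <- hist5(c(1, 2, 3, 2, 1))
  b <- hist5(c(1, 1, 1, 1, 1))
  expect_equal(rdf_gradient(a, a), rep(0, 5))
  expect_equal(rdf_gradient(hist5(c(2, 1, 1, 1, 1)), b),
               c(1, 0, 0, 0, 0))
  expect_equal(rdf_gradient(a, b), -rdf_gradient(b, a))
  expect_error(rdf_gradient(a, rdf_histogram(rdf_grid(0.2, 6), rep(1, 6))),
               "mismatch")
})

test_that("kappa damping follows the sign of the per-bin virial", {
  sch_n <- bias_schedule(gamma = 1, kappa_mode = "none")
  expect_equal(kappa_vector(c(-1, 0, 2), sch_n), c(1, 1, 1))
  sch_c <- bias_schedule(gamma = 1, kappa_mode = "anti_contraction",
                         kappa_factor = 0.25)
  expect_equal(kappa_vector(c(-1, 0, 2), sch_c), c(0.25, 1, 1))
  sch_e <- bias_schedule(gamma = 1, kappa_mode = "anti_expansion",
                         kappa_factor = 0.25)
  expect_equal(kappa_vector(c(-1, 0, 2), sch_e), c(1, 1, 0.25))
  # the damping factor only ever takes the two values {factor, 1}
  expect_true(all(kappa_vector(rnorm(50), sch_c) %in% c(0.25, 1)))
})

make_cstate <- function(target, lambda0 = rep(0, 5)) {
  st <- bias_state(grid5, ref_volume = 1000, lambda_hat = lambda0)
  controller_state(st, target)
}

absorb1 <- function(cs, avg, vpb = rep(0, 5)) {
  rdfbias:::controller_absorb(cs, avg, vpb, 1)
}

test_that("the multiplier update is l1-normalised to gamma * kT", {
  target <- hist5(c(1, 1, 1.2, 1, 0.8))
  sch <- bias_schedule(gamma = 3)
  cs <- absorb1(make_cstate(target), c(1, 1, 1, 1, 1))
  cs2 <- update_multipliers(cs, sch, temperature = 0.7)
  expect_equal(sum(abs(cs2$bias$lambda_hat)), 3 * 0.7, tolerance = 1e-12)
  # and with kappa = 1 this holds exactly for any gradient
  set.seed(12)
  for (k in 1:5) {
    cs <- absorb1(make_cstate(target), runif(5, 0.5, 1.5))
    cs2 <- update_multipliers(cs, sch, temperature = 1)
    expect_equal(sum(abs(cs2$bias$lambda_hat)), 3, tolerance = 1e-12)
  }
})

test_that("update splits the budget by the normalised gradient", {
  # Delta g = (+0.2, -0.2) with gamma = 1: changes (-1/2, +1/2) * kT
  target <- hist5(c(1.2, 0.8, 1, 1, 1))
  cs <- absorb1(make_cstate(target), c(1, 1, 1, 1, 1))
  cs2 <- update_multipliers(cs, bias_schedule(gamma = 1), temperature = 1)
  expect_equal(cs2$bias$lambda_hat, c(-0.5, 0.5, 0, 0, 0))
  # sign: where the target exceeds the average the multiplier decreases,
  # lowering the bias energy of configurations with more intensity there
  expect_lt(cs2$bias$lambda_hat[1], 0)
  expect_gt(cs2$bias$lambda_hat[2], 0)
})

test_that("a perfectly matched window is a logged no-op", {
  target <- hist5(c(1, 1, 1, 1, 1))
  cs <- absorb1(make_cstate(target, lambda0 = c(1, 2, 3, 4, 5)),
                c(1, 1, 1, 1, 1))
  expect_message(cs2 <- update_multipliers(cs, bias_schedule(gamma = 2)),
                 "no-op")
  expect_equal(cs2$bias$lambda_hat, c(1, 2, 3, 4, 5))
  expect_equal(length(cs2$mae_history), 1)
  expect_equal(cs2$mae_history[1], 0)
})

test_that("window averages reset after every update", {
  target <- hist5(c(1.5, 1, 1, 1, 1))
  cs <- absorb1(make_cstate(target), c(1, 1, 1, 1, 1))
  cs2 <- update_multipliers(cs, bias_schedule(gamma = 1))
  expect_equal(cs2$acc$count(), 0)
  expect_equal(cs2$vpb_n, 0L)
  expect_error(cs2$acc$mean(), "empty")
  expect_equal(cs2$update_count, 1L)
})

test_that("kappa damping reweights but keeps the sign of each update", {
  target <- hist5(c(1.2, 0.8, 1, 1, 1))
  sch <- bias_schedule(gamma = 1, kappa_mode = "anti_contraction",
                       kappa_factor = 0.25)
  cs <- absorb1(make_cstate(target), c(1, 1, 1, 1, 1),
                vpb = c(-1, 1, 0, 0, 0))
  cs2 <- update_multipliers(cs, sch)
  expect_equal(cs2$bias$lambda_hat, c(-0.5 * 0.25, 0.5, 0, 0, 0))
})

test_that("schedules validate their cadence and presets", {
  # the liquid-matching cadence: sample every 10, average 100, gamma 10
  s1 <- bias_schedule(gamma = 10, sample_every = 10, window = 100)
  expect_equal(s1$window %/% s1$sample_every, 10)
  # the ice cadence: sample 10, window 1000, equilibrate 100 (update
  # cycle 1100 steps), gamma 2.5
  s2 <- bias_schedule(gamma = 2.5, sample_every = 10, window = 1000,
                      equilibrate = 100)
  expect_equal(s2$window + s2$equilibrate, 1100)
  expect_error(bias_schedule(gamma = -1), "gamma")
  expect_error(bias_schedule(gamma = 1, sample_every = 30, window = 100))
  expect_error(bias_schedule(gamma = 1, kappa_factor = 0))
})

test_that("a zero-multiplier bias reproduces the unbiased trajectory", {
  frame <- lattice_frame(3, density = 0.8)
  cfg <- engine_config(temperature = 1, damp = 1)
  g <- rdf_grid(delta = 0.1, b = 15)
  st0 <- bias_state(g, ref_volume = prod(frame$box))  # lambda = 0
  r_bias <- run_md(frame, cfg, 200, bias = st0, seed = 77)
  r_plain <- run_md(frame, cfg, 200, seed = 77)
  expect_identical(r_bias$frame$positions, r_plain$frame$positions)
  expect_identical(r_bias$velocities, r_plain$velocities)
})

test_that("thin bins trigger the statistics guidance warning", {
  frame <- lattice_frame(3, density = 0.8)
  sch <- bias_schedule(gamma = 1, sample_every = 10, window = 10)
  expect_warning(
    rdfbias:::check_bin_statistics(frame, rdf_grid(0.02, 100), sch),
    "pair count")
})
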