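# the generators must reproduce the statistical structure the downstream
# analysis assumes; closed forms and simple oracles fix the expectations

test_that("Langevin sampling of a harmonic well satisfies equipartition", {
  k <- 10
  tbl <- suppressMessages(langevin_sample(
    harmonic_potential(k), langevin_spec(330, 1, 0.002, 2e5, seed = 3),
    initial = 0))
  # kB T / k = 0.274 Å^2 at 330 K
  expect_equal(var(tbl$x), thermo_state(330)$kt / k, tolerance = 0.05)
})

test_that("zero-temperature Langevin dynamics is monotone gradient descent", {
  tbl <- suppressMessages(langevin_sample(
    harmonic_potential(10), langevin_spec(0, 1, 0.01, 200, seed = 1),
    initial = 1))
  expect_true(all(diff(tbl$x) < 0))
  expect_lt(tbl$x[200], 1e-4)
})

test_that("generators are pure functions of their seed", {
  spec <- langevin_spec(330, 1, 0.002, 5000, seed = 99)
  a <- suppressMessages(langevin_sample(harmonic_potential(5), spec, 0))
  b <- suppressMessages(langevin_sample(harmonic_potential(5), spec, 0))
  expect_identical(a$x, b$x)
  t1 <- suppressMessages(brownian_trajectory(1, 10, 50, seed = 7))
  t2 <- suppressMessages(brownian_trajectory(1, 10, 50, seed = 7))
  expect_identical(t1$x, t2$x)
  r1 <- suppressMessages(two_state_residence_series(10, 10, 20, seed = 5))
  r2 <- suppressMessages(two_state_residence_series(10, 10, 20, seed = 5))
  expect_identical(r1$bound, r2$bound)
})

test_that("custom R potentials integrate through the same contract", {
  # same harmonic well through the R path
  pot <- custom_potential(function(x) 0.5 * 10 * x^2, function(x) 10 * x,
                          dim = 1)
  tbl <- suppressMessages(langevin_sample(
    pot, langevin_spec(330, 1, 0.002, 2e4, seed = 3), initial = 0))
  expect_equal(var(tbl$x), thermo_state(330)$kt / 10, tolerance = 0.15)
  expect_error(
    suppressMessages(langevin_sample(
      custom_potential(function(x) x, function(x) NaN, dim = 1),
      langevin_spec(n_steps = 10), 0)),
    "finite")
})

test_that("free relative diffusion in a sphere samples the r^2 shell law", {
  tbl <- suppressMessages(sample_radial_pair(
    flat_sphere_potential(8),
    langevin_spec(330, 1, 0.001, 4e5, seed = 11, stride = 40)))
  # decimate to near-independent samples, KS against F(d) = (d/R)^3
  d <- tbl$d[seq(1, nrow(tbl), by = 10)]
  ks <- stats::ks.test(d, function(q) pmin(1, pmax(0, (q / 8)^3)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a deep basin dominates the sampled distance distribution", {
  pot <- pair_potential(tibble::tibble(center = 2.9, depth = 25, width = 0.15),
                        charge_product = 0, tail_on_window = NULL)
  tbl <- suppressMessages(sample_radial_pair(
    pot, langevin_spec(330, 1, 2e-4, 2e5, seed = 2), initial_r = 2.9))
  hx <- seq(2, 4, by = 0.02)
  h <- hist(tbl$d[tbl$d < 4], breaks = hx, plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)] - 2.9), 0.05)
})

test_that("hard upper walls confine the sampled separation", {
  pot <- preset_pair_potential("ideal")
  wall <- list(wall_spec("d", 15, kappa = 20, side = "upper"))
  # unbiased dynamics: penetration is Boltzmann in the quadratic wall
  pen <- sqrt(thermo_state(330)$kt / (2 * 20))
  tbl <- suppressMessages(langevin_sample(
    pot, langevin_spec(330, 0.5, 5e-4, 2e5, seed = 4),
    initial = c(5, 0, 0), walls = wall))
  # extreme over 2e5 correlated samples: 5 sigma is the sample-max bound
  expect_lt(max(tbl$d), 15 + 5 * pen)
  expect_gt(mean(tbl$d > 15), 0) # the wall region is actually probed
  # under OPES the effective wall temperature is scaled by the bias factor
  run <- suppressMessages(opes_run(
    pot, opes_params(30, 500, 0.1), wall,
    langevin_spec(330, 0.5, 5e-4, 2e5, seed = 4), initial = c(5, 0, 0)))
  gamma <- run$bias_state$gamma
  expect_lt(max(run$table$d), 15 + 5 * sqrt(gamma) * pen)
})

test_that("Brownian steps have the converted variance and degenerate limits", {
  # 2.4e-5 cm^2/s -> 0.24 Å^2/ps -> per-axis increment sd sqrt(2*0.24*dt)
  tr <- suppressMessages(brownian_trajectory(2.4, 200, 100, timestep = 0.5,
                                             seed = 1))
  arr <- positions_array(tr)
  inc <- arr[, 1, -1] - arr[, 1, -dim(arr)[3]]
  expect_equal(sd(inc), sqrt(2 * 0.24 * 0.5), tolerance = 0.03)
  tr0 <- suppressMessages(brownian_trajectory(0, 5, 20, seed = 1))
  a0 <- positions_array(tr0)
  expect_equal(a0[, , 1], a0[, , 21])
})

test_that("residence series dwell times follow the exponential law", {
  rs <- suppressMessages(two_state_residence_series(100, 50, 1e4, seed = 8))
  dw <- attr(rs, "dwell")
  bound <- dw$duration[dw$state]
  se <- sd(bound) / sqrt(length(bound))
  expect_lt(abs(mean(bound) - 100), 3 * se)
  # single event: exactly one bound interval
  r1 <- suppressMessages(two_state_residence_series(10, 10, 1, seed = 1))
  runs <- rle(r1$bound)
  expect_equal(sum(runs$values), 1)
  # symmetric rates: half the time bound
  rsym <- suppressMessages(two_state_residence_series(50, 50, 5e3, seed = 9))
  expect_equal(mean(rsym$bound), 0.5, tolerance = 0.05)
})

test_that("layered interface frames place particles as declared", {
  layers <- tibble::tibble(z = c(2, 6), species = "O", count = 500,
                           width = c(0.1, 0.1))
  tr <- suppressMessages(layered_interface_frames(layers, n_frames = 2,
                                                  seed = 3))
  h <- hist(tr$z, breaks = seq(0, 10, 0.25), plot = FALSE)
  pk <- h$mids[which.max(h$counts)]
  expect_lt(abs(pk - 2) %% 4, 0.25 + 1e-9) # peak at one of the layers
  n1 <- sum(tr$z < 4)
  n2 <- sum(tr$z >= 4)
  expect_lt(abs(n1 - n2) / (n1 + n2), 0.05) # equal integrated weight
  tr0 <- suppressMessages(layered_interface_frames(
    tibble::tibble(z = 2, species = "O", count = 50, width = 0), seed = 1))
  expect_true(all(tr0$z == 2))
})

test_that("committee force sets encode the requested disagreement", {
  f0 <- matrix(rnorm(30), 10, 3)
  same <- suppressMessages(committee_force_sets(list(f0), 4, 0, seed = 2))
  expect_identical(same[[1]][[1]], same[[4]][[1]])
  expect_equal(committee_deviation(same)$deviation, 0)
  # one config much noisier than the rest maximises the deviation
  fs <- suppressMessages(committee_force_sets(list(f0, f0, f0), 4,
                                              c(0.01, 0.5, 0.01), seed = 3))
  dev <- committee_deviation(fs)
  expect_equal(which.max(dev$deviation), 2L)
})

test_that("committee deviation scale matches an independent Monte-Carlo mean", {
  # statistic: max over atoms of rms deviation about the committee mean;
  # oracle: direct simulation of the same max-of-rms statistic with rnorm
  scale <- 0.3
  n_atoms <- 20
  f0 <- matrix(0, n_atoms, 3)
  set.seed(1)
  stat <- replicate(300, {
    fs <- committee_force_sets(list(f0), 4, scale,
                               seed = sample.int(1e6, 1))
    committee_deviation(fs)$deviation
  })
  set.seed(42)
  oracle <- replicate(2000, {
    noise <- array(rnorm(4 * n_atoms * 3, sd = scale), c(4, n_atoms, 3))
    mu <- apply(noise, c(2, 3), mean)
    dev2 <- sapply(seq_len(n_atoms), function(i) {
      mean(rowSums((noise[, i, ] - matrix(mu[i, ], 4, 3, byrow = TRUE))^2))
    })
    max(sqrt(dev2))
  })
  expect_equal(mean(stat), mean(oracle), tolerance = 0.03)
})

test_that("the protonation landscape has the constructed topology", {
  fld <- proton_transfer_surface()
  n <- seq(0, 1, by = 0.01)
  for (d in c(2.5, 3, 5, 7)) {
    f <- fld$f(d, n)
    # valleys exactly at the ends
    expect_equal(which.min(f[n < 0.5]), 1L)
    expect_true(f[length(f)] < max(f))
    expect_equal(fld$grad(d, 0)$dn, 0, tolerance = 1e-12)
    expect_equal(fld$grad(d, 1)$dn, 0, tolerance = 1e-12)
  }
  barrier_at <- function(d) {
    f <- fld$f(d, n)
    max(f) - f[1]
  }
  expect_lt(barrier_at(3), barrier_at(7))
  expect_gt(barrier_at(7), 40)
  # analytic gradient against central finite differences
  set.seed(5)
  for (i in 1:20) {
    d <- runif(1, 2, 8)
    nn <- runif(1, 0.05, 0.95)
    h <- 1e-6
    g <- fld$grad(d, nn)
    fd_d <- (fld$f(d + h, nn) - fld$f(d - h, nn)) / (2 * h)
    fd_n <- (fld$f(d, nn + h) - fld$f(d, nn - h)) / (2 * h)
    expect_equal(g$dd, fd_d, tolerance = 1e-6)
    expect_equal(g$dn, fd_n, tolerance = 1e-6)
  }
})

test_that("model potential gradients match finite differences", {
  for (nm in c("caco3_lr", "caco3_sr")) {
    pot <- preset_pair_potential(nm)
    for (r in c(2.5, 3.2, 4.05, 5.5, 6.2, 9, 12.5)) {
      h <- 1e-6
      fd <- (pair_potential_energy(pot, r + h) -
             pair_potential_energy(pot, r - h)) / (2 * h)
      expect_equal(potential_gradient(pot, c(r, 0, 0))[1], fd,
                   tolerance = 1e-4)
    }
  }
})
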