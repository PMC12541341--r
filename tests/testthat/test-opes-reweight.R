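test_that("harmonic walls are one-sided, quadratic and C1 at the wall", {
  w <- wall_spec("d", 15, kappa = 20, side = "upper")
  expect_equal(harmonic_wall_energy(14, w), 0)
  expect_equal(harmonic_wall_energy(16, w), 20) # kappa * (1 Å)^2
  h <- 1e-7
  dplus <- (harmonic_wall_energy(15 + h, w) - harmonic_wall_energy(15, w)) / h
  dminus <- (harmonic_wall_energy(15, w) - harmonic_wall_energy(15 - h, w)) / h
  expect_equal(dplus, 0, tolerance = 1e-5)
  expect_equal(dminus, 0, tolerance = 1e-5)
  wl <- wall_spec("d", 3, kappa = 10, side = "lower")
  expect_equal(harmonic_wall_energy(2, wl), 10)
  expect_equal(harmonic_wall_energy(4, wl), 0)
})

test_that("OPES parameters are validated", {
  expect_error(opes_params(barrier = -1), "barrier")
  expect_error(opes_params(bandwidth = 0), "bandwidth")
  expect_error(opes_params(bias_factor = 0.5), "bias_factor")
  expect_error(wall_spec("d", 1, kappa = -1), "kappa")
})

test_that("on a flat landscape the converged OPES bias is flat", {
  walls <- list(wall_spec("x", 4, 20, "upper"), wall_spec("x", -4, 20, "lower"))
  run <- suppressMessages(opes_run(
    harmonic_potential(1e-9), opes_params(30, 500, 0.8), walls,
    langevin_spec(330, 1, 0.002, 2e6, seed = 2, stride = 20),
    initial = 0, grid_range = c(-4, 4)))
  g <- run$bias_state$grid
  inner <- g$s > -3 & g$s < 3
  expect_lt(diff(range(g$bias[inner])), 0.5)
})

test_that("the deposited bias is bounded by the barrier parameter", {
  # structured, flat and radial systems; bound (1 - 1/gamma) * barrier <= barrier
  systems <- list(
    suppressMessages(opes_run(
      barrier_double_well(12, 0.25, 2, 100), opes_params(30, 500, 0.15),
      list(), langevin_spec(330, 1, 0.002, 2e5, seed = 3),
      initial = -2, grid_range = c(-3.5, 3.5))),
    suppressMessages(opes_run(
      preset_pair_potential("caco3_sr"), opes_params(30, 500, 0.1),
      list(wall_spec("d", 15, 20, "upper")),
      langevin_spec(330, 0.2, 4e-4, 2e5, seed = 4)))
  )
  for (run in systems) {
    expect_lte(max(run$table$bias), 30 + 1e-9)
    expect_lte(max(run$bias_state$grid$bias),
               run$bias_state$max_bias_bound + 1e-9)
  }
})

test_that("OPES turns a rare barrier crossing into routine transitions", {
  # 12 kJ/mol Gaussian barrier between flat wells; 150 K makes the unbiased
  # crossing rare within the run length while the biased run crosses freely
  count_trans <- function(x, a = 1) {
    s <- ifelse(x > a, 1L, ifelse(x < -a, -1L, NA))
    s <- s[!is.na(s)]
    sum(diff(s) != 0)
  }
  dw <- barrier_double_well(height = 12, width = 0.25, halfwidth = 2,
                            k_conf = 100)
  sp <- langevin_spec(150, 2, 0.002, 1e6, seed = 3, stride = 10)
  unb <- suppressMessages(langevin_sample(dw, sp, initial = -2))
  bia <- suppressMessages(opes_run(dw, opes_params(30, 500, 0.15), list(), sp,
                                   initial = -2, grid_range = c(-3.5, 3.5)))
  expect_lt(count_trans(unb$x), 2)
  expect_gte(count_trans(bia$table$x), 20)
})

test_that("reweighting reduces to the plain histogram when unbiased", {
  set.seed(9)
  th <- thermo_state(330)
  s <- rnorm(20000)
  tb <- cv_table(time = seq_along(s), s = s, bias = 0)
  f <- suppressMessages(reweight_fes(tb, "s", list(s = c(-3, 3, 30)), th))
  h <- hist(s[abs(s) < 3], breaks = seq(-3, 3, by = 0.2), plot = FALSE)
  ref <- -th$kt * log(h$counts)
  ref <- ref - min(ref[is.finite(ref)])
  expect_equal(f$free_energy[f$visited], ref[f$visited], tolerance = 1e-9)
})

test_that("reweighting is gauge invariant in the bias", {
  tb <- random_cv_table(seed = 2, n = 2000)
  f1 <- suppressMessages(reweight_fes(tb, "d", list(d = c(2, 10, 16)), th330))
  tb$bias <- tb$bias + 123.4
  f2 <- suppressMessages(reweight_fes(tb, "d", list(d = c(2, 10, 16)), th330))
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-9)
})

test_that("two-sample reweighting reproduces the hand-computed difference", {
  th <- thermo_state(330)
  tb <- cv_table(time = c(0, 1), s = c(0, 1),
                 bias = c(0, th$kt * log(2)))
  f <- suppressWarnings(suppressMessages(
    reweight_fes(tb, "s", list(s = c(-0.5, 1.5, 2)), th)))
  expect_equal(f$free_energy[1] - f$free_energy[2], th$kt * log(2),
               tolerance = 1e-12)
  expect_equal(f$free_energy[1] - f$free_energy[2], 1.902, tolerance = 1e-3)
})

test_that("degenerate single-bin reweighting warns", {
  tb <- cv_table(time = 1:5, s = rep(0.5, 5), bias = 0)
  expect_warning(suppressMessages(reweight_fes(tb, "s", list(s = c(0, 1, 1)))),
                 "degenerate|single bin")
})

test_that("identical runs average with zero spread; formatter applies", {
  tb <- random_cv_table(seed = 3, n = 3000)
  out <- suppressMessages(multi_run_fes(list(tb, tb, tb, tb), "d",
                                        list(d = c(2, 10, 16)), th330))
  expect_true(all(out$se[out$visited & out$n_runs == 4] == 0))
  expect_warning(suppressMessages(multi_run_fes(list(tb), "d",
                                                list(d = c(2, 10, 16)), th330)),
                 "fewer than 2")
})

test_that("averaging independent runs reduces the error of the surface", {
  # 1D harmonic reference: F(x) = 0.5 k x^2; mean-of-4 should beat every
  # single run (L2 over well-visited bins) in >= 90% of repetitions
  k <- 5
  th <- thermo_state(330)
  grid <- list(x = c(-2, 2, 40))
  centers <- seq(-2, 2, length.out = 41)
  centers <- (centers[-1] + centers[-41]) / 2
  truth <- 0.5 * k * centers^2
  wins <- 0
  for (rep in 1:20) {
    tbs <- lapply(1:4, function(j) {
      suppressMessages(langevin_sample(
        harmonic_potential(k),
        langevin_spec(330, 1, 0.002, 2e4, seed = 1000 * rep + j), 0))
    })
    tbs <- lapply(tbs, function(tb) {
      names(tb)[2] <- "x"
      tb
    })
    singles_f <- lapply(tbs, function(tb) {
      suppressMessages(reweight_fes(tb, "x", grid, th))
    })
    # common well-sampled bins; gauge-free L2 (centered difference)
    sel <- Reduce(`&`, lapply(singles_f, function(f) f$visited & f$count > 50))
    l2 <- function(f) {
      d <- f$free_energy[sel] - truth[sel]
      sqrt(mean((d - mean(d))^2))
    }
    mean4 <- suppressMessages(multi_run_fes(tbs, "x", grid, th))
    if (l2(mean4) < min(vapply(singles_f, l2, 1.0))) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("committee deviation matches hand calculation and invariances", {
  # 1D forces (1,1,1,3): rms deviation about the mean = sqrt(0.75)
  fs <- lapply(c(1, 1, 1, 3), function(v) list(matrix(v, 1, 1)))
  expect_equal(committee_deviation(fs)$deviation, sqrt(0.75))
  expect_error(committee_deviation(fs[1]), "single model")
  # translation invariance
  set.seed(4)
  f0 <- matrix(rnorm(15), 5, 3)
  sets <- suppressMessages(committee_force_sets(list(f0), 4, 0.2, seed = 6))
  shifted <- lapply(sets, function(m) lapply(m, function(f) f + 3.3))
  expect_equal(committee_deviation(sets)$deviation,
               committee_deviation(shifted)$deviation, tolerance = 1e-12)
  # joint rotation invariance
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  rotated <- lapply(sets, function(m) lapply(m, function(f) f %*% t(R)))
  expect_equal(committee_deviation(sets)$deviation,
               committee_deviation(rotated)$deviation, tolerance = 1e-12)
})

test_that("selection window is inclusive-low, exclusive-high, order-preserving", {
  expect_equal(select_configs(c(0.1, 0.6, 5.0), 0.5, 2.0), 2L)
  expect_equal(select_configs(c(1, 2, 3), 5, 5), integer(0))
  expect_equal(select_configs(rep(0.5, 3), 0.5, 2), 1:3)
  expect_equal(select_configs(c(3, 1, 2, 1.5), 1, 2.5), c(2L, 3L, 4L))
})
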