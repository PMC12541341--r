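make_wc_frame <- function(atoms, wcs, L = 12) {
  species <- c(atoms$species, rep("WC", nrow(wcs)))
  pos <- rbind(as.matrix(atoms[, c("x", "y", "z")]), as.matrix(wcs))
  trajectory(species, pos, sim_box(rep(L, 3)), wrapped = TRUE)
}

test_that("tetrahedral centers give a zero centroid displacement", {
  a <- 0.3
  tet <- rbind(c(a, a, a), c(a, -a, -a), c(-a, a, -a), c(-a, -a, a))
  fr <- make_wc_frame(tibble::tibble(species = "O", x = 6, y = 6, z = 6),
                      sweep(tet, 2, c(6, 6, 6), `+`))
  asg <- assign_centroids(fr)
  expect_equal(c(asg$dx, asg$dy, asg$dz), rep(0, 3), tolerance = 1e-12)
})

test_that("uniformly shifted centers shift the centroid, incl. across images", {
  tet <- 0.3 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  wc <- sweep(tet, 2, c(6, 6, 6), `+`)
  wc[, 1] <- wc[, 1] + 0.1
  fr <- make_wc_frame(tibble::tibble(species = "O", x = 6, y = 6, z = 6), wc)
  asg <- assign_centroids(fr)
  expect_equal(c(asg$dx[1], asg$dy[1], asg$dz[1]), c(0.1, 0, 0),
               tolerance = 1e-12)
  # atom near the box edge, centers wrapped to the other side
  wc2 <- sweep(tet, 2, c(0.05, 6, 6), `+`)
  wc2[, 1] <- wc2[, 1] %% 12
  fr2 <- make_wc_frame(tibble::tibble(species = "O", x = 11.95, y = 6, z = 6),
                       wc2)
  asg2 <- assign_centroids(fr2)
  expect_equal(c(asg2$dx, asg2$dy, asg2$dz), c(0.1, 0, 0), tolerance = 1e-10)
})

test_that("greedy-plus-swaps assignment matches exhaustive optimal splits", {
  set.seed(9)
  for (rep in 1:25) {
    atoms <- tibble::tibble(species = c("O", "O"),
                            x = runif(2, 2, 10), y = runif(2, 2, 10),
                            z = runif(2, 2, 10))
    wc <- cbind(runif(8, 0, 12), runif(8, 0, 12), runif(8, 0, 12))
    fr <- make_wc_frame(atoms, wc)
    asg <- suppressWarnings(assign_centroids(fr))
    mp <- attr(asg, "mapping")
    got <- sum(mp$dist)
    # enumerate all 8-choose-4 splits
    box <- sim_box(rep(12, 3))
    cost <- sapply(1:2, function(j) {
      d <- minimum_image_displacement(
        matrix(rep(as.numeric(atoms[j, c("x", "y", "z")]), 8), 8, 3,
               byrow = TRUE), wc, box)
      sqrt(rowSums(matrix(d, ncol = 3)^2))
    })
    best <- min(apply(utils::combn(8, 4), 2, function(s) {
      sum(cost[s, 1]) + sum(cost[-s, 2])
    }))
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("center-count mismatches are rejected", {
  fr <- make_wc_frame(tibble::tibble(species = "O", x = 6, y = 6, z = 6),
                      matrix(6, 3, 3))
  expect_error(assign_centroids(fr), "expected 4")
})

test_that("charge bookkeeping yields the formal ionic charges", {
  ct <- charge_table()
  # water: O +6, 2 H +1, centroid -8 -> 0
  expect_equal(6 + 2 * 1 + ct$centroid, 0)
  expect_equal(fragment_net_charge(ct, "H2O"), 0)
  expect_equal(fragment_net_charge(ct, "OH"), -1)
  expect_equal(fragment_net_charge(ct, "CO3"), -2)
  expect_equal(fragment_net_charge(ct, "HCO3"), -1)
  expect_equal(fragment_net_charge(ct, "Ca"), 2)
  expect_equal(fragment_net_charge(charge_table("explicit"), "Ca"), 2)
})

test_that("built site sets carry the declared charges per mode", {
  tet <- 0.25 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  atoms <- tibble::tibble(species = c("O", "H", "H"),
                          x = c(6, 6.8, 5.2), y = c(6, 6.4, 6.4), z = 6)
  fr <- make_wc_frame(atoms, sweep(tet, 2, c(6, 6, 6), `+`))
  asg <- assign_centroids(fr)
  sites <- build_charged_sites(fr, asg)
  expect_equal(attr(sites, "net_charge"), 0) # water
  expect_equal(sort(unique(sites$q)), c(-8, 1, 6))
  # effective-Ca mode: single +2 site, no Ca centroid
  frca <- trajectory("Ca", matrix(5, 1, 3), sim_box(rep(10, 3)))
  sca <- build_charged_sites(frca)
  expect_equal(sca$q, 2)
  expect_error(build_charged_sites(
    trajectory("Xx", matrix(1, 1, 3), sim_box(rep(5, 3)))), "unknown species")
})

test_that("widely separated opposite Gaussians recover the Coulomb energy", {
  box <- sim_box(rep(60, 3))
  s <- charged_sites(rbind(c(10, 30, 30), c(20, 30, 30)), c(1, -1), box,
                     beta = 1.2)
  ew <- suppressMessages(gaussian_ewald_energy(s, grid_spacing = 0.25))
  # image corrections ~ dipole^2/L^3 are below 0.1% here
  expect_equal(ew$energy, -coulomb_kjmol_ang / 10, tolerance = 1e-3 * 138.9)
})

test_that("a single Gaussian keeps only the lattice self-image energy", {
  # with the self-energy excluded and the background correction applied, a
  # single point-like charge must land on the simple-cubic Wigner constant
  # -2.837297 k q^2 / (2 L); an unexcluded self-energy would be off by
  # k q^2 beta / sqrt(2 pi), orders of magnitude larger
  q <- 1.5
  L <- 10
  s <- charged_sites(matrix(5, 1, 3), q, sim_box(rep(L, 3)), beta = 1.5)
  ew <- suppressMessages(gaussian_ewald_energy(s, grid_spacing = 0.2))
  wigner <- -2.837297 * coulomb_kjmol_ang * q^2 / (2 * L)
  expect_equal(ew$energy, wigner, tolerance = 1e-4 * abs(wigner))
})

test_that("the resolution guard names a usable spacing", {
  s <- charged_sites(rbind(c(1, 1, 1), c(3, 3, 3)), c(1, -1),
                     sim_box(rep(8, 3)), beta = 2)
  expect_error(gaussian_ewald_energy(s, grid_spacing = 1), "spacing")
})

test_that("reciprocal-space energies match the direct-sum oracle", {
  set.seed(17)
  for (i in 1:12) {
    n <- sample(4:16, 1)
    L <- runif(1, 8, 15)
    q <- rnorm(n)
    q <- q - mean(q)
    s <- charged_sites(matrix(runif(3 * n, 0, L), n, 3), q,
                       sim_box(rep(L, 3)), beta = 0.25)
    ew <- suppressMessages(gaussian_ewald_energy(s, grid_spacing = 0.3))
    or <- direct_sum_oracle(s, shells = 16)
    expect_lt(abs(ew$energy - or$energy), 1e-4)
  }
})

test_that("oracle shell sums converge and respect symmetries", {
  set.seed(23)
  L <- 10
  q <- rnorm(8)
  q <- q - mean(q)
  pos <- matrix(runif(24, 0, L), 8, 3)
  s <- charged_sites(pos, q, sim_box(rep(L, 3)), beta = 0.25)
  or <- direct_sum_oracle(s, shells = 16)
  es <- or$shell_energies
  n <- length(es)
  expect_lt(abs(es[n] - es[n - 1]), abs(es[4] - es[3]))
  # rigid translation of all sites leaves the energy unchanged (neutral set)
  s2 <- charged_sites(sweep(pos, 2, c(1.3, -2.1, 0.7), `+`), q,
                      sim_box(rep(L, 3)), beta = 0.25)
  or2 <- direct_sum_oracle(s2, shells = 16)
  expect_equal(or$energy, or2$energy, tolerance = 1e-6)
  # point limit: erf -> 1 recovers plain Coulomb for a tight pair
  sp <- charged_sites(rbind(c(2, 5, 5), c(4, 5, 5)), c(1, -1),
                      sim_box(rep(40, 3)), beta = 3)
  orp <- direct_sum_oracle(sp, shells = 10)
  expect_equal(orp$energy, -coulomb_kjmol_ang / 2, tolerance = 0.3)
})

test_that("Ewald forces equal the negative energy gradient", {
  set.seed(31)
  n <- 6
  L <- 9
  q <- rnorm(n)
  q <- q - mean(q)
  pos <- matrix(runif(3 * n, 0, L), n, 3)
  s <- charged_sites(pos, q, sim_box(rep(L, 3)), beta = 0.3)
  ew <- suppressMessages(gaussian_ewald_energy(s, 0.3))
  h <- 1e-5
  for (i in c(1, 4)) {
    for (k in 1:3) {
      pp <- pos
      pp[i, k] <- pp[i, k] + h
      pm <- pos
      pm[i, k] <- pm[i, k] - h
      ep <- suppressMessages(gaussian_ewald_energy(
        charged_sites(pp, q, sim_box(rep(L, 3)), 0.3), 0.3))$energy
      em <- suppressMessages(gaussian_ewald_energy(
        charged_sites(pm, q, sim_box(rep(L, 3)), 0.3), 0.3))$energy
      fd <- -(ep - em) / (2 * h)
      expect_equal(ew$forces[i, k], fd,
                   tolerance = 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("Ewald energy is exactly lattice periodic", {
  set.seed(37)
  L <- 10
  q <- c(1, -1, 0.5, -0.5)
  pos <- matrix(runif(12, 0, L), 4, 3)
  e1 <- suppressMessages(gaussian_ewald_energy(
    charged_sites(pos, q, sim_box(rep(L, 3)), 0.25), 0.4))$energy
  pos2 <- pos
  pos2[2, ] <- pos2[2, ] + c(L, -L, 2 * L)
  e2 <- suppressMessages(gaussian_ewald_energy(
    charged_sites(pos2, q, sim_box(rep(L, 3)), 0.25), 0.4))$energy
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("group tails share the single Coulomb constant across modules", {
  ct <- charge_table()
  expect_equal(lr_tail_from_charges(ct, c("Ca", "CO3"), 102, 14),
               -3.892, tolerance = 1e-3)
  expect_equal(lr_tail_from_charges(ct, c("Ca", "CO3"), 102, 14),
               coulomb_tail(14, tail_spec(-4, 102)), tolerance = 1e-12)
  expect_gt(lr_tail_from_charges(ct, c("CO3", "CO3"), 102, 10), 0)
})
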