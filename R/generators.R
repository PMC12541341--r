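#' Brownian trajectory with known diffusion coefficient
#'
#' Unwrapped Gaussian random walks for `n_particles` independent particles:
#' per-axis increments have variance `2 D dt` with `D` converted from the
#' customary 1e-5 cm^2/s scale (1e-5 cm^2/s = 0.1 Å^2/ps).  Ground truth for
#' the Einstein mean-squared-displacement estimator.
#'
#' @param d_true diffusion coefficient in 1e-5 cm^2/s.
#' @param n_particles,n_steps walk dimensions.
#' @param timestep ps.
#' @param seed RNG seed.
#' @param box a [sim_box()] (starting positions uniform inside it;
#'   coordinates are left unwrapped).
#' @param species particle label.
#' @return an unwrapped [trajectory()].
#' @export
brownian_trajectory <- function(d_true, n_particles, n_steps, timestep = 1,
                                seed = 1, box = sim_box(c(36, 36, 36)),
                                species = "O") {
  stopifnot(d_true >= 0, n_particles >= 1, n_steps >= 1)
  set.seed(seed)
  inform(sprintf("brownian_trajectory: seed = %d", seed))
  D <- 0.1 * d_true # Å^2/ps
  s <- sqrt(2 * D * timestep)
  arr <- array(NA_real_, c(n_particles, 3, n_steps + 1))
  for (k in 1:3) {
    start <- runif(n_particles, 0, box$edge_lengths[k])
    inc <- matrix(rnorm(n_particles * n_steps, sd = s), n_particles, n_steps)
    arr[, k, ] <- cbind(start, start + t(apply(inc, 1, cumsum)))
  }
  trajectory(rep(species, n_particles), arr, box,
             times = seq(0, n_steps) * timestep, wrapped = FALSE)
}

#' Two-state residence indicator series
#'
#' Alternating exponential dwell times between a bound and a free state,
#' sampled on a regular time grid.  The generator exposes the raw indicator
#' series (plus the exact dwell times as an attribute) rather than committing
#' to any residence-time estimator.
#'
#' @param tau_bound,tau_free mean dwell times, ps.
#' @param n_events number of bound intervals.
#' @param seed RNG seed.
#' @param resolution sampling interval, ps (default: the shorter mean dwell
#'   divided by 50).
#' @return tibble with columns `time` (ps) and `bound` (logical); attribute
#'   `dwell` holds the exact interval table.
#' @export
two_state_residence_series <- function(tau_bound, tau_free, n_events,
                                       seed = 1, resolution = NULL) {
  stopifnot(tau_bound > 0, tau_free > 0, n_events >= 1)
  if (is.null(resolution)) resolution <- min(tau_bound, tau_free) / 50
  set.seed(seed)
  inform(sprintf("two_state_residence_series: seed = %d", seed))
  tb <- rexp(n_events, 1 / tau_bound)
  tf <- rexp(n_events, 1 / tau_free)
  # bound first, then free, alternating
  dur <- as.numeric(rbind(tb, tf))
  state <- rep(c(TRUE, FALSE), n_events)
  ends <- cumsum(dur)
  starts <- c(0, head(ends, -1))
  tgrid <- seq(0, max(ends), by = resolution)
  idx <- findInterval(tgrid, starts)
  idx[idx < 1] <- 1
  idx[idx > length(state)] <- length(state)
  tibble(time = tgrid, bound = state[idx]) |>
    structure(dwell = tibble(state = state, start = starts, duration = dur),
              resolution = resolution)
}

#' Layered interfacial particle distributions
#'
#' Synthetic frames of an interface: per layer, `count` particles of one
#' species Gaussian-distributed in z about the layer position and uniform
#' laterally.  Emulates the stacked atomic layers of a mineral--water
#' interface for testing density-profile machinery.
#'
#' @param layers tibble with columns `z` (Å), `species`, `count`, `width`
#'   (Gaussian sigma in z, Å; 0 pins particles exactly at `z`).
#' @param lateral numeric(2), lateral box edges, Å.
#' @param lz box height, Å (default: max layer z + 10).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a wrapped [trajectory()] (z non-periodic).
#' @export
layered_interface_frames <- function(layers, lateral = c(20, 20), lz = NULL,
                                     n_frames = 1, seed = 1) {
  layers <- as_tibble(layers)
  stopifnot(all(c("z", "species", "count", "width") %in% names(layers)))
  if (is.null(lz)) lz <- max(layers$z) + 10
  set.seed(seed)
  inform(sprintf("layered_interface_frames: seed = %d", seed))
  n <- sum(layers$count)
  species <- rep(layers$species, layers$count)
  zmu <- rep(layers$z, layers$count)
  zsd <- rep(layers$width, layers$count)
  arr <- array(NA_real_, c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    arr[, 1, f] <- runif(n, 0, lateral[1])
    arr[, 2, f] <- runif(n, 0, lateral[2])
    arr[, 3, f] <- rnorm(n, zmu, zsd)
  }
  trajectory(species, arr, sim_box(c(lateral, lz), periodic = c(TRUE, TRUE, FALSE)),
             times = seq_len(n_frames) - 1, wrapped = TRUE)
}

#' Committee force predictions with controlled disagreement
#'
#' Emulates an ensemble of independently trained force models: each model's
#' prediction for a configuration is the true force field plus i.i.d.
#' Gaussian noise with that configuration's `disagreement_scale`.  Used to
#' validate the committee-deviation statistic and the active-learning
#' selection window.
#'
#' @param true_forces list of `n_atoms x 3` force matrices, one per
#'   configuration (a single matrix is treated as one configuration).
#' @param n_models committee size (default 4).
#' @param disagreement_scale per-configuration noise scale (recycled).
#' @param seed RNG seed.
#' @return list of length `n_models`; element m is the list of that model's
#'   force matrices per configuration.
#' @export
committee_force_sets <- function(true_forces, n_models = 4,
                                 disagreement_scale = 0.1, seed = 1) {
  if (is.matrix(true_forces)) true_forces <- list(true_forces)
  nc <- length(true_forces)
  scale <- rep_len(disagreement_scale, nc)
  set.seed(seed)
  inform(sprintf("committee_force_sets: seed = %d", seed))
  lapply(seq_len(n_models), function(m) {
    lapply(seq_len(nc), function(i) {
      f <- true_forces[[i]]
      f + matrix(rnorm(length(f), sd = scale[i]), nrow(f), ncol(f))
    })
  })
}

#' Analytic carbonate-protonation free-energy landscape
#'
#' A differentiable 2D model surface over the ion--ion distance `d` (Å) and a
#' protonation coordination number `n` in [0, 1]: two valleys pinned exactly
#' at n = 0 (carbonate-like) and n = 1 (bicarbonate-like), separated by a
#' saddle whose height grows with `d` -- lowest for the contact pair near
#' 3 Å and substantially higher beyond 6 Å, mimicking proton transfer that
#' is easiest when the ions are tightly associated.
#'
#' F(d, n) = 16 h(d) n^2 (1-n)^2 + b n^2 (3-2n) + g(d), with h(d) a logistic
#' ramp between `barrier_near` and `barrier_far` around `d_mid`, b the valley
#' offset, and g(d) a shallow attraction at contact.
#'
#' @param barrier_near,barrier_far saddle heights (kJ/mol) in the associated
#'   and dissociated limits.
#' @param d_mid,d_scale center and width (Å) of the logistic ramp.
#' @param valley_offset free-energy offset of the n = 1 valley (kJ/mol).
#' @param contact_depth,contact_center,contact_width Gaussian well in d
#'   describing the contact ion pair (kJ/mol, Å, Å).
#' @return object of class `scalar_field_2d`: list with vectorised `f(d, n)`,
#'   `grad(d, n)` (returning `dd` and `dn`), and the parameters.
#' @export
proton_transfer_surface <- function(barrier_near = 18, barrier_far = 48,
                                    d_mid = 4.5, d_scale = 0.8,
                                    valley_offset = 4,
                                    contact_depth = 6, contact_center = 3,
                                    contact_width = 0.6) {
  h <- function(d) {
    barrier_near + (barrier_far - barrier_near) / (1 + exp(-(d - d_mid) / d_scale))
  }
  dh <- function(d) {
    s <- 1 / (1 + exp(-(d - d_mid) / d_scale))
    (barrier_far - barrier_near) * s * (1 - s) / d_scale
  }
  g <- function(d) -contact_depth * exp(-(d - contact_center)^2 / (2 * contact_width^2))
  dg <- function(d) {
    contact_depth * (d - contact_center) / contact_width^2 *
      exp(-(d - contact_center)^2 / (2 * contact_width^2))
  }
  f <- function(d, n) 16 * h(d) * n^2 * (1 - n)^2 + valley_offset * n^2 * (3 - 2 * n) + g(d)
  grad <- function(d, n) {
    list(dd = 16 * dh(d) * n^2 * (1 - n)^2 + dg(d),
         dn = 16 * h(d) * (2 * n * (1 - n)^2 - 2 * n^2 * (1 - n)) +
           valley_offset * 6 * n * (1 - n))
  }
  structure(list(f = f, grad = grad,
                 params = list(barrier_near = barrier_near,
                               barrier_far = barrier_far, d_mid = d_mid,
                               d_scale = d_scale, valley_offset = valley_offset,
                               contact_depth = contact_depth,
                               contact_center = contact_center,
                               contact_width = contact_width)),
            class = "scalar_field_2d")
}
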