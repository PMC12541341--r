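#' Overdamped Langevin sampling specification
#'
#' Parameters of the overdamped (Euler--Maruyama) integrator
#' `x <- x - (dt/friction) grad U + sqrt(2 D dt) eta`, with diffusion
#' coefficient `D = kB T / friction`.  Only the stationary distribution
#' matters for the downstream free-energy machinery, so no inertial dynamics
#' or thermostats are involved.  Every run is a pure function of `seed`.
#'
#' @param temperature K.
#' @param friction friction coefficient, 1/ps (sets `D = kB T / friction`).
#' @param timestep integration step, ps (> 0).
#' @param n_steps number of steps.
#' @param seed RNG seed (integer).
#' @param stride record every `stride`-th step.
#' @return object of class `langevin_spec`.
#' @export
langevin_spec <- function(temperature = 330, friction = 1, timestep = 1e-3,
                          n_steps = 1e5, seed = 1, stride = 1L) {
  if (timestep <= 0) abort("`timestep` must be > 0")
  if (friction <= 0) abort("`friction` must be > 0")
  if (temperature < 0) abort("`temperature` must be >= 0")
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, n_steps = as.numeric(n_steps),
                 seed = as.integer(seed), stride = as.integer(stride)),
            class = "langevin_spec")
}

#' Sample a model potential with overdamped Langevin dynamics
#'
#' Runs the seeded overdamped integrator on a model potential and records the
#' collective variable (the coordinate itself in 1D, the radius `d` for 3D
#' radial potentials) every `stride` steps.  Built-in potential families run
#' in compiled code; [custom_potential()] objects are integrated in R.
#'
#' @param potential a model potential (see [toy_potentials] and
#'   [pair_potential()]).
#' @param spec a [langevin_spec()]; its seed is logged in the result.
#' @param initial initial position vector (defaults to the origin shifted to
#'   a valid radius for radial potentials).
#' @param record_positions keep the full position record as an attribute
#'   `positions` (matrix, one row per record).
#' @param walls optional [wall_spec()] (or list of them) restraining the
#'   recorded CV (built-in potentials only).
#' @return a CV tibble (columns `time`, CV, `bias`, `wall`; bias and wall are
#'   zero for unbiased runs) with attributes `seed` and optionally
#'   `positions`.
#' @examples
#' tbl <- langevin_sample(harmonic_potential(10),
#'                        langevin_spec(n_steps = 2000, seed = 7), initial = 0)
#' var(tbl$x) # ~ kB T / k
#' @export
langevin_sample <- function(potential, spec, initial = NULL,
                            record_positions = FALSE, walls = list()) {
  code <- pot_code(potential)
  dim <- pot_dim(potential)
  if (is.null(initial)) {
    initial <- if (dim == 3) c(pmax(3, 1), 0, 0) else rep(0, dim)
  }
  initial <- as.numeric(initial)
  stopifnot(length(initial) == dim)
  g0 <- potential_gradient(potential, initial)
  if (any(!is.finite(g0))) abort("gradient not finite at the initial point")
  inform(sprintf("langevin_sample: seed = %d", spec$seed))
  if (!is.na(code)) {
    set.seed(spec$seed)
    res <- cpp_langevin(code, pot_par(potential), dim, spec$temperature,
                        spec$friction, spec$timestep, spec$n_steps,
                        spec$stride, initial, record_positions,
                        FALSE, 0, 2, 0.1, 1L, 0, 1, 1L,
                        walls_matrix(walls))
    out <- tibble(time = res$time, cv = res$cv, bias = res$bias,
                  wall = res$wall)
  } else {
    if (length(walls)) abort("walls require a built-in model potential")
    res <- r_langevin(potential, spec, initial, record_positions)
    out <- res$table
  }
  names(out)[2] <- if (dim == 3) "d" else "x"
  attr(out, "seed") <- spec$seed
  if (record_positions) attr(out, "positions") <- res$positions
  out
}

# plain-R integrator for custom potentials
r_langevin <- function(potential, spec, x, record_positions) {
  dim <- length(x)
  kt <- kb_kjmol * spec$temperature
  D <- kt / spec$friction
  mob <- spec$timestep / spec$friction
  noise <- sqrt(2 * D * spec$timestep)
  nrec <- floor(spec$n_steps / spec$stride)
  tv <- sv <- bv <- numeric(nrec)
  pos <- if (record_positions) matrix(NA_real_, nrec, dim) else NULL
  set.seed(spec$seed)
  irec <- 0L
  for (step in seq_len(spec$n_steps)) {
    g <- potential_gradient(potential, x)
    x <- x - mob * g + noise * rnorm(dim)
    if (!all(is.finite(x)) || sum(x^2) > 1e16) {
      abort(sprintf("Langevin dynamics diverged at step %d", step))
    }
    if (step %% spec$stride == 0) {
      irec <- irec + 1L
      tv[irec] <- step * spec$timestep
      sv[irec] <- if (dim == 3) sqrt(sum(x^2)) else x[1]
      bv[irec] <- 0
      if (record_positions) pos[irec, ] <- x
    }
  }
  list(table = tibble(time = tv, cv = sv, bias = bv, wall = 0),
       positions = pos)
}

#' Sample the relative coordinate of an ion pair
#'
#' Overdamped dynamics of a single 3D relative coordinate under a radial pair
#' potential, optionally with a static radial bias.  Because the dynamics are
#' genuinely three-dimensional, the `4 pi r^2` configurational-entropy factor
#' arises naturally in the sampled distance distribution -- exactly the level
#' at which the entropy-corrected potential of mean force and the association
#' integral operate.  With a zero potential inside a reflecting sphere
#' ([flat_sphere_potential()]) this is the executable ideal-pair null.
#'
#' @inheritParams langevin_sample
#' @param bias optional static bias: `list(f = function(r), df = function(r))`
#'   in kJ/mol (integrated in R).
#' @param initial_r initial separation, Å.
#' @return CV tibble with columns `time`, `d` (Å), `bias`, `wall` (kJ/mol).
#' @export
sample_radial_pair <- function(potential, spec, bias = NULL, initial_r = NULL) {
  stopifnot(inherits(potential, c("pair_potential", "flat_sphere_potential")))
  if (is.null(initial_r)) {
    initial_r <- if (inherits(potential, "pair_potential")) {
      max(potential$inner_radius + 1, potential$basins$center[1])
    } else {
      potential$radius / 2
    }
  }
  if (inherits(potential, "pair_potential") &&
      initial_r <= potential$inner_radius) {
    abort("initial separation must exceed the inner-wall radius")
  }
  if (is.null(bias)) {
    out <- langevin_sample(potential, spec, initial = c(initial_r, 0, 0))
  } else {
    stopifnot(is.function(bias$f), is.function(bias$df))
    eff <- custom_potential(
      fn = function(x) {
        r <- sqrt(sum(x^2))
        potential_energy(potential, x) + bias$f(r)
      },
      grad = function(x) {
        r <- sqrt(sum(x^2))
        potential_gradient(potential, x) + bias$df(r) * x / max(r, 1e-12)
      },
      dim = 3
    )
    out <- langevin_sample(eff, spec, initial = c(initial_r, 0, 0))
    names(out)[2] <- "d"
    out$bias <- bias$f(out$d)
  }
  out
}
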