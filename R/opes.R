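#' OPES bias parameters
#'
#' Settings of the on-the-fly probability enhanced sampling bias: a kernel
#' density estimate of the sampled CV distribution is updated every
#' `pace` steps (each kernel weighted by `exp(beta V)` at deposition), and
#' the bias is `V(s) = (1 - 1/gamma) kB T log(P(s)/max P + eps)` with
#' regularisation `eps = exp(-beta DeltaE / (1 - 1/gamma))`.  The barrier
#' parameter `DeltaE` bounds the deposited bias: `max V <= (1 - 1/gamma)
#' DeltaE` at all times.  The bias factor defaults to
#' `gamma = DeltaE / (kB T)`; kernels have fixed bandwidth (no compression).
#'
#' @param barrier `DeltaE`, the barrier for maximum free-energy exploration,
#'   kJ/mol (> 0; default 30).
#' @param pace bias update frequency in steps (default 500).
#' @param bandwidth Gaussian kernel bandwidth in CV units (> 0).
#' @param bias_factor optional override for gamma (> 1).
#' @param grid_bins resolution of the internal bias grid.
#' @return object of class `opes_params`.
#' @export
opes_params <- function(barrier = 30, pace = 500, bandwidth = 0.1,
                        bias_factor = NULL, grid_bins = 500L) {
  if (barrier <= 0) abort("`barrier` must be > 0")
  if (bandwidth <= 0) abort("kernel `bandwidth` must be > 0")
  if (!is.null(bias_factor) && bias_factor <= 1) abort("`bias_factor` must be > 1")
  structure(list(barrier = barrier, pace = as.integer(pace),
                 bandwidth = bandwidth, bias_factor = bias_factor,
                 grid_bins = as.integer(grid_bins)),
            class = "opes_params")
}

#' Harmonic wall on a collective variable
#'
#' One-sided quadratic restraint: zero on the allowed side,
#' `kappa (excess)^2` beyond the wall, continuous with continuous first
#' derivative at the wall.  The default force constant 20 kJ/mol/Å^2
#' corresponds to 2e3 kJ/mol/nm^2 in the quadratic-wall convention.
#'
#' @param cv name of the restrained CV.
#' @param location wall position, CV units.
#' @param kappa force constant, kJ/mol per (CV unit)^2 (>= 0).
#' @param side `"upper"` or `"lower"`.
#' @return object of class `wall_spec`.
#' @export
wall_spec <- function(cv = "d", location, kappa = 20,
                      side = c("upper", "lower")) {
  side <- match.arg(side)
  if (kappa < 0) abort("`kappa` must be >= 0")
  structure(list(cv = cv, location = location, kappa = kappa, side = side),
            class = "wall_spec")
}

#' @rdname wall_spec
#' @param value CV value(s).
#' @param wall a `wall_spec`.
#' @return [harmonic_wall_energy()] returns the wall energy in kJ/mol.
#' @examples
#' harmonic_wall_energy(16, wall_spec("d", 15, kappa = 20))  # 20 kJ/mol
#' @export
harmonic_wall_energy <- function(value, wall) {
  ex <- if (wall$side == "upper") value - wall$location else wall$location - value
  ifelse(ex > 0, wall$kappa * ex^2, 0)
}

walls_matrix <- function(walls) {
  if (inherits(walls, "wall_spec")) walls <- list(walls)
  if (!length(walls)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(walls, function(w) {
    c(w$location, w$kappa, if (w$side == "upper") 1 else -1)
  }))
}

#' Run OPES-biased Langevin sampling on a model potential
#'
#' Couples the overdamped Langevin integrator to an adaptive OPES bias on the
#' scalar CV (the coordinate in 1D, the radial distance `d` for pair
#' potentials) plus optional harmonic walls.  The bias is rebuilt from the
#' weighted on-the-fly probability estimate every `pace` steps and recorded
#' (at sampling time) in the `bias` column; wall energies are recorded
#' separately in `wall`.  The deposited bias respects
#' `max V <= (1 - 1/gamma) * barrier` throughout.
#'
#' @inheritParams langevin_sample
#' @param params an [opes_params()].
#' @param walls a [wall_spec()] or list of them (all on the sampled CV).
#' @param grid_range numeric(2): CV range of the bias grid.  Defaults to the
#'   wall positions padded by 1 CV unit, or the initial CV +/- 5.
#' @return list of class `opes_run` with elements `table` (CV tibble) and
#'   `bias_state` (class `opes_bias`: grid, final bias, kernels, convergence
#'   diagnostics).
#' @export
opes_run <- function(potential, params, walls = list(), spec,
                     initial = NULL, grid_range = NULL) {
  stopifnot(inherits(params, "opes_params"), inherits(spec, "langevin_spec"))
  code <- pot_code(potential)
  if (is.na(code)) {
    abort("OPES runs require a built-in model potential (compiled path)")
  }
  dim <- pot_dim(potential)
  if (is.null(initial)) {
    initial <- if (dim == 3) {
      r0 <- if (inherits(potential, "pair_potential")) {
        max(potential$inner_radius + 1, potential$basins$center[1])
      } else potential$radius / 2
      c(r0, 0, 0)
    } else rep(0, dim)
  }
  wm <- walls_matrix(walls)
  if (is.null(grid_range)) {
    s0 <- if (dim == 3) sqrt(sum(initial^2)) else initial[1]
    if (nrow(wm)) {
      lo <- if (any(wm[, 3] < 0)) min(wm[wm[, 3] < 0, 1]) - 1 else
        min(s0, wm[, 1]) - 5
      hi <- if (any(wm[, 3] > 0)) max(wm[wm[, 3] > 0, 1]) + 1 else
        max(s0, wm[, 1]) + 5
      grid_range <- c(lo, hi)
    } else {
      grid_range <- s0 + c(-5, 5)
    }
  }
  if (dim == 3) grid_range[1] <- max(grid_range[1], 1e-3)
  kt <- kb_kjmol * spec$temperature
  gamma <- params$bias_factor %||% (params$barrier / kt)
  if (gamma <= 1) abort("bias factor gamma must exceed 1; raise `barrier`")
  inform(sprintf("opes_run: seed = %d, gamma = %.3f", spec$seed, gamma))
  set.seed(spec$seed)
  res <- cpp_langevin(code, pot_par(potential), dim, spec$temperature,
                      spec$friction, spec$timestep, spec$n_steps, spec$stride,
                      as.numeric(initial), FALSE,
                      TRUE, params$barrier, gamma, params$bandwidth,
                      params$pace, grid_range[1], grid_range[2],
                      params$grid_bins, wm)
  tbl <- tibble(time = res$time, cv = res$cv, bias = res$bias, wall = res$wall)
  names(tbl)[2] <- if (dim == 3) "d" else "x"
  bs <- res$bias_state
  linf <- bs$update_linf
  vmax <- max(abs(bs$bias), kt) # floor at kB T for near-flat systems
  # quasi-static check: mean L-inf drift of the bias per update over the
  # last 10% of updates, relative to the bias norm
  nwin <- max(1, bs$n_updates - bs$snapshot_update)
  drift <- if (length(bs$bias_snapshot)) {
    max(abs(bs$bias - bs$bias_snapshot)) / nwin / vmax
  } else Inf
  converged <- length(linf) > 10 && drift < 1e-3
  bias_state <- structure(
    list(grid = tibble(s = bs$grid_centers, bias = bs$bias, prob = bs$prob),
         kernels = tibble(center = bs$kernel_centers,
                          weight = bs$kernel_weights,
                          bandwidth = params$bandwidth),
         sum_weights = bs$sum_weights,
         gamma = gamma, barrier = params$barrier,
         epsilon = exp(-params$barrier / kt / (1 - 1 / gamma)),
         max_bias_bound = (1 - 1 / gamma) * params$barrier,
         update_linf = linf, converged = converged),
    class = "opes_bias")
  structure(list(table = tbl, bias_state = bias_state), class = "opes_run")
}

#' @export
print.opes_bias <- function(x, ...) {
  cat(sprintf(
    "<opes_bias> %d kernels, gamma = %.2f, max|V| = %.3f kJ/mol (bound %.3f), %s\n",
    nrow(x$kernels), x$gamma, max(abs(x$grid$bias)), x$max_bias_bound,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}
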