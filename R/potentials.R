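#' Model radial pair potential
#'
#' Analytic radial potential for the relative coordinate of an ion pair in
#' implicit solvent: a sum of Gaussian basins (solvent-structure minima; a
#' negative `depth` gives a repulsive hump), a screened-Coulomb tail
#' `qq * 1389.35458 / (eps * r)` kJ/mol, and a harmonic inner wall below
#' `inner_radius` standing in for core repulsion.  Bulk dielectric screening
#' does not describe ions in contact, so the tail ramps on smoothly across
#' `tail_on_window` (beyond the explicit solvation-shell basins); at short
#' range the basins alone carry the interaction.  With `truncated = TRUE`
#' the tail is additionally switched off (cubic switch) across
#' `trunc_window`, emulating a short-range model whose pair free energy
#' reaches zero at about twice its interaction cutoff.
#'
#' @param basins tibble/data.frame with columns `center` (Å), `depth`
#'   (kJ/mol, positive = attractive basin) and `width` (Å, > 0).
#' @param charge_product product of the ion charges, units of e^2
#'   (default -4 for a +2/-2 pair).
#' @param dielectric relative dielectric constant of the solvent model
#'   (> 1; default 102).
#' @param inner_radius radius of the repulsive inner wall, Å.
#' @param inner_k force constant of the inner wall, kJ/mol/Å^2.
#' @param truncated logical; switch the tail off over `trunc_window`.
#' @param trunc_window numeric(2), Å: full tail below the first value, zero
#'   beyond the second.
#' @param tail_on_window numeric(2), Å: tail zero below the first value,
#'   fully on beyond the second (`NULL` applies the tail at all r).
#' @return object of class `pair_potential`.
#' @seealso [preset_pair_potential()] for the shipped parameter sets.
#' @export
pair_potential <- function(basins,
                           charge_product = -4,
                           dielectric = 102,
                           inner_radius = 2.4,
                           inner_k = 400,
                           truncated = FALSE,
                           trunc_window = c(6, 12),
                           tail_on_window = c(6, 10)) {
  basins <- as_tibble(basins)
  stopifnot(all(c("center", "depth", "width") %in% names(basins)))
  if (any(basins$width <= 0)) abort("basin widths must be > 0")
  if (dielectric <= 1) abort("`dielectric` must exceed 1")
  if (truncated && trunc_window[1] >= trunc_window[2]) {
    abort("`trunc_window` must be increasing")
  }
  if (!is.null(tail_on_window) && tail_on_window[1] >= tail_on_window[2]) {
    abort("`tail_on_window` must be increasing")
  }
  structure(
    list(basins = basins, charge_product = charge_product,
         dielectric = dielectric, inner_radius = inner_radius,
         inner_k = inner_k, truncated = isTRUE(truncated),
         trunc_window = as.numeric(trunc_window),
         tail_on_window = if (is.null(tail_on_window)) NULL
                          else as.numeric(tail_on_window)),
    class = c("pair_potential", "model_potential")
  )
}

# parameter pack understood by the compiled integrator (code 3)
pack_pair_potential <- function(pot) {
  b <- pot$basins
  ton <- !is.null(pot$tail_on_window)
  c(nrow(b), as.numeric(t(cbind(b$center, -b$depth, b$width))),
    pot$charge_product, pot$dielectric, pot$inner_radius, pot$inner_k,
    as.numeric(pot$truncated), pot$trunc_window,
    as.numeric(ton), if (ton) pot$tail_on_window else c(0, 0))
}

#' Preset model pair potentials
#'
#' Named, versioned parameter sets for the toy generators.  `"caco3_lr"` is a
#' qualitative mimic of the calcium--carbonate pairing free-energy profile:
#' a deep bidentate basin near 2.9 Å, a shallower monodentate basin near
#' 3.4 Å, a solvent-reorganisation hump near 4 Å, a solvent-shared basin near
#' 5 Å and an attractive screened-Coulomb tail (charge product -4,
#' dielectric 102) ramping on over 6--10 Å, where bulk screening becomes
#' meaningful.  `"caco3_sr"` is its tail-truncated counterpart (tail
#' switched back to zero between 6 and 12 Å, i.e. twice a 6 Å model cutoff).
#' `"ideal"` has no basins and no tail: the ideal-pair null.
#' These presets are hand-chosen shapes, not fits to any published curve.
#'
#' @param name one of `"caco3_lr"`, `"caco3_sr"`, `"ideal"`.
#' @return a [pair_potential()] (with a `preset` attribute naming it and the
#'   preset version).
#' @export
preset_pair_potential <- function(name = c("caco3_lr", "caco3_sr", "ideal")) {
  name <- match.arg(name)
  basins <- tibble(
    center = c(2.9, 3.4, 5.0, 4.05),
    depth  = c(12,  7,   5,   -3),    # negative depth = repulsive hump
    width  = c(0.17, 0.17, 0.4, 0.2)
  )
  pot <- switch(name,
    caco3_lr = pair_potential(basins, tail_on_window = c(6, 10)),
    caco3_sr = pair_potential(basins, truncated = TRUE, trunc_window = c(6, 12),
                              tail_on_window = c(6, 10)),
    ideal = pair_potential(tibble(center = 3, depth = 0, width = 1),
                           charge_product = 0)
  )
  attr(pot, "preset") <- list(name = name, version = "1.0")
  pot
}

#' Simple test potentials for the Langevin sampler
#'
#' `harmonic_potential()` is an isotropic harmonic well 0.5 k |x - center|^2;
#' `barrier_double_well()` a 1D Gaussian barrier of the given height and
#' width at the origin with harmonic confinement beyond `halfwidth` (two flat
#' wells separated by a narrow barrier); `flat_sphere_potential()` zero
#' potential inside a reflecting sphere; `custom_potential()` wraps R
#' functions for energy and gradient (integrated in R, so markedly slower
#' than the built-in forms).
#'
#' @param k,center force constant (kJ/mol/Å^2) and center (Å).
#' @param dim dimensionality (1, 2 or 3).
#' @name toy_potentials
#' @export
harmonic_potential <- function(k, center = 0, dim = 1) {
  stopifnot(k > 0, dim %in% 1:3)
  structure(list(k = k, center = center, dim = dim),
            class = c("harmonic_potential", "model_potential"))
}

#' @rdname toy_potentials
#' @param height,width barrier height (kJ/mol) and Gaussian width (Å).
#' @param halfwidth half-width of the confined interval (Å).
#' @param k_conf confinement force constant (kJ/mol/Å^2).
#' @export
barrier_double_well <- function(height = 12, width = 0.25, halfwidth = 2,
                                k_conf = 100) {
  structure(list(height = height, width = width, halfwidth = halfwidth,
                 k_conf = k_conf),
            class = c("barrier_double_well", "model_potential"))
}

#' @rdname toy_potentials
#' @param radius reflecting-sphere radius (Å).
#' @export
flat_sphere_potential <- function(radius) {
  stopifnot(radius > 0)
  structure(list(radius = radius),
            class = c("flat_sphere_potential", "model_potential"))
}

#' @rdname toy_potentials
#' @param fn,grad energy `fn(x)` (kJ/mol) and gradient `grad(x)` (kJ/mol/Å)
#'   taking a position vector of length `dim`.
#' @export
custom_potential <- function(fn, grad, dim = 1) {
  stopifnot(is.function(fn), is.function(grad))
  structure(list(fn = fn, grad = grad, dim = dim),
            class = c("custom_potential", "model_potential"))
}

pot_code <- function(pot) {
  if (inherits(pot, "harmonic_potential")) 1L
  else if (inherits(pot, "barrier_double_well")) 2L
  else if (inherits(pot, "pair_potential")) 3L
  else if (inherits(pot, "flat_sphere_potential")) 4L
  else NA_integer_
}

pot_par <- function(pot) {
  switch(pot_code(pot),
         c(pot$k, pot$center),
         c(pot$height, pot$width, pot$halfwidth, pot$k_conf),
         pack_pair_potential(pot),
         c(pot$radius))
}

pot_dim <- function(pot) {
  if (inherits(pot, c("pair_potential", "flat_sphere_potential"))) 3L
  else if (inherits(pot, "barrier_double_well")) 1L
  else as.integer(pot$dim)
}

#' Evaluate a model potential
#'
#' @param pot a model potential.
#' @param x position vector (length = dimensionality) or, for radial
#'   potentials, a vector of radii via [pair_potential_energy()].
#' @return energy in kJ/mol ([potential_energy()]) or the gradient vector
#'   ([potential_gradient()]).
#' @export
potential_energy <- function(pot, x) {
  if (inherits(pot, "custom_potential")) return(pot$fn(x))
  cpp_pot_eval(pot_code(pot), pot_par(pot), as.numeric(x))$energy
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(pot, x) {
  if (inherits(pot, "custom_potential")) return(pot$grad(x))
  cpp_pot_eval(pot_code(pot), pot_par(pot), as.numeric(x))$gradient
}

#' Radial profile of a pair potential
#'
#' Vectorised U(r) for [pair_potential()] objects; this is the deterministic
#' ground truth against which sampled, reweighted and aligned potentials of
#' mean force are compared.
#'
#' @param pot a [pair_potential()].
#' @param r radii, Å (> 0).
#' @return energies, kJ/mol.
#' @export
pair_potential_energy <- function(pot, r) {
  stopifnot(inherits(pot, "pair_potential"))
  vapply(r, function(ri) {
    cpp_pot_eval(3L, pack_pair_potential(pot), c(ri, 0, 0))$energy
  }, 1.0)
}
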