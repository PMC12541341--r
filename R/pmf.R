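#' Radial potential of mean force
#'
#' A `radial_pmf` is a tibble with columns `r` (Å, strictly increasing,
#' positive) and `W` (kJ/mol), carrying its alignment state (`"raw"`,
#' `"zeroed_tail"` or `"coulomb_tail"`), the thermodynamic context and --
#' when Coulomb-aligned -- the screened-tail parameters as attributes.  The
#' alignment state gates downstream operations: the association integral
#' requires an aligned curve, whose tail convention defines W(r) -> 0 at
#' large r.
#'
#' @param r,W grids (Å, kJ/mol).
#' @param thermo a [thermo_state()].
#' @param alignment alignment state string.
#' @param count optional per-bin sample counts.
#' @param tail a [tail_spec()] when coulomb-aligned.
#' @return a `radial_pmf` tibble.
#' @export
radial_pmf <- function(r, W, thermo = thermo_state(), alignment = "raw",
                       count = NULL, tail = NULL) {
  if (any(r <= 0)) abort("radii must be strictly positive")
  if (any(diff(r) <= 0)) abort("`r` must be strictly increasing")
  out <- tibble(r = as.numeric(r), W = as.numeric(W))
  if (!is.null(count)) out$count <- count
  structure(out, thermo = as_thermo(thermo), alignment = alignment,
            tail = tail, class = c("radial_pmf", class(tibble())))
}

pmf_alignment <- function(pmf) attr(pmf, "alignment")

#' Remove the radial configurational entropy from a free-energy curve
#'
#' Converts a radial free energy G(r) (from reweighting the pair distance)
#' into the potential of mean force `W(r) = G(r) + kB T log(4 pi r^2)`,
#' removing the ideal `4 pi r^2` shell-volume contribution.  For an ideal
#' (non-interacting) pair W is flat; any additive gauge of G is preserved.
#'
#' @param fes a 1D [fes_grid()] over the pair distance, or a data frame with
#'   the distance in the first column and the free energy in a column named
#'   `free_energy` (or `G`, or the second column).
#' @param thermo a [thermo_state()] or temperature (K).
#' @return a `radial_pmf` in alignment state `"raw"`.
#' @examples
#' th <- thermo_state(330)
#' g <- tibble::tibble(r = 1:10, free_energy = 0)
#' entropy_correct(g, th) # W = kB T log(4 pi r^2)
#' @export
entropy_correct <- function(fes, thermo = thermo_state()) {
  thermo <- as_thermo(thermo)
  if (inherits(fes, "fes_grid")) {
    if (length(fes_axes(fes)) != 1) {
      abort("entropy correction applies to 1D radial grids")
    }
    r <- fes[[fes_axis_names(fes)]]
    G <- fes$free_energy
    cnt <- fes$count
    keep <- fes$visited
    r <- r[keep]
    G <- G[keep]
    cnt <- cnt[keep]
  } else {
    fes <- as.data.frame(fes)
    r <- fes[[1]]
    G <- fes[["free_energy"]] %||% fes[["G"]] %||% fes[[2]]
    cnt <- fes[["count"]]
  }
  if (any(r <= 0)) abort("entropy correction requires r > 0")
  W <- G + thermo$kt * log(4 * pi * r^2)
  radial_pmf(r, W, thermo, alignment = "raw", count = cnt)
}

#' Screened-Coulomb tail specification
#'
#' Parameters of the long-range electrostatic tail
#' `E(r) = q1 q2 * 1389.35458 / (eps * r)` kJ/mol to which a long-range
#' potential of mean force is aligned.  The default charge product -4
#' describes a +2/-2 ion pair.
#'
#' @param charge_product q1*q2 in units of e^2.
#' @param dielectric relative dielectric constant (> 1).
#' @param window numeric(2): radial fit window for the alignment, Å.
#' @return object of class `tail_spec`.
#' @export
tail_spec <- function(charge_product = -4, dielectric = 102,
                      window = c(12, 15)) {
  if (dielectric <= 1) abort("`dielectric` must exceed 1")
  if (window[1] >= window[2]) abort("fit window must be increasing")
  structure(list(charge_product = charge_product, dielectric = dielectric,
                 window = as.numeric(window)), class = "tail_spec")
}

#' Screened Coulomb interaction energy
#'
#' @param r distance(s), Å.
#' @param tail a [tail_spec()].
#' @return energy in kJ/mol: `charge_product * 1389.35458 / (dielectric * r)`.
#' @examples
#' coulomb_tail(14, tail_spec(-4, 102)) # about -3.892 kJ/mol
#' @export
coulomb_tail <- function(r, tail) {
  stopifnot(inherits(tail, "tail_spec"))
  tail$charge_product * coulomb_kjmol_ang / (tail$dielectric * r)
}

#' Align a PMF tail to zero (short-range convention)
#'
#' For a short-range model the PMF reaches zero at about twice the model
#' cutoff; the curve is shifted by the unweighted mean of W over
#' `[2 * model_cutoff, window_end]` so that the window mean is exactly zero.
#'
#' @param pmf a `radial_pmf`.
#' @param model_cutoff interaction cutoff of the model, Å (default 6, so the
#'   window starts at 12 Å).
#' @param window_end end of the averaging window, Å.
#' @return the shifted `radial_pmf`, alignment state `"zeroed_tail"`.
#' @export
align_tail_zero <- function(pmf, model_cutoff = 6, window_end = NULL) {
  stopifnot(inherits(pmf, "radial_pmf"))
  lo <- 2 * model_cutoff
  if (is.null(window_end)) window_end <- max(pmf$r)
  sel <- pmf$r >= lo & pmf$r <= window_end & is.finite(pmf$W)
  if (!any(sel)) abort("empty alignment window: no W values in [2*cutoff, window_end]")
  shift <- mean(pmf$W[sel])
  out <- pmf
  out$W <- out$W - shift
  attr(out, "alignment") <- "zeroed_tail"
  attr(out, "shift") <- shift
  out
}

#' Align a PMF to the screened-Coulomb tail (long-range convention)
#'
#' For a model with explicit long-range electrostatics W(r) does not vanish
#' at finite r; the curve is aligned to the analytic screened interaction
#' E(r) of the ion charges by subtracting the mean of `W - E` over the fit
#' window, so that afterwards the window mean of `W - E` is exactly zero.
#'
#' @param pmf a `radial_pmf`.
#' @param tail a [tail_spec()] (charges, dielectric, fit window).
#' @return the shifted `radial_pmf`, alignment state `"coulomb_tail"`, with
#'   the tail context attached.
#' @export
align_tail_coulomb <- function(pmf, tail) {
  stopifnot(inherits(pmf, "radial_pmf"), inherits(tail, "tail_spec"))
  sel <- pmf$r >= tail$window[1] & pmf$r <= tail$window[2] & is.finite(pmf$W)
  if (!any(sel)) abort("alignment window lies outside the PMF grid")
  shift <- mean(pmf$W[sel] - coulomb_tail(pmf$r[sel], tail))
  out <- pmf
  out$W <- out$W - shift
  attr(out, "alignment") <- "coulomb_tail"
  attr(out, "tail") <- tail
  attr(out, "shift") <- shift
  out
}

#' Standard-state association specification
#'
#' @param volume standard-state volume per formula unit, Å^3 (default 1660,
#'   the 1 M value; see [standard_state_volume()]).
#' @param r_star separation below which the pair counts as associated, Å
#'   (default 14, the Bjerrum-length convention for a 2:2 pair in water).
#' @return object of class `association_spec`.
#' @export
association_spec <- function(volume = 1660, r_star = 14) {
  if (volume <= 0 || r_star <= 0) abort("`volume` and `r_star` must be positive")
  structure(list(volume = volume, r_star = r_star), class = "association_spec")
}

# composite Simpson on a uniform grid (with 3/8 tail when the interval count
# is odd); `x` ascending, `y` same length
simpson_uniform <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  if (n == 2) return(diff(x) * mean(y))
  h <- diff(x)
  if (diff(range(h)) > 1e-8 * mean(h)) {
    # non-uniform fallback: trapezoid
    return(sum((y[-1] + y[-n]) / 2 * h))
  }
  h <- mean(h)
  m <- n - 1 # intervals
  if (m %% 2 == 0) {
    even <- seq(2, n - 1, by = 2)
    odd <- if (n >= 5) seq(3, n - 2, by = 2) else integer(0)
    return(h / 3 * (y[1] + y[n] + 4 * sum(y[even]) + 2 * sum(y[odd])))
  }
  # odd interval count: Simpson on the first m-3, 3/8 rule on the last 3
  if (m == 3) {
    return(3 * h / 8 * (y[1] + 3 * y[2] + 3 * y[3] + y[4]))
  }
  head_end <- n - 3
  simpson_uniform(x[1:head_end], y[1:head_end]) +
    3 * h / 8 * (y[head_end] + 3 * y[head_end + 1] + 3 * y[head_end + 2] + y[n])
}

#' Standard-state ion association free energy
#'
#' Integrates the aligned potential of mean force into the association free
#' energy `DeltaG = -kB T log( C0 * Int_0^r* 4 pi r^2 exp(-beta W(r)) dr )`,
#' with `C0 = 1/volume` the standard-state concentration.  Quadrature is
#' composite Simpson on the native grid from the smallest tabulated r to
#' `r_star` (interpolating W at `r_star` when it falls between grid points);
#' the hard-core region below the first grid point contributes zero because
#' `exp(-beta W)` vanishes there -- a note is emitted when that first point
#' exceeds 1 Å.
#'
#' @param pmf an aligned `radial_pmf` (state `"zeroed_tail"` or
#'   `"coulomb_tail"`; the alignment establishes the W -> 0 limit that makes
#'   the integral meaningful).
#' @param spec an [association_spec()].
#' @param thermo a [thermo_state()] (defaults to the PMF's own).
#' @return `DeltaG` in kJ/mol (class `assoc_fe`, a numeric scalar with the
#'   integral, `r_star` and standard-state volume attached; see
#'   [glance.assoc_fe()]).
#' @export
association_delta_g <- function(pmf, spec = association_spec(), thermo = NULL) {
  stopifnot(inherits(pmf, "radial_pmf"))
  if (!pmf_alignment(pmf) %in% c("zeroed_tail", "coulomb_tail")) {
    abort(paste0("association free energy requires an aligned PMF ",
                 "(zeroed_tail or coulomb_tail); call align_tail_zero() or ",
                 "align_tail_coulomb() first"))
  }
  thermo <- if (is.null(thermo)) attr(pmf, "thermo") else as_thermo(thermo)
  ok <- is.finite(pmf$W)
  r <- pmf$r[ok]
  W <- pmf$W[ok]
  if (spec$r_star > max(r) + 1e-9) {
    abort(sprintf("r* = %g Å lies beyond the PMF grid (max %g Å)",
                  spec$r_star, max(r)))
  }
  if (r[1] > 1) {
    inform(sprintf(
      "association_delta_g: hard-core region below r = %.3g Å contributes 0",
      r[1]))
  }
  sel <- r <= spec$r_star + 1e-12
  rr <- r[sel]
  WW <- W[sel]
  if (max(rr) < spec$r_star - 1e-12) {
    Wstar <- approx(r, W, xout = spec$r_star)$y
    rr <- c(rr, spec$r_star)
    WW <- c(WW, Wstar)
  }
  integrand <- 4 * pi * rr^2 * exp(-thermo$beta * WW)
  # Simpson on the uniform body; trapezoid on a trailing partial interval
  nuni <- length(rr)
  h <- diff(rr)
  if (nuni > 2 && abs(h[length(h)] - h[1]) > 1e-8 * h[1]) {
    I <- simpson_uniform(rr[-nuni], integrand[-nuni]) +
      h[length(h)] * (integrand[nuni - 1] + integrand[nuni]) / 2
  } else {
    I <- simpson_uniform(rr, integrand)
  }
  dg <- -thermo$kt * log(I / spec$volume)
  structure(dg, class = c("assoc_fe", "numeric"),
            integral = I, r_star = spec$r_star, volume = spec$volume,
            alignment = pmf_alignment(pmf), thermo = thermo)
}

#' @export
print.assoc_fe <- function(x, ...) {
  cat(sprintf("Ion association free energy: %.3f kJ/mol (r* = %g Å, V0 = %g Å^3, %s)\n",
              unclass(x)[1], attr(x, "r_star"), attr(x, "volume"),
              attr(x, "alignment")))
  invisible(x)
}

#' Effect of a different dielectric constant on the association free energy
#'
#' Replaces the screened-Coulomb tail `E(r; eps_old)` by `E(r; eps_new)`
#' beyond the start of the fit window (`W <- W - E_old + E_new` there),
#' recomputes the association free energy and returns the change.
#'
#' @param pmf a `radial_pmf` in state `"coulomb_tail"`.
#' @param new_dielectric the alternative dielectric constant.
#' @param spec an [association_spec()].
#' @return `DeltaDeltaG` (new minus old) in kJ/mol, with attributes
#'   `delta_g_old`, `delta_g_new` and `pmf` (the rescaled curve).
#' @export
dielectric_rescale <- function(pmf, new_dielectric, spec = association_spec()) {
  stopifnot(inherits(pmf, "radial_pmf"))
  if (pmf_alignment(pmf) != "coulomb_tail") {
    abort("dielectric rescaling requires a coulomb_tail-aligned PMF")
  }
  tail_old <- attr(pmf, "tail")
  tail_new <- tail_spec(tail_old$charge_product, new_dielectric,
                        tail_old$window)
  dg_old <- association_delta_g(pmf, spec)
  out <- pmf
  sel <- out$r >= tail_old$window[1]
  out$W[sel] <- out$W[sel] - coulomb_tail(out$r[sel], tail_old) +
    coulomb_tail(out$r[sel], tail_new)
  attr(out, "tail") <- tail_new
  dg_new <- association_delta_g(out, spec)
  structure(as.numeric(dg_new) - as.numeric(dg_old),
            delta_g_old = as.numeric(dg_old), delta_g_new = as.numeric(dg_new),
            pmf = out)
}

#' Association free energy by direct quadrature of a model potential
#'
#' Deterministic reference: treats the analytic pair potential itself as
#' W(r) (aligning it with the same tail convention as the sampled pipeline)
#' and evaluates the association integral on a fine grid.  Used as ground
#' truth for end-to-end parameter-recovery checks.
#'
#' @param potential a [pair_potential()].
#' @param alignment `"zeroed_tail"` or `"coulomb_tail"`.
#' @param spec an [association_spec()].
#' @param thermo a [thermo_state()].
#' @param window alignment window, Å.
#' @param dr quadrature spacing, Å.
#' @param r_min lower end of the tabulation, Å.
#' @return `DeltaG` in kJ/mol (class `assoc_fe`).
#' @export
association_delta_g_true <- function(potential,
                                     alignment = c("zeroed_tail", "coulomb_tail"),
                                     spec = association_spec(),
                                     thermo = thermo_state(),
                                     window = c(12, 15), dr = 0.01,
                                     r_min = NULL) {
  alignment <- match.arg(alignment)
  if (is.null(r_min)) r_min <- max(0.5, potential$inner_radius - 1)
  r <- seq(r_min, max(window[2], spec$r_star), by = dr)
  W <- pair_potential_energy(potential, r)
  pmf <- radial_pmf(r, W, thermo)
  pmf <- if (alignment == "zeroed_tail") {
    align_tail_zero(pmf, model_cutoff = window[1] / 2, window_end = window[2])
  } else {
    align_tail_coulomb(pmf, tail_spec(potential$charge_product,
                                      potential$dielectric, window))
  }
  association_delta_g(pmf, spec, thermo)
}
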