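#' Physical constants and thermodynamic state
#'
#' The package works in a fixed unit system: lengths in Angstrom (Å), times in
#' ps, temperatures in K and energies in kJ/mol.  Charges are in units of the
#' elementary charge e.  Two constants tie these together:
#' `kb_kjmol` is Boltzmann's constant in kJ/mol/K and `coulomb_kjmol_ang` is
#' e^2/(4 pi eps0) in kJ Å / mol, so that the Coulomb energy of two unit
#' charges at distance r Å is `coulomb_kjmol_ang / r` kJ/mol.
#'
#' @name constants
NULL

#' @rdname constants
#' @export
kb_kjmol <- 0.008314463

#' @rdname constants
#' @export
coulomb_kjmol_ang <- 1389.35458

#' Volume per formula unit at a reference molar concentration
#'
#' Converts a molar concentration to the volume (Å^3) occupied by one formula
#' unit, the standard-state volume entering the ion association free energy.
#' At 1 M this is 1/C0 ≈ 1660 Å^3.
#'
#' @param molarity concentration in mol/L.
#' @return volume per formula unit in Å^3.
#' @examples
#' standard_state_volume()      # ~1660 Å^3 at 1 M
#' @export
standard_state_volume <- function(molarity = 1) {
  avogadro <- 6.02214076e23
  litre_ang3 <- 1e27 # 1 L in Å^3
  litre_ang3 / (avogadro * molarity)
}

#' Thermodynamic state
#'
#' Bundles temperature, Boltzmann's constant and the inverse temperature
#' beta = 1/(kB T) used throughout reweighting and free-energy integration.
#'
#' @param temperature temperature in K.  The default (330 K) matches the
#'   simulation temperature used for the calcium carbonate system, chosen
#'   above room temperature to compensate the known temperature shift of the
#'   underlying density functional.
#' @return object of class `thermo_state` with fields `temperature`, `kb`,
#'   `kt` (kB·T, kJ/mol) and `beta` (mol/kJ).
#' @examples
#' th <- thermo_state(330)
#' th$beta * th$kb * th$temperature  # 1 by construction
#' @export
thermo_state <- function(temperature = 330) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature < 0) {
    abort("`temperature` must be a single non-negative number (K)")
  }
  kt <- kb_kjmol * temperature
  structure(
    list(
      temperature = temperature,
      kb = kb_kjmol,
      kt = kt,
      beta = if (temperature > 0) 1 / kt else Inf
    ),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %g K, kB T = %.6g kJ/mol\n",
              x$temperature, x$kt))
  invisible(x)
}

as_thermo <- function(x) {
  if (inherits(x, "thermo_state")) return(x)
  if (is.numeric(x) && length(x) == 1) return(thermo_state(x))
  abort("expected a `thermo_state` or a temperature in K")
}
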