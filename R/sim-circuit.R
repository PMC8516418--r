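#' Forward model of the whole-cell three-element equivalent circuit
#'
#' Computes the complex admittance seen by the pipette for the standard
#' patch-clamp circuit: series (access) conductance `Gs` in series with the
#' parallel combination of membrane conductance `Gm` and membrane capacitance
#' `Cm`,
#' `Y = Gs*(Gm + i*omega*Cm) / (Gs + Gm + i*omega*Cm)`,
#' together with the DC conductance `Gt = Gs*Gm / (Gs + Gm)`.
#'
#' @param Cm membrane capacitance, farads (>= 0).
#' @param Gm membrane conductance, siemens (> 0).
#' @param Gs series conductance, siemens (> 0).
#' @param f sinusoidal stimulus frequency, Hz.
#' @return list with `Y` (complex, siemens) and `Gt` (siemens).
#' @seealso [solve_equivalent_circuit()] for the inversion.
#' @export
simulate_whole_cell_admittance <- function(Cm, Gm, Gs, f) {
  stopifnot(Cm >= 0, Gm > 0, Gs > 0, f > 0)
  omega <- 2 * pi * f
  w <- complex(real = Gm, imaginary = omega * Cm)
  list(Y = Gs * w / (Gs + w), Gt = Gs * Gm / (Gs + Gm))
}
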