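#' Standard binding Gibbs energy from the association constant
#'
#' \deqn{\Delta G^\circ_b = -RT \ln K_b}
#' with R = 8.314 J mol^-1 K^-1 and the result in kJ mol^-1.
#'
#' @param K_b Association constant, M^-1 (> 0, vectorised).
#' @param T Temperature, K (> 0).
#' @return Gibbs energy of binding, kJ mol^-1.
#' @examples
#' gibbs_from_kb(6778, 300) # about -22 kJ/mol
#' @export
gibbs_from_kb <- function(K_b, T) {
  if (any(K_b <= 0)) {
    abort("`K_b` must be positive.", class = "bindspectra_error")
  }
  if (any(T <= 0)) {
    abort("`T` must be positive (kelvin).", class = "bindspectra_error")
  }
  -R_GAS * T * log(K_b) / 1000
}

#' Two-point van't Hoff binding enthalpy
#'
#' The standard binding enthalpy from association constants measured at two
#' temperatures, assuming \eqn{\Delta H^\circ} constant over the interval:
#' \deqn{\Delta H^\circ = \frac{\Delta G^\circ(T_1)/T_1 -
#'   \Delta G^\circ(T_2)/T_2}{1/T_1 - 1/T_2}
#'   = \frac{R \ln(K_2/K_1)}{1/T_1 - 1/T_2}.}
#' Both algebraic forms are evaluated and must agree to 1e-9 relative; a
#' disagreement indicates numerical corruption and raises an error.
#'
#' @param K1,K2 Association constants (M^-1) at `T1` and `T2`.
#' @param T1,T2 Temperatures, K. Must differ.
#' @return Binding enthalpy, kJ mol^-1.
#' @examples
#' vant_hoff_two_point(6778, 300, 3038, 310) # about -62 kJ/mol
#' @export
vant_hoff_two_point <- function(K1, T1, K2, T2) {
  if (T1 == T2) {
    abort("`T1` and `T2` must differ for a van't Hoff slope.",
          class = "bindspectra_error")
  }
  dG1 <- gibbs_from_kb(K1, T1)
  dG2 <- gibbs_from_kb(K2, T2)
  dH_gibbs <- (dG1 / T1 - dG2 / T2) / (1 / T1 - 1 / T2)
  dH_logratio <- R_GAS * log(K2 / K1) / (1 / T1 - 1 / T2) / 1000
  if (abs(dH_gibbs - dH_logratio) > 1e-9 * max(abs(dH_gibbs), 1)) {
    abort("Internal inconsistency between van't Hoff forms.",
          class = "bindspectra_error")
  }
  dH_gibbs
}

#' Binding entropy from Gibbs energy and enthalpy
#'
#' Rearranges \eqn{\Delta G^\circ = \Delta H^\circ - T \Delta S^\circ}:
#' \deqn{\Delta S^\circ = (\Delta H^\circ - \Delta G^\circ) \cdot 1000 / T}
#' (inputs in kJ mol^-1, result in J mol^-1 K^-1).
#'
#' @param delta_G Gibbs energy of binding, kJ mol^-1.
#' @param delta_H Binding enthalpy, kJ mol^-1.
#' @param T Temperature, K (> 0).
#' @return Binding entropy, J mol^-1 K^-1.
#' @examples
#' entropy_from_gh(-22, -62.1, 300) # about -134 J/mol/K
#' @export
entropy_from_gh <- function(delta_G, delta_H, T) {
  if (any(T <= 0)) {
    abort("`T` must be positive (kelvin).", class = "bindspectra_error")
  }
  (delta_H - delta_G) * 1000 / T
}

#' Classify the dominant intermolecular force from thermodynamic signs
#'
#' The classical sign rules for protein-ligand association: negative
#' enthalpy and entropy changes indicate van der Waals contacts and/or
#' hydrogen bonding; positive enthalpy and entropy indicate hydrophobic
#' burial; negative enthalpy with positive entropy indicates electrostatic
#' interactions. Zero (or mixed) signs are reported as `"mixed"`.
#'
#' @param delta_H Binding enthalpy, kJ mol^-1.
#' @param delta_S Binding entropy, J mol^-1 K^-1.
#' @return One of `"vdW_or_Hbond"`, `"hydrophobic"`, `"electrostatic"`,
#'   `"mixed"`.
#' @examples
#' classify_driving_force(-62.1, -133.6)
#' @export
classify_driving_force <- function(delta_H, delta_S) {
  if (!is.finite(delta_H) || !is.finite(delta_S)) {
    abort("`delta_H` and `delta_S` must be finite.",
          class = "bindspectra_error")
  }
  if (delta_H < 0 && delta_S < 0) {
    "vdW_or_Hbond"
  } else if (delta_H > 0 && delta_S > 0) {
    "hydrophobic"
  } else if (delta_H < 0 && delta_S > 0) {
    "electrostatic"
  } else {
    "mixed"
  }
}

#' Thermodynamic table from isotherms at two temperatures
#'
#' Chains the van't Hoff analysis: \eqn{\Delta G^\circ} at each temperature
#' from its binding constant, a shared \eqn{\Delta H^\circ} from the
#' two-point van't Hoff relation, and \eqn{\Delta S^\circ} at each
#' temperature from the Gibbs-Helmholtz identity. The chained identity
#' \eqn{\Delta G = \Delta H - T \Delta S} therefore holds at both
#' temperatures by construction, and is asserted to 0.1 kJ mol^-1.
#'
#' @param result_T1,result_T2 Either [isotherm_fit][double_reciprocal_fit]
#'   objects or lists with elements `K_b` (M^-1) and `temperature` (K), at
#'   two distinct temperatures.
#' @return A tibble with one row per temperature: `temperature_K`,
#'   `K_b`, `delta_G_kJ_mol`, `delta_H_kJ_mol`, `delta_S_J_mol_K`, and
#'   `driving_force` (from [classify_driving_force()]).
#' @examples
#' thermo_table(list(K_b = 6778, temperature = 300),
#'              list(K_b = 3038, temperature = 310))
#' @export
thermo_table <- function(result_T1, result_T2) {
  take <- function(r) list(K_b = r$K_b, T = r$temperature)
  a <- take(result_T1)
  b <- take(result_T2)
  if (is.null(a$K_b) || is.null(b$K_b) || is.null(a$T) || is.null(b$T)) {
    abort("Inputs must carry `K_b` and `temperature` fields.",
          class = "bindspectra_error")
  }
  if (a$T == b$T) {
    abort("The two isotherms must be at distinct temperatures.",
          class = "bindspectra_error")
  }
  dH <- vant_hoff_two_point(a$K_b, a$T, b$K_b, b$T)
  out <- tibble(
    temperature_K = c(a$T, b$T),
    K_b = c(a$K_b, b$K_b)
  )
  out$delta_G_kJ_mol <- gibbs_from_kb(out$K_b, out$temperature_K)
  out$delta_H_kJ_mol <- dH
  out$delta_S_J_mol_K <- entropy_from_gh(out$delta_G_kJ_mol, dH,
                                         out$temperature_K)
  resid_kJ <- abs(out$delta_G_kJ_mol -
                    (dH - out$temperature_K * out$delta_S_J_mol_K / 1000))
  stopifnot(all(resid_kJ <= 0.1))
  out$driving_force <- vapply(
    seq_len(nrow(out)),
    function(i) classify_driving_force(dH, out$delta_S_J_mol_K[i]),
    character(1)
  )
  out
}
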