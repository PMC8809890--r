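#' Screened Coulomb energy of the charged beads
#'
#' Sum of pairwise Debye-Hueckel terms
#' `q_i q_j B exp(-d / lambda_D) / max(d, floor)` over all charged beads:
#' deprotonated carboxylates carry -1, the essential arginine aR176 +1.
#'
#' @param state An [fo_state()].
#' @param phi Ring angle in degrees.
#' @param model An [fo_model()].
#' @return Energy in kT.
#' @export
coulomb_energy <- function(state, phi, model) {
  unname(fo_energy_cpp(.model_to_cpp(model), as.integer(state),
                       .deg2rad(phi))[["v_coulomb"]])
}

#' Membrane-burial penalty of deprotonated c-sites
#'
#' Each deprotonated c-site whose stator-relative angle lies outside the
#' a-facing window pays `eps_mem` kT (edges smoothed over a small angular
#' scale so the torque is defined everywhere); protonated sites pay nothing.
#'
#' @inheritParams coulomb_energy
#' @param eps_mem Optional override of the model's penalty (kT).
#' @return Energy in kT.
#' @export
membrane_penalty <- function(state, phi, model, eps_mem = NULL) {
  mc <- .model_to_cpp(model)
  if (!is.null(eps_mem)) {
    if (eps_mem < 0) stop("eps_mem must be >= 0")
    mc$eps_mem <- eps_mem
  }
  unname(fo_energy_cpp(mc, as.integer(state), .deg2rad(phi))[["v_mem"]])
}

#' Free energy of protonating a site from a reservoir
#'
#' `ln(10) kT (pH_reservoir - pKa) + ` the electrostatic work of moving the
#' proton from that reservoir to the site's depth along the membrane
#' potential profile (`psi_fraction_at_ring` of the drop measured from the
#' matrix side; kT/e = 25.693 mV at 298 K).
#'
#' @param pKa The site's pKa.
#' @param env An [fo_env()].
#' @param reservoir `"IMS"` or `"matrix"`.
#' @return Free energy change in kT (negative = protonation favourable).
#' @examples
#' protonation_free_energy(8, fo_env(delta_psi = 0), "IMS")  # -ln(10)
#' @export
protonation_free_energy <- function(pKa, env = fo_env(),
                                    reservoir = c("IMS", "matrix")) {
  reservoir <- match.arg(reservoir)
  psi_site <- env$psi_fraction_at_ring * env$delta_psi
  psi_res <- switch(reservoir, IMS = env$delta_psi, matrix = 0)
  pH <- switch(reservoir, IMS = env$pH_IMS, matrix = env$pH_matrix)
  .LN10 * (pH - pKa) * env$kT + (psi_site - psi_res) / env$mv_per_kT
}

#' Total energy and its breakdown
#'
#' `V_total = V_coulomb + V_mem + V_pKa + V_background`.  The protonation
#' term uses the IMS reservoir as reference, so energy differences between
#' two protonation states decompose into per-site protonation free energies
#' (IMS reference) plus the Coulomb and membrane differences.
#'
#' @inheritParams coulomb_energy
#' @return List of class `fo_energy` with components `v_coulomb`, `v_mem`,
#'   `v_pka`, `v_background`, `total` (kT).
#' @export
total_energy <- function(state, phi, model) {
  v <- fo_energy_cpp(.model_to_cpp(model), as.integer(state), .deg2rad(phi))
  structure(as.list(v), class = "fo_energy")
}

#' @export
print.fo_energy <- function(x, ...) {
  cat(sprintf(
    "V_total = %.4f kT (Coulomb %.4f, membrane %.4f, pKa %.4f, bg %.4f)\n",
    x$total, x$v_coulomb, x$v_mem, x$v_pka, x$v_background))
  invisible(x)
}

#' Torque on the ring angle
#'
#' Minus the derivative of the total energy with respect to the ring angle,
#' in kT per radian.
#'
#' @inheritParams coulomb_energy
#' @return Torque in kT/rad.
#' @export
fo_torque <- function(state, phi, model) {
  fo_torque_cpp(.model_to_cpp(model), as.integer(state), .deg2rad(phi))
}
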