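#' Environmental conditions driving the motor
#'
#' pH of the two aqueous reservoirs and the membrane potential.  The IMS
#' (periplasmic-equivalent) side is the positive, acidic side.  kT is the
#' internal energy unit; millivolts convert at 25.693 mV/kT (T = 298 K).
#' `psi_fraction_at_ring` is the fraction of the potential drop between the
#' IMS bulk and the depth of the protonatable sites.
#'
#' @param pH_IMS,pH_matrix Reservoir pH values (defaults 7.0 and 8.0).
#' @param delta_psi Membrane potential in mV, IMS side positive (default 150).
#' @param psi_fraction_at_ring Fraction in `[0, 1]` (default 0.5).
#' @param mv_per_kT Conversion factor, mV per kT (default 25.693).
#' @return List of class `fo_env`.
#' @export
fo_env <- function(pH_IMS = 7.0, pH_matrix = 8.0, delta_psi = 150,
                   psi_fraction_at_ring = 0.5, mv_per_kT = 25.693) {
  if (pH_IMS <= 0 || pH_matrix <= 0) stop("pH values must be positive")
  if (psi_fraction_at_ring < 0 || psi_fraction_at_ring > 1)
    stop("psi_fraction_at_ring must be in [0, 1]")
  structure(list(pH_IMS = pH_IMS, pH_matrix = pH_matrix,
                 delta_psi = delta_psi,
                 psi_fraction_at_ring = psi_fraction_at_ring,
                 mv_per_kT = mv_per_kT, kT = 1),
            class = "fo_env")
}

#' Energetic and kinetic constants of the reduced model
#'
#' @param B Coulomb coupling strength (kT nm).
#' @param debye_length Screening length (nm).
#' @param dist_floor Minimum-distance floor (nm) preventing singularities.
#' @param eps_mem Penalty (kT) per deprotonated c-site in the membrane
#'   sector.
#' @param g_theta0,g_sigma Centre and width (degrees) of the Gaussian
#'   side-chain orientation factor.
#' @param reservoir_weight Constant attempt weight of reservoir-exchange
#'   channels.
#' @param pKa_aE223,pKa_aE162 Relay pKa values.  The default 8.0 matches the
#'   c-site glutamate (buried-carboxylate upshift), making c-site/relay hops
#'   thermoneutral so that the proton-motive driving acts entirely at the
#'   reservoir exchanges and the relays neither trap protons nor add a
#'   chemical barrier.
#' @param background_amplitude,background_n_fold,background_phase Optional
#'   smooth periodic background potential
#'   `amplitude * cos(n_fold * phi + phase)` (amplitude in kT, phase in
#'   degrees); stands in for the non-electrostatic protein energy and is
#'   identically zero by default.
#' @return List of class `fo_energetics`.
#' @export
fo_energetics <- function(B = 2.0, debye_length = 1.0, dist_floor = 0.3,
                          eps_mem = 8.0, g_theta0 = 0, g_sigma = 30,
                          reservoir_weight = 1.0, pKa_aE223 = 8.0,
                          pKa_aE162 = 8.0, background_amplitude = 0,
                          background_n_fold = 10L, background_phase = 0) {
  if (g_sigma <= 0) stop("configuration error: g_sigma must be positive")
  if (eps_mem < 0) stop("eps_mem must be >= 0")
  if (reservoir_weight < 0 || reservoir_weight > 1)
    stop("reservoir_weight must be in [0, 1]")
  structure(list(B = B, debye_length = debye_length, dist_floor = dist_floor,
                 eps_mem = eps_mem, g_theta0 = g_theta0, g_sigma = g_sigma,
                 reservoir_weight = reservoir_weight,
                 pKa_aE223 = pKa_aE223, pKa_aE162 = pKa_aE162,
                 background_amplitude = background_amplitude,
                 background_n_fold = as.integer(background_n_fold),
                 background_phase = background_phase),
            class = "fo_energetics")
}

#' Assemble the reduced Fo motor model
#'
#' Bundles geometry, per-site transfer parameters (after applying the
#' mutation pattern), energetic constants and environmental conditions into
#' one model object consumed by the energy, Monte Carlo and dynamics
#' routines.
#'
#' @param mutant Mutation pattern string (`""` for wild type, `"e"`,
#'   `"ef"`, ...).
#' @param geometry An [fo_geometry()].
#' @param env An [fo_env()].
#' @param energetics An [fo_energetics()].
#' @param glu,asp Site parameter bundles (see [fo_site_params()]); pass
#'   overrides here for the sensitivity variants.
#' @return Object of class `fo_model`.
#' @examples
#' m <- fo_model("ef")
#' m$site_params[m$site_params$residue_kind == "ASP", ]
#' @export
fo_model <- function(mutant = "", geometry = fo_geometry(), env = fo_env(),
                     energetics = fo_energetics(),
                     glu = fo_site_params("GLU"), asp = fo_site_params("ASP")) {
  pattern <- if (is.character(mutant)) fo_mutation(mutant) else mutant
  structure(list(geometry = geometry, env = env, energetics = energetics,
                 mutation = pattern,
                 site_params = apply_mutations(pattern, glu, asp)),
            class = "fo_model")
}

#' @export
print.fo_model <- function(x, ...) {
  nm <- if (nzchar(x$mutation$name)) x$mutation$name else "WT"
  cat("Reduced Fo motor model (", nm, ")\n", sep = "")
  cat("  ", sum(x$site_params$residue_kind == "ASP"),
      "aspartate-substituted c-site(s);",
      "pH", x$env$pH_IMS, "/", x$env$pH_matrix, ", delta psi",
      x$env$delta_psi, "mV\n")
  invisible(x)
}

# flatten an fo_model into the numeric list (angles in radians) that the
# C++ kernels consume
.model_to_cpp <- function(model) {
  g <- model$geometry; e <- model$energetics; env <- model$env
  list(
    n_sites = g$n_subunits,
    c_radius = g$c_radius, a_radius = g$a_radius,
    site_offsets = .deg2rad(g$site_offsets),
    ang_e162 = .deg2rad(g$angle_aE162),
    ang_r176 = .deg2rad(g$angle_aR176),
    ang_e223 = .deg2rad(g$angle_aE223),
    window_half = .deg2rad(g$window_half_width),
    edge_scale = .deg2rad(g$edge_smooth) / 4,
    A = model$site_params$A, r0 = model$site_params$r0,
    pka = model$site_params$pKa,
    pka_e223 = e$pKa_aE223, pka_e162 = e$pKa_aE162,
    B = e$B, lambda_d = e$debye_length, dist_floor = e$dist_floor,
    eps_mem = e$eps_mem,
    g_theta0 = .deg2rad(e$g_theta0), g_sigma = .deg2rad(e$g_sigma),
    reservoir_weight = e$reservoir_weight,
    pH_ims = env$pH_IMS, pH_matrix = env$pH_matrix,
    delta_psi = env$delta_psi, psi_fraction = env$psi_fraction_at_ring,
    mv_per_kt = env$mv_per_kT,
    bg_amp = e$background_amplitude, bg_nfold = e$background_n_fold,
    bg_phase = .deg2rad(e$background_phase)
  )
}

#' Protonation state of the twelve protonatable sites
#'
#' Ordered occupancy flags for the ten c-ring carboxylates `a`..`j`
#' followed by the two a-subunit relays `aE223` and `aE162`.
#'
#' @param occupancy Integer vector of length 12 of 0/1 flags, or a
#'   12-character string of 0s and 1s.
#' @param deprotonated Alternatively, labels of sites to deprotonate
#'   (all others protonated); relays are addressed as `"aE223"` / `"aE162"`.
#' @return Named integer vector of class `fo_state`.
#' @examples
#' fo_state(deprotonated = c("a", "aE162"))
#' @export
fo_state <- function(occupancy = NULL, deprotonated = NULL) {
  nm <- c(.site_labels, "aE223", "aE162")
  if (is.null(occupancy)) {
    occupancy <- rep(1L, 12L)
    if (!is.null(deprotonated)) {
      bad <- setdiff(deprotonated, nm)
      if (length(bad)) stop("unknown site(s): ", paste(bad, collapse = ", "))
      occupancy[match(deprotonated, nm)] <- 0L
    }
  } else if (is.character(occupancy) && length(occupancy) == 1L) {
    if (nchar(occupancy) != 12L || grepl("[^01]", occupancy))
      stop("occupancy string must be 12 characters of 0/1")
    occupancy <- as.integer(strsplit(occupancy, "")[[1]])
  }
  occupancy <- as.integer(occupancy)
  if (length(occupancy) != 12L || anyNA(occupancy) ||
      !all(occupancy %in% 0:1))
    stop("occupancy must be 12 flags of 0/1")
  structure(setNames(occupancy, nm), class = "fo_state")
}

#' @export
print.fo_state <- function(x, ...) {
  cat("Protonation state [a..j, aE223, aE162]:",
      paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

#' Default initial protonation state
#'
#' All c-sites protonated except those whose angle at `phi` lies strictly
#' between the two relays (the a-facing channel mouth); the IMS relay aE223
#' starts loaded and the matrix relay aE162 empty.
#'
#' @param model An `fo_model`.
#' @param phi Initial ring angle (degrees).
#' @return An [fo_state()].
#' @export
initial_state <- function(model, phi = 0) {
  g <- model$geometry
  rel <- .wrap_deg(phi + g$site_offsets - g$angle_aR176)
  occ <- rep(1L, 12L)
  occ[rel > g$angle_aE162 & rel < g$angle_aE223] <- 0L
  occ[11L] <- 1L  # aE223 loaded from the IMS
  occ[12L] <- 0L  # aE162 empty toward the matrix
  fo_state(occ)
}

# wrap degrees to (-180, 180]
.wrap_deg <- function(x) {
  y <- (x + 180) %% 360
  y[y == 0] <- 360
  y - 180
}
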