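#' Distance factor of the proton-transfer weight
#'
#' `f(r) = min(1, exp(-A (r - r0)))`: exponential decay beyond the offset
#' distance `r0` (the summed side-chain lengths of donor and acceptor),
#' capped at 1 so the weight is a probability factor.
#'
#' @param r Donor-acceptor distance (nm), `r >= 0`.
#' @param params An [fo_site_params()] (fields `A`, `r0`).
#' @return Dimensionless factor in `[0, 1]`.
#' @examples
#' distance_factor(1.2, fo_site_params("GLU"))  # exp(-1)
#' @export
distance_factor <- function(r, params) {
  stopifnot(all(r >= 0))
  pmin(1, exp(-params$A * (r - params$r0)))
}

#' Side-chain orientation factor
#'
#' Gaussian in the angle `theta` between the c-site's outward radial
#' direction and the site-to-relay direction:
#' `g(theta) = exp(-(theta - theta0)^2 / (2 sigma^2))`.
#'
#' @param theta Angle in degrees.
#' @param theta0,sigma Gaussian centre and width (degrees); `sigma > 0`.
#' @return Dimensionless factor in `(0, 1]`.
#' @export
orientation_factor <- function(theta, theta0 = 0, sigma = 30) {
  if (sigma <= 0) stop("configuration error: sigma must be positive")
  exp(-((theta - theta0)^2) / (2 * sigma^2))
}

#' Arginine gate factor
#'
#' Mimics the essential arginine aR176 that blocks proton leakage between
#' the two half-channels: a c-site may exchange with the matrix relay aE162
#' only while on the matrix side of aR176, and with the IMS relay aE223 only
#' on the IMS side.  Reservoir-exchange channels are ungated.
#'
#' @param site_angle Stator-relative angle of the c-site (degrees).
#' @param channel One of `"release"` (c <-> aE162), `"uptake"`
#'   (aE223 <-> c), `"relay_ims"`, `"relay_matrix"`.
#' @param geometry An [fo_geometry()].
#' @return 0 or 1.
#' @export
arg_gate <- function(site_angle, channel = c("release", "uptake",
                                             "relay_ims", "relay_matrix"),
                     geometry = fo_geometry()) {
  channel <- match.arg(channel)
  if (channel %in% c("relay_ims", "relay_matrix")) return(1)
  rel <- .wrap_deg(site_angle - geometry$angle_aR176)
  ok <- switch(channel,
               release = rel < 0 & rel > -180,
               uptake = rel > 0 & rel < 180)
  as.numeric(ok)
}

# planar helpers: distance and orientation angle between c-site at
# stator-relative angle `a` (deg) and a relay at angle `b` (deg)
.site_relay_distance <- function(geometry, a, b) {
  sqrt(geometry$c_radius^2 + geometry$a_radius^2 -
         2 * geometry$c_radius * geometry$a_radius * cos(.deg2rad(a - b)))
}

.site_relay_theta <- function(geometry, a, b) {
  ar <- .deg2rad(a); br <- .deg2rad(b)
  p <- geometry$c_radius * c(cos(ar), sin(ar))
  q <- geometry$a_radius * c(cos(br), sin(br))
  v <- q - p
  ct <- sum(c(cos(ar), sin(ar)) * v) / sqrt(sum(v^2))
  .rad2deg(acos(pmin(1, pmax(-1, ct))))
}

#' Proton-transfer attempt weight of a channel
#'
#' `w = f(r) g(theta) h(R176)`, evaluated symmetrically for the two
#' directions of a site-relay pair (distance and orientation do not depend
#' on direction), which preserves detailed balance.  Reservoir channels use
#' the model's constant attempt weight.
#'
#' @param model An [fo_model()].
#' @param site Subunit label `"a"`..`"j"` (ignored for reservoir channels).
#' @param channel Channel kind as in [arg_gate()].
#' @param phi Ring angle (degrees).
#' @return Weight in `[0, 1]`.
#' @export
transfer_weight <- function(model, site, channel = c("release", "uptake",
                                                     "relay_ims",
                                                     "relay_matrix"),
                            phi = 0) {
  channel <- match.arg(channel)
  if (channel %in% c("relay_ims", "relay_matrix"))
    return(model$energetics$reservoir_weight)
  i <- match(site, .site_labels)
  if (is.na(i)) stop("unknown subunit label: ", site)
  g <- model$geometry
  a <- phi + g$site_offsets[i]
  b <- switch(channel, release = g$angle_aE162, uptake = g$angle_aE223)
  h <- arg_gate(a, channel, g)
  if (h == 0) return(0)
  p <- list(A = model$site_params$A[i], r0 = model$site_params$r0[i])
  f <- distance_factor(.site_relay_distance(g, a, b), p)
  gg <- orientation_factor(.site_relay_theta(g, a, b),
                           model$energetics$g_theta0,
                           model$energetics$g_sigma)
  f * gg * h
}

#' Metropolis acceptance probability
#'
#' @param delta_energy Energy change of the trial move (kT).
#' @return `min(1, exp(-delta_energy))`.
#' @export
metropolis_acceptance <- function(delta_energy) {
  stopifnot(all(is.finite(delta_energy)))
  pmin(1, exp(-delta_energy))
}

#' One Monte Carlo proton-transfer sweep
#'
#' Iterates over all admissible channels (ten c-site/aE162, ten
#' c-site/aE223, and the two reservoir exchanges) in fresh random order.
#' Each admissible channel is attempted with probability equal to its
#' transfer weight; attempts are logged as trials and accepted with the
#' Metropolis probability of the total-energy change, in which case the move
#' is logged as a success and the occupancy updated.  Proton number changes
#' only through the reservoir channels.
#'
#' @param model An [fo_model()].
#' @param state An [fo_state()].
#' @param phi Ring angle (degrees).
#' @param md_step Timestamp recorded on the events.
#' @param seed Optional seed for reproducibility.
#' @return List with the new `state` and an `events` data frame (columns
#'   `md_step`, `channel_kind`, `subunit`, `direction`, `outcome`,
#'   `delta_energy`).
#' @export
mc_sweep <- function(model, state, phi, md_step = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- fo_sweep_cpp(.model_to_cpp(model), as.integer(state),
                      .deg2rad(phi), md_step)
  list(state = fo_state(res$occ), events = .decorate_events(res$events))
}

# map integer event codes to the external representation
.decorate_events <- function(ev) {
  su <- rep(NA_character_, length(ev$subunit))
  has <- ev$subunit >= 0
  su[has] <- .site_labels[ev$subunit[has] + 1L]
  data.frame(
    md_step = ev$md_step,
    channel_kind = .kind_names[ev$kind],
    subunit = su,
    direction = ifelse(ev$direction > 0, "forward", "reverse"),
    outcome = ifelse(ev$outcome == 1, "success", "trial"),
    delta_energy = ev$delta_energy,
    stringsAsFactors = FALSE
  )
}
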