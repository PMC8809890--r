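#' Rotor/stator geometry of the reduced Fo model
#'
#' Builds the planar geometry of the ten-site c-ring and the stator
#' (a-subunit) landmarks.  The rotational axis of the ring is the z-axis and
#' the essential arginine aR176 defines the x-axis (angle 0); the matrix-side
#' relay aE162 sits clockwise of it and the IMS-side relay aE223
#' counterclockwise, so a counterclockwise-moving c-site meets the matrix
#' relay first, then the arginine, then the IMS relay.  Counterclockwise is
#' the ATP-synthesis direction and is positive.
#'
#' Default radii are chosen so that a c-site aligned with a relay sits at
#' `a_radius - c_radius = 0.8` nm from it, the offset distance of the
#' glutamate proton-transfer weight.
#'
#' @param n_subunits Number of c-subunits in the ring (default 10).
#' @param c_radius,a_radius Radii (nm) of the c-site circle and of the stator
#'   landmark circle.
#' @param angle_aE162,angle_aR176,angle_aE223 Stator landmark angles
#'   (degrees).
#' @param window_half_width Half width (degrees) of the a-subunit-facing
#'   sector; c-sites outside it are in the membrane.
#' @param edge_smooth Angular scale (degrees) over which the membrane edge
#'   penalty is smoothed so that torque is defined everywhere.
#' @return An object of class `fo_geometry`.
#' @examples
#' g <- fo_geometry()
#' diff(g$site_offsets)   # 36 degrees apart
#' @export
fo_geometry <- function(n_subunits = 10L, c_radius = 2.5, a_radius = 3.3,
                        angle_aE162 = -36, angle_aR176 = 0,
                        angle_aE223 = 36, window_half_width = 72,
                        edge_smooth = 2) {
  n_subunits <- as.integer(n_subunits)
  if (is.na(n_subunits) || n_subunits < 3L)
    stop("configuration error: n_subunits must be an integer >= 3")
  if (!is.finite(c_radius) || c_radius <= 0 || !is.finite(a_radius) ||
      a_radius <= 0)
    stop("configuration error: radii must be positive")
  if (!(angle_aE162 < angle_aR176 && angle_aR176 < angle_aE223))
    stop("configuration error: require angle_aE162 < angle_aR176 < angle_aE223")
  if (window_half_width <= 0 || window_half_width > 180)
    stop("configuration error: window_half_width must be in (0, 180]")
  if (max(abs(c(angle_aE162, angle_aE223))) > window_half_width)
    stop("configuration error: the a-facing window must cover both relays")
  g <- list(
    n_subunits = n_subunits,
    c_radius = c_radius,
    a_radius = a_radius,
    site_offsets = (seq_len(n_subunits) - 1L) * 360 / n_subunits,
    angle_aE162 = angle_aE162,
    angle_aR176 = angle_aR176,
    angle_aE223 = angle_aE223,
    window_half_width = window_half_width,
    edge_smooth = edge_smooth,
    synthesis_sign = +1
  )
  class(g) <- "fo_geometry"
  g
}

#' @export
print.fo_geometry <- function(x, ...) {
  cat("Reduced Fo geometry:", x$n_subunits, "c-sites on a",
      x$c_radius, "nm ring\n")
  cat("  stator radius", x$a_radius, "nm; aE162 / aR176 / aE223 at",
      x$angle_aE162, "/", x$angle_aR176, "/", x$angle_aE223, "deg\n")
  cat("  a-facing window half-width", x$window_half_width, "deg\n")
  invisible(x)
}

#' Per-site proton-transfer parameters
#'
#' Parameter bundle (decay rate `A`, offset distance `r0`, `pKa`) of a
#' protonatable c-ring carboxylate.  Glutamate keeps a longer side chain and
#' an empirically raised pKa; the aspartate mutant has a side chain shorter
#' by one methylene group (smaller `r0`), a much faster distance decay
#' (no side-chain reorientation toward the relay) and a pKa lower by one
#' unit.  Defaults: GLU A = 2.5 /nm, r0 = 0.8 nm, pKa = 8.0;
#' ASP A = 9.0 /nm, r0 = 0.6 nm, pKa = 7.0.  Overrides support the
#' sensitivity variants A_ASP = 2.5 /nm and pKa_ASP = 7.8.
#'
#' @param residue_kind `"GLU"` or `"ASP"`.
#' @param A,r0,pKa Optional overrides of the kind defaults.
#' @return A list of class `fo_site_params` with fields `residue_kind`,
#'   `A` (1/nm), `r0` (nm), `pKa`, and the site charges.
#' @examples
#' fo_site_params("ASP")
#' @export
fo_site_params <- function(residue_kind = c("GLU", "ASP"), A = NULL,
                           r0 = NULL, pKa = NULL) {
  residue_kind <- match.arg(residue_kind)
  def <- switch(residue_kind,
                GLU = list(A = 2.5, r0 = 0.8, pKa = 8.0),
                ASP = list(A = 9.0, r0 = 0.6, pKa = 7.0))
  p <- list(residue_kind = residue_kind,
            A = if (is.null(A)) def$A else A,
            r0 = if (is.null(r0)) def$r0 else r0,
            pKa = if (is.null(pKa)) def$pKa else pKa,
            charge_deprotonated = -1, charge_protonated = 0)
  if (p$A <= 0 || p$r0 <= 0) stop("A and r0 must be positive")
  class(p) <- "fo_site_params"
  p
}

#' Mutation patterns on the c-ring
#'
#' Parses a pattern such as `""` (wild type), `"e"`, or `"ej"` into the set
#' of aspartate-substituted subunits.  For double mutants the separation is
#' the minimal number of c-subunits between the two mutated chains along the
#' ring (ef = 1, eg = 2, eh = 3, ei = 4, ej = 5).
#'
#' @param pattern Character string of mutated subunit labels among `a`..`j`.
#' @param allow_many Allow more than two mutated subunits (default `FALSE`).
#' @return List of class `fo_mutation` with `name`, `mutated_labels`,
#'   `separation`.
#' @examples
#' fo_mutation("ej")$separation  # 5
#' @export
fo_mutation <- function(pattern = "", allow_many = FALSE) {
  labels <- if (nzchar(pattern)) strsplit(pattern, "")[[1]] else character(0)
  if (anyDuplicated(labels)) stop("duplicated subunit label in pattern")
  bad <- setdiff(labels, .site_labels)
  if (length(bad))
    stop("unknown subunit label(s): ", paste(bad, collapse = ", "))
  if (length(labels) > 2 && !allow_many)
    stop("unsupported pattern: more than two mutated subunits")
  separation <- if (length(labels) == 2) {
    d <- abs(diff(match(labels, .site_labels)))
    min(d, 10L - d)
  } else 0L
  structure(list(name = pattern, mutated_labels = labels,
                 separation = as.integer(separation)),
            class = "fo_mutation")
}

#' Apply a mutation pattern to the ring
#'
#' Returns the per-site transfer-parameter table for the ten c-sites:
#' mutated labels get aspartate parameters, all others glutamate.
#'
#' @param pattern An `fo_mutation`, or a pattern string.
#' @param glu,asp Parameter bundles used for wild-type and mutated sites.
#' @return `data.frame` with one row per subunit `a`..`j` and columns
#'   `site`, `residue_kind`, `A`, `r0`, `pKa`.
#' @examples
#' apply_mutations("e")
#' @export
apply_mutations <- function(pattern = "", glu = fo_site_params("GLU"),
                            asp = fo_site_params("ASP")) {
  if (is.character(pattern)) pattern <- fo_mutation(pattern)
  stopifnot(inherits(pattern, "fo_mutation"))
  mut <- .site_labels %in% pattern$mutated_labels
  data.frame(
    site = .site_labels,
    residue_kind = ifelse(mut, asp$residue_kind, glu$residue_kind),
    A = ifelse(mut, asp$A, glu$A),
    r0 = ifelse(mut, asp$r0, glu$r0),
    pKa = ifelse(mut, asp$pKa, glu$pKa),
    stringsAsFactors = FALSE
  )
}
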