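#' Define the channel geometry and helix assignment
#'
#' Encodes the conventions used by every analysis stage: the four
#' transmembrane helix residue ranges, the pore axis (z by default, with z
#' increasing toward the extracellular side), the membrane z-slab, the
#' water-selection cylinder and the gate residues. Defaults follow the
#' Hv1 voltage-sensor domain: S1 97-120, S2 133-157, S3 166-188,
#' S4 193-214, with the constriction formed by Asp108 (S1), Leu143 and
#' Phe146 (S2), Phe178 (S3) and Arg204 (S4).
#'
#' @param helix_ranges named list mapping helix label to
#'   `c(first_residue, last_residue)`.
#' @param axis pore axis unit vector (only the z axis is supported by the
#'   analyses; kept for documentation of the convention).
#' @param membrane_z numeric `c(z_lo, z_hi)` membrane slab bounds, Angstrom.
#' @param water_cylinder_radius radius of the water-selection cylinder
#'   about the pore axis, Angstrom.
#' @param boundary_margin how far beyond the slab a water may sit and still
#'   be considered (Angstrom); spanning is judged against the slab itself.
#' @param gate_residues data.frame with columns `resnum`, `resname`.
#' @return object of class `"channel_definition"`.
#' @export
channel_definition <- function(helix_ranges = list(S1 = c(97, 120),
                                                   S2 = c(133, 157),
                                                   S3 = c(166, 188),
                                                   S4 = c(193, 214)),
                               axis = c(0, 0, 1),
                               membrane_z = c(-18, 18),
                               water_cylinder_radius = 8,
                               boundary_margin = 2,
                               gate_residues = data.frame(
                                 resnum = c(108L, 143L, 146L, 178L, 204L),
                                 resname = c("ASP", "LEU", "PHE", "PHE", "ARG"),
                                 stringsAsFactors = FALSE)) {
  stopifnot(length(membrane_z) == 2)
  if (membrane_z[1] >= membrane_z[2]) stop("membrane_z must satisfy z_lo < z_hi")
  if (water_cylinder_radius <= 0) stop("water_cylinder_radius must be > 0")
  rng <- do.call(rbind, helix_ranges)
  if (any(rng[, 1] > rng[, 2])) stop("helix ranges must be increasing")
  o <- order(rng[, 1])
  if (any(rng[o, 1][-1] <= rng[o, 2][-nrow(rng)]))
    stop("helix ranges must not overlap")
  structure(list(helix_ranges = helix_ranges,
                 axis = axis / sqrt(sum(axis^2)),
                 membrane_z = as.numeric(membrane_z),
                 water_cylinder_radius = water_cylinder_radius,
                 boundary_margin = boundary_margin,
                 gate_residues = gate_residues),
            class = "channel_definition")
}

#' Membrane electric field from potential and thickness
#'
#' The applied field is perpendicular to the membrane plane with magnitude
#' E = V / z where V is the membrane potential (mV) and z the membrane
#' thickness (Angstrom, ~36 A for a DOPC bilayer).
#'
#' @param potential_mV membrane potential, mV (sign preserved).
#' @param thickness_A membrane thickness, Angstrom; must be > 0.
#' @return object of class `"field_spec"` with `potential_mV`,
#'   `thickness_A` and `magnitude_mV_per_A`.
#' @export
field_magnitude <- function(potential_mV, thickness_A = 36) {
  if (!is.finite(thickness_A) || thickness_A <= 0)
    stop("membrane thickness must be positive, got ", thickness_A)
  structure(list(potential_mV = potential_mV, thickness_A = thickness_A,
                 magnitude_mV_per_A = potential_mV / thickness_A),
            class = "field_spec")
}

#' Detect the end of the equilibration stage from an RMSD series
#'
#' Scans the series for the first frame at which the least-squares slope of
#' the RMSD over the next `window` frames drops below `slope_tol` in
#' absolute value, i.e. the start of the plateau. A constant series returns
#' frame 1. Frames before the returned index are the equilibration stage
#' and are conventionally discarded from analysis.
#'
#' @param rmsd_series numeric RMSD values, Angstrom, one per frame.
#' @param window window length in frames for the slope fit.
#' @param slope_tol plateau threshold, Angstrom/frame.
#' @return 1-based index of the first equilibrated frame.
#' @export
detect_equilibration <- function(rmsd_series, window = 10, slope_tol = 1e-3) {
  n <- length(rmsd_series)
  if (n < 2 * window)
    stop("series too short: need at least 2*window = ", 2 * window,
         " frames, got ", n)
  xs <- seq_len(window)
  sxx <- sum((xs - mean(xs))^2)
  for (i in seq_len(n - window + 1)) {
    y <- rmsd_series[i:(i + window - 1)]
    slope <- sum((xs - mean(xs)) * (y - mean(y))) / sxx
    if (abs(slope) < slope_tol) return(i)
  }
  warning("no plateau found; returning start of final window")
  n - window + 1L
}
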