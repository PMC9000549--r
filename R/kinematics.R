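# Helix and sidechain z-axis kinematics: the displacement series that
# constitute the gating evidence (S4 up, S2 down, Phe146 leaving the
# Asp108 gate).

new_displacement_series <- function(label, frames, z, reference) {
  structure(list(label = label, frames = frames, z = as.numeric(z),
                 reference = reference),
            class = "displacement_series")
}

#' @export
print.displacement_series <- function(x, ...) {
  cat("<displacement_series> ", x$label, " (", x$reference, "), ",
      length(x$z), " frames, final z = ",
      sprintf("%.3f", x$z[length(x$z)]), " A\n", sep = "")
  invisible(x)
}

#' Helix z-displacement relative to the four-helix center
#'
#' Per frame, the z coordinate of each helix's alpha-carbon centroid minus
#' the z of the pooled four-helix alpha-carbon centroid (union of all Ca
#' atoms, not a mean of helix means, so the atom-count-weighted sum of the
#' four series is exactly zero in every frame). Optionally re-zeroed to the
#' first analyzed frame so the series read as displacements.
#'
#' @param traj a trajectory.
#' @param channel a [channel_definition()].
#' @param equil_start first analyzed frame.
#' @param rezero subtract the first analyzed value (default TRUE).
#' @return named list of `"displacement_series"`, one per helix.
#' @export
helix_z_series <- function(traj, channel, equil_start = 1, rezero = TRUE) {
  a <- traj$atoms
  sels <- lapply(names(channel$helix_ranges), function(h) {
    r <- channel$helix_ranges[[h]]
    sel <- select_atoms(a, residues = r[1]:r[2], segment = h,
                        mode = "alpha_carbon")
    if (length(sel) == 0)
      sel <- select_atoms(a, residues = r[1]:r[2], mode = "alpha_carbon")
    if (length(sel) == 0)
      stop("no alpha carbons found for helix ", h, " (residues ",
           r[1], "-", r[2], ")")
    sel
  })
  names(sels) <- names(channel$helix_ranges)
  pooled <- unlist(sels)
  frames <- equil_start:n_frames(traj)
  out <- lapply(names(sels), function(h) {
    z <- vapply(frames, function(k) {
      mean(traj$xyz[sels[[h]], 3, k]) - mean(traj$xyz[pooled, 3, k])
    }, numeric(1))
    if (rezero) z <- z - z[1]
    new_displacement_series(h, frames, z, "four_helix_center")
  })
  names(out) <- names(sels)
  out
}

#' Sidechain z-position series for one residue
#'
#' Per frame, the z of the residue's sidechain heavy-atom centroid, after
#' (optionally) superposing a fit selection onto the first analyzed frame
#' so that reference-frame motion is removed. The default fit selection is
#' the anchor residue's heavy atoms.
#'
#' @param traj a trajectory.
#' @param residue residue spec (number or `"204:ARG"`).
#' @param superpose_on residue spec used as superposition anchor, or NULL
#'   for raw z.
#' @param equil_start first analyzed frame.
#' @param rezero subtract the first analyzed value (default FALSE).
#' @return a `"displacement_series"`.
#' @export
sidechain_z_series <- function(traj, residue, superpose_on = NULL,
                               equil_start = 1, rezero = FALSE) {
  a <- traj$atoms
  p <- parse_residue_spec(residue)
  rows <- resolve_residue(a, p$resnum, p$resname)
  sc <- rows[a$element[rows] != "H" & !(a$name[rows] %in% .backbone_names)]
  if (length(sc) == 0)
    stop("residue ", format_residue(p),
         " has no sidechain heavy atoms (glycine?)")
  frames <- equil_start:n_frames(traj)
  fit <- NULL
  if (!is.null(superpose_on)) {
    pa <- parse_residue_spec(superpose_on)
    arow <- resolve_residue(a, pa$resnum, pa$resname)
    fit <- arow[a$element[arow] != "H"]
    if (length(fit) < 3)
      stop("anchor residue ", format_residue(pa),
           " has fewer than 3 heavy atoms for superposition")
  }
  ref <- if (!is.null(fit)) traj$xyz[fit, , frames[1]] else NULL
  z <- vapply(frames, function(k) {
    xyz <- traj$xyz[, , k]
    pos <- xyz[sc, , drop = FALSE]
    if (!is.null(fit)) {
      tf <- superpose(xyz[fit, , drop = FALSE], ref)
      pos <- apply_transform(tf, pos)
    }
    mean(pos[, 3])
  }, numeric(1))
  if (rezero) z <- z - z[1]
  new_displacement_series(format_residue(p), frames, z,
                          if (is.null(superpose_on)) "raw"
                          else "residue_superposition")
}

#' Signed z-gap between a gate residue and an anchor residue
#'
#' Per frame, z(gate sidechain centroid) - z(anchor sidechain centroid)
#' after superposing the channel on the anchor residue's heavy atoms
#' (Asp108 by convention: the hydrophilic member of the constriction).
#'
#' @param traj a trajectory.
#' @param gate_residue residue spec of the gate residue (e.g. `"146:PHE"`).
#' @param anchor residue spec of the anchor (default `"108:ASP"`).
#' @param equil_start first analyzed frame.
#' @return a `"displacement_series"` of the signed gap, Angstrom.
#' @export
gate_z_gap <- function(traj, gate_residue, anchor = "108:ASP",
                       equil_start = 1) {
  gate <- sidechain_z_series(traj, gate_residue, superpose_on = anchor,
                             equil_start = equil_start)
  anch <- sidechain_z_series(traj, anchor, superpose_on = anchor,
                             equil_start = equil_start)
  new_displacement_series(
    paste0(gate$label, "-", anch$label), gate$frames, gate$z - anch$z,
    "residue_superposition")
}

#' Mean displacement over the final fraction of a series
#'
#' The "moved up/down" verdicts are read from the mean over the last
#' `fraction` of analyzed frames.
#'
#' @param series a `"displacement_series"`.
#' @param fraction tail fraction (default 0.2).
#' @return numeric scalar, Angstrom.
#' @export
final_displacement <- function(series, fraction = 0.2) {
  n <- length(series$z)
  k <- max(1L, ceiling(fraction * n))
  mean(series$z[(n - k + 1L):n])
}
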