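# Deterministic sphere-fitting pore-radius profiler. For each z slice the
# pore radius is the largest sphere, centered in the slice plane, that
# touches no atom's van der Waals surface: radius(c) = min over atoms of
# (|c - atom| - vdw). The center is seeded on the pore axis and maximized
# by monotone hill climbing with shrinking steps, which confines the
# sphere to the pore basin: a monotone ascent cannot cross the
# negative-radius barrier of the channel wall, so the search never
# "escapes" to the open space outside the protein (the failure mode a
# global grid maximization would have). Fully reproducible - no
# Monte-Carlo walk.

#' Pore radius profile along the channel axis
#'
#' Uses all atoms of the four helix residue ranges. For each slice of the
#' z grid the sphere center starts on the pore axis and is moved by
#' steepest-ascent steps of size `grid_res`, halved down to 0.01 A once no
#' step improves, maximizing the clearance radius while staying inside the
#' pore basin (monotone ascent cannot cross the channel wall, where the
#' clearance is negative). Radii are clamped to `[0, r_max]`; a slice with
#' no atoms within reach reports `r_max` with a warning.
#'
#' @param frame a `traj_frame`.
#' @param channel a [channel_definition()].
#' @param z_step slice spacing, Angstrom.
#' @param r_max search/cap radius, Angstrom ("outside the pore").
#' @param grid_res coarse grid spacing, Angstrom.
#' @return object of class `"pore_profile"`: list with `z_grid`, `radii`,
#'   `centers` (n x 2 in-plane positions), `min_radius`, `min_z`.
#' @export
pore_profile <- function(frame, channel, z_step = 0.5, r_max = 10,
                         grid_res = 0.25) {
  frame <- as_frame(frame)
  a <- frame$atoms
  helix_res <- unlist(lapply(channel$helix_ranges, function(r) r[1]:r[2]))
  sel <- select_atoms(a, residues = helix_res, mode = "all")
  sel <- sel[!is_water(a$resname[sel])]
  if (length(sel) == 0) stop("no helix atoms for pore profiling")
  pos <- frame$xyz[sel, , drop = FALSE]
  vdw <- a$vdw[sel]
  axis_xy <- colMeans(pos[, 1:2, drop = FALSE])
  zg <- seq(channel$membrane_z[1], channel$membrane_z[2], by = z_step)
  max_vdw <- max(vdw)

  radius_at <- function(cx, cy, apos, avdw, dz2) {
    min(sqrt((apos[, 1] - cx)^2 + (apos[, 2] - cy)^2 + dz2) - avdw)
  }

  radii <- numeric(length(zg))
  centers <- matrix(NA_real_, length(zg), 2)
  warned <- FALSE
  for (s in seq_along(zg)) {
    z0 <- zg[s]
    near <- abs(pos[, 3] - z0) <= r_max + max_vdw
    if (!any(near)) {
      if (!warned) {
        warning("slice(s) with no atoms within reach; reporting r_max")
        warned <- TRUE
      }
      radii[s] <- r_max
      centers[s, ] <- axis_xy
      next
    }
    apos <- pos[near, , drop = FALSE]
    avdw <- vdw[near]
    dz2 <- (apos[, 3] - z0)^2
    # steepest-ascent hill climb from the axis, steps halved to 0.01 A
    cx <- axis_xy[1]; cy <- axis_xy[2]
    bv <- radius_at(cx, cy, apos, avdw, dz2)
    step <- grid_res
    while (step >= 0.005) {
      repeat {
        cand <- rbind(c(step, 0), c(-step, 0), c(0, step), c(0, -step),
                      c(step, step), c(step, -step), c(-step, step),
                      c(-step, -step))
        vals <- vapply(seq_len(8), function(i) {
          nx <- cx + cand[i, 1]; ny <- cy + cand[i, 2]
          if ((nx - axis_xy[1])^2 + (ny - axis_xy[2])^2 > r_max^2)
            return(-Inf)
          radius_at(nx, ny, apos, avdw, dz2)
        }, numeric(1))
        k <- which.max(vals)
        if (vals[k] <= bv + 1e-12) break
        cx <- cx + cand[k, 1]; cy <- cy + cand[k, 2]; bv <- vals[k]
      }
      step <- step / 2
    }
    radii[s] <- min(max(bv, 0), r_max)
    centers[s, ] <- c(cx, cy)
  }
  imin <- which.min(radii)
  structure(list(z_grid = zg, radii = radii, centers = centers,
                 min_radius = radii[imin], min_z = zg[imin]),
            class = "pore_profile")
}

#' Minimum radius and water passability of a pore profile
#'
#' A pore is passable for water when its minimum radius is at least the
#' water threshold (1.15 A, the conventional minimum for a water molecule
#' to pass).
#'
#' @param profile a `"pore_profile"`.
#' @param water_threshold passability threshold, Angstrom.
#' @return list with `min_radius`, `min_z`, `passable`.
#' @export
min_radius_and_passability <- function(profile, water_threshold = 1.15) {
  if (length(profile$radii) == 0) stop("empty pore profile")
  # 1e-9 A slack so threshold equality counts as passable despite
  # floating-point roundoff in the distance computation
  list(min_radius = profile$min_radius, min_z = profile$min_z,
       passable = profile$min_radius >= water_threshold - 1e-9)
}

#' @export
print.pore_profile <- function(x, ...) {
  cat("<pore_profile> ", length(x$z_grid), " slices, min radius ",
      sprintf("%.3f", x$min_radius), " A at z = ",
      sprintf("%.1f", x$min_z), " A\n", sep = "")
  invisible(x)
}
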