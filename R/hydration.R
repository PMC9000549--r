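# Water-wire detection: per-frame classification of whether the pore
# waters form a membrane-spanning hydrogen-bonded chain, and occupancy
# statistics over a trajectory.

#' Water-wire adjacency criteria
#'
#' Two waters are adjacent when their oxygen-oxygen distance is strictly
#' less than `oo_cutoff` (3.4 A by convention). `boundary_margin` extends
#' the water-selection slab beyond the membrane bounds; spanning is still
#' judged against the bounds themselves.
#'
#' @param oo_cutoff O-O distance cutoff, Angstrom (strict `<`).
#' @param boundary_margin slab extension, Angstrom.
#' @return object of class `"water_wire_criteria"`.
#' @export
water_wire_criteria <- function(oo_cutoff = 3.4, boundary_margin = 2) {
  if (oo_cutoff <= 0) stop("oo_cutoff must be > 0")
  structure(list(oo_cutoff = oo_cutoff, boundary_margin = boundary_margin),
            class = "water_wire_criteria")
}

#' Select water oxygens inside the channel
#'
#' Waters (TIP3/TIP3P/HOH/WAT...) whose oxygen lies within the cylinder of
#' radius `water_cylinder_radius` about the pore axis through the
#' four-helix centroid, with z in `[z_lo - margin, z_hi + margin]`.
#'
#' @param frame a `traj_frame`.
#' @param channel a [channel_definition()].
#' @return integer vector of atom `index` values of the selected oxygens
#'   (empty when the frame holds no channel waters).
#' @export
select_channel_waters <- function(frame, channel) {
  frame <- as_frame(frame)
  a <- frame$atoms
  helix_res <- unlist(lapply(channel$helix_ranges, function(r) r[1]:r[2]))
  hsel <- select_atoms(a, residues = helix_res, mode = "all")
  hsel <- hsel[!is_water(a$resname[hsel])]  # water resnums may collide
  if (length(hsel) == 0) stop("no helix atoms found for the pore axis")
  axis_xy <- colMeans(frame$xyz[hsel, 1:2, drop = FALSE])
  wat <- which(is_water(a$resname) & a$element == "O")
  if (length(wat) == 0) return(integer(0))
  xy <- frame$xyz[wat, 1:2, drop = FALSE]
  z <- frame$xyz[wat, 3]
  r2 <- (xy[, 1] - axis_xy[1])^2 + (xy[, 2] - axis_xy[2])^2
  m <- channel$boundary_margin
  keep <- r2 <= channel$water_cylinder_radius^2 &
    z >= channel$membrane_z[1] - m & z <= channel$membrane_z[2] + m
  a$index[wat[keep]]
}

#' Water-water adjacency edges
#'
#' @param oxygens atom `index` values of water oxygens.
#' @param frame a `traj_frame`.
#' @param criteria a [water_wire_criteria()].
#' @return two-column matrix of adjacent index pairs (i < j); zero rows
#'   when no pair is within the cutoff.
#' @export
water_adjacency <- function(oxygens, frame, criteria = water_wire_criteria()) {
  frame <- as_frame(frame)
  pos <- match(oxygens, frame$atoms$index)
  if (anyNA(pos)) stop("unknown atom index in oxygen set")
  out <- matrix(integer(0), ncol = 2,
                dimnames = list(NULL, c("i", "j")))
  if (length(pos) < 2) return(out)
  d <- as.matrix(stats::dist(frame$xyz[pos, , drop = FALSE]))
  hit <- which(upper.tri(d) & d < criteria$oo_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(out)
  cbind(i = oxygens[hit[, 1]], j = oxygens[hit[, 2]])
}

#' Classify one frame as continuous or discontinuous water-wire
#'
#' The frame is continuous when the water adjacency graph has a connected
#' component holding at least one oxygen at or above the extracellular
#' bound (`z >= z_hi`) and one at or below the intracellular bound
#' (`z <= z_lo`). The reported path is a fewest-hop route between boundary
#' waters; ties are broken toward the lexicographically smallest atom-index
#' sequence.
#'
#' @inheritParams select_channel_waters
#' @param criteria a [water_wire_criteria()].
#' @return list with `continuous` (logical) and `path` (atom indices of
#'   the spanning route, empty when discontinuous).
#' @export
classify_frame <- function(frame, channel, criteria = water_wire_criteria()) {
  frame <- as_frame(frame)
  ox <- select_channel_waters(frame, channel)
  if (length(ox) == 0) return(list(continuous = FALSE, path = integer(0)))
  pos <- match(ox, frame$atoms$index)
  z <- frame$xyz[pos, 3]
  bottom <- ox[z <= channel$membrane_z[1]]
  top <- ox[z >= channel$membrane_z[2]]
  if (length(bottom) == 0 || length(top) == 0)
    return(list(continuous = FALSE, path = integer(0)))
  edges <- water_adjacency(ox, frame, criteria)
  g <- igraph::make_empty_graph(n = length(ox), directed = FALSE)
  igraph::V(g)$name <- as.character(ox)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(cbind(match(edges[, 1], ox),
                                      match(edges[, 2], ox))))
  comp <- igraph::components(g)$membership
  bmem <- comp[match(bottom, ox)]
  tmem <- comp[match(top, ox)]
  spanning <- intersect(unique(bmem), unique(tmem))
  if (length(spanning) == 0) return(list(continuous = FALSE, path = integer(0)))
  # fewest-hop spanning route, deterministic tie-break
  dmat <- igraph::distances(g, v = match(bottom, ox), to = match(top, ox))
  best <- min(dmat)
  hits <- which(dmat == best, arr.ind = TRUE)
  # order candidate endpoint pairs by (bottom index, top index)
  ord <- order(bottom[hits[, 1]], top[hits[, 2]])
  hit <- hits[ord[1], ]
  ap <- igraph::all_shortest_paths(g, from = match(bottom, ox)[hit[1]],
                                   to = match(top, ox)[hit[2]])$vpaths
  paths <- lapply(ap, function(p) ox[as.integer(p)])
  key <- vapply(paths, function(p) paste(sprintf("%09d", p), collapse = ","),
                character(1))
  list(continuous = TRUE, path = paths[[order(key)[1]]])
}

#' Water-wire occupancy over a trajectory
#'
#' Applies [classify_frame()] to every analyzed frame (from `equil_start`
#' on). Occupancy is the fraction of continuous frames; run lengths are the
#' maximal runs of consecutive continuous frames (wire lifetimes).
#'
#' @param traj a trajectory.
#' @param channel a [channel_definition()].
#' @param criteria a [water_wire_criteria()].
#' @param equil_start first analyzed frame (1-based).
#' @return object of class `"water_wire_result"`: list with `frames`
#'   (analyzed frame indices), `per_frame` (logical), `spanning_paths`,
#'   `occupancy` and `run_lengths`.
#' @export
occupancy_series <- function(traj, channel, criteria = water_wire_criteria(),
                             equil_start = 1) {
  nf <- n_frames(traj)
  if (equil_start < 1 || equil_start > nf)
    stop("empty frame range: equil_start = ", equil_start,
         " with ", nf, " frames")
  frames <- equil_start:nf
  cls <- lapply(frames, function(k) classify_frame(get_frame(traj, k),
                                                   channel, criteria))
  per_frame <- vapply(cls, `[[`, logical(1), "continuous")
  r <- rle(per_frame)
  structure(list(frames = frames, per_frame = per_frame,
                 spanning_paths = lapply(cls, `[[`, "path"),
                 occupancy = mean(per_frame),
                 run_lengths = r$lengths[r$values]),
            class = "water_wire_result")
}

#' @export
print.water_wire_result <- function(x, ...) {
  cat("<water_wire_result> ", length(x$per_frame), " frames, occupancy ",
      sprintf("%.4f", x$occupancy), ", ", length(x$run_lengths),
      " continuous run(s)\n", sep = "")
  invisible(x)
}
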