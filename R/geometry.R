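# Reference-frame machinery: atom selection, centroids, Kabsch
# superposition and RMSD series.

.backbone_names <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2",
                     "HN", "HA", "H", "H1", "H2", "H3")

#' Select atoms from an atom table
#'
#' @param atoms an atom table.
#' @param residues integer residue numbers to keep (NULL = all).
#' @param segment segment label(s) to keep (NULL = all).
#' @param mode atom subset: `"alpha_carbon"` (CA only),
#'   `"sidechain_heavy"` (non-hydrogen atoms beyond the backbone),
#'   `"all_heavy"`, or `"all"`.
#' @return integer vector of row positions into `atoms`.
#' @export
select_atoms <- function(atoms, residues = NULL, segment = NULL,
                         mode = c("all_heavy", "alpha_carbon",
                                  "sidechain_heavy", "all")) {
  mode <- match.arg(mode)
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(residues)) keep <- keep & atoms$resnum %in% residues
  if (!is.null(segment)) keep <- keep & atoms$segment %in% segment
  keep <- switch(mode,
    alpha_carbon = keep & atoms$name == "CA",
    sidechain_heavy = keep & atoms$element != "H" &
      !(atoms$name %in% .backbone_names),
    all_heavy = keep & atoms$element != "H",
    all = keep)
  which(keep)
}

#' Geometric centroid of a selection in one frame
#'
#' Unweighted mean of the selected atom positions (no mass weighting).
#'
#' @param frame a `traj_frame` (see [get_frame()]).
#' @inheritParams select_atoms
#' @return numeric length-3 position, Angstrom.
#' @export
centroid <- function(frame, residues = NULL, segment = NULL,
                     mode = "all_heavy") {
  frame <- as_frame(frame)
  sel <- select_atoms(frame$atoms, residues = residues, segment = segment,
                      mode = mode)
  if (length(sel) == 0)
    stop("empty selection: residues=", paste(residues, collapse = ","),
         " segment=", paste(segment, collapse = ","), " mode=", mode)
  colMeans(frame$xyz[sel, , drop = FALSE])
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` over paired
#' coordinate rows. Reflections are excluded by flipping the sign of the
#' smallest singular vector when the rotation determinant would be
#' negative.
#'
#' @param mobile,reference `n x 3` matrices of paired coordinates,
#'   `n >= 3`, reference not collinear.
#' @return list of class `"rigid_transform"` with `rotation` (3x3,
#'   det = +1), `translation` (length 3) and `rmsd` (post-fit, Angstrom).
#'   The fitted coordinates are `mobile %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions")
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired points")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  M <- sweep(mobile, 2, mc); R0 <- sweep(reference, 2, rc)
  if (qr(R0)$rank < 2) stop("degenerate (collinear) reference coordinates")
  H <- t(M) %*% R0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  rot <- s$v %*% D %*% t(s$u)
  fitted <- M %*% t(rot)
  rmsd_val <- sqrt(mean(rowSums((fitted - R0)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(rc - rot %*% mc),
                 rmsd = rmsd_val),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param tf a `"rigid_transform"` from [superpose()].
#' @param coords `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(tf, coords) {
  sweep(as.matrix(coords) %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Root-mean-square deviation between paired coordinate sets
#' @param a,b `n x 3` matrices.
#' @return RMSD in Angstrom (no fitting performed).
#' @export
rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Per-frame RMSD series against a reference frame
#'
#' For each frame the stated selection is rigidly superposed onto the same
#' selection in the reference frame before the RMSD is taken, so the series
#' reports internal deformation, not net drift.
#'
#' @param traj a trajectory.
#' @param reference_frame reference frame index (default 1).
#' @inheritParams select_atoms
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference_frame = 1, residues = NULL,
                        segment = NULL, mode = "alpha_carbon") {
  if (reference_frame < 1 || reference_frame > n_frames(traj))
    stop("invalid reference frame index: ", reference_frame)
  sel <- select_atoms(traj$atoms, residues = residues, segment = segment,
                      mode = mode)
  if (length(sel) == 0) stop("empty selection for RMSD series")
  ref <- traj$xyz[sel, , reference_frame]
  vapply(seq_len(n_frames(traj)), function(k) {
    superpose(traj$xyz[sel, , k], ref)$rmsd
  }, numeric(1))
}
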