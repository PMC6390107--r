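#' Superpose trajectory frames onto a reference
#'
#' Least-squares (Kabsch) superposition of every frame onto the reference
#' structure over a selection of atoms, removing rigid-body translation and
#' rotation so that only internal motion remains. The transformation is
#' fitted on the selection and applied to all atoms of the frame.
#'
#' @param traj A `coord_trajectory`.
#' @param ref Reference `protein_structure`; defaults to the trajectory's
#'   own reference.
#' @param selection Atom indices used for the fit; default all main-chain
#'   (N, CA, C, O) atoms.
#' @return A `coord_trajectory` with superposed frames.
#' @export
align_frames <- function(traj, ref = NULL, selection = NULL) {
  if (is.null(ref)) ref <- traj$ref
  if (is.null(selection)) selection <- mainchain_indices(ref)
  if (length(selection) == 0) stop("empty alignment selection")
  sel_xyz <- ref$xyz[selection, , drop = FALSE]
  # a (near-)collinear selection leaves the rotation underdetermined
  sv <- svd(scale(sel_xyz, center = TRUE, scale = FALSE))$d
  if (length(selection) < 3 || sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear) alignment selection")
  inds <- as.vector(t(cbind(3 * selection - 2, 3 * selection - 1,
                            3 * selection)))
  fixed <- as.vector(t(ref$xyz))
  fitted <- bio3d::fit.xyz(fixed, traj$xyz, fixed.inds = inds,
                           mobile.inds = inds)
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)
  coord_trajectory(traj$ref, fitted)
}

# Root-mean-square deviation between two xyz frames over a selection.
frame_rmsd <- function(a, b, selection = NULL) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3, byrow = TRUE)
  if (!is.null(selection)) {
    a <- a[selection, , drop = FALSE]
    b <- b[selection, , drop = FALSE]
  }
  sqrt(mean(rowSums((a - b)^2)))
}
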