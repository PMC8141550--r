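# Least-squares rigid-body superposition (Kabsch, mass-unweighted).

## Optimal rotation/translation mapping point set P onto Q (rows = points).
## Returns rotation R (applied as x %*% t(R)), centers, and the fitted RMSD.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  if (nrow(P) < 3L)
    stopf("superpose degeneracy error: need at least 3 fit atoms, got %d",
          nrow(P))
  muP <- colMeans(P); muQ <- colMeans(Q)
  Pc <- sweep(P, 2L, muP); Qc <- sweep(Q, 2L, muQ)
  sv_p <- svd(Pc)$d
  if (sv_p[2L] < 1e-9 * max(sv_p[1L], 1e-12))
    stopf("superpose degeneracy error: fit atoms are collinear")
  H <- crossprod(Pc, Qc)                     # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # proper rotation only
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(R = R, center_mobile = muP, center_ref = muQ, rmsd = rmsd)
}

apply_rigid <- function(positions, fit) {
  sweep(sweep(positions, 2L, fit$center_mobile) %*% t(fit$R), 2L,
        fit$center_ref, `+`)
}

#' Superpose a frame onto a reference
#'
#' Computes the optimal rigid-body transform (rotation + translation,
#' mass-unweighted Kabsch) minimising the RMSD over the fit selection, then
#' applies it to every atom of the mobile frame.
#'
#' @param mobile `Frame` to transform
#' @param reference `Frame` providing the target coordinates
#' @param fit_selection `AtomSelection` of fit atoms (at least 3,
#'   non-collinear), e.g. the alpha-carbon set
#' @return list with the transformed `frame` and the fitted `rmsd` (nm)
#' @export
superpose <- function(mobile, reference, fit_selection) {
  stopifnot(inherits(mobile, "Frame"), inherits(reference, "Frame"),
            inherits(fit_selection, "AtomSelection"))
  idx <- fit_selection$indices
  if (!length(idx)) stopf("superpose: empty fit selection")
  fit <- kabsch(mobile$positions[idx, , drop = FALSE],
                reference$positions[idx, , drop = FALSE])
  out <- frame(apply_rigid(mobile$positions, fit), mobile$time, mobile$box)
  list(frame = out, rmsd = fit$rmsd)
}

#' Superpose every frame of a trajectory onto a common reference
#'
#' @param traj a `Trajectory`
#' @param reference reference `Frame`
#' @param fit_selection `AtomSelection` of fit atoms
#' @return the aligned `Trajectory`; per-frame fit RMSDs in
#'   `attr(, "fit_rmsd")`
#' @export
superpose_trajectory <- function(traj, reference, fit_selection) {
  stopifnot(inherits(traj, "Trajectory"))
  idx <- fit_selection$indices
  rmsds <- numeric(traj$n_frames)
  coords <- traj$coords
  ref <- reference$positions[idx, , drop = FALSE]
  for (k in seq_len(traj$n_frames)) {
    p <- coords[k, , , drop = FALSE]
    dim(p) <- c(traj$n_atoms, 3L)
    fit <- kabsch(p[idx, , drop = FALSE], ref)
    coords[k, , ] <- apply_rigid(p, fit)
    rmsds[k] <- fit$rmsd
  }
  out <- trajectory(traj$replica_id, coords, traj$times, traj$box)
  attr(out, "fit_rmsd") <- rmsds
  out
}

#' Superpose all replicas of a set onto the common reference frame
#'
#' The reference defaults to the set's stored reference frame (frame 1 of the
#' first replica unless overridden at construction).
#'
#' @param rset a `ReplicaSet`
#' @param fit_selection `AtomSelection`; defaults to all atoms named CA
#' @return a `ReplicaSet` with every frame aligned
#' @export
superpose_replica_set <- function(rset, fit_selection = NULL) {
  stopifnot(inherits(rset, "ReplicaSet"))
  fit_selection <- fit_selection %||% select_atoms(rset$topology, "CA")
  trajs <- lapply(rset$trajectories, superpose_trajectory,
                  reference = rset$reference_frame,
                  fit_selection = fit_selection)
  replica_set(rset$topology, trajs, rset$reference_frame,
              rset$ion_concentration)
}
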