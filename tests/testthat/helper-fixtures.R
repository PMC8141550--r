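# Shared fixtures and independent oracles, all built in code.

## Topology of n sodium ions only
ion_topology <- function(n) {
  topology(data.frame(
    atom_id = seq_len(n) - 1L, atom_name = "NA", residue_name = "NA",
    residue_number = 1000L + seq_len(n), element = "Na", mass = 22.99))
}

## Topology with one marker atom (residue 900 "MK") plus n ions
site_topology <- function(n_ions) {
  topology(data.frame(
    atom_id = seq_len(n_ions + 1L) - 1L,
    atom_name = c("MK", rep("NA", n_ions)),
    residue_name = c("STE", rep("NA", n_ions)),
    residue_number = c(900L, 1000L + seq_len(n_ions)),
    element = c("C", rep("Na", n_ions)),
    mass = c(12.011, rep(22.99, n_ions))))
}

## Trajectory from a frames x atoms x 3 array (or a single atom's
## frames x 3 matrix)
traj_from_coords <- function(coords, dt = 0.1, box = c(20, 20, 20),
                             replica_id = 1L) {
  if (length(dim(coords)) == 2L)
    coords <- array(coords, c(nrow(coords), 1L, 3L))
  trajectory(replica_id, coords,
             (seq_len(dim(coords)[1L]) - 1L) * dt, box)
}

## A tiny hand-written 3-atom GRO fixture
write_gro_fixture <- function(path) {
  writeLines(c(
    "hand-written fixture t= 0.0",
    "    3",
    "    1ALA      N    1   1.000   2.000   3.000",
    "    1ALA     CA    2   1.100   2.100   3.100",
    "    2SER     OG    3   2.500   2.600   2.700",
    "   8.00000   8.00000   8.00000"), path)
  path
}

## Minimal 3-atom PDB with a blank element column
write_pdb_fixture <- function(path) {
  writeLines(c(
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            1, " N", "ALA", 1, 10, 20, 30),
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            2, " CA", "ALA", 1, 11, 21, 31),
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            3, " OG", "SER", 2, 25, 26, 27),
    "END"), path)
  path
}

## Rotation matrix from axis-angle
rot_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Independent superposition oracle: exhaustive search over a coarse
## axis-angle rotation grid, refined locally with optim.  Translation is
## optimal at matched centroids for any rotation.
rmsd_rotation_grid_oracle <- function(P, Q) {
  Pc <- sweep(P, 2L, colMeans(P)); Qc <- sweep(Q, 2L, colMeans(Q))
  obj <- function(v) {
    ang <- sqrt(sum(v^2))
    R <- if (ang < 1e-12) diag(3) else rot_axis_angle(v / ang, ang)
    mean(rowSums((Pc %*% t(R) - Qc)^2))
  }
  best <- c(0, 0, 0); bestv <- obj(best)
  gr <- seq(-pi, pi, length.out = 9L)
  for (x in gr) for (y in gr) for (z in gr) {
    v <- c(x, y, z)
    if (sqrt(sum(v^2)) > pi + 1e-9) next
    o <- obj(v)
    if (o < bestv) { best <- v; bestv <- o }
  }
  o1 <- stats::optim(best, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  o2 <- stats::optim(o1$par, obj, method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 1000))
  sqrt(min(o1$value, o2$value))
}

## Independent pairwise RMSD via Horn's closed-form quaternion method
## (eigen decomposition of the 4x4 key matrix; no SVD, no shared code with
## the package's superposition path)
rmsd_quaternion_oracle <- function(P, Q) {
  Pc <- sweep(P, 2L, colMeans(P)); Qc <- sweep(Q, 2L, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

## Compactness of one frame of coordinating atoms, computed independently
frame_compactness <- function(p) {
  ctr <- colMeans(p)
  mean(sqrt(rowSums(sweep(p, 2L, ctr)^2)))
}

## Small hybrid config used across tests (desk-scale sizes, study-design
## rates and geometry untouched)
desk_hybrid_config <- function(n_replicas = 4, duration = 30,
                               dt_frame = 0.05, seed = 1L, ...) {
  synthetic_config(mode = "hybrid", n_replicas = n_replicas,
                   duration = duration, dt_frame = dt_frame, seed = seed,
                   ...)
}

## Standard detector definitions for a synthetic topology
synthetic_definitions <- function(top) {
  list(gate = gate_definition(select_atoms(top, "104:CZ"),
                              select_atoms(top, "493:CD")),
       na1 = site_definition("NA1", select_atoms(top, na1_selection_expr())),
       na2 = site_definition("NA2", select_atoms(top, na2_selection_expr())),
       gate_site = site_definition("GATE", select_atoms(top, "900:MK"),
                                   min_dwell = 0),
       s1 = site_definition("S1", select_atoms(top, "901:MK"),
                            min_dwell = 0),
       ions = select_ions(top))
}

## Detect all events of a generated hybrid set -> EventTable
detect_all_events <- function(rset, duration) {
  defs <- synthetic_definitions(rset$topology)
  ev <- list()
  for (tr in rset$trajectories) {
    ev[[length(ev) + 1L]] <- detect_vestibule_entries(tr, defs$gate,
                                                     defs$ions)
    for (sd in defs[c("na1", "na2", "gate_site", "s1")])
      ev[[length(ev) + 1L]] <- detect_site_occupancy(tr, sd, defs$ions)
  }
  event_table(do.call(rbind, ev), length(rset$trajectories), duration,
              sites = c("VESTIBULE", "NA1", "NA2", "GATE", "S1"))
}
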