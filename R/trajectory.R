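# Frame / Trajectory / ReplicaSet containers and trajectory I/O.
# GRO is parsed/written natively (fixed-width text, nm); DCD through a
# minimal binary reader/writer (Angstrom-native, converted to nm on read).

#' Construct a Frame
#'
#' @param positions n_atoms x 3 numeric matrix, nm
#' @param time frame time, ns
#' @param box length-3 orthorhombic box edges, nm
#' @return object of class `Frame`
#' @export
frame <- function(positions, time, box) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, is_scalar_num(time),
            length(box) == 3L)
  if (!all(is.finite(positions))) stopf("frame: non-finite positions")
  if (any(box <= 0)) stopf("frame: box edges must be positive")
  structure(list(positions = positions, time = time, box = as.numeric(box)),
            class = "Frame")
}

#' Construct a Trajectory
#'
#' Frames are stored as a dense array `coords[frame, atom, xyz]` in nm with a
#' strictly increasing, uniformly spaced time axis in ns.
#'
#' @param replica_id integer replica label
#' @param coords n_frames x n_atoms x 3 array, nm
#' @param times frame times, ns
#' @param box length-3 box edges, nm
#' @param time_tol tolerance on spacing uniformity, ns
#' @return object of class `Trajectory` with elements `replica_id`, `coords`,
#'   `times`, `dt`, `box`, `n_frames`, `n_atoms`
#' @export
trajectory <- function(replica_id, coords, times, box, time_tol = 1e-6) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  nf <- dim(coords)[1L]
  if (nf < 2L)
    stopf("trajectory integrity error: at least 2 frames required, got %d", nf)
  if (length(times) != nf)
    stopf("trajectory integrity error: %d times for %d frames",
          length(times), nf)
  dts <- diff(times)
  if (any(dts <= 0))
    stopf("trajectory integrity error: frame times not strictly increasing")
  dt <- dts[1L]
  if (any(abs(dts - dt) > time_tol))
    stopf("trajectory integrity error: nonuniform frame spacing (max dev %.3g ns > %.3g ns)",
          max(abs(dts - dt)), time_tol)
  if (!all(is.finite(coords)))
    stopf("trajectory integrity error: non-finite coordinates")
  structure(list(replica_id = as.integer(replica_id), coords = coords,
                 times = as.numeric(times), dt = dt, box = as.numeric(box),
                 n_frames = nf, n_atoms = dim(coords)[2L]),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (replica %d): %d frames x %d atoms, dt = %g ns, %g-%g ns\n",
              x$replica_id, x$n_frames, x$n_atoms, x$dt, x$times[1L],
              x$times[x$n_frames]))
  invisible(x)
}

#' Extract one frame of a trajectory
#' @param traj a `Trajectory`
#' @param i frame index (1-based)
#' @return a `Frame`
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "Trajectory"), i >= 1L, i <= traj$n_frames)
  p <- traj$coords[i, , , drop = FALSE]
  dim(p) <- c(traj$n_atoms, 3L)
  frame(p, traj$times[i], traj$box)
}

#' Bundle replicas into a ReplicaSet
#'
#' @param top shared `Topology`
#' @param trajectories list of `Trajectory` with unique replica ids and the
#'   shared atom count
#' @param reference_frame common reference `Frame` for superposition;
#'   defaults to frame 1 of the first trajectory
#' @param ion_concentration bulk ion concentration, molar (used for the
#'   bimolecular rate conversion)
#' @return object of class `ReplicaSet`
#' @export
replica_set <- function(top, trajectories, reference_frame = NULL,
                        ion_concentration = 0.15) {
  stopifnot(inherits(top, "Topology"), length(trajectories) >= 1L)
  for (tr in trajectories) {
    stopifnot(inherits(tr, "Trajectory"))
    if (tr$n_atoms != top$n_atoms)
      stopf("replica_set integrity error: replica %d has %d atoms, topology has %d",
            tr$replica_id, tr$n_atoms, top$n_atoms)
  }
  ids <- vapply(trajectories, `[[`, integer(1L), "replica_id")
  if (anyDuplicated(ids))
    stopf("replica_set integrity error: duplicate replica ids")
  if (!is_scalar_num(ion_concentration) || ion_concentration <= 0)
    stopf("replica_set: ion_concentration must be > 0")
  if (is.null(reference_frame)) reference_frame <- get_frame(trajectories[[1L]], 1L)
  structure(list(topology = top, trajectories = trajectories,
                 reference_frame = reference_frame,
                 ion_concentration = ion_concentration),
            class = "ReplicaSet")
}

#' @export
print.ReplicaSet <- function(x, ...) {
  cat(sprintf("ReplicaSet: %d replicas x %d frames, %d atoms, [ion] = %g M\n",
              length(x$trajectories), x$trajectories[[1L]]$n_frames,
              x$topology$n_atoms, x$ion_concentration))
  invisible(x)
}

#' Read a coordinate trajectory
#'
#' Supported formats: multi-frame GRO (nm-native; frame times parsed from
#' the `t=` field of each title line, in ps per GROMACS convention) and DCD
#' (Angstrom-native; converted to nm on read, frame times from the header
#' interval unless `dt` is given).  XTC and TRR are compressed GROMACS
#' formats with no reader available here and raise an error.
#'
#' @param top the `Topology` the frames must match
#' @param path trajectory file
#' @param format `"GRO"` or `"DCD"`; defaults to the file extension
#' @param replica_id replica label stored on the trajectory
#' @param dt frame spacing in ns, overriding times recorded in the file
#' @return a `Trajectory` in nm/ns
#' @export
read_trajectory <- function(top, path, format = NULL, replica_id = 0L,
                            dt = NULL) {
  stopifnot(inherits(top, "Topology"))
  format <- toupper(format %||% tools::file_ext(path))
  if (format %in% c("XTC", "TRR"))
    stopf("read_trajectory: %s is not supported (no reader available); convert to DCD or multi-frame GRO",
          format)
  if (!format %in% c("GRO", "DCD"))
    stopf("read_trajectory: unsupported format '%s'", format)
  if (!file.exists(path)) stopf("read_trajectory: file not found: %s", path)
  if (format == "GRO") read_gro_trajectory(top, path, replica_id, dt)
  else read_dcd_trajectory(top, path, replica_id, dt)
}

read_gro_trajectory <- function(top, path, replica_id, dt) {
  lines <- readLines(path)
  blocks <- list()
  i <- 1L
  while (i <= length(lines) && nzchar(paste(trimws(lines[i:min(i + 1L, length(lines))]), collapse = ""))) {
    blk <- parse_gro_block(lines, i, path)
    if (blk$n_atoms != top$n_atoms)
      stopf("read_trajectory integrity error: frame %d has %d atoms, topology has %d",
            length(blocks) + 1L, blk$n_atoms, top$n_atoms)
    blocks[[length(blocks) + 1L]] <- blk
    i <- blk$next_line
  }
  nf <- length(blocks)
  if (nf < 2L)
    stopf("read_trajectory integrity error: %d frame(s) in %s, need at least 2",
          nf, path)
  coords <- array(NA_real_, c(nf, top$n_atoms, 3L))
  for (k in seq_len(nf)) coords[k, , ] <- blocks[[k]]$positions
  times <- vapply(blocks, `[[`, numeric(1L), "time")
  if (!is.null(dt)) times <- (seq_len(nf) - 1L) * dt
  else if (anyNA(times))
    stopf("read_trajectory: no 't=' times in %s; pass dt explicitly", path)
  trajectory(replica_id, coords, times, blocks[[1L]]$box)
}

#' Write a trajectory (or a topology snapshot) as multi-frame GRO
#'
#' Positions are written in nm at the format's 0.001 nm precision; frame
#' times go into the title line as `t=` in ps.
#'
#' @param traj a `Trajectory`, or a `Frame` for a single-snapshot file
#' @param top matching `Topology`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gro <- function(traj, top, path) {
  stopifnot(inherits(top, "Topology"))
  if (inherits(traj, "Frame"))
    traj <- list(coords = array(traj$positions,
                                c(1L, nrow(traj$positions), 3L)),
                 times = traj$time, box = traj$box,
                 n_frames = 1L, replica_id = 0L)
  a <- top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(traj$n_frames %||% length(traj$times))) {
    p <- traj$coords[k, , , drop = TRUE]
    if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
    writeLines(sprintf("replica %d t= %.6f", traj$replica_id,
                       traj$times[k] * 1000), con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$residue_number %% 100000L, a$residue_name,
                       substr(a$atom_name, 1L, 5L),
                       (a$atom_id + 1L) %% 100000L,
                       p[, 1L], p[, 2L], p[, 3L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[1L], traj$box[2L],
                       traj$box[3L]), con)
  }
  invisible(path)
}

## --- DCD (CHARMM/NAMD style, 32-bit Fortran records, little-endian) -------

write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- traj$n_frames
  rec <- function(writer) {
    # Fortran record: length, payload, length
    raw_con <- rawConnection(raw(0L), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4L, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L, endian = "little")
  }
  dt_ps <- traj$dt * 1000  # stored as the frame interval in ps
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4L, eos = NULL)
    icntrl <- integer(20L)
    icntrl[1L] <- nf; icntrl[2L] <- 0L; icntrl[3L] <- 1L; icntrl[4L] <- nf
    icntrl[20L] <- 24L
    writeBin(icntrl[1:9], c2, size = 4L, endian = "little")
    writeBin(dt_ps, c2, size = 4L, endian = "little")  # float delta
    writeBin(icntrl[11:20], c2, size = 4L, endian = "little")
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4L, endian = "little")
    writeChar(formatC("ionbindr synthetic replica", width = -80), c2,
              nchars = 80L, eos = NULL)
  })
  rec(function(c2) writeBin(traj$n_atoms, c2, size = 4L, endian = "little"))
  for (k in seq_len(nf)) {
    p <- traj$coords[k, , , drop = TRUE] * 10  # nm -> Angstrom
    for (ax in 1:3) rec(function(c2)
      writeBin(as.numeric(p[, ax]), c2, size = 4L, endian = "little"))
  }
  invisible(path)
}

read_dcd_trajectory <- function(top, path, replica_id, dt) {
  con <- file(path, "rb")
  on.exit(close(con))
  rec_len <- function() readBin(con, "integer", 1L, 4L, endian = "little")
  n1 <- rec_len()
  if (!identical(n1, 84L)) stopf("DCD format error in %s: bad header record", path)
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "CORD")) stopf("DCD format error in %s: no CORD magic", path)
  ic1 <- readBin(con, "integer", 9L, 4L, endian = "little")
  delta <- readBin(con, "double", 1L, 4L, endian = "little")
  ic2 <- readBin(con, "integer", 10L, 4L, endian = "little")
  rec_len()
  nt_len <- rec_len()
  readBin(con, "raw", nt_len)
  rec_len()
  rec_len()
  natom <- readBin(con, "integer", 1L, 4L, endian = "little")
  rec_len()
  if (natom != top$n_atoms)
    stopf("read_trajectory integrity error: DCD has %d atoms, topology has %d",
          natom, top$n_atoms)
  nf <- ic1[1L]
  has_cell <- ic2[1L] == 1L  # icntrl[11]
  coords <- array(NA_real_, c(nf, natom, 3L))
  for (k in seq_len(nf)) {
    if (has_cell) { n <- rec_len(); readBin(con, "raw", n); rec_len() }
    for (ax in 1:3) {
      rec_len()
      coords[k, , ax] <- readBin(con, "double", natom, 4L, endian = "little")
      rec_len()
    }
  }
  coords <- coords / 10  # Angstrom -> nm
  dt_ns <- dt %||% (delta / 1000)
  if (!is_scalar_num(dt_ns) || dt_ns <= 0)
    stopf("read_trajectory: DCD header carries no usable frame interval; pass dt")
  trajectory(replica_id, coords, (seq_len(nf) - 1L) * dt_ns,
             box = rep(max(coords) - min(coords) + 1, 3L))
}
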