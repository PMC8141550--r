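# Volumetric maps in the common superposed frame: ion spatial density
# (raw occupancy counts) and mean displacement-rate fields on a regular
# 0.1 nm grid, with OpenDX output.
#
# Voxel membership is half-open, [edge, edge + spacing) per axis, so every
# point belongs to exactly one voxel.  Ions outside the grid go to an
# overflow tally, never silently dropped and never wrapped (superposition
# destroys periodicity).  No smoothing is applied to either map.

#' Define a regular volumetric grid
#'
#' @param origin 3-vector, nm: position of the lower corner of voxel (1,1,1)
#' @param spacing voxel edge, nm (0.1 by default)
#' @param shape 3 integers: number of voxels per axis
#' @return list of class `GridSpec`
#' @export
grid_spec <- function(origin, spacing = 0.1, shape) {
  stopifnot(length(origin) == 3L, is_scalar_num(spacing), spacing > 0,
            length(shape) == 3L, all(shape >= 1L))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 shape = as.integer(shape)), class = "GridSpec")
}

## positions (n x 3) -> linear voxel index (x fastest), NA if outside
voxel_index <- function(pos, spec) {
  ijk <- floor(sweep(pos, 2L, spec$origin) / spec$spacing)
  ok <- ijk[, 1L] >= 0 & ijk[, 1L] < spec$shape[1L] &
        ijk[, 2L] >= 0 & ijk[, 2L] < spec$shape[2L] &
        ijk[, 3L] >= 0 & ijk[, 3L] < spec$shape[3L]
  out <- rep(NA_integer_, nrow(pos))
  out[ok] <- 1L + ijk[ok, 1L] + spec$shape[1L] *
    (ijk[ok, 2L] + spec$shape[2L] * ijk[ok, 3L])
  out
}

new_grid <- function(spec, values, samples, kind, overflow,
                     total_samples = NA_real_) {
  structure(list(spec = spec,
                 values = array(values, spec$shape),
                 samples = array(samples, spec$shape), kind = kind,
                 overflow = overflow, total_samples = total_samples),
            class = "VolumetricGrid")
}

#' @export
print.VolumetricGrid <- function(x, ...) {
  cat(sprintf("VolumetricGrid (%s): %d x %d x %d voxels, spacing %g nm, overflow %g\n",
              x$kind, x$spec$shape[1L], x$spec$shape[2L], x$spec$shape[3L],
              x$spec$spacing, x$overflow))
  invisible(x)
}

#' Accumulate an ion spatial-density map
#'
#' Raw occupancy histogram: at every sampled frame each selected ion
#' increments the voxel containing it.  Mass conservation holds exactly:
#' `sum(values) + overflow == n_sampled_frames * n_ions`.  Frames must
#' already be superposed onto the common reference (see
#' [superpose_replica_set()]).
#'
#' @param rset a `ReplicaSet` (aligned)
#' @param ion_selection `AtomSelection` of the ions to histogram
#' @param spec a `GridSpec`
#' @param sample_interval sampling interval, ns (default 0.005, i.e. every
#'   5 ps)
#' @return a `VolumetricGrid` of kind `"density"` (values = counts)
#' @export
accumulate_density <- function(rset, ion_selection, spec,
                               sample_interval = 0.005) {
  stopifnot(inherits(rset, "ReplicaSet"), inherits(spec, "GridSpec"))
  acc <- density_accumulator(spec, ion_selection)
  for (tr in rset$trajectories) acc$add(tr, sample_interval)
  acc$grid()
}

## Streaming accumulator so the pipeline can process one replica at a time.
density_accumulator <- function(spec, ion_selection) {
  nvox <- prod(spec$shape)
  counts <- numeric(nvox)
  overflow <- 0
  total <- 0
  list(
    add = function(traj, sample_interval = 0.005) {
      stride <- max(1L, as.integer(round(sample_interval / traj$dt)))
      frames <- seq(1L, traj$n_frames, by = stride)
      ions <- ion_selection$indices
      p <- traj$coords[frames, ions, , drop = FALSE]
      dim(p) <- c(length(frames) * length(ions), 3L)
      idx <- voxel_index(p, spec)
      overflow <<- overflow + sum(is.na(idx))
      idx <- idx[!is.na(idx)]
      if (length(idx)) counts <<- counts + tabulate(idx, nbins = nvox)
      total <<- total + length(frames) * length(ions)
      invisible(NULL)
    },
    grid = function() new_grid(spec, counts, counts, "density", overflow,
                               total))
}

#' Accumulate a mean displacement-rate map
#'
#' For each selected ion and each consecutive pair of frames `lag` apart,
#' the displacement magnitude divided by the lag (nm/ns) is attributed to
#' the voxel of the ion's position at the start frame (start-frame
#' attribution, deliberately asymmetric).  Values are per-voxel means;
#' voxels never visited carry NA, never 0.
#'
#' @param rset a `ReplicaSet` (aligned)
#' @param ion_selection `AtomSelection`
#' @param spec a `GridSpec`
#' @param lag snapshot interval, ns (default 0.010, i.e. every 10 ps); must
#'   be an integral multiple of the frame spacing
#' @return a `VolumetricGrid` of kind `"displacement_rate"`
#' @export
accumulate_displacement <- function(rset, ion_selection, spec, lag = 0.010) {
  stopifnot(inherits(rset, "ReplicaSet"), inherits(spec, "GridSpec"))
  acc <- displacement_accumulator(spec, ion_selection)
  for (tr in rset$trajectories) acc$add(tr, lag)
  acc$grid()
}

displacement_accumulator <- function(spec, ion_selection) {
  nvox <- prod(spec$shape)
  sums <- numeric(nvox)
  cnts <- numeric(nvox)
  overflow <- 0
  list(
    add = function(traj, lag = 0.010) {
      stride_f <- lag / traj$dt
      if (abs(stride_f - round(stride_f)) > 1e-6)
        stopf("accumulate_displacement config error: lag %g ns is not an integral multiple of frame dt %g ns",
              lag, traj$dt)
      stride <- as.integer(round(stride_f))
      frames <- seq(1L, traj$n_frames, by = stride)
      if (length(frames) < 2L) return(invisible(NULL))
      ions <- ion_selection$indices
      np <- (length(frames) - 1L) * length(ions)
      p0 <- traj$coords[frames[-length(frames)], ions, , drop = FALSE]
      p1 <- traj$coords[frames[-1L], ions, , drop = FALSE]
      dim(p0) <- dim(p1) <- c(np, 3L)
      rate <- rownorms(p1 - p0) / lag
      idx <- voxel_index(p0, spec)
      overflow <<- overflow + sum(is.na(idx))
      ok <- !is.na(idx)
      if (any(ok)) {
        sm <- rowsum(rate[ok], idx[ok])
        at <- as.integer(rownames(sm))
        sums[at] <<- sums[at] + sm[, 1L]
        cnts[at] <<- cnts[at] + tabulate(idx[ok], nbins = nvox)[at]
      }
      invisible(NULL)
    },
    grid = function() {
      vals <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
      new_grid(spec, vals, cnts, "displacement_rate", overflow)
    })
}

#' Write a volumetric grid as an OpenDX scalar field
#'
#' Standard `.dx` layout (gridpositions / gridconnections / data follows,
#' z-fastest ordering) readable by VMD, PyMOL and gridData tools.  Units
#' are nm by default or Angstrom with `units = "angstrom"`.  Missing
#' displacement voxels are written as the sentinel `-999` and documented in
#' the header comment.
#'
#' @param grid a `VolumetricGrid`
#' @param path output path
#' @param units `"nm"` or `"angstrom"`
#' @return `path`, invisibly
#' @export
write_grid <- function(grid, path, units = c("nm", "angstrom")) {
  stopifnot(inherits(grid, "VolumetricGrid"))
  units <- match.arg(units)
  scale <- if (units == "nm") 1 else 10
  sp <- grid$spec
  vals <- grid$values
  vals[!is.finite(vals)] <- -999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# OpenDX scalar field: %s", grid$kind),
    sprintf("# units: %s; missing voxels written as sentinel -999", units),
    sprintf("# overflow tally (samples outside grid): %g", grid$overflow),
    sprintf("object 1 class gridpositions counts %d %d %d",
            sp$shape[1L], sp$shape[2L], sp$shape[3L]),
    sprintf("origin %.6f %.6f %.6f", sp$origin[1L] * scale,
            sp$origin[2L] * scale, sp$origin[3L] * scale),
    sprintf("delta %.6f 0 0", sp$spacing * scale),
    sprintf("delta 0 %.6f 0", sp$spacing * scale),
    sprintf("delta 0 0 %.6f", sp$spacing * scale),
    sprintf("object 2 class gridconnections counts %d %d %d",
            sp$shape[1L], sp$shape[2L], sp$shape[3L]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(sp$shape))), con)
  ## OpenDX: z varies fastest
  v <- as.numeric(aperm(vals, c(3L, 2L, 1L)))
  pad <- (-length(v)) %% 3L
  if (pad) v <- c(v, rep(NA_real_, pad))
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.9g", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               sprintf('object "%s" class field', grid$kind),
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read back an OpenDX scalar field written by [write_grid()]
#'
#' @param path `.dx` file
#' @param units unit convention the file was written in
#' @return a `VolumetricGrid` (kind from the header comment; sentinel -999
#'   restored to NA; `samples`/`overflow` not recoverable from the format)
#' @export
read_grid <- function(path, units = c("nm", "angstrom")) {
  units <- match.arg(units)
  scale <- if (units == "nm") 1 else 10
  lines <- readLines(path)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1L]
  shape <- as.integer(strsplit(sub(".*counts +", "", gp), " +")[[1L]])
  og <- grep("^origin", lines, value = TRUE)[1L]
  origin <- as.numeric(strsplit(sub("^origin +", "", og), " +")[[1L]]) / scale
  dl <- grep("^delta", lines, value = TRUE)
  spacing <- max(as.numeric(strsplit(sub("^delta +", "", dl[1L]),
                                     " +")[[1L]])) / scale
  kind_line <- grep("^# OpenDX scalar field:", lines, value = TRUE)
  kind <- if (length(kind_line)) sub(".*: ", "", kind_line[1L]) else "density"
  start <- grep("data follows", lines)[1L] + 1L
  end <- grep("^attribute", lines)[1L] - 1L
  v <- as.numeric(unlist(strsplit(trimws(lines[start:end]), " +")))
  v[v == -999] <- NA_real_
  vals <- aperm(array(v, rev(shape)), c(3L, 2L, 1L))
  new_grid(grid_spec(origin, spacing, shape), vals,
           rep(NA_real_, prod(shape)), kind, NA_real_)
}

#' Flat CSV voxel dump of a grid
#'
#' @param grid a `VolumetricGrid`
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_grid_csv <- function(grid, path) {
  sp <- grid$spec
  ijk <- expand.grid(i = seq_len(sp$shape[1L]), j = seq_len(sp$shape[2L]),
                     k = seq_len(sp$shape[3L]))
  df <- data.frame(ijk, value = as.numeric(grid$values),
                   samples = as.numeric(grid$samples))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
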