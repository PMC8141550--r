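# Synthetic replica generator with exact ground truth.
#
# Two modes mirror the two things the estimators need:
#   * "hybrid": binding times are drawn exactly from the configured
#     exponential laws and ions are moved along scripted paths that realise
#     those events on the frame grid -- exact rate ground truth for kinetics
#     and event-detection recovery.
#   * "spatial": ions follow overdamped Langevin dynamics in a smooth
#     vestibule-shaped potential with Gaussian site wells -- geometrically
#     honest trajectories for density/displacement maps; the effective
#     association rate is emergent, not configured.
# Both modes drive the coordinating atoms of NA1/NA2 with an
# Ornstein-Uhlenbeck process whose anchor radius compacts at the moment of
# binding (induced fit by construction).

#' Vestibule potential parameters (spatial mode)
#'
#' A smooth stand-in for the attractive electrostatic funnel of the outer
#' vestibule: a broad Gaussian well along the funnel axis plus per-site
#' Gaussian wells.  Not a Poisson-Boltzmann model.  Energies in kT, so the
#' Langevin drift is `D * force`.
#'
#' @param funnel_depth well depth of the funnel, kT
#' @param funnel_axis unit 3-vector pointing into the vestibule
#' @param vestibule_radius lateral Gaussian width of the funnel, nm
#' @param smoothing_length axial Gaussian width of the funnel, nm
#' @return list of class `VestibulePotential`
#' @export
vestibule_potential <- function(funnel_depth = 4, funnel_axis = c(0, 0, -1),
                                vestibule_radius = 0.8,
                                smoothing_length = 1.2) {
  stopifnot(funnel_depth >= 0, vestibule_radius > 0, smoothing_length > 0)
  structure(list(funnel_depth = funnel_depth,
                 funnel_axis = funnel_axis / sqrt(sum(funnel_axis^2)),
                 vestibule_radius = vestibule_radius,
                 smoothing_length = smoothing_length),
            class = "VestibulePotential")
}

#' Synthetic binding-site specification
#'
#' Deep sites (NA1, NA2) are absorbing within the simulated duration: once
#' an ion is bound it never leaves, matching the absence of unbinding events
#' in the study design.  Transient sites (GATE, S1) hold an ion for an
#' exponentially distributed dwell.
#'
#' @param name one of `"GATE"`, `"S1"`, `"NA1"`, `"NA2"`, `"CL"`
#' @param center site center, nm (filled from the standard layout when NULL)
#' @param capture_radius nm
#' @param k_on_true generating bimolecular rate, M^-1 s^-1 (hybrid mode,
#'   deep sites); the pseudo-first-order rate is `k_on_true * concentration`
#' @param well_depth well depth, kT (spatial mode)
#' @param mean_dwell mean dwell time, ns (transient sites)
#' @return list of class `SiteSpec`
#' @export
site_spec <- function(name, center = NULL, capture_radius = 0.25,
                      k_on_true = NULL, well_depth = NULL,
                      mean_dwell = NULL) {
  stopifnot(capture_radius > 0)
  structure(list(name = name, center = center,
                 capture_radius = capture_radius, k_on_true = k_on_true,
                 well_depth = well_depth, mean_dwell = mean_dwell),
            class = "SiteSpec")
}

#' Coordinating-atom geometry process specification
#'
#' Each coordinating pseudo-atom fluctuates (Ornstein-Uhlenbeck, correlation
#' time `ou_time`, stationary per-coordinate standard deviation
#' `positional_stddev_*`) about an anchor at radius R(t) from the site
#' center.  R(t) sits at `mean_radius_apo` until the binding time, then
#' relaxes exponentially to `mean_radius_bound` with time constant
#' `relaxation_time`.  The bound state is also less noisy
#' (`positional_stddev_bound < positional_stddev_apo`), emulating the
#' rigidification seen on sodium binding.
#'
#' @param n_coordinating 6 for an NA1-like site, 3 for NA2-like
#' @param mean_radius_apo,mean_radius_bound anchor radii, nm (apo > bound)
#' @param relaxation_time anchor relaxation time constant, ns
#' @param positional_stddev_apo,positional_stddev_bound stationary OU
#'   standard deviation per coordinate, nm
#' @param ou_time OU correlation time, ns
#' @return list of class `GeometryProcessSpec`
#' @export
geometry_process_spec <- function(n_coordinating = 6,
                                  mean_radius_apo = 0.45,
                                  mean_radius_bound = 0.35,
                                  relaxation_time = 1.0,
                                  positional_stddev_apo = 0.04,
                                  positional_stddev_bound = 0.02,
                                  ou_time = 0.2) {
  if (!(mean_radius_apo > mean_radius_bound && mean_radius_bound > 0))
    stopf("geometry_process_spec: need mean_radius_apo > mean_radius_bound > 0")
  stopifnot(n_coordinating >= 2, relaxation_time > 0, ou_time > 0,
            positional_stddev_apo >= 0, positional_stddev_bound >= 0)
  structure(list(n_coordinating = as.integer(n_coordinating),
                 mean_radius_apo = mean_radius_apo,
                 mean_radius_bound = mean_radius_bound,
                 relaxation_time = relaxation_time,
                 positional_stddev_apo = positional_stddev_apo,
                 positional_stddev_bound = positional_stddev_bound,
                 ou_time = ou_time),
            class = "GeometryProcessSpec")
}

## Standard synthetic geometry layout for a given box (nm).  All site
## centers, the gate plane, and the bulk slab derive from here.
synthetic_layout <- function(box) {
  cx <- box[1L] / 2; cy <- box[2L] / 2
  gate_z <- box[3L] * 0.6
  list(cx = cx, cy = cy, gate_z = gate_z,
       gate_site = c(cx, cy, gate_z - 0.35),
       s1 = c(cx, cy, gate_z - 1.8),
       na1 = c(cx + 0.35, cy, gate_z - 2.4),
       na2 = c(cx - 0.35, cy, gate_z - 2.4),
       cl = c(cx + 0.35, cy, gate_z - 3.0),
       vestibule_anchor = c(cx, cy, gate_z - 1.0),
       bulk_zmin = gate_z + 0.4,
       anchor_a = c(cx - 0.8, cy, gate_z),
       anchor_b = c(cx + 0.8, cy, gate_z))
}

#' Build a synthetic replica-set configuration
#'
#' Defaults mirror the study design this generator emulates: 51 replicas of
#' 150 ns at 5 ps frame spacing, 150 mM ion concentration, deep-site
#' association rates of 4.2e7 (NA1) and 1.9e7 (NA2) M^-1 s^-1, a vestibule
#' entry rate giving a 5.7 ns half-entry time, and a 0.1 nm apo-to-bound
#' compactness shift of the NA1 coordinating shell.
#'
#' @param mode `"hybrid"` (exact event times, scripted paths) or
#'   `"spatial"` (Langevin dynamics in the vestibule potential)
#' @param n_replicas number of replicas
#' @param duration trajectory length, ns
#' @param dt_frame frame spacing, ns
#' @param box orthorhombic box edges, nm
#' @param concentration bulk ion concentration, molar
#' @param n_ions ion count; derived from `concentration` and the box volume
#'   when NULL, and checked against it (warning beyond 5 percent) otherwise
#' @param diffusion_coeff ion diffusion coefficient, nm^2/ns
#' @param entry_rate pseudo-first-order vestibule entry rate, ns^-1
#' @param potential a [vestibule_potential()] (spatial mode)
#' @param sites named list of [site_spec()]s; NULL for the standard
#'   GATE/S1/NA1/NA2 set
#' @param geometry_process named list with elements `na1`, `na2`
#'   ([geometry_process_spec()]s)
#' @param couple_na1_to_na2 if TRUE the NA1 clock starts only once NA2 is
#'   occupied (emulates the observed NA2-first binding order); default FALSE
#' @param chloride seed one distinguishable chloride ion in the CL site with
#'   escape rate `chloride_escape_rate` (ns^-1), escaping through NA1 when
#'   `chloride_via_na1`
#' @param chloride_escape_rate,chloride_via_na1 see `chloride`
#' @param dt_integration Langevin integration step, ns (spatial mode)
#' @param seed integer seed; the single source of randomness
#' @return list of class `SyntheticConfig`
#' @export
synthetic_config <- function(mode = c("hybrid", "spatial"), n_replicas = 51,
                             duration = 150, dt_frame = 0.005,
                             box = c(8, 8, 10), concentration = 0.15,
                             n_ions = NULL, diffusion_coeff = 1.3,
                             entry_rate = log(2) / 5.7,
                             potential = vestibule_potential(),
                             sites = NULL, geometry_process = NULL,
                             couple_na1_to_na2 = FALSE, chloride = FALSE,
                             chloride_escape_rate = 0.004,
                             chloride_via_na1 = TRUE,
                             dt_integration = 5e-4, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is_count(n_replicas), n_replicas >= 1, duration > 0,
            dt_frame > 0, length(box) == 3L, all(box > 0),
            concentration > 0, diffusion_coeff > 0, entry_rate > 0,
            dt_integration > 0, is_count(seed))
  nfr <- duration / dt_frame
  if (abs(nfr - round(nfr)) > 1e-8)
    stopf("synthetic_config: duration must be an integral multiple of dt_frame")
  lay <- synthetic_layout(box)
  if (is.null(sites)) {
    sites <- list(
      GATE = site_spec("GATE", lay$gate_site, 0.25, mean_dwell = 0.5,
                       well_depth = 3),
      S1 = site_spec("S1", lay$s1, 0.25, mean_dwell = 1.0, well_depth = 3),
      NA1 = site_spec("NA1", lay$na1, 0.25, k_on_true = 4.2e7,
                      well_depth = 9),
      NA2 = site_spec("NA2", lay$na2, 0.25, k_on_true = 1.9e7,
                      well_depth = 9))
  }
  for (s in sites) {
    ctr <- s$center %||% stopf("synthetic_config: site %s has no center", s$name)
    if (any(ctr < 0) || any(ctr > box))
      stopf("synthetic_config error: site %s center outside the box", s$name)
  }
  if (is.null(geometry_process))
    geometry_process <- list(
      na1 = geometry_process_spec(6, 0.45, 0.35, 1.0, 0.04, 0.02),
      na2 = geometry_process_spec(3, 0.40, 0.30, 1.0, 0.03, 0.015))
  implied <- ions_for_concentration(concentration, box)
  if (is.null(n_ions)) n_ions <- implied
  else if (implied > 0 && abs(n_ions - implied) / implied > 0.05)
    warnf("synthetic_config: n_ions = %d differs from the %d implied by %g M in this box by more than 5%%",
          n_ions, implied, concentration)
  structure(list(mode = mode, n_replicas = as.integer(n_replicas),
                 duration = duration, dt_frame = dt_frame, box = box,
                 concentration = concentration, n_ions = as.integer(n_ions),
                 diffusion_coeff = diffusion_coeff, entry_rate = entry_rate,
                 potential = potential, sites = sites,
                 geometry_process = geometry_process,
                 couple_na1_to_na2 = isTRUE(couple_na1_to_na2),
                 chloride = isTRUE(chloride),
                 chloride_escape_rate = chloride_escape_rate,
                 chloride_via_na1 = isTRUE(chloride_via_na1),
                 dt_integration = dt_integration, seed = as.integer(seed),
                 layout = lay),
            class = "SyntheticConfig")
}

## Pseudo-first-order rate (ns^-1) of a deep site under this config.
site_rate <- function(config, name) {
  k <- config$sites[[name]]$k_on_true
  if (is.null(k)) return(NULL)
  k * config$concentration / 1e9
}

#' Draw censored exponential first-binding times
#'
#' The event engine of hybrid mode: one waiting time per replica from the
#' exponential law with the given pseudo-first-order rate, right-censored at
#' the trajectory duration.
#'
#' @param rate pseudo-first-order rate, ns^-1
#' @param n_replicas number of replicas
#' @param duration censoring horizon, ns
#' @param seed optional seed; the ambient RNG stream is used when NULL
#' @return data.frame with `replica_id`, `time` (ns, NA when censored) and
#'   `censored`
#' @export
draw_binding_times <- function(rate, n_replicas, duration, seed = NULL) {
  stopifnot(rate > 0, is_count(n_replicas), duration > 0)
  draw <- function() rexp(n_replicas, rate)
  t <- if (is.null(seed)) draw() else with_seed(seed, draw())
  cens <- t > duration
  data.frame(replica_id = seq_len(n_replicas),
             time = ifelse(cens, NA_real_, t), censored = cens)
}

#' One overdamped Langevin (Euler-Maruyama) step
#'
#' `x' = x + D * F * dt + sqrt(2 D dt) * xi`, with forces in kT/nm so the
#' mobility is the diffusion coefficient itself.
#'
#' @param positions n x 3 matrix, nm
#' @param forces n x 3 matrix, kT/nm
#' @param diffusion_coeff nm^2/ns
#' @param dt integration step, ns
#' @param noise optional n x 3 matrix of standard-normal deviates (test
#'   hook; drawn from the ambient RNG when NULL).  Pass a zero matrix for
#'   the deterministic drift limit.
#' @return updated n x 3 position matrix
#' @export
step_langevin <- function(positions, forces, diffusion_coeff, dt,
                          noise = NULL) {
  stopifnot(is.matrix(positions), ncol(positions) == 3L,
            all(dim(forces) == dim(positions)), diffusion_coeff > 0, dt > 0)
  if (!all(is.finite(forces))) stopf("step_langevin: non-finite forces")
  if (is.null(noise))
    noise <- matrix(rnorm(length(positions)), ncol = 3L)
  out <- positions + diffusion_coeff * forces * dt +
    sqrt(2 * diffusion_coeff * dt) * noise
  bad <- which(!is.finite(rowSums(out)))
  if (length(bad))
    stopf("step_langevin integration error: non-finite position for ion %d",
          bad[1L])
  out
}

## Reflect coordinates into [lo, hi] (exact folding of a Brownian path).
reflect_into <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  lo + ifelse(y > L, 2 * L - y, y)
}

## Reflected Gaussian random walk: n_steps x 3 positions from `start`.
bulk_walk <- function(start, n_steps, sigma, xlim, ylim, zlim) {
  if (n_steps == 0L) return(matrix(numeric(0L), ncol = 3L))
  steps <- matrix(rnorm(n_steps * 3L, sd = sigma), ncol = 3L)
  cs <- apply(steps, 2L, cumsum)
  if (n_steps == 1L) cs <- matrix(cs, nrow = 1L)
  p <- sweep(cs, 2L, start, `+`)
  p[, 1L] <- reflect_into(p[, 1L], xlim[1L], xlim[2L])
  p[, 2L] <- reflect_into(p[, 2L], ylim[1L], ylim[2L])
  p[, 3L] <- reflect_into(p[, 3L], zlim[1L], zlim[2L])
  p
}

## Clamped AR(1) jitter around 0: n x 3, stationary sd `sd`, clamp `cl`.
ou_jitter <- function(n, sd, cl, phi = 0.6) {
  if (n == 0L) return(matrix(numeric(0L), ncol = 3L))
  e <- matrix(rnorm(n * 3L, sd = sd * sqrt(1 - phi^2)), ncol = 3L)
  out <- matrix(0, n, 3L)
  prev <- rnorm(3L, sd = sd)
  for (k in seq_len(n)) {
    prev <- phi * prev + e[k, ]
    out[k, ] <- prev
  }
  pmin(pmax(out, -cl), cl)
}

#' Evolve the coordinating-atom geometry of one site
#'
#' Ornstein-Uhlenbeck fluctuations about radial anchors that compact from
#' the apo to the bound radius starting at the binding time (see
#' [geometry_process_spec()]).  With `positional_stddev_* = 0` the trace is
#' the exact deterministic relaxation curve.
#'
#' @param spec a `GeometryProcessSpec`
#' @param binding_time ns, or NA for a censored (never-bound) replica
#' @param duration ns
#' @param dt_frame ns
#' @param center site center, nm
#' @return n_frames x n_coordinating x 3 array of positions (nm); anchor
#'   radii in `attr(, "radius")`
#' @export
evolve_site_geometry <- function(spec, binding_time, duration, dt_frame,
                                 center = c(0, 0, 0)) {
  stopifnot(inherits(spec, "GeometryProcessSpec"))
  times <- seq(0, duration, by = dt_frame)
  nf <- length(times)
  n <- spec$n_coordinating
  u <- coordination_directions(n)
  R <- rep(spec$mean_radius_apo, nf)
  sdv <- rep(spec$positional_stddev_apo, nf)
  if (is.finite(binding_time %||% NA_real_) && !is.na(binding_time)) {
    post <- times >= binding_time
    decay <- exp(-(times[post] - binding_time) / spec$relaxation_time)
    R[post] <- spec$mean_radius_bound +
      (spec$mean_radius_apo - spec$mean_radius_bound) * decay
    sdv[post] <- spec$positional_stddev_bound +
      (spec$positional_stddev_apo - spec$positional_stddev_bound) * decay
  }
  phi <- exp(-dt_frame / spec$ou_time)
  out <- array(NA_real_, c(nf, n, 3L))
  anchors0 <- sweep(u * R[1L], 2L, center, `+`)
  dev <- matrix(rnorm(n * 3L, sd = sdv[1L]), n, 3L)
  out[1L, , ] <- anchors0 + dev
  for (k in 2L:nf) {
    dev <- phi * dev +
      matrix(rnorm(n * 3L, sd = sdv[k] * sqrt(1 - phi^2)), n, 3L)
    out[k, , ] <- sweep(u * R[k], 2L, center, `+`) + dev
  }
  attr(out, "radius") <- R
  attr(out, "times") <- times
  out
}

## Unit direction vectors for n coordinating atoms; symmetric arrangements
## (octahedron for 6, equilateral triangle for 3) sum to zero so the
## centroid coincides with the site center.
coordination_directions <- function(n) {
  if (n == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else if (n == 3L) {
    th <- c(0, 2, 4) * pi / 3
    cbind(cos(th), sin(th), 0)
  } else {
    # golden-spiral points on the sphere, centered
    i <- seq_len(n) - 0.5
    th <- acos(1 - 2 * i / n); ph <- pi * (1 + sqrt(5)) * i
    u <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    sweep(u, 2L, colMeans(u))
  }
}

## Build the pseudo-protein topology (+ static base positions) for a config.
## Atom order: 8 CA, 2 gate anchors, 6 NA1 + 3 NA2 coordinating atoms,
## 3 site markers (GATE/S1/CL), chloride (optional), then the sodium ions.
build_synthetic_topology <- function(config) {
  lay <- config$layout
  th <- seq(0, 2 * pi, length.out = 9L)[1:8]
  ca <- cbind(lay$cx + 1.8 * cos(th), lay$cy + 1.8 * sin(th),
              lay$gate_z - 2.8 + 0.4 * seq_len(8L))
  na1_u <- coordination_directions(config$geometry_process$na1$n_coordinating)
  na2_u <- coordination_directions(config$geometry_process$na2$n_coordinating)
  pos <- rbind(ca, lay$anchor_a, lay$anchor_b,
               sweep(na1_u * config$geometry_process$na1$mean_radius_apo,
                     2L, lay$na1, `+`),
               sweep(na2_u * config$geometry_process$na2$mean_radius_apo,
                     2L, lay$na2, `+`),
               lay$gate_site, lay$s1, lay$cl)
  n1 <- config$geometry_process$na1$n_coordinating
  n2 <- config$geometry_process$na2$n_coordinating
  na1_names <- c("O", "CG", "OD", "O", "OG", "OD")[seq_len(n1)]
  na1_res <- c(96L, 98L, 101L, 336L, 336L, 368L)[seq_len(n1)]
  na1_resnm <- c("ALA", "ASP", "ASN", "SER", "SER", "ASN")[seq_len(n1)]
  na2_names <- c("O", "O", "O")[seq_len(n2)]
  na2_res <- c(94L, 97L, 434L)[seq_len(n2)]
  na2_resnm <- c("GLY", "VAL", "LEU")[seq_len(n2)]
  atom_name <- c(rep("CA", 8L), "CZ", "CD", na1_names, na2_names,
                 "MK", "MK", "MK")
  res_name <- c(rep("GLY", 8L), "ARG", "GLU", na1_resnm, na2_resnm,
                "GTE", "S1S", "CLS")
  res_num <- c(1:8, 104L, 493L, na1_res, na2_res, 900L, 901L, 902L)
  if (config$chloride) {
    atom_name <- c(atom_name, "CL"); res_name <- c(res_name, "CL")
    res_num <- c(res_num, 999L); pos <- rbind(pos, lay$cl)
  }
  if (config$n_ions > 0L) {
    atom_name <- c(atom_name, rep("NA", config$n_ions))
    res_name <- c(res_name, rep("NA", config$n_ions))
    res_num <- c(res_num, 1000L + seq_len(config$n_ions))
    pos <- rbind(pos, matrix(rep(c(lay$cx, lay$cy, config$box[3L] - 0.5),
                                 each = config$n_ions), ncol = 3L))
  }
  elem <- infer_element(atom_name)
  top <- topology(data.frame(
    atom_id = seq_along(atom_name) - 1L, atom_name = atom_name,
    residue_name = res_name, residue_number = res_num, element = elem,
    mass = mass_of_element(elem), stringsAsFactors = FALSE))
  list(topology = top, base_positions = pos,
       idx = list(ca = 1:8, anchors = 9:10, na1 = 10L + seq_len(n1),
                  na2 = 10L + n1 + seq_len(n2),
                  markers = 10L + n1 + n2 + 1:3,
                  chloride = if (config$chloride) 10L + n1 + n2 + 4L,
                  ions = if (config$n_ions > 0L)
                    (10L + n1 + n2 + 3L + config$chloride) +
                      seq_len(config$n_ions)))
}

#' Generate a synthetic replica set with ground truth
#'
#' @param config a [synthetic_config()]
#' @param replicas optional integer subset of replica ids to materialise
#'   (each replica derives its own sub-seed from the config seed, so a
#'   subset is bit-identical to the same replicas of the full set)
#' @param materialize if FALSE only the ground truth (event times, rates,
#'   seeds) is generated -- no trajectories; useful for kinetics work at
#'   scale
#' @return list with `replica_set` (a [replica_set()], or NULL when
#'   `materialize = FALSE`) and `ground_truth` (class
#'   `SyntheticGroundTruth`)
#' @export
generate_replica_set <- function(config, replicas = NULL,
                                 materialize = TRUE) {
  stopifnot(inherits(config, "SyntheticConfig"))
  replicas <- replicas %||% seq_len(config$n_replicas)
  stopifnot(all(replicas >= 1L), all(replicas <= config$n_replicas))
  seeds <- spawn_seeds(config$seed, config$n_replicas)
  build <- build_synthetic_topology(config)
  trajs <- list()
  reps <- list()
  for (r in replicas) {
    g <- with_seed(seeds[r], gen_replica(config, build, r, materialize))
    reps[[as.character(r)]] <- g$truth
    if (materialize) trajs[[length(trajs) + 1L]] <- g$trajectory
  }
  gt <- structure(list(
    seed = config$seed, mode = config$mode, n_replicas = config$n_replicas,
    duration = config$duration, dt_frame = config$dt_frame,
    rates = list(entry = config$entry_rate,
                 NA1 = site_rate(config, "NA1"),
                 NA2 = site_rate(config, "NA2")),
    replica_seeds = seeds, replicas = reps), class = "SyntheticGroundTruth")
  rs <- NULL
  if (materialize)
    rs <- replica_set(build$topology, trajs,
                      ion_concentration = config$concentration)
  list(replica_set = rs, ground_truth = gt)
}

## Hybrid- or spatial-mode single replica (RNG already seeded by caller).
gen_replica <- function(config, build, rid, materialize) {
  if (config$mode == "hybrid") gen_replica_hybrid(config, build, rid, materialize)
  else gen_replica_spatial(config, build, rid, materialize)
}

## ---- hybrid mode ---------------------------------------------------------

gen_replica_hybrid <- function(config, build, rid, materialize) {
  dt <- config$dt_frame
  nf <- as.integer(round(config$duration / dt)) + 1L
  times <- (seq_len(nf) - 1L) * dt
  lay <- config$layout
  ## event draws (fixed order for reproducibility)
  t_entry <- rexp(1L, config$entry_rate)
  d_gate <- rexp(1L, 1 / (config$sites$GATE$mean_dwell %||% 0.5))
  d_s1 <- rexp(1L, 1 / (config$sites$S1$mean_dwell %||% 1))
  rate1 <- site_rate(config, "NA1")
  rate2 <- site_rate(config, "NA2")
  t_na2 <- if (!is.null(rate2)) rexp(1L, rate2) else Inf
  t_na1 <- if (!is.null(rate1)) {
    if (config$couple_na1_to_na2) t_na2 + rexp(1L, rate1)
    else rexp(1L, rate1)
  } else Inf
  t_cl <- if (config$chloride) rexp(1L, config$chloride_escape_rate) else Inf
  ## frame-quantised realisations (1-based frame index; time = (i-1)*dt)
  bind_frame <- function(t) {
    if (!is.finite(t) || t > config$duration) NA_integer_
    else min(max(as.integer(ceiling(t / dt)) + 1L, 3L), nf)
  }
  i_e <- bind_frame(t_entry)
  i_b1 <- bind_frame(t_na1)
  i_b2 <- bind_frame(t_na2)
  i_cl <- bind_frame(t_cl)
  events <- list()
  add_event <- function(site, ion, entry_i, exit_i) {
    censored <- is.na(exit_i) || exit_i > nf
    events[[length(events) + 1L]] <<- data.frame(
      site = site, ion_id = ion, entry_ns = times[entry_i],
      exit_ns = if (censored) NA_real_ else times[exit_i],
      censored = censored)
  }
  n_ions <- config$n_ions
  roles <- list(tracer = if (n_ions >= 1L) 1L,
                na1 = if (n_ions >= 2L) 2L,
                na2 = if (n_ions >= 3L) 3L)
  coords <- NULL
  if (materialize) {
    coords <- array(NA_real_, c(nf, build$topology$n_atoms, 3L))
    np <- nrow(build$base_positions)
    for (axn in 1:3)
      coords[, seq_len(np), axn] <- matrix(build$base_positions[, axn], nf,
                                           np, byrow = TRUE)
    ## coordinating-atom OU processes
    gp <- config$geometry_process
    coords[, build$idx$na1, ] <- evolve_site_geometry(
      gp$na1, if (is.na(i_b1)) NA_real_ else times[i_b1],
      config$duration, dt, lay$na1)
    coords[, build$idx$na2, ] <- evolve_site_geometry(
      gp$na2, if (is.na(i_b2)) NA_real_ else times[i_b2],
      config$duration, dt, lay$na2)
  }
  sigma <- sqrt(2 * config$diffusion_coeff * dt)
  bulk_lim <- list(x = c(0, config$box[1L]), y = c(0, config$box[2L]),
                   z = c(lay$bulk_zmin, config$box[3L]))
  place_bulk <- function() c(runif(1L, 0, config$box[1L]),
                             runif(1L, 0, config$box[2L]),
                             runif(1L, lay$bulk_zmin, config$box[3L]))
  ion_path_bulk <- function(start, n) bulk_walk(start, n, sigma,
                                               bulk_lim$x, bulk_lim$y,
                                               bulk_lim$z)
  entry_frames <- rep(NA_integer_, max(n_ions, 0L))
  ## --- tracer itinerary: bulk -> gate dwell -> S1 dwell -> vestibule ------
  if (!is.null(roles$tracer)) {
    ion <- roles$tracer
    if (!is.na(i_e)) {
      entry_frames[ion] <- i_e
      dg <- max(1L, as.integer(round(d_gate / dt)))
      ds <- max(1L, as.integer(round(d_s1 / dt)))
      add_event("GATE", ion, i_e, i_e + dg)
      s1_start <- i_e + dg + 1L
      if (s1_start <= nf) add_event("S1", ion, s1_start, s1_start + ds)
      if (materialize) {
        p <- matrix(NA_real_, nf, 3L)
        nb <- i_e - 2L
        if (nb > 0L) p[seq_len(nb), ] <- ion_path_bulk(place_bulk(), nb)
        p[i_e - 1L, ] <- c(lay$cx, lay$cy, lay$gate_z + 0.15)
        g_end <- min(i_e + dg - 1L, nf)
        gseg <- i_e:g_end
        p[gseg, ] <- sweep(ou_jitter(length(gseg), 0.05, 0.15), 2L,
                           lay$gate_site, `+`)
        if (i_e + dg <= nf)
          p[i_e + dg, ] <- lay$vestibule_anchor
        s_end <- min(s1_start + ds - 1L, nf)
        if (s1_start <= s_end) {
          sseg <- s1_start:s_end
          p[sseg, ] <- sweep(ou_jitter(length(sseg), 0.05, 0.15), 2L,
                             lay$s1, `+`)
        }
        rest <- s1_start + ds
        if (rest <= nf) {
          rseg <- rest:nf
          p[rseg, ] <- sweep(ou_jitter(length(rseg), 0.05, 0.2), 2L,
                             lay$vestibule_anchor, `+`)
        }
        coords[, build$idx$ions[ion], ] <- p
      }
    } else if (materialize) {
      coords[, build$idx$ions[ion], ] <- ion_path_bulk(place_bulk(), nf)
    }
  }
  ## --- deep-site binder itineraries --------------------------------------
  script_binder <- function(ion, i_b, center, site) {
    if (is.na(i_b)) {
      if (materialize)
        coords[, build$idx$ions[ion], ] <<- ion_path_bulk(place_bulk(), nf)
      return(invisible())
    }
    entry_frames[ion] <<- i_b - 1L
    add_event(site, ion, i_b, NA_integer_)   # absorbing: always censored
    if (materialize) {
      p <- matrix(NA_real_, nf, 3L)
      nb <- i_b - 3L
      if (nb > 0L) p[seq_len(nb), ] <- ion_path_bulk(place_bulk(), nb)
      p[i_b - 2L, ] <- c(lay$cx, lay$cy, lay$gate_z + 0.2)
      p[i_b - 1L, ] <- center + c(0, 0, 0.45)
      bseg <- i_b:nf
      p[bseg, ] <- sweep(ou_jitter(length(bseg), 0.02, 0.08), 2L, center,
                         `+`)
      coords[, build$idx$ions[ion], ] <<- p
    }
  }
  if (!is.null(roles$na1)) script_binder(roles$na1, i_b1, lay$na1, "NA1")
  if (!is.null(roles$na2)) script_binder(roles$na2, i_b2, lay$na2, "NA2")
  ## --- remaining bulk ions ------------------------------------------------
  if (materialize && n_ions > 3L) {
    for (ion in 4:n_ions)
      coords[, build$idx$ions[ion], ] <- ion_path_bulk(place_bulk(), nf)
  }
  ## --- chloride ------------------------------------------------------------
  chl <- NULL
  if (config$chloride) {
    rel <- !is.na(i_cl)
    chl <- list(release_ns = if (rel) times[i_cl] else NA_real_,
                via_na1 = if (rel) config$chloride_via_na1 else NA)
    if (materialize) {
      p <- matrix(NA_real_, nf, 3L)
      pre <- min(i_cl - 1L, nf, na.rm = TRUE)
      if (!rel) pre <- nf
      pseg <- seq_len(pre)
      p[pseg, ] <- sweep(ou_jitter(length(pseg), 0.03, 0.1), 2L, lay$cl, `+`)
      if (rel && i_cl <= nf) {
        via <- if (config$chloride_via_na1) lay$na1
               else lay$na2 + c(-0.6, 0, 0)
        p[i_cl, ] <- via
        if (i_cl + 1L <= nf) p[i_cl + 1L, ] <- lay$s1
        if (i_cl + 2L <= nf)
          p[i_cl + 2L, ] <- c(lay$cx, lay$cy, lay$bulk_zmin + 0.2)
        if (i_cl + 3L <= nf)
          p[(i_cl + 3L):nf, ] <- ion_path_bulk(
            c(lay$cx, lay$cy, lay$bulk_zmin + 0.2), nf - i_cl - 2L)
      }
      coords[, build$idx$chloride, ] <- p
    }
  }
  events_df <- if (length(events)) do.call(rbind, events)
    else data.frame(site = character(), ion_id = integer(),
                    entry_ns = numeric(), exit_ns = numeric(),
                    censored = logical())
  first_in <- suppressWarnings(min(entry_frames, na.rm = TRUE))
  truth <- list(
    replica_id = rid,
    vestibule_entry_ns = if (is.finite(first_in)) times[first_in] else NA_real_,
    ion_entry_ns = ifelse(is.na(entry_frames), NA_real_,
                          times[pmax(entry_frames, 1L)]),
    na1_ns = if (is.na(i_b1)) NA_real_ else times[i_b1],
    na2_ns = if (is.na(i_b2)) NA_real_ else times[i_b2],
    raw = list(entry = t_entry, na1 = t_na1, na2 = t_na2),
    events = events_df, chloride = chl)
  traj <- NULL
  if (materialize)
    traj <- trajectory(rid, coords, times, config$box)
  list(truth = truth, trajectory = traj)
}

## ---- spatial mode --------------------------------------------------------

## Analytic force field (kT/nm): funnel Gaussian + per-site Gaussian wells.
spatial_forces <- function(pos, config) {
  lay <- config$layout
  pot <- config$potential
  F <- matrix(0, nrow(pos), 3L)
  if (pot$funnel_depth > 0) {
    cf <- c(lay$cx, lay$cy, (lay$gate_z + lay$s1[3L]) / 2)
    d <- sweep(pos, 2L, cf)
    w2 <- c(pot$vestibule_radius^2, pot$vestibule_radius^2,
            pot$smoothing_length^2)
    s <- (d[, 1L]^2 / w2[1L] + d[, 2L]^2 / w2[2L] + d[, 3L]^2 / w2[3L]) / 2
    amp <- pot$funnel_depth * exp(-s)
    F <- F - amp * sweep(d, 2L, w2, `/`)
  }
  for (st in config$sites) {
    if (is.null(st$well_depth) || st$well_depth <= 0) next
    d <- sweep(pos, 2L, st$center)
    w2 <- st$capture_radius^2
    amp <- st$well_depth * exp(-rowSums(d^2) / (2 * w2))
    F <- F - (amp / w2) * d
  }
  F
}

gen_replica_spatial <- function(config, build, rid, materialize) {
  dt <- config$dt_frame
  nf <- as.integer(round(config$duration / dt)) + 1L
  times <- (seq_len(nf) - 1L) * dt
  lay <- config$layout
  nsub <- max(1L, as.integer(round(dt / config$dt_integration)))
  dti <- dt / nsub
  n_ions <- config$n_ions
  deep <- Filter(function(s) s$name %in% c("NA1", "NA2"), config$sites)
  pos <- cbind(runif(n_ions, 0, config$box[1L]),
               runif(n_ions, 0, config$box[2L]),
               runif(n_ions, 0, config$box[3L]))
  pinned <- rep(FALSE, max(n_ions, 1L))
  site_taken <- setNames(rep(FALSE, length(deep)),
                         vapply(deep, `[[`, character(1L), "name"))
  absorb_ns <- setNames(rep(NA_real_, length(deep)), names(site_taken))
  absorb_ion <- setNames(rep(NA_integer_, length(deep)), names(site_taken))
  entry_frame <- rep(NA_integer_, max(n_ions, 1L))
  ion_coords <- if (materialize && n_ions > 0L)
    array(NA_real_, c(nf, n_ions, 3L))
  record <- function(k) {
    if (!is.null(ion_coords)) ion_coords[k, , ] <<- pos
    if (n_ions == 0L) return(invisible())
    ## gate-plane membership (ground truth uses the same geometric
    ## definition the detector implements, evaluated on frame positions)
    rel <- sweep(pos, 2L, c(lay$cx, lay$cy, lay$gate_z))
    inside <- rel[, 3L] < 0 & sqrt(rel[, 1L]^2 + rel[, 2L]^2) <= 1.2
    newly <- which(inside & is.na(entry_frame))
    entry_frame[newly] <<- k
    for (sn in names(site_taken)) {
      if (site_taken[[sn]]) next
      st <- config$sites[[sn]]
      d <- rownorms(sweep(pos, 2L, st$center))
      hit <- which(!pinned & d <= st$capture_radius)
      if (length(hit)) {
        ion <- hit[1L]
        pos[ion, ] <<- st$center   # bound: held at the site
        pinned[ion] <<- TRUE
        site_taken[[sn]] <<- TRUE
        absorb_ns[[sn]] <<- times[k]
        absorb_ion[[sn]] <<- ion
      }
    }
  }
  if (n_ions > 0L) record(1L)
  for (k in 2L:nf) {
    if (n_ions > 0L) {
      for (s in seq_len(nsub)) {
        mob <- !pinned
        if (any(mob)) {
          pm <- pos[mob, , drop = FALSE]
          pm <- step_langevin(pm, spatial_forces(pm, config),
                             config$diffusion_coeff, dti)
          pm[, 1L] <- reflect_into(pm[, 1L], 0, config$box[1L])
          pm[, 2L] <- reflect_into(pm[, 2L], 0, config$box[2L])
          pm[, 3L] <- reflect_into(pm[, 3L], 0, config$box[3L])
          pos[mob, ] <- pm
        }
      }
      record(k)
    }
  }
  events <- list()
  for (sn in names(site_taken)) {
    if (site_taken[[sn]])
      events[[length(events) + 1L]] <- data.frame(
        site = sn, ion_id = absorb_ion[[sn]], entry_ns = absorb_ns[[sn]],
        exit_ns = NA_real_, censored = TRUE)
  }
  events_df <- if (length(events)) do.call(rbind, events)
    else data.frame(site = character(), ion_id = integer(),
                    entry_ns = numeric(), exit_ns = numeric(),
                    censored = logical())
  first_in <- suppressWarnings(min(entry_frame, na.rm = TRUE))
  truth <- list(
    replica_id = rid,
    vestibule_entry_ns = if (is.finite(first_in)) times[first_in] else NA_real_,
    ion_entry_ns = ifelse(is.na(entry_frame), NA_real_,
                          times[pmax(entry_frame, 1L)]),
    na1_ns = if ("NA1" %in% names(absorb_ns)) absorb_ns[["NA1"]] else NA_real_,
    na2_ns = if ("NA2" %in% names(absorb_ns)) absorb_ns[["NA2"]] else NA_real_,
    raw = NULL, events = events_df, chloride = NULL)
  traj <- NULL
  if (materialize) {
    coords <- array(NA_real_, c(nf, build$topology$n_atoms, 3L))
    np <- nrow(build$base_positions)
    for (axn in 1:3)
      coords[, seq_len(np), axn] <- matrix(build$base_positions[, axn], nf,
                                           np, byrow = TRUE)
    gp <- config$geometry_process
    coords[, build$idx$na1, ] <- evolve_site_geometry(
      gp$na1, truth$na1_ns, config$duration, dt, lay$na1)
    coords[, build$idx$na2, ] <- evolve_site_geometry(
      gp$na2, truth$na2_ns, config$duration, dt, lay$na2)
    if (n_ions > 0L) coords[, build$idx$ions, ] <- ion_coords
    if (config$chloride)
      coords[, build$idx$chloride, ] <-
        matrix(rep(lay$cl, each = nf), nrow = nf)
    traj <- trajectory(rid, coords, times, config$box)
  }
  list(truth = truth, trajectory = traj)
}

## ---- ground truth serialisation -----------------------------------------

#' Write / read synthetic ground truth as JSON
#'
#' Round-trips bit-exactly (full double precision).
#'
#' @param gt a `SyntheticGroundTruth`
#' @param path JSON file path
#' @return `path` (write) or the reloaded `SyntheticGroundTruth` (read)
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "SyntheticGroundTruth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$replica_seeds <- as.integer(x$replica_seeds)
  x$replicas <- lapply(x$replicas, function(r) {
    ev <- r$events
    r$events <- data.frame(
      site = as.character(ev$site %||% character()),
      ion_id = as.integer(ev$ion_id %||% integer()),
      entry_ns = as.numeric(ev$entry_ns %||% numeric()),
      exit_ns = as.numeric(ev$exit_ns %||% numeric()),
      censored = as.logical(ev$censored %||% logical()))
    for (f in c("vestibule_entry_ns", "na1_ns", "na2_ns"))
      r[[f]] <- as.numeric(r[[f]] %||% NA_real_)
    r$ion_entry_ns <- as.numeric(r$ion_entry_ns)
    r
  })
  structure(x, class = "SyntheticGroundTruth")
}

#' Write one replica to disk
#'
#' Emits a GRO topology-plus-trajectory file (and optionally a DCD) readable
#' by [read_trajectory()], plus a JSON ground-truth sidecar when given.
#'
#' @param traj a `Trajectory`
#' @param top matching `Topology`
#' @param out_dir output directory (created if needed)
#' @param formats subset of `c("gro", "dcd")`
#' @param truth optional per-replica ground-truth list for the sidecar
#' @return named character vector of written paths
#' @export
write_replica <- function(traj, top, out_dir, formats = "gro",
                          truth = NULL) {
  formats <- tolower(formats)
  bad <- setdiff(formats, c("gro", "dcd"))
  if (length(bad))
    stopf("write_replica config error: unsupported format '%s'", bad[1L])
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stopf("write_replica filesystem error: cannot create %s", out_dir)
  paths <- c()
  base <- file.path(out_dir, sprintf("replica_%03d", traj$replica_id))
  if ("gro" %in% formats) {
    write_gro(traj, top, paste0(base, ".gro"))
    paths["gro"] <- paste0(base, ".gro")
  }
  if ("dcd" %in% formats) {
    write_dcd(traj, paste0(base, ".dcd"))
    paths["dcd"] <- paste0(base, ".dcd")
  }
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(base, "_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
    paths["truth"] <- paste0(base, "_truth.json")
  }
  paths
}
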