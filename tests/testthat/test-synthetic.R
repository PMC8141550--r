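# Synthetic replica generator: event engine, Langevin stepper, OU site
# geometry, writers, determinism.

test_that("hybrid first-binding times follow the configured exponential law", {
  ## median of the exponential is ln2 / rate
  lam <- 0.0063
  meds <- sapply(1:20, function(s)
    median(draw_binding_times(lam, 51, Inf, seed = s)$time))
  expect_lt(abs(median(meds) / (log(2) / lam) - 1), 0.30)
  ## large-sample KS check against the configured law
  t <- draw_binding_times(lam, 1e4, Inf, seed = 99)$time
  expect_gt(stats::ks.test(t, "pexp", lam)$p.value, 0.01)
})

test_that("generation is bit-reproducible from (config, seed)", {
  cfg <- desk_hybrid_config(2, 4, 0.05, seed = 21)
  g1 <- generate_replica_set(cfg)
  g2 <- generate_replica_set(cfg)
  expect_identical(g1$replica_set$trajectories[[1L]]$coords,
                   g2$replica_set$trajectories[[1L]]$coords)
  expect_identical(g1$ground_truth, g2$ground_truth)
  ## a materialised subset reproduces the same replica bit-exactly
  g3 <- generate_replica_set(cfg, replicas = 2L)
  expect_identical(g3$replica_set$trajectories[[1L]]$coords,
                   g1$replica_set$trajectories[[2L]]$coords)
})

test_that("n_ions = 0 yields protein pseudo-atoms only and zero events", {
  cfg <- suppressWarnings(desk_hybrid_config(2, 2, 0.05, n_ions = 0L))
  g <- generate_replica_set(cfg)
  expect_equal(nrow(g$ground_truth$replicas[[1L]]$events), 0L)
  expect_false(any(g$replica_set$topology$atoms$element == "Na"))
})

test_that("concentration bookkeeping ties ion count to box volume", {
  expect_equal(ions_for_concentration(0.15, c(8, 8, 10)), 58L)
  cfg <- desk_hybrid_config(1, 1, 0.05)
  imp <- cfg$n_ions / (6.02214076e23 * prod(cfg$box) * 1e-24)
  expect_lt(abs(imp - cfg$concentration) / cfg$concentration, 0.05)
  expect_warning(desk_hybrid_config(1, 1, 0.05, n_ions = 20L),
                 "differs from")
})

test_that("deep-site occupancy is absorbing: no NA1/NA2 exits in ground truth", {
  for (s in 1:5) {
    g <- generate_replica_set(desk_hybrid_config(3, 60, 0.1, seed = s),
                              materialize = FALSE)
    for (r in g$ground_truth$replicas) {
      deep <- r$events[r$events$site %in% c("NA1", "NA2"), , drop = FALSE]
      if (nrow(deep)) expect_true(all(deep$censored))
    }
  }
})

test_that("free-diffusion Langevin steps have per-dimension MSD 2 D dt", {
  set.seed(31)
  D <- 1; dt <- 0.001
  pos <- matrix(0, 1000L, 3L)
  tot <- 0; n <- 0
  for (k in 1:100) {
    new <- step_langevin(pos, matrix(0, 1000L, 3L), D, dt)
    tot <- tot + sum((new - pos)^2); n <- n + length(pos)
    pos <- new
  }
  expect_lt(abs(tot / n / (2 * D * dt) - 1), 0.02)
})

test_that("zero-noise Langevin drifts in a straight line at D * F", {
  pos <- matrix(0, 4L, 3L)
  Fc <- matrix(rep(c(1, -2, 0.5), each = 4L), 4L)
  for (k in 1:10)
    pos <- step_langevin(pos, Fc, 0.5, 0.01, noise = matrix(0, 4L, 3L))
  expect_equal(pos, Fc * 0.5 * 0.01 * 10, tolerance = 1e-12)
})

test_that("harmonic-well Langevin reaches the equipartition variance kT/k", {
  set.seed(32)
  k_spring <- 5; D <- 1; dt <- 0.001
  pos <- matrix(0, 200L, 3L)
  acc <- 0; n <- 0
  for (s in 1:4000) {
    pos <- step_langevin(pos, -k_spring * pos, D, dt)
    if (s > 1000) { acc <- acc + sum(pos^2); n <- n + length(pos) }
  }
  expect_lt(abs(acc / n / (1 / k_spring) - 1), 0.05)
})

test_that("spatial-mode ions in a closed box with no potential stay uniform (Poisson dispersion)", {
  set.seed(33)
  ## direct check of the density histogram on uniform positions (1e5 samples)
  coords <- array(runif(100 * 1000 * 3, 0, 5), c(100L, 1000L, 3L))
  top <- ion_topology(1000L)
  rs <- replica_set(top, list(traj_from_coords(coords, dt = 0.005,
                                               box = c(5, 5, 5))))
  g <- accumulate_density(rs, select_ions(top),
                          grid_spec(c(0, 0, 0), 0.5, c(10, 10, 10)), 0.005)
  disp <- stats::var(as.numeric(g$values)) / mean(g$values)
  expect_gt(disp, 0.9); expect_lt(disp, 1.1)
})

test_that("OU site geometry holds the apo radius when censored", {
  set.seed(34)
  spec <- geometry_process_spec(6, 0.45, 0.35, 1, 0.01, 0.005)
  arr <- evolve_site_geometry(spec, NA, 100, 0.1, c(2, 2, 2))
  v <- apply(arr, 1L, frame_compactness)
  ## OU standard error of the time mean: sd/sqrt(n_eff)
  n_eff <- length(v) * 0.1 / (2 * spec$ou_time)
  se <- stats::sd(v) / sqrt(n_eff)
  expect_lt(abs(mean(v) - 0.45), 3 * se + 1e-4)
})

test_that("instant relaxation pins the radius at the bound value", {
  spec <- geometry_process_spec(6, 0.45, 0.35, relaxation_time = 1e-9,
                                positional_stddev_apo = 0,
                                positional_stddev_bound = 0)
  arr <- evolve_site_geometry(spec, 0, 5, 0.1, c(0, 0, 0))
  v <- apply(arr, 1L, frame_compactness)
  expect_equal(v[-1L], rep(0.35, length(v) - 1L), tolerance = 1e-6)
})

test_that("noise-free geometry follows the exact deterministic relaxation curve", {
  spec <- geometry_process_spec(6, 0.45, 0.35, 1.0, 0, 0)
  arr <- evolve_site_geometry(spec, 10, 30, 0.1, c(1, 1, 1))
  v <- apply(arr, 1L, frame_compactness)
  tt <- attr(arr, "times")
  expected <- ifelse(tt < 10, 0.45, 0.35 + 0.1 * exp(-(tt - 10) / 1))
  expect_equal(v, expected, tolerance = 1e-12)
})

test_that("write_replica round-trips trajectories and the ground-truth sidecar", {
  cfg <- desk_hybrid_config(1, 2, 0.1, seed = 36)
  g <- generate_replica_set(cfg)
  tr <- g$replica_set$trajectories[[1L]]
  out <- tempfile()
  paths <- write_replica(tr, g$replica_set$topology, out,
                         formats = c("gro", "dcd"),
                         truth = g$ground_truth$replicas[[1L]])
  back <- read_trajectory(g$replica_set$topology, paths[["gro"]], "GRO", 1L)
  expect_equal(back$n_frames, tr$n_frames)
  expect_equal(back$times, tr$times, tolerance = 1e-9)
  expect_error(write_replica(tr, g$replica_set$topology, out, "xtc"),
               "unsupported format")
  ## full ground-truth JSON round trip
  gt_path <- tempfile(fileext = ".json")
  write_ground_truth(g$ground_truth, gt_path)
  gt2 <- read_ground_truth(gt_path)
  expect_equal(gt2$rates, g$ground_truth$rates, tolerance = 1e-12)
  expect_equal(gt2$replicas[[1L]]$events, g$ground_truth$replicas[[1L]]$events,
               tolerance = 1e-12)
  expect_equal(gt2$replicas[[1L]]$na1_ns, g$ground_truth$replicas[[1L]]$na1_ns)
})

test_that("chloride emulation seeds a releasable ion with a known escape route", {
  cfg <- desk_hybrid_config(6, 40, 0.05, seed = 37, chloride = TRUE,
                            chloride_escape_rate = 0.1)
  g <- generate_replica_set(cfg)
  top <- g$replica_set$topology
  cl_sel <- select_ions(top, "Cl")
  cl_site <- site_definition("CL", select_atoms(top, "902:MK"),
                             min_dwell = 0)
  na1 <- site_definition("NA1", select_atoms(top, na1_selection_expr()))
  found <- FALSE
  for (i in seq_along(g$replica_set$trajectories)) {
    gt <- g$ground_truth$replicas[[as.character(i)]]
    rel <- detect_release(g$replica_set$trajectories[[i]], cl_site, na1,
                          cl_sel)
    if (!is.na(gt$chloride$release_ns)) {
      found <- TRUE
      expect_equal(rel$release_ns, gt$chloride$release_ns)
      expect_true(rel$passed_via)
    } else expect_equal(nrow(rel), 0L)
  }
  expect_true(found)
})

test_that("NA2-first coupling concentrates the binding order", {
  cfg <- synthetic_config("hybrid", n_replicas = 60, duration = 150,
                          dt_frame = 1, seed = 38, couple_na1_to_na2 = TRUE)
  g <- generate_replica_set(cfg, materialize = FALSE)
  t1 <- sapply(g$ground_truth$replicas, `[[`, "na1_ns")
  t2 <- sapply(g$ground_truth$replicas, `[[`, "na2_ns")
  both <- !is.na(t1) & !is.na(t2)
  expect_true(all(t2[both] <= t1[both]))
})
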