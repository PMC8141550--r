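# Event detection: gate crossings, occupancy hysteresis, censoring,
# binding order, release routes.

## a gate at z = 5 with anchors on the x axis, axis pointing down
make_gate <- function(top) {
  gate_definition(select_atoms(top, "104:CZ"), select_atoms(top, "493:CD"))
}

gate_topology <- function(n_ions) {
  topology(data.frame(
    atom_id = seq_len(n_ions + 2L) - 1L,
    atom_name = c("CZ", "CD", rep("NA", n_ions)),
    residue_name = c("ARG", "GLU", rep("NA", n_ions)),
    residue_number = c(104L, 493L, 1000L + seq_len(n_ions)),
    element = c("C", "C", rep("Na", n_ions)),
    mass = c(12, 12, rep(22.99, n_ions))))
}

## frames x (2 anchors + ions) x 3 coordinates with static anchors
gate_coords <- function(ion_z, ion_xy = c(4, 4)) {
  nf <- length(ion_z)
  coords <- array(NA_real_, c(nf, 3L, 3L))
  coords[, 1L, ] <- matrix(rep(c(3.2, 4, 5), each = nf), nf)
  coords[, 2L, ] <- matrix(rep(c(4.8, 4, 5), each = nf), nf)
  coords[, 3L, 1L] <- ion_xy[1L]
  coords[, 3L, 2L] <- ion_xy[2L]
  coords[, 3L, 3L] <- ion_z
  coords
}

test_that("a scripted gate crossing yields one event at the crossing frame", {
  top <- gate_topology(1L)
  z <- c(rep(6, 100L), rep(4.5, 100L))   # crosses into the vestibule at frame 101
  tr <- traj_from_coords(gate_coords(z), dt = 0.01)
  ev <- detect_vestibule_entries(tr, make_gate(top), select_ions(top))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$entry_ns, 100 * 0.01)
  expect_true(ev$censored)
})

test_that("gate dwell filtering discards flicker and keeps nothing for absent ions", {
  top <- gate_topology(1L)
  z <- c(rep(c(6, 4.5), 49L), 6, 6)      # 1-frame flickers, ends outside
  tr <- traj_from_coords(gate_coords(z), dt = 0.01)
  gate <- gate_definition(select_atoms(top, "104:CZ"),
                          select_atoms(top, "493:CD"), min_dwell = 0.05)
  ev <- detect_vestibule_entries(tr, gate, select_ions(top))
  expect_equal(nrow(ev), 0L)
  ## never entering: empty result
  tr2 <- traj_from_coords(gate_coords(rep(7, 50L)), dt = 0.01)
  ev2 <- detect_vestibule_entries(tr2, make_gate(top), select_ions(top))
  expect_equal(nrow(ev2), 0L)
  ## beside the protein: inside in z but beyond the lateral radius
  tr3 <- traj_from_coords(gate_coords(rep(4.5, 50L), ion_xy = c(7.5, 4)),
                          dt = 0.01)
  ev3 <- detect_vestibule_entries(tr3, make_gate(top), select_ions(top))
  expect_equal(nrow(ev3), 0L)
})

## site occupancy scripts: marker at the origin, one ion at distance d(t)
site_traj <- function(d, dt = 0.1) {
  nf <- length(d)
  coords <- array(0, c(nf, 2L, 3L))
  coords[, 2L, 1L] <- d
  traj_from_coords(coords, dt = dt)
}

test_that("an ion pinned at the site center is one censored occupancy from t = 0", {
  top <- site_topology(1L)
  site <- site_definition("NA1", select_atoms(top, "900:MK"))
  tr <- site_traj(rep(0.01, 100L))
  ev <- detect_site_occupancy(tr, site, select_ions(top))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$entry_ns, 0)
  expect_true(ev$censored)
  expect_true(is.na(ev$exit_ns))
})

test_that("scripted approach and departure give the exact scripted event times", {
  top <- site_topology(1L)
  site <- site_definition("NA1", select_atoms(top, "900:MK"),
                          min_dwell = 1.0)
  ## approach: outside until frame 50, inside entry cutoff frames 51-80
  ## (dwell 3 ns = 2 x min_dwell at 0.1 ns), out past exit at frame 81
  d <- c(rep(1.0, 50L), rep(0.2, 30L), rep(0.8, 20L))
  tr <- site_traj(d)
  ev <- detect_site_occupancy(tr, site, select_ions(top))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$entry_ns, 50 * 0.1)
  expect_equal(ev$exit_ns, 80 * 0.1)
  expect_false(ev$censored)
})

test_that("hysteresis keeps one unbroken event while hovering between cutoffs", {
  top <- site_topology(1L)
  site <- site_definition("NA1", select_atoms(top, "900:MK"),
                          min_dwell = 0)
  d <- c(rep(1, 10L), 0.2, rep(c(0.45, 0.25), 20L), rep(1, 10L))
  tr <- site_traj(d)
  ev <- detect_site_occupancy(tr, site, select_ions(top))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$entry_ns, 10 * 0.1)
})

test_that("raising min_dwell never increases the number of events", {
  set.seed(41)
  top <- site_topology(1L)
  d <- 0.2 + abs(cumsum(rnorm(400L, sd = 0.08)))
  tr <- site_traj(d)
  counts <- sapply(c(0, 0.2, 0.5, 1, 2), function(md) {
    site <- site_definition("NA1", select_atoms(top, "900:MK"),
                            min_dwell = md)
    nrow(detect_site_occupancy(tr, site, select_ions(top)))
  })
  expect_true(all(diff(counts) <= 0L))
})

test_that("detection is invariant under a global rigid motion of all frames", {
  cfg <- desk_hybrid_config(2, 20, 0.05, seed = 42)
  g <- generate_replica_set(cfg)
  tr <- g$replica_set$trajectories[[1L]]
  top <- g$replica_set$topology
  defs <- synthetic_definitions(top)
  ev0 <- rbind(detect_vestibule_entries(tr, defs$gate, defs$ions),
               detect_site_occupancy(tr, defs$na1, defs$ions))
  R <- rot_axis_angle(c(1, 2, 3), 1.1)
  shift <- c(5, -3, 2)
  coords <- tr$coords
  for (k in seq_len(tr$n_frames))
    coords[k, , ] <- tr$coords[k, , ] %*% t(R) +
      matrix(rep(shift, each = tr$n_atoms), tr$n_atoms)
  trm <- trajectory(1L, coords, tr$times, tr$box)
  ## the gate's vestibule axis is a lab-frame direction: it moves with the
  ## rigid motion, like the atoms it is defined against
  gate_m <- gate_definition(select_atoms(top, "104:CZ"),
                            select_atoms(top, "493:CD"),
                            vestibule_axis = as.numeric(R %*% c(0, 0, -1)))
  ev1 <- rbind(detect_vestibule_entries(trm, gate_m, defs$ions),
               detect_site_occupancy(trm, defs$na1, defs$ions))
  expect_equal(ev0$entry_ns, ev1$entry_ns, tolerance = 1e-9)
  expect_equal(ev0$site, ev1$site)
})

test_that("first_binding_times takes per-replica minima and flags censoring", {
  ev <- data.frame(replica_id = c(1L, 1L, 3L), ion_id = 1L,
                   site = "NA1", entry_ns = c(40, 12, 7),
                   exit_ns = NA_real_, censored = TRUE)
  tab <- event_table(ev, 3L, 150)
  ft <- first_binding_times(tab, "NA1")
  expect_equal(ft$time, c(12, NA, 7))
  expect_equal(ft$censored, c(FALSE, TRUE, FALSE))
  expect_error(first_binding_times(tab, "NOPE"), "key error")
})

test_that("binding-order counts partition the replicas exhaustively", {
  ## nine both-bound replicas, eight with NA2 first, plus assorted singles
  mk <- function(r, site, t) data.frame(replica_id = r, ion_id = 1L,
                                        site = site, entry_ns = t,
                                        exit_ns = NA_real_, censored = TRUE)
  ev <- rbind(
    do.call(rbind, lapply(1:8, function(r) rbind(mk(r, "NA2", 10 + r),
                                                 mk(r, "NA1", 50 + r)))),
    mk(9L, "NA1", 5), mk(9L, "NA2", 80),
    mk(10L, "NA1", 33), mk(11L, "NA2", 44),
    mk(12L, "NA1", 60), mk(12L, "NA2", 60))
  tab <- event_table(ev, 14L, 150)
  counts <- binding_order_counts(tab)
  expect_equal(counts[["NA2_first"]], 8L)
  expect_equal(counts[["NA1_first"]], 1L)
  expect_equal(counts[["tie"]], 1L)
  expect_equal(counts[["only_NA1"]], 1L)
  expect_equal(counts[["only_NA2"]], 1L)
  expect_equal(counts[["neither"]], 2L)
  expect_equal(sum(counts), 14L)
  ## empty table: everything in 'neither'
  empty <- event_table(ev[0L, ], 5L, 150, sites = c("NA1", "NA2"))
  expect_equal(binding_order_counts(empty)[["neither"]], 5L)
})

test_that("release detection reports the scripted route through the via site", {
  top <- topology(data.frame(
    atom_id = 0:2, atom_name = c("MK", "MK", "CL"),
    residue_name = c("CLS", "STE", "CL"),
    residue_number = c(902L, 900L, 999L),
    element = c("C", "C", "Cl"), mass = c(12, 12, 35.45)))
  cl_site <- site_definition("CL", select_atoms(top, "902:MK"),
                             min_dwell = 0)
  via <- site_definition("NA1", select_atoms(top, "900:MK"), min_dwell = 0)
  nf <- 60L
  coords <- array(0, c(nf, 3L, 3L))
  coords[, 2L, 1L] <- 2                      # via marker at x = 2
  path_x <- c(rep(0.05, 30L), 2.0, rep(5, 29L))  # via at frame 31
  coords[, 3L, 1L] <- path_x
  tr <- traj_from_coords(coords, dt = 0.1)
  rel <- detect_release(tr, cl_site, via, select_ions(top, "Cl"))
  expect_equal(rel$release_ns, 30 * 0.1)
  expect_true(rel$passed_via)
  ## a path that skips the via region
  coords[, 3L, 1L] <- c(rep(0.05, 30L), rep(5, 30L))
  coords[, 3L, 2L] <- c(rep(0, 30L), rep(3, 30L))
  tr2 <- traj_from_coords(coords, dt = 0.1)
  rel2 <- detect_release(tr2, cl_site, via, select_ions(top, "Cl"))
  expect_false(rel2$passed_via)
  ## unbound start violates the precondition
  coords[1L, 3L, 1L] <- 4
  tr3 <- traj_from_coords(coords, dt = 0.1)
  expect_error(detect_release(tr3, cl_site, via, select_ions(top, "Cl")),
               "precondition")
  ## never released: empty result
  coords2 <- array(0, c(nf, 3L, 3L))
  coords2[, 2L, 1L] <- 2
  coords2[, 3L, 1L] <- 0.05
  rel3 <- detect_release(traj_from_coords(coords2, dt = 0.1), cl_site, via,
                         select_ions(top, "Cl"))
  expect_equal(nrow(rel3), 0L)
})

test_that("event tables reject out-of-range and inverted event times", {
  ev <- data.frame(replica_id = 1L, ion_id = 1L, site = "NA1",
                   entry_ns = 200, exit_ns = NA_real_, censored = TRUE)
  expect_error(event_table(ev, 1L, 150), "integrity")
  ev2 <- data.frame(replica_id = 1L, ion_id = 1L, site = "NA1",
                    entry_ns = 50, exit_ns = 40, censored = FALSE)
  expect_error(event_table(ev2, 1L, 150), "integrity")
})
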