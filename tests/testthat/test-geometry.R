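# Compactness, smoothing, pre/post splits, RMSD matrices.

test_that("compactness of symmetric arrangements equals the circumradius", {
  ## octahedron of circumradius r
  r <- 0.37
  u <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  nf <- 5L
  coords <- array(NA_real_, c(nf, 7L, 3L))
  for (k in seq_len(nf)) coords[k, , ] <- rbind(u * r + 2, c(9, 9, 9))
  top <- topology(data.frame(
    atom_id = 0:6, atom_name = c(rep("O", 6L), "NA"),
    residue_name = c(rep("GLY", 6L), "NA"),
    residue_number = c(1:6, 1000L), element = c(rep("O", 6L), "Na"),
    mass = c(rep(16, 6L), 23)))
  tr <- traj_from_coords(coords, dt = 0.1)
  sel <- select_atoms(top, "1:O, 2:O, 3:O, 4:O, 5:O, 6:O")
  cs <- compactness_series(tr, sel, 0.1)
  expect_equal(cs$value, rep(r, nf), tolerance = 1e-12)
  ## two atoms separated by d -> d/2
  coords2 <- array(0, c(3L, 2L, 3L))
  coords2[, 2L, 1L] <- 0.8
  tr2 <- traj_from_coords(coords2, dt = 0.1)
  cs2 <- compactness_series(tr2, structure(list(expression = "x",
                                                indices = 1:2,
                                                atom_ids = 0:1),
                                           class = "AtomSelection"), 0.1)
  expect_equal(cs2$value, rep(0.4, 3L), tolerance = 1e-12)
  expect_error(compactness_series(tr2, structure(list(expression = "x",
                                                      indices = 1L,
                                                      atom_ids = 0L),
                                                 class = "AtomSelection")),
               "definition error")
})

test_that("compactness recovers the configured apo radius of the OU process", {
  set.seed(61)
  spec <- geometry_process_spec(6, 0.45, 0.35, 1, 0.02, 0.01)
  arr <- evolve_site_geometry(spec, NA, 80, 0.1, c(3, 3, 3))
  v <- apply(arr, 1L, frame_compactness)
  n_eff <- length(v) * 0.1 / (2 * spec$ou_time)
  se <- stats::sd(v) / sqrt(n_eff)
  expect_lt(abs(mean(v) - 0.45), 3 * se + 2e-3)
})

test_that("compactness is invariant under rigid motion of the frame", {
  set.seed(62)
  p <- matrix(rnorm(18, sd = 0.4), 6L)
  coords <- array(NA_real_, c(2L, 6L, 3L))
  coords[1L, , ] <- p
  coords[2L, , ] <- p %*% t(rot_axis_angle(c(1, 1, 0), 0.9)) +
    matrix(rep(c(3, -1, 2), each = 6L), 6L)
  tr <- traj_from_coords(coords + 10, dt = 0.1)
  sel <- structure(list(expression = "x", indices = 1:6, atom_ids = 0:5),
                   class = "AtomSelection")
  cs <- compactness_series(tr, sel, 0.1)
  expect_lt(abs(cs$value[1L] - cs$value[2L]), 1e-9)
})

test_that("running averages fix constants, spread impulses, and keep ramps", {
  s <- data.frame(time = seq(0, 10, 0.1), value = 3)
  expect_equal(running_average(s, 1)$value, s$value)
  imp <- data.frame(time = seq(0, 10, 0.1), value = 0)
  imp$value[51L] <- 1
  sm <- running_average(imp, 1)   # 11-sample centered window
  expect_equal(sm$value[51L], 1 / 11, tolerance = 1e-12)
  expect_equal(sum(sm$value > 0), 11L)
  ramp <- data.frame(time = seq(0, 10, 0.1), value = seq(0, 10, 0.1) * 2)
  smr <- running_average(ramp, 1)
  expect_equal(smr$value[10:92], ramp$value[10:92], tolerance = 1e-12)
  expect_error(running_average(s, 0.01), "config error")
})

test_that("pre/post splits respect censoring and boundaries", {
  s <- data.frame(time = seq(0, 10, 0.1), value = rnorm(101L, 0.4, 0.01))
  cen <- split_pre_post(s, NA)
  expect_null(cen$post)
  expect_equal(cen$pre$n, 101L)
  expect_true(is.na(cen$value_at_binding))
  zero <- split_pre_post(s, 0)
  expect_equal(zero$pre$n, 0L)
  expect_equal(zero$post$n, 101L)
  mid <- split_pre_post(s, 5.04)
  expect_equal(mid$pre$n + mid$post$n, 101L)
  expect_equal(mid$value_at_binding, s$value[51L])
})

test_that("the apo-bound compactness shift is recovered from the generator", {
  ## configured shift 0.1 nm; relaxation fast relative to the post window
  deltas <- sapply(1:10, function(s) {
    set.seed(600 + s)
    spec <- geometry_process_spec(6, 0.45, 0.35, 1, 0.04, 0.02)
    bt <- 30
    arr <- evolve_site_geometry(spec, bt, 90, 0.1, c(2, 2, 2))
    v <- apply(arr, 1L, frame_compactness)
    sp <- split_pre_post(data.frame(time = attr(arr, "times"), value = v),
                         bt)
    sp$pre$mean - sp$post$mean
  })
  expect_true(all(abs(deltas - 0.1) < 0.02))
})

test_that("RMSD matrices are symmetric, zero-diagonal, and match the quaternion oracle", {
  cfg <- desk_hybrid_config(3, 10, 0.05, seed = 63)
  g <- generate_replica_set(cfg)
  top <- g$replica_set$topology
  sel <- select_atoms(top, na1_selection_expr())
  ft <- data.frame(replica_id = 1:3, time = c(4, NA, 1),
                   censored = c(FALSE, TRUE, FALSE))
  m <- rmsd_matrix(g$replica_set, sel, ft, stride = 3)
  expect_equal(m$values, t(m$values), tolerance = 1e-12)
  expect_true(all(diag(m$values) == 0))
  ## ordering: bound replicas by ascending time (3, 1), censored (2) last
  expect_equal(m$order, c(3L, 1L, 2L))
  ## independent all-pairs recomputation, quaternion method, n = 10 frames
  idx <- sel$indices
  snaps <- list()
  for (tr in g$replica_set$trajectories[order(c(4, NA, 1), na.last = TRUE)])
    for (k in seq(1L, tr$n_frames, by = round(3 / tr$dt))) {
      p <- tr$coords[k, idx, , drop = FALSE]; dim(p) <- c(length(idx), 3L)
      snaps[[length(snaps) + 1L]] <- p
    }
  n <- length(snaps)
  expect_gte(n, 10L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    expect_lt(abs(m$values[i, j] -
                  rmsd_quaternion_oracle(snaps[[i]], snaps[[j]])), 1e-9)
})

test_that("two-state geometries separate into blocks in the RMSD matrix", {
  ## apo-like vs bound-like frames of a noiseless coordinating shell
  u <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  apo <- u * 0.45; bound <- u * 0.35
  snaps <- c(replicate(5, apo, simplify = FALSE),
             replicate(5, bound, simplify = FALSE))
  within_bound <- ionbindr:::pair_rmsd(snaps[[6L]], snaps[[7L]],
                                       "pairwise")$rmsd
  across <- ionbindr:::pair_rmsd(snaps[[1L]], snaps[[6L]], "pairwise")$rmsd
  expect_lt(within_bound, across)
})

test_that("degenerate collinear pairs are flagged, not fatal", {
  line <- cbind(1:3, 1:3, 1:3) * 0.1
  r <- ionbindr:::pair_rmsd(line, line + 0.2, "pairwise")
  expect_true(r$degenerate)
  expect_lt(r$rmsd, 1e-12)   # pure translation removed by centering
})

test_that("post-binding compactness variance drops when the bound state is stiffer", {
  wins <- sapply(1:20, function(s) {
    set.seed(700 + s)
    spec <- geometry_process_spec(6, 0.45, 0.35, 1, 0.04, 0.02)
    arr <- evolve_site_geometry(spec, 20, 60, 0.1, c(2, 2, 2))
    v <- apply(arr, 1L, frame_compactness)
    tt <- attr(arr, "times")
    stats::var(v[tt >= 20]) < stats::var(v[tt < 20])
  })
  expect_gte(sum(wins), 18L)
})
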