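# Spatial density and displacement-rate maps, OpenDX I/O.

test_that("a fixed ion fills exactly one voxel and mass is conserved", {
  top <- ion_topology(1L)
  coords <- array(rep(c(1.25, 2.25, 3.25), each = 100L), c(100L, 1L, 3L))
  rs <- replica_set(top, list(traj_from_coords(coords, dt = 0.005)))
  spec <- grid_spec(c(0, 0, 0), 0.1, c(40, 40, 40))
  g <- accumulate_density(rs, select_ions(top), spec, 0.005)
  expect_equal(max(g$values), 100)
  expect_equal(sum(g$values), 100)
  expect_equal(g$overflow, 0)
  expect_equal(sum(g$values) + g$overflow, g$total_samples)
  ## half-open voxel membership: the occupied voxel is (13, 23, 33)
  expect_equal(g$values[13, 23, 33], 100)
})

test_that("doubling the sampling interval halves the counts; outside ions hit overflow", {
  set.seed(51)
  top <- ion_topology(3L)
  coords <- array(runif(200 * 3 * 3, 0, 4), c(200L, 3L, 3L))
  coords[, 3L, 1L] <- 50   # ion 3 lives outside the grid
  rs <- replica_set(top, list(traj_from_coords(coords, dt = 0.005)))
  spec <- grid_spec(c(0, 0, 0), 0.1, c(40, 40, 40))
  g1 <- accumulate_density(rs, select_ions(top), spec, 0.005)
  g2 <- accumulate_density(rs, select_ions(top), spec, 0.010)
  expect_equal(g1$overflow, 200)
  expect_equal(sum(g1$values) + g1$overflow, g1$total_samples)
  expect_lte(abs(sum(g2$values) * 2 - sum(g1$values)), 3 * 2)
})

test_that("uniform occupancy shows Poisson voxel dispersion at 1e5 samples", {
  set.seed(52)
  top <- ion_topology(500L)
  coords <- array(runif(200 * 500 * 3, 0, 5), c(200L, 500L, 3L))
  rs <- replica_set(top, list(traj_from_coords(coords, dt = 0.005,
                                               box = c(5, 5, 5))))
  g <- accumulate_density(rs, select_ions(top),
                          grid_spec(c(0, 0, 0), 0.5, c(10, 10, 10)), 0.005)
  disp <- stats::var(as.numeric(g$values)) / mean(g$values)
  expect_gt(disp, 0.9); expect_lt(disp, 1.1)
})

test_that("displacement maps attribute rates to the start-frame voxel", {
  top <- ion_topology(1L)
  ## straight line at 1 nm/ns along x
  nf <- 101L
  coords <- array(0, c(nf, 1L, 3L))
  coords[, 1L, 1L] <- (seq_len(nf) - 1L) * 0.01  # dt 0.01 -> 1 nm/ns
  coords[, 1L, 2L] <- 2.05; coords[, 1L, 3L] <- 2.05
  rs <- replica_set(top, list(traj_from_coords(coords, dt = 0.01)))
  spec <- grid_spec(c(0, 0, 0), 0.1, c(40, 40, 40))
  g <- accumulate_displacement(rs, select_ions(top), spec, lag = 0.01)
  visited <- g$values[!is.na(g$values)]
  expect_equal(unname(visited), rep(1, length(visited)), tolerance = 1e-9)
  ## static ion: rate 0 in its voxel, NA elsewhere (never 0 by default)
  coords0 <- array(rep(c(1.05, 1.05, 1.05), each = nf), c(nf, 1L, 3L))
  rs0 <- replica_set(top, list(traj_from_coords(coords0, dt = 0.01)))
  g0 <- accumulate_displacement(rs0, select_ions(top), spec, lag = 0.01)
  expect_equal(g0$values[11, 11, 11], 0)
  expect_equal(sum(!is.na(g0$values)), 1L)
  ## lag must be a multiple of dt
  expect_error(accumulate_displacement(rs0, select_ions(top), spec,
                                       lag = 0.015), "config error")
})

test_that("free-diffusion grand mean displacement matches the Maxwell closed form", {
  set.seed(53)
  D <- 1.3; lag <- 0.01
  nf <- 2001L; ni <- 50L      # 1e5 displacement pairs
  coords <- array(0, c(nf, ni, 3L))
  for (i in seq_len(ni)) {
    start <- runif(3L, 2, 6)
    steps <- matrix(rnorm((nf - 1L) * 3L, sd = sqrt(2 * D * lag)),
                    ncol = 3L)
    coords[, i, ] <- rbind(matrix(start, 1L),
                           sweep(apply(steps, 2L, cumsum), 2L, start, `+`))
  }
  top <- ion_topology(ni)
  rs <- replica_set(top, list(traj_from_coords(coords, dt = lag,
                                               box = c(1e3, 1e3, 1e3))))
  spec <- grid_spec(c(-500, -500, -500), 1000 / 3, c(3, 3, 3))
  g <- accumulate_displacement(rs, select_ions(top), spec, lag)
  grand <- sum(g$values * g$samples, na.rm = TRUE) / sum(g$samples)
  maxwell <- 2 * sqrt(2 / pi) * sqrt(2 * D * lag) / lag
  expect_lt(abs(grand / maxwell - 1), 0.05)
})

test_that("OpenDX grids round-trip origin, spacing, shape, values and missing voxels", {
  sp <- grid_spec(c(0.5, 1, 1.5), 0.1, c(2, 3, 4))
  vals <- array(seq_len(24) / 7, c(2, 3, 4))
  vals[1, 1, 1] <- NA
  g <- ionbindr:::new_grid(sp, vals, vals * 0 + 1, "displacement_rate", 0)
  f <- tempfile(fileext = ".dx")
  write_grid(g, f)
  back <- read_grid(f)
  expect_equal(back$spec$origin, sp$origin)
  expect_equal(back$spec$spacing, sp$spacing)
  expect_equal(back$spec$shape, sp$shape)
  expect_true(is.na(back$values[1, 1, 1]))
  expect_equal(back$values[-1], vals[-1], tolerance = 1e-8)
})

test_that("a 2x2x2 grid matches the hand-written OpenDX golden file", {
  sp <- grid_spec(c(0, 0, 0), 0.1, c(2, 2, 2))
  g <- ionbindr:::new_grid(sp, array(1:8, c(2, 2, 2)), array(1, c(2, 2, 2)),
                           "density", 0)
  f <- tempfile(fileext = ".dx")
  write_grid(g, f)
  golden <- c(
    "# OpenDX scalar field: density",
    "# units: nm; missing voxels written as sentinel -999",
    "# overflow tally (samples outside grid): 0",
    "object 1 class gridpositions counts 2 2 2",
    "origin 0.000000 0.000000 0.000000",
    "delta 0.100000 0 0",
    "delta 0 0.100000 0",
    "delta 0 0 0.100000",
    "object 2 class gridconnections counts 2 2 2",
    "object 3 class array type double rank 0 items 8 data follows",
    "1 5 3",             # z-fastest ordering of the column-major array
    "7 2 6",
    "4 8",
    'attribute "dep" string "positions"',
    'object "density" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3')
  expect_identical(readLines(f), golden)
})

test_that("density and displacement grids of one spec are co-registered", {
  top <- ion_topology(2L)
  coords <- array(runif(2 * 50 * 3, 0, 3), c(50L, 2L, 3L))
  rs <- replica_set(top, list(traj_from_coords(coords, dt = 0.01)))
  sp <- grid_spec(c(0, 0, 0), 0.1, c(30, 30, 30))
  f1 <- tempfile(fileext = ".dx"); f2 <- tempfile(fileext = ".dx")
  write_grid(accumulate_density(rs, select_ions(top), sp, 0.01), f1)
  write_grid(accumulate_displacement(rs, select_ions(top), sp, 0.01), f2)
  h1 <- grep("^(origin|delta|object 1)", readLines(f1), value = TRUE)
  h2 <- grep("^(origin|delta|object 1)", readLines(f2), value = TRUE)
  expect_identical(h1, h2)
})

test_that("maps are invariant under a rigid motion applied to frames and grid origin", {
  set.seed(54)
  top <- ion_topology(5L)
  coords <- array(runif(5 * 100 * 3, 1, 4), c(100L, 5L, 3L))
  rs <- replica_set(top, list(traj_from_coords(coords, dt = 0.01)))
  sp <- grid_spec(c(0, 0, 0), 0.1, c(50, 50, 50))
  d0 <- accumulate_density(rs, select_ions(top), sp, 0.01)
  v0 <- accumulate_displacement(rs, select_ions(top), sp, 0.01)
  shift <- c(1.7, -0.9, 2.3)   # translation: the voxel lattice moves along
  coords2 <- sweep(coords, 3L, shift, `+`)
  rs2 <- replica_set(top, list(traj_from_coords(coords2, dt = 0.01)))
  sp2 <- grid_spec(shift, 0.1, c(50, 50, 50))
  d1 <- accumulate_density(rs2, select_ions(top), sp2, 0.01)
  v1 <- accumulate_displacement(rs2, select_ions(top), sp2, 0.01)
  expect_identical(d0$values, d1$values)
  expect_equal(v0$values, v1$values, tolerance = 1e-9)
})
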