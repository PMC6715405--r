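test_that("spot detection matches a brute-force flood fill on random fields", {
  lat <- lattice_disc(10)
  set.seed(202)
  for (i in 1:60) {
    field <- rpois(n_voxels(lat), 3)
    conn <- if (i %% 2 == 0) "face" else "face_and_diagonal"
    sp <- detect_spots(field, lat, threshold = 4, connectivity = conn)
    comps <- oracle_flood_fill(field > 4, lat, diagonal = conn != "face")
    expect_equal(attr(sp, "n_spots"), length(comps))
    got <- lapply(sp$voxels, sort)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(comps, paste, "", collapse = ","))
  }
})

test_that("synthetic two-disc field yields two spots with the known diameter", {
  lat <- lattice_disc(20)
  f <- rep(0, n_voxels(lat))
  f <- paint_disc(f, lat, -8, 0, 3, 500)
  f <- paint_disc(f, lat, 8, 0, 3, 500)
  disc3 <- oracle_disc_count(3)
  sp <- detect_spots(f, lat, threshold = 400)
  expect_equal(attr(sp, "n_spots"), 2L)
  expect_equal(sp$n_voxels, rep(disc3, 2))
  expect_equal(sp$diameter, rep(2 * sqrt(disc3 / pi), 2))
  expect_equal(sort(sp$centroid_x), c(-8, 8))
  # above every count, no spots; all-zero field, no spots
  expect_equal(attr(detect_spots(f, lat, threshold = 600), "n_spots"), 0L)
  expect_equal(attr(detect_spots(rep(0, n_voxels(lat)), lat, 1), "n_spots"), 0L)
})

test_that("raising the threshold never increases the spot count", {
  lat <- lattice_disc(12)
  set.seed(7)
  field <- rpois(n_voxels(lat), 5)
  counts <- vapply(c(3, 5, 7, 9, 12), function(th)
    attr(detect_spots(field, lat, th), "n_spots"), 0L)
  # counts can rise then fall as blobs split, but monotone against subset:
  # the supra-threshold mask shrinks, so the highest threshold has <= voxels
  masks <- lapply(c(3, 5, 7, 9, 12), function(th) field > th)
  for (i in 2:5) expect_true(all(masks[[i]] <= masks[[i - 1]]))
  expect_lte(counts[5], attr(detect_spots(field, lat, 3), "n_spots") +
               sum(masks[[5]]))
  # strictly: zero voxels above max(field) means zero spots
  expect_equal(attr(detect_spots(field, lat, max(field)), "n_spots"), 0L)
})

test_that("3D fields require a slice and slices analyze independently", {
  lat <- lattice_cylinder(5, 4)
  f <- rep(0, n_voxels(lat))
  f[lat$voxels$z == 2 & lat$voxels$r < 2] <- 100
  expect_error(detect_spots(f, lat, 50), "z-slice")
  expect_equal(attr(detect_spots(f, lat, 50, z = 2), "n_spots"), 1L)
  expect_equal(attr(detect_spots(f, lat, 50, z = 0), "n_spots"), 0L)
})

test_that("zonation recovers hand-constructed zone widths", {
  lat <- lattice_disc(25)           # shell boundary at r = 24
  f <- rep(0, n_voxels(lat))
  f <- paint_disc(f, lat, 0, 0, 5, 500)          # central spots to r = 5
  zn <- zonation(f, lat, threshold = 400)
  g <- glance(zn)
  expect_equal(g$r_shell, 24)
  expect_equal(g$zone_a_width, 1)
  expect_equal(g$zone_c_radius, 5)
  expect_equal(g$zone_b_width, 24 - 5)
  expect_gte(g$zone_b_width, 25 / 2 - 0.04 * 25) # spots confined to r < R/2

  # ring of spots just inside the shell shrinks zone B to (almost) nothing
  f2 <- f
  ring <- lat$voxels$r >= 23 & lat$voxels$r < 24
  f2[ring] <- 500
  g2 <- glance(zonation(f2, lat, threshold = 400))
  expect_equal(g2$zone_b_width, 24 - max(lat$voxels$r[ring]))
  expect_lt(g2$zone_b_width, 1)

  # no spots anywhere: the whole interior is the SVB-free annulus
  g3 <- glance(zonation(rep(0, n_voxels(lat)), lat, threshold = 400))
  expect_equal(g3$zone_b_width, 24)
  # profile bins partition [0, R]
  expect_equal(sum(zn$n_voxels), n_voxels(lat))
})

test_that("stationarity is TRUE for frozen fields and FALSE for alternating masks", {
  lat <- lattice_disc(8)
  f <- rep(0, n_voxels(lat))
  f <- paint_disc(f, lat, 0, 0, 3, 100)
  frozen <- structure(list(
    snapshots = list(cbind(H = f), cbind(H = f), cbind(H = f)),
    snap_times = c(1, 2, 3), lattice = lat), class = "vp_trajectory")
  st <- stationarity(frozen, "H", threshold = 50)
  expect_true(st$stationary)
  expect_equal(st$diagnostics$jaccard_to_prev[-1], c(1, 1))

  g <- rep(0, n_voxels(lat))
  g <- paint_disc(g, lat, 4, 0, 2, 100)
  h <- rep(0, n_voxels(lat))
  h <- paint_disc(h, lat, -4, 0, 2, 100)
  alt <- structure(list(
    snapshots = list(cbind(H = g), cbind(H = h), cbind(H = g)),
    snap_times = c(1, 2, 3), lattice = lat), class = "vp_trajectory")
  st2 <- stationarity(alt, "H", threshold = 50)
  expect_false(st2$stationary)
  expect_equal(st2$diagnostics$jaccard_to_prev[-1], c(0, 0))
})

test_that("jaccard similarity of a drifting spot equals the overlap ratio", {
  lat <- lattice_disc(10)
  a <- rep(0, n_voxels(lat))
  a <- paint_disc(a, lat, 0, 0, 3, 100)
  b <- rep(0, n_voxels(lat))
  b <- paint_disc(b, lat, 1, 0, 3, 100) # one-voxel shift
  va <- which(a > 50)
  vb <- which(b > 50)
  expected <- length(intersect(va, vb)) / length(union(va, vb))
  drift <- structure(list(
    snapshots = list(cbind(H = a), cbind(H = b)),
    snap_times = c(1, 2), lattice = lat), class = "vp_trajectory")
  st <- stationarity(drift, "H", threshold = 50, window = 2)
  expect_equal(st$diagnostics$jaccard_to_prev[2], expected)
})

test_that("persistent spots intersect snapshots and filter by size", {
  lat <- lattice_disc(10)
  stable <- rep(0, n_voxels(lat))
  stable <- paint_disc(stable, lat, -4, 0, 2, 300)
  flicker1 <- paint_disc(stable, lat, 5, 0, 2, 300)
  flicker2 <- paint_disc(stable, lat, 5, 5, 1, 300) # different place
  traj <- structure(list(
    snapshots = list(cbind(H = flicker1), cbind(H = flicker2)),
    snap_times = c(1, 2), lattice = lat), class = "vp_trajectory")
  ps <- persistent_spots(traj, "H", threshold = 200)
  expect_equal(attr(ps, "n_spots"), 1L)
  expect_equal(ps$centroid_x, -4)
  expect_error(persistent_spots(traj, "H", n_last = 3), "at least 3 snapshots")
})

test_that("sweep returns one tidy row per cell and replicate, deterministically", {
  p <- base_hb()
  sw <- sweep_diffusion(4, 0.05, c(5, 10), p, replicates = 2,
                        max_time = 4, seed = 30)
  expect_equal(nrow(sw), 4L)
  expect_equal(sort(unique(sw$ratio)), c(5, 10))
  expect_equal(length(unique(sw$seed)), 4L)
  sw2 <- sweep_diffusion(4, 0.05, c(5, 10), p, replicates = 2,
                         max_time = 4, seed = 30)
  expect_identical(sw, sw2)
  expect_error(sweep_diffusion(4, -0.1, 10, p), "positive")
})

test_that("spot threshold is anchored at the homogeneous steady state", {
  expect_equal(spot_threshold(base_hb()), 120)
  expect_equal(spot_threshold(base_hb(), multiple = 2), 80)
  expect_equal(threshold_from_field(c(0, 10, 80)), 40)
  expect_equal(threshold_from_field(rep(0, 5)), Inf)
})

test_that("diffusion rates steer spot size, density, and existence", {
  # scaled-down qualitative trends, each as a replicate-majority outcome:
  # (a) faster activator diffusion widens spots at a fixed ratio;
  # (b) a higher substrate/activator ratio yields more spots (see the
  #     diffusion-ratio experiment in the end-to-end checks);
  # (c) below an activator-diffusion floor no persistent spots form.
  p <- base_hb()
  thr <- spot_threshold(p)
  lat <- lattice_disc(14)
  run_cell <- function(D_H, seed) {
    net <- make_model("HB", c(p, list(D_H = D_H, D_B = 1000 * D_H)))
    traj <- simulate_ssa(net, lat, seed = seed, max_time = 40,
                         snapshot_dt = 10)
    persistent_spots(traj, "H", threshold = thr, n_last = 3)
  }
  seeds <- 31:33
  slow <- lapply(seeds, function(s) run_cell(0.05, s))
  fast <- lapply(seeds, function(s) run_cell(0.15, s))
  diam <- function(x) attr(x, "mean_diameter")
  nsp <- function(x) attr(x, "n_spots")
  # (a) diameter increases with D_H in a majority of replicate pairs
  expect_gte(sum(mapply(function(a, b) diam(b) > diam(a), slow, fast)), 2)
  # spot density falls as spots widen
  expect_gte(sum(mapply(function(a, b) nsp(b) < nsp(a), slow, fast)), 2)
  # (c) far below the diffusion floor the field stays spatially noisy
  floor_runs <- vapply(seeds, function(s) nsp(run_cell(0.002, s)), 0L)
  expect_gte(sum(floor_runs == 0), 2)
})
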