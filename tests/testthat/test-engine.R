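test_that("longitudinal move probability follows the saturating form", {
  expect_equal(longitudinal_move_probability(0, 1, 1), 1 / 3)
  # half saturation at P = 6 D / alpha: baseline 1/3 plus Vmax/2 = 1/3
  expect_equal(longitudinal_move_probability(6, 1, 1), 2 / 3)
  expect_equal(longitudinal_move_probability(12, 2, 4), (4 + 48) / (12 + 48))
  expect_lt(1 - longitudinal_move_probability(1e9, 1, 1), 1e-8)
  # monotone, bounded in [1/3, 1)
  p <- longitudinal_move_probability(0:100, 0.7, 0.3)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 1 / 3 & p < 1))
  expect_error(longitudinal_move_probability(3, 0, 1), "positive")
  expect_error(longitudinal_move_probability(-1, 1, 1), ">= 0")
})

test_that("movement propensities combine diffusion and facilitated transport", {
  lat <- lattice_cylinder(4, 9)
  net <- reaction_network(
    tibble::tibble(name = c("Hc", "P"), D = c(1, 0)),
    transport = list(transport_rule("P", "Hc", alpha = 2))
  )
  interior <- which(rowSums(lat$nbr != 0) == 6 & lat$voxels$x == 0 &
                      lat$voxels$y == 0)[1]
  counts <- matrix(0L, n_voxels(lat), 2, dimnames = list(NULL, c("Hc", "P")))
  counts[interior, ] <- c(5L, 3L)
  st <- init_state(lat, net, counts)

  mp <- movement_propensities(st, net, lat, "Hc", interior)
  expect_equal(sum(mp$rate), (6 * 1 + 2 * 3) * 5)
  long <- sum(mp$rate[mp$direction %in% c("+z", "-z")])
  expect_equal(long / sum(mp$rate), (2 + 6) / 12)
  # immobile carrier has no movement channels with positive rate
  mpP <- movement_propensities(st, net, lat, "P", interior)
  expect_true(all(mpP$rate == 0))

  # basipetal rule sends the facilitated propensity only downward
  netb <- reaction_network(
    tibble::tibble(name = c("Hc", "P"), D = c(1, 0)),
    transport = list(transport_rule("P", "Hc", alpha = 2,
                                    directionality = "basipetal_only"))
  )
  mpb <- movement_propensities(st, netb, lat, "Hc", interior)
  expect_equal(mpb$rate[mpb$kind == "transport"], 2 * 3 * 5)
  expect_equal(mpb$direction[mpb$kind == "transport"], "-z")
})

test_that("a single production channel advances counts one molecule per event", {
  net <- reaction_network(tibble::tibble(name = "H", D = 0),
                          list(reaction("X4", NULL, c(H = 1), 2)))
  lat <- lattice_disc(1)
  tr <- simulate_ssa(net, lat, seed = 1, max_events = 137)
  expect_equal(sum(tr$state$counts), 137)
  expect_equal(tr$state$events, 137)
})

test_that("stationary birth-death counts are Poisson (exactness oracle)", {
  # 5 decoupled voxels (D = 0), time-sampled past burn-in: mean k4/k5,
  # variance/mean 1
  tr <- simulate_ssa(birth_death_net(50, 1), lattice_disc(1), seed = 5,
                     max_time = 12030, snapshot_dt = 3)
  samp <- unlist(lapply(tr$snapshots[-(1:10)], function(m) m[, "H"]))
  expect_gt(length(samp), 1.9e4)
  se <- stats::sd(samp) / sqrt(length(samp) / 3) # conservative for autocorr
  expect_lt(abs(mean(samp) - 50), 3 * se)
  expect_lt(abs(stats::var(samp) / mean(samp) - 1), 0.05)
})

test_that("diffusion and transport conserve molecules; nothing leaves the domain", {
  lat <- lattice_disc(6)
  counts <- matrix(0L, n_voxels(lat), 1, dimnames = list(NULL, "S"))
  counts[1:10, 1] <- 50L
  st <- init_state(lat, diffusion_net(1), counts)
  tr <- simulate_ssa(diffusion_net(1), lat, seed = 2, max_events = 2e4,
                     init = st, snapshot_every = 2000)
  expect_equal(sum(tr$state$counts), 500)
  for (s in tr$snapshots) expect_equal(sum(s), 500)
  expect_true(all(tr$state$counts >= 0))

  # with a carrier: facilitated hops also conserve cargo
  lat3 <- lattice_cylinder(3, 6)
  net3 <- reaction_network(tibble::tibble(name = c("Hc", "P"), D = c(1, 0)),
                           transport = list(transport_rule("P", "Hc", 3)))
  counts3 <- matrix(10L, n_voxels(lat3), 2, dimnames = list(NULL, c("Hc", "P")))
  st3 <- init_state(lat3, net3, counts3)
  tr3 <- simulate_ssa(net3, lat3, seed = 3, max_events = 3e4, init = st3)
  expect_equal(colSums(tr3$state$counts), colSums(counts3))
})

test_that("empirical longitudinal hop fraction matches the saturating law", {
  lat <- lattice_cylinder(4, 9)
  interior6 <- rowSums(lat$nbr != 0) == 6
  for (nP in c(0, 6)) {
    net <- reaction_network(tibble::tibble(name = c("Hc", "P"), D = c(1, 0)),
                            transport = list(transport_rule("P", "Hc", 1)))
    counts <- matrix(0L, n_voxels(lat), 2, dimnames = list(NULL, c("Hc", "P")))
    counts[, "Hc"] <- 20L
    counts[, "P"] <- as.integer(nP)
    st <- init_state(lat, net, counts)
    tr <- simulate_ssa(net, lat, seed = 17 + nP, max_events = 4e4, init = st,
                       log_events = TRUE)
    lg <- tr$event_log
    hops <- lg[interior6[lg$voxel], ]
    frac <- mean(hops$dir %in% c("+z", "-z"))
    pred <- longitudinal_move_probability(nP, 1, 1)
    se <- sqrt(pred * (1 - pred) / nrow(hops))
    expect_lt(abs(frac - pred), 3.3 * se)
  }
})

test_that("single-voxel means track the mean-field kinetics at large counts", {
  # scale counts up 100x (k2, k4 x100; k1 / 100^2) so relative noise is ~1%
  s <- 100
  p <- base_hb()
  p$k1 <- p$k1 / s^2
  p$k2 <- p$k2 * s
  p$k4 <- p$k4 * s
  net <- make_model("HB", c(p, list(D_H = 0, D_B = 0)))
  lat <- lattice_disc(1)
  tr <- simulate_ssa(net, lat, seed = 8, max_time = 80, snapshot_dt = 1)
  post <- tr$snapshots[-(1:40)]
  meanH <- mean(vapply(post, function(m) mean(m[, "H"]), 0))
  meanB <- mean(vapply(post, function(m) mean(m[, "B"]), 0))
  ss <- homogeneous_steady_state(p)
  ss <- ss[which.max(ss$H), ]
  expect_lt(abs(meanH / ss$H - 1), 0.05)
  expect_lt(abs(meanB / ss$B - 1), 0.05)
})

test_that("absorbing states terminate cleanly and max_events = 0 is a no-op", {
  net <- reaction_network(tibble::tibble(name = "B", D = 0),
                          list(reaction("X3", c(B = 1), NULL, 1)))
  lat <- lattice_disc(1)
  counts <- matrix(3L, n_voxels(lat), 1, dimnames = list(NULL, "B"))
  st <- init_state(lat, net, counts)
  tr <- simulate_ssa(net, lat, seed = 1, max_events = 1e6, init = st)
  expect_equal(tr$reason, "absorbing")
  expect_equal(sum(tr$state$counts), 0)

  tr0 <- simulate_ssa(birth_death_net(), lattice_disc(2), seed = 1,
                      max_events = 0)
  expect_equal(tr0$state$events, 0)
  expect_equal(sum(tr0$state$counts), 0)
  expect_error(simulate_ssa(birth_death_net(), lattice_disc(2), seed = 1),
               "stop condition")
})

test_that("same seed gives bit-identical trajectories", {
  net <- make_model("HB", c(base_hb(), list(D_H = 0.05, D_B = 5)))
  lat <- lattice_disc(6)
  a <- simulate_ssa(net, lat, seed = 99, max_events = 2e4, snapshot_every = 5e3)
  b <- simulate_ssa(net, lat, seed = 99, max_events = 2e4, snapshot_every = 5e3)
  expect_identical(a$state, b$state)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$snap_times, b$snap_times)
  c_ <- simulate_ssa(net, lat, seed = 100, max_events = 2e4)
  expect_false(identical(a$state$counts, c_$state$counts))
})

test_that("checkpoint/resume reproduces an uninterrupted run event for event", {
  net <- make_model("HB", c(base_hb(), list(D_H = 0.05, D_B = 5)))
  lat <- lattice_disc(6)
  full <- simulate_ssa(net, lat, seed = 42, max_events = 1e4)
  half <- simulate_ssa(net, lat, seed = 42, max_events = 5e3)

  # in-memory resume
  res <- resume_ssa(half, max_events = 5e3)
  expect_identical(res$state$counts, full$state$counts)
  expect_equal(res$state$events, full$state$events)
  expect_equal(res$state$time, full$state$time, tolerance = 1e-12)

  # resume after a round trip through a checkpoint file
  tmp <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(half, tmp)
  res2 <- resume_ssa(read_checkpoint(tmp), max_events = 5e3)
  expect_identical(res2$state$counts, full$state$counts)

  # altered configuration is rejected
  p2 <- c(base_hb(), list(D_H = 0.05, D_B = 5))
  p2$k1 <- p2$k1 * 2
  expect_error(resume_ssa(half, max_events = 10,
                          network = make_model("HB", p2)),
               "hash mismatch")
})

test_that("region-restricted channels only fire where allowed (event audit)", {
  p <- c(base_hb(), list(D_H = 0.05, D_B = 50, k6 = 0.05, k7 = 1, alpha = 1,
                         k9 = 400, k10 = 0.05, k11 = 0.05, D_M = 7.5))
  net <- make_model("HBPM", p)
  lat <- lattice_disc(8)
  tr <- simulate_ssa(net, lat, seed = 4, max_events = 5e4, log_events = TRUE)
  x9 <- tr$event_log[tr$event_log$channel == "X9", ]
  expect_gt(nrow(x9), 0)
  expect_true(all(shell_mask(lat, lat$shell_fraction)[x9$voxel]))
})

test_that("apex-restricted production happens only in the top layer", {
  p <- c(base_hb(), list(D_H = 0.05, D_B = 50, k6 = 0.05, k7 = 1, alpha = 1,
                         k9 = 400, k10 = 0.05, k11 = 0.05, D_M = 7.5,
                         k13 = 50, k14 = 0.1, k_AH = 0.5, k_HA = 0.05,
                         D_A = 1))
  net <- make_model("HBPMA", p)
  lat <- lattice_cylinder(4, 6)
  tr <- simulate_ssa(net, lat, seed = 6, max_events = 5e4, log_events = TRUE)
  x13 <- tr$event_log[tr$event_log$channel == "X13", ]
  expect_gt(nrow(x13), 0)
  expect_true(all(apex_mask(lat)[x13$voxel]))
  # basipetal transport of A never hops upward
  trA <- tr$event_log[tr$event_log$channel == "transport:A", ]
  if (nrow(trA) > 0) expect_true(all(trA$dir == "-z"))
  # apex-restricted channels demand a 3D lattice
  expect_error(simulate_ssa(net, lattice_disc(4), seed = 1, max_events = 10),
               "apex-restricted")
})

test_that("trajectory tidiers return well-formed tibbles", {
  tr <- simulate_ssa(birth_death_net(), lattice_disc(3), seed = 1,
                     max_events = 500, snapshot_every = 250)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), n_voxels(lattice_disc(3)))
  expect_true(all(c("x", "y", "species", "count") %in% names(td)))
  gl <- glance(tr)
  expect_equal(gl$events, 500)
  expect_equal(gl$H, sum(tr$state$counts))
})
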