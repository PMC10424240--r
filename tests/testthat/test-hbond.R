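test_that("collinear and right-angle geometries give cos(theta) -1 and 0", {
  acc <- c(0, 0, 0)
  # linear O_a...H-O_d arrangement along x
  w <- rbind(c(1.8 + 0.97, 0, 0), c(1.8, 0, 0), c(1.8 + 0.97 + 0.7, 0.67, 0))
  fr <- trajectory_frame(acc, list(w))
  g <- hbond_geometry(fr, 1)
  expect_equal(g$r_OH[1], 1.8)
  expect_equal(g$cos_theta[1], -1)
  # right angle at the hydrogen
  w2 <- rbind(c(1.8, 0.97, 0), c(1.8, 0, 0), c(1.8 + 0.9, 1.33, 0))
  g2 <- hbond_geometry(trajectory_frame(acc, list(w2)), 1)
  expect_equal(g2$cos_theta[1], 0)
})

test_that("overlapping atoms are rejected", {
  # first hydrogen sits 0.05 A from the acceptor oxygen
  w <- rbind(c(0.97, 0, 0), c(0.05, 0, 0), c(1.5, 0.7, 0))
  expect_error(hbond_geometry(trajectory_frame(c(0, 0, 0), list(w)), 1),
               "overlapping")
})

test_that("periodic geometry equals brute-force image enumeration", {
  set.seed(5)
  L <- 15.9581
  for (i in 1:50) {
    acc <- runif(3, 0, L)
    ow <- runif(3, 0, L)
    h1 <- ow + 0.97 * random_orientations(1)[1, ]
    h2 <- ow + 0.97 * random_orientations(1)[1, ]
    fr <- trajectory_frame(acc, list(rbind(ow, h1, h2)), box_length = L)
    g <- hbond_geometry(fr, 1)
    expect_equal(g$r_OH[1], image_min_dist(acc, h1, L), tolerance = 1e-10)
    expect_equal(g$r_OH[2], image_min_dist(acc, h2, L), tolerance = 1e-10)
  }
})

test_that("classifier agrees with the direct inequality everywhere", {
  set.seed(6)
  geom <- data.frame(r_OH = runif(1e4, 0.5, 4),
                     cos_theta = runif(1e4, -1, 1))
  expect_identical(is_hbonded(geom),
                   geom$r_OH < -1.71 * geom$cos_theta + 1.37)
  # the two boundary examples: linear at 1.8 A bonded, perpendicular not
  expect_true(is_hbonded(data.frame(r_OH = 1.8, cos_theta = -1)))
  expect_false(is_hbonded(data.frame(r_OH = 1.5, cos_theta = 0)))
})

test_that("a water bonded through both hydrogens counts once", {
  acc <- c(0, 0, 0)
  # symmetric geometry: both hydrogens 1.5 A from the acceptor
  half <- 104.5 / 2 * pi / 180
  od <- c(-1.883, 0, 0)
  h1 <- od + 0.97 * c(cos(half), sin(half), 0)
  h2 <- od + 0.97 * c(cos(half), -sin(half), 0)
  fr <- trajectory_frame(acc, list(rbind(od, h1, h2)))
  expect_true(all(is_hbonded(hbond_geometry(fr, 1))))
  expect_equal(count_hbonds(fr)$count, 1)
})

test_that("constructed frames are counted and partitioned correctly", {
  acc <- c(0, 0, 0)
  waters <- list(make_bonded_water(acc, direction = c(1, 0, 0)),
                 make_bonded_water(acc, direction = c(-1, 0.3, 0)),
                 make_free_water(acc, d = 3.0, direction = c(0, 1, 0)),
                 make_free_water(acc, d = 4.5, direction = c(0, -1, 0)),
                 make_free_water(acc, d = 6.0, direction = c(0, 0, 1)))
  fr <- trajectory_frame(acc, waters)
  cb <- count_hbonds(fr)
  expect_equal(cb$count, 2)
  expect_equal(cb$bonded, c(1L, 2L))
  # water 3 is in the first shell (3.0 < 3.3) but fails the angle criterion
  expect_equal(interstitial_waters(fr), 3L)
  expect_equal(interstitial_waters(fr, r_cut = 2.0), integer())
  expect_equal(count_hbonds(trajectory_frame(acc))$count, 0)
})

test_that("bonded and interstitial sets are disjoint on generated frames", {
  frames <- generate_trajectory(trajectory_spec(), n_frames = 30, seed = 8)
  for (fr in frames) {
    cb <- count_hbonds(fr)
    iw <- interstitial_waters(fr)
    expect_length(intersect(cb$bonded, iw), 0)
  }
})

test_that("classification is invariant under box translations", {
  fr <- generate_trajectory(trajectory_spec(), n_frames = 1, seed = 12)[[1]]
  L <- fr$box_length
  shifted <- trajectory_frame(fr$acceptor_O + c(L, -2 * L, 3 * L),
                              lapply(fr$waters, function(w) {
                                sweep(w, 2, c(-L, 2 * L, 0), `+`)
                              }), box_length = L)
  expect_equal(count_hbonds(shifted), count_hbonds(fr))
  expect_equal(interstitial_waters(shifted), interstitial_waters(fr))
})

test_that("population distribution behaves on degenerate trajectories", {
  acc <- c(0, 0, 0)
  f2 <- trajectory_frame(acc, list(make_bonded_water(acc, direction = c(1, 0, 0)),
                                   make_bonded_water(acc, direction = c(-1, 0, 0))))
  f0 <- trajectory_frame(acc, list(make_free_water(acc)))
  pd <- population_distribution(list(f2, f2, f2))
  expect_equal(pd$probability[pd$n_hbonds == 2], 1)
  pd2 <- population_distribution(list(f2, f0, f2, f0))
  expect_equal(pd2$probability[pd2$n_hbonds %in% c(0, 2)], c(0.5, 0.5))
  expect_equal(sum(pd2$probability), 1)
})

test_that("generator round trip recovers the target populations", {
  target <- c("1" = 0.10, "2" = 0.60, "3" = 0.30)
  n <- 400
  frames <- generate_trajectory(trajectory_spec(populations = target),
                                n_frames = n, seed = 99)
  pd <- population_distribution(frames)
  for (k in names(target)) {
    p_hat <- pd$probability[pd$n_hbonds == as.integer(k)]
    if (length(p_hat) == 0) p_hat <- 0
    # 99% binomial interval around the target proportion
    half <- qnorm(0.995) * sqrt(target[[k]] * (1 - target[[k]]) / n)
    expect_lt(abs(p_hat - target[[k]]), half + 1e-12)
  }
})

test_that("snapshot labeling transfers trajectory counts", {
  frames <- generate_trajectory(trajectory_spec(), n_frames = 10, seed = 4)
  sn <- generate_snapshots(ensemble_spec(), n = 10, seed = 4)
  sn$n_hbonds <- NULL
  lab <- label_snapshots(sn, frames)
  expect_equal(lab$n_hbonds,
               vapply(frames, function(f) count_hbonds(f)$count, integer(1)))
  expect_error(label_snapshots(sn, frames[1:3]), "differ in length")
})
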