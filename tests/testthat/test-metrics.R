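g <- tank_geometry()

test_that("scripted hops give exact speeds, path length and immobility", {
  # 10 mm hops at 1 s intervals, alternating between two points 10 times
  a <- c(5, 5, 5); b <- c(6, 5, 5)  # 1 cm = 10 mm apart
  wp <- do.call(rbind, rep(list(a, b), 10))
  tr <- make_scripted_trajectory(wp, frame_interval = 1, geometry = g)
  vel <- compute_velocity(tr)
  expect_equal(vel$speeds, rep(10, 19))
  expect_equal(distance_traveled(tr), 19 * 1)
  expect_equal(percent_immobile(vel, threshold = 1.5), 0)
  expect_equal(percent_immobile(vel, threshold = 11), 100)
})

test_that("stationary fish: zero speeds, one voxel, full immobility", {
  wp <- matrix(rep(c(3.2, 9.9, 0.4), 100), ncol = 3, byrow = TRUE)
  tr <- make_scripted_trajectory(wp, frame_interval = 1 / 30, geometry = g)
  vel <- compute_velocity(tr)
  expect_true(all(vel$speeds == 0))
  expect_equal(distance_traveled(tr), 0)
  expect_equal(percent_explored(tr), 0.1)   # 1 of 1000 voxels
  expect_equal(percent_immobile(vel), 100)
  expect_equal(max_velocity(vel), 0)
})

test_that("bottom and center distance match hand geometry", {
  # fixed at mid-height
  wp <- matrix(rep(c(7.5, 7.5, 7.5), 10), ncol = 3, byrow = TRUE)
  tr <- make_scripted_trajectory(wp, 1, g)
  expect_equal(mean_bottom_distance(tr), 7.5)
  expect_equal(mean_center_distance(tr), 0)
  # half frames at floor, half at surface
  wp <- rbind(matrix(rep(c(1, 1, 0), 5), ncol = 3, byrow = TRUE),
              matrix(rep(c(1, 1, 15), 5), ncol = 3, byrow = TRUE))
  tr <- make_scripted_trajectory(wp, 1, g)
  expect_equal(mean_bottom_distance(tr), 7.5)
  # horizontal corner: distance from the central axis is 7.5 * sqrt(2)
  wp <- matrix(rep(c(0, 0, 3), 10), ncol = 3, byrow = TRUE)
  tr <- make_scripted_trajectory(wp, 1, g)
  expect_equal(mean_center_distance(tr), 7.5 * sqrt(2))
  # 3D convention includes the vertical offset
  expect_equal(mean_center_distance(tr, use_3d = TRUE),
               sqrt(2 * 7.5^2 + 4.5^2))
})

test_that("percent explored counts distinct voxels exactly", {
  for (m in c(1, 250, 1000)) {
    wp <- voxel_center_waypoints(m)
    if (m == 1) wp <- rbind(wp, wp)  # constant path needs >= 2 frames
    tr <- make_scripted_trajectory(wp, 1, g)
    expect_equal(percent_explored(tr), m / 10)
  }
  # positions on the far boundary fold into the last cell, not out of range
  wp <- rbind(c(15, 15, 15), c(15, 15, 15))
  tr <- make_scripted_trajectory(wp, 1, g)
  expect_equal(percent_explored(tr), 0.1)
})

test_that("max velocity is the median of the top 5% of speeds", {
  v <- polscope:::as_velocity_series
  expect_equal(max_velocity(v(1:100)), 98)          # top {96..100}
  expect_equal(max_velocity(v(1:40)), 39.5)         # even subset midpoint
  expect_equal(max_velocity(v(rep(7, 50))), 7)      # constant speed
  expect_error(max_velocity(v(1:19)), ">= 20")
})

test_that("immobility threshold finds the valley of a bimodal speed mix", {
  set.seed(42)
  speeds <- c(rlnorm(3000, log(0.2), 0.45), rlnorm(3000, log(20), 0.45))
  thr <- detect_immobility_threshold(polscope:::as_velocity_series(speeds))
  expect_false(attr(thr, "defaulted"))
  expect_gt(as.numeric(thr), 0.6)
  expect_lt(as.numeric(thr), 5)
  # independent valley oracle: dense histogram scan between the modes
  h <- hist(log10(speeds), breaks = seq(min(log10(speeds)) - 0.01,
                                        max(log10(speeds)) + 0.01,
                                        length.out = 80), plot = FALSE)
  between <- h$mids > log10(0.2) & h$mids < log10(20)
  valley <- h$mids[between][which.min(h$counts[between])]
  expect_lt(abs(log10(as.numeric(thr)) - valley), log10(3))
})

test_that("unimodal or degenerate speeds fall back to the 1.5 mm/s default", {
  un <- polscope:::as_velocity_series(rlnorm(2000, log(5), 0.3))
  expect_warning(thr <- detect_immobility_threshold(un), "default")
  expect_equal(as.numeric(thr), 1.5)
  expect_true(attr(thr, "defaulted"))
  zero <- polscope:::as_velocity_series(rep(0, 100))
  expect_warning(thr0 <- detect_immobility_threshold(zero), "default")
  expect_equal(as.numeric(thr0), 1.5)
  const <- polscope:::as_velocity_series(rep(3, 100))
  expect_warning(thrc <- detect_immobility_threshold(const), "default")
  expect_equal(as.numeric(thrc), 1.5)
})

test_that("every metric equals its naive-loop oracle on random trajectories", {
  for (seed in 1:25) {
    tr <- random_trajectory(seed, n = 150)
    vel <- compute_velocity(tr)
    expect_equal(vel$speeds, oracle_velocity(tr), tolerance = 1e-12)
    expect_equal(distance_traveled(tr), oracle_distance(tr),
                 tolerance = 1e-12)
    expect_equal(mean_bottom_distance(tr), oracle_bottom(tr),
                 tolerance = 1e-12)
    expect_equal(mean_center_distance(tr), oracle_center(tr),
                 tolerance = 1e-12)
    expect_equal(percent_explored(tr), oracle_explored(tr))
    expect_equal(percent_immobile(vel), oracle_immobile(vel$speeds))
    expect_equal(max_velocity(vel), oracle_max_velocity(vel$speeds))
  }
})

test_that("percent explored never decreases when a trajectory is extended", {
  for (seed in 1:10) {
    tr <- random_trajectory(seed, n = 300)
    pe_full <- percent_explored(tr)
    sub <- trajectory3d(tr$times[1:150], tr$positions[1:150, 1],
                        tr$positions[1:150, 2], tr$positions[1:150, 3],
                        tr$geometry, tr$fish_id)
    expect_lte(percent_explored(sub), pe_full)
  }
})

test_that("path length is translation invariant and additive; bounds hold", {
  for (seed in 1:10) {
    tr <- random_trajectory(seed, n = 200)
    pos <- tr$positions
    # shrink toward the center so a rigid shift stays in-tank
    pos <- sweep(sweep(pos, 2, c(7.5, 7.5, 7.5), "-") * 0.5, 2,
                 c(6, 6, 6), "+")
    base <- trajectory3d(tr$times, pos[, 1], pos[, 2], pos[, 3],
                         tr$geometry)
    shifted <- trajectory3d(tr$times, pos[, 1] + 1, pos[, 2] - 1,
                            pos[, 3] + 1, tr$geometry)
    expect_equal(distance_traveled(base), distance_traveled(shifted),
                 tolerance = 1e-12)
    # additivity under concatenation at a shared endpoint
    n <- nrow(pos)
    first <- trajectory3d(tr$times[1:100], pos[1:100, 1], pos[1:100, 2],
                          pos[1:100, 3], tr$geometry)
    second <- trajectory3d(tr$times[100:n], pos[100:n, 1], pos[100:n, 2],
                           pos[100:n, 3], tr$geometry)
    expect_equal(distance_traveled(first) + distance_traveled(second),
                 distance_traveled(base), tolerance = 1e-12)
    # path length >= net displacement; max velocity within its bracket
    net <- sqrt(sum((pos[n, ] - pos[1, ])^2))
    expect_gte(distance_traveled(base), net - 1e-12)
    vel <- compute_velocity(base)
    mv <- max_velocity(vel)
    expect_lte(mv, max(vel$speeds))
    expect_gte(mv, unname(quantile(vel$speeds, 0.95)) - 1e-12)
  }
})

test_that("extract_profile bundles all six measures deterministically", {
  tr <- random_trajectory(3, n = 250)
  p1 <- extract_profile(tr)
  p2 <- extract_profile(tr)
  expect_identical(p1, p2)
  expect_named(p1, c("fish_id", "bottom_distance", "center_distance",
                     "distance_traveled", "percent_explored",
                     "percent_immobile", "max_velocity"))
  expect_equal(p1$distance_traveled, oracle_distance(tr),
               tolerance = 1e-12)
  # stationary fish with few frames: degenerate max_velocity flagged
  wp <- matrix(rep(c(2, 2, 2), 10), ncol = 3, byrow = TRUE)
  short <- make_scripted_trajectory(wp, 1, g)
  expect_warning(ps <- extract_profile(short), "max_velocity")
  expect_true(is.na(ps$max_velocity))
  expect_equal(ps$percent_immobile, 100)
  expect_equal(ps$percent_explored, 0.1)
  expect_equal(ps$distance_traveled, 0)
})
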