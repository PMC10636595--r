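geom <- arena_geometry()

test_that("speed: constants are preserved and smoothing spreads a step over ~100 ms", {
  fr <- 40
  # stationary trajectory
  tr0 <- trajectory(rep(0, 100), rep(30, 100))
  expect_equal(compute_speed(tr0), rep(0, 100))
  # constant velocity 20 cm/s straight down
  t <- seq(0, 2, by = 1 / fr)
  tr1 <- trajectory(rep(0, length(t)), 40 - 20 * t)
  v <- compute_speed(tr1)
  expect_equal(v[10:70], rep(20, 61), tolerance = 1e-6)
  # a step change is smeared with the Gaussian convolution oracle
  speeds <- c(rep(0, 60), rep(30, 60)) / fr
  y <- 40 - cumsum(speeds)
  tr2 <- trajectory(rep(0, 120), y)
  v2 <- compute_speed(tr2)
  half <- ceiling(3 * 4)
  k <- dnorm(seq(-half, half), sd = 4); k <- k / sum(k)
  raw <- c(abs(diff(y))[1], abs(diff(y))) * fr
  pad <- c(raw[half:1 + 1], raw, raw[length(raw) - (1:half)])
  oracle <- as.numeric(stats::filter(pad, k, sides = 2))[(half + 1):(half + 120)]
  expect_equal(v2, oracle, tolerance = 1e-9)
  expect_error(compute_speed(trajectory(0, 0)), "two frames")
})

test_that("body direction: north heading, rotation equivariance, average-based oracle", {
  n <- 20
  tr <- trajectory(rep(0, n), seq(0, 5, length.out = n))
  tr <- add_bodyparts(tr)
  h <- compute_body_direction(tr)
  expect_equal(h[5, ], c(0, 1), tolerance = 1e-9, ignore_attr = TRUE)
  # rigid rotation of all parts rotates the heading identically
  th <- pi / 5
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  bp <- attr(tr, "bodyparts")
  bp2 <- lapply(bp, function(m) t(Rm %*% t(m)))
  tr2 <- tr; attr(tr2, "bodyparts") <- bp2
  h2 <- compute_body_direction(tr2)
  expect_equal(h2[5, ], as.numeric(Rm %*% h[5, ]), tolerance = 1e-9)
  # noisy parts: matches a direct recomputation from the two printed averages
  set.seed(1)
  bp3 <- lapply(bp, function(m) m + matrix(rnorm(length(m), sd = 0.2), nrow(m)))
  tr3 <- tr; attr(tr3, "bodyparts") <- bp3
  h3 <- compute_body_direction(tr3)
  lower <- c("lower_left_limb", "lower_right_limb", "lower_back", "tail_base")
  upper <- c("upper_left_limb", "upper_right_limb", "upper_back")
  lo <- Reduce(`+`, bp3[lower]) / 4
  hi <- Reduce(`+`, bp3[upper]) / 3
  v <- hi[7, ] - lo[7, ]
  expect_equal(h3[7, ], v / sqrt(sum(v^2)), tolerance = 1e-12)
  expect_error(compute_body_direction(trajectory(1:3, 1:3)), "body part")
})

test_that("escape target score: endpoints, midpoint and mirror symmetry", {
  for (x0 in c(-10, 0, 8)) for (y0 in c(25, 35)) {
    p0 <- c(x0, y0)
    # aimed at the shelter -> 0
    expect_equal(escape_target_score(p0, geom$shelter, geom, "left"), 0)
    # aimed at the edge -> 1
    expect_equal(escape_target_score(p0, geom$edge_left, geom, "left"), 1)
    # halfway -> 0.5
    cross <- function(p) p0 + (p - p0) * (geom$score_line_y - p0[2]) / (p[2] - p0[2])
    mid <- (cross(geom$shelter) + cross(geom$edge_left)) / 2
    expect_equal(escape_target_score(p0, mid, geom, "left"), 0.5)
    # mirror symmetry: reflecting start and target across the axis preserves
    # the score with the opposite side
    p0m <- c(-x0, y0)
    expect_equal(escape_target_score(p0m, c(-mid[1], mid[2]), geom, "right"), 0.5)
  }
  expect_error(escape_target_score(c(0, 30), c(0, 35), geom, "left"), "descend")
})

test_that("score threshold classification is strict at 0.65", {
  expect_identical(classify_escape(0.66), "edge_vector")
  expect_identical(classify_escape(0.65), "homing_vector")
  expect_identical(classify_escape(0), "homing_vector")
})

test_that("escape initiation: shelter-ward 20 cm/s crossing, direction-sensitive", {
  fr <- 40
  t <- seq(0, 3, by = 1 / fr); n <- length(t)
  # immediate 30 cm/s run toward the shelter
  tr <- trajectory(rep(0, n), 30 - 30 * t)
  k <- detect_escape_initiation(tr, stimulus_time = 1, geom)
  expect_true(!is.na(k))
  expect_lte(abs(tr$t[k] - 1), 0.15)
  # fast run away from the shelter is not detected
  tr2 <- trajectory(rep(0, n), 10 + 30 * t)
  expect_true(is.na(detect_escape_initiation(tr2, 1, geom)))
  # ramped speed: detection matches the analytic crossing of 20 cm/s
  v <- pmin(40, pmax(0, (t - 1) * 40))     # reaches 20 cm/s at t = 1.5
  y <- 30 - cumsum(v) / fr
  tr3 <- trajectory(rep(0, n), y)
  k3 <- detect_escape_initiation(tr3, 0.5, geom)
  expect_lt(abs(tr3$t[k3] - 1.5), 0.15)
})

test_that("spatial efficiency: straight = 1, semicircle = 2/pi, always <= 1", {
  expect_equal(spatial_efficiency(c(0, 1, 2, 3), c(0, 0, 0, 0)), 1)
  th <- seq(0, pi, length.out = 400)
  expect_equal(spatial_efficiency(10 * cos(th), 10 * sin(th)), 2 / pi,
               tolerance = 1e-4)
  set.seed(2)
  for (i in 1:10) {
    x <- cumsum(rnorm(30)); y <- cumsum(rnorm(30))
    expect_lte(spatial_efficiency(x, y), 1)
  }
  expect_error(spatial_efficiency(c(1, 1), c(2, 2)), "zero path")
})

test_that("homing-run extraction: empty sessions, single dashes, sub-second rejections", {
  fr <- 40
  # stationary session: nothing
  tr0 <- trajectory(rep(5, 400), rep(30, 400))
  expect_identical(nrow(extract_homing_runs(tr0, geom)), 0L)
  # one 40 cm/s dash from the threat zone to the shelter amid stillness
  still1 <- cbind(rep(0, 200), rep(30, 200))
  n_dash <- ceiling(sqrt(sum((c(0, 30) - geom$shelter)^2)) / 40 * fr)
  dash <- cbind(seq(0, geom$shelter[1], length.out = n_dash),
                seq(30, geom$shelter[2], length.out = n_dash))
  still2 <- cbind(rep(geom$shelter[1], 200), rep(geom$shelter[2], 200))
  pos <- rbind(still1, dash, still2)
  tr1 <- trajectory(pos[, 1], pos[, 2])
  runs <- extract_homing_runs(tr1, geom)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$destination, "shelter")
  expect_false(runs$is_edge_vector)
  expect_gte(runs$duration, 1)
  # a 0.8-second dash is rejected (duration criterion)
  n08 <- round(0.8 * fr)
  dash8 <- cbind(rep(0, n08), seq(30, 30 - 0.8 * 40, length.out = n08))
  pos8 <- rbind(still1, dash8,
                cbind(rep(0, 200), rep(30 - 0.8 * 40, 200)))
  tr8 <- trajectory(pos8[, 1], pos8[, 2])
  runs8 <- extract_homing_runs(tr8, geom)
  expect_true(all(runs8$duration >= 1))
  expect_identical(nrow(runs8), 0L)
})

test_that("edge-vector runs are detected by inclusive rectangle containment", {
  fr <- 40
  mk <- function(via_x, via_y) {
    still <- cbind(rep(-5, 200), rep(30, 200))
    leg1 <- cbind(seq(-5, via_x, length.out = 40), seq(30, via_y, length.out = 40))
    leg2 <- cbind(seq(via_x, geom$shelter[1], length.out = 45),
                  seq(via_y, geom$shelter[2], length.out = 45))
    pos <- rbind(still, leg1, leg2, cbind(rep(0, 100), rep(geom$shelter[2], 100)))
    trajectory(pos[, 1], pos[, 2])
  }
  # through the rectangle center: edge-vector run
  rc <- geom$edge_rect_left
  runs <- extract_homing_runs(mk(mean(rc[c("xmin", "xmax")]), 0), geom)
  expect_identical(nrow(runs), 1L)
  expect_true(runs$is_edge_vector)
  # straight to the shelter, missing the rectangles
  runs2 <- extract_homing_runs(mk(0, 10), geom)
  expect_identical(nrow(runs2), 1L)
  expect_false(runs2$is_edge_vector)
  # grazing the rectangle boundary counts (inclusive containment)
  runs3 <- extract_homing_runs(mk(unname(rc["xmax"]), unname(rc["ymax"])), geom)
  expect_identical(nrow(runs3), 1L)
  expect_true(runs3$is_edge_vector)
})

test_that("escape side at the platform-center crossing, ties to the left", {
  y <- seq(30, -30, length.out = 50)
  expect_identical(escape_side(rep(-10, 50), y), "left")
  expect_identical(escape_side(rep(10, 50), y), "right")
  # mirror image swaps sides
  x <- seq(5, 15, length.out = 50)
  expect_identical(escape_side(x, y), "right")
  expect_identical(escape_side(-x, y), "left")
  # exactly on the axis: left by convention
  expect_identical(escape_side(rep(0, 50), y), "left")
  expect_error(escape_side(rep(0, 10), seq(30, 10, length.out = 10)), "never crosses")
})

test_that("trajectory CSV and geometry JSON round-trip", {
  tr <- add_bodyparts(trajectory(cumsum(rnorm(50)), cumsum(rnorm(50)) + 20))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  tr2 <- read_trajectory_csv(path)
  expect_equal(tr2$x, tr$x)
  expect_equal(tr2$y, tr$y)
  expect_equal(attr(tr2, "bodyparts")$snout, attr(tr, "bodyparts")$snout,
               ignore_attr = TRUE)
  gpath <- tempfile(fileext = ".json")
  write_geometry_json(geom, gpath)
  g2 <- read_geometry_json(gpath)
  expect_equal(g2$radius, geom$radius)
  expect_equal(unlist(g2$edge_rect_left), unlist(geom$edge_rect_left),
               ignore_attr = TRUE)
})

test_that("pose-export dialect: header rows, likelihood cutoff, median filter", {
  n <- 60
  x <- seq(0, 10, length.out = n); y <- rep(25, n)
  lik <- rep(0.99, n); lik[30] <- 0.1           # one low-confidence point
  xs <- x; xs[30] <- 400                        # a wild outlier to be dropped
  path <- tempfile(fileext = ".csv")
  hdr1 <- c("scorer", rep("model", 6))
  hdr2 <- c("bodyparts", rep(c("snout", "tail_base"), each = 3))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), 2))
  body <- cbind(seq_len(n) - 1, xs, y, lik, x - 2, y, rep(0.99, n))
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), path)
  utils::write.table(body, path, sep = ",", append = TRUE, col.names = FALSE,
                     row.names = FALSE)
  tr <- read_pose_csv(path, likelihood_cutoff = 0.9, median_width = 7)
  bp <- attr(tr, "bodyparts")
  expect_identical(names(bp), c("snout", "tail_base"))
  # the outlier was removed by the cutoff + interpolation + median filter
  expect_lt(max(abs(bp$snout[, 1] - x)), 1)
})

test_that("extraction is invariant to time translation and idempotent on planted sessions", {
  ss <- generate_session(session_spec(seed = 12, n_homing = 1, n_edge_left = 1,
                                      n_edge_right = 0, duration_s = 120))
  runs1 <- extract_homing_runs(ss$traj, geom)
  tr_shift <- trajectory(ss$traj$x, ss$traj$y, t = ss$traj$t + 100)
  runs2 <- extract_homing_runs(tr_shift, geom)
  expect_identical(runs1$start_frame, runs2$start_frame)
  expect_identical(runs1$is_edge_vector, runs2$is_edge_vector)
  runs3 <- extract_homing_runs(ss$traj, geom)
  expect_identical(runs1, runs3)
})
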