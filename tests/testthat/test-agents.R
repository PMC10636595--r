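hp0 <- default_hyperparameters("q")

test_that("Q-learning update follows decay, increment, TD order", {
  Q <- matrix(0, 10, 8); e <- matrix(0, 10, 8)
  # zero trace, zero table, r = 0: nothing changes
  u <- q_update(Q, e, 3, 2, 0, 4, hp0)
  expect_equal(sum(abs(u$Q)), 0)
  # shelter entry from a zeroed table: Q(s,a) = alpha * r = 10
  u <- q_update(Q, e, 3, 2, 100, 4, hp0)
  expect_equal(u$Q[3, 2], 10)
  expect_equal(sum(abs(u$Q)) - abs(u$Q[3, 2]), 0)
  # two consecutive updates: the first pair's trace weight is lambda*gamma
  u2 <- q_update(u$Q, u$e, 4, 1, 0, 5, hp0)
  expect_equal(u2$e[3, 2], 0.5 * 0.9)
  # and the first pair moved by alpha * delta * (lambda*gamma)
  delta <- 0 + 0.9 * max(u$Q[5, ]) - u$Q[4, 1]
  expect_equal(u2$Q[3, 2], u$Q[3, 2] + 0.1 * delta * 0.45)
})

test_that("SARSA coincides with Q-learning under the greedy action and is below it otherwise", {
  set.seed(11)
  Q <- matrix(rnorm(80), 10, 8); e <- matrix(0, 10, 8)
  a_greedy <- which.max(Q[5, ])
  uq <- q_update(Q, e, 2, 1, -1, 5, hp0)
  us <- sarsa_update(Q, e, 2, 1, -1, 5, a_greedy, hp0)
  expect_equal(us$Q, uq$Q)
  # any other next action gives a target no larger than the max target
  for (a2 in seq_len(8)[-a_greedy]) {
    us2 <- sarsa_update(Q, e, 2, 1, -1, 5, a2, hp0)
    expect_lte(us2$Q[2, 1], uq$Q[2, 1])
  }
})

test_that("one hand-worked SARSA update on a 3-state chain matches brute force", {
  # states 1-2-3, 2 actions; transition (s=1, a=1, r=2, s'=2, a'=2)
  Q <- matrix(c(0.5, -0.2, 0.1, 0.3, 0, 0), 3, 2, byrow = TRUE)
  e <- matrix(0, 3, 2); e[3, 1] <- 0.4   # a pre-existing trace entry
  hp <- list(gamma = 0.99, lambda = 0.5, alpha = 0.1)
  u <- sarsa_update(Q, e, 1, 1, 2, 2, 2, hp)
  # brute force
  e2 <- 0.5 * 0.99 * e; e2[1, 1] <- e2[1, 1] + 1
  delta <- 2 + 0.99 * Q[2, 2] - Q[1, 1]
  expect_equal(u$Q, Q + 0.1 * delta * e2)
  expect_equal(u$e, e2)
})

test_that("blocked attempts are updated but dropped from the trace", {
  Q <- matrix(0, 4, 8); e <- matrix(0, 4, 8)
  u <- q_update(Q, e, 2, 3, -1, 2, hp0, blocked = TRUE)
  expect_equal(u$Q[2, 3], 0.1 * -1)
  expect_equal(u$e[2, 3], 0)
})

test_that("SR update writes the one-hot occupancy and bootstraps the realized next row", {
  n_s <- 5; n_a <- 8
  M <- matrix(0, n_s * n_a, n_s); Rv <- numeric(n_s); e <- numeric(n_s * n_a)
  hp <- default_hyperparameters("sr")
  u <- sr_update(M, Rv, e, 2, 3, 4, 0, hp, a2 = 1)
  sa <- (2 - 1) * n_a + 3
  expect_equal(u$M[sa, 4], 0.1)
  expect_equal(sum(abs(u$M)) - abs(u$M[sa, 4]), 0)
  # reward-vector update lands at the successor state: R(shelter) = 10
  u2 <- sr_update(M, Rv, e, 2, 3, 4, 100, hp, a2 = 1)
  expect_equal(u2$Rv[4], 10)
  expect_equal(sum(u2$Rv[-4]), 0)
})

test_that("fixed-policy SR converges to the closed-form successor matrix", {
  # 4-state cycle, one action per state under the fixed policy
  n_s <- 4; n_a <- 2
  P <- matrix(0, n_s, n_s)
  nxt <- c(2, 3, 4, 1)
  for (s in 1:n_s) P[s, nxt[s]] <- 1
  gam <- 0.9
  closed <- solve(diag(n_s) - gam * P)   # state-level successor under pi
  hp <- list(gamma = gam, lambda = 0, alpha = 0.2)
  M <- matrix(0, n_s * n_a, n_s); Rv <- numeric(n_s); e <- numeric(n_s * n_a)
  s <- 1
  for (t in 1:4000) {
    s2 <- nxt[s]
    u <- sr_update(M, Rv, e, s, 1, s2, 0, hp, a2 = 1, n_actions = n_a)
    M <- u$M; Rv <- u$Rv; e <- numeric(n_s * n_a)  # lambda = 0
    s <- s2
  }
  # fixed point of M = P + gamma * P M  =>  M = P (I - gamma P)^{-1}
  analytic <- P %*% closed
  for (s in 1:n_s) {
    expect_equal(M[(s - 1) * n_a + 1, ], analytic[s, ],
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("sr_value is the full dot product and reduces to the one-hot case", {
  n_s <- 6; n_a <- 8
  set.seed(3)
  M <- matrix(rnorm(n_s * n_a * n_s), n_s * n_a, n_s)
  Rv <- rnorm(n_s)
  expect_equal(sr_value(M, Rv, 4, 2), sum(M[(4 - 1) * 8 + 2, ] * Rv))
  expect_equal(sr_value(M, numeric(n_s), 4, 2), 0)
  M1 <- matrix(0, n_s * n_a, n_s); M1[(4 - 1) * 8 + 2, 5] <- 1
  Rv1 <- numeric(n_s); Rv1[5] <- 100
  expect_equal(sr_value(M1, Rv1, 4, 2), 100)
})

test_that("tile coding covers every cell, values are exact weight sums, and tiles generalize", {
  acc <- build_condition_map(1, "training")$accessible
  for (cell in which(acc)) {
    f <- tile_features(cell)
    expect_gte(sum(f <= 144), 1)   # at least one 2x2 tile
    expect_gte(sum(f > 144), 1)    # at least one 3x3 tile
  }
  set.seed(5)
  w <- matrix(rnorm(265 * 8), 265, 8)
  cell <- cell_id(6, 6)
  expect_equal(tile_q_value(w, cell, 3), sum(w[tile_features(cell), 3]))
  # shelter-entry update from zero weights: each active weight gets an equal
  # share of alpha * r
  w0 <- matrix(0, 265, 8)
  w1 <- tile_q_update(w0, cell, 2, 100, cell_id(6, 7), hp0)
  f <- tile_features(cell)
  expect_equal(unname(w1[f, 2]), rep(0.1 * 100 / length(f), length(f)))
  expect_equal(sum(abs(w1)), sum(abs(w1[f, 2])))
  # two cells sharing a 3x3 tile generalize
  other <- cell_id(7, 6)
  expect_gt(tile_q_value(w1, other, 2), 0)
})

test_that("graph model: observation, deletion and majority-vote edges", {
  g <- graph_model("immediate")
  g <- mb_observe(g, cell_id(5, 5), cell_id(6, 5), blocked = FALSE)
  expect_true(cell_id(6, 5) %in% g$nodes)
  p <- mb_plan(g, cell_id(5, 5), cell_id(6, 5))
  expect_equal(p$cost, 1)
  # a blocked attempt deletes the edge
  g <- mb_observe(g, cell_id(5, 5), cell_id(6, 5), blocked = TRUE)
  expect_null(mb_plan(g, cell_id(5, 5), cell_id(6, 5)))
  # gradual: 8 open vs 7 blocked observations keep the edge usable
  gg <- graph_model("gradual", n = 15)
  for (i in 1:8) gg <- mb_observe(gg, 1, 2, blocked = FALSE)
  for (i in 1:7) gg <- mb_observe(gg, 1, 2, blocked = TRUE)
  expect_false(is.null(mb_plan(gg, 1, 2)))
  # one more blocked observation tips the majority
  gg <- mb_observe(gg, 1, 2, blocked = TRUE)
  gg <- mb_observe(gg, 1, 2, blocked = TRUE)
  expect_null(mb_plan(gg, 1, 2))
})

test_that("planner returns shortest routes: corners of an open 3x3 block", {
  g <- graph_model("immediate")
  cells <- as.vector(outer(4:6, 4:6, function(c, r) cell_id(c, r)))
  acts <- action_set()
  for (s in cells) for (a in 1:8) {
    cr <- cell_colrow(s)
    t2 <- cell_id(cr[1, "col"] + acts$dx[a], cr[1, "row"] + acts$dy[a])
    if (t2 %in% cells) g <- mb_observe(g, s, t2, blocked = FALSE)
  }
  expect_equal(mb_plan(g, cell_id(4, 4), cell_id(4, 4))$cost, 0)
  p <- mb_plan(g, cell_id(4, 4), cell_id(6, 6))
  expect_equal(p$cost, 2 * sqrt(2))
})

test_that("plan cost equals the igraph shortest-path cost on random graphs", {
  skip_if_not_installed("igraph")
  acts <- action_set()
  set.seed(21)
  for (rep in 1:5) {
    cells <- sample(which(build_condition_map(1, "training")$accessible), 30)
    g <- graph_model("immediate")
    edges <- NULL
    for (s in cells) for (a in 1:8) {
      cr <- cell_colrow(s)
      tc <- cr[1, "col"] + acts$dx[a]; tr <- cr[1, "row"] + acts$dy[a]
      if (tc < 0 || tc > 12 || tr < 0 || tr > 12) next
      t2 <- cell_id(tc, tr)
      if (t2 %in% cells && runif(1) < 0.8) {
        g <- mb_observe(g, s, t2, blocked = FALSE)
        edges <- rbind(edges, c(s, t2, acts$length[a]))
      }
    }
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2]),
                 weight = edges[, 3]), directed = FALSE)
    from <- cells[1]; to <- cells[15]
    p <- mb_plan(g, from, to)
    vn <- igraph::V(ig)$name
    d <- if (all(as.character(c(from, to)) %in% vn))
      igraph::distances(ig, as.character(from), as.character(to))[1, 1]
    else Inf
    if (is.null(p)) expect_true(is.infinite(d))
    else expect_equal(p$cost, unname(d))
  }
})

test_that("region updates fire only at boundary crossings, with centroid-distance penalties", {
  p <- region_partition()
  hp <- default_hyperparameters("hss_q")
  Q <- numeric(40); e <- numeric(40)
  # within-region movement: no defined action, no update
  expect_null(hss_update(Q, e, p, 1, 1, hp = hp))
  # a defined crossing applies exactly one update with the centroid penalty
  k <- 1
  fr <- p$actions[k, "from"]; to <- p$actions[k, "to"]
  u <- hss_update(Q, e, p, fr, to, accum = 0, hp = hp)
  d <- sqrt(sum((p$centroids[fr, ] - p$centroids[to, ])^2))
  expect_equal(u$reward, -hp$step_scale * d)
  expect_equal(sum(u$e > 0), 1L)
  # hand-check a centroid distance: threat (6, 2.24...) to above_center
  i_th <- match("threat", p$names); i_ac <- match("above_center", p$names)
  d2 <- sqrt(sum((p$centroids[i_th, ] - p$centroids[i_ac, ])^2))
  expect_equal(d2, sqrt((p$centroids[i_th, 1] - p$centroids[i_ac, 1])^2 +
                        (p$centroids[i_th, 2] - p$centroids[i_ac, 2])^2))
  # terminal macro step: accumulated bonus, zero bootstrap
  u2 <- hss_update(Q, e, p, fr, to, accum = 100, hp = hp, terminal = TRUE)
  gam_eff <- hp$gamma^d
  expect_equal(u2$Q[1], hp$alpha * (100 - hp$step_scale * d))
})

test_that("region-level execution rasterizes straight lines and halts at blocks", {
  m_te <- build_condition_map(1, "test")
  m_tr <- build_condition_map(1, "training")
  p <- m_te$regions
  i_le <- match("left_edge", p$names)
  # already at the anchor: nothing to execute
  out0 <- hss_execute(m_te, p$anchors[i_le], i_le)
  expect_identical(out0$path, p$anchors[i_le])
  # axis-aligned move: straight south through repeated cardinal steps
  i_sh <- match("shelter", p$names)
  out1 <- hss_execute(m_te, cell_id(6, 7), i_sh)
  cr <- cell_colrow(out1$path)
  expect_true(all(cr[, "col"] == 6))
  expect_false(out1$halted)
  # diagonal displacement matches the package rasterizer
  out2 <- hss_execute(m_te, m_te$threat, i_le)
  expect_identical(out2$path, rasterize_line(m_te$threat, p$anchors[i_le]))
  # the obstacle halts execution on the training map
  out3 <- hss_execute(m_tr, cell_id(6, 5), i_sh)
  expect_true(out3$halted)
  expect_true(all(cell_colrow(out3$path)[, "row"] <= 5))
})

test_that("dual-system selection: strict threshold, fallback, no-plan result", {
  Q <- matrix(-1, 5, 8)
  fallback <- function(s) 7L
  expect_identical(dual_system_select(Q, 2, 0, fallback), 7L)
  Q[2, 4] <- 0.5
  expect_identical(dual_system_select(Q, 2, 0, fallback), 4L)
  # threshold exactly equal to the max value: strict inequality, fallback
  expect_identical(dual_system_select(Q, 2, 0.5, fallback), 7L)
  none <- function(s) NA_integer_
  Q2 <- matrix(-1, 5, 8)
  expect_true(is.na(dual_system_select(Q2, 2, 0, none)))
})

test_that("trace decay property: an untouched pair decays by (lambda*gamma)^k", {
  Q <- matrix(0, 6, 8); e <- matrix(0, 6, 8)
  u <- q_update(Q, e, 1, 1, 0, 2, hp0)
  w0 <- u$e[1, 1]
  for (k in 1:5) {
    u <- q_update(u$Q, u$e, 2, 2, 0, 3, hp0)
    expect_equal(u$e[1, 1], w0 * (0.5 * 0.9)^k * (0.5 * 0.9)^0, tolerance = 1e-12)
    w0 <- w0  # decays once per update
    expect_equal(u$e[1, 1], (0.5 * 0.9)^k, tolerance = 1e-12)
  }
})
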