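# Agent families: update and action-selection rules. The functions here are
# the reference implementations of each learning rule, operating on plain R
# matrices; the compiled protocol driver (src/rl_core.cpp) applies the same
# rules in its hot loop, and the two are held together by replay tests.

ALGORITHMS <- c(q = 1L, sarsa = 2L, sr = 3L, tile = 4L, mb_i = 5L, mb_g = 6L,
                hss_q = 7L, hss_sarsa = 8L, dual = 9L)

#' Default hyperparameters per algorithm
#'
#' Values follow the published configuration: tabular Q-learning gamma 0.9,
#' lambda 0.5, alpha 0.1, step-penalty scale 0.01; SR gamma 0.9, lambda 0.5,
#' alpha 0.1 (no step penalty: with one, the reward vector would be non-zero
#' everywhere and the value could not reduce to the single-reward form
#' M(S,A,shelter)R(shelter)); SARSA gamma 0.99, lambda 0.5, alpha 0.1,
#' step-penalty scale 0.001; tile sizes 2x2 and 3x3; gradual model-based
#' buffer window N = 15. Q tables are initialized from N(0, var 0.1); the SR
#' tensor from small zero-mean noise (sd 0.01 -- see the methods vignette for
#' why a large init variance is incompatible with the published budgets); SR
#' reward vectors at zero.
#'
#' @param algorithm One of "q", "sarsa", "sr", "tile", "mb_i", "mb_g",
#'   "hss_q", "hss_sarsa", "dual".
#' @param ... Overrides of individual fields.
#' @return A list of hyperparameters.
#' @export
default_hyperparameters <- function(algorithm = "q", ...) {
  algorithm <- match.arg(algorithm, names(ALGORITHMS))
  hp <- list(
    gamma = 0.9, lambda = 0.5, alpha = 0.1, step_scale = 0.01,
    # the dual-system threshold must sit above the value-table initialization
    # noise (sd ~0.32) and below any genuinely learned value; 1 is ~3 init
    # standard deviations and 1% of the shelter reward
    init_sd_q = sqrt(0.1), init_sd_m = 0.01, dual_threshold = 1,
    trace_cutoff = 1e-8, buffer_n = 15L, sr_onpolicy = TRUE
  )
  if (algorithm == "sarsa") { hp$gamma <- 0.99; hp$step_scale <- 0.001 }
  # The SR configuration carries no per-step penalty: with one the reward
  # vector would be non-zero everywhere and the value could not reduce to
  # M(S,A,shelter)R(shelter), the stated single-reward form.
  if (algorithm == "sr") hp$step_scale <- 0
  over <- list(...)
  hp[names(over)] <- over
  hp
}

#' Published training-step budgets
#'
#' The calibrated number of training steps per algorithm and exploration
#' regime (random walk with or without practice runs), as published.
#'
#' @param algorithm Algorithm name.
#' @param practice Logical; practice runs interleaved with the random walk.
#' @return Integer step count (NA if the combination was not calibrated).
#' @export
default_training_steps <- function(algorithm, practice = TRUE) {
  key <- paste0(match.arg(algorithm, names(ALGORITHMS)), if (practice) "_p" else "_r")
  tab <- c(q_r = 45000, q_p = 30000, hss_q_r = 2500, hss_q_p = 1500,
           tile_r = 285000, sr_r = 125000, sr_p = 20000,
           mb_i_p = 3000, mb_g_p = 3000, sarsa_p = 35000, hss_sarsa_p = 2000,
           # uncalibrated combinations fall back to the nearest published one
           mb_i_r = 3000, mb_g_r = 3000, sarsa_r = 45000, tile_p = 285000,
           hss_sarsa_r = 2500, dual_p = 30000, dual_r = 45000)
  as.integer(unname(tab[key]))
}

# --- tabular Q-learning / SARSA --------------------------------------------

#' One Q-learning update with an accumulating eligibility trace
#'
#' Applies, in order: trace decay `e <- lambda*gamma*e`; trace increment
#' `e(s,a) <- e(s,a) + 1`; TD update
#' `Q <- Q + alpha * (r + gamma * max_a Q(s', a) - Q(s, a)) * e`
#' across all traced pairs.
#'
#' @param Q n_states x n_actions value matrix.
#' @param e Eligibility trace, same shape.
#' @param s,a,r,s2 Transition: state, action, reward, next state.
#' @param hp Hyperparameters (`gamma`, `lambda`, `alpha`).
#' @param terminal Transition enters the absorbing shelter state (bootstrap
#'   is zero; the caller clears the trace afterwards).
#' @param blocked The attempt was blocked: the pair is updated once but does
#'   not stay in the trace (a non-move is not credited with later progress).
#' @return list(Q, e) updated.
#' @export
q_update <- function(Q, e, s, a, r, s2, hp, terminal = FALSE, blocked = FALSE) {
  boot <- if (terminal) 0 else max(Q[s2, ])
  e <- hp$lambda * hp$gamma * e
  if (!is.null(hp$trace_cutoff)) e[e < hp$trace_cutoff] <- 0
  e[s, a] <- e[s, a] + 1
  delta <- r + hp$gamma * boot - Q[s, a]
  Q <- Q + hp$alpha * delta * e
  if (blocked) e[s, a] <- 0
  list(Q = Q, e = e)
}

#' One SARSA update (on-policy bootstrap)
#'
#' Identical to [q_update()] except the bootstrap term uses the action
#' actually taken next.
#'
#' @inheritParams q_update
#' @param a2 The next action taken (required unless the transition is
#'   terminal, or NA at an episode truncation, where the expectation under
#'   the uniform random policy closes the pending step).
#' @return list(Q, e).
#' @export
sarsa_update <- function(Q, e, s, a, r, s2, a2, hp, terminal = FALSE,
                         blocked = FALSE) {
  if (terminal) boot <- 0
  else if (is.null(a2) || is.na(a2)) boot <- mean(Q[s2, ])
  else boot <- Q[s2, a2]
  e <- hp$lambda * hp$gamma * e
  if (!is.null(hp$trace_cutoff)) e[e < hp$trace_cutoff] <- 0
  e[s, a] <- e[s, a] + 1
  delta <- r + hp$gamma * boot - Q[s, a]
  Q <- Q + hp$alpha * delta * e
  if (blocked) e[s, a] <- 0
  list(Q = Q, e = e)
}

# --- successor representation ----------------------------------------------

#' One successor-representation update with an eligibility trace
#'
#' Moves every traced row of M toward the one-hot successor indicator plus
#' the discounted expected next row:
#' `M(s,a,:) <- M(s,a,:) + alpha * (1_{s'} + gamma * E_a M(s',a,:) - M(s,a,:)) * e`.
#' On policy, the expectation E_a is sampled by the action actually taken at
#' the successor state (`a2`); with `a2 = NULL` it is the uniform average over
#' the actions (the expectation under the random exploration policy, also
#' used to close a pending step at an episode truncation). The reward vector
#' is updated at the state where the reward is received:
#' `R(s') <- R(s') + alpha * (r - R(s'))`.
#'
#' @param M (n_states*n_actions) x n_states successor matrix; row index
#'   `(s-1)*n_actions + a`.
#' @param Rv Reward vector, length n_states.
#' @param e Trace over state-action rows.
#' @param s,a,s2,r Transition.
#' @param hp Hyperparameters.
#' @param n_actions Number of actions (8 on the arena).
#' @return list(M, Rv, e).
#' @export
sr_update <- function(M, Rv, e, s, a, s2, r, hp, a2 = NULL, terminal = FALSE,
                      blocked = FALSE, n_actions = 8) {
  if (terminal) {
    exp_row <- 0
  } else if (!is.null(a2) && !is.na(a2)) {
    exp_row <- M[(s2 - 1) * n_actions + a2, ]
  } else {
    rows2 <- (s2 - 1) * n_actions + seq_len(n_actions)
    exp_row <- colMeans(M[rows2, , drop = FALSE])
  }
  onehot <- numeric(ncol(M)); onehot[s2] <- 1
  sa <- (s - 1) * n_actions + a
  delta <- onehot + hp$gamma * exp_row - M[sa, ]
  e <- hp$lambda * hp$gamma * e
  if (!is.null(hp$trace_cutoff)) e[e < hp$trace_cutoff] <- 0
  e[sa] <- e[sa] + 1
  traced <- which(e > 0)
  M[traced, ] <- M[traced, , drop = FALSE] + hp$alpha * outer(e[traced], delta)
  if (blocked) e[sa] <- 0
  Rv[s2] <- Rv[s2] + hp$alpha * (r - Rv[s2])
  list(M = M, Rv = Rv, e = e)
}

#' State-action value under the successor representation
#'
#' `Q(s,a) = sum_x M(s,a,x) R(x)`, reducing to `M(s,a,shelter) R(shelter)`
#' when the shelter is the only rewarded state.
#'
#' @inheritParams sr_update
#' @return Scalar value.
#' @export
sr_value <- function(M, Rv, s, a, n_actions = 8) {
  sum(M[(s - 1) * n_actions + a, ] * Rv)
}

# --- tile coding ------------------------------------------------------------

#' Active tile features of a cell
#'
#' Overlapping rectangular receptive fields of size 2x2 (on a 12x12 lattice of
#' placements) and 3x3 (11x11), shifted by 1 in both coordinates; a feature is
#' active iff the cell lies inside the tile. Feature ids are 1-based; 2x2
#' tiles occupy 1..144, 3x3 tiles 145..265.
#'
#' @param cell Cell id (1-based).
#' @return Integer vector of active tile ids.
#' @export
tile_features <- function(cell) {
  cr <- cell_colrow(cell)
  c0 <- cr[1, "col"]; r0 <- cr[1, "row"]
  f <- integer(0)
  for (tx in max(0, c0 - 1):min(11, c0))
    for (ty in max(0, r0 - 1):min(11, r0)) f <- c(f, ty * 12 + tx + 1L)
  for (tx in max(0, c0 - 2):min(10, c0))
    for (ty in max(0, r0 - 2):min(10, r0)) f <- c(f, 144L + ty * 11 + tx + 1L)
  f
}

#' Tile-coded approximate value and its SGD update
#'
#' `Qhat(s,a) = sum of weights of active (tile, action) features`; the update
#' distributes `alpha * (r + gamma * max_a' Qhat(s',a') - Qhat(s,a))` across
#' the active weights (binary features; the step size is divided by the
#' number of active tiles so that overlapping tilings do not overshoot).
#'
#' @param w 265 x n_actions weight matrix.
#' @param s,a,r,s2 Transition (cell ids and action).
#' @param hp Hyperparameters.
#' @return `tile_q_update`: updated `w`. `tile_q_value`: scalar Qhat.
#' @export
tile_q_update <- function(w, s, a, r, s2, hp) {
  boot <- max(vapply(seq_len(ncol(w)), function(b) tile_q_value(w, s2, b), 0))
  delta <- r + hp$gamma * boot - tile_q_value(w, s, a)
  f <- tile_features(s)
  # the learning rate is shared across the active overlapping tiles
  w[f, a] <- w[f, a] + hp$alpha / length(f) * delta
  w
}

#' @rdname tile_q_update
#' @export
tile_q_value <- function(w, s, a) sum(w[tile_features(s), a])

# --- model-based graph agent ------------------------------------------------

#' Create an empty graph model
#'
#' @param mode `"immediate"` (plans with the latest observation per edge) or
#'   `"gradual"` (majority vote over a buffer of up to `n` observations per
#'   edge; node rewards are the buffer average).
#' @param n Buffer capacity.
#' @return A `graph_model` list.
#' @export
graph_model <- function(mode = c("immediate", "gradual"), n = 15) {
  mode <- match.arg(mode)
  structure(list(mode = mode, n = n, nodes = integer(0),
                 edges = list(), rewards = list()), class = "graph_model")
}

.edge_key <- function(s, t) paste(min(s, t), max(s, t))

#' Record one transition attempt in the graph model
#'
#' Success adds both endpoints as nodes and the undirected edge (an open
#' observation in gradual mode); a blocked attempt deletes the edge
#' (immediate) or appends a blocked observation (gradual). The arrival
#' reward labels the destination node (immediate) or is appended to its
#' reward buffer (gradual).
#'
#' @param g A `graph_model`.
#' @param s,t Source and intended target cell.
#' @param blocked Whether the attempt was blocked.
#' @param reward Arrival reward bonus (100 on shelter entry, else 0).
#' @return Updated `graph_model`.
#' @export
mb_observe <- function(g, s, t, blocked, reward = 0) {
  g$nodes <- union(g$nodes, s)
  key <- .edge_key(s, t)
  obs <- if (blocked) 0L else 1L
  if (g$mode == "immediate") {
    g$edges[[key]] <- obs
  } else {
    buf <- c(g$edges[[key]], obs)
    if (length(buf) > g$n) buf <- buf[(length(buf) - g$n + 1):length(buf)]
    g$edges[[key]] <- buf
  }
  if (!blocked) {
    g$nodes <- union(g$nodes, t)
    rk <- as.character(t)
    if (g$mode == "immediate") g$rewards[[rk]] <- reward
    else {
      rb <- c(g$rewards[[rk]], reward)
      if (length(rb) > g$n) rb <- rb[(length(rb) - g$n + 1):length(rb)]
      g$rewards[[rk]] <- rb
    }
  }
  g
}

.edge_usable <- function(g, s, t) {
  buf <- g$edges[[.edge_key(s, t)]]
  if (is.null(buf)) return(FALSE)
  if (g$mode == "immediate") return(buf == 1L)
  sum(buf == 1L) * 2 > length(buf)
}

.node_value <- function(g, x) {
  rb <- g$rewards[[as.character(x)]]
  if (is.null(rb)) return(0)
  if (g$mode == "immediate") rb else mean(rb)
}

#' Plan a shortest route through the graph model
#'
#' A* search over known nodes and usable edges (cardinal weight 1, diagonal
#' sqrt(2)), straight-line (octile) heuristic. Equally short first actions are
#' sampled uniformly at random.
#'
#' @param g A `graph_model`.
#' @param start,goal Cell ids; `goal` must be a known node.
#' @return list(path = cell ids incl. endpoints, cost) or NULL if no route.
#' @export
mb_plan <- function(g, start, goal) {
  if (!(start %in% g$nodes) || !(goal %in% g$nodes)) return(NULL)
  if (start == goal) return(list(path = start, cost = 0))
  octile <- function(x) {
    a <- cell_colrow(x); b <- cell_colrow(goal)
    dx <- abs(a[1, 1] - b[1, 1]); dy <- abs(a[1, 2] - b[1, 2])
    (sqrt(2) - 1) * min(dx, dy) + max(dx, dy)
  }
  dist <- rep(Inf, 169); prev <- rep(NA_integer_, 169)
  dist[start] <- 0
  open <- c(start)
  closed <- logical(169)
  while (length(open) > 0) {
    f <- dist[open] + vapply(open, octile, 0)
    u <- open[which.min(f)]
    open <- setdiff(open, u)
    if (u == goal) break
    if (closed[u]) next
    closed[u] <- TRUE
    cr <- cell_colrow(u)
    for (a in 1:8) {
      tc <- cr[1, "col"] + .ACT$dx[a]; tr <- cr[1, "row"] + .ACT$dy[a]
      if (tc < 0 || tc > 12 || tr < 0 || tr > 12) next
      v <- cell_id(tc, tr)
      if (!(v %in% g$nodes) || !.edge_usable(g, u, v)) next
      nd <- dist[u] + .ACT$length[a]
      if (nd < dist[v] - 1e-12) { dist[v] <- nd; prev[v] <- u; open <- union(open, v) }
    }
  }
  if (!is.finite(dist[goal])) return(NULL)
  path <- goal
  while (path[1] != start) path <- c(prev[path[1]], path)
  # uniform tie-break among equally short first steps
  firsts <- integer(0)
  cr <- cell_colrow(start)
  for (a in 1:8) {
    tc <- cr[1, "col"] + .ACT$dx[a]; tr <- cr[1, "row"] + .ACT$dy[a]
    if (tc < 0 || tc > 12 || tr < 0 || tr > 12) next
    v <- cell_id(tc, tr)
    if ((v %in% g$nodes) && .edge_usable(g, start, v) &&
        isTRUE(all.equal(.ACT$length[a] + .mb_dist(g, v, goal), dist[goal]))) {
      firsts <- c(firsts, v)
    }
  }
  if (length(firsts) > 1) {
    pick <- firsts[sample.int(length(firsts), 1)]
    if (pick != path[2]) {
      sub <- mb_plan_det(g, pick, goal)
      path <- c(start, sub$path)
    }
  }
  list(path = path, cost = dist[goal])
}

# deterministic Dijkstra distance / path helpers (internal)
.mb_dist <- function(g, start, goal) {
  d <- mb_plan_det(g, start, goal)
  if (is.null(d)) Inf else d$cost
}

mb_plan_det <- function(g, start, goal) {
  if (!(start %in% g$nodes) || !(goal %in% g$nodes)) return(NULL)
  dist <- rep(Inf, 169); prev <- rep(NA_integer_, 169)
  dist[start] <- 0
  todo <- g$nodes
  while (length(todo) > 0) {
    u <- todo[which.min(dist[todo])]
    if (!is.finite(dist[u])) break
    todo <- setdiff(todo, u)
    cr <- cell_colrow(u)
    for (a in 1:8) {
      tc <- cr[1, "col"] + .ACT$dx[a]; tr <- cr[1, "row"] + .ACT$dy[a]
      if (tc < 0 || tc > 12 || tr < 0 || tr > 12) next
      v <- cell_id(tc, tr)
      if (!(v %in% g$nodes) || !.edge_usable(g, u, v)) next
      nd <- dist[u] + .ACT$length[a]
      if (nd < dist[v] - 1e-12) { dist[v] <- nd; prev[v] <- u }
    }
  }
  if (!is.finite(dist[goal])) return(NULL)
  path <- goal
  while (path[1] != start) path <- c(prev[path[1]], path)
  list(path = path, cost = dist[goal])
}

# --- hierarchical state space ----------------------------------------------

#' One region-level Q update
#'
#' Fires only at region-boundary crossings. A region action is temporally
#' extended, so discounting and trace decay use `gamma^(centroid distance)`
#' (the action's effective duration in grid steps); the step penalty is the
#' centroid distance times the step-penalty scale. The reward carries the
#' shelter-cell entry bonus accumulated while the agent was inside the region
#' being left, which is why the update for a region action is applied at the
#' *next* crossing (or at the terminal shelter entry, with a zero bootstrap).
#'
#' @param Q Region-action value vector (one entry per directed region pair).
#' @param e Trace over region-action pairs.
#' @param partition A [region_partition()].
#' @param from_region,to_region The region action being scored (1-based).
#' @param accum Shelter-entry bonus accumulated during the macro step.
#' @param hp Hyperparameters.
#' @param has_shelter Whether the map carries a shelter (no rewards without).
#' @param terminal The macro step ended at the shelter cell (zero bootstrap;
#'   caller clears the trace).
#' @param boot_action For the on-policy (SARSA) variant, the index of the next
#'   region action taken; NULL bootstraps with the max over the actions
#'   available from `to_region`.
#' @return list(Q, e, reward) or NULL when (from, to) is not a defined
#'   region action.
#' @export
hss_update <- function(Q, e, partition, from_region, to_region, accum = 0,
                       hp = default_hyperparameters("hss_q"),
                       has_shelter = TRUE, terminal = FALSE, boot_action = NULL) {
  acts <- partition$actions
  sa <- which(acts[, "from"] == from_region & acts[, "to"] == to_region)
  if (length(sa) == 0) return(NULL)
  d <- sqrt(sum((partition$centroids[from_region, ] - partition$centroids[to_region, ])^2))
  r <- if (has_shelter) accum - hp$step_scale * d else 0
  gam_eff <- hp$gamma^d
  boot <- if (terminal) 0
  else if (!is.null(boot_action)) Q[boot_action]
  else max(Q[acts[, "from"] == to_region])
  e <- hp$lambda * gam_eff * e
  e[sa] <- e[sa] + 1
  delta <- r + gam_eff * boot - Q[sa]
  Q <- Q + hp$alpha * delta * e
  list(Q = Q, e = e, reward = r)
}

#' Execute a region-level action as a straight grid run
#'
#' Rasterizes the straight line from the current cell to the target region's
#' anchor cell and walks it with grid actions; execution halts at the first
#' blocked step.
#'
#' @param map A `gridmap`.
#' @param cell Current cell.
#' @param to_region Target region index.
#' @return list(path = cells actually visited incl. start, halted).
#' @export
hss_execute <- function(map, cell, to_region) {
  target <- map$regions$anchors[to_region]
  line <- rasterize_line(cell, target)
  path <- cell
  halted <- FALSE
  if (length(line) >= 2) for (k in 2:length(line)) {
    a <- .action_between(line[k - 1], line[k])
    st <- grid_step(map, path[length(path)], a)
    if (st$blocked) { halted <- TRUE; break }
    path <- c(path, st$next_state)
  }
  list(path = path, halted = halted)
}

.action_between <- function(from, to) {
  a <- cell_colrow(from); b <- cell_colrow(to)
  which(.ACT$dx == b[1, 1] - a[1, 1] & .ACT$dy == b[1, 2] - a[1, 2])
}

# --- dual system ------------------------------------------------------------

#' Dual-system action selection
#'
#' Takes the greedy Q action when its value strictly exceeds the threshold;
#' otherwise invokes the model-based immediate planner. Returns NA when the
#' fallback has no plan either.
#'
#' @param Q n_states x n_actions value matrix.
#' @param s Current state.
#' @param threshold Value threshold (strict inequality); the protocol default
#'   is 1, above the value-table initialization noise.
#' @param fallback A function(s) returning an action or NA (e.g. the first
#'   action of an MB-I plan).
#' @return Action index or NA.
#' @export
dual_system_select <- function(Q, s, threshold = 1, fallback) {
  a <- which.max(Q[s, ])
  if (Q[s, a] > threshold) return(a)
  fallback(s)
}

# --- snapshots ---------------------------------------------------------------

#' Save / load an agent snapshot
#'
#' Serializes the learned structures returned by [run_protocol()] with
#' `return_agent = TRUE` (value tables, successor matrix and reward vector,
#' tile weights, graph state or region-action values) to a portable JSON
#' container, for inspection and test fixtures.
#'
#' @param agent The `agent` element of a [run_protocol()] result.
#' @param path File path.
#' @return `write_agent_snapshot` returns `path` invisibly;
#'   `read_agent_snapshot` the snapshot list.
#' @export
write_agent_snapshot <- function(agent, path) {
  jsonlite::write_json(agent, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_agent_snapshot
#' @export
read_agent_snapshot <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
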