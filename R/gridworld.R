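# Grid-world arena: a 13x13 discretization of the circular escape arena with a
# central obstacle, shelter, threat zone and (in two conditions) a one-way
# optogenetic "trip wire" implemented as directed blocked transitions.
#
# Conventions (also stored in map file headers):
#   * 0-based (col, row) coordinates, row 0 at the top (threat side).
#   * cell id (1-based, R side) = row * 13 + col + 1.
#   * 8 compass actions; cardinal step length 1, diagonal sqrt(2).

GRID_N <- 13L

#' Compass action set
#'
#' The eight movement actions of the grid-world MDP, ordered
#' N, NE, E, SE, S, SW, W, NW. North points toward the threat side (row 0).
#'
#' @return A data.frame with columns `action`, `name`, `dx`, `dy`, `length`
#'   (1 for cardinal moves, sqrt(2) for diagonal moves).
#' @export
action_set <- function() {
  data.frame(
    action = 1:8,
    name = c("N", "NE", "E", "SE", "S", "SW", "W", "NW"),
    dx = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
    dy = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
    length = c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)),
    stringsAsFactors = FALSE
  )
}

.ACT <- action_set()

#' Convert between cell ids and (col, row) coordinates
#'
#' @param col,row 0-based column/row.
#' @return `cell_id` returns the 1-based cell id; `cell_colrow` a matrix with
#'   columns `col`, `row`.
#' @export
cell_id <- function(col, row) as.integer(row) * GRID_N + as.integer(col) + 1L

#' @rdname cell_id
#' @param id 1-based cell id.
#' @export
cell_colrow <- function(id) {
  id0 <- as.integer(id) - 1L
  cbind(col = id0 %% GRID_N, row = id0 %/% GRID_N)
}

# Accessible column span per row: a hand-fixed discretized disc with
# 125 cells; removing the 7 obstacle cells leaves the canonical 118.
.ROW_SPAN <- cbind(
  lo = c(4L, 3L, 2L, 1L, 1L, 0L, 0L, 0L, 1L, 1L, 2L, 3L, 4L),
  hi = c(8L, 9L, 10L, 11L, 11L, 12L, 12L, 12L, 11L, 11L, 10L, 9L, 8L)
)

.OBSTACLE_CELLS <- cell_id(3:9, 6L)          # central obstacle row
.SHELTER_CELL <- cell_id(6L, 9L)
.THREAT_CELL <- cell_id(6L, 2L)              # the "threat zone square"
.MIDDLE_CELLS <- cell_id(5:7, 5L)            # three middle states above obstacle
.EDGE_TARGETS <- c(left = cell_id(2L, 6L), right = cell_id(10L, 6L))
.EDGE_LEFT <- cell_id(rep(2L, 3L), 5:7)      # cells flanking the left obstacle end
.EDGE_RIGHT <- cell_id(rep(10L, 3L), 5:7)

# Threat zone: start-cell set for the condition-4 wire and for practice runs.
.THREAT_ZONE <- as.integer(outer(cell_id(4:8, 1L), (0:3) * GRID_N, `+`))

.disc_cells <- function() {
  cells <- integer(0)
  for (r in 0:12) cells <- c(cells, cell_id(.ROW_SPAN[r + 1L, "lo"]:.ROW_SPAN[r + 1L, "hi"], r))
  cells
}

.accessible_vec <- function(obstacle = TRUE) {
  acc <- logical(GRID_N * GRID_N)
  acc[.disc_cells()] <- TRUE
  if (obstacle) acc[.OBSTACLE_CELLS] <- FALSE
  acc
}

# --- one-way trip wires -----------------------------------------------------

# Condition 3: full wire on the row4/row5 boundary. Southward crossings that
# land in columns 1..11 are blocked (threat-area-to-obstacle-edge direction);
# the perimeter columns 0 and 12 remain open, and all northward crossings are
# always permitted.
.oneway_cond3 <- function(acc) {
  out <- NULL
  south <- which(.ACT$dy == 1L)
  for (c0 in 1:11) {
    from <- cell_id(c0, 4L)
    if (!acc[from]) next
    for (a in south) {
      tc <- c0 + .ACT$dx[a]
      if (tc < 1L || tc > 11L) next
      to <- cell_id(tc, 5L)
      if (acc[to]) out <- rbind(out, c(from, a))
    }
  }
  out
}

# Condition 4: partial wire. Edge-directed actions out of threat-zone cells
# (pure lateral and down-lateral: W, E, SW, SE) are blocked — edge-vector runs
# from the threat zone itself; poleward moves (N, NW, NE) head away from the
# obstacle and are not edge-directed, and runs from nearby non-zone cells are
# unaffected.
.oneway_cond4 <- function(acc) {
  out <- NULL
  lateral <- which(.ACT$dx != 0L & .ACT$dy >= 0L)
  for (from in .THREAT_ZONE) {
    cr <- cell_colrow(from)
    for (a in lateral) {
      tc <- cr[1, "col"] + .ACT$dx[a]
      tr <- cr[1, "row"] + .ACT$dy[a]
      if (tc < 0L || tc > 12L || tr < 0L || tr > 12L) next
      to <- cell_id(tc, tr)
      if (acc[to]) out <- rbind(out, c(from, a))
    }
  }
  out
}

# --- region partition (hierarchical state space) ----------------------------

# 10 regions reconstructed from the segmented-arena figure: threat area,
# shelter area, left/right obstacle-edge areas, left/right mid-field,
# above/below-obstacle center, left/right back perimeter. The partition was
# fixed so that cell-level 8-adjacency between regions yields exactly 40
# directed region-action pairs.
.REGION_NAMES <- c("threat", "left_mid", "right_mid", "above_center",
                   "left_edge", "right_edge", "below_center", "shelter",
                   "left_back", "right_back")

.region_assignment <- function() {
  reg <- rep(NA_integer_, GRID_N * GRID_N)
  assign_cells <- function(cells, name) reg[cells] <<- match(name, .REGION_NAMES)
  th <- c(as.integer(outer(cell_id(4:8, 0L), (0:4) * GRID_N, `+`)),
          cell_id(rep(3L, 4L), 1:4), cell_id(rep(9L, 4L), 1:4))
  assign_cells(th, "threat")
  assign_cells(c(cell_id(2L, 2L), cell_id(1:2, 3L), cell_id(1:2, 4L)), "left_mid")
  assign_cells(c(cell_id(10L, 2L), cell_id(10:11, 3L), cell_id(10:11, 4L)), "right_mid")
  assign_cells(cell_id(3:9, 5L), "above_center")
  assign_cells(c(cell_id(0:2, 5L), cell_id(0:2, 6L), cell_id(0:2, 7L)), "left_edge")
  assign_cells(c(cell_id(10:12, 5L), cell_id(10:12, 6L), cell_id(10:12, 7L)), "right_edge")
  assign_cells(c(cell_id(3:9, 7L), cell_id(4:8, 8L)), "below_center")
  assign_cells(as.integer(outer(cell_id(4:8, 9L), (0:3) * GRID_N, `+`)), "shelter")
  assign_cells(c(cell_id(1:3, 8L), cell_id(1:3, 9L), cell_id(2:3, 10L), cell_id(3L, 11L)), "left_back")
  assign_cells(c(cell_id(9:11, 8L), cell_id(9:11, 9L), cell_id(9:10, 10L), cell_id(9L, 11L)), "right_back")
  # Obstacle-footprint cells are mapped to above_center for position lookup on
  # the open test map; they are excluded when deriving the region action set,
  # which is defined on the 118 accessible training-map cells.
  reg[.OBSTACLE_CELLS] <- match("above_center", .REGION_NAMES)
  reg
}

#' Region partition for the hierarchical state space
#'
#' Partitions the 118 accessible cells into 10 named regions and derives the
#' region-level action set (vectors between adjacent regions; exactly 40
#' directed region-action pairs), region centroids and anchor cells.
#'
#' @return A list with `assignment` (integer per cell id, NA off-arena),
#'   `names`, `centroids` (10 x 2, col/row), `anchors` (cell ids),
#'   `actions` (40 x 2 matrix of from/to region indices).
#' @export
region_partition <- function() {
  reg <- .region_assignment()
  acc <- .accessible_vec(obstacle = TRUE)
  cells <- which(acc)
  cr <- cell_colrow(cells)
  cent <- matrix(NA_real_, 10L, 2L, dimnames = list(.REGION_NAMES, c("col", "row")))
  anchors <- integer(10L)
  for (k in 1:10) {
    m <- reg[cells] == k
    cent[k, ] <- c(mean(cr[m, "col"]), mean(cr[m, "row"]))
    d2 <- (cr[m, "col"] - cent[k, 1])^2 + (cr[m, "row"] - cent[k, 2])^2
    anchors[k] <- cells[m][which.min(d2)]
  }
  # adjacency over accessible cells only
  adj <- matrix(FALSE, 10L, 10L)
  for (i in seq_along(cells)) {
    ci <- cr[i, "col"]; ri <- cr[i, "row"]
    for (a in 1:8) {
      tc <- ci + .ACT$dx[a]; tr <- ri + .ACT$dy[a]
      if (tc < 0L || tc > 12L || tr < 0L || tr > 12L) next
      to <- cell_id(tc, tr)
      if (acc[to] && reg[to] != reg[cells[i]]) adj[reg[cells[i]], reg[to]] <- TRUE
    }
  }
  actions <- which(adj, arr.ind = TRUE)
  actions <- actions[order(actions[, 1], actions[, 2]), , drop = FALSE]
  dimnames(actions) <- list(NULL, c("from", "to"))
  list(assignment = reg, names = .REGION_NAMES, centroids = cent,
       anchors = anchors, actions = actions)
}

# --- map construction -------------------------------------------------------

#' Build the grid map for an experimental condition
#'
#' Training maps: condition 1 has obstacle and shelter; condition 2 has the
#' obstacle but no shelter; condition 3 adds a full one-way trip wire between
#' the threat area and the obstacle edges; condition 4 adds a partial wire
#' blocking edge-ward transitions out of the threat zone only. Every test map
#' has a shelter and neither obstacle nor wire.
#'
#' @param condition Integer 1-4.
#' @param phase `"training"` or `"test"`.
#' @return An object of class `gridmap`.
#' @export
build_condition_map <- function(condition, phase = c("training", "test")) {
  phase <- match.arg(phase)
  if (!condition %in% 1:4) stop("unknown condition id: ", condition)
  condition <- as.integer(condition)
  obstacle <- phase == "training"
  acc <- .accessible_vec(obstacle = obstacle)
  has_shelter <- !(phase == "training" && condition == 2L)
  oneway <- NULL
  if (phase == "training" && condition == 3L) oneway <- .oneway_cond3(acc)
  if (phase == "training" && condition == 4L) oneway <- .oneway_cond4(acc)
  if (is.null(oneway)) oneway <- matrix(integer(0), 0L, 2L)
  colnames(oneway) <- c("cell", "action")
  part <- region_partition()
  structure(list(
    n = GRID_N,
    condition = condition,
    phase = phase,
    accessible = acc,
    obstacle = if (obstacle) .OBSTACLE_CELLS else integer(0),
    shelter = if (has_shelter) .SHELTER_CELL else NA_integer_,
    threat = .THREAT_CELL,
    threat_zone = .THREAT_ZONE,
    edge_left = .EDGE_LEFT,
    edge_right = .EDGE_RIGHT,
    edge_targets = .EDGE_TARGETS,
    middle = .MIDDLE_CELLS,
    oneway = oneway,
    reward = 100,
    regions = part
  ), class = "gridmap")
}

#' @export
print.gridmap <- function(x, ...) {
  cat(sprintf("gridmap: condition %d (%s), %d accessible cells, %d one-way blocked transitions\n",
              x$condition, x$phase, sum(x$accessible), nrow(x$oneway)))
  cat(format_gridmap(x), sep = "\n")
  invisible(x)
}

#' Render a map as character rows
#'
#' One character per cell: `#` blocked, `.` accessible, `S` shelter,
#' `T` threat cell, `E` obstacle-edge target, `z` other threat-zone cells.
#' @param map A `gridmap`.
#' @return Character vector of 13 rows.
#' @export
format_gridmap <- function(map) {
  ch <- matrix("#", GRID_N, GRID_N)   # [row, col]
  cr <- cell_colrow(which(map$accessible))
  ch[cbind(cr[, "row"] + 1L, cr[, "col"] + 1L)] <- "."
  put <- function(cells, s) {
    cr <- cell_colrow(cells)
    ch[cbind(cr[, "row"] + 1L, cr[, "col"] + 1L)] <<- s
  }
  put(setdiff(map$threat_zone, map$threat), "z")
  put(map$threat, "T")
  put(map$edge_targets[map$accessible[map$edge_targets]], "E")
  if (!is.na(map$shelter)) put(map$shelter, "S")
  apply(ch, 1, paste0, collapse = "")
}

#' Write / read a map file
#'
#' Plain-text grid (one character per cell) plus a JSON sidecar holding the
#' one-way blocked transitions, condition metadata and region assignment.
#' `read_gridmap(write_gridmap(map, path))` is an exact round trip.
#'
#' @param map A `gridmap`.
#' @param path Path of the text grid file; the sidecar is `<path>.json`.
#' @return `write_gridmap` returns `path` invisibly; `read_gridmap` a `gridmap`.
#' @export
write_gridmap <- function(map, path) {
  header <- c("; 13x13 grid, 0-based (col,row), row 0 at top (threat side)",
              "; chars: # blocked, . accessible, S shelter, T threat, E edge target, z threat zone")
  writeLines(c(header, format_gridmap(map)), path)
  side <- list(
    condition = map$condition, phase = map$phase,
    oneway = unname(apply(map$oneway, 1, function(r) as.list(unname(r)))),
    reward = map$reward,
    regions = as.list(stats::setNames(lapply(1:10, function(k)
      which(map$regions$assignment == k & map$accessible)), map$regions$names))
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gridmap
#' @export
read_gridmap <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  map <- build_condition_map(side$condition, side$phase)
  lines <- readLines(path)
  rows <- lines[!startsWith(lines, ";")]
  stopifnot(identical(rows, format_gridmap(map)))
  if (length(side$oneway)) {
    ow <- side$oneway
    if (!is.matrix(ow)) ow <- matrix(as.integer(unlist(ow)), ncol = 2L, byrow = TRUE)
    storage.mode(ow) <- "integer"
    colnames(ow) <- c("cell", "action")
    stopifnot(identical(ow, map$oneway))
  }
  map
}

# --- MDP step ---------------------------------------------------------------

#' One environment transition
#'
#' Deterministic MDP step: moving into a blocked cell, off the arena, or
#' through a one-way trip wire in the blocked direction leaves the agent in
#' place. Reward is +100 on shelter entry; each transition is charged the
#' attempted step length (1 or sqrt(2)) times `step_scale`, except on maps
#' with no shelter, where the step penalty is absent.
#'
#' @param map A `gridmap`.
#' @param state Accessible cell id.
#' @param action Action 1-8.
#' @param step_scale Scale of the per-step negative reward (agent
#'   hyperparameter; 1 charges the raw distance).
#' @return list(next_state, reward, blocked).
#' @export
grid_step <- function(map, state, action, step_scale = 1) {
  if (!map$accessible[state]) stop("inaccessible source state: ", state)
  cr <- cell_colrow(state)
  tc <- cr[1, "col"] + .ACT$dx[action]
  tr <- cr[1, "row"] + .ACT$dy[action]
  blocked <- tc < 0L || tc > 12L || tr < 0L || tr > 12L
  to <- if (blocked) NA_integer_ else cell_id(tc, tr)
  if (!blocked && !map$accessible[to]) blocked <- TRUE
  if (!blocked && nrow(map$oneway) > 0 &&
      any(map$oneway[, "cell"] == state & map$oneway[, "action"] == action)) blocked <- TRUE
  ns <- if (blocked) state else to
  reward <- 0
  if (!is.na(map$shelter)) {
    reward <- -step_scale * .ACT$length[action]
    if (!blocked && ns == map$shelter && state != map$shelter) reward <- reward + map$reward
  }
  list(next_state = ns, reward = reward, blocked = blocked)
}

#' Rasterize a straight grid line
#'
#' 8-connected Bresenham line between two cells; used by the hierarchical
#' agent's low-level controller ("move directly in a straight line").
#'
#' @param from,to Cell ids.
#' @return Integer vector of cell ids from `from` to `to` inclusive.
#' @export
rasterize_line <- function(from, to) {
  a <- cell_colrow(from); b <- cell_colrow(to)
  x0 <- a[1, "col"]; y0 <- a[1, "row"]; x1 <- b[1, "col"]; y1 <- b[1, "row"]
  dx <- abs(x1 - x0); sx <- sign(x1 - x0)
  dy <- -abs(y1 - y0); sy <- sign(y1 - y0)
  err <- dx + dy
  path <- cell_id(x0, y0)
  while (!(x0 == x1 && y0 == y1)) {
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
    path <- c(path, cell_id(x0, y0))
  }
  path
}

#' Default practice-run specification
#'
#' Hard-coded rapid action sequences mimicking mice's non-uniform exploration:
#' threat-area starts run to an obstacle edge, edge starts run to the shelter.
#' Each sequence is the geodesic on the obstacle training map; trip wires
#' interrupt a sequence exactly as they interrupt ordinary moves (the blocked
#' attempt is executed, then the remainder of the sequence is abandoned).
#'
#' @param prob Trigger probability on entering a start cell.
#' @return A list of class `practice_spec`: `starts`, `seqs` (parallel lists;
#'   a start cell may carry several sequences, chosen uniformly), `prob`.
#' @export
practice_run_spec <- function(prob = 0.2) {
  A <- stats::setNames(.ACT$action, .ACT$name)
  toshL <- c("SE", "SE", "SE", "E")   # left edge -> shelter leg
  toshR <- c("SW", "SW", "SW", "W")
  runs <- list(
    # threat-area starts: compound runs to an obstacle edge and on to the
    # shelter location (one scripted trajectory)
    list(start = cell_id(3L, 1L), seq = unname(A[c("S", "S", "S", "SW", "S", toshL)])),
    list(start = cell_id(3L, 2L), seq = unname(A[c("S", "S", "SW", "S", toshL)])),
    list(start = cell_id(3L, 3L), seq = unname(A[c("S", "SW", "S", toshL)])),
    list(start = cell_id(3L, 4L), seq = unname(A[c("SW", "S", toshL)])),
    list(start = cell_id(4L, 2L), seq = unname(A[c("S", "SW", "SW", "S", toshL)])),
    list(start = cell_id(5L, 2L), seq = unname(A[c("SW", "SW", "SW", "S", toshL)])),
    list(start = cell_id(6L, 2L), seq = unname(A[c("SW", "SW", "SW", "SW", toshL)])),
    list(start = cell_id(6L, 2L), seq = unname(A[c("SE", "SE", "SE", "SE", toshR)])),
    list(start = cell_id(7L, 2L), seq = unname(A[c("SE", "SE", "SE", "S", toshR)])),
    list(start = cell_id(8L, 2L), seq = unname(A[c("S", "SE", "SE", "S", toshR)])),
    list(start = cell_id(9L, 1L), seq = unname(A[c("S", "S", "S", "SE", "S", toshR)])),
    list(start = cell_id(9L, 2L), seq = unname(A[c("S", "S", "SE", "S", toshR)])),
    list(start = cell_id(9L, 3L), seq = unname(A[c("S", "SE", "S", toshR)])),
    list(start = cell_id(9L, 4L), seq = unname(A[c("SE", "S", toshR)])),
    # edge starts: shelter-vector runs
    list(start = cell_id(2L, 6L), seq = unname(A[toshL])),
    list(start = cell_id(10L, 6L), seq = unname(A[toshR]))
  )
  structure(list(
    starts = vapply(runs, `[[`, integer(1), "start"),
    seqs = lapply(runs, `[[`, "seq"),
    prob = prob
  ), class = "practice_spec")
}
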