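# Synthetic mouse-like sessions and escape datasets with known ground truth,
# so that every analysis stage is testable without recorded data. Exploration
# is a persistent correlated random walk confined to the arena and avoiding
# the obstacle footprint; planted homing/edge-vector dashes, shelter visits
# and threat stimuli are spliced in with kinematics that satisfy the
# extraction thresholds by construction.

#' Session specification
#'
#' @param duration_s Session length (s).
#' @param frame_rate Frames per second.
#' @param explore_speed Mean exploration speed (cm/s); slow meandering.
#' @param persistence Heading persistence of the correlated random walk
#'   (0-1; higher = straighter).
#' @param n_homing,n_edge_left,n_edge_right Planted runs: shelter-directed
#'   homing dashes and edge-vector dashes per side, all started inside the
#'   threat zone at dash speed.
#' @param dash_speed Planted run speed (cm/s; > the 15 cm/s homing-speed and
#'   20 cm/s escape thresholds with margin).
#' @param noise_sd Isotropic tracking noise (cm).
#' @param seed Random seed.
#' @return List of class `session_spec`.
#' @export
session_spec <- function(duration_s = 300, frame_rate = 40,
                         explore_speed = 6, persistence = 0.9,
                         n_homing = 2, n_edge_left = 2, n_edge_right = 1,
                         dash_speed = 40, noise_sd = 0.25, seed = 1) {
  structure(as.list(environment()), class = "session_spec")
}

.clamp_arena <- function(p, geometry, margin = 1) {
  r <- sqrt(sum(p^2))
  if (r > geometry$radius - margin) p <- p * (geometry$radius - margin) / r
  # keep out of the obstacle footprint (a thin band around y = 0)
  if (abs(p[2]) < 1.5 && abs(p[1]) <= geometry$obstacle_halflength + 1)
    p[2] <- sign(p[2] + 1e-9) * 1.5
  p
}

# straight constant-speed dash between two points at the session frame rate
.dash_frames <- function(from, to, speed, frame_rate) {
  len <- sqrt(sum((to - from)^2))
  n <- max(2L, ceiling(len / speed * frame_rate))
  cbind(seq(from[1], to[1], length.out = n), seq(from[2], to[2], length.out = n))
}

# correlated random walk from p for n frames; gentle turning so that smoothed
# angular speeds stay below the extraction threshold away from planted events
.crw <- function(p, ang, n, step, persistence, geometry) {
  out <- matrix(NA_real_, n, 2)
  turn_sd <- (1 - persistence) / 2
  for (i in seq_len(n)) {
    ang <- ang + stats::rnorm(1, sd = turn_sd)
    cand <- p + step * c(cos(ang), sin(ang))
    fixed <- .clamp_arena(cand, geometry)
    if (!identical(fixed, cand)) ang <- ang + pi / 2   # deflect at boundaries
    p <- fixed
    out[i, ] <- p
  }
  list(pos = out, p = p, ang = ang)
}

# meander toward a target at exploration speed (slow, sub-threshold
# approach); routes via an obstacle-end waypoint when start and target lie on
# opposite sides of the obstacle band
.guided <- function(p, target, step, geometry) {
  leg <- function(p, tg) {
    out <- NULL
    guard <- 0L
    while (sqrt(sum((p - tg)^2)) > 2 * step && guard < 8000L) {
      dir <- atan2(tg[2] - p[2], tg[1] - p[1]) + stats::rnorm(1, sd = 0.1)
      p <- .clamp_arena(p + step * c(cos(dir), sin(dir)), geometry)
      out <- rbind(out, p)
      guard <- guard + 1L
    }
    list(pos = out, p = p)
  }
  straddles <- sign(p[2]) != sign(target[2]) &&
    (abs(p[1]) <= geometry$obstacle_halflength + 2 ||
     abs(target[1]) <= geometry$obstacle_halflength + 2)
  pos <- NULL
  if (straddles) {
    sidex <- if (mean(c(p[1], target[1])) < 0) -1 else 1
    wp <- c(sidex * (geometry$obstacle_halflength + 8), 0)
    l1 <- leg(p, wp)
    pos <- rbind(pos, l1$pos); p <- l1$p
  }
  l2 <- leg(p, target)
  list(pos = rbind(pos, l2$pos), p = l2$p)
}

#' Generate a synthetic session
#'
#' Builds the session sequentially: slow correlated-random-walk exploration,
#' a sub-threshold guided approach to each planted start point, then the
#' planted dash (homing runs to the shelter; edge-vector runs through an
#' edge-entry rectangle and on to the shelter) followed by a one-second
#' shelter visit, and exploration again. Sequential construction keeps the
#' trajectory continuous so the planted runs are the only segments that
#' exceed the extraction thresholds. The ground-truth log records every
#' planted run with its frame span.
#'
#' @param spec A [session_spec()].
#' @param geometry An [arena_geometry()].
#' @return list(traj = [trajectory()], truth = data.frame of planted events).
#' @export
generate_session <- function(spec, geometry = arena_geometry()) {
  set.seed(spec$seed)
  fr <- spec$frame_rate
  n <- spec$duration_s * fr
  step <- spec$explore_speed / fr
  kinds <- c(rep("homing", spec$n_homing),
             rep("edge_left", spec$n_edge_left),
             rep("edge_right", spec$n_edge_right))
  if (length(kinds)) kinds <- sample(kinds)
  # exploration budget split evenly around the planted events
  n_chunks <- length(kinds) + 1L
  pos <- NULL
  events <- list()
  p <- c(0, geometry$threat_y_min + 5)
  ang <- stats::runif(1, 0, 2 * pi)
  est_event <- 16 * fr          # rough frames per approach + dash + visit
  explore_each <- max(fr, ((n - length(kinds) * est_event) %/% n_chunks))
  for (j in seq_along(kinds)) {
    w <- .crw(p, ang, explore_each, step, spec$persistence, geometry)
    pos <- rbind(pos, w$pos); p <- w$p; ang <- w$ang
    start <- c(stats::runif(1, -12, 12),
               stats::runif(1, geometry$threat_y_min + 3, geometry$radius - 8))
    gu <- .guided(p, start, step, geometry)
    pos <- rbind(pos, gu$pos); p <- gu$p
    dest <- geometry$shelter + c(0, geometry$shelter_radius / 2)
    seg <- if (kinds[j] == "homing") .dash_frames(p, dest, spec$dash_speed, fr)
    else {
      via <- if (kinds[j] == "edge_left")
        c(mean(geometry$edge_rect_left[c("xmin", "xmax")]), 0)
      else c(mean(geometry$edge_rect_right[c("xmin", "xmax")]), 0)
      rbind(.dash_frames(p, via, spec$dash_speed, fr),
            .dash_frames(via, dest, spec$dash_speed, fr)[-1, ])
    }
    i0 <- nrow(pos) + 1L
    pos <- rbind(pos, seg)
    i1 <- nrow(pos)
    pos <- rbind(pos, matrix(pos[i1, ], fr, 2, byrow = TRUE))  # shelter visit
    p <- pos[nrow(pos), ]; ang <- stats::runif(1, 0, 2 * pi)
    events[[j]] <- data.frame(kind = kinds[j], start_frame = i0, end_frame = i1,
                              start_x = seg[1, 1], start_y = seg[1, 2])
  }
  # top up with exploration; the session is extended past the nominal
  # duration if needed so that every planted event is present in full
  if (nrow_or0(pos) < n) {
    w <- .crw(p, ang, n - nrow_or0(pos), step, spec$persistence, geometry)
    pos <- rbind(pos, w$pos)
  }
  nf <- nrow(pos)
  noisy <- pos + matrix(stats::rnorm(2 * nf, sd = spec$noise_sd), nf, 2)
  truth <- if (length(events)) do.call(rbind, events)
  else data.frame(kind = character(0), start_frame = integer(0),
                  end_frame = integer(0), start_x = numeric(0), start_y = numeric(0))
  list(traj = trajectory(noisy[, 1], noisy[, 2], frame_rate = fr), truth = truth)
}

nrow_or0 <- function(x) if (is.null(x)) 0L else nrow(x)

#' Attach a rigid body-part template
#'
#' Translates and rotates a 13-point rigid template (snout, eyes, ears, neck,
#' limbs, back points, tail base) along the path, oriented by the movement
#' direction, to exercise [compute_body_direction()].
#'
#' @param traj A [trajectory()].
#' @param scale Template scale (cm).
#' @return The trajectory with a `bodyparts` attribute.
#' @export
add_bodyparts <- function(traj, scale = 1) {
  tmpl <- list(
    snout = c(4.5, 0), left_eye = c(3.8, 0.6), right_eye = c(3.8, -0.6),
    left_ear = c(3.2, 1.0), neck = c(3.0, 0), right_ear = c(3.2, -1.0),
    upper_left_limb = c(1.8, 1.2), upper_back = c(1.8, 0),
    upper_right_limb = c(1.8, -1.2), lower_left_limb = c(-1.2, 1.1),
    lower_back = c(-1.0, 0), lower_right_limb = c(-1.2, -1.1),
    tail_base = c(-2.5, 0))
  dx <- c(diff(traj$x)[1], diff(traj$x)); dy <- c(diff(traj$y)[1], diff(traj$y))
  ang <- atan2(dy, dx)
  ang[!is.finite(ang)] <- 0
  bp <- lapply(tmpl, function(off) {
    ox <- off[1] * scale; oy <- off[2] * scale
    cbind(traj$x + ox * cos(ang) - oy * sin(ang),
          traj$y + ox * sin(ang) + oy * cos(ang))
  })
  attr(traj, "bodyparts") <- bp
  traj
}

#' Generate a synthetic escape dataset with planted logistic structure
#'
#' Samples escape initiation points over the threat zone (plus a history of
#' spontaneous edge-vector-run starts), computes the five spatial predictors,
#' and draws binary outcomes from the planted logistic model
#' `logit P(edge) = intercept + coefficients . predictors`.
#'
#' @param n_escapes Number of escapes (the pooled dataset emulated has 207
#'   escapes over 40 sessions).
#' @param coefficients Named vector over (a subset of) the five predictors.
#' @param intercept Planted intercept.
#' @param n_runs Spontaneous edge-vector-run starts per side.
#' @param geometry An [arena_geometry()].
#' @param seed Random seed.
#' @return list(data = data.frame with predictors, side and outcome;
#'   run_starts; truth = planted coefficients).
#' @export
generate_escape_dataset <- function(n_escapes = 207,
                                    coefficients = c(dist_axis = 0.15),
                                    intercept = -1,
                                    n_runs = 8,
                                    geometry = arena_geometry(),
                                    seed = 1) {
  set.seed(seed)
  bins <- threat_zone_bins(geometry)
  run_starts <- data.frame(
    x = c(stats::runif(n_runs, -15, -3), stats::runif(n_runs, 3, 15)),
    y = stats::runif(2 * n_runs, geometry$threat_y_min, geometry$threat_y_min + 15),
    side = rep(c("left", "right"), each = n_runs))
  ix <- sample.int(nrow(bins), n_escapes, replace = TRUE)
  pts <- bins[ix, , drop = FALSE] +
    matrix(stats::runif(2 * n_escapes, -0.5, 0.5), ncol = 2)
  side <- ifelse(pts[, "x"] <= 0, "left", "right")
  X <- t(vapply(seq_len(n_escapes), function(i)
    spatial_metrics(pts[i, 1], pts[i, 2], side[i], run_starts, geometry),
    numeric(5)))
  eta <- rep(intercept, n_escapes)
  for (nm in names(coefficients)) eta <- eta + coefficients[[nm]] * X[, nm]
  pr <- stats::plogis(eta)
  outcome <- stats::rbinom(n_escapes, 1, pr)
  if (length(unique(outcome)) < 2)
    stop("degenerate coefficients: single-class outcomes at this n")
  list(data = data.frame(x = pts[, 1], y = pts[, 2], side = side, X,
                         outcome = outcome),
       run_starts = run_starts,
       truth = list(intercept = intercept, coefficients = coefficients))
}

#' Threat-stimulus triggering
#'
#' Applies the four criteria to a session trajectory: the animal is in the
#' threat zone now, was in the threat zone 1.5 s ago, is moving away from the
#' shelter at more than 5 cm/s, and the most recent stimulus was more than
#' 45 s ago.
#'
#' @param traj A [trajectory()].
#' @param geometry An [arena_geometry()].
#' @param dwell_s In-zone dwell requirement (s).
#' @param away_speed Away-from-shelter speed threshold (cm/s).
#' @param refractory_s Minimum time between stimuli (s).
#' @return Numeric vector of stimulus times (s).
#' @export
trigger_threat_stimuli <- function(traj, geometry, dwell_s = 1.5,
                                   away_speed = 5, refractory_s = 45) {
  fr <- attr(traj, "frame_rate")
  inzone <- traj$y >= geometry$threat_y_min &
    traj$x^2 + traj$y^2 <= geometry$radius^2
  v_away <- -.speed_toward(traj, geometry$shelter, sigma_frames = 4)
  lag <- round(dwell_s * fr)
  times <- numeric(0)
  last <- -Inf
  for (i in seq_len(nrow(traj))) {
    if (i <= lag) next
    if (inzone[i] && inzone[i - lag] && v_away[i] > away_speed &&
        (traj$t[i] - last) > refractory_s) {
      times <- c(times, traj$t[i])
      last <- traj$t[i]
    }
  }
  times
}
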