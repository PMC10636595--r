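# Continuous-trajectory quantification: kinematics, escape target scoring and
# spontaneous homing-/edge-vector-run extraction for mouse-style tracking data
# on the circular escape arena.
#
# Coordinate frame: origin at the arena center, +y toward the threat zone,
# -y toward the shelter, units cm. Positions are sampled at 40 frames/s.

#' Arena geometry
#'
#' The circular platform (92 cm diameter) with a central 50-cm obstacle
#' segment along the x axis, shelter below, threat zone above, and the two
#' edge-entry rectangles (10 cm along the obstacle axis x 5 cm across it,
#' centered 2.5 cm lateral of each obstacle end).
#'
#' @param arena_diameter_cm Platform diameter.
#' @param obstacle_halflength_cm Half-length of the obstacle segment (y = 0).
#' @param shelter_xy Shelter position (front of the entrance).
#' @param shelter_radius_cm Arrival radius ("within 10 cm of the entrance").
#' @param threat_y_min Lower bound of the threat-zone circular segment; the
#'   default gives 1652 one-cm-square bins inside the zone.
#' @param score_line_y The transect "10 cm in front of the obstacle" on which
#'   escape target scores are measured.
#' @return A list of class `arena_geometry`.
#' @export
arena_geometry <- function(arena_diameter_cm = 92,
                           obstacle_halflength_cm = 25,
                           shelter_xy = c(0, -40),
                           shelter_radius_cm = 10,
                           threat_y_min = 18.7,
                           score_line_y = 10) {
  r <- arena_diameter_cm / 2
  structure(list(
    radius = r,
    obstacle_halflength = obstacle_halflength_cm,
    edge_left = c(-obstacle_halflength_cm, 0),
    edge_right = c(obstacle_halflength_cm, 0),
    shelter = shelter_xy,
    shelter_radius = shelter_radius_cm,
    threat_y_min = threat_y_min,
    score_line_y = score_line_y,
    # edge-entry rectangles: 10 cm (parallel, x) x 5 cm (perpendicular, y),
    # centered 2.5 cm lateral (outward) of the obstacle end
    edge_rect_left = c(xmin = -obstacle_halflength_cm - 7.5,
                       xmax = -obstacle_halflength_cm + 2.5,
                       ymin = -2.5, ymax = 2.5),
    edge_rect_right = c(xmin = obstacle_halflength_cm - 2.5,
                        xmax = obstacle_halflength_cm + 7.5,
                        ymin = -2.5, ymax = 2.5),
    frame_rate = 40
  ), class = "arena_geometry")
}

#' One-cm-square bins of the threat zone
#'
#' Centers of the 1 cm x 1 cm bins whose centers lie inside the threat zone
#' (the circular segment y >= `threat_y_min`).
#'
#' @param geometry An [arena_geometry()].
#' @return Two-column matrix (x, y) of bin centers.
#' @export
threat_zone_bins <- function(geometry) {
  g <- expand.grid(x = seq(-geometry$radius + 0.5, geometry$radius - 0.5, by = 1),
                   y = seq(geometry$threat_y_min + 0.5, geometry$radius, by = 1))
  keep <- g$x^2 + g$y^2 <= geometry$radius^2 & g$y >= geometry$threat_y_min
  as.matrix(g[keep, c("x", "y")])
}

#' Gaussian smoothing with reflected padding
#'
#' @param x Numeric vector.
#' @param sigma Kernel standard deviation in samples.
#' @return Smoothed vector, same length.
#' @export
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(half:1 + 1L, n)], x, x[pmax(n - (1:half), 1L)])
  as.numeric(stats::filter(pad, k, sides = 2))[(half + 1):(half + n)]
}

#' Build a trajectory object
#'
#' @param x,y Positions (cm).
#' @param frame_rate Frames per second (40 in the recordings emulated here).
#' @param t Timestamps (s); default regular sampling.
#' @param bodyparts Optional named list of 2-column matrices (one per body
#'   part) with per-frame positions.
#' @return A data.frame of class `trajectory` with attributes `frame_rate`
#'   and `bodyparts`.
#' @export
trajectory <- function(x, y, frame_rate = 40, t = NULL, bodyparts = NULL) {
  if (is.null(t)) t <- (seq_along(x) - 1) / frame_rate
  stopifnot(length(x) == length(y), !is.unsorted(t))
  out <- data.frame(frame = seq_along(x), t = t, x = x, y = y)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "bodyparts") <- bodyparts
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Per-frame speed
#'
#' Finite-difference speed smoothed with a Gaussian filter of
#' sigma = 4 frames (100 ms at 40 frames/s).
#'
#' @param traj A [trajectory()].
#' @param sigma_frames Smoothing sigma in frames.
#' @return Numeric vector (cm/s), length nrow(traj).
#' @export
compute_speed <- function(traj, sigma_frames = 4) {
  if (nrow(traj) < 2) stop("speed needs at least two frames")
  fr <- attr(traj, "frame_rate")
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) * fr
  raw <- c(d[1], d)   # align to frames; first frame repeats the first step
  gaussian_smooth(raw, sigma_frames)
}

# signed speed toward a target: rate of decrease of distance to it (cm/s)
.speed_toward <- function(traj, target, sigma_frames = 0) {
  fr <- attr(traj, "frame_rate")
  dist <- sqrt((traj$x - target[1])^2 + (traj$y - target[2])^2)
  v <- -c(diff(dist)[1], diff(dist)) * fr
  if (sigma_frames > 0) v <- gaussian_smooth(v, sigma_frames) else v
}

#' Body direction from tracked body parts
#'
#' Unit vector from the lower body (average of lower left limb, lower right
#' limb, lower back and tail base) to the front of the body (average of upper
#' left limb, upper right limb and upper back). Frames with missing parts are
#' marked invalid (NA).
#'
#' @param traj A [trajectory()] whose `bodyparts` attribute contains the
#'   seven named parts.
#' @return n x 2 matrix of unit heading vectors (NA rows where invalid).
#' @export
compute_body_direction <- function(traj) {
  bp <- attr(traj, "bodyparts")
  lower <- c("lower_left_limb", "lower_right_limb", "lower_back", "tail_base")
  upper <- c("upper_left_limb", "upper_right_limb", "upper_back")
  if (is.null(bp) || !all(c(lower, upper) %in% names(bp)))
    stop("body direction needs the seven lower/upper body parts")
  avg <- function(parts) {
    xs <- sapply(parts, function(p) bp[[p]][, 1])
    ys <- sapply(parts, function(p) bp[[p]][, 2])
    cbind(rowMeans(xs), rowMeans(ys))
  }
  lo <- avg(lower); hi <- avg(upper)
  v <- hi - lo
  len <- sqrt(rowSums(v^2))
  out <- v / len
  out[!is.finite(len) | len == 0, ] <- NA_real_
  out
}

#' Escape target score
#'
#' Scores the escape heading on the transect 10 cm in front of the obstacle:
#' `score = |offsetHV - offsetEV + offsetHV_EV| / (2 * offsetHV_EV)`, where
#' offsetHV (offsetEV) is the distance from the animal's transect crossing to
#' where the homing-vector (edge-vector) path crosses it, and offsetHV_EV the
#' distance between those two reference crossings. Shelter-directed headings
#' score 0, edge-directed 1, halfway 0.5.
#'
#' @param initiation_pos Escape initiation position c(x, y).
#' @param pos_at_line Position when crossing the transect (its y coordinate is
#'   projected onto the transect along the initiation-to-position direction).
#' @param geometry An [arena_geometry()].
#' @param side `"left"` or `"right"` obstacle edge as the edge-vector target.
#' @return Scalar score (>= 0).
#' @export
escape_target_score <- function(initiation_pos, pos_at_line, geometry,
                                side = c("left", "right")) {
  side <- match.arg(side)
  yline <- geometry$score_line_y
  cross_x <- function(p) {
    d <- p - initiation_pos
    if (d[2] >= 0) stop("path does not descend toward the obstacle")
    initiation_pos[1] + d[1] * (yline - initiation_pos[2]) / d[2]
  }
  edge <- if (side == "left") geometry$edge_left else geometry$edge_right
  x_m <- cross_x(pos_at_line)
  x_hv <- cross_x(geometry$shelter)
  x_ev <- cross_x(edge)
  off_hv_ev <- abs(x_hv - x_ev)
  if (off_hv_ev == 0) stop("degenerate geometry: homing and edge paths coincide")
  abs(abs(x_m - x_hv) - abs(x_m - x_ev) + off_hv_ev) / (2 * off_hv_ev)
}

#' Classify an escape by its target score
#'
#' Scores strictly above 0.65 are edge vectors; all others homing vectors.
#'
#' @param score Escape target score.
#' @param threshold Classification threshold.
#' @return `"edge_vector"` or `"homing_vector"`.
#' @export
classify_escape <- function(score, threshold = 0.65) {
  stopifnot(is.finite(score))
  if (score > threshold) "edge_vector" else "homing_vector"
}

#' Escape initiation frame
#'
#' First post-stimulus frame in which the shelter-ward speed (rate of
#' approach to the shelter, smoothed like [compute_speed()]) exceeds
#' 20 cm/s.
#'
#' @param traj A [trajectory()].
#' @param stimulus_time Stimulus onset (s).
#' @param geometry An [arena_geometry()].
#' @param threshold Speed threshold (cm/s).
#' @return Frame index, or NA if the threshold is never crossed.
#' @export
detect_escape_initiation <- function(traj, stimulus_time, geometry,
                                     threshold = 20) {
  stopifnot(stimulus_time >= traj$t[1], stimulus_time <= traj$t[nrow(traj)])
  v <- .speed_toward(traj, geometry$shelter, sigma_frames = 4)
  post <- which(traj$t >= stimulus_time & v > threshold)
  if (length(post) == 0) NA_integer_ else post[1]
}

#' Spatial efficiency of a path segment
#'
#' Straight-line (chord) length divided by traveled path length; 1 is the
#' direct path.
#'
#' @param x,y Path coordinates.
#' @return Scalar in (0, 1].
#' @export
spatial_efficiency <- function(x, y) {
  stopifnot(length(x) >= 2)
  arc <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (arc == 0) stop("zero path length")
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  min(chord / arc, 1)
}

#' Extract spontaneous homing runs
#'
#' Five-step extraction: (1) homing speed toward the shelter or either
#' obstacle edge (max over the three targets), Gaussian-smoothed with
#' sigma = 0.5 s, and angular homing speed (rate of decrease of the absolute
#' angle between movement direction and the target direction); (2) frames
#' qualify when homing speed > 15 cm/s or angular homing speed > 90 deg/s;
#' (3) qualifying frames are dilated by 1 s; (4) frames neither approaching
#' nor turning toward a target are rejected; (5) runs shorter than 1 s, or
#' that decrease the distance to their destination by less than 20%, or that
#' do not start inside the threat zone, are rejected.
#'
#' @param traj A [trajectory()].
#' @param geometry An [arena_geometry()].
#' @param speed_threshold,turn_threshold,min_duration,min_decrease The
#'   thresholds of steps (2) and (5).
#' @return A data.frame of runs (one row each) with frame span, start/end
#'   positions, duration, destination, spatial efficiency and
#'   `is_edge_vector` flag; zero rows when nothing qualifies.
#' @export
extract_homing_runs <- function(traj, geometry, speed_threshold = 15,
                                turn_threshold = 90, min_duration = 1,
                                min_decrease = 0.2) {
  fr <- attr(traj, "frame_rate")
  sigma <- 0.5 * fr
  targets <- list(shelter = geometry$shelter,
                  edge_left = geometry$edge_left,
                  edge_right = geometry$edge_right)
  n <- nrow(traj)
  vs <- sapply(targets, function(tg) .speed_toward(traj, tg, sigma_frames = sigma))
  # angular homing speed: rate of decrease of |angle between movement
  # direction and the target-ward direction|, positive when turning toward
  dx <- c(diff(traj$x)[1], diff(traj$x)); dy <- c(diff(traj$y)[1], diff(traj$y))
  mv <- atan2(dy, dx)
  av <- sapply(targets, function(tg) {
    ang_t <- atan2(tg[2] - traj$y, tg[1] - traj$x)
    off <- abs(((mv - ang_t + pi) %% (2 * pi)) - pi)   # |heading error|, 0..pi
    w <- -c(diff(off)[1], diff(off)) * fr * 180 / pi
    gaussian_smooth(w, sigma)
  })
  v_best <- apply(vs, 1, max)
  a_best <- apply(av, 1, max)
  qualify <- v_best > speed_threshold | a_best > turn_threshold
  # dilate by 1 s
  half <- fr
  dil <- qualify
  for (k in which(qualify)) dil[max(1, k - half):min(n, k + half)] <- TRUE
  # reject frames neither approaching nor turning toward any target; this
  # uses near-instantaneous (lightly smoothed) signals so that the rejection
  # tracks what the animal is doing frame by frame rather than the broad
  # kernel used for the speed threshold
  vr <- sapply(targets, function(tg) .speed_toward(traj, tg, sigma_frames = 0))
  ar <- sapply(targets, function(tg) {
    ang_t <- atan2(tg[2] - traj$y, tg[1] - traj$x)
    off <- abs(((mv - ang_t + pi) %% (2 * pi)) - pi)
    -c(diff(off)[1], diff(off)) * fr * 180 / pi
  })
  dil <- dil & (apply(vr, 1, max) > 0 | apply(ar, 1, max) > 0)
  # bridge momentary dropouts (e.g. the instant of the turn at an obstacle
  # edge) so that one run is not split by a single non-approaching frame
  gap <- round(0.25 * fr)
  rg <- rle(dil)
  if (length(rg$lengths) > 2) {
    ends_g <- cumsum(rg$lengths)
    for (k in 2:(length(rg$lengths) - 1)) {
      if (!rg$values[k] && rg$lengths[k] <= gap && rg$values[k - 1] && rg$values[k + 1])
        dil[(ends_g[k - 1] + 1):ends_g[k]] <- TRUE
    }
  }
  runs <- NULL
  rl <- rle(dil)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  inzone <- traj$y >= geometry$threat_y_min &
    traj$x^2 + traj$y^2 <= geometry$radius^2
  for (k in which(rl$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if ((traj$t[i1] - traj$t[i0]) < min_duration) next
    if (!inzone[i0]) next
    seg <- traj[i0:i1, ]
    is_ev <- .enters_edge_rect(seg, geometry)
    dest <- if (is_ev) {
      if (mean(seg$x) < 0) geometry$edge_left else geometry$edge_right
    } else geometry$shelter
    d <- sqrt((seg$x - dest[1])^2 + (seg$y - dest[2])^2)
    if ((d[1] - min(d)) / d[1] < min_decrease) next
    runs <- rbind(runs, data.frame(
      start_frame = i0, end_frame = i1,
      start_x = seg$x[1], start_y = seg$y[1],
      end_x = seg$x[nrow(seg)], end_y = seg$y[nrow(seg)],
      duration = traj$t[i1] - traj$t[i0],
      destination = if (is_ev) "edge" else "shelter",
      is_edge_vector = is_ev,
      efficiency = spatial_efficiency(seg$x, seg$y)
    ))
  }
  if (is.null(runs)) {
    runs <- data.frame(start_frame = integer(0), end_frame = integer(0),
                       start_x = numeric(0), start_y = numeric(0),
                       end_x = numeric(0), end_y = numeric(0),
                       duration = numeric(0), destination = character(0),
                       is_edge_vector = logical(0), efficiency = numeric(0))
  }
  runs
}

.enters_edge_rect <- function(seg, geometry) {
  inside <- function(rect)
    any(seg$x >= rect["xmin"] & seg$x <= rect["xmax"] &
        seg$y >= rect["ymin"] & seg$y <= rect["ymax"])
  inside(geometry$edge_rect_left) || inside(geometry$edge_rect_right)
}

#' Is a homing run an edge-vector run?
#'
#' TRUE iff any frame of the run lies inside either side's edge-entry
#' rectangle (boundary inclusive).
#'
#' @param traj The session [trajectory()].
#' @param run One row of [extract_homing_runs()] output.
#' @param geometry An [arena_geometry()].
#' @return Logical.
#' @export
is_edge_vector_run <- function(traj, run, geometry) {
  seg <- traj[run$start_frame:run$end_frame, ]
  .enters_edge_rect(seg, geometry)
}

#' Side of an escape
#'
#' The side of the arena (left/right of the vertical threat-shelter axis) on
#' which the path first crosses the platform's horizontal center line (y = 0);
#' exactly-on-axis crossings are assigned left.
#'
#' @param x,y Escape path coordinates (from initiation onward).
#' @return `"left"` or `"right"`.
#' @export
escape_side <- function(x, y) {
  cross <- which(y[-1] <= 0 & y[-length(y)] > 0)
  if (length(cross) == 0) stop("path never crosses the platform center line")
  i <- cross[1]
  f <- (y[i] - 0) / (y[i] - y[i + 1])
  x0 <- x[i] + f * (x[i + 1] - x[i])
  if (x0 <= 0) "left" else "right"
}

# --- trajectory I/O ---------------------------------------------------------

#' Read and write trajectory CSV files
#'
#' The tidy format has columns frame, time_s, x_cm, y_cm and optionally
#' `<part>_x`/`<part>_y` body-part columns. `read_pose_csv` reads the common
#' pose-estimation export dialect (three header rows: scorer, bodyparts,
#' coords; x/y/likelihood triplets per part), drops low-confidence points and
#' median-filters each coordinate (width 7 frames).
#'
#' @param traj A [trajectory()].
#' @param path File path.
#' @return `write_trajectory_csv` returns `path` invisibly; the readers
#'   return a [trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(frame = traj$frame, time_s = traj$t,
                    x_cm = traj$x, y_cm = traj$y)
  bp <- attr(traj, "bodyparts")
  if (!is.null(bp)) for (nm in names(bp)) {
    out[[paste0(nm, "_x")]] <- bp[[nm]][, 1]
    out[[paste0(nm, "_y")]] <- bp[[nm]][, 2]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  fr <- if (nrow(d) > 1) 1 / stats::median(diff(d$time_s)) else 40
  parts <- sub("_x$", "", grep("_x$", names(d), value = TRUE))
  parts <- setdiff(parts, "x_cm")
  bp <- NULL
  if (length(parts)) {
    bp <- lapply(parts, function(p) cbind(d[[paste0(p, "_x")]], d[[paste0(p, "_y")]]))
    names(bp) <- parts
  }
  trajectory(d$x_cm, d$y_cm, frame_rate = round(fr), t = d$time_s, bodyparts = bp)
}

#' @rdname write_trajectory_csv
#' @param likelihood_cutoff Points with likelihood below this are set NA and
#'   linearly interpolated.
#' @param median_width Median-filter width in frames.
#' @param frame_rate Acquisition frame rate.
#' @export
read_pose_csv <- function(path, likelihood_cutoff = 0.9, median_width = 7,
                          frame_rate = 40) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  d <- utils::read.csv(path, header = FALSE, skip = 3)
  parts <- as.character(unlist(hdr[2, -1]))
  coords <- as.character(unlist(hdr[3, -1]))
  uparts <- unique(parts)
  clean <- function(v) {
    if (median_width > 1) v <- stats::runmed(v, k = median_width)
    v
  }
  bp <- lapply(uparts, function(p) {
    ix <- which(parts == p & coords == "x") + 1L
    iy <- which(parts == p & coords == "y") + 1L
    il <- which(parts == p & coords == "likelihood") + 1L
    x <- d[[ix]]; y <- d[[iy]]
    if (length(il)) {
      bad <- d[[il]] < likelihood_cutoff
      x[bad] <- NA; y[bad] <- NA
      x <- stats::approx(seq_along(x), x, seq_along(x), rule = 2)$y
      y <- stats::approx(seq_along(y), y, seq_along(y), rule = 2)$y
    }
    cbind(clean(x), clean(y))
  })
  names(bp) <- uparts
  cx <- rowMeans(sapply(bp, function(m) m[, 1]))
  cy <- rowMeans(sapply(bp, function(m) m[, 2]))
  trajectory(cx, cy, frame_rate = frame_rate, bodyparts = bp)
}

#' @rdname write_trajectory_csv
#' @param geometry An [arena_geometry()].
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(unclass(geometry), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(g, class = "arena_geometry")
}
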