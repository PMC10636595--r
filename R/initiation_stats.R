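# Initiation-set analyses: spatial predictors of edge-vector escapes,
# logistic regression with McFadden pseudo-R2 and permutation p-values, AIC
# model comparison, residual-based metric normalization, binned correlation,
# the pooled-mean-difference group permutation test, and the Von Mises
# classification-bias simulation.

#' Spatial predictors of an escape
#'
#' The five predictors of edge-vector escape probability, measured from the
#' escape initiation point: distance to the nearest start of a same-side
#' spontaneous edge-vector run, distance to the obstacle (along y), distance
#' to the central vertical axis (along x), distance to the shelter, and the
#' angle between the edge-vector and homing-vector paths.
#'
#' @param x,y Escape initiation position.
#' @param side Escape side ("left"/"right"); selects the edge and which runs
#'   count as same-side.
#' @param run_starts Data.frame with columns `x`, `y`, `side` of spontaneous
#'   edge-vector-run start points (may have zero rows).
#' @param geometry An [arena_geometry()].
#' @return Named numeric vector; `dist_nearest_run` is NA when no same-side
#'   run exists (the escape is then dropped from that one regression).
#' @export
spatial_metrics <- function(x, y, side, run_starts, geometry) {
  edge <- if (side == "left") geometry$edge_left else geometry$edge_right
  sh <- geometry$shelter
  same <- run_starts[run_starts$side == side, , drop = FALSE]
  d_run <- if (nrow(same) == 0) NA_real_
  else min(sqrt((same$x - x)^2 + (same$y - y)^2))
  v_ev <- edge - c(x, y); v_hv <- sh - c(x, y)
  ang <- acos(pmin(1, pmax(-1, sum(v_ev * v_hv) /
                             (sqrt(sum(v_ev^2)) * sqrt(sum(v_hv^2)))))) * 180 / pi
  c(dist_nearest_run = d_run,
    dist_obstacle = abs(y),
    dist_axis = abs(x),
    dist_shelter = sqrt(sum(v_hv^2)),
    angle_ev_hv = ang)
}

#' Logistic regression with McFadden pseudo-R2
#'
#' Unregularized maximum-likelihood fit of binary outcomes on one or more
#' predictors, with the intercept-only model as the null:
#' `pseudoR2 = 1 - LLfull / LLnull`; `AIC = 2k - 2 LLfull` with k counting
#' the intercept. Complete separation is flagged, not silently converged.
#'
#' @param predictors Numeric vector or matrix/data.frame (one column per
#'   predictor).
#' @param outcomes Binary vector (1 = edge-vector escape).
#' @return List of class `logistic_fit`: coefficients, their standard errors
#'   (observed-information), ll_full, ll_null, pseudo_r2, aic, n, k,
#'   separated.
#' @export
fit_logistic <- function(predictors, outcomes) {
  X <- as.matrix(predictors)
  stopifnot(length(outcomes) == nrow(X), all(outcomes %in% c(0, 1)))
  if (length(unique(outcomes)) < 2) stop("outcomes contain a single class")
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xi, outcomes,
                                         family = stats::binomial(),
                                         control = list(epsilon = 1e-8, maxit = 200)))
  mu <- fit$fitted.values
  ll_full <- sum(outcomes * log(mu) + (1 - outcomes) * log(1 - mu))
  p0 <- mean(outcomes)
  ll_null <- sum(outcomes * log(p0) + (1 - outcomes) * log(1 - p0))
  separated <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)
  k <- ncol(Xi)
  w <- mu * (1 - mu)
  info <- crossprod(Xi * sqrt(w))
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, k))
  structure(list(coefficients = stats::setNames(fit$coefficients, colnames(Xi)),
                 se = stats::setNames(se, colnames(Xi)),
                 ll_full = ll_full, ll_null = ll_null,
                 pseudo_r2 = 1 - ll_full / ll_null,
                 aic = 2 * k - 2 * ll_full,
                 n = length(outcomes), k = k, separated = separated),
            class = "logistic_fit")
}

#' Permutation p-value for a predictor's pseudo-R2
#'
#' Shuffles the escape responses and refits; p is the fraction of shuffles
#' whose pseudo-R2 is at least the observed one (ties count toward p, and the
#' identity arrangement is included, so the smallest attainable p is
#' 1/(n_shuffles + 1)).
#'
#' @inheritParams fit_logistic
#' @param n_shuffles Number of shuffles (10,000 in the analyses emulated).
#' @param seed Optional seed for the shuffles.
#' @return List: p, observed pseudo-R2, null distribution.
#' @export
permutation_pvalue_r2 <- function(predictors, outcomes, n_shuffles = 10000,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- fit_logistic(predictors, outcomes)$pseudo_r2
  null <- vapply(seq_len(n_shuffles), function(i)
    fit_logistic(predictors, sample(outcomes))$pseudo_r2, 0)
  list(p = (sum(null >= obs) + 1) / (n_shuffles + 1),
       observed = obs, null = null)
}

#' Delta-AIC model comparison
#'
#' `dAIC_i = AIC_i - AIC_ref`, with the reference model chosen by name
#' (the single distance-from-central-axis predictor in the published
#' comparison) rather than the minimum.
#'
#' @param fits Named list of `logistic_fit` objects fit on the same escapes.
#' @param reference Name of the reference model.
#' @return Named numeric vector of delta-AIC values.
#' @export
aic_compare <- function(fits, reference = names(fits)[1]) {
  stopifnot(reference %in% names(fits))
  ns <- vapply(fits, `[[`, 0, "n")
  if (length(unique(ns)) != 1) stop("models were fit on different escapes")
  aics <- vapply(fits, `[[`, 0, "aic")
  aics - aics[[reference]]
}

#' Binned correlation of a metric with edge-vector proportion
#'
#' Chooses the widest range that starts and ends on a multiple of 2.5 cm such
#' that all seven equal-sized bins contain at least `min_per_bin` escapes,
#' then correlates bin centers with the per-bin edge-vector proportion.
#'
#' @param metric Per-escape metric (cm).
#' @param outcomes Binary outcomes.
#' @param n_bins Number of equal-sized bins.
#' @param min_per_bin Minimum escapes per bin.
#' @return List: r, bins (centers, proportions, counts), range.
#' @export
binned_correlation <- function(metric, outcomes, n_bins = 7, min_per_bin = 6) {
  grid <- seq(floor(min(metric) / 2.5) * 2.5, ceiling(max(metric) / 2.5) * 2.5,
              by = 2.5)
  best <- NULL
  for (lo in grid) for (hi in rev(grid)) {
    if (hi <= lo) next
    if (!is.null(best) && (hi - lo) <= best$width) next
    br <- seq(lo, hi, length.out = n_bins + 1)
    idx <- findInterval(metric, br, rightmost.closed = TRUE)
    inside <- idx >= 1 & idx <= n_bins & metric >= lo & metric <= hi
    counts <- tabulate(idx[inside], n_bins)
    if (all(counts >= min_per_bin)) best <- list(lo = lo, hi = hi, width = hi - lo)
  }
  if (is.null(best)) stop("no range satisfies the per-bin minimum")
  br <- seq(best$lo, best$hi, length.out = n_bins + 1)
  centers <- (br[-1] + br[-(n_bins + 1)]) / 2
  idx <- findInterval(metric, br, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= n_bins & metric >= best$lo & metric <= best$hi
  prop <- vapply(seq_len(n_bins), function(b) mean(outcomes[inside & idx == b]), 0)
  counts <- tabulate(idx[inside], n_bins)
  if (stats::sd(prop) == 0) {
    warning("edge-vector proportion constant across bins; correlation undefined")
    r <- NA_real_
  } else r <- stats::cor(centers, prop)
  list(r = r, bins = data.frame(center = centers, proportion = prop, n = counts),
       range = c(best$lo, best$hi))
}

#' Residual-normalized binned correlation
#'
#' Regresses metric y on metric x (OLS), then runs [binned_correlation()] on
#' the residuals: whether, at a given x, y still predicts edge-vector use.
#'
#' @param y_metric,x_metric Per-escape metrics.
#' @param outcomes Binary outcomes.
#' @param ... Passed to [binned_correlation()].
#' @return As [binned_correlation()], plus the OLS slope/intercept.
#' @export
normalize_metric <- function(y_metric, x_metric, outcomes, ...) {
  if (stats::sd(x_metric) == 0) stop("constant x metric")
  fit <- stats::lm.fit(cbind(1, x_metric), y_metric)
  res <- fit$residuals
  if (all(abs(res) < 1e-12)) {
    warning("residuals are all zero; correlation undefined")
    return(list(r = NA_real_, slope = fit$coefficients[2],
                intercept = fit$coefficients[1]))
  }
  out <- binned_correlation(res, outcomes, ...)
  out$slope <- fit$coefficients[2]
  out$intercept <- fit$coefficients[1]
  out
}

#' Pooled-mean-difference permutation test
#'
#' Test statistic: difference of pooled trial means between two groups (every
#' trial weighted equally, not collapsed per animal). Group labels are
#' shuffled at the animal level; when the number of distinct label
#' assignments is small, all assignments are enumerated and the p-value is
#' exact. Ties count toward p.
#'
#' @param values Per-trial values.
#' @param animal Animal id per trial.
#' @param group Group label per trial (two levels; constant within animal).
#' @param n_shuffles Monte-Carlo shuffles when enumeration is infeasible.
#' @param tail `"greater"` (group1 mean - group2 mean > 0), `"less"`, or
#'   `"two.sided"`.
#' @param seed Optional seed.
#' @return List: p, observed, null, exact (logical).
#' @export
group_permutation_test <- function(values, animal, group, n_shuffles = 10000,
                                   tail = c("greater", "less", "two.sided"),
                                   seed = NULL) {
  tail <- match.arg(tail)
  if (!is.null(seed)) set.seed(seed)
  animal <- as.character(animal)
  per_animal <- tapply(as.character(group), animal, unique)
  if (any(lengths(per_animal) != 1)) stop("group must be constant within animal")
  ids <- names(per_animal)
  g <- unlist(per_animal)
  levs <- unique(g)
  if (length(levs) != 2) stop("exactly two groups required")
  stat <- function(glab) {
    gv <- glab[match(animal, ids)]
    mean(values[gv == levs[1]]) - mean(values[gv == levs[2]])
  }
  obs <- stat(g)
  n1 <- sum(g == levs[1])
  n_assign <- choose(length(ids), n1)
  exact <- n_assign <= n_shuffles
  if (exact) {
    combs <- utils::combn(length(ids), n1)
    null <- apply(combs, 2, function(ix) {
      glab <- rep(levs[2], length(ids)); glab[ix] <- levs[1]
      stat(glab)
    })
  } else {
    null <- vapply(seq_len(n_shuffles), function(i) stat(sample(g)), 0)
  }
  side_p <- function(x) switch(tail,
    greater = mean(null >= x),
    less = mean(null <= x),
    two.sided = mean(abs(null) >= abs(x)))
  p <- side_p(obs)
  if (!exact) p <- (p * n_shuffles + 1) / (n_shuffles + 1)
  list(p = p, observed = obs, null = null, exact = exact)
}

#' Von Mises sampler (Best-Fisher)
#'
#' Draws from the Von Mises distribution with mean `mu` and concentration
#' `kappa` by the Best & Fisher (1979) wrapped-Cauchy rejection algorithm.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration.
#' @return Numeric vector of angles in (-pi, pi] + mu.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5)[ok] * acos(f[ok])
    take <- min(length(theta), m)
    if (take > 0) out[(got + 1):(got + take)] <- theta[seq_len(take)]
    got <- got + take
  }
  out + mu
}

#' Von Mises classification-bias simulation
#'
#' From every 1 cm x 1 cm bin of the threat zone, samples escape headings
#' from a Von Mises distribution centered on the direction whose escape
#' target score is `center_fraction` (60% of the way from the homing-vector
#' to the edge-vector path), scores each heading on the 10-cm transect,
#' classifies at the 0.65 threshold, and correlates per-bin edge-vector
#' probability with the bin's distance from the central axis and from the
#' obstacle.
#'
#' @param geometry An [arena_geometry()].
#' @param kappa Von Mises concentration.
#' @param center_fraction Score-space location of the mean direction.
#' @param trials_per_bin Sampled escapes per square-cm bin.
#' @param side Which obstacle edge the edge-vector path targets.
#' @param threshold Edge-vector classification threshold.
#' @param seed Optional seed.
#' @return List: edge_fraction (overall, in %), bin table (x, y, p_edge),
#'   cor_axis, cor_obstacle (Pearson, with p-values), n_bins, n_trials.
#' @export
vonmises_bias_simulation <- function(geometry = arena_geometry(), kappa = 8,
                                     center_fraction = 0.6,
                                     trials_per_bin = 100, side = "left",
                                     threshold = 0.65, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bins <- threat_zone_bins(geometry)
  n_bins <- nrow(bins)
  if (n_bins != 1652)
    warning("threat zone has ", n_bins, " one-cm bins (expected 1652)")
  edge <- if (side == "left") geometry$edge_left else geometry$edge_right
  yline <- geometry$score_line_y
  p_edge <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    p <- bins[i, ]
    th_hv <- atan2(geometry$shelter[2] - p[2], geometry$shelter[1] - p[1])
    th_ev <- atan2(edge[2] - p[2], edge[1] - p[1])
    # mean direction: the heading whose target score is center_fraction,
    # i.e. the direction to the point center_fraction of the way between the
    # homing- and edge-vector crossings of the transect
    x_hv <- p[1] + (geometry$shelter[1] - p[1]) * (yline - p[2]) / (geometry$shelter[2] - p[2])
    x_ev <- p[1] + (edge[1] - p[1]) * (yline - p[2]) / (edge[2] - p[2])
    x_mu <- x_hv + center_fraction * (x_ev - x_hv)
    mu <- atan2(yline - p[2], x_mu - p[1])
    th <- rvonmises(trials_per_bin, mu, kappa)
    dx <- cos(th); dy <- sin(th)
    down <- dy < 0
    xm <- p[1] + dx[down] * (yline - p[2]) / dy[down]
    d_hv_ev <- abs(x_hv - x_ev)
    if (d_hv_ev < 1e-6) { p_edge[i] <- NA_real_; next }  # degenerate bin:
    # homing- and edge-vector transect crossings coincide from this start
    score <- abs(abs(xm - x_hv) - abs(xm - x_ev) + d_hv_ev) / (2 * d_hv_ev)
    p_edge[i] <- sum(score > threshold) / trials_per_bin
  }
  ok <- is.finite(p_edge)
  ca <- stats::cor.test(abs(bins[ok, "x"]), p_edge[ok])
  co <- stats::cor.test(bins[ok, "y"], p_edge[ok])
  list(edge_fraction = 100 * mean(p_edge[ok]),
       bins = data.frame(x = bins[, "x"], y = bins[, "y"], p_edge = p_edge),
       cor_axis = c(r = unname(ca$estimate), p = ca$p.value),
       cor_obstacle = c(r = unname(co$estimate), p = co$p.value),
       n_bins = n_bins, n_trials = sum(ok) * trials_per_bin)
}
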