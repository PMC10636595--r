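geom <- arena_geometry()

test_that("spatial metrics: axis distance, run proximity and the path angle oracle", {
  runs <- data.frame(x = c(-10, 12), y = c(25, 30), side = c("left", "right"))
  m <- spatial_metrics(0, 30, "left", runs, geom)
  expect_equal(unname(m["dist_axis"]), 0)
  m2 <- spatial_metrics(-10, 25, "left", runs, geom)
  expect_equal(unname(m2["dist_nearest_run"]), 0)
  # no same-side run: NA (excluded from that regression only)
  m3 <- spatial_metrics(5, 30, "right",
                        data.frame(x = -1, y = 25, side = "left"), geom)
  expect_true(is.na(m3["dist_nearest_run"]))
  # law-of-cosines oracle for the EV/HV path angle
  p <- c(-8, 28)
  a <- sqrt(sum((geom$edge_left - p)^2))
  b <- sqrt(sum((geom$shelter - p)^2))
  cc <- sqrt(sum((geom$edge_left - geom$shelter)^2))
  ang <- acos((a^2 + b^2 - cc^2) / (2 * a * b)) * 180 / pi
  m4 <- spatial_metrics(p[1], p[2], "left", runs, geom)
  expect_equal(unname(m4["angle_ev_hv"]), ang, tolerance = 1e-9)
  expect_equal(unname(m4["dist_shelter"]), b)
  expect_equal(unname(m4["dist_obstacle"]), abs(p[2]))
})

test_that("logistic fit matches a grid-search maximum-likelihood oracle", {
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  yy <- c(0, 0, 1, 0, 1, 1)
  fit <- fit_logistic(x, yy)
  # brute-force likelihood maximization over a fine coefficient grid
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(yy * log(p) + (1 - yy) * log(1 - p))
  }
  grid <- expand.grid(b0 = seq(-2, 2, by = 0.01), b1 = seq(-1, 4, by = 0.01))
  lls <- mapply(ll, grid$b0, grid$b1)
  best <- grid[which.max(lls), ]
  expect_equal(unname(fit$coefficients[1]), best$b0, tolerance = 1e-2)
  expect_equal(unname(fit$coefficients[2]), best$b1, tolerance = 1e-2)
  expect_equal(fit$ll_full, max(lls), tolerance = 1e-4)
  # McFadden pseudo-R2 identity and AIC with k counting the intercept
  expect_equal(fit$pseudo_r2, 1 - fit$ll_full / fit$ll_null)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$ll_full)
  expect_false(fit$separated)
})

test_that("shuffled predictors give near-zero pseudo-R2; separation is flagged", {
  set.seed(4)
  x <- rnorm(200)
  yy <- rbinom(200, 1, 0.4)
  fit <- fit_logistic(sample(x), yy)
  expect_lt(fit$pseudo_r2, 0.05)
  sep <- fit_logistic(c(-3, -2, -1, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_true(sep$separated)
  expect_error(fit_logistic(x, rep(1, 200)), "single class")
})

test_that("permutation p-values floor at 1/(n+1) and are honest under the null", {
  yy <- rep(c(0, 1), each = 15)
  p1 <- permutation_pvalue_r2(yy + 0, yy, n_shuffles = 200, seed = 1)
  expect_equal(p1$p, 1 / 201, tolerance = 1e-12)
  # pure-noise predictor: p should be unremarkable across replicate datasets
  set.seed(9)
  ps <- replicate(25, {
    y2 <- rbinom(40, 1, 0.5)
    if (length(unique(y2)) < 2) return(NA_real_)
    permutation_pvalue_r2(rnorm(40), y2, n_shuffles = 120)$p
  })
  ps <- ps[!is.na(ps)]
  expect_gt(mean(ps > 0.05), 0.75)
  expect_gt(min(ps), 1 / 121 - 1e-12)
})

test_that("delta-AIC: identical models at zero; informative predictors help, noise hurts on average", {
  set.seed(14)
  x <- rnorm(300); strong <- x * 2 + rnorm(300, sd = 0.3)
  yy <- rbinom(300, 1, plogis(x * 2))
  f1 <- fit_logistic(x, yy)
  expect_equal(unname(aic_compare(list(a = f1, b = f1), "a")["b"]), 0)
  # adding a planted informative predictor lowers AIC
  f_base <- fit_logistic(rnorm(300), yy)
  f_info <- fit_logistic(cbind(rnorm(300), x), yy)
  expect_lt(aic_compare(list(base = f_base, info = f_info), "base")["info"], 0)
  # adding pure noise raises AIC by about 2 - E[chi2 draw] (simulation)
  deltas <- replicate(60, {
    y2 <- rbinom(120, 1, plogis(0.8 * x[1:120]))
    fa <- fit_logistic(x[1:120], y2)
    fb <- fit_logistic(cbind(x[1:120], rnorm(120)), y2)
    fb$aic - fa$aic
  })
  expect_gt(mean(deltas), 0)
  expect_lt(abs(mean(deltas) - 1), 1.2)   # E[2 - chi2_1] = 1
  expect_error(aic_compare(list(a = f1, b = fit_logistic(x[1:100], yy[1:100]))),
               "different escapes")
})

test_that("binned correlation: 2.5-cm grid range, monotone recovery, bin-count robustness", {
  set.seed(6)
  metric <- runif(400, 0, 40)
  yy <- rbinom(400, 1, plogis(-2 + 0.12 * metric))
  bc <- binned_correlation(metric, yy)
  expect_gt(bc$r, 0.5)
  expect_equal(bc$range %% 2.5, c(0, 0))
  expect_identical(nrow(bc$bins), 7L)
  expect_true(all(bc$bins$n >= 6))
  # robust to the number of bins
  for (nb in c(5, 6, 8, 9)) {
    expect_gt(binned_correlation(metric, yy, n_bins = nb)$r, 0.4)
  }
  # constant proportions: flagged as undefined
  const_m <- rep(seq(1.25, 16.25, by = 2.5), each = 10)
  const_o <- rep(rep(c(0, 1), 5), 7)
  expect_warning(r0 <- binned_correlation(const_m, const_o), "constant")
  expect_true(is.na(r0$r))
  # too few escapes for seven filled bins
  expect_error(binned_correlation(c(1, 2, 30), c(0, 1, 1)), "minimum")
})

test_that("normalize_metric: OLS residual oracle and degenerate-input flags", {
  set.seed(3)
  big_x <- runif(300, 0, 30)
  big_y <- 2 * big_x + rnorm(300, sd = 6)
  out <- normalize_metric(big_y, big_x, rbinom(300, 1, 0.5))
  # analytic OLS: slope = cov(x, y)/var(x), intercept = mean(y) - slope mean(x)
  sl <- sum((big_x - mean(big_x)) * (big_y - mean(big_y))) / sum((big_x - mean(big_x))^2)
  expect_equal(unname(out$slope), sl, tolerance = 1e-10)
  expect_equal(unname(out$intercept), mean(big_y) - sl * mean(big_x),
               tolerance = 1e-10)
  expect_error(normalize_metric(big_y[1:4], rep(1, 4), c(0, 1, 0, 1)), "constant x")
  expect_warning(normalize_metric(big_x, big_x, rbinom(300, 1, 0.5)), "zero")
  # y independent of x: residual correlation tracks the raw correlation
  set.seed(8)
  ym <- runif(300, 0, 30); xm <- runif(300, 0, 30)
  yy <- rbinom(300, 1, plogis(-2 + 0.12 * ym))
  raw <- binned_correlation(ym, yy)$r
  res <- normalize_metric(ym, xm, yy)$r
  expect_lt(abs(raw - res), 0.35)
})

test_that("group permutation test matches exhaustive enumeration on tiny groups", {
  vals <- c(1.0, 1.2, 0.8, 1.1, 2.0, 2.2, 1.9, 2.3)
  animal <- rep(c("m1", "m2", "m3", "m4"), each = 2)
  grp <- rep(c("a", "a", "b", "b"), each = 2)
  out <- group_permutation_test(vals, animal, grp, tail = "greater")
  expect_true(out$exact)
  # enumeration by hand: choose(4, 2) = 6 assignments
  combs <- combn(4, 2)
  stats <- apply(combs, 2, function(ix) {
    ga <- rep("b", 4); ga[ix] <- "a"
    gv <- ga[match(animal, c("m1", "m2", "m3", "m4"))]
    mean(vals[gv == "a"]) - mean(vals[gv == "b"])
  })
  expect_equal(sort(out$null), sort(stats))
  expect_equal(out$p, mean(stats >= out$observed))
  # identical groups: p near 0.5 for either tail
  set.seed(2)
  v2 <- rnorm(40)
  an2 <- rep(paste0("m", 1:10), each = 4)
  g2 <- rep(rep(c("a", "b"), each = 4), 5)
  pg <- group_permutation_test(v2, an2, g2, tail = "greater")$p
  expect_gt(pg, 0.15); expect_lt(pg, 0.85)
  # binary outcomes reduce to proportions of edge vectors
  vb <- c(1, 1, 0, 1, 0, 0, 1, 0)
  ob <- group_permutation_test(vb, animal, grp, tail = "greater")
  expect_equal(ob$observed, mean(vb[1:4]) - mean(vb[5:8]))
  expect_error(group_permutation_test(vals, animal, rep("a", 8)), "two groups")
})

test_that("Von Mises sampler has the right circular mean and concentration", {
  set.seed(10)
  th <- rvonmises(30000, mu = 0.7, kappa = 8)
  mu_hat <- atan2(mean(sin(th)), mean(cos(th)))
  expect_equal(mu_hat, 0.7, tolerance = 0.02)
  rbar <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  # for kappa = 8, E[cos(theta - mu)] = I1(8)/I0(8)
  expect_equal(rbar, besselI(8, 1) / besselI(8, 0), tolerance = 0.01)
  # kappa = 0 is uniform
  u <- rvonmises(20000, 0, 0)
  expect_lt(sqrt(mean(sin(u))^2 + mean(cos(u))^2), 0.02)
})

test_that("bias simulation degenerates correctly as kappa grows", {
  # center 60% of the way: every trial scores ~0.6 < 0.65, no edge vectors
  vm1 <- vonmises_bias_simulation(geom, kappa = 5e5, center_fraction = 0.6,
                                  trials_per_bin = 3, seed = 1)
  expect_lt(vm1$edge_fraction, 1)
  # center on the edge path: everything classifies as an edge vector
  vm2 <- vonmises_bias_simulation(geom, kappa = 5e5, center_fraction = 1,
                                  trials_per_bin = 3, seed = 1)
  expect_gt(vm2$edge_fraction, 99)
  expect_identical(vm1$n_bins, 1652L)
})

test_that("planted logistic structure is recovered by the binned correlation", {
  ds <- generate_escape_dataset(n_escapes = 400,
                                coefficients = c(dist_axis = 0.2),
                                intercept = -2, seed = 5)
  bc <- binned_correlation(ds$data$dist_axis, ds$data$outcome)
  expect_gt(bc$r, 0.5)
})
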