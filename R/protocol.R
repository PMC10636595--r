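# Three-phase simulation protocol: training on the condition's training map
# (random walk interleaved with practice runs), pre-test random walk from the
# shelter to the threat cell on the test map (learning on), then a test-phase
# rollout of the learned policy, three trials per seed.

.map_cpp <- function(map) {
  list(accessible = map$accessible,
       oneway = map$oneway,
       shelter = map$shelter,
       threat = map$threat,
       reward = map$reward)
}

.regions_cpp <- function(map) {
  p <- map$regions
  list(assignment = p$assignment,
       actions = p$actions,
       centroids = p$centroids,
       anchors = p$anchors,
       shelter_region = match("shelter", p$names))
}

.practice_cpp <- function(practice) {
  if (is.null(practice)) return(list())
  list(starts = as.integer(practice$starts), seqs = practice$seqs,
       prob = practice$prob)
}

#' Run the full three-phase protocol for one seed
#'
#' Training (random policy with optional practice runs, learning on),
#' then `n_trials` cycles of pre-test (random walk shelter -> threat cell on
#' the test map, learning on) and test (learned policy from the threat cell,
#' capped at `test_cap` steps).
#'
#' @param algorithm Algorithm name (see [default_hyperparameters()]).
#' @param condition Condition 1-4.
#' @param n_train Training steps; default from [default_training_steps()].
#' @param practice A [practice_run_spec()], or NULL for a pure random walk.
#' @param seed Integer seed.
#' @param n_trials Number of pre-test/test cycles (3 in the study design).
#' @param hp Hyperparameters; default per algorithm.
#' @param test_cap Maximum test-phase steps (100).
#' @param pretest_cap Safety cap on the pre-test walk; exceeding it flags the
#'   trial rather than looping silently.
#' @param record Record training transitions (for replay tests).
#' @param return_agent Return the learned tables/graph snapshot.
#' @param eval_at Training-step checkpoints at which to evaluate a frozen
#'   greedy rollout from the threat cell on the training map (used by
#'   [calibrate_training_steps()]).
#' @param learn_at_test Continue value learning during the test rollout
#'   (FALSE: the published frozen-policy reading; model-based world models
#'   always update).
#' @param episode_cap Maximum training-episode length in steps.
#' @return list(trials = list of integer cell paths, evals, pretest_steps,
#'   pretest_capped, and optionally transitions/init/agent).
#' @export
run_protocol <- function(algorithm, condition, n_train = NULL,
                         practice = practice_run_spec(), seed = 1L,
                         n_trials = 3L, hp = NULL, test_cap = 100L,
                         pretest_cap = 10000L, record = FALSE,
                         return_agent = FALSE, eval_at = integer(0),
                         learn_at_test = FALSE, episode_cap = 100L) {
  algorithm <- match.arg(algorithm, names(ALGORITHMS))
  if (is.null(hp)) hp <- default_hyperparameters(algorithm)
  if (is.null(n_train)) n_train <- default_training_steps(algorithm, !is.null(practice))
  m_tr <- build_condition_map(condition, "training")
  m_te <- build_condition_map(condition, "test")
  set.seed(seed)
  out <- cpp_simulate(.map_cpp(m_tr), .map_cpp(m_te), .regions_cpp(m_tr),
                      ALGORITHMS[[algorithm]], hp, .practice_cpp(practice),
                      as.integer(n_train), as.integer(n_trials),
                      as.integer(eval_at), record, return_agent,
                      as.integer(test_cap), as.integer(pretest_cap), learn_at_test,
                      as.integer(episode_cap))
  out$algorithm <- algorithm
  out$condition <- condition
  out$seed <- seed
  out
}

#' Classify a simulated escape route
#'
#' Four-way classification. Non-escapes do not reach the shelter within the
#' step limit. Among shelter-reaching routes, the approach segment (cells at
#' or above the obstacle row) is compared against the direct reference paths:
#' the homing vector (straight threat -> shelter line, passing the three
#' middle cells above the obstacle location) and the two edge vectors
#' (threat -> obstacle edge). Routes within one step of an edge path that
#' touch the edge cells are edge vectors; routes within one step of the homing
#' path that pass a middle cell and continue shelter-ward (S/SW/SE) are homing
#' vectors; all other successful routes deviate by two or more steps and are
#' tortuous.
#'
#' @param path Integer vector of cell ids (a test-phase rollout).
#' @param map The test-phase `gridmap`.
#' @param limit Step limit for the non-escape criterion (the rollout cap).
#' @return One of "homing_vector", "edge_vector", "tortuous", "non_escape".
#' @export
classify_escape_route <- function(path, map, limit = 100L) {
  if (length(path) == 0) return("non_escape")
  reached <- !is.na(map$shelter) && map$shelter %in% path &&
    (which(path == map$shelter)[1] - 1L) <= limit
  if (!reached) return("non_escape")
  path <- path[1:which(path == map$shelter)[1]]
  cr <- cell_colrow(path)
  obs_row <- 6L
  approach <- path[cr[, "row"] <= obs_row]
  ref_hv <- rasterize_line(map$threat, map$shelter)
  ref_hv <- ref_hv[cell_colrow(ref_hv)[, "row"] <= obs_row]
  ref_el <- rasterize_line(map$threat, map$edge_targets["left"])
  ref_er <- rasterize_line(map$threat, map$edge_targets["right"])
  dev <- function(cells, ref) {
    a <- cell_colrow(cells); b <- cell_colrow(ref)
    max(vapply(seq_len(nrow(a)), function(i)
      min(pmax(abs(b[, "col"] - a[i, "col"]), abs(b[, "row"] - a[i, "row"]))), 0))
  }
  visits_edge <- any(c(map$edge_left, map$edge_right) %in% approach)
  if (visits_edge && min(dev(approach, ref_el), dev(approach, ref_er)) <= 1)
    return("edge_vector")
  hits_mid <- which(path %in% map$middle)
  if (length(hits_mid) > 0 && dev(approach, ref_hv) <= 1) {
    k <- hits_mid[length(hits_mid)]
    if (k < length(path)) {
      d <- cell_colrow(path[k + 1]) - cell_colrow(path[k])
      if (d[1, "row"] == 1L && abs(d[1, "col"]) <= 1L) return("homing_vector")
    }
  }
  "tortuous"
}

#' Run one algorithm x condition cell of the simulation study
#'
#' Repeats the three-phase protocol across seeds, classifies every test-phase
#' route, and tabulates outcome proportions pooled across trials (and per
#' trial index).
#'
#' @param algorithm,condition As in [run_protocol()].
#' @param n_seeds Number of random seeds (100 in the study design).
#' @param base_seed Seeds used are `base_seed + 0:(n_seeds-1)`.
#' @param ... Passed to [run_protocol()] (e.g. `n_train`, `practice`).
#' @return list with `outcomes` (n_seeds x n_trials character matrix),
#'   `proportions` (pooled), `per_trial` proportions, and the configuration.
#' @export
run_condition <- function(algorithm, condition, n_seeds = 100L, base_seed = 1L,
                          n_trials = 3L, ...) {
  m_te <- build_condition_map(condition, "test")
  levs <- c("homing_vector", "edge_vector", "tortuous", "non_escape")
  outcomes <- matrix(NA_character_, n_seeds, n_trials)
  for (i in seq_len(n_seeds)) {
    res <- run_protocol(algorithm, condition, seed = base_seed + i - 1L,
                        n_trials = n_trials, ...)
    outcomes[i, ] <- vapply(res$trials, classify_escape_route, "", map = m_te)
  }
  prop <- function(x) {
    tab <- table(factor(x, levels = levs))
    as.numeric(tab) / length(x)
  }
  proportions <- stats::setNames(prop(outcomes), levs)
  per_trial <- t(apply(outcomes, 2, prop))
  colnames(per_trial) <- levs
  list(algorithm = algorithm, condition = condition, n_seeds = n_seeds,
       outcomes = outcomes, proportions = proportions, per_trial = per_trial)
}

#' Calibrate the training-step budget for an algorithm
#'
#' Finds the smallest budget on the rounding lattice (multiples of 500 up to
#' 10k steps, multiples of 5k above) at which every seed's greedy policy,
#' evaluated with learning frozen from the threat cell on the condition-1
#' training map, reaches the shelter. Implemented by checkpointing one
#' incremental training run per seed at each lattice point.
#'
#' @param algorithm Algorithm name.
#' @param practice Logical; include practice runs.
#' @param n_seeds Seeds that must all succeed.
#' @param cap Largest budget tried.
#' @param base_seed First seed.
#' @return list(steps = calibrated budget (NA if cap reached without
#'   success), lattice, n_pass = seeds passing per lattice point).
#' @export
calibrate_training_steps <- function(algorithm, practice = TRUE, n_seeds = 100L,
                                     cap = 500000L, base_seed = 1L) {
  lattice <- seq(500L, min(10000L, as.integer(cap)), by = 500L)
  if (cap > 10000L) lattice <- c(lattice, seq(15000L, as.integer(cap), by = 5000L))
  spec <- if (practice) practice_run_spec() else NULL
  pass <- matrix(FALSE, n_seeds, length(lattice))
  for (i in seq_len(n_seeds)) {
    res <- run_protocol(algorithm, 1L, n_train = max(lattice), practice = spec,
                        seed = base_seed + i - 1L, n_trials = 0L,
                        eval_at = lattice)
    pass[i, ] <- res$evals
  }
  n_pass <- colSums(pass)
  ok <- which(n_pass == n_seeds)
  list(steps = if (length(ok)) lattice[min(ok)] else NA_integer_,
       lattice = lattice, n_pass = n_pass)
}
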