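test_that("a tiny training run completes with the expected bookkeeping", {
  pairs <- make_scan_pairs(5, seed0 = 6000)
  cfg <- sarlm_config(epochs = 2, max_episode = 3, n_train = 30, seed = 77)
  m <- do.call(train_sarlm, c(list(pairs, "left", cfg, variant = "dqn"),
                              tiny_net_args))
  expect_s3_class(m, "sarlm_model")
  expect_length(m$reward_curve, 2L)
  expect_true(all(is.finite(m$reward_curve)))
  # every episode start offset comes from the margin list, per axis
  margins <- cfg$train_margins
  expect_true(all(m$start_offsets[, 1] %in% margins))
  expect_true(all(m$start_offsets[, 2] %in% margins))
  d <- sqrt(rowSums(m$start_offsets^2))
  expect_true(all(d >= sqrt(32) - 1e-9 & d <= sqrt(392) + 1e-9))
  # same dataset and seed: identical episode start offsets and weights
  m2 <- do.call(train_sarlm, c(list(pairs, "left", cfg, variant = "dqn"),
                               tiny_net_args))
  expect_identical(m$start_offsets, m2$start_offsets)
  expect_identical(m$network$weights, m2$network$weights)
})

test_that("left and right agents trained identically still diverge", {
  pairs <- make_scan_pairs(3, seed0 = 6500)
  cfg <- sarlm_config(epochs = 1, max_episode = 2, n_train = 25, seed = 5)
  ml <- do.call(train_sarlm, c(list(pairs, "left", cfg), tiny_net_args))
  mr <- do.call(train_sarlm, c(list(pairs, "right", cfg), tiny_net_args))
  expect_false(identical(ml$network$weights, mr$network$weights))
})

test_that("the validation start grid enumerates 16 offsets up to ~19.8 px", {
  g <- grid_offsets()
  expect_equal(nrow(g), 16L)
  expect_equal(nrow(unique(g)), 16L)
  norms <- sqrt(rowSums(g^2))
  expect_equal(max(norms), sqrt(14^2 + 14^2))
  expect_gte(max(norms), 19)
  expect_equal(min(norms), sqrt(32))
})

test_that("a distance-oracle agent refines every grid offset to within 1 px", {
  g <- generate_bscan(noiseless_config(seed = 8), 46, seed = 8)
  tgt <- g$ann$left
  # oracle Q: prefers the action that reduces distance; values plateau at 0
  oracle <- function(state) {
    pos <- state$position
    vapply(list(c(0, -1), c(0, 1), c(-1, 0), c(1, 0)), function(d)
      -euclid_dist(pos + d, tgt), numeric(1))
  }
  res <- evaluate_grid(oracle, list(g), side = "left")
  expect_true(all(res$final_dists <= 1))
  expect_equal(length(res$final_dists), 16L)
  expect_lt(res$aed, mean(res$initial_dists))
})

test_that("greedy test episodes stay inside the box and respect the budget", {
  g <- generate_bscan(noiseless_config(seed = 9), 40, seed = 9)
  # a drifting oscillation keeps the plateau statistic at exactly 8 in every
  # window, so the episode only ends at the step budget
  flip <- local({ i <- 0; function(state) { i <<- i + 1
    rep(i + 100 * (-1)^i, 4) } })
  res <- locate_side(g$scan, flip, start = c(64, 64))
  expect_equal(res$steps, 60L)
  expect_equal(res$terminated_by, "budget")
  reg <- active_region(c(64, 64), 128, 128, side = 80)
  expect_true(all(res$positions[, 1] >= reg$x0 & res$positions[, 1] <= reg$x1))
  expect_true(all(res$positions[, 2] >= reg$y0 & res$positions[, 2] <= reg$y1))
  # constant Q values plateau immediately: steps == 17, reason delta_q
  const <- function(state) rep(1, 4)
  res2 <- locate_side(g$scan, const, start = c(64, 64))
  expect_equal(res2$steps, 17L)
  expect_equal(res2$terminated_by, "delta_q")
})

test_that("the cascade runs per side and run_patient preserves frame order", {
  g <- generate_bscan(noiseless_config(seed = 10), 44, seed = 10)
  const <- function(state) rep(0, 4)
  res <- locate_joint(g$scan, "heuristic", const, const)
  expect_s3_class(res, "location_result")
  expect_equal(res$init_source, "heuristic")
  expect_false(res$init_fallback)
  series <- generate_patient_series(phantom_config(n_frames_per_patient = 4,
                                                   speckle_sigma = 0, seed = 3))
  out <- run_patient(series, "heuristic", const, const)
  expect_length(out, 4L)
  expect_true(all(vapply(out, inherits, logical(1), "location_result")))
  empty <- structure(list(patient_id = "e", scans = list(), d_max = 0L),
                     class = "patient_series")
  expect_identical(run_patient(empty, "heuristic", const, const), list())
})
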