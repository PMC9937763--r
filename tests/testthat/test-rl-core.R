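test_that("the reward is the clipped decrease in distance to the target", {
  expect_equal(euclid_dist(c(0, 0), c(3, 4)), 5)
  expect_equal(euclid_dist(c(1, 1), c(1, 1)), 0)
  expect_equal(euclid_dist(c(1, 1), c(2, 1)), 1)
  expect_equal(compute_reward(c(10, 10), c(10, 11), c(10, 20)), 1)   # approach
  expect_equal(compute_reward(c(0, 0), c(1, 0), c(0, 0)), -1)        # retreat
  expect_equal(compute_reward(c(3, 4), c(2, 4), c(0, 0)), 5 - sqrt(20))
})

test_that("clipping is a no-op for unit steps (randomized sweep)", {
  set.seed(99)
  n <- 1e5
  bx <- runif(n, -50, 50); by <- runif(n, -50, 50)
  a <- sample.int(4L, n, replace = TRUE)
  deltas <- rbind(c(0, -1), c(0, 1), c(-1, 0), c(1, 0))
  ax <- bx + deltas[a, 1]; ay <- by + deltas[a, 2]
  tx <- runif(n, -50, 50); ty <- runif(n, -50, 50)
  raw <- sqrt((bx - tx)^2 + (by - ty)^2) - sqrt((ax - tx)^2 + (ay - ty)^2)
  expect_true(all(abs(raw) <= 1 + 1e-12))
  idx <- sample.int(n, 2000)
  clipped <- vapply(idx, function(i)
    compute_reward(c(bx[i], by[i]), c(ax[i], ay[i]), c(tx[i], ty[i])),
    numeric(1))
  expect_equal(clipped, raw[idx])
})

test_that("observation patches are centred, edge-padded, and unit-scaled", {
  scan <- bscan(matrix(128, 64, 64))
  p <- extract_patch(scan, c(32, 32))
  expect_equal(dim(p), c(32L, 32L))
  expect_true(all(p == 128 / 255))
  # ramp image: neighbouring positions give column-shifted patches
  ramp <- bscan(matrix(rep(0:63, each = 64), 64, 64))
  p1 <- extract_patch(ramp, c(30, 32))
  p2 <- extract_patch(ramp, c(31, 32))
  expect_equal(p2[, 1:31], p1[, 2:32])
  # the agent position maps to patch index (15, 15) 0-based
  marker <- matrix(0, 64, 64); marker[33, 33] <- 255
  pm <- extract_patch(bscan(marker), c(32, 32))
  expect_equal(which(pm == 1, arr.ind = TRUE), cbind(row = 16L, col = 16L))
  # corner position: padding replicates the edge
  corner <- extract_patch(ramp, c(0, 0))
  expect_equal(dim(corner), c(32L, 32L))
  expect_equal(corner[1, 1], ramp$pixels[1, 1] / 255)
  expect_error(extract_patch(ramp, c(-1, 0)), "outside")
})

test_that("reset replicates the start patch and rejects starts outside the box", {
  g <- generate_bscan(noiseless_config(seed = 3), 40, seed = 3)
  reg <- active_region(c(60, 60), 128, 128, side = 80)
  st <- agent_reset(g$scan, reg, c(60, 60))
  expect_equal(dim(st$patches), c(32L, 32L, 4L))
  for (k in 2:4) expect_identical(st$patches[, , k], st$patches[, , 1])
  expect_equal(unname(st$position), c(60, 60))
  expect_error(agent_reset(g$scan, reg, c(5, 5)), "outside")
})

test_that("steps move one pixel, shift the patch history, and clamp at walls", {
  g <- generate_bscan(noiseless_config(seed = 3), 40, seed = 3)
  reg <- active_region(c(60, 60), 128, 128, side = 80)
  st <- agent_reset(g$scan, reg, c(60, 60))
  up <- agent_step(g$scan, reg, st, ACTIONS[["UP"]], target = c(60, 40))
  expect_equal(unname(up$state$position), c(60, 59))   # UP decreases y
  expect_equal(up$state$patches[, , 1:3], st$patches[, , 2:4])
  expect_equal(up$reward, 1)
  # at the region's left edge a LEFT action is a no-move with reward 0
  stL <- agent_reset(g$scan, reg, c(reg$x0, 60))
  left <- agent_step(g$scan, reg, stL, ACTIONS[["LEFT"]], target = c(90, 90))
  expect_equal(unname(left$state$position), c(reg$x0, 60))
  expect_equal(left$reward, 0)
  # test time: no target, no reward
  expect_null(agent_step(g$scan, reg, st, ACTIONS[["DOWN"]])$reward)
})

test_that("the agent never leaves its active region under any action sequence", {
  g <- generate_bscan(noiseless_config(seed = 23), 50, seed = 23)
  set.seed(23)
  for (center in list(c(64, 64), c(5, 5), c(120, 100))) {
    reg <- active_region(center, 128, 128, side = 80)
    st <- agent_reset(g$scan, reg, clamp <- c(
      min(max(center[1], reg$x0), reg$x1), min(max(center[2], reg$y0), reg$y1)))
    for (i in 1:200) {
      st <- agent_step(g$scan, reg, st, sample.int(4L, 1L))$state
      expect_true(st$position[["x"]] >= reg$x0 && st$position[["x"]] <= reg$x1)
      expect_true(st$position[["y"]] >= reg$y0 && st$position[["y"]] <= reg$y1)
    }
  }
})

test_that("training termination honours the distance rule and the step budget", {
  expect_true(train_terminated(c(5, 5), c(5, 5), step = 0))
  expect_true(train_terminated(c(5, 5), c(5, 6), step = 0))          # D = 1, leq
  expect_false(train_terminated(c(5, 5), c(5, 6), step = 0, rule = "strict"))
  expect_false(train_terminated(c(0, 0), c(3, 4), step = 10))
  expect_true(train_terminated(c(0, 0), c(3, 4), step = 100))        # budget
})

test_that("the Q-plateau statistic and its shift invariance behave as defined", {
  expect_equal(delta_q(rep(3.3, 16)), 0)
  expect_equal(delta_q(1:16), 8)
  expect_equal(delta_q(c(100, 1:16)), 8)     # only the last 16 count
  expect_true(is.na(delta_q(1:15)))          # not ready
  set.seed(5)
  for (i in 1:20) {
    q <- rnorm(sample(16:40, 1))
    expect_equal(delta_q(q + 17.3), delta_q(q))
  }
})

test_that("test-time termination counts plateau events and obeys the budget", {
  # constant Q values: ready at step 16 (q = 1), terminate at step 17 (q = 2)
  tt <- test_termination()
  for (i in 1:16) { u <- tt_update(tt, 1); tt <- u$tt }
  expect_false(u$terminate)
  expect_equal(tt$q, 1L)
  u <- tt_update(tt, 1)
  expect_true(u$terminate)
  expect_equal(u$tt$step, 17L)
  expect_equal(u$tt$reason, "delta_q")
  # a drifting oscillation (delta-Q = 8 in every window) never plateaus:
  # termination exactly at the budget, never earlier
  tt <- test_termination()
  fired <- c()
  for (i in 1:60) {
    u <- tt_update(tt, i + 100 * (-1)^i); tt <- u$tt
    fired <- c(fired, u$terminate)
  }
  expect_equal(which(fired), 60L)
  expect_equal(tt$step, 60L)
  expect_equal(tt$reason, "budget")
  # fewer than 16 values and step < budget: never terminates
  tt <- test_termination()
  for (i in 1:15) { u <- tt_update(tt, rnorm(1)); tt <- u$tt }
  expect_false(u$terminate)
})

test_that("the experience memory is a bounded FIFO with uniform sampling", {
  m <- replay_memory(5)
  for (i in 1:7) mem_push(m, list(s = i, a = 1L, r = 0, sp = i, terminal = FALSE))
  expect_equal(mem_size(m), 5L)
  stored <- sort(vapply(m$records, `[[`, numeric(1), "s"))
  expect_equal(stored, 3:7)                  # the two oldest were evicted
  set.seed(1)
  batch <- mem_sample(m, 3)
  expect_length(batch, 3L)
})
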