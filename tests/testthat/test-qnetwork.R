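test_that("Q networks emit one finite value per action, deterministically", {
  g <- generate_bscan(noiseless_config(seed = 2), 40, seed = 2)
  reg <- active_region(c(64, 64), 128, 128)
  st <- agent_reset(g$scan, reg, c(64, 64))
  for (v in c("dqn", "ddqn", "dueldqn", "duelddqn")) {
    net <- do.call(q_network, c(list(variant = v, seed = 42), tiny_net_args))
    qv <- q_values(net, st)
    expect_length(qv, 4L)
    expect_named(qv, c("UP", "DOWN", "LEFT", "RIGHT"))
    expect_true(all(is.finite(qv)))
    expect_identical(qv, q_values(net, st))
  }
  # wrong state shape is rejected
  small <- structure(list(position = c(x = 1, y = 1),
                          patches = array(0, c(16, 16, 4))),
                     class = "agent_state")
  net <- do.call(q_network, c(list(variant = "dqn", seed = 1), tiny_net_args))
  expect_error(q_values(net, small), "expected")
})

test_that("dueling aggregation reduces to the value head when advantages vanish", {
  net <- do.call(q_network, c(list(variant = "dueldqn", seed = 7), tiny_net_args))
  net$weights$Wa[] <- 0
  net$weights$ba[] <- 0
  g <- generate_bscan(noiseless_config(seed = 2), 40, seed = 2)
  st <- agent_reset(g$scan, active_region(c(64, 64), 128, 128), c(64, 64))
  qv <- q_values(net, st)
  expect_equal(unname(qv), rep(qv[[1]], 4))
  # mean-centred aggregation: a constant added to the advantage head cancels
  net2 <- do.call(q_network, c(list(variant = "dueldqn", seed = 8), tiny_net_args))
  qv1 <- q_values(net2, st)
  net2$weights$ba <- net2$weights$ba + 5
  expect_equal(q_values(net2, st), qv1)
})

test_that("epsilon-greedy selection is greedy, tie-broken, and uniform at 1", {
  expect_equal(select_action(c(0, 0, 0, 0), epsilon = 0), ACTIONS[["UP"]])
  expect_equal(select_action(c(0, 1, 0, 0), epsilon = 0), ACTIONS[["DOWN"]])
  set.seed(31)
  draws <- vapply(1:1e4, function(i) select_action(c(0, 1, 0, 0), epsilon = 1),
                  integer(1))
  counts <- tabulate(draws, 4L)
  sigma <- sqrt(1e4 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) <= 3 * sigma))
})

test_that("TD targets follow the single- and double-estimator rules", {
  qnt <- matrix(c(0.1, 0.5, -0.2, 0), 4, 1)
  expect_equal(td_target(1, FALSE, 0.95, "dqn", qnt), 1.475)
  expect_equal(td_target(1, TRUE, 0.95, "dqn", qnt), 1)     # terminal: R only
  # double estimator: online argmax is action 3, evaluated under the target net
  qno <- matrix(c(0, 0, 9, 0), 4, 1)
  expect_equal(td_target(1, FALSE, 0.95, "ddqn", qnt, qno), 1 + 0.95 * (-0.2))
  expect_error(td_target(1, FALSE, 0.95, "ddqn", qnt), "online")
  # batched
  tg <- td_target(c(1, -1), c(FALSE, TRUE), 0.95, "dqn", cbind(qnt, qnt))
  expect_equal(tg, c(1.475, -1))
})

test_that("the TD loss is the mean squared error with its obvious zeros", {
  expect_equal(dqn_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(dqn_loss(0, 1), 1)
  expect_equal(dqn_loss(c(0, 0), c(1, 3)), 5)
  expect_error(dqn_loss(c(1, 2), 1), "length")
})

test_that("target-network sync copies weights and is idempotent", {
  online <- do.call(q_network, c(list(variant = "dqn", seed = 3), tiny_net_args))
  target <- do.call(q_network, c(list(variant = "dqn", seed = 4), tiny_net_args))
  g <- generate_bscan(noiseless_config(seed = 2), 40, seed = 2)
  st <- agent_reset(g$scan, active_region(c(64, 64), 128, 128), c(64, 64))
  expect_false(isTRUE(all.equal(q_values(target, st), q_values(online, st))))
  target <- sync_target(target, online)
  expect_identical(q_values(target, st), q_values(online, st))
  target2 <- sync_target(target, online)
  expect_identical(target2$weights, target$weights)
  bad <- do.call(q_network, c(list(variant = "dqn", seed = 5),
                              list(conv_filters = c(4L), fc_units = 8L)))
  expect_error(sync_target(bad, online), "match")
})

test_that("analytic gradients of the network agree with finite differences", {
  set.seed(42)
  for (duel in c(FALSE, TRUE)) {
    spec <- dqloc:::nn_spec(10L, 2L, c(3L), 6L, 4L, dueling = duel)
    w <- dqloc:::nn_init_weights(spec)
    x <- array(runif(10 * 10 * 2 * 2), c(10, 10, 2, 2))
    G <- matrix(rnorm(8), 4, 2)
    loss_fn <- function(w) sum(dqloc:::nn_forward(w, spec, x) * G)
    bw <- dqloc:::nn_grad(w, spec, x, G)
    for (nm in names(w)) {
      idx <- sample(length(w[[nm]]), min(6, length(w[[nm]])))
      for (k in idx) {
        e <- 1e-5
        w1 <- w; w1[[nm]][k] <- w1[[nm]][k] + e
        w2 <- w; w2[[nm]][k] <- w2[[nm]][k] - e
        num <- (loss_fn(w1) - loss_fn(w2)) / (2 * e)
        expect_equal(as.numeric(bw$grads[[nm]][k]), num, tolerance = 1e-5)
      }
    }
  }
})
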